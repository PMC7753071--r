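# Breadth-limited expansion over all edge kinds; regulatory edges are
# traversed in both directions so a deregulated target pulls in its
# TF/miRNA regulators.
expand_seeds <- function(net, seeds, level) {
  reached <- seeds
  frontier <- seeds
  for (i in seq_len(level)) {
    if (length(frontier) == 0) break
    nxt <- setdiff(net_neighbours(net, frontier), reached)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  sort(reached)
}

new_filtered_network <- function(net, ids, seeds, level, table,
                                 driver = "expression") {
  sub <- induce_subnetwork(net, ids, class = "filtered_network")
  sub$seeds <- sort(seeds)
  sub$level <- as.integer(level)
  sub$driver <- driver
  sub$status <- tibble(id = sub$nodes$id,
                       status = node_status(table, sub$nodes$id))
  sub
}

#' Extract the context-specific filtered network
#'
#' Seeds the parent meta-interactome with every deregulated or altered
#' node from the deregulation table and keeps the seeds plus their 1st-
#' or 2nd-level interactors (breadth-limited expansion over all edge
#' kinds, regulatory edges followed in both directions). The result is
#' the induced subgraph on the retained nodes, annotated with per-node
#' omics status.
#'
#' @param net A `meta_interactome`.
#' @param table A `deregulation_table`.
#' @param level Expansion depth, 1 or 2.
#' @return A `filtered_network` (subclass of `meta_interactome` with
#'   `seeds`, `level` and a per-node `status` tibble).
#' @export
extract_filtered_network <- function(net, table, level = 1) {
  stopifnot(level %in% c(1L, 2L))
  seeds <- intersect(table$id[table$status %in% c("up", "down", "altered")],
                     net$nodes$id)
  if (length(seeds) == 0) {
    abort("no deregulated/altered nodes map to the network",
          class = "panomix_empty_seeds")
  }
  ids <- expand_seeds(net, seeds, level)
  new_filtered_network(net, ids, seeds, level, table)
}

#' Metabolite-driven enzyme network
#'
#' Maps a metabolomics identifier list onto the meta-interactome: every
#' enzyme incident to a listed metabolite becomes a seed, the seeds are
#' expanded one hop over PPI edges, and the listed metabolite nodes are
#' retained as leaves of the induced subgraph.
#'
#' @param net A `meta_interactome`.
#' @param metabolite_ids Character vector of metabolite identifiers (or a
#'   `metabolomics` `omics_profile`).
#' @return A `filtered_network` with `driver = "metabolomics"`; its seeds
#'   are the incident enzymes.
#' @export
metabolites_to_enzyme_network <- function(net, metabolite_ids) {
  if (inherits(metabolite_ids, "omics_profile")) {
    metabolite_ids <- metabolite_ids$data$id
  }
  hits <- intersect(metabolite_ids, net$nodes$id[net$nodes$kind == "metabolite"])
  if (length(hits) == 0) {
    abort("no supplied metabolite maps to the network",
          class = "panomix_empty_seeds")
  }
  em <- net$edges[net$edges$kind == "enzyme_metabolite", , drop = FALSE]
  seeds <- sort(unique(em$source[em$target %in% hits]))
  if (length(seeds) == 0) {
    abort("no enzyme is linked to the supplied metabolites",
          class = "panomix_empty_seeds")
  }
  proteins <- net_neighbours(net, seeds, kind = "ppi")
  ids <- sort(unique(c(seeds, proteins, hits)))
  out <- new_filtered_network(net, ids, seeds, 1L, deregulation_table(),
                              driver = "metabolomics")
  out$status$status[out$status$id %in% seeds] <- "altered"
  out
}
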
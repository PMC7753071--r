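#' @importFrom rlang abort warn %||%
#' @importFrom dplyr filter mutate select distinct arrange bind_rows left_join
#'   group_by summarise ungroup pull rename n
#' @importFrom tibble tibble as_tibble
NULL

EDGE_KINDS <- c("ppi", "mirna_target", "tf_target", "enzyme_metabolite")
NODE_KINDS <- c("protein", "mirna", "metabolite")

empty_edges <- function() {
  tibble(
    source = character(), target = character(),
    kind = character(), score = double(), role = character()
  )
}

# Canonical source < target ordering for undirected PPI edges.
canonicalise_ppi <- function(edges) {
  swap <- edges$source > edges$target
  s <- ifelse(swap, edges$target, edges$source)
  t <- ifelse(swap, edges$source, edges$target)
  edges$source <- s
  edges$target <- t
  edges
}

#' Read a STRING-style protein links table
#'
#' Parses a whitespace- or tab-delimited STRING protein-links file (header
#' row with `protein1`, `protein2` and per-channel integer scores in
#' 0--1000) and keeps protein--protein edges whose evidence score passes a
#' minimum threshold. The default channel is the `experimental` score with
#' a minimum of 700 (the "medium confidence of experimental evidence"
#' convention); `combined_score` can be selected explicitly instead.
#'
#' Edges are returned undirected with canonical `source < target` ordering,
#' deduplicated, and with self-interactions removed.
#'
#' @param path Path to the links file.
#' @param min_experimental Minimum score (0--1000) an edge must reach.
#' @param score_column Which score channel to filter on:
#'   `"experimental"` (default) or `"combined_score"`.
#' @return A tibble of edges with columns `source`, `target`, `kind`
#'   (`"ppi"`), `score` and `role` (`NA` for PPI edges).
#' @export
read_string_edges <- function(path, min_experimental = 700,
                              score_column = c("experimental", "combined_score")) {
  score_column <- match.arg(score_column)
  stopifnot(min_experimental >= 0, min_experimental <= 1000)
  df <- utils::read.table(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("protein1", "protein2", score_column)) {
    if (!col %in% names(df)) {
      abort(sprintf("column '%s' is missing from '%s'", col, path),
            class = "panomix_format_error")
    }
  }
  score <- suppressWarnings(as.numeric(df[[score_column]]))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    abort(sprintf("unreadable %s score at data line %d of '%s'",
                  score_column, bad, path),
          class = "panomix_format_error")
  }
  keep <- score >= min_experimental & df$protein1 != df$protein2
  edges <- tibble(
    source = df$protein1[keep], target = df$protein2[keep],
    kind = "ppi", score = score[keep], role = NA_character_
  )
  edges <- canonicalise_ppi(edges)
  edges |>
    group_by(.data$source, .data$target, .data$kind) |>
    summarise(score = max(.data$score), role = NA_character_, .groups = "drop") |>
    arrange(.data$source, .data$target)
}

#' Read a regulatory edge table (miRNA-target or TF-target)
#'
#' @param path Path to a TSV with columns `regulator` and `target`.
#' @param kind `"mirna_target"` or `"tf_target"`.
#' @return A tibble of directed edges (duplicates collapsed); an empty
#'   file yields an empty edge set with a warning.
#' @export
read_regulatory_edges <- function(path, kind = c("mirna_target", "tf_target")) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    warn(sprintf("'%s' is empty; returning no %s edges", path, kind))
    return(empty_edges())
  }
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("regulator", "target")) {
    if (!col %in% names(df)) {
      abort(sprintf("column '%s' is missing from '%s'", col, path),
            class = "panomix_format_error")
    }
  }
  tibble(source = df$regulator, target = df$target, kind = kind,
         score = NA_real_, role = NA_character_) |>
    filter(.data$source != .data$target) |>
    distinct(.data$source, .data$target, .keep_all = TRUE) |>
    arrange(.data$source, .data$target)
}

#' Read an enzyme-metabolite edge table
#'
#' @param path Path to a TSV with columns `enzyme`, `metabolite`, `role`
#'   (`substrate` or `product`).
#' @return A tibble of `enzyme_metabolite` edges; an enzyme-metabolite
#'   pair listed under both roles collapses to one edge with role
#'   `"both"`.
#' @export
read_metabolite_edges <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    return(empty_edges())
  }
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("enzyme", "metabolite", "role")) {
    if (!col %in% names(df)) {
      abort(sprintf("column '%s' is missing from '%s'", col, path),
            class = "panomix_format_error")
    }
  }
  bad <- which(!df$role %in% c("substrate", "product"))
  if (length(bad) > 0) {
    abort(sprintf("unknown role '%s' at data line %d of '%s'",
                  df$role[bad[1]], bad[1], path),
          class = "panomix_format_error")
  }
  tibble(source = df$enzyme, target = df$metabolite,
         kind = "enzyme_metabolite", score = NA_real_, role = df$role) |>
    distinct() |>
    group_by(.data$source, .data$target, .data$kind) |>
    summarise(
      score = NA_real_,
      role = if (dplyr::n_distinct(.data$role) > 1) "both" else .data$role[1],
      .groups = "drop"
    ) |>
    arrange(.data$source, .data$target)
}

#' Build the multi-layer meta-interactome
#'
#' Merges PPI, miRNA-target, TF-target and enzyme-metabolite edge sets
#' into one typed graph. Node kinds are inferred from edge roles: sources
#' of `mirna_target` edges become miRNA nodes, targets of
#' `enzyme_metabolite` edges become metabolite nodes, everything else is a
#' protein/gene node (one node per gene symbol). TF sources are flagged
#' `is_tf`, enzyme sources `is_metabolic_enzyme`. Optional annotation
#' vectors add signaling, metabolic-enzyme, crosstalk and rate-limiting
#' flags.
#'
#' @param edge_sets A single edge tibble or a list of edge tibbles as
#'   returned by the `read_*_edges()` readers.
#' @param annotations Optional named list of character vectors:
#'   `signaling`, `metabolic`, `crosstalk`, `rate_limiting`.
#' @return A `meta_interactome` object: a list with tibbles `nodes`
#'   (id, kind, flags) and `edges` (source, target, kind, score, role).
#' @export
build_meta_interactome <- function(edge_sets, annotations = NULL) {
  if (is.data.frame(edge_sets)) edge_sets <- list(edge_sets)
  edges <- bind_rows(edge_sets)
  if (nrow(edges) == 0) edges <- empty_edges()
  edges <- filter(edges, .data$source != .data$target)
  is_ppi <- edges$kind == "ppi"
  edges[is_ppi, ] <- canonicalise_ppi(edges[is_ppi, ])
  edges <- edges |>
    group_by(.data$source, .data$target, .data$kind) |>
    summarise(
      score = if (all(is.na(.data$score))) NA_real_ else max(.data$score, na.rm = TRUE),
      role = {
        r <- unique(.data$role[!is.na(.data$role)])
        if (length(r) == 0) NA_character_ else if (length(r) > 1) "both" else r
      },
      .groups = "drop"
    ) |>
    arrange(.data$kind, .data$source, .data$target)

  mirna_ids <- unique(edges$source[edges$kind == "mirna_target"])
  metab_ids <- unique(edges$target[edges$kind == "enzyme_metabolite"])
  tf_ids <- unique(edges$source[edges$kind == "tf_target"])
  enzyme_ids <- unique(edges$source[edges$kind == "enzyme_metabolite"])
  protein_ids <- setdiff(
    unique(c(edges$source[edges$kind == "ppi"], edges$target[edges$kind == "ppi"],
             edges$target[edges$kind %in% c("mirna_target", "tf_target")],
             tf_ids, enzyme_ids)),
    character(0)
  )

  clash <- list(
    "mirna/protein" = intersect(mirna_ids, protein_ids),
    "mirna/metabolite" = intersect(mirna_ids, metab_ids),
    "protein/metabolite" = intersect(protein_ids, metab_ids)
  )
  clash <- clash[lengths(clash) > 0]
  if (length(clash) > 0) {
    abort(paste0("conflicting node kinds: ",
                 paste(sprintf("%s: %s", names(clash),
                               vapply(clash, function(x) paste(x, collapse = ", "),
                                      character(1))),
                       collapse = "; ")),
          class = "panomix_kind_conflict")
  }

  ids <- c(protein_ids, mirna_ids, metab_ids)
  kinds <- c(rep("protein", length(protein_ids)),
             rep("mirna", length(mirna_ids)),
             rep("metabolite", length(metab_ids)))
  ord <- order(ids)
  nodes <- tibble(
    id = ids[ord], kind = kinds[ord],
    is_tf = ids[ord] %in% tf_ids,
    is_signaling = FALSE,
    is_metabolic_enzyme = ids[ord] %in% enzyme_ids,
    is_crosstalk = FALSE,
    is_rate_limiting = FALSE
  )
  if (!is.null(annotations)) {
    if (!is.null(annotations$signaling))
      nodes$is_signaling <- nodes$is_signaling |
        (nodes$id %in% annotations$signaling & nodes$kind == "protein")
    if (!is.null(annotations$metabolic))
      nodes$is_metabolic_enzyme <- nodes$is_metabolic_enzyme |
        (nodes$id %in% annotations$metabolic & nodes$kind == "protein")
    if (!is.null(annotations$crosstalk))
      nodes$is_crosstalk <- nodes$id %in% annotations$crosstalk & nodes$kind == "protein"
    if (!is.null(annotations$rate_limiting))
      nodes$is_rate_limiting <- nodes$id %in% annotations$rate_limiting &
        nodes$kind == "protein"
  }
  new_meta_interactome(nodes, edges)
}

new_meta_interactome <- function(nodes, edges, class = character()) {
  structure(list(nodes = nodes, edges = edges),
            class = c(class, "meta_interactome"))
}

#' @export
print.meta_interactome <- function(x, ...) {
  cat(sprintf("<%s> %d nodes, %d edges\n", class(x)[1],
              nrow(x$nodes), nrow(x$edges)))
  kt <- table(x$nodes$kind)
  cat("  nodes:", paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), "\n")
  et <- table(x$edges$kind)
  if (length(et) > 0)
    cat("  edges:", paste(sprintf("%s=%d", names(et), et), collapse = ", "), "\n")
  invisible(x)
}

# Long adjacency table: one row per (node, neighbour, kind, direction).
# PPI and enzyme_metabolite count as both directions; regulatory edges are
# out at the regulator and in at the target.
adjacency_table <- function(net) {
  e <- net$edges
  undirected <- e$kind %in% c("ppi", "enzyme_metabolite")
  bind_rows(
    tibble(node = e$source, neighbour = e$target, kind = e$kind,
           direction = ifelse(undirected, "both", "out")),
    tibble(node = e$target, neighbour = e$source, kind = e$kind,
           direction = ifelse(undirected, "both", "in"))
  )
}

#' Neighbours of a node, optionally restricted by edge kind
#'
#' Regulatory (miRNA-target, TF-target) edges are directed; by default
#' both directions are followed so that a deregulated target also pulls
#' in its regulators.
#'
#' @param net A `meta_interactome`.
#' @param ids Node identifier(s).
#' @param kind Optional subset of edge kinds.
#' @param direction `"all"`, `"out"` or `"in"` (relative to `ids`).
#' @return Character vector of unique neighbour ids.
#' @export
net_neighbours <- function(net, ids, kind = NULL,
                           direction = c("all", "out", "in")) {
  direction <- match.arg(direction)
  adj <- adjacency_table(net)
  adj <- adj[adj$node %in% ids, , drop = FALSE]
  if (!is.null(kind)) adj <- adj[adj$kind %in% kind, , drop = FALSE]
  if (direction != "all")
    adj <- adj[adj$direction %in% c("both", direction), , drop = FALSE]
  sort(unique(adj$neighbour))
}

# igraph view of (a subset of) the network. Undirected simple graph by
# default; used for topology and PPI path enumeration.
as_igraph <- function(net, kinds = NULL, directed = FALSE) {
  e <- net$edges
  if (!is.null(kinds)) e <- e[e$kind %in% kinds, , drop = FALSE]
  ids <- if (is.null(kinds)) net$nodes$id else
    sort(unique(c(e$source, e$target)))
  g <- igraph::graph_from_data_frame(
    e[, c("source", "target")], directed = directed,
    vertices = data.frame(name = ids)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Induced subgraph on a node id set, preserving node flags.
induce_subnetwork <- function(net, ids, class = character()) {
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  keep <- net$edges$source %in% ids & net$edges$target %in% ids
  new_meta_interactome(nodes, net$edges[keep, , drop = FALSE], class = class)
}

#' Export a network as JSON
#'
#' Writes a documented JSON graph dialect (`nodes[]`, `edges[]`, per-node
#' flags and optional status annotation) that round-trips through
#' [read_network_json()].
#'
#' @param net A `meta_interactome` (or `filtered_network`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  payload <- list(nodes = net$nodes, edges = net$edges)
  if (!is.null(net$status)) payload$status <- net$status
  if (!is.null(net$seeds)) payload$seeds <- net$seeds
  if (!is.null(net$level)) payload$level <- net$level
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' Import a network written by [write_network_json()]
#'
#' @param path JSON file path.
#' @return A `meta_interactome` (a `filtered_network` if the file carries
#'   seed/level metadata).
#' @export
read_network_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as_tibble(payload$nodes)
  edges <- if (length(payload$edges) == 0) empty_edges() else as_tibble(payload$edges)
  if (nrow(edges) > 0 && !"score" %in% names(edges)) edges$score <- NA_real_
  edges$score <- as.numeric(edges$score)
  edges$role <- as.character(edges$role %||% NA_character_)
  net <- new_meta_interactome(nodes, edges)
  if (!is.null(payload$seeds)) {
    net$seeds <- as.character(payload$seeds)
    net$level <- as.integer(payload$level)
    net$status <- as_tibble(payload$status)
    class(net) <- c("filtered_network", class(net))
  }
  net
}
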
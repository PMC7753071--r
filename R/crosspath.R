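CONNECTIVITY_MODES <- c("signaling_to_metabolic", "tf_to_metabolic",
                        "mirna_to_metabolic")
WEIGHT_OPTIONS <- c("deregulated_gene", "crosstalk_gene",
                    "rate_limiting_enzyme", "hub", "central_node",
                    "bottleneck")
PATH_TYPES <- c("XM", "XPM", "XPPM", "XPPPM")

match_mode <- function(mode) {
  aliases <- c(s2m = "signaling_to_metabolic", tf2m = "tf_to_metabolic",
               mirna2m = "mirna_to_metabolic")
  if (mode %in% names(aliases)) mode <- aliases[[mode]]
  match.arg(mode, CONNECTIVITY_MODES)
}

#' Node-weight configuration for path scoring
#'
#' Up to four of the six weight options may be selected: three biological
#' (deregulated gene, signaling crosstalk gene, rate-limiting enzyme) and
#' three topological (hub, central node, bottleneck). A node earns weight
#' 1 for each selected option it satisfies.
#'
#' @param options Character vector, non-empty subset of
#'   `r paste(WEIGHT_OPTIONS, collapse = ", ")`, at most 4 entries.
#' @return A `weight_config` object.
#' @export
weight_config <- function(options) {
  options <- unique(options)
  bad <- setdiff(options, WEIGHT_OPTIONS)
  if (length(bad) > 0) {
    abort(sprintf("unknown weight option(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(options) < 1 || length(options) > 4) {
    abort("select between one and four weight options",
          class = "panomix_bad_config")
  }
  structure(list(options = options), class = "weight_config")
}

#' Enumerate candidate cross-pathway paths
#'
#' Finds every simple path from an X node to a metabolic enzyme (M)
#' through at most `max_intermediates` protein-protein interactors,
#' giving the path grammar XM, XPM, XPPM, XPPPM. In
#' `signaling_to_metabolic` mode, X ranges over signaling proteins. In
#' the TF and miRNA modes, X ranges over targets of the deregulated
#' regulators (all regulators when no deregulation table is given), the
#' regulator is recorded as a path prefix, and the full node sequence
#' (regulator included) must be simple. PPI hops are undirected;
#' the regulator-to-target hop follows the regulatory edge direction.
#' Output order is deterministic (lexicographic by regulator, then node
#' sequence).
#'
#' @param net A `meta_interactome` with signaling/metabolic flags.
#' @param mode One of `r paste(CONNECTIVITY_MODES, collapse = ", ")` (or
#'   the short forms s2m, tf2m, mirna2m).
#' @param table Optional `deregulation_table` used to restrict TF/miRNA
#'   regulators to deregulated ones.
#' @param max_intermediates Maximum number of P nodes between X and M
#'   (0--3, default 3).
#' @return A `crosspath_result` tibble `(mode, regulator, nodes,
#'   path_type)` with `nodes` a list column of ordered protein ids.
#' @export
enumerate_paths <- function(net, mode, table = NULL, max_intermediates = 3) {
  mode <- match_mode(mode)
  stopifnot(max_intermediates >= 0, max_intermediates <= 3)
  g <- as_igraph(net, kinds = "ppi")
  in_g <- intersect(net$nodes$id, igraph::V(g)$name)
  m_set <- intersect(net$nodes$id[net$nodes$is_metabolic_enzyme], in_g)
  if (length(m_set) == 0) {
    abort("network has no metabolic enzyme (M) in the PPI layer",
          class = "panomix_missing_class")
  }

  if (mode == "signaling_to_metabolic") {
    x_by_reg <- list(stats::setNames(
      list(intersect(net$nodes$id[net$nodes$is_signaling], in_g)), NA_character_
    ))
    x_by_reg <- x_by_reg[[1]]
    if (length(x_by_reg[[1]]) == 0) {
      abort("network has no signaling (S) protein in the PPI layer",
            class = "panomix_missing_class")
    }
  } else {
    kind <- if (mode == "tf_to_metabolic") "tf_target" else "mirna_target"
    regs <- if (mode == "tf_to_metabolic") {
      net$nodes$id[net$nodes$is_tf]
    } else {
      net$nodes$id[net$nodes$kind == "mirna"]
    }
    if (!is.null(table)) {
      regs <- intersect(regs, table$id[table$status %in% c("up", "down")])
    }
    e <- net$edges[net$edges$kind == kind & net$edges$source %in% regs, ,
                   drop = FALSE]
    x_by_reg <- split(e$target, e$source)
    x_by_reg <- purrr::map(x_by_reg, function(x) intersect(unique(x), in_g))
    x_by_reg <- x_by_reg[lengths(x_by_reg) > 0]
    if (length(x_by_reg) == 0) {
      abort(sprintf("no %s regulator with a target in the PPI layer",
                    if (kind == "tf_target") "TF" else "miRNA"),
            class = "panomix_missing_class")
    }
  }

  rows <- list()
  for (reg in names(x_by_reg) %||% NA_character_) {
    xs <- if (mode == "signaling_to_metabolic") x_by_reg[[1]] else x_by_reg[[reg]]
    for (x in sort(xs)) {
      targets <- setdiff(m_set, x)
      if (length(targets) == 0) next
      sp <- igraph::all_simple_paths(g, from = x,
                                     to = targets,
                                     cutoff = max_intermediates + 1)
      for (p in sp) {
        seq_ids <- names(p)
        if (!utils::tail(seq_ids, 1) %in% m_set) next
        if (!is.na(reg) && reg %in% seq_ids) next
        rows[[length(rows) + 1]] <- list(regulator = reg, nodes = seq_ids)
      }
    }
  }
  if (length(rows) == 0) {
    out <- tibble(mode = character(), regulator = character(),
                  nodes = list(), path_type = character())
  } else {
    out <- tibble(
      mode = mode,
      regulator = purrr::map_chr(rows, "regulator"),
      nodes = purrr::map(rows, "nodes"),
      path_type = PATH_TYPES[lengths(purrr::map(rows, "nodes")) - 1]
    )
    key <- paste(ifelse(is.na(out$regulator), "", out$regulator),
                 purrr::map_chr(out$nodes, paste, collapse = "\r"))
    out <- out[order(key), , drop = FALSE]
    out <- distinct(out, .data$regulator,
                    sig = purrr::map_chr(.data$nodes, paste, collapse = "\r"),
                    .keep_all = TRUE) |> select(-"sig")
  }
  structure(out, class = c("crosspath_result", class(tibble())), mode = mode)
}

path_terminals <- function(paths) {
  last <- purrr::map_chr(paths$nodes, function(n) n[length(n)])
  first <- if (all(is.na(paths$regulator))) {
    purrr::map_chr(paths$nodes, 1)
  } else {
    paths$regulator
  }
  list(first = first, last = last)
}

path_interiors <- function(paths) {
  regulatory <- !is.na(paths$regulator)
  purrr::map2(paths$nodes, regulatory, function(n, reg) {
    if (reg) n[-length(n)] else n[-c(1, length(n))]
  })
}

#' Filter paths on deregulation status
#'
#' Keeps a path only when both terminals (the signaling protein or the
#' regulator, and the metabolic enzyme) are deregulated (up or down) and
#' every remaining node on the path is at least expressed in the primary
#' omics data. Paths touching nodes absent from the primary data are
#' dropped.
#'
#' @param paths A `crosspath_result` from [enumerate_paths()].
#' @param table A `deregulation_table` built from at least one primary
#'   layer.
#' @return The filtered `crosspath_result` (possibly empty).
#' @export
filter_paths <- function(paths, table) {
  if (!isTRUE(attr(table, "has_primary"))) {
    abort("path filtering requires at least one primary omics layer",
          class = "panomix_no_primary")
  }
  if (nrow(paths) == 0) return(paths)
  term <- path_terminals(paths)
  inter <- path_interiors(paths)
  keep <- node_status(table, term$first) %in% c("up", "down") &
    node_status(table, term$last) %in% c("up", "down") &
    purrr::map_lgl(inter, function(n) {
      all(node_status(table, n) %in% c("up", "down", "expressed"))
    })
  out <- paths[keep, , drop = FALSE]
  structure(out, class = class(paths), mode = attr(paths, "mode"))
}

#' Expression score of nodes
#'
#' `s(v) = 1 + |combined_score(v)|`: expressed nodes score exactly 1,
#' deregulated nodes score above 1 (at most `1 + k` for `k` primary
#' layers), so products of scores stay positive.
#'
#' @param ids Character vector of node ids present in the table.
#' @param table A `deregulation_table`.
#' @return Numeric vector of scores.
#' @export
expression_score <- function(ids, table) {
  idx <- match(ids, table$id)
  if (anyNA(idx)) {
    abort(sprintf("node(s) absent from the deregulation table: %s",
                  paste(ids[is.na(idx)], collapse = ", ")),
          class = "panomix_absent_node")
  }
  1 + abs(table$combined_score[idx])
}

# Neighbour sets used for transition normalization and entropy: PPI
# partners for proteins plus regulatory targets for regulators; only
# neighbours covered by primary omics (up/down/expressed) are eligible.
eligible_neighbours <- function(net, id, table, kind = NULL) {
  nb <- net_neighbours(net, id, kind = kind,
                       direction = if (is.null(kind)) "all" else "out")
  elig <- table$id[table$status %in% c("up", "down", "expressed")]
  intersect(nb, elig)
}

#' Local (first-neighbourhood) entropy of a node
#'
#' Shannon entropy of the normalized edge-weight distribution around a
#' node, with edge weight the product of endpoint expression scores:
#' `H(v) = -sum_u p_u log p_u`, `p_u = s(v)s(u) / sum_u' s(v)s(u')` over
#' eligible neighbours. A node with no eligible neighbour has entropy 0;
#' uniform weights over k neighbours give `log k`.
#'
#' @param ids Node id(s).
#' @param net A `meta_interactome`.
#' @param table A `deregulation_table`.
#' @return Numeric vector of entropies (natural log).
#' @export
local_entropy <- function(ids, net, table) {
  vapply(ids, function(v) {
    nb <- eligible_neighbours(net, v, table)
    if (length(nb) == 0) return(0)
    w <- expression_score(nb, table)
    p <- w / sum(w)
    -sum(p * log(p))
  }, double(1), USE.NAMES = FALSE)
}

#' Per-edge transition probabilities along paths
#'
#' For each step `u -> v` the raw weight is the product of expression
#' scores `s(u) s(v)`; the transition probability divides by the summed
#' raw weight over all eligible network neighbours of `u` of the same
#' edge kind (regulatory targets for the regulator step, PPI partners
#' otherwise), so probabilities out of each node sum to 1 over eligible
#' neighbours.
#'
#' @param paths A filtered `crosspath_result`.
#' @param table A `deregulation_table`.
#' @param net The parent `meta_interactome`.
#' @return `paths` with a list column `trans_probs` (one probability per
#'   step, regulator step included).
#' @export
transition_probabilities <- function(paths, table, net) {
  mode <- attr(paths, "mode")
  reg_kind <- switch(mode, tf_to_metabolic = "tf_target",
                     mirna_to_metabolic = "mirna_target", NULL)
  probs <- purrr::map2(paths$nodes, paths$regulator, function(nodes, reg) {
    steps <- list()
    if (!is.na(reg)) {
      steps[[1]] <- list(from = reg, to = nodes[1], kind = reg_kind)
    }
    if (length(nodes) > 1) {
      for (i in seq_len(length(nodes) - 1)) {
        steps[[length(steps) + 1]] <-
          list(from = nodes[i], to = nodes[i + 1], kind = "ppi")
      }
    }
    vapply(steps, function(st) {
      nb <- eligible_neighbours(net, st$from, table, kind = st$kind)
      if (!st$to %in% nb) {
        abort(sprintf("step %s->%s has no eligible transition", st$from, st$to),
              class = "panomix_degenerate")
      }
      s_nb <- expression_score(nb, table)
      s_to <- expression_score(st$to, table)
      s_to / sum(s_nb)
    }, double(1))
  })
  paths$trans_probs <- probs
  paths
}

#' Node weights from the selected weight options
#'
#' Counts, per node, how many of the selected predicates hold:
#' deregulated (status up/down), crosstalk gene, rate-limiting enzyme
#' (node flags), hub, central node, bottleneck (topology report flags).
#'
#' @param ids Node id(s).
#' @param config A `weight_config`.
#' @param table A `deregulation_table`.
#' @param net A `meta_interactome` (for biological flags).
#' @param report A `topology_report`; required when a topological option
#'   is selected.
#' @return Integer vector of weights in `[0, length(config$options)]`.
#' @export
node_weight <- function(ids, config, table, net, report = NULL) {
  stopifnot(inherits(config, "weight_config"))
  opts <- config$options
  needs_report <- intersect(opts, c("hub", "central_node", "bottleneck"))
  if (length(needs_report) > 0 && is.null(report)) {
    abort("topological weight options need a topology report",
          class = "panomix_bad_config")
  }
  nd <- net$nodes[match(ids, net$nodes$id), , drop = FALSE]
  ri <- if (!is.null(report)) match(ids, report$id) else rep(NA_integer_, length(ids))
  flag <- function(col) {
    v <- report[[col]][ri]
    v[is.na(v)] <- FALSE
    v
  }
  w <- rep(0L, length(ids))
  if ("deregulated_gene" %in% opts)
    w <- w + (node_status(table, ids) %in% c("up", "down"))
  if ("crosstalk_gene" %in% opts)
    w <- w + dplyr::coalesce(nd$is_crosstalk, FALSE)
  if ("rate_limiting_enzyme" %in% opts)
    w <- w + dplyr::coalesce(nd$is_rate_limiting, FALSE)
  if ("hub" %in% opts) w <- w + flag("is_hub")
  if ("central_node" %in% opts) w <- w + flag("is_central")
  if ("bottleneck" %in% opts) w <- w + flag("is_bottleneck")
  as.integer(w)
}

#' HMM-style log-likelihood path scores
#'
#' The score of a path is the sum of log transition probabilities over
#' its steps plus the sum of log emissions over its nodes (regulator
#' included). The emission of node `v` is
#' `(1 + w(v) + H(v)/H_max) / (2 + k)` where `w(v)` is the node weight,
#' `k` the number of selected weight options, and the local-entropy term
#' (scaled by the network-wide maximum entropy) is included only when
#' `include_entropy = TRUE`. Higher scores mean more probable, more
#' heavily weighted routes; the score is finite for every filtered path.
#'
#' @param paths A filtered `crosspath_result` (transition probabilities
#'   are computed if missing).
#' @param config A `weight_config`.
#' @param table A `deregulation_table`.
#' @param net The parent `meta_interactome`.
#' @param report Optional `topology_report` for topological weights.
#' @param include_entropy Include the local-entropy emission term.
#' @return `paths` with columns `node_weights` (list), `trans_probs`
#'   (list) and `score`.
#' @export
path_score <- function(paths, config, table, net, report = NULL,
                       include_entropy = FALSE) {
  if (nrow(paths) == 0) {
    paths$node_weights <- list(); paths$trans_probs <- list()
    paths$score <- double()
    return(paths)
  }
  if (!"trans_probs" %in% names(paths)) {
    paths <- transition_probabilities(paths, table, net)
  }
  k <- length(config$options)
  h_max <- 0
  if (include_entropy) {
    elig <- table$id[table$status %in% c("up", "down", "expressed")]
    elig <- intersect(elig, net$nodes$id)
    h_all <- local_entropy(elig, net, table)
    h_max <- max(h_all, 0)
  }
  full_nodes <- purrr::map2(paths$nodes, paths$regulator, function(n, r) {
    if (is.na(r)) n else c(r, n)
  })
  paths$node_weights <- purrr::map(full_nodes, node_weight, config = config,
                                   table = table, net = net, report = report)
  emissions <- purrr::map2(full_nodes, paths$node_weights, function(n, w) {
    h_term <- if (include_entropy && h_max > 0) {
      local_entropy(n, net, table) / h_max
    } else 0
    (1 + w + h_term) / (2 + k)
  })
  paths$score <- purrr::map2_dbl(paths$trans_probs, emissions, function(p, e) {
    if (any(p <= 0)) {
      abort("zero transition probability on a filtered path",
            class = "panomix_degenerate")
    }
    sum(log(p)) + sum(log(e))
  })
  paths
}

#' Select important paths by path-score z-score
#'
#' Converts path scores to z-scores over all filtered paths of the run
#' and flags paths with `z >= 1` (inclusive) as important. Output is
#' sorted by descending z, ties broken lexicographically.
#'
#' @param paths A scored `crosspath_result` (>= 2 paths with distinct
#'   scores).
#' @return `paths` with columns `z` and `important`.
#' @export
select_important <- function(paths) {
  if (nrow(paths) < 2) {
    abort("need at least two scored paths to standardize",
          class = "panomix_degenerate")
  }
  z <- to_zscores(paths$score)
  paths$z <- z
  paths$important <- z >= 1
  key <- paste(ifelse(is.na(paths$regulator), "", paths$regulator),
               purrr::map_chr(paths$nodes, paste, collapse = "\r"))
  paths[order(-paths$z, key), , drop = FALSE]
}

#' Enumerate, filter and score cross-pathway paths in one call
#'
#' @inheritParams enumerate_paths
#' @inheritParams path_score
#' @return A scored `crosspath_result` with importance flags.
#' @export
score_paths <- function(net, mode, table, config, report = NULL,
                        max_intermediates = 3, include_entropy = FALSE) {
  paths <- enumerate_paths(net, mode, table, max_intermediates)
  paths <- filter_paths(paths, table)
  if (nrow(paths) == 0) {
    warn("no path survived the deregulation filter")
    paths$node_weights <- list(); paths$trans_probs <- list()
    paths$score <- double(); paths$z <- double(); paths$important <- logical()
    return(paths)
  }
  paths <- path_score(paths, config, table, net, report, include_entropy)
  select_important(paths)
}

#' Path signatures for overlap counting
#'
#' @param paths A `crosspath_result`.
#' @return Character vector `regulator|node->node->...`.
#' @export
path_signatures <- function(paths) {
  paste0(ifelse(is.na(paths$regulator), "", paths$regulator), "|",
         purrr::map_chr(paths$nodes, paste, collapse = "->"))
}

#' Venn overlap of path sets across datasets
#'
#' @param runs Named list of 2--3 `crosspath_result`s from the same
#'   connectivity mode.
#' @return Venn region counts as in [overlap_report()].
#' @export
path_overlap <- function(runs) {
  modes <- unique(purrr::map_chr(runs, function(r) attr(r, "mode") %||%
                                   unique(r$mode)))
  if (length(modes) > 1) {
    abort("all runs must use the same connectivity mode",
          class = "panomix_mode_mismatch")
  }
  overlap_report(purrr::map(runs, path_signatures))
}

#' Metabolites attached to metabolic enzymes
#'
#' @param net A `meta_interactome`.
#' @param ids Enzyme node ids.
#' @return Tibble `(id, metabolites)` with a comma-joined metabolite list
#'   per enzyme.
#' @export
enzyme_metabolites <- function(net, ids) {
  em <- net$edges[net$edges$kind == "enzyme_metabolite", , drop = FALSE]
  tibble(id = ids) |>
    mutate(metabolites = purrr::map_chr(.data$id, function(e) {
      paste(sort(unique(em$target[em$source == e])), collapse = ",")
    }))
}
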
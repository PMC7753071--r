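#' Candidate nodes for topological ranking
#'
#' Topologically important nodes are selected among omics-covered nodes
#' only. For expression-driven runs (primary layers present) candidates
#' are network nodes with status up, down or expressed; for
#' alteration-only runs, the altered nodes; for metabolite-driven
#' networks, the seeded enzymes. Metabolite nodes are never candidates.
#'
#' @param network A `filtered_network`.
#' @param table Optional `deregulation_table`; defaults to the network's
#'   own status annotation.
#' @return Character vector of candidate node ids.
#' @export
candidate_nodes <- function(network, table = NULL) {
  stopifnot(inherits(network, "filtered_network"))
  driver <- network$driver %||% "expression"
  if (driver == "metabolomics") {
    ids <- network$seeds
  } else {
    status <- if (!is.null(table)) node_status(table, network$nodes$id) else
      network$status$status[match(network$nodes$id, network$status$id)]
    has_primary <- if (!is.null(table)) isTRUE(attr(table, "has_primary")) else
      any(status %in% c("up", "down", "expressed"))
    wanted <- if (has_primary) c("up", "down", "expressed") else "altered"
    ids <- network$nodes$id[status %in% wanted &
                              network$nodes$kind != "metabolite"]
  }
  ids <- sort(intersect(ids, network$nodes$id))
  if (length(ids) == 0) {
    abort("no candidate nodes: no omics-covered node is in the network",
          class = "panomix_empty_candidates")
  }
  ids
}

#' Per-node topology indices on the undirected projection
#'
#' Degree, betweenness, closeness and local clustering coefficient,
#' computed on the simple undirected projection of all edge kinds.
#' Betweenness is normalized by `(N-1)(N-2)/2`; closeness is the
#' component-scaled harmonic form `(r/sum_d) * (r/(N-1))` with `r` the
#' number of reachable nodes (excluding self). Isolated nodes get
#' closeness 0; nodes with fewer than two neighbours get clustering 0.
#'
#' @param network A `meta_interactome` or `filtered_network`.
#' @return Tibble `(id, degree, betweenness, closeness, clustering)`.
#' @export
compute_centralities <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n < 2) abort("centralities need at least two nodes")
  ids <- igraph::V(g)$name
  degree <- igraph::degree(g)
  btw_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  denom <- (n - 1) * (n - 2) / 2
  betweenness <- if (denom > 0) btw_raw / denom else rep(0, n)
  dmat <- igraph::distances(g)
  closeness <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    finite <- is.finite(d)
    r <- sum(finite)
    if (r == 0) return(0)
    (r / sum(d[finite])) * (r / (n - 1))
  }, double(1))
  clustering <- igraph::transitivity(g, type = "local", isolates = "zero")
  tibble(id = ids, degree = unname(as.numeric(degree)),
         betweenness = unname(betweenness), closeness = unname(closeness),
         clustering = unname(as.numeric(clustering))) |>
    arrange(.data$id)
}

#' Normalize an index by its maximum
#'
#' Divides each value by the distribution's maximum so the top node maps
#' to 1.
#'
#' @param values Non-negative numeric vector with a positive maximum.
#' @return Values scaled into \[0, 1\].
#' @export
normalize_index <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) {
    abort("index maximum is not positive; normalization is undefined",
          class = "panomix_degenerate")
  }
  values / m
}

# Zero-tolerant variant for combined-score components: an all-zero index
# (e.g. betweenness on a clique) contributes zeros instead of erroring.
normalize_index0 <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) return(rep(0, length(values)))
  values / m
}

#' Convert values to z-scores
#'
#' Centers and scales with the sample standard deviation (ddof = 1).
#' Because z-scores are affine-invariant, the z of max-normalized values
#' equals the z of the raw values.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return z-scores with mean 0 and sample SD 1.
#' @export
to_zscores <- function(values) {
  if (length(values) < 2) {
    abort("z-scores need at least two values", class = "panomix_degenerate")
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    abort("degenerate distribution; threshold selection impossible",
          class = "panomix_degenerate")
  }
  (values - mean(values)) / s
}

#' Density histogram of a z-score distribution
#'
#' Tabulates the probability distribution function of z-scores as a
#' density-normalized histogram (total area 1), the table users inspect
#' to choose selection thresholds.
#'
#' @param z Numeric vector of z-scores.
#' @param bins Number of equal-width bins (>= 1).
#' @return Tibble `(mid, density, width, count)`.
#' @export
pdf_plot_data <- function(z, bins = 20) {
  stopifnot(length(z) >= 1)
  if (bins < 1) abort("bins must be >= 1")
  lo <- min(z); hi <- max(z)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = bins + 1)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE, right = TRUE,
                      include.lowest = TRUE)
  tibble(mid = h$mids, density = h$density,
         width = diff(breaks), count = h$counts)
}

#' Cumulative centrality scores
#'
#' The per-node combined score is the sum of the max-normalized
#' betweenness, closeness and clustering coefficients; the cumulative
#' centrality score (CCS) adds to a node's own combined score the
#' combined scores of its first-layer interactors, crediting nodes whose
#' neighbourhood is itself central.
#'
#' @param network A `meta_interactome` or `filtered_network`.
#' @param centralities Output of [compute_centralities()]; computed if
#'   missing.
#' @return Tibble `(id, combined, ccs)`.
#' @export
compute_ccs <- function(network, centralities = NULL) {
  if (is.null(centralities)) centralities <- compute_centralities(network)
  cent <- centralities |>
    mutate(combined = normalize_index0(.data$betweenness) +
             normalize_index0(.data$closeness) +
             normalize_index0(.data$clustering))
  g <- as_igraph(network)
  comb <- stats::setNames(cent$combined, cent$id)
  ccs <- vapply(cent$id, function(v) {
    nb <- names(igraph::neighbors(g, v))
    comb[[v]] + sum(comb[nb])
  }, double(1))
  tibble(id = cent$id, combined = cent$combined, ccs = unname(ccs))
}

#' Full per-node topology report with TIN and IIN flags
#'
#' Computes topology indices on the filtered network, restricts to the
#' candidate set, max-normalizes and z-scores degree, CCS and
#' betweenness, and flags hubs (`z_degree > z_hub`), central nodes
#' (`z_ccs > z_cn`), bottlenecks (`z_betweenness > z_bn`), TINs (any
#' flag) and IINs (at least two flags). Threshold comparisons are strict.
#'
#' @param network A `filtered_network`.
#' @param table Optional `deregulation_table` for candidate selection.
#' @param z_hub,z_cn,z_bn z-score thresholds (default 1).
#' @return A `topology_report` tibble, one row per candidate node.
#' @export
topology_report <- function(network, table = NULL,
                            z_hub = 1, z_cn = 1, z_bn = 1) {
  cands <- candidate_nodes(network, table)
  cent <- compute_centralities(network)
  ccs <- compute_ccs(network, cent)
  rep <- left_join(cent, ccs, by = "id") |>
    filter(.data$id %in% cands)
  rep <- rep |>
    mutate(
      z_degree = to_zscores(normalize_index(.data$degree)),
      z_ccs = to_zscores(normalize_index(.data$ccs)),
      z_betweenness = to_zscores(normalize_index0(.data$betweenness)),
      is_hub = .data$z_degree > z_hub,
      is_central = .data$z_ccs > z_cn,
      is_bottleneck = .data$z_betweenness > z_bn,
      n_tin = .data$is_hub + .data$is_central + .data$is_bottleneck,
      is_tin = .data$n_tin >= 1,
      is_iin = .data$n_tin >= 2
    )
  structure(rep, class = c("topology_report", class(tibble())),
            thresholds = c(z_hub = z_hub, z_cn = z_cn, z_bn = z_bn))
}

#' Select hub nodes by z-scored degree
#'
#' @param report A `topology_report`.
#' @param z_threshold Strict lower bound on `z_degree`.
#' @return Character vector of hub ids (possibly empty).
#' @export
select_hubs <- function(report, z_threshold = 1) {
  sort(report$id[report$z_degree > z_threshold])
}

#' Select central nodes by z-scored cumulative centrality score
#'
#' @inheritParams select_hubs
#' @export
select_central_nodes <- function(report, z_threshold = 1) {
  sort(report$id[report$z_ccs > z_threshold])
}

#' Select bottleneck nodes by z-scored betweenness
#'
#' @inheritParams select_hubs
#' @export
select_bottlenecks <- function(report, z_threshold = 1) {
  sort(report$id[report$z_betweenness > z_threshold])
}

#' Important interacting nodes (IINs)
#'
#' Nodes satisfying at least two of the three TIN categories (hub,
#' central node, bottleneck).
#'
#' @param report A `topology_report`.
#' @return Character vector of IIN ids.
#' @export
identify_iins <- function(report) {
  sort(report$id[report$n_tin >= 2])
}

#' Subnetwork around the topologically important nodes
#'
#' @param network A `filtered_network`.
#' @param tins Character vector of TIN ids (seeds).
#' @param level Expansion depth, 1 or 2.
#' @return A `filtered_network` seeded at the TINs.
#' @export
tin_subnetwork <- function(network, tins, level = 1) {
  stopifnot(level %in% c(1L, 2L))
  seeds <- intersect(tins, network$nodes$id)
  if (length(seeds) == 0) {
    abort("no TIN maps to the network", class = "panomix_empty_seeds")
  }
  ids <- expand_seeds(network, seeds, level)
  pseudo <- new_deregulation_table(
    tibble(id = network$status$id, combined_score = 0,
           status = network$status$status),
    has_primary = TRUE
  )
  out <- new_filtered_network(network, ids, seeds, level, pseudo,
                              driver = network$driver %||% "expression")
  out$status <- network$status[network$status$id %in% ids, , drop = FALSE]
  out
}

#' Venn region counts for 2--3 sets
#'
#' Partitions the union of the supplied sets into exclusive Venn regions
#' and counts each region, the statistic behind cross-dataset overlap
#' diagrams.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble `(region, count)`; region labels join member set names
#'   with `&`. Counts sum to the size of the union.
#' @export
overlap_report <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) {
    abort("overlap_report accepts 2 or 3 sets", class = "panomix_bad_arity")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1, function(p) {
    sum(apply(membership, 1, function(m) all(m == p)))
  })
  region <- apply(patterns, 1, function(p) {
    paste(names(sets)[as.logical(p)], collapse = "&")
  })
  tibble(region = region, count = as.integer(counts)) |>
    arrange(.data$region)
}
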
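# In-code fixture builders shared across the suite.

ppi_edges <- function(...) {
  pairs <- list(...)
  tibble::tibble(
    source = vapply(pairs, `[[`, character(1), 1),
    target = vapply(pairs, `[[`, character(1), 2),
    kind = "ppi", score = 900, role = NA_character_
  )
}

# Meta-interactome from a plain PPI edge list (+ optional flags).
mk_ppi_net <- function(edges, signaling = NULL, metabolic = NULL,
                       crosstalk = NULL, rate_limiting = NULL) {
  build_meta_interactome(edges, annotations = list(
    signaling = signaling, metabolic = metabolic,
    crosstalk = crosstalk, rate_limiting = rate_limiting
  ))
}

# Meta-interactome from an adjacency matrix with vertex names V1..Vn.
net_from_adjacency <- function(A, ids = sprintf("V%02d", seq_len(nrow(A))),
                               ...) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = ids[idx[, 1]], target = ids[idx[, 2]],
    kind = "ppi", score = 900, role = NA_character_
  )
  mk_ppi_net(edges, ...)
}

# Deregulation table straight from status/score vectors.
mk_table <- function(ids, status, combined = NULL, has_primary = TRUE) {
  if (is.null(combined)) {
    combined <- ifelse(status == "up", 0.5, ifelse(status == "down", -0.5, 0))
  }
  panomix:::new_deregulation_table(
    tibble::tibble(id = ids, combined_score = combined, status = status),
    has_primary = has_primary
  )
}

# Quantitative profile from parallel vectors.
mk_profile <- function(ids, logfc, p, layer = "mrna", ...) {
  omics_profile(tibble::tibble(id = ids, logFC = logfc, p = p), layer, ...)
}

path_net <- function(ids) {
  e <- ppi_edges()
  for (i in seq_len(length(ids) - 1)) {
    e <- dplyr::bind_rows(e, ppi_edges(c(ids[i], ids[i + 1])))
  }
  mk_ppi_net(e)
}

small_study <- function(seed = 1) {
  simulate_study(synth_config(seed = seed))
}
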
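#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a meta-interactome into its node table
#'
#' @param x A `meta_interactome`.
#' @param ... Unused.
#' @return The node tibble (id, kind, flags).
#' @method tidy meta_interactome
#' @export
tidy.meta_interactome <- function(x, ...) x$nodes

#' One-row summary of a meta-interactome
#'
#' @param x A `meta_interactome`.
#' @param ... Unused.
#' @return Tibble of node/edge counts per kind.
#' @method glance meta_interactome
#' @export
glance.meta_interactome <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_proteins = sum(x$nodes$kind == "protein"),
    n_mirnas = sum(x$nodes$kind == "mirna"),
    n_metabolites = sum(x$nodes$kind == "metabolite"),
    n_edges = nrow(x$edges),
    n_ppi = sum(x$edges$kind == "ppi"),
    n_mirna_target = sum(x$edges$kind == "mirna_target"),
    n_tf_target = sum(x$edges$kind == "tf_target"),
    n_enzyme_metabolite = sum(x$edges$kind == "enzyme_metabolite")
  )
}

#' One-row summary of a topology report
#'
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return Tibble with candidate and TIN/IIN counts.
#' @method glance topology_report
#' @export
glance.topology_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_hubs = sum(x$is_hub), n_central = sum(x$is_central),
    n_bottlenecks = sum(x$is_bottleneck),
    n_tins = sum(x$is_tin), n_iins = sum(x$is_iin)
  )
}

#' One-row summary of an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return Tibble with pathway counts and the cancer fraction of the
#'   selected pathways.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_tested = nrow(x), n_selected = sum(x$selected),
    min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_,
    cancer_fraction = if (sum(x$selected) > 0)
      mean(x$class[x$selected] == "cancer") else NA_real_
  )
}

#' One-row summary of a cross-pathway run
#'
#' @param x A `crosspath_result`.
#' @param ... Unused.
#' @return Tibble with path counts by type and importance.
#' @method glance crosspath_result
#' @export
glance.crosspath_result <- function(x, ...) {
  tibble(
    mode = attr(x, "mode") %||% NA_character_,
    n_paths = nrow(x),
    n_xm = sum(x$path_type == "XM"), n_xpm = sum(x$path_type == "XPM"),
    n_xppm = sum(x$path_type == "XPPM"),
    n_xpppm = sum(x$path_type == "XPPPM"),
    n_important = if ("important" %in% names(x)) sum(x$important) else
      NA_integer_
  )
}
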
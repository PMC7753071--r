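PRIMARY_LAYERS <- c("mrna", "mirna", "proteomics")
ALTERATION_LAYERS <- c("phospho", "genomics", "epigenomics")
OMICS_LAYERS <- c(PRIMARY_LAYERS, ALTERATION_LAYERS, "metabolomics")

#' Construct an omics profile from a data frame
#'
#' Quantitative layers (`mrna`, `mirna`, `proteomics`) require columns
#' `id`, `logFC` and `p` plus per-layer thresholds; alteration layers
#' (`phospho`, `genomics`, `epigenomics`) and `metabolomics` carry an
#' identifier column only. Duplicate identifiers in quantitative layers
#' keep the record with the smallest p-value.
#'
#' @param data A data frame: `(id, logFC, p)` for quantitative layers or
#'   `(id)` for alteration/metabolite layers.
#' @param layer Layer name, one of `r paste(OMICS_LAYERS, collapse = ", ")`.
#' @param logfc_up,logfc_down logFC thresholds (up > 0 > down) used by the
#'   deregulation call; comparisons are inclusive.
#' @param p_max Adjusted p-value threshold in (0, 1].
#' @return An `omics_profile` object.
#' @export
omics_profile <- function(data, layer, logfc_up = 1, logfc_down = -1,
                          p_max = 0.05) {
  layer <- match.arg(layer, OMICS_LAYERS)
  data <- as_tibble(data)
  if (!"id" %in% names(data)) {
    abort("omics data needs an 'id' column", class = "panomix_format_error")
  }
  quantitative <- layer %in% PRIMARY_LAYERS
  if (quantitative) {
    stopifnot(logfc_up > 0, logfc_down < 0, p_max > 0, p_max <= 1)
    for (col in c("logFC", "p")) {
      if (!col %in% names(data)) {
        abort(sprintf("quantitative layer '%s' needs a '%s' column", layer, col),
              class = "panomix_format_error")
      }
    }
    data$logFC <- suppressWarnings(as.numeric(data$logFC))
    data$p <- suppressWarnings(as.numeric(data$p))
    ok <- !is.na(data$id) & nzchar(data$id) & is.finite(data$logFC) &
      is.finite(data$p) & data$p >= 0 & data$p <= 1
    n_bad <- sum(!ok)
    if (all(!ok) && nrow(data) > 0) {
      abort(sprintf("no valid rows in %s data", layer),
            class = "panomix_format_error")
    }
    if (n_bad > 0) {
      warn(sprintf("%d invalid %s row(s) skipped", n_bad, layer))
    }
    data <- data[ok, c("id", "logFC", "p")]
    dup <- anyDuplicated(data$id) > 0
    if (dup) {
      data <- data |>
        arrange(.data$id, .data$p) |>
        distinct(.data$id, .keep_all = TRUE)
      warn(sprintf("duplicate ids in %s data: kept the smallest-p record", layer))
    }
    data <- arrange(data, .data$id)
  } else {
    ok <- !is.na(data$id) & nzchar(data$id)
    data <- tibble(id = sort(unique(data$id[ok])))
  }
  structure(
    list(layer = layer, data = data,
         thresholds = if (quantitative)
           list(logfc_up = logfc_up, logfc_down = logfc_down, p_max = p_max)
         else NULL),
    class = "omics_profile"
  )
}

#' @export
print.omics_profile <- function(x, ...) {
  cat(sprintf("<omics_profile> layer=%s, %d record(s)\n", x$layer, nrow(x$data)))
  invisible(x)
}

#' Read a processed omics table from a TSV file
#'
#' @inheritParams omics_profile
#' @param path Path to a TSV with header `id<TAB>logFC<TAB>p` (quantitative
#'   layers) or a single `id` column.
#' @return An `omics_profile`.
#' @export
read_omics_table <- function(path, layer, logfc_up = 1, logfc_down = -1,
                             p_max = 0.05) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  omics_profile(df, layer, logfc_up = logfc_up, logfc_down = logfc_down,
                p_max = p_max)
}

#' Normalize log fold changes to the [-1, +1] scale
#'
#' Divides every logFC in the profile by the profile's maximum absolute
#' logFC, so the largest-magnitude record maps to +1 or -1 and signs are
#' preserved. Normalization is per uploaded dataset: only the records in
#' this profile define the maximum.
#'
#' @param profile A quantitative `omics_profile`.
#' @return The profile's data tibble with an added `logfc_norm` column.
#' @export
normalize_logfc <- function(profile) {
  stopifnot(inherits(profile, "omics_profile"))
  if (!profile$layer %in% PRIMARY_LAYERS) {
    abort("logFC normalization applies to quantitative primary layers only")
  }
  m <- max(abs(profile$data$logFC))
  if (!is.finite(m) || m == 0) {
    abort("all logFC values are zero; normalization is undefined",
          class = "panomix_degenerate")
  }
  mutate(profile$data, logfc_norm = .data$logFC / m)
}

#' Call per-layer up/down/expressed status
#'
#' A record is `up` when `logFC >= logfc_up` and `p <= p_max`, `down` when
#' `logFC <= logfc_down` and `p <= p_max`, and `expressed` otherwise
#' (present in the layer but not passing both thresholds). All comparisons
#' are inclusive.
#'
#' @param profile A quantitative `omics_profile`.
#' @return A tibble `(id, call)` with `call` in up/down/expressed.
#' @export
call_layer_deregulation <- function(profile) {
  stopifnot(inherits(profile, "omics_profile"))
  if (!profile$layer %in% PRIMARY_LAYERS) {
    abort("deregulation calls apply to quantitative primary layers only")
  }
  th <- profile$thresholds
  d <- profile$data
  call <- ifelse(d$logFC >= th$logfc_up & d$p <= th$p_max, "up",
          ifelse(d$logFC <= th$logfc_down & d$p <= th$p_max, "down",
                 "expressed"))
  tibble(id = d$id, call = call)
}

#' Combine primary omics layers into a deregulation table
#'
#' Per node, the combined score is the sum over primary layers of the
#' normalized logFC, restricted to records that pass the layer's own
#' up/down call. A node with non-zero combined score is deregulated (`up`
#' if positive, `down` if negative); a node present in a primary layer but
#' with zero combined score is `expressed`. Nodes absent from every
#' primary layer do not appear in the table and are excluded from all
#' downstream analysis regardless of secondary (alteration) layers.
#' Exact cancellation across layers is tested with tolerance 1e-12.
#'
#' @param profiles A single primary `omics_profile` or a list of them.
#' @return A `deregulation_table`: tibble `(id, combined_score, status)`.
#' @export
combine_primary <- function(profiles) {
  if (inherits(profiles, "omics_profile")) profiles <- list(profiles)
  profiles <- Filter(function(p) p$layer %in% PRIMARY_LAYERS, profiles)
  if (length(profiles) == 0) {
    abort("at least one primary omics layer (mrna, mirna, proteomics) is required",
          class = "panomix_no_primary")
  }
  per_layer <- purrr::map(profiles, function(p) {
    norm <- normalize_logfc(p)
    calls <- call_layer_deregulation(p)
    left_join(norm, calls, by = "id") |>
      mutate(contribution = ifelse(.data$call %in% c("up", "down"),
                                   .data$logfc_norm, 0)) |>
      select("id", "contribution")
  })
  combined <- bind_rows(per_layer) |>
    group_by(.data$id) |>
    summarise(combined_score = sum(.data$contribution), .groups = "drop") |>
    mutate(status = ifelse(abs(.data$combined_score) <= 1e-12, "expressed",
                    ifelse(.data$combined_score > 0, "up", "down"))) |>
    mutate(combined_score = ifelse(.data$status == "expressed", 0,
                                   .data$combined_score)) |>
    arrange(.data$id)
  new_deregulation_table(combined, has_primary = TRUE)
}

new_deregulation_table <- function(data, has_primary) {
  for (col in c("is_mutated", "is_methylated", "is_phosphorylated")) {
    if (!col %in% names(data)) data[[col]] <- FALSE
  }
  structure(data, class = c("deregulation_table", class(tibble())),
            has_primary = has_primary)
}

#' An empty deregulation table for alteration-only runs
#'
#' Used when no primary (quantitative) omics layer is supplied, e.g. a
#' genomics-only analysis; [mark_alterations()] then promotes altered
#' identifiers into the table with status `"altered"`.
#'
#' @return An empty `deregulation_table`.
#' @export
deregulation_table <- function() {
  new_deregulation_table(
    tibble(id = character(), combined_score = double(), status = character()),
    has_primary = FALSE
  )
}

#' Record mutation/methylation/phosphorylation alterations
#'
#' Alteration layers never override a primary up/down call: an altered
#' node already in the table keeps its status and gains the per-layer
#' flag. When the table was built without primary data (alteration-only
#' runs) altered identifiers are added with status `"altered"`; with
#' primary data present, nodes absent from all primary layers stay
#' excluded. If `net` is supplied, added nodes are restricted to the
#' network's node set.
#'
#' @param table A `deregulation_table`.
#' @param alteration_profiles List of `omics_profile`s with layers among
#'   phospho, genomics, epigenomics.
#' @param net Optional `meta_interactome` bounding added altered nodes.
#' @return The updated `deregulation_table`.
#' @export
mark_alterations <- function(table, alteration_profiles, net = NULL) {
  stopifnot(inherits(table, "deregulation_table"))
  if (inherits(alteration_profiles, "omics_profile")) {
    alteration_profiles <- list(alteration_profiles)
  }
  flag_col <- c(genomics = "is_mutated", epigenomics = "is_methylated",
                phospho = "is_phosphorylated")
  has_primary <- isTRUE(attr(table, "has_primary"))
  for (p in alteration_profiles) {
    if (!p$layer %in% ALTERATION_LAYERS) {
      abort(sprintf("'%s' is not an alteration layer", p$layer))
    }
    ids <- p$data$id
    if (!has_primary) {
      new_ids <- setdiff(ids, table$id)
      if (!is.null(net)) new_ids <- intersect(new_ids, net$nodes$id)
      if (length(new_ids) > 0) {
        add <- tibble(id = new_ids, combined_score = 0, status = "altered",
                      is_mutated = FALSE, is_methylated = FALSE,
                      is_phosphorylated = FALSE)
        table <- new_deregulation_table(bind_rows(as_tibble(table), add),
                                        has_primary = has_primary)
      }
    }
    col <- flag_col[[p$layer]]
    table[[col]] <- table[[col]] | (table$id %in% ids)
  }
  table <- table[order(table$id), ]
  new_deregulation_table(as_tibble(table), has_primary = has_primary)
}

# Status lookup with "absent" fill for ids outside the table.
node_status <- function(table, ids) {
  idx <- match(ids, table$id)
  status <- table$status[idx]
  status[is.na(idx)] <- "absent"
  status
}
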
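PATHWAY_CLASSES <- c("signaling", "metabolic", "cancer", "other")

#' Construct a pathway gene-set database
#'
#' @param pathways A data frame with columns `name`, `class` (signaling,
#'   metabolic, cancer or other; unknown labels map to `other`) and
#'   `members` (list column of character vectors).
#' @return A `pathway_db`: the pathway tibble plus the universe (exact
#'   union of all member sets).
#' @export
pathway_db <- function(pathways) {
  pathways <- as_tibble(pathways)
  stopifnot(all(c("name", "class", "members") %in% names(pathways)))
  pathways$class <- ifelse(pathways$class %in% PATHWAY_CLASSES,
                           pathways$class, "other")
  pathways$members <- purrr::map(pathways$members,
                                 function(m) sort(unique(as.character(m))))
  if (any(lengths(pathways$members) == 0)) {
    abort("pathway member sets must be non-empty", class = "panomix_format_error")
  }
  pathways$size <- lengths(pathways$members)
  universe <- sort(unique(unlist(pathways$members, use.names = FALSE)))
  structure(list(pathways = arrange(pathways, .data$name), universe = universe),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways, universe of %d genes\n",
              nrow(x$pathways), length(x$universe)))
  invisible(x)
}

#' Read pathway gene sets from a GMT file
#'
#' One pathway per line: name, description and member genes, tab
#' separated. The first whitespace-delimited token of the description
#' field is read as the pathway class (signaling / metabolic / cancer /
#' other; anything else maps to `other`). Duplicate genes within a line
#' are collapsed.
#'
#' @param path GMT file path.
#' @return A `pathway_db`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields", i),
            class = "panomix_format_error")
    }
    cls <- strsplit(trimws(fields[2]), "[[:space:]]+")[[1]][1]
    tibble(name = fields[1],
           class = if (isTRUE(cls %in% PATHWAY_CLASSES)) cls else "other",
           members = list(unique(fields[-(1:2)])))
  })
  pathway_db(bind_rows(parsed))
}

#' Write a pathway database to GMT
#'
#' @param db A `pathway_db`.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  lines <- purrr::pmap_chr(db$pathways[, c("name", "class", "members")],
                           function(name, class, members) {
    paste(c(name, class, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

check_hyper_args <- function(a, b, c, d) {
  ok <- all(c(a, b, c, d) >= 0) && a == round(a) && b == round(b) &&
    c == round(c) && d == round(d) && a <= b && c <= d && a + c <= b + d
  if (!ok) {
    abort("invalid hypergeometric arguments: need 0 <= a <= b, 0 <= c <= d",
          class = "panomix_domain_error")
  }
}

#' Point hypergeometric probability of an enrichment table
#'
#' The probability of the single observed contingency configuration,
#' `C(b, a) * C(d, c) / C(b + d, a + c)`, where `a` is the overlap drawn
#' from the query list, `b` the query-list size, `c` the pathway size and
#' `d` the size of the pathway universe. Evaluated in log space.
#'
#' @param a,b,c,d Non-negative integers with `a <= b`, `c <= d`.
#' @return The point probability in \[0, 1\].
#' @export
hypergeom_point <- function(a, b, c, d) {
  check_hyper_args(a, b, c, d)
  exp(lchoose(b, a) + lchoose(d, c) - lchoose(b + d, a + c))
}

#' Upper-tail hypergeometric (over-representation) p-value
#'
#' One-sided Fisher-exact style p-value `P[overlap >= a]` under the
#' hypergeometric law with population `d` (the pathway universe),
#' `c` successes (pathway members), and `b` draws (the query list):
#' the standard enrichment orientation.
#'
#' @inheritParams hypergeom_point
#' @return Upper-tail p-value in \[0, 1\].
#' @export
hypergeom_tail <- function(a, b, c, d) {
  check_hyper_args(a, b, c, d)
  if (b > d) {
    abort("draws (b) exceed the population (d) in the tail orientation",
          class = "panomix_domain_error")
  }
  if (a == 0) return(1)
  stats::phyper(a - 1, m = c, n = d - c, k = b, lower.tail = FALSE)
}

#' Pathway enrichment of a gene list
#'
#' Scores every pathway with a non-empty overlap against the query list
#' using the hypergeometric test; a pathway is selected when its p-value
#' is at most `p_cutoff` (raw p-values by default, mirroring the p <=
#' 0.05 selection convention; Benjamini-Hochberg adjustment is available
#' behind `adjust`). `b` counts the full query list, including genes
#' outside the pathway universe.
#'
#' @param query Character vector of gene ids (non-empty).
#' @param db A `pathway_db`.
#' @param statistic `"tail"` (default, upper-tail over-representation) or
#'   `"point"` (single-table probability).
#' @param p_cutoff Selection threshold (inclusive), default 0.05.
#' @param adjust Apply Benjamini-Hochberg correction before selection.
#' @return An `enrichment_result` tibble sorted by ascending p (ties by
#'   pathway name): `(pathway, class, a, b, c, d, p_point, p_tail,
#'   p_value, selected)`.
#' @export
enrich <- function(query, db, statistic = c("tail", "point"),
                   p_cutoff = 0.05, adjust = FALSE) {
  statistic <- match.arg(statistic)
  query <- unique(query)
  if (length(query) == 0) {
    abort("query gene set is empty", class = "panomix_empty_query")
  }
  b <- length(query)
  d <- length(db$universe)
  res <- db$pathways |>
    mutate(a = purrr::map_int(.data$members,
                              function(m) length(intersect(m, query))),
           b = b, c = .data$size, d = d) |>
    filter(.data$a > 0) |>
    select("name", "class", "a", "b", "c", "d") |>
    rename(pathway = "name")
  if (nrow(res) == 0) {
    res$p_point <- double(); res$p_value <- double()
    res$p_tail <- double(); res$selected <- logical()
    return(structure(res, class = c("enrichment_result", class(tibble())),
                     statistic = statistic))
  }
  res <- res |>
    mutate(
      p_point = purrr::pmap_dbl(list(.data$a, .data$b, .data$c, .data$d),
                                hypergeom_point),
      p_tail = purrr::pmap_dbl(list(.data$a, .data$b, .data$c, .data$d),
                               hypergeom_tail),
      p_value = if (statistic == "tail") .data$p_tail else .data$p_point
    )
  if (adjust) res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res |>
    mutate(selected = .data$p_value <= p_cutoff) |>
    arrange(.data$p_value, .data$pathway)
  structure(res, class = c("enrichment_result", class(tibble())),
            statistic = statistic)
}

#' Bipartite TIN-pathway network
#'
#' Connects each topologically important node to the selected enriched
#' pathways that contain it.
#'
#' @param tins Character vector of TIN ids.
#' @param results An `enrichment_result`.
#' @param db The `pathway_db` used for enrichment.
#' @return List with `nodes` (id, type = tin/pathway) and `edges`
#'   (tin, pathway) tibbles; only TINs with at least one edge appear.
#' @export
tin_pathway_network <- function(tins, results, db) {
  sel <- results$pathway[results$selected]
  members <- db$pathways$members[match(sel, db$pathways$name)]
  edges <- purrr::map2(sel, members, function(pw, m) {
    hit <- sort(intersect(m, tins))
    if (length(hit) == 0) return(NULL)
    tibble(tin = hit, pathway = pw)
  })
  edges <- bind_rows(edges)
  if (nrow(edges) == 0) {
    edges <- tibble(tin = character(), pathway = character())
  }
  nodes <- bind_rows(
    tibble(id = sort(unique(edges$tin)), type = "tin"),
    tibble(id = sel, type = "pathway")
  )
  list(nodes = nodes, edges = arrange(edges, .data$pathway, .data$tin))
}

#' Best prognostic-marker annotation per node
#'
#' Joins a prognostic-marker table (gene, cancer type, favorable or
#' unfavorable direction, Kaplan-Meier p-value) onto a node list and
#' reports, per node, the cancer type with the minimum p-value. Nodes
#' without a marker row receive no annotation.
#'
#' @param nodes Character vector of node ids.
#' @param marker_table Data frame with columns `gene`, `cancer_type`,
#'   `direction`, `p`.
#' @return Tibble `(id, cancer_type, direction, p, n_records)` restricted
#'   to annotated nodes.
#' @export
annotate_prognostic <- function(nodes, marker_table) {
  marker_table <- as_tibble(marker_table)
  stopifnot(all(c("gene", "cancer_type", "direction", "p") %in%
                  names(marker_table)))
  p <- suppressWarnings(as.numeric(marker_table$p))
  if (anyNA(p)) {
    abort(sprintf("malformed p-value at marker row %d", which(is.na(p))[1]),
          class = "panomix_format_error")
  }
  marker_table$p <- p
  marker_table |>
    filter(.data$gene %in% nodes) |>
    group_by(.data$gene) |>
    arrange(.data$p, .data$cancer_type, .by_group = TRUE) |>
    summarise(cancer_type = .data$cancer_type[1],
              direction = .data$direction[1],
              p = .data$p[1], n_records = dplyr::n(), .groups = "drop") |>
    rename(id = "gene") |>
    arrange(.data$id)
}

#' Fraction of selected pathways that are cancer pathways
#'
#' @param results An `enrichment_result`.
#' @return Fraction in \[0, 1\]; 0 with a warning when nothing was
#'   selected.
#' @export
cancer_pathway_fraction <- function(results) {
  sel <- results[results$selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    warn("no pathway selected; cancer fraction is 0")
    return(0)
  }
  mean(sel$class == "cancer")
}
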
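# Flatten a crosspath result for TSV output.
crosspath_table <- function(paths, net = NULL) {
  if (nrow(paths) == 0) {
    return(tibble(mode = character(), regulator = character(),
                  path_type = character(), path = character(),
                  score = double(), z = double(), important = logical(),
                  metabolites = character()))
  }
  out <- tibble(
    mode = paths$mode,
    regulator = paths$regulator,
    path_type = paths$path_type,
    path = purrr::map_chr(paths$nodes, paste, collapse = "->"),
    score = paths$score %||% NA_real_,
    z = paths$z %||% NA_real_,
    important = paths$important %||% NA
  )
  if (!is.null(net)) {
    m_nodes <- purrr::map_chr(paths$nodes, function(n) n[length(n)])
    out$metabolites <- enzyme_metabolites(net, m_nodes)$metabolites
  } else {
    out$metabolites <- NA_character_
  }
  out
}

write_manifest <- function(out_dir, config) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "panomix",
    version = as.character(utils::packageVersion("panomix")),
    config = config,
    outputs = lapply(seq_along(files), function(i) {
      list(file = files[i], md5 = unname(sums[i]))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the omics-mapping and network-analysis module
#'
#' The end-to-end first analysis module: harmonize the primary omics
#' layers into a deregulation table, mark alterations, extract the
#' filtered network, compute the topology report with its z-score PDF
#' tables, select TINs and IINs, build the TIN subnetwork, and (when a
#' pathway database is given) enrich the TINs and join prognostic
#' markers. All outputs are written as re-parseable TSV/JSON files under
#' `out_dir` together with a checksum manifest.
#'
#' @param net A `meta_interactome`.
#' @param primary_profiles List of primary `omics_profile`s (>= 1).
#' @param out_dir Output directory (created).
#' @param alteration_profiles Optional list of alteration profiles.
#' @param db Optional `pathway_db` for TIN enrichment.
#' @param markers Optional prognostic marker table.
#' @param level Interactor expansion depth (1 or 2).
#' @param z_hub,z_cn,z_bn z-score selection thresholds (default 1, the
#'   non-interactive convention).
#' @param statistic Enrichment statistic (`"tail"` or `"point"`).
#' @return Invisible list with the in-memory results (`table`, `network`,
#'   `report`, `tins`, `iins`, `enrichment`, `prognostic`, `manifest`).
#' @export
run_network_analysis <- function(net, primary_profiles, out_dir,
                                 alteration_profiles = NULL, db = NULL,
                                 markers = NULL, level = 1,
                                 z_hub = 1, z_cn = 1, z_bn = 1,
                                 statistic = "tail") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- combine_primary(primary_profiles)
  if (!is.null(alteration_profiles)) {
    table <- mark_alterations(table, alteration_profiles, net)
  }
  network <- extract_filtered_network(net, table, level)
  readr::write_tsv(as_tibble(table), file.path(out_dir, "deregulation.tsv"))
  write_network_json(network, file.path(out_dir, "filtered_network.json"))

  report <- topology_report(network, table, z_hub = z_hub, z_cn = z_cn,
                            z_bn = z_bn)
  for (idx in c("z_degree", "z_ccs", "z_betweenness")) {
    readr::write_tsv(pdf_plot_data(report[[idx]]),
                     file.path(out_dir, paste0("pdf_", idx, ".tsv")))
  }
  readr::write_tsv(as_tibble(report), file.path(out_dir, "topology_report.tsv"))
  tins <- sort(report$id[report$is_tin])
  iins <- identify_iins(report)
  writeLines(tins, file.path(out_dir, "tins.txt"))
  writeLines(iins, file.path(out_dir, "iins.txt"))
  if (length(tins) > 0) {
    write_network_json(tin_subnetwork(network, tins, level),
                       file.path(out_dir, "tin_subnetwork.json"))
  }

  enrichment <- NULL
  prognostic <- NULL
  if (!is.null(db) && length(tins) > 0) {
    enrichment <- enrich(tins, db, statistic = statistic)
    readr::write_tsv(as_tibble(enrichment),
                     file.path(out_dir, "enrichment.tsv"))
    bip <- tin_pathway_network(tins, enrichment, db)
    jsonlite::write_json(bip, file.path(out_dir, "tin_pathway_network.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(markers) && length(tins) > 0) {
    prognostic <- annotate_prognostic(tins, markers)
    readr::write_tsv(prognostic, file.path(out_dir, "prognostic.tsv"))
  }
  manifest <- write_manifest(out_dir, list(
    module = "network_analysis", level = level,
    z_hub = z_hub, z_cn = z_cn, z_bn = z_bn, statistic = statistic
  ))
  invisible(list(table = table, network = network, report = report,
                 tins = tins, iins = iins, enrichment = enrichment,
                 prognostic = prognostic, manifest = manifest))
}

#' Run the pathway-connectivity module
#'
#' Enumerates, filters and scores cross-pathway paths for one
#' connectivity mode (only one mode per run) and writes the path table,
#' the JSON graph of the union of important paths, and a checksum
#' manifest.
#'
#' @param net A `meta_interactome`.
#' @param table A `deregulation_table` from primary omics data.
#' @param mode Connectivity mode (one of s2m/tf2m/mirna2m or the long
#'   names).
#' @param weights Character vector of weight options (see
#'   [weight_config()]).
#' @param out_dir Output directory.
#' @param report Optional `topology_report` for topological weights.
#' @param max_intermediates Maximum P nodes between X and M (default 3).
#' @param include_entropy Include the local-entropy emission term.
#' @return Invisible list with `paths` and `manifest`.
#' @export
run_pathway_connectivity <- function(net, table, mode, weights, out_dir,
                                     report = NULL, max_intermediates = 3,
                                     include_entropy = FALSE) {
  mode <- match_mode(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- weight_config(weights)
  paths <- tryCatch(
    score_paths(net, mode, table, config, report = report,
                max_intermediates = max_intermediates,
                include_entropy = include_entropy),
    panomix_degenerate = function(e) {
      warn(paste("path scoring degenerate:", conditionMessage(e)))
      tibble(mode = character(), regulator = character(), nodes = list(),
             path_type = character(), score = double(), z = double(),
             important = logical())
    }
  )
  readr::write_tsv(crosspath_table(paths, net),
                   file.path(out_dir, "paths.tsv"))

  important <- paths[isTRUE(nrow(paths) > 0) & (paths$important %||% FALSE), ,
                     drop = FALSE]
  edges <- list()
  if (nrow(important) > 0) {
    for (i in seq_len(nrow(important))) {
      full <- c(if (!is.na(important$regulator[i])) important$regulator[i],
                important$nodes[[i]])
      edges[[length(edges) + 1]] <-
        tibble(source = full[-length(full)], target = full[-1])
    }
  }
  graph <- list(
    mode = mode,
    nodes = if (length(edges) > 0)
      sort(unique(unlist(purrr::map(edges, function(e) c(e$source, e$target)))))
    else character(),
    edges = if (length(edges) > 0) distinct(bind_rows(edges)) else
      tibble(source = character(), target = character())
  )
  jsonlite::write_json(graph, file.path(out_dir, "important_paths.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (nrow(important) == 0) warn("no important path at z >= 1")
  manifest <- write_manifest(out_dir, list(
    module = "pathway_connectivity", mode = mode,
    weights = config$options, max_intermediates = max_intermediates,
    include_entropy = include_entropy
  ))
  invisible(list(paths = paths, manifest = manifest))
}
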
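# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic study generator
#'
#' The defaults define the simulated study conditions used throughout
#' the package's tests: a 200-protein PPI layer with mean degree about 4,
#' 20 miRNAs, 10 TFs, 30 metabolites, 15% signaling and 15% metabolic
#' proteins, 20% planted-deregulated nodes with logFC drawn from
#' `Normal(+/-2, 0.3)` and significant p-values, against an expressed
#' background.
#'
#' @param n_proteins,n_mirnas,n_tfs,n_metabolites Node counts.
#' @param ppi_model `"erdos_renyi"` (parameter = edge probability) or
#'   `"barabasi_albert"` (parameter = edges added per node).
#' @param ppi_param Random-graph parameter; default `4 / (n_proteins - 1)`
#'   (mean degree 4) for the Erdos-Renyi model.
#' @param frac_signaling,frac_metabolic Fractions of proteins flagged
#'   signaling / metabolic (independent draws; overlap allowed).
#' @param frac_deregulated Fraction of nodes planted as deregulated.
#' @param logfc_mu,logfc_sd Magnitude and spread of planted logFC.
#' @param seed Integer RNG seed; every generator draw derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 200, n_mirnas = 20, n_tfs = 10,
                         n_metabolites = 30,
                         ppi_model = c("erdos_renyi", "barabasi_albert"),
                         ppi_param = NULL,
                         frac_signaling = 0.15, frac_metabolic = 0.15,
                         frac_deregulated = 0.2,
                         logfc_mu = 2, logfc_sd = 0.3, seed = 1) {
  ppi_model <- match.arg(ppi_model)
  if (is.null(ppi_param)) {
    ppi_param <- if (ppi_model == "erdos_renyi") 4 / (n_proteins - 1) else 2
  }
  stopifnot(n_proteins > 0, n_mirnas > 0, n_tfs > 0, n_metabolites > 0,
            frac_signaling > 0, frac_signaling < 1,
            frac_metabolic > 0, frac_metabolic < 1,
            frac_deregulated > 0, frac_deregulated < 1,
            logfc_sd > 0)
  structure(list(
    n_proteins = n_proteins, n_mirnas = n_mirnas, n_tfs = n_tfs,
    n_metabolites = n_metabolites, ppi_model = ppi_model,
    ppi_param = ppi_param, frac_signaling = frac_signaling,
    frac_metabolic = frac_metabolic, frac_deregulated = frac_deregulated,
    logfc_mu = logfc_mu, logfc_sd = logfc_sd, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a synthetic meta-interactome and its input files
#'
#' Draws a PPI layer from the configured random-graph model, wires every
#' miRNA and TF to a random target set (each regulator gets at least one
#' target), attaches metabolites to metabolic enzymes, and assigns
#' signaling / metabolic / crosstalk / rate-limiting annotations. All
#' layers are written in the package's input dialects (STRING-style links
#' file including sub-threshold decoy edges, regulatory and metabolite
#' TSVs, annotation tables) and read back through the package's own
#' parsers, so the generated fixture validates every reader.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (created if needed); a fresh temporary
#'   directory by default.
#' @return List with the `meta_interactome` (`net`), the file paths
#'   (`files`) and the annotation vectors (`annotations`).
#' @export
generate_network <- function(config, dir = tempfile("panomix_net_")) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    proteins <- sprintf("GEN%04d", seq_len(config$n_proteins))
    g <- if (config$ppi_model == "erdos_renyi") {
      igraph::sample_gnp(config$n_proteins, config$ppi_param)
    } else {
      igraph::sample_pa(config$n_proteins, m = config$ppi_param,
                        directed = FALSE)
    }
    el <- igraph::as_edgelist(g)
    ppi <- tibble(protein1 = proteins[el[, 1]], protein2 = proteins[el[, 2]],
                  experimental = sample(700:1000, nrow(el), replace = TRUE))
    # decoy edges under the confidence threshold exercise the score filter
    n_decoy <- max(10L, nrow(el) %/% 5L)
    decoy <- tibble(
      protein1 = sample(proteins, n_decoy, replace = TRUE),
      protein2 = sample(proteins, n_decoy, replace = TRUE),
      experimental = sample(100:699, n_decoy, replace = TRUE)
    )
    decoy <- decoy[decoy$protein1 != decoy$protein2, , drop = FALSE]
    links <- bind_rows(ppi, decoy)
    links$combined_score <- pmin(1000L, links$experimental +
                                   sample(0:150, nrow(links), replace = TRUE))

    signaling <- sort(sample(proteins,
                             max(2L, round(config$frac_signaling *
                                             config$n_proteins))))
    metabolic <- sort(sample(proteins,
                             max(2L, round(config$frac_metabolic *
                                             config$n_proteins))))
    tfs <- sort(sample(proteins, config$n_tfs))
    tf_edges <- bind_rows(lapply(tfs, function(tf) {
      tibble(regulator = tf,
             target = sample(setdiff(proteins, tf),
                             sample(5:15, 1)))
    }))
    mirnas <- sprintf("hsa-miR-sim-%03d", seq_len(config$n_mirnas))
    mirna_edges <- bind_rows(lapply(mirnas, function(mir) {
      tibble(regulator = mir, target = sample(proteins, sample(3:10, 1)))
    }))
    metabolites <- sprintf("MET%04d", seq_len(config$n_metabolites))
    met_edges <- bind_rows(lapply(metabolites, function(m) {
      tibble(enzyme = sample(metabolic, sample(1:3, 1)), metabolite = m,
             role = sample(c("substrate", "product"),
                           1, replace = TRUE))
    }))
    crosstalk <- sort(sample(signaling, max(2L, length(signaling) %/% 4L)))
    rate_limiting <- sort(sample(metabolic, max(2L, length(metabolic) %/% 4L)))

    files <- list(
      string = file.path(dir, "string_links.txt"),
      mirna = file.path(dir, "mirna_targets.tsv"),
      tf = file.path(dir, "tf_targets.tsv"),
      metabolite = file.path(dir, "enzyme_metabolites.tsv"),
      signaling = file.path(dir, "signaling_proteins.txt"),
      metabolic = file.path(dir, "metabolic_proteins.txt"),
      crosstalk = file.path(dir, "crosstalk_genes.txt"),
      rate_limiting = file.path(dir, "rate_limiting_enzymes.txt")
    )
    utils::write.table(links, files$string, sep = " ", quote = FALSE,
                       row.names = FALSE)
    readr::write_tsv(mirna_edges, files$mirna)
    readr::write_tsv(tf_edges, files$tf)
    readr::write_tsv(met_edges, files$metabolite)
    writeLines(signaling, files$signaling)
    writeLines(metabolic, files$metabolic)
    writeLines(crosstalk, files$crosstalk)
    writeLines(rate_limiting, files$rate_limiting)

    annotations <- list(signaling = signaling, metabolic = metabolic,
                        crosstalk = crosstalk, rate_limiting = rate_limiting)
    net <- build_meta_interactome(
      list(read_string_edges(files$string, min_experimental = 700),
           read_regulatory_edges(files$mirna, "mirna_target"),
           read_regulatory_edges(files$tf, "tf_target"),
           read_metabolite_edges(files$metabolite)),
      annotations = annotations
    )
    list(net = net, files = files, annotations = annotations, dir = dir)
  })
}

#' Generate synthetic omics tables with planted deregulation
#'
#' Plants a configured fraction of proteins (mRNA layer) and miRNAs
#' (miRNA layer) as deregulated, with `logFC ~ Normal(+/-logfc_mu,
#' logfc_sd)` (random sign) and `p ~ Uniform(0, 0.045)`; the remaining
#' nodes form an expressed background with sub-threshold logFC
#' (`Uniform(-0.8, 0.8)`) and `p ~ Uniform(0, 1)`. Alteration layers
#' (genomics, epigenomics, phospho) and a metabolomics list are sampled
#' node subsets. Ground-truth planted labels are returned and written
#' alongside for recovery tests.
#'
#' @param config A `synth_config`.
#' @param network Output of [generate_network()].
#' @param dir Output directory; defaults to the network's directory.
#' @return List of `omics_profile`s (`profiles`), ground truth (`truth`),
#'   and file paths (`files`).
#' @export
generate_omics <- function(config, network, dir = network$dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed + 1L, {
    proteins <- network$net$nodes$id[network$net$nodes$kind == "protein"]
    mirnas <- network$net$nodes$id[network$net$nodes$kind == "mirna"]
    metabolites <- network$net$nodes$id[network$net$nodes$kind == "metabolite"]

    plant_layer <- function(ids) {
      n_plant <- max(1L, round(config$frac_deregulated * length(ids)))
      planted <- sort(sample(ids, n_plant))
      sign <- sample(c(-1, 1), length(ids), replace = TRUE)
      is_planted <- ids %in% planted
      logfc <- ifelse(
        is_planted,
        sign * stats::rnorm(length(ids), config$logfc_mu, config$logfc_sd),
        stats::runif(length(ids), -0.8, 0.8)
      )
      p <- ifelse(is_planted, stats::runif(length(ids), 0, 0.045),
                  stats::runif(length(ids), 0, 1))
      list(table = tibble(id = ids, logFC = logfc, p = p), planted = planted)
    }
    mrna <- plant_layer(proteins)
    mirna <- plant_layer(mirnas)
    genomics_ids <- sort(sample(proteins, max(1L, length(proteins) %/% 10L)))
    epigenomics_ids <- sort(sample(proteins, max(1L, length(proteins) %/% 12L)))
    phospho_ids <- sort(sample(proteins, max(1L, length(proteins) %/% 12L)))
    metabolomics_ids <- sort(sample(metabolites,
                                    max(1L, length(metabolites) %/% 3L)))

    files <- list(
      mrna = file.path(dir, "omics_mrna.tsv"),
      mirna = file.path(dir, "omics_mirna.tsv"),
      genomics = file.path(dir, "omics_genomics.tsv"),
      epigenomics = file.path(dir, "omics_epigenomics.tsv"),
      phospho = file.path(dir, "omics_phospho.tsv"),
      metabolomics = file.path(dir, "omics_metabolomics.tsv"),
      truth = file.path(dir, "ground_truth.json")
    )
    readr::write_tsv(mrna$table, files$mrna)
    readr::write_tsv(mirna$table, files$mirna)
    readr::write_tsv(tibble(id = genomics_ids), files$genomics)
    readr::write_tsv(tibble(id = epigenomics_ids), files$epigenomics)
    readr::write_tsv(tibble(id = phospho_ids), files$phospho)
    readr::write_tsv(tibble(id = metabolomics_ids), files$metabolomics)

    truth <- list(planted_mrna = mrna$planted, planted_mirna = mirna$planted,
                  genomics = genomics_ids, epigenomics = epigenomics_ids,
                  phospho = phospho_ids, metabolomics = metabolomics_ids)
    jsonlite::write_json(truth, files$truth, auto_unbox = FALSE)

    profiles <- list(
      mrna = read_omics_table(files$mrna, "mrna"),
      mirna = read_omics_table(files$mirna, "mirna"),
      genomics = read_omics_table(files$genomics, "genomics"),
      epigenomics = read_omics_table(files$epigenomics, "epigenomics"),
      phospho = read_omics_table(files$phospho, "phospho"),
      metabolomics = read_omics_table(files$metabolomics, "metabolomics")
    )
    list(profiles = profiles, truth = truth, files = files)
  })
}

#' Generate a synthetic pathway database and annotation tables
#'
#' Builds a classed gene-set collection of random protein groups covering
#' all four classes, plus one planted cancer pathway drawing a
#' disproportionate share of its members from the planted-deregulated
#' genes (so enrichment of the deregulated list should rank it first),
#' and a sampled prognostic-marker table.
#'
#' @param config A `synth_config`.
#' @param network Output of [generate_network()].
#' @param truth Ground truth from [generate_omics()].
#' @param dir Output directory; defaults to the network's directory.
#' @return List with the `pathway_db` (`db`), the planted pathway name
#'   (`planted`), the marker tibble (`markers`) and file paths.
#' @export
generate_pathways <- function(config, network, truth, dir = network$dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed + 2L, {
    proteins <- network$net$nodes$id[network$net$nodes$kind == "protein"]
    planted_genes <- intersect(truth$planted_mrna, proteins)
    classes <- rep(c("signaling", "metabolic", "cancer", "other"), 3)
    background <- purrr::imap(classes, function(cls, i) {
      tibble(name = sprintf("SYN_PW_%02d", i), class = cls,
             members = list(sort(sample(proteins, sample(20:40, 1)))))
    })
    n_from_planted <- min(length(planted_genes), 15L)
    planted_members <- sort(unique(c(
      sample(planted_genes, n_from_planted),
      sample(proteins, 10)
    )))
    planted <- tibble(name = "SYN_PW_PLANTED", class = "cancer",
                      members = list(planted_members))
    db <- pathway_db(bind_rows(c(background, list(planted))))

    markers <- tibble(
      gene = sample(proteins, min(60L, length(proteins)), replace = FALSE),
      cancer_type = sample(c("renal", "liver", "cervical", "breast",
                             "ovarian"),
                           min(60L, length(proteins)), replace = TRUE),
      direction = sample(c("favorable", "unfavorable"),
                         min(60L, length(proteins)), replace = TRUE),
      p = stats::runif(min(60L, length(proteins)), 1e-4, 0.05)
    )
    files <- list(gmt = file.path(dir, "pathways.gmt"),
                  markers = file.path(dir, "prognostic_markers.tsv"))
    write_gmt(db, files$gmt)
    readr::write_tsv(markers, files$markers)
    list(db = db, planted = "SYN_PW_PLANTED", markers = markers,
         files = files)
  })
}

#' Generate a complete synthetic study
#'
#' One call producing the meta-interactome, all omics layers, the
#' pathway database, annotation tables, and ground-truth labels, all
#' written under one directory.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (default: fresh temporary directory).
#' @return List with `net`, `profiles`, `db`, `markers`, `annotations`,
#'   `truth`, `files` and `dir`.
#' @export
simulate_study <- function(config = synth_config(), dir = tempfile("panomix_study_")) {
  network <- generate_network(config, dir)
  omics <- generate_omics(config, network, dir)
  pathways <- generate_pathways(config, network, omics$truth, dir)
  list(net = network$net, profiles = omics$profiles, db = pathways$db,
       markers = pathways$markers, annotations = network$annotations,
       planted_pathway = pathways$planted, truth = omics$truth,
       files = c(network$files, omics$files, pathways$files), dir = dir)
}
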
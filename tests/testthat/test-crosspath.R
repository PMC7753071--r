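# Small signaling->metabolic fixture: S -PPI- P1 -PPI- M
chain_net <- function() {
  mk_ppi_net(ppi_edges(c("S", "P1"), c("P1", "M")),
             signaling = "S", metabolic = "M")
}

test_that("path enumeration follows the XM/XPM/XPPM/XPPPM grammar", {
  paths <- enumerate_paths(chain_net(), "s2m")
  expect_equal(nrow(paths), 1)
  expect_equal(paths$path_type, "XPM")
  expect_equal(paths$nodes[[1]], c("S", "P1", "M"))

  # n = 0 keeps only direct X-M edges
  direct <- mk_ppi_net(ppi_edges(c("S", "M"), c("S", "P"), c("P", "M")),
                       signaling = "S", metabolic = "M")
  xm_only <- enumerate_paths(direct, "s2m", max_intermediates = 0)
  expect_equal(nrow(xm_only), 1)
  expect_equal(xm_only$path_type, "XM")

  # K5 with one S and one M: exhaustive DFS count of simple paths <= 4 edges
  ids <- c("S", "M", "P1", "P2", "P3")
  prs <- utils::combn(ids, 2)
  k5 <- mk_ppi_net(do.call(ppi_edges, lapply(seq_len(ncol(prs)),
                                             function(i) prs[, i])),
                   signaling = "S", metabolic = "M")
  got <- enumerate_paths(k5, "s2m")
  expect_equal(nrow(got), 16)  # 1 + 3 + 3*2 + 3*2*1

  expect_error(enumerate_paths(mk_ppi_net(ppi_edges(c("A", "B"))), "s2m"),
               class = "panomix_missing_class")
})

test_that("enumeration equals the brute-force simple-path oracle", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    A <- random_adjacency(n, 0.45, connected = FALSE)
    ids <- sprintf("V%02d", seq_len(n))
    s_set <- sample(ids, 2)
    m_set <- sample(setdiff(ids, s_set[1]), 2)
    net <- try(net_from_adjacency(A, signaling = s_set, metabolic = m_set),
               silent = TRUE)
    if (inherits(net, "try-error")) next  # isolated-vertex graphs lack nodes
    s_in <- intersect(s_set, net$nodes$id)
    m_in <- intersect(m_set, net$nodes$id)
    if (length(s_in) == 0 || length(m_in) == 0) next
    got <- enumerate_paths(net, "s2m")
    want <- character(0)
    for (s in s_in) {
      for (m in setdiff(m_in, s)) {
        ps <- oracle_simple_paths(A, match(s, ids), match(m, ids),
                                  max_edges = 4)
        want <- c(want, vapply(ps, function(p) {
          paste(ids[p], collapse = "->")
        }, character(1)))
      }
    }
    expect_setequal(purrr::map_chr(got$nodes, paste, collapse = "->"),
                    unique(want))
  }
})

test_that("regulator modes record the prefix and respect deregulation", {
  edges <- list(
    ppi_edges(c("X", "P1"), c("P1", "M"), c("X", "M")),
    tibble::tibble(source = c("TF1", "TF2"), target = c("X", "P1"),
                   kind = "tf_target", score = NA_real_,
                   role = NA_character_)
  )
  net <- build_meta_interactome(edges, annotations = list(metabolic = "M"))
  all_paths <- enumerate_paths(net, "tf2m")
  expect_true(all(!is.na(all_paths$regulator)))
  # restricting to deregulated regulators drops TF2's paths
  tab <- mk_table(c("TF1", "TF2", "X", "P1", "M"),
                  c("up", "expressed", "expressed", "expressed", "down"))
  dereg <- enumerate_paths(net, "tf2m", tab)
  expect_setequal(unique(dereg$regulator), "TF1")
  # the regulator never reappears inside its own path (simple sequence)
  expect_false(any(purrr::map2_lgl(dereg$regulator, dereg$nodes,
                                   function(r, n) r %in% n)))

  filtered <- filter_paths(dereg, tab)
  expect_true(nrow(filtered) >= 1)
  term <- panomix:::path_terminals(filtered)
  expect_true(all(term$first == "TF1"))
})

test_that("the deregulation filter checks terminals and interiors", {
  net <- chain_net()
  paths <- enumerate_paths(net, "s2m")
  keep <- filter_paths(paths, mk_table(c("S", "P1", "M"),
                                       c("up", "expressed", "down")))
  expect_equal(nrow(keep), 1)
  # terminal not deregulated -> dropped
  drop1 <- filter_paths(paths, mk_table(c("S", "P1", "M"),
                                        c("up", "expressed", "expressed")))
  expect_equal(nrow(drop1), 0)
  # interior absent from primary omics -> dropped
  drop2 <- filter_paths(paths, mk_table(c("S", "M"), c("up", "down")))
  expect_equal(nrow(drop2), 0)
  expect_error(filter_paths(paths, mk_table("S", "up", has_primary = FALSE)),
               class = "panomix_no_primary")
})

test_that("expression scores are 1 + |combined| and error on absent nodes", {
  tab <- mk_table(c("a", "b"), c("expressed", "down"), c(0, -1))
  expect_equal(expression_score(c("a", "b"), tab), c(1, 2))
  expect_error(expression_score("zzz", tab), class = "panomix_absent_node")
  # single-layer case: |combined| <= 1 so scores lie in [1, 2]
  prof <- mk_profile(sprintf("g%d", 1:20), stats::rnorm(20, 0, 2),
                     stats::runif(20, 0, 0.04))
  t1 <- combine_primary(prof)
  s <- expression_score(t1$id, t1)
  expect_true(all(s >= 1 & s <= 2))
})

test_that("local entropy is maximal for uniform weights and bounded by log k", {
  star <- mk_ppi_net(ppi_edges(c("C", "N1"), c("C", "N2"), c("C", "N3")))
  tab_unif <- mk_table(c("C", "N1", "N2", "N3"), rep("expressed", 4))
  expect_equal(local_entropy("C", star, tab_unif), log(3))
  expect_equal(local_entropy("N1", star, tab_unif), 0)  # degree 1
  set.seed(31)
  for (i in 1:10) {
    status <- sample(c("up", "down", "expressed"), 4, replace = TRUE)
    combined <- ifelse(status == "expressed", 0, stats::runif(4, 0.1, 1))
    tab <- mk_table(c("C", "N1", "N2", "N3"), status, combined)
    h <- local_entropy("C", star, tab)
    expect_lte(h, log(3) + 1e-12)
    expect_gte(h, 0)
  }
})

test_that("transition probabilities normalize over eligible neighbours", {
  net <- chain_net()
  tab <- mk_table(c("S", "P1", "M"), c("up", "expressed", "down"),
                  c(1, 0, -1))
  paths <- filter_paths(enumerate_paths(net, "s2m"), tab)
  paths <- transition_probabilities(paths, tab, net)
  probs <- paths$trans_probs[[1]]
  expect_equal(probs[1], 1)  # S's only eligible neighbour is P1
  # P1 -> M against neighbours {S (score 2), M (score 2)}
  expect_equal(probs[2], 2 / 4)

  # two equally scored branches share mass 0.5/0.5
  y <- mk_ppi_net(ppi_edges(c("S", "A"), c("S", "B"), c("A", "M"),
                            c("B", "M")),
                  signaling = "S", metabolic = "M")
  tab_y <- mk_table(c("S", "A", "B", "M"),
                    c("up", "expressed", "expressed", "down"), c(1, 0, 0, -1))
  p_y <- transition_probabilities(filter_paths(enumerate_paths(y, "s2m"),
                                               tab_y), tab_y, y)
  first_steps <- vapply(p_y$trans_probs, `[[`, double(1), 1)
  expect_true(all(abs(first_steps[c(1, 2)] - 0.5) < 1e-12))

  # per-source distribution sums to 1 over eligible neighbours
  for (i in seq_len(nrow(p_y))) {
    nodes <- p_y$nodes[[i]]
    for (j in seq_len(length(nodes) - 1)) {
      nb <- panomix:::eligible_neighbours(y, nodes[j], tab_y, kind = "ppi")
      s_nb <- expression_score(nb, tab_y)
      expect_equal(sum(s_nb / sum(s_nb)), 1, tolerance = 1e-12)
    }
  }
})

test_that("node weights count satisfied selected predicates", {
  net <- mk_ppi_net(ppi_edges(c("A", "B")), crosstalk = "A",
                    rate_limiting = "B")
  tab <- mk_table(c("A", "B"), c("up", "expressed"))
  report <- tibble::tibble(id = "A", is_hub = TRUE, is_central = FALSE,
                           is_bottleneck = FALSE)
  cfg <- weight_config(c("deregulated_gene", "hub"))
  expect_equal(node_weight(c("A", "B"), cfg, tab, net, report), c(2L, 0L))
  cfg_bio <- weight_config(c("crosstalk_gene", "rate_limiting_enzyme"))
  expect_equal(node_weight(c("A", "B"), cfg_bio, tab, net), c(1L, 1L))
  expect_error(node_weight("A", cfg, tab, net, report = NULL),
               class = "panomix_bad_config")
  # weight never exceeds the number of selected options
  expect_true(all(node_weight(c("A", "B"), cfg, tab, net, report) <=
                    length(cfg$options)))

  expect_error(weight_config(character(0)), class = "panomix_bad_config")
  expect_error(weight_config(c("deregulated_gene", "crosstalk_gene",
                               "rate_limiting_enzyme", "hub",
                               "bottleneck")), class = "panomix_bad_config")
  expect_error(weight_config("not_an_option"))
})

test_that("path scores reduce correctly and grow with interior weight", {
  # forced single-edge XM path: PS = log e(X) + log e(M) + log 1
  xm <- mk_ppi_net(ppi_edges(c("S", "M")), signaling = "S", metabolic = "M")
  tab <- mk_table(c("S", "M"), c("up", "down"), c(1, -1))
  cfg <- weight_config("deregulated_gene")
  scored <- path_score(filter_paths(enumerate_paths(xm, "s2m"), tab),
                       cfg, tab, xm)
  e_dereg <- (1 + 1) / (2 + 1)
  expect_equal(scored$score, 2 * log(e_dereg) + log(1), tolerance = 1e-12)

  # identical twin routes, one interior crosstalk-flagged: higher score
  twin <- mk_ppi_net(ppi_edges(c("S", "A"), c("S", "B"), c("A", "M"),
                               c("B", "M")),
                     signaling = "S", metabolic = "M", crosstalk = "A")
  tab2 <- mk_table(c("S", "A", "B", "M"),
                   c("up", "expressed", "expressed", "down"), c(1, 0, 0, -1))
  scored2 <- path_score(filter_paths(enumerate_paths(twin, "s2m"), tab2),
                        weight_config(c("deregulated_gene", "crosstalk_gene")),
                        tab2, twin)
  via <- purrr::map_chr(scored2$nodes, 2)
  expect_gt(scored2$score[via == "A"], scored2$score[via == "B"])
})

test_that("importance selection standardizes scores with an inclusive z >= 1", {
  mk_paths <- function(scores) {
    structure(tibble::tibble(
      mode = "signaling_to_metabolic",
      regulator = NA_character_,
      nodes = lapply(seq_along(scores), function(i) c(sprintf("S%d", i), "M")),
      path_type = "XM", score = scores
    ), class = c("crosspath_result", class(tibble::tibble())),
    mode = "signaling_to_metabolic")
  }
  sel <- select_important(mk_paths(c(0, 0, 10)))
  expect_equal(sel$z[1], 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(sum(sel$important), 1)

  # z exactly 1 is selected
  sel2 <- select_important(mk_paths(c(0, 1, 2)))
  expect_equal(sel2$z, c(1, 0, -1))
  expect_true(sel2$important[1])
  expect_equal(sum(sel2$important), 1)
  expect_true(all(diff(sel2$z) <= 0))  # sorted by descending z

  expect_error(select_important(mk_paths(c(3, 3))),
               class = "panomix_degenerate")
  expect_error(select_important(mk_paths(7)), class = "panomix_degenerate")
})

test_that("path overlap compares signature sets within one mode", {
  net <- chain_net()
  tab <- mk_table(c("S", "P1", "M"), c("up", "expressed", "down"))
  a <- filter_paths(enumerate_paths(net, "s2m"), tab)
  same <- path_overlap(list(run1 = a, run2 = a))
  expect_equal(same$count[same$region == "run1&run2"], nrow(a))
  expect_equal(sum(same$count), nrow(a))

  b <- enumerate_paths(mk_ppi_net(ppi_edges(c("S2", "M2")),
                                  signaling = "S2", metabolic = "M2"), "s2m")
  disjoint <- path_overlap(list(x = a, y = b))
  expect_equal(disjoint$count[disjoint$region == "x&y"], 0)

  c_tf <- enumerate_paths(
    build_meta_interactome(list(
      ppi_edges(c("X", "M3")),
      tibble::tibble(source = "TF", target = "X", kind = "tf_target",
                     score = NA_real_, role = NA_character_)
    ), annotations = list(metabolic = "M3")), "tf2m")
  expect_error(path_overlap(list(a, c_tf)), class = "panomix_mode_mismatch")
})

test_that("enzyme metabolite listings come straight from the edge table", {
  edges <- list(
    ppi_edges(c("E1", "P")),
    tibble::tibble(source = c("E1", "E1"), target = c("glc", "g6p"),
                   kind = "enzyme_metabolite", score = NA_real_,
                   role = c("substrate", "product"))
  )
  net <- build_meta_interactome(edges)
  em <- enzyme_metabolites(net, c("E1", "P"))
  expect_equal(em$metabolites, c("g6p,glc", ""))
})
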
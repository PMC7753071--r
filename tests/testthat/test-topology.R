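test_that("centralities match hand-derived values on canonical graphs", {
  # star S_4: center degree 4, betweenness 1 (normalized), clustering 0
  star <- mk_ppi_net(ppi_edges(c("C0", "L1"), c("C0", "L2"), c("C0", "L3"),
                               c("C0", "L4")))
  cent <- compute_centralities(star)
  ctr <- cent[cent$id == "C0", ]
  expect_equal(ctr$degree, 4)
  expect_equal(ctr$betweenness, 1)
  expect_equal(ctr$clustering, 0)
  expect_equal(ctr$closeness, 1)

  tri <- mk_ppi_net(ppi_edges(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(compute_centralities(tri)$clustering, rep(1, 3))

  p3 <- path_net(c("x", "y", "z"))
  expect_equal(compute_centralities(p3)$betweenness[2], 1)
})

test_that("centralities agree with the exhaustive path-enumeration oracle", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    A <- random_adjacency(n, stats::runif(1, 0.3, 0.7))
    net <- net_from_adjacency(A)
    got <- compute_centralities(net)
    got <- got[order(match(got$id, sprintf("V%02d", 1:n))), ]
    want <- oracle_centralities(A)
    expect_equal(got$degree, unname(want$degree))
    expect_equal(got$clustering, want$clustering)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
  }
})

test_that("max-normalization rescales into [0,1] preserving the argmax", {
  expect_equal(normalize_index(c(4, 2, 1)), c(1, 0.5, 0.25))
  expect_equal(normalize_index(c(3, 3)), c(1, 1))
  set.seed(11)
  for (i in 1:100) {
    v <- stats::runif(sample(2:20, 1), 0, 10)
    out <- normalize_index(v)
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(which.max(out), which.max(v))
    expect_equal(max(out), 1)
  }
  expect_error(normalize_index(c(0, 0)), class = "panomix_degenerate")
})

test_that("z-scores center, scale, and are invariant to max-normalization", {
  expect_equal(to_zscores(c(0, 1)), c(-1, 1) / sqrt(2))
  set.seed(13)
  for (i in 1:50) {
    v <- stats::runif(sample(3:40, 1), 0, 5)
    if (stats::sd(v) == 0) next
    z <- to_zscores(v)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z), 1, tolerance = 1e-12)
    expect_equal(z, to_zscores(normalize_index(v)), tolerance = 1e-9)
  }
  expect_error(to_zscores(c(2, 2, 2)), class = "panomix_degenerate")
  expect_error(to_zscores(1), class = "panomix_degenerate")
})

test_that("the z-score PDF table is a proper density histogram", {
  set.seed(17)
  z <- stats::rnorm(1000)
  tab <- pdf_plot_data(z, 20)
  expect_equal(sum(tab$density * tab$width), 1, tolerance = 1e-12)
  expect_equal(sum(tab$count), 1000)
  # coarse agreement with the standard normal density
  cdf_hat <- cumsum(tab$density * tab$width)
  cdf <- stats::pnorm(tab$mid + tab$width / 2)
  expect_lt(max(abs(cdf_hat - cdf)), 0.1)

  single <- pdf_plot_data(0.3, 5)
  expect_equal(sum(single$count > 0), 1)
  expect_error(pdf_plot_data(z, 0))
})

test_that("cumulative centrality scores sum the neighbourhood combined scores", {
  # star S_3: leaves symmetric; hand sum of Eq-2-normalized components
  star <- mk_ppi_net(ppi_edges(c("C0", "L1"), c("C0", "L2"), c("C0", "L3")))
  cent <- compute_centralities(star)
  ccs <- compute_ccs(star, cent)
  c_center <- ccs$combined[ccs$id == "C0"]
  c_leaf <- ccs$combined[ccs$id == "L1"]
  expect_equal(ccs$ccs[ccs$id == "C0"], c_center + 3 * c_leaf)
  expect_equal(ccs$ccs[ccs$id == "L1"], c_leaf + c_center)

  # disconnected singleton pair: CCS reduces to own combined score
  iso <- mk_ppi_net(ppi_edges(c("a", "b"), c("c", "d")))
  ccs_iso <- compute_ccs(iso)
  expect_equal(ccs_iso$ccs, ccs_iso$combined +
                 c(ccs_iso$combined[2], ccs_iso$combined[1],
                   ccs_iso$combined[4], ccs_iso$combined[3]))
})

test_that("candidate restriction follows the omics driver", {
  net <- path_net(c("A", "B", "C"))
  tab <- mk_table(c("A", "B"), c("up", "expressed"))
  fn <- extract_filtered_network(net, tab, 2)
  # C is in the network but not in the omics data: not a candidate
  expect_setequal(candidate_nodes(fn, tab), c("A", "B"))

  # genomics-only run: altered nodes are the candidates
  alt_tab <- mark_alterations(deregulation_table(),
                              omics_profile(tibble::tibble(id = "A"),
                                            "genomics"))
  fn2 <- extract_filtered_network(net, alt_tab, 1)
  expect_equal(candidate_nodes(fn2, alt_tab), "A")

  # metabolite nodes are never candidates
  edges <- list(ppi_edges(c("E1", "P1")),
                tibble::tibble(source = "E1", target = "m1",
                               kind = "enzyme_metabolite", score = NA_real_,
                               role = "substrate"))
  net3 <- build_meta_interactome(edges)
  tab3 <- mk_table(c("E1", "P1", "m1"), c("up", "expressed", "expressed"))
  fn3 <- extract_filtered_network(net3, tab3, 1)
  expect_false("m1" %in% candidate_nodes(fn3, tab3))
})

test_that("TIN selection honours strict thresholds and count monotonicity", {
  s <- small_study(seed = 2)
  tab <- combine_primary(s$profiles[c("mrna", "mirna")])
  fn <- extract_filtered_network(s$net, tab, 1)
  rep <- topology_report(fn, tab)
  expect_setequal(select_hubs(rep, -Inf), rep$id)
  expect_equal(select_hubs(rep, Inf), character(0))
  expect_equal(select_bottlenecks(rep, Inf), character(0))
  # z-score columns standardize over the candidate set
  for (col in c("z_degree", "z_ccs", "z_betweenness")) {
    expect_equal(mean(rep[[col]]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(rep[[col]]), 1, tolerance = 1e-9)
  }
  thresholds <- seq(-2, 3, by = 0.25)
  for (sel in list(select_hubs, select_central_nodes, select_bottlenecks)) {
    counts <- vapply(thresholds, function(th) length(sel(rep, th)), double(1))
    expect_true(all(diff(counts) <= 0))
  }
  # IIN = nodes in at least two TIN categories = union of pairwise intersections
  hubs <- select_hubs(rep, 1); cns <- select_central_nodes(rep, 1)
  bns <- select_bottlenecks(rep, 1)
  pairwise <- sort(unique(c(intersect(hubs, cns), intersect(hubs, bns),
                            intersect(cns, bns))))
  expect_equal(identify_iins(rep), pairwise)
})

test_that("bridge of a barbell graph is a bottleneck", {
  barbell <- mk_ppi_net(ppi_edges(
    c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),   # left triangle
    c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),   # right triangle
    c("a1", "br"), c("br", "b1")                   # bridge node
  ))
  cent <- compute_centralities(barbell)
  A <- matrix(0L, 7, 7)
  ids <- sort(barbell$nodes$id)
  for (i in seq_len(nrow(barbell$edges))) {
    u <- match(barbell$edges$source[i], ids)
    v <- match(barbell$edges$target[i], ids)
    A[u, v] <- A[v, u] <- 1L
  }
  want <- oracle_centralities(A)
  expect_equal(cent$betweenness, want$betweenness, tolerance = 1e-9)
  expect_equal(which.max(cent$betweenness), match("br", cent$id))
  z <- to_zscores(normalize_index(cent$betweenness))
  expect_true(z[cent$id == "br"] > 1)
})

test_that("TIN subnetworks behave like seed expansion", {
  net <- mk_ppi_net(ppi_edges(c("C0", "L1"), c("C0", "L2"), c("L2", "L3")))
  tab <- mk_table(net$nodes$id, rep("up", 4))
  fn <- extract_filtered_network(net, tab, 2)
  sub1 <- tin_subnetwork(fn, "C0", 1)
  expect_setequal(sub1$nodes$id, c("C0", "L1", "L2"))
  sub2 <- tin_subnetwork(fn, "C0", 2)
  expect_true(all(sub1$nodes$id %in% sub2$nodes$id))
  expect_error(tin_subnetwork(fn, character(0)),
               class = "panomix_empty_seeds")
})

test_that("Venn region counts partition the union", {
  r <- overlap_report(list(one = c("A", "B"), two = c("B", "C")))
  expect_equal(r$count[r$region == "one"], 1)
  expect_equal(r$count[r$region == "two"], 1)
  expect_equal(r$count[r$region == "one&two"], 1)

  same <- overlap_report(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(same$count[same$region == "x&y"], 2)
  expect_equal(sum(same$count), 2)

  set.seed(19)
  sets <- list(a = sample(letters, 10), b = sample(letters, 12),
               c = sample(letters, 8))
  r3 <- overlap_report(sets)
  expect_equal(nrow(r3), 7)
  expect_equal(sum(r3$count), length(unique(unlist(sets))))
  expect_error(overlap_report(list(1:2, 2:3, 3:4, 4:5)),
               class = "panomix_bad_arity")
})
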
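test_that("pearson_with_p matches the direct-formula oracle and frozen references", {
  # identity and orthogonal-contrast corner cases
  v <- c(1, 3, 2, 5, 4)
  res <- pearson_with_p(v, v)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  res <- pearson_with_p(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(res$r, 0)
  expect_equal(res$p, 1)

  # frozen independent reference (scipy, direct covariance formula + t CDF)
  res <- pearson_with_p(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
  expect_equal(res$r, 0.8219949365267865, tolerance = 1e-14)
  expect_equal(res$p, 0.08770664700806556, tolerance = 1e-14)

  # random small vectors against the brute-force oracle and cor.test
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- pearson_with_p(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("pearson correlation is symmetric and affine-equivariant", {
  set.seed(11)
  x <- rnorm(8)
  y <- rnorm(8)
  expect_identical(pearson_with_p(x, y), pearson_with_p(y, x))
  base <- pearson_with_p(x, y)
  expect_equal(pearson_with_p(3 * x + 2, y)$r, base$r, tolerance = 1e-12)
  expect_equal(pearson_with_p(-2 * x + 1, y)$r, -base$r, tolerance = 1e-12)
})

test_that("zero-variance inputs are flagged degenerate, not fatal", {
  res <- pearson_with_p(rep(1, 5), rnorm(5))
  expect_true(res$degenerate)
  expect_true(is.na(res$r) && is.na(res$p))
})

test_that("fisher z difference test follows its closed form", {
  expect_equal(fisher_z_diff_test(0.6, 30, 0.6, 12), 1)
  expect_lt(fisher_z_diff_test(0.9, 200, 0.0, 200), 1e-6)
  # frozen independent evaluation of the closed form (scipy)
  expect_equal(fisher_z_diff_test(0.75, 9, -0.48, 9), 0.00956855450571319,
               tolerance = 1e-10)
  # symmetry in the two correlations
  expect_equal(fisher_z_diff_test(0.3, 20, -0.2, 25),
               fisher_z_diff_test(-0.2, 25, 0.3, 20))
  expect_warning(p <- fisher_z_diff_test(1, 10, 0.2, 10), "clamped")
  expect_true(p > 0 && p < 1)
})

test_that("fisher z p-values are uniform under the null", {
  set.seed(202)
  n <- 40
  rho <- 0.5
  p <- replicate(2000, {
    x1 <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
    x2 <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
    fisher_z_diff_test(cor(x1)[1, 2], n, cor(x2)[1, 2], n)
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches brute-force step-up enumeration", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p))          # q >= p elementwise
    expect_equal(order(q[order(p)]), seq_along(p))  # order preserved
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("candidate filter keeps pairs reaching the threshold in either condition", {
  pairs <- data.frame(
    r_control = c(0.4, -0.6, 0.2, NA, 0.5),
    r_exposed = c(0.45, 0.1, 0.9, 0.8, -0.5)
  )
  kept <- candidate_filter(pairs, coexp_config(r_threshold = 0.5))
  expect_equal(rownames(kept), c("2", "3", "5"))  # NA row (degenerate) dropped
  expect_equal(nrow(candidate_filter(pairs[0, ])), 0)
})

test_that("edge classes follow the sign-flip taxonomy", {
  expect_equal(classify_edge(0.75, -0.48),
               data.frame(delta_r = 1.23, edge_class = "switched_opposite"))
  expect_equal(classify_edge(0.6, 0.6)$edge_class, "same_signed")
  expect_equal(classify_edge(0.3, -0.3)$edge_class, "diff_signed")
  # boundary: a flip with delta_r exactly at the threshold is diff_signed
  expect_equal(classify_edge(0.5, -0.5)$edge_class, "diff_signed")
  # zero counts as non-negative
  expect_equal(classify_edge(0, -0.6)$edge_class, "diff_signed")
  expect_equal(classify_edge(0, 0.6)$edge_class, "same_signed")
  # exhaustive and mutually exclusive over a grid
  grid <- expand.grid(rc = seq(-0.95, 0.95, by = 0.19),
                      re = seq(-0.95, 0.95, by = 0.19))
  cls <- classify_edge(grid$rc, grid$re)$edge_class
  expect_true(all(cls %in% c("switched_opposite", "diff_signed", "same_signed")))
  flip <- (grid$rc >= 0) != (grid$re >= 0)
  expect_true(all(cls[!flip] == "same_signed"))
  expect_true(all(cls[flip] != "same_signed"))
})

test_that("build_dc_network recovers planted differential pairs with few false edges", {
  design <- expression_design(100, 50, flip_pairs_10(), seed = 42)
  sim <- simulate_expression(design)
  net <- build_dc_network(sim$matrix)
  hits <- pair_key(sim$truth) %in% pair_key(net$edges)
  expect_gte(sum(hits), 9)
  false_edges <- sum(!pair_key(net$edges) %in% pair_key(sim$truth))
  n_unplanted <- choose(100, 2) - 10
  expect_lte(false_edges / n_unplanted, 0.01)
  # every edge passed the filter and the significance cut
  expect_true(all(abs(net$edges$r_control) >= 0.5 |
                    abs(net$edges$r_exposed) >= 0.5))
  expect_true(all(net$edges$q_diff < 0.05))
  expect_true(all(net$edges$q_diff >= net$edges$p_diff))
})

test_that("a null matrix yields an FDR-controlled (near-empty) edge set", {
  design <- expression_design(60, 20, seed = 5)
  sim <- simulate_expression(design)
  net <- build_dc_network(sim$matrix)
  expect_lte(nrow(net$edges) / choose(60, 2), 0.05)
})

test_that("degenerate inputs are handled: missing genes, tiny networks, flat genes", {
  design <- expression_design(10, 10, seed = 2)
  sim <- simulate_expression(design)
  w <- capture_warnings(net <- build_dc_network(sim$matrix,
                                                genes = c("g1", "nope")))
  expect_match(w, "nope", all = FALSE)
  expect_match(w, "fewer than 2", all = FALSE)
  expect_equal(nrow(net$edges), 0)
  # case-insensitive gene matching
  net2 <- build_dc_network(sim$matrix, genes = c("G1", "G2", "G3"))
  expect_setequal(net2$nodes, c("g1", "g2", "g3"))
  # a flat gene is excluded pairwise, not fatal
  m <- sim$matrix
  m$values["g1", ] <- 7
  expect_message(net3 <- build_dc_network(m), "zero-variance")
  expect_false("g1" %in% c(net3$pairs$gene_a, net3$pairs$gene_b))
})

test_that("driver scoring matches the exact binomial tail and finds a planted hub", {
  # hand-built network: gene h has 5/5 significant links, global rate 0.1
  others <- paste0("x", 1:10)
  cand <- data.frame(
    gene_a = c(rep("h", 5), t(combn(others, 2))[1:45, 1]),
    gene_b = c(paste0("s", 1:5), t(combn(others, 2))[1:45, 2]),
    candidate = TRUE, stringsAsFactors = FALSE
  )
  edges <- cand[1:5, ]
  net <- structure(list(pairs = cand, edges = edges,
                        config = coexp_config()), class = "dc_network")
  dr <- identify_drivers(net)
  h <- dr[dr$gene == "h", ]
  expect_equal(h$p0, 0.1)
  expect_equal(h$p_binom, 1e-5, tolerance = 1e-12)
  expect_equal(h$p_binom, oracle_binom_tail(5, 5, 0.1), tolerance = 1e-12)
  # k = 0 genes get P(X >= 0) = 1
  expect_true(all(dr$p_binom[dr$k_dc == 0] == 1))

  # planted hub recovery on a simulated matrix
  sim <- simulate_expression(hub_design())
  net <- build_dc_network(sim$matrix)
  dr <- identify_drivers(net)
  expect_true(dr$is_driver[dr$gene == "g1"])
  expect_equal(dr$gene[1], "g1")
  # attribution marks the hub on its edges
  net <- attribute_drivers(net, dr)
  hub_edges <- net$edges$gene_a == "g1" | net$edges$gene_b == "g1"
  expect_true(all(grepl("g1", net$edges$driver[hub_edges])))
})

test_that("TF annotation reports common regulators, in-pair TFs, and a ranking", {
  tf <- read_tf_table(extdata("tf_interactions_mouse.tsv"))
  edges <- data.frame(
    gene_a = c("Dkk1", "Ikzf1", "Dkk1"), gene_b = c("Vegfa", "Kdr", "Trp53"),
    stringsAsFactors = FALSE
  )
  net <- structure(list(edges = edges), class = "dc_network")
  ann <- annotate_tf_regulators(net, tf)
  expect_equal(ann$edges$common_tfs[1], "Bmi1,Ets1,Runx2")
  expect_true(ann$edges$tf_in_pair[2])    # Ikzf1 itself regulates Kdr
  expect_false(ann$edges$tf_in_pair[1])
  # a TF regulating only one member is not common
  expect_false(grepl("Trp53", ann$edges$common_tfs[1]))
  expect_true(all(ann$ranking$n_edges[1] >= ann$ranking$n_edges))
  # empty table: all annotations empty
  empty <- annotate_tf_regulators(net, tf[0, ])
  expect_true(all(empty$edges$n_common == 0))
  expect_equal(nrow(empty$ranking), 0)
})

test_that("per-timepoint pooling combines within-timepoint correlations", {
  pp <- data.frame(gene_a = c("g1", "g2", "g3"), gene_b = c("g7", "g8", "g9"),
                   r_control = c(0.75, -0.70, 0.80),
                   r_exposed = c(-0.48, 0.55, -0.52))
  design <- expression_design(12, 24, pp, seed = 9)
  sim <- simulate_expression(design)
  m <- sim$matrix
  m$timepoint <- rep(rep(c(24, 48, 72), each = 8), 2)
  net_p <- build_dc_network(m, config = coexp_config(pooling = "per_timepoint"))
  net_0 <- build_dc_network(m)
  # planted flips survive either pooling; effective n is reduced
  expect_gte(sum(pair_key(sim$truth) %in% pair_key(net_p$edges)), 2)
  expect_lt(net_p$n_control, net_0$n_control)
})
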
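test_that("build_adjacency counts lattice neighbors correctly", {
  expect_equal(nrow(build_adjacency(gen_spot_lattice(1, 2))$edges), 1L)
  expect_equal(nrow(build_adjacency(gen_spot_lattice(3, 3), "rook")$edges), 12L)
  # brute-force neighbor enumeration gives 20 queen edges on 3x3
  expect_equal(nrow(build_adjacency(gen_spot_lattice(3, 3), "queen")$edges), 20L)

  # rook edge count r(c-1) + c(r-1) on full grids
  for (rc in list(c(2, 5), c(4, 4), c(3, 7))) {
    g <- gen_spot_lattice(rc[1], rc[2])
    expect_equal(nrow(build_adjacency(g)$edges),
                 rc[1] * (rc[2] - 1) + rc[2] * (rc[1] - 1))
  }
  expect_error(build_adjacency(gen_spot_lattice(2, 2), "bishop"))

  # partial lattices: only present spots are connected
  g <- gen_spot_lattice(2, 2)
  g_sparse <- spot_grid(g$spots[-2, ], 2, 2)  # drop (1,0)
  expect_equal(nrow(build_adjacency(g_sparse)$edges), 2L)
})

test_that("assign_pair_labels resolves co-positivity by coordinate parity", {
  g <- gen_spot_lattice(4, 4)
  both <- rep(TRUE, 16)
  calls <- make_calls(g, list(A = both, B = both))
  ll <- assign_pair_labels(calls, c("A", "B"), g)
  even <- (g$spots$x + g$spots$y) %% 2 == 0
  # (0,0) even -> A under even_gets = "A"; (2,3) odd -> B
  expect_equal(as.character(ll$labels[g$spots$x == 0 & g$spots$y == 0]), "A")
  expect_equal(as.character(ll$labels[g$spots$x == 2 & g$spots$y == 3]), "B")
  expect_equal(as.character(ll$labels), ifelse(even, "A", "B"))
  expect_true(all(ll$assignment_record %in% c("both_even", "both_odd")))

  # swapping the parity convention swaps every co-positive label
  ll_b <- assign_pair_labels(calls, c("A", "B"), g, even_gets = "B")
  expect_equal(as.character(ll_b$labels), ifelse(even, "B", "A"))

  # single-positive and background spots ignore parity
  calls2 <- make_calls(g, list(A = g$spots$x == 0, B = g$spots$x == 3))
  ll2 <- assign_pair_labels(calls2, c("A", "B"), g)
  expect_equal(as.character(ll2$labels[g$spots$x == 0]), rep("A", 4))
  expect_equal(as.character(ll2$labels[g$spots$x == 3]), rep("B", 4))
  expect_equal(as.character(ll2$labels[g$spots$x %in% 1:2]), rep("BG", 8))
  expect_equal(unique(ll2$assignment_record[g$spots$x %in% 1:2]), "neither")

  expect_error(assign_pair_labels(calls, c("A", "Z"), g), "not found")
})

test_that("observed_joins counts only heterogeneous A-B edges", {
  g2 <- gen_spot_lattice(1, 2)
  graph2 <- build_adjacency(g2)
  ll_ab <- assign_pair_labels(
    make_calls(g2, list(A = c(TRUE, FALSE), B = c(FALSE, TRUE))),
    c("A", "B"), g2)
  expect_equal(observed_joins(ll_ab, graph2), 1L)

  ll_aa <- assign_pair_labels(
    make_calls(g2, list(A = c(TRUE, TRUE), B = c(FALSE, FALSE))),
    c("A", "B"), g2)
  expect_equal(observed_joins(ll_aa, graph2), 0L)

  # 4x4 perfect checkerboard, rook: every one of the 24 edges heterogeneous
  g4 <- gen_spot_lattice(4, 4)
  both <- rep(TRUE, 16)
  ll_cb <- assign_pair_labels(make_calls(g4, list(A = both, B = both)),
                              c("A", "B"), g4)
  graph4 <- build_adjacency(g4)
  expect_equal(nrow(graph4$edges), 24L)
  expect_equal(observed_joins(ll_cb, graph4), 24L)

  # conservation: AB + AA + BB + BG-touching joins = |edges| for any labeling
  set.seed(8)
  for (i in 1:10) {
    lab <- factor(sample(c("A", "B", "BG"), 16, replace = TRUE),
                  levels = c("A", "B", "BG"))
    l1 <- lab[graph4$edges[, 1]]
    l2 <- lab[graph4$edges[, 2]]
    j_ab <- sum((l1 == "A" & l2 == "B") | (l1 == "B" & l2 == "A"))
    j_aa <- sum(l1 == "A" & l2 == "A")
    j_bb <- sum(l1 == "B" & l2 == "B")
    j_bg <- sum(l1 == "BG" | l2 == "BG")
    expect_equal(j_ab + j_aa + j_bb + j_bg, nrow(graph4$edges))
  }
})

test_that("analytic null collapses to the closed form on small grids", {
  # 1x2 grid, one A one B: mean = 2*1*1*1/(2*1) = 1, and the permutation
  # null is degenerate (every permutation yields J = 1)
  g2 <- gen_spot_lattice(1, 2)
  ll <- assign_pair_labels(
    make_calls(g2, list(A = c(TRUE, FALSE), B = c(FALSE, TRUE))),
    c("A", "B"), g2)
  graph2 <- build_adjacency(g2)
  an <- analytic_null(ll, graph2)
  expect_equal(an$null_mean, 1)
  expect_equal(an$null_sd, 0)
  expect_error(permutation_null(ll, graph2, 99, seed = 1),
               class = "spatialcoloc_degenerate_null")

  # 3x3 rook (m = 12, n = 9), 3 A, 3 B: mean = 2*12*9/72 = 3
  g9 <- gen_spot_lattice(3, 3)
  ll9 <- assign_pair_labels(
    make_calls(g9, list(A = c(rep(TRUE, 3), rep(FALSE, 6)),
                        B = c(rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 3)))),
    c("A", "B"), g9)
  expect_equal(analytic_null(ll9, build_adjacency(g9))$null_mean, 3)
})

test_that("permutation null is seeded, reproducible and matches the analytic mean", {
  g <- gen_spot_lattice(3, 3)
  graph <- build_adjacency(g)
  ll <- assign_pair_labels(
    make_calls(g, list(A = c(rep(TRUE, 3), rep(FALSE, 6)),
                       B = c(rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 3)))),
    c("A", "B"), g)

  p1 <- permutation_null(ll, graph, n_perm = 500, seed = 42)
  p2 <- permutation_null(ll, graph, n_perm = 500, seed = 42)
  expect_identical(p1, p2)
  expect_error(permutation_null(ll, graph, n_perm = 10, seed = 1), "at least 99")

  # agreement with the analytic mean on random configurations, within 3 MC SE
  set.seed(99)
  for (i in 1:10) {
    na <- sample(2:5, 1); nb <- sample(2:min(4L, 9L - na), 1)
    lab <- sample(c(rep(TRUE, na), rep(FALSE, 9 - na)))
    labb <- rep(FALSE, 9)
    labb[sample(which(!lab), nb)] <- TRUE
    lli <- assign_pair_labels(make_calls(g, list(A = lab, B = labb)),
                              c("A", "B"), g)
    an <- analytic_null(lli, graph)
    pn <- permutation_null(lli, graph, n_perm = 2000, seed = i)
    expect_lt(abs(pn$null_mean - an$null_mean),
              3 * an$null_sd / sqrt(2000) + 1e-12)
  }
})

test_that("joincount_z reports degenerate nulls as not-computable", {
  g <- gen_spot_lattice(1, 2)
  calls <- make_calls(g, list(A = c(TRUE, FALSE), B = c(FALSE, TRUE)))
  r <- joincount_z(calls, g, c("A", "B"), n_perm = 99, seed = 1)
  expect_false(r$computable)
  expect_true(is.na(r$z))
  expect_match(r$reason, "degenerate")

  # a type entirely absent is degenerate too, not silently zero
  calls0 <- make_calls(gen_spot_lattice(3, 3),
                       list(A = rep(TRUE, 9), B = rep(FALSE, 9)))
  r0 <- joincount_z(calls0, gen_spot_lattice(3, 3), c("A", "B"),
                    n_perm = 99, seed = 1)
  expect_false(r0$computable)
})

test_that("pairwise sweep enumerates unordered pairs deterministically", {
  g <- gen_spot_lattice(6, 6)
  set.seed(3)
  calls <- make_calls(g, list(
    t1 = sample(c(TRUE, FALSE), 36, TRUE),
    t2 = sample(c(TRUE, FALSE), 36, TRUE),
    t3 = sample(c(TRUE, FALSE), 36, TRUE),
    t4 = sample(c(TRUE, FALSE), 36, TRUE)))

  two <- pairwise_joincount_matrix(
    structure(list(positive = calls$positive[, 1:2, drop = FALSE],
                   quantile = 0.75), class = "positivity_calls"),
    g, n_perm = 99, seed = 5)
  expect_length(two, 1L)

  res <- pairwise_joincount_matrix(calls, g, n_perm = 99, seed = 5)
  expect_length(res, 6L)  # C(4,2)
  expect_equal(names(res), c("t1|t2", "t1|t3", "t1|t4",
                             "t2|t3", "t2|t4", "t3|t4"))
  res2 <- pairwise_joincount_matrix(calls, g, n_perm = 99, seed = 5)
  expect_identical(joincount_table(res), joincount_table(res2))

  # |z| invariant to swapping the pair together with the parity convention
  r_ab <- joincount_z(calls, g, c("t1", "t2"), n_perm = 199, seed = 7,
                      even_gets = "A")
  r_ba <- joincount_z(calls, g, c("t2", "t1"), n_perm = 199, seed = 7,
                      even_gets = "B")
  expect_equal(abs(r_ab$z), abs(r_ba$z))
})

test_that("z sign tracks the generated spatial pattern", {
  g <- gen_spot_lattice(20, 20)
  # dispersed: only boundary joins -> below the null mean
  fl <- gen_pattern_pair(g, c("A", "B"), "dispersed", seed = 21)
  r_disp <- joincount_z(call_positivity(field_scores(fl)), g, c("A", "B"),
                        n_perm = 199, seed = 21)
  expect_lt(r_disp$z, 0)

  # aggregated: shared blobs checkerboarded -> far above the null mean
  fl <- gen_pattern_pair(g, c("A", "B"), "aggregated",
                         params = list(sigma = 2), seed = 21)
  r_agg <- joincount_z(call_positivity(field_scores(fl)), g, c("A", "B"),
                       n_perm = 199, seed = 21)
  expect_gt(r_agg$z, 3)

  # analytic and permutation z agree on the same labeling
  r_an <- joincount_z(call_positivity(field_scores(fl)), g, c("A", "B"),
                      null_method = "analytic")
  expect_equal(r_an$z, r_agg$z, tolerance = 0.1)
})
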
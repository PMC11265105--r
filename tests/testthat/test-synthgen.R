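test_that("gen_spot_lattice enumerates the requested lattice", {
  g <- gen_spot_lattice(1, 2)
  expect_equal(nrow(g$spots), 2L)
  expect_equal(g$spots$x, c(0L, 1L))
  expect_equal(g$spots$y, c(0L, 0L))

  g9 <- gen_spot_lattice(3, 3)
  expect_equal(nrow(g9$spots), 9L)
  expect_setequal(paste(g9$spots$x, g9$spots$y),
                  paste(rep(0:2, 3), rep(0:2, each = 3)))
  expect_false(anyDuplicated(g9$spots$spot_id) > 0)

  expect_equal(nrow(gen_spot_lattice(20, 20)$spots), 400L)
  expect_error(gen_spot_lattice(0, 3), "positive")
})

test_that("abundance fields are deterministic under seed and pattern-shaped", {
  g <- gen_spot_lattice(2, 2)
  f1 <- gen_celltype_field(g, "A", "random", seed = 1)
  f2 <- gen_celltype_field(g, "A", "random", seed = 1)
  expect_identical(f1$values, f2$values)
  expect_false(identical(
    f1$values, gen_celltype_field(g, "A", "random", seed = 2)$values))
  expect_error(gen_celltype_field(g, "A", "swirl", seed = 1), "unknown pattern")
  expect_error(gen_celltype_field(g, "A", "random"), "seed")

  # dispersed: A-mass and B-mass on disjoint column ranges by construction
  g10 <- gen_spot_lattice(10, 10)
  pair <- gen_pattern_pair(g10, c("A", "B"), "dispersed", seed = 3)
  cols_a <- g10$spots$x[pair$A$values > 0]
  cols_b <- g10$spots$x[pair$B$values > 0]
  expect_length(intersect(cols_a, cols_b), 0)
  expect_true(all(pair$A$values >= 0) && all(pair$B$values >= 0))
})

test_that("aggregated fields show positive neighbor covariance, random fields do not", {
  g <- gen_spot_lattice(20, 20)
  f <- gen_celltype_field(g, "A", "aggregated", list(sigma = 2), seed = 4)
  expect_gt(neighbor_cov(f), 0)

  # null fidelity: random fields stay inside the 95% permutation envelope
  # of the neighbor covariance in >= 90% of seeded replicates
  inside <- vapply(1:100, function(s) {
    fr <- gen_celltype_field(g, "A", "random", seed = s)
    obs <- neighbor_cov(fr)
    null <- vapply(1:199, function(i) {
      shuffled <- fr
      shuffled$values <- sample(fr$values)
      neighbor_cov(shuffled)
    }, numeric(1))
    abs(obs) <= stats::quantile(abs(null), 0.95)
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("expression generator follows the stated negative-binomial model", {
  g <- gen_spot_lattice(10, 20)  # 200 spots
  f <- gen_celltype_field(g, "A", "random", seed = 1)
  sets <- list(A = sprintf("mk_%02d", 1:10))

  # determinism
  e1 <- gen_expression_matrix(g, list(f), sets, seed = 9)
  e2 <- gen_expression_matrix(g, list(f), sets, seed = 9)
  expect_identical(unclass(e1), unclass(e2))
  expect_true(all(e1 >= 0))
  expect_error(gen_expression_matrix(g, list(f), list(B = "x"), seed = 1),
               "missing marker set")

  # effect_size = 0: marker and background genes identically distributed
  e0 <- gen_expression_matrix(g, list(f), sets, effect_size = 0, seed = 10)
  p <- stats::wilcox.test(as.vector(e0[sets$A, ]),
                          as.vector(e0[grep("^bg_", rownames(e0)), ]))$p.value
  expect_gt(p, 0.01)

  # binary abundance, effect_size = 5: marker mean in positive spots ~ 6x
  # baseline, within 3 standard errors of the NB moment prediction
  fb <- f
  fb$values <- as.numeric(f$values > stats::median(f$values))
  baseline <- 2; disp <- 2; eff <- 5
  eb <- gen_expression_matrix(g, list(fb), sets, baseline_mean = baseline,
                              effect_size = eff, dispersion = disp, seed = 11)
  pos_counts <- as.vector(eb[sets$A, fb$values == 1])
  mu <- baseline * (1 + eff)
  se <- sqrt((mu + mu^2 / disp) / length(pos_counts))
  expect_lt(abs(mean(pos_counts) - mu), 3 * se)
})

test_that("channel pairs honor their requested overlap geometry", {
  # zero overlap: disjoint signal supports
  cp0 <- gen_channel_pair(c(12, 12), 100, 0, 100, 0, seed = 1)
  expect_false(any(cp0$mask_a_true & cp0$mask_b_true))
  expect_equal(cp0$truth$sum_a_in_b, 0)

  # full containment: channel-a support inside channel-b support
  cp1 <- gen_channel_pair(c(12, 12), 100, 1, 100, 0.5, seed = 1)
  expect_true(all(which(cp1$mask_a_true) %in% which(cp1$mask_b_true)))

  # truth invariants always satisfied
  for (s in 1:10) {
    fr <- stats::runif(2)
    cp <- gen_channel_pair(c(9, 15), 50, fr[1], 80, fr[2], seed = s)
    expect_lte(cp$truth$sum_a_in_b, cp$truth$sum_a_total)
    expect_gte(cp$truth$sum_a_in_b, 0)
    expect_lte(cp$truth$sum_b_in_a, cp$truth$sum_b_total)
  }
  expect_error(gen_channel_pair(c(2, 2), 1, 0.5, 1, 0.5, seed = 1), "3 x 3")
})

test_that("score tables realize their distribution contract", {
  s <- gen_score_table(8, 1, "distinct", seed = 1)
  expect_equal(length(unique(as.vector(s))), 8L)

  s1 <- gen_score_table(200, 1, "distinct", seed = 7)
  s2 <- gen_score_table(200, 1, "distinct", seed = 7)
  expect_identical(unclass(s1), unclass(s2))

  sc <- gen_score_table(100, 1, "constant", seed = 1)
  expect_equal(length(unique(as.vector(sc))), 1L)

  # tied: duplicates straddle the 75th-percentile nearest-rank value
  st <- gen_score_table(100, 1, "tied", seed = 3)
  thr <- sort(st[, 1])[ceiling(0.75 * 100)]
  expect_gte(sum(st[, 1] == thr), 2)

  expect_error(gen_score_table(3, 1, "distinct", seed = 1), "at least 4")
})
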
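# Independent oracles used across the suite.  These deliberately re-derive
# each statistic by brute force (explicit loops, full enumeration) so that the
# package's vectorized implementations are checked against something that
# shares no code with them.

# Loop-based single-sample enrichment running sum: rank genes by descending
# expression (stable), walk the ranking accumulating the weighted in-set and
# unweighted out-of-set ECDFs, and total their difference.
brute_ssgsea <- function(expression, gene_set, alpha) {
  n <- length(expression)
  ord <- order(-expression, seq_len(n))
  inset <- names(expression)[ord] %in% gene_set
  total_w <- 0
  for (i in seq_len(n)) if (inset[i]) total_w <- total_w + (n - i + 1)^alpha
  n_out <- n - sum(inset)
  cin <- 0; cout <- 0; score <- 0
  for (i in seq_len(n)) {
    if (inset[i]) cin <- cin + (n - i + 1)^alpha / total_w
    else cout <- cout + 1 / n_out
    score <- score + cin - cout
  }
  score
}

# Exhaustive enumeration of the heterogeneous join-count distribution under
# the nonfree-sampling null: every distinguishable placement of n_a A's and
# n_b B's (rest background) over the n sites.
enum_join_moments <- function(graph, n_a, n_b) {
  n <- graph$n
  e1 <- graph$edges[, 1]; e2 <- graph$edges[, 2]
  js <- integer(0)
  a_sets <- utils::combn(n, n_a, simplify = FALSE)
  for (a in a_sets) {
    rest <- setdiff(seq_len(n), a)
    b_sets <- utils::combn(length(rest), n_b, simplify = FALSE)
    for (bi in b_sets) {
      lab <- integer(n) + 3L
      lab[a] <- 1L
      lab[rest[bi]] <- 2L
      js <- c(js, sum(lab[e1] + lab[e2] == 3L))
    }
  }
  list(mean = mean(js), var = mean(js^2) - mean(js)^2, values = js)
}

# Positivity-calls object from per-type logical vectors aligned to the grid.
make_calls <- function(grid, pos_list) {
  m <- do.call(cbind, pos_list)
  rownames(m) <- grid$spots$spot_id
  structure(list(positive = m,
                 thresholds = stats::setNames(rep(0, ncol(m)), colnames(m)),
                 quantile = 0.75),
            class = "positivity_calls")
}

# Brute-force rook-neighbor covariance of a field (Moran-style numerator):
# positive for spatially aggregated fields, ~0 for i.i.d. ones.
neighbor_cov <- function(field) {
  grid <- field$grid_ref
  v <- field$values - mean(field$values)
  e <- build_adjacency(grid, "rook")$edges
  mean(v[e[, 1]] * v[e[, 2]])
}

# Brute-force Otsu: try all 256 bin-edge thresholds, maximize between-class
# variance computed from first principles on the raw pixels.
brute_otsu <- function(channel, n_bins = 256L) {
  edges <- seq(min(channel), max(channel), length.out = n_bins + 1L)
  best <- -Inf; best_t <- NA_real_
  for (t in edges[-c(1L, n_bins + 1L)]) {
    lo <- channel[channel <= t]; hi <- channel[channel > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(channel)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}
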
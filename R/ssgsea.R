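#' Score matrix container
#'
#' Per-spot, per-cell-type enrichment scores: a numeric matrix with spots in
#' rows and cell types (gene-set names) in columns, all entries finite.
#'
#' @param scores numeric matrix spots x cell types with dimnames.
#' @return The matrix with class `score_matrix` prepended.
#' @export
new_score_matrix <- function(scores) {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (any(!is.finite(scores))) stop_invalid("scores must be finite")
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop_invalid("score matrix needs spot ids (rownames) and cell types (colnames)")
  }
  class(scores) <- c("score_matrix", "matrix", "array")
  scores
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Rank-based weighted running-sum enrichment of one gene set in one spot's
#' expression profile.  Genes are ranked by descending expression, ties
#' broken by the stable order of the input vector.  Walking down the
#' ranking, the in-set empirical CDF steps by `|r|^alpha / sum(|r|^alpha)`
#' at each in-set gene — `r` being the rank weight `N - position + 1`, so the
#' top-ranked gene carries weight `N` — and the out-of-set CDF steps by
#' `1 / (N - |set|)` at each out-of-set gene.  The score is the sum of the
#' (in-set minus out-of-set) CDF difference over all `N` positions: positive
#' when the set concentrates at the top of the ranking.  At `alpha = 0` this
#' is the unweighted Kolmogorov-style running sum.  The score depends on the
#' expression vector only through its ranks, so any strictly monotone
#' transform of the input leaves it unchanged.
#'
#' @param expression named numeric vector, one spot's expression over all
#'   measured genes.
#' @param gene_set character vector of gene symbols (non-empty, no
#'   duplicates).
#' @param alpha rank-weight exponent, `>= 0`; default 0.25.
#' @return A single numeric score.
#' @export
ssgsea_score <- function(expression, gene_set, alpha = 0.25) {
  if (length(gene_set) == 0L) stop_invalid("empty gene set")
  if (anyDuplicated(gene_set)) stop_invalid("gene set contains duplicate genes")
  if (is.null(names(expression))) stop_invalid("expression vector must be named by gene")
  if (!is.numeric(alpha) || alpha < 0) stop_invalid("`alpha` must be >= 0")
  genes <- names(expression)
  in_set_gene <- genes %in% gene_set
  n_in <- sum(in_set_gene)
  if (n_in == 0L) stop_invalid("gene set not measured in the expression vector")
  n <- length(expression)
  if (n_in == n) {
    stop_invalid("degenerate set: gene set covers every measured gene")
  }
  ord <- order(-expression, seq_len(n))  # descending, stable in input order
  in_set <- in_set_gene[ord]
  w <- (n - seq_len(n) + 1)^alpha
  w[!in_set] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (n - n_in)
  sum(p_in - p_out)
}

#' Score every spot against every gene set
#'
#' Applies [ssgsea_score()] per (spot, set); columns follow the set order of
#' the collection.  Errors raised for a particular set are rethrown with the
#' set name attached.
#'
#' @param expr an `expression_matrix` (genes x spots) or any numeric matrix
#'   with gene rownames and spot colnames.
#' @param sets a [gene_set_collection()] or a named list of gene vectors.
#' @param alpha rank-weight exponent passed to [ssgsea_score()].
#' @return A `score_matrix` (spots x sets).
#' @export
score_celltypes <- function(expr, sets, alpha = 0.25) {
  stopifnot(is.matrix(expr))
  sets <- as_gene_set_list(sets)
  scores <- matrix(NA_real_, ncol(expr), length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  for (s in names(sets)) {
    scores[, s] <- tryCatch(
      apply(expr, 2, ssgsea_score, gene_set = sets[[s]], alpha = alpha),
      error = function(e) {
        stop_invalid("scoring set '%s': %s", s, conditionMessage(e))
      }
    )
  }
  new_score_matrix(scores)
}

#' Top-quartile positivity calls
#'
#' Per cell type, the threshold is the nearest-rank quantile of that type's
#' scores across all spots of the sample (for the default `quantile = 0.75`,
#' the 75th-percentile score), and a spot is called positive when its score
#' strictly exceeds the threshold — "greater than the top 25%".  Strictness
#' means a constant score column calls nothing positive, and with all-distinct
#' scores and `n` divisible by 4 exactly `n/4` spots are positive.  A spot may
#' be positive for several cell types simultaneously.  Thresholds are always
#' per sample: pooling spots from different samples changes the rule.
#'
#' @param scores a `score_matrix` (spots x cell types).
#' @param quantile threshold quantile in (0, 1); default 0.75.
#' @return A `positivity_calls` object: list with logical matrix `positive`
#'   (spots x cell types), numeric `thresholds` (one per type), and
#'   `quantile`.
#' @export
call_positivity <- function(scores, quantile = 0.75) {
  stopifnot(is.matrix(scores))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1) {
    stop_invalid("`quantile` must lie strictly between 0 and 1")
  }
  n <- nrow(scores)
  if (n < 2L) stop_invalid("positivity needs at least 2 spots")
  thresholds <- apply(scores, 2, function(s) {
    sort(s)[ceiling(quantile * n)]  # nearest-rank quantile
  })
  positive <- sweep(unclass(scores), 2, thresholds, ">")
  structure(
    list(positive = positive, thresholds = thresholds, quantile = quantile),
    class = "positivity_calls"
  )
}

#' @export
print.positivity_calls <- function(x, ...) {
  cat(sprintf("<positivity_calls> %d spots x %d cell types (quantile %.2f)\n",
              nrow(x$positive), ncol(x$positive), x$quantile))
  counts <- colSums(x$positive)
  for (ct in colnames(x$positive)) {
    cat(sprintf("  %s: %d positive (threshold %.4g)\n",
                ct, counts[[ct]], x$thresholds[[ct]]))
  }
  invisible(x)
}
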
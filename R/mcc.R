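#' Threshold an intensity channel
#'
#' Produces the binary mask `channel > threshold`.  With `method = "otsu"`
#' the threshold maximizes the between-class variance of the 256-bin
#' intensity histogram (candidate thresholds are the bin edges); with
#' `method = "fixed"` the caller supplies the value.
#'
#' @param channel 2-D numeric intensity matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value threshold when `method = "fixed"`.
#' @return List with logical `mask`, numeric `threshold`, `method`.
#' @export
threshold_channel <- function(channel, method = c("otsu", "fixed"),
                              fixed_value = NULL) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (length(channel) == 0L) stop_invalid("empty image")
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value)) stop_invalid("`fixed_value` required for method = 'fixed'")
    thr <- fixed_value
  } else {
    thr <- otsu_threshold(channel)
  }
  list(mask = channel > thr, threshold = thr, method = method)
}

# Otsu's method on a 256-bin histogram spanning the intensity range.
otsu_threshold <- function(channel, n_bins = 256L) {
  lo <- min(channel)
  hi <- max(channel)
  if (hi <= lo) stop_invalid("degenerate histogram: constant image")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(findInterval(channel, edges, rightmost.closed = TRUE), n_bins),
    nbins = n_bins
  )
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)                         # class probability below cut k
  mu0 <- cumsum(p * mids)                 # unnormalized class mean
  mu_t <- mu0[n_bins]
  # between-class variance at each candidate cut (after bin k)
  denom <- w0 * (1 - w0)
  sigma_b <- ifelse(denom > 0, (mu_t * w0 - mu0)^2 / denom, -Inf)
  k <- which.max(sigma_b[-n_bins])
  edges[k + 1L]
}

#' Manders' colocalization coefficients
#'
#' Intensity-weighted overlap fractions of two aligned channels:
#' `M1 = sum(A over mask_a & mask_b) / sum(A over mask_a)` — the fraction of
#' channel-A signal that lies where channel B is present — and `M2` the
#' symmetric quantity for channel B.  Sums are of intensities, not pixel
#' counts.  A channel with zero total masked intensity yields a
#' not-computable coefficient (`NA` with `computable_m1`/`computable_m2`
#' flags), never 0/0 coerced to 0.
#'
#' @param pair a `channel_pair` (see [gen_channel_pair()], [read_channel()]),
#'   or any list with numeric matrices `channel_a`, `channel_b`.
#' @param mask_a,mask_b logical matrices of the channels' supports.  Omitted
#'   masks are computed with [threshold_channel()] using `threshold_method`.
#' @param threshold_method passed to [threshold_channel()] when masks are
#'   omitted.
#' @param fixed_a,fixed_b fixed thresholds per channel when
#'   `threshold_method = "fixed"`.
#' @return An `mcc_result`: list with `m1`, `m2`, `threshold_a`,
#'   `threshold_b`, `method`, `sums` (`sum_a_total`, `sum_a_in_b`,
#'   `sum_b_total`, `sum_b_in_a`) and computability flags.
#' @export
manders <- function(pair, mask_a = NULL, mask_b = NULL,
                    threshold_method = c("otsu", "fixed"),
                    fixed_a = NULL, fixed_b = NULL) {
  a <- pair$channel_a
  b <- pair$channel_b
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(dim(a), dim(b))) stop_invalid("channels must share a shape")
  threshold_method <- match.arg(threshold_method)
  thr_a <- thr_b <- NA_real_
  method <- "mask"
  if (is.null(mask_a)) {
    ta <- threshold_channel(a, threshold_method, fixed_a)
    mask_a <- ta$mask; thr_a <- ta$threshold; method <- ta$method
  }
  if (is.null(mask_b)) {
    tb <- threshold_channel(b, threshold_method, fixed_b)
    mask_b <- tb$mask; thr_b <- tb$threshold; method <- tb$method
  }
  if (!identical(dim(mask_a), dim(a)) || !identical(dim(mask_b), dim(b))) {
    stop_invalid("masks must share the channels' shape")
  }
  both <- mask_a & mask_b
  sums <- list(
    sum_a_total = sum(a[mask_a]),
    sum_a_in_b  = sum(a[both]),
    sum_b_total = sum(b[mask_b]),
    sum_b_in_a  = sum(b[both])
  )
  m1 <- if (sums$sum_a_total > 0) sums$sum_a_in_b / sums$sum_a_total else NA_real_
  m2 <- if (sums$sum_b_total > 0) sums$sum_b_in_a / sums$sum_b_total else NA_real_
  structure(
    list(m1 = m1, m2 = m2, threshold_a = thr_a, threshold_b = thr_b,
         method = method, sums = sums,
         computable_m1 = sums$sum_a_total > 0,
         computable_m2 = sums$sum_b_total > 0),
    class = "mcc_result"
  )
}

#' @export
print.mcc_result <- function(x, ...) {
  fmt <- function(m, ok) if (ok) sprintf("%.4f", m) else "not computable"
  cat(sprintf("<mcc_result> M1 = %s, M2 = %s [%s]\n",
              fmt(x$m1, x$computable_m1), fmt(x$m2, x$computable_m2),
              x$method))
  invisible(x)
}

#' Render a Manders coefficient as a percentage
#'
#' `100 * m` rounded to one decimal, the convention used to report M1/M2 in
#' prose (e.g. `0.074` -> `7.4`).
#'
#' @param m coefficient in `[0, 1]`.
#' @return Numeric percentage with one decimal.
#' @export
coefficient_to_percent <- function(m) {
  if (any(is.na(m)) || any(m < 0) || any(m > 1)) {
    stop_invalid("coefficient must lie in [0, 1]")
  }
  round(100 * m, 1)
}

#' Summarize Manders coefficients across grouped images
#'
#' Per-group n, mean and SD of M1 and M2 across images — the time-course /
#' treatment summary.  Groups keep their first-appearance order; SD is `NA`
#' (not computable) for single-image groups.  No hypothesis testing is
#' performed.
#'
#' @param records either a data.frame with columns `group`, `m1`, `m2`, or a
#'   list of `list(group = , mcc = <mcc_result>)`.
#' @return An `mcc_group_summary`: list with data.frame `summary`
#'   (`group`, `n`, `mean_m1`, `sd_m1`, `mean_m2`, `sd_m2`) and the
#'   per-image `records` data.frame.
#' @export
mcc_timecourse <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      data.frame(group = r$group, m1 = r$mcc$m1, m2 = r$mcc$m2,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.data.frame(records) || nrow(records) == 0L ||
      !all(c("group", "m1", "m2") %in% names(records))) {
    stop_invalid("records must be non-empty with columns group, m1, m2")
  }
  groups <- unique(records$group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group == g, , drop = FALSE]
    data.frame(
      group = g, n = nrow(r),
      mean_m1 = mean(r$m1), sd_m1 = if (nrow(r) > 1) sd(r$m1) else NA_real_,
      mean_m2 = mean(r$m2), sd_m2 = if (nrow(r) > 1) sd(r$m2) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(summary = summary, records = records),
            class = "mcc_group_summary")
}

#' @export
print.mcc_group_summary <- function(x, ...) {
  cat("<mcc_group_summary>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
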
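#' Synthetic cell-type abundance fields
#'
#' Generates one non-negative abundance value per spot under one of three
#' spatial patterns, with all randomness controlled by `seed`:
#'
#' * `"aggregated"` — abundance concentrated in isotropic Gaussian blobs
#'   (centers either supplied via `params$centers` or drawn uniformly on the
#'   lattice), on a small uniform baseline.  Emulates spatially clustered
#'   cell types, the structure join-count analysis detects as aggregation.
#' * `"dispersed"` — abundance supported on one half of the lattice only
#'   (`params$side` is `"left"` or `"right"`, split by column).  Two types
#'   generated on opposite sides occupy disjoint column ranges, making the
#'   expected join-count z-sign unambiguous.
#' * `"random"` — i.i.d. uniform abundance, the spatial null.
#'
#' @param grid a [spot_grid()].
#' @param cell_type cell-type name carried through to scoring.
#' @param pattern one of `"aggregated"`, `"dispersed"`, `"random"`.
#' @param params list of pattern parameters: `centers` (2-column matrix of
#'   blob centers, aggregated), `sigma` (blob width in lattice units,
#'   default 2), `n_blobs` (default 3, used when `centers` is NULL),
#'   `baseline` (additive noise amplitude, default 0.01), `side`
#'   (dispersed).
#' @param seed integer; mandatory, same seed gives identical fields.
#' @return An `abundance_field`: list with `grid_ref`, `cell_type`, `values`
#'   (one per spot, `>= 0`), `pattern`, `truth_params`.
#' @export
gen_celltype_field <- function(grid, cell_type, pattern, params = list(), seed) {
  stopifnot(inherits(grid, "spot_grid"))
  if (missing(seed)) stop_invalid("`seed` is required for gen_celltype_field")
  pattern <- as.character(pattern)
  if (!pattern %in% c("aggregated", "dispersed", "random")) {
    stop_invalid("unknown pattern '%s'", pattern)
  }
  x <- grid$spots$x
  y <- grid$spots$y
  n <- n_spots(grid)
  baseline <- if (is.null(params$baseline)) 0.01 else params$baseline

  values <- with_seed(seed, {
    if (pattern == "random") {
      runif(n)
    } else if (pattern == "dispersed") {
      side <- if (is.null(params$side)) "left" else params$side
      if (!side %in% c("left", "right")) {
        stop_invalid("dispersed `side` must be 'left' or 'right'")
      }
      half <- grid$n_cols %/% 2L
      inside <- if (side == "left") x < half else x >= grid$n_cols - half
      ifelse(inside, runif(n, 0.5, 1), 0)
    } else { # aggregated
      sigma <- if (is.null(params$sigma)) 2 else params$sigma
      centers <- params$centers
      if (is.null(centers)) {
        n_blobs <- if (is.null(params$n_blobs)) 3L else as.integer(params$n_blobs)
        centers <- cbind(runif(n_blobs, 0, grid$n_cols - 1),
                         runif(n_blobs, 0, grid$n_rows - 1))
      }
      centers <- matrix(as.numeric(centers), ncol = 2L)
      v <- numeric(n)
      for (k in seq_len(nrow(centers))) {
        v <- v + exp(-((x - centers[k, 1])^2 + (y - centers[k, 2])^2) /
                       (2 * sigma^2))
      }
      v + baseline * runif(n)
    }
  })

  structure(
    list(grid_ref = grid, cell_type = as.character(cell_type), values = values,
         pattern = pattern,
         truth_params = c(params, list(seed = as.integer(seed)))),
    class = "abundance_field"
  )
}

#' Generate a matched pair of abundance fields
#'
#' Convenience wrapper producing two fields with the between-type spatial
#' relationship each pattern implies: `aggregated` shares the same blob
#' centers between the pair (co-localized types), `dispersed` places the
#' types on disjoint half-lattices, `random` draws the two fields
#' independently.
#'
#' @inheritParams gen_celltype_field
#' @param types character vector of two cell-type names.
#' @return Named list of two `abundance_field`s.
#' @export
gen_pattern_pair <- function(grid, types = c("A", "B"), pattern,
                             params = list(), seed) {
  stopifnot(length(types) == 2L)
  seed <- as.integer(seed)
  if (pattern == "aggregated" && is.null(params$centers)) {
    # draw the shared centers once so both fields use identical blobs
    n_blobs <- if (is.null(params$n_blobs)) 3L else as.integer(params$n_blobs)
    params$centers <- with_seed(seed, {
      cbind(runif(n_blobs, 0, grid$n_cols - 1),
            runif(n_blobs, 0, grid$n_rows - 1))
    })
  }
  p1 <- params
  p2 <- params
  if (pattern == "dispersed") {
    p1$side <- "left"
    p2$side <- "right"
  }
  out <- list(
    gen_celltype_field(grid, types[1], pattern, p1, seed = seed),
    gen_celltype_field(grid, types[2], pattern, p2, seed = seed + 1L)
  )
  names(out) <- types
  out
}

#' Synthetic spot expression matrix with negative-binomial counts
#'
#' Marker genes of each cell type receive counts drawn from a negative
#' binomial with mean `baseline_mean * (1 + effect_size * abundance)`, where
#' abundance is the type's field rescaled to `[0, 1]`; background genes (and
#' all genes at zero abundance) sit at `baseline_mean`.  The NB is
#' parameterized by mean and dispersion with
#' `variance = mean + mean^2 / dispersion`, the standard over-dispersed UMI
#' model.
#'
#' @param grid a [spot_grid()].
#' @param fields list of `abundance_field`s on `grid`.
#' @param marker_sets named list mapping each field's `cell_type` to its
#'   marker gene symbols; sets must be disjoint from each other and from the
#'   background pool.
#' @param baseline_mean mean count of an unmodulated gene (default 2).
#' @param effect_size multiplicative abundance effect (default 5; at binary
#'   abundance the marker mean in positive spots is
#'   `(1 + effect_size) * baseline_mean`).
#' @param dispersion NB size parameter (default 2).
#' @param n_background number of background genes (`bg_###`, default 50).
#' @param seed integer, mandatory.
#' @return An `expression_matrix`: integer count matrix genes x spots with
#'   dimnames, plus attribute `marker_sets`.
#' @export
gen_expression_matrix <- function(grid, fields, marker_sets,
                                  baseline_mean = 2, effect_size = 5,
                                  dispersion = 2, n_background = 50L, seed) {
  stopifnot(inherits(grid, "spot_grid"))
  if (missing(seed)) stop_invalid("`seed` is required for gen_expression_matrix")
  types <- vapply(fields, function(f) f$cell_type, character(1))
  missing_sets <- setdiff(types, names(marker_sets))
  if (length(missing_sets)) {
    stop_invalid("missing marker set for cell type(s): %s",
                 paste(missing_sets, collapse = ", "))
  }
  marker_genes <- unlist(marker_sets[types], use.names = FALSE)
  if (anyDuplicated(marker_genes)) {
    stop_invalid("marker sets must be disjoint across cell types")
  }
  bg_genes <- sprintf("bg_%03d", seq_len(n_background))
  if (length(intersect(marker_genes, bg_genes))) {
    stop_invalid("marker genes collide with the background gene pool")
  }
  genes <- c(marker_genes, bg_genes)
  ns <- n_spots(grid)

  mu <- matrix(baseline_mean, nrow = length(genes), ncol = ns,
               dimnames = list(genes, grid$spots$spot_id))
  for (f in fields) {
    ab <- f$values
    if (max(ab) > 0) ab <- ab / max(ab)
    rows <- marker_sets[[f$cell_type]]
    mu[rows, ] <- rep(baseline_mean * (1 + effect_size * ab),
                      each = length(rows))
  }
  counts <- with_seed(seed, {
    matrix(rnbinom(length(mu), mu = mu, size = dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  })
  storage.mode(counts) <- "integer"
  structure(counts, marker_sets = marker_sets[types],
            class = c("expression_matrix", "matrix", "array"))
}

#' Synthetic two-channel image pair with known Manders ground truth
#'
#' Builds a pair of aligned intensity images on a zero background from three
#' disjoint pixel regions: an overlap region where both channels carry
#' signal, an A-only region and a B-only region.  The fraction of each
#' channel's total intensity placed in the overlap region equals the
#' requested Manders coefficient exactly, so at `noise_sd = 0` the
#' downstream [manders()] computation with the ideal (support) masks
#' recovers `m1 = frac_a_in_b`, `m2 = frac_b_in_a` exactly.  Region sizes
#' scale with the requested fractions so that each channel's per-pixel
#' intensity is near-constant across its support, which keeps Otsu
#' thresholding robust once noise is added.
#'
#' Because the ideal mask of a channel is its support, a pixel in the
#' overlap carries positive intensity in both channels; a strictly positive
#' `frac_a_in_b` therefore forces `frac_b_in_a > 0` and vice versa —
#' requesting one zero and the other positive is geometrically infeasible
#' and rejected.
#'
#' @param shape `c(h, w)` image dimensions, both at least 3; about 40% of
#'   the pixels are kept as zero background.
#' @param sum_a_total,sum_b_total total signal intensity per channel.
#' @param frac_a_in_b,frac_b_in_a requested M1 / M2 in `[0, 1]`.
#' @param noise_sd additive Gaussian noise sd (truncated at 0); 0 for exact
#'   ground truth.
#' @param seed integer, mandatory (used for the noise draw).
#' @return A `channel_pair`: list with matrices `channel_a`, `channel_b`,
#'   logical matrices `mask_a_true`, `mask_b_true` (noise-free supports) and
#'   `truth` (`sum_a_total`, `sum_a_in_b`, `sum_b_total`, `sum_b_in_a`,
#'   computed by summation over the constructed noise-free images).
#' @export
gen_channel_pair <- function(shape, sum_a_total, frac_a_in_b,
                             sum_b_total, frac_b_in_a,
                             noise_sd = 0, seed) {
  if (missing(seed)) stop_invalid("`seed` is required for gen_channel_pair")
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (is.na(h) || is.na(w) || h < 3L || w < 3L) {
    stop_invalid("shape must be at least 3 x 3 to place disjoint signal regions")
  }
  fa <- frac_a_in_b; fb <- frac_b_in_a
  for (f in c(fa, fb)) {
    if (is.na(f) || f < 0 || f > 1) stop_invalid("overlap fractions must lie in [0, 1]")
  }
  if ((fa > 0) != (fb > 0)) {
    stop_invalid(paste("infeasible overlap: with support masks, a pixel shared",
                       "by both channels has positive intensity in both, so",
                       "frac_a_in_b and frac_b_in_a must be zero together or",
                       "positive together"))
  }
  if (sum_a_total <= 0 || sum_b_total <= 0) {
    stop_invalid("channel totals must be positive")
  }

  npix <- h * w
  budget <- npix %/% 3L  # per-channel pixel budget; >= 1/3 stays background
  # overlap sized to the smaller fraction so both channels can keep a
  # near-constant per-pixel level (n_only ~ n_overlap * (1 - f) / f)
  n_ovl <- if (fa > 0) max(1L, as.integer(round(budget * min(fa, fb)))) else 0L
  n_only <- function(f) {
    if (f == 0) budget
    else if (f == 1) 0L
    else max(1L, as.integer(round(n_ovl * (1 - f) / f)))
  }
  cap <- max(1L, (npix - n_ovl) %/% 2L)
  n_a <- min(n_only(fa), cap)
  n_b <- min(n_only(fb), cap)
  if (n_ovl + n_a + n_b > npix) {
    stop_invalid("infeasible overlap: signal regions exceed the image")
  }

  # flat pixel layout: [overlap | A-only | B-only | background]
  a <- matrix(0, h, w)
  b <- matrix(0, h, w)
  px_ovl <- seq_len(n_ovl)
  px_a <- n_ovl + seq_len(n_a)
  px_b <- n_ovl + n_a + seq_len(n_b)
  if (fa > 0) a[px_ovl] <- sum_a_total * fa / n_ovl
  if (n_a > 0 && fa < 1) a[px_a] <- sum_a_total * (1 - fa) / n_a
  if (fb > 0) b[px_ovl] <- sum_b_total * fb / n_ovl
  if (n_b > 0 && fb < 1) b[px_b] <- sum_b_total * (1 - fb) / n_b

  mask_a <- a > 0
  mask_b <- b > 0
  truth <- list(
    sum_a_total = sum(a[mask_a]),
    sum_a_in_b  = sum(a[mask_a & mask_b]),
    sum_b_total = sum(b[mask_b]),
    sum_b_in_a  = sum(b[mask_a & mask_b])
  )

  if (noise_sd > 0) {
    noise <- with_seed(seed, {
      list(a = matrix(rnorm(h * w, sd = noise_sd), h, w),
           b = matrix(rnorm(h * w, sd = noise_sd), h, w))
    })
    a <- pmax(a + noise$a, 0)
    b <- pmax(b + noise$b, 0)
  }

  structure(
    list(channel_a = a, channel_b = b,
         mask_a_true = mask_a, mask_b_true = mask_b, truth = truth),
    class = "channel_pair"
  )
}

#' Synthetic per-spot score tables
#'
#' Fixture generator for the positivity rule: `distinct` draws all-unique
#' scores, `tied` plants duplicate scores straddling the 75th-percentile
#' boundary, `constant` sets every score equal (so the strict `>` rule calls
#' nothing positive).
#'
#' @param n_spots number of spots (`>= 4`).
#' @param n_types number of cell-type columns.
#' @param distribution `"distinct"`, `"tied"` or `"constant"`.
#' @param seed integer, mandatory.
#' @return A `score_matrix` (spots x cell types).
#' @export
gen_score_table <- function(n_spots, n_types = 1L,
                            distribution = c("distinct", "tied", "constant"),
                            seed) {
  if (missing(seed)) stop_invalid("`seed` is required for gen_score_table")
  distribution <- match.arg(distribution)
  n_spots <- as.integer(n_spots)
  if (is.na(n_spots) || n_spots < 4L) {
    stop_invalid("`n_spots` must be at least 4")
  }
  scores <- with_seed(seed, {
    vapply(seq_len(n_types), function(j) {
      if (distribution == "constant") {
        rep(1, n_spots)
      } else if (distribution == "distinct") {
        # ranks plus sub-unit jitter: all-unique by construction
        sample.int(n_spots) + runif(n_spots, 0, 0.5)
      } else { # tied: duplicates planted at the quartile boundary
        s <- as.numeric(sample.int(n_spots))
        k <- as.integer(ceiling(0.75 * n_spots))
        idx <- intersect(seq(k - 2L, k + 2L), seq_len(n_spots))
        s[order(s)[idx]] <- sort(s)[k]
        s
      }
    }, numeric(n_spots))
  })
  dimnames(scores) <- list(sprintf("spot_%04d", seq_len(n_spots)),
                           sprintf("type_%02d", seq_len(n_types)))
  new_score_matrix(scores)
}

#' Turn abundance fields into a score matrix
#'
#' Binds the per-spot values of several abundance fields into a
#' `score_matrix` (columns named by cell type), the direct route from
#' synthetic fields to positivity calls when no expression step is wanted.
#'
#' @param fields list of `abundance_field`s sharing a grid.
#' @return A `score_matrix` with spot ids taken from the fields' grid.
#' @export
field_scores <- function(fields) {
  stopifnot(length(fields) >= 1L)
  grid <- fields[[1]]$grid_ref
  m <- vapply(fields, function(f) f$values, numeric(n_spots(grid)))
  dimnames(m) <- list(grid$spots$spot_id,
                      vapply(fields, function(f) f$cell_type, character(1)))
  new_score_matrix(m)
}
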
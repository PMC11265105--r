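#' Lattice adjacency graph
#'
#' Builds the neighbor graph of a spot grid under rook (4-neighbor,
#' edge-sharing) or queen (8-neighbor, edge- or corner-sharing) contiguity.
#' Works on partial lattices: only spots present in the grid are connected.
#' On a full `r x c` grid, rook yields `r(c-1) + c(r-1)` edges.
#'
#' @param grid a [spot_grid()].
#' @param scheme `"rook"` (default) or `"queen"`.
#' @return An `adjacency_graph`: list with integer matrix `edges` (two
#'   columns of spot indices into `grid$spots`, `i < j`, deterministic
#'   order), `scheme`, and `n` (number of spots).
#' @export
build_adjacency <- function(grid, scheme = c("rook", "queen")) {
  stopifnot(inherits(grid, "spot_grid"))
  scheme <- match.arg(scheme)
  x <- grid$spots$x
  y <- grid$spots$y
  # index spots by coordinate key for O(1) neighbor lookup
  key <- x + y * grid$n_cols
  idx <- integer(grid$n_rows * grid$n_cols)
  idx[key + 1L] <- seq_along(key)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (scheme == "queen") offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0)
  to <- integer(0)
  for (off in offsets) {
    nx <- x + off[1]
    ny <- y + off[2]
    ok <- nx >= 0L & nx < grid$n_cols & ny >= 0L & ny < grid$n_rows
    j <- integer(length(x))
    j[ok] <- idx[nx[ok] + ny[ok] * grid$n_cols + 1L]
    ok <- ok & j > 0L
    from <- c(from, which(ok))
    to <- c(to, j[ok])
  }
  edges <- cbind(pmin(from, to), pmax(from, to))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(edges = edges, scheme = scheme, n = length(x)),
            class = "adjacency_graph")
}

#' Parity assignment of co-positive spots
#'
#' Reduces two positivity columns to a single label per spot for join
#' counting.  Spots positive for only one type keep that type; spots positive
#' for neither are background (`"BG"`).  Spots positive for both are resolved
#' by the coordinate parity of the site: sites with `(x + y)` even receive
#' `even_gets` (the first type by default) and odd sites the other type — a
#' deterministic checkerboard, so co-positive regions contribute the maximal
#' number of heterogeneous joins.  Because parity is origin-dependent, the
#' grid's 0-based coordinate convention is part of the contract.
#'
#' @param calls a [call_positivity()] result.
#' @param pair character vector `c(type_a, type_b)`; both must be columns of
#'   the calls.
#' @param grid the [spot_grid()] the calls live on; must cover every call
#'   spot.
#' @param even_gets which type takes even-parity sites, `"A"` or `"B"`.
#' @return A `labeled_lattice`: list with `grid_ref`, `pair`, `labels`
#'   (factor per spot in `A`/`B`/`BG`, grid order) and `assignment_record`
#'   (per-spot provenance in `only_a`, `only_b`, `both_even`, `both_odd`,
#'   `neither`).
#' @export
assign_pair_labels <- function(calls, pair, grid, even_gets = c("A", "B")) {
  stopifnot(inherits(calls, "positivity_calls"), inherits(grid, "spot_grid"))
  even_gets <- match.arg(even_gets)
  pair <- as.character(pair)
  if (length(pair) != 2L || !all(pair %in% colnames(calls$positive))) {
    stop_invalid("pair types not found in positivity calls: %s",
                 paste(setdiff(pair, colnames(calls$positive)), collapse = ", "))
  }
  call_spots <- rownames(calls$positive)
  pos <- match(grid$spots$spot_id, call_spots)
  if (anyNA(match(call_spots, grid$spots$spot_id))) {
    stop_invalid("grid does not cover all spots in the positivity calls")
  }
  pos_a <- calls$positive[, pair[1]][pos]
  pos_b <- calls$positive[, pair[2]][pos]
  pos_a[is.na(pos_a)] <- FALSE
  pos_b[is.na(pos_b)] <- FALSE
  even <- (grid$spots$x + grid$spots$y) %% 2L == 0L

  labels <- rep("BG", n_spots(grid))
  record <- rep("neither", n_spots(grid))
  labels[pos_a & !pos_b] <- "A"
  record[pos_a & !pos_b] <- "only_a"
  labels[pos_b & !pos_a] <- "B"
  record[pos_b & !pos_a] <- "only_b"
  both <- pos_a & pos_b
  even_label <- even_gets
  odd_label <- setdiff(c("A", "B"), even_gets)
  labels[both & even] <- even_label
  labels[both & !even] <- odd_label
  record[both & even] <- "both_even"
  record[both & !even] <- "both_odd"

  structure(
    list(grid_ref = grid, pair = pair,
         labels = factor(labels, levels = c("A", "B", "BG")),
         assignment_record = record, even_gets = even_gets),
    class = "labeled_lattice"
  )
}

#' Observed heterogeneous join count
#'
#' Number of adjacency edges whose endpoints are labeled `A` and `B`
#' (in either order).  Edges touching background never count.
#'
#' @param labels a [assign_pair_labels()] result.
#' @param graph a [build_adjacency()] result on the same grid.
#' @return Integer join count.
#' @export
observed_joins <- function(labels, graph) {
  check_shared_grid(labels, graph)
  count_ab_joins(as.integer(labels$labels), graph$edges)
}

check_shared_grid <- function(labels, graph) {
  if (length(labels$labels) != graph$n) {
    stop_invalid("labels and adjacency graph do not share a grid")
  }
  invisible(TRUE)
}

# labels coded 1 = A, 2 = B, 3 = BG; an edge sums to 3 iff its endpoints
# are {A, B} (1+2; all other label pairs sum to 2, 4, 5 or 6)
count_ab_joins <- function(lab, edges) {
  sum(lab[edges[, 1]] + lab[edges[, 2]] == 3L)
}

#' Permutation null for the heterogeneous join count
#'
#' Nonfree-sampling null: the observed label multiset (counts of A, B and BG
#' preserved) is permuted uniformly over all spots `n_perm` times and the
#' heterogeneous join count recomputed each time.  The two-sided permutation
#' p-value uses the add-one estimator
#' `(1 + #(|J_perm - mean| >= |J_obs - mean|)) / (n_perm + 1)`.
#'
#' @param labels a [assign_pair_labels()] result with at least one `A` and
#'   one `B` spot.
#' @param graph matching [build_adjacency()] result.
#' @param n_perm number of permutations, `>= 99`.
#' @param seed integer, mandatory.
#' @return List with `null_mean`, `null_sd`, `p_perm`, `j_obs`, `n_perm`.
#'   When every permutation yields the same count (`null_sd = 0`) an error
#'   of class `spatialcoloc_degenerate_null` is raised, as for labelings
#'   missing one of the two types.
#' @export
permutation_null <- function(labels, graph, n_perm = 999L, seed) {
  check_shared_grid(labels, graph)
  if (missing(seed)) stop_invalid("`seed` is required for permutation_null")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 99L) stop_invalid("`n_perm` must be at least 99")
  lab <- as.integer(labels$labels)
  if (sum(lab == 1L) < 1L || sum(lab == 2L) < 1L) {
    degenerate_null_error("labeling has fewer than one A or one B spot")
  }
  e1 <- graph$edges[, 1]
  e2 <- graph$edges[, 2]
  j_obs <- count_ab_joins(lab, graph$edges)
  j_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pl <- lab[sample.int(length(lab))]
      sum(pl[e1] + pl[e2] == 3L)
    }, integer(1))
  })
  null_mean <- mean(j_perm)
  null_sd <- sd(j_perm)
  if (null_sd == 0) {
    degenerate_null_error("all permutations give the same join count")
  }
  p_perm <- (1 + sum(abs(j_perm - null_mean) >= abs(j_obs - null_mean))) /
    (n_perm + 1)
  list(null_mean = null_mean, null_sd = null_sd, p_perm = p_perm,
       j_obs = j_obs, n_perm = n_perm)
}

degenerate_null_error <- function(msg) {
  stop(structure(
    class = c("spatialcoloc_degenerate_null", "error", "condition"),
    list(message = paste("null degenerate:", msg), call = NULL)
  ))
}

#' Analytic (closed-form) null for the heterogeneous join count
#'
#' First and second moments of the A-B join count under the nonfree-sampling
#' null — labels permuted without replacement conditional on the observed
#' counts `n_A`, `n_B` (background spots form a third color that never joins).
#' With `n` spots and `m` edges,
#' `E[J] = 2 m n_A n_B / (n (n - 1))`.  The variance follows from summing
#' `P(both edges are A-B)` over ordered edge pairs, split into identical
#' edges, edges sharing one vertex, and disjoint edges; the three
#' probabilities are the corresponding factorial-moment ratios.  Verified
#' against exhaustive enumeration of all distinguishable labelings on every
#' grid with at most 9 spots (see the package tests).
#'
#' @inheritParams permutation_null
#' @return List with `null_mean`, `null_sd`, `j_obs`.
#' @export
analytic_null <- function(labels, graph) {
  check_shared_grid(labels, graph)
  lab <- as.integer(labels$labels)
  n <- length(lab)
  if (n < 2L) stop_invalid("analytic null needs at least 2 spots")
  na <- sum(lab == 1L)
  nb <- sum(lab == 2L)
  if (na < 1L || nb < 1L) {
    degenerate_null_error("labeling has fewer than one A or one B spot")
  }
  m <- nrow(graph$edges)
  deg <- tabulate(graph$edges, nbins = n)
  pairs_shared <- sum(choose(deg, 2))           # unordered pairs sharing a vertex
  pairs_disjoint <- choose(m, 2) - pairs_shared # unordered disjoint pairs

  p_same <- 2 * na * nb / (n * (n - 1))
  ej <- m * p_same
  ej2 <- m * p_same
  if (pairs_shared > 0) {
    p_shared <- na * nb * (na + nb - 2) / (n * (n - 1) * (n - 2))
    ej2 <- ej2 + 2 * pairs_shared * p_shared
  }
  if (pairs_disjoint > 0) {
    p_disjoint <- 4 * na * (na - 1) * nb * (nb - 1) /
      (n * (n - 1) * (n - 2) * (n - 3))
    ej2 <- ej2 + 2 * pairs_disjoint * p_disjoint
  }
  v <- ej2 - ej^2
  list(null_mean = ej, null_sd = sqrt(max(v, 0)),
       j_obs = count_ab_joins(lab, graph$edges))
}

#' Join-count z-score for one cell-type pair
#'
#' Composes parity assignment, adjacency construction, the observed
#' heterogeneous join count and the chosen null into a z-score:
#' `z = (J_obs - null_mean) / null_sd`.  Positive z means the pair shares
#' more adjacencies than expected at random — spatial aggregation; negative z
#' means spatial dispersion.  Significance is called at `|z| >= z_cutoff`
#' (default 3).  A degenerate null (a type absent, or zero null variance)
#' yields a result flagged not-computable rather than a silent zero.
#'
#' @param calls a [call_positivity()] result.
#' @param grid the [spot_grid()].
#' @param pair character vector `c(type_a, type_b)`.
#' @param scheme adjacency scheme, `"rook"` or `"queen"`.
#' @param null_method `"permutation"` (default) or `"analytic"`.
#' @param n_perm permutations for the permutation null.
#' @param seed integer; required when `null_method = "permutation"`.
#' @param z_cutoff significance cutoff on `|z|`, default 3.
#' @param even_gets parity convention, see [assign_pair_labels()].
#' @param graph optionally a precomputed [build_adjacency()] result
#'   (saves rebuilding in pairwise sweeps).
#' @return A `join_count_result`: list with `pair`, `j_obs`, `null_mean`,
#'   `null_sd`, `z`, `p_perm` (NA for the analytic null), `n_perm`,
#'   `significant`, `method`, `computable` and (when not computable)
#'   `reason`.
#' @export
joincount_z <- function(calls, grid, pair, scheme = "rook",
                        null_method = c("permutation", "analytic"),
                        n_perm = 999L, seed = NULL, z_cutoff = 3,
                        even_gets = "A", graph = NULL) {
  null_method <- match.arg(null_method)
  labels <- assign_pair_labels(calls, pair, grid, even_gets = even_gets)
  if (is.null(graph)) graph <- build_adjacency(grid, scheme)
  res <- list(pair = pair, method = null_method, n_perm = NA_integer_,
              p_perm = NA_real_)

  null <- tryCatch(
    if (null_method == "permutation") {
      if (is.null(seed)) stop_invalid("`seed` is required for the permutation null")
      permutation_null(labels, graph, n_perm = n_perm, seed = seed)
    } else {
      analytic_null(labels, graph)
    },
    spatialcoloc_degenerate_null = function(e) e
  )

  if (inherits(null, "condition")) {
    res <- c(res, list(
      j_obs = count_ab_joins(as.integer(labels$labels), graph$edges),
      null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
      significant = NA, computable = FALSE, reason = conditionMessage(null)
    ))
  } else {
    z <- (null$j_obs - null$null_mean) / null$null_sd
    res$n_perm <- if (null_method == "permutation") null$n_perm else NA_integer_
    res$p_perm <- if (null_method == "permutation") null$p_perm else NA_real_
    res <- c(res, list(
      j_obs = null$j_obs, null_mean = null$null_mean, null_sd = null$null_sd,
      z = z, significant = abs(z) >= z_cutoff, computable = TRUE
    ))
  }
  structure(res, class = "join_count_result")
}

#' @export
print.join_count_result <- function(x, ...) {
  if (isTRUE(x$computable)) {
    cat(sprintf(
      "<join_count_result> %s-%s: J = %d, null %.3f (sd %.3f), z = %.3f%s [%s]\n",
      x$pair[1], x$pair[2], x$j_obs, x$null_mean, x$null_sd, x$z,
      if (isTRUE(x$significant)) " *" else "", x$method))
  } else {
    cat(sprintf("<join_count_result> %s-%s: not computable (%s)\n",
                x$pair[1], x$pair[2], x$reason))
  }
  invisible(x)
}

#' Join-count z-scores for all cell-type pairs
#'
#' Runs [joincount_z()] for every unordered pair of cell types in the calls,
#' in lexicographic pair order, reusing one adjacency graph.
#'
#' @inheritParams joincount_z
#' @param ... further arguments passed to [joincount_z()].
#' @return List of `join_count_result` named `"A|B"`; see
#'   [joincount_table()] for a data.frame rendering.
#' @export
pairwise_joincount_matrix <- function(calls, grid, scheme = "rook", ...) {
  types <- sort(colnames(calls$positive))
  if (length(types) < 2L) stop_invalid("need at least 2 cell types")
  graph <- build_adjacency(grid, scheme)
  pairs <- combn(types, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    tryCatch(
      joincount_z(calls, grid, p, scheme = scheme, graph = graph, ...),
      error = function(e) {
        stop_invalid("pair %s|%s: %s", p[1], p[2], conditionMessage(e))
      }
    )
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "|")
  out
}

#' Tabulate join-count results
#'
#' @param results list of `join_count_result` (e.g. from
#'   [pairwise_joincount_matrix()]).
#' @return data.frame with one row per pair: `type_a`, `type_b`, `j_obs`,
#'   `null_mean`, `null_sd`, `z`, `p_perm`, `significant`, `method`,
#'   `computable`.
#' @export
joincount_table <- function(results) {
  if (inherits(results, "join_count_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      type_a = r$pair[1], type_b = r$pair[2], j_obs = r$j_obs,
      null_mean = r$null_mean, null_sd = r$null_sd, z = r$z,
      p_perm = r$p_perm, significant = r$significant,
      method = r$method, computable = r$computable,
      stringsAsFactors = FALSE
    )
  }))
}
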
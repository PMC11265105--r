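#' Spot lattices
#'
#' A `spot_grid` is the spatial substrate for scoring and join counts: a set
#' of spots with unique ids at unique integer coordinates on a square lattice.
#' Coordinates are 0-based with `x` the column index and `y` the row index,
#' which fixes the meaning of the parity rule used downstream (a shift of
#' either axis by 1 flips every site's parity).
#'
#' @param spots data.frame with columns `spot_id` (character, unique),
#'   `x`, `y` (integers, unique as pairs, `0 <= x < n_cols`,
#'   `0 <= y < n_rows`).
#' @param n_rows,n_cols lattice extent.
#' @return An object of class `spot_grid` with fields `n_rows`, `n_cols`,
#'   `spots` and `geometry = "square"`.
#' @seealso [gen_spot_lattice()] for the full-lattice constructor,
#'   [read_coords()] to build a grid from a coordinate CSV.
#' @export
spot_grid <- function(spots, n_rows, n_cols) {
  if (!is.data.frame(spots) || !all(c("spot_id", "x", "y") %in% names(spots))) {
    stop_invalid("`spots` must be a data.frame with columns spot_id, x, y")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop_invalid("lattice dimensions must be positive integers")
  }
  spots <- data.frame(
    spot_id = as.character(spots$spot_id),
    x = as.integer(spots$x),
    y = as.integer(spots$y),
    stringsAsFactors = FALSE
  )
  if (anyNA(spots$x) || anyNA(spots$y)) {
    stop_invalid("spot coordinates must be integers")
  }
  if (anyDuplicated(spots$spot_id)) {
    stop_invalid("duplicate spot_id: %s",
                 paste(unique(spots$spot_id[duplicated(spots$spot_id)]), collapse = ", "))
  }
  key <- paste(spots$x, spots$y)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate coordinates: (%s)",
                 paste(unique(key[duplicated(key)]), collapse = "), ("))
  }
  if (any(spots$x < 0L) || any(spots$x >= n_cols) ||
      any(spots$y < 0L) || any(spots$y >= n_rows)) {
    stop_invalid("coordinates out of range for a %d x %d lattice", n_rows, n_cols)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, spots = spots, geometry = "square"),
    class = "spot_grid"
  )
}

#' Generate a full rectangular spot lattice
#'
#' Creates one spot per lattice site of an `n_rows` x `n_cols` grid, in
#' row-major order, with stable deterministic ids of the form `s<x>x<y>`.
#'
#' @param n_rows,n_cols positive integers.
#' @return A [spot_grid()].
#' @examples
#' g <- gen_spot_lattice(3, 3)
#' nrow(g$spots)  # 9
#' @export
gen_spot_lattice <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop_invalid("`n_rows` and `n_cols` must be positive integers")
  }
  x <- rep(seq_len(n_cols) - 1L, times = n_rows)
  y <- rep(seq_len(n_rows) - 1L, each = n_cols)
  spot_grid(
    data.frame(spot_id = sprintf("s%dx%d", x, y), x = x, y = y,
               stringsAsFactors = FALSE),
    n_rows = n_rows, n_cols = n_cols
  )
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("<spot_grid> %d x %d square lattice, %d spots\n",
              x$n_rows, x$n_cols, nrow(x$spots)))
  invisible(x)
}

n_spots <- function(grid) nrow(grid$spots)
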
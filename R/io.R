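#' Gene-set collections and GMT files
#'
#' A `gene_set_collection` is a named list of non-empty character vectors of
#' unique gene symbols.  [read_gmt()] parses the standard tab-separated GMT
#' dialect (set name, description, then one gene per column); duplicate genes
#' within a set are dropped with a warning, a line with no genes is an error.
#'
#' @param sets named list of character vectors.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop_invalid("gene sets must be a named list")
  }
  for (nm in names(sets)) {
    g <- as.character(sets[[nm]])
    if (length(g) == 0L) stop_invalid("gene set '%s' is empty", nm)
    if (anyDuplicated(g)) stop_invalid("gene set '%s' has duplicate genes", nm)
    sets[[nm]] <- g
  }
  structure(sets, class = "gene_set_collection")
}

as_gene_set_list <- function(sets) {
  if (inherits(sets, "gene_set_collection")) return(unclass(sets))
  unclass(gene_set_collection(sets))
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_invalid("GMT file '%s' is empty", path)
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3L) {
      stop_invalid("GMT line %d: need name, description and at least one gene", i)
    }
    genes <- parts[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': dropping %d duplicate gene(s)",
                      parts[1], sum(duplicated(genes))), call. = FALSE)
      genes <- unique(genes)
    }
    sets[[parts[1]]] <- genes
  }
  gene_set_collection(sets)
}

#' @rdname gene_set_collection
#' @param description optional per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  sets <- as_gene_set_list(sets)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spot expression matrix
#'
#' Accepts either an MTX triplet directory (`matrix.mtx` + `features.tsv` +
#' `barcodes.tsv`, genes x spots) or a CSV with gene rows, spot-id header and
#' the gene symbol in the first column.  Counts are validated: non-integer or
#' negative entries are rejected with their (gene, spot) location.
#'
#' @param path directory containing the triplet, a `.mtx` file, or a CSV.
#' @return An `expression_matrix` (integer matrix genes x spots).
#' @export
read_expression <- function(path) {
  if (dir.exists(path) || grepl("\\.mtx$", path)) {
    read_expression_mtx(path)
  } else {
    read_expression_csv(path)
  }
}

read_expression_mtx <- function(path) {
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx <- file.path(dir, "matrix.mtx")
  feats <- file.path(dir, "features.tsv")
  bars <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feats, bars)) {
    if (!file.exists(f)) stop_invalid("MTX triplet member missing: %s", f)
  }
  m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
    stop_invalid("parse error in '%s': %s", mtx, conditionMessage(e))
  })
  genes <- readLines(feats, warn = FALSE)
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
  spots <- readLines(bars, warn = FALSE)
  if (nrow(m) != length(genes) || ncol(m) != length(spots)) {
    stop_invalid(
      "MTX dimensions (%d x %d) disagree with features (%d) / barcodes (%d)",
      nrow(m), ncol(m), length(genes), length(spots))
  }
  counts <- as.matrix(m)
  dimnames(counts) <- list(genes, spots)
  validate_counts(counts)
}

read_expression_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_invalid("expression CSV needs a gene column plus spots")
  genes <- as.character(df[[1]])
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop_invalid("expression CSV has non-numeric entries")
  rownames(counts) <- genes
  validate_counts(counts)
}

validate_counts <- function(counts) {
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_invalid("invalid count at gene '%s', spot '%s' (value %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]]))
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("expression_matrix", "matrix", "array"))
}

#' Write an expression matrix
#'
#' `write_expression_mtx()` emits the MTX triplet (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`); `write_expression_csv()` a dense CSV with
#' a `gene` first column.
#'
#' @param expr matrix genes x spots with dimnames.
#' @param dir,path output location.
#' @return The output location, invisibly.
#' @export
write_expression_mtx <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(unclass(expr), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr), file.path(dir, "features.tsv"))
  writeLines(colnames(expr), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
write_expression_csv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spot coordinates into a grid
#'
#' Parses a CSV with columns `spot_id`, `x`, `y`.  Coordinates must be
#' integers; they are normalized to the package's 0-based convention by
#' subtracting the minimum of each axis, and the offset is recorded (as
#' attribute `offset`) because any shift of x or y by 1 flips every site's
#' parity and hence the co-positive assignments.
#'
#' @param path CSV path.
#' @return A [spot_grid()] with attribute `offset = c(x0, y0)` (the
#'   subtracted origin).
#' @export
read_coords <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(df))) {
    stop_invalid("coordinate CSV needs columns spot_id, x, y")
  }
  for (axis in c("x", "y")) {
    v <- df[[axis]]
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad)) {
      stop_invalid("non-integer %s coordinate in row %d of '%s'",
                   axis, bad[1], path)
    }
  }
  x0 <- min(df$x)
  y0 <- min(df$y)
  grid <- spot_grid(
    data.frame(spot_id = df$spot_id, x = df$x - x0, y = df$y - y0,
               stringsAsFactors = FALSE),
    n_rows = max(df$y) - y0 + 1L, n_cols = max(df$x) - x0 + 1L
  )
  attr(grid, "offset") <- c(x = x0, y = y0)
  grid
}

#' @rdname read_coords
#' @param grid a [spot_grid()].
#' @export
write_coords <- function(grid, path) {
  write.csv(grid$spots, path, row.names = FALSE)
  invisible(path)
}

#' Channel images as plain-text PGM
#'
#' Reads and writes single-channel intensity images as plain (P2, ASCII) PGM
#' with a 16-bit maxval — a text format, so images round-trip without any
#' binary dependency.  `read_channel()` also accepts a headerless CSV matrix
#' of intensities.
#'
#' @param channel numeric intensity matrix with values in `[0, maxval]`.
#' @param path file path.
#' @param maxval PGM maximum sample value (default 65535).
#' @return `read_channel()`: a numeric matrix; writers return `path`
#'   invisibly.
#' @export
write_channel <- function(channel, path, maxval = 65535L) {
  stopifnot(is.matrix(channel))
  v <- round(channel)
  if (any(v < 0) || any(v > maxval)) {
    stop_invalid("intensities must lie in [0, %d] for PGM output", maxval)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(channel), nrow(channel)),
               sprintf("%d", maxval)), con)
  # row-major pixel order, one image row per line
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_channel
#' @export
read_channel <- function(path) {
  if (grepl("\\.csv$", path)) {
    m <- as.matrix(read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    return(m)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 4L || trimws(lines[1]) != "P2") {
    stop_invalid("'%s' is not a plain (P2) PGM file", path)
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2]) {
    stop_invalid("PGM '%s': expected %d pixels, found %d",
                 path, dims[1] * dims[2], length(vals))
  }
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Write scores, calls and join-count results
#'
#' CSV/JSON writers for the pipeline outputs: the score matrix as CSV with a
#' `spot_id` first column, positivity calls likewise (logicals as
#' TRUE/FALSE) with the per-type thresholds in a JSON sidecar, and
#' join-count results via [joincount_table()].
#'
#' @param scores a `score_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(spot_id = rownames(scores), unclass(scores),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @param calls a `positivity_calls` object.
#' @param sidecar path for the JSON thresholds sidecar (default: `path` with
#'   `.thresholds.json` appended).
#' @export
write_positivity <- function(calls, path,
                             sidecar = paste0(path, ".thresholds.json")) {
  df <- data.frame(spot_id = rownames(calls$positive), calls$positive,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(quantile = calls$quantile, thresholds = as.list(calls$thresholds)),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_scores
#' @param results list of `join_count_result`.
#' @export
write_joincounts <- function(results, path) {
  write.csv(joincount_table(results), path, row.names = FALSE)
  invisible(path)
}
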
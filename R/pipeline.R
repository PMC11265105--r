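#' Run configuration
#'
#' A single structured JSON config drives every pipeline mode; unknown keys
#' (top-level or within a section) are rejected rather than ignored, and a
#' seed is mandatory so every run is a pure function of (config, inputs).
#'
#' @param config named list (parsed JSON) or a path to a JSON file.
#' @return A validated `run_config` (named list with defaults filled in).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    mode = NULL,
    seed = NULL,
    output_dir = ".",
    inputs = list(expression = NULL, coords = NULL, gmt = NULL,
                  manifest = NULL),
    scoring = list(alpha = 0.25, quantile = 0.75),
    joincount = list(scheme = "rook", null_method = "permutation",
                     n_perm = 999L, z_cutoff = 3, even_gets = "A"),
    mcc = list(threshold_method = "otsu", fixed_a = NULL, fixed_b = NULL),
    generator = list(n_rows = 20L, n_cols = 20L, pattern = "aggregated",
                     sigma = 2, n_blobs = 3L, baseline_mean = 2,
                     effect_size = 5, dispersion = 2, markers_per_type = 8L)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (section in c("inputs", "scoring", "joincount", "mcc", "generator")) {
    extra <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(extra)) {
      stop_invalid("unknown key(s) in config section '%s': %s",
                   section, paste(extra, collapse = ", "))
    }
    defaults[[section]][names(config[[section]])] <- config[[section]]
  }
  for (k in c("mode", "seed", "output_dir")) {
    if (!is.null(config[[k]])) defaults[[k]] <- config[[k]]
  }
  if (is.null(defaults$mode) ||
      !defaults$mode %in% c("spatial", "mcc", "synthetic-demo")) {
    stop_invalid("config `mode` must be spatial, mcc or synthetic-demo")
  }
  if (is.null(defaults$seed)) stop_invalid("config `seed` is mandatory")
  defaults$seed <- as.integer(defaults$seed)
  structure(defaults, class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

new_report <- function(config) {
  list(config = unclass(config), config_hash = config_hash(config),
       version = as.character(utils::packageVersion("spatialcoloc")),
       files = character(0), stages = list(), status = "ok")
}

run_stage <- function(report, name, expr) {
  t0 <- Sys.time()
  value <- tryCatch(expr, error = function(e) {
    # abort with stage context; partial outputs are removed by the caller
    stop_invalid("stage '%s' failed: %s", name, conditionMessage(e))
  })
  report$stages[[name]] <- list(
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  list(report = report, value = value)
}

write_report <- function(report, outdir) {
  missing <- report$files[!file.exists(report$files)]
  if (length(missing)) {
    stop_invalid("report lists missing output file(s): %s",
                 paste(missing, collapse = ", "))
  }
  path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  report$files <- c(report$files, path)
  structure(report, class = "run_report")
}

#' Run the spatial co-localization pipeline
#'
#' Expression + coordinates + marker gene sets -> per-spot ssGSEA scores ->
#' top-quartile positivity calls -> pairwise join-count z-scores, with all
#' outputs (scores.csv, positivity.csv + thresholds sidecar, joincounts.csv,
#' report.json) written under the config's `output_dir`.  Any stage error
#' aborts the run with the stage name attached and removes partial outputs.
#'
#' @param config a `run_config` (or path / list accepted by
#'   [read_run_config()]) with `mode = "spatial"` and input paths
#'   `expression`, `coords`, `gmt`.
#' @return A `run_report` (invisible file side effects listed in `$files`).
#' @export
run_spatial <- function(config) {
  config <- read_run_config(config)
  if (config$mode != "spatial") stop_invalid("run_spatial needs mode = 'spatial'")
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- new_report(config)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  for (f in c("expression", "coords", "gmt")) {
    if (is.null(config$inputs[[f]])) {
      stop_invalid("stage 'read-inputs' failed: config inputs$%s is missing", f)
    }
  }
  st <- run_stage(report, "read-inputs", {
    list(expr = read_expression(config$inputs$expression),
         grid = read_coords(config$inputs$coords),
         sets = read_gmt(config$inputs$gmt))
  })
  report <- st$report
  inputs <- st$value
  offset <- attr(inputs$grid, "offset")
  report$coordinate_offset <- as.list(offset)  # parity depends on the origin

  st <- run_stage(report, "score", {
    score_celltypes(inputs$expr, inputs$sets, alpha = config$scoring$alpha)
  })
  report <- st$report
  scores <- st$value

  st <- run_stage(report, "positivity", {
    call_positivity(scores, quantile = config$scoring$quantile)
  })
  report <- st$report
  calls <- st$value

  st <- run_stage(report, "joincount", {
    pairwise_joincount_matrix(
      calls, inputs$grid, scheme = config$joincount$scheme,
      null_method = config$joincount$null_method,
      n_perm = config$joincount$n_perm, seed = config$seed,
      z_cutoff = config$joincount$z_cutoff,
      even_gets = config$joincount$even_gets
    )
  })
  report <- st$report
  results <- st$value

  files <- c(
    write_scores(scores, file.path(outdir, "scores.csv")),
    write_positivity(calls, file.path(outdir, "positivity.csv")),
    file.path(outdir, "positivity.csv.thresholds.json"),
    write_joincounts(results, file.path(outdir, "joincounts.csv"))
  )
  written <- files
  report$files <- files
  report$joincounts <- joincount_table(results)
  report <- write_report(report, outdir)
  ok <- TRUE
  invisible(report)
}

#' Run the Manders colocalization pipeline over an image manifest
#'
#' The manifest CSV (`image_id`, `group_label`, `path_a`, `path_b`) lists one
#' two-channel image per row; each is thresholded per config and its M1/M2
#' computed.  Unreadable images are recorded as per-image failures and the
#' run continues; the report status is `"partial"` when any image failed.
#' Not-computable coefficients are flagged, never dropped.
#'
#' @param config a `run_config` with `mode = "mcc"` and `inputs$manifest`.
#' @return A `run_report` with `$results` (per-image data.frame),
#'   `$failures`, and files `mcc_results.csv`, `mcc_summary.csv`,
#'   `report.json`.
#' @export
run_mcc <- function(config) {
  config <- read_run_config(config)
  if (config$mode != "mcc") stop_invalid("run_mcc needs mode = 'mcc'")
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- new_report(config)
  if (is.null(config$inputs$manifest)) {
    stop_invalid("stage 'read-manifest' failed: config inputs$manifest is missing")
  }
  manifest <- read.csv(config$inputs$manifest, stringsAsFactors = FALSE)
  need <- c("image_id", "group_label", "path_a", "path_b")
  if (!all(need %in% names(manifest))) {
    stop_invalid("manifest needs columns %s", paste(need, collapse = ", "))
  }

  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    res <- tryCatch({
      pair <- list(channel_a = read_channel(rec$path_a),
                   channel_b = read_channel(rec$path_b))
      mcc <- manders(pair, threshold_method = config$mcc$threshold_method,
                     fixed_a = config$mcc$fixed_a, fixed_b = config$mcc$fixed_b)
      data.frame(image_id = rec$image_id, group = rec$group_label,
                 m1 = mcc$m1, m2 = mcc$m2,
                 m1_percent = if (mcc$computable_m1) coefficient_to_percent(mcc$m1) else NA_real_,
                 m2_percent = if (mcc$computable_m2) coefficient_to_percent(mcc$m2) else NA_real_,
                 threshold_a = mcc$threshold_a, threshold_b = mcc$threshold_b,
                 computable_m1 = mcc$computable_m1,
                 computable_m2 = mcc$computable_m2,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        image_id = rec$image_id, error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(results)) stop_invalid("no image in the manifest could be processed")

  summary <- mcc_timecourse(
    data.frame(group = results$group, m1 = results$m1, m2 = results$m2,
               stringsAsFactors = FALSE))

  files <- c(file.path(outdir, "mcc_results.csv"),
             file.path(outdir, "mcc_summary.csv"))
  write.csv(results, files[1], row.names = FALSE)
  write.csv(summary$summary, files[2], row.names = FALSE)
  report$files <- files
  report$results <- results
  report$failures <- if (length(failures)) do.call(rbind, failures) else NULL
  report$status <- if (length(failures)) "partial" else "ok"
  report <- write_report(report, outdir)
  invisible(report)
}

#' Synthetic end-to-end demonstration run
#'
#' Generates a complete synthetic spatial dataset with known structure — an
#' aggregated (co-localized) pair `typeA`/`typeB` sharing abundance blobs and
#' a spatially random `typeC` — writes it to disk in the standard formats
#' (MTX triplet, coordinate CSV, GMT), then runs the full spatial pipeline on
#' those files.  At the default generator settings the designated aggregated
#' pair yields a join-count z well above the +3 significance cutoff.
#'
#' @param outdir output directory.
#' @param seed integer seed controlling every random draw.
#' @param config optional named list of config overrides (see
#'   [read_run_config()]).
#' @return The `run_report` from [run_spatial()].
#' @export
run_demo <- function(outdir, seed, config = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  base <- list(mode = "synthetic-demo", seed = seed, output_dir = outdir)
  base[names(config)] <- config
  cfg <- read_run_config(base)
  gp <- cfg$generator

  grid <- gen_spot_lattice(gp$n_rows, gp$n_cols)
  pair <- gen_pattern_pair(grid, c("typeA", "typeB"), gp$pattern,
                           params = list(sigma = gp$sigma, n_blobs = gp$n_blobs),
                           seed = seed)
  rand <- gen_celltype_field(grid, "typeC", "random", seed = seed + 2L)
  fields <- c(pair, list(typeC = rand))
  marker_sets <- lapply(setNames(names(fields), names(fields)), function(ct) {
    sprintf("%s_marker_%02d", ct, seq_len(gp$markers_per_type))
  })
  expr <- gen_expression_matrix(
    grid, fields, marker_sets, baseline_mean = gp$baseline_mean,
    effect_size = gp$effect_size, dispersion = gp$dispersion,
    seed = seed + 3L
  )

  input_dir <- file.path(outdir, "inputs")
  write_expression_mtx(expr, file.path(input_dir, "expression"))
  write_coords(grid, file.path(input_dir, "coords.csv"))
  write_gmt(gene_set_collection(marker_sets), file.path(input_dir, "markers.gmt"))

  cfg$mode <- "spatial"
  cfg$inputs$expression <- file.path(input_dir, "expression")
  cfg$inputs$coords <- file.path(input_dir, "coords.csv")
  cfg$inputs$gmt <- file.path(input_dir, "markers.gmt")
  run_spatial(cfg)
}
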
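#' Run configuration
#'
#' Single source of truth for a pipeline run. Analysis parameters (not paths)
#' are echoed into the metadata header of every output file, so two runs of
#' the same configuration in different directories are byte-identical.
#'
#' @param bits quantization depth (default 6).
#' @param distance GLCM pair spacing in pixels (default 5).
#' @param normality_alpha test-selection gate level (default 0.05).
#' @param flag_alpha H/L flag level (default 0.05).
#' @param seed master seed for all randomness in the run.
#' @param n_frames number of synthetic frames for [run_simulate()].
#' @param n_implants cohort size for [run_simulate()].
#' @param timepoints timepoints simulated/reported.
#' @param input_dir,output_dir directories consumed/produced by the `run_*`
#'   steps.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(bits = 6L, distance = 5L, normality_alpha = 0.05,
                       flag_alpha = 0.05, seed = 1L, n_frames = 2L,
                       n_implants = 100L,
                       timepoints = c("initial", "y5", "y10"),
                       input_dir = NULL, output_dir = NULL) {
  if (!is_count(bits) || !is_count(distance))
    stop_input("'bits' and 'distance' must be positive integers")
  if (!is_count(n_frames) || !is_count(n_implants))
    stop_input("'n_frames' and 'n_implants' must be positive integers")
  structure(list(bits = as.integer(bits), distance = as.integer(distance),
                 normality_alpha = normality_alpha, flag_alpha = flag_alpha,
                 seed = as.integer(seed), n_frames = as.integer(n_frames),
                 n_implants = as.integer(n_implants), timepoints = timepoints,
                 input_dir = input_dir, output_dir = output_dir),
            class = "run_config")
}

config_meta <- function(config) {
  list(bits = config$bits, distance = config$distance,
       normality_alpha = config$normality_alpha,
       flag_alpha = config$flag_alpha, seed = config$seed,
       n_frames = config$n_frames, n_implants = config$n_implants,
       timepoints = paste(config$timepoints, collapse = ","))
}

write_table_with_meta <- function(df, path, meta) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, paste, "", collapse = " ")), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a reproducible fixture bundle
#'
#' Writes, under `config$output_dir`: `n_frames` synthetic radiograph frames
#' (`frame_<i>.png`) with JSON ROI sidecars (`frame_<i>.rois.json`), a
#' simulated longitudinal cohort (`cohort.csv`), the generator's ground truth
#' (`ground_truth.json`) and the effective configuration (`config.json`).
#' Everything is a deterministic function of `config$seed`.
#'
#' @param config a [run_config()] with `output_dir` set.
#' @return Character vector of the files written, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  if (is.null(out)) stop_input("run_simulate needs config$output_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, config$n_frames + 1L)
  files <- character(0)
  for (i in seq_len(config$n_frames)) {
    fr <- generate_study_frame(seeds[i])
    img_path <- file.path(out, sprintf("frame_%03d.png", i))
    roi_path <- file.path(out, sprintf("frame_%03d.rois.json", i))
    write_radiograph(fr$image, img_path)
    write_roi_specs(fr$rois, roi_path)
    files <- c(files, img_path, roi_path)
  }
  sim <- generate_cohort(cohort_sim_config(n_implants = config$n_implants,
                                           timepoints = config$timepoints,
                                           seed = seeds[config$n_frames + 1L]))
  cohort_path <- file.path(out, "cohort.csv")
  write_cohort_table(sim$cohort, cohort_path)
  truth <- sim$truth
  truth$config <- NULL # echoed separately in config.json
  truth_path <- file.path(out, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(config_meta(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(files, cohort_path, truth_path, cfg_path))
}

#' Batch texture analysis of a frame directory
#'
#' Analyzes every `*.png` / `*.pgm` frame in `config$input_dir` that has a
#' `<frame>.rois.json` sidecar, computing the texture features and CI of each
#' ROI, and writes `features.csv` to `config$output_dir`. Per-frame failures
#' (e.g. a missing sidecar) are logged to stderr and skipped; the run fails
#' only if no frame can be analyzed.
#'
#' @param config a [run_config()] with `input_dir` and `output_dir` set.
#' @return Path of the feature table, invisibly.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_dir) || is.null(config$output_dir))
    stop_input("run_analyze needs config$input_dir and config$output_dir")
  frames <- sort(list.files(config$input_dir, "\\.(png|pgm|pnm)$",
                            full.names = TRUE))
  if (length(frames) == 0L)
    stop_input("no frames found in '%s'", config$input_dir)
  params <- glcm_params(distance = config$distance)
  rows <- list()
  for (f in frames) {
    sidecar <- sub("\\.(png|pgm|pnm)$", ".rois.json", f)
    res <- tryCatch({
      specs <- read_roi_specs(sidecar)
      img <- read_radiograph(f)
      lapply(specs, function(s)
        as.data.frame(analyze_roi(img, s, params = params,
                                  bits = config$bits)))
    }, error = function(e) {
      message(sprintf("skipping '%s': %s", basename(f), conditionMessage(e)))
      NULL
    })
    rows <- c(rows, res)
  }
  if (length(rows) == 0L)
    stop_input("all frames failed; nothing to write")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$output_dir, "features.csv")
  write_feature_table(do.call(rbind, rows), path, meta = config_meta(config))
  invisible(path)
}

#' Cohort statistics report bundle
#'
#' Reads `cohort.csv` from `config$input_dir` and writes the four report
#' tables to `config$output_dir`: `longitudinal.csv` (per-timepoint CI/MBL
#' summary and regression) with `longitudinal_comparisons.csv`,
#' `covariate_quantitative.csv` / `covariate_categorical.csv`,
#' `design_features.csv` (all design features incl. prosthetic and platform
#' switching, with H/L flags), and `prevalence.csv`, plus `summary.json`.
#' Timepoints absent from the cohort are reported as missing, not errors.
#'
#' @param config a [run_config()] with `input_dir` and `output_dir` set.
#' @return Character vector of files written, invisibly.
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_dir) || is.null(config$output_dir))
    stop_input("run_stats needs config$input_dir and config$output_dir")
  cohort_path <- file.path(config$input_dir, "cohort.csv")
  cohort <- read_cohort_table(cohort_path)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  meta <- config_meta(config)
  files <- character(0)

  lsum <- longitudinal_summary(cohort)
  f <- file.path(out, "longitudinal.csv")
  write_table_with_meta(lsum$table, f, meta); files <- c(files, f)
  if (!is.null(lsum$comparisons)) {
    f <- file.path(out, "longitudinal_comparisons.csv")
    write_table_with_meta(lsum$comparisons, f, meta); files <- c(files, f)
  }

  rel <- covariate_relations(cohort, alpha = config$flag_alpha)
  f <- file.path(out, "covariate_quantitative.csv")
  write_table_with_meta(rel$quantitative, f, meta); files <- c(files, f)
  f <- file.path(out, "covariate_categorical.csv")
  write_table_with_meta(rel$categorical, f, meta); files <- c(files, f)

  feats <- intersect(design_feature_cols, names(cohort))
  dtabs <- list()
  for (feat in feats) {
    tab <- tryCatch(design_feature_table(cohort, feat,
                                         alpha = config$flag_alpha),
                    error = function(e) NULL)
    if (!is.null(tab)) dtabs[[feat]] <- tab
  }
  if (length(dtabs)) {
    f <- file.path(out, "design_features.csv")
    write_table_with_meta(do.call(rbind, c(dtabs, make.row.names = FALSE)),
                          f, meta)
    files <- c(files, f)
  }

  prev <- lapply(intersect(timepoint_levels, cohort_timepoints(cohort)),
                 function(tp) {
    p <- tryCatch(mbl_prevalence(cohort, tp), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    data.frame(timepoint = tp, n = p$n, fraction_zero = p$fraction_zero,
               fraction_positive = p$fraction_positive,
               mean_positive = p$mean_positive, sd_positive = p$sd_positive,
               stringsAsFactors = FALSE)
  })
  prev <- do.call(rbind, prev)
  if (!is.null(prev)) {
    f <- file.path(out, "prevalence.csv")
    write_table_with_meta(prev, f, meta); files <- c(files, f)
  }

  summary_json <- list(
    parameters = meta,
    n_implants = nrow(cohort),
    timepoints = cohort_timepoints(cohort),
    ci_mean = stats::setNames(lsum$table$ci_mean, lsum$table$timepoint),
    mbl_mean = stats::setNames(lsum$table$mbl_mean, lsum$table$timepoint),
    tables = basename(files))
  f <- file.path(out, "summary.json")
  jsonlite::write_json(summary_json, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, f))
}
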
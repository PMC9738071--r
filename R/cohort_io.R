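## Cohort table schema: one row per implant, wide per-timepoint CI/MBL columns.

#' Cohort table column enumerations
#'
#' Named list of the allowed values for every categorical column of the
#' cohort table: implant design features (alloy grade, immersion level,
#' connection, neck microthreads, body shape/threads, apex), prosthetic
#' restoration and patient covariates. Used by [read_cohort_table()] for
#' validation and by [generate_cohort()] when sampling design features.
#'
#' @format A named list of character vectors.
#' @export
cohort_enums <- list(
  titanium_alloy       = c("grade4", "grade5"),
  level                = c("bone", "tissue", "subcrestal"),
  connection_type      = c("internal", "custom"),
  connection_shape     = c("conical", "internal_hexagon", "internal_octagon",
                           "one_piece_abutment"),
  neck_microthreads    = c("yes", "no"),
  body_shape           = c("tapered", "straight"),
  body_threads         = c("buttress", "reverse_buttress", "v_shape",
                           "square", "no_threads"),
  apex_shape           = c("cone", "dome", "flat"),
  apex_hole            = c("round", "none"),
  apex_groove          = c("yes", "no"),
  prosthetic           = c("single_crown", "splinted_crowns", "bridge",
                           "overdenture"),
  platform_switching   = c("yes", "no"),
  sex                  = c("female", "male"),
  smoking              = c("yes", "no"),
  jaw                  = c("maxilla", "mandible"),
  arch_location        = c("anterior", "posterior"),
  augmented            = c("yes", "no"),
  augmentation_technique = c("none", "bone_chips", "bone_substitute",
                             "sinus_lift")
)

design_feature_cols <- c("titanium_alloy", "level", "connection_type",
                         "connection_shape", "neck_microthreads", "body_shape",
                         "body_threads", "apex_shape", "apex_hole",
                         "apex_groove", "prosthetic", "platform_switching")

covariate_num_cols <- c("age_y", "height_m", "weight_kg", "bmi", "tsh_mu_l",
                        "calcium_mmol_dl", "triglycerides_mmol_l")

timepoint_levels <- c("initial", "y5", "y10")

ci_cols  <- paste0("ci_",  timepoint_levels)
mbl_cols <- paste0("mbl_", timepoint_levels)

#' Read and validate a cohort table
#'
#' Reads a CSV with one row per implant: design features, prosthetic type,
#' patient covariates, and per-timepoint corticalization index (`ci_initial`,
#' `ci_y5`, `ci_y10`) and marginal bone loss in mm (`mbl_initial`, `mbl_y5`,
#' `mbl_y10`). Categorical values are checked against [cohort_enums]; CI and
#' MBL must be non-negative where present. Missing values stay missing.
#'
#' @param path CSV file path (UTF-8, '.' decimal separator). Lines starting
#'   with '#' are treated as metadata comments.
#' @return A `data.frame`, one validated row per implant.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_input("cohort table '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_cohort(df)
}

#' @rdname read_cohort_table
#' @param cohort a cohort `data.frame` (e.g. from [generate_cohort()]).
#' @export
write_cohort_table <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_cohort <- function(df) {
  if (!"implant_id" %in% names(df))
    stop_input("cohort table lacks an 'implant_id' column")
  for (col in intersect(names(cohort_enums), names(df))) {
    vals <- df[[col]]
    bad <- which(!is.na(vals) & vals != "" & !vals %in% cohort_enums[[col]])
    if (length(bad))
      stop_input("cohort table: invalid value '%s' in column '%s', row %d",
                 vals[bad[1]], col, bad[1])
    df[[col]][!is.na(vals) & vals == ""] <- NA
  }
  for (col in intersect(c(ci_cols, mbl_cols, covariate_num_cols), names(df))) {
    if (!is.numeric(df[[col]]))
      stop_input("cohort table: column '%s' must be numeric", col)
  }
  for (col in intersect(c(ci_cols, mbl_cols), names(df))) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stop_input("cohort table: negative value in column '%s', row %d",
                 col, bad[1])
  }
  df
}

#' Write / read a texture feature table
#'
#' One row per analyzed ROI with the stable column order
#' `roi_id, label, timepoint, n_pixels, mean_od, difentr_avg, lngremph_avg,
#' ci`. Values round-trip losslessly at (at least) 12 significant digits.
#'
#' @param features a list of `texture_features` objects (from [analyze_roi()])
#'   or an already-assembled `data.frame`.
#' @param path CSV destination.
#' @param meta optional named list echoed as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, meta = NULL) {
  if (is.data.frame(features)) {
    df <- features
  } else {
    if (!is.list(features) || length(features) == 0L)
      stop_input("'features' must be a non-empty list of texture_features")
    df <- do.call(rbind, lapply(features, as.data.frame))
  }
  if (nrow(df) == 0L) stop_input("no feature rows to write")
  want <- c("roi_id", "label", "timepoint", "n_pixels", "mean_od",
            "difentr_avg", "lngremph_avg", "ci")
  df <- df[, want]
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, paste, "", collapse = " ")), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_input("feature table '%s' does not exist", path)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
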
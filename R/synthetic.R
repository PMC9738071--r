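#' Texture simulation parameters
#'
#' Parameter set for the smoothed-Gaussian-field texture proxy used in place
#' of the request-only clinical radiographs. The three tissue classes emulate
#' the radiographic appearance the analysis must discriminate:
#'
#' * `trabecular` — heterogeneous, mid-density cancellous bone: short
#'   correlation length (4 px), mean gray 120, high contrast (SD 40);
#' * `cortical` — corticalized bone: bright (mean 190), homogeneous
#'   (contrast SD 12), long correlation length (12 px), hence long
#'   equal-level runs and low difference entropy;
#' * `soft_tissue` — dark, homogeneous bone-loss/soft-tissue areas:
#'   mean 60, contrast SD 8.
#'
#' The field is Gaussian white noise smoothed so its autocorrelation is
#' `exp(-d^2 / (2 * correlation_length_px^2))`, rescaled to
#' `mean_level`/`contrast_sd`, plus i.i.d. sensor noise. It reproduces the
#' gray-level statistics the features consume, not bone physics.
#'
#' @param tissue_class `"trabecular"`, `"cortical"` or `"soft_tissue"`.
#' @param correlation_length_px positive Gaussian autocorrelation scale.
#' @param mean_level target mean gray level in `[0, 255]`.
#' @param contrast_sd standard deviation of the structural component.
#' @param sensor_noise_sd i.i.d. detector noise SD (default 3).
#' @param patch_shape `c(rows, cols)` of the generated patch.
#' @param seed integer seed; identical seeds give bit-identical patches.
#' @return An object of class `texture_params`.
#' @export
texture_params <- function(tissue_class = c("trabecular", "cortical",
                                            "soft_tissue"),
                           correlation_length_px = NULL, mean_level = NULL,
                           contrast_sd = NULL, sensor_noise_sd = 3,
                           patch_shape = c(50L, 50L), seed = 1L) {
  tissue_class <- match.arg(tissue_class)
  defaults <- switch(tissue_class,
    trabecular  = list(corr = 4,  mean = 120, sd = 40),
    cortical    = list(corr = 12, mean = 190, sd = 12),
    soft_tissue = list(corr = 8,  mean = 60,  sd = 8))
  correlation_length_px <- correlation_length_px %||% defaults$corr
  mean_level <- mean_level %||% defaults$mean
  contrast_sd <- contrast_sd %||% defaults$sd
  if (!is_scalar_num(correlation_length_px) || correlation_length_px <= 0)
    stop_input("'correlation_length_px' must be a positive number")
  if (!is_scalar_num(mean_level) || mean_level < 0 || mean_level > 255)
    stop_input("'mean_level' must lie in [0, 255]")
  if (!is_scalar_num(contrast_sd) || contrast_sd < 0)
    stop_input("'contrast_sd' must be non-negative")
  if (!is_scalar_num(sensor_noise_sd) || sensor_noise_sd < 0)
    stop_input("'sensor_noise_sd' must be non-negative")
  if (length(patch_shape) != 2L || !all(vapply(patch_shape, is_count, TRUE)))
    stop_input("'patch_shape' must be two positive integers")
  structure(list(tissue_class = tissue_class,
                 correlation_length_px = correlation_length_px,
                 mean_level = mean_level, contrast_sd = contrast_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 patch_shape = as.integer(patch_shape),
                 seed = as.integer(seed)),
            class = "texture_params")
}

## separable Gaussian smoothing of a noise field, 'valid' region only
smooth_field <- function(rows, cols, corr_len) {
  s <- corr_len / sqrt(2) # kernel sd; field autocorr scale becomes corr_len
  m <- max(1L, as.integer(ceiling(3 * s)))
  kern <- stats::dnorm(seq(-m, m), sd = s)
  kern <- kern / sum(kern)
  z <- matrix(stats::rnorm((rows + 2L * m) * (cols + 2L * m)),
              rows + 2L * m, cols + 2L * m)
  z <- stats::filter(z, kern, sides = 2)                 # smooth columns
  z <- t(stats::filter(t(z), kern, sides = 2))           # smooth rows
  z[(m + 1L):(m + rows), (m + 1L):(m + cols), drop = FALSE]
}

#' Generate one texture patch
#'
#' Draws the smoothed-Gaussian-field texture described in [texture_params()],
#' standardizes it to the configured mean/contrast, adds sensor noise, clips
#' to `[0, 255]` and quantizes to 8 bits.
#'
#' @param params a [texture_params()].
#' @return An 8-bit [radiograph()] of dimension `patch_shape`.
#' @examples
#' p <- generate_texture_patch(texture_params("cortical", seed = 7))
#' mean(p$pixels)
#' @export
generate_texture_patch <- function(params) {
  stopifnot(inherits(params, "texture_params"))
  withr::with_seed(params$seed, {
    f <- smooth_field(params$patch_shape[1], params$patch_shape[2],
                      params$correlation_length_px)
    f <- (f - mean(f)) / stats::sd(f)
    x <- f * params$contrast_sd + params$mean_level +
      stats::rnorm(length(f), sd = params$sensor_noise_sd)
    px <- matrix(as.integer(pmin.int(pmax.int(round(x), 0), 255)),
                 params$patch_shape[1], params$patch_shape[2])
    radiograph(px, bit_depth = 8L,
               image_id = sprintf("%s_seed%d", params$tissue_class, params$seed))
  })
}

#' Generate a synthetic study frame
#'
#' Builds one 476 x 620, 70 um/px radiograph-like canvas mimicking the layout
#' of a standardized peri-implant intraoral radiograph: trabecular background,
#' a dark soft-tissue band along the top (crest line), a dark implant
#' silhouette, a corticalized collar around the implant, and two
#' protocol-sized ROIs — a `peri_implant` ROI in the collar at the implant
#' neck and a distant `reference` ROI in intact trabecular bone. Each ROI
#' resolves to exactly 1500 pixels.
#'
#' @param seed integer seed; fixed seed gives a byte-identical frame.
#' @param timepoint timepoint tag stored in the ROI specs.
#' @return List with `image` (a [radiograph()]) and `rois` (list of two
#'   [roi_spec()], `peri_implant` and `reference`).
#' @export
generate_study_frame <- function(seed = 1L, timepoint = "initial") {
  nr <- 476L; nc <- 620L
  seeds <- derive_seeds(seed, 4L)
  shape <- c(nr, nc)
  base <- generate_texture_patch(
    texture_params("trabecular", patch_shape = shape, seed = seeds[1]))$pixels
  cort <- generate_texture_patch(
    texture_params("cortical", patch_shape = shape, seed = seeds[2]))$pixels
  soft <- generate_texture_patch(
    texture_params("soft_tissue", patch_shape = shape, seed = seeds[3]))$pixels
  px <- base
  crest <- 60L
  px[1:crest, ] <- soft[1:crest, ]
  # implant silhouette: tapered vertical slab from the crest down
  cc <- nc %/% 2L
  r_top <- crest + 1L; r_bot <- r_top + 259L
  w_top <- 18; w_bot <- 8
  collar <- 40L
  dark <- withr::with_seed(seeds[4], {
    matrix(as.integer(pmax(round(stats::rnorm(nr * nc, 14, 2)), 0L)), nr, nc)
  })
  for (r in r_top:r_bot) {
    w <- round(w_top + (w_bot - w_top) * (r - r_top) / (r_bot - r_top))
    px[r, (cc - w):(cc + w)] <- dark[r, (cc - w):(cc + w)]
    b <- min(w + collar, nc - cc - 1L)
    left <- (cc - b):(cc - w - 1L)
    right <- (cc + w + 1L):(cc + b)
    px[r, c(left, right)] <- cort[r, c(left, right)]
  }
  img <- radiograph(px, bit_depth = 8L, pixel_spacing_mm = 0.07,
                    image_id = sprintf("frame_seed%d", seed))
  # peri-implant ROI: 50 x 30 in the collar at the neck (0-based half-open)
  peri_r0 <- r_top + 4L; peri_c0 <- cc + w_top + 4L
  peri <- roi_spec(sprintf("peri_seed%d", seed), "peri_implant", timepoint,
                   rect = c(peri_r0 - 1L, peri_c0 - 1L,
                            peri_r0 + 49L, peri_c0 + 29L))
  # reference ROI: 30 x 50 in distant intact bone
  ref <- roi_spec(sprintf("ref_seed%d", seed), "reference", timepoint,
                  rect = c(379L, 59L, 409L, 109L))
  list(image = img, rois = list(peri_implant = peri, reference = ref))
}

#' Longitudinal cohort simulation configuration
#'
#' Stated world for the cohort simulator. Defaults mirror the published
#' cohort-level structure: per-timepoint CI mean/SD (200/146, 282/182,
#' 261/168), zero-inflated MBL with zero fractions 0.867 / 0.544 / 0.444 and
#' positive-component mean/SD 1.93/1.85, 1.91/1.26, 2.67/2.04 mm, a weak
#' positive CI-MBL coupling calibrated to population correlations 0 (n.s.),
#' 0.11 and 0.12 at the three timepoints, and signed covariate effects
#' (age +, height -, weight -, TSH +, calcium -, triglycerides +).
#'
#' CI is drawn from a zero-left-truncated normal whose parent parameters are
#' moment-matched so the truncated distribution has exactly the configured
#' mean/SD; likewise for the positive MBL component. `ci_mbl_slope` may be a
#' single value or a per-timepoint named vector; `NULL` (default) derives the
#' slopes from `ci_mbl_cc` and the configured moments.
#'
#' @param n_implants number of implants (rows) to simulate.
#' @param timepoints subset of `c("initial", "y5", "y10")`.
#' @param ci_mean,ci_sd per-timepoint CI marginal moments.
#' @param mbl_zero_fraction per-timepoint probability of zero MBL.
#' @param mbl_mean_pos,mbl_sd_pos per-timepoint moments of MBL given MBL > 0.
#' @param ci_mbl_cc per-timepoint target population correlation between CI
#'   and MBL (used when `ci_mbl_slope` is `NULL`).
#' @param ci_mbl_slope CI units per mm of MBL, per timepoint (overrides
#'   `ci_mbl_cc`).
#' @param covariate_effects named vector: latent CI shift per +1 SD of each
#'   quantitative covariate.
#' @param design_feature_frequencies named list of per-option sampling
#'   probabilities for the design-feature columns (defaults approximate the
#'   published implant mix).
#' @param design_ci_effects optional named list (feature -> named option
#'   vector) of latent CI shifts, for injection-recovery experiments.
#' @param seed integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_implants = 500L,
    timepoints = c("initial", "y5", "y10"),
    ci_mean = c(initial = 200, y5 = 282, y10 = 261),
    ci_sd = c(initial = 146, y5 = 182, y10 = 168),
    mbl_zero_fraction = c(initial = 0.867, y5 = 0.544, y10 = 0.444),
    mbl_mean_pos = c(initial = 1.93, y5 = 1.91, y10 = 2.67),
    mbl_sd_pos = c(initial = 1.85, y5 = 1.26, y10 = 2.04),
    ci_mbl_cc = c(initial = 0, y5 = 0.11, y10 = 0.12),
    ci_mbl_slope = NULL,
    covariate_effects = c(age_y = 15, height_m = -15, weight_kg = -15,
                          tsh_mu_l = 15, calcium_mmol_dl = -15,
                          triglycerides_mmol_l = 15),
    design_feature_frequencies = NULL,
    design_ci_effects = NULL,
    seed = 1L) {
  if (!is_count(n_implants))
    stop_input("'n_implants' must be a positive integer")
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  pick <- function(x) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, 3L), timepoint_levels)
    x[timepoints]
  }
  ci_mean <- pick(ci_mean); ci_sd <- pick(ci_sd)
  mbl_zero_fraction <- pick(mbl_zero_fraction)
  mbl_mean_pos <- pick(mbl_mean_pos); mbl_sd_pos <- pick(mbl_sd_pos)
  ci_mbl_cc <- pick(ci_mbl_cc)
  if (any(ci_sd < 0) || any(mbl_sd_pos < 0))
    stop_input("standard deviations must be non-negative")
  if (any(mbl_zero_fraction < 0 | mbl_zero_fraction > 1))
    stop_input("'mbl_zero_fraction' entries must lie in [0, 1]")
  if (any(ci_mean < 0) || any(mbl_mean_pos < 0))
    stop_input("means must be non-negative")
  if (!is.null(ci_mbl_slope)) ci_mbl_slope <- pick(ci_mbl_slope)
  structure(list(
    n_implants = as.integer(n_implants), timepoints = timepoints,
    ci_mean = ci_mean, ci_sd = ci_sd,
    mbl_zero_fraction = mbl_zero_fraction,
    mbl_mean_pos = mbl_mean_pos, mbl_sd_pos = mbl_sd_pos,
    ci_mbl_cc = ci_mbl_cc, ci_mbl_slope = ci_mbl_slope,
    covariate_effects = covariate_effects,
    design_feature_frequencies = design_feature_frequencies %||%
      default_design_frequencies(),
    design_ci_effects = design_ci_effects,
    seed = as.integer(seed)), class = "cohort_sim_config")
}

## option frequencies approximating the published implant mix
default_design_frequencies <- function() {
  list(
    titanium_alloy = c(grade4 = 0.09, grade5 = 0.91),
    level = c(bone = 0.86, tissue = 0.06, subcrestal = 0.08),
    connection_type = c(internal = 0.94, custom = 0.06),
    connection_shape_internal = c(conical = 0.35, internal_hexagon = 0.62,
                                  internal_octagon = 0.03),
    neck_microthreads = c(yes = 0.65, no = 0.35),
    body_shape = c(tapered = 0.85, straight = 0.15),
    body_threads = c(buttress = 0.02, reverse_buttress = 0.48,
                     v_shape = 0.17, square = 0.25, no_threads = 0.08),
    apex_shape = c(cone = 0.06, dome = 0.60, flat = 0.34),
    apex_hole = c(round = 0.05, none = 0.95),
    apex_groove = c(yes = 0.90, no = 0.10),
    prosthetic = c(single_crown = 0.32, splinted_crowns = 0.35,
                   bridge = 0.26, overdenture = 0.07),
    platform_switching = c(yes = 0.19, no = 0.81),
    sex = c(female = 0.55, male = 0.45),
    smoking = c(yes = 0.25, no = 0.75),
    jaw = c(maxilla = 0.5, mandible = 0.5),
    arch_location = c(anterior = 0.3, posterior = 0.7),
    augmented = c(yes = 0.2, no = 0.8),
    augmentation_technique_given = c(bone_chips = 0.4, bone_substitute = 0.4,
                                     sinus_lift = 0.2)
  )
}

## parent (mean, sd) of a zero-left-truncated normal whose truncated
## distribution has moments (target_mean, target_sd)
match_truncnorm <- function(target_mean, target_sd) {
  target_mean <- unname(target_mean); target_sd <- unname(target_sd)
  obj <- function(par) {
    m <- par[1]; s <- exp(par[2])
    em <- truncnorm::etruncnorm(a = 0, mean = m, sd = s)
    es <- sqrt(truncnorm::vtruncnorm(a = 0, mean = m, sd = s))
    (em / target_mean - 1)^2 + (es / target_sd - 1)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

## analytic moments of the zero-inflated MBL marginal
mbl_marginal_moments <- function(zero_frac, mean_pos, sd_pos) {
  zero_frac <- unname(zero_frac); mean_pos <- unname(mean_pos)
  sd_pos <- unname(sd_pos)
  p <- 1 - zero_frac
  m <- p * mean_pos
  v <- p * (sd_pos^2 + mean_pos^2) - m^2
  c(mean = m, sd = sqrt(v))
}

#' Simulate a longitudinal implant cohort
#'
#' Draws `n_implants` records under the stated world of a
#' [cohort_sim_config()]: design features and covariates sampled at the
#' configured frequencies; zero-inflated MBL with nested onset (an implant
#' with bone loss at one timepoint still has it later, matching the
#' monotonically shrinking zero fractions); CI from a moment-matched
#' zero-truncated normal whose latent mean is linearly coupled to the
#' implant's centred MBL and shifted by the signed covariate effects.
#'
#' @param config a [cohort_sim_config()].
#' @return List with `cohort` (data.frame in the [read_cohort_table()] schema)
#'   and `truth` (ground-truth parameters actually used: matched parent
#'   moments, per-timepoint slopes, implied population correlations, covariate
#'   betas), for parameter-recovery tests.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_implants
  tps <- config$timepoints
  fr <- config$design_feature_frequencies
  draw <- function(freq) sample(names(freq), n, replace = TRUE, prob = freq)
  rtrunc0 <- function(n, mean, sd) truncnorm::rtruncnorm(n, a = 0, mean = mean, sd = sd)

  mblm <- vapply(tps, function(tp) mbl_marginal_moments(
    config$mbl_zero_fraction[tp], config$mbl_mean_pos[tp],
    config$mbl_sd_pos[tp]), numeric(2))
  slopes <- if (!is.null(config$ci_mbl_slope)) {
    config$ci_mbl_slope
  } else {
    stats::setNames(vapply(tps, function(tp) {
      sdm <- mblm["sd", tp]
      if (sdm == 0) 0 else config$ci_mbl_cc[tp] * config$ci_sd[tp] / sdm
    }, 0), tps)
  }
  parents <- vapply(tps, function(tp)
    match_truncnorm(config$ci_mean[tp], config$ci_sd[tp]), numeric(2))
  pos_parents <- vapply(tps, function(tp)
    match_truncnorm(config$mbl_mean_pos[tp], config$mbl_sd_pos[tp]), numeric(2))

  withr::with_seed(config$seed, {
    cohort <- data.frame(implant_id = sprintf("imp%05d", seq_len(n)),
                         stringsAsFactors = FALSE)
    cohort$titanium_alloy <- draw(fr$titanium_alloy)
    cohort$level <- draw(fr$level)
    cohort$connection_type <- draw(fr$connection_type)
    cohort$connection_shape <- ifelse(
      cohort$connection_type == "custom", "one_piece_abutment",
      draw(fr$connection_shape_internal))
    cohort$neck_microthreads <- draw(fr$neck_microthreads)
    cohort$body_shape <- draw(fr$body_shape)
    cohort$body_threads <- draw(fr$body_threads)
    cohort$apex_shape <- draw(fr$apex_shape)
    cohort$apex_hole <- draw(fr$apex_hole)
    cohort$apex_groove <- draw(fr$apex_groove)
    cohort$prosthetic <- draw(fr$prosthetic)
    cohort$platform_switching <- draw(fr$platform_switching)
    cohort$sex <- draw(fr$sex)
    cohort$smoking <- draw(fr$smoking)
    cohort$jaw <- draw(fr$jaw)
    cohort$arch_location <- draw(fr$arch_location)
    cohort$augmented <- draw(fr$augmented)
    cohort$augmentation_technique <- ifelse(
      cohort$augmented == "yes", draw(fr$augmentation_technique_given), "none")
    cohort$age_y <- round(rtrunc0(n, 47, 13))
    cohort$height_m <- round(rtrunc0(n, 1.70, 0.09), 2)
    cohort$weight_kg <- round(rtrunc0(n, 75, 19))
    cohort$bmi <- round(cohort$weight_kg / cohort$height_m^2, 1)
    cohort$tsh_mu_l <- round(rtrunc0(n, 1.73, 1.07), 2)
    cohort$calcium_mmol_dl <- round(rtrunc0(n, 2.39, 0.61), 2)
    cohort$triglycerides_mmol_l <- round(rtrunc0(n, 1.24, 0.57), 2)

    # signed covariate contribution to the latent CI (per +1 SD of covariate)
    cov_sd <- c(age_y = 13, height_m = 0.09, weight_kg = 19, tsh_mu_l = 1.07,
                calcium_mmol_dl = 0.61, triglycerides_mmol_l = 0.57)
    cov_mean <- c(age_y = 47, height_m = 1.70, weight_kg = 75, tsh_mu_l = 1.73,
                  calcium_mmol_dl = 2.39, triglycerides_mmol_l = 1.24)
    eff <- config$covariate_effects
    eff <- eff[names(eff) %in% names(cov_sd)]
    cov_shift <- rep(0, n)
    for (cv in names(eff))
      cov_shift <- cov_shift +
        eff[[cv]] * (cohort[[cv]] - cov_mean[cv]) / cov_sd[cv]

    design_shift <- rep(0, n)
    for (feat in names(config$design_ci_effects %||% list())) {
      shifts <- config$design_ci_effects[[feat]]
      hit <- cohort[[feat]] %in% names(shifts)
      design_shift[hit] <- design_shift[hit] + shifts[cohort[[feat]][hit]]
    }

    onset <- stats::runif(n) # nested bone-loss onset across timepoints
    for (tp in tps) {
      positive <- onset > config$mbl_zero_fraction[tp]
      mbl <- numeric(n)
      npos <- sum(positive)
      if (npos > 0) # 0.01 mm floor: rounding must not erase a positive loss
        mbl[positive] <- pmax(round(rtrunc0(npos, pos_parents["mean", tp],
                                            pos_parents["sd", tp]), 2), 0.01)
      m <- parents["mean", tp]; s <- parents["sd", tp]
      extra_var <- slopes[tp]^2 * mblm["sd", tp]^2 + sum(eff^2)
      s_resid <- sqrt(max(s^2 - extra_var, (0.1 * s)^2))
      mu_i <- m + slopes[tp] * (mbl - mblm["mean", tp]) + cov_shift +
        design_shift
      ci <- rtrunc0(n, mu_i, s_resid)
      cohort[[paste0("mbl_", tp)]] <- mbl
      cohort[[paste0("ci_", tp)]] <- round(ci, 1)
    }
    truth <- list(
      config = config, ci_parent = parents, mbl_pos_parent = pos_parents,
      mbl_marginal = mblm, ci_mbl_slope = slopes,
      implied_cc = stats::setNames(
        slopes * mblm["sd", ] / config$ci_sd[tps], tps),
      covariate_effects = eff)
    list(cohort = cohort, truth = truth)
  })
}
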
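#' Normalize and quantize an ROI
#'
#' Implements the standard texture-analysis preprocessing for radiograph ROIs
#' (the MaZda convention): gray levels are windowed to `mu +/- 3 sigma`
#' computed from the raw ROI pixels, mapped linearly onto `Ng = 2^bits`
#' optical-density levels, and clipped. With `lo = mu - 3*sigma` and
#' `hi = mu + 3*sigma`,
#'
#' `level(x) = clamp(floor((x - lo) / (hi - lo) * Ng), 0, Ng - 1) + 1`
#'
#' so levels run from 1 to `Ng` (default 64, i.e. 6 bits). The windowing makes
#' every downstream feature exactly invariant to affine rescaling of the raw
#' gray levels (`x -> a*x + b`, `a > 0`): the window co-transforms with the
#' data. `sigma` is the sample standard deviation. A constant ROI
#' (`sigma = 0`) maps to level 1 everywhere and is flagged degenerate rather
#' than raising an error, so batch runs survive pathological ROIs.
#'
#' @param image a [radiograph()].
#' @param roi an [roi_spec()] or resolved `roi_pixels` (see [resolve_roi()]).
#' @param bits quantization depth; `Ng = 2^bits` levels (default 6 bits).
#' @return An object of class `normalized_roi`: list with `levels` (integer
#'   matrix over the ROI bounding box, `NA` outside the ROI), `Ng`, raw-ROI
#'   `mu` and `sigma`, `degenerate` flag, pixel count `n`, and the ROI's
#'   `roi_id`/`label`/`timepoint`.
#' @export
normalize_quantize <- function(image, roi, bits = 6L) {
  stopifnot(inherits(image, "radiograph"))
  if (inherits(roi, "roi_spec")) roi <- resolve_roi(image, roi)
  stopifnot(inherits(roi, "roi_pixels"))
  if (!is_count(bits) || bits < 1 || bits > 8)
    stop_input("'bits' must be an integer in 1..8")
  Ng <- as.integer(2^bits)
  x <- as.numeric(image$pixels[cbind(roi$rows, roi$cols)])
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (is.na(sigma)) sigma <- 0 # single-pixel ROI
  r0 <- min(roi$rows); c0 <- min(roi$cols)
  lev <- matrix(NA_integer_, max(roi$rows) - r0 + 1L, max(roi$cols) - c0 + 1L)
  if (sigma == 0) {
    lev[cbind(roi$rows - r0 + 1L, roi$cols - c0 + 1L)] <- 1L
    degenerate <- TRUE
  } else {
    lev[cbind(roi$rows - r0 + 1L, roi$cols - c0 + 1L)] <-
      quantize_gray(x, mu, sigma, Ng)
    degenerate <- FALSE
  }
  structure(list(levels = lev, Ng = Ng, mu = mu, sigma = sigma,
                 degenerate = degenerate, n = roi$n, roi_id = roi$roi_id,
                 label = roi$label, timepoint = roi$timepoint),
            class = "normalized_roi")
}

#' @rdname normalize_quantize
#' @param x raw gray value(s).
#' @param mu,sigma window centre and scale (raw-ROI mean and SD).
#' @param Ng number of output levels.
#' @return `quantize_gray()`: integer level(s) in `1..Ng`.
#' @examples
#' quantize_gray(c(70, 100, 135), mu = 100, sigma = 10, Ng = 64) # 1, 33, 64
#' @export
quantize_gray <- function(x, mu, sigma, Ng = 64L) {
  if (sigma <= 0) stop_input("'sigma' must be positive; constant ROIs are handled by normalize_quantize()")
  lo <- mu - 3 * sigma
  hi <- mu + 3 * sigma
  k <- floor((x - lo) / (hi - lo) * Ng)
  as.integer(pmin.int(pmax.int(k, 0), Ng - 1L)) + 1L
}

#' Build a quantized ROI directly from a level matrix
#'
#' Constructor for a `normalized_roi` from already-quantized levels, used when
#' textures are defined programmatically (small synthetic patterns, oracle
#' sweeps) rather than extracted from a radiograph. `NA` entries mark pixels
#' outside the ROI.
#'
#' @param levels integer matrix with values in `1..Ng` (or `NA`).
#' @param Ng number of optical-density levels.
#' @return A `normalized_roi`.
#' @export
normalized_roi <- function(levels, Ng = 64L) {
  if (!is.matrix(levels) || length(levels) == 0L)
    stop_input("'levels' must be a non-empty matrix")
  storage.mode(levels) <- "integer"
  rng <- range(levels, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] < 1L || rng[2] > Ng)
    stop_input("levels must lie in 1..Ng")
  n <- sum(!is.na(levels))
  structure(list(levels = levels, Ng = as.integer(Ng), mu = NA_real_,
                 sigma = NA_real_, degenerate = rng[1] == rng[2], n = n,
                 roi_id = "adhoc", label = "reference", timepoint = "initial"),
            class = "normalized_roi")
}

#' GLCM parameters
#'
#' Pixel pairs for the co-occurrence analysis are taken at a spacing of
#' `distance` lattice steps (default 5) along the four standard directions
#' 0, 45, 90 and 135 degrees, i.e. offsets `(0,d), (-d,d), (-d,0), (-d,-d)`
#' in (row, col) convention. Diagonal spacing is `d` lattice steps per axis
#' (Chebyshev distance `d`).
#'
#' @param distance positive integer pair spacing.
#' @param directions optional list of length-2 integer offsets overriding the
#'   four defaults.
#' @return An object of class `glcm_params`.
#' @export
glcm_params <- function(distance = 5L, directions = NULL) {
  if (!is_count(distance)) stop_input("'distance' must be a positive integer")
  d <- as.integer(distance)
  if (is.null(directions))
    directions <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
  ok <- vapply(directions, function(o)
    length(o) == 2L && all(o == round(o)) && any(o != 0L), logical(1))
  if (!all(ok)) stop_input("each direction must be a non-zero length-2 integer offset")
  structure(list(distance = d, directions = lapply(directions, as.integer)),
            class = "glcm_params")
}

#' First-order mean optical density
#'
#' The mean of the normalized gray-level histogram, `sum_i i * p(i)` with
#' `p(i)` the fraction of ROI pixels at level `i` — equivalently the mean
#' quantized level of the ROI. Bright (radio-opaque, corticalized) bone gives
#' high values. Computed on the normalized, quantized levels so that all
#' features describe one prepared ROI.
#'
#' @param nroi a `normalized_roi`.
#' @return Mean level in `[1, Ng]`.
#' @export
mean_optical_density <- function(nroi) {
  stopifnot(inherits(nroi, "normalized_roi"))
  mean(nroi$levels[!is.na(nroi$levels)])
}

#' GLCM difference histogram
#'
#' Enumerates every ordered pixel pair `(p, p + offset)` and
#' `(p, p - offset)` with both members inside the ROI (symmetric counting)
#' and tallies the absolute level difference `k = |i - j|`. The normalized
#' tally is the difference histogram `p_{x-y}(k)`, `k = 0..Ng-1`, from which
#' the difference entropy is computed. Pairs never bridge pixels outside the
#' ROI mask.
#'
#' @param nroi a `normalized_roi`.
#' @param offset length-2 integer `(row, col)` lattice offset, e.g. `c(0, 5)`.
#' @return An object of class `difference_histogram`: list with `probs`
#'   (numeric vector indexed by `k = 0..Ng-1`, summing to 1), `pair_count`
#'   and `offset`.
#' @export
glcm_difference_histogram <- function(nroi, offset) {
  stopifnot(inherits(nroi, "normalized_roi"))
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop_input("'offset' must be a non-zero length-2 integer vector")
  M <- nroi$levels
  nr <- nrow(M); nc <- ncol(M)
  dr <- offset[1]; dc <- offset[2]
  if (nr - abs(dr) < 1L || nc - abs(dc) < 1L)
    stop_input("insufficient extent: no pixel pair fits offset (%d, %d)", dr, dc)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  d <- abs(M[r1, c1, drop = FALSE] - M[r1 + dr, c1 + dc, drop = FALSE])
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    stop_input("insufficient extent: no in-ROI pixel pair for offset (%d, %d)",
               dr, dc)
  tab <- tabulate(d + 1L, nroi$Ng) * 2L # each unordered pair counted both ways
  structure(list(probs = tab / sum(tab), pair_count = 2L * length(d),
                 offset = offset),
            class = "difference_histogram")
}

#' Difference entropy (DifEntr)
#'
#' Shannon entropy of the GLCM difference histogram using the common (base-10)
#' logarithm: `-sum_k p(k) log10 p(k)` with `0 * log10(0) := 0`. High values
#' indicate the chaotic, scattered gray-level arrangement typical of
#' cancellous (trabecular) bone; corticalized bone scores low. Bounded by
#' `log10(Ng)`.
#'
#' @param dh a `difference_histogram`.
#' @return Non-negative entropy value.
#' @export
difference_entropy <- function(dh) {
  stopifnot(inherits(dh, "difference_histogram"))
  p <- dh$probs[dh$probs > 0]
  -sum(p * log10(p))
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of identical quantized level along lines of the given
#' direction. Only the direction of `offset` matters (it is reduced to a unit
#' lattice step): runs are contiguous by definition, while the GLCM spacing
#' applies to pixel pairs only. A run is broken wherever the next lattice
#' point leaves the ROI, so runs never bridge non-ROI pixels.
#'
#' @param nroi a `normalized_roi`.
#' @param offset length-2 integer direction, e.g. `c(0, 5)` (scanned as
#'   `(0, 1)` lines).
#' @return An object of class `run_length_matrix`: list with `counts`
#'   (matrix, `Ng` rows, one column per run length), `direction` (unit step)
#'   and `n_pixels` covered.
#' @export
run_length_matrix <- function(nroi, offset) {
  stopifnot(inherits(nroi, "normalized_roi"))
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop_input("'offset' must be a non-zero length-2 integer vector")
  u <- sign(offset)
  M <- nroi$levels
  key <- if (u[1] == 0L) {
    .row(dim(M))
  } else if (u[2] == 0L) {
    .col(dim(M))
  } else if (u[1] == u[2]) {
    .col(dim(M)) - .row(dim(M)) # main diagonals, direction (1, 1)
  } else {
    .row(dim(M)) + .col(dim(M)) # anti-diagonals, direction (-1, 1)
  }
  lines <- split(M, key)
  v <- unlist(lapply(lines, function(x) c(x, NA_integer_)), use.names = FALSE)
  r <- rle(v)
  keep <- !is.na(r$values)
  lev <- r$values[keep]
  len <- r$lengths[keep]
  if (length(lev) == 0L) stop_input("ROI contains no pixels")
  Ng <- nroi$Ng
  maxk <- max(len)
  counts <- matrix(tabulate((len - 1L) * Ng + lev, Ng * maxk), Ng, maxk)
  structure(list(counts = counts, direction = u,
                 n_pixels = sum(as.numeric(len))),
            class = "run_length_matrix")
}

#' Long-run emphasis (LngREmph)
#'
#' Run-length statistic weighting each run by its squared length:
#' `sum_{i,k} k^2 p(i,k) / sum_{i,k} p(i,k)`. Minimum 1 (all runs of length
#' one); large for the thick, uniformly dense radio-opaque structures seen in
#' corticalized bone.
#'
#' @param rlm a `run_length_matrix`.
#' @return Value `>= 1`.
#' @export
long_run_emphasis <- function(rlm) {
  stopifnot(inherits(rlm, "run_length_matrix"))
  s <- colSums(rlm$counts)
  total <- sum(s)
  if (total == 0) stop_input("run-length matrix contains no runs")
  k <- seq_along(s)
  sum(s * k^2) / total
}

#' Arithmetic mean over the four analysis directions
#'
#' Second-order features are computed per direction (0, 45, 90, 135 degrees)
#' and the arithmetic mean of the four primary values is carried forward, so
#' the analysis is not directional.
#'
#' @param values numeric vector of exactly 4 finite per-direction values.
#' @return Their arithmetic mean.
#' @export
directional_average <- function(values) {
  if (length(values) != 4L || !all(is.finite(values)))
    stop_input("'values' must be exactly 4 finite numbers")
  mean(values)
}

#' Corticalization index (CI)
#'
#' Composite radiomic score: the product of the long-run measure and the mean
#' optical density of the site, divided by the difference entropy —
#'
#' `CI = mean_od * LngREmph_avg / DifEntr_avg`.
#'
#' High values indicate bright, homogeneous texture with long uniform runs
#' (corticalized bone); trabecular bone scores lower. When the averaged
#' difference entropy is zero (a degenerate, constant ROI) the index is
#' undefined and returned as `NA` with a warning, so batch runs continue.
#'
#' @param mean_od mean optical density (first-order).
#' @param lngremph_avg direction-averaged long-run emphasis.
#' @param difentr_avg direction-averaged difference entropy.
#' @return CI value (`>= 0`), or `NA` when undefined.
#' @examples
#' corticalization_index(30, 10, 1.5) # 200
#' @export
corticalization_index <- function(mean_od, lngremph_avg, difentr_avg) {
  if (!is_scalar_num(mean_od) || !is_scalar_num(lngremph_avg) ||
      !is_scalar_num(difentr_avg))
    stop_input("all three feature values must be finite scalars")
  if (difentr_avg < 0) stop_input("'difentr_avg' must be non-negative")
  if (difentr_avg == 0) {
    warning("difference entropy is 0; corticalization index undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean_od * lngremph_avg / difentr_avg
}

#' Full texture analysis of one ROI
#'
#' Composes the pipeline: resolve the ROI, normalize (`mu +/- 3 sigma`) and
#' quantize to `2^bits` levels, compute the mean optical density, the
#' per-direction difference entropy and long-run emphasis, their arithmetic
#' means over the four directions, and the corticalization index.
#'
#' @param image a [radiograph()].
#' @param roi an [roi_spec()] or resolved `roi_pixels`.
#' @param params [glcm_params()] (pair spacing and directions).
#' @param bits quantization depth (default 6).
#' @param mean_od_on compute the first-order mean on the `"quantized"` levels
#'   (default, so all features describe one prepared ROI) or on the `"raw"`
#'   gray values.
#' @return An object of class `texture_features`: list with `roi_id`, `label`,
#'   `timepoint`, `n_pixels`, `mean_od`, per-direction `difentr` and
#'   `lngremph`, their `_avg` means, `ci` and the `degenerate` flag.
#' @export
analyze_roi <- function(image, roi, params = glcm_params(), bits = 6L,
                        mean_od_on = c("quantized", "raw")) {
  mean_od_on <- match.arg(mean_od_on)
  stopifnot(inherits(params, "glcm_params"))
  if (inherits(roi, "roi_spec")) roi <- resolve_roi(image, roi)
  nroi <- normalize_quantize(image, roi, bits = bits)
  mean_od <- if (mean_od_on == "raw") {
    mean(image$pixels[cbind(roi$rows, roi$cols)])
  } else {
    mean_optical_density(nroi)
  }
  ndir <- length(params$directions)
  difentr <- lngremph <- numeric(ndir)
  for (i in seq_len(ndir)) {
    off <- params$directions[[i]]
    difentr[i] <- difference_entropy(glcm_difference_histogram(nroi, off))
    lngremph[i] <- long_run_emphasis(run_length_matrix(nroi, off))
  }
  difentr_avg <- if (ndir == 4L) directional_average(difentr) else mean(difentr)
  lngremph_avg <- if (ndir == 4L) directional_average(lngremph) else mean(lngremph)
  ci <- if (difentr_avg == 0) {
    warning(sprintf("ROI '%s': difference entropy is 0; CI undefined",
                    nroi$roi_id), call. = FALSE)
    NA_real_
  } else {
    mean_od * lngremph_avg / difentr_avg
  }
  structure(list(roi_id = nroi$roi_id, label = nroi$label,
                 timepoint = nroi$timepoint, n_pixels = nroi$n,
                 mean_od = mean_od, difentr = difentr,
                 difentr_avg = difentr_avg, lngremph = lngremph,
                 lngremph_avg = lngremph_avg, ci = ci,
                 degenerate = nroi$degenerate),
            class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf(
    "<texture_features '%s' (%s, %s): n=%d, mean_od=%.3f, DifEntr=%.4f, LngREmph=%.4f, CI=%.2f%s>\n",
    x$roi_id, x$label, x$timepoint, x$n_pixels, x$mean_od, x$difentr_avg,
    x$lngremph_avg, x$ci, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.texture_features <- function(x, ...) {
  data.frame(roi_id = x$roi_id, label = x$label, timepoint = x$timepoint,
             n_pixels = x$n_pixels, mean_od = x$mean_od,
             difentr_avg = x$difentr_avg, lngremph_avg = x$lngremph_avg,
             ci = x$ci, stringsAsFactors = FALSE)
}
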
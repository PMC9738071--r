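test_that("mu +/- 3 sigma quantization maps window bounds and centre correctly", {
  expect_identical(quantize_gray(70, 100, 10, 64), 1L)   # lower bound
  expect_identical(quantize_gray(100, 100, 10, 64), 33L) # floor(0.5*64)+1
  expect_identical(quantize_gray(135, 100, 10, 64), 64L) # clipped above
  expect_identical(quantize_gray(65, 100, 10, 64), 1L)   # clipped below
  expect_error(quantize_gray(1, 100, 0, 64), "positive")
})

test_that("normalize_quantize windows on the raw ROI and flags degenerate ROIs", {
  set.seed(11)
  px <- matrix(sample(0:4095, 1200, replace = TRUE), 30, 40)
  img <- radiograph(px, bit_depth = 16)
  rp <- resolve_roi(img, roi_spec("r", "reference", "initial",
                                  rect = c(0, 0, 30, 40)),
                    protocol_pixels = NA)
  nroi <- normalize_quantize(img, rp)
  expect_identical(nroi$Ng, 64L)
  x <- as.numeric(px)
  expect_equal(nroi$mu, mean(x))
  expect_equal(nroi$sigma, sd(x))
  expect_identical(sort(unique(as.vector(nroi$levels))),
                   sort(unique(quantize_gray(x, mean(x), sd(x), 64L))))
  expect_false(nroi$degenerate)
  expect_true(all(nroi$levels >= 1L & nroi$levels <= 64L))

  const <- radiograph(matrix(40L, 10, 10))
  nc <- normalize_quantize(const, roi_spec("c", "reference", "initial",
                                           rect = c(0, 0, 10, 10)) |>
                             resolve_roi(image = const, protocol_pixels = NA))
  expect_true(nc$degenerate)
  expect_true(all(nc$levels == 1L))
})

test_that("mean optical density is the histogram mean", {
  expect_identical(mean_optical_density(normalized_roi(matrix(10L, 5, 5))), 10)
  expect_equal(mean_optical_density(normalized_roi(matrix(1:64, 8, 8))), 32.5)
  lev <- matrix(c(rep(1L, 25), rep(64L, 75)), 10, 10)
  expect_equal(mean_optical_density(normalized_roi(lev)), 48.25)
})

test_that("difference histogram matches pair enumeration on stated examples", {
  nroi <- normalized_roi(matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE), Ng = 4L)
  dh <- glcm_difference_histogram(nroi, c(0, 1))
  expect_equal(dh$probs, c(1, 0, 0, 0))
  expect_identical(dh$pair_count, 4L)
  dh2 <- glcm_difference_histogram(nroi, c(1, 0))
  expect_equal(dh2$probs, c(0, 1, 0, 0))
  expect_error(
    glcm_difference_histogram(normalized_roi(matrix(1L, 3, 3)), c(0, 5)),
    "insufficient extent")
  # pairs never bridge non-ROI pixels
  lev <- matrix(c(1L, NA, 3L), 1, 3)
  dh3 <- glcm_difference_histogram(normalized_roi(lev, Ng = 4L), c(0, 2))
  expect_equal(dh3$probs, c(0, 0, 1, 0)) # only the (1,3) pair at distance 2
  expect_error(glcm_difference_histogram(normalized_roi(lev, Ng = 4L), c(0, 1)),
               "insufficient extent")
})

test_that("difference entropy uses log10 with closed-form values", {
  nroi <- normalized_roi(matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE), Ng = 4L)
  expect_identical(difference_entropy(glcm_difference_histogram(nroi, c(0, 1))), 0)
  dh <- structure(list(probs = c(0.5, 0.5), pair_count = 2L, offset = c(0L, 1L)),
                  class = "difference_histogram")
  expect_equal(difference_entropy(dh), log10(2))
  dh4 <- structure(list(probs = rep(0.25, 4), pair_count = 4L, offset = c(0L, 1L)),
                   class = "difference_histogram")
  expect_equal(difference_entropy(dh4), log10(4))
})

test_that("run-length matrix enumerates maximal runs, broken at ROI edges", {
  r <- run_length_matrix(normalized_roi(matrix(c(5L, 5L, 5L, 2L), 1, 4), Ng = 8L),
                         c(0, 1))
  expect_identical(r$counts[5, 3], 1L)
  expect_identical(r$counts[2, 1], 1L)
  expect_identical(sum(r$counts), 2L)

  r2 <- run_length_matrix(normalized_roi(matrix(c(1L, 2L, 1L, 2L), 1, 4), Ng = 4L),
                          c(0, 1))
  expect_identical(ncol(r2$counts), 1L) # four runs of length 1
  expect_identical(sum(r2$counts), 4L)

  r3 <- run_length_matrix(normalized_roi(matrix(7L, 1, 1), Ng = 8L), c(0, 1))
  expect_identical(r3$counts[7, 1], 1L)

  # NA inside the ROI bounding box breaks a run
  r4 <- run_length_matrix(normalized_roi(matrix(c(3L, NA, 3L), 1, 3), Ng = 4L),
                          c(0, 1))
  expect_identical(r4$counts[3, 1], 2L)
})

test_that("long-run emphasis weights squared lengths", {
  mk <- function(lev, Ng = 8L) run_length_matrix(normalized_roi(lev, Ng), c(0, 1))
  expect_equal(long_run_emphasis(mk(matrix(c(5L, 5L, 5L, 2L), 1, 4))), 5)
  expect_equal(long_run_emphasis(mk(matrix(4L, 1, 4))), 16)
  expect_equal(long_run_emphasis(mk(matrix(c(1L, 2L, 1L, 2L), 1, 4))), 1)
})

test_that("directional average and CI arithmetic", {
  expect_identical(directional_average(c(1, 2, 3, 4)), 2.5)
  expect_identical(directional_average(rep(3.7, 4)), 3.7)
  expect_identical(directional_average(c(0, 0, 0, 2)), 0.5)
  expect_error(directional_average(c(1, 2, 3)), "exactly 4")
  expect_error(directional_average(c(1, 2, 3, NA)), "finite")

  expect_equal(corticalization_index(30, 10, 1.5), 200)
  expect_equal(round(corticalization_index(32.5, 1, log10(4)), 2), 53.98)
  expect_warning(ci <- corticalization_index(30, 10, 0), "undefined")
  expect_true(is.na(ci))
})

test_that("run-length totals cover every ROI pixel in every direction", {
  set.seed(21)
  for (i in 1:10) {
    lev <- matrix(sample(1:8, 120, replace = TRUE), 10, 12)
    lev[sample(120, 20)] <- NA # ragged ROI
    nroi <- normalized_roi(lev, Ng = 8L)
    for (off in std_offsets)
      expect_identical(run_length_matrix(nroi, off)$n_pixels, 100)
  }
})

test_that("implementation matches brute-force oracles on random small images", {
  set.seed(31)
  for (i in 1:40) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    lev <- matrix(sample(1:4, nr * nc, replace = TRUE), nr, nc)
    if (i %% 3 == 0) lev[sample(nr * nc, 1)] <- NA
    if (all(is.na(lev))) next
    nroi <- normalized_roi(lev, Ng = 4L)
    for (off in std_offsets) {
      oracle <- brute_diff_hist(lev, off[1], off[2], 4L)
      impl <- glcm_difference_histogram(nroi, off)
      expect_equal(impl$probs, oracle$probs)
      expect_identical(impl$pair_count, oracle$pair_count)
      expect_identical(trim_rlm(run_length_matrix(nroi, off)$counts),
                       trim_rlm(brute_run_counts(lev, off[1], off[2], 4L)))
    }
  }
})

test_that("analyze_roi composes the pipeline; degenerate ROI is flagged", {
  img <- radiograph(matrix(77L, 40, 40))
  suppressWarnings(
    ft <- analyze_roi(img, roi_spec("c", "reference", "initial",
                                    rect = c(0, 0, 40, 40))))
  expect_identical(ft$difentr_avg, 0)
  expect_true(is.na(ft$ci))
  expect_true(ft$degenerate)

  # checkerboard, period 2: at d=5 axial offsets always pair unlike levels
  board <- matrix(0L, 12, 12)
  board[(row(board) + col(board)) %% 2 == 1] <- 200L
  img2 <- radiograph(board)
  ft2 <- suppressWarnings(analyze_patch(img2))
  nroi <- normalize_quantize(
    img2, resolve_roi(img2, roi_spec("b", "reference", "initial",
                                     rect = c(0, 0, 12, 12)),
                      protocol_pixels = NA))
  for (k in seq_along(std_offsets)) {
    off <- std_offsets[[k]] * 5L
    oracle <- brute_diff_hist(nroi$levels, off[1], off[2], 64L)
    expect_equal(ft2$difentr[k],
                 -sum(oracle$probs[oracle$probs > 0] *
                        log10(oracle$probs[oracle$probs > 0])))
  }
  # axial offsets (0,5), (5,0) flip parity: all differences equal, entropy 0
  expect_equal(ft2$difentr[c(1, 3)], c(0, 0))
  # diagonal offsets preserve parity: same level, entropy 0, but long runs
  expect_equal(ft2$difentr[c(2, 4)], c(0, 0))
  expect_true(is.na(ft2$ci))
})

test_that("feature bounds hold across random ROIs", {
  set.seed(41)
  for (i in 1:8) {
    px <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
    ft <- analyze_patch(radiograph(px))
    expect_true(ft$mean_od >= 1 && ft$mean_od <= 64)
    expect_true(all(ft$difentr >= 0 & ft$difentr <= log10(64)))
    expect_true(all(ft$lngremph >= 1))
    expect_true(ft$ci >= 0)
  }
})

test_that("features are exactly invariant to affine gray-level rescaling", {
  set.seed(51)
  img16 <- radiograph(matrix(sample(200:1800, 1500), 30, 50), bit_depth = 16)
  spec <- roi_spec("a", "peri_implant", "initial", rect = c(0, 0, 30, 50))
  base <- normalize_quantize(img16, resolve_roi(img16, spec))
  ftb <- analyze_roi(img16, spec)
  for (a in c(2L, 7L, 30L)) {
    b <- sample(0:500, 1)
    timg <- radiograph(a * img16$pixels + b, bit_depth = 16)
    tr <- normalize_quantize(timg, resolve_roi(timg, spec))
    expect_identical(tr$levels, base$levels)
    ftt <- analyze_roi(timg, spec)
    expect_identical(ftt$ci, ftb$ci)
  }
})

test_that("difference histograms always sum to one", {
  set.seed(61)
  for (i in 1:10) {
    lev <- matrix(sample(1:64, 400, replace = TRUE), 20, 20)
    nroi <- normalized_roi(lev)
    for (off in list(c(0L, 5L), c(-5L, 5L), c(-5L, 0L), c(-5L, -5L)))
      expect_equal(sum(glcm_difference_histogram(nroi, off)$probs), 1,
                   tolerance = 1e-12)
  }
})
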
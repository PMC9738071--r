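test_that("the normality gate selects parametric vs rank tests", {
  set.seed(101)
  hits_t <- hits_w <- 0L
  for (i in 1:20) {
    g_norm <- list(rnorm(200), rnorm(200))
    g_skew <- list(rlnorm(200, sdlog = 1.5), rlnorm(200, sdlog = 1.5))
    hits_t <- hits_t + (choose_test(g_norm) == "t")
    hits_w <- hits_w + (choose_test(g_skew) == "W")
  }
  # three alpha=0.05 gates (2x Shapiro + Bartlett) pass jointly with
  # probability ~0.95^3 = 0.86 on Gaussian data
  expect_gte(hits_t, 14L)
  expect_gte(hits_w, 18L) # heavy lognormal skew is rejected near-certainly
  expect_identical(choose_test(list(rnorm(50), rnorm(50), rnorm(50))), "anova")
  expect_identical(
    choose_test(list(rlnorm(50, sdlog = 2), rlnorm(50, sdlog = 2),
                     rlnorm(50, sdlog = 2))), "kruskal_wallis")
  expect_error(choose_test(list(1, c(1, 2))), "insufficient data")
})

test_that("identical groups give p = 1 and no flags", {
  g <- list(rep(2.5, 30), rep(2.5, 30))
  res <- compare_groups(g)
  expect_identical(res$test_used, "W")
  expect_identical(res$p_value, 1)
  expect_true(all(res$summaries$flag == ""))

  res3 <- compare_groups(list(rep(1, 10), rep(1, 10), rep(1, 10)))
  expect_identical(res3$test_used, "kruskal_wallis")
  expect_identical(res3$p_value, 1)
})

test_that("a 2-pooled-SD shift is detected and flagged on the right group", {
  set.seed(111)
  hits <- 0L
  for (i in 1:25) {
    res <- compare_groups(list(rnorm(100), rnorm(100, mean = 2)),
                          labels = c("low", "high"))
    ok <- res$p_value < 0.05 &&
      res$summaries$flag[res$summaries$label == "high"] == "H" &&
      res$summaries$flag[res$summaries$label == "low"] == "L"
    hits <- hits + ok
  }
  expect_identical(hits, 25L)
})

test_that("three equal-median skewed groups go to Kruskal-Wallis, rarely flagged", {
  set.seed(121)
  sig <- 0L
  for (i in 1:60) {
    g <- lapply(1:3, function(j) rlnorm(60, sdlog = 1.5))
    res <- compare_groups(g)
    expect_identical(res$test_used, "kruskal_wallis")
    sig <- sig + (res$p_value < 0.05)
  }
  expect_lte(sig, 10L) # ~5% nominal; binomial 99.9% bound at 60 reps
})

test_that("simple regression reports CC, R^2 in percent and the slope p", {
  r <- suppressWarnings(simple_regression(1:10, 2 * (1:10) + 1))
  expect_equal(r$cc, 1)
  expect_equal(r$r_squared_pct, 100)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)

  rc <- simple_regression(rep(3, 10), rnorm(10))
  expect_true(rc$undefined)
  expect_true(is.na(rc$cc))

  set.seed(131)
  for (i in 1:10) {
    x <- rnorm(50); y <- 0.3 * x + rnorm(50)
    r <- simple_regression(x, y)
    expect_equal(r$r_squared_pct, 100 * r$cc^2)
    expect_equal(r$p_value, cor.test(x, y)$p.value)
  }

  # printed-precision checks: CC 0.11 -> 1.2%, CC 0.12 -> 1.4%
  expect_equal(round(100 * 0.11^2, 1), 1.2)
  expect_equal(round(100 * 0.12^2, 1), 1.4)
})

test_that("longitudinal summary recovers configured means and pairs timepoints", {
  cfg <- cohort_sim_config(n_implants = 1200, seed = 14)
  sim <- generate_cohort(cfg)
  ls <- longitudinal_summary(sim$cohort)
  expect_identical(ls$table$timepoint, c("initial", "y5", "y10"))
  for (i in seq_len(3)) {
    tp <- ls$table$timepoint[i]
    se <- cfg$ci_sd[tp] / sqrt(ls$table$n_ci[i])
    expect_lt(abs(ls$table$ci_mean[i] - cfg$ci_mean[tp]), 3 * se)
  }
  # MBL grows over the follow-up, as configured
  expect_true(all(diff(ls$table$mbl_mean) > 0))
  # paired consecutive comparisons for CI and MBL
  expect_identical(nrow(ls$comparisons), 4L)
  expect_true(all(ls$comparisons$paired))
  # the CI jump initial -> y5 is strongly significant at this n
  p_ci <- ls$comparisons$p_value[ls$comparisons$variable == "CI" &
                                   ls$comparisons$from == "initial"]
  expect_lt(p_ci, 0.001)

  one <- sim$cohort[, c("implant_id", "ci_initial", "mbl_initial")]
  ls1 <- longitudinal_summary(one)
  expect_identical(nrow(ls1$table), 1L)
  expect_null(ls1$comparisons)

  none <- sim$cohort[, c("implant_id", "sex")]
  expect_error(longitudinal_summary(none), "no CI or MBL")
})

test_that("design feature tables flag injected differences, and only those", {
  cfg <- cohort_sim_config(
    n_implants = 1500, seed = 15,
    design_ci_effects = list(body_shape = c(tapered = 50, straight = -50)))
  sim <- generate_cohort(cfg)
  tab <- design_feature_table(sim$cohort, "body_shape")
  ci_rows <- tab[tab$measure == "CI" & tab$timepoint == "y5", ]
  expect_identical(ci_rows$flag[ci_rows$option == "tapered"], "H")
  expect_identical(ci_rows$flag[ci_rows$option == "straight"], "L")
  # no effect injected on MBL: flags at most at the nominal rate, so the
  # medians table itself stays usable; we only check the structure
  expect_true(all(c("feature", "option", "measure", "timepoint", "n",
                    "median", "flag", "test", "p_value") %in% names(tab)))
  expect_error(design_feature_table(sim$cohort, "color"), "unknown design feature")
  single <- sim$cohort
  single$body_shape <- "tapered"
  expect_error(design_feature_table(single, "body_shape"),
               "fewer than two options")
})

test_that("null design features are flagged at about the nominal rate", {
  set.seed(161)
  flagged <- 0L
  reps <- 60L
  for (i in seq_len(reps)) {
    opt <- sample(c("yes", "no"), 200, replace = TRUE)
    ci <- rlnorm(200, log(200), 0.6)
    cohort <- data.frame(implant_id = sprintf("i%03d", 1:200),
                         neck_microthreads = opt, ci_y5 = ci,
                         stringsAsFactors = FALSE)
    tab <- design_feature_table(cohort, "neck_microthreads")
    flagged <- flagged + any(tab$flag != "")
  }
  expect_lte(flagged, qbinom(0.999, reps, 0.05)) # one-sided guard band
})

test_that("covariate relations label direct and inverse associations", {
  cfg <- cohort_sim_config(n_implants = 2500, seed = 16)
  sim <- generate_cohort(cfg)
  rel <- covariate_relations(sim$cohort)
  q <- rel$quantitative
  # configured signs are recovered in the correlation estimates at y5 ...
  for (cv in names(sim$truth$covariate_effects)) {
    row <- q[q$covariate == cv & q$timepoint == "y5", ]
    expect_identical(sign(row$cc), sign(sim$truth$covariate_effects[[cv]]))
    # ... and never as a significant relation of the opposite sign
    expect_false(row$relation ==
                   if (sim$truth$covariate_effects[[cv]] > 0) "inverse" else "direct")
  }
  # the stronger (untruncated) covariates reach significance at this n
  age <- q[q$covariate == "age_y" & q$timepoint == "y5", ]
  wgt <- q[q$covariate == "weight_kg" & q$timepoint == "y5", ]
  expect_identical(age$relation, "direct")
  expect_identical(wgt$relation, "inverse")
  expect_true(all(c("covariate", "option", "timepoint", "n", "ci_median",
                    "flag") %in% names(rel$categorical)))
})

test_that("mbl prevalence splits zero and affected implants", {
  cohort <- data.frame(implant_id = c("a", "b", "c", "d"),
                       mbl_initial = c(0, 0, 0, 1))
  p <- mbl_prevalence(cohort, "initial")
  expect_equal(p$fraction_zero, 0.75)
  expect_equal(p$fraction_positive, 0.25)
  expect_equal(p$mean_positive, 1)
  expect_equal(p$sd_positive, 0)

  allz <- data.frame(implant_id = "a", mbl_y5 = 0)
  p0 <- mbl_prevalence(allz, "y5")
  expect_equal(p0$fraction_zero, 1)
  expect_true(is.na(p0$mean_positive))

  expect_error(mbl_prevalence(data.frame(implant_id = "a",
                                         mbl_y10 = NA_real_), "y10"),
               "no MBL data")

  # binomial recovery of the configured zero fraction at n = 2000
  sim <- generate_cohort(cohort_sim_config(n_implants = 2000, seed = 17))
  p2 <- mbl_prevalence(sim$cohort, "initial")
  expect_lt(abs(p2$fraction_zero - 0.867), 0.02)
})

test_that("holm adjustment can only remove flags", {
  cfg <- cohort_sim_config(n_implants = 1000, seed = 18)
  sim <- generate_cohort(cfg)
  raw <- design_feature_table(sim$cohort, "titanium_alloy")
  adj <- design_feature_table(sim$cohort, "titanium_alloy", adjust = "holm")
  expect_true(all(adj$p_value >= raw$p_value))
  expect_true(all(adj$flag == "" | raw$flag != ""))
})
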
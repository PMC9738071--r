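#' Normality-gated test selection
#'
#' Chooses between parametric and rank-based comparisons the way the clinical
#' workflow does: Shapiro-Wilk on each group (on the paired differences when
#' `paired = TRUE`) at `alpha`, plus a Bartlett variance-homogeneity check for
#' unpaired groups. Only when every gate passes is the mean-based test used
#' (t-test for two groups, one-way ANOVA for more); otherwise the rank-based
#' counterpart (Wilcoxon-family "W-test" for two groups, Kruskal-Wallis for
#' more). Constant groups fail the gate (ranks handle them; moments do not).
#'
#' @param groups list of numeric sample vectors (NAs dropped).
#' @param paired two equal-length groups compared within implants.
#' @param alpha gate significance level (default 0.05).
#' @return `"t"`, `"W"`, `"anova"` or `"kruskal_wallis"`.
#' @export
choose_test <- function(groups, paired = FALSE, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop_input("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop_input("insufficient data: every group needs n >= 2")
  if (paired) {
    if (length(groups) != 2L || ns[1] != ns[2])
      stop_input("paired comparison needs two equal-length groups")
    d <- groups[[2]] - groups[[1]]
    return(if (gate_normal(list(d), alpha, check_var = FALSE)) "t" else "W")
  }
  normal <- gate_normal(groups, alpha, check_var = TRUE)
  if (length(groups) == 2L) {
    if (normal) "t" else "W"
  } else {
    if (normal) "anova" else "kruskal_wallis"
  }
}

gate_normal <- function(groups, alpha, check_var = TRUE) {
  for (g in groups) {
    if (length(g) < 3L) return(FALSE) # too small for the gate: stay rank-based
    if (stats::sd(g) == 0) return(FALSE)
    if (length(g) > 5000L) g <- g[seq(1L, length(g), length.out = 5000L)]
    if (stats::shapiro.test(g)$p.value <= alpha) return(FALSE)
  }
  if (check_var && length(groups) >= 2L) {
    x <- unlist(groups, use.names = FALSE)
    f <- factor(rep.int(seq_along(groups), lengths(groups)))
    if (stats::bartlett.test(x, f)$p.value <= alpha) return(FALSE)
  }
  TRUE
}

#' Compare groups with the gated test and assign H/L flags
#'
#' Runs [choose_test()] and then the selected test: pooled-variance t-test,
#' Wilcoxon rank test (normal approximation with tie correction; signed-rank
#' when paired, rank-sum otherwise), classic one-way ANOVA, or Kruskal-Wallis.
#' When `p < alpha`, the group with the highest median is flagged `H` and the
#' one with the lowest median `L` — the flagging convention of the published
#' design-feature tables. When all pooled values are identical the rank tests
#' are degenerate and `p = 1` is returned (no evidence of any difference).
#'
#' @param groups list of numeric sample vectors.
#' @param labels optional group labels (default `group1`, `group2`, ...).
#' @param alpha flag significance level (default 0.05).
#' @param paired passed to [choose_test()]; NAs are dropped pairwise.
#' @return An object of class `group_comparison`: `test_used`, `statistic`,
#'   `p_value`, and a `summaries` data.frame (label, n, mean, sd, median,
#'   flag).
#' @export
compare_groups <- function(groups, labels = NULL, alpha = 0.05,
                           paired = FALSE) {
  labels <- labels %||% paste0("group", seq_along(groups))
  if (length(labels) != length(groups))
    stop_input("'labels' must match the number of groups")
  if (paired) {
    if (length(groups) != 2L) stop_input("paired comparison needs two groups")
    keep <- !is.na(groups[[1]]) & !is.na(groups[[2]])
    groups <- lapply(groups, `[`, keep)
  } else {
    groups <- lapply(groups, function(g) g[!is.na(g)])
  }
  test <- choose_test(groups, paired = paired, alpha = alpha)
  x <- groups[[1]]
  pooled <- unlist(groups, use.names = FALSE)
  res <- if (test == "t") {
    stats::t.test(x, groups[[2]], var.equal = TRUE, paired = paired)
  } else if (test == "W") {
    if (stats::sd(pooled) == 0) {
      list(statistic = c(W = length(x) * length(groups[[2]]) / 2), p.value = 1)
    } else {
      suppressWarnings(stats::wilcox.test(x, groups[[2]], paired = paired,
                                          exact = FALSE, correct = TRUE))
    }
  } else if (test == "anova") {
    f <- factor(rep.int(labels, lengths(groups)))
    a <- stats::oneway.test(pooled ~ f, var.equal = TRUE)
    list(statistic = a$statistic, p.value = a$p.value)
  } else {
    if (stats::sd(pooled) == 0) {
      list(statistic = c(`Kruskal-Wallis chi-squared` = 0), p.value = 1)
    } else {
      stats::kruskal.test(groups)
    }
  }
  p <- res$p.value
  med <- vapply(groups, stats::median, 0)
  flags <- rep("", length(groups))
  if (is.finite(p) && p < alpha && max(med) > min(med)) {
    flags[which.max(med)] <- "H"
    flags[which.min(med)] <- "L"
  }
  summaries <- data.frame(
    label = labels, n = lengths(groups),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, stats::sd, 0),
    median = med, flag = flags, stringsAsFactors = FALSE)
  structure(list(test_used = test, statistic = unname(res$statistic),
                 p_value = unname(p), summaries = summaries, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s, statistic = %.4g, p = %.4g>\n",
              x$test_used, x$statistic, x$p_value))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Simple linear regression with CC and R-squared
#'
#' Least-squares line of `y` on `x` with the Pearson correlation coefficient
#' (CC), the coefficient of determination as a percentage
#' (`R^2 = 100 * CC^2`), and the two-sided p-value of the slope. Pairs with a
#' missing member are dropped. If either variable is constant the result is
#' flagged undefined rather than raising an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return An object of class `regression_result`: `cc`, `r_squared_pct`,
#'   `p_value`, `slope`, `intercept`, `n`, `undefined`.
#' @examples
#' r <- simple_regression(1:10, 2 * (1:10) + 1)
#' r$cc            # 1
#' r$r_squared_pct # 100
#' @export
simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop_input("'x' and 'y' must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_input("insufficient data: regression needs n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(cc = NA_real_, r_squared_pct = NA_real_,
                          p_value = NA_real_, slope = NA_real_,
                          intercept = NA_real_, n = n, undefined = TRUE),
                     class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  cc <- stats::cor(x, y)
  structure(list(cc = cc, r_squared_pct = 100 * cc^2,
                 p_value = unname(cf[2, 4]), slope = unname(cf[2, 1]),
                 intercept = unname(cf[1, 1]), n = n, undefined = FALSE),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  if (x$undefined) {
    cat("<regression_result: undefined (constant variable)>\n")
  } else {
    cat(sprintf("<regression_result: CC = %.3f, R^2 = %.2f%%, p = %.3g, n = %d>\n",
                x$cc, x$r_squared_pct, x$p_value, x$n))
  }
  invisible(x)
}

cohort_timepoints <- function(cohort) {
  tps <- timepoint_levels[paste0("ci_", timepoint_levels) %in% names(cohort) |
                            paste0("mbl_", timepoint_levels) %in% names(cohort)]
  tps[vapply(tps, function(tp) {
    any(!is.na(cohort[[paste0("ci_", tp)]])) ||
      any(!is.na(cohort[[paste0("mbl_", tp)]]))
  }, logical(1))]
}

#' Longitudinal CI/MBL summary
#'
#' Per timepoint: n, CI mean +/- SD, MBL mean +/- SD and the CI-MBL
#' [simple_regression()] (CC, R^2 %, p). In addition, consecutive timepoints
#' are compared for both CI and MBL — paired on the implants observed at both
#' timepoints (falling back to unpaired when fewer than 3 complete pairs
#' exist).
#'
#' @param cohort cohort data.frame ([read_cohort_table()] schema).
#' @return List with `table` (one row per timepoint) and `comparisons`
#'   (one row per consecutive-timepoint test per variable).
#' @export
longitudinal_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  tps <- cohort_timepoints(cohort)
  if (length(tps) == 0L)
    stop_input("cohort has no CI or MBL values at any timepoint")
  rows <- lapply(tps, function(tp) {
    ci <- cohort[[paste0("ci_", tp)]]
    mbl <- cohort[[paste0("mbl_", tp)]]
    reg <- tryCatch(simple_regression(ci, mbl), error = function(e) NULL)
    data.frame(
      timepoint = tp,
      n_ci = sum(!is.na(ci)), ci_mean = mean(ci, na.rm = TRUE),
      ci_sd = stats::sd(ci[!is.na(ci)]),
      n_mbl = sum(!is.na(mbl)), mbl_mean = mean(mbl, na.rm = TRUE),
      mbl_sd = stats::sd(mbl[!is.na(mbl)]),
      cc = if (is.null(reg) || reg$undefined) NA_real_ else reg$cc,
      r_squared_pct = if (is.null(reg) || reg$undefined) NA_real_ else reg$r_squared_pct,
      reg_p = if (is.null(reg) || reg$undefined) NA_real_ else reg$p_value,
      reg_n = if (is.null(reg)) NA_integer_ else reg$n,
      stringsAsFactors = FALSE)
  })
  comparisons <- NULL
  if (length(tps) >= 2L) {
    cmp <- list()
    for (i in seq_len(length(tps) - 1L)) {
      for (var in c("ci", "mbl")) {
        a <- cohort[[paste0(var, "_", tps[i])]]
        b <- cohort[[paste0(var, "_", tps[i + 1L])]]
        both <- !is.na(a) & !is.na(b)
        paired <- sum(both) >= 3L
        g <- if (paired) list(a[both], b[both]) else list(a[!is.na(a)], b[!is.na(b)])
        res <- tryCatch(compare_groups(g, labels = tps[c(i, i + 1L)],
                                       paired = paired),
                        error = function(e) NULL)
        if (!is.null(res))
          cmp[[length(cmp) + 1L]] <- data.frame(
            variable = toupper(var), from = tps[i], to = tps[i + 1L],
            paired = paired, n = length(g[[1]]) + length(g[[2]]),
            test = res$test_used, statistic = res$statistic,
            p_value = res$p_value, stringsAsFactors = FALSE)
      }
    }
    comparisons <- if (length(cmp)) do.call(rbind, cmp) else NULL
  }
  list(table = do.call(rbind, rows), comparisons = comparisons)
}

#' Median group table for one design feature
#'
#' The design-feature analysis: implants are grouped by the options of one
#' design column (e.g. `body_threads`), and per timepoint the median MBL and
#' median CI of each option are tabulated with `H`/`L` flags from
#' [compare_groups()] — `H` marks the option with a significantly higher
#' value than the other options within the observation period (`p < alpha`),
#' `L` the lower one.
#'
#' The workflow tests each (measure, timepoint) cell at `alpha` with no
#' multiple-testing correction, matching per-comparison `p < 0.05` reporting;
#' `adjust = "holm"` optionally applies a Holm correction across the cells of
#' the table before flagging.
#'
#' @param cohort cohort data.frame.
#' @param feature a design-feature column name (see [cohort_enums]).
#' @param alpha flag significance level.
#' @param adjust `"none"` (default, per-comparison testing) or `"holm"`.
#' @return Long data.frame: feature, option, measure (MBL/CI), timepoint, n,
#'   median, flag, test, p_value.
#' @export
design_feature_table <- function(cohort, feature, alpha = 0.05,
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(cohort))
  if (!feature %in% design_feature_cols)
    stop_input("unknown design feature '%s'", feature)
  if (!feature %in% names(cohort))
    stop_input("cohort table has no column '%s'", feature)
  opts <- sort(unique(stats::na.omit(cohort[[feature]])))
  if (length(opts) < 2L)
    stop_input("feature '%s' has fewer than two options in this cohort", feature)
  tps <- cohort_timepoints(cohort)
  out <- list()
  for (tp in tps) {
    for (measure in c("MBL", "CI")) {
      col <- paste0(if (measure == "MBL") "mbl_" else "ci_", tp)
      if (!col %in% names(cohort)) next
      groups <- lapply(opts, function(o)
        stats::na.omit(cohort[[col]][cohort[[feature]] == o]))
      use <- lengths(groups) >= 2L
      if (sum(use) < 2L) next
      res <- compare_groups(groups[use], labels = opts[use], alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        feature = feature, option = opts[use], measure = measure,
        timepoint = tp, n = res$summaries$n, median = res$summaries$median,
        flag = res$summaries$flag, test = res$test_used,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    stop_input("feature '%s': no timepoint has two usable option groups", feature)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (adjust == "holm") {
    cell <- paste(df$measure, df$timepoint)
    p_cell <- tapply(df$p_value, cell, `[`, 1L)
    p_adj <- stats::p.adjust(p_cell, method = "holm")[cell]
    df$p_value <- unname(p_adj)
    df$flag[df$p_value >= alpha] <- ""
  }
  df
}

#' Covariate-vs-CI relations table
#'
#' For each quantitative covariate (age, height, weight, BMI, TSH, calcium,
#' triglycerides) and timepoint: the Pearson correlation with CI (labelled
#' `direct` / `inverse` / `none` at `alpha`). For each categorical covariate
#' (sex, smoking, jaw, arch location, augmentation fields): the per-option CI
#' medians with H/L flags from [compare_groups()].
#'
#' @param cohort cohort data.frame.
#' @param alpha significance level.
#' @return List with `quantitative` and `categorical` data.frames.
#' @export
covariate_relations <- function(cohort, alpha = 0.05) {
  tps <- cohort_timepoints(cohort)
  quant <- list()
  for (cv in intersect(covariate_num_cols, names(cohort))) {
    for (tp in tps) {
      ci <- cohort[[paste0("ci_", tp)]]
      reg <- tryCatch(simple_regression(cohort[[cv]], ci),
                      error = function(e) NULL)
      if (is.null(reg) || reg$undefined) next
      quant[[length(quant) + 1L]] <- data.frame(
        covariate = cv, timepoint = tp, n = reg$n, cc = reg$cc,
        p_value = reg$p_value,
        relation = if (reg$p_value >= alpha) "none"
                   else if (reg$cc > 0) "direct" else "inverse",
        stringsAsFactors = FALSE)
    }
  }
  cat_cols <- intersect(c("sex", "smoking", "jaw", "arch_location",
                          "augmented", "augmentation_technique"),
                        names(cohort))
  categ <- list()
  for (cv in cat_cols) {
    opts <- sort(unique(stats::na.omit(cohort[[cv]])))
    if (length(opts) < 2L) next
    for (tp in tps) {
      col <- paste0("ci_", tp)
      groups <- lapply(opts, function(o)
        stats::na.omit(cohort[[col]][cohort[[cv]] == o]))
      use <- lengths(groups) >= 2L
      if (sum(use) < 2L) next
      res <- compare_groups(groups[use], labels = opts[use], alpha = alpha)
      categ[[length(categ) + 1L]] <- data.frame(
        covariate = cv, option = opts[use], timepoint = tp,
        n = res$summaries$n, ci_median = res$summaries$median,
        flag = res$summaries$flag, test = res$test_used,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  list(
    quantitative = if (length(quant)) do.call(rbind, quant) else
      data.frame(covariate = character(), timepoint = character(),
                 n = integer(), cc = numeric(), p_value = numeric(),
                 relation = character(), stringsAsFactors = FALSE),
    categorical = if (length(categ)) do.call(rbind, categ) else
      data.frame(covariate = character(), option = character(),
                 timepoint = character(), n = integer(), ci_median = numeric(),
                 flag = character(), test = character(), p_value = numeric(),
                 stringsAsFactors = FALSE))
}

#' Marginal bone loss prevalence at a timepoint
#'
#' Splits the implants observed at a timepoint into the zero-MBL fraction and
#' the affected fraction, with the conditional mean +/- SD of MBL in the
#' affected subgroup. The SD is reported as 0 when exactly one implant is
#' affected and `NA` (with an undefined mean) when none is.
#'
#' @param cohort cohort data.frame.
#' @param timepoint `"initial"`, `"y5"` or `"y10"`.
#' @return List: `fraction_zero`, `fraction_positive`, `mean_positive`,
#'   `sd_positive`, `n`.
#' @export
mbl_prevalence <- function(cohort, timepoint = c("initial", "y5", "y10")) {
  timepoint <- match.arg(timepoint)
  col <- paste0("mbl_", timepoint)
  if (!col %in% names(cohort))
    stop_input("cohort table has no column '%s'", col)
  v <- cohort[[col]]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop_input("no MBL data at timepoint '%s'", timepoint)
  pos <- v[v > 0]
  list(fraction_zero = mean(v == 0), fraction_positive = mean(v > 0),
       mean_positive = if (length(pos)) mean(pos) else NA_real_,
       sd_positive = if (length(pos) >= 2L) stats::sd(pos)
                     else if (length(pos) == 1L) 0 else NA_real_,
       n = length(v))
}
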
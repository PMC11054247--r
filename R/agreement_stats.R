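#' Two-way ANOVA mean squares for an n x k measurement matrix
#'
#' Decomposes a subjects-by-raters matrix into the mean squares underlying
#' the Shrout–Fleiss intraclass correlation forms: between-subjects (BMS),
#' within-subjects (WMS), between-raters (JMS) and residual (EMS).
#' Rows containing missing cells are dropped (listwise deletion) and the
#' retained sample size is reported.
#'
#' @param x numeric matrix, subjects in rows, raters/systems in columns.
#' @return list with `BMS`, `WMS`, `JMS`, `EMS`, their degrees of freedom
#'   (`df_subjects`, `df_within`, `df_raters`, `df_residual`), `n`, `k` and
#'   `n_dropped` (rows removed by listwise deletion).
#' @export
anova_decompose <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be a numeric matrix")
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L)
    stop("need at least 2 complete rows and 2 columns (got ", n, " x ", k, ")")

  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)

  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_within <- sum((x - row_m)^2)              # within-subject variation
  ss_resid <- ss_within - ss_cols              # after removing rater effect

  list(
    BMS = ss_rows / (n - 1),
    WMS = ss_within / (n * (k - 1)),
    JMS = ss_cols / (k - 1),
    EMS = ss_resid / ((n - 1) * (k - 1)),
    df_subjects = n - 1L,
    df_within = n * (k - 1L),
    df_raters = k - 1L,
    df_residual = (n - 1L) * (k - 1L),
    n = n, k = k, n_dropped = n_dropped
  )
}

#' Intraclass correlation coefficients (Shrout–Fleiss forms)
#'
#' Computes a single ICC form with its F test and 95% confidence interval.
#' Forms follow the Shrout–Fleiss two-way conventions: `"1,1"`/`"1,k"` are
#' one-way random (test–retest), `"2,1"`/`"2,k"` two-way random absolute
#' agreement, `"3,1"`/`"3,k"` two-way mixed consistency; the `k` variants are
#' average-measures.
#'
#' @param x numeric matrix, subjects in rows, raters/systems in columns.
#' @param form one of `"1,1"`, `"1,k"`, `"2,1"`, `"2,k"`, `"3,1"`, `"3,k"`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `icc_result`: list with `form`, `estimate`,
#'   `ci95` (lo, hi), `f_stat`, `df1`, `df2`, `p`, `label` (from
#'   [classify_icc()]), `n`, `k`.
#' @export
icc <- function(x, form = c("2,k", "3,k", "1,k", "1,1", "2,1", "3,1"),
                conf_level = 0.95) {
  form <- match.arg(form)
  ms <- anova_decompose(x)
  n <- ms$n; k <- ms$k
  BMS <- ms$BMS; WMS <- ms$WMS; JMS <- ms$JMS; EMS <- ms$EMS
  if (BMS <= 0)
    stop("between-subject mean square is zero; ICC undefined for this matrix")
  alpha <- 1 - conf_level

  sb <- function(r) r * k / (1 + (k - 1) * r)  # Spearman-Brown single -> average

  if (form %in% c("1,1", "1,k")) {
    f <- BMS / WMS
    df1 <- n - 1; df2 <- n * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    if (form == "1,1") {
      est <- (BMS - WMS) / (BMS + (k - 1) * WMS)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      est <- (BMS - WMS) / BMS
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  } else if (form %in% c("3,1", "3,k")) {
    f <- BMS / EMS
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    if (form == "3,1") {
      est <- (BMS - EMS) / (BMS + (k - 1) * EMS)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      est <- (BMS - EMS) / BMS
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  } else {
    # two-way random, absolute agreement; CI via the Fleiss-Shrout
    # Satterthwaite approximation on the single-measures coefficient
    est1 <- (BMS - EMS) / (BMS + (k - 1) * EMS + k * (JMS - EMS) / n)
    f <- BMS / EMS
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fj <- JMS / EMS
    vn <- (k - 1) * (n - 1) *
      (k * est1 * fj + n * (1 + (k - 1) * est1) - k * est1)^2
    vd <- (n - 1) * k^2 * est1^2 * fj^2 +
      (n * (1 + (k - 1) * est1) - k * est1)^2
    v <- vn / vd
    f3u <- qf(1 - alpha / 2, n - 1, v)
    f3l <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (BMS - f3u * EMS) /
      (f3u * (k * JMS + (k * n - k - n) * EMS) + n * BMS)
    hi1 <- n * (f3l * BMS - EMS) /
      (k * JMS + (k * n - k - n) * EMS + n * f3l * BMS)
    if (form == "2,1") {
      est <- est1
      ci <- c(lo1, hi1)
    } else {
      est <- (BMS - EMS) / (BMS + (JMS - EMS) / n)
      ci <- c(sb(lo1), sb(hi1))
    }
  }

  p <- pf(f, df1, df2, lower.tail = FALSE)
  structure(
    list(form = form, estimate = est, ci95 = ci, f_stat = f,
         df1 = df1, df2 = df2, p = p, label = classify_icc(est),
         n = n, k = k, conf_level = conf_level),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f [%.3f, %.3f] (%s), F(%d,%d) = %.2f, p = %.3g, n = %d\n",
              x$form, x$estimate, x$ci95[1], x$ci95[2], x$label,
              x$df1, x$df2, x$f_stat, x$p, x$n))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_j s_j^2 / s_{total}^2)} where \eqn{s_j^2}
#' are item variances and \eqn{s_{total}^2} the variance of row sums. For a
#' complete matrix alpha equals the consistency-form average-measures
#' ICC(3,k).
#'
#' @param x numeric matrix, subjects in rows, items/raters in columns.
#' @return object of class `alpha_result`: list with `alpha`, `k`, `n`.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 complete rows and 2 columns")
  total_var <- var(rowSums(x))
  if (total_var <= 0) stop("zero total variance; alpha undefined")
  a <- k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
  structure(list(alpha = a, k = k, n = n), class = "alpha_result")
}

#' @export
print.alpha_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (k = %d, n = %d)\n", x$alpha, x$k, x$n))
  invisible(x)
}

#' Validity regression of a reference system on a candidate system
#'
#' Ordinary least squares of the reference measurements on the candidate
#' measurements (candidate as independent variable), with a t-based 95%
#' confidence interval for the slope, Pearson r and R-squared.
#'
#' @param x_candidate candidate-system values (independent variable).
#' @param y_reference reference-system values (dependent variable).
#' @param conf_level confidence level for the slope interval.
#' @return object of class `regression_result`: list with `slope`,
#'   `constant`, `ci95_slope`, `p_slope`, `r`, `r_squared`, `n`.
#' @export
validity_regression <- function(x_candidate, y_reference, conf_level = 0.95) {
  ok <- is.finite(x_candidate) & is.finite(y_reference)
  x <- x_candidate[ok]; y <- y_reference[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (var(x) <= 0) stop("zero variance in candidate values; slope undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(confint(fit, "x", level = conf_level))
  r <- cor(x, y)
  structure(
    list(slope = unname(coef(fit)[2]), constant = unname(coef(fit)[1]),
         ci95_slope = unname(c(ci[1], ci[2])),
         p_slope = sm$coefficients["x", "Pr(>|t|)"],
         r = r, r_squared = r^2, n = n),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("y = %.3f x + %.3f, 95%% CI for slope [%.3f, %.3f], p = %.3g, R2 = %.3f, n = %d\n",
              x$slope, x$constant, x$ci95_slope[1], x$ci95_slope[2],
              x$p_slope, x$r_squared, x$n))
  invisible(x)
}

#' Bland–Altman agreement analysis
#'
#' Differences are taken as `reference - candidate`. Reports the fixed bias
#' (mean difference) with a t-based confidence interval and paired t-test
#' against zero, the 95% limits of agreement `bias +/- 1.96 sd(d)`, and the
#' proportional bias as the OLS regression of the differences on the
#' pairwise means.
#'
#' @param reference reference-system values.
#' @param candidate candidate-system values (paired with `reference`).
#' @param conf_level confidence level for the bias interval.
#' @param loa_mult multiplier for the limits of agreement (default 1.96).
#' @return object of class `bland_altman_result`: list with `bias`,
#'   `ci95_bias`, `p_bias`, `loa` (lower, upper), `sd_diff`, `prop_slope`,
#'   `prop_intercept`, `p_prop`, `n`.
#' @export
bland_altman <- function(reference, candidate, conf_level = 0.95,
                         loa_mult = 1.96) {
  ok <- is.finite(reference) & is.finite(candidate)
  r <- reference[ok]; c_ <- candidate[ok]
  n <- length(r)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- r - c_
  m <- (r + c_) / 2
  bias <- mean(d)
  sdd <- sd(d)
  tq <- qt(1 - (1 - conf_level) / 2, n - 1)
  ci <- bias + c(-1, 1) * tq * sdd / sqrt(n)
  p_bias <- if (sdd > 0) t.test(d)$p.value else
    if (abs(bias) > 0) 0 else NA_real_
  loa <- bias + c(-1, 1) * loa_mult * sdd
  if (var(m) > 0) {
    fit <- lm(d ~ m)
    prop_slope <- unname(coef(fit)[2])
    prop_int <- unname(coef(fit)[1])
    p_prop <- suppressWarnings(summary(fit))$coefficients["m", "Pr(>|t|)"]
  } else {
    prop_slope <- 0; prop_int <- bias; p_prop <- NA_real_
  }
  structure(
    list(bias = bias, ci95_bias = ci, p_bias = p_bias, loa = loa,
         sd_diff = sdd, prop_slope = prop_slope, prop_intercept = prop_int,
         p_prop = p_prop, n = n),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("bias = %.3f [%.3f, %.3f] (p = %.3g), LoA [%.3f, %.3f], prop: y = %.3fx + %.3f (p = %.3g), n = %d\n",
              x$bias, x$ci95_bias[1], x$ci95_bias[2], x$p_bias,
              x$loa[1], x$loa[2], x$prop_slope, x$prop_intercept,
              x$p_prop, x$n))
  invisible(x)
}

#' Reconstruct limits of agreement from a printed bias and its CI
#'
#' A reported mean-difference confidence interval implies the SD of the
#' differences: `sd = ((ci_hi - ci_lo)/2) * sqrt(n) / t(0.975, n-1)`. The
#' limits of agreement are then `bias +/- 1.96 sd`. This links the columns
#' of a published Bland–Altman table so their internal consistency can be
#' checked without the underlying raw data.
#'
#' @param bias reported mean difference.
#' @param ci_lo,ci_hi reported confidence bounds for the bias.
#' @param n sample size behind the report.
#' @param conf_level confidence level of the reported interval.
#' @param loa_mult limits-of-agreement multiplier.
#' @return numeric vector `c(lower, upper)`.
#' @export
reconstruct_loa_from_ci <- function(bias, ci_lo, ci_hi, n,
                                    conf_level = 0.95, loa_mult = 1.96) {
  if (!(ci_lo <= ci_hi)) stop("ci_lo must not exceed ci_hi")
  if (n < 2) stop("n must be at least 2")
  sdd <- ((ci_hi - ci_lo) / 2) * sqrt(n) / qt(1 - (1 - conf_level) / 2, n - 1)
  bias + c(-1, 1) * loa_mult * sdd
}

#' Qualitative agreement bands
#'
#' `classify_icc()` maps an ICC to poor (< 0.5), moderate (0.5–0.75), good
#' (0.75–0.9) or excellent (>= 0.9). `classify_correlation()` maps |r| to
#' negligible (< 0.1), small (0.1–0.3), medium (0.3–0.5) or large (>= 0.5);
#' `classify_r2()` maps R-squared to negligible (< 0.01), small (0.01–0.09),
#' medium (0.09–0.25) or large (>= 0.25). All bands are left-closed.
#'
#' @param value ICC estimate (<= 1).
#' @return character label.
#' @export
classify_icc <- function(value) {
  stopifnot(all(value <= 1 + 1e-12))
  cut_label(value, c(0.5, 0.75, 0.9),
            c("poor", "moderate", "good", "excellent"))
}

#' @rdname classify_icc
#' @param r Pearson correlation coefficient (|r| <= 1).
#' @export
classify_correlation <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  cut_label(abs(r), c(0.1, 0.3, 0.5),
            c("negligible", "small", "medium", "large"))
}

#' @rdname classify_icc
#' @param r2 coefficient of determination in [0, 1].
#' @export
classify_r2 <- function(r2) {
  stopifnot(all(r2 >= 0), all(r2 <= 1 + 1e-12))
  cut_label(r2, c(0.01, 0.09, 0.25),
            c("negligible", "small", "medium", "large"))
}

# left-closed banding: value < breaks[1] -> labels[1], etc.
cut_label <- function(value, breaks, labels) {
  idx <- findInterval(value, breaks) + 1L
  labels[idx]
}
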
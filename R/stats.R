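#' Intraclass correlation ICC(2,1) with exact confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two sets of measurements on the same subjects,
#' computed from the two-way ANOVA mean squares (rows = subjects, columns =
#' raters/methods):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% confidence interval uses the exact F-distribution method
#' (Shrout-Fleiss / McGraw-Wong form with Satterthwaite degrees of freedom).
#'
#' @param x,y Numeric vectors of paired measurements (n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, the mean squares, and `n`.
#' @export
icc_2_1 <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("ICC requires at least 3 complete pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || msr <= 0)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                msr = msr, msc = msc, mse = mse, n = n,
                flag = "zero between-subject variance"))
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- qf(1 - alpha / 2, n - 1, v)
  f2 <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  list(icc = icc, ci_low = lo, ci_high = hi,
       msr = msr, msc = msc, mse = mse, n = n, flag = "")
}

#' Bland-Altman agreement summary
#'
#' Mean error (bias) of `x - y` and the 95% limits of agreement
#' `bias +/- 1.96 sd(x - y)`.
#'
#' @param x,y Numeric vectors of paired measurements (n >= 2).
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`, and the
#'   plot coordinates (`mean`, `diff`) for a Bland-Altman plot.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stopf("Bland-Altman requires at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(x), mean = (x + y) / 2, diff = d)
}

# inclusion-exclusion effect estimates for one subset of factors on a
# complete balanced table; returns the per-observation effect values
effect_values <- function(df, dv, fac_subset) {
  n <- nrow(df)
  vals <- numeric(n)
  subsets <- if (length(fac_subset) == 0) list(character(0)) else {
    unlist(lapply(0:length(fac_subset), function(m)
      utils::combn(fac_subset, m, simplify = FALSE)), recursive = FALSE)
  }
  for (s in subsets) {
    sign <- (-1)^(length(fac_subset) - length(s))
    if (length(s) == 0) {
      vals <- vals + sign * mean(df[[dv]])
    } else {
      key <- interaction(df[s], drop = FALSE)
      mm <- tapply(df[[dv]], key, mean)
      vals <- vals + sign * as.numeric(mm[as.character(key)])
    }
  }
  vals
}

#' Repeated-measures (within-subject) factorial ANOVA
#'
#' Full-factorial decomposition of a complete, balanced within-subject design
#' (every subject measured in every condition cell exactly once). Each
#' effect's F statistic is its mean square over the mean square of its
#' subject-by-effect interaction, the classical univariate repeated-measures
#' analysis. For each within-subject effect with at least 3 cells, Mauchly's
#' sphericity test and the Greenhouse-Geisser epsilon are reported;
#' Greenhouse-Geisser-corrected p values are applied only on request
#' (`gg_correct = TRUE`), otherwise sphericity is assumed.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric outcome column.
#' @param subject Name of the subject ID column.
#' @param factors Character vector of within-subject factor columns.
#' @param gg_correct Use Greenhouse-Geisser-corrected p values.
#' @return Data frame with one row per effect: `effect`, `ss`, `df1`, `df2`,
#'   `ms`, `f`, `p`, `gg_epsilon`, `p_gg`, `mauchly_w`, `mauchly_p`.
#' @export
rm_anova <- function(data, dv, subject, factors, gg_correct = FALSE) {
  df <- as.data.frame(data)
  df[[subject]] <- factor(df[[subject]])
  for (f in factors) df[[f]] <- factor(df[[f]])
  lev <- vapply(c(subject, factors), function(f) nlevels(df[[f]]), 1L)
  if (nrow(df) != prod(lev))
    stopf("design must be complete and balanced: expected %d rows, got %d (no imputation)",
          prod(lev), nrow(df))
  cell <- interaction(df[c(subject, factors)], drop = FALSE)
  if (any(table(cell) != 1))
    stopf("design must have exactly one observation per subject x condition cell")
  nlev <- setNames(as.integer(lev), c(subject, factors))
  effects <- unlist(lapply(seq_along(factors), function(m)
    utils::combn(factors, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(e) {
    ss_e <- sum(effect_values(df, dv, e)^2)
    df1 <- prod(nlev[e] - 1L)
    ss_err <- sum(effect_values(df, dv, c(subject, e))^2)
    df2 <- (nlev[subject] - 1L) * df1
    ms_e <- ss_e / df1
    ms_err <- ss_err / df2
    fstat <- ms_e / ms_err
    p <- pf(fstat, df1, df2, lower.tail = FALSE)
    # sphericity diagnostics on the per-subject cell means of this effect
    gg <- NA_real_; p_gg <- NA_real_; mw <- NA_real_; mp <- NA_real_
    ncell <- prod(nlev[e])
    if (ncell >= 3) {
      key <- interaction(df[e], drop = FALSE)
      tab <- tapply(df[[dv]], list(df[[subject]], key), mean)
      S <- stats::cov(tab)
      m <- ncol(tab)
      # Greenhouse-Geisser epsilon from the double-centred covariance matrix
      Sd <- S - matrix(rowMeans(S), m, m) - matrix(colMeans(S), m, m, byrow = TRUE) + mean(S)
      gg <- sum(diag(Sd))^2 / ((m - 1) * sum(Sd^2))
      if (!is.finite(gg)) gg <- NA_real_
      p_gg <- if (is.finite(gg)) pf(fstat, gg * df1, gg * df2, lower.tail = FALSE)
              else NA_real_
      # rank-deficient condition covariances (few subjects) yield NA quietly
      mt <- suppressWarnings(tryCatch(
        mauchly.test(lm(tab ~ 1), X = ~1),
        error = function(e) NULL))
      if (!is.null(mt) && !is.finite(mt$p.value)) mt <- NULL
      if (!is.null(mt)) { mw <- unname(mt$statistic); mp <- mt$p.value }
    }
    data.frame(effect = paste(e, collapse = ":"), ss = ss_e, df1 = df1,
               df2 = df2, ms = ms_e, f = fstat,
               p = if (gg_correct && is.finite(p_gg)) p_gg else p,
               gg_epsilon = gg, p_gg = p_gg,
               mauchly_w = mw, mauchly_p = mp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Post-hoc paired t-test
#'
#' Two-sided paired t-test on the differences `x - y`. No multiple-testing
#' correction is applied: comparisons are reported at raw alpha, as in the
#' evaluation protocol this harness mirrors (document accordingly when
#' reporting many comparisons).
#'
#' @param x,y Paired numeric vectors (n >= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`, and `flag` (set when
#'   the differences have zero variance).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stopf("paired t-test requires at least 2 pairs")
  d <- x - y
  if (sd(d) <= .Machine$double.eps^0.5 * max(abs(d), 1)) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), n = length(d),
                flag = "zero-variance differences"))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), n = length(x), flag = "")
}

#' Normality and sphericity assumption checks
#'
#' Shapiro-Wilk statistic and p value, sample skewness and excess kurtosis of
#' the residuals, Q-Q plot coordinates, and — when a repeated-measures table
#' with at least 3 conditions is supplied — Mauchly's test of sphericity on
#' the condition covariance matrix (with 2 conditions sphericity holds
#' trivially and the test is skipped with a note).
#'
#' @param residuals Numeric vector (n >= 3).
#' @param repeated Optional subjects x conditions matrix.
#' @return List with `shapiro_w`, `shapiro_p`, `skewness`, `kurtosis`,
#'   `qq` (data frame of theoretical/sample quantiles), `mauchly_w`,
#'   `mauchly_p`, `note`.
#' @export
assumption_checks <- function(residuals, repeated = NULL) {
  r <- residuals[is.finite(residuals)]
  if (length(r) < 3) stopf("need at least 3 residuals")
  sw <- shapiro.test(if (length(r) > 5000) r[seq_len(5000)] else r)
  qq <- qqnorm(r, plot.it = FALSE)
  out <- list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
              skewness = e1071::skewness(r, type = 2),
              kurtosis = e1071::kurtosis(r, type = 2),
              qq = data.frame(theoretical = qq$x, sample = qq$y),
              mauchly_w = NA_real_, mauchly_p = NA_real_, note = "")
  if (!is.null(repeated)) {
    repeated <- as.matrix(repeated)
    if (ncol(repeated) < 3) {
      out$note <- "fewer than 3 conditions: sphericity holds trivially, Mauchly skipped"
    } else {
      mt <- mauchly.test(lm(repeated ~ 1), X = ~1)
      out$mauchly_w <- unname(mt$statistic)
      out$mauchly_p <- mt$p.value
    }
  }
  out
}
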
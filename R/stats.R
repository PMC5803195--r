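cv_bin <- function(cv) {
  if (is.na(cv)) return(NA_character_)
  if (cv <= 10) "good" else if (cv < 25) "moderate" else "poor"
}

rho_bin <- function(rho) {
  if (is.na(rho)) return("undefined")
  a <- abs(rho)
  if (a < 0.25) "low" else if (a < 0.5) "weak" else
    if (a < 0.75) "moderate" else "strong"
}

#' Test-retest coefficient of variation
#'
#' Within-subject coefficient of variation for paired repeat measurements.
#' The default (`method = "rms"`) is the root-mean-square within-subject
#' CV standard in repeatability work:
#' \deqn{CV = 100 \sqrt{\mathrm{mean}_i[(x_{i1} - x_{i2})^2 / 2]} / \bar x,}
#' with the grand mean over all values in the denominator.
#' `method = "per_subject"` instead averages the per-subject CVs
#' (SD/mean of each pair). Bins: <= 10% good, 10–25% moderate,
#' >= 25% poor reproducibility.
#'
#' @param x1,x2 Positive paired measurements (exam 1, exam 2), same length
#'   (>= 2 pairs).
#' @param method `"rms"` (default) or `"per_subject"`.
#' @return A list with `cv_percent`, `bin`, `n` and `method`.
#' @export
#' @examples
#' cv_test_retest(c(10, 12, 9), c(11, 12, 9.5))
cv_test_retest <- function(x1, x2, method = c("rms", "per_subject")) {
  method <- match.arg(method)
  if (length(x1) != length(x2)) stop("x1 and x2 lengths differ")
  if (length(x1) < 2) stop("need >= 2 pairs")
  if (any(!is.finite(c(x1, x2))) || any(c(x1, x2) <= 0))
    stop("all values must be positive and finite")
  cv <- if (method == "rms") {
    100 * sqrt(mean((x1 - x2)^2 / 2)) / mean(c(x1, x2))
  } else {
    per <- vapply(seq_along(x1), function(i) {
      p <- c(x1[i], x2[i]); 100 * stats::sd(p) / mean(p)
    }, 0)
    mean(per)
  }
  list(cv_percent = cv, bin = cv_bin(cv), n = length(x1), method = method)
}

#' Percentage Bland-Altman limits of agreement
#'
#' Per-subject percentage differences `d_i = 100 (x_i1 - x_i2) / m_i` with
#' `m_i` the pair mean; bias is `mean(d)` and the 95% limits of agreement
#' are `bias +/- 1.96 sd(d)` (sample SD).
#'
#' @inheritParams cv_test_retest
#' @return A list with `bias_percent`, `lower`, `upper`, `sd_percent`, `n`.
#' @export
bland_altman_percent <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 lengths differ")
  if (length(x1) < 2) stop("need >= 2 pairs")
  m <- (x1 + x2) / 2
  if (any(m == 0)) stop("pair mean of zero: percentage difference undefined")
  d <- 100 * (x1 - x2) / m
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias_percent = bias, lower = bias - 1.96 * s,
       upper = bias + 1.96 * s, sd_percent = s, n = length(x1))
}

#' Spearman correlation of a parameter with echo time
#'
#' Spearman's rho (midrank ties) between pooled parameter values and their
#' TE labels, with a two-sided p-value and the conventional strength bins:
#' |rho| < 0.25 low, 0.25–0.5 weak, 0.5–0.75 moderate, >= 0.75 strong.
#' Constant input yields a flagged `NA` result rather than an error.
#'
#' @param values Numeric parameter values (>= 3).
#' @param te Echo-time labels aligned with `values`.
#' @return A list with `rho`, `p_value`, `bin`, `n` and `defined`.
#' @export
spearman_te_trend <- function(values, te) {
  if (length(values) != length(te)) stop("values and te lengths differ")
  if (length(values) < 3) stop("need >= 3 observations")
  if (stats::sd(values) == 0 || stats::sd(te) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, bin = "undefined",
                n = length(values), defined = FALSE))
  ct <- suppressWarnings(
    stats::cor.test(values, te, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p_value = ct$p.value, bin = rho_bin(rho),
       n = length(values), defined = TRUE)
}

#' One-way ANOVA across echo-time levels
#'
#' Classical one-way analysis of variance (equal-variance F test) of a
#' parameter across TE groups. Degenerate input with zero variance
#' everywhere returns a flagged `NA` F.
#'
#' @param groups List of numeric vectors, one per TE level (>= 2 groups,
#'   each with >= 2 values).
#' @return A list with `f_statistic`, `p_value`, `df` (c(between, within))
#'   and `defined`.
#' @export
#' @examples
#' anova_across_te(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5
anova_across_te <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs >= 2 values")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  within_var <- sum(vapply(groups, function(x)
    sum((x - mean(x))^2), 0)) / df2
  if (within_var == 0) {
    means <- vapply(groups, mean, 0)
    fstat <- if (max(means) - min(means) == 0) NA_real_ else Inf
    return(list(f_statistic = fstat,
                p_value = if (is.na(fstat)) NA_real_ else 0,
                df = c(df1, df2), defined = !is.na(fstat)))
  }
  tst <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(f_statistic = unname(tst$statistic), p_value = tst$p.value,
       df = c(df1, df2), defined = TRUE)
}

#' Muscle-referenced signal-to-noise ratio
#'
#' Operational SNR of a diffusion image: the mean ROI signal at
#' b = 1000 s/mm^2 divided by the standard deviation of the pixel values
#' in a muscle reference ROI on the same image.
#'
#' @param roi_signal_b1000 ROI signal value(s) at b = 1000 (>= 0).
#' @param muscle_samples >= 2 muscle-ROI pixel values.
#' @return The SNR (dimensionless).
#' @export
snr_estimate <- function(roi_signal_b1000, muscle_samples) {
  if (length(muscle_samples) < 2) stop("need >= 2 muscle samples")
  if (any(roi_signal_b1000 < 0)) stop("ROI signal must be non-negative")
  s <- stats::sd(muscle_samples)
  if (s == 0) stop("muscle SD is zero: SNR undefined")
  mean(roi_signal_b1000) / s
}
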
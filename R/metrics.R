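#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`.  Both masks empty is defined as
#' perfect agreement (1).
#'
#' @param pred,ref binary arrays or [seg_mask()]s on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  a <- if (inherits(pred, "ct_volume")) pred$data else pred
  b <- if (inherits(ref, "ct_volume")) ref$data else ref
  if (inherits(pred, "ct_volume") && inherits(ref, "ct_volume"))
    check_same_grid(pred, ref, "masks")
  if (!identical(dim(a), dim(b)))
    stop("alignment error: masks have different shapes")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a * b) / (sa + sb)
}

#' Relative EAT volume error (percent)
#'
#' `100 * |v_pred - v_ref| / v_ref`.
#'
#' @param v_pred,v_ref volumes (cm^3); `v_ref > 0`.
#' @return Percentage error (>= 0).
#' @export
relative_volume_error <- function(v_pred, v_ref) {
  if (any(v_ref <= 0)) stop("domain error: v_ref must be > 0")
  100 * abs(v_pred - v_ref) / v_ref
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as `x - y` (convention: x = predicted, y =
#' reference, so an underestimating method gives a negative bias).  Limits
#' are `bias +/- 1.96 * sd` with the sample (n-1) standard deviation.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return `list(bias, loa_low, loa_high, sd_diff, n)`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("domain error: x and y lengths differ")
  if (length(x) < 2L) stop("domain error: need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(x))
}

#' Pearson correlation
#'
#' Standard product-moment correlation; requires n >= 3 and non-degenerate
#' variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("domain error: x and y lengths differ")
  if (length(x) < 3L) stop("domain error: need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("domain error: zero variance")
  stats::cor(x, y)
}

#' Two-way random-effects absolute-agreement single-measure ICC
#'
#' ICC(2,1) from the two-way mean-squares decomposition of an n-subjects by
#' k-raters table (here k = 2: the two columns), with the standard
#' F-distribution confidence interval.  This is the conventional form for
#' two-reader absolute-volume agreement.
#'
#' @param x,y paired measurements of the same subjects by two raters
#'   (n >= 5).
#' @param conf confidence level (default 0.95).
#' @return `list(icc, ci_low, ci_high, degenerate)`.  Exactly identical
#'   ratings return `icc = 1` with a degenerate CI flagged.
#' @export
icc_absolute <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("domain error: x and y lengths differ")
  n <- length(x)
  if (n < 5L) stop("domain error: need at least 5 pairs")
  dat <- cbind(x, y)
  k <- 2L
  grand <- mean(dat)
  si <- rowMeans(dat); rj <- colMeans(dat)
  msr <- k * sum((si - grand)^2) / (n - 1)
  msc <- n * sum((rj - grand)^2) / (k - 1)
  mse <- sum((dat - outer(si, rep(1, k)) - outer(rep(1, n), rj) + grand)^2) /
    ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps && mse < .Machine$double.eps)
    return(list(icc = 1.0, ci_low = NA_real_, ci_high = NA_real_,
                degenerate = TRUE))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse < .Machine$double.eps * max(1, msr))
    return(list(icc = 1.0, ci_low = 1.0, ci_high = 1.0, degenerate = TRUE))
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, degenerate = FALSE)
}

#' Index a volume to body surface area
#'
#' @param volume volume in cm^3.
#' @param bsa body surface area in m^2 (> 0).
#' @return Indexed volume, cm^3/m^2.
#' @export
bsa_index <- function(volume, bsa) {
  if (any(bsa <= 0)) stop("domain error: bsa must be > 0")
  volume / bsa
}

#' Full agreement report for paired volume measurements
#'
#' Computes the evaluation suite used for method comparison: mean relative
#' volume error, Pearson r, Bland-Altman bias and limits of agreement, and
#' ICC(2,1) with its CI.  Optionally a mean Dice if mask pairs are supplied.
#'
#' @param v_pred,v_ref paired volumes (cm^3), reference > 0.
#' @param mask_pairs optional list of `list(pred =, ref =)` mask pairs.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(v_pred, v_ref, mask_pairs = NULL) {
  ba <- bland_altman(v_pred, v_ref)
  icc <- tryCatch(icc_absolute(v_pred, v_ref),
                  error = function(e) list(icc = NA_real_, ci_low = NA_real_,
                                           ci_high = NA_real_,
                                           degenerate = TRUE))
  r <- tryCatch(pearson(v_pred, v_ref), error = function(e) NA_real_)
  dsc <- if (!is.null(mask_pairs))
    mean(vapply(mask_pairs, function(p) dice(p$pred, p$ref), numeric(1)))
  else NA_real_
  structure(list(n = length(v_pred),
                 rel_vol_err_pct = mean(relative_volume_error(v_pred, v_ref)),
                 pearson_r = r,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 icc = icc$icc, icc_ci = c(icc$ci_low, icc$ci_high),
                 dice = dsc),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  mean relative volume error: %.2f%%\n", x$rel_vol_err_pct))
  cat(sprintf("  Pearson r: %.3f\n", x$pearson_r))
  cat(sprintf("  Bland-Altman bias %.2f cm^3, LoA [%.2f, %.2f] cm^3\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  ICC(2,1): %.3f [%.3f, %.3f]\n", x$icc, x$icc_ci[1],
              x$icc_ci[2]))
  if (!is.na(x$dice)) cat(sprintf("  mean Dice: %.3f\n", x$dice))
  invisible(x)
}
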
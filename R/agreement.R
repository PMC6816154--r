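# Agreement statistics for paired measurements (two methods or two readers)
# and categorical ratings: Bland-Altman bias and 95% limits of agreement,
# within-subject coefficient of variation, intraclass correlation from the
# two-way mean-squares decomposition, and Cohen's kappa.

check_pairs <- function(a, b, min_n = 2L) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < min_n) stop(sprintf("need at least %d pairs", min_n))
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  invisible(NULL)
}

#' Bland-Altman analysis
#'
#' Bias is the mean of the pairwise differences `a - b`; the 95% limits of
#' agreement are `bias +/- 1.96 * SD` with the sample (n-1) standard
#' deviation of the differences.
#'
#' @param a,b paired measurements in the same units (length >= 2).
#' @return A list `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(a, b) {
  check_pairs(a, b)
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Within-subject coefficient of variation
#'
#' The per-subject SD of the two measurements, pooled as the root of the
#' mean per-subject variance, divided by the grand mean, times 100. The
#' alternative convention (SD of the paired differences over the grand
#' mean) is returned alongside by [agreement_report()].
#'
#' @inheritParams bland_altman
#' @return CV in percent.
#' @export
cv_percent <- function(a, b) {
  check_pairs(a, b, min_n = 1L)
  gm <- mean(c(a, b))
  if (gm <= 0) stop("grand mean must be positive")
  per_subject_var <- (a - b)^2 / 2   # variance of two values
  100 * sqrt(mean(per_subject_var)) / gm
}

#' Intraclass correlation coefficient
#'
#' Two-way model, single measurement, computed from the standard
#' mean-squares decomposition of the subjects-by-raters table. The default
#' form is absolute agreement, ICC(A,1); the consistency form ICC(C,1) is
#' selectable.
#'
#' @param a,b paired measurements (length >= 3 subjects).
#' @param form `"agreement"` (default) or `"consistency"`.
#' @return ICC in `[-1, 1]`.
#' @export
icc <- function(a, b, form = c("agreement", "consistency")) {
  form <- match.arg(form)
  check_pairs(a, b, min_n = 3L)
  X <- cbind(a, b)
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X)
  if (all(X == X[1])) {
    # zero total variance: defined as 1 for exact agreement
    if (all(a == b)) return(1)
    stop("degenerate input: zero total variance without exact agreement")
  }
  row_m <- rowMeans(X); col_m <- colMeans(X)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sst <- sum((X - grand)^2)
  mse <- (sst - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)) /
    ((n - 1) * (k - 1))
  if (form == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Cohen's kappa
#'
#' Chance-corrected agreement of two categorical ratings:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_e` from the marginal products.
#' Perfect agreement with a degenerate margin (`p_e = 1`) is defined as 1.
#'
#' @param labels_a,labels_b equal-length label vectors over a shared
#'   alphabet.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 1) {
    stop("label vectors must have equal length >= 1")
  }
  lev <- sort(unique(c(labels_a, labels_b)))
  ta <- factor(labels_a, levels = lev)
  tb <- factor(labels_b, levels = lev)
  tab <- table(ta, tb) / length(ta)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (1 - pe < .Machine$double.eps) {
    if (po == 1) return(1)
    stop("degenerate margins: expected agreement is 1")
  }
  (po - pe) / (1 - pe)
}

#' Full agreement report for paired measurements
#'
#' @inheritParams bland_altman
#' @param icc_form passed to [icc()].
#' @return An `agreement_report` list: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `icc`, `cv_percent` (within-subject form),
#'   `cv_diff_percent` (SD-of-differences form), `n`.
#' @export
agreement_report <- function(a, b, icc_form = "agreement") {
  ba <- bland_altman(a, b)
  gm <- mean(c(a, b))
  structure(c(ba[c("bias", "sd_diff", "loa_low", "loa_high")],
              list(icc = if (length(a) >= 3) icc(a, b, icc_form) else NA_real_,
                   cv_percent = cv_percent(a, b),
                   cv_diff_percent = 100 * ba$sd_diff / gm,
                   n = ba$n)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n = %d; bias %.3f (LOA %.3f, %.3f); ICC %.3f; CV %.1f%%\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$icc, x$cv_percent))
  invisible(x)
}
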
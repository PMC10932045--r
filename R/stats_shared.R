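#' Pearson correlation with Student t test and Fisher z interval
#'
#' Single shared implementation of the correlation primitive used by every
#' stage of the screen: pair correlation, module-trait correlation,
#' replication correlation, and fraction-expression correlation.  Computes
#' the product-moment correlation `r`, the Student t statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, a two-sided p-value on `n - 2`
#' degrees of freedom, and a Fisher z confidence interval for `r`.
#'
#' Inputs must be complete: missing or non-finite values are rejected rather
#' than silently dropped, because pairwise deletion changes `n` from pair to
#' pair and is a known irreproducibility source.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite throughout.
#' @param conf_level Confidence level for the Fisher z interval.
#' @return A list with elements `ok`, `reason`, `r`, `n`, `t`, `p`, and
#'   `conf_int` (length-2 numeric).  When either input has zero variance the
#'   correlation is undefined: `ok` is `FALSE`, `reason` is
#'   `"zero_variance"`, and the numeric fields are `NA` — never a silent 0.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
#' @export
pearson_cor <- function(x, y, conf_level = 0.95) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values not accepted: inputs must be complete")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(ok = FALSE, reason = "zero_variance", r = NA_real_, n = n,
                t = NA_real_, p = NA_real_,
                conf_int = c(NA_real_, NA_real_)))
  }
  r <- min(max(stats::cor(x, y), -1), 1)
  if (1 - r^2 < .Machine$double.eps) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  # Fisher z interval; clamp so atanh stays finite at |r| = 1
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- if (n > 3) 1 / sqrt(n - 3) else Inf
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  list(ok = TRUE, reason = NA_character_, r = r, n = n, t = tstat, p = p,
       conf_int = ci)
}

#' Correlation test p-value from r and n
#'
#' Convenience wrapper computing the two-sided Student p-value for a given
#' correlation coefficient and sample size, using the same transform as
#' [pearson_cor()].
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value.
#' @export
cor_p_student <- function(r, n) {
  stopifnot(is.numeric(r), abs(r) <= 1, n >= 3)
  if (1 - r^2 < .Machine$double.eps) return(0)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}
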
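#' Validation-cohort differential-expression veto
#'
#' Each member of every surviving pair must remain differentially expressed
#' (Kruskal-Wallis p < alpha) in the validation cohort; pairs containing a
#' non-significant member are dropped.  The validation cohort only vetoes —
#' it never adds pairs.
#'
#' @param pairs Pair data.frame (training cascade output).
#' @param valid_expr Matrix genes x samples, validation cohort log2
#'   expression.
#' @param valid_groups `CTRL`/`CASE` labels for the validation samples.
#' @param alpha Significance level (default 0.05).
#' @return The pair data.frame with columns `kw_p_lnc_valid`,
#'   `kw_p_mrna_valid` added and `status` updated
#'   (`"dropped:member_de_validation"`, or `"dropped:absent_in_validation"`
#'   with a warning when a member is missing from the validation matrix).
#' @export
replicate_de <- function(pairs, valid_expr, valid_groups, alpha = 0.05) {
  x <- as.matrix(valid_expr)
  groups <- match_groups(valid_groups, colnames(x), ncol(x))
  pairs$kw_p_lnc_valid <- NA_real_
  pairs$kw_p_mrna_valid <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    if (!is_surviving(pairs$status[i])) next
    l <- pairs$lncRNA[i]; m <- pairs$mRNA[i]
    if (!(l %in% rownames(x)) || !(m %in% rownames(x))) {
      warning("pair member absent from validation cohort: ",
              paste(setdiff(c(l, m), rownames(x)), collapse = ", "))
      pairs$status[i] <- "dropped:absent_in_validation"
      next
    }
    pl <- kruskal_wallis(x[l, ], groups, alpha)$p
    pm <- kruskal_wallis(x[m, ], groups, alpha)$p
    pairs$kw_p_lnc_valid[i] <- pl
    pairs$kw_p_mrna_valid[i] <- pm
    if (!(pl < alpha && pm < alpha)) {
      pairs$status[i] <- "dropped:member_de_validation"
    }
  }
  pairs
}

#' Validation-cohort correlation test
#'
#' Each pair surviving the validation DE veto must show a significant
#' (p < alpha) and positive Pearson correlation in the validation cohort;
#' the p-value is the two-sided Student transform of r.  Survivors are
#' marked `"replicated"`.
#'
#' @param pairs Pair data.frame that already passed [replicate_de()].
#' @param valid_expr Matrix genes x samples, validation cohort log2
#'   expression.
#' @param alpha Significance level (default 0.05).
#' @return The pair data.frame with `r_valid` and `p_corr_valid` added and
#'   `status` set to `"replicated"` or `"dropped:corr_validation"` (a
#'   zero-variance member also drops the pair, with reason
#'   `"dropped:zero_variance_validation"`).
#' @export
replicate_correlation <- function(pairs, valid_expr, alpha = 0.05) {
  x <- as.matrix(valid_expr)
  pairs$r_valid <- NA_real_
  pairs$p_corr_valid <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    if (!is_surviving(pairs$status[i])) next
    ct <- pearson_cor(x[pairs$lncRNA[i], ], x[pairs$mRNA[i], ])
    if (!ct$ok) {
      pairs$status[i] <- "dropped:zero_variance_validation"
      next
    }
    pairs$r_valid[i] <- ct$r
    pairs$p_corr_valid[i] <- ct$p
    pairs$status[i] <- if (ct$p < alpha && ct$r > 0) "replicated" else
      "dropped:corr_validation"
  }
  pairs
}
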
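#' Remove genes with low total counts
#'
#' Drops genes whose summed count across all samples is below `min_total`
#' (default 1, i.e. all-zero genes are removed).  Gene order is otherwise
#' preserved.
#'
#' @param m A [count_matrix()].
#' @param min_total Minimum row sum to retain a gene.
#' @return A filtered `count_matrix`.
#' @export
filter_low_counts <- function(m, min_total = 1) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- rowSums(m$counts) >= min_total
  if (!any(keep)) stop("all genes removed by the low-count filter")
  count_matrix(m$counts[keep, , drop = FALSE], m$group)
}

#' Median-of-ratios normalization
#'
#' Size factor of sample j = median, over genes expressed in every sample, of
#' count_gj / geometric mean of gene g across samples.  Normalized value =
#' count / size factor; log2 expression = log2(normalized + 1).  If no gene
#' is expressed in all samples the function falls back to total-count
#' scaling with a warning.
#'
#' @param m A [count_matrix()] or a bare counts matrix.
#' @return List with `normalized` (matrix), `log2_expr` (matrix),
#'   `size_factors` (named vector), `method` (`"median_of_ratios"` or
#'   `"total_count"`).
#' @export
normalize_counts <- function(m) {
  counts <- as_count_mat(m)
  method <- "median_of_ratios"
  if (ncol(counts) == 1) {
    sf <- stats::setNames(1, colnames(counts))
  } else {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) {
      warning("no gene expressed in all samples; falling back to total-count scaling")
      method <- "total_count"
      tot <- colSums(counts)
      sf <- tot / exp(mean(log(tot)))
    } else {
      loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
      ratios <- counts[pos, , drop = FALSE] / exp(loggeo)
      sf <- apply(ratios, 2, stats::median)
    }
  }
  normalized <- sweep(counts, 2, sf, "/")
  list(normalized = normalized, log2_expr = log2(normalized + 1),
       size_factors = sf, method = method)
}

#' Two-group differential expression screen
#'
#' Welch two-sample t test on log2 expression per gene, CASE vs CTRL;
#' log2 fold change = mean(CASE) - mean(CTRL); Benjamini-Hochberg adjusted
#' p-values; a gene is a DEG when |log2FC| > `lfc_threshold` AND
#' adjusted p < `alpha`.
#'
#' @param log2_expr Matrix genes x samples of log2 expression.
#' @param groups Character vector (`CTRL`/`CASE`), named by sample or in
#'   column order; >= 2 samples per group.
#' @param lfc_threshold DEG log2 fold-change threshold.
#' @param alpha DEG adjusted-p threshold.
#' @return data.frame with columns `gene_id`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`, `is_deg`.
#' @export
de_test <- function(log2_expr, groups, lfc_threshold = 1, alpha = 0.05) {
  log2_expr <- as.matrix(log2_expr)
  groups <- match_groups(groups, colnames(log2_expr), ncol(log2_expr))
  case <- log2_expr[, groups == "CASE", drop = FALSE]
  ctrl <- log2_expr[, groups == "CTRL", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf * sign(lfc)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
              ifelse(lfc == 0, 1, 0))
  adj <- bh_adjust(p)
  data.frame(gene_id = rownames(log2_expr), log2_fold_change = lfc,
             p_value = p, adjusted_p = adj,
             is_deg = abs(lfc) > lfc_threshold & adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Align a group label vector to a set of sample ids.
match_groups <- function(groups, sample_ids, n) {
  if (!is.null(names(groups)) && !is.null(sample_ids)) {
    missing_s <- setdiff(sample_ids, names(groups))
    if (length(missing_s)) stop("sample(s) without group label: ",
                                paste(missing_s, collapse = ", "))
    groups <- groups[sample_ids]
  }
  if (length(groups) != n) stop("group vector does not match sample count")
  as.character(groups)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, in the input order, clipped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Kruskal-Wallis rank test
#'
#' H statistic with midrank tie correction, p-value from the chi-square
#' approximation with k - 1 degrees of freedom.  The two-group case is
#' permitted (equivalent to a rank-sum test).  The chi-square approximation
#' is used for all sample sizes; for fewer than ~5 observations per group it
#' is a documented approximation.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 non-empty groups).
#' @param alpha Significance threshold for the `significant` flag.
#' @return List with `H`, `p`, `significant`.
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tabulate(g) == 0)) stop("each group must be non-empty")
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, significant = FALSE))
  }
  kt <- stats::kruskal.test(values, g)
  p <- kt$p.value
  list(H = unname(kt$statistic), p = p, significant = is.finite(p) && p < alpha)
}

#' Relative abundance by the 2^-ddCt method
#'
#' Computes `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl -
#' ct_ref_ctrl))`, the standard relative quantification of qPCR abundance
#' against a reference gene and a control condition.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Finite cycle
#'   threshold values.
#' @return Relative abundance (dimensionless).
#' @examples
#' fold_change_ddct(20, 15, 22, 15)  # 4
#' @export
fold_change_ddct <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
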
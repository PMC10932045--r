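#' Estimate cell-type fractions from bulk expression
#'
#' Linear deconvolution of each mixture column against a marker-gene
#' signature matrix, following the published support-vector-regression
#' ensemble sketch: restrict to shared genes, z-score the mixture column and
#' standardize the signature, fit a linear nu-SVR for each nu in `nu_grid`,
#' keep the fit whose reconstruction has the smallest root-mean-square
#' error, clip negative coefficients to zero and normalize to sum 1.  A
#' plain non-negative least-squares fit (`method = "nnls"`) is available as
#' a dependency-light alternative.  An optional permutation p-value shuffles
#' the mixture values across genes `n_permutations` times and reports the
#' fraction of shuffles whose best fit correlation reaches the observed one
#' (computed as `(1 + #{perm >= obs}) / (n_permutations + 1)`).
#'
#' @param mixture_expr Matrix genes x samples of bulk expression (>= as many
#'   shared marker genes as cell types; all-zero mixture columns are
#'   rejected).
#' @param signature Marker genes x cell types matrix (see
#'   [read_signature_matrix()]).
#' @param method `"svr_ensemble"` (default) or `"nnls"`.
#' @param nu_grid nu values for the SVR ensemble.
#' @param n_permutations Number of gene-label shuffles (0 disables the
#'   permutation p-value).
#' @param seed Integer seed for the permutation shuffles.
#' @return List with `fractions` (samples x cell types, rows sum to 1),
#'   `fit_rmse`, `fit_correlation`, `permutation_p` (per-sample vectors;
#'   `permutation_p` is `NA` when disabled), and `method`.
#' @export
estimate_fractions <- function(mixture_expr, signature,
                               method = c("svr_ensemble", "nnls"),
                               nu_grid = c(0.25, 0.5, 0.75),
                               n_permutations = 1000, seed = 1L) {
  method <- match.arg(method)
  mix <- as.matrix(mixture_expr)
  sig <- as.matrix(signature)
  shared <- intersect(rownames(mix), rownames(sig))
  if (length(shared) < ncol(sig)) {
    stop("need at least ", ncol(sig), " marker genes shared between mixture and signature")
  }
  mix <- mix[shared, , drop = FALSE]
  sig <- sig[shared, , drop = FALSE]
  X <- (sig - mean(sig)) / stats::sd(sig)   # global standardization
  n_s <- ncol(mix)
  K <- ncol(sig)
  fractions <- matrix(0, n_s, K, dimnames = list(colnames(mix), colnames(sig)))
  rmse <- corr <- perm_p <- stats::setNames(rep(NA_real_, n_s), colnames(mix))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  for (j in seq_len(n_s)) {
    y_raw <- mix[, j]
    if (all(y_raw == 0)) stop("all-zero mixture column: ", colnames(mix)[j])
    y <- as.vector(scale(y_raw))
    fit <- deconv_fit(X, y, method, nu_grid)
    fractions[j, ] <- fit$w
    rmse[j] <- fit$rmse
    corr[j] <- fit$corr
    if (n_permutations > 0) {
      perm_corr <- vapply(seq_len(n_permutations), function(b) {
        deconv_fit(X, sample(y), method, nu_grid)$corr
      }, numeric(1))
      perm_p[j] <- (1 + sum(perm_corr >= fit$corr)) / (n_permutations + 1)
    }
  }
  list(fractions = fractions, fit_rmse = rmse, fit_correlation = corr,
       permutation_p = perm_p, method = method)
}

# Single-sample deconvolution fit on standardized inputs.  Returns the
# normalized non-negative weights plus reconstruction RMSE and correlation.
deconv_fit <- function(X, y, method, nu_grid) {
  candidates <- if (method == "nnls") {
    w <- pracma::lsqnonneg(X, y)$x
    list(w)
  } else {
    lapply(nu_grid, function(nu) {
      m <- tryCatch(
        e1071::svm(x = X, y = y, type = "nu-regression", kernel = "linear",
                   nu = nu, scale = FALSE),
        error = function(e) NULL)
      if (is.null(m)) return(NULL)
      pmax(as.vector(t(m$coefs) %*% m$SV), 0)
    })
  }
  best <- NULL
  for (w in candidates) {
    if (is.null(w) || sum(w) == 0) next
    w <- w / sum(w)
    k <- as.vector(X %*% w)
    r <- sqrt(mean((k - y)^2))
    if (is.null(best) || r < best$rmse) {
      best <- list(w = w, rmse = r,
                   corr = if (stats::sd(k) > 0) stats::cor(k, y) else 0)
    }
  }
  if (is.null(best)) {
    # degenerate: no fit produced positive weights; fall back to NNLS
    w <- pracma::lsqnonneg(X, y)$x
    if (sum(w) == 0) w <- rep(1, ncol(X))
    w <- w / sum(w)
    k <- as.vector(X %*% w)
    best <- list(w = w, rmse = sqrt(mean((k - y)^2)),
                 corr = if (stats::sd(k) > 0) stats::cor(k, y) else 0)
  }
  best
}

#' Compare estimated fractions between groups
#'
#' Kruskal-Wallis test (two groups) per cell type on the estimated
#' fractions; direction is the difference of group medians (CASE - CTRL).
#'
#' @param fractions Samples x cell types matrix (e.g.
#'   `estimate_fractions()$fractions`).
#' @param groups `CTRL`/`CASE` labels (named by sample or in row order).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with columns `cell_type`, `H`, `p`, `direction`,
#'   `significant`.
#' @export
compare_fractions <- function(fractions, groups, alpha = 0.05) {
  f <- as.matrix(fractions)
  groups <- match_groups(groups, rownames(f), nrow(f))
  res <- lapply(colnames(f), function(ct) {
    kw <- kruskal_wallis(f[, ct], groups, alpha)
    data.frame(cell_type = ct, H = kw$H, p = kw$p,
               direction = stats::median(f[groups == "CASE", ct]) -
                 stats::median(f[groups == "CTRL", ct]),
               significant = kw$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Correlate gene expression with cell-type fractions
#'
#' Pearson correlation of each selected gene's log2 expression with each
#' estimated cell-type fraction, with the Student t p-value of the shared
#' correlation implementation.
#'
#' @param log2_expr Matrix genes x samples (selected genes only).
#' @param fractions Samples x cell types matrix over the same samples.
#' @param alpha Significance level for the flag (default 0.05).
#' @return data.frame with columns `gene`, `cell_type`, `r`, `p`,
#'   `significant`, `reason` (`"zero_variance"` when r is undefined, else
#'   `NA`).
#' @export
correlate_expression_fractions <- function(log2_expr, fractions,
                                           alpha = 0.05) {
  x <- as.matrix(log2_expr)
  f <- as.matrix(fractions)
  if (ncol(x) != nrow(f)) stop("expression and fractions must cover the same samples")
  if (!is.null(colnames(x)) && !is.null(rownames(f))) {
    if (!all(colnames(x) == rownames(f))) f <- f[colnames(x), , drop = FALSE]
  }
  out <- list()
  for (g in rownames(x)) {
    for (ct in colnames(f)) {
      res <- pearson_cor(x[g, ], f[, ct])
      out[[length(out) + 1]] <- data.frame(
        gene = g, cell_type = ct, r = res$r, p = res$p,
        significant = isTRUE(res$ok) && res$p < alpha,
        reason = res$reason, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
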
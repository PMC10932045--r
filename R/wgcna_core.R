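# Standard module color sequence, assigned in decreasing module size order.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Select the most variable genes by absolute deviation
#'
#' Ranks genes by the (unscaled) median absolute deviation of their log2
#' expression across samples — the robust dispersion conventionally used to
#' pick the input set for co-expression network construction — and keeps the
#' top `min(k, n)` genes.  Ties are broken by lexicographic gene id so the
#' selection is deterministic.
#'
#' @param log2_expr Matrix genes x samples.
#' @param k Number of genes to keep (default 5000).
#' @param method `"median"` for median absolute deviation (default) or
#'   `"mean"` for mean absolute deviation.
#' @return The reduced expression matrix, most variable genes first.
#' @export
select_top_mad <- function(log2_expr, k = 5000, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(k >= 1)
  x <- as.matrix(log2_expr)
  disp <- if (method == "median") {
    apply(x, 1, function(v) stats::median(abs(v - stats::median(v))))
  } else {
    rowMeans(abs(x - rowMeans(x)))
  }
  ord <- order(-disp, rownames(x))
  x[ord[seq_len(min(k, nrow(x)))], , drop = FALSE]
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `n_bins` equal-width bins over their range,
#' then regresses log10(bin frequency) on log10(mean bin connectivity) over
#' the non-empty bins.  Returns R^2 signed by the negative of the fitted
#' slope, so a decreasing (power-law-like) distribution scores positively.
#'
#' @param k Non-negative connectivity vector.
#' @param n_bins Number of bins (default 10).
#' @return List with `r2_signed`, `slope`, `r2`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k)]
  if (length(k) < 2 || max(k) == min(k)) {
    return(list(r2_signed = NA_real_, slope = NA_real_, r2 = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tabulate(bin, nbins = n_bins) / length(k)
  ok <- !is.na(mean_k) & freq > 0 & mean_k > 0
  if (sum(ok) < 2) {
    return(list(r2_signed = NA_real_, slope = NA_real_, r2 = NA_real_))
  }
  lx <- log10(mean_k[ok]); ly <- log10(freq[ok])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  slope <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(r2_signed = unname(r2 * -sign(slope)), slope = unname(slope),
       r2 = unname(r2))
}

#' Soft-threshold scan
#'
#' For each candidate power beta, forms the adjacency `|r|^beta` (diagonal
#' excluded), computes each gene's connectivity `k_i = sum_{j != i} a_ij`,
#' and evaluates the scale-free topology fit of the connectivity
#' distribution via [scale_free_fit()].
#'
#' @param expr Matrix genes x samples (>= 3 genes).  Zero-variance genes are
#'   excluded with a warning before correlation.
#' @param beta_range Ascending integer powers (default 1..20).
#' @return data.frame with one row per beta: `beta`, `scale_free_r2_signed`,
#'   `slope`, `mean_connectivity`, `median_connectivity`,
#'   `max_connectivity`.
#' @export
scan_soft_threshold <- function(expr, beta_range = 1:20) {
  expr <- as.matrix(expr)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance gene(s) from the scan")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 3) stop("need at least 3 genes with variance")
  absr <- abs(stats::cor(t(expr)))
  diag(absr) <- 0
  out <- lapply(beta_range, function(b) {
    a <- absr^b
    k <- rowSums(a)
    sf <- scale_free_fit(k)
    data.frame(beta = b, scale_free_r2_signed = sf$r2_signed,
               slope = sf$slope, mean_connectivity = mean(k),
               median_connectivity = stats::median(k),
               max_connectivity = max(k))
  })
  do.call(rbind, out)
}

#' Pick the soft-threshold power
#'
#' Smallest beta whose signed scale-free R^2 reaches `r2_target`; if none
#' does, the beta maximizing the signed R^2 is returned with
#' `met_target = FALSE` and a warning.
#'
#' @param scan Output of [scan_soft_threshold()].
#' @param r2_target Scale-free fit target (default 0.85).
#' @return List with `beta`, `r2`, `met_target`.
#' @export
pick_beta <- function(scan, r2_target = 0.85) {
  stopifnot(nrow(scan) >= 1)
  r2 <- scan$scale_free_r2_signed
  hit <- which(!is.na(r2) & r2 >= r2_target)
  if (length(hit)) {
    i <- hit[1]
    list(beta = scan$beta[i], r2 = r2[i], met_target = TRUE)
  } else {
    i <- which.max(r2)
    warning("no power reached the scale-free target R^2 = ", r2_target,
            "; using the maximizing power ", scan$beta[i])
    list(beta = scan$beta[i], r2 = r2[i], met_target = FALSE)
  }
}

#' Signed-power adjacency matrix
#'
#' `a_ij = |pearson(x_i, x_j)|^beta` with unit diagonal (unsigned network).
#'
#' @param expr Matrix genes x samples; zero-variance genes are rejected and
#'   must be filtered upstream.
#' @param beta Power >= 1.
#' @return Symmetric gene x gene matrix in `[0, 1]`.
#' @export
adjacency_power <- function(expr, beta) {
  stopifnot(beta >= 1)
  expr <- as.matrix(expr)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  }
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Standard unsigned topological overlap:
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' for i != j, with connectivity `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`.
#'
#' @param a Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return List with `tom` and `dissimilarity` (`1 - tom`) matrices.
#' @export
tom_similarity <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) stop("adjacency values must lie in [0, 1]")
  if (any(abs(diag(a) - 1) > 1e-12)) stop("adjacency must have unit diagonal")
  k <- rowSums(a) - 1
  # (a %*% a)_ij = sum_u a_iu a_uj includes u = i and u = j, each contributing
  # a_ij (unit diagonal), so the u != i,j sum is (a %*% a)_ij - 2 a_ij.
  shared <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  list(tom = tom, dissimilarity = 1 - tom)
}

#' Detect modules by average-linkage clustering and a static cut
#'
#' Hierarchically clusters the topological overlap dissimilarity (average
#' linkage) and cuts the tree at 0.99 x the maximum merge height.  Clusters
#' of at least `min_module_size` genes become modules, labeled with the
#' conventional color sequence ("turquoise", "blue", "brown", ...) in
#' decreasing size order (ties broken by the lexicographically smallest
#' member gene id); smaller clusters are labeled `"unassigned"`.
#'
#' @param dissimilarity Square matrix in `[0, 1]` (1 - TOM).
#' @param min_module_size Minimum genes per module (default 30).
#' @return Named character vector gene -> module label.
#' @export
cluster_modules <- function(dissimilarity, min_module_size = 30) {
  d <- as.matrix(dissimilarity)
  genes <- rownames(d)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(d)))
  if (nrow(d) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(stats::setNames(rep("unassigned", nrow(d)), genes))
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h <- 0.99 * max(tree$height)
  cl <- if (max(tree$height) == 0) rep(1L, nrow(d)) else stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order modules by decreasing size, tie -> smallest member gene id
  first_member <- vapply(keep, function(id) min(genes[cl == id]), character(1))
  ord <- keep[order(-as.integer(sizes[keep]), first_member)]
  labels <- stats::setNames(rep("unassigned", nrow(d)), genes)
  for (i in seq_along(ord)) {
    lab <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else paste0("module", i)
    labels[cl == as.integer(ord[i])] <- lab
  }
  labels
}

#' Module eigengenes and variance explained
#'
#' For each module, member genes are standardized to zero mean and unit
#' variance across samples; the eigengene is the first principal component
#' score vector scaled to unit variance, with its sign oriented so the mean
#' correlation with member genes is non-negative (an exact tie is resolved
#' toward positive correlation with the lexicographically first member).
#' Variance explained is the leading eigenvalue share.
#'
#' @param log2_expr Matrix genes x samples.
#' @param assignment Named character vector gene -> module label;
#'   `"unassigned"` genes are skipped.  Constant genes are excluded from the
#'   PC with a warning.
#' @return List with `eigengenes` (samples x modules matrix),
#'   `variance_explained` (named vector), `size` (named vector).
#' @export
module_eigengenes <- function(log2_expr, assignment) {
  x <- as.matrix(log2_expr)
  mods <- sort(setdiff(unique(assignment), "unassigned"))
  if (!length(mods)) stop("no assigned modules")
  eg <- matrix(NA_real_, nrow = ncol(x), ncol = length(mods),
               dimnames = list(colnames(x), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  sz <- stats::setNames(integer(length(mods)), mods)
  for (m in mods) {
    members <- sort(names(assignment)[assignment == m])
    sz[m] <- length(members)
    if (length(members) < 2) stop("module ", m, " has fewer than 2 genes")
    sub <- x[members, , drop = FALSE]
    const <- apply(sub, 1, stats::var) == 0
    if (any(const)) {
      warning("excluding ", sum(const), " constant gene(s) from module ", m)
      sub <- sub[!const, , drop = FALSE]
      members <- members[!const]
    }
    z <- t(scale(t(sub)))           # genes x samples, standardized per gene
    sv <- svd(t(z))                 # samples x genes
    pc <- sv$u[, 1] * sv$d[1]
    pc <- pc / stats::sd(pc)
    mc <- mean(stats::cor(pc, t(z)))
    if (mc < 0 || (mc == 0 && stats::cor(pc, z[1, ]) < 0)) pc <- -pc
    eg[, m] <- pc
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, variance_explained = ve, size = sz)
}

#' Correlate module eigengenes with a binary trait
#'
#' Pearson correlation of each eigengene with the 0/1 trait (CASE = 1) and a
#' two-sided Student p-value, the shared [pearson_cor()] implementation.
#'
#' @param eigengenes Samples x modules matrix.
#' @param trait Numeric 0/1 vector per sample (or `CTRL`/`CASE` labels).
#' @return data.frame with columns `module`, `r`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (is.character(trait) || is.factor(trait)) {
    trait <- as.integer(as.character(trait) == "CASE")
  }
  stopifnot(length(trait) == nrow(eigengenes), nrow(eigengenes) >= 3)
  res <- lapply(colnames(eigengenes), function(m) {
    ct <- pearson_cor(eigengenes[, m], trait)
    data.frame(module = m, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Select the key modules
#'
#' Returns the module most positively and most negatively correlated with
#' the trait.  Ties are broken lexicographically.  If every correlation has
#' the same sign, the absent side is `NA`.
#'
#' @param table Output of [module_trait_correlation()].
#' @return List with `positive` and `negative` module labels (or `NA`).
#' @export
select_key_modules <- function(table) {
  stopifnot(nrow(table) >= 1)
  pick <- function(r, decreasing) {
    ord <- order(if (decreasing) -r else r, table$module)
    table$module[ord[1]]
  }
  pos <- if (max(table$r) > 0) pick(table$r, TRUE) else NA_character_
  neg <- if (min(table$r) < 0) pick(table$r, FALSE) else NA_character_
  list(positive = pos, negative = neg)
}
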
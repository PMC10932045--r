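#' Construct a validated count matrix
#'
#' The universal input container of the screen: a genes x samples matrix of
#' non-negative integer counts plus a per-sample group label from
#' `{CTRL, CASE}`.  `CASE` is the disease group and is coded 1 when a 0/1
#' trait vector is needed (module-trait correlation).
#'
#' @param counts Numeric matrix (genes x samples) of non-negative integers,
#'   with unique rownames (gene ids) and colnames (sample ids).
#' @param group Character vector of `"CTRL"`/`"CASE"` labels, either named by
#'   sample id or in column order.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `sample_ids`, `group` (named by sample).
#' @export
count_matrix <- function(counts, group) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g)) stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-numeric count for gene ", rownames(counts)[bad[1, 1]],
         ", sample ", colnames(counts)[bad[1, 2]])
  }
  if (any(counts != round(counts))) {
    g <- rownames(counts)[which(counts != round(counts), arr.ind = TRUE)[1, 1]]
    stop("non-integer count found for gene ", g)
  }
  if (is.null(names(group))) {
    if (length(group) != ncol(counts)) stop("group length must match sample count")
    names(group) <- colnames(counts)
  }
  missing_s <- setdiff(colnames(counts), names(group))
  if (length(missing_s)) {
    stop("sample(s) without group label: ", paste(missing_s, collapse = ", "))
  }
  group <- as.character(group[colnames(counts)])
  names(group) <- colnames(counts)
  bad_lab <- unique(group[!group %in% c("CTRL", "CASE")])
  if (length(bad_lab)) stop("group labels must be CTRL or CASE, found: ",
                            paste(bad_lab, collapse = ", "))
  tab <- table(group)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need at least 2 samples in each of CTRL and CASE")
  }
  structure(list(counts = counts, gene_ids = rownames(counts),
                 sample_ids = colnames(counts), group = group),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      sum(x$group == "CTRL"), "CTRL /", sum(x$group == "CASE"), "CASE )\n")
  invisible(x)
}

# Accept either a count_matrix or a bare matrix where only counts are needed.
as_count_mat <- function(m) {
  if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
}

#' Read a count matrix and its group labels from TSV files
#'
#' @param path TSV with a header row of sample ids; first column gene ids.
#' @param groups_path TSV with columns `sample` and `group`
#'   (values `CTRL`/`CASE`).
#' @return A validated [count_matrix()]; file order is preserved.
#' @export
read_count_matrix <- function(path, groups_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a gene id column plus >=1 sample")
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- gene_ids
  g <- utils::read.delim(groups_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g))) {
    stop("groups file must have columns 'sample' and 'group'")
  }
  group <- stats::setNames(as.character(g$group), as.character(g$sample))
  count_matrix(m, group)
}

#' Write a count matrix (and optionally its groups) to TSV
#'
#' Inverse of [read_count_matrix()]: a write/read round trip reproduces
#' values and orderings exactly.
#'
#' @param m A [count_matrix()].
#' @param path Output TSV path for the counts.
#' @param groups_path Optional output TSV path for the group labels.
#' @export
write_count_matrix <- function(m, path, groups_path = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene_id = m$gene_ids, m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample = m$sample_ids, group = unname(m$group)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene biotype annotation table
#'
#' @param path TSV with columns `gene_id` and `biotype`
#'   (`mRNA`, `lncRNA`, or `other`).
#' @return Named character vector gene id -> biotype.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "biotype") %in% names(df))) {
    stop("annotation must have columns 'gene_id' and 'biotype'")
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) stop("duplicated annotation for gene(s): ",
                        paste(dup, collapse = ", "))
  bad <- unique(df$biotype[!df$biotype %in% c("mRNA", "lncRNA", "other")])
  if (length(bad)) stop("unknown biotype(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$biotype, df$gene_id)
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path Text file, one gene id per line.
#' @return Character vector of unique ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read a miRNA-target interaction catalog
#'
#' @param path TSV with columns `mirna`, `target`, `target_biotype`
#'   (`mRNA` or `lncRNA`).
#' @return data.frame of unique edges.
#' @export
read_interaction_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "target", "target_biotype") %in% names(df))) {
    stop("catalog must have columns 'mirna', 'target', 'target_biotype'")
  }
  bad <- unique(df$target_biotype[!df$target_biotype %in% c("mRNA", "lncRNA")])
  if (length(bad)) stop("unknown target biotype(s): ", paste(bad, collapse = ", "))
  dup <- duplicated(df[, c("mirna", "target")])
  if (any(dup)) {
    warning(sum(dup), " duplicated catalog edge(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a cell-type signature matrix
#'
#' @param path TSV, first column marker gene ids, remaining columns one per
#'   cell type; expression values >= 0.
#' @return Numeric matrix markers x cell types.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  if (ncol(m) < 2) stop("signature needs at least 2 cell types")
  if (any(duplicated(genes))) stop("duplicated signature gene id(s)")
  if (any(duplicated(colnames(m)))) stop("duplicated cell type id(s)")
  if (any(!is.finite(m) | m < 0)) stop("signature values must be finite and >= 0")
  m
}

#' Pipeline configuration
#'
#' Collects the tunable constants of the screen.  Defaults are the published
#' screening constants: correlation cutoff 0.75, DEG thresholds
#' |log2FC| > 1 and adjusted p < 0.05, top-5000 most variable genes,
#' soft-threshold powers 1..20 with scale-free fit target R^2 = 0.85,
#' minimum module size 30, SVR nu grid {0.25, 0.5, 0.75}, 1000 permutations.
#'
#' @param corr_cutoff Pair correlation cutoff (strict, positive-only by
#'   default).
#' @param corr_absolute Use |r| > cutoff instead of r > cutoff.
#' @param lfc_threshold DEG |log2 fold change| threshold (log2 units).
#' @param alpha Significance level used by every test of the cascade.
#' @param top_k_mad Number of most-variable genes kept for module detection.
#' @param mad_method `"median"` (median absolute deviation, unscaled) or
#'   `"mean"` (mean absolute deviation).
#' @param beta_range Ascending integer soft-threshold powers to scan.
#' @param r2_target Scale-free fit target for picking the power.
#' @param min_module_size Minimum genes per module.
#' @param deconv_method `"svr_ensemble"` or `"nnls"`.
#' @param deconv_nu_grid nu values for the SVR ensemble.
#' @param n_permutations Deconvolution permutation count (0 disables the
#'   permutation p-value).
#' @param rng_seed Integer seed governing all stochastic steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corr_cutoff = 0.75, corr_absolute = FALSE,
                            lfc_threshold = 1, alpha = 0.05,
                            top_k_mad = 5000, mad_method = "median",
                            beta_range = 1:20, r2_target = 0.85,
                            min_module_size = 30,
                            deconv_method = "svr_ensemble",
                            deconv_nu_grid = c(0.25, 0.5, 0.75),
                            n_permutations = 1000, rng_seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, corr_cutoff > 0, corr_cutoff < 1,
            min_module_size >= 2, length(beta_range) >= 1,
            all(diff(beta_range) > 0), top_k_mad >= 1,
            n_permutations >= 0)
  mad_method <- match.arg(mad_method, c("median", "mean"))
  deconv_method <- match.arg(deconv_method, c("svr_ensemble", "nnls"))
  structure(list(corr_cutoff = corr_cutoff, corr_absolute = corr_absolute,
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 top_k_mad = top_k_mad, mad_method = mad_method,
                 beta_range = beta_range, r2_target = r2_target,
                 min_module_size = min_module_size,
                 deconv_method = deconv_method,
                 deconv_nu_grid = deconv_nu_grid,
                 n_permutations = n_permutations,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Export a ceRNA network as an edge table
#'
#' Writes the lncRNA-miRNA and miRNA-mRNA edges of a network built by
#' [build_cerna_network()] in a form consumable by graph viewers such as
#' Cytoscape.
#'
#' @param network A `cerna_network` (see [build_cerna_network()]).
#' @param path Output file path.
#' @param dialect `"tsv"` (columns source, interaction, target,
#'   node_type_source, node_type_target) or `"sif"`
#'   (`source interaction target` lines).
#' @return The path, invisibly.  Edges are written in deterministic
#'   lexicographic order; an empty network yields a header-only TSV or an
#'   empty SIF.
#' @export
write_edge_table <- function(network, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "cerna_network"))
  ed <- network$edges
  if (nrow(ed)) {
    ord <- order(ed$source, ed$target, ed$interaction)
    ed <- ed[ord, , drop = FALSE]
  }
  if (dialect == "tsv") {
    utils::write.table(
      ed[, c("source", "interaction", "target",
             "node_type_source", "node_type_target")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- if (nrow(ed)) paste(ed$source, ed$interaction, ed$target) else character()
    writeLines(lines, path)
  }
  invisible(path)
}
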
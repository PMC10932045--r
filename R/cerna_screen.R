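#' Intersect key-module genes with an immune gene list, split by biotype
#'
#' @param key_module_genes Character vector of genes in the key module(s).
#' @param annotation Named biotype vector (gene -> `mRNA`/`lncRNA`/`other`),
#'   as from [read_gene_annotation()].
#' @param immune_list Character vector of immune-related gene ids.
#' @return List with `lncRNAs` and `mRNAs` (sorted character vectors; either
#'   may be empty).  Genes with biotype `"other"` or missing annotation are
#'   excluded.
#' @export
split_immune_genes <- function(key_module_genes, annotation, immune_list) {
  hits <- intersect(key_module_genes, immune_list)
  bt <- annotation[hits]
  list(lncRNAs = sort(hits[!is.na(bt) & bt == "lncRNA"]),
       mRNAs = sort(hits[!is.na(bt) & bt == "mRNA"]))
}

#' Correlate all lncRNA x mRNA combinations
#'
#' Evaluates the Pearson correlation of every lncRNA-mRNA combination on the
#' training log2 expression.  A pair is a candidate iff `r > cutoff`
#' (strictly greater; positive correlations only, unless
#' `absolute = TRUE`).  All combinations are returned — pairs failing the
#' criterion carry status `"dropped:low_correlation"` so the cascade is
#' auditable.
#'
#' @param log2_expr Matrix genes x samples covering all listed genes.
#' @param lncRNAs,mRNAs Character vectors of gene ids.
#' @param cutoff Correlation cutoff (default 0.75).
#' @param absolute Use `|r| > cutoff` instead of `r > cutoff`.
#' @return data.frame of candidate pairs: `lncRNA`, `mRNA`, `r_train`,
#'   `p_corr_train`, `shared_mirnas`, `kw_p_lnc`, `kw_p_mrna`, `status`.
#' @export
correlate_pairs <- function(log2_expr, lncRNAs, mRNAs, cutoff = 0.75,
                            absolute = FALSE) {
  x <- as.matrix(log2_expr)
  missing_g <- setdiff(c(lncRNAs, mRNAs), rownames(x))
  if (length(missing_g)) {
    stop("gene(s) missing from expression: ", paste(missing_g, collapse = ", "))
  }
  if (!length(lncRNAs) || !length(mRNAs)) return(empty_pairs())
  grid <- expand.grid(lncRNA = sort(lncRNAs), mRNA = sort(mRNAs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(l, m) {
    ct <- pearson_cor(x[l, ], x[m, ])
    c(r = ct$r, p = ct$p)
  }, grid$lncRNA, grid$mRNA)
  r <- unname(res["r", ]); p <- unname(res["p", ])
  passed <- !is.na(r) & (if (absolute) abs(r) else r) > cutoff
  data.frame(lncRNA = grid$lncRNA, mRNA = grid$mRNA, r_train = r,
             p_corr_train = p, shared_mirnas = NA_character_,
             kw_p_lnc = NA_real_, kw_p_mrna = NA_real_,
             status = ifelse(passed, "candidate", "dropped:low_correlation"),
             stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(lncRNA = character(), mRNA = character(), r_train = numeric(),
             p_corr_train = numeric(), shared_mirnas = character(),
             kw_p_lnc = numeric(), kw_p_mrna = numeric(),
             status = character(), stringsAsFactors = FALSE)
}

is_surviving <- function(status) !startsWith(status, "dropped")

# miRNA neighbor sets per target gene from a catalog data.frame.
mirna_neighbors <- function(catalog) {
  split(catalog$mirna, catalog$target)
}

#' Shared-miRNA filter
#'
#' For every surviving pair, computes the intersection of the miRNA neighbor
#' sets of its lncRNA and mRNA in the interaction catalog.  Pairs with an
#' empty intersection are dropped with reason `"no_shared_mirna"`; the
#' others advance with `shared_mirnas` populated (semicolon-joined, sorted).
#' This filter is exact, not statistical.
#'
#' @param pairs Candidate pair data.frame from [correlate_pairs()].
#' @param catalog Interaction catalog data.frame (`mirna`, `target`,
#'   `target_biotype`).
#' @return The pair data.frame with `shared_mirnas` and `status` updated.
#' @export
shared_mirna_filter <- function(pairs, catalog) {
  if (!nrow(pairs)) return(pairs)
  nb <- mirna_neighbors(catalog)
  for (i in seq_len(nrow(pairs))) {
    if (!is_surviving(pairs$status[i])) next
    shared <- sort(intersect(nb[[pairs$lncRNA[i]]], nb[[pairs$mRNA[i]]]))
    if (length(shared)) {
      pairs$shared_mirnas[i] <- paste(shared, collapse = ";")
      pairs$status[i] <- "passed_mirna"
    } else {
      pairs$status[i] <- "dropped:no_shared_mirna"
    }
  }
  pairs
}

#' Differential-expression filter on pair members
#'
#' Runs the Kruskal-Wallis test (CASE vs CTRL) on each member of each
#' surviving pair; a pair advances iff both members have p < `alpha`.
#'
#' @param pairs Pair data.frame.
#' @param log2_expr Matrix genes x samples.
#' @param groups `CTRL`/`CASE` labels (named by sample or in column order).
#' @param alpha Significance level (default 0.05).
#' @return The pair data.frame with `kw_p_lnc`, `kw_p_mrna`, `status`
#'   updated (`"passed_de"` or `"dropped:member_not_de"`).
#' @export
de_filter <- function(pairs, log2_expr, groups, alpha = 0.05) {
  if (!nrow(pairs)) return(pairs)
  x <- as.matrix(log2_expr)
  groups <- match_groups(groups, colnames(x), ncol(x))
  kw_cache <- new.env(parent = emptyenv())
  kw_p <- function(g) {
    if (is.null(kw_cache[[g]])) {
      kw_cache[[g]] <- kruskal_wallis(x[g, ], groups, alpha)$p
    }
    kw_cache[[g]]
  }
  for (i in seq_len(nrow(pairs))) {
    if (!is_surviving(pairs$status[i])) next
    pl <- kw_p(pairs$lncRNA[i])
    pm <- kw_p(pairs$mRNA[i])
    pairs$kw_p_lnc[i] <- pl
    pairs$kw_p_mrna[i] <- pm
    pairs$status[i] <- if (pl < alpha && pm < alpha) "passed_de" else
      "dropped:member_not_de"
  }
  pairs
}

#' Summarize a pair list
#'
#' @param pairs data.frame with `lncRNA` and `mRNA` columns (any status
#'   filtering should be done by the caller).
#' @return List `n_pairs`, `n_lncRNAs`, `n_mRNAs` (exact distinct counts).
#' @export
summarize_pairs <- function(pairs) {
  list(n_pairs = nrow(pairs),
       n_lncRNAs = length(unique(pairs$lncRNA)),
       n_mRNAs = length(unique(pairs$mRNA)))
}

#' Build the ceRNA network from screened pairs
#'
#' For each pair and each of its shared miRNAs mu, emits the edges
#' (lncRNA - mu) and (mu - mRNA).  Nodes are deduplicated and typed; edge
#' order is deterministic.
#'
#' @param pairs Pair data.frame with `shared_mirnas` populated for every
#'   surviving pair (pairs with `dropped:*` status are ignored).
#' @param catalog Unused placeholder kept for interface symmetry; the shared
#'   sets on `pairs` are authoritative.
#' @return Object of class `cerna_network`: list with `pairs`, `nodes`
#'   (data.frame `id`, `type`) and `edges` (data.frame `source`,
#'   `interaction`, `target`, `node_type_source`, `node_type_target`).
#' @export
build_cerna_network <- function(pairs, catalog = NULL) {
  keep <- pairs[is_surviving(pairs$status), , drop = FALSE]
  if (nrow(keep) && any(is.na(keep$shared_mirnas) | keep$shared_mirnas == "")) {
    stop("surviving pair(s) with empty shared miRNA set")
  }
  edges <- list()
  for (i in seq_len(nrow(keep))) {
    mus <- strsplit(keep$shared_mirnas[i], ";")[[1]]
    for (mu in mus) {
      edges[[length(edges) + 1]] <- data.frame(
        source = c(keep$lncRNA[i], mu), interaction = "ceRNA",
        target = c(mu, keep$mRNA[i]),
        node_type_source = c("lncRNA", "miRNA"),
        node_type_target = c("miRNA", "mRNA"), stringsAsFactors = FALSE)
    }
  }
  ed <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(), interaction = character(),
               target = character(), node_type_source = character(),
               node_type_target = character(), stringsAsFactors = FALSE)
  ed <- ed[order(ed$source, ed$target), , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- unique(data.frame(
    id = c(ed$source, ed$target),
    type = c(ed$node_type_source, ed$node_type_target),
    stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(pairs = keep, nodes = nodes, edges = ed),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("cerna_network:", nrow(x$pairs), "pairs,", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Reference set of reported immune-related ceRNA pairs
#'
#' Loads the bundled transcription of the 26 immune-related lncRNA-mRNA
#' pairs reported by a published hypertrophic cardiomyopathy co-expression
#' screen (each pair passed a correlation cutoff of 0.75 and shares at
#' least one catalog miRNA).  Useful as a desk-scale fixture: the set
#' comprises 9 distinct lncRNAs and 17 distinct mRNAs.
#'
#' @return data.frame with columns `mRNA`, `lncRNA`, `correlation`.
#' @export
reference_pairs <- function() {
  path <- system.file("extdata", "hcm_cerna_pairs.tsv",
                      package = "cernascreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
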
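#' Run the full ceRNA screening cascade
#'
#' Executes the stages in screening order: low-count filtering and
#' normalization of both cohorts, the cohort-level DEG screen, most-variable
#' gene selection, soft-threshold scan and module detection, module
#' eigengenes and module-trait correlation, key-module selection, immune
#' intersection, the three-criterion pair screen (correlation, shared
#' miRNA, member differential expression), validation-cohort replication,
#' and — when a signature matrix is supplied — immune-cell deconvolution
#' with group comparison and fraction-expression correlation for the final
#' pair members.  With a fixed seed and fixed inputs the output (including
#' the written `summary.json`) is identical across runs.
#'
#' @param config A [pipeline_config()].
#' @param training,validation [count_matrix()] cohorts.
#' @param annotation Named biotype vector (gene -> `mRNA`/`lncRNA`/`other`).
#' @param immune_list Character vector of immune-related gene ids.
#' @param catalog Interaction catalog data.frame (`mirna`, `target`,
#'   `target_biotype`).
#' @param signature Optional marker x cell-type signature matrix; enables
#'   the deconvolution stage.
#' @param mixture Optional mixture expression matrix for deconvolution
#'   (genes x training samples).  Defaults to the normalized training
#'   expression.
#' @param out_dir Optional directory; when set, all intermediate tables and
#'   a machine-readable `summary.json` are written.
#' @return A run report list; see Details in the methods vignette.  An
#'   empty key module yields a documented empty pair set, not an error.
#' @export
run_pipeline <- function(config, training, validation, annotation,
                         immune_list, catalog, signature = NULL,
                         mixture = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(training, "count_matrix"),
            inherits(validation, "count_matrix"))
  set.seed(config$rng_seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  train_f <- stage("filter_low_counts", filter_low_counts(training))
  valid_f <- stage("filter_low_counts", filter_low_counts(validation))
  norm_train <- stage("normalize", normalize_counts(train_f))
  norm_valid <- stage("normalize", normalize_counts(valid_f))

  deg <- stage("deg_screen",
               de_test(norm_train$log2_expr, train_f$group,
                       config$lfc_threshold, config$alpha))

  expr_top <- stage("select_top_mad",
                    select_top_mad(norm_train$log2_expr, config$top_k_mad,
                                   config$mad_method))
  v <- apply(expr_top, 1, stats::var)
  expr_top <- expr_top[v > 0, , drop = FALSE]

  scan <- stage("soft_threshold", scan_soft_threshold(expr_top, config$beta_range))
  beta <- stage("soft_threshold",
                suppressWarnings(pick_beta(scan, config$r2_target)))
  adj <- stage("adjacency", adjacency_power(expr_top, beta$beta))
  tom <- stage("tom", tom_similarity(adj))
  assignment <- stage("modules",
                      cluster_modules(tom$dissimilarity, config$min_module_size))

  trait <- as.integer(train_f$group == "CASE")
  if (all(assignment == "unassigned")) {
    me <- NULL
    mtt <- data.frame(module = character(), r = numeric(), p = numeric())
    keys <- list(positive = NA_character_, negative = NA_character_)
    key_genes <- character()
  } else {
    me <- stage("eigengenes", module_eigengenes(expr_top, assignment))
    mtt <- stage("module_trait",
                 module_trait_correlation(me$eigengenes, trait))
    keys <- stage("key_modules", select_key_modules(mtt))
    key_genes <- names(assignment)[assignment %in%
                                     stats::na.omit(unlist(keys))]
  }

  imm <- stage("immune_split",
               split_immune_genes(key_genes, annotation, immune_list))
  pairs <- stage("correlate_pairs",
                 correlate_pairs(norm_train$log2_expr, imm$lncRNAs,
                                 imm$mRNAs, config$corr_cutoff,
                                 config$corr_absolute))
  pairs <- stage("shared_mirna", shared_mirna_filter(pairs, catalog))
  pairs <- stage("de_filter",
                 de_filter(pairs, norm_train$log2_expr, train_f$group,
                           config$alpha))
  pairs <- stage("replicate_de",
                 replicate_de(pairs, norm_valid$log2_expr, valid_f$group,
                              config$alpha))
  pairs <- stage("replicate_correlation",
                 replicate_correlation(pairs, norm_valid$log2_expr,
                                       config$alpha))
  final_pairs <- pairs[pairs$status == "replicated", , drop = FALSE]
  network <- stage("network", build_cerna_network(final_pairs, catalog))

  deconv <- NULL
  if (!is.null(signature)) {
    mix <- if (is.null(mixture)) norm_train$normalized else as.matrix(mixture)
    fr <- stage("deconvolution",
                estimate_fractions(mix, signature,
                                   method = config$deconv_method,
                                   nu_grid = config$deconv_nu_grid,
                                   n_permutations = config$n_permutations,
                                   seed = config$rng_seed))
    grp <- train_f$group[rownames(fr$fractions)]
    cmp <- stage("compare_fractions",
                 compare_fractions(fr$fractions, grp, config$alpha))
    infil <- NULL
    final_genes <- unique(c(final_pairs$lncRNA, final_pairs$mRNA))
    final_genes <- intersect(final_genes, rownames(norm_train$log2_expr))
    if (length(final_genes)) {
      infil <- stage(
        "infiltration_correlation",
        correlate_expression_fractions(
          norm_train$log2_expr[final_genes, rownames(fr$fractions),
                               drop = FALSE],
          fr$fractions, config$alpha))
    }
    deconv <- list(fractions = fr, comparison = cmp,
                   infiltration_correlation = infil)
  }

  report <- list(
    config = unclass(config),
    size_factors = list(train = norm_train$size_factors,
                        valid = norm_valid$size_factors),
    deg = deg,
    soft_threshold = list(scan = scan, beta = beta$beta, r2 = beta$r2,
                          met_target = beta$met_target),
    module_assignment = assignment,
    module_trait = mtt,
    key_modules = keys,
    immune = imm,
    pairs = pairs,
    final_pairs = final_pairs,
    network = network,
    deconvolution = deconv,
    summary = list(
      seed = config$rng_seed,
      n_genes_after_filter = nrow(train_f$counts),
      n_degs = sum(deg$is_deg),
      beta = beta$beta,
      n_modules = length(setdiff(unique(assignment), "unassigned")),
      key_modules = keys,
      n_immune_lncRNAs = length(imm$lncRNAs),
      n_immune_mRNAs = length(imm$mRNAs),
      n_candidate_pairs = sum(pairs$status != "dropped:low_correlation"),
      n_final_pairs = nrow(final_pairs),
      final_pairs = if (nrow(final_pairs))
        paste(final_pairs$lncRNA, final_pairs$mRNA, sep = "~") else character()
    ))

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Write the intermediate tables and the machine-readable summary.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$deg, "deg.tsv")
  wt(report$soft_threshold$scan, "soft_threshold_scan.tsv")
  wt(data.frame(gene = names(report$module_assignment),
                module = unname(report$module_assignment)),
     "module_assignment.tsv")
  wt(report$module_trait, "module_trait.tsv")
  wt(report$pairs, "pairs.tsv")
  write_edge_table(report$network, file.path(out_dir, "network.tsv"), "tsv")
  if (!is.null(report$deconvolution)) {
    fr <- report$deconvolution$fractions$fractions
    wt(data.frame(sample = rownames(fr), fr, check.names = FALSE),
       "fractions.tsv")
    wt(report$deconvolution$comparison, "fraction_comparison.tsv")
    if (!is.null(report$deconvolution$infiltration_correlation)) {
      wt(report$deconvolution$infiltration_correlation,
         "infiltration_correlation.tsv")
    }
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
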
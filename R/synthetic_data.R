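#' Parameters for the synthetic cohort generator
#'
#' Defaults are the study conditions the rest of the package is tested
#' against: 20 + 20 samples per cohort, four planted modules of 60 genes
#' with latent-factor loading 0.9, a group (disease) effect of 2 log2 units
#' on the disease-module and planted-pair genes, negative-binomial counts
#' with dispersion 0.05, five true ceRNA pairs planted at population
#' log-expression correlation 0.85, and three decoys per failure class
#' (no shared miRNA, low correlation, no differential expression, no
#' replication in the validation cohort).
#'
#' @param n_genes Total gene count.
#' @param n_lnc Background lncRNA genes (pair lncRNAs are extra).
#' @param n_samples_train,n_samples_valid Named counts `c(CTRL=, CASE=)`.
#' @param n_modules,module_size Planted co-expression modules; module 1 is
#'   the disease module (its genes carry the group effect).
#' @param factor_loading Latent loading of module genes (within-module
#'   correlation = loading^2).
#' @param group_effect CASE shift in log2 units for DE-designated genes.
#' @param nb_dispersion Negative-binomial dispersion (var = mu + phi mu^2).
#' @param baseline_log_mean_range log2 baseline mean range for module and
#'   background genes.
#' @param pair_baseline_log_mean log2 baseline range for pair genes (higher,
#'   so count noise does not erode the planted correlation).
#' @param n_true_pairs,n_decoy_no_mirna,n_decoy_low_corr,n_decoy_no_de,n_decoy_no_replication
#'   Planted pair counts per class.
#' @param pair_target_corr Target population log-expression correlation of
#'   true pairs (the screening cutoff downstream is 0.75; the default 0.85
#'   leaves margin).
#' @param pair_module_loading Loading of pair genes on the disease-module
#'   factor, so they cluster into the key module.
#' @param gene_signal_sd log2-scale standard deviation of the biological
#'   signal per gene.
#' @param n_other_biotype Background genes annotated with biotype "other".
#' @param n_immune_extra Background mRNAs added to the immune list beyond
#'   the pair members.
#' @param n_background_mirnas Extra catalog miRNAs targeting background
#'   genes only.
#' @param n_celltypes,markers_per_type Signature matrix dimensions.
#' @param mixture_noise_sd Gaussian noise sd on mixture expression.
#' @param mixture_concentration Dirichlet concentration of the fraction
#'   draws.
#' @param mixture_shift Planted CASE increase of cell type 1's mean
#'   fraction.
#' @param library_size_range Per-sample size factors drawn log-uniformly in
#'   this range, so normalization is exercised.
#' @param seed Integer seed; all generator functions derive their streams
#'   from it.
#' @return List of class `synth_params`.
#' @export
synth_params <- function(n_genes = 800, n_lnc = 40,
                         n_samples_train = c(CTRL = 20, CASE = 20),
                         n_samples_valid = c(CTRL = 20, CASE = 20),
                         n_modules = 4, module_size = 60,
                         factor_loading = 0.9, group_effect = 2,
                         nb_dispersion = 0.01,
                         baseline_log_mean_range = c(6, 9),
                         pair_baseline_log_mean = c(9, 11),
                         n_true_pairs = 5, n_decoy_no_mirna = 3,
                         n_decoy_low_corr = 3, n_decoy_no_de = 3,
                         n_decoy_no_replication = 3,
                         pair_target_corr = 0.85,
                         pair_module_loading = 0.65,
                         gene_signal_sd = 1.0,
                         n_other_biotype = 10, n_immune_extra = 20,
                         n_background_mirnas = 30,
                         n_celltypes = 5, markers_per_type = 30,
                         mixture_noise_sd = 1,
                         mixture_concentration = 60, mixture_shift = 0.15,
                         library_size_range = c(0.5, 2), seed = 1L) {
  p <- as.list(environment())
  p$n_pairs_total <- n_true_pairs + n_decoy_no_mirna + n_decoy_low_corr +
    n_decoy_no_de + n_decoy_no_replication
  stopifnot(n_genes >= 1, module_size >= 2 || n_modules == 0,
            pair_target_corr > 0, pair_target_corr < 1,
            nb_dispersion > 0, gene_signal_sd > 0,
            all(n_samples_train >= 2), all(n_samples_valid >= 2))
  used <- n_modules * module_size + 2 * p$n_pairs_total + n_other_biotype
  if (used > n_genes) {
    stop("infeasible params: modules, pairs and annotations need ", used,
         " genes but n_genes = ", n_genes)
  }
  structure(p, class = "synth_params")
}

# log2-scale count-noise variance of an NB draw at baseline mean 2^b
# (delta method: var(log2(Y)) ~ (1/mu + phi) / ln(2)^2).
nb_log2_var <- function(b, phi) (1 / 2^b + phi) / log(2)^2

#' Generate the training and validation cohorts
#'
#' Counts are negative binomial with
#' `log2 mean = baseline + signal + group_effect x I(CASE, DE gene)`, where
#' the signal of a module gene loads on its module's per-sample latent
#' factor and the two members of a planted pair share a dedicated latent
#' factor.  Pair loadings are chosen (via a delta-method estimate of the
#' count noise and the shared group-effect covariance) so the population
#' log-expression correlation of a true pair equals `pair_target_corr`.
#' Decoy classes deviate per their labels: no dedicated factor
#' (low correlation), no group effect (no DE), or a group effect present
#' only in the training cohort (no replication).  Per-sample library size
#' factors are drawn log-uniformly so normalization is exercised.  Both
#' cohorts are drawn independently conditional on the same gene-level truth.
#'
#' @param params A [synth_params()] object.
#' @return List with `train` and `valid` ([count_matrix()]), `annotation`
#'   (named biotype vector) and `truth` (module assignments, pair table
#'   with classes, DE gene set, immune list, sample bookkeeping).
#' @export
generate_cohorts <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)

  classes <- rep(c("true", "no_mirna", "low_corr", "no_de", "no_replication"),
                 times = c(p$n_true_pairs, p$n_decoy_no_mirna,
                           p$n_decoy_low_corr, p$n_decoy_no_de,
                           p$n_decoy_no_replication))
  n_pairs <- length(classes)
  pair_lnc <- sprintf("LNCP%02d", seq_len(n_pairs))
  pair_mrna <- sprintf("MRNP%02d", seq_len(n_pairs))
  module_genes <- if (p$n_modules > 0)
    sprintf("G%04d", seq_len(p$n_modules * p$module_size)) else character()
  module_of <- rep(seq_len(p$n_modules), each = p$module_size)
  n_bg <- p$n_genes - length(module_genes) - 2 * n_pairs
  bg <- sprintf("B%04d", seq_len(n_bg))
  n_bg_lnc <- min(p$n_lnc, max(n_bg - p$n_other_biotype, 0))
  bg_lnc <- utils::head(bg, n_bg_lnc)
  bg_other <- utils::head(setdiff(bg, bg_lnc), p$n_other_biotype)
  genes <- c(module_genes, pair_lnc, pair_mrna, bg)

  annotation <- stats::setNames(rep("mRNA", length(genes)), genes)
  annotation[c(pair_lnc, bg_lnc)] <- "lncRNA"
  annotation[bg_other] <- "other"

  baseline <- stats::setNames(
    stats::runif(length(genes), p$baseline_log_mean_range[1],
                 p$baseline_log_mean_range[2]), genes)
  baseline[c(pair_lnc, pair_mrna)] <-
    stats::runif(2 * n_pairs, p$pair_baseline_log_mean[1],
                 p$pair_baseline_log_mean[2])

  de_module <- if (p$n_modules > 0) module_genes[module_of == 1] else character()
  de_pair_classes <- c("true", "no_mirna", "low_corr", "no_replication")
  de_pairs_idx <- which(classes %in% de_pair_classes)
  de_genes <- c(de_module, pair_lnc[de_pairs_idx], pair_mrna[de_pairs_idx])

  # latent loadings per pair: alpha on the disease-module factor, gamma on
  # the pair's own factor, chosen so the population log-expression
  # correlation hits its class target
  s2 <- p$gene_signal_sd^2
  bal <- p$n_samples_train["CASE"] / sum(p$n_samples_train)
  ge_var <- p$group_effect^2 * bal * (1 - bal)
  # low-correlation decoys keep a weaker module loading so the residual
  # correlation they inherit from the shared module factor and group effect
  # stays well below the screening cutoff
  pair_alpha <- if (p$n_modules > 0)
    ifelse(classes == "low_corr", 0.45, p$pair_module_loading) else
    rep(0, n_pairs)
  pair_gamma2 <- vapply(seq_len(n_pairs), function(i) {
    if (classes[i] == "low_corr") return(0)
    vbar <- mean(nb_log2_var(baseline[c(pair_lnc[i], pair_mrna[i])],
                             p$nb_dispersion))
    ge <- if (classes[i] %in% de_pair_classes) ge_var else 0
    shared <- (p$pair_target_corr * (s2 + ge + vbar) - ge) / s2
    min(max(shared - pair_alpha[i]^2, 0), 0.98 - pair_alpha[i]^2)
  }, numeric(1))

  # Per-gene loading jitter inside modules plus many small (sub-threshold)
  # correlated background groups give the network the long-tailed,
  # approximately scale-free connectivity distribution real co-expression
  # data shows; without them the degree histogram is a two-point mass and no
  # soft threshold can fit a power law.
  module_loading <- stats::setNames(
    pmin(pmax(p$factor_loading *
                stats::runif(length(module_genes), 0.85, 1.1), 0.3), 0.98),
    module_genes)
  # bimodal global loadings: a minority of weakly coupled background genes
  # below a strongly coupled majority makes the low-power connectivity
  # histogram rise then fall (a poor scale-free fit, as in real data), while
  # at moderate powers the global edges vanish entirely
  bg_global <- stats::setNames(
    ifelse(stats::runif(length(bg)) < 0.15,
           stats::runif(length(bg), 0.15, 0.30),
           stats::runif(length(bg), 0.60, 0.70)), bg)
  noise_groups <- list()
  pool <- bg
  sizes_avail <- 3:25
  while (length(pool) >= 3) {
    sz <- min(sample(sizes_avail, 1, prob = sizes_avail^(-1.5)), length(pool))
    noise_groups[[length(noise_groups) + 1]] <-
      list(genes = pool[seq_len(sz)],
           loading = stats::runif(1, 0.35, 0.85))
    pool <- pool[-seq_len(sz)]
  }

  truth <- list(
    module_of_gene = if (p$n_modules > 0)
      stats::setNames(paste0("M", module_of), module_genes) else
      stats::setNames(character(), character()),
    pairs = data.frame(lncRNA = pair_lnc, mRNA = pair_mrna, class = classes,
                       stringsAsFactors = FALSE),
    de_genes = de_genes,
    immune_list = c(pair_lnc, pair_mrna,
                    utils::head(setdiff(bg, c(bg_lnc, bg_other)),
                                p$n_immune_extra)),
    annotation = annotation)

  draw_cohort <- function(n_per_group, prefix, with_replication_effect) {
    n_s <- sum(n_per_group)
    samples <- sprintf("%s%02d", prefix, seq_len(n_s))
    group <- stats::setNames(rep(c("CTRL", "CASE"), n_per_group), samples)
    case_ind <- as.numeric(group == "CASE")
    f_mod <- if (p$n_modules > 0)
      matrix(stats::rnorm(p$n_modules * n_s), p$n_modules, n_s) else NULL
    f_pair <- if (n_pairs > 0)
      matrix(stats::rnorm(n_pairs * n_s), n_pairs, n_s) else NULL
    log2mu <- matrix(rep(baseline, n_s), ncol = n_s,
                     dimnames = list(genes, samples))
    for (m in seq_len(p$n_modules)) {
      idx <- module_genes[module_of == m]
      lam <- module_loading[idx]
      z <- matrix(stats::rnorm(length(idx) * n_s), length(idx), n_s)
      log2mu[idx, ] <- log2mu[idx, ] + p$gene_signal_sd *
        (lam * matrix(f_mod[m, ], length(idx), n_s, byrow = TRUE) +
           sqrt(1 - lam^2) * z)
    }
    # Background genes share a pervasive global factor (technical/global
    # covariation) plus their small noise-group factor; together with the
    # module loading jitter this reproduces the poor scale-free fit at low
    # powers and the long-tailed connectivity at moderate powers that real
    # co-expression data shows.
    f_glob <- stats::rnorm(n_s)
    grouped <- unlist(lapply(noise_groups, `[[`, "genes"))
    for (ng in noise_groups) {
      fg <- stats::rnorm(n_s)
      g2 <- bg_global[ng$genes]
      le <- ng$loading * sqrt(1 - g2^2)
      d <- sqrt(pmax(1 - g2^2 - le^2, 0))
      z <- matrix(stats::rnorm(length(ng$genes) * n_s), length(ng$genes), n_s)
      log2mu[ng$genes, ] <- log2mu[ng$genes, ] + p$gene_signal_sd *
        (g2 * matrix(f_glob, length(ng$genes), n_s, byrow = TRUE) +
           le * matrix(fg, length(ng$genes), n_s, byrow = TRUE) + d * z)
    }
    loose <- setdiff(bg, grouped)
    if (length(loose)) {
      g2 <- bg_global[loose]
      z <- matrix(stats::rnorm(length(loose) * n_s), length(loose), n_s)
      log2mu[loose, ] <- log2mu[loose, ] + p$gene_signal_sd *
        (g2 * matrix(f_glob, length(loose), n_s, byrow = TRUE) +
           sqrt(1 - g2^2) * z)
    }
    for (i in seq_len(n_pairs)) {
      g2 <- pair_gamma2[i]
      a <- pair_alpha[i]
      d2 <- max(1 - a^2 - g2, 0)
      for (g in c(pair_lnc[i], pair_mrna[i])) {
        zi <- stats::rnorm(n_s)
        sig <- sqrt(g2) * f_pair[i, ] + sqrt(d2) * zi
        if (p$n_modules > 0) sig <- sig + a * f_mod[1, ]
        log2mu[g, ] <- log2mu[g, ] + p$gene_signal_sd * sig
      }
    }
    effect_genes <- de_genes
    if (!with_replication_effect) {
      drop_idx <- which(classes == "no_replication")
      effect_genes <- setdiff(effect_genes,
                              c(pair_lnc[drop_idx], pair_mrna[drop_idx]))
    }
    if (length(effect_genes)) {
      log2mu[effect_genes, ] <- log2mu[effect_genes, ] +
        p$group_effect * matrix(case_ind, length(effect_genes), n_s,
                                byrow = TRUE)
    }
    libsize <- exp(stats::runif(n_s, log(p$library_size_range[1]),
                                log(p$library_size_range[2])))
    mu <- sweep(2^log2mu, 2, libsize, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / p$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    count_matrix(counts, group)
  }

  train <- draw_cohort(p$n_samples_train, "T", TRUE)
  valid <- draw_cohort(p$n_samples_valid, "V", FALSE)
  truth$train_samples <- train$sample_ids
  truth$train_group <- train$group
  list(train = train, valid = valid, annotation = annotation, truth = truth)
}

#' Generate a miRNA-target interaction catalog consistent with the truth
#'
#' Every planted pair except the "no shared miRNA" decoys receives 1-3
#' dedicated miRNAs targeting both members; "no shared miRNA" decoys
#' receive disjoint miRNA sets (two per member).  Additional background
#' miRNAs target background genes only, so they can never rescue a
#' no-shared-miRNA decoy.
#'
#' @param truth Truth list from [generate_cohorts()].
#' @param params The same [synth_params()].
#' @return data.frame with columns `mirna`, `target`, `target_biotype`
#'   (unique edges).
#' @export
generate_interaction_catalog <- function(truth, params) {
  set.seed(params$seed + 1L)
  pairs <- truth$pairs
  edges <- list()
  mir_i <- 0
  next_mirna <- function() {
    mir_i <<- mir_i + 1
    sprintf("MIR%03d", mir_i)
  }
  add_edge <- function(mu, target) {
    edges[[length(edges) + 1]] <<- data.frame(
      mirna = mu, target = target,
      target_biotype = unname(truth$annotation[target]),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pairs))) {
    if (pairs$class[i] == "no_mirna") {
      for (k in 1:2) add_edge(next_mirna(), pairs$lncRNA[i])
      for (k in 1:2) add_edge(next_mirna(), pairs$mRNA[i])
    } else {
      for (k in seq_len(sample(1:3, 1))) {
        mu <- next_mirna()
        add_edge(mu, pairs$lncRNA[i])
        add_edge(mu, pairs$mRNA[i])
      }
    }
  }
  background <- setdiff(names(truth$annotation),
                        c(pairs$lncRNA, pairs$mRNA))
  background <- background[truth$annotation[background] != "other"]
  for (b in seq_len(params$n_background_mirnas)) {
    mu <- next_mirna()
    for (t in sample(background, sample(3:6, 1))) add_edge(mu, t)
  }
  out <- unique(do.call(rbind, edges))
  rownames(out) <- NULL
  out
}

#' Generate a signature matrix and cell-type mixtures
#'
#' The signature has block structure (each marker gene high in its own cell
#' type, low elsewhere).  Per-sample fractions are Dirichlet draws whose
#' mean for cell type 1 is shifted up by `mixture_shift` in CASE samples —
#' planting both a group difference in that type and, because the planted
#' pair genes are also group-shifted, a correlation between fractions and
#' pair expression.  Mixture expression = signature x fractions + Gaussian
#' noise, truncated at zero.  Mixture samples are the training cohort
#' samples.
#'
#' @param params A [synth_params()].
#' @param truth Truth list from [generate_cohorts()].
#' @return List with `signature` (markers x cell types), `mixture` (markers
#'   x samples), `fractions` (samples x cell types, rows sum to 1), and
#'   `shifted_type`.
#' @export
generate_mixtures <- function(params, truth) {
  p <- params
  set.seed(p$seed + 2L)
  types <- sprintf("CT%d", seq_len(p$n_celltypes))
  markers <- unlist(lapply(types, function(t)
    sprintf("MK_%s_%02d", t, seq_len(p$markers_per_type))))
  sig <- matrix(stats::runif(length(markers) * p$n_celltypes, 1, 3),
                nrow = length(markers), dimnames = list(markers, types))
  for (k in seq_along(types)) {
    own <- grepl(paste0("^MK_", types[k], "_"), markers)
    sig[own, k] <- stats::runif(sum(own), 8, 12)
  }
  samples <- truth$train_samples
  group <- truth$train_group
  K <- p$n_celltypes
  base_mean <- rep(1 / K, K)
  case_mean <- base_mean
  case_mean[1] <- base_mean[1] + p$mixture_shift
  case_mean[-1] <- case_mean[-1] * (1 - case_mean[1]) / sum(base_mean[-1])
  fractions <- t(vapply(samples, function(s) {
    m <- if (group[s] == "CASE") case_mean else base_mean
    g <- stats::rgamma(K, shape = p$mixture_concentration * m)
    g / sum(g)
  }, numeric(K)))
  dimnames(fractions) <- list(samples, types)
  mixture <- sig %*% t(fractions) +
    matrix(stats::rnorm(length(markers) * length(samples),
                        sd = p$mixture_noise_sd),
           nrow = length(markers))
  mixture <- pmax(mixture, 0)
  dimnames(mixture) <- list(markers, samples)
  list(signature = sig, mixture = mixture, fractions = fractions,
       shifted_type = types[1])
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper calling [generate_cohorts()],
#' [generate_interaction_catalog()], and [generate_mixtures()].  With
#' `out_dir` set, writes every input file in the formats the readers of
#' this package consume, plus `truth.json`.
#'
#' @param params A [synth_params()].
#' @param out_dir Optional output directory.
#' @return List with `train`, `valid`, `annotation`, `immune_list`,
#'   `catalog`, `signature`, `mixture`, `fractions`, `truth`.
#' @export
simulate_study <- function(params = synth_params(), out_dir = NULL) {
  co <- generate_cohorts(params)
  catalog <- generate_interaction_catalog(co$truth, params)
  mix <- generate_mixtures(params, co$truth)
  out <- list(train = co$train, valid = co$valid,
              annotation = co$annotation,
              immune_list = co$truth$immune_list, catalog = catalog,
              signature = mix$signature, mixture = mix$mixture,
              fractions = mix$fractions, truth = co$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(co$train, file.path(out_dir, "train_counts.tsv"),
                       file.path(out_dir, "train_groups.tsv"))
    write_count_matrix(co$valid, file.path(out_dir, "valid_counts.tsv"),
                       file.path(out_dir, "valid_groups.tsv"))
    utils::write.table(
      data.frame(gene_id = names(co$annotation),
                 biotype = unname(co$annotation)),
      file.path(out_dir, "annotation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeLines(co$truth$immune_list, file.path(out_dir, "immune.txt"))
    utils::write.table(catalog, file.path(out_dir, "catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = rownames(mix$signature), mix$signature,
                 check.names = FALSE),
      file.path(out_dir, "signature.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = rownames(mix$mixture), mix$mixture,
                 check.names = FALSE),
      file.path(out_dir, "mixture.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(module_of_gene = as.list(co$truth$module_of_gene),
           pairs = co$truth$pairs, de_genes = co$truth$de_genes,
           fractions = as.data.frame(mix$fractions)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
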
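test_that("immune split intersects module, list, and biotype", {
  ann <- c(l1 = "lncRNA", l2 = "lncRNA", m1 = "mRNA", m2 = "mRNA", o1 = "other")
  mod <- c("l1", "l2", "m1", "o1", "x9")
  expect_equal(split_immune_genes(mod, ann, character()),
               list(lncRNAs = character(), mRNAs = character()))
  sp <- split_immune_genes(mod, ann, c("l1", "m1", "m2", "o1"))
  expect_equal(sp$lncRNAs, "l1")          # only in the lncRNA slot
  expect_equal(sp$mRNAs, "m1")            # m2 not in module, o1 excluded
})

test_that("pair correlation applies the strict positive cutoff", {
  set.seed(31)
  n <- 20
  base <- rnorm(n)
  x <- rbind(lnc_same = base,
             lnc_anti = -base + rnorm(n, sd = 1e-6),
             mrna_same = base,
             mrna_edge = base)
  colnames(x) <- paste0("s", 1:n)
  pairs <- correlate_pairs(x, c("lnc_same", "lnc_anti"),
                           c("mrna_same", "mrna_edge"), cutoff = 0.75)
  get <- function(l, m) pairs[pairs$lncRNA == l & pairs$mRNA == m, ]
  expect_identical(get("lnc_same", "mrna_same")$status, "candidate")  # r = 1
  expect_identical(get("lnc_anti", "mrna_same")$status,
                   "dropped:low_correlation")                         # r = -1
  # r exactly at the cutoff is excluded (strict inequality)
  p0 <- correlate_pairs(x, "lnc_same", "mrna_same", cutoff = 1)
  expect_identical(p0$status, "dropped:low_correlation")
  # absolute-value mode rescues the negative pair
  pa <- correlate_pairs(x, "lnc_anti", "mrna_same", cutoff = 0.75,
                        absolute = TRUE)
  expect_identical(pa$status, "candidate")
  expect_error(correlate_pairs(x, "missing_gene", "mrna_same"), "missing_gene")
})

test_that("shared-miRNA filter computes exact set intersections", {
  pairs <- data.frame(lncRNA = c("L1", "L2"), mRNA = c("M1", "M2"),
                      r_train = c(0.9, 0.9), p_corr_train = 0,
                      shared_mirnas = NA_character_, kw_p_lnc = NA_real_,
                      kw_p_mrna = NA_real_, status = "candidate",
                      stringsAsFactors = FALSE)
  catalog <- data.frame(
    mirna = c("m1", "m2", "m2", "m3", "m4", "m5"),
    target = c("L1", "L1", "M1", "M1", "L2", "M2"),
    target_biotype = c("lncRNA", "lncRNA", "mRNA", "mRNA", "lncRNA", "mRNA"),
    stringsAsFactors = FALSE)
  out <- shared_mirna_filter(pairs, catalog)
  expect_identical(out$status, c("passed_mirna", "dropped:no_shared_mirna"))
  expect_identical(out$shared_mirnas[1], "m2")
  # empty catalog drops everything
  empty_cat <- catalog[0, ]
  out0 <- shared_mirna_filter(pairs, empty_cat)
  expect_true(all(out0$status == "dropped:no_shared_mirna"))
})

test_that("member DE filter requires both Kruskal-Wallis p-values below alpha", {
  set.seed(32)
  groups <- rep(c("CTRL", "CASE"), each = 10)
  shift <- c(rep(0, 10), rep(3, 10))
  x <- rbind(L1 = rnorm(20) + shift, M1 = rnorm(20) + shift,
             L2 = rnorm(20) + shift, M2 = rep(5, 20))   # M2 constant
  colnames(x) <- paste0("s", 1:20)
  pairs <- data.frame(lncRNA = c("L1", "L2"), mRNA = c("M1", "M2"),
                      r_train = 0.9, p_corr_train = 0,
                      shared_mirnas = "m1", kw_p_lnc = NA_real_,
                      kw_p_mrna = NA_real_, status = "passed_mirna",
                      stringsAsFactors = FALSE)
  out <- de_filter(pairs, x, groups)
  expect_identical(out$status, c("passed_de", "dropped:member_not_de"))
  expect_equal(out$kw_p_mrna[2], 1)      # constant member
  # alpha = 1 drops nothing whose members vary at all (p < 1 always)
  x1 <- x; x1["M2", ] <- seq(-1, 1, length.out = 20)
  out1 <- de_filter(pairs, x1, groups, alpha = 1)
  expect_true(all(out1$status == "passed_de"))
})

test_that("the three screening filters commute", {
  st <- default_study()
  nt <- normalize_counts(st$train)
  tp <- st$truth$pairs
  lncs <- tp$lncRNA
  mrnas <- tp$mRNA
  base <- correlate_pairs(nt$log2_expr, lncs, mrnas, 0.75)
  base$status <- "candidate"          # start all filters from the same set
  low_corr_drop <- correlate_pairs(nt$log2_expr, lncs, mrnas, 0.75)
  surviving <- function(df) sort(pair_key(df[!startsWith(df$status, "dropped"), ]))
  f_corr <- function(df) {
    verdict <- low_corr_drop$status[match(pair_key(df), pair_key(low_corr_drop))]
    hit <- startsWith(verdict, "dropped") & !startsWith(df$status, "dropped")
    df$status[hit] <- "dropped:low_correlation"
    df
  }
  f_mir <- function(df) shared_mirna_filter(df, st$catalog)
  f_de <- function(df) de_filter(df, nt$log2_expr, st$train$group)
  orders <- list(c("c", "m", "d"), c("m", "d", "c"), c("d", "c", "m"))
  results <- lapply(orders, function(ord) {
    df <- base
    for (o in ord) df <- switch(o, c = f_corr(df), m = f_mir(df), d = f_de(df))
    surviving(df)
  })
  expect_identical(results[[1]], results[[2]])
  expect_identical(results[[1]], results[[3]])
})

test_that("pair summaries count exact distinct members", {
  expect_equal(summarize_pairs(data.frame(lncRNA = character(),
                                          mRNA = character())),
               list(n_pairs = 0L, n_lncRNAs = 0L, n_mRNAs = 0L))
  one <- data.frame(lncRNA = "L1", mRNA = "M1")
  expect_equal(summarize_pairs(one),
               list(n_pairs = 1L, n_lncRNAs = 1L, n_mRNAs = 1L))
  set.seed(33)
  for (i in 1:5) {
    df <- data.frame(lncRNA = sample(paste0("L", 1:6), 12, replace = TRUE),
                     mRNA = sample(paste0("M", 1:9), 12, replace = TRUE))
    s <- summarize_pairs(df)
    expect_equal(s$n_pairs, nrow(df))
    expect_equal(s$n_lncRNAs, length(unique(df$lncRNA)))
    expect_equal(s$n_mRNAs, length(unique(df$mRNA)))
  }
})

test_that("network construction deduplicates nodes and enumerates edges", {
  pairs <- data.frame(lncRNA = c("L1", "L2"), mRNA = c("M1", "M2"),
                      r_train = 0.9, p_corr_train = 0,
                      shared_mirnas = c("mu1", "mu1"),
                      kw_p_lnc = 0.01, kw_p_mrna = 0.01,
                      status = "passed_de", stringsAsFactors = FALSE)
  net <- build_cerna_network(pairs)
  # two pairs sharing the same miRNA: the node appears once, 4 edges total
  expect_equal(nrow(net$edges), 4)
  expect_equal(sum(net$nodes$id == "mu1"), 1)
  expect_setequal(net$nodes$type[net$nodes$id == "mu1"], "miRNA")
  one <- build_cerna_network(pairs[1, ])
  expect_equal(nrow(one$nodes), 3)
  expect_equal(nrow(one$edges), 2)
  empty <- build_cerna_network(pairs[0, ])
  expect_equal(nrow(empty$edges), 0)
  bad <- pairs; bad$shared_mirnas <- NA_character_
  expect_error(build_cerna_network(bad), "empty shared miRNA")
})

test_that("edge tables are written deterministically in both dialects", {
  pairs <- data.frame(lncRNA = c("L2", "L1"), mRNA = c("M2", "M1"),
                      r_train = 0.9, p_corr_train = 0,
                      shared_mirnas = c("mu1", "mu1"),
                      kw_p_lnc = 0.01, kw_p_mrna = 0.01,
                      status = "replicated", stringsAsFactors = FALSE)
  net <- build_cerna_network(pairs)
  tsv <- tempfile(fileext = ".tsv"); sif <- tempfile(fileext = ".sif")
  write_edge_table(net, tsv, "tsv")
  tab <- read.delim(tsv)
  expect_identical(names(tab), c("source", "interaction", "target",
                                 "node_type_source", "node_type_target"))
  expect_equal(nrow(tab), 4)
  expect_false(is.unsorted(tab$source))
  write_edge_table(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), 4)
  expect_true(all(grepl("^\\S+ ceRNA \\S+$", lines)))
  # empty network: header-only tsv, empty sif
  e <- build_cerna_network(pairs[0, ])
  write_edge_table(e, tsv, "tsv"); write_edge_table(e, sif, "sif")
  expect_equal(nrow(read.delim(tsv)), 0)
  expect_equal(length(readLines(sif)), 0)
})

test_that("the bundled reference pair table loads with its reported shape", {
  ref <- reference_pairs()
  expect_identical(names(ref), c("mRNA", "lncRNA", "correlation"))
  expect_true(is.numeric(ref$correlation))
})
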
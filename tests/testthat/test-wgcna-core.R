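test_that("top-MAD selection ranks by dispersion with deterministic ties", {
  x <- rbind(flat = c(1, 1, 1), mid = c(1, 2, 3), wide = c(1, 3, 5))
  colnames(x) <- paste0("s", 1:3)
  sel <- select_top_mad(x, 2)
  expect_identical(rownames(sel), c("wide", "mid"))    # MADs 2, 1, 0
  expect_identical(rownames(select_top_mad(x, 10)), c("wide", "mid", "flat"))
  sel1 <- select_top_mad(x, 1)
  expect_identical(rownames(sel1), "wide")
  # mean-based alternative is available
  expect_identical(rownames(select_top_mad(x, 1, method = "mean")), "wide")
})

test_that("scale-free fit is exact on a constructed power-law histogram", {
  # counts 2520/b at connectivity b (b = 1..10) sit at the centers of the 10
  # equal-width bins, so log10(freq) is exactly linear in log10(k)
  k <- rep(1:10, times = 2520 / (1:10))
  sf <- scale_free_fit(k)
  expect_equal(sf$r2, 1, tolerance = 1e-9)
  expect_equal(sf$slope, -1, tolerance = 1e-9)
  expect_equal(sf$r2_signed, 1, tolerance = 1e-9)
})

test_that("scan connectivity matches a brute-force double loop", {
  set.seed(21)
  x <- matrix(rnorm(5 * 12), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  scan <- scan_soft_threshold(x, c(1, 3, 6))
  r <- cor(t(x))
  for (row in seq_len(nrow(scan))) {
    b <- scan$beta[row]
    k <- numeric(5)
    for (i in 1:5) for (j in 1:5) if (i != j) k[i] <- k[i] + abs(r[i, j])^b
    expect_equal(scan$mean_connectivity[row], mean(k), tolerance = 1e-12)
    expect_equal(scan$max_connectivity[row], max(k), tolerance = 1e-12)
    expect_equal(scan$median_connectivity[row], median(k), tolerance = 1e-12)
  }
  # beta = 1 adjacency equals |r|
  a1 <- adjacency_power(x, 1)
  expect_equal(a1[1, 2], abs(r[1, 2]), tolerance = 1e-12)
})

test_that("pick_beta implements smallest-hit, fallback, and tie rules", {
  scan <- data.frame(beta = 1:2, scale_free_r2_signed = c(0.2, 0.9))
  expect_equal(pick_beta(scan, 0.85)$beta, 2)
  scan2 <- data.frame(beta = 1:8,
                      scale_free_r2_signed = c(.1, .2, .3, .4, .5, .8, .7, .6))
  expect_warning(b2 <- pick_beta(scan2, 0.85), "no power reached")
  expect_equal(b2$beta, 6)
  expect_false(b2$met_target)
  scan3 <- data.frame(beta = 3:5, scale_free_r2_signed = c(0.5, 0.9, 0.9))
  expect_equal(pick_beta(scan3, 0.85)$beta, 4)   # smallest of the ties
})

test_that("power adjacency has unit diagonal and rejects constant genes", {
  set.seed(22)
  x <- matrix(rnorm(4 * 10), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  x[2, ] <- x[1, ]                       # duplicated gene
  a <- adjacency_power(x, 5)
  expect_equal(diag(a), setNames(rep(1, 4), rownames(x)))
  expect_equal(a[1, 2], 1, tolerance = 1e-12)
  expect_equal(a, t(a))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(0.5^5, 0.03125)           # the power rule itself
  xc <- rbind(x, const = rep(1, 10))
  expect_error(adjacency_power(xc, 5), "const")
})

test_that("topological overlap matches the formula and a triple-loop oracle", {
  # hand case: a12 = a13 = 0.5, a23 = 0 -> TOM23 = 0.25 / 1.5
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.5
  a[1, 3] <- a[3, 1] <- 0.5
  tom <- tom_similarity(a)$tom
  expect_equal(tom[2, 3], 0.25 / 1.5, tolerance = 1e-12)
  expect_equal(round(tom[2, 3], 4), 0.1667)
  # complete unit graph -> all ones
  ones <- matrix(1, 3, 3)
  expect_true(all(tom_similarity(ones)$tom == 1))
  # disconnected pair with no shared neighbours -> 0
  a0 <- diag(4)
  a0[1, 2] <- a0[2, 1] <- 0.9
  a0[3, 4] <- a0[4, 3] <- 0.9
  expect_equal(tom_similarity(a0)$tom[1, 3], 0)
  # random adjacency vs brute force
  set.seed(23)
  r <- abs(cor(matrix(rnorm(10 * 15), ncol = 10)))
  expect_equal(tom_similarity(r)$tom, tom_oracle(r), tolerance = 1e-10)
  expect_error(tom_similarity(matrix(c(1, .2, .4, 1), 2)), "symmetric")
})

test_that("static tree cut recovers perfect blocks and labels by size", {
  d <- matrix(1, 10, 10)
  d[1:6, 1:6] <- 0
  d[7:10, 7:10] <- 0
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:10), paste0("g", 1:10))
  asg <- cluster_modules(d, min_module_size = 3)
  expect_equal(unname(asg[1:6]), rep("turquoise", 6))   # bigger block first
  expect_equal(unname(asg[7:10]), rep("blue", 4))
  # all-ones dissimilarity: every gene is a singleton, nothing reaches the
  # minimum size
  d1 <- matrix(1, 40, 40); diag(d1) <- 0
  dimnames(d1) <- list(paste0("g", 1:40), paste0("g", 1:40))
  expect_true(all(cluster_modules(d1, 30) == "unassigned"))
  expect_warning(cluster_modules(d[1:5, 1:5], 30), "fewer genes")
})

test_that("module detection is invariant to gene order permutation", {
  st <- default_study()
  nt <- normalize_counts(st$train)
  expr <- select_top_mad(nt$log2_expr, 300)
  tom <- tom_similarity(adjacency_power(expr, 6))
  a1 <- cluster_modules(tom$dissimilarity, 30)
  set.seed(24)
  perm <- sample(nrow(expr))
  tom2 <- tom_similarity(adjacency_power(expr[perm, ], 6))
  a2 <- cluster_modules(tom2$dissimilarity, 30)
  # same partition up to labels: compare co-membership on a gene subset
  genes <- rownames(expr)[1:100]
  co1 <- outer(a1[genes], a1[genes], "==")
  co2 <- outer(a2[genes], a2[genes], "==")
  expect_true(all(co1 == co2))
})

test_that("module eigengenes explain the leading variance and orient positively", {
  set.seed(25)
  base <- rnorm(12)
  # five copies of one profile: variance explained is 1
  x <- matrix(rep(base, 5), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  asg <- setNames(rep("turquoise", 5), rownames(x))
  me <- module_eigengenes(x, asg)
  expect_equal(unname(me$variance_explained["turquoise"]), 1, tolerance = 1e-12)
  expect_equal(abs(cor(me$eigengenes[, "turquoise"], base)), 1, tolerance = 1e-12)
  # two genes with known correlation: variance explained = (1 + r) / 2
  y <- rbind(g1 = base, g2 = as.numeric(0.5 * scale(base) + sqrt(0.75) * rnorm(12)))
  colnames(y) <- paste0("s", 1:12)
  r <- cor(y[1, ], y[2, ])
  me2 <- module_eigengenes(y, setNames(rep("blue", 2), rownames(y)))
  expect_equal(unname(me2$variance_explained["blue"]), (1 + abs(r)) / 2,
               tolerance = 1e-10)
  # orientation contract on random modules
  for (i in 1:5) {
    z <- matrix(rnorm(6 * 10), nrow = 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    mez <- module_eigengenes(z, setNames(rep("brown", 6), rownames(z)))
    mc <- mean(cor(mez$eigengenes[, "brown"], t(z)))
    expect_gte(mc, 0)
  }
})

test_that("module-trait correlation uses the Student transform", {
  eg <- matrix(c(rep(0, 5), rep(1, 5)), ncol = 1,
               dimnames = list(paste0("s", 1:10), "turquoise"))
  trait <- c(rep(0, 5), rep(1, 5))
  tab <- module_trait_correlation(eg, trait)
  expect_equal(tab$r, 1)
  expect_equal(tab$p, 0)
  # r = 0.8, n = 20 -> t = 5.657, p ~ 2.2e-5 (checked against the t CDF)
  t20 <- 0.8 * sqrt(18) / sqrt(1 - 0.64)
  expect_equal(t20, 5.6569, tolerance = 1e-4)
  expect_equal(cor_p_student(0.8, 20), 2 * pt(t20, 18, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(cor_p_student(0.8, 20) - 2.2e-5), 1e-5)
})

test_that("key-module selection handles signs and ties", {
  tab <- data.frame(module = c("M1", "M2", "M3"), r = c(0.9, -0.8, 0.1),
                    p = c(0, 0, 1))
  keys <- select_key_modules(tab)
  expect_equal(keys$positive, "M1")
  expect_equal(keys$negative, "M2")
  allpos <- data.frame(module = c("a", "b"), r = c(0.2, 0.5), p = c(1, 1))
  expect_true(is.na(select_key_modules(allpos)$negative))
  tie <- data.frame(module = c("brown", "blue"), r = c(0.9, 0.9), p = c(0, 0))
  expect_equal(select_key_modules(tie)$positive, "blue")
})
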
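# Shared fixtures and independent oracles used across the suite.

# Small deterministic count matrix with balanced groups.
make_counts <- function(n_genes = 10, n_per_group = 3, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * 2 * n_per_group, lambda = 50), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(2 * n_per_group))))
  count_matrix(m, rep(c("CTRL", "CASE"), each = n_per_group))
}

# Independent step-up oracle for Benjamini-Hochberg (literal definition).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# Independent Kruskal-Wallis oracle from the rank formula with tie
# correction.
kw_oracle <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(x) length(x) * (mean(x) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Brute-force topological overlap by triple loop.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Cache one default synthetic study per session to avoid regenerating it in
# every file.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(synth_params(seed = 1))
    cache
  }
})

pair_key <- function(df) paste(df$lncRNA, df$mRNA)
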
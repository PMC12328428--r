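# Independent oracles used across tests; deliberately naive implementations.

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# two-sided Fisher exact p by full enumeration over the hypergeometric support
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_enum <- function(x, y) {
  v <- c(x, y); nx <- length(x); n <- length(v)
  ustat <- function(a, b) sum(outer(a, b, function(p, q) (p > q) + 0.5 * (p == q)))
  obs <- ustat(x, y)
  mu <- nx * (n - nx) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(ia) ustat(v[ia], v[-ia]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Spearman rho by rank-then-Pearson with midranks
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# greedy one-to-one matching of recovered clusters to true clusters by
# centroid distance (adequate for well-separated fixtures)
match_clusters <- function(recovered_centroids, true_centroids) {
  d <- as.matrix(stats::dist(rbind(recovered_centroids, true_centroids)))
  nr <- nrow(recovered_centroids)
  d <- d[seq_len(nr), -seq_len(nr), drop = FALSE]
  map <- integer(nr)
  for (i in order(apply(d, 1, min))) {
    j <- order(d[i, ])
    j <- j[!(j %in% map)][1]
    map[i] <- j
  }
  map
}

# small planted-signal binary classification fixture
toy_signal <- function(n = 33, p = 6, shift = 1, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p) +
    outer(y, rep(c(shift, -shift), length.out = p))
  list(X = X, y = y)
}

# small synthetic cohort used by several selection tests
small_cohort <- function(seed, n_clusters = 16, effects = c(`2` = 1.5, `7` = -1.5),
                         dispersion = 30, confounding = 1,
                         n_hc = 3, n_sn = 8, n_sp = 8, n_cells = 1500) {
  cc <- cohort_config(n_hc = n_hc, n_sn = n_sn, n_sp = n_sp,
                      n_cells_per_subject = n_cells, n_clusters = n_clusters,
                      effect_map = effects, dispersion = dispersion,
                      confounding_strength = confounding, seed = seed)
  simulate_composition(cc)
}
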
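blob_data <- function(n = 2000, K = 4, sep = 8, sd = 0.3, p = 2, seed = 5) {
  set.seed(seed)
  ctr <- matrix(stats::runif(K * p, 0, 1), K, p)
  ctr <- ctr + sep * (seq_len(K) - 1)   # well separated along the diagonal
  lab <- sample(seq_len(K), n, replace = TRUE)
  list(x = ctr[lab, ] + matrix(rnorm(n * p, 0, sd), n, p),
       lab = lab, ctr = ctr)
}

test_that("arcsinh transform is the exact elementwise map", {
  expect_equal(arcsinh_transform(matrix(0), 5)[1, 1], 0)
  expect_equal(arcsinh_transform(matrix(5), 5)[1, 1], 0.881374,
               tolerance = 1e-6)
  set.seed(1)
  x <- matrix(abs(rnorm(50)) * 20, 10, 5)
  y <- arcsinh_transform(x, 5)
  expect_identical(order(x[, 2]), order(y[, 2]))  # monotone
  expect_error(arcsinh_transform(x, 0), "positive")
})

test_that("SOM collapses to the single point of a degenerate dataset", {
  v <- c(1.5, -2, 0.3)
  x <- matrix(rep(v, each = 300), 300, 3)
  som <- som_train(x, 4, 4, epochs = 5, seed = 1)
  expect_lt(max(abs(sweep(som$codebook, 2, v))), 1e-6)
})

test_that("SOM training is deterministic and quantization error decreases", {
  bl <- blob_data()
  s1 <- som_train(bl$x, 10, 10, epochs = 10, seed = 3)
  s2 <- som_train(bl$x, 10, 10, epochs = 10, seed = 3)
  expect_identical(s1$codebook, s2$codebook)
  expect_true(all(diff(s1$qe) <= 1e-6))
})

test_that("nodes resolve well-separated blobs with near-perfect purity", {
  bl <- blob_data()
  som <- som_train(bl$x, 10, 10, epochs = 10, seed = 3)
  bmu <- seroclust:::.bmu(bl$x, som$codebook)
  # each node votes for its dominant blob
  node_lab <- vapply(seq_len(100), function(m) {
    inm <- bl$lab[bmu == m]
    if (!length(inm)) return(NA_integer_)
    as.integer(names(which.max(table(inm))))
  }, integer(1))
  purity <- mean(node_lab[bmu] == bl$lab)
  expect_gte(purity, 0.99)
})

test_that("metaclustering cuts the node dendrogram at exactly K clusters", {
  bl <- blob_data()
  som <- som_train(bl$x, 10, 10, epochs = 10, seed = 3)
  # identity at K = number of nodes
  mc_full <- metacluster(som, 100)
  expect_equal(length(unique(mc_full$node_to_cluster)), 100)
  for (K in c(44, 12)) {
    mc <- metacluster(som, K)
    expect_equal(length(unique(mc$node_to_cluster)), K)
    expect_true(all(mc$node_to_cluster %in% 0:(K - 1)))
  }
  expect_error(metacluster(som, 0), "range")
  expect_error(metacluster(som, 101), "range")
})

test_that("metacluster recovery of separated blobs reaches ARI >= 0.95", {
  bl <- blob_data()
  som <- som_train(bl$x, 10, 10, epochs = 10, seed = 3)
  mc <- metacluster(som, 4)
  cl <- mc$node_to_cluster[seroclust:::.bmu(bl$x, som$codebook)]
  expect_gte(ari(cl, bl$lab), 0.95)
})

test_that("per-subject counting follows best-matching units exactly", {
  # hand-built SOM: 4 nodes at known positions, identity metaclustering
  som <- structure(list(codebook = matrix(c(0, 0, 10, 0, 0, 10, 10, 10),
                                          4, 2, byrow = TRUE),
                        grid_rows = 2, grid_cols = 2, epochs = 0, seed = 0,
                        qe = 0),
                   class = "som_model")
  mc <- structure(list(node_to_cluster = 0:3, K = 4L),
                  class = "metacluster_assignment")
  cells <- list(s1 = matrix(c(0.1, 9.9), 10, 2, byrow = TRUE))
  comp <- assign_and_count(cells, som, mc)
  expect_equal(unname(comp$fractions[1, ]), c(0, 0, 1, 0))
  # arithmetic on counts (2, 3, 5)
  cells2 <- list(s2 = rbind(matrix(c(0, 0), 2, 2, byrow = TRUE),
                            matrix(c(10, 0), 3, 2, byrow = TRUE),
                            matrix(c(0, 10), 5, 2, byrow = TRUE)))
  mc3 <- structure(list(node_to_cluster = c(0L, 1L, 2L, 2L), K = 3L),
                   class = "metacluster_assignment")
  comp2 <- assign_and_count(cells2, som, mc3)
  expect_equal(unname(comp2$fractions[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(rowSums(comp2$counts)), 10)
  # empty subject rejected
  expect_error(assign_and_count(list(s = matrix(numeric(0), 0, 2)), som, mc),
               "zero cells")
})

test_that("end-to-end composition recovery correlates with the ground truth", {
  K <- 6; p <- 4
  set.seed(31)
  ctr <- matrix(runif(K * p, 0, 0.5), K, p) + 4 * matrix(seq_len(K), K, p)
  cc <- cohort_config(n_hc = 2, n_sn = 4, n_sp = 4,
                      n_cells_per_subject = 1000, n_clusters = K,
                      n_markers = p, centroids = ctr, noise_sd = 0.25,
                      effect_map = c(`1` = 1), seed = 31)
  sim <- simulate_cells(cc)
  tr <- arcsinh_transform(sim$cells, cc$cofactor)
  pooled <- do.call(rbind, tr)
  som <- som_train(pooled, 8, 8, epochs = 8, seed = 31)
  mc <- metacluster(som, K)
  comp <- assign_and_count(tr, som, mc)
  prof <- cluster_profiles(tr, som, mc)
  map <- match_clusters(prof$medians, ctr)
  r <- cor(as.numeric(comp$fractions[, order(map)]),
           as.numeric(sim$truth$true_subject_proportions))
  expect_gte(r, 0.95)
})

test_that("cluster profiles are exact medians over assigned cells", {
  som <- structure(list(codebook = matrix(c(0, 10), 2, 1),
                        grid_rows = 1, grid_cols = 2, epochs = 0, seed = 0,
                        qe = 0),
                   class = "som_model")
  mc <- structure(list(node_to_cluster = 0:1, K = 2L),
                  class = "metacluster_assignment")
  cells <- list(s = matrix(c(1, 2, 9), 3, 1))
  prof <- cluster_profiles(cells, som, mc)
  # values 1 and 2 map to node 1 (distance to 0 smaller), 9 to node 2
  expect_equal(unname(prof$medians[1, 1]), median(c(1, 2)))
  expect_equal(unname(prof$medians[2, 1]), 9)   # single-cell cluster
  expect_equal(prof$sizes, c(2, 1))
  # sort-based oracle on a random fixture
  set.seed(7)
  cells2 <- list(s = matrix(rnorm(60, 5), 30, 2))
  somr <- structure(list(codebook = matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE),
                         grid_rows = 1, grid_cols = 2, epochs = 0, seed = 0,
                         qe = 0), class = "som_model")
  profr <- cluster_profiles(cells2, somr, mc)
  bmu <- seroclust:::.bmu(cells2$s, somr$codebook)
  for (k in 1:2) if (any(bmu == k))
    expect_equal(unname(profr$medians[k, ]),
                 apply(cells2$s[bmu == k, , drop = FALSE], 2,
                       function(v) sort(v)[ceiling(length(v) / 2)] / 2 +
                         sort(v)[floor(length(v) / 2 + 1)] / 2))
})

test_that("activation gating recovers a planted double-positive population", {
  # thresholds at the extremes
  cells <- list(a = matrix(rnorm(40, 2), 10, 4,
                           dimnames = list(NULL, c("CD38", "HLA-DR", "x", "y"))))
  all_in <- gate_activated(cells, thresholds = c(`CD38` = -Inf, `HLA-DR` = -Inf))
  expect_equal(nrow(all_in$a), 10)
  none <- gate_activated(cells, thresholds = c(`CD38` = Inf, `HLA-DR` = Inf))
  expect_equal(nrow(none$a), 0)
  expect_error(gate_activated(list(m = matrix(0, 1, 1,
                                              dimnames = list(NULL, "x")))),
               "missing gating marker")
  # planted 5% CD38+HLA-DR+ cluster; gate at the 90th percentile of HC cells
  K <- 5
  ctr <- matrix(1, K, 25)
  act_idx <- which(default_marker_panel() %in% c("CD38", "HLA-DR"))
  ctr[5, act_idx] <- 4
  p0 <- c(rep(0.95 / 4, 4), 0.05)
  cc <- cohort_config(n_hc = 3, n_sn = 3, n_sp = 3,
                      n_cells_per_subject = 1000, n_clusters = K,
                      centroids = ctr, base_proportions = p0,
                      effect_map = numeric(0), noise_sd = 0.3, seed = 41)
  sim <- simulate_cells(cc)
  tr <- arcsinh_transform(sim$cells, cc$cofactor)
  gated <- gate_activated(tr, sim$covariates)
  recovered <- sum(vapply(gated, function(m) sum(attr(m, "cluster") == 4L),
                          numeric(1)))
  planted <- sum(vapply(sim$cells, function(m) sum(attr(m, "cluster") == 4L),
                        numeric(1)))
  expect_gte(recovered / planted, 0.80)
})
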
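test_that("composition cohort has the study's dimensions and closes to 1", {
  sim <- simulate_composition(cohort_config(seed = 1))
  expect_equal(dim(sim$composition$counts), c(50, 44))
  expect_equal(unname(rowSums(sim$composition$fractions)), rep(1, 50),
               tolerance = 1e-9)
  expect_true(all(rowSums(sim$composition$counts) == 5000))
  expect_equal(table(sim$covariates$group)[["HC"]], 17)
  expect_equal(table(sim$covariates$group)[["SN"]], 17)
  expect_equal(table(sim$covariates$group)[["SP"]], 16)
  # serostatus defined iff RA
  expect_true(all(is.na(sim$covariates$serostatus[sim$covariates$group == "HC"])))
  expect_true(all(sim$covariates$serostatus[sim$covariates$group == "SP"] == 1))
  # truth bookkeeping
  expect_equal(sort(sim$truth$discriminative_set), c(2, 7, 13, 21, 28, 35))
  expect_equal(unname(rowSums(sim$truth$true_subject_proportions)),
               rep(1, 50), tolerance = 1e-9)
})

test_that("identical configs reproduce bitwise-identical cohorts", {
  a <- simulate_composition(cohort_config(seed = 77))
  b <- simulate_composition(cohort_config(seed = 77))
  expect_identical(a$composition$counts, b$composition$counts)
  expect_identical(a$covariates, b$covariates)
  c1 <- simulate_cells(cohort_config(seed = 78, n_cells_per_subject = 100,
                                     n_hc = 2, n_sn = 3, n_sp = 3,
                                     n_clusters = 5))
  c2 <- simulate_cells(cohort_config(seed = 78, n_cells_per_subject = 100,
                                     n_hc = 2, n_sn = 3, n_sp = 3,
                                     n_clusters = 5))
  expect_identical(c1$cells, c2$cells)
})

test_that("null configuration plants no group difference", {
  diffs <- vapply(1:200, function(s) {
    sim <- simulate_composition(
      cohort_config(seed = s, effect_map = numeric(0),
                    confounding_strength = 0, n_cells_per_subject = 500,
                    n_clusters = 10))
    sp <- sim$covariates$group == "SP"
    sn <- sim$covariates$group == "SN"
    mean(sim$composition$fractions[sp, 3]) -
      mean(sim$composition$fractions[sn, 3])
  }, numeric(1))
  expect_gt(stats::t.test(diffs)$p.value, 0.01)
})

test_that("a planted positive effect raises SP abundance in nearly all replicates", {
  up <- vapply(1:100, function(s) {
    sim <- simulate_composition(
      cohort_config(seed = s, effect_map = c(`3` = 1.0),
                    n_cells_per_subject = 1000, n_clusters = 10))
    sp <- sim$covariates$group == "SP"
    sn <- sim$covariates$group == "SN"
    mean(sim$composition$fractions[sp, 4]) >
      mean(sim$composition$fractions[sn, 4])
  }, logical(1))
  expect_gte(mean(up), 0.95)
})

test_that("confounding plants a real age imbalance between SP and SN", {
  smd <- vapply(1:100, function(s) {
    sim <- simulate_composition(cohort_config(seed = s, n_cells_per_subject = 100))
    cov <- sim$covariates
    a1 <- cov$age[cov$group == "SP"]; a0 <- cov$age[cov$group == "SN"]
    (mean(a1) - mean(a0)) / sqrt((stats::var(a1) + stats::var(a0)) / 2)
  }, numeric(1))
  expect_gt(mean(smd), 0.2)
})

test_that("cell-level simulation matches the panel and respects noise scale", {
  cc <- cohort_config(seed = 5, n_hc = 2, n_sn = 2, n_sp = 2,
                      n_cells_per_subject = 200, n_clusters = 4)
  sim <- simulate_cells(cc)
  expect_length(sim$cells, 6)
  expect_true(all(vapply(sim$cells, ncol, integer(1)) == 25))
  expect_true(all(vapply(sim$cells, function(m) all(m >= 0), logical(1))))
  # zero noise: transformed values recover centroids exactly
  cc0 <- cohort_config(seed = 5, n_hc = 2, n_sn = 2, n_sp = 2,
                       n_cells_per_subject = 50, n_clusters = 3,
                       noise_sd = 0)
  sim0 <- simulate_cells(cc0)
  m <- sim0$cells[[1]]
  lab <- attr(m, "cluster") + 1L
  back <- asinh(m / cc0$cofactor)
  expect_equal(unname(back),
               unname(sim0$truth$true_cluster_centroids[lab, ]),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("well-separated centroids are recoverable by nearest-centroid", {
  K <- 4; p <- 5
  ctr <- matrix(0, K, p)
  for (k in 1:K) ctr[k, ] <- (k - 1) * 2
  cc <- cohort_config(seed = 9, n_hc = 1, n_sn = 1, n_sp = 1,
                      n_cells_per_subject = 2000, n_clusters = K,
                      n_markers = p, centroids = ctr, noise_sd = 0.2)
  sim <- simulate_cells(cc)
  m <- arcsinh_transform(sim$cells[[1]], cc$cofactor)
  d <- as.matrix(stats::dist(rbind(m, ctr)))[seq_len(nrow(m)),
                                             nrow(m) + seq_len(K)]
  pred <- max.col(-d)
  expect_gte(mean(pred == attr(sim$cells[[1]], "cluster") + 1L), 0.99)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_hc = 0), "n_hc")
  expect_error(cohort_config(dispersion = 0), "dispersion")
  expect_error(cohort_config(effect_map = c(`50` = 1)), "cluster indices")
  expect_error(cohort_config(n_clusters = 3, base_proportions = c(0.5, 0.5, 0)),
               "positive")
  expect_error(simulate_cells(cohort_config(n_clusters = 30,
                                            n_cells_per_subject = 10)),
               "exceeds")
})

test_that("cohort tables round-trip through delimited text", {
  sim <- simulate_composition(cohort_config(seed = 3, n_hc = 2, n_sn = 3,
                                            n_sp = 3, n_clusters = 6,
                                            n_cells_per_subject = 400,
                                            effect_map = c(`1` = 1)))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  expect_true(all(file.exists(paths)))
  comp <- read_composition(paths[["counts"]])
  expect_equal(comp$counts, sim$composition$counts)
  expect_equal(comp$fractions, sim$composition$fractions)
})
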
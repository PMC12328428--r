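test_that("CLR transform matches hand computation and closes to zero", {
  x <- matrix(c(0.5, 0.25, 0.25), 1)
  out <- clr_transform(x, pseudocount = 0)
  expect_equal(as.numeric(out), c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)
  # uniform composition maps to zero
  u <- clr_transform(matrix(rep(1 / 5, 5), 1), pseudocount = 0)
  expect_equal(as.numeric(u), rep(0, 5), tolerance = 1e-12)
  # any row sums to zero; scale invariance in the counts
  set.seed(1)
  m <- matrix(rpois(60, 40) + 1, 6, 10)
  out <- clr_transform(m, pseudocount = 0)
  expect_equal(unname(rowSums(out)), rep(0, 6), tolerance = 1e-8)
  expect_equal(clr_transform(m * 7, pseudocount = 0), out, tolerance = 1e-10)
  expect_error(clr_transform(matrix(c(0, 1, 1), 1), pseudocount = 0), "zero")
})

test_that("Mann-Whitney test is exact for small tie-free samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$U, 0)
  # identical groups: U = n^2/2, p = 1
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$U, 4.5)
  expect_equal(mw_enum(c(1, 2, 3), c(1, 2, 3)), 1)
  # swap symmetry
  a <- c(0.3, 1.1, 2.5, 0.9); b <- c(1.7, 2.2, 0.1)
  ra <- mann_whitney(a, b); rb <- mann_whitney(b, a)
  expect_equal(rb$U, length(a) * length(b) - ra$U)
  expect_equal(ra$p, rb$p)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p matches full enumeration for n <= 10", {
  set.seed(42)
  for (i in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(mann_whitney(x, y)$p, mw_enum(x, y), tolerance = 1e-12)
  }
})

test_that("weighted Mann-Whitney reduces to the classical statistic and scales", {
  x <- c(1.2, 0.4, 2.2, 3.1); y <- c(0.9, 2.8, 1.5)
  r <- weighted_mann_whitney(x, y, exhaustive = TRUE)
  expect_equal(r$U_w, mann_whitney(x, y)$U)
  # doubling weights scales U by 4 and leaves p unchanged
  r2 <- weighted_mann_whitney(x, y, wx = rep(2, 4), wy = rep(2, 3),
                              exhaustive = TRUE)
  expect_equal(r2$U_w, 4 * r$U_w)
  expect_equal(r2$p, r$p)
  # tiny example against enumeration
  r3 <- weighted_mann_whitney(c(1, 2), c(3, 4), exhaustive = TRUE)
  expect_equal(r3$p, 2 / 6)
  expect_error(weighted_mann_whitney(x, y, wx = c(1, 1, -1, 1)), "positive")
})

test_that("unit-weight permutation test agrees with the exact test's decisions", {
  set.seed(7)
  agree <- vapply(1:300, function(i) {
    nx <- sample(3:5, 1); ny <- sample(3:4, 1)
    x <- rnorm(nx, sample(c(0, 2), 1)); y <- rnorm(ny)
    pw <- weighted_mann_whitney(x, y, exhaustive = TRUE)$p
    pe <- mann_whitney(x, y)$p
    (pw < 0.05) == (pe < 0.05)
  }, logical(1))
  expect_true(all(agree))
})

test_that("BH adjustment follows the step-up rule within families", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)          # single-member family
  # families are corrected independently
  p <- c(0.01, 0.02, 0.5, 0.04)
  fam <- c("a", "a", "b", "b")
  q <- bh_adjust(p, fam)
  expect_equal(q[1:2], stats::p.adjust(p[1:2], "BH"))
  expect_equal(q[3:4], stats::p.adjust(p[3:4], "BH"))
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  # monotone in sorted-p order
  set.seed(3)
  pr <- runif(20)
  qr <- bh_adjust(pr)
  expect_true(all(diff(qr[order(pr)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("weighted median uses cumulative weights with midpoint convention", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median(c(1, 2, 3), c(10, 1, 1)), 1)
  expect_equal(weighted_median(c(1, 3), c(1, 1)), 2)
  expect_equal(weighted_median(c(3, 1), c(1, 1)), 2)  # order-free
  expect_error(weighted_median(numeric(0)), "empty")
})

test_that("Fisher exact matches enumeration, including the clinical tables", {
  # RF+ serostatus table: all 16 SP positive, all 17 SN negative
  expect_equal(fisher_exact_2x2(matrix(c(0, 16, 17, 0), 2, 2)),
               8.570e-10, tolerance = 5e-4)
  expect_equal(fisher_exact_2x2(matrix(c(8, 8, 9, 8), 2, 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2, 2)), 1)
  set.seed(11)
  for (i in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum(tab), tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(1, -1, 2, 3), 2, 2)), "non-negative")
})

test_that("Kruskal-Wallis matches the hand-ranked statistic", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$H, 7.2)
  # identical groups: H = 0, p = 1
  r0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$H, 0)
  expect_equal(r0$p, 1)
  # permutation of group order leaves H unchanged
  r2 <- kruskal_wallis(list(c(7, 8, 9), c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r2$H, r$H)
  expect_error(kruskal_wallis(list(1:3)), "two")
})

test_that("Spearman correlations match the rank-Pearson oracle", {
  set.seed(5)
  X <- cbind(a = rnorm(20), b = rnorm(20), c = sample(1:5, 20, TRUE))
  out <- spearman_corr_bh(X)
  expect_equal(out$rho["a", "a"], 1)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(out$rho[i, j], spearman_oracle(X[, i], X[, j]),
                 tolerance = 1e-12)
  # perfect inverse ranks
  out2 <- spearman_corr_bh(cbind(x = 1:4, y = 4:1))
  expect_equal(out2$rho["x", "y"], -1)
  # constant variable flagged missing and excluded from the BH count
  X3 <- cbind(X, d = rep(1, 20))
  out3 <- spearman_corr_bh(X3)
  expect_true(all(is.na(out3$rho["d", c("a", "b", "c")])))
  expect_equal(out3$q[upper.tri(out3$q)][!is.na(out3$p[upper.tri(out3$p)])],
               bh_adjust(out3$p[upper.tri(out3$p)][
                 !is.na(out3$p[upper.tri(out3$p)])]))
})

test_that("U statistic and rank AUC are dual on identical data", {
  set.seed(8)
  x <- rnorm(9, 1); y <- rnorm(7)
  U_first <- mann_whitney(x, y)$U
  auc <- roc_auc(c(x, y), c(rep(1, 9), rep(0, 7)))
  expect_equal(auc, U_first / (9 * 7), tolerance = 1e-12)
})

test_that("group comparison table carries medians, IQRs and family q-values", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, paste0("TCL0", 1:4)))
  g <- rep(c("SN", "SP"), each = 5)
  out <- group_comparison(X, g, family = c("core", "core", "act", "act"))
  expect_equal(nrow(out), 4)
  expect_true(all(out$q >= out$p - 1e-12))
  expect_equal(out$median_1[1], stats::median(X[1:5, 1]))
  # weighted variant uses weighted medians and the permutation test
  outw <- group_comparison(X, g, weights = rep(1, 10), n_mc = 200)
  expect_true(all(outw$weighted))
  expect_equal(outw$U, out$U, tolerance = 1e-12)
})
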
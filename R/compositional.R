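#' Centered log-ratio transform of a composition table
#'
#' Shifts counts by a pseudocount, renormalizes to fractions and applies the
#' centered log-ratio: `clr_k = log(x_k) - mean_j log(x_j)`. Rows of the
#' result sum to zero, removing the compositional closure constraint before
#' downstream modelling.
#'
#' @param comp A `composition_table` (from [simulate_composition()] or
#'   [assign_and_count()]) or a non-negative subject x cluster matrix of
#'   counts or fractions.
#' @param pseudocount Non-negative count-scale shift applied before
#'   renormalization; must be positive if any entry is zero. Default 0.5.
#' @return Subject x cluster matrix of CLR values with a `pseudocount`
#'   attribute.
#' @export
clr_transform <- function(comp, pseudocount = 0.5) {
  m <- if (inherits(comp, "composition_table")) comp$counts else as.matrix(comp)
  if (any(m < 0)) stop("negative composition entries")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(m == 0) && pseudocount == 0)
    stop("zero fractions require a positive pseudocount")
  m <- m + pseudocount
  x <- m / rowSums(m)
  lx <- log(x)
  out <- lx - rowMeans(lx)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. For combined sample size at most 25
#' without ties the exact permutation null is used; otherwise the normal
#' approximation with tie and continuity correction. The U statistic uses
#' midranks for ties and is reported for the first group.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 25) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Weighted Mann-Whitney U test with a permutation null
#'
#' Weighted two-sample rank statistic
#' `U_w = sum_ij wx_i wy_j (1(x_i > y_j) + 0.5 * 1(x_i = y_j))`, typically
#' with inverse-probability-of-treatment weights attached to subjects. The
#' two-sided p-value comes from a Monte-Carlo permutation null that shuffles
#' group labels while each observation keeps its weight, with the
#' `(1 + #extreme) / (n_mc + 1)` convention; extremeness is measured as
#' distance from the permutation-estimated null mean.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param wx,wy Strictly positive weights aligned to `x` and `y`.
#' @param n_mc Number of label permutations (ignored when `exhaustive`).
#' @param seed Integer seed for the permutation draw.
#' @param exhaustive If `TRUE`, enumerate all label assignments instead of
#'   sampling (feasible only for small samples).
#' @return List with `U_w`, `p`, and the permutation null mean `null_mean`.
#' @export
weighted_mann_whitney <- function(x, y, wx = rep(1, length(x)),
                                  wy = rep(1, length(y)), n_mc = 2000,
                                  seed = 1L, exhaustive = FALSE) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (any(wx <= 0) || any(wy <= 0)) stop("weights must be strictly positive")
  stat <- function(xa, wa, yb, wb) {
    cmp <- outer(xa, yb, function(a, b) (a > b) + 0.5 * (a == b))
    as.numeric(t(wa) %*% cmp %*% wb)
  }
  obs <- stat(x, wx, y, wy)
  v <- c(x, y); w <- c(wx, wy); nx <- length(x); n <- length(v)
  if (exhaustive) {
    idx <- utils::combn(n, nx)
    null <- apply(idx, 2, function(ia) {
      ib <- setdiff(seq_len(n), ia)
      stat(v[ia], w[ia], v[ib], w[ib])
    })
    mu <- mean(null)
    p <- mean(abs(null - mu) >= abs(obs - mu) - 1e-12)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_mc), function(b) {
      ia <- sample.int(n, nx)
      ib <- setdiff(seq_len(n), ia)
      stat(v[ia], w[ia], v[ib], w[ib])
    }, numeric(1))
    mu <- mean(null)
    p <- (1 + sum(abs(null - mu) >= abs(obs - mu) - 1e-12)) / (n_mc + 1)
  }
  list(U_w = obs, p = min(p, 1), null_mean = mu)
}

#' Benjamini-Hochberg adjustment within feature families
#'
#' Applies the BH step-up FDR correction independently within each declared
#' feature family (e.g. core subsets, activated subsets, Th/Treg ratios),
#' so that multiplicity is controlled within biologically defined groups
#' rather than across the whole table.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param family Factor or character vector of family labels, recycled if a
#'   single value; `NULL` treats all p-values as one family.
#' @return Numeric q-values in the original order.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  if (is.null(family)) family <- rep("all", length(p))
  family <- rep_len(as.character(family), length(p))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    i <- which(family == f & !is.na(p))
    q[i] <- stats::p.adjust(p[i], method = "BH")
  }
  q
}

#' Weighted median
#'
#' Smallest value whose cumulative normalized weight reaches 1/2, with the
#' midpoint convention when the cumulative weight lands exactly on 1/2
#' between two distinct values.
#'
#' @param values Numeric vector.
#' @param weights Strictly positive weights.
#' @return Scalar weighted median.
#' @export
weighted_median <- function(values, weights = rep(1, length(values))) {
  if (!length(values)) stop("empty input")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  i <- which(cw >= 0.5 - 1e-12)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(v)) (v[i] + v[i + 1]) / 2 else v[i]
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the observed table's
#' probability (within a small relative tolerance).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  stats::fisher.test(tab)$p.value
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with the tie-corrected statistic `H`, degrees of freedom and
#'   chi-squared p-value.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least two non-empty groups")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Spearman correlation matrix with BH-adjusted p-values
#'
#' Pairwise Spearman rank correlations (midranks for ties,
#' pairwise-complete observations) with Benjamini-Hochberg adjustment over
#' all tested pairs. Compositional variables are expected to arrive already
#' CLR-transformed; set `clr_checked = TRUE` to assert that the caller did so.
#'
#' @param x Subject x variable numeric matrix or data frame.
#' @param clr_checked Flag recorded in the result confirming compositional
#'   columns were CLR-transformed upstream.
#' @return List with matrices `rho`, `p`, `q` (constant variables give `NA`
#'   and are excluded from the BH count).
#' @export
spearman_corr_bh <- function(x, clr_checked = FALSE) {
  x <- as.matrix(x)
  v <- ncol(x)
  rho <- p <- matrix(NA_real_, v, v, dimnames = list(colnames(x), colnames(x)))
  diag(rho) <- 1
  for (i in seq_len(v)) for (j in seq_len(v)) {
    if (j <= i) next
    ok <- stats::complete.cases(x[, i], x[, j])
    if (sum(ok) < 3) next
    if (stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[ok, i], x[ok, j],
                                           method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  q <- p
  q[up] <- bh_adjust(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(rho = rho, p = p, q = q, clr_checked = isTRUE(clr_checked))
}

#' Per-feature two-group comparison table
#'
#' For each feature, compares the two groups with a Mann-Whitney U test
#' (optionally the IPW-weighted permutation variant) and reports medians and
#' interquartile ranges per group, with BH q-values computed within each
#' declared feature family.
#'
#' @param x Subject x feature matrix.
#' @param group Two-level factor/vector aligned to rows of `x`.
#' @param family Optional feature family labels (length `ncol(x)`).
#' @param weights Optional positive subject weights; when supplied the
#'   weighted Mann-Whitney permutation test and weighted medians are used.
#' @param n_mc Permutations for the weighted test.
#' @param seed Seed for the weighted test.
#' @return Data frame with one row per feature: U, p, q, family, group
#'   medians and IQRs.
#' @export
group_comparison <- function(x, group, family = NULL, weights = NULL,
                             n_mc = 2000, seed = 1L) {
  x <- as.matrix(x)
  g <- as.factor(group)
  stopifnot(nlevels(g) == 2, nrow(x) == length(g))
  lv <- levels(g)
  a <- g == lv[1]; b <- g == lv[2]
  weighted <- !is.null(weights)
  res <- lapply(seq_len(ncol(x)), function(k) {
    xa <- x[a, k]; xb <- x[b, k]
    if (weighted) {
      tst <- weighted_mann_whitney(xa, xb, weights[a], weights[b],
                                   n_mc = n_mc, seed = seed + k)
      meda <- weighted_median(xa, weights[a])
      medb <- weighted_median(xb, weights[b])
      U <- tst$U_w
    } else {
      tst <- mann_whitney(xa, xb)
      meda <- stats::median(xa); medb <- stats::median(xb)
      U <- tst$U
    }
    data.frame(feature = colnames(x)[k] %||% paste0("f", k),
               U = U, p = tst$p,
               median_1 = meda, iqr_lo_1 = stats::quantile(xa, 0.25),
               iqr_hi_1 = stats::quantile(xa, 0.75),
               median_2 = medb, iqr_lo_2 = stats::quantile(xb, 0.25),
               iqr_hi_2 = stats::quantile(xb, 0.75))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$family <- if (is.null(family)) "all" else rep_len(family, ncol(x))
  out$q <- bh_adjust(out$p, out$family)
  out$weighted <- weighted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
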
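#' @useDynLib seroclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# weighted column standardization; zero-variance columns get scale 1 and are
# flagged so the penalty can exclude them
.w_standardize <- function(X, w) {
  ctr <- drop(w %*% X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(drop(w %*% (Xc^2)))
  zero <- scl < 1e-12
  scl[zero] <- 1
  list(X = sweep(Xc, 2, scl, "/"), center = ctr, scale = scl, zero = zero)
}

# stratified fold assignment, deterministic given the RNG state
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.weighted_deviance <- function(y, mu, w) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Adaptive LASSO weighted logistic regression
#'
#' Two-stage estimator for sparse logistic modelling of serostatus on CLR
#' cluster features with observation (IPW) weights. Stage 1 fits a
#' ridge-penalized weighted logistic regression; stage 2 solves the weighted
#' L1 problem with per-coefficient penalty factors `1/|beta_init|^gamma`
#' (capped, which forces exclusion) by cyclic coordinate descent over a
#' log-spaced lambda grid, choosing lambda by stratified inner
#' cross-validation on the weighted deviance (one-standard-error rule by
#' default; see `lambda_rule`). The entire two-stage estimator is refit
#' inside every inner fold so the penalty factors never see the held-out
#' labels. Features are standardized internally to weighted mean 0 / SD 1;
#' reported coefficients are on the original feature scale and the
#' intercept is unpenalized.
#'
#' @param X Numeric feature matrix (subjects x features).
#' @param y Binary 0/1 response.
#' @param weights Positive observation weights (an `ipw_weights` object or a
#'   numeric vector); default equal weights.
#' @param gamma Adaptive-LASSO exponent (default 1).
#' @param nlambda Lambda grid size (default 100).
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @param lambda Optional fixed lambda value(s); skips inner CV and uses the
#'   (first) supplied value as the solution.
#' @param inner_folds Inner CV folds (default 5; reduced if a class is
#'   smaller).
#' @param lambda_rule `"1se"` (default) picks the largest lambda whose CV
#'   deviance is within one standard error of the minimum — the sparser,
#'   null-calibrated choice; `"min"` picks the deviance-minimizing lambda.
#' @param ridge_init Stage-1 ridge penalty on standardized slopes.
#' @param pen_cap Penalty-factor cap; factors at the cap force a zero
#'   coefficient.
#' @param seed Seed controlling the inner-CV fold split.
#' @return Object of class `adaptive_lasso`: `coefficients` (original
#'   scale, intercept first), `beta_std`, `lambda`, `lambda_grid`,
#'   `penalty_factors`, `cv_deviance`, `selected` (names of nonzero
#'   features), plus standardization records.
#' @export
adaptive_lasso <- function(X, y, weights = NULL, gamma = 1, nlambda = 100,
                           lambda_min_ratio = 1e-3, lambda = NULL,
                           inner_folds = 5, ridge_init = 0.1,
                           pen_cap = 1e8, lambda_rule = c("1se", "min"),
                           seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes required")
  if (inherits(weights, "ipw_weights")) weights <- weights$weights
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  w <- weights / sum(weights)
  std <- .w_standardize(X, w)

  # stage 1: ridge-penalized weighted logistic initial estimator giving
  # penalty factors, normalized so the mean finite factor is 1 (keeps the
  # lambda scale comparable when stage 1 is refit inside CV folds)
  stage1_pen <- function(Xs, ys, ws, zero) {
    init <- .irls_logistic(Xs, ys, obs_w = ws, ridge = ridge_init)
    p1 <- 1 / pmax(abs(init$coefficients[-1]), 1e-12)^gamma
    p1[p1 > pen_cap | zero] <- pen_cap
    fin <- p1 < pen_cap
    if (any(fin)) p1[fin] <- p1[fin] / mean(p1[fin])
    attr(p1, "converged") <- init$converged
    p1
  }
  pen <- stage1_pen(std$X, y, w, std$zero)
  if (all(pen >= pen_cap)) stop("all features excluded: zero penalty path")

  # lambda grid from the weighted score at the null model
  ybar <- sum(w * y)
  g0 <- abs(drop(w %*% (std$X * (y - ybar))))
  lambda_max <- max(g0[pen < pen_cap] / pen[pen < pen_cap])
  lambda_max <- max(lambda_max, 1e-10)
  if (is.null(lambda)) {
    grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = nlambda))
  } else {
    grid <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  }

  fit_path <- function(Xs, ys, ws, lams, pf = pen, tol = 1e-9,
                       max_outer = 100L) {
    lasso_logistic_path_cpp(Xs, ys, ws / sum(ws), pf, lams, pen_cap,
                            tol, max_outer, 1000L)
  }

  if (is.null(lambda)) {
    k <- min(inner_folds, min(table(y)))
    if (k < 2) stop("too few subjects per class for inner CV")
    set.seed(seed)
    fold <- .stratified_folds(y, k)
    # per-fold mean held-out deviance (per unit weight); the whole two-stage
    # estimator (standardization, ridge init, penalty factors) is refit
    # inside each fold — reusing full-data penalty factors would leak the
    # held-out labels into the lambda choice
    devm <- matrix(NA_real_, k, length(grid))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      w_f <- w[tr] / sum(w[tr])
      std_f <- .w_standardize(X[tr, , drop = FALSE], w_f)
      pen_f <- stage1_pen(std_f$X, y[tr], w_f, std_f$zero)
      path <- fit_path(std_f$X, y[tr], w[tr], grid, pf = pen_f, tol = 1e-6,
                       max_outer = 25L)
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, std_f$center), 2,
                   std_f$scale, "/")
      eta <- cbind(1, Xte) %*% path
      for (l in seq_along(grid))
        devm[f, l] <- .weighted_deviance(y[!tr], stats::plogis(eta[, l]),
                                         w[!tr]) / sum(w[!tr])
    }
    cv_dev <- colMeans(devm, na.rm = TRUE)
    cv_se <- apply(devm, 2, stats::sd) / sqrt(k)
    i_min <- which(cv_dev <= min(cv_dev) + 1e-12)[1]  # tie -> sparser model
    best <- if (lambda_rule == "1se")
      which(cv_dev <= cv_dev[i_min] + cv_se[i_min])[1] else i_min
  } else {
    cv_dev <- rep(NA_real_, length(grid))
    best <- length(grid)  # smallest requested lambda is the solution
  }

  # fit the final path only down to the chosen lambda; the denser tail of
  # the grid is never used and is by far the most expensive region
  path <- fit_path(std$X, y, w, grid[seq_len(best)])
  b_std <- path[, best]
  slopes <- b_std[-1] / std$scale
  intercept <- b_std[1] - sum(b_std[-1] * std$center / std$scale)
  coefs <- c(`(Intercept)` = unname(intercept),
             stats::setNames(slopes, colnames(X)))
  structure(list(coefficients = coefs, beta_std = b_std,
                 lambda = grid[best], lambda_grid = grid,
                 lambda_rule = if (is.null(lambda)) lambda_rule else "fixed",
                 cv_deviance = cv_dev, penalty_factors = pen,
                 gamma = gamma, pen_cap = pen_cap,
                 center = std$center, scale = std$scale,
                 weights = w, y = y,
                 selected = colnames(X)[slopes != 0],
                 init_converged = attr(pen, "converged")),
            class = "adaptive_lasso")
}

#' @export
print.adaptive_lasso <- function(x, ...) {
  cat("Adaptive LASSO weighted logistic fit\n")
  cat(sprintf("  lambda = %.5g (grid of %d), gamma = %g\n", x$lambda,
              length(x$lambda_grid), x$gamma))
  nz <- x$selected
  cat(sprintf("  %d nonzero feature(s): %s\n", length(nz),
              paste(utils::head(nz, 10), collapse = ", ")))
  invisible(x)
}

#' @export
coef.adaptive_lasso <- function(object, ...) object$coefficients

#' @export
predict.adaptive_lasso <- function(object, newdata,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  beta <- object$coefficients
  eta <- drop(beta[1] + newdata %*% beta[-1])
  if (type == "link") eta else stats::plogis(eta)
}

#' Karush-Kuhn-Tucker residuals of an adaptive LASSO solution
#'
#' Gradient of the weighted logistic loss on the standardized scale checked
#' against the subgradient conditions of the L1 penalty: for zero slopes the
#' score must not exceed `lambda * penalty`, for nonzero slopes it must equal
#' `-lambda * penalty * sign(beta)`. Returns the largest violation (0 when
#' the conditions hold exactly).
#'
#' @param fit An [adaptive_lasso()] object.
#' @param X The feature matrix the model was fitted on.
#' @return Maximum KKT violation (scalar).
#' @export
lasso_kkt_check <- function(fit, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  mu <- stats::plogis(drop(cbind(1, Xs) %*% fit$beta_std))
  g <- drop(fit$weights %*% (Xs * (fit$y - mu)))
  b <- fit$beta_std[-1]
  lam <- fit$lambda * fit$penalty_factors
  viol <- ifelse(fit$penalty_factors >= fit$pen_cap, 0,
                 ifelse(b == 0, pmax(abs(g) - lam, 0), abs(g - lam * sign(b))))
  viol <- c(viol, abs(sum(fit$weights * (fit$y - mu))))  # intercept score
  max(viol)
}
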
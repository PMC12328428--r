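#' Default propensity covariate sets
#'
#' The serostatus propensity model can adjust for the four background
#' covariates (age, sex, symptom duration, NSAID use) or additionally for
#' disease activity (DAS28-CRP). Both variants are supported; the extended
#' set is the default.
#'
#' @param variant `"extended"` (with DAS28-CRP) or `"basic"`.
#' @return Character vector of covariate names.
#' @export
propensity_covariates <- function(variant = c("extended", "basic")) {
  variant <- match.arg(variant)
  base <- c("age", "sex", "symptom_duration", "nsaid_use")
  if (variant == "extended") c(base, "das28crp") else base
}

# design matrix for the propensity model; binary/character covariates are
# indicator-coded, constant columns dropped with a warning
.propensity_design <- function(covariates, covariate_set,
                               drop_constant = TRUE) {
  if (!length(covariate_set))   # intercept-only model
    return(matrix(numeric(0), nrow(covariates), 0))
  miss <- setdiff(covariate_set, names(covariates))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  cols <- lapply(covariate_set, function(nm) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      as.numeric(v == levels(v)[nlevels(v)])
    } else as.numeric(v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariate_set
  if (drop_constant) {
    keep <- apply(X, 2, function(v) stats::sd(v) > 0)
    if (!all(keep)) {
      warning("dropping constant covariate(s): ",
              paste(colnames(X)[!keep], collapse = ", "))
      X <- X[, keep, drop = FALSE]
    }
  }
  X
}

# ridge-stabilized weighted logistic IRLS; ridge applies to slopes only
.irls_logistic <- function(X, y, obs_w = rep(1, length(y)), ridge = 1e-6,
                           max_iter = 100, tol = 1e-10) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  beta <- numeric(p)
  D <- diag(c(0, rep(ridge, p - 1)), p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    W <- obs_w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    XtW <- t(Xi * W)
    new_beta <- tryCatch(solve(XtW %*% Xi + D, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(new_beta)) break
    new_beta <- drop(new_beta)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  names(beta) <- colnames(Xi)
  fitted <- stats::plogis(drop(Xi %*% beta))
  list(coefficients = beta, fitted = fitted, converged = converged)
}

#' Fit a serostatus propensity model
#'
#' Logistic regression of serostatus on clinical covariates, fitted by
#' iteratively reweighted least squares with a small ridge penalty on the
#' slopes so that near-separation (likely at n around 33) cannot prevent
#' convergence. Fitted probabilities are clipped away from 0 and 1.
#'
#' @param covariates Data frame of RA subjects (one row each).
#' @param label Binary serostatus vector; defaults to the `serostatus`
#'   column.
#' @param covariate_set Covariate names; see [propensity_covariates()].
#' @param ridge Ridge stabilizer applied to slope coefficients.
#' @return Object of class `propensity_model` with `coefficients`, `fitted`,
#'   `converged`, `covariates` (names used).
#' @export
fit_propensity <- function(covariates, label = covariates$serostatus,
                           covariate_set = propensity_covariates(),
                           ridge = 1e-6) {
  y <- as.numeric(label)
  if (length(unique(y)) < 2) stop("both serostatus classes required")
  if (any(table(y) < 2)) stop("need at least 2 subjects per class")
  X <- .propensity_design(covariates, covariate_set)
  fit <- .irls_logistic(X, y, ridge = ridge)
  fitted <- pmin(pmax(fit$fitted, 1e-6), 1 - 1e-6)
  structure(list(coefficients = fit$coefficients, fitted = fitted,
                 converged = fit$converged, covariates = colnames(X),
                 label = y, ridge = ridge),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (ridge-stabilized logistic IRLS)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("converged: %s; fitted range [%.3f, %.3f]\n", x$converged,
              min(x$fitted), max(x$fitted)))
  invisible(x)
}

#' @export
predict.propensity_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- .propensity_design(newdata, object$covariates)
  X <- X[, intersect(colnames(X), names(object$coefficients)), drop = FALSE]
  beta <- object$coefficients
  eta <- beta["(Intercept)"] + drop(X %*% beta[colnames(X)])
  pmin(pmax(stats::plogis(eta), 1e-6), 1 - 1e-6)
}

#' Inverse-probability-of-treatment weights
#'
#' Unstabilized weights are `1/e` for serostatus 1 and `1/(1-e)` for
#' serostatus 0, where `e` is the fitted propensity. Stabilized weights
#' multiply by the group prevalence, and optional truncation clips weights
#' to stated percentiles of their distribution.
#'
#' @param model A fitted [fit_propensity()] model.
#' @param label Binary serostatus; defaults to the model's labels.
#' @param stabilize Multiply by group prevalence (default `TRUE`).
#' @param truncate Percentile pair for clipping (default `c(0.01, 0.99)`),
#'   or `NULL` for none.
#' @return Object of class `ipw_weights`: positive `weights` plus flags and
#'   the truncation bounds used.
#' @export
ipw_weights <- function(model, label = model$label, stabilize = TRUE,
                        truncate = c(0.01, 0.99)) {
  e <- model$fitted
  if (any(e <= 0 | e >= 1)) stop("propensities must lie strictly in (0,1)")
  y <- as.numeric(label)
  w <- ifelse(y == 1, 1 / e, 1 / (1 - e))
  if (stabilize) {
    prev <- mean(y)
    w <- ifelse(y == 1, prev * w, (1 - prev) * w)
  }
  bounds <- NULL
  if (!is.null(truncate)) {
    bounds <- stats::quantile(w, truncate, names = FALSE)
    w <- pmin(pmax(w, bounds[1]), bounds[2])
  }
  structure(list(weights = w, stabilized = stabilize,
                 truncation_bounds = bounds, label = y),
            class = "ipw_weights")
}

#' Covariate balance diagnostics under weighting
#'
#' Standardized mean differences (weighted and unweighted) between the two
#' serostatus groups: the (weighted) mean difference divided by the pooled
#' unweighted standard deviation. Binary covariates use proportions. A zero
#' pooled SD yields `NA`.
#'
#' @param covariates Data frame of subjects.
#' @param label Binary group label.
#' @param weights Positive weights (an `ipw_weights` object or numeric).
#' @param covariate_set Covariate names to diagnose.
#' @return Data frame with `covariate`, `smd_unweighted`, `smd_weighted`.
#' @export
balance_diagnostics <- function(covariates, label, weights,
                                covariate_set = propensity_covariates()) {
  if (inherits(weights, "ipw_weights")) weights <- weights$weights
  y <- as.numeric(label)
  X <- .propensity_design(covariates, covariate_set, drop_constant = FALSE)
  wmean <- function(v, w) sum(v * w) / sum(w)
  rows <- lapply(colnames(X), function(nm) {
    v <- X[, nm]
    v1 <- v[y == 1]; v0 <- v[y == 0]
    sd_pool <- sqrt((stats::var(v1) + stats::var(v0)) / 2)
    if (!is.finite(sd_pool) || sd_pool == 0)
      return(data.frame(covariate = nm, smd_unweighted = NA_real_,
                        smd_weighted = NA_real_))
    data.frame(covariate = nm,
               smd_unweighted = (mean(v1) - mean(v0)) / sd_pool,
               smd_weighted = (wmean(v1, weights[y == 1]) -
                               wmean(v0, weights[y == 0])) / sd_pool)
  })
  do.call(rbind, rows)
}
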
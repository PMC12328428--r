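#' Default CyTOF T cell marker panel
#'
#' Twenty-five surface/functional markers typical of a T cell-focused mass
#' cytometry panel, used as column names by the synthetic cohort generator.
#'
#' @return Character vector of length 25.
#' @export
default_marker_panel <- function() {
  c("CD3", "CD4", "CD8", "CD45RA", "CD45RO", "CCR7", "CD25", "CD127",
    "PD-1", "CXCR5", "ICOS", "CD38", "HLA-DR", "CD161", "TIM-3", "CTLA-4",
    "CXCR3", "CCR6", "CCR4", "CD27", "CD28", "CD57", "CD56", "TCRgd", "CD20")
}

#' Default planted cluster-abundance effects
#'
#' Places six discriminative clusters (log-fold effects of seropositive vs
#' seronegative status on cluster abundance) with alternating sign and
#' magnitude 1.2, spread across the cluster index range.
#'
#' @param n_clusters Number of ground-truth clusters.
#' @return Named numeric vector mapping 0-based cluster index to log-fold
#'   effect.
#' @export
default_effect_map <- function(n_clusters = 44) {
  idx <- c(2, 7, 13, 21, 28, 35)
  idx <- idx[idx < n_clusters]
  if (length(idx) < 6) idx <- seq_len(min(6, n_clusters)) - 1
  eff <- rep(c(1.2, -1.2), length.out = length(idx))
  stats::setNames(eff, as.character(idx))
}

#' Configuration for a synthetic CyTOF cohort
#'
#' Defines the cohort conditions emulated by the generator: subject counts in
#' the three groups (healthy controls, seronegative RA, seropositive RA),
#' panel size, number of ground-truth T cell clusters, planted abundance
#' effects, covariate confounding, and compositional dispersion.
#'
#' Cluster abundances are modelled as Dirichlet-multinomial: each subject's
#' Dirichlet mean is a softmax of baseline cluster log-proportions plus the
#' planted seropositive effect (log scale) plus covariate-linked shifts scaled
#' by `confounding_strength`. The same covariate score that shifts abundances
#' also tilts the serostatus label odds, so covariates genuinely confound the
#' label-abundance association when `confounding_strength > 0`.
#'
#' @param n_hc,n_sn,n_sp Subject counts (healthy control, seronegative RA,
#'   seropositive RA).
#' @param n_cells_per_subject CD3+ cells simulated per subject.
#' @param n_markers Number of markers on the panel.
#' @param n_clusters Number of ground-truth clusters.
#' @param effect_map Named numeric vector: 0-based cluster index -> log-fold
#'   effect of seropositive vs seronegative status on abundance.
#' @param confounding_strength Non-negative scalar; 0 means the serostatus
#'   label is independent of covariates and covariates do not shift abundances.
#' @param dispersion Dirichlet concentration (larger = less between-subject
#'   compositional noise). The default of 30 reproduces the degree of
#'   between-subject variability under which cluster-based discrimination of
#'   serostatus is good but imperfect, the regime this analysis targets.
#' @param seed Integer seed; identical configs produce identical cohorts.
#' @param marker_names Optional marker names (length `n_markers`).
#' @param centroids Optional cluster x marker centroid matrix on the asinh
#'   scale; drawn uniformly on 0 to 3.5 when `NULL`.
#' @param noise_sd Cell-level Gaussian noise on the asinh scale.
#' @param cofactor arcsinh cofactor used to map to/from the raw scale.
#' @param base_proportions Optional baseline cluster proportions (positive,
#'   length `n_clusters`); drawn log-normally when `NULL`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 17, n_sn = 17, n_sp = 16,
                          n_cells_per_subject = 5000, n_markers = 25,
                          n_clusters = 44,
                          effect_map = default_effect_map(n_clusters),
                          confounding_strength = 1, dispersion = 30,
                          seed = 1L, marker_names = NULL, centroids = NULL,
                          noise_sd = 0.35, cofactor = 5,
                          base_proportions = NULL) {
  stopifnot(n_hc > 0, n_sn > 0, n_sp > 0, n_cells_per_subject > 0,
            n_markers > 0, n_clusters > 0, dispersion > 0,
            confounding_strength >= 0, noise_sd >= 0, cofactor > 0)
  if (length(effect_map)) {
    ki <- suppressWarnings(as.integer(names(effect_map)))
    if (anyNA(ki) || any(ki < 0) || any(ki >= n_clusters))
      stop("effect_map keys must be 0-based cluster indices < n_clusters")
  }
  if (is.null(marker_names)) {
    marker_names <- if (n_markers == 25) default_marker_panel()
                    else sprintf("M%02d", seq_len(n_markers))
  }
  stopifnot(length(marker_names) == n_markers)
  if (!is.null(centroids))
    stopifnot(is.matrix(centroids), nrow(centroids) == n_clusters,
              ncol(centroids) == n_markers)
  if (!is.null(base_proportions)) {
    if (length(base_proportions) != n_clusters || any(base_proportions <= 0))
      stop("base_proportions must be positive and of length n_clusters")
  }
  structure(list(n_hc = n_hc, n_sn = n_sn, n_sp = n_sp,
                 n_cells_per_subject = n_cells_per_subject,
                 n_markers = n_markers, n_clusters = n_clusters,
                 effect_map = effect_map,
                 confounding_strength = confounding_strength,
                 dispersion = dispersion, seed = as.integer(seed),
                 marker_names = marker_names, centroids = centroids,
                 noise_sd = noise_sd, cofactor = cofactor,
                 base_proportions = base_proportions),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d HC / %d SN-RA / %d SP-RA\n", x$n_hc, x$n_sn, x$n_sp))
  cat(sprintf("  %d markers, %d clusters, %d cells/subject\n",
              x$n_markers, x$n_clusters, x$n_cells_per_subject))
  cat(sprintf("  planted effects on %d cluster(s); confounding %.2f; dispersion %.1f; seed %d\n",
              length(x$effect_map), x$confounding_strength, x$dispersion, x$seed))
  invisible(x)
}

# Covariate score driving both label odds and abundance shifts (the confounder)
.covariate_score <- function(cov) {
  z <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  dur <- ifelse(is.na(cov$symptom_duration), 0, log1p(cov$symptom_duration))
  nsaid <- ifelse(is.na(cov$nsaid_use), 0.5, cov$nsaid_use)
  0.6 * z(cov$age) + 0.4 * z(cov$das28crp) + 0.3 * z(dur) +
    0.6 * (nsaid - 0.5) + 0.4 * ((cov$sex == "male") - 0.5)
}

.draw_covariates <- function(config) {
  n <- config$n_hc + config$n_sn + config$n_sp
  n_ra <- config$n_sn + config$n_sp
  group <- c(rep("HC", config$n_hc), rep("RA", n_ra))
  age <- round(pmin(pmax(stats::rnorm(n, 57, 12), 20), 85))
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  das <- ifelse(group == "HC",
                pmax(stats::rnorm(n, 1.0, 0.3), 0),
                pmax(stats::rnorm(n, 4.5, 1.2), 0))
  dur <- ifelse(group == "HC", NA_real_,
                round(exp(stats::rnorm(n, log(12), 0.8)), 1))
  nsaid <- ifelse(group == "HC", NA_integer_,
                  as.integer(stats::runif(n) < 0.5))
  cov <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    group = group, age = age, sex = sex,
                    symptom_duration = dur, nsaid_use = nsaid,
                    das28crp = round(das, 2), stringsAsFactors = FALSE)
  # serostatus: tilt SP membership odds by the covariate score
  score <- .covariate_score(cov)
  ra_idx <- which(group == "RA")
  w <- exp(config$confounding_strength * score[ra_idx])
  sp_idx <- ra_idx[sample.int(length(ra_idx), config$n_sp, prob = w)]
  cov$group[ra_idx] <- "SN"
  cov$group[sp_idx] <- "SP"
  cov$serostatus <- ifelse(cov$group == "SP", 1L,
                           ifelse(cov$group == "SN", 0L, NA_integer_))
  attr(cov, "score") <- score
  cov
}

.effect_vector <- function(config) {
  eff <- numeric(config$n_clusters)
  if (length(config$effect_map))
    eff[as.integer(names(config$effect_map)) + 1L] <- as.numeric(config$effect_map)
  eff
}

.dirichlet_means <- function(config, cov, score) {
  K <- config$n_clusters
  p0 <- config$base_proportions
  if (is.null(p0)) {
    p0 <- exp(stats::rnorm(K, 0, 0.75))
    p0 <- p0 / sum(p0)
    # planted discriminative clusters sit at typical detectable abundances
    # (60th-85th abundance percentiles); an effect on a cluster whose
    # expected per-subject count is near zero would be unobservable at any
    # realistic cell count
    pl <- as.integer(names(config$effect_map)[config$effect_map != 0])
    if (length(pl)) {
      tgt <- stats::quantile(p0, seq(0.60, 0.85, length.out = length(pl)))
      for (i in seq_along(pl)) {
        j <- which.min(abs(p0 - tgt[i]))
        tmp <- p0[pl[i] + 1L]
        p0[pl[i] + 1L] <- p0[j]
        p0[j] <- tmp
      }
    }
  }
  if (any(p0 <= 0)) stop("non-positive Dirichlet mean component")
  p0 <- p0 / sum(p0)
  loadings <- stats::rnorm(K, 0, 0.3)
  eff <- .effect_vector(config)
  means <- t(vapply(seq_len(nrow(cov)), function(i) {
    lp <- log(p0) + eff * as.numeric(cov$group[i] == "SP") +
      config$confounding_strength * score[i] * loadings
    m <- exp(lp - max(lp))
    m / sum(m)
  }, numeric(K)))
  list(p0 = p0, loadings = loadings, means = means)
}

.rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

.new_composition <- function(counts, subject_ids, cluster_ids) {
  rownames(counts) <- subject_ids
  colnames(counts) <- cluster_ids
  fr <- counts / rowSums(counts)
  structure(list(counts = counts, fractions = fr,
                 subject_ids = subject_ids, cluster_ids = cluster_ids),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("Composition table: %d subjects x %d clusters (counts + fractions)\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Simulate a subject-by-cluster composition cohort
#'
#' Fast generator path that skips cell-level simulation: draws clinical
#' covariates, serostatus labels confounded with those covariates, and
#' Dirichlet-multinomial cluster counts whose subject-level Dirichlet means
#' carry the planted seropositive-vs-seronegative log-fold effects.
#'
#' @param config A [cohort_config()].
#' @return List with `covariates` (data frame), `composition`
#'   (`composition_table`: integer counts plus row-normalized fractions) and
#'   `truth` (baseline proportions, per-subject true proportions, confounder
#'   loadings and score, and the discriminative cluster set).
#' @export
simulate_composition <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cov <- .draw_covariates(config)
  score <- attr(cov, "score")
  dm <- .dirichlet_means(config, cov, score)
  n <- nrow(cov)
  K <- config$n_clusters
  props <- matrix(0, n, K)
  counts <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    q <- .rdirichlet_row(config$dispersion * dm$means[i, ])
    props[i, ] <- q
    counts[i, ] <- as.integer(stats::rmultinom(1, config$n_cells_per_subject, q))
  }
  cluster_ids <- sprintf("TCL%02d", seq_len(K) - 1L)
  truth <- list(base_proportions = dm$p0,
                dirichlet_means = dm$means,
                true_subject_proportions = props,
                confound_loadings = dm$loadings,
                covariate_score = score,
                discriminative_set = as.integer(
                  names(config$effect_map)[config$effect_map != 0]))
  list(covariates = cov,
       composition = .new_composition(counts, cov$subject_id, cluster_ids),
       truth = truth)
}

#' Simulate cell-level CyTOF events for a cohort
#'
#' Draws per-subject cluster labels from the subject's true cluster
#' proportions, then marker values as Gaussian noise around the cluster
#' centroid on the asinh scale, mapped back to the raw intensity scale with
#' `sinh(y) * cofactor` (clamped at zero). arcsinh re-transformation of the
#' raw values therefore recovers approximately Gaussian clusters.
#'
#' @param config A [cohort_config()].
#' @return List with `covariates`, `cells` (named list of cells x markers raw
#'   intensity matrices, one per subject, each carrying a `cluster` attribute
#'   with the true 0-based per-cell labels), and `truth` (including
#'   `true_cluster_centroids` on the asinh scale).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_clusters > config$n_cells_per_subject)
    stop("n_clusters exceeds cells per subject")
  set.seed(config$seed)
  cov <- .draw_covariates(config)
  score <- attr(cov, "score")
  dm <- .dirichlet_means(config, cov, score)
  K <- config$n_clusters
  centroids <- config$centroids
  if (is.null(centroids))
    centroids <- matrix(stats::runif(K * config$n_markers, 0, 3.5),
                        K, config$n_markers)
  rownames(centroids) <- sprintf("TCL%02d", seq_len(K) - 1L)
  colnames(centroids) <- config$marker_names
  n <- nrow(cov)
  props <- matrix(0, n, K)
  cells <- vector("list", n)
  names(cells) <- cov$subject_id
  for (i in seq_len(n)) {
    q <- .rdirichlet_row(config$dispersion * dm$means[i, ])
    props[i, ] <- q
    lab <- sample.int(K, config$n_cells_per_subject, replace = TRUE, prob = q)
    y <- centroids[lab, , drop = FALSE]
    if (config$noise_sd > 0)
      y <- y + matrix(stats::rnorm(length(y), 0, config$noise_sd),
                      nrow(y), ncol(y))
    raw <- pmax(sinh(y) * config$cofactor, 0)
    colnames(raw) <- config$marker_names
    attr(raw, "cluster") <- lab - 1L
    attr(raw, "subject_id") <- cov$subject_id[i]
    cells[[i]] <- raw
  }
  truth <- list(true_cluster_centroids = centroids,
                base_proportions = dm$p0,
                true_subject_proportions = props,
                confound_loadings = dm$loadings,
                covariate_score = score,
                discriminative_set = as.integer(
                  names(config$effect_map)[config$effect_map != 0]))
  list(covariates = cov, cells = cells, truth = truth)
}

#' Write cohort tables as delimited text
#'
#' Writes the covariate table and composition counts/fractions as CSV files
#' with a header row, plus the ground truth as an RDS sidecar for test
#' harnesses.
#'
#' @param cohort Result of [simulate_composition()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(covariates = file.path(dir, "covariates.csv"),
             counts = file.path(dir, "composition_counts.csv"),
             fractions = file.path(dir, "composition_fractions.csv"),
             truth = file.path(dir, "ground_truth.rds"))
  utils::write.csv(cohort$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(data.frame(subject_id = cohort$composition$subject_ids,
                              cohort$composition$counts, check.names = FALSE),
                   paths["counts"], row.names = FALSE)
  utils::write.csv(data.frame(subject_id = cohort$composition$subject_ids,
                              cohort$composition$fractions, check.names = FALSE),
                   paths["fractions"], row.names = FALSE)
  saveRDS(cohort$truth, paths["truth"])
  invisible(paths)
}

#' Read a composition table written by [write_cohort()]
#'
#' @param counts_path CSV with a `subject_id` column and one integer column
#'   per cluster.
#' @return A `composition_table`.
#' @export
read_composition <- function(counts_path) {
  df <- utils::read.csv(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(counts) <- "integer"
  .new_composition(counts, df$subject_id, colnames(counts))
}
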
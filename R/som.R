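#' arcsinh transform of raw cytometry intensities
#'
#' Elementwise `asinh(x / cofactor)`, the standard variance-stabilizing
#' preprocessing for mass cytometry (cofactor 5 by convention). Monotone and
#' order-preserving. Accepts a matrix or a list of per-subject matrices;
#' per-cell attributes (`cluster`, `subject_id`) are preserved.
#'
#' @param x Non-negative matrix (cells x markers) or list of such matrices.
#' @param cofactor Positive divisor applied before `asinh`.
#' @return Transformed matrix/list with the same shape.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (cofactor <= 0) stop("cofactor must be positive")
  tr1 <- function(m) {
    out <- asinh(m / cofactor)
    attr(out, "cluster") <- attr(m, "cluster")
    attr(out, "subject_id") <- attr(m, "subject_id")
    out
  }
  if (is.list(x)) lapply(x, tr1) else tr1(x)
}

# squared Euclidean BMU search; ties broken by lowest node index
.bmu <- function(x, codebook) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(codebook))) -
    2 * x %*% t(codebook) +
    outer(rep(1, nrow(x)), rowSums(codebook^2))
  max.col(-d2, ties.method = "first")
}

#' Train a batch self-organizing map
#'
#' Batch SOM over pooled (transformed) cell events: nodes live on a
#' rectangular grid, each epoch assigns every event to its best-matching
#' unit and replaces each node's codebook vector by the Gaussian-
#' neighborhood-weighted mean of the events, with the neighborhood radius
#' shrinking linearly from half the grid diagonal to 1 over the epochs.
#' Batch (rather than online) updates make training deterministic given the
#' seed, which only controls the initialization sample.
#'
#' @param x Events x markers numeric matrix on the transformed scale.
#' @param grid_rows,grid_cols SOM grid dimensions (default 10 x 10).
#' @param epochs Training epochs (default 10).
#' @param seed Seed for codebook initialization.
#' @return Object of class `som_model`: `codebook`
#'   (nodes x markers), grid dimensions, per-epoch quantization error
#'   `qe` (mean squared distance of events to their BMU), and training
#'   metadata.
#' @export
som_train <- function(x, grid_rows = 10, grid_cols = 10, epochs = 10,
                      seed = 1L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("NaN/NA in events")
  if (!nrow(x)) stop("empty input")
  n_nodes <- grid_rows * grid_cols
  if (nrow(x) < n_nodes) stop("need at least grid_rows*grid_cols events")
  set.seed(seed)
  codebook <- x[sample.int(nrow(x), n_nodes), , drop = FALSE]
  # grid coordinates and inter-node squared distances
  gr <- expand.grid(row = seq_len(grid_rows), col = seq_len(grid_cols))
  gd2 <- as.matrix(stats::dist(gr))^2
  sigma0 <- sqrt(grid_rows^2 + grid_cols^2) / 2
  sigmas <- if (epochs == 1) sigma0 else
    seq(sigma0, 1, length.out = epochs)
  qe <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    bmu <- .bmu(x, codebook)
    # per-node sufficient statistics
    S <- rowsum(x, bmu, reorder = FALSE)
    cnt <- as.numeric(table(factor(bmu, levels = seq_len(n_nodes))))
    Sfull <- matrix(0, n_nodes, ncol(x))
    Sfull[as.integer(rownames(S)), ] <- S
    H <- exp(-gd2 / (2 * sigmas[ep]^2))
    denom <- drop(H %*% cnt)
    upd <- (H %*% Sfull) / denom
    nonzero <- denom > 0
    codebook[nonzero, ] <- upd[nonzero, ]
    bmu2 <- .bmu(x, codebook)
    qe[ep] <- mean(rowSums((x - codebook[bmu2, , drop = FALSE])^2))
  }
  colnames(codebook) <- colnames(x)
  structure(list(codebook = codebook, grid_rows = grid_rows,
                 grid_cols = grid_cols, epochs = epochs, seed = seed,
                 qe = qe),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("Batch SOM: %dx%d grid, %d markers, %d epochs (final QE %.4g)\n",
              x$grid_rows, x$grid_cols, ncol(x$codebook), x$epochs,
              x$qe[length(x$qe)]))
  invisible(x)
}

#' Hierarchical metaclustering of SOM nodes
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' codebook vectors, cut at `K` metaclusters. Deterministic; the merge
#' history is recorded.
#'
#' @param som A [som_train()] model.
#' @param K Target metacluster count, between 1 and the number of nodes.
#' @return Object of class `metacluster_assignment`: `node_to_cluster`
#'   (0-based cluster id per node), `K`, and the `hclust` merge record.
#' @export
metacluster <- function(som, K) {
  n_nodes <- nrow(som$codebook)
  if (K < 1 || K > n_nodes) stop("K out of range")
  hc <- stats::hclust(stats::dist(som$codebook), method = "average")
  cl <- stats::cutree(hc, k = K)
  structure(list(node_to_cluster = as.integer(cl) - 1L, K = as.integer(K),
                 linkage_record = hc),
            class = "metacluster_assignment")
}

#' Per-subject cluster counts and fractions
#'
#' Maps every cell to its best-matching SOM node (ties to the lowest node
#' index), then to that node's metacluster, and tabulates counts and
#' row-normalized fractions per subject.
#'
#' @param cells Named list of per-subject cells x markers matrices on the
#'   same transformed scale and marker set as the SOM codebook.
#' @param som A [som_train()] model.
#' @param assignment A [metacluster()] assignment.
#' @return A `composition_table` (subject x cluster counts and fractions).
#' @export
assign_and_count <- function(cells, som, assignment) {
  stopifnot(is.list(cells), length(cells) > 0)
  K <- assignment$K
  markers <- colnames(som$codebook)
  counts <- t(vapply(cells, function(m) {
    if (!nrow(m)) stop("subject with zero cells")
    if (!is.null(colnames(m)) && !is.null(markers) &&
        !identical(colnames(m), markers))
      stop("marker columns do not match the SOM codebook")
    if (ncol(m) != ncol(som$codebook)) stop("marker count mismatch")
    cl <- assignment$node_to_cluster[.bmu(as.matrix(m), som$codebook)]
    tabulate(cl + 1L, nbins = K)
  }, integer(K)))
  ids <- names(cells) %||% sprintf("S%03d", seq_along(cells))
  .new_composition(matrix(as.integer(counts), nrow(counts),
                          dimnames = list(ids, sprintf("TCL%02d",
                                                       seq_len(K) - 1L))),
                   ids, sprintf("TCL%02d", seq_len(K) - 1L))
}

#' Per-metacluster marker expression profiles
#'
#' Median marker expression (transformed scale) per metacluster over all
#' assigned cells, plus cluster sizes. Clusters receiving no cells are
#' flagged with missing profiles.
#'
#' @param cells Named list of per-subject matrices (transformed scale).
#' @param som A [som_train()] model.
#' @param assignment A [metacluster()] assignment.
#' @return List with `medians` (K x markers, `NA` rows for empty clusters),
#'   `sizes`, and `empty` (logical flags).
#' @export
cluster_profiles <- function(cells, som, assignment) {
  pooled <- do.call(rbind, lapply(cells, as.matrix))
  cl <- assignment$node_to_cluster[.bmu(pooled, som$codebook)]
  K <- assignment$K
  med <- matrix(NA_real_, K, ncol(pooled),
                dimnames = list(sprintf("TCL%02d", seq_len(K) - 1L),
                                colnames(som$codebook)))
  sizes <- tabulate(cl + 1L, nbins = K)
  for (k in seq_len(K) - 1L) {
    if (sizes[k + 1L] > 0)
      med[k + 1L, ] <- apply(pooled[cl == k, , drop = FALSE], 2,
                             stats::median)
  }
  list(medians = med, sizes = sizes, empty = sizes == 0)
}

#' Gate activated (CD38+ HLA-DR+) cells
#'
#' Returns the subset of cells above per-marker activation thresholds. By
#' default the thresholds are the 90th percentiles of the pooled
#' healthy-control values for each gating marker; explicit thresholds
#' override this. The thresholds used are recorded on the result.
#'
#' @param cells Named list of per-subject matrices (transformed scale) with
#'   marker column names.
#' @param covariates Optional covariate data frame with `subject_id` and
#'   `group`; used to pool HC subjects for default thresholds. When absent,
#'   all subjects are pooled.
#' @param markers Gating marker names (default CD38 and HLA-DR).
#' @param thresholds Optional named numeric thresholds per gating marker.
#' @param percentile Reference percentile for default thresholds.
#' @return List of gated per-subject matrices (possibly with zero rows),
#'   with per-cell `cluster` attributes subset accordingly and the
#'   `thresholds` attached as an attribute.
#' @export
gate_activated <- function(cells, covariates = NULL,
                           markers = c("CD38", "HLA-DR"),
                           thresholds = NULL, percentile = 0.9) {
  cn <- colnames(cells[[1]])
  if (!all(markers %in% cn))
    stop("missing gating marker column(s): ",
         paste(setdiff(markers, cn), collapse = ", "))
  if (is.null(thresholds)) {
    ref_ids <- names(cells)
    if (!is.null(covariates)) {
      hc <- covariates$subject_id[covariates$group == "HC"]
      if (length(hc)) ref_ids <- intersect(ref_ids, hc)
    }
    pooled <- do.call(rbind, lapply(cells[ref_ids],
                                    function(m) m[, markers, drop = FALSE]))
    thresholds <- apply(pooled, 2, stats::quantile, probs = percentile)
  }
  thresholds <- thresholds[markers]
  gated <- lapply(cells, function(m) {
    keep <- rep(TRUE, nrow(m))
    for (mk in markers) keep <- keep & (m[, mk] > thresholds[[mk]])
    out <- m[keep, , drop = FALSE]
    if (!is.null(attr(m, "cluster")))
      attr(out, "cluster") <- attr(m, "cluster")[keep]
    attr(out, "subject_id") <- attr(m, "subject_id")
    out
  })
  attr(gated, "thresholds") <- thresholds
  gated
}
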
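#' Generate labelled point clouds whose geometry tracks a hierarchy
#'
#' Creates a synthetic sample x feature matrix with one Gaussian blob per
#' graph node. Class centroids interpolate between a hierarchy-faithful
#' layout and a random one: at `hierarchy_fidelity = 1` the centroids are a
#' classical multidimensional scaling of the label-graph distance matrix
#' (with the Cailliez additive correction, so centroid distances are a
#' monotone — Spearman 1 — transform of graph distances for any connected
#' graph); at fidelity 0 they are i.i.d. Gaussian, carrying no hierarchical
#' signal. Disconnected label pairs are placed at twice `maxdist` before the
#' scaling. Points are the centroid plus isotropic Gaussian noise.
#'
#' This emulates the structure of a labelled expression matrix whose latent
#' geometry partially reflects a known class hierarchy; it does not model
#' count noise, sparsity/dropout or batch effects of real single-cell data.
#'
#' @param hg a [hierarchy_graph()]; one class per node.
#' @param n_per_class points per class (default 50).
#' @param n_features feature dimension (default 30).
#' @param hierarchy_fidelity in `[0, 1]`: weight of the hierarchy-faithful
#'   centroid layout (default 0.7).
#' @param noise_sd within-class standard deviation per feature (default 1).
#' @param centroid_scale root-mean-square pairwise centroid distance of each
#'   layout before mixing (default 5, i.e. clearly but not perfectly
#'   separated classes at the default noise).
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with `X` (matrix, rownames are sample ids) and `assignment`,
#'   a data.frame with columns `sample_id`, `label`.
#' @export
make_hierarchical_blobs <- function(hg, n_per_class = 50, n_features = 30,
                                    hierarchy_fidelity = 0.7, noise_sd = 1,
                                    centroid_scale = 5, seed = NULL) {
  stopifnot(inherits(hg, "hierarchy_graph"))
  if (n_per_class < 1L) stop("'n_per_class' must be >= 1")
  if (hierarchy_fidelity < 0 || hierarchy_fidelity > 1) {
    stop("'hierarchy_fidelity' must lie in [0, 1]")
  }
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (!is.null(seed)) set.seed(seed)
  labs <- hg$nodes
  L <- length(labs)
  if (n_features < L - 1L) {
    stop("'n_features' must be at least the number of classes minus one")
  }

  scale_rms <- function(C) {
    pd <- stats::dist(C)
    r <- sqrt(mean(pd^2))
    if (r == 0) C else C * (centroid_scale / r)
  }

  # hierarchy-faithful layout
  Dg <- path_matrix(hg)$dist
  if (any(!is.finite(Dg))) Dg[!is.finite(Dg)] <- 2 * max(hg$maxdist, 1)
  M <- matrix(0, L, n_features)
  if (L > 1L) {
    fit <- suppressWarnings(stats::cmdscale(stats::as.dist(Dg),
                                            k = L - 1L, add = TRUE))
    pts <- fit$points
    keep <- seq_len(min(ncol(pts), n_features))
    M[, keep] <- pts[, keep, drop = FALSE]
    M <- scale_rms(M)
  }
  # random layout
  R <- matrix(stats::rnorm(L * n_features), L, n_features)
  if (L > 1L) R <- scale_rms(R)

  centroids <- hierarchy_fidelity * M + (1 - hierarchy_fidelity) * R
  rownames(centroids) <- labs

  n <- L * n_per_class
  label <- rep(labs, each = n_per_class)
  X <- centroids[label, , drop = FALSE] +
    matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
  ids <- sprintf("s%0*d", nchar(n), seq_len(n))
  rownames(X) <- ids
  colnames(X) <- paste0("f", seq_len(n_features))
  list(X = X,
       assignment = data.frame(sample_id = ids, label = label,
                               stringsAsFactors = FALSE))
}

#' Replace a fraction of one class's labels with a dummy label
#'
#' Semi-supervised fixture: relabels a seeded uniform random subset (exactly
#' `round(fraction * n_target)` samples) of the target class with a dummy
#' label that must not be a node of the hierarchy graph. Since off-graph
#' labels keep a distancing factor of 1 against everything, the relabelled
#' samples retain their raw pairwise distances at any strength.
#'
#' @param assignment data.frame with columns `sample_id`, `label` (as from
#'   [make_hierarchical_blobs()]).
#' @param target_label the class whose labels are replaced.
#' @param fraction fraction in `[0, 1]` of target samples to relabel.
#' @param dummy replacement label; must not collide with a graph node.
#' @param hg optional [hierarchy_graph()] used to check the collision.
#' @param seed integer seed for the subset draw.
#' @return the assignment with relabelled rows.
#' @export
dropout_labels <- function(assignment, target_label, fraction, dummy = "dummy",
                           hg = NULL, seed = NULL) {
  stopifnot(is.data.frame(assignment), "label" %in% names(assignment))
  if (fraction < 0 || fraction > 1) stop("'fraction' must lie in [0, 1]")
  if (!is.null(hg) && dummy %in% hg$nodes) {
    stop("dummy label '", dummy, "' is a node of the hierarchy graph; it ",
         "must be absent from the graph so the relabelled samples are ",
         "excluded from the hierarchical distancing")
  }
  idx <- which(assignment$label == target_label)
  if (length(idx) == 0L) stop("target label '", target_label, "' not present")
  n_swap <- round(fraction * length(idx))
  if (n_swap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    swap <- if (n_swap == length(idx)) idx else sample(idx, n_swap)
    assignment$label[swap] <- dummy
  }
  assignment
}

#' Sum-of-expression label classifier
#'
#' A deliberately simple predictor for probability-weighted supervision: for
#' each sample, the features (e.g. UMI counts of marker genes) belonging to
#' each hierarchy node's gene set are summed; the predicted label is the node
#' with the largest sum and its probability is that sum divided by the total
#' over all nodes. Ties are broken by the first node in `names(gene_sets)`
#' order (a message reports how many samples were tied). A sample with total
#' 0 over all gene sets gets a missing label with probability 0.
#'
#' @param X nonnegative sample x feature matrix.
#' @param gene_sets named list mapping node label to a vector of feature
#'   indices or feature (column) names; every set must be nonempty.
#' @return data.frame with columns `sample_id`, `label`, `probability`.
#' @export
expression_classifier <- function(X, gene_sets) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be nonnegative (count-like)")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    stop("'gene_sets' must be a named list (node -> feature set)")
  }
  if (any(lengths(gene_sets) == 0L)) stop("every gene set must be nonempty")
  sums <- vapply(gene_sets, function(g) {
    if (is.character(g)) g <- match(g, colnames(X))
    if (anyNA(g) || any(g < 1L) || any(g > ncol(X))) {
      stop("gene set refers to unknown features")
    }
    rowSums(X[, g, drop = FALSE])
  }, numeric(nrow(X)))
  sums <- matrix(sums, nrow = nrow(X),
                 dimnames = list(rownames(X), names(gene_sets)))
  total <- rowSums(sums)
  best <- max.col(sums, ties.method = "first")
  ties <- rowSums(sums == sums[cbind(seq_len(nrow(sums)), best)]) > 1L
  ties <- ties & total > 0
  if (any(ties)) {
    message(sum(ties), " sample(s) had tied top scores; first node in ",
            "gene-set order used")
  }
  label <- names(gene_sets)[best]
  probability <- ifelse(total > 0, sums[cbind(seq_len(nrow(sums)), best)] / total, 0)
  label[total == 0] <- NA_character_
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(X)))
  data.frame(sample_id = ids, label = label, probability = probability,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variance filter and per-sample min-max normalization
#'
#' The preprocessing applied to count-like matrices before distance
#' computation: feature columns with variance below `min_variance` are
#' dropped, then each sample row is min-max normalized to `[0, 1]` (a
#' constant row maps to all zeros).
#'
#' @param X nonnegative sample x feature matrix.
#' @param min_variance variance threshold (default 0.1).
#' @return the filtered, row-normalized matrix.
#' @export
preprocess_counts <- function(X, min_variance = 0.1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be nonnegative")
  v <- apply(X, 2L, stats::var)
  keep <- v >= min_variance
  if (!any(keep)) {
    stop("all features fall below the variance threshold ", min_variance)
  }
  X <- X[, keep, drop = FALSE]
  rng <- t(apply(X, 1L, range))
  span <- rng[, 2L] - rng[, 1L]
  out <- (X - rng[, 1L]) / ifelse(span == 0, 1, span)
  out[span == 0, ] <- 0
  out
}
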
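#' Embed a (possibly hierarchy-perturbed) distance matrix
#'
#' Runs a dimensionality-reduction backend on a precomputed distance matrix.
#' t-SNE and UMAP consume the matrix through their precomputed-distance
#' interfaces (packages \pkg{Rtsne} and \pkg{uwot}); PHATE requires the
#' optional \pkg{phateR} package; PCA is always available and is executed on
#' the matrix `H` itself (each row of `H` is treated as the sample's feature
#' vector), which makes the effect of the perturbation directly visible
#' without any stochastic optimisation.
#'
#' With a fixed `seed`, two runs on identical inputs produce identical
#' coordinates for every backend.
#'
#' @param H symmetric distance matrix with zero diagonal, typically from
#'   [hier_distances()] or [apply_theta()].
#' @param method `"pca"`, `"tsne"`, `"umap"` or `"phate"`.
#' @param n_components embedding dimension (default 2).
#' @param seed integer seed applied before any stochastic backend runs.
#' @param perplexity t-SNE perplexity (default `max(5, n/20)` capped to the
#'   Rtsne feasibility bound).
#' @param n_neighbors UMAP neighbourhood size (default 15, capped at `n - 1`).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param knn,alpha PHATE neighbourhood size and decay (passed through).
#' @param ... further arguments passed to the backend.
#' @return an object of class `hdr_embedding`: list with `coords`
#'   (sample x n_components matrix), `method`, `seed`, `params`, and the
#'   perturbation `config` when `H` carries one.
#' @details At high strength many pairwise distances are strongly contracted
#'   and large neighbourhoods crowd the embedding; if the strength recorded on
#'   `H` exceeds 0.5 and the neighbourhood parameter exceeds `n/10`, a warning
#'   suggests lowering perplexity / `n_neighbors` / `knn`. The parameter is
#'   never changed automatically.
#' @export
hdr_embed <- function(H, method = c("pca", "tsne", "umap", "phate"),
                      n_components = 2, seed = NULL,
                      perplexity = NULL, n_neighbors = NULL, min_dist = 0.1,
                      knn = 5, alpha = 40, ...) {
  method <- match.arg(method)
  H <- as.matrix(H)
  n <- nrow(H)
  if (n != ncol(H)) stop("H must be square")
  if (max(abs(H - t(H))) > 1e-8) {
    stop("H must be a symmetric distance matrix")
  }
  if (any(!is.finite(H))) stop("H contains non-finite entries")
  strength <- attr(H, "strength")

  nb <- switch(method,
    tsne = if (is.null(perplexity)) min(max(5, n / 20), (n - 2) / 3) else perplexity,
    umap = if (is.null(n_neighbors)) min(15L, n - 1L) else n_neighbors,
    phate = knn,
    NULL
  )
  if (!is.null(strength) && !is.null(nb) && strength > 0.5 && nb > n / 10) {
    warning(sprintf(
      "strength = %.3g with neighbourhood parameter %g > n/10 = %g: strongly ",
      strength, nb, n / 10),
      "contracted distances crowd large neighbourhoods; consider lowering ",
      "perplexity/n_neighbors/knn", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  coords <- switch(
    method,
    pca = {
      p <- stats::prcomp(H, center = TRUE, scale. = FALSE)
      k <- min(n_components, ncol(p$x))
      out <- p$x[, seq_len(k), drop = FALSE]
      if (k < n_components) { # degenerate rank: pad with zeros
        out <- cbind(out, matrix(0, n, n_components - k))
      }
      out
    },
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE)) {
        stop("the t-SNE backend requires the 'Rtsne' package")
      }
      fit <- Rtsne::Rtsne(H, is_distance = TRUE, dims = n_components,
                          perplexity = nb, check_duplicates = FALSE, ...)
      fit$Y
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE)) {
        stop("the UMAP backend requires the 'uwot' package")
      }
      uwot::umap(stats::as.dist(H), n_neighbors = nb,
                 n_components = n_components, min_dist = min_dist,
                 n_threads = 1, n_sgd_threads = 1, ...)
    },
    phate = {
      if (!requireNamespace("phateR", quietly = TRUE)) {
        stop("the PHATE backend requires the optional 'phateR' package; ",
             "install it or use method = 'pca', 'tsne' or 'umap'")
      }
      fit <- phateR::phate(H, knn.dist.method = "precomputed", knn = knn,
                           decay = alpha, ndim = n_components, seed = seed, ...)
      fit$embedding
    }
  )
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("backend produced non-finite coordinates")
  rownames(coords) <- rownames(H)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(
    list(coords = coords, method = method, seed = seed,
         params = list(perplexity = if (method == "tsne") nb,
                       n_neighbors = if (method == "umap") nb,
                       min_dist = if (method == "umap") min_dist,
                       knn = if (method == "phate") knn,
                       alpha = if (method == "phate") alpha,
                       n_components = n_components),
         config = attr(H, "config")),
    class = "hdr_embedding"
  )
}

#' @export
print.hdr_embedding <- function(x, ...) {
  cat(sprintf("hdr_embedding: %d samples x %d dims (method = %s, seed = %s)\n",
              nrow(x$coords), ncol(x$coords), x$method,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# accept either an hdr_embedding or a bare coordinate matrix
.embedding_coords <- function(x) {
  if (inherits(x, "hdr_embedding")) x$coords else as.matrix(x)
}

#' Verify the kernel-level effect of the distance perturbation
#'
#' The perturbation acts on kernels as exponent weighting. For the Gaussian
#' kernel of t-SNE on squared distances,
#' \eqn{\hat{s}_{j|i} = \exp(-\theta_{ij} d^2 / 2\sigma^2) = (s_{j|i})^{\theta_{ij}}};
#' for the PHATE alpha-decay kernel on raw distances,
#' \eqn{\hat{s}_{j|i} = \exp(-(\theta_{ij} d/\sigma)^\alpha) = (s_{j|i})^{\theta_{ij}^\alpha}},
#' which preserves the role of the decay exponent. This diagnostic evaluates
#' both sides of the relevant identity on every pair and reports the maximum
#' absolute deviation (machine-precision small when the implementation is
#' consistent).
#'
#' @param D raw distance matrix (unsquared for `"phate"`, squared convention
#'   handled internally for `"tsne"`).
#' @param theta a [theta_matrix()] or plain matrix of factors in `[0, 1]`.
#' @param method `"tsne"` or `"phate"`.
#' @param sigma kernel bandwidth (fixed, shared across points for the check).
#' @param alpha PHATE decay exponent.
#' @return list with `max_deviation`, `method`, and the two kernel matrices
#'   `modified` and `reference`.
#' @export
kernel_check <- function(D, theta, method = c("tsne", "phate"),
                         sigma = 1, alpha = 2) {
  method <- match.arg(method)
  D <- as.matrix(D)
  th <- unclass(as.matrix(theta))
  stopifnot(all(dim(D) == dim(th)))
  if (method == "tsne") {
    s <- exp(-D^2 / (2 * sigma^2))
    modified <- exp(-th * D^2 / (2 * sigma^2))
    reference <- s^th
  } else {
    s <- exp(-(D / sigma)^alpha)
    modified <- exp(-(th * D / sigma)^alpha)
    reference <- s^(th^alpha)
  }
  list(method = method,
       max_deviation = max(abs(modified - reference)),
       modified = modified, reference = reference)
}
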
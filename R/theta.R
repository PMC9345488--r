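#' Configuration of the hierarchical distancing factor
#'
#' Bundles the tunable parameters that shape the factor \eqn{\theta_{ij}}
#' applied to each pairwise distance.
#'
#' @param strength interpolation weight `str` in `[0, 1)`: 0 leaves every
#'   distance untouched; values approaching 1 scale each pair fully by its
#'   normalized label-graph distance. `strength = 1` is rejected because at
#'   `str = 1` a same-label pair has \eqn{\theta = 0}, its kernel similarity
#'   degenerates to exactly 1 and the pair drops out of the embedding cost;
#'   pass a value such as 0.999 instead.
#' @param self_distance value in `[0, 1]` assigned, after normalization, to
#'   same-label pairs whose label is listed in `avoid_self`. 0 (default)
#'   maximally contracts same-label pairs; 1 disables intra-class contraction
#'   for those labels.
#' @param avoid_self character vector of labels whose same-label pairs use
#'   `self_distance` instead of 0.
#' @param disconnected_distance nonnegative value substituted, before any
#'   min-max rescaling, for label pairs in different graph components. The
#'   default 1 keeps cross-component pairs at their raw distances; values
#'   above 1 exaggerate cross-component separation and (via the min-max
#'   rescaling they trigger) compress within-component contrasts.
#' @param squared whether the Euclidean metric should be squared when
#'   distances are computed for the t-SNE pathway (the convention of the
#'   Gaussian-kernel formulation); not enforced for other methods.
#'
#' @return an object of class `hdr_config`.
#' @export
hdr_config <- function(strength = 0, self_distance = 0,
                       avoid_self = character(), disconnected_distance = 1,
                       squared = TRUE) {
  if (!is.numeric(strength) || length(strength) != 1L || is.na(strength) ||
      strength < 0 || strength >= 1) {
    stop("'strength' must lie in [0, 1): at strength = 1 same-label pairs ",
         "get theta = 0, the modified kernel similarity becomes exactly 1 ",
         "and those pairs vanish from the embedding cost; use e.g. 0.999")
  }
  if (!is.numeric(self_distance) || length(self_distance) != 1L ||
      is.na(self_distance) || self_distance < 0 || self_distance > 1) {
    stop("'self_distance' must lie in [0, 1]")
  }
  if (!is.numeric(disconnected_distance) || length(disconnected_distance) != 1L ||
      is.na(disconnected_distance) || disconnected_distance < 0) {
    stop("'disconnected_distance' must be >= 0")
  }
  structure(
    list(strength = strength, self_distance = self_distance,
         avoid_self = as.character(avoid_self),
         disconnected_distance = disconnected_distance,
         squared = isTRUE(squared)),
    class = "hdr_config"
  )
}

#' Normalize a label path matrix to [0, 1]
#'
#' Applies the fixed normalization pipeline to the raw shortest-path matrix:
#' \enumerate{
#'   \item connected off-diagonal pairs are divided by `maxdist`
#'     (label mode) or mapped as `(path - 1) / (maxdist - 1)` (probability
#'     mode);
#'   \item disconnected pairs are set to `disconnected_distance` verbatim
#'     (not divided by `maxdist`);
#'   \item if any off-diagonal entry now exceeds 1 (possible only when
#'     `disconnected_distance > 1`), the whole off-diagonal block is min-max
#'     rescaled to `[0, 1]`, which compresses within-component contrasts;
#'   \item diagonal entries are 0, except labels in `avoid_self`, which get
#'     `self_distance` (applied after normalization).
#' }
#'
#' @param pm a [path_matrix()].
#' @param config an [hdr_config()].
#' @param mode `"label"` for the `path/maxdist` scaling used with known
#'   labels, `"probability"` for the `(path-1)/(maxdist-1)` scaling used with
#'   predicted labels. The two conventions are deliberately kept distinct.
#' @return the `path_matrix` with a `normalized` matrix field added, all
#'   entries in `[0, 1]`.
#' @export
normalize_paths <- function(pm, config = hdr_config(),
                            mode = c("label", "probability")) {
  stopifnot(inherits(pm, "path_matrix"), inherits(config, "hdr_config"))
  mode <- match.arg(mode)
  # off-graph labels behave like missing labels: their theta is forced to 1
  # downstream, and they must not perturb the normalization of real pairs
  # (e.g. by dragging a disconnected_distance > 1 into the min-max step)
  on <- !(pm$labels %in% pm$off_graph)
  d <- pm$dist[on, on, drop = FALSE]
  n <- nrow(d)
  norm <- matrix(0, n, n, dimnames = dimnames(d))
  off <- row(d) != col(d)
  fin <- is.finite(d) & off
  md <- pm$maxdist
  expand <- function(sub) {
    # re-embed the on-graph submatrix; off-graph rows/cols act like missing
    # labels (normalized distance 1 off the diagonal, unused downstream)
    full <- matrix(1, length(pm$labels), length(pm$labels),
                   dimnames = list(pm$labels, pm$labels))
    diag(full) <- 0
    full[on, on] <- sub # the submatrix diagonal carries self/avoid_self
    structure(c(pm, list(normalized = full, mode = mode)),
              class = "path_matrix")
  }
  if (md == 0) {
    if (any(fin)) {
      stop("internal: finite off-diagonal path with maxdist = 0")
    }
    warning("maxdist is 0 (single node or edgeless graph): all hierarchical ",
            "distancing factors are 1 and the hierarchy has no effect")
    norm[off] <- 1
    return(expand(norm))
  }
  if (mode == "label") {
    norm[fin] <- d[fin] / md
  } else {
    if (md == 1) {
      warning("maxdist = 1: the probability-mode scaling (path-1)/(maxdist-1) ",
              "is 0/0; adjacent labels are assigned path term 0")
      norm[fin] <- 0
    } else {
      norm[fin] <- (d[fin] - 1) / (md - 1)
    }
  }
  norm[off & !fin] <- config$disconnected_distance
  if (any(norm[off] > 1)) {
    rng <- range(norm[off])
    norm[off] <- (norm[off] - rng[1L]) / (rng[2L] - rng[1L])
  }
  diag(norm) <- 0
  sel <- rownames(norm) %in% config$avoid_self
  if (any(sel)) {
    idx <- which(sel)
    norm[cbind(idx, idx)] <- config$self_distance
  }
  expand(norm)
}

# label-level theta broadcast to samples via integer label codes; lab_codes
# is NA for MISSING/off-graph samples, whose rows/columns are forced to 1
.broadcast_theta <- function(theta_lab, lab_codes, n) {
  th <- matrix(1, n, n)
  ok <- !is.na(lab_codes)
  if (any(ok)) {
    th[ok, ok] <- theta_lab[lab_codes[ok], lab_codes[ok], drop = FALSE]
  }
  th
}

#' Hierarchical distancing factor matrix
#'
#' Builds the sample-by-sample factor matrix \eqn{\theta}. With known labels
#' (no `probabilities`),
#' \deqn{\theta_{ij} = (1 - str) + str \cdot \bar{d}(i', j')}
#' where \eqn{\bar d} is the normalized label-graph distance between the two
#' samples' labels. With per-sample label probabilities, the strength of each
#' pair is weighted by \eqn{m_{ij} = \min(p_i, p_j)}:
#' \deqn{\theta_{ij} = (1 - m_{ij} str) + m_{ij} str \cdot (d(i',j') - 1)/(maxdist - 1)}
#' so that a low-confidence label barely perturbs its sample's distances.
#' In both modes a sample whose label is missing (`NA`) or not a node of the
#' graph keeps \eqn{\theta = 1} against every other sample: its raw distances
#' are maintained.
#'
#' Label-level factors are computed once per label pair and broadcast to
#' sample pairs, so cost is O(L^2 + n^2) not O(n^2) graph queries.
#'
#' @param pm a [path_matrix()] over (at least) the labels that occur.
#' @param labels character vector, one label per sample; `NA` = missing.
#' @param config an [hdr_config()].
#' @param probabilities optional numeric vector in `[0, 1]`, one per sample;
#'   switches to the probability-weighted formula (all samples must have one).
#' @return an object of class `theta_matrix`: the numeric matrix with the
#'   config attached as attribute `config`.
#' @examples
#' hg <- hierarchy_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
#' pm <- path_matrix(hg)
#' th <- theta_matrix(pm, c("A", "B", "C"), hdr_config(strength = 0.999))
#' th[1, 2] # 0.001 + 0.999 * 0.5 = 0.5005
#' @export
theta_matrix <- function(pm, labels, config = hdr_config(),
                         probabilities = NULL) {
  stopifnot(inherits(pm, "path_matrix"), inherits(config, "hdr_config"))
  labels <- as.character(labels)
  labels[!is.na(labels) & labels == ""] <- NA_character_
  n <- length(labels)
  present <- unique(labels[!is.na(labels)])
  missing_from_pm <- setdiff(present, pm$labels)
  # labels never seen by the path matrix are off-graph by construction
  off_graph <- union(pm$off_graph, missing_from_pm)
  str <- config$strength
  mode <- if (is.null(probabilities)) "label" else "probability"
  npm <- normalize_paths(pm, config, mode = mode)
  normd <- npm$normalized
  lab_codes <- match(labels, pm$labels)
  lab_codes[labels %in% off_graph] <- NA_integer_

  if (is.null(probabilities)) {
    theta_lab <- (1 - str) + str * normd
    th <- .broadcast_theta(theta_lab, lab_codes, n)
  } else {
    if (length(probabilities) != n) {
      stop("'probabilities' must have one entry per sample")
    }
    if (anyNA(probabilities[!is.na(lab_codes)])) {
      stop("probability mode requires a probability for every labelled sample")
    }
    if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
      stop("probabilities must lie in [0, 1]")
    }
    p <- probabilities
    p[is.na(p)] <- 0
    ok <- !is.na(lab_codes)
    th <- matrix(1, n, n)
    if (any(ok)) {
      m <- outer(p[ok], p[ok], pmin)
      nd <- normd[lab_codes[ok], lab_codes[ok], drop = FALSE]
      th[ok, ok] <- (1 - m * str) + m * str * nd
    }
  }
  if (pm$maxdist == 0) th[] <- 1 # degenerate graph: no hierarchical effect
  th <- (th + t(th)) / 2 # numerical guard against asymmetry drift
  th <- pmin(pmax(th, 0), 1)
  if (!is.null(names(labels))) {
    dimnames(th) <- list(names(labels), names(labels))
  }
  structure(th, class = c("theta_matrix", class(th)),
            config = config, mode = mode, off_graph = off_graph)
}

#' @export
print.theta_matrix <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("theta_matrix: %d x %d (strength = %g, mode = %s)\n",
              nrow(x), ncol(x), cfg$strength, attr(x, "mode")))
  m <- unclass(x)
  attr(m, "config") <- attr(m, "mode") <- attr(m, "off_graph") <- NULL
  print(m, ...)
  invisible(x)
}

#' Pairwise distance matrix of a data matrix
#'
#' Standard sample-by-sample distances used as the raw input to the
#' hierarchical perturbation. `squared` applies to the Euclidean metric only
#' (the squared-distance convention of the t-SNE Gaussian kernel).
#'
#' @param X numeric sample x feature matrix (finite entries).
#' @param metric one of `"euclidean"`, `"manhattan"`, `"cosine"`,
#'   `"correlation"`, or a function taking two numeric vectors and returning
#'   a nonnegative scalar.
#' @param squared square the Euclidean distances (ignored for other metrics).
#' @return symmetric nonnegative matrix with zero diagonal, attribute
#'   `metric` set to the metric name.
#' @export
pairwise_distances <- function(X, metric = "euclidean", squared = FALSE) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) {
    stop("X must be a finite numeric matrix")
  }
  n <- nrow(X)
  if (is.function(metric)) {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        D[i, j] <- D[j, i] <- metric(X[i, ], X[j, ])
      }
    }
    mname <- "custom"
  } else {
    mname <- match.arg(metric, c("euclidean", "sqeuclidean", "manhattan",
                                 "cosine", "correlation"))
    D <- switch(
      mname,
      euclidean = as.matrix(stats::dist(X, method = "euclidean")),
      sqeuclidean = as.matrix(stats::dist(X, method = "euclidean"))^2,
      manhattan = as.matrix(stats::dist(X, method = "manhattan")),
      cosine = {
        nrm <- sqrt(rowSums(X^2))
        nrm[nrm == 0] <- 1
        S <- (X %*% t(X)) / outer(nrm, nrm)
        1 - S
      },
      correlation = 1 - stats::cor(t(X))
    )
    if (mname == "euclidean" && squared) {
      D <- D^2
      mname <- "sqeuclidean"
    }
  }
  D[D < 0 & D > -1e-12] <- 0 # clip numerical negatives (cosine/correlation)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  rownames(D) <- colnames(D) <- rownames(X)
  attr(D, "metric") <- mname
  D
}

#' Apply a theta matrix to a distance matrix
#'
#' Element-wise product `H = theta * D`: the hierarchy-perturbed
#' ("path-pairwise") distance matrix fed to an embedding method as a
#' precomputed metric. Zero diagonal and symmetry are preserved.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param theta a [theta_matrix()] (or plain matrix) of the same shape.
#' @return the modified distance matrix, with the theta's config carried in
#'   attributes `config` and `strength`.
#' @export
apply_theta <- function(D, theta) {
  D <- as.matrix(D)
  th <- unclass(theta)
  if (!all(dim(D) == dim(th))) {
    stop("shape mismatch: distance matrix is ", nrow(D), "x", ncol(D),
         ", theta is ", nrow(th), "x", ncol(th))
  }
  H <- D * th
  diag(H) <- 0
  cfg <- attr(theta, "config")
  attributes(H) <- list(dim = dim(D), dimnames = dimnames(D))
  attr(H, "metric") <- attr(D, "metric")
  if (!is.null(cfg)) {
    attr(H, "config") <- cfg
    attr(H, "strength") <- cfg$strength
  }
  H
}

#' One-call hierarchy-perturbed distance matrix
#'
#' Convenience wrapper: computes raw pairwise distances on `X`, the theta
#' matrix from `labels` and the hierarchy, and returns their element-wise
#' product.
#'
#' @inheritParams pairwise_distances
#' @inheritParams theta_matrix
#' @param hg a [hierarchy_graph()].
#' @return modified distance matrix `H` (see [apply_theta()]).
#' @export
hier_distances <- function(X, labels, hg, config = hdr_config(),
                           metric = "euclidean", squared = FALSE,
                           probabilities = NULL) {
  stopifnot(inherits(hg, "hierarchy_graph"))
  if (length(labels) != nrow(as.matrix(X))) {
    stop("'labels' must have one entry per row of X")
  }
  D <- pairwise_distances(X, metric = metric, squared = squared)
  pm <- path_matrix(hg, union(hg$nodes, unique(stats::na.omit(as.character(labels)))))
  th <- theta_matrix(pm, labels, config, probabilities)
  apply_theta(D, th)
}
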
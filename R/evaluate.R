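#' Neighbourhood hierarchy-concordance (HC) score
#'
#' For each embedded point, the labels of its `k` nearest neighbours
#' (including the point itself) are compared, by the chi-squared statistic on
#' the count scale, to an expected label distribution derived from the
#' hierarchy: for a point with label \eqn{\ell}, each label `c` receives the
#' weight `1 - nd(l, c) * (1 - 1/maxdist)` — linearly decreasing from 1 at
#' graph distance 0 to `1/maxdist` at the maximal (normalized) distance —
#' and the weights are L1-normalized. The reported score is
#' `1 - sqrt(mean statistic)`, so 1 is ideal (every neighbourhood matches its
#' hierarchy-expected composition) and lower values indicate discordance.
#'
#' Points with a missing or off-graph label are excluded from the average
#' (their expected distribution is undefined). Conventional choices of `k`
#' are 3, `n/100` and `n/10`.
#'
#' @param embedding an [hdr_embed()] result or a coordinate matrix.
#' @param labels one label per embedded point (`NA` = missing).
#' @param hg the [hierarchy_graph()] the embedding is judged against.
#' @param k neighbourhood size, self included; `1 <= k <= n`.
#' @param config an [hdr_config()] controlling only the normalization of the
#'   label graph distances (its `strength` plays no role here).
#' @return a single number, at most 1.
#' @export
hc_score <- function(embedding, labels, hg, k = 3, config = hdr_config()) {
  coords <- .embedding_coords(embedding)
  labels <- as.character(labels)
  n <- nrow(coords)
  if (length(labels) != n) stop("'labels' must have one entry per point")
  k <- as.integer(k)
  if (k < 1L || k > n) stop("'k' must lie in [1, n]")

  pm <- path_matrix(hg, union(hg$nodes, unique(stats::na.omit(labels))))
  npm <- normalize_paths(pm, config, mode = "label")
  # label universe: labels present in the data, restricted to graph nodes
  present <- unique(labels[!is.na(labels)])
  lab_set <- intersect(present, hg$nodes)
  if (length(lab_set) == 0L) stop("no on-graph labels present")
  md <- max(pm$maxdist, 1) # maxdist 0: degenerate, uniform weights scale
  nd <- npm$normalized[lab_set, lab_set, drop = FALSE]
  W <- 1 - nd * (1 - 1 / md)       # same label -> 1, farthest -> 1/maxdist
  W <- W / rowSums(W)              # L1 normalization, rows sum to 1
  L <- length(lab_set)

  Demb <- as.matrix(stats::dist(coords))
  eps <- 1 / (k * L)
  scored <- which(labels %in% lab_set)
  stats_i <- vapply(scored, function(i) {
    nbr <- order(Demb[i, ])[seq_len(k)] # self has distance 0, always included
    obs_lab <- labels[nbr]
    obs <- vapply(lab_set, function(l) sum(obs_lab == l, na.rm = TRUE),
                  numeric(1))
    expc <- W[labels[i], ] * k
    denom <- ifelse(expc > 0, expc, eps)
    sum((obs - expc)^2 / denom)
  }, numeric(1))
  1 - sqrt(mean(stats_i))
}

#' Hierarchically weighted silhouette
#'
#' A silhouette-style statistic in `[-1, 1]` whose inter-class term is
#' weighted by the normalized hierarchy distance: for point `i` with label
#' \eqn{\ell}, `a(i)` is the mean embedding distance to same-label points and
#' \deqn{b_w(i) = \min_{c \ne \ell} nd(\ell, c) \cdot \bar{d}_{emb}(i, c),}
#' the per-point score being \eqn{(b_w - a) / \max(a, b_w)}. The dataset score
#' (the mean) is 0 when classes are separated exactly in proportion to their
#' hierarchy distance: positive values indicate over-separation relative to
#' the hierarchy, negative values under-separation. Unlike the classical
#' silhouette, 0 — not 1 — is the ideal value.
#'
#' Singleton classes contribute 0 (the classical convention); points with
#' missing/off-graph labels are skipped.
#'
#' @inheritParams hc_score
#' @return a single number in `[-1, 1]`; closer to 0 is better.
#' @export
h_silhouette <- function(embedding, labels, hg, config = hdr_config()) {
  coords <- .embedding_coords(embedding)
  labels <- as.character(labels)
  n <- nrow(coords)
  if (length(labels) != n) stop("'labels' must have one entry per point")
  pm <- path_matrix(hg, union(hg$nodes, unique(stats::na.omit(labels))))
  npm <- normalize_paths(pm, config, mode = "label")
  lab_set <- intersect(unique(labels[!is.na(labels)]), hg$nodes)
  if (length(lab_set) < 2L) {
    stop("h_silhouette requires at least two on-graph labels")
  }
  nd <- npm$normalized[lab_set, lab_set, drop = FALSE]
  Demb <- as.matrix(stats::dist(coords))
  idx_by_lab <- split(seq_len(n), factor(labels, levels = lab_set))

  s_vals <- unlist(lapply(lab_set, function(l) {
    own <- idx_by_lab[[l]]
    if (length(own) == 0L) return(numeric(0))
    others <- setdiff(lab_set, l)
    vapply(own, function(i) {
      if (length(own) == 1L) return(0) # singleton class
      a <- mean(Demb[i, setdiff(own, i)])
      b_w <- min(vapply(others, function(c) {
        nd[l, c] * mean(Demb[i, idx_by_lab[[c]]])
      }, numeric(1)))
      m <- max(a, b_w)
      if (m == 0) 0 else (b_w - a) / m
    }, numeric(1))
  }))
  mean(s_vals)
}

# ---- convex hull helpers ---------------------------------------------------

# signed area (shoelace); vertices as two-column matrix, not closed
.poly_area <- function(P) {
  n <- nrow(P)
  if (is.null(n) || n < 3L) return(0)
  x <- P[, 1L]; y <- P[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

.ccw_hull <- function(pts) {
  h <- grDevices::chull(pts)        # clockwise order
  pts[rev(h), , drop = FALSE]       # counter-clockwise
}

# Sutherland-Hodgman: clip convex subject polygon by convex CCW clip polygon
.clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(nrow(out)) || nrow(out) == 0L) return(matrix(numeric(0), 0, 2))
    A <- clip[e, ]
    B <- clip[if (e == nc) 1L else e + 1L, ]
    # inside = left of directed edge A->B for a CCW clip polygon
    side <- function(p) (B[1] - A[1]) * (p[2] - A[2]) - (B[2] - A[2]) * (p[1] - A[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    np <- nrow(inp)
    for (i in seq_len(np)) {
      P <- inp[i, ]
      Q <- inp[if (i == np) 1L else i + 1L, ]
      sp <- side(P); sq <- side(Q)
      if (sp >= 0) out <- rbind(out, P)
      if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
        t <- sp / (sp - sq)
        out <- rbind(out, P + t * (Q - P))
      }
    }
  }
  out
}

#' Mean convex-hull overlap between label clusters
#'
#' A visual-analysis heuristic for choosing the perturbation strength: for
#' each label, outliers are removed by per-coordinate z-score, the convex
#' hull of the remaining points is built, the nearest other-label hull (by
#' centroid distance) is found, and the intersection area is expressed as a
#' fraction of the label's own hull area. The mean over labels is returned as
#' a percentage: 0 means every cluster is disjoint from its nearest
#' neighbour, 100 means each cluster lies entirely inside it. Intermediate
#' values (roughly 35-45) tend to mark strengths that separate the hierarchy
#' while keeping the raw embedding's character.
#'
#' @param embedding an [hdr_embed()] result or 2-D coordinate matrix.
#' @param labels one label per point.
#' @param z_threshold per-coordinate z-score beyond which a point is dropped
#'   before hull construction (default 3).
#' @return mean overlap percentage over labels with a usable hull.
#' @export
hull_overlap <- function(embedding, labels, z_threshold = 3) {
  coords <- .embedding_coords(embedding)
  if (ncol(coords) != 2L) stop("hull_overlap requires a 2-D embedding")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(coords))
  labs <- unique(labels[!is.na(labels)])

  hulls <- list()
  for (l in labs) {
    P <- coords[which(labels == l), , drop = FALSE]
    if (nrow(P) >= 3L) {
      z <- scale(P)
      z[is.na(z)] <- 0 # zero-variance coordinate: nothing is an outlier
      keep <- rowSums(abs(z) > z_threshold) == 0L
      P <- P[keep, , drop = FALSE]
    }
    if (nrow(P) < 3L) {
      warning("label '", l, "' has fewer than 3 points after outlier ",
              "removal; skipped")
      next
    }
    hull <- .ccw_hull(P)
    hulls[[l]] <- list(hull = hull, area = .poly_area(hull),
                       centroid = colMeans(P))
  }
  if (length(hulls) < 2L) {
    stop("hull_overlap needs at least 2 labels with >= 3 points each")
  }
  fracs <- vapply(names(hulls), function(l) {
    own <- hulls[[l]]
    if (own$area == 0) {
      warning("degenerate (collinear) hull for label '", l,
              "'; overlap counted as 0")
      return(0)
    }
    others <- setdiff(names(hulls), l)
    cd <- vapply(others, function(o) {
      sqrt(sum((own$centroid - hulls[[o]]$centroid)^2))
    }, numeric(1))
    nearest <- hulls[[others[which.min(cd)]]]
    inter <- .clip_convex(own$hull, nearest$hull)
    .poly_area(inter) / own$area
  }, numeric(1))
  100 * mean(fracs)
}

#' Simpson's-rule area under a sampled curve
#'
#' Composite Simpson quadrature on possibly non-uniform nodes: consecutive
#' interval pairs use the three-point non-uniform Simpson formula; a trailing
#' odd interval falls back to the trapezoid rule. On the default strength
#' grid `0, 0.1, ..., 0.9, 0.999` the 10 intervals pair exactly.
#'
#' @param x strictly increasing abscissae (length >= 2).
#' @param y values at `x`.
#' @return the quadrature value.
#' @examples
#' simpson_auc(c(seq(0, 0.9, 0.1), 0.999), rep(1, 11)) # 0.999
#' @export
simpson_auc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !is.unsorted(x),
            !anyDuplicated(x))
  n <- length(x)
  auc <- 0
  i <- 1L
  while (i + 2L <= n) {
    h0 <- x[i + 1L] - x[i]
    h1 <- x[i + 2L] - x[i + 1L]
    auc <- auc + (h0 + h1) / 6 *
      ((2 - h1 / h0) * y[i] +
         (h0 + h1)^2 / (h0 * h1) * y[i + 1L] +
         (2 - h0 / h1) * y[i + 2L])
    i <- i + 2L
  }
  if (i + 1L == n) { # odd trailing interval
    auc <- auc + (x[n] - x[n - 1L]) * (y[n] + y[n - 1L]) / 2
  }
  auc
}

#' Equal-weight baseline graph
#'
#' The comparison baseline for strength sweeps: a complete unit-weight graph
#' over the given labels, in which every inter-label distance is 1 and
#' `maxdist` is 1 — i.e. equally weighted, independent classes with no
#' hierarchical structure.
#'
#' @param labels character vector of labels (node set of the baseline).
#' @return a [hierarchy_graph()].
#' @export
equal_weight_graph <- function(labels) {
  labels <- unique(as.character(labels[!is.na(labels)]))
  if (length(labels) < 2L) stop("need at least 2 labels")
  pairs <- utils::combn(labels, 2L)
  hierarchy_graph(data.frame(from = pairs[1L, ], to = pairs[2L, ],
                             weight = 1, stringsAsFactors = FALSE))
}

#' Sweep the perturbation strength and score each embedding
#'
#' Re-embeds the data once per strength value (same seed throughout) and
#' evaluates a quality metric on each embedding, returning the curve and its
#' Simpson's-rule AUC. Scoring is always against `score_graph` (by default
#' the embedding hierarchy itself), so a sweep driven by
#' [equal_weight_graph()] but scored against the true hierarchy gives the
#' equal-weighted-independent-classes baseline.
#'
#' @param X sample x feature matrix.
#' @param labels one label per sample.
#' @param hg hierarchy used to build the perturbation.
#' @param method backend passed to [hdr_embed()].
#' @param metric_fn scoring function `f(embedding, labels, graph, ...)`;
#'   one of [hc_score()], [h_silhouette()], [hull_overlap()] (which ignores
#'   the graph) or a user callable with the same signature.
#' @param strengths grid of strength values (default `0, 0.1, ..., 0.9,
#'   0.999`).
#' @param seed seed reused for every embedding.
#' @param config base [hdr_config()]; its `strength` is overridden per grid
#'   point.
#' @param dist_metric,squared forwarded to [pairwise_distances()].
#' @param score_graph hierarchy the metric scores against (default `hg`).
#' @param ... extra arguments for `metric_fn` (e.g. `k` for [hc_score()]).
#' @return object of class `metric_curve`: data.frame with columns
#'   `strength`, `value`; attribute `auc`.
#' @export
strength_sweep <- function(X, labels, hg, method = "pca",
                           metric_fn = hc_score,
                           strengths = c(seq(0, 0.9, by = 0.1), 0.999),
                           seed = NULL, config = hdr_config(),
                           dist_metric = "euclidean", squared = FALSE,
                           score_graph = hg, ...) {
  stopifnot(inherits(hg, "hierarchy_graph"))
  X <- as.matrix(X)
  D <- pairwise_distances(X, metric = dist_metric, squared = squared)
  pm <- path_matrix(hg, union(hg$nodes,
                              unique(stats::na.omit(as.character(labels)))))
  values <- vapply(strengths, function(s) {
    cfg <- hdr_config(strength = s, self_distance = config$self_distance,
                      avoid_self = config$avoid_self,
                      disconnected_distance = config$disconnected_distance,
                      squared = config$squared)
    th <- theta_matrix(pm, labels, cfg)
    emb <- hdr_embed(apply_theta(D, th), method = method, seed = seed)
    if (identical(metric_fn, hull_overlap)) {
      metric_fn(emb, labels, ...)
    } else {
      metric_fn(emb, labels, score_graph, ...)
    }
  }, numeric(1))
  curve <- data.frame(strength = strengths, value = values)
  attr(curve, "auc") <- simpson_auc(strengths, values)
  class(curve) <- c("metric_curve", "data.frame")
  curve
}

#' @export
print.metric_curve <- function(x, ...) {
  cat("metric_curve over", nrow(x), "strengths; Simpson AUC =",
      format(attr(x, "auc"), digits = 6), "\n")
  print.data.frame(x, ...)
  invisible(x)
}
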
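#' Build a label hierarchy graph
#'
#' Constructs the undirected, optionally weighted label graph that drives the
#' hierarchical distancing factor. The graph need not be connected; isolated
#' nodes are allowed. Self-loops are rejected: the distance of a label to
#' itself is governed by `self_distance` / `avoid_self` in [hdr_config()],
#' never by an edge.
#'
#' @param edges a data.frame (or matrix) whose first two columns are the edge
#'   endpoints (label strings) and whose optional third column holds positive
#'   edge weights (default weight 1). Symmetric duplicates (`A,B` and `B,A`)
#'   are merged; duplicates with conflicting weights are an error.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to include beyond the edge endpoints.
#'
#' @return an object of class `hierarchy_graph`: a list with
#'   \describe{
#'     \item{graph}{the underlying [igraph::graph] (undirected, weighted)}
#'     \item{nodes}{character vector of node labels}
#'     \item{components}{integer membership vector, one entry per node}
#'     \item{maxdist}{largest finite shortest-path length anywhere in the
#'       graph (0 for an edgeless graph)}
#'   }
#' @seealso [read_hierarchy()] for file input, [path_matrix()] for the
#'   label-by-label shortest-path matrix.
#' @examples
#' hg <- hierarchy_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' hg$maxdist # 2: the A--C path
#' @export
hierarchy_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(from = character(), to = character(), weight = numeric())
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L) {
      stop("edge table must have at least two columns (node_a, node_b)")
    }
    w <- if (ncol(edges) >= 3L) edges[[3L]] else rep(1, nrow(edges))
    if (is.character(w) || is.factor(w)) {
      w_num <- suppressWarnings(as.numeric(as.character(w)))
      if (anyNA(w_num)) stop("edge weights must be numeric")
      w <- w_num
    }
    if (anyNA(w) || any(!is.finite(w)) || any(w <= 0)) {
      stop("edge weights must be positive finite numbers")
    }
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    if (any(is.na(a)) || any(is.na(b)) || any(a == "") || any(b == "")) {
      stop("edge endpoints must be non-empty label strings")
    }
    if (any(a == b)) {
      stop("self-loop edges are not allowed; intra-label distance is set by ",
           "'self_distance'/'avoid_self'")
    }
    # canonical unordered orientation, then merge duplicates
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    if (anyDuplicated(key)) {
      for (k in unique(key[duplicated(key)])) {
        if (length(unique(w[key == k])) > 1L) {
          stop("duplicate edge with conflicting weights: ",
               gsub("\r", " -- ", k))
        }
      }
      keep <- !duplicated(key)
      lo <- lo[keep]; hi <- hi[keep]; w <- w[keep]
    }
    ed <- data.frame(from = lo, to = hi, weight = w,
                     stringsAsFactors = FALSE)
  }
  all_nodes <- unique(c(ed$from, ed$to, as.character(nodes)))
  if (length(all_nodes) == 0L) stop("hierarchy graph has no nodes")
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  dmat <- igraph::distances(g, weights = igraph::E(g)$weight)
  finite <- dmat[is.finite(dmat)]
  maxdist <- if (length(finite)) max(finite) else 0
  structure(
    list(
      graph = g,
      nodes = all_nodes,
      components = igraph::components(g)$membership,
      maxdist = maxdist
    ),
    class = "hierarchy_graph"
  )
}

#' Read a hierarchy graph from a file
#'
#' Accepts two dialects: an edge-list CSV with columns
#' `node_a,node_b[,weight]` (header optional, detected by whether the third
#' field of the first row parses as a number and the first two do not), or a
#' JSON adjacency mapping, either `{"A": ["B","C"]}` or
#' `{"A": {"B": 0.5}}` for weighted edges.
#'
#' @param path path to a `.csv`/`.tsv` edge list or `.json` adjacency file.
#' @param format `"auto"` (by extension), `"edgelist"` or `"adjacency"`.
#' @return a [hierarchy_graph()] object.
#' @export
read_hierarchy <- function(path, format = c("auto", "edgelist", "adjacency")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      "adjacency"
    } else {
      "edgelist"
    }
  }
  if (format == "adjacency") {
    adj <- jsonlite::read_json(path)
    if (!is.list(adj) || is.null(names(adj))) {
      stop("JSON adjacency must be an object mapping label -> neighbors")
    }
    rows <- list()
    for (node in names(adj)) {
      nb <- adj[[node]]
      if (length(nb) == 0L) next
      if (is.null(names(nb))) { # plain neighbor list
        rows[[length(rows) + 1L]] <- data.frame(
          from = node, to = unlist(nb, use.names = FALSE), weight = 1,
          stringsAsFactors = FALSE
        )
      } else {                  # {neighbor: weight}
        rows[[length(rows) + 1L]] <- data.frame(
          from = node, to = names(nb),
          weight = unlist(nb, use.names = FALSE),
          stringsAsFactors = FALSE
        )
      }
    }
    edges <- if (length(rows)) do.call(rbind, rows) else NULL
    return(hierarchy_graph(edges, nodes = names(adj)))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           comment.char = "#")
  # drop a header row: endpoints that don't look like data (e.g. "node_a")
  if (nrow(raw) > 0L && ncol(raw) >= 3L) {
    first_w <- suppressWarnings(as.numeric(raw[1L, 3L]))
    if (is.na(first_w) && raw[1L, 3L] != "") raw <- raw[-1L, , drop = FALSE]
  } else if (nrow(raw) > 0L &&
             paste(tolower(raw[1L, 1L]), tolower(raw[1L, 2L])) %in%
             c("node_a node_b", "from to", "source target")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  hierarchy_graph(raw)
}

#' @export
print.hierarchy_graph <- function(x, ...) {
  cat(sprintf(
    "hierarchy_graph: %d nodes, %d edges, %d component(s), maxdist = %g\n",
    length(x$nodes), igraph::ecount(x$graph),
    max(x$components), x$maxdist
  ))
  invisible(x)
}

#' Label-by-label shortest-path matrix
#'
#' Computes weighted shortest-path distances between every pair of requested
#' labels. Pairs in different connected components — and any requested label
#' that is not a node of the graph ("off-graph") — receive `Inf`, the
#' disconnected sentinel. Compute once and reuse: all downstream functions
#' take the returned object, so label-level path distances are never
#' recomputed per sample pair.
#'
#' @param hg a [hierarchy_graph()].
#' @param labels labels to index the matrix by; defaults to all graph nodes.
#'   Off-graph labels are permitted.
#' @return an object of class `path_matrix`: list with `labels`, `dist`
#'   (label x label, `Inf` = disconnected), and `maxdist` from the graph.
#' @examples
#' hg <- hierarchy_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
#' path_matrix(hg)$dist["A", "C"] # 2
#' @export
path_matrix <- function(hg, labels = NULL) {
  stopifnot(inherits(hg, "hierarchy_graph"))
  if (is.null(labels)) labels <- hg$nodes
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("labels must be unique")
  on_graph <- labels %in% hg$nodes
  d <- matrix(Inf, length(labels), length(labels),
              dimnames = list(labels, labels))
  if (any(on_graph)) {
    sub <- igraph::distances(hg$graph, v = labels[on_graph],
                             to = labels[on_graph],
                             weights = igraph::E(hg$graph)$weight)
    d[on_graph, on_graph] <- sub
  }
  diag(d) <- 0
  structure(
    list(labels = labels, dist = d, maxdist = hg$maxdist,
         off_graph = labels[!on_graph]),
    class = "path_matrix"
  )
}

#' @export
print.path_matrix <- function(x, ...) {
  cat(sprintf("path_matrix over %d labels (maxdist = %g)\n",
              length(x$labels), x$maxdist))
  if (length(x$off_graph)) {
    cat("off-graph labels:", paste(x$off_graph, collapse = ", "), "\n")
  }
  invisible(x)
}
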
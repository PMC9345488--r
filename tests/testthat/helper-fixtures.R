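# shared fixtures built in code

chain_graph <- function(nodes = c("A", "B", "C"), weights = NULL,
                        extra_nodes = NULL) {
  ed <- data.frame(from = nodes[-length(nodes)], to = nodes[-1L],
                   stringsAsFactors = FALSE)
  if (!is.null(weights)) ed$weight <- weights
  hierarchy_graph(ed, nodes = extra_nodes)
}

# 7-label, 3-level balanced tree: root R, parents P1/P2, leaves L1..L4
tree7_graph <- function() {
  hierarchy_graph(data.frame(
    from = c("R", "R", "P1", "P1", "P2", "P2"),
    to   = c("P1", "P2", "L1", "L2", "L3", "L4"),
    stringsAsFactors = FALSE
  ))
}

# random connected-or-not graph on <= max_nodes nodes
random_graph <- function(n_nodes, p_edge = 0.4, weighted = FALSE) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(ncol(pairs), 1L)] <- TRUE
  ed <- data.frame(from = pairs[1L, keep], to = pairs[2L, keep],
                   stringsAsFactors = FALSE)
  if (weighted) ed$weight <- stats::runif(nrow(ed), 0.2, 3)
  hierarchy_graph(ed, nodes = nodes)
}

# axis-aligned unit square point cloud: the 4 corners plus interior points
# so hulls are exact squares
square_points <- function(x0, y0, side = 1, n_inner = 8, seed = 1) {
  set.seed(seed)
  corners <- cbind(c(x0, x0 + side, x0 + side, x0),
                   c(y0, y0, y0 + side, y0 + side))
  inner <- cbind(stats::runif(n_inner, x0 + 0.2 * side, x0 + 0.8 * side),
                 stats::runif(n_inner, y0 + 0.2 * side, y0 + 0.8 * side))
  rbind(corners, inner)
}
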
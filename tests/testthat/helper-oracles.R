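# independent oracles, deliberately written as plain loops against the
# definitions rather than reusing any package code path

# all-pairs shortest paths by exhaustive simple-path enumeration
oracle_shortest_paths <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = w[i]))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = w[i]))
  }
  best <- matrix(Inf, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  diag(best) <- 0
  walk <- function(at, target, visited, len) {
    if (at == target) {
      if (len < best[visited[1L], target]) {
        best[visited[1L], target] <<- len
      }
      return(invisible())
    }
    nb <- adj[[at]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      nxt <- nb$to[r]
      if (!(nxt %in% visited)) {
        walk(nxt, target, c(visited, nxt), len + nb$w[r])
      }
    }
  }
  for (s in nodes) for (t in nodes) {
    if (s != t) walk(s, t, s, 0)
  }
  best
}

# direct per-pair evaluation of the label-mode distancing factor, applying
# the normalization pipeline from its written definition
oracle_theta <- function(edges, all_nodes, labels, strength,
                         self_distance = 0, avoid_self = character(),
                         disconnected_distance = 1) {
  sp_edges <- oracle_shortest_paths(edges)
  sp <- matrix(Inf, length(all_nodes), length(all_nodes),
               dimnames = list(all_nodes, all_nodes))
  diag(sp) <- 0
  common <- intersect(all_nodes, rownames(sp_edges))
  sp[common, common] <- sp_edges[common, common]
  finite <- sp[is.finite(sp) & sp > 0]
  maxdist <- if (length(finite)) max(finite) else 0

  L <- length(all_nodes)
  norm <- matrix(0, L, L, dimnames = list(all_nodes, all_nodes))
  for (a in all_nodes) for (b in all_nodes) {
    if (a == b) next
    norm[a, b] <- if (is.finite(sp[a, b])) {
      if (maxdist > 0) sp[a, b] / maxdist else 1
    } else {
      disconnected_distance
    }
  }
  off <- row(norm) != col(norm)
  if (max(norm[off]) > 1) {
    lo <- min(norm[off]); hi <- max(norm[off])
    norm[off] <- (norm[off] - lo) / (hi - lo)
  }
  for (a in all_nodes) {
    norm[a, a] <- if (a %in% avoid_self) self_distance else 0
  }

  n <- length(labels)
  th <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    li <- labels[i]; lj <- labels[j]
    if (is.na(li) || is.na(lj) || !(li %in% all_nodes) ||
        !(lj %in% all_nodes)) {
      th[i, j] <- 1
    } else {
      th[i, j] <- (1 - strength) + strength * norm[li, lj]
    }
  }
  th
}
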
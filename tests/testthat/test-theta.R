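test_that("config validation enforces parameter ranges", {
  expect_error(hdr_config(strength = 1), "strength")
  expect_error(hdr_config(strength = -0.1), "strength")
  expect_error(hdr_config(self_distance = 1.5), "self_distance")
  expect_error(hdr_config(disconnected_distance = -1), "disconnected_distance")
  expect_s3_class(hdr_config(strength = 0.999), "hdr_config")
})

test_that("path normalization follows the fixed pipeline order", {
  hg <- chain_graph(c("A", "B", "C"), extra_nodes = "D")
  pm <- path_matrix(hg)

  # defaults: scale by maxdist, disconnected -> 1, no min-max, self 0
  nd <- normalize_paths(pm, hdr_config())$normalized
  expect_equal(nd["A", "B"], 0.5)
  expect_equal(nd["A", "C"], 1.0)
  expect_equal(nd["A", "D"], 1.0)
  expect_equal(nd["A", "A"], 0)

  # disconnected_distance 2 triggers the min-max over {0.5, 1, 2}
  nd2 <- normalize_paths(pm, hdr_config(disconnected_distance = 2))$normalized
  expect_equal(nd2["A", "B"], 0)
  expect_equal(nd2["A", "C"], 1 / 3)
  expect_equal(nd2["A", "D"], 1)

  # avoid_self substitution happens after normalization
  nd3 <- normalize_paths(
    pm, hdr_config(avoid_self = "A", self_distance = 1)
  )$normalized
  expect_equal(nd3["A", "A"], 1)
  expect_equal(nd3["B", "B"], 0)
})

test_that("label-mode theta matches the interpolation formula", {
  hg <- chain_graph(c("A", "B", "C"))
  pm <- path_matrix(hg)

  th0 <- theta_matrix(pm, c("A", "B", "C"), hdr_config(strength = 0))
  expect_true(all(unclass(th0) == 1))

  th <- theta_matrix(pm, c("A", "B", "C"), hdr_config(strength = 0.999))
  expect_equal(th[1, 2], 0.001 + 0.999 * 0.5)
  expect_equal(th[1, 3], 1)
  expect_equal(th[1, 1], 0.001)

  # a missing label maintains raw distances: full row of ones
  thm <- theta_matrix(pm, c("A", NA, "C"), hdr_config(strength = 0.8))
  expect_true(all(thm[2, ] == 1) && all(thm[, 2] == 1))

  # an off-graph label behaves like missing
  tho <- theta_matrix(path_matrix(hg, c("A", "B", "C", "Z")),
                      c("A", "Z", "C"), hdr_config(strength = 0.8))
  expect_true(all(tho[2, ] == 1))

  expect_error(theta_matrix(pm, c("A", "B"), hdr_config()), NA)
})

test_that("probability-mode theta uses min(p_i, p_j) and (path-1)/(maxdist-1)", {
  hg <- chain_graph(c("A", "B", "C"))
  pm <- path_matrix(hg)
  labs <- c("A", "B", "C")

  # p = 0 anywhere collapses that sample's row to 1
  th0 <- theta_matrix(pm, labs, hdr_config(strength = 0.9),
                      probabilities = c(0, 1, 1))
  expect_true(all(th0[1, ] == 1))

  # adjacent pair at full confidence and str = 0.999: path term (1-1)/(2-1)=0
  th <- theta_matrix(pm, labs, hdr_config(strength = 0.999),
                     probabilities = c(1, 1, 1))
  expect_equal(th[1, 2], 0.001)

  # p = 0.5 both, str = 0.8, pair (A, C): m = 0.5, term (2-1)/(2-1) = 1
  th2 <- theta_matrix(pm, labs, hdr_config(strength = 0.8),
                      probabilities = c(0.5, 1, 0.5))
  expect_equal(th2[1, 3], 1)

  expect_error(
    theta_matrix(pm, labs, hdr_config(), probabilities = c(1, NA, 1)),
    "probability"
  )
  # maxdist = 1 degenerates the (path-1)/(maxdist-1) scaling
  hg1 <- hierarchy_graph(data.frame(a = "A", b = "B"))
  expect_warning(
    theta_matrix(path_matrix(hg1), c("A", "B"), hdr_config(strength = 0.5),
                 probabilities = c(1, 1)),
    "maxdist = 1"
  )
})

test_that("theta is monotone in graph distance, strength and probability", {
  hg <- chain_graph(c("A", "B", "C", "D"))
  pm <- path_matrix(hg)
  labs <- c("A", "B", "C", "D")
  for (str in c(0.3, 0.7, 0.999)) {
    th <- theta_matrix(pm, labs, hdr_config(strength = str))
    expect_true(all(unclass(th) >= 0 & unclass(th) <= 1))
    # farther labels -> larger theta
    expect_true(th[1, 2] < th[1, 3])
    expect_true(th[1, 3] < th[1, 4] + 1e-15)
  }
  th_lo <- theta_matrix(pm, labs, hdr_config(strength = 0.2))
  th_hi <- theta_matrix(pm, labs, hdr_config(strength = 0.8))
  off <- row(th_lo) != col(th_lo) & unclass(th_lo) < 1
  expect_true(all(th_hi[off] <= th_lo[off]))

  # probability continuity: all-zero probabilities give the identity matrix
  thp <- theta_matrix(pm, labs, hdr_config(strength = 0.9),
                      probabilities = rep(0, 4))
  expect_true(all(unclass(thp) == 1))
  p_seq <- c(0.2, 0.5, 0.9)
  vals <- vapply(p_seq, function(p) {
    theta_matrix(pm, labs, hdr_config(strength = 0.9),
                 probabilities = rep(p, 4))[1, 2]
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-15))
})

test_that("theta matches the brute-force oracle on random graphs and configs", {
  set.seed(101)
  for (rep in 1:15) {
    n_nodes <- sample(3:8, 1)
    hg <- random_graph(n_nodes, weighted = rep %% 2 == 0)
    ed <- igraph::as_data_frame(hg$graph)
    names(ed)[1:2] <- c("from", "to")
    str <- stats::runif(1, 0, 0.999)
    sd_ <- stats::runif(1)
    avoid <- sample(hg$nodes, sample(0:n_nodes, 1))
    dd <- sample(c(0.5, 1, 2), 1)
    labels <- sample(c(hg$nodes, NA), 12, replace = TRUE)
    cfg <- hdr_config(strength = str, self_distance = sd_,
                      avoid_self = avoid, disconnected_distance = dd)
    th <- theta_matrix(path_matrix(hg), labels, cfg)
    or <- oracle_theta(ed, hg$nodes, labels, str, sd_, avoid, dd)
    expect_equal(unclass(th), or, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("pairwise distances implement the standard metrics", {
  X <- rbind(c(0, 0), c(3, 4), c(0, 0))
  D <- pairwise_distances(X, "euclidean")
  expect_equal(D[1, 2], 5)
  expect_equal(D[1, 3], 0)
  expect_equal(pairwise_distances(X, "euclidean", squared = TRUE)[1, 2], 25)

  Xc <- rbind(c(1, 0), c(0, 1))
  expect_equal(pairwise_distances(Xc, "cosine")[1, 2], 1)
  expect_equal(pairwise_distances(X, "manhattan")[1, 2], 7)

  Xr <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(pairwise_distances(Xr, "correlation")[1, 2], 2)

  Dc <- pairwise_distances(X, function(a, b) sum(abs(a - b))^0.5)
  expect_equal(Dc[1, 2], sqrt(7))
  expect_error(pairwise_distances(X, "mahalanobis"), "arg")
  expect_error(pairwise_distances(rbind(c(1, NA))), "finite")
})

test_that("applying theta preserves structure and the zero-strength identity", {
  hg <- chain_graph(c("A", "B", "C"))
  pm <- path_matrix(hg)
  set.seed(3)
  X <- matrix(rnorm(60), 12, 5)
  labs <- sample(c("A", "B", "C"), 12, replace = TRUE)
  D <- pairwise_distances(X)

  th0 <- theta_matrix(pm, labs, hdr_config(strength = 0))
  expect_identical(apply_theta(D, th0)[, ], D[, ]) # bitwise identity

  th <- theta_matrix(pm, labs, hdr_config(strength = 0.6))
  H <- apply_theta(D, th)
  expect_equal(H, t(H), ignore_attr = TRUE)
  expect_true(all(diag(H) == 0))
  expect_true(all(H <= D + 1e-15))

  # zero theta annihilates the pair
  th_inj <- unclass(th)
  th_inj[1, 2] <- th_inj[2, 1] <- 0
  expect_equal(apply_theta(D, th_inj)[1, 2], 0)

  # hand-computed 4-point example on a line, chain hierarchy, str = 0.5
  X4 <- matrix(c(0, 1, 2, 3), ncol = 1)
  labs4 <- c("A", "A", "B", "C")
  D4 <- pairwise_distances(X4)
  th4 <- theta_matrix(pm, labs4, hdr_config(strength = 0.5))
  H4 <- apply_theta(D4, th4)
  # theta: same label 0.5+0.5*0=0.5; A-B 0.5+0.5*0.5=0.75; A-C 1; B-C 0.75
  expect_equal(H4[1, 2], 1 * 0.5)
  expect_equal(H4[1, 3], 2 * 0.75)
  expect_equal(H4[1, 4], 3 * 1)
  expect_equal(H4[3, 4], 1 * 0.75)

  expect_error(apply_theta(D[1:3, 1:3], th), "shape")
})

test_that("theta_min cases at strength 0.999 follow the case law", {
  hg <- tree7_graph() # unit weights, maxdist 4, min path 1
  pm <- path_matrix(hg)
  labs <- hg$nodes
  # absolute: at str = 0.999 the limit is approached within (1 - str);
  # the 1e-12 covers representation error of 1 - 0.999 itself
  tol <- 1e-3 + 1e-12

  # Case 1 (defaults): min off-diagonal theta -> minpath/maxdist, self -> 0
  th1 <- unclass(theta_matrix(pm, labs, hdr_config(strength = 0.999)))
  off <- row(th1) != col(th1)
  expect_lte(abs(min(th1[off]) - 1 / 4), tol)
  expect_lte(abs(min(diag(th1)) - 0), tol)

  # Case 2: avoid_self everywhere with self_distance below minpath/maxdist
  th2 <- unclass(theta_matrix(pm, labs, hdr_config(
    strength = 0.999, avoid_self = labs, self_distance = 0.1
  )))
  expect_lte(abs(min(th2) - 0.1), tol)

  # Case 3: self_distance above minpath/maxdist -> graph term wins
  th3 <- unclass(theta_matrix(pm, labs, hdr_config(
    strength = 0.999, avoid_self = labs, self_distance = 0.9
  )))
  expect_lte(abs(min(th3) - 1 / 4), tol)
})

test_that("degenerate maxdist 0 yields all-ones theta with a warning", {
  hg <- hierarchy_graph(nodes = "A")
  pm <- path_matrix(hg, c("A", "B"))
  expect_warning(
    th <- theta_matrix(pm, c("A", "A", "B"), hdr_config(strength = 0.9)),
    "maxdist"
  )
  expect_true(all(unclass(th) == 1))
})
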
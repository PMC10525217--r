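test_that("standardization centers and scales continuous columns with the population convention", {
  X <- feature_matrix(cbind(c(1, 2, 3), c(0, 1, 1)),
                      feature_kind = c("continuous", "binary"))
  Z <- standardize_features(X)
  expect_equal(Z$values[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(Z$values[, 2], c(0, 1, 1), ignore_attr = TRUE)  # binary passes through

  # fit on a subset: mean 3, population sd 1 on rows 1:2 of (2,4,6)
  X2 <- feature_matrix(matrix(c(2, 4, 6), ncol = 1))
  Z2 <- standardize_features(X2, fit_rows = 1:2)
  expect_equal(drop(Z2$values), c(-1, 1, 3), ignore_attr = TRUE)

  # zero-variance column: centered, unscaled, warned
  X3 <- feature_matrix(cbind(c(5, 5, 5), c(1, 2, 3)))
  expect_warning(Z3 <- standardize_features(X3), "zero-variance")
  expect_equal(Z3$values[, 1], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("correlation distance matches hand computations and rejects constant rows", {
  X <- feature_matrix(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)))
  D <- correlation_distance(X)$D
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 2)          # perfectly anti-correlated
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)

  X2 <- feature_matrix(rbind(c(1, 2, 3), c(1, 2, 4), c(0, 5, 1)))
  D2 <- correlation_distance(X2)$D
  expect_equal(D2[1, 2], 1 - cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(D2[1, 2], 0.01802, tolerance = 1e-4)

  X3 <- feature_matrix(rbind(c(1, 1, 1), c(1, 2, 3), c(2, 1, 0)))
  expect_error(correlation_distance(X3), "constant")
})

test_that("local bandwidth follows the three-term neighbourhood average", {
  D <- matrix(c(0, .1, .3,
                .1, 0, .2,
                .3, .2, 0), 3, 3, byrow = TRUE)
  p <- kernel_params(mu = 0.5, k_neighbors = 1)
  # nearest neighbour of patient 1 is 2 (0.1) and of 2 is 1 (0.1)
  expect_equal(local_sigma(D, 1, 2, p), 0.5 * (0.1 + 0.1 + 0.1) / 3)
  # nearest neighbour of 3 is 2 (0.2)
  expect_equal(local_sigma(D, 1, 3, p), 0.5 * (0.1 + 0.2 + 0.3) / 3)
  expect_equal(local_sigma(D, 3, 1, p), local_sigma(D, 1, 3, p))
  # all pairwise distances equal d -> sigma = mu * d
  Dc <- matrix(0.4, 4, 4); diag(Dc) <- 0
  expect_equal(local_sigma(Dc, 1, 3, kernel_params(mu = 0.3, k_neighbors = 2)),
               0.3 * 0.4)
})

test_that("similarity kernel matches the closed form on the 3-patient instance", {
  D <- matrix(c(0, .1, .3,
                .1, 0, .2,
                .3, .2, 0), 3, 3, byrow = TRUE)
  p <- kernel_params(mu = 0.5, k_neighbors = 1)
  g <- similarity_kernel(D, p)
  # sigma(1,2) = 0.05; W = 1/sqrt(2 pi 0.0025) * exp(-0.01/0.005)
  expect_equal(g$sigma[1, 2], 0.05)
  expect_equal(g$W[1, 2], 7.9788 * exp(-2), tolerance = 1e-4)
  expect_equal(g$W[1, 2], 1.0798, tolerance = 1e-4)
  expect_equal(diag(g$W), rep(0, 3), ignore_attr = TRUE)
})

test_that("full kernel equals an elementwise brute-force loop over local_sigma", {
  X <- rand_features(14, 6, seed = 7)
  p <- kernel_params(mu = 0.4, k_neighbors = 5)
  D <- correlation_distance(X)$D
  g <- similarity_kernel(D, p)
  for (i in 1:13) for (j in (i + 1):14) {
    s <- local_sigma(D, i, j, p)
    w <- exp(-D[i, j]^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
    expect_equal(g$W[i, j], w)
    expect_equal(g$W[j, i], w)
  }
})

test_that("kernel output is symmetric with zero diagonal on random inputs", {
  for (seed in 1:4) {
    n <- sample(10:40, 1)
    X <- rand_features(n, 8, p_bin = 2, seed = seed)
    g <- build_patient_graph(X, kernel_params(mu = 0.6, k_neighbors = 5))
    expect_equal(g$W, t(g$W))
    expect_equal(g$A, t(g$A))
    expect_equal(diag(g$W), rep(0, n), ignore_attr = TRUE)
    expect_equal(diag(g$A), rep(0, n), ignore_attr = TRUE)
    expect_true(all(g$W >= 0) && all(is.finite(g$W)))
  }
})

test_that("for identical patients W decreases strictly in mu", {
  # D(1,2) = 0: only the 1/sigma prefactor remains
  X <- feature_matrix(rbind(c(1, 2, 3, 5), c(1, 2, 3, 5), c(4, 1, 2, 2),
                            c(0, 3, 1, 4)))
  D <- correlation_distance(X)$D
  w <- vapply(seq(0.1, 1, by = 0.1), function(mu) {
    similarity_kernel(D, kernel_params(mu = mu, k_neighbors = 2))$W[1, 2]
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("thresholding is strict and edge count is monotone in c", {
  X <- rand_features(20, 6, seed = 3)
  g0 <- build_patient_graph(X, kernel_params(mu = 0.8, k_neighbors = 5))
  # exact-equality boundary: W == c gives no edge
  wval <- max(g0$W)
  g_eq <- threshold_adjacency(g0, c = wval)
  expect_equal(sum(g_eq$A), 0)
  expect_equal(nrow(g_eq$edges), 0)
  # all W < c -> empty adjacency
  g_hi <- threshold_adjacency(g0, c = wval + 1)
  expect_equal(sum(g_hi$A), 0)
  # monotone sweep
  counts <- vapply(seq(0, wval, length.out = 8), function(cc) {
    nrow(threshold_adjacency(g0, c = cc)$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # edges enumerate exactly the A = 1 pairs
  g1 <- threshold_adjacency(g0, c = median(g0$W))
  expect_equal(2 * nrow(g1$edges), sum(g1$A))
})

test_that("induced subgraphs restrict W, A and edges consistently", {
  X <- rand_features(12, 5, seed = 9)
  g <- build_patient_graph(X, kernel_params(mu = 0.9, k_neighbors = 4))
  all_rows <- induce_subgraph(g, seq_len(12))
  expect_equal(all_rows$A, g$A)
  expect_equal(all_rows$edges, g$edges)

  one <- induce_subgraph(g, 5)
  expect_equal(dim(one$A), c(1L, 1L))
  expect_equal(sum(one$A), 0)

  # 4-node path graph restricted to its end nodes loses all edges
  gp <- g
  gp$A <- matrix(0, 4, 4)
  gp$A[cbind(1:3, 2:4)] <- 1
  gp$A <- gp$A + t(gp$A)
  gp$W <- gp$A * 0.7
  gp$sigma <- gp$A * 0.1
  gp$patient_ids <- paste0("P", 1:4)
  idx <- which(gp$A == 1 & upper.tri(gp$A), arr.ind = TRUE)
  gp$edges <- data.frame(i = idx[, 1], j = idx[, 2], w = gp$W[idx])
  ends <- induce_subgraph(gp, c(1, 4))
  expect_equal(sum(ends$A), 0)
  expect_equal(nrow(ends$edges), 0)

  expect_error(induce_subgraph(g, integer(0)), "empty")
})

test_that("edge list and adjacency writers round-trip through text", {
  X <- rand_features(10, 5, seed = 2)
  g <- build_patient_graph(X, kernel_params(mu = 1, k_neighbors = 3,
                                            threshold_c = 0.2))
  tmp <- tempfile(fileext = ".tsv")
  write_edge_list(g, tmp)
  back <- read.delim(tmp)
  expect_equal(back$i, g$edges$i)
  expect_equal(back$w, g$edges$w, tolerance = 1e-6)
  tmp2 <- tempfile(fileext = ".mtx")
  write_adjacency_coo(g, tmp2)
  lines <- readLines(tmp2)
  expect_match(lines[1], "MatrixMarket")
  expect_equal(length(lines), 2 + nrow(g$edges))
})
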
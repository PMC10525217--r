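#' Kernel parameters for patient-similarity graph construction
#'
#' @param mu Scaling factor for the local bandwidth, in (0, 1]. Smaller
#'   values shrink the bandwidth and sharpen the kernel.
#' @param k_neighbors Number of nearest neighbours entering the local
#'   bandwidth (default 20).
#' @param threshold_c Similarity threshold above which an edge is created
#'   (default 0.5).
#' @param distance `"correlation"` (1 - Pearson r, default) or
#'   `"abs_correlation"` (1 - |r|).
#' @param w_cap Replacement value for the degenerate case of two identical
#'   patients inside a zero-bandwidth neighbourhood, where the kernel is
#'   unbounded.
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(mu = 0.5, k_neighbors = 20L, threshold_c = 0.5,
                          distance = c("correlation", "abs_correlation"),
                          w_cap = 1e6) {
  distance <- match.arg(distance)
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0, mu <= 1,
            k_neighbors >= 1L, is.numeric(threshold_c))
  structure(list(mu = mu, k_neighbors = as.integer(k_neighbors),
                 threshold_c = threshold_c, distance = distance,
                 w_cap = w_cap),
            class = "kernel_params")
}

#' Pairwise correlation distance between patients
#'
#' Distance between patient feature vectors defined as 1 minus the Pearson
#' correlation of the rows (range \[0, 2\]); with
#' `distance = "abs_correlation"`, 1 minus its absolute value (range
#' \[0, 1\]).
#'
#' @param X A [feature_matrix()].
#' @param distance Which transform of Pearson r to use.
#' @return A list with the symmetric distance matrix `D` (zero diagonal) and
#'   `metric_name`.
#' @export
correlation_distance <- function(X,
                                 distance = c("correlation", "abs_correlation")) {
  stopifnot(inherits(X, "feature_matrix"))
  distance <- match.arg(distance)
  vals <- X$values
  rv <- apply(vals, 1L, stats::var)
  if (any(rv == 0)) {
    stop("constant feature vector for patient(s): ",
         paste(X$patient_ids[rv == 0], collapse = ", "))
  }
  r <- stats::cor(t(vals))
  D <- if (distance == "correlation") 1 - r else 1 - abs(r)
  D[D < 0] <- 0  # guard tiny negative rounding
  diag(D) <- 0
  dimnames(D) <- list(X$patient_ids, X$patient_ids)
  list(D = D, metric_name = distance)
}

# Mean distance from each patient to its k nearest neighbours (self
# excluded; ties broken by patient index).
knn_mean_distance <- function(D, k) {
  n <- nrow(D)
  if (k > n - 1L) stop("k_neighbors must be <= n - 1")
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    ord <- order(d, seq_along(d))
    mean(d[ord[seq_len(k)]])
  }, numeric(1))
}

#' Local bandwidth for one patient pair
#'
#' The kernel bandwidth for a pair (i, j) is \eqn{\sigma_{ij} = \mu
#' (\bar\rho_i + \bar\rho_j + \rho_{ij}) / 3}, where \eqn{\bar\rho_i} is the
#' mean distance from i to its k nearest neighbours. This makes the kernel
#' self-tuning: pairs embedded in tight neighbourhoods get a narrow
#' bandwidth.
#'
#' @param D Symmetric distance matrix.
#' @param i,j Patient indices (1-based), `i != j`.
#' @param params A [kernel_params()].
#' @return Scalar bandwidth, symmetric in (i, j).
#' @export
local_sigma <- function(D, i, j, params) {
  stopifnot(i != j)
  km <- knn_mean_distance(D, params$k_neighbors)
  params$mu * (km[i] + km[j] + D[i, j]) / 3
}

#' Scaled exponential similarity kernel
#'
#' Computes the full pairwise similarity matrix
#' \deqn{W_{ij} = \frac{1}{\sqrt{2\pi\sigma_{ij}^2}}
#'   \exp\left(-\frac{\rho_{ij}^2}{2\sigma_{ij}^2}\right)}
#' with the locally scaled bandwidth of [local_sigma()]. The diagonal is set
#' to zero: self-similarity is undefined by the kernel (its bandwidth would
#' collapse) and self-loops are handled by the network layers, not the
#' graph.
#'
#' If a bandwidth degenerates to zero, the pair gets `params$w_cap` when the
#' distance is also zero (identical patients in an identical neighbourhood)
#' and 0 otherwise.
#'
#' @param D Symmetric distance matrix (zero diagonal).
#' @param params A [kernel_params()].
#' @return A `similarity_graph` with `W` and `sigma` filled; `A` and `edges`
#'   are added by [threshold_adjacency()].
#' @export
similarity_kernel <- function(D, params) {
  n <- nrow(D)
  km <- knn_mean_distance(D, params$k_neighbors)
  sigma <- params$mu * (outer(km, km, "+") + D) / 3
  W <- matrix(0, n, n)
  pos <- sigma > 0
  W[pos] <- exp(-D[pos]^2 / (2 * sigma[pos]^2)) / sqrt(2 * pi * sigma[pos]^2)
  degen <- !pos & D == 0
  diag(degen) <- FALSE
  if (any(degen)) {
    warning(sprintf("%d pair(s) with zero bandwidth and zero distance capped at %g",
                    sum(degen) / 2, params$w_cap))
    W[degen] <- params$w_cap
  }
  diag(W) <- 0
  diag(sigma) <- 0
  dimnames(W) <- dimnames(D)
  structure(list(W = W, sigma = sigma, A = NULL, edges = NULL,
                 patient_ids = rownames(D), params = params),
            class = "similarity_graph")
}

#' Threshold a similarity matrix into a binary adjacency
#'
#' An undirected edge joins patients i and j when `W(i, j) > c` (strict).
#' Because the kernel carries a normal-density prefactor, W is not bounded
#' by 1 and the effective meaning of `c` depends on the distance scale;
#' `renormalize = TRUE` min-max rescales the off-diagonal similarities to
#' \[0, 1\] before comparing against `c`.
#'
#' @param graph A `similarity_graph` from [similarity_kernel()].
#' @param c Threshold (default taken from the graph's kernel parameters).
#' @param renormalize Min-max rescale W before thresholding (default FALSE,
#'   the literal kernel scale).
#' @return The graph with binary `A` (zero diagonal, symmetric) and an
#'   `edges` data frame (columns `i`, `j`, `w`; i < j).
#' @export
threshold_adjacency <- function(graph, c = graph$params$threshold_c,
                                renormalize = FALSE) {
  W <- graph$W
  n <- nrow(W)
  Wcmp <- W
  if (renormalize && n > 1L) {
    off <- W[row(W) != col(W)]
    rng <- range(off)
    if (diff(rng) > 0) Wcmp <- (W - rng[1]) / diff(rng)
  }
  A <- (Wcmp > c) * 1
  diag(A) <- 0
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  graph$A <- A
  graph$edges <- data.frame(i = idx[, 1], j = idx[, 2],
                            w = W[idx])
  graph
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d patients", nrow(x$W)))
  if (!is.null(x$A)) cat(sprintf(", %d edges", nrow(x$edges)))
  cat("\n")
  invisible(x)
}

#' Restrict a similarity graph to a subset of patients
#'
#' Used by the inductive split protocol: the cohort graph is cut into
#' disjoint training / validation / test graphs, so no message passing ever
#' crosses a split boundary.
#'
#' @param graph A `similarity_graph`.
#' @param rows Integer indices of patients to keep (order preserved).
#' @return The induced `similarity_graph`.
#' @export
induce_subgraph <- function(graph, rows) {
  rows <- as.integer(rows)
  if (length(rows) == 0L) stop("cannot induce an empty subgraph")
  out <- graph
  out$W <- graph$W[rows, rows, drop = FALSE]
  out$sigma <- graph$sigma[rows, rows, drop = FALSE]
  out$patient_ids <- graph$patient_ids[rows]
  if (!is.null(graph$A)) {
    out$A <- graph$A[rows, rows, drop = FALSE]
    idx <- which(out$A == 1 & upper.tri(out$A), arr.ind = TRUE)
    out$edges <- data.frame(i = idx[, 1], j = idx[, 2], w = out$W[idx])
  }
  out
}

#' Build the patient similarity graph in one call
#'
#' Distance, kernel and adjacency in sequence. The feature matrix should
#' already be standardized (see [standardize_features()]).
#'
#' @param X A [feature_matrix()].
#' @param params A [kernel_params()].
#' @param renormalize Passed to [threshold_adjacency()].
#' @return A `similarity_graph` with `W`, `sigma`, `A`, `edges` filled.
#' @export
build_patient_graph <- function(X, params = kernel_params(),
                                renormalize = FALSE) {
  d <- correlation_distance(X, distance = params$distance)
  g <- similarity_kernel(d$D, params)
  threshold_adjacency(g, renormalize = renormalize)
}

#' Write the weighted edge list as a 3-column TSV
#'
#' @param graph A thresholded `similarity_graph`.
#' @param path Output file.
#' @export
write_edge_list <- function(graph, path) {
  if (is.null(graph$edges)) stop("graph has no edges; run threshold_adjacency first")
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the adjacency matrix in coordinate (matrix-market style) text
#'
#' Plain-text triplet format: a size header line `n n nnz` followed by one
#' `i j 1` line per stored (upper-triangle) edge.
#'
#' @param graph A thresholded `similarity_graph`.
#' @param path Output file.
#' @export
write_adjacency_coo <- function(graph, path) {
  if (is.null(graph$A)) stop("graph has no adjacency; run threshold_adjacency first")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer symmetric", con)
  e <- graph$edges
  writeLines(sprintf("%d %d %d", nrow(graph$A), ncol(graph$A), nrow(e)), con)
  if (nrow(e)) writeLines(sprintf("%d %d 1", e$j, e$i), con)
  invisible(path)
}
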
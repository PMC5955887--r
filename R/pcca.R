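#' PCCA+ metastability analysis
#'
#' Perron-cluster cluster analysis on a reversible transition matrix:
#' membership vectors are obtained from the simplex structure of the
#' `n_clusters` dominant right eigenvectors (inner simplex algorithm:
#' spanning rows are selected as vertices and memberships follow from the
#' linear transform onto the vertex basis).  Memberships are clipped to
#' \[0, 1\] and row-normalized; crisp labels are the membership argmax with
#' ties broken toward the lower cluster index.
#'
#' @param T row-stochastic reversible transition matrix.
#' @param n_clusters number of metastable clusters (1 <= n <= spectral
#'   rank); must not exceed the number of numerically real leading
#'   eigenvalues.
#' @param pi optional stationary distribution (computed if missing).
#' @return An object of class `pcca`: `memberships` (states x clusters),
#'   `labels` (crisp assignment), `n_clusters`, `sets` (list of member
#'   state indices per cluster).
#' @export
pcca_plus <- function(T, n_clusters, pi = NULL) {
  n <- nrow(T)
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (n_clusters > n) stop("n_clusters exceeds the number of states")
  if (n_clusters == 1) {
    chi <- matrix(1, n, 1)
    return(structure(list(memberships = chi, labels = rep(1L, n),
                          n_clusters = 1L, sets = list(seq_len(n))),
                     class = "pcca"))
  }
  ed <- reversible_eigen(T, pi)
  vals <- ed$values[seq_len(n_clusters)]
  if (any(abs(Im(vals)) > 1e-10))
    stop("complex leading eigenvalues: matrix is not reversible")
  X <- ed$vectors_right[, seq_len(n_clusters), drop = FALSE]
  X[, 1] <- 1  # the stationary eigenvector, exactly constant
  verts <- inner_simplex_vertices(X)
  A <- solve(X[verts, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  labels <- max.col(chi, ties.method = "first")
  if (length(unique(labels)) < n_clusters)
    warning("PCCA+ produced an empty cluster under crisp assignment")
  structure(list(memberships = chi, labels = labels,
                 n_clusters = as.integer(n_clusters),
                 sets = split(seq_len(n), factor(labels,
                                                 levels = seq_len(n_clusters)))),
            class = "pcca")
}

# inner simplex algorithm: pick the state furthest from the origin of the
# (row-shifted) eigenvector space, then repeatedly the state furthest from
# the affine span of the vertices chosen so far
inner_simplex_vertices <- function(X) {
  m <- ncol(X)
  n <- nrow(X)
  verts <- integer(m)
  Y <- X
  # first vertex: largest norm after removing the constant first column
  norms <- rowSums(Y[, -1, drop = FALSE]^2)
  verts[1] <- which.max(norms)
  Y <- sweep(Y, 2, X[verts[1], ])  # shift vertex 1 to the origin
  for (j in 2:m) {
    norms <- sqrt(rowSums(Y^2))
    verts[j] <- which.max(norms)
    piv <- Y[verts[j], ] / norms[verts[j]]
    Y <- Y - as.vector(Y %*% piv) %o% piv
  }
  verts
}
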
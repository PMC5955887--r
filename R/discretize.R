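#' k-means microstate discretization with a reserved unbound state
#'
#' Clusters the 4D-embedded frames with d < L/2 into `n_centers` microstates
#' (k-means++ seeding, Lloyd iterations, fixed seed); every frame with
#' d >= L/2 is assigned to one reserved "unbound" microstate with index
#' `n_centers + 1`.
#'
#' @param trajs list of `cv_trajectory` objects (typically swap-augmented).
#' @param n_centers number of k-means centres (>= 2).
#' @param L box side (nm); the unbound threshold is L/2.
#' @param seed random seed for the k-means++ initialisation.
#' @param iter_max maximum Lloyd iterations.
#' @return An object of class `discretization`: `centers` (n_centers x 4),
#'   `center_cvs` (d, alpha1, alpha2 of each centre, plus the reserved
#'   unbound row with d = L/2 and NA angles), `L`, `n_states`,
#'   `unbound_state`, and `dtrajs`, the discrete trajectories.
#' @export
kmeans_discretize <- function(trajs, n_centers, L, seed = 1L,
                              iter_max = 500L) {
  if (inherits(trajs, "cv_trajectory")) trajs <- list(trajs)
  if (n_centers < 2) stop("n_centers must be >= 2")
  emb <- lapply(trajs, embed_cv)
  all_y <- do.call(rbind, emb)
  dvals <- sqrt(all_y[, 1]^2 + all_y[, 2]^2)
  bound <- dvals < L / 2
  if (!any(bound)) stop("no frames with d < L/2: nothing to cluster")
  y <- all_y[bound, , drop = FALSE]
  if (nrow(unique(y)) < n_centers)
    stop("fewer distinct bound frames than requested centres")
  set.seed(seed)
  init <- kmeanspp_init(y, n_centers)
  km <- suppressWarnings(kmeans(y, centers = init, iter.max = iter_max,
                                algorithm = "Lloyd"))
  disc <- structure(list(centers = km$centers, L = L,
                         n_states = n_centers + 1L,
                         unbound_state = n_centers + 1L),
                    class = "discretization")
  cvc <- unembed_cv(km$centers)
  cvc <- rbind(cvc, data.frame(d = L / 2, alpha1 = NA, alpha2 = NA))
  disc$center_cvs <- cvc
  disc$dtrajs <- lapply(emb, function(m) assign_microstates(disc, m))
  disc
}

# k-means++ seeding: iteratively sample centres with probability
# proportional to the squared distance to the nearest chosen centre
kmeanspp_init <- function(y, k) {
  n <- nrow(y)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((y - rep(y[idx[1], ], each = n))^2)
  for (j in seq_len(k - 1)) {
    idx[j + 1] <- sample.int(n, 1, prob = pmax(d2, 1e-300))
    d2 <- pmin(d2, rowSums((y - rep(y[idx[j + 1], ], each = n))^2))
  }
  y[idx, , drop = FALSE]
}

#' Assign embedded frames to microstates
#'
#' Nearest-centre (Euclidean, in the embedded space) assignment for frames
#' with d < L/2; all other frames get the reserved unbound index.
#'
#' @param disc a [kmeans_discretize()] object.
#' @param y embedded frames (matrix with 4 columns) or a `cv_trajectory`.
#' @return integer vector of microstate indices.
#' @export
assign_microstates <- function(disc, y) {
  if (inherits(y, "cv_trajectory") || is.data.frame(y)) y <- embed_cv(y)
  if (is.null(dim(y))) y <- matrix(y, ncol = 4)
  d <- sqrt(y[, 1]^2 + y[, 2]^2)
  out <- rep.int(disc$unbound_state, nrow(y))
  b <- d < disc$L / 2
  if (any(b)) {
    cc <- disc$centers
    # argmin over centres of |y - c|^2 = |y|^2 - 2 y.c + |c|^2
    cross <- y[b, , drop = FALSE] %*% t(cc)
    scores <- sweep(-2 * cross, 2, rowSums(cc^2), "+")
    out[b] <- max.col(-scores, ties.method = "first")
  }
  out
}

#' Sliding-window transition counts
#'
#' Counts pairs (s_t, s_{t+lag}) within each trajectory; trajectories are
#' never concatenated.  Trajectories shorter than `lag + 1` frames
#' contribute nothing (with a warning).
#'
#' @param dtrajs list of integer state sequences (or a single vector).
#' @param lag lag time in frames (>= 1).
#' @param n_states number of states (default: largest index observed).
#' @return integer count matrix with attributes `lag`.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  C <- matrix(0L, n_states, n_states)
  short <- 0L
  for (dt in dtrajs) {
    n <- length(dt)
    if (n <= lag) { short <- short + 1L; next }
    from <- dt[seq_len(n - lag)]
    to <- dt[seq_len(n - lag) + lag]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + as.matrix(unclass(tab))
  }
  if (short > 0)
    warning(short, " trajectory(ies) shorter than the lag contributed no counts")
  dimnames(C) <- NULL
  structure(C, lag = lag)
}
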
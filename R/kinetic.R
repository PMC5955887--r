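#' Identify the unbound PCCA+ cluster
#'
#' Scans the number of PCCA+ clusters upward and returns the smallest value
#' for which at least one cluster (i) contains only microstates with
#' d > `d_min` and (ii) has a flat angular distribution, operationalized as
#' a population-weighted circular resultant length of the member angles
#' below `flatness` together with occupancy of at least 3 of the 4 angular
#' quadrants of the \eqn{(\alpha_1, \alpha_2)} plane.  The reserved
#' far-distance microstate passes both conditions by construction.
#'
#' @param model an `msm` or `tram_model` (provides `T`, `pi`, `active`).
#' @param disc the matching [kmeans_discretize()] discretization.
#' @param d_min minimal member distance of the unbound cluster (nm,
#'   default 4.2).
#' @param flatness circular resultant-length threshold.
#' @param n_max largest cluster number tried before giving up.
#' @param n_min smallest cluster number tried.
#' @return list with `n_clusters`, `cluster` (unbound cluster id),
#'   `clustering` (the [pcca_plus()] object), `unbound_microstates`
#'   (indices in the original state numbering).
#' @export
select_unbound <- function(model, disc, d_min = 4.2, flatness = 0.3,
                           n_max = 40L, n_min = 2L) {
  cvs <- disc$center_cvs[model$active, , drop = FALSE]
  pi <- model$pi
  if (length(pi) != length(model$active)) pi <- pi[model$active]
  for (nc in seq.int(n_min, n_max)) {
    cl <- try(pcca_plus(model$T, nc, pi = pi / sum(pi)), silent = TRUE)
    if (inherits(cl, "try-error")) break
    for (k in seq_len(nc)) {
      mem <- cl$sets[[k]]
      if (!length(mem)) next
      if (is_unbound_cluster(cvs[mem, , drop = FALSE], pi[mem],
                             disc$unbound_state %in% model$active[mem],
                             d_min, flatness))
        return(list(n_clusters = nc, cluster = k, clustering = cl,
                    unbound_microstates = model$active[mem]))
    }
  }
  stop("no unbound cluster (all d > ", d_min,
       ", flat angles) found up to n_clusters = ", n_max)
}

is_unbound_cluster <- function(cvs, w, has_reserved, d_min, flatness) {
  far <- is.na(cvs$d) | cvs$d > d_min
  if (!all(far)) return(FALSE)
  ang <- !is.na(cvs$alpha1)
  if (!any(ang)) return(has_reserved)  # only the reserved far state
  w <- w[ang] / sum(w[ang])
  a1 <- cvs$alpha1[ang]; a2 <- cvs$alpha2[ang]
  # resultant length on the doubled angle (alpha lives on [0, pi])
  r1 <- sqrt(sum(w * cos(2 * a1))^2 + sum(w * sin(2 * a1))^2)
  r2 <- sqrt(sum(w * cos(2 * a2))^2 + sum(w * sin(2 * a2))^2)
  if (max(r1, r2) >= flatness) return(FALSE)
  quad <- unique(paste(a1 > pi / 2, a2 > pi / 2))
  length(quad) >= min(3, length(a1))
}

#' Kinetically disconnected components of the bound clusters
#'
#' Removes the unbound cluster and finds the connected components of the
#' remaining PCCA+ clusters on the support of the inter-cluster transition
#' counts (an edge exists wherever any transition between member
#' microstates was observed).  Each component is labelled C00, Cpipi, C0pi
#' or Cpi0 according to the population-weighted circular means of its
#' member microstates' angles (within pi/4 of 0 -> "0", within pi/4 of
#' pi -> "pi", anything else -> "other").
#'
#' @param clustering a [pcca_plus()] result on the model's active states.
#' @param counts count matrix over the original microstate numbering.
#' @param model the `msm`/`tram_model` the clustering was computed from.
#' @param disc the discretization (for the centre collective variables).
#' @param unbound_cluster cluster id to exclude.
#' @return An object of class `component_decomposition`: `components` (list
#'   of cluster-id vectors), `labels` (C00/Cpipi/C0pi/Cpi0/other),
#'   `microstates` (list of member microstates, original numbering),
#'   `unbound_cluster`, `unbound_microstates`, `cluster_of` (cluster id per
#'   active state), `mean_angles` (per component).
#' @export
disconnected_components <- function(clustering, counts, model, disc,
                                    unbound_cluster) {
  labels <- clustering$labels
  nc <- clustering$n_clusters
  C <- unclass(as.matrix(counts))[model$active, model$active, drop = FALSE]
  keep <- setdiff(seq_len(nc), unbound_cluster)
  # cluster-level support graph
  A <- matrix(FALSE, nc, nc)
  sup <- (C + t(C)) > 0
  for (a in keep) for (b in keep) if (a < b) {
    A[a, b] <- A[b, a] <-
      any(sup[labels == a, labels == b, drop = FALSE])
  }
  g <- igraph::graph_from_adjacency_matrix(A[keep, keep, drop = FALSE],
                                           mode = "undirected")
  comp <- igraph::components(g)
  comps <- split(keep, comp$membership)
  cvs <- disc$center_cvs[model$active, , drop = FALSE]
  pi <- model$pi
  if (length(pi) != length(model$active)) pi <- pi[model$active]
  info <- lapply(comps, function(cl_set) {
    mem <- which(labels %in% cl_set)
    ok <- !is.na(cvs$alpha1[mem])
    w <- pi[mem][ok] / sum(pi[mem][ok])
    m1 <- circ_mean_halfturn(cvs$alpha1[mem][ok], w)
    m2 <- circ_mean_halfturn(cvs$alpha2[mem][ok], w)
    list(mean = c(m1, m2), label = component_label(m1, m2),
         microstates = model$active[mem],
         weight = sum(pi[mem]))
  })
  ord <- order(-vapply(info, function(x) x$weight, 1))
  comps <- comps[ord]; info <- info[ord]
  structure(list(
    components = unname(comps),
    labels = vapply(info, function(x) x$label, ""),
    microstates = lapply(info, function(x) x$microstates),
    mean_angles = t(vapply(info, function(x) x$mean, numeric(2))),
    weights = vapply(info, function(x) x$weight, 1),
    unbound_cluster = unbound_cluster,
    unbound_microstates = model$active[labels == unbound_cluster],
    cluster_of = labels),
    class = "component_decomposition")
}

# weighted mean of angles restricted to [0, pi] (plain linear mean is the
# right notion on a half-turn; angles near 0 and pi never mix within one
# orientational basin)
circ_mean_halfturn <- function(a, w) sum(w * a)

component_label <- function(m1, m2) {
  lab <- function(m) {
    if (m <= pi / 4) "0" else if (m >= 3 * pi / 4) "pi" else "other"
  }
  l1 <- lab(m1); l2 <- lab(m2)
  if (l1 == "other" || l2 == "other") return("other")
  paste0("C", l1, l2)  # "C00", "C0pi", "Cpi0", "Cpipi"
}

#' Merge PCCA clusters into swap-symmetric macrostates
#'
#' Pairs every bound PCCA cluster with its mirror image under the protomer
#' exchange \eqn{\alpha_1 \leftrightarrow \alpha_2} (mirrors are found by
#' mapping member microstate centres through the swap and re-assigning
#' them to clusters by majority vote).  Mirrors of clusters in the
#' asymmetric components live in the opposite component, so merged
#' macrostates may span the C0pi/Cpi0 pair; the `component` column then
#' lists both.  Self-mirror clusters form singleton macrostates; mutual
#' pairs are merged; an unpaired mirror is kept unmerged with a warning.
#'
#' @param decomp a [disconnected_components()] result.
#' @param model the underlying model (for `active`).
#' @param disc the discretization.
#' @return data frame with one row per macrostate: `macrostate`,
#'   `component`, `clusters` (comma-separated cluster ids), `microstates`
#'   (list column), `weight`.
#' @export
assemble_macrostates <- function(decomp, model, disc) {
  labels <- decomp$cluster_of
  act <- model$active
  cvs <- disc$center_cvs[act, , drop = FALSE]
  # swap image of each active microstate: nearest centre of the swapped CVs
  sw <- data.frame(d = cvs$d, alpha1 = cvs$alpha2, alpha2 = cvs$alpha1)
  ok <- !is.na(sw$alpha1)
  img <- rep(NA_integer_, nrow(sw))
  img[ok] <- assign_microstates(disc, embed_cv(sw[ok, , drop = FALSE]))
  img_act <- match(img, act)  # may be NA for unvisited mirrors
  mirror_cluster <- function(cl) {
    mem <- which(labels == cl)
    tgt <- labels[img_act[mem]]
    tgt <- tgt[!is.na(tgt)]
    if (!length(tgt)) return(NA_integer_)
    as.integer(names(sort(table(tgt), decreasing = TRUE))[1])
  }
  pi <- model$pi
  if (length(pi) != length(act)) pi <- pi[act]
  comp_of <- integer(0)
  for (ci in seq_along(decomp$components))
    comp_of[decomp$components[[ci]]] <- ci
  cls <- sort(unlist(decomp$components))  # mirrors of asymmetric clusters
  mir <- vapply(cls, mirror_cluster, 1L)  # live in the mirror component
  done <- logical(length(cls))
  rows <- list()
  for (k in seq_along(cls)) {
    if (done[k]) next
    cl <- cls[k]
    partner <- mir[k]
    group <- cl
    if (!is.na(partner) && partner != cl) {
      pk <- match(partner, cls)
      if (!is.na(pk) && !done[pk] && !is.na(mir[pk]) && mir[pk] == cl) {
        group <- c(cl, partner)
        done[pk] <- TRUE
      } else {
        warning("cluster ", cl, " has no mutual swap partner; kept unmerged")
      }
    }
    done[k] <- TRUE
    mem <- which(labels %in% group)
    rows[[length(rows) + 1]] <- data.frame(
      component = paste(sort(unique(comp_of[group])), collapse = "+"),
      clusters = paste(group, collapse = ","),
      weight = sum(pi[mem]))
    rows[[length(rows)]]$microstates <- list(act[mem])
  }
  out <- do.call(rbind, rows)
  out$macrostate <- seq_len(nrow(out))
  out[, c("macrostate", "component", "clusters", "microstates", "weight")]
}

#' Cross-relaxation-preserving coarse-graining of a transition matrix
#'
#' Reduces a microstate transition matrix onto a partition while imposing
#' the cross-relaxation behaviour of the full model (the aggregated
#' zero-frequency occupation correlations): with the fundamental matrix
#' \eqn{Z = (I - T + \mathbf{1}\pi^\top)^{-1}}, the aggregate
#' \eqn{H_{JI} = \sum_{j \in J, i \in I} \pi_j Z_{ji} / \pi^{CG}_J}
#' plays the role of the coarse fundamental matrix, and
#' \eqn{T^{CG} = I + \mathbf{1}\pi_{CG}^\top - H^{-1}}.  By construction
#' the result is exactly row-stochastic and the aggregated stationary
#' distribution \eqn{\pi^{CG}_I = \sum_{i\in I}\pi_i} is exactly
#' stationary, for any partition; entries can come out (slightly) negative
#' when the partition is kinetically inconsistent with the model, which is
#' reported as an error beyond a small tolerance.
#'
#' @param T row-stochastic microstate matrix.
#' @param pi its stationary distribution.
#' @param partition list of index vectors covering all states exactly once,
#'   or an integer group-label vector.
#' @param neg_tol largest tolerated negative entry (clipped to zero with
#'   the row renormalized); beyond it the partition is rejected.
#' @return list with `T_cg`, `pi_cg` and `H` (the aggregated fundamental
#'   matrix).
#' @export
coarse_grain <- function(T, pi, partition, neg_tol = 1e-8) {
  n <- nrow(T)
  if (!is.list(partition)) partition <- split(seq_len(n), partition)
  if (!setequal(unlist(partition), seq_len(n)) ||
      length(unlist(partition)) != n)
    stop("partition must cover every state exactly once")
  m <- length(partition)
  # a reducible chain has a singular fundamental matrix; its closed classes
  # are absorbing at the coarse level, so treat each class separately
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    (T + t(T)) > 0, mode = "undirected"))$membership
  if (max(comp) > 1) {
    grp_comp <- vapply(partition, function(I) {
      u <- unique(comp[I])
      if (length(u) > 1)
        stop("a partition group straddles disconnected chain components")
      u
    }, 1)
    T_cg <- matrix(0, m, m)
    for (cc in unique(comp)) {
      gi <- which(grp_comp == cc)
      si <- which(comp == cc)
      sub <- coarse_grain(T[si, si, drop = FALSE], pi[si] / sum(pi[si]),
                          lapply(partition[gi], function(I) match(I, si)),
                          neg_tol = neg_tol)
      T_cg[gi, gi] <- sub$T_cg
    }
    pi_cg <- vapply(partition, function(I) sum(pi[I]), 1)
    return(list(T_cg = T_cg, pi_cg = pi_cg, H = NULL))
  }
  Z <- solve(diag(n) - T + matrix(pi, n, n, byrow = TRUE))
  pi_cg <- vapply(partition, function(I) sum(pi[I]), 1)
  G <- pi * Z                                  # G_ji = pi_j Z_ji
  H <- matrix(0, m, m)
  for (J in seq_len(m)) for (I in seq_len(m)) {
    H[J, I] <- sum(G[partition[[J]], partition[[I]], drop = FALSE]) / pi_cg[J]
  }
  T_cg <- diag(m) + matrix(pi_cg, m, m, byrow = TRUE) - solve(H)
  if (any(T_cg < -neg_tol))
    stop("negative coarse-grained transition probabilities (",
         signif(min(T_cg), 3),
         "): partition is kinetically inconsistent with the model")
  T_cg[T_cg < 0] <- 0
  T_cg <- T_cg / rowSums(T_cg)
  list(T_cg = T_cg, pi_cg = pi_cg, H = H)
}

#' Forward committor probabilities
#'
#' Solves the transition-path-theory linear system for the probability of
#' reaching the sink set before the source set.
#'
#' @param T row-stochastic transition matrix.
#' @param source,sink disjoint non-empty index sets.
#' @return numeric vector: 0 on the source, 1 on the sink.
#' @export
committor <- function(T, source, sink) {
  n <- nrow(T)
  if (!length(source) || !length(sink)) stop("source and sink must be non-empty")
  if (length(intersect(source, sink))) stop("source and sink must be disjoint")
  q <- rep(NA_real_, n)
  q[source] <- 0; q[sink] <- 1
  mid <- setdiff(seq_len(n), c(source, sink))
  if (length(mid)) {
    M <- diag(length(mid)) - T[mid, mid, drop = FALSE]
    rhs <- rowSums(T[mid, sink, drop = FALSE])
    sol <- try(solve(M, rhs), silent = TRUE)
    if (inherits(sol, "try-error"))
      stop("singular committor system: sink unreachable from some states")
    q[mid] <- pmin(1, pmax(0, sol))
  }
  q
}

#' Select umbrella-window centres by committor probability
#'
#' For every bound component, computes the forward committor from the
#' reserved unbound microstate to the component's most probable microstate
#' and selects all microstate centres with committor above `threshold`.
#'
#' @param model preliminary `msm` (with `T`, `pi`, `active`).
#' @param disc the discretization.
#' @param decomp a [disconnected_components()] result.
#' @param threshold committor cutoff (default 0.10).
#' @return data frame with `microstate`, `component`, `committor` and the
#'   centre collective variables; one row per selected centre (sinks are
#'   included, having committor 1).
#' @export
select_umbrella_centers <- function(model, disc, decomp, threshold = 0.1) {
  act <- model$active
  src <- match(disc$unbound_state, act)
  if (is.na(src)) stop("reserved unbound microstate not in the active set")
  pi <- model$pi
  if (length(pi) != length(act)) pi <- pi[act]
  rows <- list()
  for (ci in seq_along(decomp$microstates)) {
    mem <- match(decomp$microstates[[ci]], act)
    sink <- mem[which.max(pi[mem])]
    q <- committor(model$T, source = src, sink = sink)
    sel <- mem[q[mem] > threshold]
    if (!length(sel)) next
    rows[[length(rows) + 1]] <- data.frame(
      microstate = act[sel], component = ci, committor = q[sel],
      disc$center_cvs[act[sel], , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transition-path flux decomposition into pathways
#'
#' Computes the net reactive flux from a source to a sink set and peels it
#' into pathways by repeatedly extracting the widest (maximum-bottleneck)
#' path and removing its bottleneck flux.
#'
#' @param T row-stochastic transition matrix.
#' @param pi stationary distribution.
#' @param source,sink disjoint index sets.
#' @param max_paths maximum number of pathways returned.
#' @param frac stop once this fraction of the total flux is decomposed.
#' @return list with `total_flux` (per lag step), `pathways` (list of state
#'   index vectors), `flux` (per pathway), `fraction` (per pathway, of the
#'   total flux).
#' @export
flux_partition <- function(T, pi, source, sink, max_paths = 20L,
                           frac = 0.999) {
  qf <- committor(T, source, sink)
  qb <- 1 - qf  # reversible backward committor
  n <- nrow(T)
  F <- outer(pi * qb, qf) * T
  diag(F) <- 0
  Fnet <- pmax(F - t(F), 0)
  total <- sum(Fnet[source, setdiff(seq_len(n), source), drop = FALSE])
  if (total <= 0) stop("zero total reactive flux between source and sink")
  paths <- list(); fluxes <- numeric(0)
  Fr <- Fnet
  removed <- 0
  while (length(paths) < max_paths && removed < frac * total) {
    bp <- bottleneck_path(Fr, source, sink)
    if (is.null(bp)) break
    paths[[length(paths) + 1]] <- bp$path
    fluxes <- c(fluxes, bp$capacity)
    for (e in seq_len(length(bp$path) - 1))
      Fr[bp$path[e], bp$path[e + 1]] <- Fr[bp$path[e], bp$path[e + 1]] -
        bp$capacity
    removed <- removed + bp$capacity
  }
  list(total_flux = total, pathways = paths, flux = fluxes,
       fraction = fluxes / total)
}

# widest (maximum-bottleneck) path via a Dijkstra-like sweep
bottleneck_path <- function(F, source, sink) {
  n <- nrow(F)
  width <- rep(-Inf, n); width[source] <- Inf
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & width > -Inf)
    if (!length(cand)) break
    u <- cand[which.max(width[cand])]
    done[u] <- TRUE
    if (u %in% sink) break
    for (v in which(F[u, ] > 0)) {
      w <- min(width[u], F[u, v])
      if (w > width[v]) { width[v] <- w; prev[v] <- u }
    }
  }
  ends <- sink[width[sink] > 0]
  if (!length(ends)) return(NULL)
  end <- ends[which.max(width[ends])]
  path <- end
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  if (!(path[1] %in% source)) return(NULL)
  list(path = path, capacity = width[end])
}
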
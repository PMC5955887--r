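#' Inter-protomer residue contacts of one frame
#'
#' A residue pair (i from protomer 1, j from protomer 2) is in contact when
#' any of its backbone bead pairs lies below the cutoff (minimal-image
#' distance); each residue pair counts at most once per frame.
#'
#' @param frame a `bead_frame` (see [decorate_beads()]).
#' @param cutoff contact distance (nm, default 0.8).
#' @return data frame with columns `i`, `j` (residue numbers), possibly
#'   empty.
#' @export
frame_contacts <- function(frame, cutoff = 0.8) {
  box <- attr(frame, "box")
  p1 <- frame$protomer == 1
  p2 <- frame$protomer == 2
  if (!any(p1) || !any(p2)) stop("both protomers must have backbone beads")
  a <- as.matrix(frame[p1, c("x", "y", "z")])
  b <- as.matrix(frame[p2, c("x", "y", "z")])
  res1 <- frame$residue[p1]; res2 <- frame$residue[p2]
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.na(box[k]) && box[k] > 0) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(data.frame(i = integer(0), j = integer(0)))
  unique(data.frame(i = res1[hit[, 1]], j = res2[hit[, 2]]))
}

#' Per-microstate contact statistics and the dimeric flag
#'
#' For every microstate k, computes from unbiased frames the probability
#' \eqn{p^{Tot}_k(n)} of observing at least n inter-protomer contacts and
#' the per-residue-pair contact probability \eqn{p^{Micro}_k(i,j)}.
#' Microstates with \eqn{p^{Tot}_k(n_{dimer}) \ge p_{dimer}} are flagged
#' dimeric (defaults: at least 10 contacts with probability 0.9).
#'
#' @param dtraj integer microstate assignment, one entry per frame.
#' @param frames list of `bead_frame`s aligned with `dtraj`.
#' @param n_states total number of microstates.
#' @param cutoff contact cutoff (nm).
#' @param n_dimer,p_dimer dimeric-microstate rule.
#' @return An object of class `contact_stats`: `n_frames` (per state),
#'   `p_tot` (state x (n+1) matrix; column n+1 is P(contacts >= n)),
#'   `pairs` (data frame `state`, `i`, `j`, `p`), `dimeric` (logical,
#'   NA for states without frames).
#' @export
microstate_stats <- function(dtraj, frames, n_states,
                             cutoff = 0.8, n_dimer = 10, p_dimer = 0.9) {
  stopifnot(length(dtraj) == length(frames))
  counts <- integer(length(frames))
  pair_rows <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    ct <- frame_contacts(frames[[f]], cutoff = cutoff)
    counts[f] <- nrow(ct)
    if (nrow(ct)) pair_rows[[f]] <- cbind(state = dtraj[f], ct)
  }
  n_frames <- tabulate(dtraj, nbins = n_states)
  nmax <- max(counts, n_dimer)
  p_tot <- matrix(NA_real_, n_states, nmax + 1,
                  dimnames = list(NULL, 0:nmax))
  for (s in which(n_frames > 0)) {
    cs <- counts[dtraj == s]
    p_tot[s, ] <- vapply(0:nmax, function(n) mean(cs >= n), 1)
  }
  allp <- do.call(rbind, pair_rows)
  pairs <- if (is.null(allp)) {
    data.frame(state = integer(0), i = integer(0), j = integer(0),
               p = numeric(0))
  } else {
    ag <- stats::aggregate(cbind(n = rep(1, nrow(allp))) ~ state + i + j,
                           data = allp, FUN = sum)
    ag$p <- ag$n / n_frames[ag$state]
    ag[, c("state", "i", "j", "p")]
  }
  dimeric <- ifelse(n_frames > 0, p_tot[, n_dimer + 1] >= p_dimer, NA)
  structure(list(n_frames = n_frames, p_tot = p_tot, pairs = pairs,
                 dimeric = dimeric, n_dimer = n_dimer, p_dimer = p_dimer,
                 cutoff = cutoff),
            class = "contact_stats")
}

#' Population-weighted contact map of a macrostate
#'
#' Aggregates the per-microstate contact probabilities of a macrostate's
#' dimeric microstates, weighted by their stationary probabilities:
#' \eqn{p_K(i,j) = \sum'_{k \in K} \pi_k p^{Micro}_k(i,j)} (the prime
#' restricts the sum to dimeric microstates).  Both the raw and the
#' normalized map (divided by the summed dimeric weight, used for interface
#' naming) are returned.
#'
#' @param stats a [microstate_stats()] object.
#' @param pi stationary probabilities over all microstates.
#' @param macrostate integer vector of member microstates.
#' @param normalized return the normalized map (default TRUE).
#' @return data frame `i`, `j`, `p` (empty if the macrostate has no dimeric
#'   microstates); attribute `dimeric_weight` holds \eqn{\sum'_k \pi_k}.
#' @export
macrostate_contact_map <- function(stats, pi, macrostate,
                                   normalized = TRUE) {
  dim_states <- macrostate[which(stats$dimeric[macrostate] %in% TRUE)]
  wtot <- sum(pi[dim_states])
  pr <- stats$pairs[stats$pairs$state %in% dim_states, , drop = FALSE]
  if (!nrow(pr) || wtot == 0) {
    out <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
    attr(out, "dimeric_weight") <- wtot
    return(out)
  }
  pr$w <- pi[pr$state] * pr$p
  ag <- stats::aggregate(w ~ i + j, data = pr, FUN = sum)
  names(ag)[3] <- "p"
  if (normalized) ag$p <- ag$p / wtot
  attr(ag, "dimeric_weight") <- wtot
  ag[order(ag$i, ag$j), ]
}

#' Population-averaged per-residue contact numbers
#'
#' Computes the stationary-weighted mean number of inter-protomer contacts
#' formed by each residue (per side) over all microstates, and the weighted
#' probability of each residue pair; returns ranked tables filtered at the
#' reporting thresholds.
#'
#' @param stats a [microstate_stats()] object.
#' @param pi stationary probabilities.
#' @param rmap a [region_map()] for region annotation.
#' @param res_threshold report residues with mean contacts above this
#'   (default 0.2).
#' @param pair_threshold report pairs with probability above this
#'   (default 0.1).
#' @return list with `residues` (residue, side, region, mean_contacts) and
#'   `pairs` (i, j, regions, p), both sorted decreasingly and filtered;
#'   unfiltered versions as attributes `residues_all`, `pairs_all`.
#' @export
residue_contact_summary <- function(stats, pi, rmap = region_map(),
                                    res_threshold = 0.2,
                                    pair_threshold = 0.1) {
  pr <- stats$pairs
  covered <- which(stats$n_frames > 0)
  wts <- pi[covered] / sum(pi[covered])
  names(wts) <- covered
  if (!nrow(pr)) {
    empty_r <- data.frame(residue = integer(0), side = integer(0),
                          region = character(0), mean_contacts = numeric(0))
    empty_p <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
    return(list(residues = empty_r, pairs = empty_p))
  }
  pr <- pr[pr$state %in% covered, , drop = FALSE]
  pr$w <- wts[as.character(pr$state)] * pr$p
  pair_ag <- stats::aggregate(w ~ i + j, data = pr, FUN = sum)
  names(pair_ag)[3] <- "p"
  reg <- setNames(rmap$region, rmap$residue)
  pair_ag$region_i <- reg[as.character(pair_ag$i)]
  pair_ag$region_j <- reg[as.character(pair_ag$j)]
  r1 <- stats::aggregate(p ~ i, data = pair_ag, FUN = sum)
  r2 <- stats::aggregate(p ~ j, data = pair_ag, FUN = sum)
  residues <- rbind(
    data.frame(residue = r1$i, side = 1L, mean_contacts = r1$p),
    data.frame(residue = r2$j, side = 2L, mean_contacts = r2$p))
  residues$region <- reg[as.character(residues$residue)]
  residues <- residues[order(-residues$mean_contacts), ]
  pair_ag <- pair_ag[order(-pair_ag$p), ]
  rownames(residues) <- rownames(pair_ag) <- NULL
  out <- list(residues = residues[residues$mean_contacts > res_threshold, ],
              pairs = pair_ag[pair_ag$p > pair_threshold, ])
  attr(out, "residues_all") <- residues
  attr(out, "pairs_all") <- pair_ag
  out
}

#' Name a dimer interface from region-level contact counts
#'
#' Regions with more than three expected contacts per frame appear in the
#' interface name; regions with three or fewer (but more than zero) appear
#' in parentheses.  Regions are listed in sequence order, consecutive TM
#' helices are collapsed ("TM1,2"), and the two sides are joined by "/"
#' in canonical (lexicographically sorted) order.
#'
#' @param map a macrostate contact map (data frame `i`, `j`, `p`), expected
#'   contacts per frame after normalization.
#' @param rmap a [region_map()].
#' @param threshold full-membership threshold ("more than three contacts").
#' @return An interface label string; `""` for an empty map.
#' @export
name_interface <- function(map, rmap = region_map(), threshold = 3) {
  if (!nrow(map)) return("")
  reg <- setNames(rmap$region, rmap$residue)
  side1 <- tapply(map$p, reg[as.character(map$i)], sum)
  side2 <- tapply(map$p, reg[as.character(map$j)], sum)
  s1 <- render_side(side1, rmap, threshold)
  s2 <- render_side(side2, rmap, threshold)
  paste(sort(c(s1, s2))[c(1, 2)], collapse = "/")
}

render_side <- function(counts, rmap, threshold) {
  ord <- unique(rmap$region)
  present <- ord[ord %in% names(counts)[counts > 0]]
  if (!length(present)) return("")
  pieces <- character(0)
  prev_tm <- FALSE
  for (r in present) {
    is_tm <- grepl("^TM", r)
    lab <- if (is_tm && prev_tm) sub("^TM", "", r) else r
    if (counts[[r]] <= threshold) lab <- paste0("(", lab, ")")
    pieces <- c(pieces, lab)
    prev_tm <- is_tm
  }
  paste(pieces, collapse = ",")
}
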
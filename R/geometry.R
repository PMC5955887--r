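#' Residue-to-region map for a class-A receptor
#'
#' Contiguous assignment of residues 65--352 to the canonical topological
#' regions of a 7TM receptor (N-terminus, TM1--TM7 connected by intra- and
#' extracellular loops, the amphipathic helix H8 and the C-terminus),
#' together with generic Ballesteros--Weinstein labels for the helical
#' residues (helix.position, with position 50 at the helix midpoint).
#' Boundaries are approximate and can be replaced by a custom table.
#'
#' @param boundaries optional data frame with columns `region`, `from`, `to`
#'   covering a contiguous residue range without overlaps.
#' @return data frame with columns `residue`, `region`, `bw` (NA outside
#'   helices), of class `region_map`.
#' @export
region_map <- function(boundaries = NULL) {
  if (is.null(boundaries)) {
    boundaries <- data.frame(
      region = c("N-term", "TM1", "IL1", "TM2", "EL1", "TM3", "IL2", "TM4",
                 "EL2", "TM5", "IL3", "TM6", "EL3", "TM7", "H8", "C-term"),
      from = c(65, 77, 107, 114, 142, 147, 179, 186,
               213, 227, 261, 269, 299, 305, 333, 345),
      to   = c(76, 106, 113, 141, 146, 178, 185, 212,
               226, 260, 268, 298, 304, 332, 344, 352),
      stringsAsFactors = FALSE)
  }
  o <- order(boundaries$from)
  boundaries <- boundaries[o, ]
  if (any(boundaries$from[-1] != boundaries$to[-nrow(boundaries)] + 1))
    stop("region boundaries must tile a contiguous residue range")
  res <- unlist(Map(seq, boundaries$from, boundaries$to))
  reg <- rep(boundaries$region, boundaries$to - boundaries$from + 1)
  bw <- rep(NA_character_, length(res))
  helix_num <- c(TM1 = 1, TM2 = 2, TM3 = 3, TM4 = 4, TM5 = 5, TM6 = 6,
                 TM7 = 7, H8 = 8)
  for (h in names(helix_num)) {
    idx <- which(reg == h)
    if (!length(idx)) next
    mid <- idx[ceiling(length(idx) / 2)]
    bw[idx] <- sprintf("%d.%d", helix_num[[h]], 50 + (idx - mid))
  }
  structure(data.frame(residue = res, region = reg, bw = bw,
                       stringsAsFactors = FALSE),
            class = c("region_map", "data.frame"))
}

#' Synthetic backbone-bead template of one protomer
#'
#' Places one backbone bead per residue in a protomer-fixed frame: the eight
#' helices sit at fixed azimuths on a circle of radius `radius`, residues of
#' a helix are fanned over a small arc, loops and termini bridge their
#' flanking helices slightly outside the helical ring.  The layout is
#' quasi-two-dimensional (all beads at z = 0, in the membrane plane) so that
#' rigid-body decoration of a collective-variable frame round-trips exactly
#' through the 3D angle definition.  The TM1/TM2/H8 face points along
#' azimuth 0 and the TM4/TM5/TM6 face along azimuth pi, matching the
#' orientational convention of the interaction wells.
#'
#' @param rmap a [region_map()].
#' @param radius helical ring radius (nm).
#' @return data frame `residue`, `region`, `x`, `y`, `z` with the protomer
#'   centre of mass at the origin; attribute `tm1_residues` holds the TM1
#'   residue numbers.
#' @export
mor_bead_template <- function(rmap = region_map(), radius = 1.3) {
  azim <- c(TM1 = 0, TM2 = 45, TM3 = 100, TM4 = 150, TM5 = 190, TM6 = 230,
            TM7 = 305, H8 = 330,
            "N-term" = 350, IL1 = 72, EL1 = 72, IL2 = 125, EL2 = 170,
            IL3 = 210, EL3 = 268, "C-term" = 340) * pi / 180
  helices <- c("TM1", "TM2", "TM3", "TM4", "TM5", "TM6", "TM7", "H8")
  out <- lapply(split(rmap, rmap$region), function(seg) {
    n <- nrow(seg)
    a0 <- azim[[seg$region[1]]]
    r <- if (seg$region[1] %in% helices) radius else 1.12 * radius
    # fan the residues over a +/- 10 degree arc, alternating radius a little
    arc <- a0 + seq(-10, 10, length.out = max(n, 2))[seq_len(n)] * pi / 180
    rr <- r + 0.12 * rep_len(c(-1, 0, 1), n)
    data.frame(residue = seg$residue, region = seg$region,
               x = rr * cos(arc), y = rr * sin(arc), z = 0)
  })
  tpl <- do.call(rbind, out)
  tpl <- tpl[order(tpl$residue), ]
  rownames(tpl) <- NULL
  tpl$x <- tpl$x - mean(tpl$x)
  tpl$y <- tpl$y - mean(tpl$y)
  attr(tpl, "tm1_residues") <- rmap$residue[rmap$region == "TM1"]
  tpl
}

new_bead_frame <- function(df, box) {
  structure(df, class = c("bead_frame", "data.frame"), box = box)
}

com <- function(m) colMeans(m)

min_image <- function(v, box) {
  ok <- !is.na(box) & box > 0
  v[ok] <- v[ok] - box[ok] * round(v[ok] / box[ok])
  v
}

#' Collective variables of a bead frame
#'
#' Computes the order parameter \eqn{(d, \alpha_1, \alpha_2)}: `d` is the
#' minimal-image distance between the protomer centres of mass (backbone
#' beads only, unweighted), `alpha1` the unsigned angle at protomer 1's COM
#' between the vector to its TM1 COM and the vector to protomer 2's COM, and
#' `alpha2` the same with the protomers swapped.
#'
#' @param frame a bead frame: data frame with columns `protomer` (1/2),
#'   `residue`, `x`, `y`, `z` and a `box` attribute (periodic cell lengths,
#'   NA for non-periodic directions).
#' @param tm1_residues residue numbers forming TM1 (same in both protomers).
#' @param project `"3d"` computes the angles from the full 3D vectors
#'   (default); `"plane"` projects onto the membrane (xy) plane first.
#' @return list with elements `d`, `alpha1`, `alpha2`.
#' @export
compute_cvs <- function(frame, tm1_residues, project = c("3d", "plane")) {
  project <- match.arg(project)
  box <- attr(frame, "box")
  if (is.null(box)) box <- rep(NA_real_, 3)
  if (!length(tm1_residues)) stop("tm1_residues must be non-empty")
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  p1 <- frame$protomer == 1
  p2 <- frame$protomer == 2
  if (!any(p1) || !any(p2)) stop("both protomers must be present")
  in_tm1 <- frame$residue %in% tm1_residues
  if (!any(p1 & in_tm1) || !any(p2 & in_tm1))
    stop("tm1_residues not found in both protomers")
  c1 <- com(xyz[p1, , drop = FALSE]); c2 <- com(xyz[p2, , drop = FALSE])
  t1 <- com(xyz[p1 & in_tm1, , drop = FALSE])
  t2 <- com(xyz[p2 & in_tm1, , drop = FALSE])
  r12 <- min_image(c2 - c1, box)
  v1 <- t1 - c1
  v2 <- t2 - c2
  if (project == "plane") { r12[3] <- 0; v1[3] <- 0; v2[3] <- 0 }
  d <- sqrt(sum(r12^2))
  if (sqrt(sum(v1^2)) < 1e-10 || sqrt(sum(v2^2)) < 1e-10)
    stop("degenerate geometry: TM1 COM coincides with protomer COM")
  ang <- function(a, b) {
    cc <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    acos(pmin(1, pmax(-1, cc)))
  }
  list(d = d, alpha1 = ang(v1, r12), alpha2 = ang(v2, -r12))
}

#' 4D periodicity-free embedding of the collective variables
#'
#' Maps \eqn{(d, \alpha_1, \alpha_2)} to
#' \eqn{(d\sin\alpha_1, d\cos\alpha_1, d\sin\alpha_2, d\cos\alpha_2)}, the
#' Euclidean space in which microstates are clustered.  The Euclidean norm
#' of each coordinate pair equals `d`, and the map is invertible for d > 0.
#'
#' @param cv a `cv_trajectory`, or any data frame / list with elements
#'   `d`, `alpha1`, `alpha2`.
#' @return numeric matrix with columns `y1..y4`, one row per frame.
#' @export
embed_cv <- function(cv) {
  m <- cbind(y1 = cv$d * sin(cv$alpha1), y2 = cv$d * cos(cv$alpha1),
             y3 = cv$d * sin(cv$alpha2), y4 = cv$d * cos(cv$alpha2))
  m
}

#' Invert the 4D embedding
#'
#' @param y matrix with columns `y1..y4` (or a length-4 vector).
#' @return data frame `d`, `alpha1`, `alpha2`; the angles of a zero-distance
#'   frame are returned as 0.
#' @export
unembed_cv <- function(y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  d <- sqrt(y[, 1]^2 + y[, 2]^2)
  a1 <- ifelse(d > 0, atan2(y[, 1], y[, 2]), 0)
  a2 <- ifelse(d > 0, atan2(y[, 3], y[, 4]), 0)
  data.frame(d = d, alpha1 = a1, alpha2 = a2)
}

#' Protomer-swap augmentation
#'
#' Duplicates every trajectory with the angles \eqn{\alpha_1} and
#' \eqn{\alpha_2} exchanged, corresponding to relabelling the two identical
#' protomers.  Downstream statistics built from the augmented data are
#' exactly symmetric under protomer exchange.
#'
#' @param trajs a `cv_trajectory` or list of them.
#' @return list containing the originals followed by their swapped copies
#'   (attribute `swap_of` gives the index of the source trajectory).
#' @export
swap_augment <- function(trajs) {
  if (inherits(trajs, "cv_trajectory")) trajs <- list(trajs)
  swapped <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    tmp <- tr$alpha1; tr$alpha1 <- tr$alpha2; tr$alpha2 <- tmp
    attr(tr, "swap_of") <- i
    tr
  })
  c(trajs, swapped)
}

#' Rigid-body bead decoration of a CV trajectory
#'
#' Places two copies of a bead template in the periodic box consistently
#' with each frame's \eqn{(d, \alpha_1, \alpha_2)}: protomer 1 at the box
#' centre, protomer 2 at distance d along +x, each rotated about z so that
#' its COM-to-TM1-COM direction makes the prescribed angle with the
#' inter-protomer vector.  Feeding a decorated frame back to
#' [compute_cvs()] recovers the input collective variables.
#'
#' @param cv_traj a `cv_trajectory` (or data frame with `d`, `alpha1`,
#'   `alpha2`).
#' @param template a bead template as from [mor_bead_template()].
#' @param box_side periodic box side (nm); the frame box is
#'   `c(box_side, box_side, NA)`.
#' @param frames indices of frames to decorate (default: all).
#' @return list of `bead_frame` objects.
#' @export
decorate_beads <- function(cv_traj, template, box_side, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(nrow(cv_traj))
  tm1 <- attr(template, "tm1_residues")
  if (is.null(tm1)) stop("template lacks a tm1_residues attribute")
  txy <- as.matrix(template[, c("x", "y")])
  t1 <- colMeans(txy[template$residue %in% tm1, , drop = FALSE])
  a_t <- atan2(t1[2], t1[1])  # template azimuth of the TM1 direction
  ctr <- box_side / 2
  lapply(frames, function(i) {
    d <- cv_traj$d[i]; a1 <- cv_traj$alpha1[i]; a2 <- cv_traj$alpha2[i]
    rot <- function(theta) {
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
      txy %*% t(R)
    }
    # protomer 1: TM1 direction at azimuth a1 (vector to protomer 2 = +x)
    b1 <- rot(a1 - a_t)
    # protomer 2: TM1 direction at angle a2 from -x
    b2 <- rot(pi - a2 - a_t)
    df <- data.frame(
      protomer = rep(c(1L, 2L), each = nrow(template)),
      residue = rep(template$residue, 2),
      region = rep(template$region, 2),
      x = c(b1[, 1] + ctr, b2[, 1] + ctr + d),
      y = c(b1[, 2] + ctr, b2[, 2] + ctr),
      z = 0)
    new_bead_frame(df, box = c(box_side, box_side, NA))
  })
}
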
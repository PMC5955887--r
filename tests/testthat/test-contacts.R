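toy_frame <- function(shift = c(0, 0, 0), box = c(10, 10, NA)) {
  # protomer 1: residues 1..3 along x; protomer 2: three beads, residue 1
  # within 0.8 nm of protomer 1 residues 1 and 2, residue 2 farther away
  df <- rbind(
    data.frame(protomer = 1L, residue = 1:3,
               x = c(0, 0.5, 3), y = 0, z = 0),
    data.frame(protomer = 2L, residue = c(1L, 1L, 2L),
               x = c(0.4, 0.9, 5), y = c(0.5, 0, 0), z = 0))
  df$x <- df$x + shift[1]; df$y <- df$y + shift[2]; df$z <- df$z + shift[3]
  structure(df, class = c("bead_frame", "data.frame"), box = box)
}

test_that("frame contacts match a hand-built distance table", {
  ct <- frame_contacts(toy_frame(), cutoff = 0.8)
  # residue pairs within 0.8: p2 residue 1 bead (0.4,0.5) is 0.64 from p1
  # residue 1 and 0.51 from residue 2; bead (0.9,0) is 0.4 from residue 2
  # (and 0.9 from residue 1); residue pair counted once
  expect_setequal(paste(ct$i, ct$j), c("1 1", "2 1"))
  # rigid translation (with periodic wrap) leaves contacts unchanged
  ct2 <- frame_contacts(toy_frame(shift = c(9, 4, 0)), cutoff = 0.8)
  expect_setequal(paste(ct2$i, ct2$j), paste(ct$i, ct$j))
})

test_that("per-microstate statistics implement the dimeric rule at its boundary", {
  tpl <- mor_bead_template()
  # microstate 1: all frames fused; microstate 2: 89% fused; microstate 3:
  # exactly 90% fused; microstate 4: all far
  n <- 100
  fused <- data.frame(d = 2.9, alpha1 = 0.1, alpha2 = 3.0)
  far <- data.frame(d = 7, alpha1 = 0.1, alpha2 = 3.0)
  cvs <- rbind(fused[rep(1, n), ], rbind(fused[rep(1, 89), ], far[rep(1, 11), ]),
               rbind(fused[rep(1, 90), ], far[rep(1, 10), ]), far[rep(1, n), ])
  dtraj <- rep(1:4, each = n)
  frames <- decorate_beads(cvs, tpl, box_side = 15)
  n10 <- nrow(frame_contacts(frames[[1]], 0.8))
  expect_gte(n10, 10)  # the fused geometry really has >= 10 contacts
  st <- microstate_stats(dtraj, frames, n_states = 5)
  expect_true(st$dimeric[1])
  expect_false(st$dimeric[2])   # 0.89 < 0.9: threshold boundary
  expect_true(st$dimeric[3])    # exactly 0.9 counts as dimeric
  expect_false(st$dimeric[4])
  expect_true(is.na(st$dimeric[5]))  # state without frames is flagged
  # p_tot is non-increasing in n for every covered state
  for (s in 1:4)
    expect_true(all(diff(st$p_tot[s, ]) <= 1e-12))
  expect_equal(unname(st$p_tot[2, "10"]), 0.89, tolerance = 1e-12)
})

test_that("pair probabilities equal a brute-force recount on random frames", {
  tpl <- mor_bead_template()
  set.seed(12)
  cvs <- data.frame(d = runif(100, 2.8, 4.5),
                    alpha1 = runif(100, 0, pi),
                    alpha2 = runif(100, 0, pi))
  frames <- decorate_beads(cvs, tpl, box_side = 15)
  dtraj <- rep(1L, 100)
  st <- microstate_stats(dtraj, frames, n_states = 1)
  # independent O(n^2) oracle: direct double loop over bead pairs
  counts <- new.env()
  ncon <- integer(100)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    a <- fr[fr$protomer == 1, ]; b <- fr[fr$protomer == 2, ]
    seen <- character(0)
    for (i in seq_len(nrow(a))) {
      dx <- b$x - a$x[i]; dy <- b$y - a$y[i]
      dx <- dx - 15 * round(dx / 15); dy <- dy - 15 * round(dy / 15)
      hit <- which(dx^2 + dy^2 < 0.64)
      for (j in hit) seen <- c(seen, paste(a$residue[i], b$residue[j]))
    }
    seen <- unique(seen)
    ncon[f] <- length(seen)
    for (key in seen)
      assign(key, (if (exists(key, counts)) get(key, counts) else 0) + 1,
             counts)
  }
  expect_equal(unname(st$n_frames[1]), 100)
  expect_equal(unname(st$p_tot[1, "10"]), mean(ncon >= 10),
               tolerance = 1e-12)
  for (r in sample(nrow(st$pairs), min(25, nrow(st$pairs)))) {
    key <- paste(st$pairs$i[r], st$pairs$j[r])
    expect_equal(st$pairs$p[r], get(key, counts) / 100, tolerance = 1e-12)
  }
})

test_that("macrostate maps are pi-weighted over dimeric microstates only", {
  st <- structure(list(
    n_frames = c(10, 10, 10),
    p_tot = rbind(rep(1, 12), rep(1, 12), c(rep(1, 11), 0)),
    pairs = data.frame(state = c(1L, 1L, 2L, 3L),
                       i = c(100L, 101L, 100L, 150L),
                       j = c(200L, 200L, 200L, 250L),
                       p = c(1, 0.5, 0.6, 1)),
    dimeric = c(TRUE, TRUE, FALSE),
    n_dimer = 10, p_dimer = 0.9, cutoff = 0.8), class = "contact_stats")
  pi <- c(0.2, 0.6, 0.2)
  # single dimeric microstate: map equals its own pair probabilities
  m1 <- macrostate_contact_map(st, pi, macrostate = 1L)
  expect_equal(m1$p, c(1, 0.5))
  # two dimeric microstates with weights 0.2/0.6
  m12 <- macrostate_contact_map(st, pi, macrostate = c(1L, 2L))
  expect_equal(m12$p[m12$i == 100 & m12$j == 200],
               (0.2 * 1 + 0.6 * 0.6) / 0.8, tolerance = 1e-12)
  # the non-dimeric microstate contributes nothing
  m3 <- macrostate_contact_map(st, pi, macrostate = 3L)
  expect_identical(nrow(m3), 0L)
  expect_equal(attr(m12, "dimeric_weight"), 0.8)
  # unnormalized version is the raw weighted sum
  raw <- macrostate_contact_map(st, pi, macrostate = c(1L, 2L),
                                normalized = FALSE)
  expect_equal(raw$p[raw$i == 100 & raw$j == 200], 0.2 + 0.36)
})

test_that("residue summaries conserve totals and respect thresholds", {
  st <- structure(list(
    n_frames = c(5, 5),
    p_tot = rbind(rep(1, 3), rep(1, 3)),
    pairs = data.frame(state = c(1L, 1L, 2L),
                       i = c(80L, 80L, 90L), j = c(200L, 210L, 200L),
                       p = c(1, 0.4, 0.05)),
    dimeric = c(TRUE, TRUE), n_dimer = 10, p_dimer = 0.9, cutoff = 0.8),
    class = "contact_stats")
  pi <- c(0.5, 0.5)
  rs <- residue_contact_summary(st, pi)
  all_res <- attr(rs, "residues_all")
  all_pairs <- attr(rs, "pairs_all")
  # counting identity: summed side-1 residue contacts = summed pair probs
  expect_equal(sum(all_res$mean_contacts[all_res$side == 1]),
               sum(all_pairs$p), tolerance = 1e-12)
  expect_true(all(rs$residues$mean_contacts > 0.2))
  expect_true(all(rs$pairs$p > 0.1))
  # single persistent contact in a weight-1 state
  st2 <- st; st2$pairs <- data.frame(state = 1L, i = 80L, j = 200L, p = 1)
  st2$n_frames <- c(5, 0); st2$dimeric <- c(TRUE, NA)
  rs2 <- residue_contact_summary(st2, c(1, 0))
  expect_equal(rs2$residues$mean_contacts, c(1, 1))
})

test_that("interface names follow the count conventions", {
  rmap <- region_map()
  res_of <- function(region) rmap$residue[rmap$region == region][1:6]
  # TM1:5, TM2:4, H8:2 on both sides -> "TM1,2,(H8)/TM1,2,(H8)"
  m <- rbind(data.frame(i = res_of("TM1")[1:5], j = res_of("TM1")[1:5], p = 1),
             data.frame(i = res_of("TM2")[1:4], j = res_of("TM2")[1:4], p = 1),
             data.frame(i = res_of("H8")[1:2], j = res_of("H8")[1:2], p = 1))
  expect_identical(name_interface(m), "TM1,2,(H8)/TM1,2,(H8)")
  # exactly three contacts -> parenthetical
  m3 <- rbind(data.frame(i = res_of("TM5")[1:4], j = res_of("TM5")[1:4], p = 1),
              data.frame(i = res_of("TM6")[1:3], j = res_of("TM6")[1:3], p = 1))
  expect_identical(name_interface(m3), "TM5,(6)/TM5,(6)")
  # all regions below threshold -> fully parenthetical
  mlow <- data.frame(i = res_of("TM4")[1:2], j = res_of("TM5")[1:2], p = 1)
  expect_identical(name_interface(mlow), "(TM4)/(TM5)")
  expect_identical(name_interface(m[0, ]), "")
})
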
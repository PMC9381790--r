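# Salt-bridge contacts, occupancy tables, and the extraction ladder.

# Structure with one charged residue (SC1 bead at `sc`), a probe lipid L:1
# whose PO4 sits at `po4` (NC3 3.5 A above), and a small background bilayer
# (3 upper + 4 lower lipids) so leaflets and the reference plane are well
# defined.
one_pair_struct <- function(sc, po4) {
  atoms <- data.frame(name = c("BB", "SC1", "PO4", "NC3"),
                      resno = c(571, 571, 1, 1),
                      resname = c("ASP", "ASP", "POPC", "POPC"),
                      chain = c("P", "P", "L", "L"))
  st <- structure3d(atoms, rbind(sc + c(0, 0, 3), sc, po4, po4 + c(0, 0, 3.5)))
  bg <- make_lipid_struct(rbind(c(20, 0, 19), c(20, 20, 19), c(0, 20, 19),
                                c(0, 0, -19), c(20, 0, -19),
                                c(20, 20, -19), c(0, 20, -19)))
  bg$atoms$resno <- bg$atoms$resno + 1L
  structure3d(rbind(st$atoms[, c("name", "resno", "resname", "chain")],
                    bg$atoms[, c("name", "resno", "resname", "chain")]),
              rbind(st$xyz, bg$xyz))
}

test_that("the 6 A cutoff separates 5.9 from 6.1 A", {
  st <- one_pair_struct(sc = c(5.9, 0, 19), po4 = c(0, 0, 19))
  traj <- make_traj(st, list(st$xyz))
  res <- residue_set(571, "P")
  hits <- contacts_in_frame(traj, 1, res, lipid_ids = "L:1", cutoff_A = 6)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$moiety, "phosphate")
  expect_equal(hits$min_distance, 5.9)

  st2 <- one_pair_struct(sc = c(6.1, 0, 19), po4 = c(0, 0, 19))
  traj2 <- make_traj(st2, list(st2$xyz))
  expect_equal(nrow(contacts_in_frame(traj2, 1, res, lipid_ids = "L:1")), 0L)
  all_d <- contacts_in_frame(traj2, 1, res, lipid_ids = "L:1",
                             all_distances = TRUE)
  expect_equal(nrow(all_d), 2L)   # distances returned for non-contacts too
  expect_false(any(all_d$contact))
})

test_that("a glycine in the residue set is rejected", {
  atoms <- data.frame(name = c("BB", "PO4", "NC3"), resno = c(577, 1, 1),
                      resname = c("GLY", "POPC", "POPC"),
                      chain = c("P", "L", "L"))
  st <- structure3d(atoms, rbind(c(0, 0, 25), c(0, 0, 19), c(0, 0, 22.5)))
  traj <- make_traj(st, list(st$xyz))
  expect_error(contacts_in_frame(traj, 1, residue_set(577, "P")),
               "glycine")
})

test_that("contacts match the brute-force all-pairs scan on random frames", {
  set.seed(99)
  for (rep in 1:10) {
    n_res <- 10; n_lip <- 6
    atoms <- rbind(
      do.call(rbind, lapply(seq_len(n_res), function(i)
        data.frame(name = c("BB", "SC1", "SC2")[1:sample(2:3, 1)],
                   resno = 500 + i, resname = "ASP", chain = "P"))),
      do.call(rbind, lapply(seq_len(n_lip), function(i)
        data.frame(name = c("PO4", "NC3"), resno = i, resname = "POPC",
                   chain = "L"))))
    st <- structure3d(atoms, matrix(runif(nrow(atoms) * 3, 0, 25), ncol = 3))
    traj <- make_traj(st, list(st$xyz))
    lip <- lipid_index(st)
    res <- residue_set(500 + seq_len(n_res), "P")
    got <- contacts_in_frame(traj, 1, res, lipids = lip, all_distances = TRUE)
    want <- brute_force_contacts(traj, 1, res, lip)
    key <- function(d) d[order(d$resno, d$moiety, d$lipid), ]
    got <- key(got); want <- key(want)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-12)
    expect_equal(got$contact, want$contact)
  }
})

test_that("planted Bernoulli occupancies are recovered exactly from geometry", {
  sp <- synthetic_spec(n_lipids = 32, n_frames = 400, seed = 17)
  sim <- simulate_trajectory(sp)
  occ <- sb_occupancy(sim$trajectory, residue_set(c(568, 571), "P"))
  pooled <- occ[occ$replica == "pooled", ]
  k568 <- pooled[pooled$resno == 568 & pooled$moiety == "phosphate", ]
  d571 <- pooled[pooled$resno == 571 & pooled$moiety == "choline", ]
  # geometry realises every draw, so recovery is exact, not just close
  expect_equal(k568$occupancy, mean(sim$truth$contacts[["568:phosphate"]]))
  expect_equal(d571$occupancy, mean(sim$truth$contacts[["571:choline"]]))
  # the cross-moiety pairs stay silent
  expect_equal(pooled$occupancy[pooled$resno == 568 &
                                  pooled$moiety == "choline"], 0)
  expect_equal(pooled$occupancy[pooled$resno == 571 &
                                  pooled$moiety == "phosphate"], 0)
})

test_that("p = 0 gives exactly zero occupancy and p = 1 exactly one", {
  po <- data.frame(resno = c(568L, 571L), moiety = c("phosphate", "choline"),
                   p = c(0, 1))
  sim <- simulate_trajectory(synthetic_spec(n_lipids = 16, n_frames = 50,
                                            seed = 2,
                                            planted_occupancies = po))
  occ <- sb_occupancy(sim$trajectory, residue_set(c(568, 571), "P"))
  pooled <- occ[occ$replica == "pooled", ]
  expect_equal(pooled$occupancy[pooled$resno == 568 &
                                  pooled$moiety == "phosphate"], 0)
  expect_equal(pooled$occupancy[pooled$resno == 571 &
                                  pooled$moiety == "choline"], 1)
})

test_that("replica pooling is the frame-weighted mean", {
  # two hand-built replicas: contact in 6/10 and 9/10 frames
  mk <- function(n_on) {
    st <- one_pair_struct(sc = c(30, 0, 40), po4 = c(0, 0, 19))
    frames <- lapply(1:10, function(k) {
      xyz <- st$xyz
      if (k <= n_on) xyz[2, ] <- c(0, 0, 24)   # SC1 5 A above PO4
      xyz
    })
    make_traj(st, frames)
  }
  occ <- sb_occupancy(list(mk(6), mk(9)), residue_set(571, "P"))
  ph <- occ[occ$moiety == "phosphate", ]
  expect_equal(ph$occupancy[ph$replica == "1"], 0.6)
  expect_equal(ph$occupancy[ph$replica == "2"], 0.9)
  expect_equal(ph$occupancy[ph$replica == "pooled"], 0.75)
  expect_equal(ph$n_frames[ph$replica == "pooled"], 20L)
})

test_that("occupancy is invariant to frame-order permutation", {
  sim <- simulate_trajectory(synthetic_spec(n_lipids = 16, n_frames = 60,
                                            seed = 23))
  traj <- sim$trajectory
  set.seed(5)
  perm <- sample(n_frames(traj))
  traj2 <- trajectory3d(traj$topology, traj$coords[, , perm],
                        times = traj$times)
  res <- residue_set(c(568, 571), "P")
  o1 <- sb_occupancy(traj, res)
  o2 <- sb_occupancy(traj2, res)
  expect_equal(o1$occupancy, o2$occupancy)
})

test_that("the occupancy estimator is unbiased over repeated seeds", {
  p <- 0.5; n <- 120
  err <- vapply(1:20, function(s) {
    po <- data.frame(resno = 568L, moiety = "phosphate", p = p)
    sim <- simulate_trajectory(synthetic_spec(n_lipids = 8, n_frames = n,
                                              seed = 1000 + s,
                                              planted_occupancies = po))
    occ <- sb_occupancy(sim$trajectory, residue_set(568, "P"))
    occ$occupancy[occ$replica == "pooled" & occ$moiety == "phosphate"] - p
  }, numeric(1))
  expect_lt(abs(mean(err)), 2 * sqrt(p * (1 - p) / n))
})

test_that("the planted ladder is reproduced in order at the planted heights", {
  lp <- ladder_plan(150)
  sim <- simulate_trajectory(synthetic_spec(
    n_lipids = 32, n_frames = 150, seed = 31, planted_occupancies = NULL,
    lift_schedule = lp$lift_schedule, contact_schedule = lp$contact_schedule))
  trc <- track_extracted(sim$trajectory)
  lad <- sb_ladder(trc, sim$trajectory)
  expect_equal(lad$resno, c(571, 575, 584, 585))
  expect_true(all(lad$present))
  expect_true(attr(lad, "in_expected_order"))
  expect_equal(lad$dz_at_onset, c(10, 12, 15, 17), tolerance = 0.1)
})

test_that("residues that never contact are flagged absent", {
  lp <- ladder_plan(60, dz = c(10, 12), resno = c(571L, 575L))
  sim <- simulate_trajectory(synthetic_spec(
    n_lipids = 32, n_frames = 60, seed = 32, planted_occupancies = NULL,
    lift_schedule = lp$lift_schedule, contact_schedule = lp$contact_schedule))
  trc <- track_extracted(sim$trajectory)
  lad <- sb_ladder(trc, sim$trajectory)
  expect_equal(sum(lad$present), 2L)
  expect_setequal(lad$resno[!lad$present], c(584, 585))
})

test_that("an out-of-order plant is reported by onset and flagged", {
  n <- 100
  lift <- data.frame(from = c(21, 41, 61, 81), to = c(40, 60, 80, 100),
                     dz = c(10, 12, 15, 17))
  # E584 engages before D575: swap their windows
  cs <- data.frame(resno = c(571L, 584L, 575L, 585L), moiety = "choline",
                   from = c(21, 41, 61, 81), to = c(40, 60, 80, 100))
  sim <- simulate_trajectory(synthetic_spec(
    n_lipids = 32, n_frames = n, seed = 33, planted_occupancies = NULL,
    lift_schedule = lift, contact_schedule = cs))
  trc <- track_extracted(sim$trajectory)
  lad <- sb_ladder(trc, sim$trajectory)
  expect_equal(lad$resno, c(571, 584, 575, 585))
  expect_false(attr(lad, "in_expected_order"))
})

test_that("sustained-contact filtering suppresses single-frame flicker", {
  st <- one_pair_struct(sc = c(30, 0, 40), po4 = c(0, 0, 19))
  # lipid lifted from frame 3; contact only in frame 4 (1 frame), then 6-10
  frames <- lapply(1:10, function(k) {
    xyz <- st$xyz
    if (k >= 3) { xyz[3, 3] <- 19 + 11; xyz[4, 3] <- 22.5 + 11 }
    if (k == 4 || k >= 6) xyz[2, ] <- c(0, 0, 19 + 11 + 5)
    xyz
  })
  traj <- make_traj(st, frames)
  trc <- track_extracted(traj)
  lad1 <- sb_ladder(trc, traj, residues = residue_set(571, "P"),
                    sustain_frames = 2)
  expect_equal(lad1$onset_frame, 6L)
  lad2 <- sb_ladder(trc, traj, residues = residue_set(571, "P"),
                    sustain_frames = 1)
  expect_equal(lad2$onset_frame, 4L)
})
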
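# Lift histogram, mound detection, extraction tracking.

# A hand-built 6-lipid bilayer where lipid L:3's height is set per frame.
traj_with_heights <- function(dz_per_frame) {
  base <- rbind(c(0, 0, 19), c(9, 0, 19), c(18, 0, 19),
                c(0, 9, -19), c(9, 9, -19), c(18, 9, -19))
  st <- make_lipid_struct(base)
  frames <- lapply(dz_per_frame, function(dz) {
    xyz <- st$xyz
    xyz[5:6, 3] <- xyz[5:6, 3] + dz   # rows of lipid 3 (PO4, NC3)
    xyz
  })
  make_traj(st, frames)
}

test_that("a lipid at dz 10.5 for three frames lands in the first bin", {
  traj <- traj_with_heights(c(10.5, 10.5, 10.5))
  lh <- lift_histogram(traj, selection = "all")
  expect_equal(unname(lh$counts), c(3, 0, 0, 0, 0, 0))
  expect_equal(lh$n_frames, 3L)
})

test_that("the bins are half-open: 9.9 and 16.0 both fall outside", {
  # a tight plane trim (5 A) keeps the near-threshold lipid out of z0, so
  # its height is measured exactly
  traj <- traj_with_heights(c(9.9, 16.0))
  lh <- lift_histogram(traj, selection = "all", exclusion_height_A = 5)
  expect_equal(sum(lh$counts), 0L)
  # the left edge is inclusive
  lh10 <- lift_histogram(traj_with_heights(10), selection = "all",
                         exclusion_height_A = 5)
  expect_equal(unname(lh10$counts), c(1, 0, 0, 0, 0, 0))
})

test_that("histogram counts equal brute-force binning of measured heights", {
  lp <- list(lift_schedule = data.frame(from = c(11, 31, 51, 71),
                                        to = c(30, 50, 70, 100),
                                        dz = c(10.5, 12.4, 14.5, 15.5)))
  sp <- synthetic_spec(n_lipids = 32, n_frames = 100, seed = 6,
                       planted_occupancies = NULL,
                       lift_schedule = lp$lift_schedule)
  sim <- simulate_trajectory(sp)
  lh <- lift_histogram(sim$trajectory, selection = "all")
  # independent oracle: per-frame median split / trimmed mean / subtraction
  # / cut(), coded from scratch
  lip <- lipid_index(sim$trajectory)
  expected <- integer(6)
  for (k in 1:100) {
    z <- frame_coords(sim$trajectory, k)[lip$phosphate, 3]
    zu <- z[z > median(z)]
    z0 <- mean(zu[zu <= median(zu) + 10])
    dz <- z - z0
    dz <- dz[dz >= 10 & dz < 16]
    expected <- expected + table(cut(dz, 10:16, right = FALSE))
  }
  expect_equal(unname(lh$counts), as.vector(expected))
  # and the aggregated counts match the planted schedule binned directly
  planted <- rep(0, 100)
  for (r in seq_len(nrow(lp$lift_schedule)))
    planted[lp$lift_schedule$from[r]:lp$lift_schedule$to[r]] <-
    lp$lift_schedule$dz[r]
  expect_equal(unname(lh$counts),
               as.vector(table(cut(planted[planted > 0], 10:16,
                                   right = FALSE))))
})

test_that("the histogram total is bounded by frames x selection size", {
  sim <- simulate_trajectory(synthetic_spec(n_lipids = 16, n_frames = 20,
                                            seed = 3))
  lh <- lift_histogram(sim$trajectory, selection = "all")
  expect_lte(sum(lh$counts), 20 * 16)
  expect_error(lift_histogram(sim$trajectory, selection = integer(0)),
               "empty")
  expect_error(lift_histogram(sim$trajectory, frames = integer(0)), "empty")
})

test_that("no mound is reported on a flat membrane", {
  sim <- simulate_trajectory(synthetic_spec(n_lipids = 16, n_frames = 2,
                                            seed = 5,
                                            planted_occupancies = NULL))
  expect_null(detect_mound(sim$trajectory, frame = 1))
})

test_that("five lipids planted 10-12 A high in a tight cluster form a mound of 5", {
  sim <- simulate_trajectory(synthetic_spec(n_lipids = 32, n_frames = 5,
                                            seed = 9,
                                            planted_occupancies = NULL,
                                            mound_size = 5))
  m <- detect_mound(sim$trajectory, frame = 3)
  expect_s3_class(m, "mound_record")
  expect_equal(m$size, 5L)
  expect_gte(m$mean_height, 10)
  expect_setequal(m$members, utils::tail(sim$truth$dedicated, 5))
})

test_that("two distant lifted lipids are singletons, not a mound", {
  # lipids 3 and 6 lifted 11 A, 45 A apart laterally
  base <- rbind(c(0, 0, 19), c(9, 0, 19), c(0, 9, 30),
                c(45, 0, 19), c(45, 9, 19), c(45, 45, 30),
                c(20, 20, -19), c(25, 20, -19), c(20, 25, -19),
                c(30, 30, -19), c(35, 30, -19), c(30, 35, -19))
  st <- make_lipid_struct(base)
  traj <- make_traj(st, list(st$xyz))
  m1 <- detect_mound(traj, 1, min_size = 1, lateral_radius_A = 10)
  expect_equal(m1$size, 1L)   # hand-checked single linkage: two singletons
  expect_null(detect_mound(traj, 1, min_size = 3, lateral_radius_A = 10))
})

test_that("the planted extraction is identified and tied lifts break by mean height", {
  lp <- ladder_plan(60)
  sim <- simulate_trajectory(synthetic_spec(
    n_lipids = 32, n_frames = 60, seed = 12, planted_occupancies = NULL,
    lift_schedule = lp$lift_schedule, contact_schedule = lp$contact_schedule))
  trc <- track_extracted(sim$trajectory)
  expect_equal(trc$lipid_id, sim$truth$extracted_lipid)
  expect_equal(length(trc$dz), 60L)

  # two lifted lipids, 30 vs 70 frames: the 70-frame one wins
  base <- rbind(c(0, 0, 19), c(9, 0, 19), c(18, 0, 19), c(27, 0, 19),
                c(0, 9, 19), c(9, 18, 19),
                c(0, 0, -19), c(9, 0, -19), c(18, 0, -19), c(27, 0, -19),
                c(0, 9, -19), c(9, 18, -19))
  st <- make_lipid_struct(base)
  frames <- lapply(1:100, function(k) {
    xyz <- st$xyz
    if (k <= 30) xyz[3:4, 3] <- xyz[3:4, 3] + 12    # lipid 2 lifted
    if (k <= 70) xyz[5:6, 3] <- xyz[5:6, 3] + 11    # lipid 3 lifted
    xyz
  })
  trc2 <- track_extracted(make_traj(st, frames))
  expect_equal(trc2$lipid_id, "L:3")
  expect_equal(trc2$n_lifted_frames, 70L)
})

test_that("a flat bilayer yields no extraction trace", {
  sim <- simulate_trajectory(synthetic_spec(n_lipids = 16, n_frames = 10,
                                            seed = 30,
                                            planted_occupancies = NULL))
  expect_null(track_extracted(sim$trajectory))
})

test_that("the trace records the nearest gateway residue per frame", {
  lp <- ladder_plan(60)
  sim <- simulate_trajectory(synthetic_spec(
    n_lipids = 32, n_frames = 60, seed = 14, planted_occupancies = NULL,
    lift_schedule = lp$lift_schedule, contact_schedule = lp$contact_schedule))
  trc <- track_extracted(sim$trajectory, gateway = abca1_domains("P")$gateway)
  expect_equal(nrow(trc$nearest_residue), 60L)
  # during the first plateau the planted contact residue D571 is nearest
  k <- lp$contact_schedule$from[1] + 1
  expect_equal(trc$nearest_residue$resno[k], 571L)
})
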
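# Frame cutting, sliding centroids, distance-to-centroid, MDE, pair
# distances: hand cases, brute-force oracle, geometric invariances.

const_seq <- function(xyz, n = 10, joint = "PELVIS") {
  arr <- array(rep(xyz, each = n), c(n, 1, 3),
               dimnames = list(NULL, joint, c("x", "y", "z")))
  tracking_sequence(arr)
}

linear_seq <- function(n = 200, joint = "PELVIS") {
  arr <- array(0, c(n, 1, 3), dimnames = list(NULL, joint, c("x", "y", "z")))
  arr[, 1, 1] <- seq_len(n)  # x(t) = t, y = z = 0
  tracking_sequence(arr)
}

test_that("cutting start-up frames shortens and keeps original indices", {
  s <- make_pose_seq(n_frames = 9002, sigma = 0, seed = 1)
  s2 <- cut_frames(s, 60)
  expect_equal(n_frames(s2), 8942L)
  expect_equal(s2$frame_index[1], 60L)  # 0-based: frames 0..59 dropped
  expect_identical(cut_frames(s, 0), s)
  s61 <- make_pose_seq(n_frames = 61, sigma = 0)
  expect_equal(n_frames(cut_frames(s61, 60)), 1L)
  expect_error(cut_frames(s61, 61), "cannot cut")
})

test_that("centroids of a constant trajectory equal the constant", {
  s <- const_seq(c(10, -20, 1900), n = 50)
  cs <- sliding_centroid(s, "PELVIS", N = 5)
  expect_equal(cs$c, matrix(rep(c(10, -20, 1900), each = 50), 50, 3),
               ignore_attr = TRUE)
})

test_that("clipped windows average exactly the remaining frames", {
  s <- linear_seq(n = 10)
  cs <- sliding_centroid(s, "PELVIS", N = 2)
  # interior frame: symmetric window mean equals the position
  expect_equal(unname(cs$c[5, 1]), 5)
  # first frame: window {1, 2, 3}, mean 2
  expect_equal(unname(cs$c[1, 1]), 2)
  # last frame: window {8, 9, 10}, mean 9
  expect_equal(unname(cs$c[10, 1]), 9)
  # "full" normalization divides clipped sums by 2N+1 instead
  cs_full <- sliding_centroid(s, "PELVIS", N = 2, normalize = "full")
  expect_equal(unname(cs_full$c[1, 1]), (1 + 2 + 3) / 5)
  expect_equal(unname(cs_full$c[5, 1]), 5)
})

test_that("distance to centroid is the Euclidean norm (3-4-5 check)", {
  s <- const_seq(c(0, 0, 1900), n = 20)
  cs <- sliding_centroid(s, "PELVIS", N = 3)
  expect_equal(distance_to_centroid(s, cs), rep(0, 20))
  s_off <- s
  s_off$positions[, 1, 1] <- 3
  s_off$positions[, 1, 2] <- 4
  s_off$positions[, 1, 3] <- 1900
  # centroid held at (0, 0, 1900): offset (3, 4, 0) -> distance 5
  expect_equal(distance_to_centroid(s_off, cs), rep(5, 20))
  expect_equal(distance_to_centroid(s_off, cs, squared = TRUE), rep(25, 20))
  # misaligned frame ranges are rejected
  expect_error(distance_to_centroid(cut_frames(s, 2), cs), "different frame")
})

test_that("MDE is zero for a constant pose and positive under jitter", {
  sp <- standing_pose()
  s0 <- simulate_tracking(pose_sim_config(sp$true_positions, 0, 100), seed = 1)
  r <- compute_mde(s0, N = 30)
  expect_equal(unname(r$mde), rep(0, 18))
  s1 <- make_pose_seq(n_frames = 100, sigma = 1, seed = 1)
  expect_true(all(compute_mde(s1, N = 30)$mde > 0))
  expect_error(compute_mde(s1, joints = character(0)), "empty joint list")
  expect_error(sliding_centroid(s1, "NOT_A_JOINT"), "unknown joint")
})

test_that("MDE matches the naive per-frame oracle on short sequences", {
  for (seed in 1:4) {
    s <- make_pose_seq(n_frames = 150 + 50 * seed, sigma = 2, seed = seed)
    r <- compute_mde(s, joints = c("PELVIS", "FOOT_RIGHT"), N = 30)
    for (j in c("PELVIS", "FOOT_RIGHT")) {
      expect_equal(unname(r$mde[j]),
                   naive_mde(matrix(s$positions[, j, ], ncol = 3), N = 30),
                   tolerance = 1e-10)
    }
  }
})

test_that("linear motion contributes error only at clipped end windows", {
  s <- linear_seq(n = 200)
  cs <- sliding_centroid(s, "PELVIS", N = 30)
  d <- distance_to_centroid(s, cs)
  interior <- 31:170
  expect_equal(d[interior], rep(0, length(interior)), tolerance = 1e-10)
  expect_true(all(d[1:30] > 0) && all(d[171:200] > 0))
  r <- compute_mde(s, joints = "PELVIS", N = 30)
  expect_equal(unname(r$mde["PELVIS"]),
               naive_mde(matrix(s$positions[, 1, ], ncol = 3), N = 30),
               tolerance = 1e-10)
  expect_gt(r$mde["PELVIS"], 0)
})

test_that("metrics are invariant under translation and rotation", {
  s <- make_pose_seq(n_frames = 120, sigma = 1.5, seed = 6)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  s_t <- transform_sequence(s, shift = c(100, -250, 3000))
  s_r <- transform_sequence(s, R = R)
  m <- compute_mde(s, N = 30)
  expect_equal(compute_mde(s_t, N = 30)$mde, m$mde, tolerance = 1e-9)
  expect_equal(compute_mde(s_r, N = 30)$mde, m$mde, tolerance = 1e-9)
  a <- joint_pair_distance(s, "ANKLE_LEFT", "ANKLE_RIGHT")$d
  expect_equal(joint_pair_distance(s_t, "ANKLE_LEFT", "ANKLE_RIGHT")$d, a,
               tolerance = 1e-9)
  expect_equal(joint_pair_distance(s_r, "ANKLE_LEFT", "ANKLE_RIGHT")$d, a,
               tolerance = 1e-9)
})

test_that("a transient position peak raises only its joint's MDE", {
  sp <- standing_pose()
  cfg0 <- pose_sim_config(sp$true_positions, sp$sigma, n_frames = 600)
  cfgp <- pose_sim_config(sp$true_positions, sp$sigma, n_frames = 600,
                          peak = list(joint = "ANKLE_LEFT", start_frame = 400,
                                      duration = 15, offset = c(0, 20, 0)))
  m0 <- compute_mde(cut_frames(simulate_tracking(cfg0, seed = 12), 60), N = 30)
  mp <- compute_mde(cut_frames(simulate_tracking(cfgp, seed = 12), 60), N = 30)
  expect_gt(mp$mde["ANKLE_LEFT"], m0$mde["ANKLE_LEFT"])
  others <- setdiff(names(m0$mde), "ANKLE_LEFT")
  expect_identical(mp$mde[others], m0$mde[others])
})

test_that("pair distances are symmetric, positive and Jensen-bounded", {
  s <- const_seq(c(0, 0, 1900), n = 30)
  # two-joint constant stance: ankles at x = -50 and +50
  arr <- array(0, c(30, 2, 3),
               dimnames = list(NULL, c("ANKLE_LEFT", "ANKLE_RIGHT"),
                               c("x", "y", "z")))
  arr[, 1, 1] <- -50; arr[, 2, 1] <- 50; arr[, , 3] <- 1900
  s2 <- tracking_sequence(arr)
  d <- joint_pair_distance(s2, "ANKLE_LEFT", "ANKLE_RIGHT")
  expect_equal(d$d, rep(100, 30))
  expect_equal(d$summary$median, 100)
  expect_equal(joint_pair_distance(s2, "ANKLE_RIGHT", "ANKLE_LEFT")$d, d$d)
  expect_error(joint_pair_distance(s2, "ANKLE_LEFT", "ANKLE_LEFT"), "differ")

  # independent jitter on both joints: mean distance >= true distance
  sp <- standing_pose()
  sj <- make_pose_seq(n_frames = 6000, sigma = 3, seed = 8)
  dj <- joint_pair_distance(sj, "ANKLE_LEFT", "ANKLE_RIGHT")
  true_d <- sqrt(sum((sp$true_positions["ANKLE_LEFT", ] -
                        sp$true_positions["ANKLE_RIGHT", ])^2))
  expect_gte(mean(dj$d), true_d)
})

test_that("across-joint summaries use the shared quantile convention", {
  s <- make_pose_seq(n_frames = 200, sigma = 1, seed = 2)
  r <- compute_mde(s, N = 30)
  expect_equal(r$summary$median, unname(quantile(r$mde, 0.5, type = 7)))
  expect_equal(r$summary$q1, unname(quantile(r$mde, 0.25, type = 7)))
  expect_equal(r$summary$q3, unname(quantile(r$mde, 0.75, type = 7)))
})
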
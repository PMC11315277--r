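# Synthetic generators: determinism, degenerate configs, noise calibration,
# artifact injection, and compatibility with the io layer.

test_that("identical seeds reproduce stacks and sequences exactly", {
  dc <- depth_sim_config(1900, sigma = 1.5, invalid_prob = 0.02,
                         n_frames = 12, height = 6, width = 6)
  expect_identical(simulate_depth(dc, seed = 7)$frames,
                   simulate_depth(dc, seed = 7)$frames)
  expect_false(identical(simulate_depth(dc, seed = 7)$frames,
                         simulate_depth(dc, seed = 8)$frames))
  sp <- standing_pose()
  pc <- pose_sim_config(sp$true_positions, sp$sigma, n_frames = 20)
  expect_identical(simulate_tracking(pc, seed = 7)$positions,
                   simulate_tracking(pc, seed = 7)$positions)
  expect_false(identical(simulate_tracking(pc, seed = 7)$positions,
                         simulate_tracking(pc, seed = 8)$positions))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1); a <- runif(3)
  set.seed(1)
  invisible(simulate_depth(depth_sim_config(1900, sigma = 1, n_frames = 2,
                                            height = 3, width = 3), seed = 5))
  expect_identical(runif(3), a)
})

test_that("noise-free configs reproduce the base scene exactly", {
  base <- matrix(1500:1523, 4, 6)
  st <- simulate_depth(depth_sim_config(base, n_frames = 5), seed = 1)
  for (t in 1:5) expect_equal(st$frames[, , t], base,
                              ignore_attr = TRUE)
  st_all_invalid <- simulate_depth(
    depth_sim_config(base, invalid_prob = 1, n_frames = 3), seed = 1)
  expect_true(all(st_all_invalid$frames == 0L))
})

test_that("per-pixel sample SD recovers sigma at long exposure", {
  # Depth values are integer mm, so the sample SD targets the
  # quantization-corrected sqrt(sigma^2 + 1/12) (Sheppard), with
  # SD-of-SD ~ sd / sqrt(2 (n - 1)) as the sampling-error oracle.
  sigma <- 1.4; n <- 9000
  st <- simulate_depth(depth_sim_config(1900, sigma = sigma, n_frames = n,
                                        height = 2, width = 2), seed = 42)
  target <- sqrt(sigma^2 + 1 / 12)
  se <- target / sqrt(2 * (n - 1))
  sds <- apply(st$frames, c(1, 2), sd)
  expect_true(all(abs(sds - target) < 3 * se))
})

test_that("negative simulated depths are clamped to invalid and counted", {
  st <- simulate_depth(depth_sim_config(1, sigma = 5, n_frames = 200,
                                        height = 2, width = 2), seed = 2)
  counts <- attr(st, "sim_counts")
  expect_gt(counts$n_negative_clamped, 0)
  expect_true(all(st$frames >= 0L))
})

test_that("blob invalidation equals the clipped disk area each frame", {
  blob <- list(start_frame = 3, end_frame = 8, radius = 2.5,
               start = c(2, 2), velocity = c(0, 1.5))
  st <- simulate_depth(depth_sim_config(1900, n_frames = 10, height = 8,
                                        width = 8, blob = blob), seed = 1)
  counts <- attr(st, "sim_counts")$blob_pixels
  for (t in 1:10) {
    if (t < 3 || t > 8) {
      expect_equal(counts[t], 0L)
      next
    }
    center <- blob$start + (t - 3) * blob$velocity
    # independent pixel-by-pixel disk area, clipped to the frame
    area <- 0L
    for (i in 1:8) for (j in 1:8) {
      if ((i - center[1])^2 + (j - center[2])^2 <= blob$radius^2) {
        area <- area + 1L
      }
    }
    expect_equal(counts[t], area)
    expect_equal(sum(st$frames[, , t] == 0L), area)
  }
})

test_that("constant pose with no noise yields a constant sequence", {
  sp <- standing_pose()
  s <- simulate_tracking(pose_sim_config(sp$true_positions, 0, n_frames = 8),
                         seed = 1)
  for (t in 1:8) {
    expect_equal(matrix(s$positions[t, , ], ncol = 3,
                        dimnames = list(s$joint_set, c("x", "y", "z"))),
                 sp$true_positions,
                 ignore_attr = TRUE)
  }
})

test_that("the start-up transient decays below 1% within its length", {
  sp <- standing_pose()
  s <- simulate_tracking(
    pose_sim_config(sp$true_positions["PELVIS", , drop = FALSE],
                    0, n_frames = 120,
                    transient = list(length = 60, offset = c(50, 0, 0))),
    seed = 1)
  dev <- abs(s$positions[, "PELVIS", "x"] - sp$true_positions["PELVIS", 1])
  expect_equal(dev[1], 50)
  expect_lt(dev[61], 0.01 * 50)
  expect_true(all(diff(dev) <= 0))
})

test_that("a peak artifact offsets exactly its joint and window", {
  sp <- standing_pose()
  pk <- list(joint = "ANKLE_LEFT", start_frame = 30, duration = 10,
             offset = c(0, 20, 0))
  cfg0 <- pose_sim_config(sp$true_positions, sp$sigma, n_frames = 100)
  cfgp <- pose_sim_config(sp$true_positions, sp$sigma, n_frames = 100,
                          peak = pk)
  s0 <- simulate_tracking(cfg0, seed = 4)
  sp_ <- simulate_tracking(cfgp, seed = 4)
  dy <- sp_$positions[, "ANKLE_LEFT", "y"] - s0$positions[, "ANKLE_LEFT", "y"]
  expect_equal(dy[30:39], rep(20, 10))
  expect_equal(dy[-(30:39)], rep(0, 90))
  # max vertical deviation over the peak window is the offset plus jitter
  expect_equal(max(abs(sp_$positions[30:39, "ANKLE_LEFT", "y"] -
                         sp$true_positions["ANKLE_LEFT", 2])),
               20, tolerance = 0.25)
  # all other joints bit-identical
  others <- setdiff(s0$joint_set, "ANKLE_LEFT")
  expect_identical(sp_$positions[, others, ], s0$positions[, others, ])
})

test_that("AR(1) jitter keeps the marginal SD but adds autocorrelation", {
  sp <- standing_pose()
  cfg <- pose_sim_config(sp$true_positions["PELVIS", , drop = FALSE],
                         c(PELVIS = 2), n_frames = 6000, ar1 = 0.8)
  s <- simulate_tracking(cfg, seed = 9)
  x <- s$positions[, "PELVIS", "x"]
  expect_equal(sd(x), 2, tolerance = 0.1)
  expect_gt(cor(x[-1], x[-length(x)]), 0.7)
})

test_that("generated data pass the io layer's validation", {
  st <- make_small_stack(h = 4, w = 4, n = 5, seed = 1)
  d <- tempfile()
  write_depth_stack(st, d)
  expect_identical(read_depth_stack(d)$frames, st$frames)
  s <- make_pose_seq(n_frames = 10, seed = 1)
  f <- tempfile(fileext = ".json")
  write_tracking_json(s, f)
  expect_identical(read_tracking_json(f)$positions, s$positions)
})

test_that("unknown joints in the pose config are rejected", {
  expect_error(pose_sim_config(rbind(NOT_A_JOINT = c(0, 0, 1)), 1, 10),
               "unknown joint")
  sp <- standing_pose()
  expect_error(
    pose_sim_config(sp$true_positions, sp$sigma, 10,
                    peak = list(joint = "HEAD", start_frame = 1,
                                duration = 2, offset = c(0, 0, 1))),
    "unknown peak joint")
})
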
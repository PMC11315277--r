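# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they stay independent of the paths they check.

# Naive per-pixel random error: two-pass loop over pixels and frames.
naive_random_error <- function(frames_array, cut = 0,
                               denominator = c("valid", "analyzed")) {
  denominator <- match.arg(denominator)
  d <- dim(frames_array)
  analyzed <- (cut + 1):d[3]
  re <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      vals <- frames_array[i, j, analyzed]
      vals <- vals[vals != 0]
      if (length(vals) == 0) next
      m <- mean(vals)
      denom <- if (denominator == "valid") length(vals) else length(analyzed)
      re[i, j] <- sqrt(sum((vals - m)^2) / denom)
    }
  }
  re
}

# Naive MDE of a single trajectory (T x 3 matrix), clipped symmetric window.
naive_mde <- function(traj, N) {
  T <- nrow(traj)
  d <- numeric(T)
  for (t in seq_len(T)) {
    win <- max(1, t - N):min(T, t + N)
    cen <- colMeans(traj[win, , drop = FALSE])
    d[t] <- sqrt(sum((traj[t, ] - cen)^2))
  }
  mean(d)
}

# Tie-corrected Kruskal-Wallis H computed from ranks, for enumeration.
oracle_kw_stat <- function(values, grp) {
  r <- rank(values)
  N <- length(values)
  Rs <- tapply(r, grp, sum)
  ni <- tabulate(factor(grp))
  H <- (12 / (N * (N + 1))) * sum(Rs^2 / ni) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact permutation p-value of the KW statistic for 3 groups of size 4.
oracle_kw_exact_p <- function(values) {
  grp0 <- rep(1:3, each = 4)
  obs <- oracle_kw_stat(values, grp0)
  idx1 <- utils::combn(12, 4)
  ge <- 0L; cnt <- 0L
  for (i in seq_len(ncol(idx1))) {
    rest <- setdiff(1:12, idx1[, i])
    idx2 <- utils::combn(rest, 4)
    for (j in seq_len(ncol(idx2))) {
      grp <- integer(12)
      grp[idx1[, i]] <- 1L; grp[idx2[, j]] <- 2L; grp[grp == 0L] <- 3L
      cnt <- cnt + 1L
      if (oracle_kw_stat(values, grp) >= obs - 1e-10) ge <- ge + 1L
    }
  }
  ge / cnt
}

# Exact permutation p-value of the Friedman statistic (k = 3 columns),
# enumerating all within-row orderings.
oracle_friedman_exact_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  stopifnot(k == 3)
  R <- t(apply(m, 1, rank))
  stat_from_colsums <- function(cs) {
    12 * sum((cs - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  }
  obs <- stat_from_colsums(colSums(R))
  perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  grid <- as.matrix(expand.grid(rep(list(1:6), n)))
  cs <- matrix(0, nrow(grid), k)
  for (row in seq_len(n)) cs <- cs + R[row, ][perms3[grid[, row], ]]
  hs <- 12 * rowSums((cs - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  mean(hs >= obs - 1e-10)
}

# Fixture: small tracking sequence around the standard standing pose.
make_pose_seq <- function(n_frames = 200, sigma = 1, seed = 1, ...) {
  sp <- standing_pose()
  simulate_tracking(
    pose_sim_config(sp$true_positions, sigma, n_frames = n_frames, ...),
    seed = seed)
}

# Fixture: random small depth stack with some invalid samples.
make_small_stack <- function(h = 5, w = 5, n = 50, seed = 1,
                             invalid_prob = 0.05, sigma = 2) {
  simulate_depth(
    depth_sim_config(1900, sigma = sigma, invalid_prob = invalid_prob,
                     n_frames = n, height = h, width = w),
    seed = seed)
}

# 3D rotation matrix from an axis (unnormalized) and angle.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Apply an affine map (rotation + translation) to every joint position.
transform_sequence <- function(seq, R = diag(3), shift = c(0, 0, 0)) {
  pos <- seq$positions
  for (j in seq_along(seq$joint_set)) {
    pos[, j, ] <- sweep(matrix(pos[, j, ], ncol = 3) %*% t(R), 2, -shift)
  }
  tracking_sequence(pos, frame_index = seq$frame_index, fps = seq$fps,
                    timestamp_usec = seq$timestamp_usec, gaps = seq$gaps)
}
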
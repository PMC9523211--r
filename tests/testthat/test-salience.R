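# Row curvature, lagged variation, normalization, threshold, sigmoid,
# overlay rendering, and their symmetry properties.

# trajectory whose single configuration places each row's transverse
# positions on a given function of axial position
traj_from_profile <- function(fun, T_ = 2, roi = default_roi()) {
  grid <- feature_grid(roi, 15)
  coords <- array(0, c(T_, grid$ny, grid$nx, 2))
  for (t in seq_len(T_)) {
    coords[t, , , 1] <- grid$coords[, , 1]
    coords[t, , , 2] <- grid$coords[, , 2] + outer(rep(1, grid$ny),
                                                   fun(grid$xs, t))
  }
  make_traj(coords, grid)
}

test_that("collinear rows have exactly zero curvature, parabolic rows 2a", {
  lin <- traj_from_profile(function(x, t) 0.3 * x)
  fc <- fit_row_curvature(lin, 1)
  expect_true(all(fc$fit_valid))
  expect_equal(max(abs(fc$tau)), 0, tolerance = 1e-10)

  par <- traj_from_profile(function(x, t) 0.01 * (x - 60)^2)
  fc <- fit_row_curvature(par, 1)
  expect_equal(unname(fc$tau), rep(0.02, length(fc$tau)), tolerance = 1e-9)
})

test_that("rows with fewer than three valid points are marked unfittable", {
  traj <- static_traj(5)
  traj$valid[3, 1, 3:traj$grid$nx] <- FALSE   # row 1 keeps only 2 points
  fc <- fit_row_curvature(traj, 3)
  expect_false(fc$fit_valid[1])
  expect_true(all(fc$fit_valid[-1]))
})

test_that("curvature variation applies the lag and the first-frame rule", {
  traj <- static_traj(30)
  curv <- row_curvatures(traj)
  curv$tau[, ] <- 0
  curv$tau[11, ] <- 0.2                       # impulse at frame 11
  curv$tau[4, ] <- 0.05                       # early frame, fewer than lag
  curv$fit_valid[, ] <- TRUE
  f <- curvature_variation(curv, lag = 5)
  expect_equal(f$delta_tau[11, 1], 0.2)       # tau[11] - tau[6]
  expect_equal(f$sign[11, 1], 1)
  expect_equal(f$delta_tau[16, 1], -0.2)      # lag window passes the impulse
  expect_equal(f$delta_tau[4, 1], 0.05)       # tau[4] - tau[1]
  expect_equal(f$delta_tau[1, 1], 0)
  expect_true(all(f$delta_tau == f$sign * f$magnitude, na.rm = TRUE))
  expect_error(curvature_variation(curv, lag = 0), "lag")
})

test_that("constant curvature yields zero variation and zero salience", {
  traj <- static_traj(20)
  curv <- row_curvatures(traj)
  curv$tau[, ] <- 0.42
  curv$fit_valid[, ] <- TRUE
  f <- curvature_variation(curv, 5)
  expect_true(all(f$delta_tau == 0))
  sal <- normalize_magnitude(f)
  expect_true(all(sal$y0 == 0))               # degenerate max = min
})

test_that("normalization maps magnitudes onto [0, 1] with both ends attained", {
  traj <- static_traj(10)
  curv <- row_curvatures(traj)
  curv$tau[, ] <- 0
  curv$fit_valid[, ] <- TRUE
  f <- curvature_variation(curv, 5)
  f$magnitude[2, ] <- c(0, 0.5, 1, 0.25)      # 4 rows
  f$valid[, ] <- TRUE
  sal <- normalize_magnitude(f)
  expect_equal(min(sal$y0), 0)
  expect_equal(max(sal$y0), 1)
  expect_equal(sal$y0[2, 2], 0.5)
  expect_true(all(sal$y0 >= 0 & sal$y0 <= 1))
})

test_that("threshold is strict at the boundary and validated", {
  y0 <- matrix(c(0.6, 1.0, 0.59, 0.61), 1)
  sal <- salience_from_y0(y0)
  sal <- apply_threshold(sal, 0.6)
  expect_equal(sal$y1[1, ], c(0, 0.4, -0.01, 0.01))
  expect_equal(sal$salient[1, ], c(FALSE, TRUE, FALSE, TRUE))
  expect_error(apply_threshold(sal, 1.5), "alpha")
  expect_error(apply_threshold(sal, -0.1), "alpha")
})

test_that("sigmoid weights hit the closed-form values and respect beta", {
  sal <- apply_threshold(salience_from_y0(matrix(c(0.6, 1.0), 1)), 0.6)
  s10 <- sigmoid_weights(sal, 10)
  expect_equal(s10$y2[1, 1], 0.5)                       # y1 = 0
  expect_equal(s10$y2[1, 2], 1 / (1 + exp(-4)))         # y1 = 0.4, beta 10
  s100 <- sigmoid_weights(sal, 1000)
  expect_gt(s100$y2[1, 2], 0.999)                       # beta -> inf limit
  expect_error(sigmoid_weights(sal, 0), "beta")
})

test_that("sigmoid weight increases strictly with y1, mask shrinks with alpha", {
  y0 <- matrix(seq(0, 1, length.out = 11), 1)
  sal <- apply_threshold(salience_from_y0(y0), 0.6)
  s <- sigmoid_weights(sal, 10)
  expect_true(all(diff(s$y2[1, ]) > 0))
  masks <- sapply(c(0.2, 0.4, 0.6, 0.8), function(a)
    sum(apply_threshold(salience_from_y0(y0), a)$salient))
  expect_true(all(diff(masks) <= 0))
})

test_that("rigid translation leaves rows straight: no salience anywhere", {
  clip <- generate_translation_clip(duration_s = 40, drift_px_s = 1, seed = 9)
  traj <- smooth_trajectories(track_displacements(clip, feature_grid(default_roi(), 15)))
  f <- curvature_variation(row_curvatures(traj), 5)
  # curvature stays at tracking-noise level: orders below a real wave's
  expect_lt(max(f$magnitude, na.rm = TRUE), 1e-3)
  sal <- apply_threshold(normalize_magnitude(f), 0.6)
  g <- build_motion_graph(sal, "cervix_left")
  expect_equal(nrow(detect_wave_events(g)), 0)
})

test_that("negating transverse motion negates tau and delta-tau, keeps y0", {
  traj <- traj_from_profile(function(x, t) if (t == 1) 0 * x else
    0.005 * (x - 60)^2, T_ = 8)
  # reflect transverse positions about each row's rest line
  neg <- traj
  for (t in seq_len(dim(traj$coords)[1]))
    neg$coords[t, , , 2] <- 2 * traj$grid$coords[, , 2] - traj$coords[t, , , 2]
  neg$disp <- neg$coords[-1, , , , drop = FALSE] -
    neg$coords[-dim(neg$coords)[1], , , , drop = FALSE]
  f_pos <- curvature_variation(row_curvatures(traj), 3)
  f_neg <- curvature_variation(row_curvatures(neg), 3)
  expect_equal(f_neg$delta_tau, -f_pos$delta_tau, tolerance = 1e-9)
  expect_equal(f_neg$sign, -f_pos$sign)
  expect_equal(normalize_magnitude(f_neg)$y0, normalize_magnitude(f_pos)$y0,
               tolerance = 1e-9)
})

test_that("overlay keeps non-salient areas identical and saturates salient rows", {
  set.seed(4)
  frame <- matrix(round(runif(128 * 128, 0, 200)), 128, 128)
  grid <- feature_grid(default_roi(), 15)
  y0 <- matrix(0, 3, grid$ny)
  sal <- sigmoid_weights(apply_threshold(salience_from_y0(y0), 0.6), 10)
  out <- render_overlay(frame, sal, grid, 2)
  expect_equal(out[, , 1], frame)              # no salience: unchanged
  expect_equal(out[, , 2], frame)

  y0[2, 2] <- 1                                # row 2 fully salient
  sal <- sigmoid_weights(apply_threshold(salience_from_y0(y0), 0.6), 1000)
  out <- render_overlay(frame, sal, grid, 2, color = c(255, 0, 0))
  band_y <- grid$ys[2] + 1
  expect_true(all(out[band_y, (grid$roi$x0 + 1):(grid$roi$x0 + grid$roi$width), 1] == 255))
  expect_equal(out[, , 2], frame)              # green channel untouched
  expect_true(all(out >= 0 & out <= 255))
  expect_true(all(out[1:30, , 1] == frame[1:30, ]))   # outside ROI untouched
})
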
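test_that("motion graph counts salient rows by propagation direction", {
  y0 <- matrix(0, 5, 10)
  y0[3, 1:9] <- 1                              # 9 salient rows at frame 3
  prop <- matrix(0, 5, 10)
  prop[3, 1:7] <- -1                           # 7 move image-left (forward)
  prop[3, 8:10] <- +1                          # 3 move image-right
  sal <- apply_threshold(salience_from_y0(y0, prop), 0.6)
  g <- build_motion_graph(sal, "cervix_left")
  expect_equal(g$n_plus[3], 7)
  expect_equal(g$n_minus[3], 2)                # row 10 is not salient
  expect_true(all(g$n_plus + g$n_minus <= g$total))
  expect_equal(g$n_plus[-3], rep(0, 4))
  # empty mask: all-zero graph
  g0 <- build_motion_graph(apply_threshold(salience_from_y0(y0 * 0, prop), 0.6),
                           "cervix_left")
  expect_true(all(g0$n_plus == 0 & g0$n_minus == 0))
  # point-level counting scales by points per row
  gp <- build_motion_graph(sal, "cervix_left", count_unit = "points",
                           points_per_row = 8)
  expect_equal(gp$n_plus[3], 56)
})

test_that("a triangular activity bump segments into the brute-force run", {
  n <- c(rep(0, 20), 0:10, 10:0, rep(0, 20))   # 0 -> 10 -> 0 over 22 frames
  g <- make_graph(n, rep(0, length(n)), total = 12, frame_rate = 2)
  ev <- detect_wave_events(g, min_count = 3, min_duration_s = 2,
                           merge_gap_s = 1)
  oracle <- range(which(n >= 3))               # brute-force active scan
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$start_frame, ev$end_frame), oracle)
})

test_that("event merging bridges short gaps and activity-carried dips", {
  bump <- c(3, 5, 5, 3)                        # 4 active frames = 2 s
  zeros <- function(k) rep(0, k)
  n <- c(zeros(5), bump, 0, bump, zeros(20), bump, zeros(5))
  g <- make_graph(n, zeros(length(n)), frame_rate = 2)
  ev <- detect_wave_events(g, 3, 2, 1)         # 1 s = 2 frames at 2 fps
  expect_equal(nrow(ev), 2)                    # 1-frame gap merges, 20 does not
  # the long gap merges only when displacement activity bridges it
  ev2 <- detect_wave_events(g, 3, 2, 1, bridge = rep(TRUE, length(n)))
  expect_equal(nrow(ev2), 1)
  # all-zero graph: no events
  expect_equal(nrow(detect_wave_events(make_graph(zeros(30), zeros(30)), 3, 2, 1)), 0)
  expect_error(detect_wave_events(g, 0, 2, 1), "positive")
})

test_that("direction classification follows the motion-graph peak patterns", {
  z <- rep(0, 30)
  bump <- c(z[1:5], 0, 3, 6, 8, 6, 3, 0, z[1:18])
  # pattern A: one-way, opposite curve at zero
  g <- make_graph(bump, z, frame_rate = 2, orientation = "cervix_left")
  span <- data.frame(start_frame = 6, end_frame = 12)
  expect_equal(classify_direction(span, g, "cervix_left"), "FC")  # toward cervix
  expect_equal(classify_direction(span, g, "cervix_right"), "CF")
  g2 <- make_graph(z, bump, frame_rate = 2)
  expect_equal(classify_direction(span, g2, "cervix_left"), "CF")
  expect_equal(classify_direction(span, g2, "cervix_right"), "FC")
  # patterns B/C: both curves peak -> mixed
  shifted <- c(z[1:8], 0, 3, 6, 8, 6, 3, 0, z[1:15])
  gb <- make_graph(bump, shifted, frame_rate = 2)
  expect_equal(classify_direction(data.frame(start_frame = 6, end_frame = 15),
                                  gb, "cervix_left"), "CF_FC")
  gc <- make_graph(bump, bump, frame_rate = 2)
  expect_equal(classify_direction(span, gc, "cervix_left"), "CF_FC")
  # a span without any qualifying peak is a contract violation
  expect_error(classify_direction(span, make_graph(z, z, frame_rate = 2),
                                  "cervix_left"), "no peaks")
})

test_that("intensity classes follow the range/amplitude criteria", {
  mk <- function(rng_rows, amp_count, total = 10) {
    y0 <- matrix(0, 10, total)
    y0[5, seq_len(rng_rows)] <- 1
    sal <- apply_threshold(salience_from_y0(y0), 0.6)
    g <- make_graph(c(rep(0, 4), amp_count, rep(0, 5)), rep(0, 10),
                    total = total, frame_rate = 2)
    measure_intensity(data.frame(start_frame = 3, end_frame = 8), g, sal,
                      range_scale = 2, amp_scale = 2)
  }
  weak <- mk(4, 3)          # range 0.8, amplitude 0.6
  expect_equal(weak$range, 0.8)
  expect_equal(weak$amplitude, 0.6)
  expect_equal(weak$intensity_class, "weak")
  moderate <- mk(6, 3)      # range 1.2, amplitude 0.6
  expect_equal(moderate$intensity_class, "moderate")
  strong <- mk(6, 7)        # range 1.2, amplitude 1.4
  expect_equal(strong$intensity_class, "strong")
  expect_equal(strong$intensity_score, 1.2 + 1.4)
})

test_that("velocity is the centroid path over time, scaled by pixel size", {
  # salient centroid moving 30 px over 20 s at 0.1 mm/px -> 0.15 mm/s
  T_ <- 41; R_ <- 4
  y0 <- matrix(1, T_, R_)
  sal <- apply_threshold(salience_from_y0(y0), 0.6)
  sal$frame_rate <- 2
  sal$centroid <- matrix(rep(seq(50, 80, length.out = T_), R_), T_, R_)
  sal$peak_disp <- matrix(1, T_, R_)
  span <- data.frame(start_frame = 1, end_frame = T_)
  v <- measure_velocity(span, sal, pixel_spacing = 0.1)
  expect_equal(v$velocity_mm_s, 0.15, tolerance = 1e-9)
  expect_equal(v$shape_ratio, NA_real_)
  v2 <- measure_velocity(span, sal, 0.1,
                         intensity = list(amplitude = 2, range = 4))
  expect_equal(v2$shape_ratio, 0.5)
  expect_error(measure_velocity(data.frame(start_frame = 5, end_frame = 5),
                                sal, 0.1), "span")
})

test_that("analyze_clip recovers two known waves and is deterministic", {
  spec <- synthetic_spec(seed = 7, waves = data.frame(
    start_s = c(10, 55), direction = c("forward", "backward"),
    amplitude_px = 4, wavelength_px = 48, speed_px_s = 6))
  gen <- generate_peristalsis_clip(spec)
  rep1 <- analyze_clip(gen$clip, band_roi(spec), clip_id = "two-wave")
  expect_equal(rep1$wave_count, 2)
  expect_equal(rep1$events$direction, c("FC", "CF"))
  expect_equal(unname(rep1$direction_counts["CF"]), 1)
  # velocity close to the generated 0.6 mm/s for both events
  expect_true(all(abs(rep1$events$velocity_mm_s - 0.6) / 0.6 < 0.25))
  rep2 <- analyze_clip(gen$clip, band_roi(spec), clip_id = "two-wave")
  expect_identical(rep1$events, rep2$events)    # bit-reproducible
})

test_that("static clips yield no waves", {
  spec <- synthetic_spec(seed = 5, duration_s = 60, waves = data.frame(
    start_s = 10, direction = "forward", amplitude_px = 0,
    wavelength_px = 48, speed_px_s = 6))
  gen <- generate_peristalsis_clip(spec)
  expect_equal(analyze_clip(gen$clip, band_roi(spec))$wave_count, 0)
})

test_that("time reversal preserves the count and swaps CF and FC", {
  spec <- synthetic_spec(seed = 11, waves = data.frame(
    start_s = 20, direction = "forward", amplitude_px = 4,
    wavelength_px = 48, speed_px_s = 8))
  gen <- generate_peristalsis_clip(spec)
  fwd <- analyze_clip(gen$clip, band_roi(spec))
  expect_equal(fwd$events$direction, "FC")
  rev_frames <- gen$clip$frames[, , dim(gen$clip$frames)[3]:1]
  rev_clip <- cine_clip(rev_frames, gen$clip$frame_rate,
                        gen$clip$pixel_spacing, gen$clip$orientation)
  bwd <- analyze_clip(rev_clip, band_roi(spec))
  expect_equal(bwd$wave_count, fwd$wave_count)
  expect_equal(bwd$events$direction, "CF")
})

test_that("mirroring the clip and the declared cervix side changes nothing", {
  spec <- synthetic_spec(seed = 11, waves = data.frame(
    start_s = 20, direction = "forward", amplitude_px = 4,
    wavelength_px = 48, speed_px_s = 8))
  gen <- generate_peristalsis_clip(spec)
  roi <- band_roi(spec)
  orig <- analyze_clip(gen$clip, roi)
  W <- dim(gen$clip$frames)[2]
  mir_clip <- cine_clip(gen$clip$frames[, W:1, ], gen$clip$frame_rate,
                        gen$clip$pixel_spacing, "cervix_right")
  mir_roi <- roi_rect(W - (roi$x0 + roi$width), roi$y0, roi$width, roi$height)
  mir <- analyze_clip(mir_clip, mir_roi)
  expect_equal(mir$wave_count, orig$wave_count)
  expect_equal(mir$events$direction, orig$events$direction)
  expect_equal(mir$events$velocity_mm_s, orig$events$velocity_mm_s,
               tolerance = 0.05)
})

test_that("vertical clips use the image-down forward convention", {
  spec <- synthetic_spec(seed = 11, orientation = "cervix_up",
                         waves = data.frame(start_s = 20, direction = "forward",
                                            amplitude_px = 4, wavelength_px = 48,
                                            speed_px_s = 8))
  gen <- generate_peristalsis_clip(spec)
  rep <- analyze_clip(gen$clip, band_roi(spec))
  expect_equal(rep$wave_count, 1)
  # forward = down = away from a cervix declared at the top: CF
  expect_equal(rep$events$direction, "CF")
})

test_that("reports serialize to JSON and CSV with the config echoed", {
  spec <- synthetic_spec(seed = 11, waves = data.frame(
    start_s = 20, direction = "forward", amplitude_px = 4,
    wavelength_px = 48, speed_px_s = 8))
  gen <- generate_peristalsis_clip(spec)
  rep <- analyze_clip(gen$clip, band_roi(spec), clip_id = "ser")
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  report_to_json(rep, jp)
  events_to_csv(rep, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$wave_count, 1)
  expect_equal(back$config$alpha, 0.6)
  expect_equal(back$config$grid_spacing, 15)
  ev <- read.csv(cp)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "FC")
})
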
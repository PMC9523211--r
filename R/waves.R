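# Motion graph and wave events. Per frame, the counts n_plus / n_minus of
# salient forward- and backward-moving rows form two curves whose runs and
# peaks segment and classify the peristaltic waves:
#   (A) one-way motion: the opposite curve stays at the noise floor;
#   (B) forward-then-backward (or the reverse): peaks alternate;
#   (C) simultaneous forward and backward: peaks coincide.
# (B) and (C) are both reported as one mixed-direction (CF+FC) event.

#' Build the per-frame directional motion graph
#'
#' Counts, for every frame, the salient rows whose propagation sign points
#' in the image's forward direction (left for a horizontal endometrium,
#' down for a vertical one) and likewise backward.
#'
#' @param sal a salience field with threshold applied ([apply_threshold()]).
#' @param orientation declared cervix side (see [cine_clip()]).
#' @param count_unit \code{"rows"} counts salient rows; \code{"points"}
#'   counts every feature point belonging to a salient row.
#' @param points_per_row number of grid points per row (required for
#'   \code{count_unit = "points"}).
#' @return object of class \code{motion_graph}: vectors \code{n_plus},
#'   \code{n_minus}, plus \code{total} (rows or points per frame),
#'   \code{frame_rate}, \code{orientation}.
#' @export
build_motion_graph <- function(sal, orientation, count_unit = "rows",
                               points_per_row = NULL) {
  if (is.null(sal$salient)) stop("apply_threshold() first")
  fsign <- forward_axial_sign(orientation)
  fwd <- sal$salient & (sal$prop_sign == fsign)
  bwd <- sal$salient & (sal$prop_sign == -fsign)
  mult <- 1
  if (count_unit == "points") {
    if (is.null(points_per_row)) stop("points_per_row required for count_unit='points'")
    mult <- points_per_row
  }
  structure(list(n_plus = rowSums(fwd) * mult, n_minus = rowSums(bwd) * mult,
                 total = ncol(sal$salient) * mult,
                 frame_rate = sal$frame_rate, orientation = orientation),
            class = "motion_graph")
}

# local maxima with minimum height and prominence; plateaus yield their
# first frame
find_peaks <- function(x, min_height, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  peaks <- integer(0)
  i <- 2
  while (i < n) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j == n || x[j + 1] < x[i]) peaks <- c(peaks, i)
      i <- j + 1
    } else i <- i + 1
  }
  keep <- vapply(peaks, function(p) {
    h <- x[p]
    if (h < min_height) return(FALSE)
    l <- p; lmin <- h
    while (l > 1 && x[l - 1] <= h) { l <- l - 1; lmin <- min(lmin, x[l]) }
    if (l == 1) lmin <- min(x[1:p])
    r <- p; rmin <- h
    while (r < n && x[r + 1] <= h) { r <- r + 1; rmin <- min(rmin, x[r]) }
    if (r == n) rmin <- min(x[p:n])
    (h - max(lmin, rmin)) >= min_prominence
  }, TRUE)
  peaks[keep]
}

#' Detect wave events on the motion graph
#'
#' Frames where \code{max(n_plus, n_minus) >= min_count} are active.
#' Active runs are merged when separated by a gap shorter than
#' \code{merge_gap}, or by a gap whose every frame still shows sub-salient
#' displacement activity (\code{bridge}): the curvature-variation magnitude
#' of one wave necessarily passes through zero mid-crossing (the row
#' curvature reaches its extremum there), so a single wave shows a salience
#' dip while its tissue stays displaced, whereas between distinct waves the
#' tissue is at rest. Merged runs shorter than \code{min_duration} are then
#' discarded; each remaining run is one wave event, so a mixed CF+FC
#' episode counts once.
#'
#' @param graph a [build_motion_graph()] result.
#' @param min_count minimum salient count for an active frame (> 0).
#' @param min_duration_s minimum event duration in seconds (> 0).
#' @param merge_gap_s gaps shorter than this merge, seconds (> 0).
#' @param bridge optional per-frame logical vector marking frames with
#'   ongoing displacement activity; gaps consisting solely of such frames
#'   are merged regardless of length.
#' @return data.frame with 1-based inclusive \code{start_frame},
#'   \code{end_frame}.
#' @export
detect_wave_events <- function(graph, min_count = 3, min_duration_s = 2,
                               merge_gap_s = 1, bridge = NULL) {
  if (min_count <= 0 || min_duration_s <= 0 || merge_gap_s <= 0)
    stop("event thresholds must be positive")
  fps <- graph$frame_rate
  active <- pmax(graph$n_plus, graph$n_minus) >= min_count
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  gap_frames <- merge_gap_s * fps
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    last <- merged[[length(merged)]]
    gap <- (last[2] + 1):(runs[i, 1] - 1)
    bridged <- length(gap) > 0 && !is.null(bridge) && all(bridge[gap])
    if (runs[i, 1] - last[2] - 1 < gap_frames || bridged)
      merged[[length(merged)]] <- c(last[1], runs[i, 2])
    else merged[[length(merged) + 1]] <- runs[i, ]
  }
  m <- do.call(rbind, merged)
  min_frames <- ceiling(min_duration_s * fps)
  m <- m[m[, 2] - m[, 1] + 1 >= min_frames, , drop = FALSE]
  data.frame(start_frame = as.integer(m[, 1]), end_frame = as.integer(m[, 2]))
}

#' Classify a wave event's direction
#'
#' Locates peaks of \code{n_plus} and \code{n_minus} inside the event span
#' (local maxima at least \code{min_count} high with prominence at least
#' \code{min_count / 2}). If only one curve peaks while the other stays at
#' the noise floor the event is one-way, mapped to CF or FC through the
#' declared cervix side; if both curves peak (alternately or
#' simultaneously) the event is mixed CF+FC.
#'
#' @param span list or one-row data.frame with \code{start_frame},
#'   \code{end_frame}.
#' @param graph a [build_motion_graph()] result.
#' @param orientation declared cervix side.
#' @param min_count noise floor, as in [detect_wave_events()].
#' @return \code{"CF"}, \code{"FC"}, or \code{"CF_FC"}.
#' @export
classify_direction <- function(span, graph, orientation, min_count = 3) {
  idx <- span$start_frame:span$end_frame
  np <- graph$n_plus[idx]; nm <- graph$n_minus[idx]
  pad <- function(x) c(0, x, 0)                  # run edges count as peaks
  P <- find_peaks(pad(np), min_count, min_count / 2)
  M <- find_peaks(pad(nm), min_count, min_count / 2)
  if (length(P) == 0 && length(M) == 0)
    stop("event span contains no peaks; should not survive detect_wave_events()")
  if (length(M) == 0) return(direction_class("forward", orientation))
  if (length(P) == 0) return(direction_class("backward", orientation))
  "CF_FC"
}

#' Measure a wave event's intensity
#'
#' The peristaltic range is the maximal fraction of rows simultaneously
#' salient during the event, and the amplitude the peak motion-graph count
#' as a fraction of all countable entries, each scaled so that the value 1
#' is the class boundary (with the default scale 2, half of the rows).
#' Classes: weak when both are below 1, strong when both exceed 1,
#' moderate otherwise; the intensity score is their sum.
#'
#' @inheritParams classify_direction
#' @param sal the thresholded salience field.
#' @param range_scale,amp_scale axis scaling constants (default 2).
#' @return list with \code{range}, \code{amplitude}, \code{intensity_class},
#'   \code{intensity_score}.
#' @export
measure_intensity <- function(span, graph, sal, range_scale = 2, amp_scale = 2) {
  idx <- span$start_frame:span$end_frame
  simultaneous <- rowSums(sal$salient[idx, , drop = FALSE])
  rng <- max(simultaneous) / ncol(sal$salient) * range_scale
  amp <- max(graph$n_plus[idx] + graph$n_minus[idx]) / graph$total * amp_scale
  cls <- if (rng < 1 && amp < 1) "weak" else if (rng > 1 && amp > 1) "strong" else "moderate"
  list(range = rng, amplitude = amp, intensity_class = cls,
       intensity_score = rng + amp)
}

#' Measure a wave event's velocity
#'
#' Follows the axial centroid of the salient rows' transverse activity
#' through the event and reports its speed: path length (mm) over time (s),
#' estimated as the slope of a straight-line fit of centroid position
#' against time. The first and last 20% of the salient frames are trimmed
#' before fitting because the wave's entry into and exit from the ROI
#' compress the centroid near the borders. The secondary shape descriptor
#' is the wave-peak to wavelength ratio (amplitude / range).
#'
#' @inheritParams measure_intensity
#' @param pixel_spacing mm per pixel.
#' @param intensity optional [measure_intensity()] result for the shape
#'   ratio.
#' @param trim fraction of salient frames dropped at each end.
#' @return list with \code{velocity_mm_s}, \code{velocity_px_s},
#'   \code{shape_ratio} (NA without \code{intensity}).
#' @export
measure_velocity <- function(span, sal, pixel_spacing, intensity = NULL,
                             trim = 0.2) {
  if (span$end_frame <= span$start_frame)
    stop("event span must cover more than one frame")
  idx <- span$start_frame:span$end_frame
  fps <- sal$frame_rate
  cent <- vapply(idx, function(f) {
    r <- sal$salient[f, ]
    c_ok <- r & !is.na(sal$centroid[f, ])
    if (!any(c_ok)) return(NA_real_)
    w <- sal$peak_disp[f, c_ok]
    if (sum(w) <= 0) return(mean(sal$centroid[f, c_ok]))
    sum(sal$centroid[f, c_ok] * w) / sum(w)
  }, 0)
  ok <- which(!is.na(cent))
  if (length(ok) < 2) stop("too few salient frames to measure velocity")
  ntrim <- floor(length(ok) * trim)
  if (length(ok) - 2 * ntrim >= 2) ok <- ok[(ntrim + 1):(length(ok) - ntrim)]
  tt <- (idx[ok] - 1) / fps
  slope <- stats::coef(stats::lm(cent[ok] ~ tt))[2]
  v_px <- abs(unname(slope))
  list(velocity_mm_s = v_px * pixel_spacing, velocity_px_s = v_px,
       shape_ratio = if (is.null(intensity)) NA_real_
                     else intensity$amplitude / intensity$range)
}

#' Analyze a cine clip end to end
#'
#' Runs the full pipeline: feature grid, Lucas-Kanade tracking, temporal
#' and spatial smoothing, row-curvature fitting, lagged curvature
#' variation, normalization, thresholding, motion graph, event detection,
#' and per-event direction/intensity/velocity measurement. Deterministic
#' for fixed inputs and parameters.
#'
#' @param clip a [cine_clip()].
#' @param roi a [roi_rect()] enclosing the endometrium.
#' @param config a [run_config()].
#' @param clip_id identifier echoed into the report.
#' @return object of class \code{clip_report}: \code{clip_id},
#'   \code{wave_count}, \code{events} (data.frame), \code{direction_counts},
#'   \code{mean_intensity}, \code{mean_velocity_mm_s}, \code{config},
#'   plus the intermediate \code{salience}, \code{graph}, \code{grid} for
#'   rendering.
#' @export
analyze_clip <- function(clip, roi, config = run_config(), clip_id = "clip") {
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  axial <- axial_axis(clip$orientation)
  grid <- stage("grid", feature_grid(roi, config$grid_spacing))
  traj <- stage("tracking", track_displacements(clip, grid,
                window = config$lk_window, levels = config$lk_levels))
  traj <- stage("smoothing", smooth_trajectories(traj,
                config$temporal_window, config$spatial_window))
  curv <- stage("curvature", row_curvatures(traj, axial))
  field <- stage("variation", curvature_variation(curv, config$lag))
  sal <- stage("salience", sigmoid_weights(
    apply_threshold(normalize_magnitude(field), config$alpha), config$beta))
  ppr <- if (axial == "x") grid$nx else grid$ny
  graph <- stage("motion-graph", build_motion_graph(sal, clip$orientation,
                 config$count_unit, points_per_row = ppr))
  # sub-salient activity: rows displaced beyond a quarter of the clip's
  # peak transverse displacement keep a wave's salience dip bridged
  pk <- sal$peak_disp
  pk_max <- max(pk, na.rm = TRUE)
  bridge <- if (is.finite(pk_max) && pk_max > 0)
    rowSums(pk >= 0.25 * pk_max, na.rm = TRUE) >= config$min_count
  else rep(FALSE, nrow(pk))
  spans <- stage("events", detect_wave_events(graph, config$min_count,
                 config$min_duration_s, config$merge_gap_s, bridge = bridge))

  ev <- lapply(seq_len(nrow(spans)), function(i) {
    span <- spans[i, ]
    dir <- classify_direction(span, graph, clip$orientation, config$min_count)
    inten <- measure_intensity(span, graph, sal,
                               config$range_scale, config$amp_scale)
    vel <- measure_velocity(span, sal, clip$pixel_spacing, inten)
    data.frame(start_frame = span$start_frame, end_frame = span$end_frame,
               start_s = (span$start_frame - 1) / clip$frame_rate,
               end_s = (span$end_frame - 1) / clip$frame_rate,
               direction = dir, range = inten$range,
               amplitude = inten$amplitude,
               intensity_class = inten$intensity_class,
               intensity_score = inten$intensity_score,
               velocity_mm_s = vel$velocity_mm_s,
               velocity_px_s = vel$velocity_px_s,
               shape_ratio = vel$shape_ratio)
  })
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start_frame = integer(0), end_frame = integer(0),
               start_s = numeric(0), end_s = numeric(0),
               direction = character(0), range = numeric(0),
               amplitude = numeric(0), intensity_class = character(0),
               intensity_score = numeric(0), velocity_mm_s = numeric(0),
               velocity_px_s = numeric(0), shape_ratio = numeric(0))
  dircounts <- c(CF = sum(events$direction == "CF"),
                 FC = sum(events$direction == "FC"),
                 CF_FC = sum(events$direction == "CF_FC"))
  structure(list(
    clip_id = clip_id, wave_count = nrow(events), events = events,
    direction_counts = dircounts,
    mean_intensity = if (nrow(events)) mean(events$intensity_score) else NA_real_,
    mean_velocity_mm_s = if (nrow(events)) mean(events$velocity_mm_s) else NA_real_,
    config = unclass(config), orientation = clip$orientation,
    salience = sal, graph = graph, grid = grid),
    class = "clip_report")
}

#' @export
print.clip_report <- function(x, ...) {
  cat(sprintf("<clip_report> %s: %d wave(s) [CF %d, FC %d, CF+FC %d]\n",
              x$clip_id, x$wave_count, x$direction_counts["CF"],
              x$direction_counts["FC"], x$direction_counts["CF_FC"]))
  if (x$wave_count > 0)
    cat(sprintf("  mean intensity %.2f, mean velocity %.3f mm/s\n",
                x$mean_intensity, x$mean_velocity_mm_s))
  invisible(x)
}

#' Render the motion-amplified overlay frames for a report
#'
#' Forward-moving salient rows glow red and backward-moving rows blue,
#' matching the convention that red marks cervix-to-fundus motion when the
#' cervix lies on the forward side's opposite end.
#'
#' @param clip the analyzed [cine_clip()].
#' @param report the matching [analyze_clip()] result.
#' @return list of RGB frames suitable for [write_overlay_video()].
#' @export
overlay_frames <- function(clip, report) {
  sal <- report$salience
  fsign <- forward_axial_sign(clip$orientation)
  cf_is_fwd <- direction_class("forward", clip$orientation) == "CF"
  red <- c(255, 0, 0); blue <- c(0, 80, 255)
  col_fwd <- if (cf_is_fwd) red else blue
  col_bwd <- if (cf_is_fwd) blue else red
  lapply(seq_len(n_frames(clip)), function(f) {
    fr <- clip$frames[, , f]
    fwd_rows <- which(sal$prop_sign[f, ] == fsign)
    bwd_rows <- which(sal$prop_sign[f, ] == -fsign)
    out <- render_overlay(fr, sal, report$grid, f, col_fwd, rows = fwd_rows)
    g <- render_overlay(fr, sal, report$grid, f, col_bwd, rows = bwd_rows)
    delta <- g - c(fr)                 # add the blue contribution on top
    out <- out + delta
    out[out > 255] <- 255; out[out < 0] <- 0
    out
  })
}

#' Write a clip report as JSON
#'
#' @param report a [clip_report][analyze_clip()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
report_to_json <- function(report, path) {
  out <- report[c("clip_id", "wave_count", "direction_counts",
                  "mean_intensity", "mean_velocity_mm_s", "orientation")]
  out$direction_counts <- as.list(report$direction_counts)
  out$events <- report$events
  out$config <- report$config
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a report's events as CSV (one row per event)
#'
#' @param report a [clip_report][analyze_clip()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
events_to_csv <- function(report, path) {
  ev <- report$events
  if (nrow(ev)) ev <- cbind(clip_id = report$clip_id, ev)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
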
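#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow
#' the algorithm's published operating point where one exists (grid spacing
#' 15 px, curvature-variation lag 5 frames, salience threshold alpha 0.6);
#' the remainder are this package's documented choices.
#'
#' @param ... named overrides of any field below.
#' @return a named list of class \code{run_config} with fields:
#' \describe{
#'   \item{grid_spacing}{feature-point interval, px (15)}
#'   \item{lag}{curvature-variation lag, frames (5)}
#'   \item{alpha}{salience threshold on normalized magnitude, in 0..1 (0.6)}
#'   \item{beta}{sigmoid slope for rendering weights (10)}
#'   \item{temporal_window}{temporal boxcar length, frames, odd (5)}
#'   \item{spatial_window}{spatial boxcar side, grid cells, odd (3)}
#'   \item{min_count}{salient rows required for an active frame (3)}
#'   \item{min_duration_s}{minimum event duration, s (2)}
#'   \item{merge_gap_s}{events closer than this merge, s (1)}
#'   \item{range_scale,amp_scale}{intensity axis scales; with 2, half the
#'     rows salient sits at the weak/strong class boundary 1.0 (2, 2)}
#'   \item{lk_window}{Lucas-Kanade integration window, px, odd (21)}
#'   \item{lk_levels}{image pyramid levels (3)}
#'   \item{count_unit}{"rows" (default) or "points": what n+/n- count}
#'   \item{rounding}{"half-up" (default) or "iec" for reported fractions}
#' }
#' @export
run_config <- function(...) {
  cfg <- list(
    grid_spacing = 15, lag = 5, alpha = 0.6, beta = 10,
    temporal_window = 5, spatial_window = 3,
    min_count = 3, min_duration_s = 2, merge_gap_s = 1,
    range_scale = 2, amp_scale = 2,
    lk_window = 21, lk_levels = 3,
    count_unit = "rows", rounding = "half-up"
  )
  over <- list(...)
  bad <- setdiff(names(over), c(names(cfg), "roi", "pixel_spacing_mm",
                                "frame_rate", "orientation"))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$grid_spacing < 1) stop("grid_spacing must be >= 1 px")
  if (cfg$lag < 1) stop("lag must be >= 1 frame")
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must lie in [0, 1]")
  if (cfg$beta <= 0) stop("beta must be > 0")
  for (f in c("temporal_window", "spatial_window"))
    if (cfg[[f]] < 1 || cfg[[f]] %% 2 == 0)
      stop(f, " must be an odd positive integer")
  if (cfg$min_count <= 0 || cfg$min_duration_s <= 0 || cfg$merge_gap_s <= 0)
    stop("event thresholds must be positive")
  if (!cfg$count_unit %in% c("rows", "points"))
    stop("count_unit must be 'rows' or 'points'")
  invisible(cfg)
}

#' Read a run configuration (plus ROI and calibration) from JSON
#'
#' The file may carry any [run_config()] field plus \code{roi} (object with
#' x0, y0, width, height), \code{pixel_spacing_mm}, \code{frame_rate} and
#' \code{orientation}.
#'
#' @param path JSON file path.
#' @return list with elements \code{config} ([run_config()]), \code{roi}
#'   ([roi_rect()] or NULL), \code{pixel_spacing_mm}, \code{frame_rate},
#'   \code{orientation} (NULL where absent).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi <- NULL
  if (!is.null(raw$roi))
    roi <- roi_rect(raw$roi$x0, raw$roi$y0, raw$roi$width, raw$roi$height)
  keep <- intersect(names(raw), names(run_config()))
  cfg <- do.call(run_config, raw[keep])
  list(config = cfg, roi = roi,
       pixel_spacing_mm = raw$pixel_spacing_mm,
       frame_rate = raw$frame_rate,
       orientation = raw$orientation)
}

# --- orientation conventions -------------------------------------------
# Forward image direction is left for a horizontal endometrium and down for
# a vertical one; backward is the opposite. The declared cervix side then
# maps forward/backward onto cervix-to-fundus (CF) / fundus-to-cervix (FC).

axial_axis <- function(orientation) {
  if (orientation %in% c("cervix_left", "cervix_right")) "x" else "y"
}

# sign of the raw axial coordinate change that counts as "forward":
# left = decreasing x (-1); down = increasing y (+1)
forward_axial_sign <- function(orientation) {
  if (axial_axis(orientation) == "x") -1 else 1
}

# map a pure image direction ("forward"/"backward") to CF / FC
direction_class <- function(image_dir, orientation) {
  cervix_on_forward_side <- orientation %in% c("cervix_left", "cervix_down")
  if (image_dir == "forward") {
    if (cervix_on_forward_side) "FC" else "CF"
  } else {
    if (cervix_on_forward_side) "CF" else "FC"
  }
}
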
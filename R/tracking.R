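#' Aligned feature-point grid
#'
#' Fills the ROI with equally spaced feature points at
#' \code{x0 + i*spacing, y0 + j*spacing}, keeping every point strictly
#' inside the half-open rectangle. The default 15-px interval is the
#' algorithm's standard operating point.
#'
#' @param roi a [roi_rect()].
#' @param spacing point interval in pixels (>= 1); the ROI must measure at
#'   least \code{2*spacing} in both dimensions.
#' @return object of class \code{feature_grid}: \code{xs}, \code{ys} (pixel
#'   coordinates), \code{nx}, \code{ny}, \code{spacing}, \code{roi}, and
#'   \code{coords}, an \code{ny x nx x 2} array of initial (x, y) positions.
#' @export
feature_grid <- function(roi, spacing = 15) {
  if (!inherits(roi, "roi_rect")) stop("roi must be a roi_rect")
  if (!is.numeric(spacing) || spacing < 1) stop("spacing must be >= 1 px")
  if (roi$width < 2 * spacing || roi$height < 2 * spacing)
    stop(sprintf("ROI %gx%g too small for a 2x2 grid at spacing %g px",
                 roi$width, roi$height, spacing))
  nx <- floor((roi$width - 1e-9) / spacing) + 1
  ny <- floor((roi$height - 1e-9) / spacing) + 1
  xs <- roi$x0 + spacing * (seq_len(nx) - 1)
  ys <- roi$y0 + spacing * (seq_len(ny) - 1)
  coords <- array(0, c(ny, nx, 2))
  coords[, , 1] <- matrix(xs, ny, nx, byrow = TRUE)
  coords[, , 2] <- matrix(ys, ny, nx)
  structure(list(xs = xs, ys = ys, nx = nx, ny = ny, spacing = spacing,
                 roi = roi, coords = coords),
            class = "feature_grid")
}

#' Track grid displacements with sparse pyramidal Lucas-Kanade flow
#'
#' Estimates each feature point's subpixel displacement between every pair
#' of adjacent frames. Points on texture-free patches (ill-conditioned
#' gradient matrix), points whose matching residual is large, and points
#' leaving the frame are marked invalid from that frame on and never
#' re-seeded.
#'
#' @param clip a [cine_clip()].
#' @param grid a [feature_grid()].
#' @param window Lucas-Kanade integration window side in px (odd).
#' @param levels pyramid levels.
#' @return object of class \code{trajectory_set}: \code{coords}
#'   (\code{T x ny x nx x 2} tracked positions), \code{disp}
#'   (\code{(T-1) x ny x nx x 2} adjacent-frame displacements),
#'   \code{valid} (\code{T x ny x nx}), plus \code{grid} and
#'   \code{frame_rate}.
#' @export
track_displacements <- function(clip, grid, window = 21, levels = 3) {
  if (!inherits(clip, "cine_clip")) stop("clip must be a cine_clip")
  if (n_frames(clip) < 2) stop("clip must have at least 2 frames")
  check_roi_inside(grid$roi, dim(clip$frames))
  T_ <- n_frames(clip); ny <- grid$ny; nx <- grid$nx
  np <- ny * nx

  coords <- array(NA_real_, c(T_, ny, nx, 2))
  valid <- array(TRUE, c(T_, ny, nx))
  coords[1, , , ] <- grid$coords

  pts <- cbind(as.vector(grid$coords[, , 1]), as.vector(grid$coords[, , 2]))
  alive <- rep(TRUE, np)
  for (t in seq_len(T_ - 1)) {
    res <- .lk_track_pair(clip$frames[, , t], clip$frames[, , t + 1],
                          pts, as.integer(window), as.integer(levels))
    ok <- alive & (res[, 3] > 0)
    pts[ok, ] <- res[ok, 1:2, drop = FALSE]
    alive <- ok
    coords[t + 1, , , 1] <- matrix(pts[, 1], ny, nx)
    coords[t + 1, , , 2] <- matrix(pts[, 2], ny, nx)
    valid[t + 1, , ] <- matrix(alive, ny, nx)
  }
  disp <- coords[-1, , , , drop = FALSE] - coords[-T_, , , , drop = FALSE]
  structure(list(coords = coords, disp = disp, valid = valid, grid = grid,
                 frame_rate = clip$frame_rate),
            class = "trajectory_set")
}

# boxcar mean over a ny x nx matrix with window w (odd), shrinking at
# borders, NA cells excluded
spatial_boxcar <- function(m, w) {
  if (w == 1) return(m)
  hw <- (w - 1) / 2
  ny <- nrow(m); nx <- ncol(m)
  s <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  vals <- ifelse(is.na(m), 0, m)
  has <- !is.na(m)
  for (dy in -hw:hw) for (dx in -hw:hw) {
    ys <- pmax(1, pmin(ny, seq_len(ny) + dy)); ok_y <- (seq_len(ny) + dy) %in% seq_len(ny)
    xs <- pmax(1, pmin(nx, seq_len(nx) + dx)); ok_x <- (seq_len(nx) + dx) %in% seq_len(nx)
    sub_y <- which(ok_y); sub_x <- which(ok_x)
    s[sub_y, sub_x] <- s[sub_y, sub_x] + vals[sub_y + dy, sub_x + dx, drop = FALSE]
    cnt[sub_y, sub_x] <- cnt[sub_y, sub_x] + has[sub_y + dy, sub_x + dx, drop = FALSE]
  }
  out <- s / cnt
  out[cnt == 0] <- NA
  out
}

#' Smooth trajectories in time and space
#'
#' Replaces displacements by a temporal moving average per point followed by
#' a spatial moving average over the grid neighbourhood per frame, then
#' rebuilds the tracked coordinates as the cumulative sum of the smoothed
#' displacements. Windows shrink at sequence and grid borders rather than
#' padding, and invalid points are excluded from every average. Suppresses
#' the frame-to-frame speckle jitter of ultrasound.
#'
#' @param traj a trajectory set from [track_displacements()].
#' @param temporal_window odd boxcar length in frames.
#' @param spatial_window odd boxcar side in grid cells.
#' @return a smoothed \code{trajectory_set}.
#' @export
smooth_trajectories <- function(traj, temporal_window = 5, spatial_window = 3) {
  for (w in c(temporal_window, spatial_window))
    if (!is.numeric(w) || w < 1 || w %% 2 == 0)
      stop("smoothing windows must be odd and >= 1")
  ny <- traj$grid$ny; nx <- traj$grid$nx
  Tm1 <- dim(traj$disp)[1]
  disp <- traj$disp
  dvalid <- traj$valid[-1, , , drop = FALSE]   # displacement t valid if point alive at t+1
  for (k in 1:2) disp[, , , k][!dvalid] <- NA_real_

  if (temporal_window > 1 && Tm1 > 1) {
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) for (k in 1:2) {
      x <- disp[, iy, ix, k]
      if (all(is.na(x))) next
      disp[, iy, ix, k] <- zoo::rollapply(
        zoo::zoo(x), temporal_window,
        function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE),
        partial = TRUE, align = "center")
    }
  }
  if (spatial_window > 1) {
    for (t in seq_len(Tm1)) for (k in 1:2)
      disp[t, , , k] <- spatial_boxcar(disp[t, , , k], spatial_window)
  }
  for (k in 1:2) disp[, , , k][!dvalid] <- 0

  coords <- traj$coords
  coords[1, , , ] <- traj$grid$coords
  for (t in seq_len(Tm1)) {
    upd <- traj$valid[t + 1, , ]
    for (k in 1:2) {
      cur <- coords[t, , , k] + disp[t, , , k]
      prev <- coords[t, , , k]
      coords[t + 1, , , k] <- ifelse(upd, cur, prev)
    }
  }
  out <- traj
  out$disp <- disp
  out$coords <- coords
  out
}
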
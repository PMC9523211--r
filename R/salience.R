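# A "row" is the set of grid points sharing an initial transverse
# coordinate, ordered along the endometrial long axis. A passing
# peristaltic wave bends an initially straight row into a curve; the signed
# second derivative of a quadratic least-squares fit (2x the quadratic
# coefficient) is the curvature proxy tau. Its lagged change delta-tau
# carries the peristalsis magnitude; a rigid translation keeps every row
# straight and therefore yields tau identically zero, which is what
# distinguishes probe slip from peristalsis.

row_geometry <- function(traj, axial) {
  if (axial == "x") {
    list(nrows = traj$grid$ny,
         ax = function(f, r) traj$coords[f, r, , 1],
         tr = function(f, r) traj$coords[f, r, , 2],
         tr0 = function(r) traj$grid$coords[r, , 2],
         ok = function(f, r) traj$valid[f, r, ])
  } else {
    list(nrows = traj$grid$nx,
         ax = function(f, r) traj$coords[f, , r, 2],
         tr = function(f, r) traj$coords[f, , r, 1],
         tr0 = function(r) traj$grid$coords[, r, 1],
         ok = function(f, r) traj$valid[f, , r])
  }
}

fit_one_row <- function(ax, tr, tr0, ok) {
  if (sum(ok) < 3)
    return(list(valid = FALSE, tau = NA_real_, centroid = NA_real_, peak = 0))
  ax <- ax[ok]; tr <- tr[ok]; tr0 <- tr0[ok]
  axc <- ax - mean(ax)
  fit <- stats::lm.fit(cbind(1, axc, axc^2), tr)
  if (is.na(fit$coefficients[3]))                # degenerate axial geometry
    return(list(valid = FALSE, tau = NA_real_, centroid = NA_real_, peak = 0))
  d <- abs(tr - tr0)
  peak <- max(d)
  centroid <- if (sum(d) > 1e-9) sum(ax * d) / sum(d) else NA_real_
  list(valid = TRUE, tau = 2 * fit$coefficients[3],
       centroid = centroid, peak = peak)
}

#' Fit row curvature for one frame
#'
#' Fits a degree-2 polynomial of transverse position against axial position
#' to each grid row's valid tracked points and returns the signed curvature
#' proxy tau = 2a (the second derivative, constant along the row). Rows
#' with fewer than 3 valid points get \code{fit_valid = FALSE}.
#'
#' @param traj a trajectory set (ideally smoothed).
#' @param frame_idx 1-based frame index.
#' @param axial which image axis runs along the endometrium: \code{"x"}
#'   (horizontal band) or \code{"y"} (vertical).
#' @return list with \code{tau}, \code{fit_valid}, and the transverse
#'   activity descriptors \code{centroid} (|displacement|-weighted axial
#'   centroid) and \code{peak_disp} (max |transverse displacement|, px),
#'   one entry per row.
#' @export
fit_row_curvature <- function(traj, frame_idx, axial = c("x", "y")) {
  axial <- match.arg(axial)
  T_ <- dim(traj$coords)[1]
  if (frame_idx < 1 || frame_idx > T_) stop("frame_idx out of range")
  g <- row_geometry(traj, axial)
  rows <- lapply(seq_len(g$nrows), function(r)
    fit_one_row(g$ax(frame_idx, r), g$tr(frame_idx, r), g$tr0(r), g$ok(frame_idx, r)))
  list(tau = vapply(rows, `[[`, 0, "tau"),
       fit_valid = vapply(rows, `[[`, TRUE, "valid"),
       centroid = vapply(rows, `[[`, 0, "centroid"),
       peak_disp = vapply(rows, `[[`, 0, "peak"))
}

#' Row curvature series for a whole clip
#'
#' Runs [fit_row_curvature()] on every frame.
#'
#' @inheritParams fit_row_curvature
#' @return object of class \code{row_curvatures}: matrices (frames x rows)
#'   \code{tau}, \code{fit_valid}, \code{centroid}, \code{peak_disp}, plus
#'   \code{axial} and \code{frame_rate}.
#' @export
row_curvatures <- function(traj, axial = c("x", "y")) {
  axial <- match.arg(axial)
  T_ <- dim(traj$coords)[1]
  g <- row_geometry(traj, axial)
  tau <- fv <- cen <- pk <- matrix(NA_real_, T_, g$nrows)
  for (f in seq_len(T_)) {
    one <- fit_row_curvature(traj, f, axial)
    tau[f, ] <- one$tau; fv[f, ] <- one$fit_valid
    cen[f, ] <- one$centroid; pk[f, ] <- one$peak_disp
  }
  structure(list(tau = tau, fit_valid = fv == 1, centroid = cen,
                 peak_disp = pk, axial = axial,
                 frame_rate = traj$frame_rate),
            class = "row_curvatures")
}

#' Lagged curvature variation
#'
#' delta_tau[f] = tau[f] - tau[f - lag]; frames with fewer than \code{lag}
#' predecessors subtract the first frame instead, and the first frame
#' itself has zero variation. The variation is stored split into sign and
#' absolute value: the absolute value measures the peristalsis magnitude.
#' Alongside, a per-row propagation sign is derived from the lagged drift
#' of each row's transverse-activity centroid (+1 toward increasing axial
#' coordinate, -1 decreasing, 0 below the activity or drift floor); this is
#' the direction datum the motion graph counts, since it follows the wave's
#' travel and flips under mirroring and time reversal.
#'
#' @param curv a [row_curvatures()] object.
#' @param lag lag in frames (>= 1, default 5).
#' @param min_peak_disp minimum row activity (px) for a defined direction.
#' @param min_drift minimum |centroid drift| (px per lag) for a defined
#'   direction.
#' @return object of class \code{delta_tau_field}: frames x rows matrices
#'   \code{delta_tau}, \code{magnitude}, \code{sign} (of delta_tau),
#'   \code{prop_sign} (propagation), \code{valid}, plus \code{lag},
#'   \code{axial}, \code{frame_rate}, \code{centroid}, \code{peak_disp}.
#' @export
curvature_variation <- function(curv, lag = 5, min_peak_disp = 0.3,
                                min_drift = 0.5) {
  if (!is.numeric(lag) || lag < 1) stop("lag must be >= 1 frame")
  lag <- as.integer(lag)
  T_ <- nrow(curv$tau)
  ref <- pmax(1L, seq_len(T_) - lag)            # "subtract with the first frame"
  ref[1] <- 1L
  delta <- curv$tau - curv$tau[ref, , drop = FALSE]
  delta[1, ] <- 0
  valid <- curv$fit_valid & curv$fit_valid[ref, , drop = FALSE]
  delta[!valid] <- NA_real_

  drift <- curv$centroid - curv$centroid[ref, , drop = FALSE]
  drift[1, ] <- 0
  active <- !is.na(drift) & abs(drift) >= min_drift &
    curv$peak_disp >= min_peak_disp & curv$peak_disp[ref, , drop = FALSE] >= min_peak_disp
  prop_sign <- matrix(0, T_, ncol(curv$tau))
  prop_sign[active] <- sign(drift[active])

  structure(list(delta_tau = delta, magnitude = abs(delta),
                 sign = sign(delta), prop_sign = prop_sign, valid = valid,
                 lag = lag, axial = curv$axial, frame_rate = curv$frame_rate,
                 centroid = curv$centroid, peak_disp = curv$peak_disp),
            class = "delta_tau_field")
}

#' Normalize curvature-variation magnitude to [0, 1]
#'
#' Linear (min-max) normalization of |delta_tau| over the whole clip's
#' valid entries, so the most salient motion in the clip maps to 1 and the
#' least to 0. A clip whose magnitudes are all equal (e.g. no curvature
#' change at all) normalizes to 0 everywhere: it contains no peristalsis to
#' rank. Invalid entries get 0.
#'
#' @param field a [curvature_variation()] result.
#' @return object of class \code{salience_field} carrying \code{y0} and the
#'   direction/validity matrices of \code{field}; threshold and sigmoid
#'   stages add \code{y1}, \code{salient}, \code{y2}.
#' @export
normalize_magnitude <- function(field) {
  m <- field$magnitude
  v <- field$valid & !is.na(m)
  y0 <- matrix(0, nrow(m), ncol(m))
  if (any(v)) {
    lo <- min(m[v]); hi <- max(m[v])
    if (hi > lo) y0[v] <- (m[v] - lo) / (hi - lo)
  }
  structure(list(y0 = y0, y1 = NULL, salient = NULL, y2 = NULL,
                 alpha = NA_real_, beta = NA_real_,
                 sign = field$sign, prop_sign = field$prop_sign,
                 valid = field$valid, axial = field$axial,
                 frame_rate = field$frame_rate, centroid = field$centroid,
                 peak_disp = field$peak_disp, lag = field$lag),
            class = "salience_field")
}

#' Threshold the salience field
#'
#' y1 = y0 - alpha; entries with y0 strictly greater than alpha are salient
#' peristalsis, the rest are non-peristalsis.
#'
#' @param sal a [normalize_magnitude()] result.
#' @param alpha threshold in [0, 1] (default 0.6).
#' @return the salience field with \code{y1}, \code{salient}, \code{alpha}.
#' @export
apply_threshold <- function(sal, alpha = 0.6) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  sal$alpha <- alpha
  sal$y1 <- sal$y0 - alpha
  sal$salient <- sal$y0 > alpha
  sal
}

#' Sigmoid rendering weights
#'
#' y2 = 1 / (1 + exp(-beta * y1)). beta controls the slope: larger beta
#' pushes salient motion toward weight 1 and everything else toward 0.
#'
#' @param sal a thresholded salience field.
#' @param beta sigmoid slope (> 0, default 10).
#' @return the salience field with \code{y2}, \code{beta}.
#' @export
sigmoid_weights <- function(sal, beta = 10) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("beta must be > 0")
  if (is.null(sal$y1)) stop("apply_threshold() first")
  sal$beta <- beta
  sal$y2 <- 1 / (1 + exp(-beta * sal$y1))
  sal
}

#' Render a motion-amplified colour overlay for one frame
#'
#' Interpolates the per-row rendering weights onto every ROI pixel and adds
#' the weighted colour into the RGB channels of the grayscale frame.
#' Weights are rescaled so that sub-threshold rows (y2 <= 0.5) contribute
#' exactly zero: areas without salient peristalsis keep their grey value,
#' salient areas glow in the given colour.
#'
#' @param frame grayscale matrix (0..255).
#' @param sal a salience field with \code{y2} (see [sigmoid_weights()]).
#' @param grid the [feature_grid()] used for tracking.
#' @param frame_idx 1-based frame index into the salience field.
#' @param color RGB triple, default pure red \code{c(255, 0, 0)}.
#' @param rows optional logical/integer selector of rows to render (used to
#'   colour forward and backward rows differently).
#' @return an \code{h x w x 3} RGB array clipped to 0..255.
#' @export
render_overlay <- function(frame, sal, grid, frame_idx,
                           color = c(255, 0, 0), rows = NULL) {
  if (is.null(sal$y2)) stop("sigmoid_weights() first")
  if (length(dim(frame)) != 2) stop("frame must be a grayscale matrix")
  nr <- ncol(sal$y2)
  trans_pos <- if (sal$axial == "x") grid$ys else grid$xs
  if (length(trans_pos) != nr)
    stop("salience field and grid disagree on row count")
  w_row <- pmax(0, 2 * (sal$y2[frame_idx, ] - 0.5))
  if (!is.null(rows)) {
    keep <- rep(FALSE, nr); keep[rows] <- TRUE
    w_row[!keep] <- 0
  }
  roi <- grid$roi
  out <- array(0, c(dim(frame), 3))
  for (k in 1:3) out[, , k] <- frame

  if (sal$axial == "x") {
    ys <- (roi$y0:(roi$y0 + roi$height - 1)) + 1   # 1-based matrix rows
    xs <- (roi$x0:(roi$x0 + roi$width - 1)) + 1
    w_pix <- stats::approx(trans_pos + 1, w_row, xout = ys, rule = 2)$y
    for (k in 1:3) if (color[k] != 0)
      out[ys, xs, k] <- out[ys, xs, k] + color[k] * w_pix
  } else {
    ys <- (roi$y0:(roi$y0 + roi$height - 1)) + 1
    xs <- (roi$x0:(roi$x0 + roi$width - 1)) + 1
    w_pix <- stats::approx(trans_pos + 1, w_row, xout = xs, rule = 2)$y
    for (k in 1:3) if (color[k] != 0)
      out[ys, xs, k] <- out[ys, xs, k] + rep(w_pix * color[k], each = length(ys))
  }
  out[out > 255] <- 255
  out[out < 0] <- 0
  out
}
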
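# Shared fixture builders: everything is generated in code at test time.

default_roi <- function() roi_rect(4, 36, 120, 56)

# pair of speckle frames where the second's content is shifted by an
# integer (dx, dy); both cropped from one larger background
speckle_pair <- function(dx = 3, dy = 0, seed = 42, size = 100) {
  m <- 12   # crop margin, must exceed |shift|
  bg <- generate_speckle_background(c(size + 2 * m, size + 2 * m), 3, seed)
  ys <- (m + 1):(m + size); xs <- (m + 1):(m + size)
  list(prev = bg[ys, xs], cur = bg[ys - dy, xs - dx])
}

# exhaustive integer-shift cross-correlation oracle: best (dx, dy) over a
# +/- max_shift grid for the window around one point (1-based x, y)
oracle_shift <- function(prev, cur, x, y, win = 21, max_shift = 10) {
  hw <- (win - 1) / 2
  tpl <- prev[(y - hw):(y + hw), (x - hw):(x + hw)]
  best <- c(NA, NA); best_score <- -Inf
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys <- (y + dy - hw):(y + dy + hw); xs <- (x + dx - hw):(x + dx + hw)
    if (min(ys) < 1 || min(xs) < 1 || max(ys) > nrow(cur) || max(xs) > ncol(cur))
      next
    w <- cur[ys, xs]
    score <- sum((tpl - mean(tpl)) * (w - mean(w))) /
      (stats::sd(tpl) * stats::sd(w))
    if (score > best_score) { best_score <- score; best <- c(dx, dy) }
  }
  best
}

# hand-built trajectory set: coords[t, iy, ix, ] explicit, all valid
make_traj <- function(coords, grid, frame_rate = 2) {
  T_ <- dim(coords)[1]
  structure(list(
    coords = coords,
    disp = coords[-1, , , , drop = FALSE] - coords[-T_, , , , drop = FALSE],
    valid = array(TRUE, dim(coords)[1:3]),
    grid = grid, frame_rate = frame_rate),
    class = "trajectory_set")
}

# trajectory whose grid points sit still at their initial positions
static_traj <- function(T_ = 20, roi = default_roi(), spacing = 15,
                        frame_rate = 2) {
  grid <- feature_grid(roi, spacing)
  coords <- array(0, c(T_, grid$ny, grid$nx, 2))
  for (t in seq_len(T_)) coords[t, , , ] <- grid$coords
  make_traj(coords, grid, frame_rate)
}

# salience field built directly from a y0 matrix (frames x rows)
salience_from_y0 <- function(y0, prop_sign = NULL, frame_rate = 2,
                             axial = "x") {
  if (is.null(prop_sign)) prop_sign <- matrix(0, nrow(y0), ncol(y0))
  structure(list(y0 = y0, y1 = NULL, salient = NULL, y2 = NULL,
                 alpha = NA_real_, beta = NA_real_,
                 sign = matrix(0, nrow(y0), ncol(y0)),
                 prop_sign = prop_sign,
                 valid = matrix(TRUE, nrow(y0), ncol(y0)),
                 axial = axial, frame_rate = frame_rate,
                 centroid = matrix(NA_real_, nrow(y0), ncol(y0)),
                 peak_disp = matrix(0, nrow(y0), ncol(y0)), lag = 5L),
            class = "salience_field")
}

make_graph <- function(n_plus, n_minus, total = 8, frame_rate = 2,
                       orientation = "cervix_left") {
  structure(list(n_plus = n_plus, n_minus = n_minus, total = total,
                 frame_rate = frame_rate, orientation = orientation),
            class = "motion_graph")
}
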
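# Seeded speckle phantom: a granular ultrasound-like background whose
# endometrial band is warped by travelling transverse displacement waves of
# known count, direction, amplitude, wavelength, and speed. Stands in for
# clinical cines when validating the detector: every clip ships with its
# ground truth. Noise is additive Gaussian on intensity, enough to exercise
# the temporal/spatial filters while staying exactly reproducible.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# separable Gaussian blur; borders renormalized by the in-image kernel mass
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(mat) {                       # along columns, zero-padded
    n <- nrow(mat)
    ext <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
    out <- apply(ext, 2, function(col) stats::filter(col, k, sides = 2))
    out[(r + 1):(r + n), , drop = FALSE]
  }
  ones <- matrix(1, nrow(m), ncol(m))
  num <- t(conv1(t(conv1(m))))
  den <- t(conv1(t(conv1(ones))))
  num / den
}

#' Generate a speckle-textured background
#'
#' Low-pass-filtered seeded Gaussian noise rescaled to the intensity range
#' 30..220, with grain scale of roughly \code{grain_px} pixels: the
#' trackable substrate the warped clips are built from.
#'
#' @param shape integer c(height, width), at least 64 x 64.
#' @param grain_px speckle grain size in pixels.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @return an \code{h x w} intensity matrix.
#' @export
generate_speckle_background <- function(shape, grain_px = 3, seed = 1) {
  if (length(shape) != 2 || any(shape < 64))
    stop("shape must be c(height, width) with both >= 64")
  with_seed(seed, {
    noise <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    sm <- gaussian_blur(noise, grain_px / 2)
    lo <- min(sm); hi <- max(sm)
    30 + (sm - lo) / (hi - lo) * 190
  })
}

#' Specification of a synthetic peristalsis clip
#'
#' Defaults are the package's standard validation conditions: a 128 x 128
#' px, 2 frames/s, 100 s clip (200 frames) with a horizontal endometrial
#' band 56 px thick, waves of 4 px transverse amplitude, 48 px wavelength
#' and 6 px/s speed over 3 px speckle at additive noise sd 2, calibrated at
#' 0.1 mm/px.
#'
#' @param frame_height,frame_width frame size in px.
#' @param frame_rate frames per second.
#' @param duration_s clip length in seconds.
#' @param band_center,band_thickness transverse centre line and thickness
#'   of the endometrial band, px.
#' @param orientation cervix side, see [cine_clip()].
#' @param waves data.frame with columns \code{start_s}, \code{direction}
#'   (\code{"forward"}, \code{"backward"} or \code{"both"}),
#'   \code{amplitude_px}, \code{wavelength_px}, \code{speed_px_s}. Forward
#'   means image-left (horizontal) / image-down (vertical).
#' @param grain_px speckle grain size.
#' @param noise_sd additive Gaussian intensity noise.
#' @param pixel_spacing mm per pixel.
#' @param seed RNG seed; fixed seed gives bit-identical clips.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(frame_height = 128, frame_width = 128,
                           frame_rate = 2, duration_s = 100,
                           band_center = 64, band_thickness = 56,
                           orientation = "cervix_left",
                           waves = data.frame(start_s = 10,
                                              direction = "forward",
                                              amplitude_px = 4,
                                              wavelength_px = 48,
                                              speed_px_s = 6),
                           grain_px = 3, noise_sd = 2,
                           pixel_spacing = 0.1, seed = 1) {
  stopifnot(frame_height >= 64, frame_width >= 64, frame_rate > 0,
            duration_s > 0)
  if (!all(waves$direction %in% c("forward", "backward", "both")))
    stop("wave direction must be forward, backward, or both")
  if (any(waves$amplitude_px < 0)) stop("amplitudes must be >= 0")
  if (any(waves$speed_px_s <= 0)) stop("speeds must be > 0")
  axial_extent <- if (orientation %in% c("cervix_left", "cervix_right"))
    frame_width else frame_height
  crossing <- (axial_extent + waves$wavelength_px) / waves$speed_px_s
  total <- ifelse(waves$direction == "both",
                  2 * crossing - waves$wavelength_px / waves$speed_px_s,
                  crossing)
  if (any(waves$start_s + total > duration_s))
    stop("a wave extends beyond the clip duration")
  structure(list(frame_height = frame_height, frame_width = frame_width,
                 frame_rate = frame_rate, duration_s = duration_s,
                 band_center = band_center, band_thickness = band_thickness,
                 orientation = orientation, waves = waves,
                 grain_px = grain_px, noise_sd = noise_sd,
                 pixel_spacing = pixel_spacing, seed = seed,
                 axial_extent = axial_extent),
            class = "synthetic_spec")
}

# cos^2 bump of unit height and full width `wavelength` centred at c
wave_bump <- function(x, centre, wavelength) {
  s <- (x - centre) / wavelength
  ifelse(abs(s) <= 0.5, cos(pi * s)^2, 0)
}

#' Generate a synthetic peristalsis clip with ground truth
#'
#' Each frame is the speckle background warped by the superposed transverse
#' displacement field of the spec's travelling waves, plus seeded Gaussian
#' noise. A \code{"both"} wave is a forward pass immediately followed by a
#' backward pass (a reflected wave) and is one mixed-direction episode.
#'
#' @param spec a [synthetic_spec()].
#' @return list with \code{clip} (a [cine_clip()]) and \code{truth}, a
#'   data.frame with one row per wave: \code{direction},
#'   \code{start_frame}, \code{end_frame}, \code{speed_px_s},
#'   \code{speed_mm_s}, \code{amplitude_px}.
#' @export
generate_peristalsis_clip <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  nT <- round(spec$duration_s * spec$frame_rate)
  horizontal <- spec$orientation %in% c("cervix_left", "cervix_right")
  # build in the horizontal frame (axial = x), transpose at the end if needed
  h <- if (horizontal) spec$frame_height else spec$frame_width
  w <- spec$axial_extent
  pad <- ceiling(sum(spec$waves$amplitude_px) + 1) + 2   # worst-case overlap
  bg <- generate_speckle_background(c(h + 2 * pad, w), spec$grain_px, spec$seed)

  yb <- (seq_len(h) - 1 - spec$band_center) / (spec$band_thickness / 2)
  env <- ifelse(abs(yb) <= 1, cos(pi / 2 * yb)^2, 0)

  # per-pass description: (t0, entry side, signed speed)
  passes <- list()
  truth <- list()
  for (i in seq_len(nrow(spec$waves))) {
    wv <- spec$waves[i, ]
    crossing <- (w + wv$wavelength_px) / wv$speed_px_s
    mk <- function(t0, dirn) list(t0 = t0, dirn = dirn, A = wv$amplitude_px,
                                  lam = wv$wavelength_px, v = wv$speed_px_s)
    if (wv$direction == "forward") passes <- c(passes, list(mk(wv$start_s, -1)))
    else if (wv$direction == "backward") passes <- c(passes, list(mk(wv$start_s, 1)))
    else {
      # reflected wave: the backward pass re-enters while the forward bump
      # is leaving, keeping the episode's displacement activity continuous
      t_back <- wv$start_s + crossing - wv$wavelength_px / wv$speed_px_s
      passes <- c(passes, list(mk(wv$start_s, -1), mk(t_back, 1)))
    }
    total_s <- if (wv$direction == "both")
      2 * crossing - wv$wavelength_px / wv$speed_px_s else crossing
    truth[[i]] <- data.frame(
      wave = i, direction = wv$direction,
      start_frame = max(1L, 1L + floor(wv$start_s * spec$frame_rate)),
      end_frame = min(nT, 1L + ceiling((wv$start_s + total_s) *
                                         spec$frame_rate)),
      speed_px_s = wv$speed_px_s,
      speed_mm_s = wv$speed_px_s * spec$pixel_spacing,
      amplitude_px = wv$amplitude_px)
  }

  xs <- seq_len(w) - 1
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  frames <- with_seed(spec$seed + 1, {
    lapply(seq_len(nT), function(f) {
      t <- (f - 1) / spec$frame_rate
      bump <- rep(0, w)
      for (p in passes) {
        if (t < p$t0) next
        centre <- if (p$dirn < 0)
          (w - 1 + p$lam / 2) - p$v * (t - p$t0)
        else
          (-p$lam / 2) + p$v * (t - p$t0)
        if (centre < -p$lam / 2 - 1 || centre > w - 1 + p$lam / 2 + 1) next
        bump <- bump + p$A * wave_bump(xs, centre, p$lam)
      }
      d <- outer(env, bump)                     # transverse displacement, +down
      src <- matrix(seq_len(h), h, w) - d + pad
      iy <- floor(src); fy <- src - iy
      fr <- bg[cbind(as.vector(iy), as.vector(cols))] * (1 - as.vector(fy)) +
            bg[cbind(as.vector(iy) + 1L, as.vector(cols))] * as.vector(fy)
      fr <- matrix(fr, h, w)
      if (spec$noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
      matrix(pmin(pmax(fr, 0), 255), h, w)
    })
  })
  if (!horizontal)                              # axial x -> axial y, left -> down
    frames <- lapply(frames, function(f) t(f)[rev(seq_len(ncol(f))), , drop = FALSE])
  clip <- cine_clip(frames, spec$frame_rate, spec$pixel_spacing,
                    spec$orientation)
  list(clip = clip, truth = do.call(rbind, truth))
}

#' Generate a rigid-translation control clip
#'
#' The whole speckle field drifts as a rigid body: every grid row stays
#' straight, so a correct detector reports zero peristaltic waves however
#' large the drift (straight-line immunity, the property that separates
#' probe slip from peristalsis).
#'
#' @param shape c(height, width) in px.
#' @param frame_rate frames per second.
#' @param duration_s clip length, s.
#' @param drift_px_s rigid drift speed along x, px/s.
#' @param grain_px,noise_sd,seed,pixel_spacing,orientation as in
#'   [synthetic_spec()].
#' @return a [cine_clip()].
#' @export
generate_translation_clip <- function(shape = c(128, 128), frame_rate = 2,
                                      duration_s = 100, drift_px_s = 1,
                                      grain_px = 3, noise_sd = 2, seed = 1,
                                      pixel_spacing = 0.1,
                                      orientation = "cervix_left") {
  nT <- round(duration_s * frame_rate)
  h <- shape[1]; w <- shape[2]
  padx <- ceiling(abs(drift_px_s) * duration_s) + 2
  bg <- generate_speckle_background(c(h, w + 2 * padx), grain_px, seed)
  rows <- matrix(seq_len(h), h, w)
  frames <- with_seed(seed + 1, {
    lapply(seq_len(nT), function(f) {
      t <- (f - 1) / frame_rate
      src <- matrix(rep(seq_len(w), each = h), h, w) + drift_px_s * t + padx
      ix <- floor(src); fx <- src - ix
      fr <- bg[cbind(as.vector(rows), as.vector(ix))] * (1 - as.vector(fx)) +
            bg[cbind(as.vector(rows), as.vector(ix) + 1L)] * as.vector(fx)
      fr <- matrix(fr, h, w)
      if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
      matrix(pmin(pmax(fr, 0), 255), h, w)
    })
  })
  cine_clip(frames, frame_rate, pixel_spacing, orientation)
}

#' Sample the package's standard validation conditions
#'
#' Draws one seeded synthetic study clip: 1-4 waves with a clip-level
#' amplitude (uniform 3-5 px transverse, shared by the clip's waves, as
#' contractions within one recording share the uterus's momentary tone),
#' speeds uniform 8-12 px/s, directions uniform over forward / backward /
#' both, scheduled sequentially with 5 s rest gaps inside the default
#' 200-frame clip. The same draw backs the test suite and the acceptance
#' script, so the validation conditions are defined in exactly one place.
#'
#' @param seed integer seed; determines both the wave schedule and the
#'   clip's speckle/noise realization.
#' @return a [synthetic_spec()].
#' @export
sample_study_spec <- function(seed) {
  with_seed(seed, {
    k <- sample(1:4, 1)
    A <- stats::runif(1, 3, 5)
    cursor <- 8
    rows <- list()
    for (i in seq_len(k)) {
      dirn <- sample(c("forward", "backward", "both"), 1)
      v <- stats::runif(1, 8, 12)
      crossing <- (128 + 48) / v
      dur <- if (dirn == "both") 2 * crossing - 48 / v else crossing
      if (cursor + dur > 98) break
      rows[[i]] <- data.frame(start_s = cursor, direction = dirn,
                              amplitude_px = A, wavelength_px = 48,
                              speed_px_s = v)
      cursor <- cursor + dur + 5
    }
    synthetic_spec(seed = seed, waves = do.call(rbind, rows))
  })
}

#' ROI covering a synthetic clip's endometrial band
#'
#' @param spec a [synthetic_spec()].
#' @param margin axial margin in px left free at both ends.
#' @return a [roi_rect()] spanning the band.
#' @export
band_roi <- function(spec, margin = 4) {
  th <- spec$band_thickness
  t0 <- spec$band_center - th / 2
  if (spec$orientation %in% c("cervix_left", "cervix_right"))
    roi_rect(margin, t0, spec$frame_width - 2 * margin, th)
  else
    roi_rect(t0, margin, th, spec$frame_height - 2 * margin)
}

#' Ground-truth direction labels as CF/FC/CF_FC
#'
#' Maps a truth table's image directions through the declared cervix side:
#' a wave travelling toward the cervix is fundus-to-cervix (FC).
#'
#' @param truth truth data.frame from [generate_peristalsis_clip()].
#' @param orientation declared cervix side.
#' @return character vector of \code{"CF"}, \code{"FC"}, \code{"CF_FC"}.
#' @export
truth_directions <- function(truth, orientation) {
  vapply(truth$direction, function(d) {
    if (d == "both") "CF_FC" else direction_class(d, orientation)
  }, "")
}
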
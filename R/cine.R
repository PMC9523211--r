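#' Calibrated cine clip
#'
#' Container for a cine ultrasound loop: an ordered stack of grayscale
#' frames plus the calibration the pixel data does not carry (frame rate,
#' pixel spacing) and the declared cervix side, which maps image directions
#' to the anatomical cervix-to-fundus / fundus-to-cervix axes.
#'
#' @param frames numeric array \code{h x w x T} of intensities in 0..255,
#'   or a list of identically sized matrices.
#' @param frame_rate frames per second (> 0).
#' @param pixel_spacing physical size of one pixel in mm (> 0).
#' @param orientation one of \code{"cervix_left"}, \code{"cervix_right"},
#'   \code{"cervix_up"}, \code{"cervix_down"}: on which image side the
#'   cervix lies. Left/right imply a horizontally oriented endometrium
#'   (long axis = image x), up/down a vertical one.
#' @return object of class \code{cine_clip} with fields \code{frames}
#'   (array), \code{frame_rate}, \code{pixel_spacing}, \code{orientation}.
#' @export
cine_clip <- function(frames, frame_rate, pixel_spacing,
                      orientation = c("cervix_left", "cervix_right",
                                      "cervix_up", "cervix_down")) {
  orientation <- match.arg(orientation)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1)
      stop("all frames must share the same height x width")
    frames <- array(unlist(frames), c(dims[[1]][1], dims[[1]][2], length(frames)))
  }
  if (length(dim(frames)) != 3)
    stop("frames must be an h x w x T array or list of matrices")
  if (dim(frames)[3] < 2)
    stop("a cine clip needs at least 2 frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 || pixel_spacing <= 0)
    stop("pixel_spacing must be a single positive number (mm/px)")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_spacing = pixel_spacing, orientation = orientation),
            class = "cine_clip")
}

#' @export
print.cine_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_clip> %d frames, %dx%d px, %.3g fps, %.4g mm/px, %s\n",
              d[3], d[2], d[1], x$frame_rate, x$pixel_spacing, x$orientation))
  invisible(x)
}

n_frames <- function(clip) dim(clip$frames)[3]

#' Rectangular region of interest
#'
#' Half-open pixel rectangle \code{[x0, x0+width) x [y0, y0+height)}
#' enclosing the endometrium, in 0-based image coordinates (x right,
#' y down).
#'
#' @param x0,y0 top-left corner (0-based, inclusive).
#' @param width,height extent in pixels.
#' @return object of class \code{roi_rect}.
#' @export
roi_rect <- function(x0, y0, width, height) {
  vals <- c(x0, y0, width, height)
  if (any(!is.finite(vals)) || x0 < 0 || y0 < 0 || width < 1 || height < 1)
    stop("ROI must have non-negative origin and positive extent")
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "roi_rect")
}

check_roi_inside <- function(roi, frame_dim) {
  h <- frame_dim[1]; w <- frame_dim[2]
  if (roi$x0 + roi$width > w || roi$y0 + roi$height > h)
    stop(sprintf("ROI [%g,%g) x [%g,%g) exceeds the %dx%d frame",
                 roi$x0, roi$x0 + roi$width, roi$y0, roi$y0 + roi$height, w, h))
  invisible(TRUE)
}

# luma conversion (Rec. 601) for RGB sources
rgb_to_gray <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Load a cine clip from disk
#'
#' Reads an uncompressed AVI (24-bit DIB, as written by this package and by
#' most scan converters' "uncompressed" export) or a multi-frame grayscale
#' TIFF. RGB sources are converted to grayscale by Rec. 601 luma.
#' Compressed containers (MP4, MJPEG AVI) are rejected with instructions to
#' re-export, since decoding them requires a codec stack this package does
#' not depend on.
#'
#' @param path file path ending in \code{.avi}, \code{.tif} or \code{.tiff}.
#' @param pixel_spacing mm per pixel (> 0); AVI/TIFF carry no calibration.
#' @param frame_rate_override frames/s; overrides container metadata, and is
#'   required for TIFF input (which stores no rate).
#' @param orientation declared cervix side, see [cine_clip()].
#' @return a [cine_clip()].
#' @export
load_clip <- function(path, pixel_spacing, frame_rate_override = NULL,
                      orientation = "cervix_left") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be positive (mm/px)")
  ext <- tolower(tools::file_ext(path))
  if (ext == "avi") {
    dec <- avi_read(path)
    frames <- lapply(dec$frames, rgb_to_gray)
    fps <- if (!is.null(frame_rate_override)) frame_rate_override else dec$fps
  } else if (ext %in% c("tif", "tiff")) {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    frames <- lapply(imgs, function(im) {
      if (length(dim(im)) == 3) im <- rgb_to_gray(im * 255) / 255
      im * 255
    })
    fps <- frame_rate_override
  } else if (ext %in% c("mp4", "mov", "mkv", "webm")) {
    stop("compressed video (.", ext, ") is not supported; re-export the ",
         "cine as uncompressed AVI or multi-frame TIFF")
  } else stop("unrecognized cine format: .", ext)
  if (length(frames) < 2)
    stop("decoded fewer than 2 frames from ", path)
  if (is.null(fps) || is.na(fps))
    stop("frame rate not present in container; pass frame_rate_override")
  clip <- cine_clip(frames, fps, pixel_spacing, orientation)
  message(sprintf("loaded %s: %d frames of %dx%d at %.3g fps",
                  basename(path), n_frames(clip), dim(clip$frames)[2],
                  dim(clip$frames)[1], fps))
  clip
}

#' Write an RGB frame sequence as an uncompressed AVI
#'
#' Used for the motion-amplified colour overlays. The output is lossless,
#' so a re-decoded file reproduces the input frames exactly.
#'
#' @param frames list of \code{h x w x 3} arrays (0..255) or \code{h x w}
#'   grayscale matrices (replicated to RGB).
#' @param path output path.
#' @param frame_rate frames per second.
#' @return the path, invisibly.
#' @export
write_overlay_video <- function(frames, path, frame_rate) {
  if (!is.list(frames) || length(frames) == 0)
    stop("frames must be a non-empty list")
  dims <- unique(lapply(frames, function(f) dim(f)[1:2]))
  if (length(dims) != 1)
    stop("all frames must share the same height x width")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive")
  avi_write(frames, path, frame_rate)
  invisible(path)
}

#' Write a grayscale clip as an uncompressed AVI
#'
#' @param clip a [cine_clip()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_clip <- function(clip, path) {
  frames <- lapply(seq_len(n_frames(clip)), function(t) clip$frames[, , t])
  avi_write(frames, path, clip$frame_rate)
  invisible(path)
}
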
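# Minimal RIFF/AVI container support: uncompressed 24-bit DIB video, the one
# interchange format that needs no codec. Frames are stored bottom-up BGR
# with rows padded to 4 bytes (BITMAPINFOHEADER, biCompression = 0).

AVI_STREAM_SCALE <- 1000L

avi_frame_bytes <- function(frame) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (length(dim(frame)) == 2) frame <- array(frame, c(h, w, 3))
  ys <- rep(h:1, each = w * 3L)
  xs <- rep(rep(seq_len(w), each = 3L), h)
  cs <- rep(c(3L, 2L, 1L), w * h)                 # BGR order
  idx <- ys + (xs - 1L) * h + (cs - 1L) * h * w
  bytes <- as.raw(pmax(0, pmin(255, round(frame[idx]))))
  rowbytes <- w * 3L
  pad <- (4L - rowbytes %% 4L) %% 4L
  if (pad > 0L) {
    m <- matrix(bytes, nrow = rowbytes)
    bytes <- as.vector(rbind(m, matrix(as.raw(0), pad, h)))
  }
  bytes
}

avi_write <- function(frames, path, fps) {
  stopifnot(length(frames) >= 1, fps > 0)
  d <- dim(frames[[1]])
  h <- d[1]; w <- d[2]
  n <- length(frames)
  rowbytes <- w * 3L
  pad <- (4L - rowbytes %% 4L) %% 4L
  framesize <- (rowbytes + pad) * h

  con <- file(path, "wb")
  on.exit(close(con))
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  fcc <- function(x) writeChar(x, con, nchars = 4L, eos = NULL)

  hdrl_size <- 4L + (8L + 56L) + (8L + (4L + 64L + 48L))
  movi_size <- 4L + n * (8L + framesize)
  idx_size  <- 16L * n
  riff_size <- 4L + (8L + hdrl_size) + (8L + movi_size) + (8L + idx_size)

  fcc("RIFF"); u32(riff_size); fcc("AVI ")
  fcc("LIST"); u32(hdrl_size); fcc("hdrl")
  fcc("avih"); u32(56L)
  u32(round(1e6 / fps)); u32(framesize * ceiling(fps)); u32(0L); u32(16L)  # AVIF_HASINDEX
  u32(n); u32(0L); u32(1L); u32(framesize)
  u32(w); u32(h); u32(0L); u32(0L); u32(0L); u32(0L)
  fcc("LIST"); u32(4L + 64L + 48L); fcc("strl")
  fcc("strh"); u32(56L)
  fcc("vids"); fcc("DIB ")
  u32(0L); u32(0L); u32(0L)
  u32(AVI_STREAM_SCALE); u32(round(fps * AVI_STREAM_SCALE))
  u32(0L); u32(n); u32(framesize); u32(-1L); u32(0L)
  u16(0L); u16(0L); u16(w); u16(h)
  fcc("strf"); u32(40L)
  u32(40L); u32(w); u32(h); u16(1L); u16(24L)
  u32(0L); u32(framesize); u32(2835L); u32(2835L); u32(0L); u32(0L)
  fcc("LIST"); u32(movi_size); fcc("movi")
  for (f in frames) {
    fcc("00db"); u32(framesize)
    writeBin(avi_frame_bytes(f), con)
  }
  fcc("idx1"); u32(idx_size)
  off <- 4L
  for (i in seq_len(n)) {
    fcc("00db"); u32(16L); u32(off); u32(framesize)
    off <- off + 8L + framesize
  }
  invisible(path)
}

avi_u32 <- function(raw, off) {
  b <- as.integer(raw[off + 1:4])
  b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
}

avi_fcc <- function(raw, off) rawToChar(raw[off + 1:4])

# Decode an uncompressed AVI written by avi_write (or any 24-bit BI_RGB DIB
# stream). Returns list(frames = list of h x w x 3 arrays in 0..255, fps).
avi_read <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 32) stop("not a readable AVI file: ", path)
  raw <- readBin(path, "raw", sz)
  if (avi_fcc(raw, 0) != "RIFF" || avi_fcc(raw, 8) != "AVI ")
    stop("not an AVI (RIFF) file: ", path)

  width <- height <- NULL
  rate <- scale <- NULL
  bitcount <- compression <- NULL
  chunks <- list()

  walk <- function(pos, end) {
    while (pos + 8 <= end) {
      id <- avi_fcc(raw, pos)
      csz <- avi_u32(raw, pos + 4)
      body <- pos + 8
      if (id == "LIST") {
        ltype <- avi_fcc(raw, body)
        if (ltype %in% c("hdrl", "strl", "movi", "rec "))
          walk(body + 4, body + csz)
      } else if (id == "avih") {
        width <<- avi_u32(raw, body + 32)
        height <<- avi_u32(raw, body + 36)
      } else if (id == "strh") {
        if (avi_fcc(raw, body) == "vids") {
          scale <<- avi_u32(raw, body + 20)
          rate <<- avi_u32(raw, body + 24)
        }
      } else if (id == "strf" && is.null(bitcount)) {
        bitcount <<- avi_u32(raw, body + 12) %/% 65536
        compression <<- avi_u32(raw, body + 16)
      } else if (id %in% c("00db", "00dc") && csz > 0) {
        chunks[[length(chunks) + 1L]] <<- c(body, csz)
      }
      pos <- body + csz + csz %% 2
    }
  }
  walk(12, sz)

  if (is.null(width) || is.null(bitcount) || length(chunks) == 0)
    stop("AVI stream headers or frame data missing: ", path)
  if (compression != 0 || bitcount != 24)
    stop("only uncompressed 24-bit DIB AVI is supported (found biBitCount=",
         bitcount, ", biCompression=", compression, "); ",
         "re-export the cine as uncompressed AVI or multi-frame TIFF")

  fps <- if (!is.null(rate) && !is.null(scale) && scale > 0) rate / scale else NA_real_
  rowbytes <- width * 3L
  padrow <- (4L - rowbytes %% 4L) %% 4L
  stride <- rowbytes + padrow

  decode <- function(ch) {
    bytes <- raw[ch[1] + seq_len(ch[2])]
    m <- matrix(as.integer(bytes), nrow = stride)[seq_len(rowbytes), , drop = FALSE]
    px <- array(m, c(3L, width, height))          # (BGR, x, y-bottom-up)
    out <- array(0, c(height, width, 3L))
    out[, , 1] <- t(px[3, , height:1])
    out[, , 2] <- t(px[2, , height:1])
    out[, , 3] <- t(px[1, , height:1])
    out
  }
  list(frames = lapply(chunks, decode), fps = fps)
}
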
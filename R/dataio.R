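# Frame and instruction-file I/O.
#
# SMV is the workhorse format handed to XDS/DIALS: a 512-byte ASCII
# header followed by little-endian unsigned 16-bit counts. Minimal MRC
# (mode 2, float32) and baseline single-strip 16-bit TIFF writers carry
# the same frames for other consumers. All writers are deterministic
# byte-for-byte for identical inputs.

#' SMV header
#'
#' ADSC-style key set understood by the XDS/DIALS SMV readers. Distances
#' in mm, wavelength in Angstrom, angles in degrees, exposure in seconds.
#'
#' @param size Image dimensions, pixels (fast, slow).
#' @param pixel_size Pixel size, mm.
#' @param distance Detector distance (effective camera length), mm.
#' @param wavelength Wavelength, Angstrom.
#' @param beam_center `(x, y)` beam centre, pixels.
#' @param osc_start,osc_range Oscillation start and per-frame range, deg.
#' @param exposure Exposure time, s.
#' @return An `smv_header` list.
#' @export
smv_header <- function(size = c(516L, 516L), pixel_size = 0.055,
                       distance = 250, wavelength = 0.02508,
                       beam_center = c(258, 258), osc_start = 0,
                       osc_range = 0.23, exposure = 0.5) {
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 distance = distance, wavelength = wavelength,
                 beam_center = as.numeric(beam_center),
                 osc_start = osc_start, osc_range = osc_range,
                 exposure = exposure),
            class = "smv_header")
}

.smv_header_text <- function(h, type = "unsigned_short") {
  txt <- paste0(
    "{\nHEADER_BYTES= 512;\nDIM=2;\nBYTE_ORDER=little_endian;\n",
    sprintf("TYPE=%s;\n", type),
    sprintf("SIZE1=%d;\nSIZE2=%d;\n", h$size[1], h$size[2]),
    sprintf("PIXEL_SIZE=%.4f;\n", h$pixel_size),
    sprintf("BIN=1x1;\nDISTANCE=%.4f;\n", h$distance),
    sprintf("WAVELENGTH=%.5f;\n", h$wavelength),
    sprintf("BEAM_CENTER_X=%.4f;\nBEAM_CENTER_Y=%.4f;\n",
            h$beam_center[1], h$beam_center[2]),
    sprintf("OSC_START=%.4f;\nOSC_RANGE=%.4f;\n", h$osc_start, h$osc_range),
    sprintf("PHI=%.4f;\n", h$osc_start),
    sprintf("TIME=%.4f;\n", h$exposure),
    "}\n")
  if (nchar(txt, type = "bytes") > 512L)
    stop("SMV header exceeds 512 bytes")
  txt
}

#' Write a frame as SMV
#'
#' Counts are rounded and clamped to `[0, 65535]` (unsigned 16-bit); the
#' written file reads back bit-exactly with [read_smv()].
#'
#' @param frame `detector_frame` or numeric matrix (rows = slow axis y,
#'   columns = fast axis x).
#' @param header An [smv_header()]; its `size` is overridden by the frame.
#' @param path Output path (conventionally `.img`).
#' @return `path`, invisibly.
#' @export
write_smv <- function(frame, header = smv_header(), path) {
  px <- frame_pixels(frame)
  header$size <- c(ncol(px), nrow(px))   # SIZE1 = fast (x), SIZE2 = slow (y)
  v <- as.integer(pmin(pmax(round(px), 0), 65535))
  txt <- .smv_header_text(header)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  pad <- 512L - nchar(txt, type = "bytes")
  if (pad > 0) writeBin(raw(pad), con)
  v16 <- matrix(v, nrow(px), ncol(px))
  v16 <- as.vector(t(v16))               # fast axis (x) first
  v16[v16 > 32767L] <- v16[v16 > 32767L] - 65536L
  writeBin(as.integer(v16), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an SMV file
#'
#' @param path File written by [write_smv()] (or any little-endian
#'   unsigned-short SMV).
#' @return List with `pixels` (matrix, rows = slow axis) and `header`
#'   (parsed key list).
#' @export
read_smv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", 512L)
  txt <- rawToChar(raw_hdr[raw_hdr != as.raw(0)])
  keys <- .parse_smv_header(txt)
  hb <- as.integer(keys$HEADER_BYTES %||% 512)
  if (hb > 512L) invisible(readBin(con, "raw", hb - 512L))
  if (is.null(keys$SIZE1) || is.null(keys$SIZE2))
    stop("SMV parse error: missing SIZE1/SIZE2 key")
  n1 <- as.integer(keys$SIZE1); n2 <- as.integer(keys$SIZE2)
  if (is.na(n1) || is.na(n2)) stop("SMV parse error: bad SIZE1/SIZE2 value")
  type <- keys$TYPE %||% "unsigned_short"
  signed <- identical(type, "signed_short")
  v <- readBin(con, "integer", n1 * n2, size = 2L, signed = signed,
               endian = "little")
  px <- t(matrix(v, n1, n2))             # back to rows = slow axis
  list(pixels = px, header = keys)
}

.parse_smv_header <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- grep("=", lines, value = TRUE, fixed = TRUE)
  keys <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Z0-9_]+)\\s*=\\s*([^;]*);?", ln))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      keys[[m[2]]] <- if (is.na(num)) val else num
    } else stop(sprintf("SMV parse error near: %s", ln))
  }
  keys
}

#' Write GEO_CORR tables as SMV images
#'
#' Serializes the x/y pixel-offset tables of [geo_corr_tables()] (integer
#' hundredths of a pixel) as a pair of SMV files with
#' `TYPE=signed_short`, referenced from XDS.INP via the
#' `X-GEO_CORR`/`Y-GEO_CORR` instructions.
#'
#' @param tables Result of [geo_corr_tables()].
#' @param dir Output directory.
#' @param basename File-name stem; writes `<stem>_x.img`, `<stem>_y.img`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_geo_corr_smv <- function(tables, dir, basename = "geo_corr") {
  paths <- file.path(dir, paste0(basename, c("_x.img", "_y.img")))
  for (k in 1:2) {
    tab <- tables[[c("x", "y")[k]]]
    h <- smv_header(size = c(ncol(tab), nrow(tab)))
    txt <- .smv_header_text(h, type = "signed_short")
    con <- file(paths[k], "wb")
    writeChar(txt, con, eos = NULL)
    pad <- 512L - nchar(txt, type = "bytes")
    if (pad > 0) writeBin(raw(pad), con)
    writeBin(as.integer(as.vector(t(tab))), con, size = 2L, endian = "little")
    close(con)
  }
  invisible(paths)
}

#' Write a frame as MRC (mode 2, float32)
#'
#' Minimal MRC-2014 single-image writer; counts are stored as 32-bit
#' floats so nothing is clamped. Pixel size (Angstrom-agnostic, stored in
#' the cell fields as pixel pitch in um) and statistics are filled in.
#'
#' @param frame `detector_frame` or matrix.
#' @param path Output path.
#' @param pixel_pitch Pixel pitch, um (stored in the cell record).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(frame, path, pixel_pitch = 55) {
  px <- frame_pixels(frame)
  nx <- ncol(px); ny <- nrow(px)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L, 2L))                 # nx ny nz mode
  wi(c(0L, 0L, 0L))                     # nxstart
  wi(c(nx, ny, 1L))                     # mx my mz
  wf(c(nx * pixel_pitch, ny * pixel_pitch, pixel_pitch))  # cella
  wf(c(90, 90, 90))                     # cellb
  wi(c(1L, 2L, 3L))                     # mapc mapr maps
  wf(c(min(px), max(px), mean(px)))     # dmin dmax dmean
  wi(c(0L, 0L))                         # ispg nsymbt
  wi(integer(25L))                      # extra
  wf(c(0, 0, 0))                        # origin
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(px)))          # rms
  wi(0L)                                # nlabl
  writeBin(raw(800L), con)              # labels
  writeBin(as.numeric(as.vector(t(px))), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC file written by [write_mrc()]
#'
#' @param path File path.
#' @return List with `pixels` matrix and `header` (nx, ny, nz, mode,
#'   pixel sizes).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(4L)
  if (dims[4] != 2L) stop("only MRC mode 2 (float32) is supported")
  ri(3L); ri(3L)
  cella <- rf(3L); rf(3L); ri(3L); rf(3L); ri(2L); ri(25L); rf(3L)
  readBin(con, "raw", 8L); rf(1L); ri(1L); readBin(con, "raw", 800L)
  v <- rf(dims[1] * dims[2])
  list(pixels = t(matrix(v, dims[1], dims[2])),
       header = list(nx = dims[1], ny = dims[2], nz = dims[3],
                     mode = dims[4], pixel_pitch = cella[3]))
}

#' Write a frame as baseline 16-bit grayscale TIFF
#'
#' Single-strip, uncompressed, little-endian TIFF with the frame metadata
#' embedded as JSON in the ImageDescription tag. Counts are rounded and
#' clamped to `[0, 65535]`.
#'
#' @param frame `detector_frame` or matrix.
#' @param path Output path.
#' @param metadata Named list stored in the ImageDescription tag.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(frame, path, metadata = list()) {
  px <- frame_pixels(frame)
  w <- ncol(px); h <- nrow(px)
  desc <- paste0(jsonlite::toJSON(metadata, auto_unbox = TRUE, digits = NA))
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  n_tags <- 9L
  ifd_off <- 8L
  ifd_len <- 2L + n_tags * 12L + 4L
  desc_off <- ifd_off + ifd_len
  data_off <- desc_off + length(desc_raw)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeChar("II", con, eos = NULL); w16(42L); w32(ifd_off)
  w16(n_tags)
  tag <- function(id, type, count, value) { w16(id); w16(type); w32(count); w32(value) }
  tag(256L, 4L, 1L, w)                   # ImageWidth
  tag(257L, 4L, 1L, h)                   # ImageLength
  tag(258L, 3L, 1L, 16L)                 # BitsPerSample
  tag(259L, 3L, 1L, 1L)                  # Compression: none
  tag(262L, 3L, 1L, 1L)                  # Photometric: BlackIsZero
  tag(270L, 2L, length(desc_raw), desc_off)  # ImageDescription
  tag(273L, 4L, 1L, data_off)            # StripOffsets
  tag(278L, 4L, 1L, h)                   # RowsPerStrip
  tag(279L, 4L, 1L, w * h * 2L)          # StripByteCounts
  w32(0L)                                # next IFD
  writeBin(desc_raw, con)
  v <- as.integer(pmin(pmax(round(px), 0), 65535))
  v <- as.vector(t(matrix(v, h, w)))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(as.integer(v), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a TIFF written by [write_tiff16()]
#'
#' @param path File path.
#' @return List with `pixels` matrix and `metadata` (parsed JSON from the
#'   ImageDescription tag, if present).
#' @export
read_tiff16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = "little")
  r32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (magic != "II") stop("only little-endian TIFF is supported")
  if (r16() != 42L) stop("not a TIFF file")
  ifd <- r32()
  seek(con, ifd)
  n <- r16()
  tags <- list()
  for (i in seq_len(n)) {
    id <- r16(); type <- r16(); count <- r32(); val <- r32()
    tags[[as.character(id)]] <- list(type = type, count = count, value = val)
  }
  need <- function(id) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) stop(sprintf("TIFF tag %d missing", id))
    t
  }
  w <- need(256L)$value; h <- need(257L)$value
  off <- need(273L)$value
  meta <- NULL
  dt <- tags[["270"]]
  if (!is.null(dt)) {
    seek(con, dt$value)
    txt <- readBin(con, "raw", dt$count)
    txt <- rawToChar(txt[txt != as.raw(0)])
    meta <- tryCatch(jsonlite::fromJSON(txt), error = function(e) txt)
  }
  seek(con, off)
  v <- readBin(con, "integer", w * h, size = 2L, signed = FALSE,
               endian = "little")
  list(pixels = t(matrix(v, w, h)), metadata = meta)
}
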
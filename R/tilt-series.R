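# Tilt series container and minimal MRC stack input/output.  Images are
# stored as numeric matrices indexed [x, y] (x = fast axis), one per tilt.

#' Construct a tilt series
#'
#' @param images List of 2D numeric matrices (pixels), one per tilt image,
#'   all the same size, indexed \code{[x, y]}.
#' @param tilt_angles Nominal stage tilt angle in degrees per image; need
#'   not be sorted.
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @param fiducial_diameter Gold bead diameter in nanometres.
#' @return An object of class \code{tilt_series}.
#' @export
tilt_series <- function(images, tilt_angles, pixel_size = 1,
                        fiducial_diameter = 10) {
  if (!is.list(images) || !length(images)) {
    stop("`images` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all tilt images must have the same dimensions", call. = FALSE)
  }
  tilt_angles <- as.numeric(tilt_angles)
  if (length(tilt_angles) != length(images)) {
    stop("need exactly one tilt angle per image (", length(images),
         " images, ", length(tilt_angles), " angles)", call. = FALSE)
  }
  structure(list(images = images, tilt_angles = tilt_angles,
                 pixel_size = pixel_size,
                 fiducial_diameter = fiducial_diameter),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(
    "<tilt_series> %d image(s) of %d x %d px, tilts %.1f..%.1f deg\n",
    length(x$images), d[1], d[2], min(x$tilt_angles), max(x$tilt_angles)))
  invisible(x)
}

# fiducial radius in pixels from the physical bead size
fiducial_radius_px <- function(ts) {
  max(1, round(ts$fiducial_diameter * 10 / ts$pixel_size / 2))
}

#' Read and write MRC image stacks
#'
#' A deliberately small implementation of the MRC2014 format sufficient for
#' tilt series stacks: modes 0 (int8), 1 (int16), 2 (float32) and 6
#' (uint16) are read; mode 2 is written. Data are returned as a list of
#' \code{[x, y]} matrices, one per section.
#'
#' @param path File path.
#' @return \code{read_mrc}: list with \code{images} (list of matrices) and
#'   \code{pixel_size} (Angstrom); \code{write_mrc}: the path, invisibly.
#' @name mrc-io
#' @export
read_mrc <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]
  cella <- readBin(con, "numeric", n = 6, size = 4, endian = "little")
  apix <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  npix <- nx * ny
  images <- vector("list", nz)
  for (k in seq_len(nz)) {
    vals <- switch(as.character(mode),
      "0" = as.numeric(readBin(con, "integer", n = npix, size = 1,
                               signed = TRUE, endian = "little")),
      "1" = as.numeric(readBin(con, "integer", n = npix, size = 2,
                               signed = TRUE, endian = "little")),
      "2" = readBin(con, "numeric", n = npix, size = 4, endian = "little"),
      "6" = as.numeric(readBin(con, "integer", n = npix, size = 2,
                               signed = FALSE, endian = "little")),
      stop("unsupported MRC mode ", mode, call. = FALSE))
    images[[k]] <- matrix(vals, nrow = nx, ncol = ny)
  }
  list(images = images, pixel_size = apix)
}

#' @rdname mrc-io
#' @param images List of equally sized \code{[x, y]} matrices (or a single
#'   matrix).
#' @param pixel_size Pixel size in Angstrom recorded in the header.
#' @export
write_mrc <- function(images, path, pixel_size = 1) {
  if (is.matrix(images)) images <- list(images)
  nx <- nrow(images[[1]]); ny <- ncol(images[[1]]); nz <- length(images)
  con <- file(path, open = "wb")
  on.exit(close(con))
  all_vals <- unlist(images, use.names = FALSE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2, 0, 0, 0, nx, ny, nz))           # dims, mode 2, start, grid
  wf(c(nx, ny, nz) * pixel_size)                      # cell lengths (A)
  wf(c(90, 90, 90))                                   # cell angles
  wi(c(1, 2, 3))                                      # axis mapping
  wf(c(min(all_vals), max(all_vals), mean(all_vals))) # dmin dmax dmean
  wi(c(0, 0))                                         # ispg, nsymbt
  writeBin(raw(100), con)                             # extra
  wi(c(0, 0, 0))                                      # origin
  writeChar("MAP ", con, eos = NULL)                  # map id
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # little-endian stamp
  wf(stats::sd(all_vals))                             # rms
  wi(0)                                               # nlabl
  writeBin(raw(800), con)                             # labels
  writeBin(as.numeric(all_vals), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a tilt series from an MRC stack and a tilt-angle file
#'
#' @param mrc_path MRC stack, one section per tilt image.
#' @param tlt_path Text file with one nominal tilt angle (degrees) per line,
#'   in section order.
#' @param pixel_size Pixel size in Angstrom; \code{NULL} takes the MRC
#'   header value.
#' @param fiducial_diameter Gold bead diameter in nanometres.
#' @return A \code{\link{tilt_series}}.
#' @export
read_tilt_series <- function(mrc_path, tlt_path, pixel_size = NULL,
                             fiducial_diameter = 10) {
  stack <- read_mrc(mrc_path)
  angles <- as.numeric(readLines(tlt_path, warn = FALSE))
  angles <- angles[!is.na(angles)]
  tilt_series(stack$images, angles,
              pixel_size = pixel_size %||% stack$pixel_size,
              fiducial_diameter = fiducial_diameter)
}
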
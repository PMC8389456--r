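# Fiducial marker detection: synthetic and data-derived bead templates,
# FFT-accelerated normalized cross-correlation, greedy peak picking with
# subpixel localization, and a rotational-symmetry filter for candidate
# observations.

#' Binary synthetic bead template
#'
#' A dark disc of the given radius on a neutral (zero) background, matching
#' the contrast of gold beads in cryo-ET images, with odd side length
#' \code{4 * radius + 1}.
#'
#' @param radius_px Bead radius in pixels (>= 1).
#' @return A square numeric matrix with values 0 (background) and -1 (bead).
#' @export
synthetic_bead_template <- function(radius_px) {
  if (!is.numeric(radius_px) || radius_px < 1) {
    stop("bead template radius must be >= 1 px", call. = FALSE)
  }
  side <- 4 * round(radius_px) + 1
  ctr <- (side + 1) / 2
  d2 <- outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, `+`)
  -1 * (d2 <= radius_px^2)
}

# summed-area helper: sums of M over tx x ty windows; result has
# (nrow - tx + 1) x (ncol - ty + 1) entries (window fully inside)
box_sums <- function(M, tx, ty) {
  cs <- apply(apply(M, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nrow(M) + 1, ncol(M) + 1)
  pad[-1, -1] <- cs
  nx <- nrow(M) - tx + 1L; ny <- ncol(M) - ty + 1L
  pad[(1 + tx):(nrow(M) + 1), (1 + ty):(ncol(M) + 1)] -
    pad[1:nx, (1 + ty):(ncol(M) + 1)] -
    pad[(1 + tx):(nrow(M) + 1), 1:ny] +
    pad[1:nx, 1:ny]
}

# Normalized cross-correlation of `template` against `image` at all fully
# interior placements.  Returns list(ncc = matrix over top-left placements,
# offset = template half-width) so that the template center corresponding
# to ncc[i, j] is (i + offset, j + offset).
ncc_map <- function(image, template) {
  tx <- nrow(template); ty <- ncol(template)
  if (tx > nrow(image) || ty > ncol(image)) {
    stop("template is larger than the image", call. = FALSE)
  }
  t0 <- template - mean(template)
  tnorm <- sqrt(sum(t0^2))
  nx <- nrow(image) - tx + 1L
  ny <- ncol(image) - ty + 1L
  if (tnorm == 0) {
    return(list(ncc = matrix(0, nx, ny), offset = (tx - 1L) / 2))
  }
  # raw correlation via FFT
  px <- stats::nextn(nrow(image) + tx, c(2, 3, 5))
  py <- stats::nextn(ncol(image) + ty, c(2, 3, 5))
  IA <- matrix(0, px, py); IA[1:nrow(image), 1:ncol(image)] <- image
  TA <- matrix(0, px, py); TA[1:tx, 1:ty] <- t0
  cc <- Re(stats::fft(stats::fft(IA) * Conj(stats::fft(TA)),
                      inverse = TRUE)) / (px * py)
  cc <- cc[1:nx, 1:ny]
  # local image normalization via summed-area tables
  s1 <- box_sums(image, tx, ty)
  s2 <- box_sums(image^2, tx, ty)
  npx <- tx * ty
  denom2 <- pmax(s2 - s1^2 / npx, 0)
  denom <- sqrt(denom2) * tnorm
  ncc <- ifelse(denom > 1e-12 * npx, cc / denom, 0)
  list(ncc = ncc, offset = (tx - 1L) / 2)
}

# 3-point parabolic subpixel interpolation along one axis
parabolic_offset <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (cm - cp) / den
  max(-0.5, min(0.5, off))
}

#' Detect candidate fiducial positions by cross-correlation
#'
#' Computes the normalized cross-correlation of the template with the image
#' and returns up to \code{n_peaks} local maxima picked greedily in order
#' of descending score, suppressing a disc of \code{exclusion_radius}
#' around each accepted peak. Peak positions are refined to subpixel
#' precision by a 3-point parabolic fit. A flat image yields zero
#' observations.
#'
#' @param image Numeric \code{[x, y]} matrix.
#' @param template Square template matrix, smaller than the image.
#' @param n_peaks Maximum number of observations to return.
#' @param exclusion_radius Suppression radius in pixels; defaults to one
#'   template width.
#' @param min_score Discard peaks with a normalized correlation below this.
#' @return A data.frame with columns \code{x}, \code{y} (pixels, subpixel)
#'   and \code{score}, sorted by descending score.
#' @export
detect_candidates <- function(image, template, n_peaks = 50L,
                              exclusion_radius = NULL, min_score = 0.1) {
  nc <- ncc_map(image, template)
  cc <- nc$ncc
  off <- nc$offset
  excl <- exclusion_radius %||% nrow(template)
  out_x <- out_y <- out_s <- numeric(0)
  nx <- nrow(cc); ny <- ncol(cc)
  for (k in seq_len(n_peaks)) {
    best <- which.max(cc)
    s <- cc[best]
    if (!is.finite(s) || s < min_score) break
    i <- (best - 1L) %% nx + 1L
    j <- (best - 1L) %/% nx + 1L
    dx <- if (i > 1 && i < nx) parabolic_offset(cc[i - 1, j], s, cc[i + 1, j]) else 0
    dy <- if (j > 1 && j < ny) parabolic_offset(cc[i, j - 1], s, cc[i, j + 1]) else 0
    out_x <- c(out_x, i + off + dx)
    out_y <- c(out_y, j + off + dy)
    out_s <- c(out_s, s)
    xs <- max(1L, i - ceiling(excl)):min(nx, i + ceiling(excl))
    ys <- max(1L, j - ceiling(excl)):min(ny, j + ceiling(excl))
    mask <- outer((xs - i)^2, (ys - j)^2, `+`) <= excl^2
    cc[xs, ys][mask] <- -Inf
  }
  data.frame(x = out_x, y = out_y, score = out_s)
}

# extract a (2w+1)^2 patch centered at the nearest pixel to (x, y);
# NULL if it would cross the image border
extract_patch <- function(image, x, y, w) {
  cx <- round(x); cy <- round(y)
  if (cx - w < 1 || cx + w > nrow(image) || cy - w < 1 || cy + w > ncol(image)) {
    return(NULL)
  }
  image[(cx - w):(cx + w), (cy - w):(cy + w)]
}

#' Average a data-derived bead template from candidate detections
#'
#' Subimages are extracted at the highest-scoring candidate positions
#' across the whole tilt series and averaged, producing a template that
#' reflects the actual appearance of the beads in the data; it is used for
#' a second, more sensitive detection pass. If fewer than
#' \code{n_subimages} usable candidates exist, all are used.
#'
#' @param ts A \code{\link{tilt_series}}.
#' @param candidates A data.frame with columns \code{image}, \code{x},
#'   \code{y}, \code{score} (as from \code{\link{detect_candidates}} run
#'   per image).
#' @param n_subimages Maximum number of subimages to average (300 by
#'   default).
#' @param radius_px Template radius; the patch half-width is
#'   \code{2 * radius_px}.
#' @return A square matrix template, with the number of subimages actually
#'   averaged in attribute \code{"n_averaged"}.
#' @export
build_data_template <- function(ts, candidates, n_subimages = 300L,
                                radius_px = NULL) {
  stopifnot(inherits(ts, "tilt_series"), nrow(candidates) >= 1L)
  radius_px <- radius_px %||% fiducial_radius_px(ts)
  w <- 2L * round(radius_px)
  ord <- order(-candidates$score)
  acc <- NULL
  used <- 0L
  for (r in ord) {
    if (used >= n_subimages) break
    patch <- extract_patch(ts$images[[candidates$image[r]]],
                           candidates$x[r], candidates$y[r], w)
    if (is.null(patch)) next
    acc <- if (is.null(acc)) patch else acc + patch
    used <- used + 1L
  }
  if (used == 0L) {
    stop("no candidate subimage lies fully inside an image", call. = FALSE)
  }
  tpl <- acc / used
  attr(tpl, "n_averaged") <- used
  tpl
}

# rotate a square matrix by 90 degrees counter-clockwise
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# 3x3 box smoothing (reflecting borders); suppresses pixel noise before
# the rotational correlation so the statistic probes structure, not noise
box_smooth3 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  xp <- m[c(1, 1:n, n), c(1, 1:k, k)]
  (xp[1:n, 1:k] + xp[1:n, 2:(k + 1)] + xp[1:n, 3:(k + 2)] +
     xp[2:(n + 1), 1:k] + xp[2:(n + 1), 2:(k + 1)] + xp[2:(n + 1), 3:(k + 2)] +
     xp[3:(n + 2), 1:k] + xp[3:(n + 2), 2:(k + 1)] + xp[3:(n + 2), 3:(k + 2)]) / 9
}

# mean correlation of a (smoothed) patch with its own 90/180/270 degree
# rotations
rotational_symmetry_score <- function(patch) {
  patch <- box_smooth3(patch)
  p0 <- as.vector(patch - mean(patch))
  if (stats::sd(p0) == 0) return(0)
  r1 <- rot90(patch); r2 <- rot90(r1); r3 <- rot90(r2)
  mean(vapply(list(r1, r2, r3), function(r) {
    stats::cor(p0, as.vector(r - mean(r)))
  }, numeric(1)))
}

#' Filter observations by rotational symmetry
#'
#' Gold beads are rotationally symmetric; straight-edge artifacts (ice
#' contamination boundaries, grid bars) are not. Each observation's
#' subimage is correlated with its own 90, 180 and 270 degree rotations and
#' observations whose mean rotational self-correlation falls below the
#' threshold are discarded. Observations whose patch crosses the image
#' border are also discarded.
#'
#' @param ts A \code{\link{tilt_series}}.
#' @param observations Data.frame with columns \code{image}, \code{x},
#'   \code{y} (and any others, preserved).
#' @param threshold Minimum mean rotational correlation in [-1, 1]; at -1
#'   everything with a valid patch is retained.
#' @param radius_px Patch half-width is \code{2 * radius_px}.
#' @return The retained subset of \code{observations}, with a
#'   \code{symmetry} column appended.
#' @export
rotational_symmetry_filter <- function(ts, observations, threshold = 0.3,
                                       radius_px = NULL) {
  stopifnot(inherits(ts, "tilt_series"))
  radius_px <- radius_px %||% fiducial_radius_px(ts)
  w <- 2L * round(radius_px)
  sym <- vapply(seq_len(nrow(observations)), function(r) {
    patch <- extract_patch(ts$images[[observations$image[r]]],
                           observations$x[r], observations$y[r], w)
    if (is.null(patch)) return(NA_real_)
    rotational_symmetry_score(patch)
  }, numeric(1))
  observations$symmetry <- sym
  observations[!is.na(sym) & sym >= threshold, , drop = FALSE]
}

#' Detect candidates in every image of a tilt series
#'
#' Convenience wrapper running \code{\link{detect_candidates}} per image
#' and binding the results with an \code{image} column.
#'
#' @inheritParams detect_candidates
#' @param ts A \code{\link{tilt_series}}.
#' @return Data.frame with columns \code{image}, \code{x}, \code{y},
#'   \code{score}.
#' @export
detect_series_candidates <- function(ts, template, n_peaks = 50L,
                                     exclusion_radius = NULL,
                                     min_score = 0.1) {
  stopifnot(inherits(ts, "tilt_series"))
  res <- lapply(seq_along(ts$images), function(i) {
    obs <- detect_candidates(ts$images[[i]], template, n_peaks,
                             exclusion_radius, min_score)
    if (nrow(obs)) cbind(image = i, obs) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(image = integer(), x = numeric(), y = numeric(),
                      score = numeric())
  }
  out
}
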
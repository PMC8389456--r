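# Deterministic synthetic data: simulated gold-bead tilt series with known
# projection geometry, lattice pose sets with known neighbour structure, and
# randomized grammar-valid metadata documents for round-trip testing.
# Every generator is a pure function of its seed/recipe.

#' Recipe for a simulated gold-bead tilt series
#'
#' The defaults describe the validation conditions used throughout the
#' package: a 41-image series from -60 to +60 degrees in 3 degree steps,
#' 15 beads of 5 px radius in a slab, per-image shifts up to +/-30 px, and
#' a signal-to-noise ratio (peak bead contrast over noise sigma) of 2.
#'
#' @param n_tilts Number of tilt images.
#' @param tilt_range Length-2 vector, degrees; tilts are evenly spaced.
#' @param tilt_axis_angle True in-plane tilt-axis angle psi in degrees
#'   (counter-clockwise from the image y-axis); \code{NULL} draws it
#'   uniformly from [0, 180).
#' @param shift_max Per-image shifts are drawn uniformly from
#'   \code{[-shift_max, shift_max]} px in x and y.
#' @param n_beads Number of fiducial markers.
#' @param bead_radius_px Bead radius in pixels.
#' @param image_size Square image side in pixels.
#' @param snr Peak bead contrast divided by the noise standard deviation;
#'   \code{Inf} disables noise.
#' @param seed RNG seed; equal recipes give bit-identical output.
#' @return A list of class \code{simulation_recipe}.
#' @export
simulation_recipe <- function(n_tilts = 41L, tilt_range = c(-60, 60),
                              tilt_axis_angle = NULL, shift_max = 30,
                              n_beads = 15L, bead_radius_px = 5,
                              image_size = 512L, snr = 2, seed = 1L) {
  if (n_tilts < 1L) stop("at least one tilt image is required", call. = FALSE)
  structure(list(n_tilts = as.integer(n_tilts), tilt_range = tilt_range,
                 tilt_axis_angle = tilt_axis_angle, shift_max = shift_max,
                 n_beads = as.integer(n_beads),
                 bead_radius_px = bead_radius_px,
                 image_size = as.integer(image_size), snr = snr,
                 seed = seed),
            class = "simulation_recipe")
}

# render one Gaussian-blurred disc into `im` at subpixel center (cx, cy),
# using 2x supersampling so subpixel positions are meaningful
render_bead <- function(im, cx, cy, radius, amplitude = 1, sigma = 1) {
  hw <- ceiling(radius + 3 * sigma + 1)
  x0 <- max(1L, floor(cx) - hw); x1 <- min(nrow(im), floor(cx) + hw)
  y0 <- max(1L, floor(cy) - hw); y1 <- min(ncol(im), floor(cy) + hw)
  if (x0 > x1 || y0 > y1) return(im)
  # 2x supersampled pixel-center coordinates within each target pixel
  sub <- c(-0.25, 0.25)
  patch <- matrix(0, x1 - x0 + 1L, y1 - y0 + 1L)
  xs <- x0:x1; ys <- y0:y1
  for (ox in sub) for (oy in sub) {
    d <- sqrt(outer((xs + ox - cx)^2, (ys + oy - cy)^2, `+`))
    patch <- patch + stats::pnorm((radius - d) / sigma)
  }
  im[xs, ys] <- im[xs, ys] - amplitude * patch / 4
  im
}

#' Simulate a gold-bead tilt series with known ground truth
#'
#' Beads are placed uniformly in a slab (with a minimum mutual distance so
#' that projections rarely overlap) and rendered in every tilt image as
#' dark Gaussian-blurred discs at the positions given by the projection
#' model \code{p = Rot2(psi) P Ry(theta_i) r + d_i + center}; Gaussian
#' noise is then added at the requested SNR. The returned ground truth
#' satisfies the projection equation exactly before noise injection.
#'
#' @param recipe A \code{\link{simulation_recipe}}.
#' @return List with \code{tilt_series} (a \code{\link{tilt_series}}) and
#'   \code{ground_truth}: \code{tilt_axis_angle}, \code{shifts}
#'   (\code{n_tilts x 2}), \code{tilt_angles}, \code{markers}
#'   (\code{n_beads x 3}, volume-centered) and \code{center}.
#' @export
simulate_tilt_series <- function(recipe = simulation_recipe()) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  with_seed(recipe$seed, {
    n <- recipe$n_tilts
    size <- recipe$image_size
    tilts <- if (n == 1L) mean(recipe$tilt_range) else
      seq(recipe$tilt_range[1], recipe$tilt_range[2], length.out = n)
    psi <- recipe$tilt_axis_angle %||% stats::runif(1, 0, 180)
    shifts <- matrix(stats::runif(2 * n, -recipe$shift_max,
                                  recipe$shift_max), ncol = 2)
    markers <- place_beads(recipe$n_beads, size,
                           min_sep = 6 * recipe$bead_radius_px)
    center <- (size + 1) / 2
    proj <- project_markers(psi, tilts, shifts, markers, center)
    inside <- proj$x >= 1 & proj$x <= size & proj$y >= 1 & proj$y <= size
    visible <- tapply(inside, proj$marker, any)
    if (any(!visible)) {
      stop("bead(s) project outside every image: ",
           paste(names(visible)[!visible], collapse = ", "),
           "; enlarge the image or shrink the slab", call. = FALSE)
    }
    noise_sd <- if (is.finite(recipe$snr)) 1 / recipe$snr else 0
    images <- vector("list", n)
    for (i in seq_len(n)) {
      im <- matrix(0, size, size)
      sel <- proj$image == i
      px <- proj$x[sel]; py <- proj$y[sel]
      for (j in seq_along(px)) {
        im <- render_bead(im, px[j], py[j], recipe$bead_radius_px)
      }
      if (noise_sd > 0) {
        im <- im + matrix(stats::rnorm(size * size, sd = noise_sd),
                          size, size)
      }
      images[[i]] <- im
    }
    # pixel size 10 A/px so that the bead radius in px matches the recipe
    ts <- tilt_series(images, tilts, pixel_size = 10,
                      fiducial_diameter = recipe$bead_radius_px * 2)
    list(tilt_series = ts,
         ground_truth = list(tilt_axis_angle = psi, shifts = shifts,
                             tilt_angles = tilts, markers = markers,
                             center = center))
  })
}

# uniform bead placement in a slab with rejection for a minimum mutual
# distance (relaxed geometrically if the slab is too crowded)
place_beads <- function(n_beads, image_size, min_sep) {
  r_xy <- 0.3 * image_size
  half_z <- 0.06 * image_size
  markers <- matrix(0, 0, 3)
  sep <- min_sep
  tries <- 0L
  while (nrow(markers) < n_beads) {
    u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
    cand <- c(sqrt(u) * r_xy * cos(th), sqrt(u) * r_xy * sin(th),
              stats::runif(1, -half_z, half_z))
    ok <- !nrow(markers) ||
      min(sqrt(rowSums(sweep(markers, 2, cand)^2))) >= sep
    if (ok) {
      markers <- rbind(markers, cand)
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 200L) { sep <- sep * 0.8; tries <- 0L }
    }
  }
  dimnames(markers) <- NULL
  markers
}

#' Deterministic lattice pose sets
#'
#' Regular lattices with known neighbour structure, used as surrogates for
#' the particle arrangements seen on virus-like particles and membrane
#' arrays: a square grid, a hexagonal patch (interior sites have exactly 6
#' neighbours at the lattice spacing) or a spherical shell.
#'
#' @param kind \code{"grid"}, \code{"hexagonal"} or \code{"sphere"}.
#' @param spacing Lattice spacing (voxels).
#' @param extent Approximate lattice extent: side length for planar
#'   lattices, radius for the sphere.
#' @param tomogram Tomogram identifier.
#' @param seed RNG seed (only the sphere's in-plane angles are stochastic).
#' @return A \code{\link{pose_set}}.
#' @export
make_lattice_poses <- function(kind = c("grid", "hexagonal", "sphere"),
                               spacing, extent, tomogram = 1L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(spacing > 0, extent > 0)
  if (kind == "sphere") {
    return(seed_sphere(c(0, 0, 0), radius = extent, spacing = spacing,
                       tomogram = tomogram, seed = seed))
  }
  k <- max(0L, floor(extent / spacing / 2))
  if (kind == "grid") {
    g <- expand.grid(x = (-k:k) * spacing, y = (-k:k) * spacing)
    pos <- cbind(g$x, g$y, 0)
  } else {
    rows <- -k:k
    pos <- NULL
    for (r in rows) {
      y <- r * spacing * sqrt(3) / 2
      off <- if (r %% 2 == 0) 0 else spacing / 2
      xs <- (-k:k) * spacing + off
      pos <- rbind(pos, cbind(xs, y, 0))
    }
  }
  dimnames(pos) <- NULL
  pose_set(pos, tomogram = tomogram)
}

# -- randomized format documents ----------------------------------------------

random_word <- function(n = 1, min_len = 3, max_len = 10) {
  chars <- c(letters, as.character(0:9), ".", "_", "-")
  vapply(seq_len(n), function(i) {
    # first character a letter so a value can never be mistaken for a tag,
    # block or loop keyword at line start
    w <- paste0(sample(letters, 1),
                paste(sample(chars, sample(min_len:max_len, 1) - 1,
                             replace = TRUE), collapse = ""))
    sub("^(data_|loop_)", "v\\1", w)
  }, character(1))
}

random_value <- function(n = 1) {
  pick <- sample(3, n, replace = TRUE)
  out <- character(n)
  out[pick == 1] <- random_word(sum(pick == 1))
  out[pick == 2] <- format_real(stats::runif(sum(pick == 2), -1e4, 1e4))
  out[pick == 3] <- as.character(sample.int(10000, sum(pick == 3),
                                            replace = TRUE))
  out
}

#' Randomized grammar-valid metadata documents
#'
#' Generators for round-trip property testing: documents are valid by
#' construction and a given seed always produces the same document.
#'
#' @param seed RNG seed.
#' @param size Scale parameter: roughly the number of loop rows, particles
#'   or mdoc sections. \code{size = 0} yields a minimal valid document.
#' @return A \code{\link{star_document}}, \code{\link{dynamo_table}} or
#'   \code{\link{mdoc_document}}.
#' @name random-documents
#' @export
random_star <- function(seed, size = 10L) {
  with_seed(seed, {
    n_blocks <- sample(1:3, 1)
    blocks <- list()
    nms <- make.unique(c(random_word(n_blocks)), sep = "_")
    for (b in seq_len(n_blocks)) {
      if (stats::runif(1) < 0.4) {
        k <- sample(0:6, 1)
        blocks[[b]] <- star_simple_block(
          stats::setNames(random_value(k),
                          make.unique(random_word(k), sep = "_")[seq_len(k)]))
      } else {
        ncols <- sample(1:6, 1)
        nrows <- max(1L, sample(0:max(1, size), 1))
        df <- as.data.frame(
          stats::setNames(lapply(seq_len(ncols),
                                 function(j) random_value(nrows)),
                          make.unique(random_word(ncols), sep = "_")),
          optional = TRUE, stringsAsFactors = FALSE)
        blocks[[b]] <- star_loop_block(df)
      }
    }
    star_document(stats::setNames(blocks, nms))
  })
}

#' @rdname random-documents
#' @export
random_dynamo_table <- function(seed, size = 10L) {
  with_seed(seed, {
    n <- max(0L, as.integer(size))
    ncols <- sample(26:40, 1)
    m <- matrix(round(stats::runif(n * ncols, -1e3, 1e3), 4), nrow = n)
    if (n) {
      m[, 1] <- sample.int(10 * n, n)            # unique positive tags
      m[, 2] <- sample(0:1, n, replace = TRUE)
      m[, 3] <- sample(0:1, n, replace = TRUE)
      m[, 20] <- sample.int(5, n, replace = TRUE)
    }
    dynamo_table(m)
  })
}

#' @rdname random-documents
#' @export
random_mdoc <- function(seed, size = 3L) {
  with_seed(seed, {
    header <- c(PixelSpacing = format_real(round(stats::runif(1, 0.5, 5), 3)),
                Voltage = "300",
                ImageFile = paste0(random_word(1), ".mrc"))
    n <- max(1L, as.integer(size))
    tilt <- round(seq(-60, 60, length.out = n) +
                    stats::rnorm(n, sd = 0.01), 2)
    sections <- lapply(seq_len(n), function(i) {
      c(TiltAngle = format_real(tilt[i]),
        StagePosition = paste(format_real(round(stats::runif(2, -100, 100), 2)),
                              collapse = " "),
        SubFramePath = paste0(random_word(1), ".mrc"),
        ExposureDose = format_real(round(stats::runif(1, 0, 5), 3)))
    })
    mdoc_document(header, sections)
  })
}

#' Compare an alignment result with simulation ground truth
#'
#' The projection model has two exact invariances that any comparison must
#' respect: a half-turn of the tilt-axis angle combined with inversion of
#' the marker cloud, and a global translation of the markers absorbed into
#' the per-image shifts. This helper folds the estimate onto the ground
#' truth branch, matches estimated markers to true beads by nearest
#' (centroid-aligned) 3D distance, fits the translation gauge by the mean
#' marker offset, and reports gauge-corrected errors.
#'
#' @param result An \code{alignment_result} or \code{projection_fit}.
#' @param ground_truth The \code{ground_truth} element returned by
#'   \code{\link{simulate_tilt_series}}.
#' @return List with \code{psi_error_deg}, \code{shift_errors_px} (per
#'   image), \code{marker_errors_px} (per matched marker) and
#'   \code{n_matched}.
#' @export
alignment_vs_truth <- function(result, ground_truth) {
  model <- result$model
  gt <- ground_truth
  dpsi <- wrap180(model$tilt_axis_angle - gt$tilt_axis_angle)
  flipped <- abs(dpsi) > 90
  psi_error <- if (flipped) 180 - abs(dpsi) else abs(dpsi)
  est <- as.matrix(result$markers[c("rx", "ry", "rz")])
  if (flipped) est <- -est
  truth <- as.matrix(gt$markers)
  # match estimated markers to true beads by their observed 2D tracks,
  # which are invariant under the translation gauge
  center <- gt$center %||% model$center
  pred_true <- project_markers(gt$tilt_axis_angle, gt$tilt_angles,
                               gt$shifts, truth, center)
  trails <- result$trails
  D <- matrix(Inf, nrow(est), nrow(truth))
  for (mi in seq_len(nrow(est))) {
    rows <- which(trails$marker == result$markers$marker[mi])
    for (k in seq_len(nrow(truth))) {
      pk <- pred_true[pred_true$marker == k, ]
      at <- match(trails$image[rows], pk$image)
      D[mi, k] <- stats::median(sqrt(
        (trails$x[rows] - pk$x[at])^2 + (trails$y[rows] - pk$y[at])^2))
    }
  }
  match_idx <- integer(nrow(est))
  Dm <- D
  for (k in seq_len(min(nrow(est), nrow(truth)))) {
    best <- which(Dm == min(Dm), arr.ind = TRUE)[1, ]
    if (!is.finite(Dm[best[1], best[2]])) break
    match_idx[best[1]] <- best[2]
    Dm[best[1], ] <- Inf
    Dm[, best[2]] <- Inf
  }
  matched <- which(match_idx > 0)
  diffs <- est[matched, , drop = FALSE] -
    truth[match_idx[matched], , drop = FALSE]
  t_gauge <- apply(diffs, 2, stats::median)
  marker_err <- sqrt(rowSums(sweep(diffs, 2, t_gauge)^2))
  # shifts compare after moving the gauge translation into them
  th <- deg2rad(gt$tilt_angles)
  Bt <- cbind(cos(th) * t_gauge[1] + sin(th) * t_gauge[3], t_gauge[2])
  psi_use <- if (flipped) wrap180(model$tilt_axis_angle + 180)
             else model$tilt_axis_angle
  adj <- Bt %*% t(rot2(psi_use))
  shift_err <- sqrt(rowSums((model$shifts + adj - gt$shifts)^2))
  list(psi_error_deg = psi_error, shift_errors_px = shift_err,
       marker_errors_px = marker_err, n_matched = length(matched))
}
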
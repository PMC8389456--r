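# The single-tilt-axis projection model and its robust refinement.
#
# Model contract: with psi the (single, per-series) in-plane tilt-axis
# angle, theta_i the nominal tilt of image i (never refined), r_j the 3D
# position of marker j (pixels, volume-centered) and d_i the per-image
# shift,
#
#   predicted_2d(i, j) = Rot2(psi) %*% P %*% Ry(theta_i) %*% r_j + d_i
#
# where P projects onto the first two coordinates (orthographic) and Rot2
# is the counter-clockwise in-plane rotation. psi is measured
# counter-clockwise from the image y-axis (the projected tilt axis at
# psi = 0 is the image y direction).

rot2 <- function(psi_deg) {
  a <- deg2rad(psi_deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# 2 x 3 projection row block A_i = Rot2(psi) P Ry(theta_i)
projection_block <- function(psi_deg, theta_deg) {
  th <- deg2rad(theta_deg)
  rot2(psi_deg) %*% matrix(c(cos(th), 0, 0, 1, sin(th), 0), 2, 3)
}

#' Construct a projection model
#'
#' @param tilt_axis_angle Single in-plane tilt-axis angle psi in degrees.
#' @param shifts \code{n_img x 2} matrix of per-image shifts (pixels).
#' @param tilt_angles Nominal tilt angles in degrees; fixed, never refined.
#' @param center Image center coordinate (scalar; images are square), used
#'   to convert between centered model coordinates and pixel coordinates.
#' @return An object of class \code{projection_model}.
#' @export
projection_model <- function(tilt_axis_angle, shifts, tilt_angles, center) {
  shifts <- as.matrix(shifts)
  stopifnot(ncol(shifts) == 2L, nrow(shifts) == length(tilt_angles))
  structure(list(tilt_axis_angle = tilt_axis_angle, shifts = shifts,
                 tilt_angles = as.numeric(tilt_angles), center = center),
            class = "projection_model")
}

#' Predicted 2D marker positions under a projection model
#'
#' @param psi Tilt-axis angle (degrees).
#' @param tilt_angles Tilt angle per image (degrees).
#' @param shifts \code{n_img x 2} shift matrix (pixels).
#' @param markers \code{m x 3} matrix of marker positions (centered).
#' @param center Image center added to both coordinates.
#' @return Data.frame with \code{marker}, \code{image}, \code{x}, \code{y}.
#' @export
project_markers <- function(psi, tilt_angles, shifts, markers, center = 0) {
  markers <- as.matrix(markers)
  n <- length(tilt_angles); m <- nrow(markers)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    A <- projection_block(psi, tilt_angles[i])
    p <- markers %*% t(A)
    out[[i]] <- data.frame(marker = seq_len(m), image = i,
                           x = p[, 1] + shifts[i, 1] + center,
                           y = p[, 2] + shifts[i, 2] + center)
  }
  do.call(rbind, out)
}

# consensus translation between two candidate point clouds: the densest
# cluster of pairwise displacement vectors (voting radius `radius`),
# refined by the mean of the winning cluster.  Robust to unmatched points.
consensus_displacement <- function(ax, ay, bx, by, radius) {
  dx <- as.vector(outer(bx, ax, `-`))
  dy <- as.vector(outer(by, ay, `-`))
  if (!length(dx)) return(c(0, 0))
  votes <- vapply(seq_along(dx), function(k) {
    sum((dx - dx[k])^2 + (dy - dy[k])^2 <= radius^2)
  }, numeric(1))
  k <- which.max(votes)
  sel <- (dx - dx[k])^2 + (dy - dy[k])^2 <= radius^2
  c(mean(dx[sel]), mean(dy[sel]))
}

#' Link observations across neighbouring tilt images into marker trails
#'
#' For each pair of images adjacent in tilt-angle order, the consensus
#' displacement between the two observation clouds is estimated first (a
#' vote over pairwise displacement vectors), compensating bulk image
#' shifts; every observation is then compared with the observations of the
#' next image that lie within the search radius of its displaced position
#' by normalized cross-correlation of their local patches, and mutual best
#' matches are linked. Connected chains of links form trails, which are
#' returned sorted by length (longest first).
#'
#' @param ts A \code{\link{tilt_series}}.
#' @param observations Data.frame with columns \code{image}, \code{x},
#'   \code{y} (from at least 2 images to yield any trail).
#' @param search_radius_px Maximum inter-image displacement considered.
#' @param radius_px Patch half-width is \code{2 * radius_px}.
#' @return Data.frame of class \code{marker_trails} with columns
#'   \code{marker}, \code{image}, \code{x}, \code{y}; markers are numbered
#'   by decreasing trail length.
#' @export
index_trails <- function(ts, observations, search_radius_px = NULL,
                         radius_px = NULL) {
  stopifnot(inherits(ts, "tilt_series"))
  radius_px <- radius_px %||% fiducial_radius_px(ts)
  search_radius_px <- search_radius_px %||% (5 * radius_px)
  w <- 2L * round(radius_px)
  n_obs <- nrow(observations)
  parent <- seq_len(n_obs)  # union-find over observation rows
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  order_imgs <- order(ts$tilt_angles)
  patch_cache <- vector("list", n_obs)
  patch_of <- function(r) {
    if (is.null(patch_cache[[r]])) {
      p <- extract_patch(ts$images[[observations$image[r]]],
                         observations$x[r], observations$y[r], w)
      patch_cache[[r]] <<- if (is.null(p)) NA else p - mean(p)
    }
    p <- patch_cache[[r]]
    if (is.matrix(p)) p else NULL
  }
  for (k in seq_len(length(order_imgs) - 1L)) {
    ia <- order_imgs[k]; ib <- order_imgs[k + 1L]
    ra <- which(observations$image == ia)
    rb <- which(observations$image == ib)
    if (!length(ra) || !length(rb)) next
    disp <- consensus_displacement(observations$x[ra], observations$y[ra],
                                   observations$x[rb], observations$y[rb],
                                   search_radius_px)
    S <- matrix(-Inf, length(ra), length(rb))
    for (a in seq_along(ra)) {
      pa <- patch_of(ra[a])
      if (is.null(pa)) next
      na <- sqrt(sum(pa^2))
      if (na == 0) next
      for (b in seq_along(rb)) {
        dx <- observations$x[ra[a]] + disp[1] - observations$x[rb[b]]
        dy <- observations$y[ra[a]] + disp[2] - observations$y[rb[b]]
        if (dx * dx + dy * dy > search_radius_px^2) next
        pb <- patch_of(rb[b])
        if (is.null(pb)) next
        nb <- sqrt(sum(pb^2))
        if (nb == 0) next
        S[a, b] <- sum(pa * pb) / (na * nb)
      }
    }
    # mutual best matches
    for (a in seq_along(ra)) {
      if (all(!is.finite(S[a, ]))) next
      b <- which.max(S[a, ])
      if (which.max(S[, b]) == a && is.finite(S[a, b])) {
        parent[find(ra[a])] <- find(rb[b])
      }
    }
  }
  roots <- vapply(seq_len(n_obs), find, integer(1))
  comp <- split(seq_len(n_obs), roots)
  comp <- comp[order(-lengths(comp))]
  comp <- comp[lengths(comp) >= 2L]
  if (!length(comp)) {
    return(empty_trails())
  }
  out <- do.call(rbind, lapply(seq_along(comp), function(m) {
    rows <- comp[[m]]
    data.frame(marker = m, image = observations$image[rows],
               x = observations$x[rows], y = observations$y[rows])
  }))
  # at most one observation per image per trail: keep the first occurrence
  out <- out[!duplicated(out[c("marker", "image")]), , drop = FALSE]
  out <- out[order(out$marker, out$image), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_trails", "data.frame")
  out
}

empty_trails <- function() {
  out <- data.frame(marker = integer(), image = integer(),
                    x = numeric(), y = numeric())
  class(out) <- c("marker_trails", "data.frame")
  out
}

as_trails <- function(df) {
  stopifnot(all(c("marker", "image", "x", "y") %in% names(df)))
  df <- df[order(df$marker, df$image),
           c("marker", "image", "x", "y"), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_trails", "data.frame")
  df
}

#' Triangulate 3D marker positions from their trails
#'
#' Per-marker linear least squares solution of the projection equation for
#' the 3D position given the tilt-axis angle, shifts and (fixed) tilt
#' angles. Markers observed in fewer than 2 images with distinct tilt
#' angles are rank deficient and skipped with a message.
#'
#' @param trails A \code{marker_trails} data.frame.
#' @param model A \code{\link{projection_model}}.
#' @param weights Optional per-observation weights (rows of \code{trails}).
#' @return Data.frame with \code{marker}, \code{rx}, \code{ry}, \code{rz}
#'   and the per-marker residual \code{rmsd} under \code{model}.
#' @export
triangulate_markers <- function(trails, model, weights = NULL) {
  stopifnot(inherits(model, "projection_model"))
  weights <- weights %||% rep(1, nrow(trails))
  blocks <- lapply(seq_along(model$tilt_angles), function(i) {
    projection_block(model$tilt_axis_angle, model$tilt_angles[i])
  })
  res <- lapply(unique(trails$marker), function(m) {
    rows <- which(trails$marker == m)
    imgs <- trails$image[rows]
    if (length(unique(round(model$tilt_angles[imgs], 9))) < 2L) {
      message("marker ", m, " seen at < 2 distinct tilt angles; skipped")
      return(NULL)
    }
    A <- do.call(rbind, blocks[imgs])
    b <- as.vector(t(cbind(
      trails$x[rows] - model$shifts[imgs, 1] - model$center,
      trails$y[rows] - model$shifts[imgs, 2] - model$center)))
    w <- rep(weights[rows], each = 2)
    fit <- stats::lm.wfit(A, b, w)
    r <- fit$coefficients
    pred <- A %*% r
    e2 <- (b - pred)^2
    rmsd <- sqrt(mean(e2[seq(1, length(e2), 2)] + e2[seq(2, length(e2), 2)]))
    data.frame(marker = m, rx = r[1], ry = r[2], rz = r[3], rmsd = rmsd)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(marker = integer(), rx = numeric(), ry = numeric(),
                      rz = numeric(), rmsd = numeric())
  }
  rownames(out) <- NULL
  out
}

# residual vectors of every trail observation under (psi, shifts)
trail_residuals <- function(trails, psi, shifts, tilt_angles, markers,
                            center) {
  mk <- match(trails$marker, markers$marker)
  R <- matrix(NA_real_, nrow(trails), 2)
  for (i in unique(trails$image)) {
    rows <- which(trails$image == i)
    A <- projection_block(psi, tilt_angles[i])
    pred <- as.matrix(markers[mk[rows], c("rx", "ry", "rz")]) %*% t(A)
    R[rows, 1] <- trails$x[rows] - (pred[, 1] + shifts[i, 1] + center)
    R[rows, 2] <- trails$y[rows] - (pred[, 2] + shifts[i, 2] + center)
  }
  R
}

# Tukey bisquare weights from residual norms; tuning constant 4.685 times
# the normalized median absolute deviation
tukey_weights <- function(enorm) {
  sigma <- stats::median(enorm) / 0.6745
  # floor at the subpixel localization limit so near-perfect fits do not
  # reject mildly noisy inliers
  sigma <- max(sigma, 0.05)
  u <- enorm / (4.685 * sigma)
  w <- (1 - u^2)^2
  w[u >= 1] <- 0
  w
}

# The key structural fact exploited by the solver: substituting
# d~_i = Rot2(-psi) d_i turns the model into
#   Rot2(-psi) p_ij = B_i r_j + d~_i,   B_i = P Ry(theta_i),
# whose design matrix does not depend on psi -- only the right-hand side
# rotates.  Writing Rot2(-psi) p = cos(psi) a + sin(psi) b with a = (px, py)
# and b = (py, -px), the profiled objective is a quadratic form in
# (cos psi, sin psi) built from the two projected residual vectors, so psi
# has a closed-form global minimizer for any fixed observation weights.

# linearly interpolate shifts for images with no observations, in
# tilt-angle order (flat extrapolation at the ends)
fill_missing_shifts <- function(shifts, tilt_angles) {
  ord <- order(tilt_angles)
  for (col in 1:2) {
    v <- shifts[ord, col]
    known <- which(!is.na(v))
    if (!length(known)) stop("no image has any observation", call. = FALSE)
    v <- stats::approx(known, v[known], xout = seq_along(v),
                       rule = 2)$y
    shifts[ord, col] <- v
  }
  shifts
}

#' Solve the projection model from marker trails
#'
#' Exact profiled minimization with robust reweighting. Substituting
#' \code{d~_i = Rot2(-psi) d_i} makes the model linear in the marker
#' positions and transformed shifts with a design matrix independent of the
#' tilt-axis angle, so for fixed observation weights the weighted residual
#' is a quadratic form in \code{(cos psi, sin psi)} and psi has a
#' closed-form global minimizer; markers and shifts follow by weighted
#' linear least squares. Observation weights are then updated by
#' iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685 x the normalized median absolute deviation of
#' the residual norms), which suppresses gross outlier observations. Tilt
#' angles stay fixed at their nominal values throughout. The translation
#' gauge freedom (markers vs shifts) is fixed by centering the marker
#' cloud at the origin. psi is reported in [0, 180) unless \code{init_psi}
#' selects the other half-turn branch (which corresponds to inverting the
#' marker cloud).
#'
#' @param trails A \code{marker_trails} data.frame (>= 3 markers spanning
#'   >= 3 tilts).
#' @param ts A \code{\link{tilt_series}} (provides nominal tilt angles and
#'   the image center), or a numeric vector of tilt angles if \code{center}
#'   is given.
#' @param center Image center; required when \code{ts} is a plain vector.
#' @param robust Use Tukey bisquare IRLS (\code{TRUE}) or plain least
#'   squares (\code{FALSE}, for ablation).
#' @param init_psi Optional angle used only to pick the half-turn branch of
#'   the reported psi.
#' @param max_iter Maximum IRLS rounds.
#' @param tol Convergence threshold on the change of the mean residual
#'   (pixels).
#' @return List of class \code{projection_fit}: \code{model} (a
#'   \code{\link{projection_model}}), \code{markers} (with per-marker
#'   \code{rmsd}), \code{trails}, \code{residuals} (per-observation
#'   norms), \code{weights}, \code{mean_residual}.
#' @export
solve_projection_model <- function(trails, ts, center = NULL, robust = TRUE,
                                   init_psi = NULL, max_iter = 30L,
                                   tol = 1e-4) {
  if (inherits(ts, "tilt_series")) {
    tilt_angles <- ts$tilt_angles
    center <- center %||% ((nrow(ts$images[[1]]) + 1) / 2)
  } else {
    tilt_angles <- as.numeric(ts)
    if (is.null(center)) stop("`center` is required with bare tilt angles",
                              call. = FALSE)
  }
  trails <- as_trails(trails)
  marker_ids <- sort(unique(trails$marker))
  img_ids <- sort(unique(trails$image))
  if (length(marker_ids) < 3L || length(img_ids) < 3L) {
    stop("projection model needs at least 3 markers spanning at least 3 ",
         "tilt images (have ", length(marker_ids), " markers over ",
         length(img_ids), " images)", call. = FALSE)
  }
  n_obs <- nrow(trails)
  m <- length(marker_ids); k <- length(img_ids)
  jm <- match(trails$marker, marker_ids)
  ji <- match(trails$image, img_ids)
  # psi-independent design over (r_1..r_m, d~_1..d~_k)
  X <- matrix(0, 2L * n_obs, 3L * m + 2L * k)
  th <- deg2rad(tilt_angles[trails$image])
  rx <- 2L * seq_len(n_obs) - 1L
  X[cbind(rx, 3L * jm - 2L)] <- cos(th)
  X[cbind(rx, 3L * jm)] <- sin(th)
  X[cbind(rx + 1L, 3L * jm - 1L)] <- 1
  X[cbind(rx, 3L * m + 2L * ji - 1L)] <- 1
  X[cbind(rx + 1L, 3L * m + 2L * ji)] <- 1
  px <- trails$x - center; py <- trails$y - center
  a <- as.vector(rbind(px, py))
  b <- as.vector(rbind(py, -px))
  weights <- rep(1, n_obs)
  prev <- Inf
  psi <- 0; res <- NULL; coefs <- NULL
  for (it in seq_len(max_iter)) {
    w2 <- rep(weights, each = 2L)
    fa <- stats::lm.wfit(X, a, w2)
    fb <- stats::lm.wfit(X, b, w2)
    alpha <- sum(w2 * fa$residuals^2)
    beta <- sum(w2 * fb$residuals^2)
    gamma <- sum(w2 * fa$residuals * fb$residuals)
    psi <- rad2deg(0.5 * atan2(-2 * gamma, -(alpha - beta)))
    cp <- cos(deg2rad(psi)); sp <- sin(deg2rad(psi))
    res <- cp * fa$residuals + sp * fb$residuals
    ca <- fa$coefficients; cb <- fb$coefficients
    ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
    coefs <- cp * ca + sp * cb
    enorm <- sqrt(res[rx]^2 + res[rx + 1L]^2)
    cur <- sum(weights * enorm) / max(sum(weights), 1e-12)
    done <- abs(prev - cur) < tol
    prev <- cur
    if (!robust || done) break
    weights <- tukey_weights(enorm)
  }
  # pick the reported half-turn branch: [0, 180) by default, or the branch
  # nearer init_psi; flipping the branch negates the linear solution
  # (markers and transformed shifts invert; d = Rot2(psi) d~ is invariant)
  psi_solved <- psi
  psi <- psi %% 180
  if (!is.null(init_psi) && abs(wrap180(psi - init_psi)) > 90) {
    psi <- wrap180(psi + 180)
  }
  if (abs(wrap180(psi - psi_solved)) > 90) coefs <- -coefs
  r <- matrix(coefs[seq_len(3L * m)], ncol = 3, byrow = TRUE)
  dt <- matrix(coefs[3L * m + seq_len(2L * k)], ncol = 2, byrow = TRUE)
  # fix the translation gauge: marker centroid at the origin
  ctr <- colMeans(r)
  r <- sweep(r, 2, ctr)
  dt <- dt + cbind(cos(deg2rad(tilt_angles[img_ids])) * ctr[1] +
                     sin(deg2rad(tilt_angles[img_ids])) * ctr[3],
                   ctr[2])
  shifts <- matrix(NA_real_, length(tilt_angles), 2)
  shifts[img_ids, ] <- dt %*% t(rot2(psi))
  shifts <- fill_missing_shifts(shifts, tilt_angles)
  markers <- data.frame(marker = marker_ids, rx = r[, 1], ry = r[, 2],
                        rz = r[, 3])
  enorm <- sqrt(res[rx]^2 + res[rx + 1L]^2)
  rmsd <- sqrt(tapply(enorm^2, trails$marker, mean))
  markers$rmsd <- as.numeric(rmsd[as.character(marker_ids)])
  model <- projection_model(psi, shifts, tilt_angles, center)
  structure(list(model = model, markers = markers, trails = trails,
                 residuals = enorm, weights = weights,
                 mean_residual = prev),
            class = "projection_fit")
}

#' @export
print.projection_fit <- function(x, ...) {
  cat(sprintf(
    "<projection_fit> psi = %.3f deg, %d marker(s), mean residual %.3f px\n",
    x$model$tilt_axis_angle, nrow(x$markers), x$mean_residual))
  invisible(x)
}

#' Reindex trails by reprojection of the 3D marker model
#'
#' Every observation not yet part of a trail that falls within the distance
#' threshold of a reprojected marker position is added to that marker's
#' trail (the closest marker wins; one observation per marker per image;
#' each observation joins at most one marker). The model is re-solved and
#' the procedure iterated until the assignment set is stable.
#'
#' @param fit A \code{projection_fit} from
#'   \code{\link{solve_projection_model}}.
#' @param observations The full candidate observation data.frame
#'   (\code{image}, \code{x}, \code{y}).
#' @param distance_threshold_px Maximum reprojection distance for adding an
#'   observation; 0 adds nothing.
#' @param robust Passed to the re-solve.
#' @param max_rounds Safety bound on reindex/solve rounds.
#' @param reassign_all If \code{TRUE}, all existing assignments are
#'   discarded each round and every observation is re-assigned from the
#'   reprojected marker model; this repairs trails contaminated by
#'   mis-linked observations. If \code{FALSE} (the contract default), only
#'   unassigned observations are added.
#' @return An updated \code{projection_fit}.
#' @export
reindex_by_reprojection <- function(fit, observations,
                                    distance_threshold_px,
                                    robust = TRUE, max_rounds = 10L,
                                    reassign_all = FALSE) {
  stopifnot(inherits(fit, "projection_fit"))
  if (distance_threshold_px <= 0) return(fit)
  prev_key <- NULL
  for (round in seq_len(max_rounds)) {
    trails <- if (reassign_all) empty_trails() else fit$trails
    pred <- project_markers(fit$model$tilt_axis_angle,
                            fit$model$tilt_angles, fit$model$shifts,
                            as.matrix(fit$markers[c("rx", "ry", "rz")]),
                            fit$model$center)
    pred$marker <- fit$markers$marker[pred$marker]
    added <- 0L
    new_rows <- list()
    for (i in unique(observations$image)) {
      oi <- observations[observations$image == i, , drop = FALSE]
      # drop observations already assigned in this image
      ti <- trails[trails$image == i, , drop = FALSE]
      if (nrow(ti)) {
        used <- rep(FALSE, nrow(oi))
        for (r in seq_len(nrow(oi))) {
          used[r] <- any(abs(ti$x - oi$x[r]) < 1e-6 &
                           abs(ti$y - oi$y[r]) < 1e-6)
        }
        oi <- oi[!used, , drop = FALSE]
      }
      if (!nrow(oi)) next
      pi_ <- pred[pred$image == i, , drop = FALSE]
      # markers already observed in this image cannot take another
      pi_ <- pi_[!pi_$marker %in% ti$marker, , drop = FALSE]
      if (!nrow(pi_)) next
      D <- outer(oi$x, pi_$x, `-`)^2 + outer(oi$y, pi_$y, `-`)^2
      repeat {
        best <- which(D == min(D), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(D[best[1], best[2]]) ||
            D[best[1], best[2]] > distance_threshold_px^2) break
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          marker = pi_$marker[best[2]], image = i,
          x = oi$x[best[1]], y = oi$y[best[1]])
        added <- added + 1L
        D[best[1], ] <- Inf
        D[, best[2]] <- Inf
        if (all(!is.finite(D))) break
      }
    }
    if (!added) break
    trails <- as_trails(rbind(as.data.frame(trails),
                              do.call(rbind, new_rows)))
    # markers need at least 2 observations to be determined
    lens <- table(trails$marker)
    trails <- as_trails(
      trails[trails$marker %in% as.integer(names(lens)[lens >= 2L]), ,
             drop = FALSE])
    key <- paste(trails$marker, trails$image, round(trails$x, 3),
                 round(trails$y, 3), collapse = ";")
    if (identical(key, prev_key)) break
    prev_key <- key
    if (length(unique(trails$marker)) < 3L) break
    fit <- solve_projection_model(trails, fit$model$tilt_angles,
                                  center = fit$model$center,
                                  robust = robust,
                                  init_psi = fit$model$tilt_axis_angle)
    if (!reassign_all && !added) break
  }
  fit
}

#' Reintegrate images and markers lacking observations
#'
#' For every tilt image with no assigned observations, the reprojected
#' marker constellation is matched against the initial candidate cloud of
#' that image: markers are paired with their nearest candidates within the
#' search radius, a least-squares translation between constellation and
#' candidates is fitted, and candidates consistent with the translated
#' constellation are added as observations. The same nearest-candidate
#' procedure then fills in individually missing (marker, image)
#' observations on the remaining images. The total observation count never
#' decreases.
#'
#' @param fit A \code{projection_fit}.
#' @param observations Initial candidate cloud (\code{image}, \code{x},
#'   \code{y}).
#' @param search_radius_px Radius for the constellation match.
#' @param robust Passed to the final re-solve.
#' @return An updated \code{projection_fit}.
#' @export
reintegrate_missing <- function(fit, observations, search_radius_px,
                                robust = TRUE) {
  stopifnot(inherits(fit, "projection_fit"))
  trails <- as.data.frame(fit$trails)
  pred <- project_markers(fit$model$tilt_axis_angle, fit$model$tilt_angles,
                          fit$model$shifts,
                          as.matrix(fit$markers[c("rx", "ry", "rz")]),
                          fit$model$center)
  pred$marker <- fit$markers$marker[pred$marker]
  n_img <- length(fit$model$tilt_angles)
  empty_imgs <- setdiff(seq_len(n_img), unique(trails$image))
  added <- list()
  for (i in empty_imgs) {
    oi <- observations[observations$image == i, , drop = FALSE]
    if (!nrow(oi)) {
      message("image ", i, " has no candidates; left empty")
      next
    }
    pi_ <- pred[pred$image == i, , drop = FALSE]
    # coarse constellation registration: a consensus vote over pairwise
    # displacements tolerates the poorly interpolated shift of an image
    # that contributed no observations, then a least-squares translation
    # from the nearest-candidate pairing refines it
    disp <- consensus_displacement(pi_$x, pi_$y, oi$x, oi$y,
                                   search_radius_px)
    pi_$x <- pi_$x + disp[1]; pi_$y <- pi_$y + disp[2]
    for (pass in 1:2) {
      D <- outer(pi_$x, oi$x, `-`)^2 + outer(pi_$y, oi$y, `-`)^2
      nearest <- apply(D, 1, which.min)
      dist2 <- D[cbind(seq_len(nrow(pi_)), nearest)]
      ok <- dist2 <= search_radius_px^2
      if (sum(ok) < 2) break
      tx <- mean(oi$x[nearest[ok]] - pi_$x[ok])
      ty <- mean(oi$y[nearest[ok]] - pi_$y[ok])
      pi_$x <- pi_$x + tx
      pi_$y <- pi_$y + ty
    }
    D <- outer(pi_$x, oi$x, `-`)^2 + outer(pi_$y, oi$y, `-`)^2
    nearest <- apply(D, 1, which.min)
    dist2 <- D[cbind(seq_len(nrow(pi_)), nearest)]
    ok <- which(dist2 <= search_radius_px^2 & !duplicated(nearest))
    for (k in ok) {
      added[[length(added) + 1L]] <- data.frame(
        marker = pi_$marker[k], image = i,
        x = oi$x[nearest[k]], y = oi$y[nearest[k]])
    }
  }
  if (length(added)) {
    trails <- rbind(trails, do.call(rbind, added))
    fit <- solve_projection_model(as_trails(trails),
                                  fit$model$tilt_angles,
                                  center = fit$model$center,
                                  robust = robust,
                                  init_psi = fit$model$tilt_axis_angle)
  }
  # individual missing (marker, image) pairs via reprojection proximity
  reindex_by_reprojection(fit, observations, search_radius_px,
                          robust = robust)
}

#' Refine marker centers against per-marker reference images
#'
#' For each marker, the subimages of all its observations are averaged into
#' a per-marker reference; each observation is then re-localized by
#' cross-correlating the reference within a small search window around the
#' current position, with 3-point parabolic subpixel interpolation. The
#' procedure iterates until positions move less than \code{tol} px or
#' \code{max_pass} passes.
#'
#' @param ts A \code{\link{tilt_series}}.
#' @param trails A \code{marker_trails} data.frame.
#' @param radius_px Patch half-width is \code{2 * radius_px}.
#' @param search_px Half-width of the re-localization search window.
#' @param max_pass,tol Iteration controls.
#' @return Updated \code{marker_trails} with refined \code{x}, \code{y}.
#' @export
refine_marker_centers <- function(ts, trails, radius_px = NULL,
                                  search_px = 3L, max_pass = 5L,
                                  tol = 0.05) {
  stopifnot(inherits(ts, "tilt_series"))
  radius_px <- radius_px %||% fiducial_radius_px(ts)
  w <- 2L * round(radius_px)
  trails <- as_trails(trails)
  for (pass in seq_len(max_pass)) {
    max_move <- 0
    for (m in unique(trails$marker)) {
      rows <- which(trails$marker == m)
      if (length(rows) < 2L) next
      patches <- lapply(rows, function(r) {
        extract_patch(ts$images[[trails$image[r]]], trails$x[r],
                      trails$y[r], w)
      })
      usable <- !vapply(patches, is.null, logical(1))
      if (sum(usable) < 2L) next
      ref <- Reduce(`+`, patches[usable]) / sum(usable)
      ref0 <- ref - mean(ref)
      rnorm_ <- sqrt(sum(ref0^2))
      if (rnorm_ == 0) next
      # the averaged reference bead sits at the mean subpixel offset of its
      # contributing patches, not at the patch center; measure its
      # (dark-mass) centroid so matches can be corrected for that common
      # offset, otherwise the whole trail inherits it
      mass <- pmax(0, -ref0)
      ctr_idx <- w + 1
      ref_cx <- sum(mass * (row(ref) - ctr_idx)) / sum(mass)
      ref_cy <- sum(mass * (col(ref) - ctr_idx)) / sum(mass)
      for (r in rows) {
        win <- extract_patch(ts$images[[trails$image[r]]], trails$x[r],
                             trails$y[r], w + search_px)
        if (is.null(win)) next
        cc <- matrix(-Inf, 2 * search_px + 1, 2 * search_px + 1)
        for (du in -search_px:search_px) for (dv in -search_px:search_px) {
          sub <- win[(1 + search_px + du):(1 + search_px + du + 2 * w),
                     (1 + search_px + dv):(1 + search_px + dv + 2 * w)]
          s0 <- sub - mean(sub)
          sn <- sqrt(sum(s0^2))
          cc[du + search_px + 1, dv + search_px + 1] <-
            if (sn > 0) sum(ref0 * s0) / (sn * rnorm_) else -Inf
        }
        best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
        du <- best[1] - search_px - 1L; dv <- best[2] - search_px - 1L
        sx <- if (best[1] > 1 && best[1] < nrow(cc))
          parabolic_offset(cc[best[1] - 1, best[2]], cc[best[1], best[2]],
                           cc[best[1] + 1, best[2]]) else 0
        sy <- if (best[2] > 1 && best[2] < ncol(cc))
          parabolic_offset(cc[best[1], best[2] - 1], cc[best[1], best[2]],
                           cc[best[1], best[2] + 1]) else 0
        # displacement is relative to the rounded patch center, plus the
        # reference's own centroid offset
        newx <- round(trails$x[r]) + du + sx + ref_cx
        newy <- round(trails$y[r]) + dv + sy + ref_cy
        max_move <- max(max_move, abs(newx - trails$x[r]),
                        abs(newy - trails$y[r]))
        trails$x[r] <- newx
        trails$y[r] <- newy
      }
    }
    if (max_move < tol) break
  }
  trails
}

#' Prune markers by reprojection RMSD and re-solve once
#'
#' Markers whose root mean square deviation between measured and
#' reprojected positions exceeds the threshold are removed from the model;
#' the projection model is then re-solved once. If pruning would leave
#' fewer than 3 markers an error is raised and nothing is pruned.
#'
#' @param fit A \code{projection_fit}.
#' @param max_rmsd_px RMSD threshold in pixels (\code{Inf} prunes nothing).
#' @param robust Passed to the re-solve.
#' @return List of class \code{projection_fit} with an additional
#'   \code{pruned} element (the removed marker ids).
#' @export
prune_by_rmsd <- function(fit, max_rmsd_px, robust = TRUE) {
  stopifnot(inherits(fit, "projection_fit"))
  bad <- fit$markers$marker[fit$markers$rmsd > max_rmsd_px]
  if (!length(bad)) {
    fit$pruned <- integer(0)
    return(fit)
  }
  if (nrow(fit$markers) - length(bad) < 3L) {
    stop("pruning at RMSD ", max_rmsd_px, " px would leave fewer than 3 ",
         "markers; nothing pruned", call. = FALSE)
  }
  trails <- fit$trails[!fit$trails$marker %in% bad, , drop = FALSE]
  out <- solve_projection_model(as_trails(trails), fit$model$tilt_angles,
                                center = fit$model$center, robust = robust,
                                init_psi = fit$model$tilt_axis_angle)
  out$pruned <- bad
  out
}
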
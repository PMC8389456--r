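# The particle pose set: positions + orientations + tomogram membership in
# one canonical internal convention.  Orientations are stored as rotation
# matrices in the "rotates reference onto particle" sense (the particle
# z-axis is the third matrix column); Euler triplets appear only at format
# boundaries via the rotations module.

#' Construct a particle pose set
#'
#' @param positions \code{n x 3} matrix of positions in voxel units of the
#'   owning tomogram.
#' @param orientations \code{3 x 3 x n} array of rotation matrices mapping
#'   the reference frame onto each particle (orthonormal, determinant +1).
#'   Defaults to identity.
#' @param tomogram Tomogram identifier per particle (recycled).
#' @param tag Integer particle tags, unique within each tomogram. Defaults
#'   to \code{1..n}.
#' @param score Optional per-particle score (e.g. cross-correlation).
#' @return An object of class \code{pose_set}.
#' @export
pose_set <- function(positions, orientations = NULL, tomogram = 1L,
                     tag = NULL, score = NA_real_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) {
    stop("`positions` must be an n x 3 matrix", call. = FALSE)
  }
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (is.null(orientations)) {
    orientations <- array(diag(3), c(3, 3, n))
  }
  orientations <- check_rotation_stack(orientations, tol = 1e-8)
  if (dim(orientations)[3] != n) {
    stop("orientation count does not match position count", call. = FALSE)
  }
  tomogram <- rep_len(tomogram, n)
  tag <- if (is.null(tag)) seq_len(n) else as.integer(rep_len(tag, n))
  score <- rep_len(as.numeric(score), n)
  for (tm in unique(tomogram)) {
    if (anyDuplicated(tag[tomogram == tm])) {
      stop("particle tags must be unique within tomogram ", tm,
           call. = FALSE)
    }
  }
  structure(list(positions = positions, orientations = orientations,
                 tomogram = tomogram, tag = tag, score = score),
            class = "pose_set")
}

#' @export
length.pose_set <- function(x) nrow(x$positions)

#' @export
`[.pose_set` <- function(x, i) {
  pose_set(x$positions[i, , drop = FALSE],
           x$orientations[, , i, drop = FALSE],
           x$tomogram[i], x$tag[i], x$score[i])
}

#' Concatenate pose sets
#' @param ... \code{pose_set} objects.
#' @return A single \code{pose_set}.
#' @export
c.pose_set <- function(...) {
  sets <- list(...)
  pose_set(do.call(rbind, lapply(sets, `[[`, "positions")),
           array(unlist(lapply(sets, `[[`, "orientations")),
                 c(3, 3, sum(vapply(sets, length, integer(1))))),
           unlist(lapply(sets, `[[`, "tomogram")),
           unlist(lapply(sets, `[[`, "tag")),
           unlist(lapply(sets, `[[`, "score")))
}

#' Particle z-axes of a pose set
#'
#' The third column of each orientation matrix: the direction onto which the
#' reference z-axis is rotated (e.g. the outward surface normal for
#' surface-seeded particles).
#' @param poses A \code{pose_set}.
#' @return \code{n x 3} matrix of unit vectors.
#' @export
pose_z_axes <- function(poses) {
  stopifnot(inherits(poses, "pose_set"))
  t(poses$orientations[, 3, , drop = TRUE])
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d particle(s) in %d tomogram(s)\n",
              length(x), length(unique(x$tomogram))))
  invisible(x)
}

# orthonormal basis completion: given unit z, return a deterministic tangent
# pair (t1, t2) with [t1 t2 z] a proper rotation
tangent_basis <- function(z) {
  ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- cross3(ref, z)
  t1 <- t1 / vnorm(t1)
  t2 <- cross3(z, t1)
  cbind(t1, t2, deparse.level = 0)
}

# rotation with given z column and a random (or fixed) in-plane angle
orientation_from_normal <- function(z, inplane) {
  B <- tangent_basis(z)
  x <- cos(inplane) * B[, 1] + sin(inplane) * B[, 2]
  y <- cross3(z, x)
  cbind(x, y, z, deparse.level = 0)
}
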
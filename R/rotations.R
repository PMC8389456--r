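# Euler angle engine: batch conversion between angle triplets and rotation
# matrices under any right-handed Euler convention, plus a registry of
# software presets.
#
# Global frame conventions used throughout the package: matrices act on
# column vectors; the world coordinate system is right-handed with z toward
# the viewer; a positive angle is a counter-clockwise rotation when looking
# down the rotation axis toward the origin.

#' Describe an Euler angle convention
#'
#' An Euler convention gives meaning to an angle triplet: which axes are
#' rotated about (in order), whether rotations compose intrinsically (axes
#' rotate with the body) or extrinsically (axes fixed), the sign sense of a
#' positive angle, and whether the triplet describes rotating the reference
#' onto the particle or the particle onto the reference.
#'
#' @param axes Three-character string over \code{x}, \code{y}, \code{z} with
#'   no two consecutive characters equal, e.g. \code{"zxz"} (proper Euler) or
#'   \code{"zyx"} (Tait-Bryan). Twelve axis strings are valid.
#' @param intrinsic If \code{TRUE} the axes rotate with the body; if
#'   \code{FALSE} rotations are about the fixed world axes.
#' @param positive_ccw If \code{TRUE} a positive angle is counter-clockwise
#'   looking down the axis toward the origin.
#' @param rotates_reference If \code{TRUE} the resulting matrix rotates the
#'   reference onto the particle; if \code{FALSE} it is the transpose
#'   (particle onto reference).
#' @return An object of class \code{euler_convention}.
#' @examples
#' euler_convention("zyz")                    # RELION-style axes
#' euler_convention("zxz", intrinsic = FALSE) # Dynamo-style axes
#' @export
euler_convention <- function(axes, intrinsic = TRUE, positive_ccw = TRUE,
                             rotates_reference = TRUE) {
  axes <- tolower(as.character(axes))
  if (length(axes) != 1L || nchar(axes) != 3L ||
      !grepl("^[xyz]{3}$", axes)) {
    stop("`axes` must be a 3-character string over {x, y, z}", call. = FALSE)
  }
  ax <- strsplit(axes, "")[[1]]
  if (ax[1] == ax[2] || ax[2] == ax[3]) {
    stop("consecutive axes must differ in `axes` (got \"", axes, "\")",
         call. = FALSE)
  }
  structure(
    list(axes = axes,
         intrinsic = isTRUE(intrinsic),
         positive_ccw = isTRUE(positive_ccw),
         rotates_reference = isTRUE(rotates_reference)),
    class = "euler_convention")
}

#' @export
print.euler_convention <- function(x, ...) {
  cat(sprintf(
    "<euler_convention> axes=%s %s, %s, %s\n",
    x$axes,
    if (x$intrinsic) "intrinsic" else "extrinsic",
    if (x$positive_ccw) "positive=ccw" else "positive=cw",
    if (x$rotates_reference) "rotates reference->particle"
    else "rotates particle->reference"))
  invisible(x)
}

# -- convention registry ------------------------------------------------------

.convention_registry <- new.env(parent = emptyenv())

#' Register a named Euler convention
#'
#' Stores a convention under a name so that other functions can refer to it
#' as a string. The presets \code{"relion"} (zyz, intrinsic, ccw, rotates the
#' reference onto the particle) and \code{"dynamo"} (zxz, extrinsic, ccw,
#' rotates the particle onto the reference) ship with the package.
#'
#' @param name Registry name.
#' @param convention An \code{\link{euler_convention}}.
#' @return The convention, invisibly.
#' @export
register_convention <- function(name, convention) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(convention, "euler_convention"))
  assign(name, convention, envir = .convention_registry)
  invisible(convention)
}

#' Look up an Euler convention by name
#'
#' @param x A convention object (returned unchanged) or a registry name.
#' @return An \code{\link{euler_convention}}.
#' @export
as_euler_convention <- function(x) {
  if (inherits(x, "euler_convention")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!exists(x, envir = .convention_registry, inherits = FALSE)) {
      stop("unknown Euler convention \"", x, "\"; registered: ",
           paste(sort(ls(.convention_registry)), collapse = ", "),
           call. = FALSE)
    }
    return(get(x, envir = .convention_registry, inherits = FALSE))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an Euler convention", call. = FALSE)
}

#' Names of registered Euler conventions
#' @return Character vector of registry names.
#' @export
list_conventions <- function() sort(ls(.convention_registry))

# Presets.  RELION stores ZYZ intrinsic angles describing the rotation of the
# reference onto the particle; Dynamo stores ZXZ extrinsic angles (tdrot,
# tilt, narot) describing the rotation of the particle onto the reference.
local({
  assign("relion",
         euler_convention("zyz", intrinsic = TRUE, positive_ccw = TRUE,
                          rotates_reference = TRUE),
         envir = .convention_registry)
  assign("dynamo",
         euler_convention("zxz", intrinsic = FALSE, positive_ccw = TRUE,
                          rotates_reference = FALSE),
         envir = .convention_registry)
})

# -- elementary rotations -----------------------------------------------------

#' Elementary axis rotation matrices
#'
#' Active right-handed rotation about a coordinate axis, vectorized over
#' angles.
#'
#' @param axis One of \code{"x"}, \code{"y"}, \code{"z"}.
#' @param angles Numeric vector of angles in degrees.
#' @param positive_ccw If \code{FALSE}, a positive angle is clockwise (the
#'   angle is negated).
#' @return A \code{3 x 3 x n} array of rotation matrices.
#' @examples
#' axis_rotation("z", 90) %*% c(1, 0, 0)  # maps +x to +y
#' @export
axis_rotation <- function(axis, angles, positive_ccw = TRUE) {
  if (!is.character(axis) || length(axis) != 1L || !axis %in% c("x", "y", "z")) {
    stop("`axis` must be one of \"x\", \"y\", \"z\"", call. = FALSE)
  }
  a <- deg2rad(as.numeric(angles))
  if (!positive_ccw) a <- -a
  n <- length(a)
  ca <- cos(a); sa <- sin(a)
  R <- array(0, dim = c(3, 3, n))
  if (axis == "x") {
    R[1, 1, ] <- 1
    R[2, 2, ] <- ca; R[3, 3, ] <- ca
    R[2, 3, ] <- -sa; R[3, 2, ] <- sa
  } else if (axis == "y") {
    R[2, 2, ] <- 1
    R[1, 1, ] <- ca; R[3, 3, ] <- ca
    R[1, 3, ] <- sa; R[3, 1, ] <- -sa
  } else {
    R[3, 3, ] <- 1
    R[1, 1, ] <- ca; R[2, 2, ] <- ca
    R[1, 2, ] <- -sa; R[2, 1, ] <- sa
  }
  if (n == 1L) R[, , 1, drop = TRUE] else R
}

# stack helpers: matrices stored as 3 x 3 x n arrays
as_rotation_stack <- function(R) {
  if (is.matrix(R) && all(dim(R) == c(3, 3))) R <- array(R, c(3, 3, 1))
  if (!is.array(R) || length(dim(R)) != 3L || !all(dim(R)[1:2] == c(3, 3))) {
    stop("rotation matrices must be a 3x3 matrix or a 3x3xn array",
         call. = FALSE)
  }
  R
}

stack_matmul <- function(A, B) {
  A <- as_rotation_stack(A); B <- as_rotation_stack(B)
  n <- dim(A)[3]
  C <- array(0, dim = c(3, 3, n))
  for (i in 1:3) for (j in 1:3) {
    C[i, j, ] <- A[i, 1, ] * B[1, j, ] + A[i, 2, ] * B[2, j, ] +
      A[i, 3, ] * B[3, j, ]
  }
  C
}

stack_transpose <- function(R) {
  R <- as_rotation_stack(R)
  aperm(R, c(2, 1, 3))
}

check_rotation_stack <- function(R, tol = 1e-6) {
  R <- as_rotation_stack(R)
  n <- dim(R)[3]
  RtR <- stack_matmul(stack_transpose(R), R)
  I <- array(diag(3), c(3, 3, n))
  dev <- apply(abs(RtR - I), 3, max)
  det3 <- R[1, 1, ] * (R[2, 2, ] * R[3, 3, ] - R[2, 3, ] * R[3, 2, ]) -
    R[1, 2, ] * (R[2, 1, ] * R[3, 3, ] - R[2, 3, ] * R[3, 1, ]) +
    R[1, 3, ] * (R[2, 1, ] * R[3, 2, ] - R[2, 2, ] * R[3, 1, ])
  bad <- which(dev > tol | abs(det3 - 1) > tol)
  if (length(bad)) {
    stop("matrices are not proper rotations (orthonormal, det +1) at index ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  R
}

as_angle_matrix <- function(angles) {
  if (is.null(dim(angles))) {
    if (length(angles) != 3L) {
      stop("`angles` must be a length-3 vector or an n x 3 matrix",
           call. = FALSE)
    }
    angles <- matrix(angles, nrow = 1)
  }
  angles <- as.matrix(angles)
  if (ncol(angles) != 3L) stop("`angles` must have 3 columns", call. = FALSE)
  storage.mode(angles) <- "double"
  angles
}

# -- euler <-> matrix ---------------------------------------------------------

#' Convert Euler angle triplets to rotation matrices
#'
#' Intrinsic conventions compose as
#' \code{R = R(axis1, a1) R(axis2, a2) R(axis3, a3)}; extrinsic conventions
#' compose in the reverse order. Conventions with
#' \code{rotates_reference = FALSE} return the transpose.
#'
#' @param convention An \code{\link{euler_convention}} or registry name.
#' @param angles Length-3 vector or \code{n x 3} matrix of angles in degrees,
#'   ordered as the convention's axes.
#' @return A \code{3 x 3 x n} array of rotation matrices (a plain
#'   \code{3 x 3} matrix for a single triplet).
#' @examples
#' euler_to_matrix("relion", c(10, 20, 30))
#' @export
euler_to_matrix <- function(convention, angles) {
  conv <- as_euler_convention(convention)
  ang <- as_angle_matrix(angles)
  if (any(!is.finite(ang))) {
    stop("non-finite Euler angles at row ",
         paste(utils::head(which(!stats::complete.cases(ang) |
                                   apply(!is.finite(ang), 1, any)), 5),
               collapse = ", "), call. = FALSE)
  }
  ax <- strsplit(conv$axes, "")[[1]]
  R1 <- as_rotation_stack(axis_rotation(ax[1], ang[, 1], conv$positive_ccw))
  R2 <- as_rotation_stack(axis_rotation(ax[2], ang[, 2], conv$positive_ccw))
  R3 <- as_rotation_stack(axis_rotation(ax[3], ang[, 3], conv$positive_ccw))
  R <- if (conv$intrinsic) {
    stack_matmul(stack_matmul(R1, R2), R3)
  } else {
    stack_matmul(stack_matmul(R3, R2), R1)
  }
  if (!conv$rotates_reference) R <- stack_transpose(R)
  if (dim(R)[3] == 1L) R[, , 1, drop = TRUE] else R
}

# Extract intrinsic zxz angles (radians) from a stack; canonical middle
# angle in [0, pi].  Returns n x 3 matrix.
extract_zxz <- function(M, tol_deg = 1e-6) {
  sb <- sqrt(M[3, 1, ]^2 + M[3, 2, ]^2)
  beta <- atan2(sb, M[3, 3, ])
  degen <- pmin(abs(beta), abs(pi - beta)) < deg2rad(tol_deg)
  alpha <- ifelse(degen,
                  atan2(M[2, 1, ], M[1, 1, ]),
                  atan2(M[1, 3, ], -M[2, 3, ]))
  gamma <- ifelse(degen, 0, atan2(M[3, 1, ], M[3, 2, ]))
  cbind(alpha, beta, gamma, deparse.level = 0)
}

# Extract intrinsic zyx angles (radians); canonical middle angle in
# [-pi/2, pi/2].
extract_zyx <- function(M, tol_deg = 1e-6) {
  cb <- sqrt(M[3, 2, ]^2 + M[3, 3, ]^2)
  beta <- atan2(-M[3, 1, ], cb)
  degen <- pmin(abs(beta - pi / 2), abs(beta + pi / 2)) < deg2rad(tol_deg)
  alpha <- ifelse(degen,
                  atan2(-M[1, 2, ], M[2, 2, ]),
                  atan2(M[2, 1, ], M[1, 1, ]))
  gamma <- ifelse(degen, 0, atan2(M[3, 2, ], M[3, 3, ]))
  cbind(alpha, beta, gamma, deparse.level = 0)
}

axis_index <- function(a) match(a, c("x", "y", "z"))

# Permutation matrix P with P e_x = e_{map["x"]}, etc.  `map` is a named
# character vector with names x, y, z (canonical) and axis values (actual).
permutation_matrix <- function(map) {
  P <- matrix(0, 3, 3)
  P[axis_index(map[["x"]]), 1] <- 1
  P[axis_index(map[["y"]]), 2] <- 1
  P[axis_index(map[["z"]]), 3] <- 1
  P
}

#' Convert rotation matrices to Euler angle triplets
#'
#' Inverts \code{\link{euler_to_matrix}} at the matrix level: the returned
#' triplets reproduce the input matrices when fed back through
#' \code{euler_to_matrix} (the triplets themselves are not unique). The
#' middle angle is returned in the canonical branch: \code{[0, 180]} degrees
#' for proper Euler axis orders (first axis repeated), \code{[-90, 90]} for
#' Tait-Bryan orders. At gimbal lock (middle angle within 1e-6 degrees of a
#' degenerate value) the third angle is set to 0 and the first absorbs the
#' free sum or difference.
#'
#' @param convention An \code{\link{euler_convention}} or registry name.
#' @param matrices A \code{3 x 3} matrix or \code{3 x 3 x n} array; each
#'   matrix must be orthonormal with determinant +1 (tolerance 1e-6).
#' @return An \code{n x 3} matrix of angles in degrees (a length-3 vector for
#'   a single input matrix).
#' @export
matrix_to_euler <- function(convention, matrices) {
  conv <- as_euler_convention(convention)
  single <- is.matrix(matrices) && all(dim(matrices) == c(3, 3))
  R <- check_rotation_stack(matrices)
  if (!conv$rotates_reference) R <- stack_transpose(R)
  ax <- strsplit(conv$axes, "")[[1]]
  if (!conv$intrinsic) ax <- rev(ax)
  proper <- ax[1] == ax[3]
  if (proper) {
    # conjugate so that (ax1, ax2) become (z, x)
    map <- c(z = ax[1], x = ax[2])
    map[["y"]] <- setdiff(c("x", "y", "z"), c(ax[1], ax[2]))
  } else {
    map <- c(z = ax[1], y = ax[2], x = ax[3])
  }
  P <- permutation_matrix(map)
  sig <- det(P)
  Pn <- array(P, c(3, 3, dim(R)[3]))
  M <- stack_matmul(stack_matmul(stack_transpose(Pn), R), Pn)
  ang <- if (proper) extract_zxz(M) else extract_zyx(M)
  ang <- sig * ang
  if (proper) {
    # restore the canonical non-negative middle angle if the conjugation
    # flipped it: (a, b, c) ~ (a + pi, -b, c + pi) for proper sequences
    neg <- ang[, 2] < 0
    if (any(neg)) {
      ang[neg, 1] <- ang[neg, 1] + pi
      ang[neg, 2] <- -ang[neg, 2]
      ang[neg, 3] <- ang[neg, 3] + pi
    }
  }
  ang <- rad2deg(ang)
  if (!conv$intrinsic) ang <- ang[, 3:1, drop = FALSE]
  if (!conv$positive_ccw) ang <- -ang
  ang <- wrap180(ang)
  colnames(ang) <- strsplit(conv$axes, "")[[1]]
  if (single) ang[1, ] else ang
}

#' Convert Euler angles between conventions
#'
#' The conversion is exact at the rotation-matrix level:
#' \code{euler_to_matrix(dst, result)} equals
#' \code{euler_to_matrix(src, angles)}, including across conventions that
#' disagree in the reference/particle rotation direction (a transpose is
#' inserted).
#'
#' @param src,dst Source and target conventions (objects or registry names).
#' @param angles Length-3 vector or \code{n x 3} matrix of degrees in the
#'   source convention.
#' @return Angles in the target convention, same shape as the input.
#' @examples
#' convert_eulers("dynamo", "relion", c(30, 60, -10))
#' @export
convert_eulers <- function(src, dst, angles) {
  matrix_to_euler(dst, euler_to_matrix(src, angles))
}
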
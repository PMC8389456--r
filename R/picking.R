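# Geometrical particle picking: derive particle poses from annotated
# supporting geometries (spheres, surfaces), derive poses from existing
# poses (subboxing), and filter pose sets (duplicate exclusion,
# lattice-neighbour filtering).

#' Sphere model from a center and edge annotation
#'
#' A sphere is annotated by its center and one point on its surface.
#'
#' @param center,edge_point Length-3 vectors in voxel units.
#' @param tomogram Tomogram identifier.
#' @return List with \code{center}, \code{radius}, \code{tomogram}.
#' @examples
#' sphere_from_annotation(c(0, 0, 0), c(10, 0, 0))$radius  # 10
#' @export
sphere_from_annotation <- function(center, edge_point, tomogram = 1L) {
  center <- as.numeric(center); edge_point <- as.numeric(edge_point)
  stopifnot(length(center) == 3L, length(edge_point) == 3L)
  r <- vnorm(edge_point - center)
  if (r == 0) {
    stop("edge point coincides with center: zero-radius sphere",
         call. = FALSE)
  }
  list(center = center, radius = r, tomogram = tomogram)
}

#' Seed particle poses on a sphere
#'
#' Positions are placed on a deterministic equal-area (Fibonacci) spiral
#' lattice scaled so that the nearest-neighbour distance approximates
#' \code{spacing}; each particle's z-axis is the outward surface normal, and
#' the in-plane angle is drawn uniformly from the seeded random stream.
#'
#' @param center Sphere center (voxels).
#' @param radius Sphere radius (voxels).
#' @param spacing Target inter-particle distance (voxels).
#' @param tomogram Tomogram identifier.
#' @param seed RNG seed for the in-plane angles (NULL: current stream).
#' @return A \code{\link{pose_set}}.
#' @export
seed_sphere <- function(center, radius, spacing, tomogram = 1L, seed = NULL) {
  stopifnot(radius > 0, spacing > 0)
  center <- as.numeric(center)
  n <- max(1L, round(4 * pi * radius^2 / spacing^2))
  if (n < 2L) {
    warning("spacing ", spacing, " exceeds the sphere scale; seeding ",
            n, " particle(s)")
  }
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * (seq_len(n) - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  normals <- cbind(s * cos(phi), s * sin(phi), z)
  positions <- sweep(normals * radius, 2, center, `+`)
  inplane <- with_seed(seed, stats::runif(n, 0, 2 * pi))
  R <- array(0, c(3, 3, n))
  for (k in seq_len(n)) {
    R[, , k] <- orientation_from_normal(normals[k, ], inplane[k])
  }
  pose_set(positions, R, tomogram = tomogram)
}

#' Triangulated mesh from per-slice surface annotations
#'
#' Surfaces are annotated as groups of points in successive tomographic
#' slices (constant-z planes). Each slice's points are ordered by polar
#' angle about the slice centroid and consecutive slices are joined by a
#' band of triangles, producing a 2.5D open tube whose vertices are exactly
#' the annotated points.
#'
#' @param slices List of \code{k x 3} matrices, one per annotated slice, in
#'   slice order.
#' @param tomogram Tomogram identifier.
#' @param outside_point Optional point on the "outside" of the surface used
#'   to orient face normals; by default normals point away from the centroid
#'   of all annotated points.
#' @return List of class \code{triangle_mesh} with \code{vertices}
#'   (\code{m x 3}), \code{faces} (\code{f x 3} vertex indices),
#'   \code{normals} (\code{f x 3} unit outward normals) and \code{tomogram}.
#' @export
mesh_from_annotation <- function(slices, tomogram = 1L, outside_point = NULL) {
  if (!is.list(slices) || length(slices) < 2L) {
    stop("surface annotations need points in at least 2 slices",
         call. = FALSE)
  }
  slices <- lapply(slices, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3L) stop("slice points must be k x 3", call. = FALSE)
    storage.mode(s) <- "double"
    s
  })
  pts <- do.call(rbind, slices)
  if (nrow(pts) < 3L) {
    stop("surface annotations need at least 3 points in total",
         call. = FALSE)
  }
  # collinearity check over all points
  centered <- sweep(pts, 2, colMeans(pts))
  sv <- svd(centered)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("annotated points are collinear; no surface is defined",
         call. = FALSE)
  }
  # order each slice ring by polar angle about its centroid (slice plane
  # assumed normal to z)
  rings <- lapply(slices, function(s) {
    ctr <- colMeans(s)
    ord <- order(atan2(s[, 2] - ctr[2], s[, 1] - ctr[1]))
    s[ord, , drop = FALSE]
  })
  offsets <- cumsum(c(0L, vapply(rings, nrow, integer(1))))
  vertices <- do.call(rbind, rings)
  faces <- NULL
  for (k in seq_len(length(rings) - 1L)) {
    faces <- rbind(faces,
                   zipper_rings(rings[[k]], rings[[k + 1L]],
                                offsets[k], offsets[k + 1L]))
  }
  # drop degenerate (zero-area) faces
  areas <- apply(faces, 1, function(f) {
    v <- vertices[f, , drop = FALSE]
    vnorm(cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])) / 2
  })
  faces <- faces[areas > 1e-9, , drop = FALSE]
  if (!nrow(faces)) {
    stop("annotation is degenerate: the triangulated band has zero area",
         call. = FALSE)
  }
  normals <- t(apply(faces, 1, function(f) {
    v <- vertices[f, , drop = FALSE]
    nrm <- cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    nrm / vnorm(nrm)
  }))
  ref <- outside_point
  global_ctr <- colMeans(vertices)
  for (k in seq_len(nrow(faces))) {
    ctr <- colMeans(vertices[faces[k, ], , drop = FALSE])
    outward <- if (is.null(ref)) ctr - global_ctr else ref - ctr
    if (sum(normals[k, ] * outward) < 0) {
      faces[k, ] <- faces[k, c(1, 3, 2)]
      normals[k, ] <- -normals[k, ]
    }
  }
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 tomogram = tomogram),
            class = "triangle_mesh")
}

# join two angularly ordered rings with a closed band of triangles
# (n1 + n2 triangles); offsets give the index of each ring's first vertex
# in the merged vertex table minus one
zipper_rings <- function(a, b, off_a, off_b) {
  n1 <- nrow(a); n2 <- nrow(b)
  ang <- function(s) {
    ctr <- colMeans(s)
    th <- atan2(s[, 2] - ctr[2], s[, 1] - ctr[1])
    th
  }
  tha <- ang(a); thb <- ang(b)
  faces <- matrix(0L, 0, 3)
  i <- 1L; j <- 1L
  while (i <= n1 || j <= n2) {
    next_a <- if (i <= n1) tha[min(i, n1)] + (if (i > n1) 2 * pi else 0) else Inf
    next_b <- if (j <= n2) thb[min(j, n2)] + (if (j > n2) 2 * pi else 0) else Inf
    ia <- (i - 1L) %% n1 + 1L; ia1 <- i %% n1 + 1L
    jb <- (j - 1L) %% n2 + 1L; jb1 <- j %% n2 + 1L
    if ((next_a <= next_b && i <= n1) || j > n2) {
      faces <- rbind(faces, c(off_a + ia, off_a + ia1, off_b + jb))
      i <- i + 1L
    } else {
      faces <- rbind(faces, c(off_b + jb, off_b + jb1, off_a + ia))
      j <- j + 1L
    }
  }
  faces
}

#' Seed particle poses on a triangulated surface
#'
#' Samples positions uniformly by area over the mesh faces at a density of
#' approximately one particle per \code{spacing^2}; each particle's z-axis
#' is the (outward) normal of its face and the in-plane angle is drawn from
#' the seeded random stream. At least one particle is always returned.
#'
#' @param mesh A \code{triangle_mesh} from \code{\link{mesh_from_annotation}}.
#' @param spacing Target inter-particle distance (voxels).
#' @param seed RNG seed (NULL: current stream).
#' @return A \code{\link{pose_set}}.
#' @export
seed_surface <- function(mesh, spacing, seed = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), spacing > 0)
  areas <- apply(mesh$faces, 1, function(f) {
    v <- mesh$vertices[f, , drop = FALSE]
    vnorm(cross3(v[2, ] - v[1, ], v[3, ] - v[1, ])) / 2
  })
  total <- sum(areas)
  if (total <= 0) stop("mesh has zero area", call. = FALSE)
  n <- max(1L, round(total / spacing^2))
  with_seed(seed, {
    face_id <- sample.int(nrow(mesh$faces), n, replace = TRUE,
                          prob = areas / total)
    u <- stats::runif(n); v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    inplane <- stats::runif(n, 0, 2 * pi)
    positions <- matrix(0, n, 3)
    R <- array(0, c(3, 3, n))
    for (k in seq_len(n)) {
      f <- mesh$faces[face_id[k], ]
      vv <- mesh$vertices[f, , drop = FALSE]
      positions[k, ] <- vv[1, ] + u[k] * (vv[2, ] - vv[1, ]) +
        v[k] * (vv[3, ] - vv[1, ])
      R[, , k] <- orientation_from_normal(mesh$normals[face_id[k], ],
                                          inplane[k])
    }
    pose_set(positions, R, tomogram = mesh$tomogram)
  })
}

#' Derive subboxed particle poses
#'
#' Subboxing derives new poses at fixed offsets and rotations in the
#' reference frame of existing poses, e.g. to move from one symmetry axis of
#' a lattice to another. Child position is
#' \code{parent_position + R_parent \%*\% offset}; child orientation is
#' \code{R_parent \%*\% relative_rotation}. With several offsets the result
#' is the parents x offsets cross product.
#'
#' @param parents A \code{\link{pose_set}}.
#' @param offsets Length-3 vector or \code{m x 3} matrix of offsets in the
#'   parent particle frame (voxels).
#' @param relative_rotation A single 3x3 rotation applied to all offsets, or
#'   a list of m rotations paired with the offset rows.
#' @return A \code{\link{pose_set}} with fresh sequential tags; tomogram
#'   membership and scores are inherited.
#' @export
subbox <- function(parents, offsets = c(0, 0, 0), relative_rotation = diag(3)) {
  stopifnot(inherits(parents, "pose_set"))
  if (is.null(dim(offsets))) offsets <- matrix(offsets, nrow = 1)
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 3L) stop("`offsets` must be m x 3", call. = FALSE)
  m <- nrow(offsets)
  rots <- if (is.list(relative_rotation)) relative_rotation
          else rep(list(relative_rotation), m)
  if (length(rots) != m) {
    stop("need one relative rotation (or one per offset row)", call. = FALSE)
  }
  for (Rr in rots) check_rotation_stack(Rr, tol = 1e-8)
  n <- length(parents)
  pos <- matrix(0, n * m, 3)
  R <- array(0, c(3, 3, n * m))
  tomo <- character(0); sc <- numeric(0)
  idx <- 0L
  tomo <- rep(parents$tomogram, each = m)
  sc <- rep(parents$score, each = m)
  for (i in seq_len(n)) {
    Rp <- parents$orientations[, , i]
    for (k in seq_len(m)) {
      idx <- idx + 1L
      pos[idx, ] <- parents$positions[i, ] + as.numeric(Rp %*% offsets[k, ])
      R[, , idx] <- Rp %*% rots[[k]]
    }
  }
  pose_set(pos, R, tomogram = tomo, score = sc)
}

#' Remove duplicate particles within each tomogram
#'
#' Greedy exclusion in the spirit of Dynamo's per-volume duplicate removal:
#' particles are visited in order of descending score (ties broken by lower
#' tag) and retained only if no already-retained particle in the same
#' tomogram lies closer than \code{min_distance}. Particles in different
#' tomograms never conflict. The operation is idempotent.
#'
#' @param poses A \code{\link{pose_set}}.
#' @param min_distance Minimum allowed inter-particle distance (voxels).
#' @return The retained \code{\link{pose_set}}, in the original order.
#' @export
exclude_duplicates <- function(poses, min_distance) {
  stopifnot(inherits(poses, "pose_set"), min_distance >= 0)
  n <- length(poses)
  if (n == 0L || min_distance == 0) return(poses)
  keep <- logical(n)
  for (tm in unique(poses$tomogram)) {
    idx <- which(poses$tomogram == tm)
    sc <- poses$score[idx]
    sc[is.na(sc)] <- -Inf
    ord <- idx[order(-sc, poses$tag[idx])]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept)) {
        d2 <- rowSums((poses$positions[kept, , drop = FALSE] -
                         matrix(poses$positions[i, ], length(kept), 3,
                                byrow = TRUE))^2)
        if (any(d2 < min_distance^2)) next
      }
      kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  poses[which(keep)]
}

#' Retain particles with enough lattice neighbours
#'
#' Keeps particles that have at least \code{min_neighbors} other particles
#' in the same tomogram at the expected inter-particle distance (within a
#' fractional tolerance). Neighbour counts are computed once on the input
#' set (single pass, not iterated), so removing a boundary particle never
#' cascades.
#'
#' @param poses A \code{\link{pose_set}}.
#' @param expected_distance Expected lattice spacing (voxels).
#' @param tolerance Fractional tolerance; a neighbour counts if its distance
#'   lies in \code{expected_distance * c(1 - tolerance, 1 + tolerance)}.
#' @param min_neighbors Minimum neighbour count to retain a particle.
#' @return The retained \code{\link{pose_set}}.
#' @export
neighbor_filter <- function(poses, expected_distance, tolerance = 0.2,
                            min_neighbors = 3L) {
  stopifnot(inherits(poses, "pose_set"), expected_distance > 0,
            tolerance > 0, tolerance < 1, min_neighbors >= 0)
  n <- length(poses)
  if (n == 0L || min_neighbors == 0L) return(poses)
  lo <- expected_distance * (1 - tolerance)
  hi <- expected_distance * (1 + tolerance)
  keep <- logical(n)
  for (tm in unique(poses$tomogram)) {
    idx <- which(poses$tomogram == tm)
    if (length(idx) == 1L) next
    d <- as.matrix(stats::dist(poses$positions[idx, , drop = FALSE]))
    counts <- rowSums(d >= lo & d <= hi) - (lo <= 0)
    keep[idx[counts >= min_neighbors]] <- TRUE
  }
  poses[which(keep)]
}

#' Read geometric annotations from plain-text or JSON files
#'
#' Sphere annotations are two points (center, then edge point): either a
#' JSON object \code{{"center": [x,y,z], "edge_point": [x,y,z]}} or a
#' two-line whitespace-separated text file. Surface annotations are one
#' point group per tomographic slice: a JSON array of point arrays, or a
#' text file of \code{x y z} lines with blank lines separating slices.
#'
#' @param path Annotation file (\code{.json} is detected by extension).
#' @param tomogram Tomogram identifier attached to the annotation.
#' @return \code{read_sphere_annotation}: a sphere model list (see
#'   \code{\link{sphere_from_annotation}}); \code{read_surface_annotation}:
#'   a list of slice point matrices suitable for
#'   \code{\link{mesh_from_annotation}}.
#' @export
read_sphere_annotation <- function(path, tomogram = 1L) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(sphere_from_annotation(j$center, j$edge_point, tomogram))
  }
  m <- as.matrix(utils::read.table(path))
  if (nrow(m) != 2L || ncol(m) != 3L) {
    stop("sphere annotation needs exactly two x y z points ",
         "(center, edge)", call. = FALSE)
  }
  sphere_from_annotation(m[1, ], m[2, ], tomogram)
}

#' @rdname read_sphere_annotation
#' @export
read_surface_annotation <- function(path, tomogram = 1L) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    slices <- lapply(j, function(s) {
      m <- if (is.matrix(s)) s else do.call(rbind, s)
      matrix(as.numeric(m), ncol = 3)
    })
    return(slices)
  }
  lines <- readLines(path, warn = FALSE)
  groups <- split(lines, cumsum(is_blank(lines)))
  slices <- lapply(groups, function(g) {
    g <- g[!is_blank(g)]
    if (!length(g)) return(NULL)
    do.call(rbind, lapply(strsplit(trimws(g), "\\s+"), as.numeric))
  })
  slices <- Filter(Negate(is.null), slices)
  names(slices) <- NULL
  slices
}
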
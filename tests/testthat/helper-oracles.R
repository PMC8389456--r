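# Independent oracles used across the suite.  These deliberately avoid the
# package's own composition/filtering code paths.

# brute-force Euler composition: sequential multiplication of elementary
# matrices written out longhand
oracle_elementary <- function(axis, theta_deg, ccw = TRUE) {
  t <- theta_deg * pi / 180
  if (!ccw) t <- -t
  c_ <- cos(t); s <- sin(t)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3),
         y = matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3),
         z = matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3))
}

oracle_euler_matrix <- function(conv, angles) {
  ax <- strsplit(conv$axes, "")[[1]]
  Rs <- lapply(1:3, function(k) {
    oracle_elementary(ax[k], angles[k], conv$positive_ccw)
  })
  R <- if (conv$intrinsic) Rs[[1]] %*% Rs[[2]] %*% Rs[[3]]
       else Rs[[3]] %*% Rs[[2]] %*% Rs[[1]]
  if (!conv$rotates_reference) R <- t(R)
  R
}

all_axis_orders <- c("xyx", "xyz", "xzx", "xzy", "yxy", "yxz",
                     "yzy", "yzx", "zxy", "zxz", "zyx", "zyz")

# O(n^2) greedy duplicate-exclusion oracle over plain coordinates
oracle_exclude <- function(pos, score, tag, tomo, min_dist) {
  keep <- logical(nrow(pos))
  for (tm in unique(tomo)) {
    idx <- which(tomo == tm)
    sc <- score[idx]; sc[is.na(sc)] <- -Inf
    for (i in idx[order(-sc, tag[idx])]) {
      ok <- TRUE
      for (j in which(keep & tomo == tm)) {
        if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < min_dist) ok <- FALSE
      }
      keep[i] <- ok
    }
  }
  which(keep)
}

# brute-force pairwise neighbour counting
oracle_neighbor_count <- function(pos, expected, tol) {
  n <- nrow(pos)
  counts <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (d >= expected * (1 - tol) && d <= expected * (1 + tol)) {
      counts[i] <- counts[i] + 1L
    }
  }
  counts
}

max_stack_diff <- function(A, B) {
  A <- if (length(dim(A)) == 2) array(A, c(3, 3, 1)) else A
  B <- if (length(dim(B)) == 2) array(B, c(3, 3, 1)) else B
  max(abs(A - B))
}

# small, fast simulated series for unit tests
small_sim <- function(seed = 7, snr = 2, n_beads = 8, n_tilts = 21,
                      size = 192) {
  simulate_tilt_series(simulation_recipe(
    n_tilts = n_tilts, image_size = size, n_beads = n_beads, snr = snr,
    shift_max = 15, seed = seed))
}

# synthetic solver-level observations with known geometry
solver_case <- function(seed, psi = 85.3, n = 41, m = 15, noise = 0,
                        shift_max = 30, center = 256.5) {
  set.seed(seed)
  tilts <- seq(-60, 60, length.out = n)
  shifts <- matrix(stats::runif(2 * n, -shift_max, shift_max), ncol = 2)
  markers <- cbind(stats::runif(m, -150, 150), stats::runif(m, -150, 150),
                   stats::runif(m, -30, 30))
  obs <- project_markers(psi, tilts, shifts, markers, center)
  if (noise > 0) {
    obs$x <- obs$x + stats::rnorm(nrow(obs), sd = noise)
    obs$y <- obs$y + stats::rnorm(nrow(obs), sd = noise)
  }
  list(obs = obs[, c("marker", "image", "x", "y")],
       ground_truth = list(tilt_axis_angle = psi, shifts = shifts,
                           tilt_angles = tilts, markers = markers,
                           center = center),
       tilts = tilts, center = center)
}

# a two-optics-group RELION 3.1 document, hand-checkable
star31_fixture <- function() {
  optics <- data.frame(
    rlnOpticsGroup = c("1", "2"),
    rlnImagePixelSize = c("1.35", "2.7"),
    rlnVoltage = c("300", "300"),
    rlnSphericalAberration = c("2.7", "2.7"),
    rlnAmplitudeContrast = c("0.07", "0.07"),
    stringsAsFactors = FALSE)
  particles <- data.frame(
    rlnCoordinateX = c("10", "20", "30"),
    rlnAngleRot = c("5", "15", "25"),
    rlnOriginXAngst = c("2.7", "5.4", "-2.7"),
    rlnOpticsGroup = c("1", "2", "1"),
    stringsAsFactors = FALSE)
  star_document(list(optics = star_loop_block(optics),
                     particles = star_loop_block(particles)))
}

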
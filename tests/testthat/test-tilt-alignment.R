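test_that("the synthetic bead template is a discrete disc", {
  t3 <- synthetic_bead_template(3)
  expect_equal(dim(t3), c(13, 13))
  expect_equal(sum(t3 == -1), 29)  # lattice points with x^2 + y^2 <= 9
  t1 <- synthetic_bead_template(1)
  expect_equal(dim(t1), c(5, 5))
  expect_equal(sum(t1 == -1), 5)   # plus-shaped disc
  # rotationally symmetric under quarter turns
  expect_identical(t3, tomotools:::rot90(t3))
  expect_error(synthetic_bead_template(0.5), ">= 1 px")
})

test_that("cross-correlation detection localizes planted beads", {
  im <- matrix(0, 128, 128)
  im <- tomotools:::render_bead(im, 50, 70, 5)
  tpl <- synthetic_bead_template(5)
  obs <- detect_candidates(im, tpl, n_peaks = 3)
  expect_lt(sqrt((obs$x[1] - 50)^2 + (obs$y[1] - 70)^2), 1)
  # two beads 40 px apart are both recovered in the top 2
  im2 <- tomotools:::render_bead(im, 90, 70, 5)
  obs2 <- detect_candidates(im2, tpl, n_peaks = 2)
  d_to <- function(obs, x, y) min(sqrt((obs$x - x)^2 + (obs$y - y)^2))
  expect_lt(d_to(obs2, 50, 70), 1)
  expect_lt(d_to(obs2, 90, 70), 1)
  # a flat image yields no observations
  expect_equal(nrow(detect_candidates(matrix(1, 64, 64), tpl)), 0)
  # noise-only peaks score below planted-bead peaks in the same field
  set.seed(8)
  noise <- matrix(rnorm(128 * 128, sd = 0.5), 128, 128)
  planted <- tomotools:::render_bead(noise, 64, 64, 5)
  s_noise <- detect_candidates(noise, tpl, n_peaks = 1, min_score = -1)$score
  s_bead <- detect_candidates(planted, tpl, n_peaks = 1,
                              min_score = -1)$score
  expect_gt(s_bead, s_noise)
})

test_that("the data template averages candidate subimages", {
  sim <- small_sim(seed = 4, snr = 4, n_beads = 4, n_tilts = 7, size = 160)
  ts <- sim$tilt_series
  tpl <- synthetic_bead_template(5)
  cand <- detect_series_candidates(ts, tpl, n_peaks = 6)
  # a single candidate gives back its own subimage
  one <- cand[1, , drop = FALSE]
  t_one <- build_data_template(ts, one, radius_px = 5)
  expect_equal(attr(t_one, "n_averaged"), 1)
  patch <- tomotools:::extract_patch(ts$images[[one$image]], one$x, one$y, 10)
  expect_equal(t_one, patch, ignore_attr = TRUE)
  # averaging k patches shrinks the background noise like 1/sqrt(k)
  set.seed(15)
  flat <- lapply(1:40, function(i) matrix(rnorm(21^2, sd = 1), 21, 21))
  avg <- Reduce(`+`, flat) / 40
  expect_lt(sd(avg), 1.5 / sqrt(40))
})

test_that("the rotational symmetry filter separates beads from edges", {
  size <- 96
  im <- tomotools:::render_bead(matrix(0, size, size), 48, 70, 5)
  im[, 1:24] <- im[, 1:24] - 1  # straight-edge artifact away from the bead
  ts <- tilt_series(list(im), 0, pixel_size = 10, fiducial_diameter = 10)
  obs <- data.frame(image = c(1, 1), x = c(48, 48), y = c(70, 24))
  kept <- rotational_symmetry_filter(ts, obs, threshold = 0.5, radius_px = 5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$y, 70)
  # a -1 threshold keeps everything with a valid patch
  all_kept <- rotational_symmetry_filter(ts, obs, threshold = -1,
                                         radius_px = 5)
  expect_equal(nrow(all_kept), 2)
})

test_that("trail indexing follows beads across a clean series", {
  # hand-placed, well-separated beads: every projection stays isolated
  tilts <- seq(-50, 50, by = 10)
  markers <- rbind(c(-55, -55, 8), c(55, -55, -8), c(-55, 55, -5),
                   c(55, 55, 5), c(0, 0, 10), c(0, -60, 0))
  set.seed(77)
  shifts <- matrix(runif(2 * length(tilts), -10, 10), ncol = 2)
  pred <- project_markers(20, tilts, shifts, markers, 96.5)
  images <- lapply(seq_along(tilts), function(i) {
    im <- matrix(0, 192, 192)
    pi_ <- pred[pred$image == i, ]
    for (k in seq_len(nrow(pi_))) {
      im <- tomotools:::render_bead(im, pi_$x[k], pi_$y[k], 5)
    }
    im
  })
  ts <- tilt_series(images, tilts, pixel_size = 10, fiducial_diameter = 10)
  tpl <- synthetic_bead_template(5)
  cand <- detect_series_candidates(ts, tpl, n_peaks = 8)
  trails <- index_trails(ts, cand)
  lens <- table(trails$marker)
  expect_gte(sum(lens == length(tilts)), 5)
  expect_true(all(!duplicated(trails[c("marker", "image")])))
  # a single image yields no trails
  one <- tilt_series(ts$images[1], ts$tilt_angles[1], 10, 10)
  expect_equal(nrow(index_trails(one, cand[cand$image == 1, ])), 0)
})

test_that("triangulation inverts the projection for known geometry", {
  case <- solver_case(21, psi = 40, n = 15, m = 6)
  gt <- case$ground_truth
  model <- projection_model(gt$tilt_axis_angle, gt$shifts, gt$tilt_angles,
                            case$center)
  markers <- triangulate_markers(case$obs, model)
  expect_lt(max(abs(as.matrix(markers[c("rx", "ry", "rz")]) - gt$markers)),
            1e-6)
  expect_lt(max(markers$rmsd), 1e-6)
  # a marker at the origin with zero shifts projects to the image center
  pred <- project_markers(0, c(-30, 0, 30), matrix(0, 3, 2),
                          matrix(0, 1, 3), 128.5)
  expect_equal(pred$x, rep(128.5, 3))
  expect_equal(pred$y, rep(128.5, 3))
  # noisy triangulation averages down like sigma/sqrt(n_views)
  case_n <- solver_case(22, psi = 40, n = 41, m = 10, noise = 1)
  mk <- triangulate_markers(case_n$obs,
                            projection_model(40, case_n$ground_truth$shifts,
                                             case_n$tilts, case_n$center))
  err <- as.matrix(mk[c("rx", "ry", "rz")]) - case_n$ground_truth$markers
  expect_lt(median(abs(err)), 5 / sqrt(41))
})

test_that("the projection solver recovers psi and shifts from clean data", {
  case <- solver_case(31, psi = 85, n = 41, m = 15)
  fit <- solve_projection_model(case$obs, case$tilts, center = case$center)
  cmp <- alignment_vs_truth(fit, case$ground_truth)
  expect_lt(cmp$psi_error_deg, 0.01)
  expect_lt(max(cmp$shift_errors_px), 0.01)
  expect_lt(fit$mean_residual, 1e-8)
  # tilt angles pass through untouched
  expect_identical(fit$model$tilt_angles, case$tilts)
})

test_that("markers on the rotation axis with zero shifts fit exactly", {
  tilts <- seq(-60, 60, by = 15)
  markers <- cbind(0, c(-40, 0, 40), 0)  # on the y (tilt) axis
  obs <- project_markers(0, tilts, matrix(0, length(tilts), 2), markers,
                         100.5)
  fit <- solve_projection_model(obs, tilts, center = 100.5)
  expect_lt(max(fit$residuals), 1e-9)
})

test_that("robust fitting survives gross outliers where plain LS fails", {
  case <- solver_case(44, psi = 120, n = 41, m = 15)
  obs <- case$obs
  set.seed(99)
  out <- sample(nrow(obs), round(0.1 * nrow(obs)))
  obs$x[out] <- runif(length(out), 1, 512)
  obs$y[out] <- runif(length(out), 1, 512)
  fit_r <- solve_projection_model(obs, case$tilts, center = case$center,
                                  robust = TRUE)
  fit_p <- solve_projection_model(obs, case$tilts, center = case$center,
                                  robust = FALSE)
  err_r <- alignment_vs_truth(fit_r, case$ground_truth)$psi_error_deg
  err_p <- alignment_vs_truth(fit_p, case$ground_truth)$psi_error_deg
  expect_lt(err_r, 0.1)
  expect_gt(err_p, err_r)
})

test_that("the solver refuses underdetermined problems", {
  case <- solver_case(3, n = 5, m = 2)
  expect_error(solve_projection_model(case$obs, case$tilts,
                                      center = case$center),
               "at least 3 markers")
})

test_that("reindexing recovers withheld assignments", {
  case <- solver_case(55, psi = 30, n = 21, m = 8)
  obs <- case$obs
  set.seed(5)
  withheld <- sample(nrow(obs), round(0.2 * nrow(obs)))
  partial <- obs[-withheld, ]
  keep_m <- table(partial$marker)
  partial <- partial[partial$marker %in%
                       names(keep_m)[keep_m >= 3], ]
  fit <- solve_projection_model(partial, case$tilts, center = case$center)
  fit2 <- reindex_by_reprojection(fit, obs[c("image", "x", "y")],
                                  distance_threshold_px = 5)
  expect_equal(nrow(fit2$trails), nrow(obs))
  expect_lt(alignment_vs_truth(fit2, case$ground_truth)$psi_error_deg, 0.01)
  # a zero threshold adds nothing
  fit0 <- reindex_by_reprojection(fit, obs[c("image", "x", "y")], 0)
  expect_identical(fit0$trails, fit$trails)
})

test_that("an ambiguous observation joins only its nearest marker", {
  tilts <- c(-20, 0, 20, 40)
  markers <- rbind(c(0, 0, 0), c(0, 6, 0), c(50, -50, 10), c(-40, 30, -5))
  obs <- project_markers(0, tilts, matrix(0, 4, 2), markers, 100.5)
  # drop the observation of marker 2 in image 1, then reindex with a
  # threshold large enough to reach both marker 1 and marker 2
  partial <- obs[!(obs$marker == 2 & obs$image == 1), ]
  fit <- solve_projection_model(partial, tilts, center = 100.5)
  lost <- obs[obs$marker == 2 & obs$image == 1, c("image", "x", "y")]
  fit2 <- reindex_by_reprojection(fit, lost, distance_threshold_px = 20)
  added <- fit2$trails[fit2$trails$image == 1, ]
  expect_equal(sum(abs(added$y - lost$y) < 1e-6), 1)
  expect_false(any(duplicated(fit2$trails[c("marker", "image")])))
})

test_that("reintegration fills empty images and never loses observations", {
  case <- solver_case(66, psi = 100, n = 21, m = 8)
  obs <- case$obs
  partial <- obs[obs$image != 7, ]
  fit <- solve_projection_model(partial, case$tilts, center = case$center)
  before <- nrow(fit$trails)
  fit2 <- reintegrate_missing(fit, obs[c("image", "x", "y")],
                              search_radius_px = 25)
  expect_gte(nrow(fit2$trails), before)
  expect_equal(sum(fit2$trails$image == 7), 8)
  # an image with no candidates stays empty but is reported
  partial2 <- obs[obs$image != 3, ]
  fit3 <- solve_projection_model(partial2, case$tilts, center = case$center)
  expect_message(
    reintegrate_missing(fit3, partial2[c("image", "x", "y")],
                        search_radius_px = 25),
    "no candidates")
})

test_that("center refinement corrects truncated positions on clean beads", {
  sim <- small_sim(seed = 13, snr = Inf, n_beads = 5, n_tilts = 9,
                   size = 192)
  ts <- sim$tilt_series
  gt <- sim$ground_truth
  pred <- project_markers(gt$tilt_axis_angle, gt$tilt_angles, gt$shifts,
                          gt$markers, gt$center)
  inside <- pred$x > 20 & pred$x < 172 & pred$y > 20 & pred$y < 172
  pred <- pred[inside, ]
  # truncate the true positions to whole pixels (up to 0.5 px error)
  trails <- data.frame(marker = pred$marker, image = pred$image,
                       x = floor(pred$x), y = floor(pred$y))
  refined <- refine_marker_centers(ts, trails, radius_px = 5)
  # refined trails are re-sorted; align rows on (marker, image) keys
  key <- function(d) paste(d$marker, d$image)
  at <- match(key(refined), key(pred))
  err <- sqrt((refined$x - pred$x[at])^2 + (refined$y - pred$y[at])^2)
  err0 <- sqrt((floor(pred$x[at]) - pred$x[at])^2 +
                 (floor(pred$y[at]) - pred$y[at])^2)
  expect_lt(median(err), 0.1)
  expect_lt(mean(err), mean(err0))
  # single-observation markers are left untouched
  single <- data.frame(marker = 99, image = 1, x = 50.2, y = 60.7)
  expect_equal(refine_marker_centers(ts, single, radius_px = 5)$x, 50.2)
})

test_that("RMSD pruning removes exactly the corrupted marker", {
  case <- solver_case(77, psi = 60, n = 21, m = 8)
  obs <- case$obs
  bad <- obs$marker == 5
  obs$x[bad] <- obs$x[bad] + 10 * sign(sin(seq_len(sum(bad))))
  fit <- solve_projection_model(obs, case$tilts, center = case$center,
                                robust = FALSE)
  pruned <- prune_by_rmsd(fit, 3, robust = FALSE)
  expect_equal(pruned$pruned, 5)
  expect_false(5 %in% pruned$markers$marker)
  # global RMSD does not increase
  expect_lte(sqrt(mean(pruned$residuals^2)), sqrt(mean(fit$residuals^2)))
  # infinite threshold prunes nothing
  expect_length(prune_by_rmsd(fit, Inf)$pruned, 0)
  # refusal to prune below 3 markers
  expect_error(prune_by_rmsd(fit, 1e-12), "fewer than 3")
})

test_that("IMOD transform files encode the inverse in-plane rotation", {
  model <- projection_model(0, matrix(0, 3, 2), c(-3, 0, 3), 100.5)
  xf_path <- tempfile(fileext = ".xf")
  tlt_path <- tempfile(fileext = ".tlt")
  on.exit(unlink(c(xf_path, tlt_path)))
  out <- write_imod_alignment(model, xf_path, tlt_path)
  lines <- readLines(xf_path)
  expect_length(lines, 3)
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  expect_equal(dim(vals), c(3, 6))
  expect_equal(vals[1, ], c(1, 0, 0, 1, 0, 0))
  # psi = 90 deg: rotation part is Rot2(-90)
  m90 <- projection_model(90, matrix(0, 1, 2), 0, 100.5)
  xf90 <- write_imod_alignment(m90)$xf
  expect_equal(xf90[1, 1:4], c(0, 1, -1, 0), tolerance = 1e-12)
  # tlt re-reads bit-identically, one angle per line
  expect_identical(as.numeric(readLines(tlt_path)), c(-3, 0, 3))
  # the transform maps an observed point onto its unshifted projection
  model2 <- projection_model(35, matrix(c(4, -7), 1), 0, 100.5)
  r <- c(20, -10, 5)
  p <- rot2(35) %*% r[1:2] + c(4, -7)
  A <- matrix(write_imod_alignment(model2)$xf[1, 1:4], 2, 2, byrow = TRUE)
  tr <- write_imod_alignment(model2)$xf[1, 5:6]
  expect_equal(as.numeric(A %*% p + tr), r[1:2], tolerance = 1e-9)
})

test_that("the full pipeline recovers the simulated geometry deterministically", {
  # a fixture whose bead projections stay resolvable at every tilt; the
  # full-density study conditions are exercised by the acceptance suite
  sim <- small_sim(seed = 19, n_beads = 6, size = 224)
  res1 <- align_tilt_series(sim$tilt_series)
  cmp <- alignment_vs_truth(res1, sim$ground_truth)
  expect_lt(cmp$psi_error_deg, 0.5)
  expect_lt(median(cmp$shift_errors_px), 0.5)
  expect_lt(median(res1$markers$rmsd), 0.5)
  expect_identical(res1$model$tilt_angles, sim$tilt_series$tilt_angles)
  # bit-identical on repeated runs
  res2 <- align_tilt_series(sim$tilt_series)
  expect_identical(res1, res2)
  # reports and JSON serialize
  rp <- tempfile(); js <- tempfile(fileext = ".json")
  on.exit(unlink(c(rp, js)))
  write_alignment_report(res1, rp, js)
  expect_true(file.exists(rp) && file.exists(js))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$tilt_axis_angle, res1$model$tilt_axis_angle,
               tolerance = 1e-9)
})

test_that("a minimal three-bead series still aligns", {
  sim <- simulate_tilt_series(simulation_recipe(
    n_tilts = 15, image_size = 192, n_beads = 3, snr = 3, shift_max = 10,
    seed = 19))
  res <- align_tilt_series(sim$tilt_series)
  expect_gte(nrow(res$markers), 3)
  expect_lt(alignment_vs_truth(res, sim$ground_truth)$psi_error_deg, 0.5)
})

test_that("MRC stacks round-trip through disk", {
  sim <- small_sim(seed = 1, n_tilts = 3, n_beads = 3, size = 64)
  path <- tempfile(fileext = ".mrc")
  on.exit(unlink(path))
  write_mrc(sim$tilt_series$images, path, pixel_size = 10)
  back <- read_mrc(path)
  expect_equal(back$pixel_size, 10, tolerance = 1e-6)
  expect_equal(length(back$images), 3)
  expect_equal(back$images[[2]], sim$tilt_series$images[[2]],
               tolerance = 1e-6)
})
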
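# End-to-end fiducial-based tilt-series alignment: template -> detect ->
# data template -> re-detect -> symmetry filter -> trail indexing ->
# triangulation -> robust model solve -> reindex/reintegrate -> per-marker
# center refinement -> RMSD pruning.  All stage parameters are derived from
# the fiducial diameter and pixel size unless overridden.

#' Default alignment parameters derived from the fiducial size
#'
#' Search and suppression radii scale with the fiducial radius in pixels:
#' detection exclusion radius 2x, trail-linking and reintegration search
#' radius 5x, reprojection-reindexing threshold 2x (tight, since model
#' predictions are already subpixel-accurate when reindexing runs, and a
#' wide gate lets crossing beads contaminate each other's trails), RMSD
#' prune threshold 1.5x the radius.
#'
#' @param ts A \code{\link{tilt_series}}.
#' @return Named list of stage parameters.
#' @export
align_params <- function(ts) {
  r <- fiducial_radius_px(ts)
  list(radius_px = r,
       n_candidates = 50L,
       min_score = 0.15,
       exclusion_radius = 2 * r,
       symmetry_threshold = 0.3,
       search_radius = 5 * r,
       reindex_threshold = 2 * r,
       prune_rmsd = 1.5 * r,
       n_subimages = 300L)
}

#' Align a tilt series from gold-bead fiducials
#'
#' Runs the full alignment chain on a tilt series and returns the solved
#' projection model (single tilt-axis angle, per-image shifts, tilt angles
#' fixed at their nominal values), the refined 3D marker model, residuals
#' and the pruned marker ids. The procedure is deterministic: identical
#' input produces identical results.
#'
#' @param ts A \code{\link{tilt_series}}.
#' @param params Parameter overrides merged over \code{\link{align_params}}.
#' @param robust Use robust (Tukey bisquare IRLS) fitting.
#' @param verbose Emit per-stage progress messages.
#' @return List of class \code{alignment_result}: \code{model},
#'   \code{markers}, \code{trails}, \code{residuals}, \code{pruned},
#'   \code{params}, \code{n_candidates}.
#' @export
align_tilt_series <- function(ts, params = list(), robust = TRUE,
                              verbose = FALSE) {
  stopifnot(inherits(ts, "tilt_series"))
  p <- utils::modifyList(align_params(ts), params)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("tilt alignment failed at stage [", name, "]: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  tpl <- stage("synthetic template", synthetic_bead_template(p$radius_px))
  cand0 <- stage("initial detection",
                 detect_series_candidates(ts, tpl, p$n_candidates,
                                          p$exclusion_radius, p$min_score))
  say(nrow(cand0), " initial candidates")
  if (!nrow(cand0)) stop("no fiducial candidates detected", call. = FALSE)
  data_tpl <- stage("data template",
                    build_data_template(ts, cand0, p$n_subimages,
                                        p$radius_px))
  cand <- stage("second-pass detection",
                detect_series_candidates(ts, data_tpl, p$n_candidates,
                                         p$exclusion_radius, p$min_score))
  say(nrow(cand), " second-pass candidates")
  cand <- stage("symmetry filter",
                rotational_symmetry_filter(ts, cand, p$symmetry_threshold,
                                           p$radius_px))
  say(nrow(cand), " candidates after symmetry filter")
  trails <- stage("trail indexing",
                  index_trails(ts, cand, p$search_radius, p$radius_px))
  # seed the model from the longest trails only
  lens <- table(trails$marker)
  if (!length(lens)) stop("no linked marker trails found", call. = FALSE)
  long <- as.integer(names(lens)[lens >= max(3L, 0.5 * max(lens))])
  seed_trails <- as_trails(trails[trails$marker %in% long, , drop = FALSE])
  say(length(unique(trails$marker)), " trails; ", length(long),
      " used to seed the model")
  fit <- stage("model solve",
               solve_projection_model(seed_trails, ts, robust = robust))
  fit <- stage("reindexing",
               reindex_by_reprojection(fit, cand, p$reindex_threshold,
                                       robust = robust,
                                       reassign_all = TRUE))
  fit <- stage("reintegration",
               reintegrate_missing(fit, cand, p$search_radius,
                                   robust = robust))
  refined <- stage("center refinement",
                   refine_marker_centers(ts, fit$trails, p$radius_px))
  fit <- stage("model re-solve",
               solve_projection_model(refined, ts, robust = robust,
                                      init_psi = fit$model$tilt_axis_angle))
  fit <- stage("RMSD pruning", prune_by_rmsd(fit, p$prune_rmsd,
                                             robust = robust))
  structure(list(model = fit$model, markers = fit$markers,
                 trails = fit$trails, residuals = fit$residuals,
                 pruned = fit$pruned %||% integer(0), params = p,
                 n_candidates = nrow(cand)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<alignment_result> psi = %.3f deg, %d marker(s) (%d pruned), ",
    "%d observation(s), RMSD %.3f px\n"),
    x$model$tilt_axis_angle, nrow(x$markers), length(x$pruned),
    nrow(x$trails), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Write IMOD-compatible alignment files
#'
#' \code{.xf}: one line per image with six floats
#' \code{A11 A12 A21 A22 DX DY}, the transform that aligns the image -- an
#' in-plane rotation by \code{-psi} followed by the translation
#' \code{-Rot2(-psi) d_i}. \code{.tlt}: one nominal tilt angle per line in
#' image order, bit-identical to the input angles (tilt angles are never
#' refined).
#'
#' @param result An \code{alignment_result} (or bare
#'   \code{\link{projection_model}}).
#' @param xf_path,tlt_path Output paths; \code{NULL} skips that file.
#' @return Invisibly, a list with the \code{xf} matrix and \code{tlt}
#'   vector written.
#' @export
write_imod_alignment <- function(result, xf_path = NULL, tlt_path = NULL) {
  model <- if (inherits(result, "projection_model")) result else result$model
  Rinv <- rot2(-model$tilt_axis_angle)
  n <- length(model$tilt_angles)
  xf <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    tr <- -Rinv %*% model$shifts[i, ]
    xf[i, ] <- c(Rinv[1, 1], Rinv[1, 2], Rinv[2, 1], Rinv[2, 2], tr)
  }
  if (!is.null(xf_path)) {
    writeLines(sprintf("%12.7f%12.7f%12.7f%12.7f%12.3f%12.3f",
                       xf[, 1], xf[, 2], xf[, 3], xf[, 4], xf[, 5],
                       xf[, 6]),
               xf_path)
  }
  if (!is.null(tlt_path)) {
    # enough digits that the nominal angles re-read bit-identically
    writeLines(format_real(model$tilt_angles, digits = 15L), tlt_path)
  }
  invisible(list(xf = xf, tlt = model$tilt_angles))
}

#' Write a plain-text residual report and machine-readable result
#'
#' @param result An \code{alignment_result}.
#' @param report_path Plain-text per-marker residual summary.
#' @param json_path JSON serialization of model, markers and residuals.
#' @return Invisibly \code{result}.
#' @export
write_alignment_report <- function(result, report_path = NULL,
                                   json_path = NULL) {
  stopifnot(inherits(result, "alignment_result"))
  if (!is.null(report_path)) {
    lines <- c(
      sprintf("tilt axis angle (deg): %.4f", result$model$tilt_axis_angle),
      sprintf("images: %d  markers: %d  observations: %d  pruned: %d",
              length(result$model$tilt_angles), nrow(result$markers),
              nrow(result$trails), length(result$pruned)),
      sprintf("global RMSD (px): %.4f", sqrt(mean(result$residuals^2))),
      "",
      "marker    rx        ry        rz        rmsd_px",
      sprintf("%6d %9.2f %9.2f %9.2f %9.3f", result$markers$marker,
              result$markers$rx, result$markers$ry, result$markers$rz,
              result$markers$rmsd))
    writeLines(lines, report_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(tilt_axis_angle = result$model$tilt_axis_angle,
           tilt_angles = result$model$tilt_angles,
           shifts = result$model$shifts,
           markers = result$markers,
           global_rmsd = sqrt(mean(result$residuals^2)),
           pruned = result$pruned),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}

#' Align every tilt series found in a directory
#'
#' A thin batch driver for on-the-fly processing: each MRC stack with a
#' matching \code{.tlt} or \code{.rawtlt} file is aligned and its
#' \code{.xf}/\code{.tlt} written next to it. Already-processed stacks (an
#' \code{.xf} newer than the stack) are skipped, so the function can be
#' called repeatedly by a scheduler to poll a live acquisition folder.
#'
#' @param dir Directory containing tilt series stacks.
#' @param pixel_size,fiducial_diameter Acquisition parameters passed to
#'   \code{\link{read_tilt_series}}.
#' @param params,robust Passed to \code{\link{align_tilt_series}}.
#' @return Named list of \code{alignment_result} objects (invisibly).
#' @export
align_batch <- function(dir, pixel_size = NULL, fiducial_diameter = 10,
                        params = list(), robust = TRUE) {
  stacks <- list.files(dir, pattern = "\\.mrc$", full.names = TRUE)
  results <- list()
  for (s in stacks) {
    base <- sub("\\.mrc$", "", s)
    tlt <- if (file.exists(paste0(base, ".rawtlt"))) paste0(base, ".rawtlt")
           else paste0(base, ".tlt")
    if (!file.exists(tlt)) next
    xf <- paste0(base, ".xf")
    if (file.exists(xf) && file.mtime(xf) > file.mtime(s)) next
    ts <- read_tilt_series(s, tlt, pixel_size, fiducial_diameter)
    res <- align_tilt_series(ts, params, robust = robust)
    write_imod_alignment(res, xf_path = xf,
                         tlt_path = paste0(base, "_fid.tlt"))
    results[[basename(base)]] <- res
  }
  invisible(results)
}
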
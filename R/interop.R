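# Bidirectional metadata conversion between Dynamo tables and RELION/Warp
# STAR files, plus mdoc generation for Tomography 5 style filename listings.

RELION_COORD_TAGS <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ")
RELION_ANGLE_TAGS <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")

#' Convert a Dynamo table to a RELION particle STAR document
#'
#' Per particle, the exported coordinate is
#' \code{(position + shift) * coordinate_scale}: Dynamo's refined shifts
#' (columns 4-6) are consumed here and never re-exported, so downstream
#' refinement cannot double-count them. Orientations are converted from the
#' Dynamo ZXZ extrinsic convention to the RELION ZYZ intrinsic convention at
#' the rotation-matrix level. The output is a single flat RELION 3.0 style
#' loop block.
#'
#' @param table A \code{\link{dynamo_table}}.
#' @param coordinate_scale Multiplicative factor applied to positions, used
#'   to compensate tomogram binning between annotation and extraction.
#'   There is no inference: state the factor explicitly.
#' @param tomogram_map Named character vector mapping Dynamo tomogram
#'   indices (names) to micrograph/tomostar names. \code{NULL} uses the
#'   index itself as the name.
#' @return A \code{\link{star_document}} with one \code{data_} loop block.
#' @export
dynamo_to_relion <- function(table, coordinate_scale = 1,
                             tomogram_map = NULL) {
  stopifnot(inherits(table, "dynamo_table"), coordinate_scale > 0)
  pos <- (dyn_positions(table) + dyn_shifts(table)) * coordinate_scale
  ang <- as_angle_matrix(convert_eulers(
    "dynamo", "relion", as_angle_matrix(dyn_angles(table))))
  tomo <- dyn_tomogram(table)
  if (is.null(tomogram_map)) {
    mic <- as.character(tomo)
  } else {
    mic <- unname(tomogram_map[as.character(tomo)])
    if (anyNA(mic)) {
      stop("no micrograph name mapped for tomogram id(s): ",
           paste(sort(unique(tomo[is.na(mic)])), collapse = ", "),
           call. = FALSE)
    }
  }
  df <- data.frame(pos[, 1], pos[, 2], pos[, 3],
                   ang[, 1], ang[, 2], ang[, 3],
                   mic, stringsAsFactors = FALSE)
  names(df) <- c(RELION_COORD_TAGS, RELION_ANGLE_TAGS, "rlnMicrographName")
  star_document(stats::setNames(list(star_loop_block(df)), ""))
}

#' Convert a RELION particle STAR document to a Dynamo table
#'
#' The inverse of \code{\link{dynamo_to_relion}}: coordinates (divided by
#' \code{coordinate_scale}) are absorbed into the Dynamo position columns
#' with shifts emitted as zero, orientations are converted RELION -> Dynamo
#' at the matrix level, and fresh sequential tags are assigned.
#'
#' @param doc A \code{\link{star_document}} whose particle block carries
#'   coordinate and Euler-angle tags.
#' @param coordinate_scale Factor that was applied on export; positions are
#'   divided by it.
#' @param tomogram_map Named character vector mapping tomogram indices
#'   (names) to micrograph names, inverted here; \code{NULL} interprets the
#'   micrograph name as the index.
#' @return A \code{\link{dynamo_table}}.
#' @export
relion_to_dynamo <- function(doc, coordinate_scale = 1, tomogram_map = NULL) {
  stopifnot(inherits(doc, "star_document"), coordinate_scale > 0)
  df <- star_table(doc, convert = TRUE)
  need <- c(RELION_COORD_TAGS, RELION_ANGLE_TAGS)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("particle block lacks required tag(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  tbl <- new_dynamo_rows(n)
  m <- unclass(tbl)
  m[, 24:26] <- as.matrix(df[need[1:3]]) / coordinate_scale
  m[, 7:9] <- as_angle_matrix(convert_eulers(
    "relion", "dynamo", as_angle_matrix(as.matrix(df[need[4:6]]))))
  if ("rlnMicrographName" %in% names(df)) {
    mic <- as.character(df[["rlnMicrographName"]])
    if (is.null(tomogram_map)) {
      ids <- suppressWarnings(as.numeric(mic))
      if (anyNA(ids)) ids <- as.numeric(factor(mic, levels = unique(mic)))
    } else {
      ids <- as.numeric(names(tomogram_map))[match(mic, tomogram_map)]
      if (anyNA(ids)) {
        stop("micrograph name(s) absent from tomogram_map: ",
             paste(utils::head(unique(mic[is.na(ids)]), 5), collapse = ", "),
             call. = FALSE)
      }
    }
    m[, 20] <- ids
  }
  dynamo_table(m)
}

# fields copied from each optics group into its particle rows on downgrade,
# and 3.1-only tags translated for Warp 1.0.9 era consumers
STAR_31_ORIGIN_TAGS <- c(rlnOriginXAngst = "rlnOriginX",
                         rlnOriginYAngst = "rlnOriginY",
                         rlnOriginZAngst = "rlnOriginZ")
STAR_31_OPTICS_COPY <- c("rlnVoltage", "rlnSphericalAberration",
                         "rlnAmplitudeContrast", "rlnImagePixelSize",
                         "rlnImageSize", "rlnImageDimensionality")
STAR_31_DROP_TAGS <- c("rlnOpticsGroupName")

#' Downgrade a RELION 3.1 STAR document to the flat 3.0 dialect
#'
#' RELION 3.1 splits particle metadata into a \code{data_optics} block and a
#' \code{data_particles} block referencing it by optics group. Warp-era
#' consumers expect a single flat table. Each particle row receives a copy
#' of its optics group's acquisition fields (voltage, spherical aberration,
#' amplitude contrast, pixel size, image size/dimensionality); origins in
#' Angstrom (\code{rlnOriginXAngst} etc.) are converted to pixel origins
#' (\code{rlnOriginX} etc.) using the group pixel size; the optics block and
#' 3.1-only bookkeeping tags are removed. Documents that are already flat
#' are returned unchanged, so the operation is idempotent.
#'
#' @param doc A \code{\link{star_document}}.
#' @return A flat single-block \code{\link{star_document}}.
#' @export
star_downgrade <- function(doc) {
  stopifnot(inherits(doc, "star_document"))
  nm <- names(doc$blocks) %||% rep("", length(doc$blocks))
  oi <- which(nm == "optics")
  if (!length(oi)) return(doc)
  pi_ <- which(nm == "particles")
  if (!length(pi_)) {
    stop("document has a data_optics block but no data_particles block",
         call. = FALSE)
  }
  optics <- star_table(doc, "optics", convert = FALSE)
  particles <- doc$blocks[[pi_]]$data
  if (!"rlnOpticsGroup" %in% names(optics) ||
      !"rlnOpticsGroup" %in% names(particles)) {
    stop("optics and particles blocks must both carry rlnOpticsGroup",
         call. = FALSE)
  }
  grp <- match(particles[["rlnOpticsGroup"]], optics[["rlnOpticsGroup"]])
  if (anyNA(grp)) {
    stop("particle(s) reference absent optics group(s): ",
         paste(unique(particles[["rlnOpticsGroup"]][is.na(grp)]),
               collapse = ", "), call. = FALSE)
  }
  out <- particles
  for (tag in intersect(STAR_31_OPTICS_COPY, names(optics))) {
    if (!tag %in% names(out)) out[[tag]] <- optics[[tag]][grp]
  }
  # Angstrom origins -> pixel origins via the group pixel size
  if (any(names(STAR_31_ORIGIN_TAGS) %in% names(out))) {
    if (!"rlnImagePixelSize" %in% names(optics)) {
      stop("cannot convert Angstrom origins: optics block lacks ",
           "rlnImagePixelSize", call. = FALSE)
    }
    apix <- as.numeric(optics[["rlnImagePixelSize"]])[grp]
    for (src in intersect(names(STAR_31_ORIGIN_TAGS), names(out))) {
      out[[STAR_31_ORIGIN_TAGS[[src]]]] <-
        format_star_value(as.numeric(out[[src]]) / apix)
      out[[src]] <- NULL
    }
  }
  out[["rlnOpticsGroup"]] <- NULL
  for (tag in intersect(STAR_31_DROP_TAGS, names(out))) out[[tag]] <- NULL
  star_document(stats::setNames(list(star_loop_block(out)), ""))
}

#' Parse a Tomography 5 style micrograph filename
#'
#' Filenames of the form
#' \code{<basename>_<count>[<tilt_angle>]_fractions<suffix>.mrc} encode the
#' acquisition order and nominal tilt angle. Both the ASCII hyphen-minus and
#' the Unicode minus sign are accepted in the angle; counts may have 1-4
#' digits.
#'
#' @param name Filename (with or without directory part).
#' @return List of class \code{tomo5_filename} with \code{basename},
#'   \code{count}, \code{tilt_angle} and \code{original_name}.
#' @examples
#' parse_tomo5_filename("TS01_003[-12.00]_fractions.mrc")
#' @export
parse_tomo5_filename <- function(name) {
  bn <- basename(name)
  pat <- "^(.+)_([0-9]{1,4})\\[([-+−]?[0-9]+(?:\\.[0-9]+)?)\\]_fractions.*\\.mrc$"
  m <- regmatches(bn, regexec(pat, bn))[[1]]
  if (!length(m)) {
    stop("filename \"", bn, "\" does not match the Tomography 5 pattern ",
         "<basename>_<count>[<tilt_angle>]_fractions*.mrc", call. = FALSE)
  }
  angle_str <- sub("−", "-", m[4])
  structure(list(basename = m[2],
                 count = as.integer(m[3]),
                 tilt_angle = as.numeric(angle_str),
                 original_name = bn),
            class = "tomo5_filename")
}

#' Render a Tomography 5 filename from its fields
#'
#' Inverse of \code{\link{parse_tomo5_filename}} for files that used the
#' canonical zero-padded form.
#' @param basename,count,tilt_angle Fields of the name.
#' @param digits Zero-padding width of the count.
#' @param angle_decimals Decimal places of the tilt angle.
#' @return The filename string.
#' @export
render_tomo5_filename <- function(basename, count, tilt_angle,
                                  digits = 3L, angle_decimals = 2L) {
  sprintf("%s_%0*d[%.*f]_fractions.mrc", basename, digits, count,
          angle_decimals, tilt_angle)
}

#' Generate mdoc documents for a Tomography 5 directory listing
#'
#' Groups parseable filenames by basename (one tilt series, hence one mdoc
#' document, per basename), orders each group's sections by the count field
#' and fills in the tilt angle from the bracketed filename token. Files that
#' do not match the filename grammar are skipped with a single summarising
#' warning.
#'
#' @param filenames Character vector of micrograph filenames (a directory
#'   listing).
#' @param pixel_spacing Pixel spacing in Angstrom, written to the header.
#' @param voltage Acceleration voltage in kV, written to the header.
#' @param dose Exposure dose per tilt image (e/A^2), written per section.
#' @return Named list of \code{\link{mdoc_document}} objects, one per
#'   basename; empty input yields an empty list.
#' @export
spoof_mdoc <- function(filenames, pixel_spacing, voltage = 300, dose = 0) {
  parsed <- list()
  bad <- character()
  for (f in filenames) {
    p <- tryCatch(parse_tomo5_filename(f), error = function(e) NULL)
    if (is.null(p)) bad <- c(bad, basename(f)) else {
      parsed[[length(parsed) + 1L]] <- c(p, list(path = f))
    }
  }
  if (length(bad)) {
    warning("skipped ", length(bad), " file(s) not matching the ",
            "Tomography 5 filename pattern: ",
            paste(utils::head(bad, 3), collapse = ", "),
            if (length(bad) > 3) " ..." else "")
  }
  if (!length(parsed)) return(stats::setNames(list(), character()))
  bases <- vapply(parsed, `[[`, character(1), "basename")
  docs <- list()
  for (b in unique(bases)) {
    grp <- parsed[bases == b]
    ord <- order(vapply(grp, `[[`, integer(1), "count"))
    grp <- grp[ord]
    sections <- lapply(grp, function(p) {
      c(TiltAngle = format_real(p$tilt_angle),
        ExposureDose = format_real(dose),
        SubFramePath = p$path)
    })
    docs[[b]] <- mdoc_document(
      header = c(PixelSpacing = format_real(pixel_spacing),
                 Voltage = format_real(voltage),
                 ImageFile = paste0(b, ".mrc")),
      sections = sections)
  }
  docs
}

#' Convert between particle pose sets and Dynamo tables
#'
#' The bridge between geometrical picking (which produces
#' \code{\link{pose_set}} objects holding rotation matrices) and particle
#' metadata: orientations are written as Dynamo ZXZ extrinsic triplets
#' (columns 7-9), positions as columns 24-26, scores as the
#' cross-correlation column, with zero shifts.
#'
#' @param poses A \code{\link{pose_set}}.
#' @return \code{poses_to_dynamo_table}: a \code{\link{dynamo_table}};
#'   \code{poses_from_dynamo_table}: a \code{\link{pose_set}} (positions
#'   include the table's shifts).
#' @export
poses_to_dynamo_table <- function(poses) {
  stopifnot(inherits(poses, "pose_set"))
  n <- length(poses)
  m <- unclass(new_dynamo_rows(n))
  if (n) {
    m[, 7:9] <- as_angle_matrix(matrix_to_euler("dynamo",
                                                poses$orientations))
    m[, 10] <- ifelse(is.na(poses$score), 0, poses$score)
    tomo <- suppressWarnings(as.numeric(poses$tomogram))
    if (anyNA(tomo)) {
      tomo <- as.numeric(factor(poses$tomogram,
                                levels = unique(poses$tomogram)))
    }
    m[, 20] <- tomo
    m[, 24:26] <- poses$positions
  }
  dynamo_table(m)
}

#' @rdname poses_to_dynamo_table
#' @param table A \code{\link{dynamo_table}}.
#' @export
poses_from_dynamo_table <- function(table) {
  stopifnot(inherits(table, "dynamo_table"))
  n <- nrow(table)
  R <- euler_to_matrix("dynamo", as_angle_matrix(dyn_angles(table)))
  if (n == 1L) R <- array(R, c(3, 3, 1))
  pose_set(dyn_positions(table) + dyn_shifts(table),
           if (n) R else NULL,
           tomogram = dyn_tomogram(table),
           tag = dyn_tags(table),
           score = dyn_cc(table))
}
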
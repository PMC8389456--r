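# Dynamo .tbl tables: whitespace-separated numeric rows, one particle per
# line, with fixed 1-based column semantics.  Columns used here:
#   1 tag, 2 aligned, 3 averaged, 4-6 dx dy dz (shifts), 7-9 tdrot tilt narot
#   (ZXZ Euler angles), 10 cc, 20 tomogram index, 24-26 x y z (positions).
# All other columns are carried opaquely.

DYNAMO_MIN_COLS <- 26L

#' Construct a Dynamo table
#'
#' @param data Numeric matrix or data.frame with at least 26 columns, one
#'   row per particle, following the Dynamo column-index convention.
#' @return An object of class \code{dynamo_table} (a numeric matrix with
#'   columns named \code{c1..cn}).
#' @export
dynamo_table <- function(data) {
  m <- as.matrix(data)
  if (nrow(m) > 0 && !is.numeric(m)) {
    stop("Dynamo tables are numeric", call. = FALSE)
  }
  if (nrow(m) == 0L && ncol(m) < DYNAMO_MIN_COLS) {
    m <- matrix(numeric(), nrow = 0, ncol = DYNAMO_MIN_COLS)
  }
  if (ncol(m) < DYNAMO_MIN_COLS) {
    stop("Dynamo tables need at least ", DYNAMO_MIN_COLS,
         " columns, got ", ncol(m), call. = FALSE)
  }
  storage.mode(m) <- "double"
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  tags <- m[, 1]
  if (nrow(m) && (any(tags <= 0) || any(tags != round(tags)))) {
    stop("Dynamo tags (column 1) must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(tags)) {
    stop("Dynamo tags (column 1) must be unique", call. = FALSE)
  }
  structure(m, class = c("dynamo_table", class(m)))
}

#' Create an empty Dynamo table skeleton
#'
#' Returns an n-row matrix of zeros with sequential tags in column 1, ready
#' for the named setter columns.
#' @param n Number of particles.
#' @param ncol Total column count (>= 26).
#' @return A \code{dynamo_table}.
#' @export
new_dynamo_rows <- function(n, ncol = DYNAMO_MIN_COLS) {
  m <- matrix(0, nrow = n, ncol = max(ncol, DYNAMO_MIN_COLS))
  m[, 1] <- seq_len(n)
  dynamo_table(m)
}

#' Read a Dynamo .tbl file
#'
#' @param source File path or text with embedded newlines.
#' @return A \code{dynamo_table}. An empty file yields an empty table.
#' @export
read_dynamo_table <- function(source) {
  lines <- read_text_lines(source)
  lines <- lines[!is_blank(lines)]
  if (!length(lines)) {
    return(dynamo_table(matrix(numeric(), 0, DYNAMO_MIN_COLS)))
  }
  rows <- strsplit(trimws(lines), "\\s+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged Dynamo table: row ", bad, " has ", widths[bad],
         " columns, expected ", widths[1], call. = FALSE)
  }
  if (widths[1] < DYNAMO_MIN_COLS) {
    stop("Dynamo tables need at least ", DYNAMO_MIN_COLS, " columns, got ",
         widths[1], call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / widths[1])
    stop("non-numeric value in Dynamo table row ", bad, call. = FALSE)
  }
  dynamo_table(matrix(vals, ncol = widths[1], byrow = TRUE))
}

#' Write a Dynamo .tbl file
#'
#' Space-separated values, one particle per line. Integers round-trip
#' exactly; reals are written with 12 significant digits.
#'
#' @param table A \code{dynamo_table}.
#' @param path Optional output file; if \code{NULL} the text is returned.
#' @return The text, invisibly when written to a file.
#' @export
write_dynamo_table <- function(table, path = NULL) {
  stopifnot(inherits(table, "dynamo_table"))
  m <- unclass(table)
  lines <- apply(m, 1, function(row) paste(format_real(row), collapse = " "))
  text <- if (nrow(m)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

# named accessors --------------------------------------------------------------

#' Dynamo table column accessors
#'
#' Named views into the fixed Dynamo column map: particle tag (column 1),
#' shifts dx, dy, dz (4-6), Euler angles tdrot, tilt, narot (7-9),
#' cross-correlation score (10), tomogram index (20) and position x, y, z
#' (24-26).
#'
#' @param table A \code{dynamo_table}.
#' @return A vector (tags, cc, tomogram) or an \code{n x 3} matrix (shifts,
#'   angles, positions).
#' @name dynamo-accessors
NULL

#' @rdname dynamo-accessors
#' @export
dyn_tags <- function(table) as.vector(unclass(table)[, 1])

#' @rdname dynamo-accessors
#' @export
dyn_shifts <- function(table) {
  m <- unname(unclass(table)[, 4:6, drop = FALSE])
  colnames(m) <- c("dx", "dy", "dz"); m
}

#' @rdname dynamo-accessors
#' @export
dyn_angles <- function(table) {
  m <- unname(unclass(table)[, 7:9, drop = FALSE])
  colnames(m) <- c("tdrot", "tilt", "narot"); m
}

#' @rdname dynamo-accessors
#' @export
dyn_cc <- function(table) as.vector(unclass(table)[, 10])

#' @rdname dynamo-accessors
#' @export
dyn_tomogram <- function(table) as.vector(unclass(table)[, 20])

#' @rdname dynamo-accessors
#' @export
dyn_positions <- function(table) {
  m <- unname(unclass(table)[, 24:26, drop = FALSE])
  colnames(m) <- c("x", "y", "z"); m
}

#' @export
print.dynamo_table <- function(x, ...) {
  cat(sprintf("<dynamo_table> %d particle(s) x %d column(s)\n",
              nrow(x), ncol(x)))
  if (nrow(x)) {
    cat(sprintf("  tomograms: %s\n",
                paste(sort(unique(dyn_tomogram(x))), collapse = ", ")))
  }
  invisible(x)
}
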
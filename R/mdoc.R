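# SerialEM mdoc metadata: a global header of "Key = value" entries followed
# by one [ZValue = n] section per tilt image.  Files are written with CRLF
# line endings (SerialEM native); both endings are accepted on read.

#' Construct an mdoc document
#'
#' @param header Named character vector of global entries.
#' @param sections List of named character vectors, one per tilt image, in
#'   acquisition order. A \code{ZValue} entry is not required; sequential
#'   ZValues starting at 0 are assigned on write.
#' @return An object of class \code{mdoc_document}.
#' @export
mdoc_document <- function(header = character(), sections = list()) {
  header <- vapply(header, as.character, character(1))
  sections <- lapply(sections, function(s) {
    s <- vapply(s, as.character, character(1))
    if (length(s) && (is.null(names(s)) || any(names(s) == ""))) {
      stop("mdoc section entries must be named", call. = FALSE)
    }
    s[names(s) != "ZValue"]
  })
  structure(list(header = header, sections = sections),
            class = "mdoc_document")
}

#' Read an mdoc file
#'
#' Entries before the first \code{[ZValue = n]} header form the global
#' header; each section collects the entries that follow its header.
#' \code{[T = ...]} title lines are ignored. \code{TiltAngle} values are
#' retrievable as numbers via \code{\link{mdoc_tilt_angles}}.
#'
#' @param source File path or text with embedded newlines.
#' @return An \code{\link{mdoc_document}}.
#' @export
read_mdoc <- function(source) {
  lines <- read_text_lines(source)
  header <- character()
  sections <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (grepl("^\\[T\\b", line)) next
    zm <- regmatches(line, regexec("^\\[ZValue\\s*=\\s*([0-9]+)\\]$", line))[[1]]
    if (length(zm)) {
      if (!is.null(cur)) sections[[length(sections) + 1L]] <- cur
      cur <- character()
      next
    }
    if (grepl("^\\[", line)) {
      stop("unrecognized section header at line ", i, ": ", line,
           call. = FALSE)
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) {
      stop("expected 'Key = value' at line ", i, ": ", line, call. = FALSE)
    }
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    if (is.null(cur)) {
      header[key] <- val
    } else {
      cur[key] <- val
    }
  }
  if (!is.null(cur)) sections[[length(sections) + 1L]] <- cur
  mdoc_document(header, sections)
}

#' Write an mdoc file
#'
#' Sections are written in order with strictly increasing \code{ZValue}
#' starting from 0, CRLF line endings, ASCII only.
#'
#' @param doc An \code{\link{mdoc_document}}.
#' @param path Optional output file; if \code{NULL} the text is returned.
#' @return The text, invisibly when written to a file.
#' @export
write_mdoc <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "mdoc_document"))
  out <- character()
  if (length(doc$header)) {
    out <- c(out, paste(names(doc$header), "=", doc$header), "")
  }
  for (k in seq_along(doc$sections)) {
    s <- doc$sections[[k]]
    out <- c(out, sprintf("[ZValue = %d]", k - 1L),
             if (length(s)) paste(names(s), "=", s), "")
  }
  text <- paste0(paste(out, collapse = "\r\n"), "\r\n")
  if (is.null(path)) return(text)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL)
  invisible(text)
}

#' Tilt angles stored in an mdoc document
#'
#' @param doc An \code{\link{mdoc_document}}.
#' @return Numeric vector of per-section \code{TiltAngle} values (NA where
#'   absent).
#' @export
mdoc_tilt_angles <- function(doc) {
  stopifnot(inherits(doc, "mdoc_document"))
  vapply(doc$sections, function(s) {
    if ("TiltAngle" %in% names(s)) as.numeric(s[["TiltAngle"]]) else NA_real_
  }, numeric(1))
}

#' @export
print.mdoc_document <- function(x, ...) {
  cat(sprintf("<mdoc_document> %d header entr%s, %d section(s)\n",
              length(x$header), if (length(x$header) == 1) "y" else "ies",
              length(x$sections)))
  invisible(x)
}
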
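# STAR file reading and writing (RELION 3.0 flat and 3.1 optics-grouped
# dialects).  A document is an ordered set of named data blocks; each block
# is either "simple" (tag -> scalar string) or a "loop" (named columns +
# rows).  All cell values are stored as strings; numeric interpretation is
# applied on request, so odd cells such as "nan" or empty placeholders
# survive a round trip untouched.

#' Construct a STAR document
#'
#' @param blocks Named list of blocks created with
#'   \code{\link{star_loop_block}} or \code{\link{star_simple_block}}. Block
#'   names must be unique; the empty name corresponds to a bare
#'   \code{data_} block.
#' @return An object of class \code{star_document}.
#' @export
star_document <- function(blocks = list()) {
  if (length(blocks)) {
    nm <- names(blocks) %||% rep("", length(blocks))
    if (anyDuplicated(nm)) {
      stop("duplicate block names in STAR document", call. = FALSE)
    }
    ok <- vapply(blocks, inherits, logical(1), what = "star_block")
    if (!all(ok)) stop("all blocks must be star_block objects", call. = FALSE)
  }
  structure(list(blocks = blocks), class = "star_document")
}

#' @rdname star_document
#' @param data A data.frame of loop rows; values are coerced to character
#'   with \code{\link{format_star_value}} semantics (doubles keep >= 12
#'   significant digits).
#' @export
star_loop_block <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (ncol(data) == 0L) {
    stop("a STAR loop block needs at least one column", call. = FALSE)
  }
  if (anyDuplicated(names(data))) {
    stop("duplicate column names in STAR loop", call. = FALSE)
  }
  data[] <- lapply(data, format_star_value)
  structure(list(type = "loop", data = data), class = "star_block")
}

#' @rdname star_document
#' @param tags Named character (or coercible) vector of tag -> value pairs.
#' @export
star_simple_block <- function(tags = character()) {
  vals <- format_star_value(unname(unlist(tags)))
  nm <- names(tags)
  if (length(vals) && (is.null(nm) || any(nm == ""))) {
    stop("simple STAR block tags must be named", call. = FALSE)
  }
  structure(list(type = "simple", tags = stats::setNames(vals %||% character(), nm)),
            class = "star_block")
}

#' Format values for STAR/table output
#'
#' Doubles are rendered with 12 significant digits (round-trips to well
#' below 1e-6 relative error); other types via \code{as.character}.
#' @param x Vector to format.
#' @return Character vector.
#' @export
format_star_value <- function(x) {
  if (is.double(x)) format_real(x) else as.character(x)
}

#' Read a STAR file
#'
#' Parses all \code{data_} blocks in order, preserving loop column order.
#' Comment lines (first non-blank character \code{#}) are skipped. Empty
#' input yields an empty document. Malformed loop rows (field count
#' different from the column count) raise an error naming the line.
#'
#' @param source A file path, or a character string containing the document
#'   text (newlines embedded).
#' @return A \code{\link{star_document}}.
#' @export
read_star <- function(source) {
  lines <- read_text_lines(source)
  blocks <- list()
  block_names <- character()
  cur_name <- NULL
  cur_tags <- character()
  cur_tag_names <- character()
  state <- "none"  # none | simple | loop_header | loop_rows
  loop_cols <- character()
  loop_rows <- list()

  flush_block <- function() {
    if (is.null(cur_name)) return()
    if (length(loop_cols) || state == "loop_header") {
      if (!length(loop_cols)) {
        stop("loop_ without column definitions in block \"", cur_name, "\"",
             call. = FALSE)
      }
      if (anyDuplicated(loop_cols)) {
        stop("duplicate loop column names in block \"", cur_name, "\"",
             call. = FALSE)
      }
      df <- as.data.frame(
        stats::setNames(
          lapply(seq_along(loop_cols), function(j)
            vapply(loop_rows, `[[`, character(1), j)),
          loop_cols),
        stringsAsFactors = FALSE, optional = TRUE)
      blk <- structure(list(type = "loop", data = df), class = "star_block")
    } else {
      blk <- structure(list(type = "simple",
                            tags = stats::setNames(cur_tags, cur_tag_names)),
                       class = "star_block")
    }
    if (cur_name %in% block_names) {
      stop("duplicate STAR block name \"", cur_name, "\"", call. = FALSE)
    }
    blocks[[length(blocks) + 1L]] <<- blk
    block_names[length(block_names) + 1L] <<- cur_name
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    trimmed <- trimws(line)
    if (trimmed == "") {
      if (state == "loop_rows") state <- "simple_done"
      next
    }
    if (startsWith(trimmed, "#")) next
    if (startsWith(trimmed, "data_")) {
      flush_block()
      cur_name <- substring(trimmed, 6L)
      cur_tags <- character(); cur_tag_names <- character()
      loop_cols <- character(); loop_rows <- list()
      state <- "simple"
      next
    }
    if (is.null(cur_name)) {
      stop("content before first data_ block at line ", i, call. = FALSE)
    }
    if (trimmed == "loop_") {
      state <- "loop_header"
      loop_cols <- character(); loop_rows <- list()
      next
    }
    if (startsWith(trimmed, "_")) {
      tokens <- strsplit(trimmed, "\\s+")[[1]]
      tag <- substring(tokens[1], 2L)
      if (state == "loop_header") {
        loop_cols[length(loop_cols) + 1L] <- tag
      } else if (state == "simple") {
        if (length(tokens) < 2L) {
          stop("tag without value at line ", i, call. = FALSE)
        }
        cur_tag_names[length(cur_tag_names) + 1L] <- tag
        cur_tags[length(cur_tags) + 1L] <- tokens[2]
      } else {
        stop("unexpected tag line inside loop data at line ", i,
             call. = FALSE)
      }
      next
    }
    # data row
    if (!state %in% c("loop_header", "loop_rows")) {
      stop("unexpected data row outside a loop at line ", i, call. = FALSE)
    }
    state <- "loop_rows"
    fields <- strsplit(trimmed, "\\s+")[[1]]
    if (length(fields) != length(loop_cols)) {
      stop("malformed loop row at line ", i, ": ", length(fields),
           " fields for ", length(loop_cols), " columns", call. = FALSE)
    }
    loop_rows[[length(loop_rows) + 1L]] <- fields
  }
  flush_block()
  star_document(stats::setNames(blocks, block_names))
}

#' Write a STAR document
#'
#' Emits \code{data_}/\code{loop_}/\code{_tag} syntax with numbered column
#' headers (\code{#1..#n}) and whitespace-aligned columns. Output is
#' deterministic for equal input and re-reads to an equal document.
#'
#' @param doc A \code{\link{star_document}}.
#' @param path Optional output file; if \code{NULL} the text is returned.
#' @return The document text, invisibly when written to a file.
#' @export
write_star <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "star_document"))
  out <- character()
  nm <- names(doc$blocks) %||% rep("", length(doc$blocks))
  for (k in seq_along(doc$blocks)) {
    blk <- doc$blocks[[k]]
    out <- c(out, paste0("data_", nm[k]), "")
    if (blk$type == "simple") {
      if (length(blk$tags)) {
        tags <- paste0("_", names(blk$tags))
        w <- max(nchar(tags))
        out <- c(out, paste0(formatC(tags, width = -w), "  ", blk$tags))
      }
    } else {
      df <- blk$data
      if (ncol(df) == 0L) {
        stop("cannot write STAR loop block with zero columns", call. = FALSE)
      }
      out <- c(out, "loop_",
               sprintf("_%s #%d", names(df), seq_len(ncol(df))))
      if (nrow(df)) {
        cols <- lapply(df, function(col) {
          w <- max(nchar(col))
          formatC(col, width = w)
        })
        out <- c(out, do.call(paste, c(cols, sep = "  ")))
      }
    }
    out <- c(out, "")
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Access a STAR loop block as a typed data.frame
#'
#' @param doc A \code{\link{star_document}}.
#' @param block Block name or index; defaults to the first loop block.
#' @param convert If \code{TRUE}, columns that look numeric are converted.
#' @return A data.frame.
#' @export
star_table <- function(doc, block = NULL, convert = TRUE) {
  stopifnot(inherits(doc, "star_document"))
  if (is.null(block)) {
    idx <- which(vapply(doc$blocks, function(b) b$type == "loop", logical(1)))
    if (!length(idx)) stop("document has no loop block", call. = FALSE)
    blk <- doc$blocks[[idx[1]]]
  } else {
    blk <- doc$blocks[[block]]
    if (is.null(blk)) stop("no block \"", block, "\"", call. = FALSE)
  }
  if (blk$type != "loop") stop("block is not a loop block", call. = FALSE)
  df <- blk$data
  if (convert) {
    df[] <- lapply(df, function(col) {
      num <- suppressWarnings(as.numeric(col))
      failed <- is.na(num) & !(tolower(col) %in% c("nan", "na", ""))
      if (length(col) && !any(failed)) num else col
    })
  }
  df
}

#' @export
print.star_document <- function(x, ...) {
  cat(sprintf("<star_document> %d block(s)\n", length(x$blocks)))
  nm <- names(x$blocks) %||% rep("", length(x$blocks))
  for (k in seq_along(x$blocks)) {
    blk <- x$blocks[[k]]
    if (blk$type == "loop") {
      cat(sprintf("  data_%s: loop, %d column(s) x %d row(s)\n",
                  nm[k], ncol(blk$data), nrow(blk$data)))
    } else {
      cat(sprintf("  data_%s: simple, %d tag(s)\n", nm[k], length(blk$tags)))
    }
  }
  invisible(x)
}
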
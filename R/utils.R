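# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Read text from a file path or use a string that already contains newlines.
read_text_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE) &&
      file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(paste(source, collapse = "\n"), "\r?\n"))
}

is_blank <- function(x) grepl("^\\s*$", x)

# Format doubles for text metadata: round-trips to < 1e-6 relative error,
# integers stay exact, no locale surprises.
format_real <- function(x, digits = 12L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("nan")
    s <- sprintf("%.*g", digits, v)
    s
  }, character(1))
  out
}

vnorm <- function(x) sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles (degrees) to (-180, 180]
wrap180 <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}
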
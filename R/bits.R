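#' Binary sequences
#'
#' `as_bits()` coerces its input to an `sv_bits` object: an integer vector of
#' 0s and 1s with an optional free-text `provenance` attribute recording how
#' the sequence was produced (discretization used, trend cuts applied, seed).
#' Character input is read as a string of `0`/`1` characters, so
#' `as_bits("0011")` and `as_bits(c(0, 0, 1, 1))` are equivalent.
#'
#' @param x An integer, numeric or logical vector of 0s and 1s, or a single
#'   character string over `{"0", "1"}`.
#' @param provenance Optional character scalar describing the origin of the
#'   sequence; kept as an attribute and propagated by the transformations in
#'   this package.
#' @return An `sv_bits` object (integer vector of 0s and 1s).
#' @examples
#' as_bits("00101")
#' as_bits(c(TRUE, FALSE, TRUE))
#' @export
as_bits <- function(x, provenance = NULL) {
  if (is.character(x)) {
    stopifnot("character input must be a single string" = length(x) == 1L)
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  }
  if (is.logical(x)) x <- as.integer(x)
  x <- as.integer(x)
  if (anyNA(x) || any(x != 0L & x != 1L)) {
    stop("bits must be 0 or 1 throughout", call. = FALSE)
  }
  if (is.null(provenance)) provenance <- attr(x, "provenance")
  structure(x, class = "sv_bits", provenance = provenance)
}

#' @rdname as_bits
#' @export
bits_to_string <- function(x) paste(unclass(as_bits(x)), collapse = "")

#' @export
print.sv_bits <- function(x, ...) {
  n <- length(x)
  shown <- bits_to_string(utils::head(x, 64L))
  cat("<sv_bits> n = ", n, if (n > 64L) " (first 64 shown)" else "", "\n",
    shown, if (n > 64L) "..." else "", "\n",
    sep = ""
  )
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("provenance: ", prov, "\n", sep = "")
  invisible(x)
}

#' @export
`[.sv_bits` <- function(x, ...) {
  as_bits(NextMethod(), provenance = attr(x, "provenance"))
}

#' Read and write ASCII bit strings
#'
#' Bit sequences are stored on disk as a plain ASCII string of `0`/`1`
#' characters (whitespace and line breaks ignored), the interchange format
#' used by the command-line interface.
#'
#' @param file Path to a text file.
#' @param x An object coercible by [as_bits()].
#' @return `read_bits()` returns an `sv_bits` object; `write_bits()` returns
#'   `x` invisibly.
#' @export
read_bits <- function(file) {
  txt <- paste(readLines(file, warn = FALSE), collapse = "")
  txt <- gsub("[[:space:]]", "", txt)
  if (!nzchar(txt)) stop("no bits found in ", file, call. = FALSE)
  as_bits(txt, provenance = paste0("read from ", basename(file)))
}

#' @rdname read_bits
#' @export
write_bits <- function(x, file) {
  writeLines(bits_to_string(x), file)
  invisible(x)
}

# local seed helper: leaves the caller's RNG state untouched when seed is NULL
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

word_string <- function(value, len) {
  if (len == 0L) {
    return("")
  }
  bits <- integer(len)
  for (b in seq_len(len)) {
    bits[len - b + 1L] <- value %% 2
    value <- value %/% 2
  }
  paste(bits, collapse = "")
}
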
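#' Read an annotated RR-interval file
#'
#' Reads the plain-text Holter-export format used throughout this package:
#' one or more header lines followed by four whitespace-separated columns —
#' observation number, observation time (seconds since recording start),
#' RR-interval length, and a single-letter beat annotation (`"N"` = normal;
#' other letters mark premature, supraventricular or ventricular beats,
#' missed beats and pauses). Header lines are recognised as the leading lines
#' that do not parse as a record; after the first record every non-blank line
#' must be a record.
#'
#' RR intervals are held in milliseconds internally. With `units = "auto"`
#' (the default) a file whose median RR value is below 10 is taken to be in
#' seconds and converted, since both dialects occur in Holter exports; the
#' conversion is reported via a message.
#'
#' Subject metadata (sex, age) is conventionally encoded in the file name;
#' `filename_regex` must capture sex (`F`/`M`) in its first group and age in
#' years in its second. Absent or non-matching metadata is not an error — the
#' `meta` attribute fields are simply left `NA`.
#'
#' @param file Path to the text file (or a connection).
#' @param units `"auto"`, `"ms"` or `"s"` — units of the RR column.
#' @param filename_regex Regular expression with two capture groups (sex,
#'   age) applied to the base file name.
#' @param strict_grid If `TRUE`, require every RR value to sit on the 1/128 s
#'   grid of a 128 Hz recorder (8 ms resolution approximately); violations
#'   are an error.
#' @return A tibble with columns `beat` (integer), `time_s` (numeric),
#'   `rr_ms` (numeric) and `annotation` (character), carrying a `meta`
#'   attribute (list with `sex`, `age`, `source`).
#' @seealso [write_rr()], [filter_normal()], [clean_perturbations()],
#'   [select_nocturnal_window()]
#' @export
read_rr <- function(file, units = c("auto", "ms", "s"),
                    filename_regex = "([FfMm])[-_ ]?(\\d{1,3})",
                    strict_grid = FALSE) {
  units <- match.arg(units)
  lines <- readLines(file, warn = FALSE)
  src <- if (is.character(file)) basename(file) else NA_character_

  is_record <- function(tokens) {
    length(tokens) >= 4L &&
      !anyNA(suppressWarnings(as.numeric(tokens[1:3]))) &&
      nchar(tokens[4]) == 1L
  }
  toks <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(t) t[nzchar(t)])
  rec <- vapply(toks, is_record, logical(1))
  first <- which(rec)[1]
  if (is.na(first)) {
    stop("no RR records found (header-only or empty file)", call. = FALSE)
  }
  body <- seq(first, length(lines))
  body <- body[lengths(toks[body]) > 0L] # blank lines tolerated
  bad <- body[!rec[body]]
  if (length(bad) > 0L) {
    stop("malformed RR record at line ", bad[1], ": '", lines[bad[1]], "'",
      call. = FALSE
    )
  }

  m <- do.call(rbind, toks[body])
  out <- tibble::tibble(
    beat = as.integer(as.numeric(m[, 1])),
    time_s = as.numeric(m[, 2]),
    rr_ms = as.numeric(m[, 3]),
    annotation = m[, 4]
  )
  if (units == "s" ||
    (units == "auto" && stats::median(out$rr_ms) < 10)) {
    if (units == "auto") {
      message("RR values look like seconds (median < 10); converting to ms")
    }
    out$rr_ms <- out$rr_ms * 1000
  }
  if (any(out$rr_ms <= 0)) {
    stop("non-positive RR interval at line ",
      body[which(out$rr_ms <= 0)[1]],
      call. = FALSE
    )
  }
  if (strict_grid) {
    off <- out$rr_ms / 1000 * 128
    if (any(abs(off - round(off)) > 1e-6)) {
      stop("RR values are not on the 1/128-s grid (strict_grid = TRUE)",
        call. = FALSE
      )
    }
  }

  meta <- list(sex = NA_character_, age = NA_real_, source = src)
  if (!is.na(src) && !is.null(filename_regex)) {
    g <- regmatches(src, regexec(filename_regex, src))[[1]]
    if (length(g) >= 3L) {
      meta$sex <- toupper(g[2])
      meta$age <- as.numeric(g[3])
    }
  }
  attr(out, "meta") <- meta
  out
}

#' Write an annotated RR-interval file
#'
#' Writes the four-column text format read by [read_rr()]; `read_rr()`
#' applied to the output reproduces the series exactly (numbers are printed
#' with 17 significant digits, enough to round-trip doubles).
#'
#' @param series An RR series tibble as returned by [read_rr()] or
#'   [simulate_rr_series()].
#' @param file Path or connection to write to.
#' @return `series`, invisibly.
#' @export
write_rr <- function(series, file) {
  series <- validate_rr(series, need_time = FALSE)
  header <- "beat\ttime_s\trr_ms\tannotation"
  if (nrow(series) == 0L) {
    writeLines(header, file)
    return(invisible(series))
  }
  lines <- sprintf(
    "%d\t%.17g\t%.17g\t%s",
    series$beat, series$time_s, series$rr_ms, series$annotation
  )
  writeLines(c(header, lines), file)
  invisible(series)
}

validate_rr <- function(series, need_time = TRUE, need_annotation = TRUE) {
  stopifnot(is.data.frame(series), "rr_ms" %in% names(series))
  if (!"beat" %in% names(series)) series$beat <- seq_len(nrow(series))
  if (!"time_s" %in% names(series)) {
    if (need_time) series$time_s <- cumsum(series$rr_ms) / 1000
  }
  if (!"annotation" %in% names(series) && need_annotation) {
    series$annotation <- rep("N", nrow(series))
  }
  tibble::as_tibble(series)
}

#' Keep only normal-to-normal beats
#'
#' Drops every beat whose annotation is not `"N"`, preserving order. This is
#' the light-touch preprocessing used on the cryptographic analysis path,
#' where physiological fidelity matters less than volume of data.
#'
#' @inheritParams write_rr
#' @return The filtered series (possibly empty), metadata preserved.
#' @export
filter_normal <- function(series) {
  series <- validate_rr(series, need_time = FALSE)
  meta <- attr(series, "meta")
  out <- dplyr::filter(series, .data$annotation == "N")
  attr(out, "meta") <- meta
  out
}

#' Extract the nocturnal window of a recording
#'
#' Selects the contiguous window of the stated duration with the longest RR
#' intervals, operationalized as the window maximizing the arithmetic mean RR
#' over the beats it contains (mean RR is the standard proxy for sleep
#' bradycardia). Candidate windows start at each beat and contain every beat
#' whose time lies within `window_hours` of the start; ties are broken by the
#' earliest start.
#'
#' @inheritParams write_rr
#' @param window_hours Window duration in hours (default 6, a typical
#'   nocturnal period within a 24-h Holter recording).
#' @return The sub-series inside the selected window.
#' @export
select_nocturnal_window <- function(series, window_hours = 6) {
  series <- validate_rr(series)
  n <- nrow(series)
  w <- window_hours * 3600
  if (n == 0L || series$time_s[n] - series$time_s[1] < w) {
    stop("recording shorter than the ", window_hours, "-hour window",
      call. = FALSE
    )
  }
  t <- series$time_s
  ends <- findInterval(t + w, t) # last beat with time <= start + w
  valid <- which(t + w <= t[n])
  cs <- cumsum(series$rr_ms)
  wmean <- (cs[ends[valid]] - cs[valid] + series$rr_ms[valid]) /
    (ends[valid] - valid + 1)
  a <- valid[which.max(wmean)] # which.max: earliest on ties
  out <- series[a:ends[a], ]
  attr(out, "meta") <- attr(series, "meta")
  out
}

#' Repair or delete annotation perturbations
#'
#' The manual ("medical") preprocessing path for artifacts: each maximal run
#' of consecutively non-`"N"` beats shorter than five beats is repaired by
#' replacing every RR value in the run with the median of the seven most
#' recent preceding normal RR values (re-annotated `"N"`); runs of five or
#' more beats are deleted outright. Beats repaired earlier in the sweep count
#' as normal for later medians. A short run preceded by fewer than seven
#' normals uses however many are available; with none at all it is deleted.
#'
#' @inheritParams write_rr
#' @return The cleaned series; every annotation in the output is `"N"`.
#' @export
clean_perturbations <- function(series) {
  series <- validate_rr(series, need_time = FALSE)
  meta <- attr(series, "meta")
  n <- nrow(series)
  if (n == 0L) {
    return(series)
  }
  rr <- series$rr_ms
  ann <- series$annotation
  keep <- rep(TRUE, n)
  r <- rle(ann != "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    s <- starts[k]
    e <- ends[k]
    prev <- if (s > 1L) which(keep[1:(s - 1L)]) else integer(0)
    if (r$lengths[k] < 5L && length(prev) >= 1L) {
      med <- stats::median(rr[utils::tail(prev, 7L)])
      rr[s:e] <- med
      ann[s:e] <- "N"
    } else {
      keep[s:e] <- FALSE
    }
  }
  out <- series
  out$rr_ms <- rr
  out$annotation <- ann
  out <- out[keep, ]
  attr(out, "meta") <- meta
  out
}
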
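#' Discretize an RR series into bits
#'
#' Three schemes map a preprocessed RR-interval sequence `d_1, ..., d_n`
#' (milliseconds) to a binary sequence:
#'
#' * **accel** (default): bit `0` when the interval grows or holds —
#'   `d_i >= d_{i-1} + eta1` — i.e. the heart *decelerates*; bit `1`
#'   otherwise (acceleration). Output length `n - 1`. With the default
#'   offset `eta1 = 0`, equality counts as deceleration, and the zero/one
#'   proportion stays closest to balanced.
#' * **rapid**: bit `0` when the beat-to-beat change is rapid,
#'   `|d_i - d_{i-1}| >= eta2`; bit `1` when slow. Output length `n - 1`.
#' * **monotone**: bit `0` when three consecutive intervals are monotone in
#'   either direction (non-strict), `d_i >= d_{i-1} >= d_{i-2}` or
#'   `d_i <= d_{i-1} <= d_{i-2}`; bit `1` otherwise. Output length `n - 2`.
#'
#' The first emitted bit corresponds to the second beat (third, for
#' monotone), so offsets downstream — e.g. when excising trends — are
#' reproducible.
#'
#' @param series An RR series tibble (needs an `rr_ms` column), or a bare
#'   numeric vector of RR values in ms.
#' @param method One of `"accel"`, `"rapid"`, `"monotone"`.
#' @param eta1 Offset in ms for the accel scheme (default 0).
#' @param eta2 Non-negative threshold in ms for the rapid scheme.
#' @return An [as_bits()] sequence.
#' @examples
#' discretize(c(800, 795, 805, 805, 790)) # "1010"
#' @export
discretize <- function(series, method = c("accel", "rapid", "monotone"),
                       eta1 = 0, eta2 = 0) {
  method <- match.arg(method)
  switch(method,
    accel = discretize_accel(series, eta1),
    rapid = discretize_rapid(series, eta2),
    monotone = discretize_monotone(series)
  )
}

rr_values <- function(series, min_len) {
  d <- if (is.data.frame(series)) {
    validate_rr(series, need_time = FALSE, need_annotation = FALSE)$rr_ms
  } else {
    as.numeric(series)
  }
  if (length(d) < min_len) {
    stop("need at least ", min_len, " RR intervals", call. = FALSE)
  }
  d
}

#' @rdname discretize
#' @export
discretize_accel <- function(series, eta1 = 0) {
  d <- rr_values(series, 2L)
  bits <- as.integer(!(diff(d) >= eta1))
  as_bits(bits, provenance = sprintf("accel(eta1=%g)", eta1))
}

#' @rdname discretize
#' @export
discretize_rapid <- function(series, eta2 = 0) {
  stopifnot(eta2 >= 0)
  d <- rr_values(series, 2L)
  bits <- as.integer(!(abs(diff(d)) >= eta2))
  as_bits(bits, provenance = sprintf("rapid(eta2=%g)", eta2))
}

#' @rdname discretize
#' @export
discretize_monotone <- function(series) {
  d <- rr_values(series, 3L)
  n <- length(d)
  d0 <- d[3:n]
  d1 <- d[2:(n - 1)]
  d2 <- d[1:(n - 2)]
  mono <- (d0 >= d1 & d1 >= d2) | (d0 <= d1 & d1 <= d2)
  as_bits(as.integer(!mono), provenance = "monotone")
}
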
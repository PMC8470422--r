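#' Cut periodic acceleration/deceleration trends out of a bit sequence
#'
#' Heart rate is partially periodic by construction: several consecutive
#' accelerations are sooner or later answered by several decelerations,
#' which caps the bias any SV-style bound can certify. Trend cutting
#' removes the predictable part. The sequence must use the accel coding
#' (`1` = acceleration, `0` = deceleration). Scanning left to right, the
#' procedure locates the first window of `i` consecutive 1s, then — after
#' that window — the first window of `j` consecutive 0s, deletes both
#' windows together, and resumes scanning after the deleted 0-window,
#' repeating to the end of the sequence.
#'
#' Deletion is paired and atomic: if `i` 1s are found but no `j` 0s follow
#' before the end, neither window is deleted, so the number of removed bits
#' is always a multiple of `i + j`. In a run of 1s longer than `i` the first
#' `i` bits of the run are cut; runs shorter than the required length pass
#' through unchanged. Pattern `c(0, 0)` is the reserved no-op label.
#'
#' @param bits An [as_bits()] sequence in accel coding.
#' @param pattern Integer pair `c(i, j)`: cut `i` consecutive accelerations
#'   then the next `j` consecutive decelerations. Default `c(3, 3)`, the
#'   pattern that balances bias reduction against output length on typical
#'   recordings.
#' @return The remaining bits, order preserved.
#' @examples
#' bits_to_string(cut_trends(as_bits("111000"), c(3, 3))) # ""
#' @export
cut_trends <- function(bits, pattern = c(3, 3)) {
  bits <- as_bits(bits)
  stopifnot(length(pattern) == 2L, all(pattern == floor(pattern)))
  i <- as.integer(pattern[1])
  j <- as.integer(pattern[2])
  if (i == 0L && j == 0L) {
    return(bits)
  }
  if (i < 1L || j < 1L) {
    stop("pattern must be c(0, 0) or have both entries >= 1", call. = FALSE)
  }
  n <- length(bits)
  x <- unclass(bits)
  r <- rle(x)
  nr <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- rep(TRUE, n)

  ri <- 1L
  off <- 0L # bits of run `ri` already passed over
  repeat {
    while (ri <= nr && !(r$values[ri] == 1L && r$lengths[ri] - off >= i)) {
      ri <- ri + 1L
      off <- 0L
    }
    if (ri > nr) break
    s1 <- starts[ri] + off
    rj <- ri
    offj <- off + i
    while (rj <= nr && !(r$values[rj] == 0L && r$lengths[rj] - offj >= j)) {
      rj <- rj + 1L
      offj <- 0L
    }
    if (rj > nr) break # unpaired i-run: keep it
    s0 <- starts[rj] + offj
    keep[s1:(s1 + i - 1L)] <- FALSE
    keep[s0:(s0 + j - 1L)] <- FALSE
    ri <- rj
    off <- offj + j
  }
  prov <- attr(bits, "provenance")
  as_bits(x[keep], provenance = paste0(
    if (is.null(prov)) "" else paste0(prov, " | "),
    sprintf("cut_trends(%d,%d)", i, j)
  ))
}
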
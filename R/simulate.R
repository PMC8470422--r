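#' Simulate a Santha-Vazirani source of known bias
#'
#' An epsilon-SV source emits bits whose every next-bit conditional
#' probability, given the whole past, lies within `epsilon` of 1/2:
#' `epsilon = 0` is a fair coin, `epsilon = 1/2` admits determinism. Two
#' models are provided:
#'
#' * `"iid_coin"` — independent tosses of a biased coin with
#'   `P(1) = 1/2 + epsilon`, the canonical SV source.
#' * `"markov_adversarial"` — a maximally history-correlated order-1 source:
#'   each bit repeats the previous one with probability `1/2 + epsilon`.
#'   Heart rate's acceleration/deceleration runs are persistent, so this
#'   model stresses the history-dependent estimators in a way an iid coin
#'   cannot.
#'
#' Randomness comes from R's default Mersenne-Twister generator; identical
#' `seed` and arguments give bit-identical output, and the caller's RNG
#' state is left untouched when a seed is supplied.
#'
#' @param n Number of bits.
#' @param epsilon Bias bound, in `[0, 1/2]`.
#' @param model `"iid_coin"` or `"markov_adversarial"`.
#' @param seed Optional integer seed.
#' @return An [as_bits()] sequence of length `n`.
#' @examples
#' simulate_sv_source(20, epsilon = 0.1, seed = 1)
#' @export
simulate_sv_source <- function(n, epsilon,
                               model = c("iid_coin", "markov_adversarial"),
                               seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 1)
  if (epsilon < 0 || epsilon > 0.5) {
    stop("epsilon must lie in [0, 1/2]", call. = FALSE)
  }
  bits <- with_seed_if(seed, {
    if (model == "iid_coin") {
      as.integer(stats::runif(n) < 0.5 + epsilon)
    } else {
      first <- as.integer(stats::runif(1) < 0.5)
      switch_ <- if (n > 1L) {
        as.integer(stats::runif(n - 1L) >= 0.5 + epsilon)
      } else {
        integer(0)
      }
      (first + cumsum(c(0L, switch_))) %% 2L
    }
  })
  as_bits(bits, provenance = sprintf(
    "simulate_sv_source(model=%s, epsilon=%g, n=%d%s)",
    model, epsilon, n, if (is.null(seed)) "" else paste0(", seed=", seed)
  ))
}

#' Simulate a heart-rate-like RR-interval series
#'
#' Generates an annotated RR series with the statistical features the
#' analysis pipeline consumes, without claiming physiological fidelity: a
#' baseline plus band-limited sinusoidal oscillations with beat-periods
#' drawn from the respiratory band (3-9 beats) and the vascular band
#' (9-24 beats), a slow drifting component standing in for longer-range
#' regulation, and persistent AR(1) innovation noise. A fraction
#' `artifact_rate` of beats is marked with non-`"N"` annotations
#' (premature/supraventricular/ventricular style letters) and has its RR
#' value distorted, emulating the artifacts a Holter classifier flags.
#'
#' @param n Number of beats.
#' @param baseline_ms Mean RR in milliseconds (default 900 ms, a typical
#'   resting/nocturnal adult value, about 67 bpm).
#' @param resp_band,vasc_band Period ranges, in beats, for the two
#'   oscillation bands.
#' @param resp_amp_ms,vasc_amp_ms,slow_amp_ms Amplitudes (ms) of the two
#'   band components and the slow drift; set all three to 0 for a flat
#'   series.
#' @param noise_sd_ms Stationary standard deviation of the AR(1) noise.
#' @param ar AR(1) coefficient of the noise (persistence of beat-to-beat
#'   fluctuations).
#' @param artifact_rate Probability that a beat is annotated as an artifact.
#' @param seed Optional integer seed; identical seeds give identical series.
#' @return An RR series tibble (`beat`, `time_s`, `rr_ms`, `annotation`)
#'   as produced by [read_rr()].
#' @examples
#' simulate_rr_series(10, seed = 1)
#' @export
simulate_rr_series <- function(n, baseline_ms = 900,
                               resp_band = c(3, 9), vasc_band = c(9, 24),
                               resp_amp_ms = 25, vasc_amp_ms = 15,
                               slow_amp_ms = 20,
                               noise_sd_ms = 15, ar = 0.8,
                               artifact_rate = 0.02, seed = NULL) {
  stopifnot(
    n >= 1, artifact_rate >= 0, artifact_rate < 1, noise_sd_ms >= 0,
    baseline_ms > 0
  )
  with_seed_if(seed, {
    beat <- seq_len(n)
    rr <- rep(baseline_ms, n)
    band_component <- function(band, amp, k = 2L) {
      if (amp <= 0) {
        return(0)
      }
      periods <- stats::runif(k, band[1], band[2])
      phases <- stats::runif(k, 0, 2 * pi)
      Reduce(`+`, lapply(seq_len(k), function(i) {
        amp / k * sin(2 * pi * beat / periods[i] + phases[i])
      }))
    }
    rr <- rr + band_component(resp_band, resp_amp_ms)
    rr <- rr + band_component(vasc_band, vasc_amp_ms)
    rr <- rr + band_component(c(100, 400), slow_amp_ms, k = 1L)
    if (noise_sd_ms > 0) {
      innov <- stats::rnorm(n, 0, noise_sd_ms * sqrt(1 - ar^2))
      rr <- rr + as.numeric(stats::filter(innov, ar, method = "recursive"))
    }
    annotation <- rep("N", n)
    if (artifact_rate > 0) {
      art <- which(stats::runif(n) < artifact_rate)
      if (length(art) > 0L) {
        annotation[art] <- sample(c("V", "S", "P"), length(art), replace = TRUE)
        # premature beats come short, pauses long
        rr[art] <- rr[art] * sample(c(0.5, 1.8), length(art), replace = TRUE)
      }
    }
    rr <- pmax(rr, 250)
    out <- tibble::tibble(
      beat = beat,
      time_s = cumsum(rr) / 1000,
      rr_ms = rr,
      annotation = annotation
    )
    attr(out, "meta") <- list(
      sex = NA_character_, age = NA_real_,
      source = sprintf(
        "simulate_rr_series(n=%d%s)", n,
        if (is.null(seed)) "" else paste0(", seed=", seed)
      )
    )
    out
  })
}

#' Binary De Bruijn sequence of a given order
#'
#' Returns the lexicographically least binary De Bruijn sequence of order
#' `k`: a cyclic sequence of length `2^k` in which every `k`-bit word occurs
#' exactly once (and every shorter word of length `L` occurs exactly
#' `2^(k - L)` times). Under cyclic counting these sequences satisfy the
#' epsilon-SV condition with epsilon = 0 for every history length up to
#' `k - 1`, saturating the information-theoretic bound on how long a history
#' a sequence of length `n` can support — which makes them the natural
#' validation input for the estimator. Construction is the classic
#' concatenation, in lexicographic order, of the Lyndon words whose length
#' divides `k` (the FKM algorithm).
#'
#' @param k Order (word length), a positive integer.
#' @return An [as_bits()] sequence of length `2^k`; `de_bruijn(2)` is
#'   `0011` and `de_bruijn(3)` is `00010111`.
#' @examples
#' bits_to_string(de_bruijn(3))
#' @export
de_bruijn <- function(k) {
  stopifnot(length(k) == 1L, k >= 1, k == floor(k))
  k <- as.integer(k)
  a <- integer(k + 1L)
  out <- integer(0)
  gen <- function(t, p) {
    if (t > k) {
      if (k %% p == 0L) out <<- c(out, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      gen(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= 1L) {
        a[t + 1L] <<- j
        gen(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  gen(1L, 1L)
  as_bits(out, provenance = sprintf("de_bruijn(k=%d)", k))
}
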
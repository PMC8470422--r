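#' Count overlapping binary substrings
#'
#' Counts every binary word of length 1 to `max_len` as an overlapping
#' substring of `bits`. In linear mode (the default) the end of the sequence
#' does not wrap, so a word of length `L` has `n - L + 1` candidate
#' positions; in cyclic mode windows wrapping past the end are counted too
#' (each length then has exactly `n` positions). Cyclic counting exists for
#' validating against De Bruijn sequences, whose defining property is
#' cyclic.
#'
#' Counting is done with rolling word values: the value of the length-`L`
#' window at a position is twice the length-`(L-1)` value plus the next bit,
#' so all lengths are counted in one vectorized sweep and tabulated densely.
#'
#' @param bits An [as_bits()] sequence (or anything it accepts).
#' @param max_len Longest word length to count (at most 28; the dense count
#'   table has `2^max_len` cells). Words longer than the sequence simply get
#'   count 0 in linear mode.
#' @param cyclic Count windows that wrap the end of the sequence?
#' @return A `substring_counts` object: fields `n`, `max_len`, `cyclic` and
#'   `counts`, a list whose `L`-th element is the integer count vector over
#'   all `2^L` words of length `L` in lexicographic order. Use
#'   [count_word()] to look up a word by its string.
#' @examples
#' ct <- count_substrings(as_bits("001011011"), max_len = 3)
#' count_word(ct, "01")
#' @export
count_substrings <- function(bits, max_len, cyclic = FALSE) {
  bits <- as_bits(bits)
  n <- length(bits)
  stopifnot(max_len >= 1, n >= 1)
  if (max_len > 28) {
    stop("max_len above 28 is not supported (dense count table)",
      call. = FALSE
    )
  }
  max_len <- as.integer(max_len)
  x <- as.numeric(unclass(bits))
  if (cyclic && max_len > 1L) {
    wrap <- rep_len(x, max_len - 1L)
    w <- c(x, wrap)
  } else {
    w <- x
  }
  N <- length(w)
  counts <- vector("list", max_len)
  v <- numeric(0)
  for (L in seq_len(max_len)) {
    if (L > N) {
      counts[[L]] <- integer(2^L)
      next
    }
    v <- if (L == 1L) w else v[seq_len(N - L + 1L)] * 2 + w[L:N]
    use <- if (cyclic) v[seq_len(n)] else v
    counts[[L]] <- tabulate(use + 1, nbins = 2^L)
  }
  structure(
    list(n = n, max_len = max_len, cyclic = cyclic, counts = counts),
    class = "substring_counts"
  )
}

#' @rdname count_substrings
#' @param counts A `substring_counts` object.
#' @param word A binary word as a string, e.g. `"01"`.
#' @export
count_word <- function(counts, word) {
  stopifnot(inherits(counts, "substring_counts"))
  L <- nchar(word)
  if (L < 1L || L > counts$max_len) {
    stop("word length outside the counted range", call. = FALSE)
  }
  value <- strtoi(word, base = 2L)
  if (is.na(value)) stop("not a binary word: ", word, call. = FALSE)
  counts$counts[[L]][value + 1L]
}

#' @export
print.substring_counts <- function(x, ...) {
  cat("<substring_counts> n = ", x$n, ", word lengths 1..", x$max_len,
    if (x$cyclic) ", cyclic" else ", linear", "\n",
    sep = ""
  )
  invisible(x)
}

#' Longest usable history length
#'
#' A sequence of length `n` can satisfy the epsilon-SV condition with
#' `epsilon < 1/2` at history length `h` only if every word of length
#' `h + 1` occurs, which forces `2^(h+1) <= n - (h + 1)` and hence
#' `h <= log2(n) - 1`. `max_history()` returns `floor(log2(n)) - 1`, the
#' default upper history length for [epsilon_profile()].
#'
#' @param n Sequence length, at least 2.
#' @return An integer history length (0 for `n` in 2..3).
#' @examples
#' max_history(8) # 2
#' @export
max_history <- function(n) {
  stopifnot(length(n) == 1L, n >= 2)
  k <- floor(log2(n))
  # guard against floating-point edges at exact powers of two
  while (2^(k + 1) <= n) k <- k + 1
  while (2^k > n) k <- k - 1
  as.integer(k - 1)
}

#' Worst-case conditional bias at one history length
#'
#' Estimates `epsilon_h`, the largest deviation from 1/2 of any next-bit
#' frequency conditioned on an `h`-bit history, from overlapping substring
#' counts. Two denominator conventions are provided:
#'
#' * `"conditional"` (default): the frequency of word `u = (prefix, b)` is
#'   `count(u) / (count(prefix 0) + count(prefix 1))` — the denominator
#'   counts only prefix occurrences that admit a following bit, so the two
#'   conditional frequencies of each history sum to exactly 1 and the
#'   estimate is guaranteed to lie in `[0, 1/2]`. For `h = 0` the empty
#'   prefix has `n` extendable occurrences.
#' * `"literal"`: plain relative frequencies with the lengths' own position
#'   counts, `(count(u)/(n-h)) / (count(prefix)/(n-h+1))` in linear mode
#'   (the empty word occurring `n + 1` times); this differs from the
#'   conditional convention only at order `1/n` but is not confined to
#'   `[0, 1/2]`.
#'
#' Histories that never occur carry no evidence and are skipped in the
#' maximum; if *no* word of length `h + 1` occurs at all the estimate is
#' undefined and an error is raised.
#'
#' @param counts A `substring_counts` object with `max_len >= h + 1`.
#' @param h History length (number of conditioning bits), `>= 0`.
#' @param mode `"conditional"` or `"literal"`.
#' @return The estimate, a number, with the maximizing word attached as
#'   attribute `argmax_word` for diagnostics.
#' @examples
#' ct <- count_substrings(de_bruijn(3), max_len = 3, cyclic = TRUE)
#' epsilon_h(ct, 2) # 0: De Bruijn sequences are ideal up to order k - 1
#' @export
epsilon_h <- function(counts, h, mode = c("conditional", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "substring_counts"), h >= 0)
  h <- as.integer(h)
  if (counts$max_len < h + 1L) {
    stop("counts only cover words up to length ", counts$max_len,
      "; need ", h + 1L,
      call. = FALSE
    )
  }
  n <- counts$n
  num <- as.numeric(counts$counts[[h + 1L]])
  if (mode == "conditional") {
    ext <- .colSums(num, 2L, 2^h) # count(prefix 0) + count(prefix 1)
    denom <- rep(ext, each = 2L)
    valid <- denom > 0
    if (!any(valid)) {
      stop("no history of length ", h, " occurs; estimate undefined",
        call. = FALSE
      )
    }
    dev <- abs(num[valid] / denom[valid] - 0.5)
  } else {
    pre <- if (h == 0L) {
      if (counts$cyclic) n else n + 1
    } else {
      as.numeric(counts$counts[[h]])
    }
    num_pos <- if (counts$cyclic) n else n - h
    den_pos <- if (counts$cyclic) n else n - h + 1
    denom <- rep(pre, each = 2L) / den_pos
    valid <- denom > 0
    if (!any(valid)) {
      stop("no history of length ", h, " occurs; estimate undefined",
        call. = FALSE
      )
    }
    dev <- (num[valid] / num_pos) / denom[valid] - 0.5
  }
  best <- which.max(dev)
  word <- word_string(which(valid)[best] - 1L, h + 1L)
  structure(max(dev), argmax_word = word)
}

#' Epsilon profile of a binary sequence
#'
#' Runs the full estimator: counts overlapping substrings once, computes the
#' worst-case conditional bias [epsilon_h()] for every history length
#' `h = 0, ..., h_max`, and attributes a single epsilon to the sequence by
#' the harmonic-weighted average of [weighted_epsilon()], which down-weights
#' long histories whose occurrence counts carry little statistical support.
#'
#' @param bits An [as_bits()] sequence of length at least 2.
#' @param h_max Largest history length; defaults to [max_history()] of the
#'   sequence length, the longest history the sequence can support.
#' @param mode Denominator convention, see [epsilon_h()].
#' @param cyclic Use cyclic substring counting (De Bruijn validation).
#' @return An object of class `epsilon_profile` with fields `epsilons`
#'   (named numeric, `h0` ... ), `argmax_words`, `h_max`, `n`, `mode`,
#'   `cyclic`, `weighted` and `provenance`. Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#' @examples
#' epsilon_profile(simulate_sv_source(4096, 0.1, seed = 1))
#' @export
epsilon_profile <- function(bits, h_max = NULL,
                            mode = c("conditional", "literal"),
                            cyclic = FALSE) {
  mode <- match.arg(mode)
  bits <- as_bits(bits)
  n <- length(bits)
  stopifnot(n >= 2)
  if (is.null(h_max)) h_max <- max_history(n)
  h_max <- as.integer(h_max)
  stopifnot(h_max >= 0)
  counts <- count_substrings(bits, max_len = h_max + 1L, cyclic = cyclic)
  hs <- 0:h_max
  est <- lapply(hs, function(h) epsilon_h(counts, h, mode = mode))
  eps <- vapply(est, as.numeric, numeric(1))
  names(eps) <- paste0("h", hs)
  words <- vapply(est, attr, character(1), "argmax_word")
  structure(
    list(
      epsilons = eps,
      argmax_words = words,
      h_max = h_max,
      n = n,
      mode = mode,
      cyclic = cyclic,
      weighted = weighted_epsilon(eps),
      provenance = attr(bits, "provenance")
    ),
    class = "epsilon_profile"
  )
}

#' Harmonic-weighted aggregate epsilon
#'
#' Collapses the per-history estimates into the single epsilon attributed to
#' a sequence: a weighted average with weight `1/(h + 1)` on history length
#' `h`, normalized by the harmonic partial sum `w(h_max) = sum 1/(i+1)`.
#' Longer histories occur fewer times in a finite sequence, so their
#' estimates get proportionally less say. Being a convex combination, the
#' result always lies between the smallest and largest per-history estimate.
#'
#' @param profile An `epsilon_profile`, or a bare numeric vector of
#'   per-history estimates for `h = 0, 1, ...` in order.
#' @return A single number.
#' @examples
#' weighted_epsilon(c(0.3, 0)) # (0.3/1 + 0/2) / (1 + 1/2) = 0.2
#' @export
weighted_epsilon <- function(profile) {
  eps <- if (inherits(profile, "epsilon_profile")) profile$epsilons else profile
  eps <- as.numeric(eps)
  if (length(eps) == 0L || anyNA(eps)) {
    stop("need a complete vector of per-history estimates", call. = FALSE)
  }
  wts <- 1 / seq_along(eps) # 1/(h+1) for h = 0, 1, ...
  sum(eps * wts) / sum(wts)
}

#' @export
print.epsilon_profile <- function(x, digits = 5, ...) {
  cat("<epsilon_profile> n = ", x$n, ", mode = ", x$mode,
    if (x$cyclic) ", cyclic" else "", "\n",
    sep = ""
  )
  print(round(x$epsilons, digits))
  cat("weighted epsilon: ", format(x$weighted, digits = digits), "\n", sep = "")
  invisible(x)
}
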
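# Independent string-based oracles: substring tallies via substr() scans,
# deliberately sharing no code with the rolling-value counter in the package.

naive_count_word <- function(bits, word, cyclic = FALSE) {
  s <- bits_to_string(bits)
  n <- nchar(s)
  L <- nchar(word)
  if (cyclic) {
    s <- paste0(s, substr(s, 1, L - 1))
    last <- n
  } else {
    last <- n - L + 1
  }
  if (last < 1) {
    return(0L)
  }
  sum(vapply(
    seq_len(last),
    function(p) substr(s, p, p + L - 1) == word, logical(1)
  ))
}

# conditional-mode worst-case bias by direct tally over every history
naive_epsilon_h <- function(bits, h, cyclic = FALSE) {
  s <- bits_to_string(bits)
  n <- nchar(s)
  ext <- if (cyclic) paste0(s, substr(s, 1, h)) else s
  last <- if (cyclic) n else n - h
  stopifnot(last >= 1)
  words <- vapply(seq_len(last), function(p) substr(ext, p, p + h), character(1))
  tab <- table(words)
  prefixes <- substr(names(tab), 1, h)
  best <- 0
  for (pre in unique(prefixes)) {
    tot <- sum(tab[prefixes == pre])
    p1 <- sum(tab[prefixes == pre & substr(names(tab), h + 1, h + 1) == "1"])
    best <- max(best, abs(p1 / tot - 0.5))
  }
  best
}

random_bits <- function(n) as_bits(sample(0:1, n, replace = TRUE))

write_rr_fixture <- function(lines, file = withr::local_tempfile(
                               fileext = ".txt",
                               .local_envir = parent.frame()
                             )) {
  writeLines(lines, file)
  file
}

make_series <- function(rr, annotation = rep("N", length(rr))) {
  tibble::tibble(
    beat = seq_along(rr),
    time_s = cumsum(rr) / 1000,
    rr_ms = rr,
    annotation = annotation
  )
}
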
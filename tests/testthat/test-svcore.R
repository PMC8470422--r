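test_that("overlapping substring counts match direct string scans", {
  ct <- count_substrings(as_bits("001011011"), max_len = 3)
  expect_equal(count_word(ct, "0"), 4)
  expect_equal(count_word(ct, "1"), 5)
  expect_equal(count_word(ct, "00"), 1)
  expect_equal(count_word(ct, "01"), 3)
  expect_equal(count_word(ct, "10"), 2)
  expect_equal(count_word(ct, "11"), 2)
  expect_equal(count_word(ct, "000"), 0)
})

test_that("cyclic counting includes windows wrapping the end", {
  ct <- count_substrings(as_bits("0011"), max_len = 2, cyclic = TRUE)
  expect_equal(count_word(ct, "10"), 1) # only via the wrap
  expect_equal(count_word(ct, "01"), 1)
  lin <- count_substrings(as_bits("0011"), max_len = 2)
  expect_equal(count_word(lin, "10"), 0)
})

test_that("count conservation holds at every length, both boundary modes", {
  withr::with_seed(1, {
    for (trial in 1:10) {
      b <- random_bits(sample(20:200, 1))
      n <- length(b)
      for (cyc in c(FALSE, TRUE)) {
        ct <- count_substrings(b, max_len = 5, cyclic = cyc)
        for (L in 1:5) {
          expect_equal(sum(ct$counts[[L]]), if (cyc) n else n - L + 1)
        }
        # completion identity: count(w0) + count(w1) = extendable prefixes
        for (w in c("0", "1", "01", "10", "110")) {
          ext <- count_word(ct, paste0(w, "0")) + count_word(ct, paste0(w, "1"))
          expected <- if (cyc) {
            naive_count_word(b, w, cyclic = TRUE)
          } else {
            # occurrences among the first n - |w| positions
            sum(vapply(seq_len(n - nchar(w)), function(p) {
              bits_to_string(b[p:(p + nchar(w) - 1)]) == w
            }, logical(1)))
          }
          expect_equal(ext, expected)
        }
      }
    }
  })
})

test_that("words longer than the sequence get count zero in linear mode", {
  ct <- count_substrings(as_bits("01"), max_len = 4)
  expect_equal(sum(ct$counts[[3]]), 0)
  expect_equal(sum(ct$counts[[4]]), 0)
})

test_that("max_history is floor(log2 n) - 1 with exact power-of-two edges", {
  expect_equal(max_history(8), 2)
  expect_equal(max_history(4), 1)
  expect_equal(max_history(24447658), 23)
  expect_equal(max_history(2^20), 19)
  expect_equal(max_history(2^20 - 1), 18)
  expect_error(max_history(1))
})

test_that("epsilon_h hand-checks: ideal, deterministic, literal normalization", {
  ct <- count_substrings(as_bits("0011"), max_len = 1, cyclic = TRUE)
  expect_equal(as.numeric(epsilon_h(ct, 0)), 0)

  ones <- count_substrings(as_bits(rep(1L, 50)), max_len = 1)
  e <- epsilon_h(ones, 0)
  expect_equal(as.numeric(e), 0.5)
  # both completions deviate by 1/2; either may be reported
  expect_true(attr(e, "argmax_word") %in% c("0", "1"))

  # literal mode on "0011", h = 1: max_u (c(u)/(n-1)) / (c(prefix)/n) - 1/2
  # = (1/3)/(2/4) - 1/2 = 1/6
  lit <- count_substrings(as_bits("0011"), max_len = 2)
  expect_equal(as.numeric(epsilon_h(lit, 1, mode = "literal")), 1 / 6)
  # conditional mode sees the deterministic 1 -> 1 continuation
  expect_equal(as.numeric(epsilon_h(lit, 1)), 0.5)
})

test_that("conditional epsilon_h equals the brute-force history tally", {
  withr::with_seed(2, {
    b <- random_bits(12)
    ct <- count_substrings(b, max_len = 3)
    expect_equal(as.numeric(epsilon_h(ct, 2)), naive_epsilon_h(b, 2))
  })
})

test_that("literal and conditional modes agree to O(1/n)", {
  b <- simulate_sv_source(50000, 0.1, seed = 3)
  ct <- count_substrings(b, max_len = 4)
  for (h in 0:3) {
    expect_lt(
      abs(
        as.numeric(epsilon_h(ct, h)) -
          as.numeric(epsilon_h(ct, h, mode = "literal"))
      ),
      100 / length(b)
    )
  }
})

test_that("histories with no extendable occurrence are skipped or error", {
  # "000": at h = 1 the history "1" never occurs; only "0" contributes
  ct <- count_substrings(as_bits("000"), max_len = 4)
  expect_equal(as.numeric(epsilon_h(ct, 1)), 0.5)
  # at h = 3 no word of length 4 exists in a 3-bit sequence
  expect_error(epsilon_h(ct, 3), "undefined")
  expect_error(epsilon_h(ct, 9), "counts only cover")
})

test_that("De Bruijn sequences are ideal up to k-1 and deterministic at k", {
  db <- de_bruijn(3)
  prof <- epsilon_profile(db, h_max = 2, cyclic = TRUE)
  expect_equal(unname(prof$epsilons), c(0, 0, 0))
  expect_equal(prof$weighted, 0)
  ct <- count_substrings(db, max_len = 4, cyclic = TRUE)
  expect_equal(as.numeric(epsilon_h(ct, 3)), 0.5)
})

test_that("eventually periodic sequences reach the deterministic limit", {
  per <- as_bits(rep_len(c(0L, 1L), 400))
  prof <- epsilon_profile(per, h_max = 5)
  for (h in 2:5) {
    expect_equal(prof$epsilons[[paste0("h", h)]], 0.5)
  }
})

test_that("profile defaults to the Lemma-style history bound and shrinks with n", {
  b <- random_bits(4096)
  prof <- epsilon_profile(b)
  expect_equal(prof$h_max, max_history(4096)) # 11
  half <- epsilon_profile(b[seq_len(2048)])
  expect_equal(half$h_max, prof$h_max - 1)
})

test_that("weighted epsilon is the harmonic-weighted convex combination", {
  expect_equal(weighted_epsilon(c(0.2, 0.2, 0.2)), 0.2)
  expect_equal(weighted_epsilon(c(0.3, 0)), 0.2)
  withr::with_seed(4, {
    for (trial in 1:20) {
      eps <- runif(sample(1:8, 1), 0, 0.5)
      w <- weighted_epsilon(eps)
      expect_gte(w, min(eps))
      expect_lte(w, max(eps))
    }
  })
  expect_error(weighted_epsilon(numeric(0)))
  b <- random_bits(512)
  prof <- epsilon_profile(b)
  expect_equal(prof$weighted, weighted_epsilon(prof$epsilons))
})

test_that("iid-coin bias is recovered at every well-populated history", {
  n <- 2e5
  eps <- 0.1
  b <- simulate_sv_source(n, eps, seed = 6)
  ct <- count_substrings(b, max_len = 5)
  for (h in 0:4) {
    num <- ct$counts[[h + 1]]
    ext <- colSums(matrix(num, nrow = 2))
    if (all(ext >= 1000)) {
      sigma <- sqrt(0.6 * 0.4 / min(ext))
      expect_lte(abs(as.numeric(epsilon_h(ct, h)) - eps), 3 * sigma)
    }
  }
})
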
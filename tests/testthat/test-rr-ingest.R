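test_that("parser reads header + four-column records and filename metadata", {
  f <- write_rr_fixture(
    c(
      "RR export, subject F-63, 128 Hz",
      "beat time rr ann",
      "1 0.500 800 N",
      "2 1.300 810 N",
      "3 2.110 420 V"
    ),
    file = file.path(withr::local_tempdir(), "F63_0930.txt")
  )
  rr <- read_rr(f)
  expect_equal(nrow(rr), 3)
  expect_equal(rr$rr_ms, c(800, 810, 420))
  expect_equal(rr$annotation, c("N", "N", "V"))
  meta <- attr(rr, "meta")
  expect_equal(meta$sex, "F")
  expect_equal(meta$age, 63)
})

test_that("header-only and malformed files are rejected with line numbers", {
  f <- write_rr_fixture(c("header line", "another header"))
  expect_error(read_rr(f), "no RR records")
  f2 <- write_rr_fixture(c("hdr", "1 0.5 800 N", "2 oops 810 N"))
  expect_error(read_rr(f2), "line 3")
})

test_that("second-dialect RR values in seconds are converted to ms", {
  f <- write_rr_fixture(c("hdr", "1 0.8 0.800 N", "2 1.6 0.810 N"))
  expect_message(rr <- read_rr(f), "seconds")
  expect_equal(rr$rr_ms, c(800, 810))
})

test_that("strict 1/128-s grid mode flags off-grid values", {
  on_grid <- round(c(800, 810) * 0.128) / 0.128 # exact multiples of 1000/128
  f <- write_rr_fixture(c("hdr", sprintf("%d 0 %.10f N", 1:2, on_grid)))
  expect_silent(read_rr(f, strict_grid = TRUE, filename_regex = NULL))
  f2 <- write_rr_fixture(c("hdr", "1 0 800.3 N", "2 0 810 N"))
  expect_error(read_rr(f2, strict_grid = TRUE), "grid")
})

test_that("write_rr / read_rr round-trips, including at scale", {
  for (n in c(0L, 1000L, 20000L)) {
    s <- simulate_rr_series(max(n, 1), seed = n + 1)[seq_len(n), ]
    f <- withr::local_tempfile(fileext = ".txt")
    write_rr(s, f)
    if (n == 0L) {
      expect_error(read_rr(f), "no RR records")
    } else {
      back <- read_rr(f, filename_regex = NULL)
      expect_equal(back$beat, s$beat)
      expect_equal(back$time_s, s$time_s)
      expect_equal(back$rr_ms, s$rr_ms)
      expect_equal(back$annotation, s$annotation)
    }
  }
})

test_that("filter_normal keeps exactly the N beats, in order", {
  s <- make_series(c(800, 810, 820, 830), c("N", "V", "N", "N"))
  out <- filter_normal(s)
  expect_equal(nrow(out), 3)
  expect_equal(out$rr_ms, c(800, 820, 830))
  all_n <- make_series(c(800, 810))
  expect_equal(filter_normal(all_n), all_n)

  # length conservation at a 5% artifact rate, binomial 99% interval
  s <- simulate_rr_series(10000, artifact_rate = 0.05, seed = 7)
  kept <- nrow(filter_normal(s))
  expect_equal(kept, 10000 - sum(s$annotation != "N"))
  expect_gte(kept, qbinom(0.005, 10000, 0.95))
  expect_lte(kept, qbinom(0.995, 10000, 0.95))
})

test_that("nocturnal window maximizes mean RR, earliest start on ties", {
  # ~10 h at 600 ms except a plateau at 1000 ms just over 6 h long, so a
  # window of pure plateau beats exists and is the unique mean maximizer
  rr <- rep(600, 60000)
  rr[20001:41700] <- 1000
  s <- make_series(rr)
  win <- select_nocturnal_window(s, 6)
  expect_equal(win$beat[1], 20001)
  expect_true(all(win$rr_ms == 1000))
  expect_lte(max(win$time_s) - min(win$time_s), 6 * 3600)

  flat <- make_series(rep(900, 30000))
  expect_equal(select_nocturnal_window(flat, 6)$beat[1], 1)

  expect_error(select_nocturnal_window(make_series(rep(800, 100)), 6), "shorter")
})

test_that("nocturnal window recovers a planted night segment", {
  hits <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 45000 # ~10 h at ~800 ms
      day <- 750 + rnorm(n, 0, 20)
      night_idx <- 15000:42000
      day[night_idx] <- day[night_idx] * 1.2
      win <- select_nocturnal_window(make_series(day), 6)
      mean(win$beat %in% night_idx)
    })
  }, numeric(1))
  expect_gte(mean(hits > 0.95), 0.95)
})

test_that("short perturbation runs are repaired with the 7-normal median", {
  rr <- c(rep(800, 5), 810, 820, 500, 501, rep(790, 3))
  ann <- c(rep("N", 7), "V", "V", rep("N", 3))
  out <- clean_perturbations(make_series(rr, ann))
  expect_equal(nrow(out), 12)
  # median(800, 800, 800, 800, 800, 810, 820) = 800
  expect_equal(out$rr_ms[8:9], c(800, 800))
  expect_true(all(out$annotation == "N"))
})

test_that("perturbation runs of five or more are deleted", {
  rr <- c(rep(800, 7), rep(400, 5), rep(790, 3))
  ann <- c(rep("N", 7), rep("V", 5), rep("N", 3))
  out <- clean_perturbations(make_series(rr, ann))
  expect_equal(nrow(out), 10)
  expect_true(all(out$annotation == "N"))
})

test_that("clean_perturbations edge cases: identity, few/no preceding normals", {
  s <- make_series(rep(800, 20))
  expect_equal(clean_perturbations(s), s)

  # run at the very start with zero preceding normals is deleted
  s0 <- make_series(c(400, 400, rep(800, 6)), c("V", "V", rep("N", 6)))
  expect_equal(nrow(clean_perturbations(s0)), 6)

  # run preceded by fewer than 7 normals uses what is available
  s1 <- make_series(c(700, 720, 400, rep(800, 5)), c("N", "N", "V", rep("N", 5)))
  out <- clean_perturbations(s1)
  expect_equal(out$rr_ms[3], 710) # median of 700, 720
})

test_that("repaired beats count as normal for later medians", {
  rr <- c(rep(600, 7), 400, rep(600, 6), 400, rep(600, 2))
  ann <- rep("N", length(rr))
  ann[c(8, 15)] <- "V"
  out <- clean_perturbations(make_series(rr, ann))
  expect_equal(out$rr_ms[8], 600)
  expect_equal(out$rr_ms[15], 600) # window includes the repaired beat 8
  expect_true(all(out$annotation == "N"))
})
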
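#' Truncate a cohort of bit sequences to a common length
#'
#' Different people yield different numbers of valid beats, so their binary
#' sequences differ in length — in real cohorts by up to a factor of two —
#' which could bias between-person epsilon comparisons. This utility
#' truncates every sequence (by removing bits from the end) to the cohort
#' minimum length.
#'
#' @param cohort A non-empty list of [as_bits()] sequences.
#' @return A list of sequences, all of the minimum original length.
#' @export
trim_to_common_length <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  cohort <- lapply(cohort, as_bits)
  m <- min(lengths(cohort))
  lapply(cohort, function(b) b[seq_len(m)])
}

#' Concatenate per-person bit sequences into one merged sequence
#'
#' Joins sequences in list order, as when pooling many short recordings to
#' emulate one long one. Words spanning the joins are counted as-is by
#' downstream estimators.
#'
#' @param cohort A list of [as_bits()] sequences.
#' @return One [as_bits()] sequence.
#' @export
merge_sequences <- function(cohort) {
  as_bits(
    unlist(lapply(cohort, unclass)),
    provenance = sprintf("merged %d sequences", length(cohort))
  )
}

#' Compare trend-cut patterns on one sequence
#'
#' For each pattern `(i, j)` this computes the four quantities of the
#' standard trend-pattern comparison: the output size `m` after
#' [cut_trends()], the weighted epsilon of the *uncut control* (the first
#' `m` bits of the original sequence, so both estimates see the same amount
#' of data), the weighted epsilon of the cut sequence, and their
#' difference. A positive difference means cutting trends genuinely lowered
#' the certified bias rather than merely shortening the data. Pattern
#' `c(0, 0)` labels the no-cut row: `m = n` and the cut columns are `NA`.
#'
#' @param bits An [as_bits()] sequence in accel coding.
#' @param patterns A list of integer pairs; default `(0,0), (2,2) ... (6,6)`.
#' @param mode Estimator mode passed to [epsilon_profile()].
#' @return A tibble with columns `pattern_i`, `pattern_j`, `m`, `epsilon`,
#'   `epsilon_cut`, `delta`.
#' @export
compare_trend_patterns <- function(bits,
                                   patterns = lapply(c(0, 2:6), function(i) c(i, i)),
                                   mode = "conditional") {
  bits <- as_bits(bits)
  n <- length(bits)
  purrr::map_dfr(patterns, function(p) {
    if (p[1] == 0L && p[2] == 0L) {
      return(tibble::tibble(
        pattern_i = 0L, pattern_j = 0L, m = n,
        epsilon = epsilon_profile(bits, mode = mode)$weighted,
        epsilon_cut = NA_real_, delta = NA_real_
      ))
    }
    cut <- cut_trends(bits, p)
    m <- length(cut)
    if (m < 2L) stop("pattern (", p[1], ",", p[2], ") leaves fewer than 2 bits")
    eps_ctl <- epsilon_profile(bits[seq_len(m)], mode = mode)$weighted
    eps_cut <- epsilon_profile(cut, mode = mode)$weighted
    tibble::tibble(
      pattern_i = as.integer(p[1]), pattern_j = as.integer(p[2]),
      m = m, epsilon = eps_ctl, epsilon_cut = eps_cut,
      delta = eps_ctl - eps_cut
    )
  })
}

#' Per-person epsilon under the four processing methods
#'
#' Runs the full analysis for every person in a cohort and returns one row
#' per person with the weighted epsilon under each requested method:
#'
#' * `full` — all `"N"`-annotated beats, discretized, estimated as-is;
#' * `trim` — the `full` bit sequences truncated to the cohort minimum
#'   length (see [trim_to_common_length()]);
#' * `cut` — the `full` sequence after [cut_trends()] with `pattern`;
#' * `med` — the manual-preprocessing path: nocturnal window extraction
#'   ([select_nocturnal_window()]) followed by perturbation repair
#'   ([clean_perturbations()]), then discretization.
#'
#' @param cohort A tibble with columns `person_id`, `sex`, `age` and a
#'   list-column `series` of RR series tibbles (as from [read_rr()] or
#'   [simulate_rr_series()]).
#' @param methods Subset of `c("full", "trim", "cut", "med")`.
#' @param pattern Trend-cut pattern for the `cut` method.
#' @param window_hours Nocturnal window length for the `med` method.
#' @param mode Estimator mode passed to [epsilon_profile()].
#' @param discretization,eta1,eta2 Discretization scheme and parameters,
#'   see [discretize()].
#' @return A tibble with `person_id`, `sex`, `age` and, per method, columns
#'   `n_<method>` (bits) and `eps_<method>` (weighted epsilon).
#' @export
cohort_epsilons <- function(cohort,
                            methods = c("full", "trim", "cut", "med"),
                            pattern = c(3, 3), window_hours = 6,
                            mode = "conditional",
                            discretization = "accel", eta1 = 0, eta2 = 0) {
  stopifnot(
    is.data.frame(cohort),
    all(c("person_id", "sex", "age", "series") %in% names(cohort))
  )
  methods <- match.arg(methods, several.ok = TRUE)
  disc <- function(s) discretize(s, discretization, eta1 = eta1, eta2 = eta2)
  full_bits <- lapply(cohort$series, function(s) disc(filter_normal(s)))

  out <- tibble::tibble(
    person_id = cohort$person_id,
    sex = cohort$sex,
    age = cohort$age
  )
  wep <- function(b) epsilon_profile(b, mode = mode)$weighted
  if ("full" %in% methods) {
    out$n_full <- lengths(full_bits)
    out$eps_full <- vapply(full_bits, wep, numeric(1))
  }
  if ("trim" %in% methods) {
    trimmed <- trim_to_common_length(full_bits)
    out$n_trim <- lengths(trimmed)
    out$eps_trim <- vapply(trimmed, wep, numeric(1))
  }
  if ("cut" %in% methods) {
    cuts <- lapply(full_bits, cut_trends, pattern = pattern)
    out$n_cut <- lengths(cuts)
    out$eps_cut <- vapply(cuts, wep, numeric(1))
  }
  if ("med" %in% methods) {
    med_bits <- lapply(cohort$series, function(s) {
      disc(clean_perturbations(select_nocturnal_window(s, window_hours)))
    })
    out$n_med <- lengths(med_bits)
    out$eps_med <- vapply(med_bits, wep, numeric(1))
  }
  out
}

#' Five-number epsilon summaries by sex and age decade
#'
#' Groups a cohort table by sex and ten-year age bins `[10j, 10(j+1))` and
#' returns, per group, the five-number summary (minimum, quartiles,
#' maximum) of the chosen method's weighted epsilon plus the group mean and
#' size. Ages outside 10-89 are folded into the nearest decade bin with a
#' message.
#'
#' @param records A tibble with `sex`, `age` and an `eps_<method>` column,
#'   as returned by [cohort_epsilons()] (a bare `epsilon` column also
#'   works).
#' @param method One of `"full"`, `"trim"`, `"cut"`, `"med"` — selects the
#'   `eps_<method>` column.
#' @return A tibble with one row per (sex, decade) group: `sex`, `decade`,
#'   `q0` ... `q4`, `mean`, `n`. Quartiles are `stats::quantile()` type 7.
#' @export
summarize_groups <- function(records, method = "full") {
  col <- paste0("eps_", method)
  if (!col %in% names(records) && "epsilon" %in% names(records)) {
    col <- "epsilon"
  }
  stopifnot(is.data.frame(records), col %in% names(records))
  dec <- floor(records$age / 10)
  outside <- dec < 1 | dec > 8
  if (any(outside)) {
    message(
      sum(outside), " record(s) with age outside 10-89 folded into the ",
      "nearest decade bin"
    )
    dec <- pmin(pmax(dec, 1), 8)
  }
  records$decade <- as.integer(dec * 10)
  records$.eps <- records[[col]]
  records |>
    dplyr::group_by(.data$sex, .data$decade) |>
    dplyr::summarise(
      q0 = min(.data$.eps),
      q1 = unname(stats::quantile(.data$.eps, 0.25)),
      q2 = unname(stats::quantile(.data$.eps, 0.5)),
      q3 = unname(stats::quantile(.data$.eps, 0.75)),
      q4 = max(.data$.eps),
      mean = mean(.data$.eps),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$sex, .data$decade)
}
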
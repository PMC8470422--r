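---
title: "Estimating Santha-Vazirani epsilon from heart-rate interval series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Santha-Vazirani epsilon from heart-rate interval series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrand)
```

## The model

A binary source $S = (S_1, S_2, \dots)$ is an $\varepsilon$-Santha-Vazirani
($\varepsilon$-SV) source if every next-bit conditional probability, given
the entire past and any side information $E$ available before the source
started, stays within $\varepsilon$ of a fair coin:

$$\tfrac12 - \varepsilon \;\le\; P(S_{i+1} \mid S_i, \dots, S_1, E) \;\le\;
\tfrac12 + \varepsilon .$$

$\varepsilon = 0$ is uniform randomness; $\varepsilon = \tfrac12$ admits a
fully deterministic source. The interest of the model is that an
$\varepsilon$-SV source with $\varepsilon < \tfrac12$ can be amplified to
near-uniform private randomness by quantum device-independent protocols, so
a *certified upper estimate of $\varepsilon$* is the quantity that matters —
not a pass/fail verdict from a classical randomness test suite. The heart is
an attractive candidate source: every human carries one, it is hard for an
adversary to predict or replace, and its beat-to-beat variability is partly
stochastic. This package estimates $\varepsilon$ for such a source from a
finite realization.

## From heartbeats to bits

The raw input is an annotated RR-interval recording: for each beat, an
ordinal, the elapsed time, the RR interval $d_i$ (the time between two
consecutive normal ventricular contractions), and a one-letter annotation
from the Holter classifier, `"N"` marking normal-to-normal beats.
`read_rr()` parses the four-column text export; RR values are kept in
milliseconds (files in seconds are detected by magnitude and converted —
both dialects occur in practice).

Two preprocessing paths are supported:

* **Cryptographic**: `filter_normal()` simply drops every non-`"N"` beat.
  This has little physiological meaning but is the only preprocessing
  available in an unattended application, where no expert will clean the
  signal before its randomness is amplified.
* **Manual/medical**: `select_nocturnal_window()` extracts the six-hour
  stretch with the longest RR intervals (sleep is the quietest, least
  brain-driven part of the record), then `clean_perturbations()` repairs
  artifact runs shorter than five beats by the median of the seven most
  recent normal intervals and deletes longer runs.

Three discretizations map $\{d_i\}$ to bits (`discretize()`):

* `accel`: $s_i = 0$ if $d_i \ge d_{i-1} + \eta_1$ (deceleration), else 1.
* `rapid`: $s_i = 0$ if $|d_i - d_{i-1}| \ge \eta_2$, else 1.
* `monotone`: $s_i = 0$ if three consecutive intervals are monotone in
  either direction (non-strict), else 1.

The default is `accel` with $\eta_1 = 0$: any non-zero offset pushes the
zero/one proportion far from balance, while at $\eta_1 = 0$ the coding is
closest to symmetric. Ties $d_i = d_{i-1}$ fall to the $\ge$ branch (bit 0)
by the rule itself; no extra tie parameter exists. The first emitted bit
corresponds to the second beat (third for `monotone`), so positions in the
bit sequence can be traced back to beats.

## Cutting out trends

Heart rate is partially periodic by construction: several consecutive
accelerations must sooner or later be answered by decelerations. A genuine
$\varepsilon$-SV source with $\varepsilon < \tfrac12$ assigns probability
$(\tfrac12-\varepsilon)^n > 0$ to *every* $n$-bit pattern, so an arbitrarily
long run of accelerations must be possible — which the physiology forbids.
`cut_trends()` removes the predictable component: scanning left to right it
finds the first window of $i$ consecutive 1s (accelerations), then the first
window of $j$ consecutive 0s after it, deletes the two windows together, and
resumes after the deleted 0-window.

Three details of this procedure were genuinely open and are fixed here as
package choices:

* **Paired, atomic deletion.** An $i$-run found without a completing
  $j$-run before the end of the sequence is kept. This makes each deletion
  remove exactly $i + j$ bits, so the removed total is always a multiple of
  $i + j$ — the cycle is treated as one unit.
* **Over-long runs.** A run of more than $i$ ones loses its *first* $i$
  bits (the scan matches the first qualifying window); the remainder passes
  through.
* **Single pass.** After a deletion the scan resumes at the character
  following the removed $j$-window; bits that become adjacent across a
  deletion are not re-examined, so the procedure is deliberately not
  idempotent.

Patterns with $i \ne j$ are supported, but the symmetric patterns
$(i,i)$, $i \in \{3,\dots,6\}$, are the practically useful ones, and
$(3, 3)$ is the default: larger patterns remove progressively fewer bits on
persistent sources (they match less often), while $(2, 2)$ cuts so
aggressively that it can *raise* the estimated bias. `compare_trend_patterns()`
produces the four-row comparison — output size $m$, the epsilon of the
first-$m$-bits uncut control, the epsilon of the cut sequence, and their
difference — that motivates the choice on any given data set.

## The estimator

For history length $h$, the worst-case conditional bias is estimated from
overlapping substring frequencies. Writing $|s|_w$ for the number of
(overlapping) occurrences of word $w$ in $s$,

$$\tilde\varepsilon_h \;=\; \max_{u \,=\, (w, b),\; |u| = h+1}
\left|\; \frac{|s|_{u}}{|s|_{w0} + |s|_{w1}} \;-\; \frac12 \;\right| ,$$

i.e. the frequency of each continuation bit $b$ conditioned on each $h$-bit
history $w$, with the denominator counting only history occurrences that
admit a following bit. This *conditional* convention (the default) makes the
two conditional frequencies of each history sum to exactly 1, so
$\tilde\varepsilon_h \in [0, \tfrac12]$ is a hard invariant. A *literal*
mode is also provided that normalizes numerator and denominator by their own
position counts, $n-h$ and $n-h+1$; the two differ only at order $1/n$, and
both are exposed because the convention used by earlier closed-source
implementations of this estimator cannot be determined. Histories that never
occur contribute no term to the maximum; if no word of length $h+1$ occurs
at all, the estimate is an explicit error rather than a silent zero.

**How long a history is meaningful?** For the SV condition to hold at
history length $h$ with $\varepsilon < \tfrac12$, every word of length
$h + 1$ must occur, which forces $2^{h+1} \le n - (h+1)$ and hence
$h \le \log_2 n - 1$. `max_history(n)` returns
$\lfloor \log_2 n \rfloor - 1$, the default profile depth. The bound is
tight: the order-$k$ De Bruijn sequence (length $2^k$, every $k$-word
exactly once cyclically) satisfies the condition with $\varepsilon = 0$ up
to $h = k - 1$, and `de_bruijn()` exists precisely to validate the estimator
against this closed-form case — all $\tilde\varepsilon_h = 0$ for
$h \le k-1$ under cyclic counting, and $\tilde\varepsilon_k = \tfrac12$
since every conditional at order $k$ is deterministic. Cyclic counting
exists only for this validation; real analyses are linear (the end of a
recording does not wrap).

**One epsilon per sequence.** The longest histories occur a handful of
times and carry little statistical meaning, so the single attributed
epsilon down-weights them harmonically:

$$\tilde\varepsilon(s^n) \;=\; \frac{1}{w(h_{\max})}
\sum_{i=0}^{h_{\max}} \frac{\tilde\varepsilon_i}{i+1},
\qquad w(h) = \sum_{i=0}^{h} \frac{1}{i+1},
\qquad h_{\max} = \lfloor \log_2 n \rfloor - 1 .$$

Being a convex combination, the aggregate always lies between the smallest
and largest per-history estimate. The weighting is heuristic — other
schedules are conceivable — so `weighted_epsilon()` also accepts a bare
vector of per-history estimates, but the harmonic weights are the only
default. When cohorts are analysed, $h_{\max}$ is taken per person from
that person's own sequence length, not from any pooled file.

**Implementation.** Counting is one vectorized sweep: the value of the
length-$L$ window at a position is twice the length-$(L-1)$ value plus the
incoming bit, and each length is tabulated densely over its $2^L$ cells
(word lengths are capped at 28 for this reason; the Lemma-driven default
never exceeds $\lfloor \log_2 n \rfloor$). `max_history()` guards the
$\lfloor \log_2 n \rfloor$ computation against floating-point edges at
exact powers of two. Everything is single-pass and in-memory — at the
method's natural scale (order $10^7$ bits per merged cohort) this is a few
hundred megabytes at most; streaming estimation is deliberately out of
scope.

## The simulators, and what passing tests show

Real Holter recordings are not distributable, so every stage is tested
against generated inputs with known ground truth:

* `simulate_sv_source()` draws either an iid biased coin
  ($P(1) = \tfrac12 + \varepsilon$, the canonical SV source) or a
  *persistent* order-1 Markov source that repeats its previous bit with
  probability $\tfrac12 + \varepsilon$. The Markov model is the adversarial
  one for this estimator: its marginal is fair, so all of its bias hides in
  the history terms $h \ge 1$ — exactly where heart rate, with its
  persistent acceleration/deceleration runs, is biased.
* `simulate_rr_series()` produces RR series with the statistical features
  the pipeline consumes: a baseline (default 900 ms, a typical nocturnal
  adult value), sinusoidal components with beat-periods drawn from the
  respiratory band (3-9 beats) and the vascular band (9-24 beats), a slow
  drift component (periods of 100-400 beats) standing in for longer-range
  regulation, persistent AR(1) noise (stationary SD 15 ms, coefficient
  0.8), and artifact beats at a configurable rate (default 2%) with
  distorted RR values and non-`"N"` annotations. The amplitudes
  (25/15/20 ms) put the oscillatory and stochastic parts on the same
  footing, so the discretized output is neither near-uniform nor
  near-deterministic.

The generator reproduces band-limited oscillation, persistence, trend and
artifacts — the features the preprocessing and estimation stages react to.
It does **not** model 1/f scaling, multifractality, circadian structure, or
any pulse-timing physiology (no integrate-and-fire model), so tests passing
on simulated cohorts validate the *pipeline's mechanics and statistical
calibration*, not physiological claims about real hearts. Published
cohort-level epsilon ranges cannot be reproduced without the original
recordings, and the package does not attempt to.

## Problem sizes and calibration checks

The test suite validates, among others:

* exact reproduction of the worked counting example (`"001011011"`) and of
  the order-2 and order-3 De Bruijn sequences with their zero-epsilon
  property;
* equivalence of the optimized counter and estimator with independent
  string-scan oracles over 100 random sequences up to $n = 4096$ and
  histories up to $h = 6$;
* the history bound by exhaustive check for $n = 4\ldots64$;
* recovery of $\varepsilon \in \{0, 0.05, 0.1, 0.2\}$ from iid coins at
  $n = 10^6$ within $3\sqrt{p(1-p)/n}$;
* that trend-cutting with pattern $(3,3)$ lowers the weighted epsilon
  relative to a length-matched uncut control on persistent Markov sources
  ($\varepsilon = 0.15$, $n = 20{,}000$ — the minimum nocturnal record
  length the preprocessing targets) in at least 80% of 50 seeded runs.

These sizes were chosen to give the statistical assertions comfortable
power while keeping the default suite quick to run.

## Cohort summaries

`cohort_epsilons()` computes, per person, the weighted epsilon under the
four processing methods used for cohort comparisons — `full` (all normal
beats), `trim` (truncated to the cohort minimum length, removing the
length-difference confounder), `cut` (after trend cutting), and `med` (the
manual path) — and `summarize_groups()` reduces them to five-number
summaries by sex and ten-year age bin $[10j, 10(j+1))$ (half-open bins
uniformly; ages outside 10-89 fold into the nearest bin with a message).
`plot_group_epsilons()` renders the whisker-box convention: box at the
quartiles, whiskers at group minimum and maximum. Quartiles are
`stats::quantile()` type 7; with the small groups typical of such cohorts,
any quartile convention gives visually indistinguishable boxes.

## Known limitations

* The epsilon estimate is heuristic in two places it inherits from the
  method: the choice of $h_{\max}$ and the harmonic weighting. It is an
  *empirical* bound — a realization-level estimate, not a certified bound
  on the generating process.
* `cut_trends()` fixes three scan ambiguities by documented choice (paired
  deletion, first-window matching, resume-after-cut); other implementations
  of trend cutting may delete more per cycle and hence produce much shorter
  outputs for the same pattern.
* The RR simulator is statistical, not physiological; see above.
* Counting is dense; sequences needing word lengths beyond 28 (i.e.
  $n > 2^{29}$ under the default depth) are out of scope.
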
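---
title: "RT-signature profiling: model, estimators and simulator design"
author: "rtsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-signature profiling: model, estimators and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsig)
```

## The measurement model

Reverse transcription of a template carrying a modified ribonucleoside with
a perturbed Watson–Crick face (m1A, m22G, m1G, m3C, ...) does not proceed
cleanly. When the enzyme reaches such a site, reading the template 3'→5',
four things can happen:

* **arrest** — primer extension terminates; the abortive cDNA fragment ends
  immediately 3' of the site and, with a library protocol that captures
  abortive fragments, is still sequenced;
* **misincorporation** — a non-complementary dNTP (or an unresolvable base,
  read as `N`) is incorporated opposite the site;
* **nucleotide skipping ("jump")** — the enzyme slips past one or two
  template positions, visible as a 1–2 nt deletion in the aligned cDNA at
  or immediately 5' of the site;
* clean read-through.

Merged over all sequenced cDNAs, the per-position rates of these events
form the *RT signature* of a modification, which depends on the
modification, the 3'-preceding base (prebase), the polymerase and the
reaction buffer — notably on whether the divalent cation is Mg²⁺ or Mn²⁺.

`rtsig` computes these rates from alignments, summarises them per
modification type, compares reaction conditions, and simulates the whole
generative process so that every estimator can be validated against known
event probabilities.

## The profile table

`build_profiles()` reduces alignments to one row per reference position
with coverage ≥ `min_cov` (default 20; positions below are discarded for
data quality, boundary inclusive). The 21 columns (`profile_columns()`)
are: identifiers (`ref_seg`, `mod`, `pos`, `ref_base`, `pre_base`),
coverage `cov`, ten base counters split by read orientation (capital
letters for forward/R1 reads, small letters for reverse/R2 — the split
reflects the sequenced mate of a paired-end run, not a genomic strand,
since tRNA references are single-stranded), and five rates.

The estimators, per position $N$:

* **mismatch rate** $= (\mathrm{cov} - \text{matches})/\mathrm{cov}$,
  where matches counts the reference base in both orientations; `N` bases
  never match but stay in the denominator. This convention is forced by
  exact agreement with published worked examples whose rows contain `N`
  counts.
* **arrest rate** $= \mathrm{clamp}\!\left(\frac{\mathrm{cov}(N{+}1) -
  \mathrm{cov}(N)}{\mathrm{cov}(N{+}1)}, 0, 1\right)$ — the relative
  coverage drop from the 3' neighbor, 0 at the 3' terminus or when
  $\mathrm{cov}(N{+}1)=0$. Because synthesis runs 3'→5', coverage can only
  drop (in expectation) toward 5'; negative sampling noise is clamped.
* **jump rates** — over reads *spanning* $N$ (aligned **or** deleted
  there; deletion-bearing reads carry no aligned base at $N$ and would be
  invisible in a coverage denominator): *direct* = deletion at $N$ only,
  *delayed* = deletion at $N-1$ only (attributed to $N$), *double* =
  deletions at both. At $N=1$ delayed and double are 0 by construction.

Arrest rates are computed on the unfiltered coverage vector before the
coverage filter removes rows, so a discarded neighbor still informs the
drop at a retained position.

### Numerical and degenerate-input choices

* Coordinates are 1-based and fully closed throughout; 0-based alignment
  records are converted at the I/O boundary only.
* Zero coverage makes the mismatch rate undefined (`NA`); such positions
  never survive the filter. Zero span makes all jump rates 0.
* Output rows are ordered by `(ref_seg, pos)` so files diff stably; rates
  serialize with exactly five decimals and round-trip losslessly at that
  precision.
* Softclips and insertions consume query bases only. Removal of 3'-tailing
  remnants is an upstream concern: real-data users should trim them before
  profiling (the simulator emits untailed reads).

## The simulator

`simulate_molecule()` / `simulate_library()` implement the generative
process directly: each molecule starts at the template's 3' end and walks
5'-ward; at every reached position one event is drawn from the site's
`mod_event_params()` (the per-modification entry at annotated sites, a
single shared background elsewhere — unmodified-site deviations are small
and aggregate, so per-position background values would add nothing
testable). Event semantics:

* *arrest*: the cDNA ends 3' of the site — the blocking site itself is
  not covered. Whether real abortive cDNAs retain a base opposite the
  modification is not settled; this choice makes the coverage-drop arrest
  estimator asymptotically unbiased, which is why we adopt it.
* *direct jump*: 1 nt deletion at the site; *delayed jump*: normal
  incorporation at the site, deletion at its 5' neighbor (bookkept under
  the modified site, matching the profiling attribution); *double jump*:
  2 nt deletion spanning both.
* *read-through*: the incorporated base is drawn from `mismatch_dist`
  (the reference base's own entry is correct incorporation). The shared
  background instead uses a scalar `p_mismatch` with errors uniform over
  the three off-bases plus `N`, because one fixed vector cannot designate
  "correct" across positions of differing reference base.

Reads longer than `read_length` (default 75 nt, a typical short-read mate
length) keep their 5'-most aligned bases — the 5' end is where RT
signatures concentrate, downstream of most modified sites. A configurable
fraction of molecules is additionally emitted as a reverse-orientation
mate covering the 3'-proximal window, emulating merged paired-end data.
Each reference draws from an RNG substream hashed from `(seed, ref_seg)`,
so adding a reference never perturbs the reads of another.

The returned ground-truth table tallies every drawn event, giving exact
per-site realized counts; the event classes at each site always sum to the
number of molecules that drew an event there.

### What the simulator does *not* emulate

Sequencing quality scores and quality-dependent errors, PCR duplication,
ligation bias, TdT tailing remnants, multi-mapping ambiguity and true tRNA
secondary structure are all absent. Passing tests on simulated data
therefore validate the *estimators and statistics*, not robustness to
these real-data artifacts.

### Estimator identifiability

The per-position estimators are deliberately simple, and on data with
several simultaneous event classes they measure composites:

* the coverage-drop arrest estimator converges to
  $p_\mathrm{arrest} + p_\mathrm{direct} + p_\mathrm{double}$, because
  deletion-bearing reads also lack an aligned base at the site;
* each jump estimator converges to $p_\mathrm{jump}/(1-p_\mathrm{arrest})$,
  because arrested molecules leave the spanning denominator;
* the mismatch rate is unbiased for the misincorporation mass regardless
  of the other classes, being conditional on an aligned base.

Parameter-recovery validation therefore uses scenarios in which the
confounding class is switched off (arrest anchors with jumps off, jump
anchors with arrest off); the built-in condition presets keep
direct + double jump mass equal across conditions so that *condition
deltas* in the arrest rate remain clean even at jump-bearing sites.

### Preset calibration

`builtin_presets()` describes EpiScript RT in a 3 mM MgCl₂ reference
buffer and in MnCl₂ buffers at 0.5/1/3/5 mM. Two anchors are reported
averages for m1A sites: arrest 0.82 (Mg) vs 0.24 (Mn 3 mM) and
misincorporation mass 0.54 vs 0.80. Everything else is package
calibration, chosen once to be realistic and not revisited: the
intermediate concentrations interpolate between the anchors with the
effect peaking at 3 mM and relaxing slightly at 5 mM; m22G/m1G/m3C get
weaker versions of the same pattern; reference-condition m1A jump mass
totals 0.04 (matching the low single-position jump rates typical of
magnesium conditions) with the manganese increase carried by the delayed
class for the identifiability reason above; the background uses
per-feature probabilities in the 0.5–2.5% range, scaled up moderately
with Mn²⁺ concentration. Misincorporation composition is fixed per
modification (e.g. m1A → mostly G, then T, rarely C), standing in for the
prebase-dependent compositions seen in real data.

## Condition statistics

`summarize_signature()` reports median and mean of one feature over all
positions matching a modification filter, each with a 95% bootstrap
percentile interval (10,000 resamples, fixed seed; a single position
yields a degenerate point interval). `compare_conditions()` matches
positions present — i.e. passing the coverage filter — in both conditions
on `(ref_seg, pos)`, forms per-position deltas (treated − reference, the
"normalized reference" representation: plain subtraction, no further
scaling), and tests them with a two-sided Wilcoxon signed-rank test at
α = 0.05. The choices that were genuinely open, and how we fixed them:

* the underlying study reports significance asterisks without naming the
  test or the CI construction; we use Wilcoxon signed-rank for matched
  positions (rank-based, no normality assumption on rate deltas that are
  bounded in [0, 1]) and bootstrap percentile CIs, with no
  multiple-testing correction since comparisons are reported per panel;
* with fewer than two matched positions, or identical matched values, no
  signed-rank statistic exists; the p-value is `NA` (flagged) or 1
  respectively;
* the aggregate "jump rate" of condition comparisons defaults to
  `jump_total`, the per-position sum of the three classes.

`prevalence()` (percentage of positions with a feature strictly above a
threshold, default 0) quantifies statements like "positions bearing a
jump"; note it is a detection-limit quantity that grows with coverage.
`mismatch_composition()` normalizes merged forward+reverse non-reference
base counts to fractions, optionally stratified by prebase.

## Problem sizes used in validation

The shipped tests run the full pipeline at deliberately small scale: toy
references of 60–90 nt, libraries of 150–500 molecules for pipeline and
calibration checks, 10,000 molecules for parameter recovery (3 binomial
standard errors ≈ ±1.2 percentage points on an 0.82 rate), 200 randomized
read sets of ≤ 50 reads for brute-force oracle equivalence, and 100
replicate null comparisons for test calibration. These sizes give stable
verdicts for every estimator while keeping the whole suite inside a few
minutes on one CPU.

## Known limitations

* The arrest estimator's composite convergence (above) means absolute
  arrest rates at heavily jump-bearing sites are upper bounds on
  $p_\mathrm{arrest}$; condition deltas are reliable when deletion classes
  are comparable between conditions.
* The jump denominator (spanning reads) is one of two defensible readings;
  a coverage denominator would inflate rates at high-deletion sites.
  Printed example rows cannot disambiguate the original choice.
* Whether observed arrest rates could go negative at noisy positions in
  the original processing is unknown; we clamp to [0, 1].
* The package does not call modifications de novo (no classifier); it
  quantifies signatures at annotated sites and everywhere else
  descriptively.
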
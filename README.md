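# rtsig — reverse-transcription signature profiling of RNA modifications

Reverse transcriptases (RTs) stumble over ribonucleosides whose
Watson–Crick face is chemically modified — m1A, m22G, m1G, m3C and
friends. The stumbles end up in the sequenced cDNA as three measurable
per-position features: **misincorporation** of non-complementary bases,
premature **arrest** of primer extension, and nucleotide-skipping
**jumps** visible as 1–2 nt deletions. Merged over all reads, these rates
form the *RT signature* of a modification — the raw material of
sequencing-based modification detection in tRNA — and they shift
dramatically when reaction conditions change, for example when Mg²⁺ in
the RT buffer is replaced by Mn²⁺.

`rtsig` is an R package for the computational half of such experiments,
aimed at epitranscriptomics groups analysing (t)RNA-seq data:

* **Profiling** — `build_profiles()` turns SAM/BAM alignments against a
  tRNA reference set into a single-base-resolution profile table: per
  position, coverage, ten orientation-split base counters, the
  3'-preceding base (prebase), mismatch rate, arrest rate
  (the relative coverage drop from the 3' neighbor,
  `(cov(N+1) − cov(N))/cov(N+1)`), and three jump-rate classes — *direct*
  (deletion at the site), *delayed* (deletion at the 5' neighbor) and
  *double* (both). Positions with coverage below 20 are discarded.
* **Signature statistics** — `summarize_signature()` (median/mean with
  bootstrap 95% CIs per modification type), `compare_conditions()`
  (matched-position deltas with a two-sided Wilcoxon signed-rank test),
  `prevalence()` and `mismatch_composition()`.
* **Simulation** — `simulate_library()` with `builtin_presets()`
  implements the generative process (3'→5' synthesis with per-site
  arrest/jump/misincorporation probabilities) and returns alignments plus
  a ground-truth event tally, so every estimator is testable without
  access to sequencing archives. Presets describe EpiScript RT under a
  3 mM Mg²⁺ reference buffer and 0.5–5 mM Mn²⁺ buffers, anchored at
  reported m1A averages (arrest 82% → 24%, misincorporation 54% → 80%
  between Mg and 3 mM Mn).
* **I/O** — FASTA references (pipe-delimited tRNA-database identifiers),
  SAM/BAM via Rsamtools, Modomics/tRNAdb-style annotation TSVs, YAML
  condition files, and a lossless 5-decimal profile TSV format. A thin
  command-line wrapper (`rtsig_cli()`, shipped as
  `inst/cli/rtsig.R`) exposes `simulate`, `profile` and `compare`
  subcommands.

## Worked example

Six synthetic 76-nt tRNA-like references, each with an m1A at the
position-58 analog, reverse-transcribed under the magnesium reference
preset and under 3 mM manganese, then profiled and compared:

```r
library(rtsig)
set.seed(20)
ids  <- sprintf("synth%07d|Saccharomyces_cerevisiae|4932|ref%02d|NNN", 1:6, 1:6)
seqs <- vapply(1:6, function(i) {
  x <- sample(c("A","C","G","T"), 76, TRUE); x[58] <- "A"
  paste(x, collapse = "")
}, "")
refs <- reference_set(setNames(seqs, ids))
ann  <- data.frame(ref_seg = ids, pos = 58L, mod = "m1A")

presets <- builtin_presets()
sim_mg  <- simulate_library(refs, ann, presets$EpiScript_Mg_3mM, seed = 1)
sim_mn  <- simulate_library(refs, ann, presets$EpiScript_Mn_3mM, seed = 2)
prof_mg <- build_profiles(sim_mg$reads, refs, ann)
prof_mn <- build_profiles(sim_mn$reads, refs, ann)

prof_mg[prof_mg$mod == "m1A",
        c("pos","ref_base","cov","pre_base","mism_rate","arrest_rate")]
#>  pos ref_base cov pre_base mism_rate arrest_rate
#>   58        A  92        T     0.641       0.873
#>   58        A 117        T     0.598       0.840
#>   58        A 115        C     0.522       0.841
#>   58        A  86        T     0.547       0.882
#>   58        A 122        T     0.434       0.831
#>   58        A 107        G     0.561       0.852
```

Under magnesium the m1A sites show the classic strong signature: arrest
rates above 0.8 (most cDNAs end just 3' of the site) and mismatch rates
around 0.5 (half the read-through incorporations are wrong). Swapping to
manganese:

```r
compare_conditions(prof_mg, prof_mn, ann, mod_filter = "m1A",
                   feature = "arrest")
#> RT signature comparison: m1A / arrest (6 matched positions)
#>  condition n_positions    median      mean ci95_mean_lo ci95_mean_hi
#>  reference           6 0.8466772 0.8529591    0.8391887    0.8684264
#>    treated           6 0.2669354 0.2717973    0.2585232    0.2877544
#> mean delta (treated - reference): -0.5812
#> Wilcoxon signed-rank p = 0.036 (*)
```

Manganese collapses the arrest rate by ~0.58 on average (0.85 → 0.27, a
significant matched-position shift): the enzyme reads through the
blockade instead of aborting, trading arrests for misincorporations and
jumps. The misincorporated bases opposite m1A are mostly G, then T:

```r
mismatch_composition(prof_mg, ann, mod_filter = "m1A")
#>  n_positions n_mismatch_bases A      C     G     T N
#>            6              349 0 0.0458 0.619 0.335 0
```

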
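#' Build a deterministic synthetic test fixture
#'
#' Creates a tiny, fully synthetic bundle binding the whole pipeline
#' together: three toy tRNA-like references (60-90 nt, generated — not
#' copied from any database — with identifiers imitating the pipe-delimited
#' tRNA-database style), an annotation placing one m1A (at the position-58
#' analog), one m22G and one m3C, a reference/treated condition pair taken
#' from [builtin_presets()] (magnesium vs. 3 mM manganese, scaled down to
#' fixture size), a zero-noise condition (all event probabilities 0,
#' read length covering the longest reference) and the analytically
#' expected profile for that zero-noise condition: flat coverage, all
#' rates 0.
#'
#' @param seed integer seed (changes the sequences, never the schema).
#' @param n_molecules molecules per reference for the bundled conditions.
#' @return a list of class `"FixtureBundle"` with elements `refs`, `ann`,
#'   `conditions` (list with `reference` and `treated`), `zero_noise` and
#'   `expected` (profile `data.frame` for the zero-noise condition).
#' @export
make_fixture <- function(seed = 42L, n_molecules = 400L) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  lens <- c(72L, 64L, 90L)
  ids <- c("synth0000001|Saccharomyces_cerevisiae|4932|Arg|ACG",
           "synth0000002|Saccharomyces_cerevisiae|4932|Asn|GTT",
           "synth0000003|Saccharomyces_cerevisiae|4932|Cys|GCA")
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  ann <- data.frame(
    ref_seg = ids,
    pos = c(58L, 26L, 32L),
    mod = c("m1A", "m22G", "m3C"),
    stringsAsFactors = FALSE)
  # force the annotated sites onto their canonical reference base
  target <- c("A", "G", "C")
  for (i in 1:3) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    s[ann$pos[i]] <- target[i]
    seqs[i] <- paste(s, collapse = "")
  }
  refs <- reference_set(setNames(seqs, ids))
  ann <- validate_annotation(ann, refs)

  presets <- builtin_presets()
  shrink <- function(cond) {
    cond$n_molecules_per_ref <- as.integer(n_molecules)
    cond
  }
  zero_noise <- rt_condition_params(
    label = "zero_noise", per_mod = list(),
    background = mod_event_params(),   # deterministic, error-free RT
    n_molecules_per_ref = 50L, read_length = max(lens),
    paired_fraction = 0.5)

  expected <- do.call(rbind, lapply(seq_along(refs), function(i) {
    L <- lens[i]
    n <- zero_noise$n_molecules_per_ref
    n_rev <- as.integer(floor(zero_noise$paired_fraction * n))
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    df <- data.frame(
      ref_seg = ids[i],
      mod = annotation_lookup(rep(ids[i], L), seq_len(L), ann),
      pos = seq_len(L), ref_base = s,
      cov = n + n_rev,
      pre_base = c(s[-1], ""),
      mism_rate = 0,
      A = 0L, G = 0L, T = 0L, C = 0L, N = 0L,
      a = 0L, g = 0L, t = 0L, c = 0L, n = 0L,
      single_jump_rate_direct = 0, single_jump_rate_delayed = 0,
      double_jump_rate = 0, arrest_rate = 0,
      stringsAsFactors = FALSE)
    for (b in c("A", "G", "T", "C")) {
      df[[b]][s == b] <- n
      df[[tolower(b)]][s == b] <- n_rev
    }
    df
  }))
  expected <- expected[order(expected$ref_seg, expected$pos), ]
  rownames(expected) <- NULL
  structure(list(refs = refs, ann = ann,
                 conditions = list(
                   reference = shrink(presets$EpiScript_Mg_3mM),
                   treated = shrink(presets$EpiScript_Mn_3mM)),
                 zero_noise = zero_noise,
                 expected = validate_profiles(expected)),
            class = "FixtureBundle")
}

#' Write a fixture bundle to a directory
#'
#' Emits every file the pipeline touches: the reference FASTA, the
#' annotation TSV, one condition YAML per bundled condition, and — for the
#' reference and treated conditions — a simulated SAM alignment file, the
#' ground-truth TSV and the computed profile TSV.
#'
#' @param bundle a `"FixtureBundle"` from [make_fixture()].
#' @param dir output directory (created if missing).
#' @param seed simulation seed.
#' @param min_cov coverage filter used for the emitted profiles.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir, seed = 1L, min_cov = 20) {
  stopifnot(inherits(bundle, "FixtureBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$refs, file.path(dir, "references.fasta"))
  write_annotation(bundle$ann, file.path(dir, "annotation.tsv"))
  write_condition_yaml(bundle$zero_noise,
                       file.path(dir, "condition_zero_noise.yaml"))
  for (nm in names(bundle$conditions)) {
    cond <- bundle$conditions[[nm]]
    write_condition_yaml(cond, file.path(dir, paste0("condition_", nm,
                                                     ".yaml")))
    sim <- simulate_library(bundle$refs, bundle$ann, cond, seed = seed)
    write_sam(sim$reads, bundle$refs,
              file.path(dir, paste0(nm, ".sam")))
    write_truth(sim$truth, file.path(dir, paste0(nm, "_truth.tsv")))
    prof <- build_profiles(sim$reads, bundle$refs, bundle$ann,
                           min_cov = min_cov)
    write_profile(prof, file.path(dir, paste0(nm, "_profile.tsv")))
  }
  invisible(dir)
}
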
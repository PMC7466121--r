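#' Per-site reverse-transcription event parameters
#'
#' Describes what a reverse transcriptase does when it reaches a template
#' position: terminate (`p_arrest`), skip the site itself (`p_jump_direct`,
#' a 1-nt deletion at the site), read through the site and skip its 5'
#' neighbor (`p_jump_delayed`, a 1-nt deletion at `N - 1`), skip both
#' (`p_jump_double`, a 2-nt deletion spanning `N - 1..N`), or read through
#' and incorporate a base. The incorporated base is drawn from
#' `mismatch_dist`, a probability vector over `A,C,G,T,N` in which the
#' entry of the site's own reference base is the correct-incorporation
#' probability. For parameters shared across sites of differing reference
#' base (the unmodified-site background), pass `p_mismatch` instead: the
#' correct base is then incorporated with `1 - p_mismatch` and errors are
#' spread uniformly over the three non-reference bases plus `N`.
#'
#' @param p_arrest,p_jump_direct,p_jump_delayed,p_jump_double event
#'   probabilities; their sum must not exceed 1, the remainder being
#'   read-through with incorporation.
#' @param mismatch_dist named numeric vector over `A,C,G,T,N` summing to 1
#'   (within 1e-9), or `NULL` to use `p_mismatch`.
#' @param p_mismatch total misincorporation probability given read-through;
#'   used only when `mismatch_dist` is `NULL`.
#' @return a list of class `"ModEventParams"`.
#' @export
mod_event_params <- function(p_arrest = 0, p_jump_direct = 0,
                             p_jump_delayed = 0, p_jump_double = 0,
                             mismatch_dist = NULL, p_mismatch = 0) {
  p <- c(p_arrest, p_jump_direct, p_jump_delayed, p_jump_double)
  if (any(p < 0 | p > 1)) stop("event probabilities must lie in [0, 1]")
  if (sum(p) > 1 + 1e-12)
    stop("p_arrest + jump probabilities exceed 1 (no read-through mass left)")
  if (!is.null(mismatch_dist)) {
    bases <- c("A", "C", "G", "T", "N")
    if (is.null(names(mismatch_dist)) ||
        !all(bases %in% names(mismatch_dist)))
      stop("mismatch_dist must be named over A, C, G, T, N")
    mismatch_dist <- mismatch_dist[bases]
    if (any(mismatch_dist < 0) || abs(sum(mismatch_dist) - 1) > 1e-9)
      stop("mismatch_dist must be non-negative and sum to 1 within 1e-9")
  } else {
    if (p_mismatch < 0 || p_mismatch > 1)
      stop("p_mismatch must lie in [0, 1]")
  }
  structure(list(p_arrest = p_arrest, p_jump_direct = p_jump_direct,
                 p_jump_delayed = p_jump_delayed,
                 p_jump_double = p_jump_double,
                 mismatch_dist = mismatch_dist, p_mismatch = p_mismatch),
            class = "ModEventParams")
}

#' Reaction-condition parameters for the RT simulator
#'
#' Bundles everything that defines one simulated reverse-transcription
#' reaction: per-modification event parameters, the shared background
#' applied at unmodified positions, and library-scale settings.
#'
#' @param label condition name, e.g. `"EpiScript_Mg_3mM"`.
#' @param per_mod named list of [mod_event_params()], keyed by modification
#'   code.
#' @param background [mod_event_params()] applied at every unannotated
#'   position; each probability must stay below 0.1, reflecting the small
#'   aggregate changes seen at unmodified sites.
#' @param n_molecules_per_ref number of cDNA molecules synthesized per
#'   reference.
#' @param read_length maximum aligned read length (default 75, the typical
#'   short-read mate length); longer cDNAs are truncated keeping the
#'   5'-most — most informative — end.
#' @param paired_fraction fraction of molecules also emitted as a
#'   `REVERSE`-orientation mate covering the 3'-proximal `read_length`
#'   window.
#' @return a list of class `"RTConditionParams"`.
#' @export
rt_condition_params <- function(label, per_mod = list(),
                                background = mod_event_params(),
                                n_molecules_per_ref = 500L,
                                read_length = 75L, paired_fraction = 0) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  if (!inherits(background, "ModEventParams"))
    stop("background must be a ModEventParams")
  bgp <- c(background$p_arrest, background$p_jump_direct,
           background$p_jump_delayed, background$p_jump_double,
           if (is.null(background$mismatch_dist)) background$p_mismatch
           else 1 - max(background$mismatch_dist))
  if (any(bgp >= 0.1))
    stop("background event probabilities must each stay below 0.1")
  if (length(per_mod)) {
    if (is.null(names(per_mod)) || any(!nzchar(names(per_mod))))
      stop("per_mod must be named by modification code")
    ok <- vapply(per_mod, inherits, logical(1), "ModEventParams")
    if (any(!ok)) stop("per_mod entries must be ModEventParams")
  }
  stopifnot(n_molecules_per_ref >= 0, read_length >= 1,
            paired_fraction >= 0, paired_fraction <= 1)
  structure(list(label = label, per_mod = per_mod, background = background,
                 n_molecules_per_ref = as.integer(n_molecules_per_ref),
                 read_length = as.integer(read_length),
                 paired_fraction = paired_fraction),
            class = "RTConditionParams")
}

# per-position event/incorporation model for one reference:
# cumulative event bounds (arrest, +direct, +delayed, +double) and
# cumulative incorporation distribution over A,C,G,T,N
site_model <- function(ref_seq, mods, cond) {
  seq_chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  L <- length(seq_chars)
  bases <- c("A", "C", "G", "T", "N")
  if (length(mods)) {
    mp <- as.integer(names(mods))
    if (any(is.na(mp)) || any(mp < 1 | mp > L))
      stop("modification positions outside the reference sequence")
  }
  ev <- matrix(0, nrow = 4, ncol = L)
  inc <- matrix(0, nrow = 5, ncol = L, dimnames = list(bases, NULL))
  params_at <- function(pos) {
    mod <- mods[[as.character(pos)]]
    if (!is.null(mod) && !is.null(cond$per_mod[[mod]]))
      cond$per_mod[[mod]] else cond$background
  }
  for (p in seq_len(L)) {
    par <- params_at(p)
    ev[, p] <- cumsum(c(par$p_arrest, par$p_jump_direct,
                        par$p_jump_delayed, par$p_jump_double))
    d <- par$mismatch_dist
    if (is.null(d)) {
      d <- setNames(rep(par$p_mismatch / 4, 5), bases)
      d[seq_chars[p]] <- 1 - par$p_mismatch
    }
    inc[, p] <- cumsum(d[bases])
  }
  list(ev = ev, inc = inc, seq_chars = seq_chars, L = L,
       event_of = function(pos) {
         par <- params_at(pos)
         c(arrest = par$p_arrest, direct = par$p_jump_direct,
           delayed = par$p_jump_delayed, double = par$p_jump_double)
       })
}

# walk one molecule 3' -> 5'; u, ub are length-L uniforms for event and
# incorporation draws. Returns outcome (0 unreached, 1 aligned, 2 deleted),
# drawn bases and the event log (site, class 1..5).
walk_molecule <- function(model, u, ub) {
  L <- model$L
  bases <- c("A", "C", "G", "T", "N")
  outcome <- integer(L)
  base <- character(L)
  ev_site <- integer(L); ev_class <- integer(L); nev <- 0L
  p <- L
  while (p >= 1L) {
    cm <- model$ev[, p]
    x <- u[p]
    nev <- nev + 1L
    ev_site[nev] <- p
    if (x < cm[1L]) {                      # arrest: site left uncovered
      ev_class[nev] <- 1L
      outcome[seq_len(p)] <- 0L
      break
    } else if (x < cm[2L]) {               # direct jump
      ev_class[nev] <- 2L
      outcome[p] <- 2L
      p <- p - 1L
    } else if (x < cm[3L]) {               # delayed jump
      ev_class[nev] <- 3L
      outcome[p] <- 1L
      base[p] <- bases[findInterval(ub[p], model$inc[, p]) + 1L]
      if (p > 1L) outcome[p - 1L] <- 2L
      p <- p - 2L
    } else if (x < cm[4L]) {               # double jump
      ev_class[nev] <- 4L
      outcome[p] <- 2L
      if (p > 1L) outcome[p - 1L] <- 2L
      p <- p - 2L
    } else {                               # read-through incorporation
      ev_class[nev] <- 5L
      outcome[p] <- 1L
      base[p] <- bases[findInterval(ub[p], model$inc[, p]) + 1L]
      p <- p - 1L
    }
  }
  list(outcome = outcome, base = base,
       ev_site = ev_site[seq_len(nev)], ev_class = ev_class[seq_len(nev)])
}

# turn a walk outcome into (start, cigar, query) covering a window of
# aligned positions; returns NULL when no aligned base survives
outcome_to_read <- function(outcome, base, keep_aligned) {
  aligned <- which(outcome == 1L)
  aligned <- intersect(aligned, keep_aligned)
  if (length(aligned) == 0) return(NULL)
  fstart <- min(aligned); fend <- max(aligned)
  oc <- outcome[fstart:fend]
  r <- rle(oc)
  cigar <- paste0(r$lengths, ifelse(r$values == 1L, "M", "D"),
                  collapse = "")
  list(start = fstart, cigar = cigar,
       query = paste(base[aligned], collapse = ""))
}

#' Simulate the reverse transcription of a single molecule
#'
#' Walks the template from its 3' end toward the 5' end, drawing one event
#' per reached position from the site's [mod_event_params()] (the
#' modification-specific entry at annotated sites, the background
#' elsewhere): arrest terminates synthesis before the site, so the cDNA
#' covers only positions strictly 3' of it; a direct jump deletes the site;
#' a delayed jump incorporates at the site and deletes its 5' neighbor; a
#' double jump deletes both; read-through incorporates a base from the
#' incorporation distribution. Reads longer than `cond$read_length` aligned
#' bases are truncated keeping the 5'-most end. Draws come from the current
#' R random number generator.
#'
#' @param ref_seq template sequence (character, A/C/G/T).
#' @param mods named list or vector mapping 1-based positions (names) to
#'   modification codes.
#' @param cond an [rt_condition_params()] object.
#' @param read_id read name for the emitted record.
#' @param ref_seg reference identifier for the emitted record.
#' @return a list with `read` (a one-row `"rt_alignments"` data frame, or
#'   `NULL` when no aligned base remains, i.e. immediate arrest — arrested
#'   molecules otherwise yield their abortive fragment), `events` (data
#'   frame of per-site event draws) and `arrested` (logical).
#' @export
simulate_molecule <- function(ref_seq, mods, cond, read_id = "mol_1",
                              ref_seg = "ref") {
  mods <- as.list(mods)
  model <- site_model(ref_seq, mods, cond)
  w <- walk_molecule(model, runif(model$L), runif(model$L))
  rd <- outcome_to_read(w$outcome, w$base,
                        keep_aligned = head_aligned(w$outcome,
                                                    cond$read_length))
  events <- data.frame(pos = w$ev_site,
                       event = c("arrest", "jump_direct", "jump_delayed",
                                 "jump_double", "read_through")[w$ev_class])
  read <- if (is.null(rd)) NULL else
    aligned_reads(read_id, ref_seg, rd$start, rd$cigar, rd$query, "FORWARD")
  list(read = read, events = events,
       arrested = any(events$event == "arrest"))
}

head_aligned <- function(outcome, read_length) {
  aligned <- which(outcome == 1L)
  if (length(aligned) > read_length) aligned <- aligned[seq_len(read_length)]
  aligned
}

tail_aligned <- function(outcome, read_length) {
  aligned <- which(outcome == 1L)
  n <- length(aligned)
  if (n > read_length) aligned <- aligned[(n - read_length + 1L):n]
  aligned
}

# deterministic per-reference RNG substream: adding a reference never
# changes the reads simulated for the others
substream_seed <- function(seed, ref_seg) {
  h <- 0
  for (ch in utf8ToInt(ref_seg)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Simulate a sequencing library over a reference set
#'
#' Synthesizes `cond$n_molecules_per_ref` cDNA molecules per reference with
#' [simulate_molecule()] semantics and tallies every drawn event into a
#' ground-truth table. The first `floor(paired_fraction * n)` molecules of
#' each reference are additionally emitted as `REVERSE`-orientation mates
#' covering the 3'-proximal `read_length` window. Each reference uses an
#' RNG substream derived from `(seed, ref_seg)`, so output is deterministic
#' for a fixed seed and unaffected by other references. The caller's RNG
#' state is restored on exit.
#'
#' @param refs a `"ReferenceSet"`.
#' @param ann modification annotation data frame (`ref_seg`, `pos`, `mod`),
#'   or `NULL`.
#' @param cond an [rt_condition_params()] object.
#' @param seed integer seed.
#' @return a list with `reads` (an `"rt_alignments"` data frame) and
#'   `truth`: one row per reference position with the generating
#'   probabilities (`p_arrest`, `p_jump_direct`, `p_jump_delayed`,
#'   `p_jump_double`, `p_mismatch` — the misincorporation mass given
#'   incorporation) and realized counts (`n_reached` molecules drawing an
#'   event there, `n_arrest`, `n_jump_direct`, `n_jump_delayed`,
#'   `n_jump_double`, `n_read_through`, and `n_mismatch` incorporations
#'   differing from the reference base).
#' @export
simulate_library <- function(refs, ann = NULL, cond, seed = 1L) {
  refs <- as_reference_set(refs)
  if (!is.null(ann)) ann <- validate_annotation(ann, refs)
  stopifnot(inherits(cond, "RTConditionParams"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  n <- cond$n_molecules_per_ref
  reads_acc <- list()
  truth_acc <- list()
  bases5 <- c("A", "C", "G", "T", "N")
  for (ri in seq_along(refs)) {
    rs <- names(refs)[ri]
    seq_chars <- strsplit(refs[[rs]], "", fixed = TRUE)[[1]]
    L <- length(seq_chars)
    mods_df <- if (is.null(ann)) NULL else ann[ann$ref_seg == rs, ]
    mods <- list()
    if (!is.null(mods_df) && nrow(mods_df))
      mods <- setNames(as.list(mods_df$mod), mods_df$pos)
    model <- site_model(refs[[rs]], mods, cond)
    set.seed(substream_seed(seed, rs))
    n_paired <- as.integer(floor(cond$paired_fraction * n))
    ev_counts <- matrix(0L, nrow = 5, ncol = L)
    mm_counts <- integer(L)
    rid <- character(0); rstart <- integer(0); rcig <- character(0)
    rq <- character(0); rorient <- character(0)
    if (n > 0) {
      U <- matrix(runif(L * n), nrow = L)
      UB <- matrix(runif(L * n), nrow = L)
      for (j in seq_len(n)) {
        w <- walk_molecule(model, U[, j], UB[, j])
        idx <- (w$ev_site - 1L) * 5L + w$ev_class
        ev_counts[idx] <- ev_counts[idx] + 1L
        inc_at <- w$ev_site[w$ev_class %in% c(3L, 5L)]
        mm <- inc_at[w$base[inc_at] != seq_chars[inc_at]]
        mm_counts[mm] <- mm_counts[mm] + 1L
        id <- sprintf("r%02d_m%06d", ri, j)
        fwd <- outcome_to_read(w$outcome, w$base,
                               head_aligned(w$outcome, cond$read_length))
        if (!is.null(fwd)) {
          rid <- c(rid, id); rstart <- c(rstart, fwd$start)
          rcig <- c(rcig, fwd$cigar); rq <- c(rq, fwd$query)
          rorient <- c(rorient, "FORWARD")
        }
        if (j <= n_paired) {
          rev <- outcome_to_read(w$outcome, w$base,
                                 tail_aligned(w$outcome, cond$read_length))
          if (!is.null(rev)) {
            rid <- c(rid, id); rstart <- c(rstart, rev$start)
            rcig <- c(rcig, rev$cigar); rq <- c(rq, rev$query)
            rorient <- c(rorient, "REVERSE")
          }
        }
      }
    }
    gen <- t(vapply(seq_len(L), model$event_of, numeric(4)))
    p_mm <- vapply(seq_len(L), function(p) {
      d <- diff(c(0, model$inc[, p]))
      1 - d[match(seq_chars[p], bases5)]
    }, numeric(1))
    truth_acc[[rs]] <- data.frame(
      ref_seg = rs, pos = seq_len(L),
      mod = annotation_lookup(rep(rs, L), seq_len(L), ann),
      ref_base = seq_chars,
      p_arrest = gen[, 1], p_jump_direct = gen[, 2],
      p_jump_delayed = gen[, 3], p_jump_double = gen[, 4],
      p_mismatch = p_mm,
      n_reached = as.integer(colSums(ev_counts)),
      n_arrest = ev_counts[1, ], n_jump_direct = ev_counts[2, ],
      n_jump_delayed = ev_counts[3, ], n_jump_double = ev_counts[4, ],
      n_read_through = ev_counts[5, ], n_mismatch = mm_counts,
      stringsAsFactors = FALSE)
    reads_acc[[rs]] <- data.frame(read_id = rid,
                                  ref_seg = rep(rs, length(rid)),
                                  start = rstart, cigar = rcig, query = rq,
                                  orientation = rorient,
                                  stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads_acc)
  rownames(reads) <- NULL
  truth <- do.call(rbind, truth_acc)
  rownames(truth) <- NULL
  list(reads = validate_alignments(reads, refs), truth = truth)
}

#' Write the simulator ground-truth table
#'
#' @param truth the `truth` component of [simulate_library()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
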
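#' Accumulate a per-position pileup from alignments
#'
#' Walks every alignment once and tallies, for every reference position:
#'
#' * the ten orientation-split base counters (`A/G/T/C/N` forward,
#'   `a/g/t/c/n` reverse) incremented by `M` operations,
#' * `span` — reads whose footprint (aligned or deleted) covers the
#'   position,
#' * `del_here` — reads with a deletion at the position,
#' * per-read deletion classes relative to each position `p`: `del_direct`
#'   (deletion at `p`, none at `p - 1`), `del_delayed` (deletion at `p - 1`
#'   only) and `del_double` (deletions at both `p` and `p - 1`),
#' * `read_start_5p` — reads whose 5'-most covered position is `p`.
#'
#' Insertions and soft clips consume query bases only. Deletions contribute
#' to `span` but not to coverage.
#'
#' @param reads an `"rt_alignments"` data frame (see [aligned_reads()]).
#' @param refs a `"ReferenceSet"`.
#' @return an object of class `"PileupAccumulator"`: a list with one entry
#'   per reference, each holding `counts` (10 x L integer matrix), `span`,
#'   `del_here`, `del_direct`, `del_delayed`, `del_double` and
#'   `read_start_5p` (length-L integer vectors).
#' @export
accumulate <- function(reads, refs) {
  refs <- as_reference_set(refs)
  reads <- validate_alignments(reads, refs)
  lens <- ref_lengths(refs)
  base_row <- setNames(1:5, c("A", "G", "T", "C", "N"))

  acc <- lapply(names(refs), function(rs) {
    L <- lens[[rs]]
    list(ref_seg = rs, length = L,
         counts = matrix(0L, nrow = 10, ncol = L,
                         dimnames = list(count_columns(), NULL)),
         span = integer(L), del_here = integer(L), del_direct = integer(L),
         del_delayed = integer(L), del_double = integer(L),
         read_start_5p = integer(L))
  })
  names(acc) <- names(refs)
  if (nrow(reads) == 0) {
    class(acc) <- "PileupAccumulator"
    return(acc)
  }

  for (rs in unique(reads$ref_seg)) {
    sub <- reads[reads$ref_seg == rs, , drop = FALSE]
    L <- lens[[rs]]
    aln_idx <- vector("list", nrow(sub))   # (pos - 1) * 10 + channel
    span_d <- integer(L + 1L)
    starts <- integer(nrow(sub))
    del_pos <- vector("list", nrow(sub))
    dd_direct <- vector("list", nrow(sub))
    dd_delayed <- vector("list", nrow(sub))
    dd_double <- vector("list", nrow(sub))

    for (i in seq_len(nrow(sub))) {
      ops <- parse_cigar(sub$cigar[i])
      qb <- strsplit(sub$query[i], "", fixed = TRUE)[[1]]
      rp <- sub$start[i]; qp <- 1L
      apos <- integer(0); abase <- character(0); dpos <- integer(0)
      for (k in seq_along(ops$op)) {
        l <- ops$len[k]
        switch(ops$op[k],
               M = { apos <- c(apos, rp:(rp + l - 1L))
                     abase <- c(abase, qb[qp:(qp + l - 1L)])
                     rp <- rp + l; qp <- qp + l },
               D = { dpos <- c(dpos, rp:(rp + l - 1L)); rp <- rp + l },
               { qp <- qp + l })   # I, S
      }
      fstart <- sub$start[i]; fend <- rp - 1L
      row <- base_row[abase]
      if (anyNA(row))
        stop("query base outside A/C/G/T/N for read ", sub$read_id[i])
      off <- if (sub$orientation[i] == "REVERSE") 5L else 0L
      aln_idx[[i]] <- (apos - 1L) * 10L + row + off
      span_d[fstart] <- span_d[fstart] + 1L
      span_d[fend + 1L] <- span_d[fend + 1L] - 1L
      starts[i] <- fstart
      if (length(dpos)) {
        del_pos[[i]] <- dpos
        in_del <- logical(L)
        in_del[dpos] <- TRUE
        dd_direct[[i]] <- dpos[!c(FALSE, in_del)[dpos]]   # p - 1 not deleted
        dd_double[[i]] <- dpos[c(FALSE, in_del)[dpos]]    # p - 1 deleted
        after <- dpos + 1L
        dd_delayed[[i]] <- after[after <= fend & !in_del[after]]
      }
    }
    a <- acc[[rs]]
    idx <- unlist(aln_idx)
    if (length(idx)) {
      tab <- tabulate(idx, nbins = 10L * L)
      a$counts <- a$counts + matrix(as.integer(tab), nrow = 10)
    }
    a$span <- as.integer(cumsum(span_d[seq_len(L)]))
    a$read_start_5p <- tabulate(starts, nbins = L)
    a$del_here <- tabulate(as.integer(unlist(del_pos)), nbins = L)
    a$del_direct <- tabulate(as.integer(unlist(dd_direct)), nbins = L)
    a$del_delayed <- tabulate(as.integer(unlist(dd_delayed)), nbins = L)
    a$del_double <- tabulate(as.integer(unlist(dd_double)), nbins = L)
    acc[[rs]] <- a
  }
  class(acc) <- "PileupAccumulator"
  acc
}

#' Mismatch rate from orientation-split base counters
#'
#' The mismatch rate at a position is the fraction of mapped bases that do
#' not match the reference nucleotide. Unknown bases (`N`/`n`) never match
#' and stay in the denominator.
#'
#' @param counts named integer vector with the ten counters
#'   `A,G,T,C,N,a,g,t,c,n`.
#' @param ref_base reference base, one of `A/C/G/T`.
#' @return the mismatch fraction in `[0, 1]`; `NA` when coverage is zero
#'   (such positions are removed by the coverage filter anyway).
#' @examples
#' counts <- c(A = 10, G = 39, T = 24, C = 7, N = 0,
#'             a = 0, g = 58, t = 25, c = 4, n = 0)
#' mismatch_rate(counts, "A")   # 0.94012 at 5 decimals
#' @export
mismatch_rate <- function(counts, ref_base) {
  stopifnot(ref_base %in% c("A", "C", "G", "T"))
  counts <- counts[count_columns()]
  if (anyNA(counts)) stop("counts must name all ten base counters")
  cov <- sum(counts)
  if (cov == 0) return(NA_real_)
  matches <- counts[[ref_base]] + counts[[tolower(ref_base)]]
  (cov - matches) / cov
}

#' Arrest rate from a coverage vector
#'
#' Reverse transcription proceeds from the 3' end of the template toward the
#' 5' end, so molecules terminating at a site reduce coverage at that site
#' relative to its 3' neighbor. The arrest rate at position `N` is the
#' relative coverage reduction compared to position `N + 1`:
#' `(cov(N+1) - cov(N)) / cov(N+1)`, clamped to `[0, 1]`, and 0 when
#' `cov(N+1)` is 0 or at the 3'-terminal position.
#'
#' @param coverage integer vector of per-position coverage for one
#'   reference, indexed 1..L from the 5' end.
#' @return numeric vector of arrest rates, same length.
#' @export
arrest_rate <- function(coverage) {
  L <- length(coverage)
  if (L == 0) return(numeric(0))
  out <- numeric(L)
  if (L > 1) {
    nxt <- coverage[-1]
    cur <- coverage[-L]
    ok <- nxt > 0
    out[-L][ok] <- pmin(pmax((nxt[ok] - cur[ok]) / nxt[ok], 0), 1)
  }
  out
}

#' Jump rates at one position
#'
#' Jumps are nucleotide-skipping events visible as deletions. Relative to a
#' position `p`, a read spanning `p` carries a *direct* single jump
#' (deletion at `p` only), a *delayed* single jump (deletion at the 5'
#' neighbor `p - 1` only, attributed to `p`), or a *double* jump (deletions
#' at both). Rates are fractions of the reads spanning `p` (aligned or
#' deleted), so deletion-bearing reads count in the denominator. At `p = 1`
#' the delayed and double rates are 0.
#'
#' @param acc a `"PileupAccumulator"`.
#' @param ref_seg reference identifier.
#' @param pos 1-based position.
#' @return named numeric vector `c(direct, delayed, double)`.
#' @export
jump_rates <- function(acc, ref_seg, pos) {
  a <- acc[[ref_seg]]
  if (is.null(a)) stop("unknown reference: ", ref_seg)
  stopifnot(pos >= 1, pos <= a$length)
  s <- a$span[pos]
  if (s == 0) return(c(direct = 0, delayed = 0, double = 0))
  c(direct = a$del_direct[pos] / s,
    delayed = if (pos > 1) a$del_delayed[pos] / s else 0,
    double = if (pos > 1) a$del_double[pos] / s else 0)
}

#' Build the per-position profile table
#'
#' Turns alignments into the single-base-resolution profile table: one row
#' per reference position passing the coverage filter, holding the
#' modification annotation, reference base, 3'-preceding base (`pos + 1`,
#' the base the reverse transcriptase reads before reaching the site),
#' coverage, the ten orientation-split base counters, mismatch rate, the
#' three jump rates and the arrest rate. Arrest rates are computed on the
#' full coverage vector before filtering, so a filtered neighbor still
#' informs the drop. Rows are ordered by `(ref_seg, pos)`.
#'
#' @param reads an `"rt_alignments"` data frame or a `"PileupAccumulator"`.
#' @param refs a `"ReferenceSet"`.
#' @param ann optional modification annotation (`ref_seg`, `pos`, `mod`).
#' @param min_cov minimum coverage; positions below it are discarded
#'   (default 20, boundary inclusive).
#' @return a profile `data.frame` (see [profile_columns()]).
#' @export
build_profiles <- function(reads, refs, ann = NULL, min_cov = 20) {
  refs <- as_reference_set(refs)
  if (!is.null(ann)) ann <- validate_annotation(ann, refs)
  acc <- if (inherits(reads, "PileupAccumulator")) reads
         else accumulate(reads, refs)
  out <- lapply(names(refs), function(rs) {
    a <- acc[[rs]]
    L <- a$length
    cov <- as.integer(colSums(a$counts))
    arr <- arrest_rate(cov)
    keep <- which(cov >= min_cov)
    if (length(keep) == 0) return(NULL)
    seq_chars <- strsplit(refs[[rs]], "", fixed = TRUE)[[1]]
    s <- a$span[keep]
    direct <- ifelse(s > 0, a$del_direct[keep] / s, 0)
    delayed <- ifelse(s > 0 & keep > 1, a$del_delayed[keep] / s, 0)
    dbl <- ifelse(s > 0 & keep > 1, a$del_double[keep] / s, 0)
    cnt <- t(a$counts[, keep, drop = FALSE])
    matches <- cnt[, "A"] * 0L
    for (b in c("A", "G", "T", "C")) {
      at <- seq_chars[keep] == b
      matches[at] <- cnt[at, b] + cnt[at, tolower(b)]
    }
    df <- data.frame(ref_seg = rs,
                     mod = annotation_lookup(rep(rs, length(keep)), keep, ann),
                     pos = keep,
                     ref_base = seq_chars[keep],
                     cov = cov[keep],
                     pre_base = ifelse(keep < L, seq_chars[pmin(keep + 1L, L)],
                                       ""),
                     mism_rate = (cov[keep] - matches) / cov[keep],
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(cnt))
    df$single_jump_rate_direct <- direct
    df$single_jump_rate_delayed <- delayed
    df$double_jump_rate <- dbl
    df$arrest_rate <- arr[keep]
    df
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_profile())
  res <- do.call(rbind, out)
  res <- res[order(res$ref_seg, res$pos), ]
  rownames(res) <- NULL
  validate_profiles(res)
}
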
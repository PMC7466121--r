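# shared helpers: tiny references, quick read construction, random read
# sets for property tests, and a brute-force pileup oracle that re-walks
# every read at every position (independent of the package's accumulator)

tiny_refs <- function(seqs = c(refA = "ACGTACGTACGTACGTACGT",
                               refB = "GGGCCCAAATTTGGGCCCAAATTT")) {
  reference_set(seqs)
}

mk_reads <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(read_id = r[[1]], ref_seg = r[[2]],
               start = as.integer(r[[3]]), cigar = r[[4]], query = r[[5]],
               orientation = r[[6]], stringsAsFactors = FALSE)))
  validate_alignments(df)
}

# n identical forward reads fully matching refs[[ref]] from pos 1
perfect_reads <- function(refs, ref, n, prefix = "p") {
  seq <- refs[[ref]]
  do.call(mk_reads, lapply(seq_len(n), function(i)
    list(paste0(prefix, i), ref, 1L, paste0(nchar(seq), "M"), seq,
         "FORWARD")))
}

# random read set over a reference set; reads contain M runs interleaved
# with occasional D (1-2 nt), I and S ops and a small mismatch/N rate
random_reads <- function(refs, n_reads, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(n_reads), function(i) {
    rs <- sample(names(refs), 1)
    L <- nchar(refs[[rs]])
    start <- sample.int(max(L - 6L, 1L), 1)
    ops <- character(0); lens <- integer(0)
    rp <- start; qlen <- 0L
    if (runif(1) < 0.15) { ops <- "S"; lens <- sample(1:3, 1)
                           qlen <- qlen + lens }
    repeat {
      ml <- sample(1:6, 1)
      ml <- min(ml, L - rp + 1L)
      if (ml < 1) break
      ops <- c(ops, "M"); lens <- c(lens, ml)
      rp <- rp + ml; qlen <- qlen + ml
      if (rp > L || runif(1) < 0.4) break
      r <- runif(1)
      if (r < 0.35) {                          # deletion 1-2 nt
        dl <- min(sample(1:2, 1), L - rp)
        if (dl >= 1) { ops <- c(ops, "D"); lens <- c(lens, dl); rp <- rp + dl }
        if (rp > L) break
      } else if (r < 0.5) {                    # insertion
        il <- sample(1:2, 1)
        ops <- c(ops, "I"); lens <- c(lens, il); qlen <- qlen + il
      }
    }
    if (length(ops) == 0 || !any(ops == "M")) return(NULL)
    while (ops[length(ops)] == "D") {          # CIGAR must not end in D
      rp <- rp - lens[length(ops)]
      ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
    }
    q <- sample(c(bases, "N"), qlen, replace = TRUE,
                prob = c(rep(0.24, 4), 0.04))
    data.frame(read_id = sprintf("rr%03d", i), ref_seg = rs,
               start = start,
               cigar = paste0(lens, ops, collapse = ""),
               query = paste(q, collapse = ""),
               orientation = sample(c("FORWARD", "REVERSE"), 1),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  validate_alignments(do.call(rbind, rows))
}

# brute-force oracle: builds, for every read, an explicit pos -> state map
# ("M<base>" or "D"), then answers every per-position question by scanning
# all reads again
oracle_profiles <- function(reads, refs, ann = NULL, min_cov = 20) {
  maps <- lapply(seq_len(nrow(reads)), function(i) {
    ops <- parse_cigar(reads$cigar[i])
    qb <- strsplit(reads$query[i], "", fixed = TRUE)[[1]]
    state <- list(); rp <- reads$start[i]; qp <- 1L
    for (k in seq_along(ops$op)) {
      l <- ops$len[k]
      if (ops$op[k] == "M") {
        for (j in seq_len(l)) {
          state[[as.character(rp)]] <- paste0("M", qb[qp])
          rp <- rp + 1L; qp <- qp + 1L
        }
      } else if (ops$op[k] == "D") {
        for (j in seq_len(l)) { state[[as.character(rp)]] <- "D"
                                rp <- rp + 1L }
      } else qp <- qp + l
    }
    list(ref = reads$ref_seg[i], orient = reads$orientation[i],
         state = state, lo = reads$start[i], hi = rp - 1L)
  })
  out <- list()
  for (rs in names(refs)) {
    L <- nchar(refs[[rs]])
    seq_chars <- strsplit(refs[[rs]], "", fixed = TRUE)[[1]]
    rmaps <- Filter(function(m) m$ref == rs, maps)
    counters <- matrix(0L, nrow = L, ncol = 10,
                       dimnames = list(NULL, count_columns()))
    span <- dir_n <- del_n <- dbl_n <- integer(L)
    for (p in seq_len(L)) {
      for (m in rmaps) {
        if (p < m$lo || p > m$hi) next
        span[p] <- span[p] + 1L
        st <- m$state[[as.character(p)]]
        st_prev <- if (p > 1 && p - 1 >= m$lo)
          m$state[[as.character(p - 1)]] else NULL
        if (!is.null(st) && startsWith(st, "M")) {
          b <- substring(st, 2)
          col <- if (m$orient == "REVERSE") tolower(b) else b
          counters[p, col] <- counters[p, col] + 1L
        }
        here_del <- identical(st, "D")
        prev_del <- identical(st_prev, "D")
        if (p > 1) {
          if (here_del && prev_del) dbl_n[p] <- dbl_n[p] + 1L
          if (here_del && !prev_del) dir_n[p] <- dir_n[p] + 1L
          if (!here_del && prev_del) del_n[p] <- del_n[p] + 1L
        } else if (here_del) dir_n[p] <- dir_n[p] + 1L
      }
    }
    cov <- rowSums(counters)
    arr <- numeric(L)
    for (p in seq_len(L - 1))
      if (cov[p + 1] > 0)
        arr[p] <- min(max((cov[p + 1] - cov[p]) / cov[p + 1], 0), 1)
    keep <- which(cov >= min_cov)
    if (!length(keep)) next
    rows <- lapply(keep, function(p) {
      matches <- counters[p, seq_chars[p]] +
        counters[p, tolower(seq_chars[p])]
      cbind(data.frame(ref_seg = rs,
                       mod = rtsig:::annotation_lookup(rs, p, ann),
                       pos = p, ref_base = seq_chars[p],
                       cov = as.integer(cov[p]),
                       pre_base = if (p < L) seq_chars[p + 1] else "",
                       mism_rate = (cov[p] - matches) / cov[p],
                       stringsAsFactors = FALSE),
            as.data.frame(t(counters[p, ])),
            data.frame(
              single_jump_rate_direct =
                if (span[p] > 0) dir_n[p] / span[p] else 0,
              single_jump_rate_delayed =
                if (span[p] > 0 && p > 1) del_n[p] / span[p] else 0,
              double_jump_rate =
                if (span[p] > 0 && p > 1) dbl_n[p] / span[p] else 0,
              arrest_rate = arr[p]))
    })
    out[[rs]] <- do.call(rbind, rows)
  }
  if (!length(out)) return(rtsig:::empty_profile())
  res <- do.call(rbind, out)
  res <- res[order(res$ref_seg, res$pos), ]
  rownames(res) <- NULL
  res
}
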
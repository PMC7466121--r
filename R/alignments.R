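#' Construct an alignment table
#'
#' The package represents read alignments as a plain `data.frame` with one
#' row per aligned record:
#'
#' * `read_id` — read name,
#' * `ref_seg` — reference identifier,
#' * `start` — 1-based leftmost reference position,
#' * `cigar` — CIGAR string over the operations `M` (aligned),
#'   `D` (deletion), `I` (insertion), `S` (soft clip),
#' * `query` — read bases over `A/C/G/T/N` consumed by `M`, `I` and `S`,
#' * `orientation` — `"FORWARD"` (first-in-pair / R1) or `"REVERSE"`
#'   (second-in-pair / R2); forward reads feed the capital-letter base
#'   counters of the profile table, reverse reads the small-letter ones.
#'
#' @param read_id,ref_seg,start,cigar,query,orientation vectors of equal
#'   length as described above.
#' @param refs optional `"ReferenceSet"` used to check that every footprint
#'   stays within its reference.
#' @return a `data.frame` of class `"rt_alignments"`.
#' @export
aligned_reads <- function(read_id, ref_seg, start, cigar, query, orientation,
                          refs = NULL) {
  reads <- data.frame(read_id = as.character(read_id),
                      ref_seg = as.character(ref_seg),
                      start = as.integer(start),
                      cigar = as.character(cigar),
                      query = toupper(as.character(query)),
                      orientation = as.character(orientation),
                      stringsAsFactors = FALSE)
  validate_alignments(reads, refs)
}

#' Validate an alignment table
#'
#' @param reads an alignment `data.frame` (see [aligned_reads()]).
#' @inheritParams aligned_reads
#' @return `reads` with class `"rt_alignments"`.
#' @export
validate_alignments <- function(reads, refs = NULL) {
  need <- c("read_id", "ref_seg", "start", "cigar", "query", "orientation")
  missing <- setdiff(need, names(reads))
  if (length(missing))
    stop("alignment table misses column(s): ", paste(missing, collapse = ", "))
  if (nrow(reads)) {
    if (any(!reads$orientation %in% c("FORWARD", "REVERSE")))
      stop("orientation must be FORWARD or REVERSE")
    if (any(reads$start < 1))
      stop("alignment start positions are 1-based")
    bad <- grepl("[^ACGTN]", reads$query)
    if (any(bad))
      stop("query bases outside A/C/G/T/N for read ",
           reads$read_id[which(bad)[1]])
    ops <- lapply(reads$cigar, parse_cigar)
    qlen <- vapply(ops, function(o)
      sum(o$len[o$op %in% c("M", "I", "S")]), integer(1))
    if (any(qlen != nchar(reads$query))) {
      i <- which(qlen != nchar(reads$query))[1]
      stop("CIGAR/query length mismatch for read ", reads$read_id[i])
    }
    if (!is.null(refs)) {
      refs <- as_reference_set(refs)
      unknown <- setdiff(reads$ref_seg, names(refs))
      if (length(unknown))
        stop("alignment references sequence(s) absent from the reference ",
             "set: ", paste(unknown, collapse = ", "))
      span <- vapply(ops, function(o)
        sum(o$len[o$op %in% c("M", "D")]), integer(1))
      len <- ref_lengths(refs)[reads$ref_seg]
      over <- reads$start + span - 1L > len
      if (any(over))
        stop("alignment footprint exceeds reference length for read ",
             reads$read_id[which(over)[1]])
    }
  }
  class(reads) <- c("rt_alignments", "data.frame")
  reads
}

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string, e.g. `"10M1D5M"`.
#' @return a list with integer vector `len` and character vector `op`.
#' @examples
#' parse_cigar("10M1D5M")
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*")
    stop("malformed CIGAR: '", cigar, "'")
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) ||
      paste0(paste0(lens, ops, collapse = ""), "") != cigar)
    stop("malformed CIGAR: '", cigar, "'")
  if (any(!ops %in% c("M", "D", "I", "S")))
    stop("unsupported CIGAR operation '",
         setdiff(ops, c("M", "D", "I", "S"))[1], "' in '", cigar, "'")
  list(op = ops, len = as.integer(lens))
}

#' Read alignments from SAM or BAM
#'
#' Ingests mapped, primary alignment records. Files ending in `.sam` are
#' converted on the fly with [Rsamtools::asBam()]. Unmapped, secondary and
#' supplementary records are skipped. Orientation is taken from the
#' read-pairing flags: first-in-pair (0x40) reads become `FORWARD`,
#' second-in-pair (0x80) become `REVERSE`, unpaired reads `FORWARD` —
#' for single-stranded (t)RNA references the capital/small-letter split of
#' the profile table reflects the sequenced mate, not a genomic strand.
#'
#' @param path path to a SAM or BAM file.
#' @param refs a `"ReferenceSet"`; an error names any alignment reference
#'   absent from it.
#' @return an `"rt_alignments"` data frame.
#' @export
read_alignments <- function(path, refs) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  refs <- as_reference_set(refs)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  unknown <- setdiff(names(targets), names(refs))
  if (length(unknown))
    stop("alignment header names reference(s) absent from the reference ",
         "set: ", paste(unknown, collapse = ", "))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(rec$qname) == 0) {
    return(aligned_reads(character(0), character(0), integer(0),
                         character(0), character(0), character(0)))
  }
  orientation <- ifelse(bitwAnd(rec$flag, 128L) > 0L, "REVERSE", "FORWARD")
  reads <- aligned_reads(read_id = rec$qname,
                         ref_seg = as.character(rec$rname),
                         start = rec$pos,
                         cigar = rec$cigar,
                         query = as.character(rec$seq),
                         orientation = orientation,
                         refs = refs)
  message(nrow(reads), " mapped primary alignment(s) read from ", path)
  reads
}

#' Write alignments to SAM
#'
#' Emits a SAM file with an `@SQ` header derived from `refs`. Orientation is
#' encoded in the pairing flags ([read_alignments()] inverts the mapping):
#' `FORWARD` reads sharing their `read_id` with a `REVERSE` record get flag
#' 65 (paired, first in pair), lone `FORWARD` reads flag 0, `REVERSE` reads
#' flag 129 (paired, second in pair).
#'
#' @param reads an `"rt_alignments"` data frame.
#' @param refs the `"ReferenceSet"` the reads are aligned to.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, refs, path) {
  refs <- as_reference_set(refs)
  reads <- validate_alignments(reads, refs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), ref_lengths(refs)),
             con)
  if (nrow(reads)) {
    has_mate <- reads$read_id %in% reads$read_id[reads$orientation == "REVERSE"]
    flag <- ifelse(reads$orientation == "REVERSE", 129L,
                   ifelse(has_mate, 65L, 0L))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                       reads$read_id, flag, reads$ref_seg, reads$start,
                       reads$cigar, reads$query), con)
  }
  invisible(path)
}
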
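#' Construct a validated reference set
#'
#' A reference set maps reference identifiers (typically pipe-delimited tRNA
#' database identifiers such as
#' `"tdbR00000369|Saccharomyces_cerevisiae|4932|Arg|ACG"`) to nucleotide
#' sequences. Sequences are stored in the DNA alphabet; `U`/`u` is
#' normalized to `T`.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @return a named character vector of class `"ReferenceSet"`.
#' @examples
#' refs <- reference_set(c(ref1 = "ACGU"))
#' unname(refs["ref1"])
#' @export
reference_set <- function(sequences) {
  if (length(sequences) == 0) stop("reference set is empty")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every reference sequence needs a non-empty identifier")
  if (anyDuplicated(ids))
    stop("duplicate reference identifier: ", ids[duplicated(ids)][1])
  seqs <- chartr("Uu", "Tt", toupper(as.character(sequences)))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in reference '", ids[which(bad)[1]], "'")
  structure(setNames(seqs, ids), class = "ReferenceSet")
}

#' Read a reference FASTA file
#'
#' Reads a nucleotide FASTA file into a [reference_set()]. Identifiers are
#' taken verbatim from the header line up to the first whitespace, so
#' pipe-delimited tRNA identifiers stay intact. `U` is normalized to `T`.
#'
#' @param path path to a FASTA file.
#' @return a `"ReferenceSet"` named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(x))
  reference_set(setNames(as.character(x), ids))
}

#' Write a reference set to FASTA
#'
#' @param refs a `"ReferenceSet"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  refs <- as_reference_set(refs)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(as.character(refs), names(refs))),
    path)
  invisible(path)
}

as_reference_set <- function(refs) {
  if (inherits(refs, "ReferenceSet")) return(refs)
  reference_set(refs)
}

ref_lengths <- function(refs) setNames(nchar(as.character(refs)), names(refs))
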
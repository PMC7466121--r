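#' Read a modification annotation table
#'
#' The annotation table lists known modified sites in the style of the
#' Modomics / tRNAdb compilations: one row per site with the reference
#' identifier, the 1-based position and a modification short code
#' (e.g. `m1A`, `m22G`, `m1G`, `m3C`). Tab-separated with a header naming
#' the columns `ref_seg`, `pos` and `mod`.
#'
#' @param path path to the TSV file.
#' @param refs optional `"ReferenceSet"`; when supplied, positions are
#'   validated against the sequence lengths.
#' @return a `data.frame` with columns `ref_seg`, `pos`, `mod`.
#' @export
read_annotation <- function(path, refs = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  need <- c("ref_seg", "pos", "mod")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop("annotation file misses required column(s): ",
         paste(missing, collapse = ", "))
  ann <- ann[, need]
  pos <- suppressWarnings(as.integer(ann$pos))
  if (anyNA(pos)) stop("non-integer position in annotation row ",
                       which(is.na(pos))[1])
  ann$pos <- pos
  validate_annotation(ann, refs)
}

#' Validate a modification annotation
#'
#' Checks the annotation invariants: 1-based positions, unique
#' `(ref_seg, pos)` pairs and (if `refs` is given) positions within the
#' referenced sequence.
#'
#' @param ann a `data.frame` with columns `ref_seg`, `pos`, `mod`.
#' @inheritParams read_annotation
#' @return `ann`, with `pos` as integer, invisibly valid.
#' @export
validate_annotation <- function(ann, refs = NULL) {
  stopifnot(is.data.frame(ann), all(c("ref_seg", "pos", "mod") %in% names(ann)))
  ann$pos <- as.integer(ann$pos)
  if (nrow(ann) == 0) return(ann)
  if (any(ann$pos < 1))
    stop("annotation positions are 1-based; found pos ",
         ann$pos[ann$pos < 1][1])
  key <- paste(ann$ref_seg, ann$pos)
  if (anyDuplicated(key))
    stop("duplicate annotation for (", key[duplicated(key)][1], ")")
  if (any(!nzchar(ann$mod))) stop("empty modification code in annotation")
  if (!is.null(refs)) {
    refs <- as_reference_set(refs)
    unknown <- setdiff(ann$ref_seg, names(refs))
    if (length(unknown))
      stop("annotation references unknown sequence: ", unknown[1])
    len <- ref_lengths(refs)[ann$ref_seg]
    over <- ann$pos > len
    if (any(over))
      stop("annotation position ", ann$pos[over][1], " exceeds length of ",
           ann$ref_seg[over][1])
  }
  ann
}

#' Write a modification annotation table
#'
#' @inheritParams validate_annotation
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  ann <- validate_annotation(ann)
  write.table(ann[, c("ref_seg", "pos", "mod")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fast (ref_seg, pos) -> mod lookup; returns "" where unannotated
annotation_lookup <- function(ref_seg, pos, ann) {
  if (is.null(ann) || nrow(ann) == 0) return(character(length(ref_seg)))
  idx <- match(paste(ref_seg, pos), paste(ann$ref_seg, ann$pos))
  out <- character(length(ref_seg))
  out[!is.na(idx)] <- ann$mod[idx[!is.na(idx)]]
  out
}
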
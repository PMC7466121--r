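#' Profile table column order
#'
#' The 21 columns of the per-position profile table, in serialization order:
#' reference identifier, modification code (empty when unannotated), 1-based
#' position, reference base, coverage, 3'-preceding base, mismatch rate, ten
#' orientation-split base counters (capital letters forward, small letters
#' reverse), the three jump rates and the arrest rate.
#'
#' @return character vector of column names.
#' @export
profile_columns <- function() {
  c("ref_seg", "mod", "pos", "ref_base", "cov", "pre_base", "mism_rate",
    "A", "G", "T", "C", "N", "a", "g", "t", "c", "n",
    "single_jump_rate_direct", "single_jump_rate_delayed",
    "double_jump_rate", "arrest_rate")
}

#' @rdname profile_columns
#' @export
count_columns <- function() c("A", "G", "T", "C", "N", "a", "g", "t", "c", "n")

#' @rdname profile_columns
#' @export
rate_columns <- function() {
  c("mism_rate", "single_jump_rate_direct", "single_jump_rate_delayed",
    "double_jump_rate", "arrest_rate")
}

#' Validate a profile table
#'
#' Checks the structural invariants of a profile table: complete column set,
#' coverage equal to the sum of the ten base counters, and all rates within
#' `[0, 1]`.
#'
#' @param profiles a profile `data.frame` (see [profile_columns()]).
#' @return `profiles`, column-ordered, invisibly valid.
#' @export
validate_profiles <- function(profiles) {
  missing <- setdiff(profile_columns(), names(profiles))
  if (length(missing))
    stop("profile table misses column(s): ", paste(missing, collapse = ", "))
  profiles <- profiles[, profile_columns()]
  if (nrow(profiles)) {
    csum <- rowSums(profiles[, count_columns()])
    if (any(csum != profiles$cov)) {
      i <- which(csum != profiles$cov)[1]
      stop("coverage does not equal the base-counter sum at ",
           profiles$ref_seg[i], ":", profiles$pos[i])
    }
    for (rc in rate_columns()) {
      v <- profiles[[rc]]
      if (any(v < 0 | v > 1, na.rm = TRUE))
        stop(rc, " outside [0, 1]")
    }
  }
  profiles
}

#' Write / read the per-position profile table
#'
#' `write_profile()` serializes profile rows as a tab-separated table with
#' the exact header of [profile_columns()]; rates are printed with five
#' decimal places, counts and positions as plain integers. `read_profile()`
#' is its inverse and is lossless at that precision.
#'
#' @param profiles a profile `data.frame`.
#' @param path file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns the profile `data.frame`.
#' @export
write_profile <- function(profiles, path) {
  profiles <- validate_profiles(profiles)
  out <- profiles
  for (rc in rate_columns()) out[[rc]] <- sprintf("%.5f", profiles[[rc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  expect <- profile_columns()
  if (length(header) != length(expect) || any(header != expect)) {
    i <- which(header[seq_along(expect)] != expect |
                 is.na(header[seq_along(expect)]))[1]
    stop("profile header mismatch at column ", i, ": expected '",
         expect[i], "', found '", header[i], "'")
  }
  classes <- c(ref_seg = "character", mod = "character", pos = "integer",
               ref_base = "character", cov = "integer", pre_base = "character",
               setNames(rep("numeric", 5), rate_columns()),
               setNames(rep("integer", 10), count_columns()))
  profiles <- read.delim(path, header = TRUE, sep = "\t",
                         colClasses = classes[expect], check.names = FALSE,
                         na.strings = NULL)
  validate_profiles(profiles)
}

empty_profile <- function() {
  validate_profiles(data.frame(
    ref_seg = character(0), mod = character(0), pos = integer(0),
    ref_base = character(0), cov = integer(0), pre_base = character(0),
    mism_rate = numeric(0),
    A = integer(0), G = integer(0), T = integer(0), C = integer(0),
    N = integer(0), a = integer(0), g = integer(0), t = integer(0),
    c = integer(0), n = integer(0),
    single_jump_rate_direct = numeric(0),
    single_jump_rate_delayed = numeric(0),
    double_jump_rate = numeric(0), arrest_rate = numeric(0),
    stringsAsFactors = FALSE))
}
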
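#' Extract one RT-signature feature from a profile table
#'
#' @param profiles a profile `data.frame`.
#' @param feature one of `"arrest"`, `"mismatch"`, `"jump_direct"`,
#'   `"jump_delayed"`, `"jump_double"`, `"jump_total"` (the per-position
#'   sum of the three jump classes).
#' @return numeric vector of per-position feature values.
#' @export
feature_values <- function(profiles, feature) {
  feature <- match.arg(feature, c("arrest", "mismatch", "jump_direct",
                                  "jump_delayed", "jump_double",
                                  "jump_total"))
  switch(feature,
         arrest = profiles$arrest_rate,
         mismatch = profiles$mism_rate,
         jump_direct = profiles$single_jump_rate_direct,
         jump_delayed = profiles$single_jump_rate_delayed,
         jump_double = profiles$double_jump_rate,
         jump_total = profiles$single_jump_rate_direct +
           profiles$single_jump_rate_delayed + profiles$double_jump_rate)
}

# rows matching a modification filter; "unmodified" selects unannotated
# positions. When `ann` is supplied it overrides the profile's mod column.
select_positions <- function(profiles, ann = NULL, mod_filter) {
  mods <- if (is.null(ann)) profiles$mod
          else annotation_lookup(profiles$ref_seg, profiles$pos, ann)
  if (identical(mod_filter, "unmodified")) which(!nzchar(mods))
  else which(mods == mod_filter)
}

#' Summarise one feature over a set of positions
#'
#' Computes the median and mean of a feature over all profile positions
#' matching a modification filter, with 95% bootstrap percentile confidence
#' intervals for both (10,000 resamples by default, fixed seed for
#' reproducibility) — the accumulated representation behind per-condition
#' box/violin summaries of RT signatures.
#'
#' @inheritParams feature_values
#' @param ann optional modification annotation overriding the profile's
#'   `mod` column.
#' @param mod_filter modification code, or `"unmodified"` for unannotated
#'   positions.
#' @param condition label stored in the output.
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param seed RNG seed for the bootstrap (caller's RNG state restored).
#' @return one-row `data.frame` of class `"SignatureSummary"` with
#'   `mod`, `feature`, `condition`, `n_positions`, `median`, `mean`, the
#'   CI bounds and `p_vs_reference` (`NA` until filled by
#'   [compare_conditions()]).
#' @export
summarize_signature <- function(profiles, ann = NULL, mod_filter, feature,
                                condition = NA_character_, n_boot = 10000,
                                seed = 1L) {
  idx <- select_positions(profiles, ann, mod_filter)
  if (length(idx) == 0)
    stop("no profile positions match mod_filter '", mod_filter, "'")
  v <- feature_values(profiles[idx, , drop = FALSE], feature)
  n <- length(v)
  if (n == 1) {
    ci_med <- ci_mean <- c(v, v)
  } else {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
    m <- matrix(v[sample.int(n, n * n_boot, replace = TRUE)],
                nrow = n_boot, ncol = n)
    bmean <- rowMeans(m)
    bmed <- apply(m, 1, median)
    ci_med <- unname(quantile(bmed, c(0.025, 0.975)))
    ci_mean <- unname(quantile(bmean, c(0.025, 0.975)))
  }
  out <- data.frame(mod = mod_filter, feature = feature,
                    condition = condition, n_positions = n,
                    median = median(v), mean = mean(v),
                    ci95_median_lo = ci_med[1], ci95_median_hi = ci_med[2],
                    ci95_mean_lo = ci_mean[1], ci95_mean_hi = ci_mean[2],
                    p_vs_reference = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("SignatureSummary", "data.frame")
  out
}

#' Compare one feature between two reaction conditions
#'
#' Matches positions present (i.e. passing the coverage filter) in both
#' profile sets on `(ref_seg, pos)`, computes per-position deltas
#' (`treated - reference`, the normalized-reference representation of
#' condition effects) and tests the matched deltas with a two-sided
#' Wilcoxon signed-rank test; a difference is flagged significant at
#' p < 0.05. With fewer than two matched positions the p-value is `NA`.
#'
#' @param reference,treated profile `data.frame`s derived from the same
#'   reference set.
#' @inheritParams summarize_signature
#' @param alpha significance level for the `significant` flag.
#' @return a list of class `"rt_comparison"`: `reference` and `treated`
#'   summaries (the treated one carrying `p_vs_reference`), `p_value`,
#'   `significant`, `n_matched` and `deltas` (a `data.frame` with
#'   `ref_seg`, `pos`, `mod`, `feature`, `value_reference`,
#'   `value_treated`, `delta`).
#' @export
compare_conditions <- function(reference, treated, ann = NULL, mod_filter,
                               feature, n_boot = 10000, seed = 1L,
                               alpha = 0.05) {
  iref <- select_positions(reference, ann, mod_filter)
  itre <- select_positions(treated, ann, mod_filter)
  if (length(iref) == 0 || length(itre) == 0)
    stop("no profile positions match mod_filter '", mod_filter,
         "' in both conditions")
  ref <- reference[iref, , drop = FALSE]
  tre <- treated[itre, , drop = FALSE]
  key_ref <- paste(ref$ref_seg, ref$pos)
  key_tre <- paste(tre$ref_seg, tre$pos)
  common <- intersect(key_ref, key_tre)
  mref <- ref[match(common, key_ref), , drop = FALSE]
  mtre <- tre[match(common, key_tre), , drop = FALSE]
  v_ref <- feature_values(mref, feature)
  v_tre <- feature_values(mtre, feature)
  deltas <- data.frame(ref_seg = mref$ref_seg, pos = mref$pos,
                       mod = mref$mod, feature = feature,
                       value_reference = v_ref, value_treated = v_tre,
                       delta = v_tre - v_ref, stringsAsFactors = FALSE)
  n_matched <- nrow(deltas)
  p <- NA_real_
  if (n_matched >= 2 && any(deltas$delta != 0)) {
    p <- suppressWarnings(
      wilcox.test(v_tre, v_ref, paired = TRUE, exact = FALSE,
                  alternative = "two.sided")$p.value)
  } else if (n_matched >= 2) {
    p <- 1   # identical matched values: no evidence of a shift
  }
  sum_ref <- summarize_signature(reference, ann, mod_filter, feature,
                                 condition = "reference", n_boot = n_boot,
                                 seed = seed)
  sum_tre <- summarize_signature(treated, ann, mod_filter, feature,
                                 condition = "treated", n_boot = n_boot,
                                 seed = seed)
  sum_tre$p_vs_reference <- p
  structure(list(reference = sum_ref, treated = sum_tre, p_value = p,
                 significant = isTRUE(p < alpha), n_matched = n_matched,
                 deltas = deltas),
            class = "rt_comparison")
}

#' @export
print.rt_comparison <- function(x, ...) {
  s <- rbind(as.data.frame(x$reference), as.data.frame(x$treated))
  cat(sprintf("RT signature comparison: %s / %s (%d matched positions)\n",
              s$mod[1], s$feature[1], x$n_matched))
  print(s[, c("condition", "n_positions", "median", "mean",
              "ci95_mean_lo", "ci95_mean_hi")], row.names = FALSE, ...)
  cat(sprintf("mean delta (treated - reference): %+0.4f\n",
              mean(x$deltas$delta)))
  cat(sprintf("Wilcoxon signed-rank p = %s%s\n",
              format.pval(x$p_value, digits = 3),
              if (x$significant) " (*)" else ""))
  invisible(x)
}

#' Fraction of positions exceeding a feature threshold
#'
#' The percentage of selected positions whose feature value lies strictly
#' above `threshold`; with the default threshold 0 this is the fraction of
#' positions bearing the feature at all (e.g. "positions bearing a jump").
#'
#' @inheritParams summarize_signature
#' @param threshold feature threshold (default 0).
#' @param mod_filter optional modification code or `"unmodified"`; `NULL`
#'   selects all positions.
#' @return percentage in `[0, 100]`.
#' @export
prevalence <- function(profiles, ann = NULL, feature, threshold = 0,
                       mod_filter = NULL) {
  if (nrow(profiles) == 0) stop("empty profile table")
  idx <- if (is.null(mod_filter)) seq_len(nrow(profiles))
         else select_positions(profiles, ann, mod_filter)
  if (length(idx) == 0)
    stop("no profile positions match mod_filter '", mod_filter, "'")
  v <- feature_values(profiles[idx, , drop = FALSE], feature)
  100 * mean(v > threshold)
}

#' Composition of misincorporated bases
#'
#' Merges the forward and reverse base counters of the selected positions,
#' drops each position's reference base, and normalizes the remaining
#' (mismatching) incorporation counts to fractions summing to 1 —
#' optionally stratified by the 3'-preceding base, whose identity is known
#' to shape the misincorporation pattern.
#'
#' @inheritParams summarize_signature
#' @param mod_filter optional modification code or `"unmodified"`; `NULL`
#'   selects all positions.
#' @param group_by_prebase stratify by the `pre_base` column.
#' @return a `data.frame` with one row per stratum (single row when
#'   unstratified): `pre_base` (when stratified), `n_positions`,
#'   `n_mismatch_bases` and fractions `A`, `C`, `G`, `T`, `N`.
#' @export
mismatch_composition <- function(profiles, ann = NULL, mod_filter = NULL,
                                 group_by_prebase = FALSE) {
  idx <- if (is.null(mod_filter)) seq_len(nrow(profiles))
         else select_positions(profiles, ann, mod_filter)
  if (length(idx) == 0)
    stop("no profile positions match mod_filter '", mod_filter, "'")
  sel <- profiles[idx, , drop = FALSE]
  bases <- c("A", "C", "G", "T", "N")
  merged <- sapply(bases, function(b)
    sel[[b]] + if (b == "N") sel[["n"]] else sel[[tolower(b)]])
  merged <- matrix(merged, ncol = 5, dimnames = list(NULL, bases))
  for (b in c("A", "C", "G", "T"))
    merged[sel$ref_base == b, b] <- 0
  groups <- if (group_by_prebase) sel$pre_base else rep("all", nrow(sel))
  rows <- lapply(sort(unique(groups)), function(g) {
    tot <- colSums(merged[groups == g, , drop = FALSE])
    if (sum(tot) == 0)
      stop("no mismatching bases in selection",
           if (group_by_prebase) paste0(" (prebase ", g, ")") else "")
    out <- data.frame(n_positions = sum(groups == g),
                      n_mismatch_bases = sum(tot), stringsAsFactors = FALSE)
    if (group_by_prebase) out <- cbind(pre_base = g, out,
                                       stringsAsFactors = FALSE)
    cbind(out, as.data.frame(t(tot / sum(tot))))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
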
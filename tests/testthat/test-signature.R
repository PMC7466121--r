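# small synthetic profile table: 4 m1A sites, 3 unmodified, 1 m22G
demo_profiles <- function() {
  mk <- function(ref, pos, mod, ref_base, fwd, rev, jumps, arrest) {
    counts <- setNames(as.list(c(fwd, rev)), count_columns())
    cov <- sum(fwd) + sum(rev)
    matches <- fwd[match(ref_base, c("A", "G", "T", "C"))] +
      rev[match(ref_base, c("A", "G", "T", "C"))]
    cbind(data.frame(ref_seg = ref, mod = mod, pos = pos,
                     ref_base = ref_base, cov = cov, pre_base = "G",
                     mism_rate = (cov - matches) / cov,
                     stringsAsFactors = FALSE),
          as.data.frame(counts),
          data.frame(single_jump_rate_direct = jumps[1],
                     single_jump_rate_delayed = jumps[2],
                     double_jump_rate = jumps[3], arrest_rate = arrest))
  }
  validate_profiles(rbind(
    mk("r1", 10, "m1A", "A", c(10, 39, 24, 7, 0), c(0, 58, 25, 4, 0),
       c(0.00, 0.02, 0.02), 0.25),
    mk("r1", 20, "m1A", "A", c(50, 10, 10, 10, 0), c(20, 0, 0, 0, 0),
       c(0.01, 0.00, 0.00), 0.45),
    mk("r1", 30, "m1A", "A", c(30, 5, 5, 0, 0), c(10, 0, 0, 0, 0),
       c(0.00, 0.00, 0.00), 0.35),
    mk("r2", 15, "m1A", "A", c(40, 0, 0, 0, 0), c(20, 0, 0, 0, 0),
       c(0.10, 0.05, 0.05), 0.15),
    mk("r2", 40, "m22G", "G", c(5, 30, 5, 0, 0), c(0, 10, 0, 0, 0),
       c(0.00, 0.00, 0.00), 0.60),
    mk("r1", 5, "", "C", c(0, 0, 0, 30, 0), c(0, 0, 0, 10, 0),
       c(0, 0, 0), 0.00),
    mk("r1", 6, "", "T", c(0, 0, 30, 0, 0), c(0, 0, 10, 0, 0),
       c(0, 0, 0.01), 0.01),
    mk("r2", 7, "", "G", c(0, 30, 0, 0, 0), c(0, 15, 0, 0, 0),
       c(0, 0, 0), 0.00)))
}

test_that("summarize_signature computes point estimates and CIs", {
  prof <- demo_profiles()
  s <- summarize_signature(prof, mod_filter = "m1A", feature = "arrest",
                           n_boot = 500)
  expect_identical(s$n_positions, 4L)
  expect_equal(s$mean, mean(c(0.25, 0.45, 0.35, 0.15)))
  expect_equal(s$median, median(c(0.25, 0.45, 0.35, 0.15)))
  expect_lte(s$ci95_mean_lo, s$mean)
  expect_gte(s$ci95_mean_hi, s$mean)
  expect_lte(s$ci95_median_lo, s$median)
  expect_gte(s$ci95_median_hi, s$median)

  # single position: degenerate point interval
  s1 <- summarize_signature(prof, mod_filter = "m22G", feature = "arrest")
  expect_equal(s1$median, 0.6)
  expect_identical(s1$ci95_mean_lo, s1$ci95_mean_hi)

  # constant values: zero-width interval
  const <- prof
  const$arrest_rate <- 0.3
  sc <- summarize_signature(const, mod_filter = "m1A", feature = "arrest",
                            n_boot = 200)
  expect_equal(sc$ci95_mean_lo, 0.3)
  expect_equal(sc$ci95_mean_hi, 0.3)

  # jump_total sums the three classes per position
  sj <- summarize_signature(prof, mod_filter = "m22G",
                            feature = "jump_total")
  expect_equal(sj$mean, 0)
  sj4 <- summarize_signature(prof, mod_filter = "m1A",
                             feature = "jump_total", n_boot = 100)
  expect_equal(sj4$mean, mean(c(0.04, 0.01, 0, 0.2)))

  expect_error(summarize_signature(prof, mod_filter = "m5C",
                                   feature = "arrest"), "no profile")
})

test_that("bootstrap confidence intervals are seed-deterministic", {
  prof <- demo_profiles()
  s1 <- summarize_signature(prof, mod_filter = "m1A", feature = "mismatch",
                            n_boot = 1000, seed = 7)
  s2 <- summarize_signature(prof, mod_filter = "m1A", feature = "mismatch",
                            n_boot = 1000, seed = 7)
  expect_identical(s1, s2)
})

test_that("compare_conditions on identical profiles finds no difference", {
  prof <- demo_profiles()
  cmp <- compare_conditions(prof, prof, mod_filter = "m1A",
                            feature = "arrest", n_boot = 100)
  expect_true(all(cmp$deltas$delta == 0))
  expect_false(cmp$significant)
  expect_identical(cmp$n_matched, 4L)
})

test_that("compare_conditions deltas are antisymmetric", {
  prof <- demo_profiles()
  shifted <- prof
  shifted$arrest_rate <- pmin(shifted$arrest_rate + c(0.1, 0.2, 0, 0.05,
                                                      0.1, 0, 0, 0.3), 1)
  ab <- compare_conditions(prof, shifted, mod_filter = "m1A",
                           feature = "arrest", n_boot = 100)
  ba <- compare_conditions(shifted, prof, mod_filter = "m1A",
                           feature = "arrest", n_boot = 100)
  expect_equal(ab$deltas$delta, -ba$deltas$delta)
  expect_equal(ab$p_value, ba$p_value)

  # fewer than two matched positions: p undefined
  single <- compare_conditions(prof[prof$pos == 40, ],
                               prof[prof$pos == 40, ],
                               mod_filter = "m22G", feature = "arrest",
                               n_boot = 50)
  expect_true(is.na(single$p_value))
  expect_false(single$significant)
})

test_that("prevalence counts positions strictly above the threshold", {
  prof <- demo_profiles()
  expect_equal(prevalence(prof, feature = "jump_total",
                          mod_filter = "unmodified"), 100 / 3)
  expect_equal(prevalence(prof, feature = "jump_total",
                          mod_filter = "m1A"), 75)
  expect_equal(prevalence(prof, feature = "arrest", threshold = 0.5), 12.5)
  zero <- prof
  zero$double_jump_rate <- 0
  expect_equal(prevalence(zero, feature = "jump_double"), 0)
})

test_that("mismatch composition normalizes non-reference incorporations", {
  prof <- demo_profiles()
  comp <- mismatch_composition(prof[1, , drop = FALSE])
  # merged mismatching counters at the first site: G 97, T 49, C 11
  expect_equal(comp$G, 97 / 157, tolerance = 1e-12)
  expect_equal(comp$T, 49 / 157, tolerance = 1e-12)
  expect_equal(comp$C, 11 / 157, tolerance = 1e-12)
  expect_equal(comp$A, 0)
  expect_equal(comp$n_mismatch_bases, 157)
  expect_equal(comp$A + comp$C + comp$G + comp$T + comp$N, 1,
               tolerance = 1e-9)

  # only one mismatching base type present
  one <- mismatch_composition(prof[prof$pos == 30, , drop = FALSE])
  expect_equal(one$G, 0.5)
  expect_equal(one$T, 0.5)

  # stratified by prebase: every stratum sums to 1
  strat <- mismatch_composition(prof, mod_filter = "m1A",
                                group_by_prebase = TRUE)
  sums <- rowSums(strat[, c("A", "C", "G", "T", "N")])
  expect_true(all(abs(sums - 1) < 1e-9))

  # unmodified perfect-match selection has no mismatching bases
  expect_error(mismatch_composition(prof[prof$pos == 15, , drop = FALSE]),
               "no mismatching")
})
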
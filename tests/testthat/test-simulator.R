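zero_cond <- function(...) {
  rt_condition_params(label = "test", background = mod_event_params(),
                      n_molecules_per_ref = 20L, read_length = 100L,
                      paired_fraction = 0, ...)
}

test_that("event parameter validation enforces the probability budget", {
  expect_error(mod_event_params(p_arrest = 0.7, p_jump_direct = 0.4),
               "exceed 1")
  expect_error(mod_event_params(mismatch_dist = c(A = 0.5, C = 0.5)),
               "named over")
  expect_error(mod_event_params(
    mismatch_dist = c(A = 0.5, C = 0.3, G = 0.3, T = 0, N = 0)),
    "sum to 1")
  expect_error(rt_condition_params("x",
    background = mod_event_params(p_arrest = 0.2)), "below 0.1")
  expect_error(rt_condition_params("x",
    per_mod = list(mod_event_params())), "named")
})

test_that("error-free synthesis yields full-length perfect reads", {
  refs <- reference_set(c(r1 = "ACGTACGTACGTACGT"))
  sim <- simulate_library(refs, NULL, zero_cond(), seed = 3)
  expect_identical(nrow(sim$reads), 20L)
  expect_true(all(sim$reads$cigar == "16M"))
  expect_true(all(sim$reads$query == refs[["r1"]]))
  expect_true(all(sim$reads$start == 1L))
  expect_identical(sum(sim$truth$n_read_through), 20L * 16L)
  expect_identical(sum(sim$truth$n_mismatch), 0L)
})

test_that("certain arrest truncates every molecule before the site", {
  refs <- reference_set(c(r1 = "ACGTACGTACGTACGT"))
  ann <- data.frame(ref_seg = "r1", pos = 7L, mod = "m1A")
  cond <- zero_cond(per_mod = list(m1A = mod_event_params(p_arrest = 1)))
  sim <- simulate_library(refs, ann, cond, seed = 3)
  expect_true(all(sim$reads$start == 8L))   # site itself left uncovered
  expect_true(all(sim$reads$cigar == "9M"))
  tr <- sim$truth[sim$truth$pos == 7, ]
  expect_identical(tr$n_arrest, 20L)
  expect_identical(sum(sim$truth$n_reached[sim$truth$pos < 7]), 0L)
})

test_that("certain double jump deletes the site and its 5' neighbor", {
  refs <- reference_set(c(r1 = "ACGTACGTACGTACGT"))
  ann <- data.frame(ref_seg = "r1", pos = 7L, mod = "m1A")
  cond <- zero_cond(per_mod = list(m1A = mod_event_params(
    p_jump_double = 1)))
  sim <- simulate_library(refs, ann, cond, seed = 3)
  expect_true(all(sim$reads$cigar == "5M2D9M"))   # deletion spans 6..7
  acc <- accumulate(sim$reads, refs)
  expect_equal(unname(jump_rates(acc, "r1", 7)), c(0, 0, 1))
  expect_equal(unname(jump_rates(acc, "r1", 6)), c(1, 0, 0))
})

test_that("simulation is deterministic per seed and per-reference stream", {
  fx <- make_fixture(1)
  cond <- fx$conditions$reference
  cond$n_molecules_per_ref <- 50L
  s1 <- simulate_library(fx$refs, fx$ann, cond, seed = 11)
  s2 <- simulate_library(fx$refs, fx$ann, cond, seed = 11)
  expect_identical(s1, s2)
  s3 <- simulate_library(fx$refs, fx$ann, cond, seed = 12)
  expect_false(identical(s1$reads, s3$reads))
  # dropping a reference leaves the others' reads untouched
  sub <- reference_set(unclass(fx$refs)[1:2])
  s4 <- simulate_library(sub, fx$ann[fx$ann$ref_seg %in% names(sub), ],
                         cond, seed = 11)
  one <- names(sub)[1]
  expect_identical(s4$reads[s4$reads$ref_seg == one, ],
                   s1$reads[s1$reads$ref_seg == one, ])
})

test_that("zero molecules yield empty reads and zero truth counts", {
  refs <- reference_set(c(r1 = "ACGTACGT"))
  cond <- zero_cond()
  cond$n_molecules_per_ref <- 0L
  sim <- simulate_library(refs, NULL, cond, seed = 1)
  expect_identical(nrow(sim$reads), 0L)
  expect_true(all(sim$truth$n_reached == 0L))
})

test_that("event classes are conserved per reached site", {
  fx <- make_fixture(5)
  cond <- fx$conditions$treated
  cond$n_molecules_per_ref <- 200L
  sim <- simulate_library(fx$refs, fx$ann, cond, seed = 21)
  tr <- sim$truth
  expect_true(all(tr$n_arrest + tr$n_jump_direct + tr$n_jump_delayed +
                    tr$n_jump_double + tr$n_read_through == tr$n_reached))
  # the 3'-terminal position is reached by every molecule
  last <- tr[!duplicated(tr$ref_seg, fromLast = TRUE), ]
  expect_true(all(last$n_reached == 200L))
})

test_that("coverage is non-increasing toward the 5' end without jumps", {
  refs <- reference_set(c(r1 = paste(rep("ACGT", 15), collapse = "")))
  ann <- data.frame(ref_seg = "r1", pos = 30L, mod = "m1A")
  cond <- rt_condition_params(
    label = "arrest_only",
    per_mod = list(m1A = mod_event_params(p_arrest = 0.5)),
    background = mod_event_params(p_arrest = 0.01),
    n_molecules_per_ref = 300L, read_length = 60L, paired_fraction = 0)
  sim <- simulate_library(refs, ann, cond, seed = 8)
  cov <- colSums(accumulate(sim$reads, refs)$r1$counts)
  expect_true(all(diff(cov) >= 0))   # arrests only remove molecules 5'-ward
})

test_that("paired molecules add reverse mates over the 3' window", {
  refs <- reference_set(c(r1 = paste(rep("ACGT", 25), collapse = "")))
  cond <- rt_condition_params(label = "paired",
                              background = mod_event_params(),
                              n_molecules_per_ref = 10L, read_length = 60L,
                              paired_fraction = 0.5)
  sim <- simulate_library(refs, NULL, cond, seed = 2)
  fwd <- sim$reads[sim$reads$orientation == "FORWARD", ]
  rev <- sim$reads[sim$reads$orientation == "REVERSE", ]
  expect_identical(nrow(fwd), 10L)
  expect_identical(nrow(rev), 5L)
  expect_true(all(fwd$start == 1L))          # 5'-most 60 aligned bases
  expect_true(all(rev$start == 41L))         # 3'-proximal 60-base window
})

test_that("arrest leaves the blocking site uncovered in single molecules", {
  refs <- reference_set(c(r1 = "ACGTACGTAC"))
  cond <- zero_cond(per_mod = list(m1A = mod_event_params(p_arrest = 1)))
  set.seed(1)
  m <- simulate_molecule(refs[["r1"]], list(`4` = "m1A"), cond)
  expect_true(m$arrested)
  expect_identical(m$read$start, 5L)
  expect_identical(m$read$cigar, "6M")
  # arrest at the 3'-terminal position leaves nothing to report
  m <- simulate_molecule(refs[["r1"]], list(`10` = "m1A"), cond)
  expect_null(m$read)
})

test_that("modification positions outside the sequence are rejected", {
  cond <- zero_cond()
  expect_error(simulate_molecule("ACGT", list(`9` = "m1A"), cond),
               "outside")
})

test_that("condition YAML round-trips presets exactly", {
  cond <- builtin_presets()$EpiScript_Mn_3mM
  path <- tempfile(fileext = ".yaml")
  write_condition_yaml(cond, path)
  back <- read_condition_yaml(path)
  expect_identical(back$label, cond$label)
  expect_equal(back$per_mod$m1A$p_arrest, 0.24)
  expect_equal(back$per_mod$m1A$mismatch_dist, cond$per_mod$m1A$mismatch_dist)
  expect_equal(back$background$p_mismatch, cond$background$p_mismatch)
  expect_identical(back$read_length, cond$read_length)
})

test_that("built-in presets carry the reported m1A anchors and validate", {
  pr <- builtin_presets()
  expect_true(all(c("EpiScript_Mg_3mM", "EpiScript_Mn_3mM") %in% names(pr)))
  expect_equal(pr$EpiScript_Mg_3mM$per_mod$m1A$p_arrest, 0.82)
  expect_equal(pr$EpiScript_Mn_3mM$per_mod$m1A$p_arrest, 0.24)
  mgd <- pr$EpiScript_Mg_3mM$per_mod$m1A$mismatch_dist
  mnd <- pr$EpiScript_Mn_3mM$per_mod$m1A$mismatch_dist
  expect_equal(unname(1 - mgd["A"]), 0.54)   # misincorporation mass
  expect_equal(unname(1 - mnd["A"]), 0.80)
  for (cond in pr) {
    expect_s3_class(cond, "RTConditionParams")
    for (p in cond$per_mod)
      expect_lte(p$p_arrest + p$p_jump_direct + p$p_jump_delayed +
                   p$p_jump_double, 1)
  }
})

test_that("full-preset estimates match their composite expectations", {
  # with arrest and jumps active simultaneously, the coverage-drop arrest
  # estimator measures p_arrest + p_direct + p_double (deleted sites carry
  # no aligned base) and each jump class measures p/(1 - p_arrest)
  # (arrested molecules never span the site); the mismatch rate stays
  # unbiased for the misincorporation mass
  L <- 50L
  set.seed(66)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  s[25] <- "A"
  refs <- reference_set(c(ref1 = paste(s, collapse = "")))
  ann <- data.frame(ref_seg = "ref1", pos = 25L, mod = "m1A")
  cond <- builtin_presets()$EpiScript_Mg_3mM
  cond$n_molecules_per_ref <- 8000L
  cond$paired_fraction <- 0
  cond$read_length <- L
  sim <- simulate_library(refs, ann, cond, seed = 14)
  prof <- build_profiles(sim$reads, refs, ann, min_cov = 20)
  site <- prof[prof$pos == 25, ]
  p <- cond$per_mod$m1A
  se <- function(pr, m) sqrt(pr * (1 - pr) / m)

  exp_arrest <- p$p_arrest + p$p_jump_direct + p$p_jump_double
  expect_lt(abs(site$arrest_rate - exp_arrest),
            3 * se(exp_arrest, prof$cov[prof$pos == 26]))
  span <- 1 - p$p_arrest
  expect_lt(abs(site$single_jump_rate_direct - p$p_jump_direct / span),
            3 * se(p$p_jump_direct / span, 8000 * span))
  expect_lt(abs(site$double_jump_rate - p$p_jump_double / span),
            3 * se(p$p_jump_double / span, 8000 * span))
  mass <- unname(1 - p$mismatch_dist["A"])
  expect_lt(abs(site$mism_rate - mass), 3 * se(mass, site$cov))
})
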
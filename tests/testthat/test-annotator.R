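# Worked examples for the eight newly described variants: precursor mass,
# sulfation call, desulfated ion, arm loss, cleavage fragment, number of
# 58 Da pairs, terminus loss and hydrophilic-arm type.
arc_expected <- data.frame(
  name = paste0("ARC-", 1:8),
  precursor = c(1226, 1266, 1358, 1398, 1426, 1446, 1506, 1608),
  sulfated = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
  desulfated = c(NA, 1146, NA, 1278, NA, 1326, NA, 1488),
  arm = c(392, 392, 426, 392, 392, 398, 426, 426),
  cleavage = c(834, 754, 932, 886, 1034, 928, 1080, 1062),
  n_pairs = c(0, 0, 0, 0, 2, 0, 2, 2),
  terminus = c(NA, NA, NA, NA, 218, NA, 218, 200),
  type = c("LP-D-type", "LP-D-type", "LP-D-type", "LP-D-type",
           "AM-18-type", "LP-D-type", "AM-18-type", "AM-18-type"))

test_that("the annotator reproduces every fixture worked example", {
  fx <- make_fixture_table1()
  for (i in seq_len(nrow(arc_expected))) {
    e <- arc_expected[i, ]
    rec <- annotate_spectrum(fx$spectra[[e$name]])
    expect_equal(rec$precursor_mz, e$precursor, info = e$name)
    expect_equal(rec$sulfated, e$sulfated, info = e$name)
    if (e$sulfated)
      expect_equal(rec$desulfated_mz, e$desulfated, info = e$name)
    expect_equal(rec$arm_mass, e$arm, info = e$name)
    expect_equal(rec$cleavage_fragment_mz, e$cleavage, info = e$name)
    expect_equal(nrow(rec$carbonyl_pairs), e$n_pairs, info = e$name)
    if (is.na(e$terminus)) expect_true(is.na(rec$terminus_loss))
    else expect_equal(rec$terminus_loss, e$terminus, info = e$name)
    expect_equal(rec$hydrophilic_type, e$type, info = e$name)
    expect_equal(rec$verdict, "novel", info = e$name)
  }
})

test_that("sulfation detection requires the 120 Da fragment", {
  fx <- make_fixture_table1()
  s1 <- fx$spectra[["ARC-1"]]  # 1226, no fragment at 1106
  expect_false(detect_sulfation(s1)$sulfated)
  expect_true(is.na(detect_sulfation(s1)$desulfated_mz))
  s8 <- fx$spectra[["ARC-8"]]
  expect_equal(detect_sulfation(s8), list(sulfated = TRUE,
                                          desulfated_mz = 1488))
})

test_that("arm assignment searches from the desulfated ion when sulfated", {
  # desulfated 1326 loses 398 -> 928 (1326 - 398, subtraction oracle)
  s <- am_spectrum("arc6-like", 1446, 3.2,
                   data.frame(mz = c(928, 1326, 1446),
                              intensity = c(100, 45, 5)))
  res <- assign_arm(s)
  expect_equal(res$arm_mass, 398)
  expect_equal(res$cleavage_fragment_mz, 1326 - 398)
  # no arm-consistent fragment -> absent
  s0 <- am_spectrum("none", 1446, 3.2,
                    data.frame(mz = 700, intensity = 100))
  expect_true(is.na(assign_arm(s0)$arm_mass))
})

test_that("arm tie-breaking is by deviation, intensity, then arm mass", {
  # arm 426 target 1000.2 (off 0.3), arm 392 target 1034.2 (off 0.05)
  s <- am_spectrum("tie", 1426.2, 3,
                   data.frame(mz = c(1000.5, 1034.15),
                              intensity = c(100, 50)))
  expect_equal(assign_arm(s)$arm_mass, 392)  # smaller |delta| wins
  # equal deviation: larger intensity wins
  s2 <- am_spectrum("tie2", 1426, 3,
                    data.frame(mz = c(1000, 1034),
                               intensity = c(100, 50)))
  expect_equal(assign_arm(s2)$arm_mass, 426)
})

test_that("carbonyl pairs are found across the whole fragment list", {
  am18 <- am_spectrum("AM-18-like", 1381, 3.5,
                      data.frame(mz = c(687, 745, 963, 1105, 1163),
                                 intensity = c(40, 50, 100, 45, 55)))
  p <- detect_carbonyl_pairs(am18)
  expect_equal(p$hi_mz, c(1163, 745))
  expect_equal(p$lo_mz, c(1105, 687))
  expect_equal(p$hi_mz - p$lo_mz, c(58, 58))
  # the precursor itself never pairs
  s <- am_spectrum("p", 1000, 3,
                   data.frame(mz = c(942, 1000), intensity = c(50, 5)))
  expect_equal(nrow(detect_carbonyl_pairs(s)), 0)
  expect_equal(nrow(detect_carbonyl_pairs(
    data.frame(mz = c(100, 200), intensity = c(1, 1)))), 0)
})

test_that("terminus losses: 218 from the precursor, 200 from [M-120]", {
  fx <- make_fixture_table1()
  expect_equal(detect_terminus_loss(fx$spectra[["ARC-7"]]), 218)
  expect_equal(detect_terminus_loss(fx$spectra[["ARC-8"]]), 200)
  expect_true(is.na(detect_terminus_loss(fx$spectra[["ARC-1"]])))
  # 218 takes precedence when both would match
  s <- am_spectrum("both", 1500, 3,
                   data.frame(mz = c(1060, 1180, 1282, 1380),
                              intensity = c(60, 50, 45, 40)))
  # 1282 = 1500-218; sulfated via 1380 = 1500-120; 1180 = 1380-200
  expect_equal(detect_terminus_loss(s), 218)
})

test_that("known-variant matching needs Q1, RT and the Q3 fragment", {
  fx <- make_fixture_table1()
  lib <- default_transitions()
  s1 <- fx$spectra[["ARC-1"]]
  expect_equal(match_known(s1, lib), "ARC-1")
  expect_equal(annotate_spectrum(s1, transitions = lib)$verdict,
               "known:ARC-1")
  # a shifted library RT breaks the match at a tight tolerance
  shifted <- lib
  shifted$rt_min[shifted$variant_name == "ARC-1"] <- 3.95
  expect_true(is.na(match_known(s1, shifted, rt_tol = 0.01)))
  expect_true(is.na(match_known(s1, lib[0, ])))
  expect_true(is.na(match_known(s1, NULL)))
})

test_that("novelty requires positive structural evidence", {
  # in-range mass with no rule-consistent fragment stays non-AM
  noise <- am_spectrum("noise", 1400, 3,
                       data.frame(mz = c(333.3, 617.1, 951.7),
                                  intensity = c(40, 100, 60)))
  expect_equal(annotate_spectrum(noise)$verdict, "non-AM")
  # carbonyl pairs alone (no terminus, no arm) are not enough either
  pairs_only <- am_spectrum("pairs", 1400, 3,
                            data.frame(mz = c(700, 758),
                                       intensity = c(50, 60)))
  expect_equal(annotate_spectrum(pairs_only)$verdict, "non-AM")
})

test_that("annotation is deterministic", {
  fx <- make_fixture_table1(n_decoys = 5, seed = 3)
  a <- annotate_spectrum(fx$spectra[[5]])
  b <- annotate_spectrum(fx$spectra[[5]])
  expect_identical(a, b)
})

test_that("record arithmetic is exact on noise-free spectra", {
  set.seed(7)
  for (i in 1:100) {
    spec <- random_variant_spec()
    rec <- annotate_spectrum(make_spectrum(spec))
    if (rec$sulfated)
      expect_identical(rec$desulfated_mz, rec$precursor_mz - 120)
    base <- if (rec$sulfated) rec$desulfated_mz else rec$precursor_mz
    expect_identical(rec$cleavage_fragment_mz, base - rec$arm_mass)
    if (nrow(rec$carbonyl_pairs))
      expect_true(all(rec$carbonyl_pairs$hi_mz -
                        rec$carbonyl_pairs$lo_mz == 58))
  }
})

test_that("the grammar round-trips: all flags recovered, no decoys", {
  set.seed(101)
  n_ok <- 0L
  for (i in 1:500) {
    spec <- random_variant_spec()
    rec <- annotate_spectrum(make_spectrum(spec))
    n_ok <- n_ok + flags_recovered(spec, rec)
  }
  expect_equal(n_ok, 500L)
})

test_that("flag recovery survives up to 5 decoy peaks", {
  set.seed(202)
  n_ok <- 0L
  for (i in 1:200) {
    spec <- random_variant_spec()
    s <- make_spectrum(spec, n_decoys = sample(0:5, 1), seed = 1000 + i)
    n_ok <- n_ok + flags_recovered(spec, annotate_spectrum(s))
  }
  expect_equal(n_ok, 200L)
})
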
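test_that("the default neutral-loss library has 14 channels", {
  lib <- build_nl_library()
  expect_equal(nrow(lib), 14)
  expect_equal(sum(!lib$sulfated), 7)
  expect_equal(sum(lib$sulfated), 7)
  expect_true(all(c(392, 398, 426) %in% lib$loss_da[!lib$sulfated]))
  # the four unpublished arm masses are flagged as placeholders
  expect_equal(sum(lib$provenance == "placeholder"), 8)
  expect_equal(sum(lib$provenance == "main-text"), 6)
})

test_that("custom NL configs are honoured and duplicates rejected", {
  lib <- build_nl_library(list(non_sulfated = c(392, 398, 426)))
  expect_equal(nrow(lib), 3)
  expect_false(any(lib$sulfated))
  expect_error(build_nl_library(list(non_sulfated = c(392, 392))),
               "duplicate")
  expect_error(build_nl_library(list(non_sulfated = -5)), "> 0")
})

test_that("nl_screen finds published arm losses and nothing else", {
  lib <- build_nl_library(list(non_sulfated = c(392, 398, 426)))
  s1 <- am_spectrum("a", 1226, 3.89,
                    data.frame(mz = c(834, 1226), intensity = c(100, 5)))
  h1 <- nl_screen(s1, lib)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$channel, "arm-392")
  expect_equal(h1$q1_mz, 1226)

  s3 <- am_spectrum("c", 1358, 2.90,
                    data.frame(mz = c(932, 1358), intensity = c(100, 5)))
  expect_equal(nl_screen(s3, lib)$channel, "arm-426")

  s0 <- am_spectrum("d", 1226, 3.89,
                    data.frame(mz = c(700, 1226), intensity = c(100, 5)))
  expect_equal(nrow(nl_screen(s0, lib)), 0)
})

test_that("nl_screen agrees with a brute-force pair oracle", {
  lib <- build_nl_library()
  set.seed(42)
  for (i in 1:1000) {
    s <- random_spectrum(sprintf("r%d", i))
    got <- sort(nl_screen(s, lib)$channel)
    want <- nl_screen_oracle(s, lib)
    expect_identical(got, want)
  }
})

test_that("shrinking the m/z tolerance never adds NL hits", {
  lib <- build_nl_library()
  set.seed(43)
  for (i in 1:200) {
    s <- random_spectrum()
    wide <- nl_screen(s, lib, mz_tol = 0.5)
    narrow <- nl_screen(s, lib, mz_tol = 0.1)
    expect_true(all(narrow$channel %in% wide$channel))
  }
})

test_that("full-scan selection respects RT and mass windows", {
  mk <- function(id, prec, rt)
    am_spectrum(id, prec, rt,
                data.frame(mz = c(prec - 400, prec - 300),
                           intensity = c(100, 2)))
  inside <- mk("in", 1358, 2.90)
  low_mz <- mk("lowmz", 999, 3.0)
  edge <- mk("edge", 1506, 4.35)  # just past the 4.2 min window
  far <- mk("far", 1300, 5.5)

  expect_warning(hits <- fs_screen(list(inside, low_mz, edge, far)),
                 "outside the full-scan RT window")
  expect_equal(hits$spectrum_id, "in")
  # the near-boundary case is excluded but reported; the far case silently
  expect_equal(nrow(fs_screen(list(far))), 0)
  expect_error(fs_screen(list(inside), rt_window = c(4, 2)), "inverted")
})

test_that("fs_screen drops Q1 masses already claimed by other modes", {
  s <- am_spectrum("x", 1358, 2.90,
                   data.frame(mz = c(932, 1358), intensity = c(100, 2)))
  prior <- data.frame(spectrum_id = "x", mode = "NL", q1_mz = 1358,
                      channel = "arm-426", rt_min = 2.90, snr = 50)
  expect_equal(nrow(fs_screen(list(s), exclude = prior)), 0)
  expect_equal(nrow(fs_screen(list(s))), 1)
})

test_that("srm_detect matches transitions within tolerances", {
  tab <- default_transitions()
  pk <- data.frame(strain_id = "S1", q1_mz = 1226, q3_mz = 834,
                   rt_min = 3.90)
  hit <- srm_detect(pk, tab)
  expect_equal(hit$channel, "ARC-1")

  pk$rt_min <- 2.00
  expect_equal(nrow(srm_detect(pk, tab, rt_tol = 0.2)), 0)
  expect_equal(nrow(srm_detect(pk[0, ], tab)), 0)
})

test_that("estimate_snr implements the median/MAD formula", {
  # flat trace: no signal
  expect_equal(estimate_snr(rep(1, 10), 4:6), 0)
  # hand-computed oracle: off-peak alternating 9/11 -> median 10, raw MAD
  # 1, noise 1.4826; peak max 40 -> S/N (40-10)/1.4826
  trace <- c(9, 11, 9, 11, 40, 11, 9, 11, 9)
  expect_equal(estimate_snr(trace, 5), (40 - 10) / 1.4826,
               tolerance = 1e-10)
  # noiseless baseline with a real peak -> +Inf sentinel
  expect_equal(estimate_snr(c(rep(5, 8), 50), 9), Inf)
  expect_error(estimate_snr(rep(1, 10), 11), "outside")
})

test_that("three-mode union contains no duplicate Q1 per spectrum", {
  panel <- make_panel(panel_config(n_strains = 9, seed = 5))
  pk <- panel$peak_areas
  pk$q3_mz <- panel$transitions$q3_mz[match(pk$variant_name,
                                            panel$transitions$variant_name)]
  hits <- suppressWarnings(
    screen_spectra(panel$spectra, transitions = panel$transitions,
                   srm_peaks = pk))
  # map SRM hits (strain ids) and spectrum hits to a common scan key
  strain_of <- vapply(panel$spectra, `[[`, "", "strain_id")
  names(strain_of) <- vapply(panel$spectra, `[[`, "", "spectrum_id")
  key <- ifelse(hits$spectrum_id %in% names(strain_of),
                strain_of[hits$spectrum_id], hits$spectrum_id)
  for (k in unique(key)) {
    q1 <- sort(hits$q1_mz[key == k])
    if (length(q1) > 1) expect_true(all(diff(q1) > 0.5))
  }
})
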
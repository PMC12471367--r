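test_that("a minimal MGF block parses into one spectrum", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=s1", "PEPMASS=1226",
               "RTINSECONDS=233.4", "834 100", "754.2 10", "1106 5",
               "END IONS"), path)
  sp <- read_mgf(path)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$precursor_mz, 1226)
  expect_equal(nrow(sp[[1]]$fragments), 3)
  expect_equal(sp[[1]]$rt_min, 233.4 / 60)
  # fragments come back sorted ascending by m/z
  expect_equal(sp[[1]]$fragments$mz, sort(sp[[1]]$fragments$mz))
})

test_that("an empty MGF file yields an empty list with a warning", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), path)
  expect_warning(sp <- read_mgf(path), "no spectra")
  expect_length(sp, 0)
})

test_that("malformed MGF input is rejected with a line-anchored error", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=1226", "834 abc", "END IONS"), path)
  expect_error(read_mgf(path), "line 3")

  writeLines(c("BEGIN IONS", "RTINSECONDS=60", "834 100", "END IONS"),
             path)
  w <- capture_warnings(sp <- read_mgf(path))
  expect_match(w, "missing PEPMASS", all = FALSE)
  expect_length(sp, 0)

  writeLines(c("BEGIN IONS", "PEPMASS=1226", "834 100"), path)
  expect_error(read_mgf(path), "END IONS")
})

test_that("MGF round trip is lossless at the declared precision", {
  fx <- make_fixture_table1(n_decoys = 4, seed = 11)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(fx$spectra, path)
  back <- read_mgf(path)
  expect_length(back, 8)
  expect_equal(vapply(back, `[[`, 0, "precursor_mz"),
               c(1226, 1266, 1358, 1398, 1426, 1446, 1506, 1608),
               ignore_attr = TRUE)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$spectrum_id, fx$spectra[[i]]$spectrum_id)
    expect_equal(back[[i]]$rt_min, fx$spectra[[i]]$rt_min,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$fragments$mz, fx$spectra[[i]]$fragments$mz,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$fragments$intensity,
                 fx$spectra[[i]]$fragments$intensity, tolerance = 0.01)
  }
  # empty list -> file with zero blocks
  path2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(), path2)
  expect_warning(expect_length(read_mgf(path2), 0))
})

test_that("spectrum invariants are enforced", {
  expect_error(am_spectrum("x", -1, 1, data.frame(mz = 1, intensity = 1)),
               "positive")
  expect_error(am_spectrum("x", 1000, 1,
                           data.frame(mz = 1002, intensity = 1)),
               "exceeds precursor")
  expect_error(am_spectrum("x", 1000, 1,
                           data.frame(mz = 500, intensity = -1)),
               ">= 0")
})

test_that("transition tables are read and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variant_name,q1_mz,q3_mz,rt_min,sulfated",
               "ARC-1,1226,834,3.89,false"), path)
  tab <- read_transition_table(path)
  expect_equal(tab$q1_mz, 1226)
  expect_equal(tab$q3_mz, 834)
  expect_false(tab$sulfated)

  writeLines(c("variant_name,q1_mz,q3_mz,rt_min,sulfated",
               "BAD,1226,1300,3.89,false"), path)
  expect_error(read_transition_table(path), "q3_mz must be < q1_mz")

  writeLines(c("variant_name,q1_mz,q3_mz,rt_min,sulfated",
               "A,1226,834,3.89,false", "A,1266,754,3.03,true"), path)
  expect_error(read_transition_table(path), "duplicate variant name")
})

test_that("the shipped default library contains the eight new variants", {
  tab <- default_transitions()
  expect_true(all(paste0("ARC-", 1:8) %in% tab$variant_name))
  expect_equal(tab$q1_mz[match(paste0("ARC-", 1:8), tab$variant_name)],
               c(1226, 1266, 1358, 1398, 1426, 1446, 1506, 1608))
})

test_that("count tables are validated and cross-referenced", {
  cells <- data.frame(strain_id = "S1", n_cells = 1e6,
                      sample_volume_ul = 500)
  assay <- data.frame(
    strain_id = "S1", well_id = paste0("w", 1:9),
    well_type = c(rep("treatment", 3), rep("dmso_control", 3),
                  rep("seawater_control", 3)),
    initial_dead = 0, dead_24h = 2, dead_48h = 5, total = 60)
  cc <- am_counts(cells, assay)
  expect_s3_class(cc, "am_counts")

  bad <- assay; bad$dead_48h[1] <- 70
  expect_error(am_counts(cells, bad), "exceed well total")

  two <- assay[-1, ]
  expect_warning(am_counts(cells, two), "exactly 3 treatment wells")

  orphan <- assay; orphan$strain_id <- "S2"
  expect_warning(am_counts(cells, orphan), "not in cell_counts")

  expect_error(am_counts(data.frame(strain_id = "S1", n_cells = 0,
                                    sample_volume_ul = 500), assay),
               "n_cells")
})

test_that("count tables round-trip through CSV", {
  cells <- data.frame(strain_id = c("S1", "S2"), n_cells = c(1e6, 2e6),
                      sample_volume_ul = 500)
  assay <- expand.grid(strain_id = c("S1", "S2"), w = 1:9)
  assay$well_id <- paste0(assay$strain_id, "-", assay$w)
  assay$well_type <- rep(c(rep("treatment", 3), rep("dmso_control", 3),
                           rep("seawater_control", 3)), each = 2)
  assay$initial_dead <- 0; assay$dead_24h <- 1; assay$dead_48h <- 3
  assay$total <- 60
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(cells, p1, row.names = FALSE)
  write.csv(assay, p2, row.names = FALSE)
  cc <- read_count_tables(p1, p2)
  expect_equal(nrow(cc$assay_counts), 18)
  expect_equal(cc$cell_counts$n_cells, c(1e6, 2e6))
})
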
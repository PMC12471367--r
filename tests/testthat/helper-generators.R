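# Shared generators and independent oracles used across test files.

# Random grammar-conforming variant spec (unit-resolution masses).
random_variant_spec <- function() {
  sulfated <- runif(1) < 0.5
  terminus <- sample(c(218, 200, NA), 1)
  if (!is.na(terminus) && terminus == 200 && !sulfated) sulfated <- TRUE
  variant_spec(
    name = sprintf("RND-%06d", sample.int(1e6, 1)),
    precursor_mz = sample(1000:1800, 1),
    sulfated = sulfated,
    arm_mass = sample(c(392, 398, 426), 1),
    has_carbonyl = runif(1) < 0.5,
    terminus = terminus,
    rt_min = runif(1, 2.0, 4.2),
    base_peak = sample(c("cleavage", "precursor"), 1)
  )
}

# Random non-grammar spectrum: arbitrary peak list for screening tests.
random_spectrum <- function(id = "rnd") {
  prec <- runif(1, 1000, 1800)
  n <- sample(5:15, 1)
  am_spectrum(id, prec, runif(1, 1, 5),
              data.frame(mz = runif(n, 150, prec - 1),
                         intensity = runif(n, 1, 100)))
}

# Brute-force neutral-loss oracle: tests every (fragment, channel) pair
# directly against the definition, independent of nl_screen's loop.
nl_screen_oracle <- function(spectrum, channels, mz_tol = 0.5,
                             snr_min = 3) {
  snr <- fragment_snr(spectrum)
  hit_labels <- character(0)
  for (j in seq_len(nrow(channels))) {
    for (i in seq_len(nrow(spectrum$fragments))) {
      ok <- abs(spectrum$precursor_mz - channels$loss_da[j] -
                  spectrum$fragments$mz[i]) <= mz_tol && snr[i] >= snr_min
      if (ok) { hit_labels <- c(hit_labels, channels$label[j]); break }
    }
  }
  sort(hit_labels)
}

# Compare the structural flags recovered by the annotator with the
# generating spec; returns TRUE only on exact recovery.
flags_recovered <- function(spec, rec) {
  base <- if (spec$sulfated) spec$precursor_mz - 120 else spec$precursor_mz
  ok <- rec$sulfated == spec$sulfated &&
    identical(is.na(rec$terminus_loss), is.na(spec$terminus)) &&
    (is.na(spec$terminus) || rec$terminus_loss == spec$terminus) &&
    !is.na(rec$arm_mass) && rec$arm_mass == spec$arm_mass &&
    rec$cleavage_fragment_mz == base - spec$arm_mass &&
    (nrow(rec$carbonyl_pairs) >= 1) == spec$has_carbonyl &&
    ("LP-D-type" %in% rec$hydrophilic_type) ==
      (spec$base_peak == "cleavage")
  if (spec$sulfated) ok <- ok && rec$desulfated_mz == base
  ok
}
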
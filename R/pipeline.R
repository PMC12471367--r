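#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline: matching tolerances,
#' screening windows, the calibration standard, clustering settings and the
#' panel-generator settings. A configuration round-trips through YAML or
#' JSON via [write_run_config()] / [read_run_config()].
#'
#' @param seed Integer seed driving all simulation randomness.
#' @param panel `"synthetic"` (simulate a strain panel with
#'   [make_panel()]) or `"fixture"` (the packaged eight-variant reference
#'   fixture; screening and annotation only, since the fixture carries no
#'   counts).
#' @param n_strains,area_cv,n_decoys Panel-generator settings (see
#'   [panel_config()]).
#' @param mz_tol,rt_tol Matching tolerances (Da, minutes).
#' @param snr_min Minimum S/N for screening hits.
#' @param rt_window,mz_range Full-scan windows.
#' @param std List with `conc`, `peak_area`, `snr` of the LPD standard.
#' @param k_clusters Number of clusters cut from the ordination.
#' @param distance `"euclidean"` or `"bray"`.
#' @return An object of class `am_run_config`.
#' @export
run_config <- function(seed = 1, panel = c("synthetic", "fixture"),
                       n_strains = 54, area_cv = 0.25, n_decoys = 3,
                       mz_tol = 0.5, rt_tol = 0.1, snr_min = 3,
                       rt_window = c(2.0, 4.2), mz_range = c(1000, 1800),
                       std = list(conc = 12.5, peak_area = 5e5, snr = 50),
                       k_clusters = 3,
                       distance = c("euclidean", "bray")) {
  panel <- match.arg(panel)
  distance <- match.arg(distance)
  stopifnot(mz_tol > 0, rt_tol > 0, snr_min >= 0, k_clusters >= 1)
  structure(as.list(environment()), class = "am_run_config")
}

#' Write / read a run configuration
#'
#' @param cfg An [run_config()] object.
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @return `write_run_config`: `path` invisibly; `read_run_config`: an
#'   `am_run_config` equal to the one written.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "am_run_config"))
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  x$rt_window <- as.numeric(x$rt_window)
  x$mz_range <- as.numeric(x$mz_range)
  do.call(run_config, x[setdiff(names(x), character(0))])
}

#' Run the full discovery-to-profiling pipeline
#'
#' Orchestrates simulate -> screen -> annotate -> quantify -> toxicity ->
#' profile and writes every stage output (plain CSV/TSV/JSON) plus a run
#' manifest into `out_dir`. Stages degrade gracefully: a fixture run has
#' no count tables, so quantification, toxicity and ordination are skipped
#' with a log line; a strain that fails quantification is dropped with a
#' warning rather than aborting the panel.
#'
#' @param cfg An [run_config()].
#' @param out_dir Output directory (created; default a fresh temporary
#'   directory).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory stage results (`panel`,
#'   `hits`, `annotations`, `quant`, `toxicity`, `ordination`,
#'   `manifest`).
#' @examples
#' \donttest{
#' res <- run_all(run_config(seed = 1, n_strains = 12), quiet = TRUE)
#' table(vapply(res$annotations, `[[`, "", "verdict"))
#' }
#' @export
run_all <- function(cfg = run_config(), out_dir = tempfile("am_run_"),
                    quiet = FALSE) {
  stopifnot(inherits(cfg, "am_run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage 1: inputs
  if (cfg$panel == "synthetic") {
    pcfg <- panel_config(n_strains = cfg$n_strains, area_cv = cfg$area_cv,
                         n_decoys = cfg$n_decoys, seed = cfg$seed)
    panel <- make_panel(pcfg)
    write_panel(panel, out_dir)
    spectra <- panel$spectra
    transitions <- panel$transitions
  } else {
    fx <- make_fixture_table1(n_decoys = cfg$n_decoys, seed = cfg$seed)
    panel <- NULL
    spectra <- fx$spectra
    transitions <- fx$transitions
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    write.csv(transitions, file.path(out_dir, "transitions.csv"),
              row.names = FALSE)
  }
  say("simulate: ", length(spectra), " spectra, ",
      nrow(transitions), " library transitions")

  ## stage 2: three-mode screen
  srm_peaks <- if (!is.null(panel)) {
    pk <- panel$peak_areas
    pk$q3_mz <- transitions$q3_mz[match(pk$variant_name,
                                        transitions$variant_name)]
    pk[!is.na(pk$q3_mz), ]
  } else NULL
  hits <- screen_spectra(spectra, build_nl_library(), transitions,
                         srm_peaks, mz_tol = cfg$mz_tol,
                         rt_tol = cfg$rt_tol, snr_min = cfg$snr_min,
                         rt_window = cfg$rt_window, mz_range = cfg$mz_range)
  utils::write.table(hits, file.path(out_dir, "screen_hits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("screen: ", nrow(hits), " hits (",
      paste(sprintf("%s=%d", names(table(hits$mode)), table(hits$mode)),
            collapse = ", "), ")")

  ## stage 3: CID annotation
  ann <- annotate_spectra(spectra, transitions = transitions,
                          mz_tol = cfg$mz_tol, rt_tol = cfg$rt_tol)
  summ <- annotation_summary(ann)
  utils::write.table(summ, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    lapply(ann, function(r) { r$carbonyl_pairs <-
      as.data.frame(r$carbonyl_pairs); unclass(r) }),
    file.path(out_dir, "annotations.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  say("annotate: ", sum(summ$verdict == "novel"), " novel, ",
      sum(startsWith(summ$verdict, "known")), " known, ",
      sum(summ$verdict == "non-AM"), " non-AM")

  quant <- tox <- ord <- NULL
  if (!is.null(panel)) {
    ## stage 4: quantification
    std <- lpd_standard(cfg$std$conc, cfg$std$peak_area, cfg$std$snr)
    quant <- quantify_panel(panel$peak_areas, std, panel$counts)
    write.csv(quant, file.path(out_dir, "quant.csv"), row.names = FALSE)
    wide <- quota_matrix(quant)
    write.csv(data.frame(strain_id = rownames(wide), wide,
                         check.names = FALSE),
              file.path(out_dir, "quant_wide.csv"), row.names = FALSE)
    say("quantify: ", nrow(quant), " (strain, variant) records, ",
        sum(quant$below_lod), " below LoD")

    ## stage 5: toxicity
    tox <- assay_reduce(panel$counts)
    write.csv(tox, file.path(out_dir, "toxicity.csv"), row.names = FALSE)
    say("toxicity: ", nrow(tox), " strains, rate range ",
        sprintf("%.2f-%.2f /d", min(tox$mortality_rate_per_day),
                max(tox$mortality_rate_per_day)))

    ## stage 6: ordination + clustering
    profile <- build_strain_profile(wide, tox)
    ord <- profile_strains(profile, k = cfg$k_clusters,
                           distance = cfg$distance)
    write.csv(data.frame(strain_id = rownames(ord$scores), ord$scores),
              file.path(out_dir, "pcoa_scores.csv"), row.names = FALSE)
    write.csv(data.frame(axis = seq_along(ord$eigenvalues),
                         eigenvalue = ord$eigenvalues,
                         pct_variability = ord$pct_variability),
              file.path(out_dir, "eigenvalues.csv"), row.names = FALSE)
    write.csv(data.frame(strain_id = names(ord$cluster_labels),
                         cluster = ord$cluster_labels),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
    say("profile: ", ncol(ord$scores), " PCoA axes, k = ", cfg$k_clusters,
        " clusters of sizes ",
        paste(table(ord$cluster_labels), collapse = "/"))
  } else {
    say("quantify/toxicity/profile: skipped (no count data for this panel)")
  }

  ## manifest
  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(cfg, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("amprofiler")),
    r_version = R.version.string, seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_spectra = length(spectra), n_hits = nrow(hits),
    n_novel = sum(summ$verdict == "novel"),
    n_quant_records = if (is.null(quant)) 0L else nrow(quant),
    n_strains_toxicity = if (is.null(tox)) 0L else nrow(tox))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, hits = hits, annotations = ann,
                 quant = quant, toxicity = tox, ordination = ord,
                 manifest = manifest, out_dir = out_dir))
}
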
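#' Build the neutral-loss channel library
#'
#' Amphidinols are screened with neutral-loss (NL) scans targeting the
#' characteristic neutral fragments released by the C1/C1' cleavage. The
#' full method uses fourteen channels: seven non-sulfated lipophilic-arm
#' masses and their seven sulfated counterparts. Only three arm masses
#' (392, 398, 426 Da) are published; the remaining four non-sulfated
#' channels ship as placeholders flagged `provenance = "placeholder"` and
#' should be replaced with laboratory values. Sulfated counterparts carry
#' the additional 120 Da of the NaHSO4 moiety.
#'
#' @param config `"default"` for the 14-channel library, or a list with
#'   element `non_sulfated` (numeric masses, Da) and optional `sulfated`
#'   (numeric masses, Da).
#' @return A `data.frame` with columns `loss_da`, `sulfated`, `label`,
#'   `provenance`.
#' @examples
#' nrow(build_nl_library())              # 14
#' build_nl_library(list(non_sulfated = c(392, 398, 426)))
#' @export
build_nl_library <- function(config = "default") {
  if (identical(config, "default")) {
    printed <- c(392, 398, 426)
    placeholder <- c(406, 412, 420, 440)
    config <- list(non_sulfated = c(printed, placeholder),
                   sulfated = c(printed, placeholder) + 120)
    provenance_ns <- c(rep("main-text", 3), rep("placeholder", 4))
    provenance_s <- rep(c(rep("main-text", 3), rep("placeholder", 4)), 1)
  } else {
    provenance_ns <- rep("user", length(config$non_sulfated %||% numeric(0)))
    provenance_s <- rep("user", length(config$sulfated %||% numeric(0)))
  }
  ns <- as.numeric(config$non_sulfated %||% numeric(0))
  su <- as.numeric(config$sulfated %||% numeric(0))
  if (any(ns <= 0) || any(su <= 0)) stop("neutral-loss masses must be > 0")
  if (anyDuplicated(ns))
    stop("duplicate non-sulfated neutral-loss masses: ",
         paste(unique(ns[duplicated(ns)]), collapse = ", "))
  if (anyDuplicated(su))
    stop("duplicate sulfated neutral-loss masses: ",
         paste(unique(su[duplicated(su)]), collapse = ", "))
  out <- rbind(
    if (length(ns)) data.frame(loss_da = ns, sulfated = FALSE,
                               label = sprintf("arm-%g", ns),
                               provenance = provenance_ns),
    if (length(su)) data.frame(loss_da = su, sulfated = TRUE,
                               label = sprintf("arm-%g-sulfated", su - 120),
                               provenance = provenance_s)
  )
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(spectrum_id = character(0), mode = character(0),
              q1_mz = numeric(0), channel = character(0),
              rt_min = numeric(0), snr = numeric(0))
}

#' Neutral-loss screen of one CID spectrum
#'
#' Emits one hit per channel `L` for which some fragment `f` satisfies
#' `|precursor_mz - L - f_mz| <= mz_tol` with fragment S/N at or above
#' `snr_min` (see [fragment_snr()]). The hit carries the precursor as the
#' Q1 mass. An empty result is a valid outcome.
#'
#' @param spectrum An [am_spectrum()].
#' @param channels Channel table from [build_nl_library()].
#' @param mz_tol Absolute m/z tolerance in Da (default 0.5, unit-resolution
#'   instrument).
#' @param snr_min Minimum fragment S/N (default 3, the method's detection
#'   threshold).
#' @return Hit `data.frame` (`spectrum_id, mode, q1_mz, channel, rt_min,
#'   snr`).
#' @export
nl_screen <- function(spectrum, channels, mz_tol = 0.5, snr_min = 3) {
  stopifnot(is_am_spectrum(spectrum), mz_tol > 0)
  snr <- fragment_snr(spectrum)
  frg <- spectrum$fragments
  hits <- empty_hits()
  for (j in seq_len(nrow(channels))) {
    target <- spectrum$precursor_mz - channels$loss_da[j]
    ok <- which(abs(frg$mz - target) <= mz_tol & snr >= snr_min)
    if (length(ok)) {
      best <- ok[which.max(snr[ok])]
      hits <- rbind(hits, data.frame(
        spectrum_id = spectrum$spectrum_id, mode = "NL",
        q1_mz = spectrum$precursor_mz, channel = channels$label[j],
        rt_min = spectrum$rt_min, snr = snr[best]))
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Full-scan candidate selection
#'
#' Retains precursors whose retention time and m/z fall inside the known
#' amphidinol elution window (default 2.0--4.2 min) and mass range (default
#' m/z 1000--1800), with spectrum S/N (base-peak S/N, [fragment_snr()]) at
#' or above `snr_min`. Windows are inclusive. Precursors already matched by
#' the NL or SRM stage (passed via `exclude`) are dropped so the union of
#' modes contains each Q1 mass once. Precursors falling just beyond a window
#' edge (within `edge_margin`) are excluded but reported with a warning, as
#' genuine analytes can elute marginally outside the nominal window.
#'
#' @param spectra List of [am_spectrum()] objects.
#' @param rt_window,mz_range Length-2 inclusive windows (min, max).
#' @param snr_min Minimum S/N.
#' @param exclude Optional hit `data.frame` of prior SRM/NL detections.
#' @param mz_tol,rt_tol Tolerances used for de-duplication against
#'   `exclude`.
#' @param edge_margin Width (minutes) of the boundary-warning band outside
#'   the RT window.
#' @return Hit `data.frame` with `channel = "full-scan"`.
#' @export
fs_screen <- function(spectra, rt_window = c(2.0, 4.2),
                      mz_range = c(1000, 1800), snr_min = 3,
                      exclude = NULL, mz_tol = 0.5, rt_tol = 0.1,
                      edge_margin = 0.2) {
  if (rt_window[1] > rt_window[2] || mz_range[1] > mz_range[2])
    stop("inverted rt_window or mz_range")
  hits <- empty_hits()
  boundary <- character(0)
  for (s in spectra) {
    stopifnot(is_am_spectrum(s))
    snr <- fragment_snr(s)
    s_snr <- if (length(snr)) max(snr) else 0
    in_mz <- s$precursor_mz >= mz_range[1] && s$precursor_mz <= mz_range[2]
    in_rt <- !is.na(s$rt_min) && s$rt_min >= rt_window[1] &&
      s$rt_min <= rt_window[2]
    near_rt <- !is.na(s$rt_min) && !in_rt &&
      s$rt_min >= rt_window[1] - edge_margin &&
      s$rt_min <= rt_window[2] + edge_margin
    if (in_mz && near_rt && s_snr >= snr_min)
      boundary <- c(boundary, sprintf("%s (m/z %g, RT %.2f min)",
                                      s$spectrum_id, s$precursor_mz,
                                      s$rt_min))
    if (!(in_mz && in_rt) || s_snr < snr_min) next
    if (!is.null(exclude) && nrow(exclude)) {
      dup <- abs(exclude$q1_mz - s$precursor_mz) <= mz_tol &
        (is.na(exclude$rt_min) | is.na(s$rt_min) |
           abs(exclude$rt_min - s$rt_min) <= rt_tol)
      if (any(dup)) next
    }
    hits <- rbind(hits, data.frame(
      spectrum_id = s$spectrum_id, mode = "FS", q1_mz = s$precursor_mz,
      channel = "full-scan", rt_min = s$rt_min, snr = s_snr))
  }
  if (length(boundary))
    warning("precursor(s) just outside the full-scan RT window (excluded): ",
            paste(boundary, collapse = "; "))
  rownames(hits) <- NULL
  hits
}

#' SRM hit detection against a transition library
#'
#' A chromatographic peak is a hit when both its Q1 and Q3 m/z match a
#' library transition within `mz_tol` and its retention time matches within
#' `rt_tol`.
#'
#' @param peaks `data.frame` with columns `q1_mz`, `q3_mz`, `rt_min` and
#'   optionally `strain_id` and `snr`.
#' @param table An `am_transitions` table (see [read_transition_table()]).
#' @param mz_tol,rt_tol Match tolerances (Da, minutes).
#' @return Hit `data.frame` with `channel` set to the matched variant name.
#' @export
srm_detect <- function(peaks, table, mz_tol = 0.5, rt_tol = 0.1) {
  stopifnot(nrow(table) > 0)
  hits <- empty_hits()
  if (is.null(peaks) || !nrow(peaks)) return(hits)
  for (i in seq_len(nrow(peaks))) {
    m <- which(abs(table$q1_mz - peaks$q1_mz[i]) <= mz_tol &
               abs(table$q3_mz - peaks$q3_mz[i]) <= mz_tol &
               abs(table$rt_min - peaks$rt_min[i]) <= rt_tol)
    if (length(m)) {
      m <- m[which.min(abs(table$q1_mz[m] - peaks$q1_mz[i]))]
      hits <- rbind(hits, data.frame(
        spectrum_id = as.character(peaks$strain_id[i] %||% NA_character_),
        mode = "SRM", q1_mz = peaks$q1_mz[i],
        channel = table$variant_name[m], rt_min = peaks$rt_min[i],
        snr = if ("snr" %in% names(peaks)) peaks$snr[i] else NA_real_))
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Signal-to-noise of a chromatographic trace
#'
#' Robust S/N of a peak inside an intensity trace:
#' `(peak max - baseline median) / noise`, with the baseline median and the
#' noise (1.4826 times the median absolute deviation) estimated from the
#' off-peak samples. Returns 0 for a flat trace; a peak rising above a
#' perfectly noiseless baseline returns `Inf` (treated as passing any
#' threshold).
#'
#' @param trace Numeric intensity vector (length >= 8).
#' @param peak_index_range Integer indices of the peak region within
#'   `trace`.
#' @return S/N ratio (scalar).
#' @export
estimate_snr <- function(trace, peak_index_range) {
  stopifnot(is.numeric(trace), length(trace) >= 8)
  peak_index_range <- as.integer(peak_index_range)
  if (any(peak_index_range < 1L) || any(peak_index_range > length(trace)))
    stop("peak_index_range outside trace")
  off <- trace[-peak_index_range]
  if (!length(off)) stop("no off-peak samples left")
  baseline <- median(off)
  noise <- mad(off)  # 1.4826 * median absolute deviation
  height <- max(trace[peak_index_range]) - baseline
  if (noise == 0) {
    if (height <= 0) return(0)
    return(Inf)
  }
  height / noise
}

#' Three-mode screen of a spectrum panel
#'
#' Convenience orchestrator running, in order of specificity, SRM detection
#' on tabulated chromatographic peaks, neutral-loss screening of every CID
#' spectrum, and full-scan candidate selection excluding Q1 masses already
#' found (so each Q1 mass of a spectrum is claimed by exactly one mode).
#'
#' @param spectra List of [am_spectrum()] objects.
#' @param channels NL channel table ([build_nl_library()]).
#' @param transitions Optional `am_transitions` table for SRM.
#' @param srm_peaks Optional chromatographic peak table for [srm_detect()].
#' @param mz_tol,rt_tol,snr_min Tolerances.
#' @param rt_window,mz_range Full-scan windows.
#' @return Combined hit `data.frame`.
#' @export
screen_spectra <- function(spectra, channels = build_nl_library(),
                           transitions = NULL, srm_peaks = NULL,
                           mz_tol = 0.5, rt_tol = 0.1, snr_min = 3,
                           rt_window = c(2.0, 4.2),
                           mz_range = c(1000, 1800)) {
  hits <- empty_hits()
  if (!is.null(transitions) && !is.null(srm_peaks))
    hits <- srm_detect(srm_peaks, transitions, mz_tol, rt_tol)
  for (s in spectra) {
    nh <- nl_screen(s, channels, mz_tol, snr_min)
    if (nrow(nh)) {
      same_scan <- hits$spectrum_id %in%
        c(s$spectrum_id, if (!is.na(s$strain_id)) s$strain_id)
      dup <- vapply(seq_len(nrow(nh)), function(i) {
        any(same_scan & abs(hits$q1_mz - nh$q1_mz[i]) <= mz_tol &
              (is.na(hits$rt_min) | is.na(nh$rt_min[i]) |
                 abs(hits$rt_min - nh$rt_min[i]) <= rt_tol))
      }, logical(1))
      hits <- rbind(hits, nh[!dup, , drop = FALSE])
    }
  }
  fs <- fs_screen(spectra, rt_window, mz_range, snr_min, exclude = hits,
                  mz_tol = mz_tol, rt_tol = rt_tol)
  out <- rbind(hits, fs)
  rownames(out) <- NULL
  out
}
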
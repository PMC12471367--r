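## Diagnostic masses of the amphidinol fragmentation grammar (Da, observed
## on sodium-adduct m/z). These are constants of the chemistry, not tunables.
AM_SULFATE_LOSS <- 120   # NaHSO4 neutral loss from the sulfated precursor
AM_PAIR_DELTA <- 58      # di-gamma-hydroxy-carbonyl fragment-pair spacing
AM_TERMINUS_LOSSES <- c(218, 200)  # hydrophilic-terminus neutral losses
AM_DEFAULT_ARMS <- c(392, 398, 426)  # published lipophilic-arm masses

## Known analogs sharing a lipophilic arm, used only for evidence strings.
AM_ARM_SHARED_WITH <- c("392" = "LS-A", "398" = "AM-B")

#' Detect the 120 Da sulfation signature
#'
#' Sulfated and non-sulfated amphidinols are distinguished by a neutral loss
#' of 120 Da (NaHSO4) from the sodium-adduct precursor. Sulfation is called
#' when a fragment sits at `precursor_mz - 120` within `mz_tol`; the
#' matching fragment's observed m/z is returned as the desulfated ion.
#'
#' @param s An [am_spectrum()].
#' @param mz_tol Absolute tolerance in Da (default 0.5).
#' @return List with `sulfated` (logical) and `desulfated_mz` (m/z of the
#'   `[M - 120]` fragment, or `NA` when not sulfated).
#' @export
detect_sulfation <- function(s, mz_tol = 0.5) {
  stopifnot(is_am_spectrum(s))
  target <- s$precursor_mz - AM_SULFATE_LOSS
  d <- abs(s$fragments$mz - target)
  ok <- which(d <= mz_tol)
  if (!length(ok)) return(list(sulfated = FALSE, desulfated_mz = NA_real_))
  best <- ok[order(d[ok], -s$fragments$intensity[ok])][1]
  list(sulfated = TRUE, desulfated_mz = s$fragments$mz[best])
}

#' Assign the lipophilic-arm neutral loss
#'
#' The C1/C1' cleavage releases the lipophilic arm as a neutral fragment and
#' leaves the charged hydrophilic ion; the arm mass is conserved across
#' analogs, so the annotator searches for a fragment at `base - arm` for
#' every arm mass in the library, where `base` is the desulfated ion for
#' sulfated compounds and the precursor otherwise. Ties between candidate
#' matches are broken by smallest mass deviation, then largest fragment
#' intensity, then smallest arm mass, making the assignment deterministic.
#'
#' @param s An [am_spectrum()].
#' @param sulfation Result of [detect_sulfation()] (computed if omitted).
#' @param arm_library Numeric arm masses to try (default 392, 398, 426 Da).
#' @param mz_tol Absolute tolerance (Da).
#' @return List with `arm_mass` and `cleavage_fragment_mz` (both `NA` when
#'   no arm-consistent fragment exists).
#' @export
assign_arm <- function(s, sulfation = detect_sulfation(s, mz_tol),
                       arm_library = AM_DEFAULT_ARMS, mz_tol = 0.5) {
  stopifnot(is_am_spectrum(s), length(arm_library) > 0)
  base <- if (sulfation$sulfated) sulfation$desulfated_mz else s$precursor_mz
  frg <- s$fragments
  cand <- NULL
  for (arm in sort(as.numeric(arm_library))) {
    target <- base - arm
    d <- abs(frg$mz - target)
    ok <- which(d <= mz_tol)
    if (length(ok))
      cand <- rbind(cand, data.frame(arm = arm, mz = frg$mz[ok],
                                     delta = d[ok],
                                     intensity = frg$intensity[ok]))
  }
  if (is.null(cand))
    return(list(arm_mass = NA_real_, cleavage_fragment_mz = NA_real_))
  cand <- cand[order(cand$delta, -cand$intensity, cand$arm), , drop = FALSE]
  list(arm_mass = cand$arm[1], cleavage_fragment_mz = cand$mz[1])
}

#' Detect 58 Da di-gamma-hydroxy-carbonyl fragment pairs
#'
#' Cleavage on either side of a di-gamma-hydroxy-carbonyl group (via
#' six-membered transition states) always yields fragment pairs separated by
#' 58 Da. All fragment pairs `(hi, lo)` with `hi - lo = 58` within `mz_tol`
#' are reported, ordered by decreasing `hi`; the precursor ion itself is
#' excluded from pairing.
#'
#' @param x An [am_spectrum()], or a `data.frame`/matrix of fragments with
#'   columns `mz` and `intensity`.
#' @param mz_tol Absolute tolerance (Da).
#' @param precursor_mz Precursor m/z to exclude (taken from `x` when it is a
#'   spectrum).
#' @return `data.frame` with columns `hi_mz`, `lo_mz` (possibly 0 rows).
#' @export
detect_carbonyl_pairs <- function(x, mz_tol = 0.5, precursor_mz = NULL) {
  if (is_am_spectrum(x)) {
    precursor_mz <- precursor_mz %||% x$precursor_mz
    mz <- x$fragments$mz
  } else {
    mz <- as.data.frame(x)$mz
  }
  if (!is.null(precursor_mz))
    mz <- mz[abs(mz - precursor_mz) > mz_tol]
  mz <- sort(mz)
  out <- data.frame(hi_mz = numeric(0), lo_mz = numeric(0))
  n <- length(mz)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (abs((mz[j] - mz[i]) - AM_PAIR_DELTA) <= mz_tol)
          out <- rbind(out, data.frame(hi_mz = mz[j], lo_mz = mz[i]))
      }
    }
  }
  out <- out[order(-out$hi_mz, -out$lo_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the hydrophilic-terminus neutral loss (218/200 Da)
#'
#' A 218 Da neutral loss from the pseudo-molecular ion marks a conserved
#' hydrophilic-arm terminus; its sulfated counterparts instead lose 200 Da
#' from the desulfated `[M - 120]` ion (the 218-to-200 shift seen between
#' the AM-18/AM-19 pair). 218 takes precedence when both match.
#'
#' @param s An [am_spectrum()].
#' @param sulfation Result of [detect_sulfation()] (computed if omitted).
#' @param mz_tol Absolute tolerance (Da).
#' @return `218`, `200` or `NA_real_` (none).
#' @export
detect_terminus_loss <- function(s, sulfation = detect_sulfation(s, mz_tol),
                                 mz_tol = 0.5) {
  stopifnot(is_am_spectrum(s))
  mz <- s$fragments$mz
  if (any(abs(mz - (s$precursor_mz - 218)) <= mz_tol)) return(218)
  if (sulfation$sulfated &&
      any(abs(mz - (sulfation$desulfated_mz - 200)) <= mz_tol)) return(200)
  NA_real_
}

#' Classify the hydrophilic-arm type
#'
#' Two (co-occurring) labels are recognized: `"LP-D-type"` when the C1/C1'
#' cleavage fragment is the base peak of the spectrum (a hallmark of the
#' luteophanol-D hydrophilic arm), and `"AM-18-type"` when at least one
#' 58 Da carbonyl pair is present together with a 218 or 200 Da terminus
#' loss (the AM-18 family signature).
#'
#' @param s An [am_spectrum()].
#' @param cleavage_fragment_mz The assigned cleavage fragment (from
#'   [assign_arm()]); `NA` returns `NULL` (no call possible).
#' @param pairs Result of [detect_carbonyl_pairs()].
#' @param terminus Result of [detect_terminus_loss()].
#' @param mz_tol Absolute tolerance (Da).
#' @return Character vector of labels (possibly both), or `NULL` when no
#'   cleavage fragment was assigned.
#' @export
classify_hydrophilic_type <- function(s, cleavage_fragment_mz,
                                      pairs = detect_carbonyl_pairs(s, mz_tol),
                                      terminus = detect_terminus_loss(s, mz_tol = mz_tol),
                                      mz_tol = 0.5) {
  stopifnot(is_am_spectrum(s))
  if (is.null(cleavage_fragment_mz) || is.na(cleavage_fragment_mz))
    return(NULL)
  labels <- character(0)
  frg <- s$fragments
  if (nrow(frg)) {
    base_mz <- frg$mz[which.max(frg$intensity)]
    if (abs(base_mz - cleavage_fragment_mz) <= mz_tol)
      labels <- c(labels, "LP-D-type")
  }
  if (nrow(pairs) >= 1 && !is.na(terminus) &&
      terminus %in% AM_TERMINUS_LOSSES)
    labels <- c(labels, "AM-18-type")
  labels
}

#' Match a spectrum against a library of known variants
#'
#' A known-variant match requires the precursor to sit within `mz_tol` of a
#' library Q1 mass, the retention time within `rt_tol`, and a fragment at
#' the library Q3 mass within `mz_tol`. When several transitions match, the
#' closest Q1 wins, then the closest retention time; ambiguity is reported
#' with a message.
#'
#' @param s An [am_spectrum()].
#' @param table An `am_transitions` library (possibly empty rows -> no
#'   match).
#' @param mz_tol,rt_tol Tolerances (Da, minutes).
#' @return Matched variant name, or `NA_character_`.
#' @export
match_known <- function(s, table, mz_tol = 0.5, rt_tol = 0.1) {
  stopifnot(is_am_spectrum(s))
  if (is.null(table) || !nrow(table)) return(NA_character_)
  hits <- integer(0)
  for (i in seq_len(nrow(table))) {
    if (abs(table$q1_mz[i] - s$precursor_mz) > mz_tol) next
    if (!is.na(s$rt_min) && abs(table$rt_min[i] - s$rt_min) > rt_tol) next
    if (!any(abs(s$fragments$mz - table$q3_mz[i]) <= mz_tol)) next
    hits <- c(hits, i)
  }
  if (!length(hits)) return(NA_character_)
  if (length(hits) > 1) {
    ord <- order(abs(table$q1_mz[hits] - s$precursor_mz),
                 abs(table$rt_min[hits] - (s$rt_min %||% NA_real_)))
    hits <- hits[ord]
    message("ambiguous known-variant match for ", s$spectrum_id, ": ",
            paste(table$variant_name[hits], collapse = ", "),
            "; keeping ", table$variant_name[hits[1]])
  }
  table$variant_name[hits[1]]
}

#' Annotate a CID spectrum with the amphidinol fragmentation grammar
#'
#' Composes the four diagnostic detectors -- sulfation
#' ([detect_sulfation()]), lipophilic-arm assignment ([assign_arm()]),
#' carbonyl pairs ([detect_carbonyl_pairs()]) and terminus loss
#' ([detect_terminus_loss()]) -- plus known-variant matching
#' ([match_known()]) into a structural call:
#'
#' * `known:<variant>` when the spectrum matches a library transition;
#' * `novel` when unmatched but carrying positive structural evidence
#'   (an assigned arm, or a carbonyl pair together with a terminus loss);
#' * `non-AM` otherwise. Mass alone is never enough to call a novel
#'   amphidinol: this keeps noise precursors from full-scan screening from
#'   being auto-promoted.
#'
#' @param s An [am_spectrum()].
#' @param arm_library Arm masses to try (default 392, 398, 426 Da).
#' @param transitions Optional known-variant library; `NULL` disables
#'   known-matching.
#' @param mz_tol,rt_tol Tolerances (Da, minutes).
#' @return An object of class `am_annotation`: a list with fields
#'   `spectrum_id`, `precursor_mz`, `rt_min`, `strain_id`, `sulfated`,
#'   `desulfated_mz`, `arm_mass`, `cleavage_fragment_mz`, `carbonyl_pairs`,
#'   `terminus_loss`, `hydrophilic_type`, `verdict`, `evidence`.
#' @examples
#' fx <- make_fixture_table1()
#' rec <- annotate_spectrum(fx$spectra[[1]])
#' rec$cleavage_fragment_mz  # 834
#' @export
annotate_spectrum <- function(s, arm_library = AM_DEFAULT_ARMS,
                              transitions = NULL, mz_tol = 0.5,
                              rt_tol = 0.1) {
  stopifnot(is_am_spectrum(s))
  sulf <- detect_sulfation(s, mz_tol)
  arm <- assign_arm(s, sulf, arm_library, mz_tol)
  pairs <- detect_carbonyl_pairs(s, mz_tol)
  terminus <- detect_terminus_loss(s, sulf, mz_tol)
  htype <- classify_hydrophilic_type(s, arm$cleavage_fragment_mz, pairs,
                                     terminus, mz_tol)
  evidence <- character(0)
  if (sulf$sulfated)
    evidence <- c(evidence, sprintf("NL-120-sulfation -> m/z %g",
                                    sulf$desulfated_mz))
  if (!is.na(arm$arm_mass)) {
    shared <- AM_ARM_SHARED_WITH[as.character(arm$arm_mass)]
    tag <- sprintf("arm-%g -> m/z %g", arm$arm_mass,
                   arm$cleavage_fragment_mz)
    if (!is.na(shared))
      tag <- paste0(tag, sprintf(" (same lipophilic arm as %s)", shared))
    evidence <- c(evidence, tag)
  }
  if (nrow(pairs))
    evidence <- c(evidence, sprintf("carbonyl-pair-58 (%s)",
                                    paste(sprintf("%g/%g", pairs$hi_mz,
                                                  pairs$lo_mz),
                                          collapse = ", ")))
  if (!is.na(terminus)) {
    tag <- sprintf("terminus-%g", terminus)
    if (terminus == 200)
      tag <- paste0(tag, " (sulfated counterpart of the 218-type terminus)")
    evidence <- c(evidence, tag)
  }
  if (!is.null(htype) && length(htype))
    evidence <- c(evidence, paste0("hydrophilic-type: ",
                                   paste(htype, collapse = "+")))
  known <- match_known(s, transitions, mz_tol, rt_tol)
  verdict <- if (!is.na(known)) {
    paste0("known:", known)
  } else if (!is.na(arm$arm_mass) ||
             (nrow(pairs) >= 1 && !is.na(terminus))) {
    "novel"
  } else {
    "non-AM"
  }
  structure(
    list(spectrum_id = s$spectrum_id, precursor_mz = s$precursor_mz,
         rt_min = s$rt_min, strain_id = s$strain_id,
         sulfated = sulf$sulfated, desulfated_mz = sulf$desulfated_mz,
         arm_mass = arm$arm_mass,
         cleavage_fragment_mz = arm$cleavage_fragment_mz,
         carbonyl_pairs = pairs, terminus_loss = terminus,
         hydrophilic_type = htype, verdict = verdict, evidence = evidence),
    class = "am_annotation"
  )
}

#' @export
print.am_annotation <- function(x, ...) {
  cat(sprintf("<am_annotation %s> m/z %g -> %s\n", x$spectrum_id,
              x$precursor_mz, x$verdict))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}

#' Annotate a list of spectra
#'
#' @param spectra List of [am_spectrum()] objects.
#' @inheritParams annotate_spectrum
#' @return List of `am_annotation` records.
#' @export
annotate_spectra <- function(spectra, arm_library = AM_DEFAULT_ARMS,
                             transitions = NULL, mz_tol = 0.5,
                             rt_tol = 0.1) {
  lapply(spectra, annotate_spectrum, arm_library = arm_library,
         transitions = transitions, mz_tol = mz_tol, rt_tol = rt_tol)
}

#' Tabular summary of annotation records
#'
#' @param records List of `am_annotation` records.
#' @return `data.frame` with one row per spectrum (`spectrum_id, strain_id,
#'   precursor_mz, verdict, sulfated, arm_mass, n_pairs, terminus,
#'   hydrophilic_type`).
#' @export
annotation_summary <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(
      spectrum_id = r$spectrum_id, strain_id = r$strain_id,
      precursor_mz = r$precursor_mz, verdict = r$verdict,
      sulfated = r$sulfated, arm_mass = r$arm_mass,
      n_pairs = nrow(r$carbonyl_pairs),
      terminus = ifelse(is.na(r$terminus_loss), "none",
                        as.character(r$terminus_loss)),
      hydrophilic_type = if (is.null(r$hydrophilic_type) ||
                             !length(r$hydrophilic_type)) ""
                         else paste(r$hydrophilic_type, collapse = "+"))
  }))
}
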
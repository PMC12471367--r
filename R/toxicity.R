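#' Control-adjust a treatment well's death count
#'
#' Deaths in a treatment well are corrected by subtracting the initial
#' (inoculation) mortality and the mean death count of the control wells,
#' floored at zero.
#'
#' @param treatment_dead Dead individuals counted in the treatment well.
#' @param initial_dead Dead individuals observed 30 min after inoculation.
#' @param control_dead_mean Mean dead count across the control wells at the
#'   same time point.
#' @return Adjusted (non-negative) death count; vectorized.
#' @export
adjust_deaths <- function(treatment_dead, initial_dead, control_dead_mean) {
  if (any(treatment_dead < 0) || any(initial_dead < 0) ||
      any(control_dead_mean < 0))
    stop("counts must be >= 0")
  pmax(0, treatment_dead - initial_dead - control_dead_mean)
}

#' Brine-shrimp mortality rate (deaths per day)
#'
#' `rate = ln(dead_48h) / 48 h * 24 h`, i.e. `ln(dead_48h) / 2` per day.
#' The logarithm of a count is used deliberately (not of a proportion):
#' with wells of ~60 individuals this yields rates in `[0, ln(60)/2]`,
#' matching the 0--2.25 per-day scale reported for Amphidinium crude
#' extracts. Counts of 0 or 1 (and fractional adjusted counts below 1,
#' where the log would go negative) map to rate 0; a zero count raises a
#' warning since it usually means the adjustment consumed all deaths.
#'
#' @param dead_48h Adjusted death count(s) after 48 h, >= 0 (vectorized;
#'   fractional values arise from averaging replicate wells).
#' @return Mortality rate(s) in d^-1.
#' @export
mortality_rate <- function(dead_48h) {
  if (any(dead_48h < 0)) stop("dead_48h must be >= 0")
  if (any(dead_48h == 0))
    warning("zero 48 h death count(s): mortality rate set to 0")
  rate <- ifelse(dead_48h > 1, log(dead_48h) / 48 * 24, 0)
  pmax(0, rate)
}

#' Reduce a brine-shrimp assay to per-strain mortality rates
#'
#' For each strain: the six control wells (DMSO and seawater, pooled by
#' default) give per-timepoint control means; each treatment well is
#' adjusted with [adjust_deaths()]; the adjusted counts are averaged across
#' the (nominally three) treatment wells; and the mortality rate is
#' computed from the mean adjusted 48 h count with [mortality_rate()].
#' Per-well rates are attached for dispersion reporting.
#'
#' @param counts An `am_counts` object (see [read_count_tables()]).
#' @param pool_controls Pool DMSO and seawater control wells for the
#'   control mean (default `TRUE`); when `FALSE`, only DMSO controls are
#'   used.
#' @return `data.frame` with columns `strain_id`, `adjusted_dead_24h`,
#'   `adjusted_dead_48h`, `mortality_rate_per_day`; per-well detail in
#'   `attr(, "per_well")`. Strains with no treatment wells are skipped with
#'   a warning.
#' @export
assay_reduce <- function(counts, pool_controls = TRUE) {
  stopifnot(inherits(counts, "am_counts"))
  assay <- counts$assay_counts
  out <- NULL
  per_well <- NULL
  skipped <- character(0)
  for (strain in unique(assay$strain_id)) {
    w <- assay[assay$strain_id == strain, , drop = FALSE]
    treat <- w[w$well_type == "treatment", , drop = FALSE]
    ctrl_types <- if (pool_controls) c("dmso_control", "seawater_control")
                  else "dmso_control"
    ctrl <- w[w$well_type %in% ctrl_types, , drop = FALSE]
    if (!nrow(treat)) { skipped <- c(skipped, strain); next }
    ctrl24 <- if (nrow(ctrl)) mean(ctrl$dead_24h) else 0
    ctrl48 <- if (nrow(ctrl)) mean(ctrl$dead_48h) else 0
    adj24 <- adjust_deaths(treat$dead_24h, treat$initial_dead, ctrl24)
    adj48 <- adjust_deaths(treat$dead_48h, treat$initial_dead, ctrl48)
    rate <- suppressWarnings(mortality_rate(mean(adj48)))
    out <- rbind(out, data.frame(
      strain_id = strain, adjusted_dead_24h = mean(adj24),
      adjusted_dead_48h = mean(adj48), mortality_rate_per_day = rate))
    per_well <- rbind(per_well, data.frame(
      strain_id = strain, well_id = treat$well_id,
      adjusted_dead_24h = adj24, adjusted_dead_48h = adj48,
      rate_per_day = suppressWarnings(mortality_rate(adj48))))
  }
  if (length(skipped))
    warning("strain(s) without treatment wells skipped: ",
            paste(skipped, collapse = ", "))
  if (is.null(out))
    out <- data.frame(strain_id = character(0),
                      adjusted_dead_24h = numeric(0),
                      adjusted_dead_48h = numeric(0),
                      mortality_rate_per_day = numeric(0))
  rownames(out) <- NULL
  attr(out, "per_well") <- per_well
  out
}
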
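#' Luteophanol-D calibration standard
#'
#' All amphidinol concentrations in this package are semi-quantitative
#' luteophanol-D (LPD) equivalents, calibrated against a single external
#' LPD standard. The default concentration, 12.5 ng/uL, corresponds to
#' 10 ug of standard dissolved in 800 uL of methanol (often rounded to
#' "about 13 ng/uL").
#'
#' @param conc_ng_per_ul Standard concentration (ng/uL), > 0.
#' @param peak_area Chromatographic peak area of the standard (arbitrary
#'   units), > 0.
#' @param snr Signal-to-noise ratio of the standard peak, > 0.
#' @return An object of class `lpd_standard`.
#' @export
lpd_standard <- function(conc_ng_per_ul = 12.5, peak_area = 5e5, snr = 50) {
  if (conc_ng_per_ul <= 0) stop("standard concentration must be > 0")
  if (peak_area <= 0) stop("standard peak area must be > 0")
  if (snr <= 0) stop("standard S/N must be > 0")
  structure(list(conc_ng_per_ul = conc_ng_per_ul, peak_area = peak_area,
                 snr = snr),
            class = "lpd_standard")
}

#' Toxin concentration in LPD equivalents
#'
#' One-point calibration against the external standard:
#' `conc = peak_area_toxin * c(LPD) / peak_area(LPD)`. Linear in the toxin
#' peak area.
#'
#' @param peak_area_toxin Toxin peak area(s), >= 0 (vectorized).
#' @param std An [lpd_standard()].
#' @return Concentration(s) in ng/uL (LPD equivalents).
#' @export
concentration <- function(peak_area_toxin, std) {
  stopifnot(inherits(std, "lpd_standard"))
  if (std$peak_area <= 0) stop("standard peak area must be > 0")
  if (any(peak_area_toxin < 0)) stop("peak areas must be >= 0")
  peak_area_toxin * std$conc_ng_per_ul / std$peak_area
}

#' Toxin cell quota
#'
#' Converts an extract concentration to a per-cell quota:
#' `quota = conc * sample_volume * 1e6 / n_cells` (the factor 1e6 converts
#' ng to fg).
#'
#' @param conc Concentration in ng/uL (vectorized).
#' @param sample_volume_ul Extract volume in uL (500 uL in the standard
#'   workup).
#' @param n_cells Number of cells in the extracted pellet, > 0.
#' @return Cell quota(s) in fg per cell.
#' @export
cell_quota <- function(conc, sample_volume_ul, n_cells) {
  if (any(n_cells <= 0)) stop("n_cells must be > 0")
  if (any(sample_volume_ul <= 0)) stop("sample_volume_ul must be > 0")
  conc * sample_volume_ul * 1e6 / n_cells
}

#' Limit of detection as a cell quota
#'
#' The LoD is three times the noise-equivalent concentration of the LPD
#' standard, expressed per cell:
#' `LoD = c(LPD) * 3 / (S/N)(LPD) * sample_volume * 1e6 / n_cells`.
#'
#' @param std An [lpd_standard()] with `snr > 0`.
#' @param sample_volume_ul Extract volume (uL).
#' @param n_cells Cell count, > 0.
#' @return LoD in fg per cell.
#' @export
lod <- function(std, sample_volume_ul, n_cells) {
  stopifnot(inherits(std, "lpd_standard"))
  if (std$snr <= 0) stop("standard S/N must be > 0")
  cell_quota(std$conc_ng_per_ul * 3 / std$snr, sample_volume_ul, n_cells)
}

#' Quantify a panel of SRM peak areas
#'
#' Converts tabulated per-(strain, variant) peak areas into LPD-equivalent
#' concentrations and cell quotas, flags values below the per-strain limit
#' of detection, and accumulates per-strain totals. Totals exclude
#' below-LoD variants by default (conservative; set
#' `include_below_lod = TRUE` to include trace signals).
#'
#' @param areas `data.frame` with columns `strain_id`, `variant_name`,
#'   `peak_area` (and optionally `snr`).
#' @param std An [lpd_standard()].
#' @param counts An `am_counts` object (see [read_count_tables()]); strains
#'   absent from its `cell_counts` are skipped with a warning.
#' @param include_below_lod Include below-LoD quotas in strain totals?
#' @return `data.frame` of class `am_quant` with columns `strain_id`,
#'   `variant_name`, `conc_ng_per_ul`, `cell_quota_fg_per_cell`,
#'   `lod_fg_per_cell`, `below_lod`; per-strain totals are attached as
#'   `attr(, "totals")` (strains with no detected variant report total 0).
#' @export
quantify_panel <- function(areas, std, counts, include_below_lod = FALSE) {
  stopifnot(inherits(std, "lpd_standard"), inherits(counts, "am_counts"))
  cc <- counts$cell_counts
  missing <- setdiff(unique(areas$strain_id), cc$strain_id)
  if (length(missing))
    warning("strain(s) without cell counts skipped: ",
            paste(missing, collapse = ", "))
  keep <- areas$strain_id %in% cc$strain_id
  areas <- areas[keep, , drop = FALSE]
  idx <- match(areas$strain_id, cc$strain_id)
  conc <- concentration(areas$peak_area, std)
  quota <- cell_quota(conc, cc$sample_volume_ul[idx], cc$n_cells[idx])
  lod_ <- lod(std, cc$sample_volume_ul[idx], cc$n_cells[idx])
  out <- data.frame(
    strain_id = areas$strain_id, variant_name = areas$variant_name,
    conc_ng_per_ul = conc, cell_quota_fg_per_cell = quota,
    lod_fg_per_cell = lod_, below_lod = quota < lod_)
  counted <- if (include_below_lod) rep(TRUE, nrow(out)) else !out$below_lod
  totals <- data.frame(strain_id = cc$strain_id, total_fg_per_cell = 0)
  if (nrow(out)) {
    sums <- tapply(out$cell_quota_fg_per_cell[counted],
                   factor(out$strain_id[counted], levels = cc$strain_id),
                   sum)
    sums[is.na(sums)] <- 0
    totals$total_fg_per_cell <- as.numeric(sums)
  }
  attr(out, "totals") <- totals
  class(out) <- c("am_quant", "data.frame")
  out
}

#' Strain-by-variant cell-quota matrix
#'
#' Reshapes an [quantify_panel()] result into the wide matrix consumed by
#' the multivariate module, with a `total_AM` column appended.
#'
#' @param quant An `am_quant` data frame.
#' @param use_below_lod Include below-LoD quotas in the matrix cells
#'   (default `FALSE`: they are zeroed, matching the totals rule).
#' @return Numeric matrix, strains x (variants + `total_AM`).
#' @export
quota_matrix <- function(quant, use_below_lod = FALSE) {
  stopifnot(inherits(quant, "am_quant"))
  totals <- attr(quant, "totals")
  strains <- totals$strain_id
  variants <- sort(unique(quant$variant_name))
  m <- matrix(0, nrow = length(strains), ncol = length(variants),
              dimnames = list(strains, variants))
  q <- quant$cell_quota_fg_per_cell
  if (!use_below_lod) q[quant$below_lod] <- 0
  for (i in seq_len(nrow(quant)))
    m[quant$strain_id[i], quant$variant_name[i]] <- q[i]
  cbind(m, total_AM = totals$total_fg_per_cell[match(strains,
                                                     totals$strain_id)])
}
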
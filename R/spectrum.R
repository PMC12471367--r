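#' Construct a CID product-ion spectrum
#'
#' A spectrum holds one collision-induced dissociation (CID) scan of a
#' sodium-adduct pseudo-molecular ion: the precursor m/z, the retention time
#' and a centroided peak list. All m/z values are observed adduct m/z of
#' singly charged sodium adducts; no neutral-mass conversion is performed
#' anywhere in the package, mirroring how amphidinol fragment arithmetic is
#' done directly on adduct masses.
#'
#' @param spectrum_id Character scalar identifying the scan.
#' @param precursor_mz Precursor m/z (Da); must be positive.
#' @param rt_min Retention time in minutes.
#' @param fragments A two-column `data.frame` (or matrix) with columns `mz`
#'   and `intensity`. Fragments are sorted ascending by m/z; intensities must
#'   be non-negative and every fragment m/z must be below
#'   `precursor_mz + 1`.
#' @param strain_id Optional strain identifier.
#'
#' @return An object of class `am_spectrum`.
#' @examples
#' s <- am_spectrum("s1", 1226, 3.89,
#'                  data.frame(mz = c(834, 1226), intensity = c(100, 5)))
#' s
#' @export
am_spectrum <- function(spectrum_id, precursor_mz, rt_min, fragments,
                        strain_id = NA_character_) {
  stopifnot(is.character(spectrum_id), length(spectrum_id) == 1L)
  precursor_mz <- as.numeric(precursor_mz)
  rt_min <- as.numeric(rt_min)
  if (!is.finite(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a positive number (got ", precursor_mz, ")")
  fragments <- as.data.frame(fragments)
  if (!all(c("mz", "intensity") %in% names(fragments)))
    stop("fragments must have columns 'mz' and 'intensity'")
  fragments <- fragments[c("mz", "intensity")]
  fragments$mz <- as.numeric(fragments$mz)
  fragments$intensity <- as.numeric(fragments$intensity)
  if (nrow(fragments)) {
    if (any(!is.finite(fragments$mz)) || any(!is.finite(fragments$intensity)))
      stop("fragment m/z and intensity must be finite")
    if (any(fragments$intensity < 0))
      stop("fragment intensities must be >= 0")
    if (any(fragments$mz >= precursor_mz + 1.0))
      stop("fragment m/z ", max(fragments$mz),
           " exceeds precursor_mz + 1 (", precursor_mz + 1.0, ")")
    fragments <- fragments[order(fragments$mz), , drop = FALSE]
    rownames(fragments) <- NULL
  }
  structure(
    list(spectrum_id = spectrum_id, precursor_mz = precursor_mz,
         rt_min = rt_min, fragments = fragments,
         strain_id = as.character(strain_id)),
    class = "am_spectrum"
  )
}

#' @export
print.am_spectrum <- function(x, ...) {
  cat(sprintf("<am_spectrum %s> precursor m/z %.4g, RT %.2f min, %d fragments\n",
              x$spectrum_id, x$precursor_mz, x$rt_min, nrow(x$fragments)))
  if (!is.na(x$strain_id)) cat("  strain:", x$strain_id, "\n")
  invisible(x)
}

is_am_spectrum <- function(x) inherits(x, "am_spectrum")

#' Per-fragment signal-to-noise in a centroided peak list
#'
#' Estimates a noise floor for a spectrum as the median intensity of all
#' peaks below `noise_frac` of the base peak, and returns each fragment's
#' intensity divided by that floor. A spectrum with no sub-threshold peaks is
#' treated as noise-free and every fragment gets `Inf` (which passes any
#' finite S/N threshold). This is the S/N used when screening peak lists; the
#' chromatographic-trace estimator is [estimate_snr()].
#'
#' @param s An [am_spectrum()].
#' @param noise_frac Fraction of the base-peak intensity below which a peak
#'   is considered noise (default 0.1).
#' @return Numeric vector of S/N values, one per fragment (in m/z order).
#' @export
fragment_snr <- function(s, noise_frac = 0.1) {
  stopifnot(is_am_spectrum(s))
  ints <- s$fragments$intensity
  if (!length(ints)) return(numeric(0))
  base <- max(ints)
  if (base <= 0) return(rep(0, length(ints)))
  noise <- ints[ints < noise_frac * base]
  if (!length(noise)) return(rep(Inf, length(ints)))
  floor_ <- median(noise)
  if (floor_ <= 0) return(ifelse(ints > 0, Inf, 0))
  ints / floor_
}
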
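#' Read an MGF peak-list file
#'
#' Parses a Mascot Generic Format file (`BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS`, `RTINSECONDS` and optional `TITLE`/`STRAIN` headers) into a
#' list of [am_spectrum()] objects. Retention times are converted from
#' seconds to minutes on read and fragments are sorted ascending by m/z.
#'
#' Blocks without a `PEPMASS` are rejected with a warning naming the block's
#' first line; malformed peak lines abort with an error naming the line.
#'
#' @param path Path to the MGF file.
#' @return List of `am_spectrum` objects (empty, with a warning, for an
#'   empty file).
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  block_no <- 0L
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) { i <- i + 1L; next }
    if (toupper(line) != "BEGIN IONS")
      stop("MGF parse error at line ", i, ": expected BEGIN IONS, got '",
           line, "'")
    block_no <- block_no + 1L
    block_start <- i
    i <- i + 1L
    pepmass <- NA_real_; rt_sec <- NA_real_
    title <- NA_character_; strain <- NA_character_
    mz <- numeric(0); intensity <- numeric(0)
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[i])
      if (line == "") { i <- i + 1L; next }
      if (toupper(line) == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*", "", line))
        val <- sub("^[^=]*=", "", line)
        if (key == "PEPMASS") {
          pepmass <- suppressWarnings(as.numeric(strsplit(trimws(val),
                                                          "\\s+")[[1]][1]))
          if (is.na(pepmass))
            stop("MGF parse error at line ", i, ": unreadable PEPMASS '",
                 val, "'")
        } else if (key == "RTINSECONDS") {
          rt_sec <- suppressWarnings(as.numeric(val))
        } else if (key == "TITLE") {
          title <- trimws(val)
        } else if (key == "STRAIN") {
          strain <- trimws(val)
        }
        i <- i + 1L
        next
      }
      toks <- strsplit(line, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) < 2L || any(is.na(vals[1:2])))
        stop("MGF parse error at line ", i, ": malformed peak line '",
             line, "'")
      mz <- c(mz, vals[1]); intensity <- c(intensity, vals[2])
      i <- i + 1L
    }
    if (!closed)
      stop("MGF parse error: block starting at line ", block_start,
           " has no END IONS")
    if (is.na(pepmass)) {
      warning("MGF block starting at line ", block_start,
              " rejected: missing PEPMASS")
      next
    }
    id <- if (is.na(title)) sprintf("spectrum_%d", block_no) else title
    sp <- tryCatch(
      am_spectrum(id, pepmass, if (is.na(rt_sec)) NA_real_ else rt_sec / 60,
                  data.frame(mz = mz, intensity = intensity),
                  strain_id = strain),
      error = function(e)
        stop("MGF block starting at line ", block_start, ": ",
             conditionMessage(e), call. = FALSE)
    )
    spectra[[length(spectra) + 1L]] <- sp
  }
  if (!length(spectra)) warning("no spectra read from ", path)
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: m/z values are written to 4 decimals and
#' intensities to 2, so a read/write round trip is lossless at that declared
#' precision. Retention times are written as `RTINSECONDS`.
#'
#' @param spectra List of [am_spectrum()] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(is.list(spectra))
  out <- character(0)
  for (s in spectra) {
    stopifnot(is_am_spectrum(s))
    hdr <- c("BEGIN IONS",
             paste0("TITLE=", s$spectrum_id),
             sprintf("PEPMASS=%.4f", s$precursor_mz))
    if (!is.na(s$rt_min))
      hdr <- c(hdr, sprintf("RTINSECONDS=%.4f", s$rt_min * 60))
    if (!is.na(s$strain_id))
      hdr <- c(hdr, paste0("STRAIN=", s$strain_id))
    peaks <- sprintf("%.4f %.2f", s$fragments$mz, s$fragments$intensity)
    out <- c(out, hdr, peaks, "END IONS", "")
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("cannot write MGF to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read an SRM transition table
#'
#' Reads a CSV library of known amphidinol variants with columns
#' `variant_name, q1_mz, q3_mz, rt_min, sulfated`. Each row defines one
#' selected-reaction-monitoring transition (Q1 precursor m/z, Q3 product
#' m/z) plus the expected retention time.
#'
#' @param path CSV path.
#' @return A validated `data.frame` with class `am_transitions`.
#' @seealso [default_transitions()]
#' @export
read_transition_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("variant_name", "q1_mz", "q3_mz", "rt_min", "sulfated")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("transition table missing column(s): ",
         paste(missing, collapse = ", "))
  tab <- tab[req]
  tab$q1_mz <- as.numeric(tab$q1_mz)
  tab$q3_mz <- as.numeric(tab$q3_mz)
  tab$rt_min <- as.numeric(tab$rt_min)
  tab$sulfated <- as.logical(tab$sulfated)
  validate_transitions(tab)
}

validate_transitions <- function(tab) {
  bad <- which(tab$q3_mz >= tab$q1_mz)
  if (length(bad))
    stop("transition table row ", bad[1], " (", tab$variant_name[bad[1]],
         "): q3_mz must be < q1_mz")
  bad <- which(!is.finite(tab$rt_min) | tab$rt_min <= 0)
  if (length(bad))
    stop("transition table row ", bad[1], " (", tab$variant_name[bad[1]],
         "): rt_min must be > 0")
  dup <- tab$variant_name[duplicated(tab$variant_name)]
  if (length(dup))
    stop("duplicate variant name(s) in transition table: ",
         paste(unique(dup), collapse = ", "))
  class(tab) <- c("am_transitions", "data.frame")
  tab
}

#' Default transition library shipped with the package
#'
#' Returns the editable transition library installed at
#' `inst/extdata/am_transitions.csv`. It contains the eight ARC variants
#' (Q1 mass, retention time, sulfation flag, and the C1/C1' cleavage
#' fragment as Q3) recoverable from the published main text; the full
#' appendix library of ~50 known variants is not public, so users extend
#' this CSV with their own entries.
#'
#' @return An `am_transitions` data frame.
#' @export
default_transitions <- function() {
  read_transition_table(system.file("extdata", "am_transitions.csv",
                                    package = "amprofiler", mustWork = TRUE))
}

#' Read cell-count and brine-shrimp assay tables
#'
#' `path_cells` must be a CSV with columns
#' `strain_id, n_cells, sample_volume_ul` (one row per strain);
#' `path_assay` a CSV with columns
#' `strain_id, well_id, well_type, initial_dead, dead_24h, dead_48h, total`
#' where `well_type` is one of `treatment`, `dmso_control`,
#' `seawater_control`. The assay design expects 3 treatment wells per strain
#' (a warning is raised otherwise) alongside 6 control wells.
#'
#' @param path_cells,path_assay CSV paths.
#' @return An object of class `am_counts`: a list with elements
#'   `cell_counts` and `assay_counts`.
#' @export
read_count_tables <- function(path_cells, path_assay) {
  cells <- read.csv(path_cells, stringsAsFactors = FALSE)
  assay <- read.csv(path_assay, stringsAsFactors = FALSE)
  am_counts(cells, assay)
}

#' Assemble and validate count tables
#'
#' Programmatic constructor behind [read_count_tables()]; validates the
#' invariants (dead counts within well totals, positive cell counts and
#' volumes, known well types) and cross-references the two tables.
#'
#' @param cell_counts,assay_counts Data frames with the columns documented
#'   in [read_count_tables()].
#' @return An `am_counts` object.
#' @export
am_counts <- function(cell_counts, assay_counts) {
  req_c <- c("strain_id", "n_cells", "sample_volume_ul")
  req_a <- c("strain_id", "well_id", "well_type", "initial_dead",
             "dead_24h", "dead_48h", "total")
  if (!all(req_c %in% names(cell_counts)))
    stop("cell_counts must have columns: ", paste(req_c, collapse = ", "))
  if (!all(req_a %in% names(assay_counts)))
    stop("assay_counts must have columns: ", paste(req_a, collapse = ", "))
  cell_counts <- cell_counts[req_c]
  assay_counts <- assay_counts[req_a]
  if (any(cell_counts$n_cells <= 0))
    stop("n_cells must be > 0 for every strain")
  if (any(cell_counts$sample_volume_ul <= 0))
    stop("sample_volume_ul must be > 0 for every strain")
  if (anyDuplicated(cell_counts$strain_id))
    stop("duplicate strain_id in cell_counts")
  ok_types <- c("treatment", "dmso_control", "seawater_control")
  bad <- which(!assay_counts$well_type %in% ok_types)
  if (length(bad))
    stop("assay_counts row ", bad[1], ": unknown well_type '",
         assay_counts$well_type[bad[1]], "'")
  num <- c("initial_dead", "dead_24h", "dead_48h", "total")
  for (col in num) {
    if (any(assay_counts[[col]] < 0))
      stop("assay_counts: ", col, " must be >= 0")
  }
  bad <- which(assay_counts$dead_24h > assay_counts$total |
               assay_counts$dead_48h > assay_counts$total |
               assay_counts$initial_dead > assay_counts$total)
  if (length(bad))
    stop("assay_counts row ", bad[1], " (strain ",
         assay_counts$strain_id[bad[1]],
         "): dead counts exceed well total")
  n_treat <- tapply(assay_counts$well_type == "treatment",
                    assay_counts$strain_id, sum)
  odd <- names(n_treat)[n_treat != 3L]
  if (length(odd))
    warning("strain(s) without exactly 3 treatment wells: ",
            paste(odd, collapse = ", "))
  missing <- setdiff(unique(assay_counts$strain_id), cell_counts$strain_id)
  if (length(missing))
    warning("strain(s) in assay but not in cell_counts (excluded from cell-",
            "quota calculations): ", paste(missing, collapse = ", "))
  structure(list(cell_counts = cell_counts, assay_counts = assay_counts),
            class = "am_counts")
}

#' @export
print.am_counts <- function(x, ...) {
  cat(sprintf("<am_counts> %d strains with cell counts, %d assay wells\n",
              nrow(x$cell_counts), nrow(x$assay_counts)))
  invisible(x)
}
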
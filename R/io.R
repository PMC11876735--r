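#' Read and write planar count images
#'
#' Count matrices travel either as headerless CSV matrices (plain text,
#' lossless for counts) or as 16-bit grayscale TIFF (requires the `tiff`
#' package; counts above 65535 are rejected rather than clipped).
#'
#' @param path File path; format inferred from the extension (`.csv` or
#'   `.tif`/`.tiff`).
#' @param image Integer count matrix (for writing).
#' @return `read_count_image()` returns an integer matrix.
#' @export
read_count_image <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    return(m)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    m <- tiff::readTIFF(path, as.is = TRUE)
    storage.mode(m) <- "integer"
    return(m)
  }
  stop("unsupported image format: ", path)
}

#' @rdname read_count_image
#' @export
write_count_image <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.table(image, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(path))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package")
    if (any(image > 65535))
      stop("counts exceed the 16-bit TIFF range; use CSV")
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
    return(invisible(path))
  }
  stop("unsupported image format: ", path)
}

# Column-header contracts for the tabular interchange formats. Readers
# validate headers so unit mistakes fail loudly rather than silently.
required_columns <- list(
  activity_samples = c("source", "time_h", "fraction_ia", "sd"),
  s_values = c("target", "source", "s_value_Gy_per_GBq_h"),
  organ_masses = c("organ", "mass_g"),
  lesions = c("lesion_id", "location_class", "mass_g", "tiac_h"),
  measurements = c("lesion_id", "week", "L_mm", "W_mm", "is_lymph_node")
)

read_validated_csv <- function(path, what) {
  cols <- required_columns[[what]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop(sprintf("%s: missing required column(s) %s — check file format and units",
                 path, paste(missing, collapse = ", ")))
  d
}

#' Tabular interchange readers
#'
#' CSV readers with header validation for the pipeline's interchange tables:
#' time-activity samples (`source, time_h, fraction_ia, sd`), S-value tables
#' (`target, source, s_value_Gy_per_GBq_h`), organ masses (`organ, mass_g`),
#' lesion tables (`lesion_id, location_class, mass_g, tiac_h`) and CT
#' measurement tables (`lesion_id, week, L_mm, W_mm, is_lymph_node`).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_activity_samples <- function(path) {
  d <- read_validated_csv(path, "activity_samples")
  class(d) <- c("timed_activity_samples", "data.frame")
  d
}

#' @rdname read_activity_samples
#' @param masses_path Path of the companion organ-mass CSV.
#' @export
read_dose_factor_table <- function(path, masses_path) {
  dose_factor_table(read_validated_csv(path, "s_values"),
                    read_validated_csv(masses_path, "organ_masses"))
}

#' @rdname read_activity_samples
#' @export
read_lesion_table <- function(path) read_validated_csv(path, "lesions")

#' @rdname read_activity_samples
#' @export
read_measurements <- function(path) read_validated_csv(path, "measurements")

#' Toy reference dose-factor table
#'
#' A small synthetic S-value table for an adult-sized phantom (kidneys,
#' liver, spleen, red marrow, total body), built from electron self-dose plus
#' a minor photon cross-dose component, with masses such that the MIRD
#' remainder identity `S(t <- TB) * M_TB = sum_regions S(t <- s) * M_s`
#' holds. The numbers are plausible in magnitude for Lu-177 but are NOT a
#' published reference phantom table; they exist to exercise the dose
#' mathematics.
#'
#' @return A [dose_factor_table()].
#' @export
toy_dose_factor_table <- function() {
  read_dose_factor_table(
    system.file("extdata", "s_values_synthetic.csv", package = "prrtdose"),
    system.file("extdata", "organ_masses_synthetic.csv", package = "prrtdose"))
}

#' Write a deterministic report bundle
#'
#' Writes the cohort report produced by [run_cohort_report()] as a fixed set
#' of text artifacts: `organ_dose_summary.tsv` (per-organ cohort summary),
#' `lesion_doses.csv`, `lesion_response.csv`, `flags.json` and
#' `dose_response_scatter.csv`. Output is byte-deterministic for a given
#' report.
#'
#' @param report A `cohort_report` from [run_cohort_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
    d
  }
  utils::write.table(fmt(report$organ_summary),
                     file.path(dir, "organ_dose_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fmt(report$lesion_doses),
                     file.path(dir, "lesion_doses.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(fmt(report$lesion_response),
                     file.path(dir, "lesion_response.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(fmt(report$dose_response$table),
                     file.path(dir, "dose_response_scatter.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$flags, file.path(dir, "flags.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
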
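#' Paired dosimetric parameter cohort
#'
#' Holds one dosimetric parameter (e.g. mean heart dose, or a VxGy) per
#' patient for two contour sets of the same organ: the designated ground
#' truth and the alternative.  The two vectors are paired — same patients,
#' same order.
#'
#' @param D_gt numeric vector of ground-truth values (>= 0), one per patient.
#' @param D_alt numeric vector of alternative-contour values (>= 0), same
#'   length and patient order as `D_gt`.
#' @param parameter_name label for the dosimetric parameter, e.g. `"MHD"` or
#'   `"V5Gy"`.  Names matching `"V<x>Gy"` are treated as volume percentages
#'   and must lie in `[0, 100]`.
#' @param patient_ids optional identifiers (default `"P1"`, `"P2"`, ...).
#' @return An object of class `dose_cohort`: a list with fields
#'   `patient_ids`, `parameter_name`, `D_gt`, `D_alt`, `normalization_factor`
#'   (`NA` until normalized) and `normalized` (logical).
#' @examples
#' co <- dose_cohort(D_gt = c(10, 20, 30), D_alt = c(11, 18, 33))
#' nco <- normalize_cohort(co)
#' mean(nco$D_gt)  # 1
#' @seealso [normalize_cohort()], [read_cohort_csv()], [generate_cohort()]
#' @export
dose_cohort <- function(D_gt, D_alt, parameter_name = "MHD",
                        patient_ids = NULL) {
  if (!is.numeric(D_gt) || !is.numeric(D_alt))
    stop("'D_gt' and 'D_alt' must be numeric vectors")
  n <- length(D_gt)
  if (n < 2L) stop("a cohort needs at least 2 patients")
  if (length(D_alt) != n)
    stop("'D_gt' and 'D_alt' must have identical length (paired patients)")
  if (any(!is.finite(D_gt)) || any(!is.finite(D_alt)))
    stop("dose parameter values must be finite")
  if (any(D_gt < 0) || any(D_alt < 0))
    stop("dose parameter values must be non-negative")
  if (is_vxgy_name(parameter_name) &&
      (any(D_gt > 100) || any(D_alt > 100)))
    stop(sprintf("'%s' is a volume percentage; values must lie in [0, 100]",
                 parameter_name))
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(n))
  if (length(patient_ids) != n) stop("'patient_ids' length mismatch")
  structure(list(patient_ids = as.character(patient_ids),
                 parameter_name = parameter_name,
                 D_gt = as.numeric(D_gt), D_alt = as.numeric(D_alt),
                 normalization_factor = NA_real_, normalized = FALSE),
            class = "dose_cohort")
}

is_vxgy_name <- function(x) grepl("^V[0-9.]+Gy$", x, ignore.case = TRUE)

#' @export
print.dose_cohort <- function(x, ...) {
  cat(sprintf("Paired dose cohort: %s, n = %d patient(s)%s\n",
              x$parameter_name, length(x$D_gt),
              if (x$normalized)
                sprintf(" [normalized; factor = %.4g]", x$normalization_factor)
              else " [unnormalized]"))
  cat(sprintf("  D_gt : mean %.4g, range [%.4g, %.4g]\n",
              mean(x$D_gt), min(x$D_gt), max(x$D_gt)))
  cat(sprintf("  D_alt: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$D_alt), min(x$D_alt), max(x$D_alt)))
  invisible(x)
}

#' @export
length.dose_cohort <- function(x) length(x$D_gt)

#' Normalize a cohort so the ground-truth mean is 1
#'
#' Divides both `D_gt` and `D_alt` by the same factor, the pre-normalization
#' mean of `D_gt`, so that the ground-truth parameter has mean exactly 1 while
#' the alternative keeps its relative scale (its mean will generally differ
#' from 1).  Normalization is a pure rescaling: it changes neither ranks nor
#' correlations between the two vectors.  Applying it twice is an error, not a
#' silent re-scaling.
#'
#' @param cohort an unnormalized [dose_cohort()].
#' @return The normalized cohort, with `normalization_factor` set to the
#'   divisor and `normalized = TRUE`.
#' @export
normalize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "dose_cohort"))
  if (isTRUE(cohort$normalized))
    stop("cohort is already normalized; refusing to re-scale")
  f <- mean(cohort$D_gt)
  if (f <= 0) stop("cannot normalize: mean of D_gt is not positive")
  cohort$D_gt <- cohort$D_gt / f
  cohort$D_alt <- cohort$D_alt / f
  cohort$normalization_factor <- f
  cohort$normalized <- TRUE
  cohort
}

#' Read and write paired-cohort CSV files
#'
#' The on-disk format is one CSV per dosimetric parameter with a header and
#' columns `patient_id, D_gt, D_alt`; values are on the raw scale (Gy or %)
#' before normalization.
#'
#' @param path file path.
#' @param parameter_name label for the dosimetric parameter stored in the
#'   file (the CSV itself does not carry it).
#' @return `read_cohort_csv()` returns an unnormalized [dose_cohort()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, parameter_name = "MHD") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "D_gt", "D_alt")
  if (!all(need %in% names(df)))
    stop(sprintf("cohort CSV must have columns %s",
                 paste(need, collapse = ", ")))
  dose_cohort(D_gt = df$D_gt, D_alt = df$D_alt,
              parameter_name = parameter_name,
              patient_ids = df$patient_id)
}

#' @rdname read_cohort_csv
#' @param cohort a [dose_cohort()] to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "dose_cohort"))
  write.csv(data.frame(patient_id = cohort$patient_ids,
                       D_gt = cohort$D_gt, D_alt = cohort$D_alt),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
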
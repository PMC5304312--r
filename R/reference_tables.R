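# Bundled reference tables from the original clinical measurement campaign
# (10 healthy subjects, 6 air-puff tonometry measurements each, spread over
# the cardiac cycle).  Shipped as plain CSVs under inst/extdata; obvious
# typographical artifacts in the printed originals were normalized when
# transcribing.  Used to validate the package's summary statistics.

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "tonopulse")
  if (p == "") stopf("reference table %s not found; is the package installed?", file)
  p
}

#' Reference single-subject feature measurements
#'
#' Six repeated measurements of features `w(1)..w(5)` for one healthy
#' subject (right eye), taken in different cardiac phases.
#'
#' @return data.frame with columns `measurement`, `w1_ms..w5_mmHg`.
#' @export
reference_subject1_features <- function() {
  read.csv(ref_path("reference_subject1_features.csv"))
}

#' Reference cohort feature table
#'
#' Per-subject means and sample standard deviations of `w(1)..w(5)` for the
#' 10-subject reference cohort.
#'
#' @return data.frame, one row per subject.
#' @export
reference_cohort_feature_table <- function() {
  read.csv(ref_path("reference_cohort_feature_table.csv"))
}

#' Reference correlation extrema
#'
#' Per-subject minimum and maximum IOP-vs-phase correlations with the phase
#' shifts at which they occur, for the 10-subject reference cohort.
#'
#' @return data.frame with columns `subject`, `r_min`, `phi_min_deg`,
#'   `r_max`, `phi_max_deg`.
#' @export
reference_correlation_extrema <- function() {
  read.csv(ref_path("reference_correlation_extrema.csv"))
}
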
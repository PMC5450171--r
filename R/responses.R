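#' Assay response computations
#'
#' The five responses of an extraction-optimization experiment are simple
#' ratios of raw measurements: extraction yield from weights, total polyphenol
#' content from a gallic-acid-equivalent concentration, and percent inhibition
#' from blank-corrected absorbances for enzyme (PTP-1B, alpha-glucosidase) and
#' radical (ABTS, DPPH) assays. All operations consume already blank-corrected
#' values; plate-level blank handling is the caller's responsibility because
#' layouts differ between assays.
#'
#' @name assay_responses
NULL

#' Extraction yield in percent
#'
#' `100 * w_after / w_before`: the dry extract mass relative to the raw
#' material mass. Values above 100% are arithmetically possible (e.g. residual
#' moisture) and are returned as-is with a warning.
#'
#' @param w_after Extract weight after extraction and drying (g).
#' @param w_before Raw material weight before extraction (g); must be > 0.
#' @return Percent yield (vectorized).
#' @examples
#' extraction_yield(1.964, 5) # 39.28
#' @export
extraction_yield <- function(w_after, w_before) {
  stopifnot(is.numeric(w_after), is.numeric(w_before))
  if (any(w_before <= 0)) stop("w_before must be positive", call. = FALSE)
  if (any(w_after < 0)) stop("w_after must be non-negative", call. = FALSE)
  y <- w_after / w_before * 100
  if (any(y > 100))
    warning("extraction yield above 100% for ", sum(y > 100), " value(s)",
            call. = FALSE)
  y
}

#' Total polyphenol content in percent
#'
#' `100 * c_gae / c_total`: gallic-acid-equivalent concentration of the
#' extract solution relative to the total sample concentration.
#'
#' @param c_gae Gallic-acid equivalents (ug/mL).
#' @param c_total Total sample concentration (ug/mL); must be > 0.
#' @return Percent TPC (vectorized).
#' @examples
#' tpc_percent(4.844, 10) # 48.44
#' @export
tpc_percent <- function(c_gae, c_total) {
  stopifnot(is.numeric(c_gae), is.numeric(c_total))
  if (any(c_total <= 0)) stop("c_total must be positive", call. = FALSE)
  if (any(c_gae < 0)) stop("c_gae must be non-negative", call. = FALSE)
  c_gae / c_total * 100
}

#' Percent inhibition from control and sample absorbances
#'
#' `inhibition_enzyme()` computes `100 * (control - sample) / control`, the
#' standard microplate enzyme-inhibition rate (PTP-1B with pNPP substrate,
#' alpha-glucosidase with pNPG). `inhibition_radical()` computes the identical
#' ratio `100 * (a_blank - a_sample) / a_blank` for radical-scavenging assays
#' (ABTS, DPPH), where the "control" is the uninhibited radical solution. Both
#' are scale-invariant in the absorbances. Negative values (apparent
#' activation, or absorbance above the radical blank) are returned as-is with
#' a warning.
#'
#' @param control,sample Blank-corrected absorbances (AU); `control` must be > 0.
#' @param a_blank,a_sample Radical-assay absorbances (AU); `a_blank` must be > 0.
#' @return Percent inhibition (vectorized).
#' @examples
#' inhibition_enzyme(1.0, 0.25)   # 75
#' inhibition_radical(0.70, 0.175) # 75
#' @export
inhibition_enzyme <- function(control, sample) {
  stopifnot(is.numeric(control), is.numeric(sample))
  if (any(control <= 0)) stop("control absorbance must be positive", call. = FALSE)
  if (any(sample < 0)) stop("sample absorbance must be non-negative", call. = FALSE)
  ir <- (control - sample) / control * 100
  if (any(ir < 0))
    warning("negative inhibition (activation) for ", sum(ir < 0), " value(s)",
            call. = FALSE)
  ir
}

#' @rdname inhibition_enzyme
#' @export
inhibition_radical <- function(a_blank, a_sample) {
  stopifnot(is.numeric(a_blank), is.numeric(a_sample))
  if (any(a_blank <= 0)) stop("blank absorbance must be positive", call. = FALSE)
  if (any(a_sample < 0)) stop("sample absorbance must be non-negative", call. = FALSE)
  ir <- (a_blank - a_sample) / a_blank * 100
  if (any(ir < 0))
    warning("negative scavenging for ", sum(ir < 0), " value(s)", call. = FALSE)
  ir
}

#' Gallic-acid standard curve for the polyphenol assay
#'
#' Fits the least-squares line `absorbance = slope * conc + intercept` through
#' at least three standard points; a thin wrapper around [fit_calibration()]
#' returning the same `calibration_curve` object.
#'
#' @param conc Standard concentrations (ug/mL); at least 3 distinct values.
#' @param absorbance Measured absorbances (AU).
#' @return A [fit_calibration()] `calibration_curve` (`slope`, `intercept`, `r2`).
#' @export
gae_calibration <- function(conc, absorbance) {
  stopifnot(length(conc) >= 3L)
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct standard concentrations", call. = FALSE)
  fit_calibration(conc, absorbance, analyte = "gallic acid")
}
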
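#' Bundled four-factor extraction optimization study
#'
#' A published 29-run Box-Behnken optimization of the ethanol-water reflux
#' extraction of a two-herb antidiabetic preparation, used as the worked
#' example throughout this package. Four factors — ethanol concentration (%),
#' extraction temperature (degC), sample-to-solvent ratio (the `N` of
#' "1 : N g/mL") and extraction time (h) — each at three levels, with five
#' replicated center runs (rows 7, 13, 20, 24 and 28 of the table). Five
#' measured responses: extraction yield (%), total polyphenol content (%,
#' gallic-acid equivalents), PTP-1B inhibition rate (%), alpha-glucosidase
#' inhibition rate (%) and ABTS radical-scavenging rate (%). The table
#' stores natural factor settings; coded values are recomputed from the
#' factor specs (the published coded labels contain typos, so the natural
#' values are authoritative).
#'
#' @return A list with `factors` (named list of [factor_spec()]) and `runs`
#'   (data frame: `run`, the four natural-unit factor columns, and the five
#'   response columns `yield`, `tpc`, `ptp1b`, `aglu`, `abts`).
#' @examples
#' study <- herbal_extraction_study()
#' validate_bbd(code_runs(study$runs, study$factors)[names(study$factors)])
#' @export
herbal_extraction_study <- function() {
  runs <- utils::read.csv(
    system.file("extdata", "herbal_bbd_runs.csv", package = "bbrsm",
                mustWork = TRUE))
  factors <- list(
    factor_spec("ethanol_pct", 30, 50, 70, unit = "%"),
    factor_spec("temperature_c", 60, 70, 80, unit = "degC"),
    factor_spec("solvent_ratio", 10, 20, 30, unit = "g/mL"),
    factor_spec("time_h", 2, 3, 4, unit = "h")
  )
  list(factors = as_factor_list(factors), runs = runs)
}

#' Bundled chromatographic component table for the same study
#'
#' The twelve components identified in the purified extract of the bundled
#' study ([herbal_extraction_study()]): retention time, name, external
#' calibration line (`area = slope * conc + intercept`, concentration in
#' ug/mL), its R-squared, the published content (percent w/w, one-point
#' external-standard method) and the validated linear range. Peak 5
#' (corilagin, 18.2 min) is the reference peak for suitability metrics.
#'
#' @return Data frame with columns `peak`, `t_r_min`, `component`, `slope`,
#'   `intercept`, `r2`, `content_pct`, `range_low_ugml`, `range_high_ugml`.
#' @examples
#' comp <- herbal_uplc_components()
#' total_content(comp$content_pct)  # ~11.17
#' @export
herbal_uplc_components <- function() {
  utils::read.csv(
    system.file("extdata", "herbal_uplc_components.csv", package = "bbrsm",
                mustWork = TRUE))
}
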
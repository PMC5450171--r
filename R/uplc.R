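#' Linear calibration curve for an analyte
#'
#' Ordinary least-squares line `area = slope * conc + intercept` through the
#' standard points, with R-squared computed as `1 - SS_res/SS_tot` (defined as
#' 0 when the areas are constant). Two exact points give the interpolating
#' line with R-squared 1. The valid concentration range defaults to the range
#' of the standards; quantification outside it is flagged downstream.
#'
#' @param conc Standard concentrations (ug/mL); at least two distinct values.
#' @param area Peak areas, same length.
#' @param analyte Name label.
#' @param range Length-2 numeric, the valid (linear) range; default
#'   `range(conc)`.
#' @return A `calibration_curve` with elements `analyte`, `slope`,
#'   `intercept`, `r2`, `range`, `n`.
#' @examples
#' cc <- fit_calibration(c(10, 30, 50, 70), 6649.1 * c(10, 30, 50, 70) - 625.98)
#' c(cc$slope, cc$intercept, cc$r2)
#' @export
fit_calibration <- function(conc, area, analyte = "", range = NULL) {
  stopifnot(is.numeric(conc), is.numeric(area), length(conc) == length(area),
            length(conc) >= 2L)
  if (length(unique(conc)) < 2L)
    stop("all standard concentrations identical", call. = FALSE)
  fit <- stats::lm(area ~ conc)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, mean(area)^2)) 0
        else 1 - ss_res / ss_tot
  if (is.null(range)) range <- base::range(conc)
  stopifnot(length(range) == 2L, range[1] < range[2])
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2, range = range, n = length(conc), lm = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve>%s y = %.6g x %s %.6g, R2 = %.4f, range %g-%g ug/mL (n = %d)\n",
              if (nzchar(x$analyte)) paste0(" ", x$analyte, ":") else "",
              x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
              x$r2, x$range[1], x$range[2], x$n))
  invisible(x)
}

#' One-point external-standard quantification
#'
#' Computes an analyte's content (percent w/w of the extract) from a single
#' standard injection: the sample concentration is
#' `sample_area / standard_area * standard_conc`, and the content converts
#' that solution concentration to a mass fraction via the sample solution
#' volume, dilution factor and weighed extract mass. The result is
#' homogeneous of degree 1 in `sample_area` and `dilution` and of degree -1
#' in `mass_mg`. When a [fit_calibration()] curve is supplied, implied sample
#' concentrations outside its valid range are flagged with a warning.
#'
#' @param sample_area,standard_area Peak areas; `standard_area` > 0.
#' @param standard_conc Standard concentration (ug/mL).
#' @param volume_ml Volume of the sample solution (mL).
#' @param mass_mg Weighed extract mass (mg); > 0.
#' @param dilution Dilution factor applied to the sample solution (default 1).
#' @param curve Optional `calibration_curve` used only to range-check the
#'   implied concentration.
#' @return Content in percent w/w (vectorized over `sample_area`).
#' @examples
#' # standard corresponds to 1% content: 100 ug/mL * 10 mL / 100 mg / 10
#' quantify_one_point(500, 500, 100, volume_ml = 10, mass_mg = 100) # 1
#' @export
quantify_one_point <- function(sample_area, standard_area, standard_conc,
                               volume_ml, mass_mg, dilution = 1, curve = NULL) {
  stopifnot(is.numeric(sample_area), length(standard_area) == 1L,
            length(standard_conc) == 1L)
  if (standard_area <= 0) stop("standard_area must be positive", call. = FALSE)
  if (mass_mg <= 0) stop("mass_mg must be positive", call. = FALSE)
  stopifnot(standard_conc > 0, volume_ml > 0, dilution > 0)
  conc <- sample_area / standard_area * standard_conc            # ug/mL
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "calibration_curve"))
    out <- conc < curve$range[1] | conc > curve$range[2]
    if (any(out))
      warning(sum(out), " implied concentration(s) outside the linear range ",
              curve$range[1], "-", curve$range[2], " ug/mL", call. = FALSE)
  }
  # ug in solution / ug of extract, as percent
  conc * volume_ml * dilution / (mass_mg * 1000) * 100
}

#' Total content of quantified components
#'
#' Arithmetic sum of per-component contents (percent w/w). Sums of printed,
#' individually rounded contents can differ from the sum of unrounded values
#' in the last digit; this function performs no rounding.
#'
#' @param contents Numeric vector of non-negative percent contents.
#' @return Their sum.
#' @export
total_content <- function(contents) {
  stopifnot(is.numeric(contents))
  if (any(contents < 0)) stop("contents must be non-negative", call. = FALSE)
  sum(contents)
}

# normalize peak-table input: list of data.frames or long df with injection col
as_peak_tables <- function(tables) {
  if (is.data.frame(tables)) {
    stopifnot("injection" %in% names(tables))
    tables <- split(tables[setdiff(names(tables), "injection")],
                    tables$injection)
  }
  stopifnot(is.list(tables), length(tables) >= 1L)
  lapply(tables, function(tb) {
    tb <- as.data.frame(tb)
    need <- c("peak", "t_r", "area")
    if (!all(need %in% names(tb)))
      stop("peak table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(tb$peak)) stop("duplicate peak numbers in an injection",
                                     call. = FALSE)
    tb <- tb[order(tb$peak), ]
    if (any(tb$t_r <= 0)) stop("retention times must be positive", call. = FALSE)
    if (is.unsorted(tb$t_r, strictly = TRUE))
      stop("retention times must increase with peak number", call. = FALSE)
    tb
  })
}

#' System-suitability metrics from replicate injections
#'
#' For each peak, computes the relative retention time (RRT, retention time
#' divided by that of the reference peak) and relative peak area (RPA) within
#' each injection, then their percent relative standard deviations across
#' injections (sample standard deviation, n-1 denominator, as is
#' pharmacopoeial convention). The reference peak's RRT and RPA are
#' identically 1, so its RSD rows are exactly 0. Used for precision,
#' stability and repeatability checks — run once per injection set.
#'
#' @param tables Replicate injections: a list of data frames with columns
#'   `peak`, `t_r` (min), `area`, or one long data frame with an additional
#'   `injection` column. At least two injections.
#' @param reference_peak Peak number of the reference peak; must be present
#'   in every injection.
#' @return A `suitability_report` data frame: `peak`, `n`, `mean_rrt`,
#'   `mean_rpa`, `rsd_rrt`, `rsd_rpa` (RSDs in percent).
#' @examples
#' tb <- data.frame(peak = 1:3, t_r = c(2.4, 10.5, 18.2), area = c(100, 400, 900))
#' suitability(list(tb, tb, tb), reference_peak = 3)$rsd_rpa  # all 0
#' @export
suitability <- function(tables, reference_peak) {
  tables <- as_peak_tables(tables)
  if (length(tables) < 2L) stop("need at least 2 injections", call. = FALSE)
  rel <- lapply(tables, function(tb) {
    i <- match(reference_peak, tb$peak)
    if (is.na(i)) stop("reference peak ", reference_peak,
                       " missing in an injection", call. = FALSE)
    data.frame(peak = tb$peak,
               rrt = tb$t_r / tb$t_r[i],
               rpa = tb$area / tb$area[i])
  })
  peaks <- sort(unique(unlist(lapply(rel, `[[`, "peak"))))
  rsd <- function(x) if (mean(x) == 0) 0 else 100 * stats::sd(x) / mean(x)
  rows <- lapply(peaks, function(p) {
    rrt <- unlist(lapply(rel, function(r) r$rrt[r$peak == p]))
    rpa <- unlist(lapply(rel, function(r) r$rpa[r$peak == p]))
    data.frame(peak = p, n = length(rrt),
               mean_rrt = mean(rrt), mean_rpa = mean(rpa),
               rsd_rrt = rsd(rrt), rsd_rpa = rsd(rpa))
  })
  structure(do.call(rbind, rows),
            reference_peak = reference_peak,
            class = c("suitability_report", "data.frame"))
}

#' @export
print.suitability_report <- function(x, digits = 2, ...) {
  cat(sprintf("System suitability (%d injections, reference peak %s)\n",
              max(x$n), format(attr(x, "reference_peak"))))
  df <- as.data.frame(x)
  for (cc in c("mean_rrt", "mean_rpa", "rsd_rrt", "rsd_rpa"))
    df[[cc]] <- round(df[[cc]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
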
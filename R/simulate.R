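#' Simulate a Box-Behnken experiment from a known surface
#'
#' Generates a Box-Behnken design for the factors of `truth` and draws each
#' response as the true surface value plus iid Gaussian noise — the
#' data-generating model assumed by ordinary least squares fitting of the
#' second-order polynomial. Replicated center runs share the same mean, so
#' the pure-error mean square estimates `sd^2`. All randomness is governed by
#' the mandatory `seed`; the global RNG state is left untouched.
#'
#' @param truth A `quadratic_surface` (e.g. [quadratic_surface()] or a
#'   previous fit) defining the true response surface, or a list of them over
#'   the same factors for several responses.
#' @param sd Gaussian noise standard deviation(s), recycled per response;
#'   `sd = 0` gives responses exactly on the surface.
#' @param n_center Number of center replicates (default 5).
#' @param seed Integer seed (required).
#' @param factors Optional factor specs; defaults to those stored in `truth`,
#'   or generic unit factors when absent.
#' @return A [bbd_design()] data frame augmented with one response column per
#'   surface (named by each surface's `response`).
#' @examples
#' s <- quadratic_surface(10, c(a = 1, b = 2, c = 0), c(-1, -2, -1))
#' xp <- gen_bbd_experiment(s, sd = 0.5, n_center = 5, seed = 1)
#' nrow(xp)  # 17
#' @export
gen_bbd_experiment <- function(truth, sd, n_center = 5L, seed, factors = NULL) {
  if (inherits(truth, "quadratic_surface")) truth <- list(truth)
  stopifnot(length(truth) >= 1L, !missing(seed))
  k <- truth[[1L]]$k
  for (m in truth) stopifnot(inherits(m, "quadratic_surface"), m$k == k)
  sd <- rep_len(sd, length(truth))
  stopifnot(all(sd >= 0))
  if (is.null(factors)) factors <- truth[[1L]]$factors
  if (is.null(factors))
    factors <- lapply(truth[[1L]]$factor_names,
                      function(nm) factor_spec(nm, -1, 0, 1))
  design <- bbd_design(factors, n_center = n_center)
  m <- coded_matrix(design)
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(truth)) {
      mu <- predict(truth[[i]], m)
      design[[truth[[i]]$response]] <- mu + stats::rnorm(nrow(m), 0, sd[i])
    }
  })
  design
}

#' Simulate a microplate inhibition assay
#'
#' Draws `n` wells whose sample absorbances follow
#' `control * (1 - ir/100) + noise` for a known true inhibition rate, so
#' [inhibition_enzyme()] applied to the output recovers `ir` up to noise.
#'
#' @param ir True inhibition rate in percent, within \[0, 100\].
#' @param control Control (uninhibited) absorbance (AU), > 0.
#' @param sd Gaussian absorbance noise sd (AU).
#' @param n Number of wells.
#' @param seed Integer seed (required).
#' @return Data frame `well`, `control_abs`, `sample_abs`.
#' @export
gen_assay_plate <- function(ir, control = 0.8, sd = 0.01, n = 96L, seed) {
  stopifnot(ir >= 0, ir <= 100, control > 0, sd >= 0, n >= 1L, !missing(seed))
  mu <- control * (1 - ir / 100)
  sample_abs <- withr::with_seed(as.integer(seed),
                                 mu + stats::rnorm(n, 0, sd))
  data.frame(well = seq_len(n), control_abs = control, sample_abs = sample_abs)
}

#' Simulate replicate chromatographic injections
#'
#' Multiplies each template peak area by an iid lognormal factor with unit
#' mean and the requested coefficient of variation (areas stay positive), and
#' jitters retention times with Gaussian noise of sd `rt_sd` minutes. With
#' `area_cv = 0` and `rt_sd = 0` every injection equals the template and a
#' [suitability()] report is identically zero.
#'
#' @param template Data frame with columns `peak`, `t_r`, `area`; at least 2
#'   peaks.
#' @param n Number of injections.
#' @param area_cv Coefficient of variation of the multiplicative area error
#'   (e.g. 0.02 for 2%).
#' @param rt_sd Retention-time jitter sd (min).
#' @param seed Integer seed (required).
#' @return List of `n` peak-table data frames.
#' @export
gen_injections <- function(template, n = 6L, area_cv = 0.02, rt_sd = 0, seed) {
  template <- as_peak_tables(list(template))[[1L]]
  stopifnot(nrow(template) >= 2L, area_cv >= 0, rt_sd >= 0, n >= 1L,
            !missing(seed))
  sdlog <- sqrt(log(1 + area_cv^2))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      fac <- if (area_cv > 0)
        stats::rlnorm(nrow(template), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        else rep(1, nrow(template))
      data.frame(peak = template$peak,
                 t_r = template$t_r + stats::rnorm(nrow(template), 0, rt_sd),
                 area = template$area * fac)
    })
  })
}

#' Simulate a linear calibration series
#'
#' Evenly spaced standards over the range with areas
#' `slope * conc + intercept + noise`.
#'
#' @param slope,intercept True line parameters.
#' @param range Length-2 concentration range (ug/mL).
#' @param n_points Number of standards (>= 3).
#' @param sd Gaussian area noise sd.
#' @param seed Integer seed (required).
#' @return Data frame `conc`, `area`.
#' @export
gen_calibration <- function(slope, intercept, range, n_points = 5L, sd = 0,
                            seed) {
  stopifnot(length(range) == 2L, range[1] < range[2], n_points >= 3L, sd >= 0,
            !missing(seed))
  conc <- seq(range[1], range[2], length.out = n_points)
  area <- withr::with_seed(as.integer(seed),
                           slope * conc + intercept + stats::rnorm(n_points, 0, sd))
  data.frame(conc = conc, area = area)
}
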
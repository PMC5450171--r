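# Shared fixtures: the bundled extraction study, its published model tables,
# and small helpers used across test files.

study <- herbal_extraction_study()
study_coded <- code_runs(study$runs, study$factors)
study_cm <- study_coded[names(study$factors)]
study_responses <- c("yield", "tpc", "ptp1b", "aglu", "abts")

fit_study <- function(response) {
  fit_quadratic(study_cm, study_coded[[response]], response = response,
                factors = study$factors)
}

# Published coded-unit model equations, in this package's canonical term order:
# b0; linear (ethanol, temperature, ratio, time); quadratic (same order);
# interactions (e:t, e:r, e:h, t:r, t:h, r:h).
published_coefs <- list(
  yield = c(38.94, -0.77, 1.48, 3.75, -0.23,
            -2.81, -1.62, -3.12, -0.73,
            0.19, -0.97, 1.28, 0.36, -1.38, 0.063),
  tpc   = c(47.69, 0.27, -0.42, 2.13, -1.22,
            -0.75, 0.43, -5.83, -1.73,
            0.62, -2.51, 0.13, -2.90, -0.090, -3.38),
  ptp1b = c(86.12, -1.73, 2.89, -2.24, 2.37,
            -3.95, -2.36, -2.66, -10.86,
            -0.13, 1.94, -2.66, -1.44, 4.37, -5.86),
  aglu  = c(96.63, 1.04, -2.99, -0.79, 2.06,
            -0.98, -7.58, -1.73, -4.66,
            10.73, 1.50, -6.73, 0.42, -1.70, 4.42),
  abts  = c(75.91, 2.73, 3.70, 4.64, -1.43,
            -2.12, -11.41, -6.20, -7.65,
            8.08, 5.21, 4.05, 1.48, 3.08, 6.83)
)

# Published ANOVA panels: SS and F entries plus R2 / adjusted R2.
published_anova <- list(
  yield = list(ss_model = 321.42, ss_resid = 31.00, ss_pe = 1.17,
               ss_lof = 29.83, f_model = 10.37, f_lof = 10.24,
               r2 = 0.9120, adj_r2 = 0.8241),
  tpc   = list(ss_model = 423.50, ss_resid = 8.94, ss_pe = 2.49,
               ss_lof = 6.45, f_model = 47.38, f_lof = 1.04,
               r2 = 0.9793, adj_r2 = 0.9587),
  ptp1b = list(ss_model = 1318.42, ss_resid = 134.24, ss_pe = 31.82,
               ss_lof = 102.42, f_model = 9.82, f_lof = 1.29,
               r2 = 0.9076, adj_r2 = 0.8152),
  aglu  = list(ss_model = 1449.06, ss_resid = 138.87, ss_pe = 11.50,
               ss_lof = 127.37, f_model = 10.43, f_lof = 4.43,
               r2 = 0.9125, adj_r2 = 0.8251),
  abts  = list(ss_model = 2213.57, ss_resid = 66.33, ss_pe = 8.87,
               ss_lof = 57.46, f_model = 33.37, f_lof = 2.59,
               r2 = 0.9709, adj_r2 = 0.9418)
)

# Published predicted single-response optima: natural factor settings.
published_optima <- rbind(
  yield = c(48.80, 74.29, 25.09, 3.04),
  tpc   = c(50.11, 72.06, 22.73, 2.93),
  ptp1b = c(52.10, 73.80, 21.84, 2.95),
  aglu  = c(47.57, 69.74, 22.22, 3.03),
  abts  = c(52.70, 71.50, 22.38, 3.01)
)

published_surface <- function(response) {
  b <- published_coefs[[response]]
  quadratic_surface(b0 = b[1], linear = setNames(b[2:5], names(study$factors)),
                    quadratic = b[6:9], interaction = b[10:15],
                    factors = study$factors, response = response)
}

fit_coef_vector <- function(fit)
  c(fit$b0, fit$linear, fit$quadratic, fit$interaction)

# canonical-order t-based confidence intervals of a fit
fit_confint <- function(fit, level = 0.95) {
  q <- qt(1 - (1 - level) / 2, fit$df_residual)
  cbind(fit$coef_stats$estimate - q * fit$coef_stats$se,
        fit$coef_stats$estimate + q * fit$coef_stats$se)
}

# independent oracle: sampling distribution of the MEDIAN percent RSD of
# relative peak areas over the non-reference peaks, with unit-mean lognormal
# area noise of the given CV and the reference denominator shared within each
# injection (which correlates the per-peak RSDs and widens the median's
# spread), across n injections
rsd_band_oracle <- function(cv, n, n_peaks = 12, probs = c(0.025, 0.975),
                            reps = 1000, seed = 99) {
  sdlog <- sqrt(log(1 + cv^2))
  draws <- withr::with_seed(seed, replicate(reps, {
    fac <- matrix(rlnorm(n * n_peaks, -sdlog^2 / 2, sdlog), n, n_peaks)
    rpa <- fac[, -1] / fac[, 1]
    median(apply(rpa, 2, function(x) 100 * sd(x) / mean(x)))
  }))
  quantile(draws, probs)
}

# 12-peak template mirroring the bundled chromatogram (reference peak 5)
peak_template <- function() {
  comp <- herbal_uplc_components()
  data.frame(peak = comp$peak, t_r = comp$t_r_min,
             area = comp$slope * (comp$range_low_ugml + comp$range_high_ugml) / 2 +
                    comp$intercept)
}
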
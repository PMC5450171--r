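test_that("noiseless data from a known surface is recovered exactly", {
  set.seed(5)
  fs <- lapply(c("a", "b", "c", "d"), function(n) factor_spec(n, -1, 0, 1))
  truth <- quadratic_surface(b0 = rnorm(1), linear = setNames(rnorm(4), c("a", "b", "c", "d")),
                             quadratic = rnorm(4), interaction = rnorm(6),
                             factors = fs)
  xp <- gen_bbd_experiment(truth, sd = 0, n_center = 5, seed = 1)
  fit <- fit_quadratic(xp[, c("a", "b", "c", "d")], xp$y)
  expect_equal(fit_coef_vector(fit),
               c(truth$b0, truth$linear, truth$quadratic, truth$interaction),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("the bundled yield and TPC fits reproduce the published equations", {
  for (r in c("yield", "tpc")) {
    fit <- fit_study(r)
    expect_equal(fit_coef_vector(fit), published_coefs[[r]],
                 tolerance = 0.011, ignore_attr = TRUE)
  }
  fit <- fit_study("yield")
  expect_equal(round(fit$b0, 2), 38.94)
  expect_equal(round(unname(fit$linear["solvent_ratio"]), 2), 3.75)
  fit2 <- fit_study("tpc")
  expect_equal(round(unname(fit2$interaction["solvent_ratio:time_h"]), 2), -3.38)
})

test_that("ANOVA identities hold and pure error comes from the center runs", {
  fit <- fit_study("yield")
  an <- rsm_anova(fit)
  ss <- function(src) an$ss[an$source == src]
  expect_equal(ss("model") + ss("residual"), ss("total"), tolerance = 1e-8)
  expect_equal(ss("pure error") + ss("lack of fit"), ss("residual"),
               tolerance = 1e-8)
  expect_equal(an$df[an$source == "total"], 28)
  expect_equal(an$df[an$source == "model"], 14)
  expect_equal(an$df[an$source == "pure error"], 4)

  centers <- study_coded$yield[c(7, 13, 20, 24, 28)]
  expect_equal(round(ss("pure error"), 2),
               round(sum((centers - mean(centers))^2), 2))
  expect_equal(round(ss("pure error"), 2), 1.17)

  # residuals orthogonal to every model-matrix column
  res <- fit$y - predict(fit)
  mm <- cbind(1, as.matrix(study_cm), as.matrix(study_cm)^2)
  for (j in seq_len(ncol(mm)))
    expect_lt(abs(sum(res * mm[, j])),
              1e-8 * sqrt(sum(res^2)) * sqrt(sum(mm[, j]^2)) + 1e-10)
})

test_that("lack-of-fit F and p match the published TPC panel", {
  an <- rsm_anova(fit_study("tpc"))
  lof <- an[an$source == "lack of fit", ]
  expect_equal(round(lof$f, 2), 1.04)
  expect_equal(round(lof$p, 4), 0.5314, tolerance = 0.001)
  expect_equal(lof$df, 10)
})

test_that("designs without replicates drop the lack-of-fit partition", {
  fs <- lapply(c("a", "b", "c"), function(n) factor_spec(n, -1, 0, 1))
  truth <- quadratic_surface(1, setNames(1:3, c("a", "b", "c")), rep(-1, 3),
                             factors = fs)
  xp <- gen_bbd_experiment(truth, sd = 0.1, n_center = 1, seed = 3)
  fit <- fit_quadratic(xp[, c("a", "b", "c")], xp$y)
  expect_warning(an <- rsm_anova(fit), "no replicated runs")
  expect_false("lack of fit" %in% an$source)
  expect_false("pure error" %in% an$source)
})

test_that("fitting rejects mismatched and rank-deficient inputs", {
  expect_error(fit_quadratic(study_cm, 1:5), "does not match")
  degenerate <- study_cm
  degenerate$time_h <- degenerate$solvent_ratio
  expect_error(fit_quadratic(degenerate, study_coded$yield), "rank-deficient")
})

test_that("influence ranking orders factors by |linear coefficient|", {
  expect_equal(as.character(influence_ranking(fit_study("tpc"))),
               c("solvent_ratio", "time_h", "temperature_c", "ethanol_pct"))
  expect_equal(as.character(influence_ranking(fit_study("ptp1b"))),
               c("temperature_c", "time_h", "solvent_ratio", "ethanol_pct"))
  expect_equal(as.character(influence_ranking(fit_study("abts"))),
               c("solvent_ratio", "temperature_c", "ethanol_pct", "time_h"))

  tied <- quadratic_surface(0, c(a = 2, b = 2, c = 2), rep(-1, 3))
  expect_warning(rk <- influence_ranking(tied), "tied")
  expect_equal(as.character(rk), c("a", "b", "c"))
  expect_true(attr(rk, "ties"))
})

test_that("coefficient estimates are unbiased with calibrated intervals", {
  fs <- lapply(c("a", "b", "c"), function(n) factor_spec(n, -1, 0, 1))
  truth <- quadratic_surface(10, setNames(c(1, -2, 0.5), c("a", "b", "c")),
                             quadratic = c(-1, 0.5, -2),
                             interaction = c(0.8, 0, -0.6), factors = fs)
  tv <- c(truth$b0, truth$linear, truth$quadratic, truth$interaction)
  sigma <- 0.6
  n_sim <- 200
  est <- matrix(NA_real_, n_sim, 10)
  covered <- matrix(NA, n_sim, 10)
  for (s in seq_len(n_sim)) {
    xp <- gen_bbd_experiment(truth, sd = sigma, n_center = 5, seed = 1000 + s)
    fit <- fit_quadratic(xp[, c("a", "b", "c")], xp$y)
    est[s, ] <- fit_coef_vector(fit)
    ci <- fit_confint(fit)
    covered[s, ] <- tv >= ci[, 1] & tv <= ci[, 2]
  }
  # mean estimate within 3 standard errors of the mean of truth, per term
  se_mean <- apply(est, 2, sd) / sqrt(n_sim)
  expect_true(all(abs(colMeans(est) - tv) < 3 * se_mean + 1e-12))
  cov <- mean(covered)
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.99)
})

test_that("pure-noise factors do not inflate adjusted R-squared on average", {
  fs <- lapply(c("a", "b", "c", "d"), function(n) factor_spec(n, -1, 0, 1))
  truth <- quadratic_surface(5, setNames(c(2, -1, 1.5, 0), c("a", "b", "c", "d")),
                             quadratic = c(-1, -2, -0.5, 0),
                             interaction = c(1, 0, 0, -0.5, 0, 0), factors = fs)
  adj_full <- adj_sub <- numeric(30)
  for (s in 1:30) {
    xp <- gen_bbd_experiment(truth, sd = 1, n_center = 5, seed = 2000 + s)
    full <- fit_quadratic(xp[, c("a", "b", "c", "d")], xp$y)
    sub <- fit_quadratic(xp[, c("a", "b", "c")], xp$y)
    adj_full[s] <- full$adj_r2
    adj_sub[s] <- sub$adj_r2
  }
  # factor d is pure noise: the larger model should not look better on average
  expect_lte(mean(adj_full), mean(adj_sub) + 0.005)
})

test_that("significance flags at alpha = 0.05 match the published yield panel", {
  sig <- significant_terms(fit_study("yield"), alpha = 0.05)
  expect_setequal(sig, c("temperature_c", "solvent_ratio", "ethanol_pct^2",
                         "temperature_c^2", "solvent_ratio^2"))
})
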
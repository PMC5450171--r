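test_that("surface prediction is exact polynomial evaluation", {
  fit <- fit_study("yield")
  expect_equal(round(unname(predict(fit, rep(0, 4))), 2), 38.94)

  set.seed(21)
  s <- quadratic_surface(rnorm(1), setNames(rnorm(3), c("a", "b", "c")),
                         rnorm(3), rnorm(3))
  # at the all-ones vertex the value is the sum of all coefficients
  expect_equal(unname(predict(s, c(1, 1, 1))),
               s$b0 + sum(s$linear) + sum(s$quadratic) + sum(s$interaction),
               tolerance = 1e-12)

  # term-by-term summation oracle at random points
  oracle <- function(surf, x) {
    v <- surf$b0
    k <- surf$k
    for (i in seq_len(k)) v <- v + surf$linear[i] * x[i] + surf$quadratic[i] * x[i]^2
    idx <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      idx <- idx + 1
      v <- v + surf$interaction[idx] * x[i] * x[j]
    }
    unname(v)
  }
  pts <- matrix(runif(1000 * 3, -1.5, 1.5), ncol = 3)
  pred <- predict(s, pts)
  for (i in seq_len(200))
    expect_lt(abs(pred[i] - oracle(s, pts[i, ])), 1e-10)
  expect_equal(pred, apply(pts, 1, oracle, surf = s), tolerance = 1e-12)
})

test_that("stationary points solve the gradient system and classify curvature", {
  sep <- quadratic_surface(0, c(a = 1, b = 1, c = 1), rep(-1, 3))
  sp <- stationary_point(sep)
  expect_equal(unname(sp$point), rep(0.5, 3), tolerance = 1e-10)
  expect_equal(sp$classification, "maximum")

  bowl <- quadratic_surface(2, c(a = 0, b = 0), c(1, 1))
  spb <- stationary_point(bowl)
  expect_equal(unname(spb$point), c(0, 0), tolerance = 1e-12)
  expect_equal(spb$classification, "minimum")

  # the TPC surface has a positive temperature^2 coefficient: a saddle
  expect_equal(stationary_point(fit_study("tpc"))$classification, "saddle")

  flat <- quadratic_surface(1, c(a = 1, b = 0), c(0, 0))
  expect_equal(stationary_point(flat)$classification, "degenerate")
  expect_null(stationary_point(flat)$point)
})

test_that("box optimization finds the exact optimum of simple surfaces", {
  dome <- quadratic_surface(1, c(a = 0, b = 0), c(-1, -1))
  opt <- maximize_in_box(dome)
  expect_equal(opt$value, 1, tolerance = 1e-8)
  expect_equal(unname(opt$coded), c(0, 0), tolerance = 1e-6)
  expect_false(any(opt$boundary))

  concave <- quadratic_surface(0, c(a = 0.6, b = -0.4, c = 0.2),
                               c(-1, -0.8, -1.2), c(0.3, -0.1, 0.2))
  sp <- stationary_point(concave)
  expect_equal(sp$classification, "maximum")
  opt2 <- maximize_in_box(concave)
  expect_equal(unname(opt2$coded), unname(sp$point), tolerance = 1e-6)

  # minimization mirrors maximization of the negated surface
  expect_equal(maximize_in_box(dome, direction = "min")$value, -1,
               tolerance = 1e-8)
})

test_that("box optima match a dense grid oracle on random surfaces", {
  set.seed(33)
  g <- seq(-1, 1, length.out = 41)
  grid <- as.matrix(expand.grid(g, g, g))
  for (rep in 1:5) {
    s <- quadratic_surface(rnorm(1), setNames(rnorm(3, 0, 2), c("a", "b", "c")),
                           rnorm(3, 0, 2), rnorm(3, 0, 2))
    opt <- maximize_in_box(s)
    grid_best <- max(predict(s, grid))
    expect_gte(opt$value, grid_best - 1e-8)
    expect_lte(opt$value, grid_best + 0.02)
    expect_true(all(opt$coded >= -1 - 1e-9 & opt$coded <= 1 + 1e-9))
  }
})

test_that("desirability follows the Derringer-Suich ramps", {
  sp2 <- list(list(goal = "max", low = 0, high = 10),
              list(goal = "max", low = 0, high = 10))
  expect_equal(desirability(c(10, 12), sp2)$D, 1)
  expect_equal(desirability(c(0, 10), sp2)$D, 0)
  expect_equal(desirability(c(2.5, 10), sp2)$D, 0.5)  # sqrt(0.25 * 1)

  # weight exponent bends the ramp
  spw <- list(list(goal = "max", low = 0, high = 10, weight = 2))
  expect_equal(desirability(5, spw)$d, 0.25)

  spmin <- list(list(goal = "min", low = 0, high = 10))
  expect_equal(desirability(0, spmin)$d, 1)
  expect_equal(desirability(10, spmin)$d, 0)

  spt <- list(list(goal = "target", low = 0, high = 10, target = 4))
  expect_equal(desirability(4, spt)$d, 1)
  expect_equal(desirability(2, spt)$d, 0.5)
  expect_equal(desirability(7, spt)$d, 0.5)

  expect_error(desirability(1, list(list(goal = "max", low = 5, high = 5))),
               "degenerate")
})

test_that("desirability is monotone toward each goal", {
  set.seed(44)
  for (i in 1:50) {
    lo <- rnorm(1); hi <- lo + runif(1, 0.5, 3)
    w <- runif(1, 0.5, 3)
    sp <- list(list(goal = "max", low = lo, high = hi, weight = w),
               list(goal = "min", low = lo, high = hi, weight = w))
    y <- sort(runif(2, lo - 1, hi + 1))
    expect_lte(desirability(c(y[1], 0), sp)$d[1],
               desirability(c(y[2], 0), sp)$d[1])
    expect_gte(desirability(c(0, y[1]), sp)$d[2],
               desirability(c(0, y[2]), sp)$d[2])
  }
})

test_that("joint optimization balances competing surfaces", {
  m1 <- quadratic_surface(1, c(a = 1, b = 0), c(-1, -1), response = "up")
  m2 <- quadratic_surface(1, c(a = -1, b = 0), c(-1, -1), response = "down")
  opt <- joint_optimize(list(m1, m2))
  # symmetric opposing pulls: compromise on the a-axis near zero
  expect_lt(abs(opt$coded[["a"]]), 0.15)
  expect_gt(opt$value, 0)
  expect_named(opt$predictions, c("up", "down"))
  # joint optimum is at least as desirable as the center point
  spec <- desirability_spec(list(m1, m2))
  D_center <- desirability(c(predict(m1, c(0, 0)), predict(m2, c(0, 0))),
                           spec)$D
  expect_gte(opt$value, D_center - 1e-6)
})

test_that("grid predictions enumerate the lattice and export CSV", {
  s <- quadratic_surface(1, c(a = 1, b = -1), c(-1, -1), response = "resp")
  gp <- grid_predictions(s, n_axis = 5)
  expect_equal(nrow(gp), 25)
  expect_equal(names(gp), c("a", "b", "resp"))
  expect_equal(gp$resp, unname(predict(s, as.matrix(gp[, c("a", "b")]))))
  f <- tempfile(fileext = ".csv")
  grid_predictions(s, n_axis = 3, file = f)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.csv(f)), 9)
})
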
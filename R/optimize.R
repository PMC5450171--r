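#' Stationary point and curvature of a quadratic surface
#'
#' Solves the linear gradient system `b + H x = 0` (where `H` is the Hessian:
#' twice the pure-quadratic coefficients on the diagonal, interaction
#' coefficients off-diagonal) and classifies the stationary point from the
#' Hessian eigenvalue signs: all negative = maximum, all positive = minimum,
#' mixed = saddle. A numerically singular Hessian is reported as `"degenerate"`
#' with no point.
#'
#' @param object A `quadratic_surface` or `rsm_fit`.
#' @param tol Relative eigenvalue tolerance for singularity / sign calls.
#' @return List with `point` (coded, or `NULL` if degenerate), `value`,
#'   `classification` (`"maximum"`, `"minimum"`, `"saddle"` or
#'   `"degenerate"`), and `eigenvalues` of the Hessian.
#' @examples
#' s <- quadratic_surface(0, linear = c(a = 1, b = 1), quadratic = c(-1, -1))
#' stationary_point(s)$point  # (0.5, 0.5)
#' @export
stationary_point <- function(object, tol = 1e-10) {
  stopifnot(inherits(object, "quadratic_surface"))
  H <- quad_hessian(object)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev))
  if (scale == 0 || min(abs(ev)) < tol * scale)
    return(list(point = NULL, value = NA_real_, classification = "degenerate",
                eigenvalues = ev))
  x <- drop(solve(H, -object$linear))
  names(x) <- object$factor_names
  cls <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  list(point = x, value = unname(predict(object, x)),
       classification = cls, eigenvalues = ev)
}

#' Optimize a quadratic surface over a coded box
#'
#' Deterministic multi-start local optimization of the fitted second-order
#' polynomial over a box in coded units (default the design cube
#' \eqn{[-1, 1]^k}). Starts are the full \eqn{\{-1, 0, +1\}^k} lattice clipped
#' to the box, plus the unconstrained stationary point when it lies inside the
#' box; each start is polished with box-constrained BFGS (`L-BFGS-B`) using the
#' analytic gradient, and the best local result is returned. Because the start
#' lattice contains every Box-Behnken design point, the returned value is never
#' below the model prediction at any design point.
#'
#' @param object A `quadratic_surface` or `rsm_fit`.
#' @param lower,upper Box bounds in coded units; scalars are recycled to all
#'   factors.
#' @param direction `"max"` (default) or `"min"`.
#' @return An `rsm_optimum` list: `coded` (the optimizing point), `natural`
#'   (decoded, when factor specs are available), `value`, `boundary` (logical
#'   per factor: at a box bound), `classification` of the unconstrained
#'   stationary point, and `diagnostics` (number of starts, convergence).
#' @examples
#' s <- quadratic_surface(1, linear = c(a = 0, b = 0), quadratic = c(-1, -1))
#' maximize_in_box(s)$value  # 1 at the origin
#' @export
maximize_in_box <- function(object, lower = -1, upper = 1,
                            direction = c("max", "min")) {
  stopifnot(inherits(object, "quadratic_surface"))
  direction <- match.arg(direction)
  k <- object$k
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  if (any(lower >= upper)) stop("empty box: need lower < upper", call. = FALSE)
  sgn <- if (direction == "max") 1 else -1

  starts <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), k)))
  starts <- pmin(pmax(starts, matrix(lower, nrow(starts), k, byrow = TRUE)),
                 matrix(upper, nrow(starts), k, byrow = TRUE))
  starts <- unique(starts)
  sp <- stationary_point(object)
  if (!is.null(sp$point) && all(sp$point >= lower & sp$point <= upper))
    starts <- rbind(starts, sp$point)

  fn <- function(x) -sgn * sum(quad_model_matrix(x, k)[1L, ] * coef_vector(object))
  gr <- function(x) -sgn * quad_gradient(object, x)

  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper)
    if (o$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  coded <- pmin(pmax(best$par, lower), upper)
  names(coded) <- object$factor_names
  structure(list(
    coded = coded,
    natural = decode_point(object, coded),
    value = sgn * -best$value,
    boundary = stats::setNames(coded <= lower + 1e-6 | coded >= upper - 1e-6,
                               object$factor_names),
    classification = sp$classification,
    diagnostics = list(n_starts = nrow(starts), n_converged = n_conv,
                       direction = direction)
  ), class = "rsm_optimum")
}

decode_point <- function(object, coded) {
  if (is.null(object$factors)) return(NULL)
  stats::setNames(
    mapply(function(f, x) decode_value(f, x), object$factors, coded),
    object$factor_names)
}

#' @export
print.rsm_optimum <- function(x, digits = 3, ...) {
  cat("<rsm_optimum> value =", round(x$value, digits), "\n")
  cat("  coded:  ", paste(sprintf("%s = %.*f", names(x$coded), digits, x$coded),
                          collapse = ", "), "\n")
  if (!is.null(x$natural))
    cat("  natural:", paste(sprintf("%s = %.2f", names(x$natural), x$natural),
                            collapse = ", "), "\n")
  if (any(x$boundary))
    cat("  at box boundary:", paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' Derringer-Suich desirability of a set of response values
#'
#' Maps each response value to a desirability `d` in \[0, 1\] through a
#' power-weighted ramp — for a `"max"` goal, 0 at or below the lower anchor, 1
#' at or above the upper anchor, `((y - low)/(high - low))^weight` between; the
#' `"min"` goal mirrors it; `"target"` ramps up to the target then down — and
#' combines them as the geometric mean `D = (prod d_i)^(1/m)`, so any fully
#' undesirable response annihilates the joint score.
#'
#' @param values Numeric vector, one value per response, in the order of
#'   `spec`.
#' @param spec A list of per-response settings, each a list with elements
#'   `goal` (`"max"`, `"min"` or `"target"`), `low`, `high`, optional `target`
#'   (required for `"target"` goals) and `weight` (> 0, default 1). See
#'   [desirability_spec()].
#' @return List with `D` (scalar) and `d` (per-response desirabilities).
#' @examples
#' sp <- list(list(goal = "max", low = 0, high = 1),
#'            list(goal = "max", low = 0, high = 1))
#' desirability(c(0.25, 1), sp)$D  # 0.5
#' @export
desirability <- function(values, spec) {
  stopifnot(length(values) == length(spec))
  d <- vapply(seq_along(spec), function(i) one_desirability(values[i], spec[[i]]),
              numeric(1))
  list(D = prod(d)^(1 / length(d)), d = d)
}

one_desirability <- function(y, s) {
  goal <- match.arg(s$goal, c("max", "min", "target"))
  w <- if (is.null(s$weight)) 1 else s$weight
  stopifnot(w > 0)
  if (!(is.numeric(s$low) && is.numeric(s$high)) || s$high <= s$low)
    stop("degenerate desirability anchors: need low < high", call. = FALSE)
  ramp <- function(z) pmin(pmax(z, 0), 1)^w
  switch(goal,
    max = ramp((y - s$low) / (s$high - s$low)),
    min = ramp((s$high - y) / (s$high - s$low)),
    target = {
      if (is.null(s$target) || s$target <= s$low || s$target >= s$high)
        stop("target goal needs low < target < high", call. = FALSE)
      if (y <= s$target) ramp((y - s$low) / (s$target - s$low))
      else ramp((s$high - y) / (s$high - s$target))
    })
}

#' Default desirability settings for a set of fitted surfaces
#'
#' Anchors each response at the range of its fitted surface over the box
#' (computed exactly by [maximize_in_box()] in both directions), with goal
#' `"max"` and weight 1 — i.e. "as high as the surface allows". All settings
#' can be overridden per response.
#'
#' @param models List of `quadratic_surface` objects.
#' @param lower,upper Coded box, as in [maximize_in_box()].
#' @param goals Character vector of goals, recycled (default all `"max"`).
#' @param weights Numeric weights, recycled (default 1).
#' @return A named list of per-response specs, suitable for [desirability()]
#'   and [joint_optimize()].
#' @export
desirability_spec <- function(models, lower = -1, upper = 1,
                              goals = "max", weights = 1) {
  stopifnot(length(models) >= 1L)
  goals <- rep_len(goals, length(models))
  weights <- rep_len(weights, length(models))
  out <- lapply(seq_along(models), function(i) {
    hi <- maximize_in_box(models[[i]], lower, upper, "max")$value
    lo <- maximize_in_box(models[[i]], lower, upper, "min")$value
    list(goal = goals[i], low = lo, high = hi, weight = weights[i])
  })
  names(out) <- vapply(models, function(m) m$response, character(1))
  out
}

#' Joint multi-response optimization by desirability
#'
#' Maximizes the overall desirability `D(x)` of several fitted surfaces over a
#' coded box. The objective is evaluated on a coarse deterministic lattice
#' (9 points per axis for up to 4 factors, 5 otherwise), and the best lattice
#' points — together with the \eqn{\{-1, 0, +1\}^k} start lattice and each
#' surface's own box optimum — seed box-constrained local searches
#' (`L-BFGS-B`, numerical gradient; `D` is piecewise-smooth). The best point
#' found is returned.
#'
#' @param models List of `quadratic_surface` objects fitted over the same
#'   factors.
#' @param spec Per-response desirability settings; defaults to
#'   [desirability_spec()] over the same box.
#' @param lower,upper Coded box bounds.
#' @return An `rsm_optimum` whose `value` is the joint desirability `D`, plus
#'   `predictions`: the per-response model values at the optimum.
#' @examples
#' m1 <- quadratic_surface(1, c(a = 1, b = 0), c(-1, -1))
#' m2 <- quadratic_surface(1, c(a = -1, b = 0), c(-1, -1))
#' opt <- joint_optimize(list(m1, m2))
#' abs(opt$coded[["a"]]) < 0.2  # balanced compromise near 0
#' @export
joint_optimize <- function(models, spec = NULL, lower = -1, upper = 1) {
  stopifnot(is.list(models), length(models) >= 1L)
  k <- models[[1L]]$k
  for (m in models) stopifnot(inherits(m, "quadratic_surface"), m$k == k)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  if (is.null(spec)) spec <- desirability_spec(models, lower, upper)
  stopifnot(length(spec) == length(models))

  coefs <- lapply(models, coef_vector)
  D_at <- function(x) {
    mm <- quad_model_matrix(x, k)
    vals <- vapply(coefs, function(b) drop(mm %*% b), numeric(nrow(mm)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    apply(vals, 1L, function(v) desirability(v, spec)$D)
  }

  # coarse lattice scan (vectorized), then local polish from the best points
  n_axis <- if (k <= 4L) 9L else 5L
  lat <- as.matrix(expand.grid(lapply(seq_len(k), function(i)
    seq(lower[i], upper[i], length.out = n_axis))))
  Dlat <- D_at(lat)
  top <- lat[order(-Dlat)[seq_len(min(10L, nrow(lat)))], , drop = FALSE]

  starts <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), k)))
  starts <- pmin(pmax(starts, matrix(lower, nrow(starts), k, byrow = TRUE)),
                 matrix(upper, nrow(starts), k, byrow = TRUE))
  for (m in models)
    starts <- rbind(starts, maximize_in_box(m, lower, upper)$coded)
  starts <- unique(rbind(starts, top))

  best_par <- starts[1L, ]; best_val <- -Inf; n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(starts[i, ], function(x) -D_at(matrix(x, 1L)),
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence == 0L) n_conv <- n_conv + 1L
    if (-o$value > best_val) { best_val <- -o$value; best_par <- o$par }
  }
  coded <- stats::setNames(pmin(pmax(best_par, lower), upper),
                           models[[1L]]$factor_names)
  preds <- vapply(models, function(m) unname(predict(m, coded)), numeric(1))
  names(preds) <- vapply(models, function(m) m$response, character(1))
  structure(list(
    coded = coded,
    natural = decode_point(models[[1L]], coded),
    value = best_val,
    predictions = preds,
    boundary = stats::setNames(coded <= lower + 1e-6 | coded >= upper - 1e-6,
                               models[[1L]]$factor_names),
    classification = "desirability",
    diagnostics = list(n_starts = nrow(starts), n_converged = n_conv)
  ), class = "rsm_optimum")
}

#' Predictions of one or more surfaces on a regular coded lattice
#'
#' Evaluates each surface on an `n_axis^k` grid over the box and returns a
#' long table of coded coordinates plus one prediction column per response —
#' the raw material for external surface/contour plotting. Optionally written
#' to CSV.
#'
#' @param models A `quadratic_surface` or list of them (same factors).
#' @param n_axis Grid points per axis (default 21).
#' @param lower,upper Coded box bounds.
#' @param file Optional path; when given the grid is written as CSV.
#' @return Data frame, invisibly when `file` is given.
#' @export
grid_predictions <- function(models, n_axis = 21L, lower = -1, upper = 1,
                             file = NULL) {
  if (inherits(models, "quadratic_surface")) models <- list(models)
  k <- models[[1L]]$k
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  grid <- expand.grid(lapply(seq_len(k), function(i)
    seq(lower[i], upper[i], length.out = n_axis)))
  names(grid) <- models[[1L]]$factor_names
  mm <- quad_model_matrix(as.matrix(grid), k)
  for (m in models) grid[[m$response]] <- drop(mm %*% coef_vector(m))
  if (!is.null(file)) {
    utils::write.csv(grid, file, row.names = FALSE)
    return(invisible(grid))
  }
  grid
}
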
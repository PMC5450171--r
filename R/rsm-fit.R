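#' Full second-order response-surface model
#'
#' `fit_quadratic()` fits, by ordinary least squares in coded units, the
#' complete second-order polynomial
#' \deqn{y = b_0 + \sum_i b_i x_i + \sum_i b_{ii} x_i^2 + \sum_{i<j} b_{ij} x_i x_j,}
#' i.e. intercept, `k` linear terms, `k` pure-quadratic terms and `k(k-1)/2`
#' pairwise interactions — `k(k+3)/2 + 1` coefficients in total. No term
#' selection is performed: the full model is always kept, matching standard
#' response-surface practice where non-significant terms are reported rather
#' than dropped. Per-term standard errors come from the unscaled coefficient
#' covariance times the residual mean square, and two-sided p-values from the
#' t distribution on the residual degrees of freedom.
#'
#' @param design A [bbd_design()], or any coded runs table accepted by
#'   [coded_matrix()] (columns in coded units).
#' @param y Numeric response vector, one value per run.
#' @param response Name used to label the fitted response.
#' @param factors Optional factor specs for plain coded tables; enables
#'   natural-unit reporting downstream.
#' @return An object of class `c("rsm_fit", "quadratic_surface")` with
#'   components `b0`, `linear`, `interaction`, `quadratic` (named coefficient
#'   vectors), `coef_stats` (estimate/SE/t/p per term), `lm` (the underlying
#'   [stats::lm] fit), `r2`, `adj_r2`, and the coded matrix and response used.
#' @examples
#' study <- herbal_extraction_study()
#' coded <- code_runs(study$runs, study$factors)
#' fit <- fit_quadratic(coded[names(study$factors)], coded$yield,
#'                      response = "yield", factors = study$factors)
#' round(fit$b0, 2)          # 38.94
#' round(fit$linear, 2)
#' @seealso [rsm_anova()], [maximize_in_box()], [stationary_point()]
#' @export
fit_quadratic <- function(design, y, response = "y", factors = NULL) {
  if (inherits(design, "bbd_design") && is.null(factors))
    factors <- attr(design, "factors")
  m <- coded_matrix(design, factors)
  k <- ncol(m)
  stopifnot(k >= 2L)
  if (length(y) != nrow(m))
    stop("response length ", length(y), " does not match ", nrow(m), " runs",
         call. = FALSE)
  if (anyNA(y) || anyNA(m)) stop("missing values in design or response", call. = FALSE)
  p <- k * (k + 3) / 2 + 1
  if (length(y) <= p)
    stop("need more runs (", length(y), ") than model terms (", p, ")", call. = FALSE)

  fnames <- colnames(m)
  if (is.null(fnames)) fnames <- paste0("x", seq_len(k))
  # fit with internal syntactic names, relabel afterwards
  dd <- as.data.frame(m)
  names(dd) <- paste0(".x", seq_len(k))
  dd$.y <- as.numeric(y)
  lin <- names(dd)[seq_len(k)]
  fml <- stats::as.formula(paste(
    ".y ~", paste(c(lin, sprintf("I(%s^2)", lin),
                    utils::combn(lin, 2, paste, collapse = ":")), collapse = " + ")))
  fit <- stats::lm(fml, data = dd)
  if (fit$rank < p)
    stop("rank-deficient model matrix (rank ", fit$rank, " < ", p, " terms)",
         call. = FALSE)

  cf <- stats::coef(fit)
  labels <- term_labels(fnames)
  est <- c(cf["(Intercept)"],
           cf[lin],
           cf[sprintf("I(%s^2)", lin)],
           cf[utils::combn(lin, 2, paste, collapse = ":")])
  names(est) <- unlist(labels, use.names = FALSE)

  sm <- summary(fit)$coefficients
  sm <- sm[match(internal_order(lin), rownames(sm)), , drop = FALSE]
  coef_stats <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(sm[, "Std. Error"]),
    t = unname(sm[, "t value"]),
    p = unname(sm[, "Pr(>|t|)"]),
    row.names = NULL
  )

  r2 <- summary(fit)$r.squared
  adj_r2 <- summary(fit)$adj.r.squared
  structure(list(
    response = response,
    factor_names = fnames,
    factors = if (!is.null(factors)) as_factor_list(factors) else NULL,
    k = k,
    b0 = unname(est[1L]),
    linear = stats::setNames(unname(est[labels$linear]), fnames),
    quadratic = est[labels$quadratic],
    interaction = est[labels$interaction],
    coef_stats = coef_stats,
    vcov = relabel_vcov(stats::vcov(fit), internal_order(lin), names(est)),
    sigma2 = summary(fit)$sigma^2,
    df_residual = fit$df.residual,
    n = length(y),
    r2 = r2,
    adj_r2 = adj_r2,
    coded = m,
    y = as.numeric(y),
    lm = fit
  ), class = c("rsm_fit", "quadratic_surface"))
}

# canonical term labels: intercept, linear, quadratic ("f^2"), interaction ("f:g")
term_labels <- function(fnames) {
  list(intercept = "(Intercept)",
       linear = fnames,
       quadratic = paste0(fnames, "^2"),
       interaction = if (length(fnames) >= 2)
         utils::combn(fnames, 2, paste, collapse = ":") else character(0))
}

internal_order <- function(lin) {
  c("(Intercept)", lin, sprintf("I(%s^2)", lin),
    utils::combn(lin, 2, paste, collapse = ":"))
}

relabel_vcov <- function(v, internal, labels) {
  v <- v[match(internal, rownames(v)), match(internal, colnames(v))]
  dimnames(v) <- list(labels, labels)
  v
}

#' Construct a quadratic surface from known coefficients
#'
#' Builds a `quadratic_surface` directly from coefficient values, without
#' fitting — used to define ground truth for simulations and to evaluate
#' published model equations. Interactions are named `"a:b"` with factor pairs
#' in the order of `factor_names`.
#'
#' @param b0 Intercept (value of the surface at the coded center).
#' @param linear Named (or ordered) numeric vector of k linear coefficients.
#' @param quadratic Numeric vector of k pure-quadratic coefficients.
#' @param interaction Numeric vector of k(k-1)/2 interaction coefficients, in
#'   lexicographic pair order; may be named `"a:b"`.
#' @param factors Optional list of [factor_spec()]; supplies names and the
#'   natural-unit map.
#' @param response Label for the response.
#' @return A `quadratic_surface` usable with [predict()],
#'   [stationary_point()], [maximize_in_box()] and the simulators.
#' @examples
#' s <- quadratic_surface(1, linear = c(a = 1, b = 1), quadratic = c(-1, -1),
#'                        interaction = 0)
#' stationary_point(s)$classification # "maximum"
#' @export
quadratic_surface <- function(b0, linear, quadratic, interaction = NULL,
                              factors = NULL, response = "y") {
  k <- length(linear)
  stopifnot(k >= 2L, length(quadratic) == k)
  n_int <- k * (k - 1) / 2
  if (is.null(interaction)) interaction <- rep(0, n_int)
  if (length(interaction) == 1L && n_int > 1L) interaction <- rep(interaction, n_int)
  stopifnot(length(interaction) == n_int)
  fnames <- if (!is.null(factors)) factor_names(as_factor_list(factors))
            else if (!is.null(names(linear))) names(linear)
            else paste0("x", seq_len(k))
  labels <- term_labels(fnames)
  structure(list(
    response = response,
    factor_names = fnames,
    factors = if (!is.null(factors)) as_factor_list(factors) else NULL,
    k = k,
    b0 = unname(b0),
    linear = stats::setNames(as.numeric(linear), fnames),
    quadratic = stats::setNames(as.numeric(quadratic), labels$quadratic),
    interaction = stats::setNames(as.numeric(interaction), labels$interaction)
  ), class = "quadratic_surface")
}

# model matrix for the full second-order polynomial at coded points
# x: matrix (points x k) or length-k vector
quad_model_matrix <- function(x, k) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  stopifnot(ncol(x) == k)
  ij <- utils::combn(k, 2L)
  inter <- sapply(seq_len(ncol(ij)), function(c2) x[, ij[1L, c2]] * x[, ij[2L, c2]])
  if (nrow(x) == 1L) inter <- matrix(inter, nrow = 1L)
  cbind(1, x, x^2, inter)
}

coef_vector <- function(object)
  c(object$b0, object$linear, object$quadratic, object$interaction)

#' Evaluate a quadratic surface at coded points
#'
#' Exact polynomial evaluation of the second-order model at one or more coded
#' points.
#'
#' @param object A `quadratic_surface` or `rsm_fit`.
#' @param newdata Length-k coded vector, or a matrix / data frame with one
#'   column per factor. Defaults to the design points of a fitted model.
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.quadratic_surface <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$coded))
      stop("newdata required for a surface without stored design points",
           call. = FALSE)
    newdata <- object$coded
  }
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, object$factor_names, drop = FALSE])
  drop(quad_model_matrix(newdata, object$k) %*% coef_vector(object))
}

# gradient of the surface at a single coded point
quad_gradient <- function(object, x) {
  H <- quad_hessian(object)
  object$linear + drop(H %*% x)
}

# Hessian: 2*diag(b_ii) with b_ij off-diagonal
quad_hessian <- function(object) {
  k <- object$k
  H <- diag(2 * as.numeric(object$quadratic), k)
  ij <- utils::combn(k, 2L)
  for (c2 in seq_len(ncol(ij))) {
    H[ij[1L, c2], ij[2L, c2]] <- object$interaction[c2]
    H[ij[2L, c2], ij[1L, c2]] <- object$interaction[c2]
  }
  dimnames(H) <- list(object$factor_names, object$factor_names)
  H
}

#' @export
print.quadratic_surface <- function(x, digits = 2, ...) {
  cat(sprintf("<quadratic_surface> response '%s', %d factors\n", x$response, x$k))
  cat(model_equation(x, digits = digits), "\n")
  if (inherits(x, "rsm_fit"))
    cat(sprintf("n = %d, R2 = %.4f, adj. R2 = %.4f\n", x$n, x$r2, x$adj_r2))
  invisible(x)
}

#' Coded-unit model equation as text
#'
#' @param object A `quadratic_surface`.
#' @param digits Decimal places for the coefficients.
#' @return A single character string like `"y = 38.94 - 0.77*a + ..."`.
#' @export
model_equation <- function(object, digits = 2) {
  cf <- coef_vector(object)[-1L]
  terms <- c(object$factor_names,
             paste0(object$factor_names, "^2"),
             names(object$interaction))
  pieces <- sprintf("%s %s*%s", ifelse(cf < 0, "-", "+"),
                    formatC(abs(cf), format = "f", digits = digits), terms)
  paste(object$response, "=",
        formatC(object$b0, format = "f", digits = digits),
        paste(pieces, collapse = " "))
}

#' Rank factors by the size of their linear effects
#'
#' Orders the factors by decreasing absolute value of their coded linear
#' coefficients — the conventional "influence ranking" of a response-surface
#' study. Exact ties keep the original factor order and are flagged via the
#' `"ties"` attribute (with a warning).
#'
#' @param object A `quadratic_surface` or `rsm_fit`.
#' @return Character vector of factor names, most influential first, with
#'   attribute `ties` (logical).
#' @examples
#' s <- quadratic_surface(0, linear = c(a = 1, b = -3), quadratic = c(0, 0))
#' influence_ranking(s) # "b" "a"
#' @export
influence_ranking <- function(object) {
  stopifnot(inherits(object, "quadratic_surface"))
  a <- abs(object$linear)
  ties <- anyDuplicated(a) > 0L
  if (ties)
    warning("tied linear coefficients; original factor order kept within ties",
            call. = FALSE)
  out <- object$factor_names[order(-a)]  # order() is stable
  attr(out, "ties") <- ties
  out
}

#' Terms significant at a given level
#'
#' @param object An `rsm_fit`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param include_intercept Keep the intercept row? Default `FALSE`.
#' @return Character vector of term labels with p < alpha.
#' @export
significant_terms <- function(object, alpha = 0.05, include_intercept = FALSE) {
  stopifnot(inherits(object, "rsm_fit"), alpha > 0, alpha < 1)
  cs <- object$coef_stats
  if (!include_intercept) cs <- cs[cs$term != "(Intercept)", ]
  cs$term[cs$p < alpha]
}
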
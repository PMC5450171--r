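#' Define an experimental factor with three equally spaced levels
#'
#' A factor specification records the natural-unit low/center/high levels of one
#' independent variable together with the linear map between natural and coded
#' units. In coded units the low, center and high levels are \eqn{-1}, \eqn{0}
#' and \eqn{+1}; all design construction and model fitting in this package work
#' in coded units, with natural units kept as a labelled view.
#'
#' @param name Short label, e.g. `"ethanol"`. Used as the column name in design
#'   tables and as the term label in fitted models.
#' @param low,center,high Natural-unit levels; must satisfy `low < center < high`.
#'   The center is expected to be the midpoint of `low` and `high` (three-level
#'   designs assume equal spacing); a center off the midpoint is accepted with a
#'   warning, and coding then uses the half-range `(high - low)/2` around `center`.
#' @param unit Free-text unit label (e.g. `"%"`, `"degC"`); purely descriptive.
#'
#' @return An object of class `factor_spec`.
#' @examples
#' ethanol <- factor_spec("ethanol", 30, 50, 70, unit = "%")
#' code_value(ethanol, 70)    # +1
#' decode_value(ethanol, 0.5) # 60
#' @seealso [code_value()], [decode_value()], [bbd_design()]
#' @export
factor_spec <- function(name, low, center, high, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in list(low, center, high))
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (high <= low)
    stop("degenerate factor spec for '", name, "': need low < high", call. = FALSE)
  if (!(low < center && center < high))
    stop("factor '", name, "': levels must satisfy low < center < high", call. = FALSE)
  if (abs(center - (low + high) / 2) > 1e-8 * (high - low))
    warning("factor '", name, "': center is not the midpoint of low and high; ",
            "coded low/high will not be exactly -1/+1", call. = FALSE)
  structure(
    list(name = name, unit = unit, low = low, center = center, high = high),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  u <- if (nzchar(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("<factor_spec> %s: %g / %g / %g%s  (coded -1 / 0 / +1)\n",
              x$name, x$low, x$center, x$high, u))
  invisible(x)
}

half_range <- function(spec) (spec$high - spec$low) / 2

#' Convert between natural and coded factor units
#'
#' `code_value()` maps natural units to coded units by
#' `(natural - center) / ((high - low)/2)`; `decode_value()` is its exact
#' inverse. Values coding beyond the design region (|coded| > 1) are allowed —
#' the map is linear everywhere — but flagged with a warning, since a fitted
#' second-order surface is only trusted inside the region.
#'
#' @param spec A [factor_spec()].
#' @param natural,coded Numeric vectors.
#' @return A numeric vector of the same length.
#' @examples
#' ratio <- factor_spec("ratio", 10, 20, 30, unit = "g/mL")
#' code_value(ratio, 25.09)  # 0.509
#' @export
code_value <- function(spec, natural) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(natural))
  coded <- (natural - spec$center) / half_range(spec)
  out_of_region <- is.finite(coded) & abs(coded) > 1 + 1e-8
  if (any(out_of_region))
    warning(sum(out_of_region), " value(s) of '", spec$name,
            "' lie outside the design region (|coded| > 1)", call. = FALSE)
  coded
}

#' @rdname code_value
#' @export
decode_value <- function(spec, coded) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(coded))
  spec$center + coded * half_range(spec)
}

# validate and normalize a list of factor specs
as_factor_list <- function(factors) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  stopifnot(is.list(factors), length(factors) >= 1L)
  ok <- vapply(factors, inherits, logical(1), "factor_spec")
  if (!all(ok)) stop("'factors' must be a list of factor_spec objects", call. = FALSE)
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate factor names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "),
                              call. = FALSE)
  names(factors) <- nm
  factors
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")
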
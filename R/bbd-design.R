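#' Construct a Box-Behnken design
#'
#' Builds the three-level Box-Behnken design for `k` factors: for every
#' unordered pair of factors the four (+/-1, +/-1) combinations are run with all
#' remaining factors at their center (0), giving `2*k*(k-1)` edge runs, plus
#' `n_center` replicated all-center runs from which pure experimental error is
#' estimated. Run order is deterministic (factor pairs in lexicographic order,
#' sign combinations in (-,-), (-,+), (+,-), (+,+) order, centers last) unless
#' `shuffle_seed` is given, in which case rows are permuted reproducibly.
#'
#' @param factors List of [factor_spec()] objects; between 3 and 7 factors
#'   (the Box-Behnken construction is undefined for fewer than 3).
#' @param n_center Number of center-point replicates (>= 1; >= 2 is needed
#'   later for a lack-of-fit test).
#' @param shuffle_seed Optional integer; if supplied, the run order is shuffled
#'   with this seed (run ids are renumbered in the shuffled order).
#'
#' @return A `bbd_design`: a data frame with a `run` column and one coded
#'   column per factor (entries in \{-1, 0, +1\}), carrying the factor specs in
#'   `attr(, "factors")` and the center count in `attr(, "n_center")`.
#' @examples
#' fs <- list(factor_spec("A", 30, 50, 70), factor_spec("B", 60, 70, 80),
#'            factor_spec("C", 10, 20, 30))
#' d <- bbd_design(fs, n_center = 3)
#' nrow(d)  # 2*3*2 + 3 = 15
#' @export
bbd_design <- function(factors, n_center = 5L, shuffle_seed = NULL) {
  factors <- as_factor_list(factors)
  k <- length(factors)
  if (k < 3L || k > 7L)
    stop("Box-Behnken designs are supported for 3 to 7 factors (got ", k, ")",
         call. = FALSE)
  stopifnot(length(n_center) == 1L, n_center >= 1, n_center == as.integer(n_center))
  n_center <- as.integer(n_center)

  pairs <- utils::combn(k, 2L)
  signs <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  m <- matrix(0, nrow = 4L * ncol(pairs) + n_center, ncol = k,
              dimnames = list(NULL, factor_names(factors)))
  row <- 0L
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    for (s in seq_len(4L)) {
      row <- row + 1L
      m[row, i] <- signs[s, 1L]
      m[row, j] <- signs[s, 2L]
    }
  }
  # remaining rows are already all-zero center runs
  if (!is.null(shuffle_seed))
    m <- withr::with_seed(as.integer(shuffle_seed), m[sample.int(nrow(m)), , drop = FALSE])

  out <- data.frame(run = seq_len(nrow(m)), m, check.names = FALSE)
  attr(out, "factors") <- factors
  attr(out, "n_center") <- n_center
  class(out) <- c("bbd_design", "data.frame")
  out
}

#' @export
print.bbd_design <- function(x, ...) {
  k <- length(attr(x, "factors"))
  cat(sprintf("<bbd_design> %d factors, %d runs (%d edge + %d center)\n",
              k, nrow(x), 2L * k * (k - 1L), attr(x, "n_center")))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more runs\n", sep = "")
  invisible(x)
}

#' Coded run matrix of a design
#'
#' Extracts the coded factor-settings matrix (runs x factors) from a
#' `bbd_design`, or from a plain data frame / matrix already in coded units
#' (any `run` column is dropped).
#'
#' @param design A `bbd_design`, data frame or numeric matrix.
#' @param factors Optional list of [factor_spec()]; required for plain inputs
#'   whose columns cannot be matched otherwise, ignored for `bbd_design`.
#' @return Numeric matrix with one column per factor.
#' @export
coded_matrix <- function(design, factors = NULL) {
  if (inherits(design, "bbd_design")) factors <- attr(design, "factors")
  if (is.matrix(design)) m <- design
  else {
    df <- as.data.frame(design)
    df$run <- NULL
    if (!is.null(factors)) df <- df[factor_names(as_factor_list(factors))]
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  if (!is.null(factors)) colnames(m) <- factor_names(as_factor_list(factors))
  m
}

#' Convert design tables between natural and coded units
#'
#' `code_runs()` takes a table of natural-unit factor settings (plus any other
#' columns, e.g. measured responses, which are passed through untouched) and
#' returns it with the factor columns replaced by coded values. `decode_runs()`
#' is the inverse.
#'
#' @param runs Data frame containing one column per factor, named as in the
#'   specs, in natural (`code_runs`) or coded (`decode_runs`) units.
#' @param factors List of [factor_spec()] objects.
#' @return Data frame of the same shape.
#' @examples
#' fs <- list(factor_spec("ethanol", 30, 50, 70), factor_spec("temp", 60, 70, 80),
#'            factor_spec("ratio", 10, 20, 30))
#' nat <- data.frame(ethanol = c(30, 50), temp = c(70, 80), ratio = c(20, 10))
#' code_runs(nat, fs)
#' @export
code_runs <- function(runs, factors) {
  factors <- as_factor_list(factors)
  runs <- as.data.frame(runs)
  for (f in factors) {
    if (!f$name %in% names(runs))
      stop("runs table has no column '", f$name, "'", call. = FALSE)
    runs[[f$name]] <- code_value(f, runs[[f$name]])
  }
  runs
}

#' @rdname code_runs
#' @export
decode_runs <- function(runs, factors) {
  factors <- as_factor_list(factors)
  runs <- as.data.frame(runs)
  for (f in factors) {
    if (!f$name %in% names(runs))
      stop("runs table has no column '", f$name, "'", call. = FALSE)
    runs[[f$name]] <- decode_value(f, runs[[f$name]])
  }
  runs
}

#' Check the structural invariants of a coded Box-Behnken table
#'
#' Verifies that every coded entry is in \{-1, 0, +1\}, that each coded column
#' sums to zero, that distinct coded columns are orthogonal (zero dot product),
#' and that the run count equals `2k(k-1) + n_center` where `n_center` is the
#' number of all-zero rows. Errors with an informative message on the first
#' violated invariant.
#'
#' @param design A `bbd_design` or coded table accepted by [coded_matrix()].
#' @param factors Optional factor specs for plain tables.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_bbd <- function(design, factors = NULL) {
  m <- coded_matrix(design, factors)
  k <- ncol(m)
  if (!all(m %in% c(-1, 0, 1)))
    stop("coded entries outside {-1, 0, +1}", call. = FALSE)
  n_center <- sum(rowSums(m != 0) == 0L)
  if (nrow(m) != 2L * k * (k - 1L) + n_center)
    stop("run count ", nrow(m), " != 2k(k-1) + n_center = ",
         2L * k * (k - 1L) + n_center, call. = FALSE)
  if (any(colSums(m) != 0))
    stop("coded column sums are not all zero", call. = FALSE)
  g <- crossprod(m)
  if (any(g[upper.tri(g)] != 0))
    stop("coded columns are not pairwise orthogonal", call. = FALSE)
  invisible(TRUE)
}
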
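#' Read factor specifications from a YAML or JSON file
#'
#' The file holds a list of factor entries, each with `name`, `low`,
#' `center`, `high` and optional `unit` — e.g. in YAML:
#' ```yaml
#' - {name: ethanol_pct, unit: "%", low: 30, center: 50, high: 70}
#' ```
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` vs
#'   `.json`).
#' @return Named list of [factor_spec()] objects.
#' @export
read_factor_specs <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  as_factor_list(lapply(raw, function(e)
    factor_spec(e$name, e$low, e$center, e$high,
                unit = if (is.null(e$unit)) "" else e$unit)))
}

#' Read a design/response run table from CSV
#'
#' Expects a header row with a `run` column, one natural-unit column per
#' factor and any number of response columns. Factor columns are checked for
#' presence when specs are supplied.
#'
#' @param path CSV path.
#' @param factors Optional list of [factor_spec()]; when given, presence of
#'   every factor column is enforced.
#' @return Data frame.
#' @export
read_design_csv <- function(path, factors = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path)
  if (!"run" %in% names(df)) df$run <- seq_len(nrow(df))
  if (!is.null(factors)) {
    factors <- as_factor_list(factors)
    miss <- setdiff(factor_names(factors), names(df))
    if (length(miss))
      stop("design CSV lacks factor column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  df
}

#' Serialize a quadratic surface to JSON (and back)
#'
#' Stores the response label, factor specs, all coefficients, and — for
#' fitted models — the coefficient covariance matrix, residual variance,
#' degrees of freedom and R-squared values, at full double precision. Numbers
#' are written with deterministic formatting so identical models produce
#' byte-identical files. `read_model_json()` reconstructs a
#' `quadratic_surface` (plus the stored fit statistics) usable for prediction
#' and optimization; the original `lm` object is not retained.
#'
#' @param object A `quadratic_surface` or `rsm_fit`.
#' @param path Output (input) file path.
#' @return `write_model_json()` the path invisibly; `read_model_json()` a
#'   `quadratic_surface`.
#' @export
write_model_json <- function(object, path) {
  stopifnot(inherits(object, "quadratic_surface"))
  x <- list(
    response = object$response,
    factor_names = as.list(object$factor_names),
    factors = if (!is.null(object$factors))
      unname(lapply(object$factors,
                    function(f) f[c("name", "unit", "low", "center", "high")])),
    coefficients = list(
      b0 = object$b0,
      linear = as.list(object$linear),
      quadratic = as.list(object$quadratic),
      interaction = as.list(object$interaction))
  )
  if (inherits(object, "rsm_fit")) {
    x$fit <- list(n = object$n, sigma2 = object$sigma2,
                  df_residual = object$df_residual,
                  r2 = object$r2, adj_r2 = object$adj_r2)
    x$vcov <- object$vcov
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  stopifnot(file.exists(path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  factors <- if (!is.null(x$factors))
    lapply(seq_len(nrow(x$factors)), function(i)
      factor_spec(x$factors$name[i], x$factors$low[i], x$factors$center[i],
                  x$factors$high[i], unit = x$factors$unit[i]))
  obj <- quadratic_surface(
    b0 = x$coefficients$b0,
    linear = stats::setNames(unlist(x$coefficients$linear), x$factor_names),
    quadratic = unlist(x$coefficients$quadratic),
    interaction = unlist(x$coefficients$interaction),
    factors = factors,
    response = x$response)
  if (!is.null(x$fit)) {
    obj[names(x$fit)] <- x$fit
    if (!is.null(x$vcov)) obj$vcov <- as.matrix(x$vcov)
  }
  obj
}

#' Markdown report for a fitted response
#'
#' Renders the ANOVA partition, R-squared values, coded model equation and
#' per-term significance of one fitted response as markdown lines, in the
#' layout conventional for response-surface publications (coefficients to 2
#' decimals, R-squared to 4, p-values to 4 with `<0.0001` for smaller).
#'
#' @param fit An [fit_quadratic()] result.
#' @param anova Optional precomputed [rsm_anova()]; computed when omitted.
#' @param alpha Significance level for flagging terms.
#' @return Character vector of markdown lines.
#' @export
fit_report <- function(fit, anova = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (is.null(anova)) anova <- rsm_anova(fit)
  fmt_p <- function(p) ifelse(is.na(p), "",
                              ifelse(p < 1e-4, "<0.0001",
                                     formatC(p, format = "f", digits = 4)))
  num <- function(v, d = 2) ifelse(is.na(v), "", formatC(v, format = "f", digits = d))
  lines <- c(
    sprintf("## Response: %s", fit$response),
    "",
    "| Source | Sum of squares | df | Mean square | F | p |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %s | %s | %s |",
            anova$source, num(anova$ss), anova$df, num(anova$ms),
            num(anova$f), fmt_p(anova$p)),
    "",
    sprintf("R2 = %.4f, adjusted R2 = %.4f", attr(anova, "r2"), attr(anova, "adj_r2")),
    "",
    paste0("Model equation (coded units): ", model_equation(fit, digits = 2)),
    "",
    sprintf("Terms significant at alpha = %g: %s", alpha,
            paste(significant_terms(fit, alpha), collapse = ", "))
  )
  lines
}

#' Run the full analysis pipeline on a design/response table
#'
#' End-to-end reproducible analysis: codes the natural-unit run table, fits
#' the full second-order model to every requested response, computes the
#' lack-of-fit ANOVA, optimizes each response over the coded box, and finds
#' the joint desirability optimum. When an output directory is given, each
#' stage's artifacts are written there (model JSONs, a combined markdown
#' report, per-response and joint optima as CSV, and a log with the package
#' version and seed); every stage is also logged via [message()].
#'
#' @param runs Data frame of natural-unit factor settings plus response
#'   columns (e.g. `herbal_extraction_study()$runs`), or a CSV path.
#' @param factors List of [factor_spec()], or a YAML/JSON path for
#'   [read_factor_specs()].
#' @param responses Character vector of response column names; default: all
#'   non-factor, non-`run` columns.
#' @param alpha Significance level used in reports (in (0, 0.5]).
#' @param lower,upper Optimization box in coded units.
#' @param desirability Optional desirability spec (see [joint_optimize()]);
#'   default anchors each response at its achievable range.
#' @param seed Integer seed recorded in the log (the deterministic pipeline
#'   itself draws no random numbers; the seed is for provenance and for any
#'   seeded extensions).
#' @param out_dir Optional output directory, created if needed.
#' @return List with `fits`, `anovas`, `optima`, `joint`, and `report`
#'   (markdown lines), invisibly.
#' @examples
#' study <- herbal_extraction_study()
#' res <- run_pipeline(study$runs, study$factors, responses = "yield")
#' round(res$optima$yield$value, 2)
#' @export
run_pipeline <- function(runs, factors, responses = NULL, alpha = 0.05,
                         lower = -1, upper = 1, desirability = NULL,
                         seed = 1L, out_dir = NULL) {
  stopifnot(alpha > 0, alpha <= 0.5)
  if (is.character(factors)) factors <- read_factor_specs(factors)
  factors <- as_factor_list(factors)
  if (is.character(runs)) runs <- read_design_csv(runs, factors)
  runs <- as.data.frame(runs)
  if (is.null(responses))
    responses <- setdiff(names(runs), c("run", factor_names(factors)))
  if (!length(responses)) stop("no response columns found", call. = FALSE)
  for (r in responses) {
    if (!r %in% names(runs)) stop("no response column '", r, "'", call. = FALSE)
    if (all(is.na(runs[[r]])) || !is.numeric(runs[[r]]))
      stop("response column '", r, "' is empty or non-numeric", call. = FALSE)
  }
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[bbrsm] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  say("pipeline start: %d runs, %d factors, responses: %s (bbrsm %s, seed %d)",
      nrow(runs), length(factors), paste(responses, collapse = ", "),
      as.character(utils::packageVersion("bbrsm")), as.integer(seed))

  coded <- code_runs(runs, factors)
  cm <- coded[factor_names(factors)]
  say("stage design: coded %d runs (%d center replicates)",
      nrow(cm), sum(rowSums(as.matrix(cm) != 0) == 0))

  fits <- anovas <- optima <- list()
  report <- character(0)
  for (r in responses) {
    fits[[r]] <- fit_quadratic(cm, coded[[r]], response = r, factors = factors)
    anovas[[r]] <- rsm_anova(fits[[r]])
    report <- c(report, fit_report(fits[[r]], anovas[[r]], alpha), "")
    say("stage fit: %s R2 = %.4f", r, fits[[r]]$r2)
  }
  for (r in responses) {
    optima[[r]] <- maximize_in_box(fits[[r]], lower, upper)
    say("stage optimize: %s best %.2f in box", r, optima[[r]]$value)
  }
  joint <- NULL
  if (length(responses) >= 2L) {
    joint <- joint_optimize(fits, spec = desirability, lower, upper)
    say("stage joint-optimize: D = %.3f at (%s)", joint$value,
        paste(sprintf("%.2f", joint$natural), collapse = ", "))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in responses)
      write_model_json(fits[[r]], file.path(out_dir, paste0("model_", r, ".json")))
    writeLines(report, file.path(out_dir, "report.md"))
    opt_df <- do.call(rbind, lapply(responses, function(r) {
      o <- optima[[r]]
      data.frame(response = r, t(o$coded), value = o$value, check.names = FALSE)
    }))
    utils::write.csv(opt_df, file.path(out_dir, "optima.csv"), row.names = FALSE)
    if (!is.null(joint)) {
      jd <- data.frame(t(joint$coded), D = joint$value, check.names = FALSE)
      utils::write.csv(jd, file.path(out_dir, "joint_optimum.csv"), row.names = FALSE)
    }
    say("stage report: artifacts written to %s", out_dir)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(list(fits = fits, anovas = anovas, optima = optima, joint = joint,
                 report = report, log = log_lines))
}
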
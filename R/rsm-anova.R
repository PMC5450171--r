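#' ANOVA with lack-of-fit for a response-surface fit
#'
#' Partitions the total sum of squares of a fitted second-order model into
#' model and residual components, and the residual further into pure error and
#' lack of fit. Pure error is computed from exact replicate runs (runs with
#' identical coded settings — in a Box-Behnken design, the replicated center
#' points): the sum of squared deviations from each replicate-group mean, on
#' `sum(n_g - 1)` degrees of freedom. Lack of fit is the remainder of the
#' residual; its F ratio against pure error tests the adequacy of the
#' quadratic form. With no replicated runs the lack-of-fit partition is
#' undefined and those rows are omitted with a warning.
#'
#' @param fit An [fit_quadratic()] result.
#' @return An `rsm_anova`: a data frame with columns `source`, `ss`, `df`,
#'   `ms`, `f`, `p` and rows model / residual / pure error / lack of fit /
#'   total, carrying `r2`, `adj_r2` and `response` as attributes.
#' @examples
#' study <- herbal_extraction_study()
#' coded <- code_runs(study$runs, study$factors)
#' fit <- fit_quadratic(coded[names(study$factors)], coded$yield,
#'                      response = "yield", factors = study$factors)
#' rsm_anova(fit)
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  y <- fit$y
  fitted <- predict(fit)
  n <- length(y)

  ss_total <- sum((y - mean(y))^2)
  ss_model <- sum((fitted - mean(y))^2)
  ss_resid <- sum((y - fitted)^2)
  df_model <- fit$k * (fit$k + 3) / 2
  df_resid <- n - 1L - df_model

  groups <- interaction(as.data.frame(fit$coded), drop = TRUE)
  tab <- table(groups)
  rep_groups <- names(tab)[tab > 1L]
  ss_pe <- sum(unlist(lapply(rep_groups, function(g) {
    yy <- y[groups == g]
    (yy - mean(yy))^2
  })))
  df_pe <- sum(tab[tab > 1L] - 1L)

  ms_model <- ss_model / df_model
  ms_resid <- ss_resid / df_resid
  f_model <- ms_model / ms_resid
  p_model <- stats::pf(f_model, df_model, df_resid, lower.tail = FALSE)

  rows <- data.frame(
    source = c("model", "residual"),
    ss = c(ss_model, ss_resid),
    df = c(df_model, df_resid),
    ms = c(ms_model, ms_resid),
    f = c(f_model, NA),
    p = c(p_model, NA)
  )
  if (df_pe > 0L) {
    ss_lof <- ss_resid - ss_pe
    df_lof <- df_resid - df_pe
    ms_pe <- ss_pe / df_pe
    ms_lof <- if (df_lof > 0L) ss_lof / df_lof else NA_real_
    f_lof <- if (df_lof > 0L) ms_lof / ms_pe else NA_real_
    p_lof <- if (df_lof > 0L)
      stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE) else NA_real_
    rows <- rbind(rows, data.frame(
      source = c("pure error", "lack of fit"),
      ss = c(ss_pe, ss_lof), df = c(df_pe, df_lof),
      ms = c(ms_pe, ms_lof), f = c(NA, f_lof), p = c(NA, p_lof)))
  } else {
    warning("no replicated runs: lack-of-fit partition omitted", call. = FALSE)
  }
  rows <- rbind(rows, data.frame(source = "total", ss = ss_total, df = n - 1L,
                                 ms = NA, f = NA, p = NA))
  structure(rows,
            r2 = ss_model / ss_total,
            adj_r2 = 1 - (1 - ss_model / ss_total) * (n - 1) / df_resid,
            response = fit$response,
            class = c("rsm_anova", "data.frame"))
}

#' @export
print.rsm_anova <- function(x, digits = 2, ...) {
  cat(sprintf("Analysis of variance — response '%s'\n", attr(x, "response")))
  df <- as.data.frame(x)
  df$ss <- round(df$ss, digits)
  df$ms <- round(df$ms, digits)
  df$f <- round(df$f, digits)
  df$p <- ifelse(is.na(df$p), NA,
                 ifelse(df$p < 1e-4, "<0.0001", formatC(df$p, format = "f", digits = 4)))
  print(df, row.names = FALSE)
  cat(sprintf("R2 = %.4f   adj. R2 = %.4f\n", attr(x, "r2"), attr(x, "adj_r2")))
  invisible(x)
}

anova_row <- function(an, source) {
  i <- match(source, an$source)
  if (is.na(i)) stop("no ANOVA row '", source, "'", call. = FALSE)
  an[i, ]
}
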
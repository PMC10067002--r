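#' Income elasticity of demand for health care
#'
#' The elasticity \eqn{\beta_h} is the log-log regression slope in
#' \eqn{\ln Q_{health} = \alpha + \beta_h \ln Y + \varepsilon}: the
#' percent change in health expenditure per percent change in income.
#' A single cross-sectional regression yields one slope; to give each
#' individual an `E_H` with realistic dispersion, the default strategy
#' estimates the slope within urban/rural x age-decile strata and assigns
#' each record its stratum's slope, truncated below at zero (the
#' elasticity is defined nonnegative).
#'
#' @name elasticity
NULL

#' Ordinary least squares log-log fit
#'
#' @param ln_q Log health expenditure (rows with zero expenditure are
#'   excluded upstream).
#' @param ln_i Log income.
#' @return List with `alpha` (intercept), `beta_h` (slope), `se_beta`
#'   and `n`.
#' @export
fit_loglog <- function(ln_q, ln_i) {
  if (length(ln_q) != length(ln_i)) stop_hv("length mismatch")
  if (length(ln_q) < 3L) stop_hv("need at least 3 observations")
  if (!all(is.finite(ln_q)) || !all(is.finite(ln_i)))
    stop_hv("inputs must be finite")
  sxx <- sum((ln_i - mean(ln_i))^2)
  if (sxx < 1e-12) stop_hv("zero variance in ln income")
  beta <- sum((ln_i - mean(ln_i)) * (ln_q - mean(ln_q))) / sxx
  alpha <- mean(ln_q) - beta * mean(ln_i)
  res <- ln_q - alpha - beta * ln_i
  se <- sqrt(sum(res^2) / (length(ln_q) - 2L) / sxx)
  list(alpha = alpha, beta_h = beta, se_beta = se, n = length(ln_q))
}

stratum_labels <- function(table, strata) {
  parts <- lapply(strata, function(s) switch(s,
    urban = ifelse(table$urban == 1, "urban", "rural"),
    age_decile = sprintf("age_d%02d", decile_of(table$age)),
    income_decile = sprintf("inc_d%02d", decile_of(table$income)),
    region = table$region,
    stop_hv("unknown stratum variable '%s'", s)))
  do.call(paste, c(parts, sep = ":"))
}

#' Fit the elasticity model
#'
#' Rows with nonpositive income or zero health expenditure are excluded
#' from fitting (the log transform is undefined there); the exclusion
#' count is recorded on the model.
#'
#' @param table Data frame with `income`, `health_expenditure` and the
#'   stratum variables.
#' @param strategy `"stratified"` (default) or `"global"`.
#' @param strata Character vector of stratum variables (default
#'   `c("urban", "age_decile")`; `"income_decile"` is also available).
#' @param min_n Minimum stratum size; smaller strata fall back to the
#'   pooled slope at assignment time.
#' @return An `elasticity_model`: `strategy`, `strata_definition`,
#'   `beta_by_stratum`, `intercepts`, `se_by_stratum`, `n_by_stratum`,
#'   `pooled` (global fit) and `n_excluded`.
#' @export
fit_elasticity <- function(table, strategy = c("stratified", "global"),
                           strata = c("urban", "age_decile"), min_n = 30L) {
  strategy <- match.arg(strategy)
  keep <- is.finite(table$income) & table$income > 0 &
    is.finite(table$health_expenditure) & table$health_expenditure > 0
  n_excluded <- sum(!keep)
  fitting <- table[keep, , drop = FALSE]
  if (nrow(fitting) < 3L) stop_hv("too few rows with positive Q and I")
  ln_q <- log(fitting$health_expenditure)
  ln_i <- log(fitting$income)
  pooled <- fit_loglog(ln_q, ln_i)

  if (strategy == "global") {
    mdl <- list(strategy = strategy, strata_definition = "global",
                beta_by_stratum = c(global = pooled$beta_h),
                intercepts = c(global = pooled$alpha),
                se_by_stratum = c(global = pooled$se_beta),
                n_by_stratum = c(global = pooled$n),
                pooled = pooled, min_n = min_n, strata = character(0),
                n_excluded = n_excluded)
    return(structure(mdl, class = "elasticity_model"))
  }

  lab <- stratum_labels(fitting, strata)
  fits <- lapply(split(seq_along(lab), lab), function(idx) {
    if (length(idx) < 3L) return(NULL)
    fit_loglog(ln_q[idx], ln_i[idx])
  })
  ok <- !vapply(fits, is.null, logical(1))
  mdl <- list(strategy = strategy,
              strata_definition = paste(strata, collapse = " x "),
              beta_by_stratum = vapply(fits[ok], `[[`, numeric(1), "beta_h"),
              intercepts = vapply(fits[ok], `[[`, numeric(1), "alpha"),
              se_by_stratum = vapply(fits[ok], `[[`, numeric(1), "se_beta"),
              n_by_stratum = vapply(fits[ok], `[[`, numeric(1), "n"),
              pooled = pooled, min_n = min_n, strata = strata,
              n_excluded = n_excluded)
  structure(mdl, class = "elasticity_model")
}

#' @export
print.elasticity_model <- function(x, ...) {
  cat(sprintf("Elasticity model (%s; strata: %s)\n", x$strategy,
              x$strata_definition))
  cat(sprintf("  pooled beta_h = %.4f (se %.4f, n = %d; %d rows excluded)\n",
              x$pooled$beta_h, x$pooled$se_beta, x$pooled$n, x$n_excluded))
  if (x$strategy == "stratified")
    cat(sprintf("  %d strata, slope range [%.3f, %.3f]\n",
                length(x$beta_by_stratum), min(x$beta_by_stratum),
                max(x$beta_by_stratum)))
  invisible(x)
}

#' Assign per-individual E_H
#'
#' Each record receives its stratum's estimated slope, truncated below at
#' zero.  Records in strata below `min_n` (or absent from the fit)
#' receive the pooled slope, with a warning naming the strata.
#'
#' @param table Data frame of records.
#' @param model An [fit_elasticity()] model.
#' @return Nonnegative numeric vector with a `summary` attribute
#'   (mean, sd, number of fallback rows).
#' @export
assign_eh <- function(table, model) {
  if (model$strategy == "global") {
    eh <- rep(max(model$pooled$beta_h, 0), nrow(table))
  } else {
    lab <- stratum_labels(table, model$strata)
    beta <- model$beta_by_stratum[lab]
    small <- names(model$n_by_stratum)[model$n_by_stratum < model$min_n]
    fallback <- is.na(beta) | lab %in% small
    if (any(fallback)) {
      warning(sprintf(
        "%d record(s) in underpopulated strata (%s); pooled slope assigned",
        sum(fallback),
        paste(unique(lab[fallback]), collapse = ", ")), call. = FALSE)
      beta[fallback] <- model$pooled$beta_h
    }
    eh <- pmax(as.numeric(beta), 0)
  }
  attr(eh, "summary") <- c(mean = mean(eh), sd = stats::sd(eh),
                           n_fallback = if (model$strategy == "global") 0
                                        else sum(is.na(model$beta_by_stratum[
                                          stratum_labels(table, model$strata)])))
  eh
}
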
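#' Vulnerability as expected poverty (VEP)
#'
#' Vulnerability is the probability that a unit's future log welfare falls
#' below a poverty line.  With log welfare modelled as
#' \eqn{\ln C = X\alpha + e}, \eqn{Var(e|X) = X\beta}, and normal shocks,
#' \deqn{VUL = \Phi\left(\frac{\ln z - X\hat\alpha}{\sqrt{X\hat\beta}}\right)}
#' where \eqn{\ln z} is the log poverty line.  \eqn{\hat\alpha} and
#' \eqn{\hat\beta} come from the three-stage feasible GLS of the
#' Chaudhuri/Amemiya tradition: (1) OLS of log welfare on X gives
#' residuals \eqn{\hat e}; (2) OLS of \eqn{\hat e^2} on X gives a pilot
#' variance fit, refined by one weighted pass of \eqn{\hat e^2} on X with
#' weights from the pilot fit; (3) weighted least squares of log welfare
#' on X with weights \eqn{1/(X\hat\beta)}.
#'
#' @name vep
NULL

ols_fit <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(coef = fit$coefficients, residuals = fit$residuals, r2 = r2)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop_hv("design matrix is rank deficient; collinear column(s): %s",
            paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the heteroskedastic welfare model by three-stage FGLS
#'
#' @param ln_welfare Numeric vector of log welfare (e.g. log consumption
#'   or the log of one minus the combined health-deprivation score).
#' @param X Design matrix including an intercept column; column names are
#'   retained as `design_columns`.
#' @param variance_floor Lower clip for fitted variances (default 1e-4);
#'   rows at or below zero before flooring are counted and reported.
#' @return A `welfare_model` with `alpha`, `beta`, `design_columns`,
#'   `n_obs`, stage R-squareds and the floored-row count.
#' @export
fit_welfare_fgls <- function(ln_welfare, X, variance_floor = 1e-4) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(ln_welfare) != nrow(X)) stop_hv("length mismatch")
  if (anyNA(ln_welfare) || anyNA(X)) stop_hv("missing values in inputs")
  if (nrow(X) <= ncol(X)) stop_hv("need more observations than columns")
  check_full_rank(X)

  # stage 1: OLS mean equation
  s1 <- ols_fit(ln_welfare, X)
  e2 <- s1$residuals^2

  # stage 2: pilot OLS of squared residuals, then one weighted refinement
  s2a <- ols_fit(e2, X)
  v0 <- pmax(as.numeric(X %*% s2a$coef), variance_floor)
  w2 <- 1 / v0^2
  s2b <- stats::lm.wfit(X, e2, w2)
  beta <- s2b$coefficients
  v <- as.numeric(X %*% beta)
  n_floored <- sum(v <= 0)
  if (all(v <= 0))
    stop_hv("all fitted variances are nonpositive before flooring")
  v <- pmax(v, variance_floor)
  r2_var <- 1 - sum(s2b$residuals^2) / sum((e2 - mean(e2))^2)
  if (stats::var(e2) < 1e-12)
    warning("residual variance is (near) zero; variance equation floored",
            call. = FALSE)

  # stage 3: WLS mean equation with weights 1/variance
  s3 <- stats::lm.wfit(X, ln_welfare, 1 / v)

  structure(list(alpha = s3$coefficients, beta = beta,
                 design_columns = colnames(X), n_obs = nrow(X),
                 r2_mean = s1$r2, r2_var = r2_var,
                 n_floored = n_floored, variance_floor = variance_floor),
            class = "welfare_model")
}

#' @export
print.welfare_model <- function(x, ...) {
  cat("Three-stage FGLS welfare model\n")
  cat(sprintf("  n = %d, columns = %d, floored variances = %d\n",
              x$n_obs, length(x$design_columns), x$n_floored))
  cat(sprintf("  stage-1 R2 = %.4f, variance-equation R2 = %.4f\n",
              x$r2_mean, x$r2_var))
  invisible(x)
}

#' Predict vulnerability probabilities
#'
#' @param model A `welfare_model` from [fit_welfare_fgls()], or a list
#'   with `alpha`, `beta` and `design_columns` (a known variance model
#'   may be supplied directly).
#' @param X Design matrix with columns matching `model$design_columns`.
#' @param ln_poverty_line Log poverty line \eqn{\ln z}.
#' @inheritParams fit_welfare_fgls
#' @return Vector of probabilities \eqn{\Phi((\ln z - X\hat\alpha) /
#'   \sqrt{\max(X\hat\beta, floor)})}.
#' @export
predict_vulnerability <- function(model, X, ln_poverty_line,
                                  variance_floor = model$variance_floor %||% 1e-4) {
  X <- as.matrix(X)
  if (!identical(colnames(X), model$design_columns))
    stop_hv("design columns do not match the model (expected: %s)",
            paste(model$design_columns, collapse = ", "))
  mu <- as.numeric(X %*% model$alpha)
  v <- pmax(as.numeric(X %*% model$beta), variance_floor)
  stats::pnorm((ln_poverty_line - mu) / sqrt(v))
}

#' Binarize vulnerability into the VEP outcome
#'
#' @param vulnerability Probability vector.
#' @param cutoff Fraction in (0, 1); boundary inclusive (a vulnerability
#'   exactly at the cutoff is classified vulnerable).
#' @return Integer 0/1 vector.
#' @export
binarize_vep <- function(vulnerability, cutoff = 0.5) {
  assert_fraction(cutoff, "cutoff")
  if (any(vulnerability < 0 | vulnerability > 1, na.rm = TRUE))
    stop_hv("vulnerability values must lie in [0,1]")
  as.integer(vulnerability >= cutoff)
}

#' Welfare input derived from A-F deprivation scores
#'
#' Maps a combined weighted deprivation score `k` in \[0, 1\] to log
#' welfare `ln(1 - k + eps)`; the matching poverty line for cutoff
#' `gamma` is `ln(1 - gamma + eps)`.
#'
#' @param combined_score Combined deprivation score in \[0, 1\].
#' @param eps Offset keeping the logarithm finite at `k = 1`.
#' @return Numeric vector of log welfare.
#' @export
af_welfare <- function(combined_score, eps = 1e-3) {
  if (any(combined_score < 0 | combined_score > 1))
    stop_hv("combined_score must lie in [0,1]")
  log(1 - combined_score + eps)
}
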
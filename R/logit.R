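#' Two-layer logistic regression with interaction terms
#'
#' The first-layer model is a pooled logit of the binary VEP outcome on
#' the key variables (government subsidy GS, public-mechanism rating PM)
#' and covariates, with province fixed effects as dummy columns.  The
#' second layer lets the GS and PM coefficients shift with the income
#' elasticity of health demand `E_H`, which after substitution adds `E_H`
#' and the interaction columns `GS x E_H` and `PM x E_H` to the design.
#' Estimation is maximum likelihood via iteratively reweighted least
#' squares; standard errors come from the inverse observed information.
#'
#' @name two_level_logit
NULL

#' Specify a regression design
#'
#' @param outcome Outcome column (binary).
#' @param main_terms Ordered main-effect columns.
#' @param second_layer If `TRUE`, `eh_column` and `interactions` are
#'   added to the design.
#' @param eh_column Column holding E_H.
#' @param interactions Character vector of terms to interact with E_H
#'   (only allowed when `second_layer` is set).
#' @param fixed_effects Grouping column expanded to reference-coded
#'   dummies (first level as reference), or `NULL`.
#' @param subgroup Optional named list of `column = value` filters.
#' @return A `regression_spec`.
#' @export
regression_spec <- function(outcome, main_terms, second_layer = FALSE,
                            eh_column = NULL, interactions = character(0),
                            fixed_effects = NULL, subgroup = NULL) {
  if (length(interactions) && !second_layer)
    stop_hv("interactions are only allowed in a second-layer design")
  if (second_layer && is.null(eh_column))
    stop_hv("second_layer designs require eh_column")
  structure(list(outcome = outcome, main_terms = main_terms,
                 second_layer = second_layer, eh_column = eh_column,
                 interactions = interactions, fixed_effects = fixed_effects,
                 subgroup = subgroup),
            class = "regression_spec")
}

#' Build the design matrix and outcome vector
#'
#' Interaction columns are elementwise products of the named term and
#' E_H; fixed effects expand to dummy columns against the first level;
#' rows with missing values are dropped (count recorded).
#'
#' @param table Analysis table.
#' @param spec A [regression_spec()].
#' @return List: `X` (with intercept), `y`, `interaction_map` (column ->
#'   c(parent, modifier)), `n_dropped` (missing values),
#'   `n_dropped_separated` (rows in fixed-effect groups with a constant
#'   outcome), `fe_levels`.
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "regression_spec"))
  needed <- c(spec$outcome, spec$main_terms, spec$eh_column,
              spec$fixed_effects, names(spec$subgroup))
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop_hv("column(s) not in analysis table: %s",
            paste(missing, collapse = ", "))
  if (!is.null(spec$subgroup))
    for (nm in names(spec$subgroup))
      table <- table[table[[nm]] == spec$subgroup[[nm]], , drop = FALSE]
  if (!nrow(table)) stop_hv("empty subgroup after filtering")

  cols <- c(spec$main_terms,
            if (spec$second_layer) spec$eh_column)
  keep <- stats::complete.cases(table[, c(spec$outcome, cols,
                                          spec$fixed_effects), drop = FALSE])
  n_dropped <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  y <- table[[spec$outcome]]
  if (!all(y %in% c(0, 1))) stop_hv("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop_hv("constant outcome")

  # fixed-effect groups with a constant outcome carry no information and
  # their dummies diverge (quasi-separation); drop them, as conditional
  # fixed-effects logit does with concordant groups
  n_dropped_separated <- 0L
  if (!is.null(spec$fixed_effects)) {
    gmean <- tapply(y, table[[spec$fixed_effects]], mean)
    const_grp <- names(gmean)[gmean %in% c(0, 1)]
    if (length(const_grp)) {
      sep <- table[[spec$fixed_effects]] %in% const_grp
      n_dropped_separated <- sum(sep)
      table <- table[!sep, , drop = FALSE]
      y <- table[[spec$outcome]]
      if (length(unique(y)) < 2L) stop_hv("constant outcome")
    }
  }

  X <- as.matrix(do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(table))),
                                  lapply(stats::setNames(cols, cols),
                                         function(nm) as.numeric(table[[nm]])))))
  interaction_map <- list()
  for (term in spec$interactions) {
    cn <- paste0(term, ":", spec$eh_column)
    X <- cbind(X, as.numeric(table[[term]]) * as.numeric(table[[spec$eh_column]]))
    colnames(X)[ncol(X)] <- cn
    interaction_map[[cn]] <- c(parent = term, modifier = spec$eh_column)
  }
  fe_levels <- 0L
  if (!is.null(spec$fixed_effects)) {
    f <- factor(table[[spec$fixed_effects]])
    fe_levels <- nlevels(f)
    if (fe_levels > 1L) {
      D <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(D) <- paste0(spec$fixed_effects,
                            substring(colnames(D), 2L))
      X <- cbind(X, D)
    }
  }
  list(X = X, y = as.integer(y), interaction_map = interaction_map,
       n_dropped = n_dropped, n_dropped_separated = n_dropped_separated,
       fe_levels = fe_levels)
}

#' Fit a logistic regression by IRLS
#'
#' Newton/IRLS iterations to tolerance 1e-8 on the coefficient change,
#' at most `maxit` iterations.  Collinear columns are dropped greedily by
#' QR pivoting (recorded in `dropped_columns`).  A coefficient diverging
#' beyond `sep_threshold` triggers a perfect-separation error naming the
#' term.
#'
#' @param design List from [build_design()], or a bare design matrix.
#' @param outcome Outcome vector (ignored when `design` is a
#'   [build_design()] list).
#' @param tol,maxit,sep_threshold Convergence controls.
#' @return A `logit_fit`: `coefficients` data frame (term, estimate, se,
#'   z, p), `vcov`, `log_likelihood`, `n_obs`, `converged`, `fitted`,
#'   plus design metadata for downstream marginal effects.
#' @export
fit_logit <- function(design, outcome = NULL, tol = 1e-8, maxit = 100L,
                      sep_threshold = 30) {
  if (is.list(design) && !is.data.frame(design)) {
    X <- design$X; y <- design$y
    interaction_map <- design$interaction_map %||% list()
    fe_levels <- design$fe_levels %||% 0L
  } else {
    X <- as.matrix(design); y <- as.integer(outcome)
    interaction_map <- list(); fe_levels <- 0L
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (!all(y %in% c(0L, 1L))) stop_hv("outcome must be binary 0/1")

  # drop collinear columns by pivoted QR
  q <- qr(X)
  dropped <- character(0)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }

  beta <- numeric(ncol(X))
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    delta <- max(abs(new_beta - beta))
    trace <- c(trace, delta)
    beta <- new_beta
    if (max(abs(beta)) > sep_threshold) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop_hv("perfect separation suspected: coefficient for '%s' diverged (|b| > %g)",
              worst, sep_threshold)
    }
    if (delta < tol) break
  }
  converged <- delta < tol
  if (!converged)
    stop_hv("IRLS did not converge in %d iterations (last deltas: %s)",
            maxit, paste(signif(utils::tail(trace, 5), 3), collapse = ", "))

  eta <- as.numeric(X %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  info <- crossprod(X * sqrt(W))
  V <- tryCatch(solve(info), error = function(e)
    stop_hv("information matrix is singular"))
  se <- sqrt(diag(V))
  zstat <- beta / se
  coefs <- data.frame(term = colnames(X), estimate = unname(beta),
                      se = unname(se), z = unname(zstat),
                      p = unname(2 * stats::pnorm(-abs(zstat))),
                      stringsAsFactors = FALSE)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(list(coefficients = coefs, vcov = V, log_likelihood = ll,
                 n_obs = nrow(X), converged = converged, fitted = p,
                 X = X, y = y, interaction_map = interaction_map,
                 fe_absorbed = fe_levels, dropped_columns = dropped,
                 iterations = it),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logit fit: n = %d, logLik = %.2f, %d iterations\n",
              x$n_obs, x$log_likelihood, x$iterations))
  print(x$coefficients[!grepl("^province", x$coefficients$term), ],
        row.names = FALSE, digits = 4)
  invisible(x)
}

coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop_hv("term '%s' absent from fit", term)
  i
}

#' Average marginal effects
#'
#' Continuous terms: sample average of \eqn{\partial p / \partial x =
#' p(1-p) \cdot d\eta/dx}, where the derivative includes any interaction
#' column involving the term.  Binary terms: average discrete change
#' \eqn{p(x{=}1) - p(x{=}0)} with interaction columns recomputed
#' consistently.  Standard errors by the delta method.
#'
#' @param fit A `logit_fit`.
#' @param terms Terms to report (default: every non-intercept,
#'   non-fixed-effect column).
#' @return A `marginal_effects` data frame: term, dydx, se, z, and a
#'   `discrete` flag.
#' @export
marginal_effects <- function(fit, terms = NULL) {
  X <- fit$X
  b <- fit$coefficients$estimate
  names(b) <- fit$coefficients$term
  imap <- fit$interaction_map
  if (is.null(terms)) {
    terms <- setdiff(colnames(X), "(Intercept)")
    terms <- terms[!grepl("^province", terms)]
  }
  p <- fit$fitted
  f <- p * (1 - p)
  fp <- f * (1 - 2 * p)

  res <- lapply(terms, function(term) {
    i <- coef_of(fit, term)
    vals <- X[, term]
    is_binary <- all(vals %in% c(0, 1)) && is.null(imap[[term]])
    if (is_binary) {
      X1 <- X; X0 <- X
      X1[, term] <- 1; X0[, term] <- 0
      for (cn in names(imap)) {
        pm <- imap[[cn]]
        if (pm[["parent"]] == term) {
          X1[, cn] <- 1 * X[, pm[["modifier"]]]
          X0[, cn] <- 0
        } else if (pm[["modifier"]] == term) {
          X1[, cn] <- X[, pm[["parent"]]]
          X0[, cn] <- 0
        }
      }
      keepc <- colnames(X)
      p1 <- stats::plogis(as.numeric(X1 %*% b[keepc]))
      p0 <- stats::plogis(as.numeric(X0 %*% b[keepc]))
      ame <- mean(p1 - p0)
      g <- colMeans(p1 * (1 - p1) * X1 - p0 * (1 - p0) * X0)
      discrete <- TRUE
    } else {
      # d eta / d term, including interaction columns touching the term
      m <- rep(b[[term]], nrow(X))
      dm <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
      dm[, term] <- 1
      for (cn in names(imap)) {
        pm <- imap[[cn]]
        partner <- if (pm[["parent"]] == term) pm[["modifier"]]
                   else if (pm[["modifier"]] == term) pm[["parent"]]
                   else NA_character_
        if (!is.na(partner) && cn %in% colnames(X)) {
          m <- m + b[[cn]] * X[, partner]
          dm[, cn] <- X[, partner]
        }
      }
      ame <- mean(f * m)
      g <- colMeans(fp * X * m) + colMeans(f * dm)
      discrete <- FALSE
    }
    se <- sqrt(as.numeric(t(g) %*% fit$vcov %*% g))
    data.frame(term = term, dydx = ame, se = se, z = ame / se,
               discrete = discrete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("marginal_effects", class(out))
  out
}

#' Joint Wald test
#'
#' \eqn{W = b' V^{-1} b} over the selected coefficients, chi-square with
#' df equal to the number of terms.
#'
#' @param fit A `logit_fit`.
#' @param terms Coefficient names to test jointly against zero.
#' @return List: `statistic`, `df`, `p_value`, `terms_tested`.
#' @export
wald_joint <- function(fit, terms) {
  idx <- vapply(terms, function(t) coef_of(fit, t), integer(1))
  b <- fit$coefficients$estimate[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop_hv("singular covariance sub-block for terms: %s",
            paste(terms, collapse = ", ")))
  W <- as.numeric(t(b) %*% Vi %*% b)
  list(statistic = W, df = length(terms),
       p_value = stats::pchisq(W, length(terms), lower.tail = FALSE),
       terms_tested = terms)
}

#' Likelihood-ratio test against the intercept + fixed-effects null
#'
#' The published tables print an unexplained "Prob > F" for each logit;
#' this package reports instead an explicitly labelled likelihood-ratio
#' test of the fitted model against a null containing only the intercept
#' and the fixed-effect dummies.
#'
#' @param fit A `logit_fit`.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
lr_test_null <- function(fit) {
  null_cols <- c("(Intercept)",
                 grep("^province", colnames(fit$X), value = TRUE))
  X0 <- fit$X[, null_cols, drop = FALSE]
  f0 <- fit_logit(X0, fit$y)
  stat <- 2 * (fit$log_likelihood - f0$log_likelihood)
  df <- ncol(fit$X) - ncol(X0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}
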
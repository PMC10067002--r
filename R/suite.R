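#' Run the full regression table suite
#'
#' Executes, in order: the first-layer baseline logit (key variables GS
#' and PM plus covariates and province fixed effects), the joint
#' interaction tests, the second-layer fit adding E_H and its GS/PM
#' interactions, the urban/rural split, and the east/central/west split.
#' Each block carries the sample size, coefficient table, average
#' marginal effects with z statistics and 10/5/1 percent significance
#' stars, and a likelihood-ratio test against the intercept +
#' fixed-effects null.  A failed subgroup is recorded as an error message
#' without aborting the remaining subgroups.
#'
#' @param table Analysis table containing the outcome, key variables,
#'   covariates, `eh`, and the fixed-effects column.
#' @param outcome Outcome column name (default `"vep"`).
#' @param eh_column E_H column name (default `"eh"`).
#' @param fixed_effects Fixed-effects column (default `"province"`).
#' @param covariates Covariate columns for both layers.
#' @param designs Subset of `c("table4","table5","table6","table7",
#'   "table8")` to run; default all.
#' @return A `vep_report` list of result blocks.
#' @export
run_table_suite <- function(table, outcome = "vep", eh_column = "eh",
                            fixed_effects = "province",
                            covariates = c("gender", "age", "family_size",
                                           "marriage", "education",
                                           "job_satisfaction", "social_status",
                                           "smoke", "drink", "exercise",
                                           "patient_trust", "urban"),
                            designs = c("table4", "table5", "table6",
                                        "table7", "table8")) {
  designs <- match.arg(designs, several.ok = TRUE)
  key <- c("gs", "pm_s")
  main1 <- c(key, covariates)

  fit_block <- function(spec, label) {
    tryCatch({
      d <- build_design(table, spec)
      fit <- fit_logit(d)
      ame <- marginal_effects(fit)
      ame$stars <- significance_stars(2 * stats::pnorm(-abs(ame$z)))
      lr <- lr_test_null(fit)
      list(label = label, n = fit$n_obs, fit = fit, ame = ame, lr = lr,
           n_dropped = d$n_dropped,
           n_dropped_separated = d$n_dropped_separated, error = NULL)
    }, error = function(e) list(label = label, error = conditionMessage(e)))
  }

  blocks <- list()
  spec6 <- function(subgroup = NULL, terms = main1)
    regression_spec(outcome, terms, second_layer = TRUE,
                    eh_column = eh_column, interactions = key,
                    fixed_effects = fixed_effects, subgroup = subgroup)

  if ("table4" %in% designs)
    blocks$table4 <- fit_block(
      regression_spec(outcome, main1, fixed_effects = fixed_effects),
      "first layer: baseline")
  second <- NULL
  if (any(c("table5", "table6") %in% designs)) {
    second <- fit_block(spec6(), "second layer: E_H and interactions")
    if ("table6" %in% designs) blocks$table6 <- second
  }
  if ("table5" %in% designs) {
    blocks$table5 <- if (is.null(second$error)) {
      ints <- paste0(key, ":", eh_column)
      per_term <- lapply(ints, function(t) wald_joint(second$fit, t))
      names(per_term) <- ints
      list(label = "interaction joint tests", per_term = per_term,
           joint = wald_joint(second$fit, ints), error = NULL)
    } else list(label = "interaction joint tests", error = second$error)
  }
  if ("table7" %in% designs) {
    cov_nu <- setdiff(covariates, "urban")
    blocks$table7_urban <- fit_block(spec6(list(urban = 1),
                                           c(key, cov_nu)),
                                     "urban subgroup")
    blocks$table7_rural <- fit_block(spec6(list(urban = 0),
                                           c(key, cov_nu)),
                                     "rural subgroup")
  }
  if ("table8" %in% designs)
    for (r in c("east", "central", "west"))
      blocks[[paste0("table8_", r)]] <-
        fit_block(spec6(list(region = r)), paste(r, "region subgroup"))

  structure(blocks, class = "vep_report")
}

#' @export
print.vep_report <- function(x, ...) {
  for (nm in names(x)) {
    b <- x[[nm]]
    cat("==", nm, "--", b$label, "==\n")
    if (!is.null(b$error)) {
      cat("  FAILED:", b$error, "\n\n")
      next
    }
    if (!is.null(b$per_term)) {
      for (t in names(b$per_term))
        cat(sprintf("  %-10s chi2(%d) = %.2f, p = %.4f\n", t,
                    b$per_term[[t]]$df, b$per_term[[t]]$statistic,
                    b$per_term[[t]]$p_value))
      j <- b$joint
      cat(sprintf("  joint      chi2(%d) = %.2f, p = %.4f\n\n",
                  j$df, j$statistic, j$p_value))
      next
    }
    cat(sprintf("  n = %d (%d rows dropped); LR chi2(%d) = %.1f, p = %.4g\n",
                b$n, b$n_dropped, b$lr$df, b$lr$statistic, b$lr$p_value))
    a <- b$ame
    cat(sprintf("  %-14s %9s %9s %7s\n", "term", "dy/dx", "dy/dx(%)", "z"))
    for (i in seq_len(nrow(a)))
      cat(sprintf("  %-14s %9.4f %9.2f %7.2f %s\n", a$term[i], a$dydx[i],
                  100 * a$dydx[i], a$z[i], a$stars[i]))
    cat("\n")
  }
  invisible(x)
}

#' Write a report to machine-readable CSV and formatted text
#'
#' @param report A `vep_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  rows <- list()
  for (nm in names(report)) {
    b <- report[[nm]]
    if (!is.null(b$error) || !is.null(b$per_term)) next
    co <- b$fit$coefficients
    a <- b$ame
    m <- merge(co, a[, c("term", "dydx", "se", "z")], by = "term",
               suffixes = c("", "_dydx"), all.x = TRUE)
    m$block <- nm
    rows[[nm]] <- m
  }
  if (length(rows)) {
    csv <- file.path(dir, "results.csv")
    utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
    paths <- c(paths, csv)
  }
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  sink(); on.exit()
  invisible(c(paths, txt))
}
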
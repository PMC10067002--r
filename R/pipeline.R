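#' End-to-end pipeline orchestration
#'
#' [run_pipeline()] executes the full analysis in order: simulate or
#' ingest the microdata, A-F scoring of physical and mental health
#' poverty, income-elasticity estimation and E_H assignment, FGLS
#' vulnerability estimation and binarization to the VEP outcome, the
#' regression table suite, and the inequality report.  Every stage
#' writes its artifact plus a manifest row (inputs, parameters, seed,
#' rows in/out) so the exclusion cascade that determines the analytic
#' sample is auditable.
#'
#' @name cli_io
NULL

#' Pipeline configuration
#'
#' @param gamma A-F poverty cutoff in (0, 1).
#' @param combine_rule How PHP and MHP statuses merge
#'   (see [combine_indices()]).
#' @param welfare_source `"af-score"` (log of one minus the combined
#'   deprivation score) or `"column:<name>"` to use an existing log
#'   welfare column.
#' @param ln_poverty_line Log poverty line; default matches the
#'   af-score welfare at cutoff `gamma`.
#' @param cutoff VEP binarization cutoff in (0, 1); 0.5 by default
#'   (0.29 is a common alternative convention).
#' @param elasticity_strategy,elasticity_strata,min_stratum_n Passed to
#'   [fit_elasticity()].
#' @param designs Regression designs for [run_table_suite()].
#' @param fixed_effects Fixed-effects column.
#' @param seed Master seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gamma = 0.30,
                            combine_rule = "either",
                            welfare_source = "af-score",
                            ln_poverty_line = NULL,
                            cutoff = 0.5,
                            elasticity_strategy = "stratified",
                            elasticity_strata = c("urban", "age_decile"),
                            min_stratum_n = 30L,
                            designs = c("table4", "table5", "table6",
                                        "table7", "table8"),
                            fixed_effects = "province",
                            seed = 1L) {
  assert_fraction(gamma, "gamma")
  assert_fraction(cutoff, "cutoff")
  if (is.null(ln_poverty_line)) ln_poverty_line <- log(1 - gamma + 1e-3)
  structure(list(gamma = gamma, combine_rule = combine_rule,
                 welfare_source = welfare_source,
                 ln_poverty_line = ln_poverty_line, cutoff = cutoff,
                 elasticity_strategy = elasticity_strategy,
                 elasticity_strata = elasticity_strata,
                 min_stratum_n = as.integer(min_stratum_n),
                 designs = designs, fixed_effects = fixed_effects,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as flat key-value text (DCF)
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- lapply(unclass(config), function(v)
    paste(vapply(v, function(x)
      if (is.numeric(x)) format(x, digits = 17) else as.character(x),
      character(1)), collapse = ","))
  write.dcf(as.data.frame(flat, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  m <- read.dcf(path)
  g <- function(nm) if (nm %in% colnames(m)) m[1, nm] else NULL
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  splt <- function(x) if (is.null(x)) NULL else trimws(strsplit(x, ",")[[1]])
  args <- list(gamma = num(g("gamma")), combine_rule = g("combine_rule"),
               welfare_source = g("welfare_source"),
               ln_poverty_line = num(g("ln_poverty_line")),
               cutoff = num(g("cutoff")),
               elasticity_strategy = g("elasticity_strategy"),
               elasticity_strata = splt(g("elasticity_strata")),
               min_stratum_n = num(g("min_stratum_n")),
               designs = splt(g("designs")),
               fixed_effects = g("fixed_effects"),
               seed = num(g("seed")))
  do.call(pipeline_config, args[!vapply(args, is.null, logical(1))])
}

#' Sample-determination accounting
#'
#' Applies a cascade of exclusion counts to a total sample size, the way
#' survey analyses report how the analytic n was determined.
#'
#' @param total Starting sample size.
#' @param exclusions Named or unnamed vector of exclusion counts applied
#'   in order.
#' @return List with the step-by-step `ledger` data frame and
#'   `analytic_n`.
#' @export
sample_accounting <- function(total, exclusions) {
  if (any(exclusions < 0)) stop_hv("exclusion counts must be nonnegative")
  remaining <- total - cumsum(exclusions)
  if (any(remaining < 0)) stop_hv("exclusions exceed the total")
  ledger <- data.frame(
    step = c("total", names(exclusions) %||% paste0("exclusion_",
                                                    seq_along(exclusions))),
    excluded = c(0, unname(exclusions)),
    remaining = c(total, remaining))
  list(ledger = ledger, analytic_n = unname(remaining[length(remaining)]))
}

#' Run the pipeline
#'
#' @param input Either a data frame of individual records, a path to a
#'   population CSV, or a [pop_config()] to simulate from.
#' @param out_dir Results directory (created).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the analysis `table`, the `af`,
#'   `elasticity`, `vep` stage outputs, the regression `report`, the
#'   `inequality` tables and the `manifest`.  Artifacts and
#'   `manifest.csv` are written under `out_dir`.
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, n_in, n_out, params = "") {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, rows_in = n_in, rows_out = n_out,
                 params = params, seed = config$seed)
  }

  # -- stage 1: simulate / ingest ------------------------------------
  if (inherits(input, "pop_config")) {
    tbl <- generate_population(input)
    note("simulate", 0L, nrow(tbl),
         sprintf("n=%d;seed=%d", input$n_individuals, input$seed))
  } else if (is.character(input)) {
    tbl <- read_population(input)
    note("ingest", NA, nrow(tbl), input)
  } else {
    tbl <- validate_population(input)
    note("ingest", nrow(input), nrow(tbl), "in-memory table")
  }
  write_population(tbl, file.path(out_dir, "population.csv"))

  # -- stage 2: A-F scoring ------------------------------------------
  specs <- builtin_specs()
  php <- score_and_classify(apply_deprivations(tbl, specs$php), specs$php,
                            config$gamma)
  mhp <- score_and_classify(apply_deprivations(tbl, specs$mhp), specs$mhp,
                            config$gamma)
  comb <- combine_indices(php, mhp, config$combine_rule, config$gamma)
  af <- data.frame(person_id = tbl$person_id,
                   php_score = php$weighted_score, php_poor = php$poor,
                   mhp_score = mhp$weighted_score, mhp_poor = mhp$poor,
                   combined_score = comb$weighted_score,
                   combined_poor = comb$poor)
  utils::write.csv(af, file.path(out_dir, "af_scores.csv"),
                   row.names = FALSE)
  note("af-score", nrow(tbl), nrow(af),
       sprintf("gamma=%g;rule=%s", config$gamma, config$combine_rule))

  # -- stage 3: elasticity (E_H feeds the welfare design) ------------
  emod <- fit_elasticity(tbl, config$elasticity_strategy,
                         config$elasticity_strata, config$min_stratum_n)
  tbl$eh <- as.numeric(assign_eh(tbl, emod))
  utils::write.csv(data.frame(person_id = tbl$person_id, eh = tbl$eh),
                   file.path(out_dir, "elasticity.csv"), row.names = FALSE)
  note("elasticity", nrow(tbl), nrow(tbl),
       sprintf("strategy=%s;strata=%s;excluded=%d", emod$strategy,
               emod$strata_definition, emod$n_excluded))

  # -- stage 4: VEP via three-stage FGLS -----------------------------
  ln_w <- if (identical(config$welfare_source, "af-score")) {
    af_welfare(af$combined_score)
  } else if (startsWith(config$welfare_source, "column:")) {
    tbl[[sub("^column:", "", config$welfare_source)]]
  } else stop_hv("unknown welfare_source '%s'", config$welfare_source)
  X <- welfare_design(tbl, tbl$eh)
  wm <- fit_welfare_fgls(ln_w, X)
  vul <- predict_vulnerability(wm, X, config$ln_poverty_line)
  tbl$vep <- binarize_vep(vul, config$cutoff)
  utils::write.csv(data.frame(person_id = tbl$person_id,
                              vulnerability = vul, vep_binary = tbl$vep),
                   file.path(out_dir, "vep.csv"), row.names = FALSE)
  note("vep", nrow(tbl), nrow(tbl),
       sprintf("source=%s;line=%.4f;cutoff=%g;floored=%d",
               config$welfare_source, config$ln_poverty_line,
               config$cutoff, wm$n_floored))

  # -- stage 5: regression suite -------------------------------------
  tbl$pm_s <- tbl$pm / 10
  report <- run_table_suite(tbl, outcome = "vep", eh_column = "eh",
                            fixed_effects = config$fixed_effects,
                            designs = config$designs)
  write_report(report, file.path(out_dir, "regressions"))
  note("fit", nrow(tbl), length(report),
       paste(config$designs, collapse = ","))

  # -- stage 6: inequality -------------------------------------------
  eii <- regional_gap_report(tbl, "income", "region")
  mii <- regional_gap_report(tbl, "pm", "region")
  ineq <- rbind(eii, mii)
  utils::write.csv(ineq, file.path(out_dir, "inequality.csv"),
                   row.names = FALSE)
  note("inequality", nrow(tbl), nrow(ineq), "value=income,pm;groups=region")

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(table = tbl, af = af, elasticity = emod,
                 welfare_model = wm, vulnerability = vul, report = report,
                 inequality = ineq, manifest = manifest))
}
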
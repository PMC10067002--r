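#' Synthetic survey microdata with known ground truth
#'
#' [generate_population()] draws individual-level records shaped like the
#' analytic sample of a Chinese household survey: demographics, log-normal
#' income with region- and urbanicity-specific parameters, annual health
#' expenditure generated from a log-log income link, physical- and
#' mental-health deprivation indicators driven by a latent propensity,
#' government-subsidy receipt, a 1-10 public-mechanism rating, a
#' heteroskedastic log-welfare outcome, and a binary vulnerability outcome
#' drawn from a logistic model with interaction effects.  Every structural
#' parameter is carried in the configuration so downstream estimators can
#' be validated against ground truth.
#'
#' @name synthetic_data
NULL

#' Welfare design matrix
#'
#' The covariate design shared by the welfare data-generating process and
#' the FGLS vulnerability stage.  Bounded codings keep every column in
#' \[0, 1\] so that any nonnegative variance-equation coefficient vector
#' with a positive intercept yields strictly positive variances.
#'
#' @param table Data frame of individual records.
#' @param eh Numeric vector of per-row income elasticities of health
#'   demand (the `E_H` variable).
#' @return Numeric matrix with columns `intercept`, `urban`, `gender`,
#'   `age01`, `edu01`, `fam01`, `lninc01`, `gs`, `pm01`, `eh`, `gs_eh`,
#'   `pm_eh`.
#' @export
welfare_design <- function(table, eh) {
  stopifnot(length(eh) == nrow(table))
  pm01 <- table$pm / 10
  cbind(intercept = rep(1, nrow(table)),
        urban = table$urban,
        gender = table$gender,
        age01 = (table$age - 16) / 80,
        edu01 = table$education / 22,
        fam01 = (table$family_size - 1) / 16,
        lninc01 = clip01((log(table$income) - 7) / 6),
        gs = table$gs,
        pm01 = pm01,
        eh = eh,
        gs_eh = table$gs * eh,
        pm_eh = pm01 * eh)
}

welfare_design_columns <- function() {
  c("intercept", "urban", "gender", "age01", "edu01", "fam01", "lninc01",
    "gs", "pm01", "eh", "gs_eh", "pm_eh")
}

# Calibrated intercepts (fixed once against the published sample means:
# binary vulnerability outcome mean 0.953 and subsidy-receipt rate 0.335,
# evaluated at n = 200,000 under the default configuration).
.VEP_INTERCEPT <- 9.4825
.GS_INTERCEPT <- -0.7797

#' Population configuration
#'
#' Defaults encode the analytic-sample structure of the study population:
#' n = 8831 with 5036 urban residents, regional shares 4259/2508/2064
#' (east/central/west), covariate means and ranges matching the published
#' descriptive table, a subsidy-receipt rate of 0.335, and a logistic
#' vulnerability outcome whose coefficient defaults are derived from the
#' published average marginal effects (sign pattern: GS -, PM -, E_H -,
#' GS:E_H +, PM:E_H -).
#'
#' @param n_individuals Number of records.
#' @param urban_share Fraction urban.
#' @param region_shares Named fractions for east/central/west; must sum
#'   to 1.
#' @param welfare_alpha Named mean-equation coefficients over
#'   [welfare_design()] columns.
#' @param welfare_beta Named nonnegative variance-equation coefficients
#'   over the same columns (positive intercept).
#' @param ln_poverty_line Log poverty line for the welfare outcome.
#' @param elasticity_true Global income elasticity of health demand used
#'   when `elasticity_stratified = FALSE`.
#' @param elasticity_profile Stratum slope rule
#'   `base + per_decile * (age decile - 1) + urban * urban_bonus`.
#' @param elasticity_stratified Whether expenditure slopes vary by
#'   urban x age-decile stratum (the default world) or are global.
#' @param expenditure Intercept, residual SD, and zero-spending rate of
#'   the log expenditure equation.
#' @param logit_coefs Named coefficients of the logistic vulnerability
#'   outcome (`pm` acts on the 0-1 rescaled rating).
#' @param gs_rate Target subsidy-receipt rate.
#' @param gs_link Slope of subsidy assignment on the standardized
#'   covariate-driven deprivation propensity.
#' @param income Log-income location/scale parameters by region and
#'   urbanicity.
#' @param indicator_base_rates Marginal deprivation base rates.
#' @param indicator_loadings Latent-propensity loadings by dimension.
#' @param frailty_sd SD of the shared within-person indicator frailty.
#' @param income_gradient Weight of (negative) standardized log income in
#'   the deprivation propensity.
#' @param pm_scale `"unit"` to analyse the rating rescaled to (0, 1\],
#'   `"raw"` for the 1-10 scale.
#' @param seed Master seed; all stage randomness derives from named
#'   substreams.
#' @return A `pop_config` list, validated.
#' @export
pop_config <- function(n_individuals = 8831,
                       urban_share = 5036 / 8831,
                       region_shares = c(east = 4259, central = 2508,
                                         west = 2064) / 8831,
                       welfare_alpha = NULL,
                       welfare_beta = NULL,
                       ln_poverty_line = log(1 - 0.30 + 1e-3),
                       elasticity_true = 0.417,
                       elasticity_profile = c(base = -0.11, per_decile = 0.11,
                                              urban = 0.05),
                       elasticity_stratified = TRUE,
                       expenditure = c(intercept = 2.25, sd = 0.3,
                                       zero_rate = 0.05),
                       logit_coefs = NULL,
                       gs_rate = 0.335,
                       gs_link = 0.8,
                       income = NULL,
                       indicator_base_rates = NULL,
                       indicator_loadings = c(need = 0.8, enabling = 0.3,
                                              predisposing = 0.3),
                       frailty_sd = 0.6,
                       income_gradient = 1.0,
                       pm_scale = c("unit", "raw"),
                       seed = 1L) {
  pm_scale <- match.arg(pm_scale)
  cols <- welfare_design_columns()
  if (is.null(welfare_alpha))
    welfare_alpha <- c(intercept = -0.60, urban = 0.02, gender = 0.01,
                       age01 = -0.10, edu01 = 0.15, fam01 = -0.08,
                       lninc01 = 0.45, gs = 0.087, pm01 = 0.007, eh = 0.393,
                       gs_eh = -0.1135, pm_eh = 0.1965)
  if (is.null(welfare_beta))
    welfare_beta <- c(intercept = 0.02, urban = 0.005, gender = 0,
                      age01 = 0.01, edu01 = 0, fam01 = 0.02, lninc01 = 0,
                      gs = 0.01, pm01 = 0, eh = 0, gs_eh = 0, pm_eh = 0)
  if (is.null(logit_coefs))
    logit_coefs <- c(intercept = .VEP_INTERCEPT,
                     gs = -1.74, pm = -0.14, eh = -7.87,
                     gs_eh = 2.27, pm_eh = -3.93,
                     gender = -0.26, age = 0.011, family_size = 0.475,
                     marriage = -0.42, education = -0.045,
                     job_satisfaction = -0.045, social_status = -0.022,
                     smoke = -0.016, drink = 0.11, exercise = -0.009,
                     patient_trust = -0.009, urban = -0.225)
  if (is.null(income))
    income <- list(base = 9.2,
                   region = c(east = 0.25, central = 0.05, west = -0.10),
                   urban_premium = c(east = 0.55, central = 0.40,
                                     west = 0.25),
                   sd_urban = c(east = 0.90, central = 0.85, west = 0.80),
                   sd_rural = c(east = 0.75, central = 0.75, west = 0.75))
  if (is.null(indicator_base_rates))
    indicator_base_rates <- c(
      insurance = 0.05, chronic = 0.28, bronchitis = 0.08, asthma = 0.04,
      hospitalized = 0.12, unwell = 0.35, weekend_break = 0.45,
      dep_depress = 0.25, dep_struggle = 0.30, dep_sleep = 0.30,
      dep_unpleasant = 0.25, dep_lonely = 0.22, dep_sad = 0.25,
      dep_difficulty = 0.28, dep_desire = 0.10, social_rel = 0.20)

  cfg <- list(n_individuals = n_individuals, urban_share = urban_share,
              region_shares = region_shares, welfare_alpha = welfare_alpha,
              welfare_beta = welfare_beta, ln_poverty_line = ln_poverty_line,
              elasticity_true = elasticity_true,
              elasticity_profile = elasticity_profile,
              elasticity_stratified = elasticity_stratified,
              expenditure = expenditure, logit_coefs = logit_coefs,
              gs_rate = gs_rate, gs_link = gs_link, income = income,
              indicator_base_rates = indicator_base_rates,
              indicator_loadings = indicator_loadings,
              frailty_sd = frailty_sd, income_gradient = income_gradient,
              pm_scale = pm_scale, seed = as.integer(seed))
  class(cfg) <- "pop_config"
  validate_pop_config(cfg)
}

validate_pop_config <- function(cfg) {
  if (!is.numeric(cfg$n_individuals) || length(cfg$n_individuals) != 1L ||
      cfg$n_individuals < 0 || cfg$n_individuals != round(cfg$n_individuals))
    stop_hv("n_individuals must be a nonnegative integer")
  assert_fraction(cfg$urban_share, "urban_share", closed_lo = TRUE,
                  closed_hi = TRUE)
  rs <- cfg$region_shares
  if (length(rs) != 3L || !setequal(names(rs), c("east", "central", "west")))
    stop_hv("region_shares must be named east/central/west")
  if (abs(sum(rs) - 1) > 1e-12 || any(rs < 0) || any(rs > 1))
    stop_hv("region_shares must lie in [0,1] and sum to 1")
  cols <- welfare_design_columns()
  for (nm in c("welfare_alpha", "welfare_beta"))
    if (!identical(names(cfg[[nm]]), cols))
      stop_hv("%s must be named over the welfare design columns", nm)
  if (any(cfg$welfare_beta < 0) || cfg$welfare_beta[["intercept"]] <= 0)
    stop_hv("welfare_beta must be nonnegative with a positive intercept")
  if (cfg$elasticity_true < 0) stop_hv("elasticity_true must be >= 0")
  cfg
}

# Age-decile x urbanicity elasticity slope (before the E_H >= 0 truncation
# applied at assignment time).
true_slope <- function(cfg, urban, age_decile) {
  if (!cfg$elasticity_stratified)
    return(rep(cfg$elasticity_true, length(urban)))
  p <- cfg$elasticity_profile
  p[["base"]] + p[["per_decile"]] * (age_decile - 1) + p[["urban"]] * urban
}

#' Generate a synthetic population
#'
#' @param config A [pop_config()].
#' @return Data frame of individual records including generator-only
#'   ground-truth columns (`eh_true`, `ln_welfare`, `true_vulnerability`,
#'   `true_vep_prob`, `vep`).  Deterministic given the config seed.
#' @export
generate_population <- function(config) {
  config <- validate_pop_config(config)
  n <- as.integer(config$n_individuals)
  if (n == 0L) {
    tmpl <- generate_population(modifyList2(config, n_individuals = 1L))
    return(tmpl[0L, , drop = FALSE])
  }

  # -- geography ------------------------------------------------------
  set.seed(substream_seed(config$seed, "geography"))
  region <- sample(c("east", "central", "west"), n, replace = TRUE,
                   prob = config$region_shares[c("east", "central", "west")])
  prov_pool <- list(east = sprintf("P%02d", 1:11),
                    central = sprintf("P%02d", 12:19),
                    west = sprintf("P%02d", 20:30))
  province <- vapply(region, function(r)
    prov_pool[[r]][sample.int(length(prov_pool[[r]]), 1L)], character(1))
  urban <- stats::rbinom(n, 1L, config$urban_share)

  # -- demographics (calibrated to the published means/SDs/ranges) ----
  set.seed(substream_seed(config$seed, "demographics"))
  gender <- stats::rbinom(n, 1L, 0.602)
  age <- round(rtruncnorm(n, 39.1, 12.1, 16, 96))
  family_size <- pmin(pmax(round(rtruncnorm(n, 3.9, 2.0, 1, 17)), 1L), 17L)
  marriage <- stats::rbinom(n, 1L, 0.803)
  education <- round(rtruncnorm(n, 10.5, 4.1, 0, 22))
  job_satisfaction <- round(rtruncnorm(n, 3.64, 0.86, 1, 5))
  social_status <- round(rtruncnorm(n, 2.92, 0.98, 1, 5))
  smoke <- stats::rbinom(n, 1L, 0.360)
  drink <- stats::rbinom(n, 1L, 0.174)
  exercise <- pmin(stats::rnbinom(n, size = 0.30, mu = 3.28), 50L)
  patient_trust <- round(rtruncnorm(n, 6.54, 2.29, 0, 10))

  # -- income ---------------------------------------------------------
  set.seed(substream_seed(config$seed, "income"))
  inc <- config$income
  mu <- inc$base + inc$region[region] +
    ifelse(urban == 1L, inc$urban_premium[region], 0)
  sdv <- ifelse(urban == 1L, inc$sd_urban[region], inc$sd_rural[region])
  ln_income <- stats::rnorm(n, mu, sdv)
  income <- exp(ln_income)
  z_lninc <- zscale(ln_income)

  # -- elasticity ground truth (urban x age-decile strata) ------------
  age_dec <- decile_of(age)
  slope <- true_slope(config, urban, age_dec)
  eh_true <- pmax(slope, 0)

  # -- health expenditure: ln Q = a0 + slope * ln I + eps -------------
  set.seed(substream_seed(config$seed, "expenditure"))
  ex <- config$expenditure
  ln_q <- ex[["intercept"]] + slope * ln_income +
    stats::rnorm(n, 0, ex[["sd"]])
  health_expenditure <- exp(ln_q)
  health_expenditure[stats::runif(n) < ex[["zero_rate"]]] <- 0

  # -- government subsidy: targets the covariate-driven deprivation
  #    propensity (observable covariates only, so downstream regressions
  #    remain consistent) -------------------------------------------
  cf <- config$logit_coefs
  cov_index <- cf[["gender"]] * gender + cf[["age"]] * age +
    cf[["family_size"]] * family_size + cf[["marriage"]] * marriage +
    cf[["education"]] * education +
    cf[["job_satisfaction"]] * job_satisfaction +
    cf[["social_status"]] * social_status + cf[["smoke"]] * smoke +
    cf[["drink"]] * drink + cf[["exercise"]] * exercise +
    cf[["patient_trust"]] * patient_trust + cf[["urban"]] * urban
  eta_cov <- zscale(cov_index - config$income_gradient * z_lninc)
  set.seed(substream_seed(config$seed, "subsidy"))
  gs <- stats::rbinom(n, 1L, stats::plogis(.GS_INTERCEPT +
                                             config$gs_link * eta_cov))

  # -- public mechanism rating (1-10 integer) -------------------------
  set.seed(substream_seed(config$seed, "mechanism"))
  pm <- round(rtruncnorm(n, 6.4, 2.3, 1, 10))
  pm_s <- pm / 10

  # -- vulnerability outcome: logistic with interactions --------------
  theta <- cf[["gs"]] * gs + cf[["pm"]] * pm_s + cf[["eh"]] * eh_true +
    cf[["gs_eh"]] * gs * eh_true + cf[["pm_eh"]] * pm_s * eh_true +
    cov_index
  true_vep_prob <- stats::plogis(cf[["intercept"]] + theta)
  set.seed(substream_seed(config$seed, "outcome"))
  vep <- stats::rbinom(n, 1L, true_vep_prob)

  # -- deprivation indicators ----------------------------------------
  eta_full <- zscale(theta - config$income_gradient * z_lninc)
  set.seed(substream_seed(config$seed, "indicators"))
  omega <- stats::rnorm(n, 0, config$frailty_sd)
  br <- config$indicator_base_rates
  lo <- config$indicator_loadings
  item_dim <- c(insurance = "enabling", chronic = "need", bronchitis = "need",
                asthma = "need", hospitalized = "need", unwell = "need",
                weekend_break = "predisposing",
                dep_depress = "need", dep_struggle = "need",
                dep_sleep = "need", dep_unpleasant = "need",
                dep_lonely = "need", dep_sad = "need", dep_difficulty = "need",
                dep_desire = "need", social_rel = "predisposing")
  depriv <- sapply(names(item_dim), function(it) {
    p <- stats::plogis(stats::qlogis(br[[it]]) +
                         lo[[item_dim[[it]]]] * (eta_full + omega))
    stats::rbinom(n, 1L, p)
  })
  if (n == 1L) depriv <- matrix(depriv, nrow = 1L,
                                dimnames = list(NULL, names(item_dim)))
  # raw survey codings: insurance / weekend break / social relationship
  # are "Yes" variables (deprivation = No); psychometric items carry 1-4
  # scores with 3-4 marking deprivation
  set.seed(substream_seed(config$seed, "scores"))
  psy_cols <- grep("^dep_", names(item_dim), value = TRUE)
  psy <- sapply(psy_cols, function(it)
    ifelse(depriv[, it] == 1L, 3L + stats::rbinom(n, 1L, 0.5),
           1L + stats::rbinom(n, 1L, 0.5)))
  if (n == 1L) psy <- matrix(psy, nrow = 1L, dimnames = list(NULL, psy_cols))

  # -- heteroskedastic log welfare ------------------------------------
  tbl0 <- data.frame(urban = urban, gender = gender, age = age,
                     education = education, family_size = family_size,
                     income = income, gs = gs, pm = pm)
  X <- welfare_design(tbl0, eh_true)
  v <- as.numeric(X %*% config$welfare_beta)
  if (any(v <= 0))
    stop_hv("variance positivity violated at row %d (X.beta = %g)",
            which(v <= 0)[1L], min(v))
  xa <- as.numeric(X %*% config$welfare_alpha)
  set.seed(substream_seed(config$seed, "welfare"))
  ln_welfare <- xa + stats::rnorm(n, 0, sqrt(v))
  true_vulnerability <- stats::pnorm((config$ln_poverty_line - xa) / sqrt(v))

  out <- data.frame(
    person_id = sprintf("id%06d", seq_len(n)),
    urban = urban, region = region, province = province, gender = gender,
    age = age, family_size = family_size, marriage = marriage,
    education = education, job_satisfaction = job_satisfaction,
    social_status = social_status, smoke = smoke, drink = drink,
    exercise = as.integer(exercise), patient_trust = patient_trust,
    income = income, health_expenditure = health_expenditure,
    gs = gs, pm = pm,
    insurance = 1L - depriv[, "insurance"],
    chronic = depriv[, "chronic"], bronchitis = depriv[, "bronchitis"],
    asthma = depriv[, "asthma"], hospitalized = depriv[, "hospitalized"],
    unwell = depriv[, "unwell"],
    weekend_break = 1L - depriv[, "weekend_break"],
    social_rel = 1L - depriv[, "social_rel"],
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(psy))
  out$eh_true <- eh_true
  out$ln_welfare <- ln_welfare
  out$true_vulnerability <- true_vulnerability
  out$true_vep_prob <- true_vep_prob
  out$vep <- vep
  rownames(out) <- NULL
  out
}

# modifyList for classed config lists, keeping validation.
modifyList2 <- function(cfg, ...) {
  out <- utils::modifyList(unclass(cfg), list(...))
  class(out) <- "pop_config"
  validate_pop_config(out)
}
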
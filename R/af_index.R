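#' Alkire-Foster identification of multidimensional health poverty
#'
#' The package measures physical-health poverty (PHP) and mental-health
#' poverty (MHP) with the three-step Alkire-Foster (A-F) method: (1) each
#' indicator is mapped to a binary deprivation, (2) deprivations are
#' combined into a weighted score \eqn{k = \sum_n w_n \varphi_n} with
#' \eqn{\sum_n w_n = 1}, and (3) a unit is identified as multidimensionally
#' poor when \eqn{k \ge \gamma} (boundary inclusive).  Indicator systems
#' are organized along the Andersen model of health-services utilization
#' into predisposing, enabling and need dimensions.
#'
#' @name af_index
NULL

#' Define a single A-F indicator
#'
#' @param name Indicator label.
#' @param column Name of the raw data column the indicator reads.
#' @param dimension One of `"predisposing"`, `"enabling"`, `"need"`.
#' @param weight Indicator weight in (0, 1].
#' @param rule Deprivation rule: `"identity"` (raw 1 means deprived),
#'   `"negate"` (raw 0/No means deprived), or `"score34"` (psychometric
#'   item scored 1-4; a score of 3 or 4 means deprived).
#' @return An object of class `indicator_spec`.
#' @export
indicator_spec <- function(name, column, dimension, weight,
                           rule = c("identity", "negate", "score34")) {
  dimension <- match.arg(dimension, c("predisposing", "enabling", "need"))
  rule <- match.arg(rule)
  assert_fraction(weight, "weight", closed_hi = TRUE)
  structure(list(name = name, column = column, dimension = dimension,
                 weight = weight, rule = rule),
            class = "indicator_spec")
}

validate_spec_list <- function(spec) {
  if (!length(spec) || !all(vapply(spec, inherits, logical(1), "indicator_spec")))
    stop_hv("`spec` must be a non-empty list of indicator_spec objects")
  w <- vapply(spec, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-12)
    stop_hv("indicator weights must sum to 1 (got %.15f)", sum(w))
  invisible(spec)
}

#' Built-in PHP and MHP indicator systems
#'
#' Returns the seven-indicator physical-health poverty (PHP) system and the
#' ten-indicator mental-health poverty (MHP) system, with equal weights
#' within each index (1/7 and 1/10).  PHP: lack of health-insurance access
#' (enabling), five illness/hospitalization need indicators, and lack of a
#' weekend break (predisposing).  MHP: lack of health-insurance access
#' (enabling), eight psychometric need items where a 1-4 score of 3-4
#' marks deprivation, and an unsatisfactory social relationship
#' (predisposing).
#'
#' @return A list with elements `php` (7 `indicator_spec`s) and
#'   `mhp` (10 `indicator_spec`s).
#' @export
#' @examples
#' specs <- builtin_specs()
#' length(specs$php)  # 7
#' length(specs$mhp)  # 10
builtin_specs <- function() {
  php <- list(
    indicator_spec("health insurance", "insurance", "enabling", 1 / 7, "negate"),
    indicator_spec("chronic illness", "chronic", "need", 1 / 7, "identity"),
    indicator_spec("bronchitis illness", "bronchitis", "need", 1 / 7, "identity"),
    indicator_spec("asthma illness", "asthma", "need", 1 / 7, "identity"),
    indicator_spec("hospitalization", "hospitalized", "need", 1 / 7, "identity"),
    indicator_spec("health status", "unwell", "need", 1 / 7, "identity"),
    indicator_spec("degree of work strain", "weekend_break", "predisposing",
                   1 / 7, "negate"))
  mhp_need <- c(depression = "dep_depress", struggle = "dep_struggle",
                `poor sleep` = "dep_sleep", unpleasantness = "dep_unpleasant",
                loneliness = "dep_lonely", sadness = "dep_sad",
                difficulty = "dep_difficulty",
                `loss of desire to live` = "dep_desire")
  mhp <- c(
    list(indicator_spec("health insurance", "insurance", "enabling", 1 / 10,
                        "negate")),
    unname(Map(function(nm, col)
      indicator_spec(paste("degree of", nm), col, "need", 1 / 10, "score34"),
      names(mhp_need), mhp_need)),
    list(indicator_spec("satisfactory social relationship", "social_rel",
                        "predisposing", 1 / 10, "negate")))
  list(php = validate_spec_list(php), mhp = validate_spec_list(mhp))
}

apply_rule <- function(raw, rule, name) {
  if (anyNA(raw)) stop_hv("indicator '%s': raw values contain NA", name)
  switch(rule,
    identity = ,
    negate = {
      if (!all(raw %in% c(0, 1)))
        stop_hv("indicator '%s': raw values must be 0/1", name)
      if (rule == "negate") 1L - as.integer(raw) else as.integer(raw)
    },
    score34 = {
      if (!all(raw %in% 1:4))
        stop_hv("indicator '%s': psychometric scores must be integers in 1-4",
                name)
      as.integer(raw >= 3)
    })
}

#' Map raw survey responses to binary deprivations
#'
#' @param table Data frame of individual records supplying every raw column
#'   named by `spec`.
#' @param spec List of [indicator_spec()] objects.
#' @return Integer matrix (rows = records, one column per indicator) of
#'   0/1 deprivations.
#' @export
apply_deprivations <- function(table, spec) {
  validate_spec_list(spec)
  cols <- vapply(spec, `[[`, character(1), "column")
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    bad <- vapply(spec[match(missing, cols)], `[[`, character(1), "name")
    stop_hv("missing raw field(s) for indicator(s): %s",
            paste(bad, collapse = ", "))
  }
  out <- vapply(spec, function(s)
    apply_rule(table[[s$column]], s$rule, s$name), integer(nrow(table)))
  if (nrow(table) == 1L) out <- matrix(out, nrow = 1L)
  if (nrow(table) == 0L) out <- matrix(integer(0), nrow = 0L, ncol = length(spec))
  colnames(out) <- vapply(spec, `[[`, character(1), "name")
  out
}

#' Score deprivation vectors and identify the poor
#'
#' Computes the weighted deprivation score \eqn{k = \sum w_n \varphi_n} and
#' identifies a unit as poor when \eqn{k \ge \gamma} (boundary inclusive).
#'
#' @param indicator_values Binary matrix from [apply_deprivations()] (or a
#'   single 0/1 vector).
#' @param spec List of [indicator_spec()]s matching the columns.
#' @param gamma Poverty cutoff in (0, 1]; default 0.30 (equivalent, for
#'   seven equally weighted indicators, to deprivation in three or more).
#' @return Data frame with columns `weighted_score` and `poor`.
#' @export
score_and_classify <- function(indicator_values, spec, gamma = 0.30) {
  validate_spec_list(spec)
  assert_fraction(gamma, "gamma", closed_hi = TRUE)
  if (is.vector(indicator_values))
    indicator_values <- matrix(indicator_values, nrow = 1L)
  if (ncol(indicator_values) != length(spec))
    stop_hv("indicator_values has %d columns but spec has %d indicators",
            ncol(indicator_values), length(spec))
  if (length(indicator_values) && !all(indicator_values %in% c(0, 1)))
    stop_hv("indicator_values must be 0/1")
  w <- vapply(spec, `[[`, numeric(1), "weight")
  score <- as.numeric(indicator_values %*% w)
  data.frame(weighted_score = score, poor = as.integer(score >= gamma))
}

#' Aggregate deprivation profiles
#'
#' Standard A-F aggregates: the headcount ratio H (share poor), the mean
#' intensity A among the poor (NA when no one is poor), and the adjusted
#' headcount M0 = H x A (0 when no one is poor).
#'
#' @param profiles Data frame with `weighted_score` and `poor` columns as
#'   returned by [score_and_classify()].
#' @return Named list: `headcount_ratio`, `mean_intensity_among_poor`,
#'   `adjusted_headcount`.
#' @export
af_aggregate <- function(profiles) {
  if (!nrow(profiles)) stop_hv("empty profile list")
  h <- mean(profiles$poor)
  a <- if (any(profiles$poor == 1))
    mean(profiles$weighted_score[profiles$poor == 1]) else NA_real_
  list(headcount_ratio = h,
       mean_intensity_among_poor = a,
       adjusted_headcount = if (is.na(a)) 0 else h * a)
}

#' Minimum deprivation count implying poverty under equal weights
#'
#' For an equally weighted indicator system, the smallest number of
#' deprivations that identifies a unit as poor at cutoff `gamma`, found by
#' scoring each candidate count through [score_and_classify()].
#'
#' @param spec Equal-weight indicator list.
#' @inheritParams score_and_classify
#' @return Integer count.
#' @export
min_deprivation_count <- function(spec, gamma = 0.30) {
  validate_spec_list(spec)
  w <- vapply(spec, `[[`, numeric(1), "weight")
  if (diff(range(w)) > 1e-12)
    stop_hv("min_deprivation_count is defined for equal-weight systems only")
  m <- length(spec)
  for (cnt in 0:m) {
    v <- c(rep(1L, cnt), rep(0L, m - cnt))
    if (score_and_classify(v, spec, gamma)$poor == 1L) return(cnt)
  }
  m + 1L  # unreachable for gamma <= 1
}

#' Combine PHP and MHP into a joint health-poverty status
#'
#' The joint physical-and-mental status used as the welfare input of the
#' vulnerability stage.  The combined weighted score pools the 7 PHP and
#' 10 MHP indicators in proportion to their counts:
#' \eqn{k = (7 k_{PHP} + 10 k_{MHP}) / 17}.  The combined poverty status
#' follows `rule`: poor in either index (default), poor in both, or
#' combined score at least `gamma` (`"score-union"`).
#'
#' @param php,mhp Data frames from [score_and_classify()] for each index.
#' @param rule Combination rule.
#' @param gamma Cutoff used by the `"score-union"` rule.
#' @return Data frame with `weighted_score` and `poor`.
#' @export
combine_indices <- function(php, mhp, rule = c("either", "both", "score-union"),
                            gamma = 0.30) {
  rule <- match.arg(rule)
  if (nrow(php) != nrow(mhp)) stop_hv("php and mhp profiles differ in length")
  score <- (7 * php$weighted_score + 10 * mhp$weighted_score) / 17
  poor <- switch(rule,
    either = as.integer(php$poor | mhp$poor),
    both = as.integer(php$poor & mhp$poor),
    `score-union` = as.integer(score >= gamma))
  data.frame(weighted_score = score, poor = poor)
}

#' Serialize / deserialize indicator systems
#'
#' Indicator systems round-trip through a plain-text DCF file so users can
#' define alternative indices.
#'
#' @param spec List of [indicator_spec()]s.
#' @param path File path.
#' @return `read_spec_file()` returns the indicator list.
#' @export
write_spec_file <- function(spec, path) {
  validate_spec_list(spec)
  df <- do.call(rbind, lapply(spec, function(s)
    data.frame(name = s$name, column = s$column, dimension = s$dimension,
               weight = format(s$weight, digits = 17), rule = s$rule)))
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_spec_file
#' @export
read_spec_file <- function(path) {
  m <- read.dcf(path)
  spec <- lapply(seq_len(nrow(m)), function(i)
    indicator_spec(unname(m[i, "name"]), unname(m[i, "column"]),
                   unname(m[i, "dimension"]),
                   as.numeric(m[i, "weight"]), unname(m[i, "rule"])))
  validate_spec_list(spec)
}
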
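#' Inequality indices
#'
#' Urban-rural economic and public-health-service gaps are contrasted
#' with two scale-invariant indices: the coefficient of variation
#' (sample SD over mean) and the Theil T entropy index
#' \eqn{T = \sum_i (x_i / \sum x) \ln(x_i / \mu)}.  Both are zero exactly
#' when the input is constant and are invariant to multiplying all
#' values by a positive constant.
#'
#' @name inequality
NULL

check_positive <- function(values, what) {
  if (!length(values)) stop_hv("%s: empty input", what)
  if (any(!is.finite(values)) || any(values <= 0))
    stop_hv("%s requires strictly positive values", what)
  invisible(values)
}

#' @param values Strictly positive numeric vector.
#' @return Nonnegative scalar.
#' @rdname inequality
#' @export
coefficient_of_variation <- function(values) {
  check_positive(values, "coefficient_of_variation")
  if (length(values) == 1L) return(0)
  stats::sd(values) / mean(values)
}

#' @rdname inequality
#' @export
theil_t <- function(values) {
  check_positive(values, "theil_t")
  s <- values / sum(values)
  sum(s * log(values / mean(values)))
}

#' Urban-rural inequality gap report
#'
#' For each level of each grouping column, computes both indices on the
#' value column within the urban and rural subsets and their
#' urban-minus-rural gap.  Groups where either subset has fewer than two
#' observations are flagged missing and skipped without aborting.
#'
#' @param table Data frame with an `urban` column, the grouping columns
#'   and the value column.
#' @param value_column Column to measure (e.g. `income` for the economic
#'   inequality index, `pm` for the public-health-service index).
#' @param group_columns Grouping columns (default region and province).
#' @return Data frame: grouping, group, index_name, urban, rural, gap,
#'   missing flag.
#' @export
regional_gap_report <- function(table, value_column,
                                group_columns = c("region", "province")) {
  for (nm in c(value_column, group_columns, "urban"))
    if (!nm %in% names(table)) stop_hv("column '%s' not in table", nm)
  out <- list()
  for (g in group_columns) {
    for (lev in sort(unique(table[[g]]))) {
      sub <- table[table[[g]] == lev, , drop = FALSE]
      u <- sub[[value_column]][sub$urban == 1]
      r <- sub[[value_column]][sub$urban == 0]
      for (idx in c("cv", "theil_t")) {
        fn <- if (idx == "cv") coefficient_of_variation else theil_t
        if (length(u) < 2L || length(r) < 2L) {
          out[[length(out) + 1L]] <-
            data.frame(grouping = g, group = lev, index_name = idx,
                       input_variable = value_column, urban = NA_real_,
                       rural = NA_real_, gap = NA_real_, missing = TRUE)
        } else {
          vu <- fn(u); vr <- fn(r)
          out[[length(out) + 1L]] <-
            data.frame(grouping = g, group = lev, index_name = idx,
                       input_variable = value_column, urban = vu,
                       rural = vr, gap = vu - vr, missing = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
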
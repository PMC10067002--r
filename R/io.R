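#' Read and write individual-record tables
#'
#' Tables are UTF-8, comma-separated CSV with a header row and "." decimal
#' marks.  [write_population()] serializes numeric columns at full
#' precision so that a write/read round trip reproduces the table exactly;
#' [read_population()] validates the schema and the documented value
#' ranges and reports the offending column or row on failure.
#'
#' @name population_io
NULL

# column -> c(lo, hi) closed range; NA bound = unbounded on that side
population_ranges <- function() {
  list(urban = c(0, 1), gender = c(0, 1), age = c(16, 96),
       family_size = c(1, 17), marriage = c(0, 1), education = c(0, 22),
       job_satisfaction = c(1, 5), social_status = c(1, 5),
       smoke = c(0, 1), drink = c(0, 1), exercise = c(0, 50),
       patient_trust = c(0, 10), income = c(NA, NA),
       health_expenditure = c(0, NA), gs = c(0, 1), pm = c(1, 10),
       insurance = c(0, 1), chronic = c(0, 1), bronchitis = c(0, 1),
       asthma = c(0, 1), hospitalized = c(0, 1), unwell = c(0, 1),
       weekend_break = c(0, 1), social_rel = c(0, 1),
       dep_depress = c(1, 4), dep_struggle = c(1, 4), dep_sleep = c(1, 4),
       dep_unpleasant = c(1, 4), dep_lonely = c(1, 4), dep_sad = c(1, 4),
       dep_difficulty = c(1, 4), dep_desire = c(1, 4))
}

required_population_columns <- function() {
  c("person_id", "region", "province", names(population_ranges()))
}

#' @param records Data frame of individual records.
#' @param path File path.
#' @rdname population_io
#' @export
write_population <- function(records, path) {
  out <- records
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname population_io
#' @export
read_population <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  validate_population(tbl)
}

#' @rdname population_io
#' @export
validate_population <- function(tbl) {
  missing <- setdiff(setdiff(required_population_columns(),
                             c("person_id")),  # ids optional on ingest
                     names(tbl))
  if (length(missing))
    stop_hv("schema error: missing required column(s): %s",
            paste(missing, collapse = ", "))
  if (!("person_id" %in% names(tbl)))
    tbl$person_id <- sprintf("id%06d", seq_len(nrow(tbl)))
  if (nrow(tbl)) {
    bad_region <- which(!(tbl$region %in% c("east", "central", "west")))
    if (length(bad_region))
      stop_hv("validation error: row %d: region '%s' not in east/central/west",
              bad_region[1L], tbl$region[bad_region[1L]])
    if (any(!is.finite(tbl$income)) || any(tbl$income <= 0))
      stop_hv("validation error: row %d: income must be strictly positive",
              which(!is.finite(tbl$income) | tbl$income <= 0)[1L])
    for (nm in names(population_ranges())) {
      r <- population_ranges()[[nm]]
      x <- tbl[[nm]]
      if (anyNA(x))
        stop_hv("validation error: row %d: %s is missing",
                which(is.na(x))[1L], nm)
      bad <- which((!is.na(r[1]) & x < r[1]) | (!is.na(r[2]) & x > r[2]))
      if (length(bad))
        stop_hv("validation error: row %d: %s = %s outside range %s-%s",
                bad[1L], nm, format(x[bad[1L]]),
                format(r[1]), format(r[2]))
    }
  }
  tbl
}
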
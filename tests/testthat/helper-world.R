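# Shared fixtures, built in code at load time.

# a small generated population reused by read-only tests
small_pop <- generate_population(pop_config(n_individuals = 4000, seed = 11))

# a hand-built record with no deprivations at all
clean_record <- function() {
  data.frame(insurance = 1L, chronic = 0L, bronchitis = 0L, asthma = 0L,
             hospitalized = 0L, unwell = 0L, weekend_break = 1L,
             dep_depress = 1L, dep_struggle = 1L, dep_sleep = 2L,
             dep_unpleasant = 1L, dep_lonely = 2L, dep_sad = 1L,
             dep_difficulty = 1L, dep_desire = 1L, social_rel = 1L)
}

# brute-force A-F scoring oracle: explicit loop over indicators
af_oracle <- function(values, weights, gamma) {
  stopifnot(length(values) == length(weights))
  k <- 0
  for (i in seq_along(values)) k <- k + unname(weights[i] * values[i])
  list(score = k, poor = as.integer(k >= gamma))
}

# brute-force Theil T oracle
theil_oracle <- function(x) {
  tot <- sum(x); mu <- mean(x); out <- 0
  for (v in x) out <- out + (v / tot) * log(v / mu)
  out
}

# default second-layer regression spec used across logit tests
default_spec2 <- function(outcome = "vep") {
  regression_spec(outcome,
                  c("gs", "pm_s", "gender", "age", "family_size", "marriage",
                    "education", "job_satisfaction", "social_status", "smoke",
                    "drink", "exercise", "patient_trust", "urban"),
                  second_layer = TRUE, eh_column = "eh",
                  interactions = c("gs", "pm_s"), fixed_effects = "province")
}
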
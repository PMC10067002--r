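test_that("config invariants are enforced", {
  expect_error(pop_config(n_individuals = -1), "nonnegative")
  expect_error(pop_config(region_shares = c(east = 0.5, central = 0.5,
                                            west = 0.5)), "sum to 1")
  bad_beta <- pop_config()$welfare_beta
  bad_beta[["gs"]] <- -0.1
  expect_error(pop_config(welfare_beta = bad_beta), "nonnegative")
})

test_that("n = 0 yields an empty table with the full header", {
  empty <- generate_population(pop_config(n_individuals = 0))
  expect_identical(nrow(empty), 0L)
  expect_true(all(required_population_columns() %in% names(empty)))
  expect_true(all(c("eh_true", "ln_welfare", "true_vulnerability", "vep")
                  %in% names(empty)))
})

test_that("generation is deterministic given the seed", {
  a <- generate_population(pop_config(n_individuals = 300, seed = 99))
  b <- generate_population(pop_config(n_individuals = 300, seed = 99))
  expect_identical(a, b)
  c <- generate_population(pop_config(n_individuals = 300, seed = 100))
  expect_false(identical(a, c))
})

test_that("generated fields respect the documented ranges", {
  pop <- small_pop
  expect_true(all(pop$age >= 16 & pop$age <= 96))
  expect_true(all(pop$family_size >= 1 & pop$family_size <= 17))
  expect_true(all(pop$education >= 0 & pop$education <= 22))
  expect_true(all(pop$pm %in% 1:10))
  expect_true(all(pop$income > 0))
  expect_true(all(pop$health_expenditure >= 0))
  expect_true(all(pop$exercise >= 0 & pop$exercise <= 50))
  expect_true(all(as.matrix(pop[, grep("^dep_", names(pop))]) %in% 1:4))
  expect_true(all(pop$region %in% c("east", "central", "west")))
  expect_true(all(pop$true_vulnerability >= 0 & pop$true_vulnerability <= 1))
  # no validation complaints on the generator's own output
  expect_silent(validate_population(pop))
})

test_that("welfare noise variance tracks X beta within strata", {
  cfg <- pop_config(n_individuals = 50000, seed = 21)
  pop <- generate_population(cfg)
  X <- welfare_design(pop, pop$eh_true)
  e <- pop$ln_welfare - as.numeric(X %*% cfg$welfare_alpha)
  v_true <- as.numeric(X %*% cfg$welfare_beta)
  strat <- interaction(pop$urban, pop$gs, pop$gender)
  for (s in levels(strat)) {
    idx <- strat == s
    if (sum(idx) < 1000) next
    expect_lt(abs(var(e[idx]) / mean(v_true[idx]) - 1), 0.05)
  }
})

test_that("expenditure obeys the log-log income link", {
  cfg <- pop_config(n_individuals = 20000, seed = 31,
                    elasticity_stratified = FALSE)
  pop <- generate_population(cfg)
  keep <- pop$health_expenditure > 0
  fit <- fit_loglog(log(pop$health_expenditure[keep]),
                    log(pop$income[keep]))
  expect_lt(abs(fit$beta_h - cfg$elasticity_true), 0.02)
})

test_that("tables round-trip through CSV exactly", {
  pop <- small_pop[1:100, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back, pop, ignore_attr = TRUE)
  expect_identical(back$income, pop$income)  # full double precision
})

test_that("schema and range validation report the offending field", {
  pop <- small_pop[1:20, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop[, setdiff(names(pop), "income")], path)
  expect_error(read_population(path), "income")
  bad <- pop
  bad$age[3] <- 120
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_population(bad, path2)
  expect_error(read_population(path2), "row 3.*age.*16-96")
})
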
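test_that("log-log fit handles identity, constants and degeneracy", {
  i <- log(c(100, 200, 400, 800, 1600))
  fit <- fit_loglog(i, i)  # Q = I exactly
  expect_equal(fit$beta_h, 1, tolerance = 1e-12)
  expect_equal(fit$alpha, 0, tolerance = 1e-12)
  fitc <- fit_loglog(rep(2, 5), i)  # Q constant
  expect_equal(fitc$beta_h, 0, tolerance = 1e-12)
  expect_error(fit_loglog(i, rep(1, 5)), "zero variance")
  expect_error(fit_loglog(i[1:2], i[1:2]), "at least 3")
})

test_that("a known slope is recovered from noisy data", {
  set.seed(23)
  ln_i <- rnorm(10000, 9, 0.8)
  ln_q <- 2 + 0.5 * ln_i + rnorm(10000, 0, 0.3)
  fit <- fit_loglog(ln_q, ln_i)
  expect_lt(abs(fit$beta_h - 0.5), 0.02)
  expect_gt(fit$se_beta, 0)
})

test_that("elasticities are invariant to currency rescaling", {
  pop <- small_pop
  keep <- pop$health_expenditure > 0
  f1 <- fit_loglog(log(pop$health_expenditure[keep]), log(pop$income[keep]))
  f2 <- fit_loglog(log(pop$health_expenditure[keep] * 6.9),
                   log(pop$income[keep] * 6.9))
  expect_lt(abs(f1$beta_h - f2$beta_h), 1e-10)
  m1 <- fit_elasticity(pop)
  pop2 <- pop
  pop2$income <- pop2$income * 3.5
  pop2$health_expenditure <- pop2$health_expenditure * 3.5
  m2 <- fit_elasticity(pop2)
  expect_equal(m1$beta_by_stratum, m2$beta_by_stratum, tolerance = 1e-8)
})

test_that("global and stratified fits agree under a common true slope", {
  cfg <- pop_config(n_individuals = 20000, seed = 41,
                    elasticity_stratified = FALSE)
  pop <- generate_population(cfg)
  g <- fit_elasticity(pop, "global")
  s <- fit_elasticity(pop, "stratified")
  # every stratum slope within ~2 MC SEs of the global one
  expect_true(all(abs(s$beta_by_stratum - g$pooled$beta_h) <=
                    2.5 * s$se_by_stratum + 0.01))
})

test_that("assignment truncates at zero and falls back for small strata", {
  # two urban strata with known slopes, one negative
  set.seed(7)
  n <- 400
  tbl <- data.frame(urban = rep(c(0L, 1L), each = n),
                    income = exp(rnorm(2 * n, 9, 0.8)))
  ln_i <- log(tbl$income)
  slope <- ifelse(tbl$urban == 1, 0.5, -0.1)
  tbl$health_expenditure <- exp(1 + slope * ln_i + rnorm(2 * n, 0, 0.1))
  mdl <- fit_elasticity(tbl, "stratified", strata = "urban")
  eh <- assign_eh(tbl, mdl)
  expect_true(all(eh >= 0))
  expect_true(all(eh[tbl$urban == 0] == 0))  # negative slope truncated
  expect_lt(abs(mean(eh[tbl$urban == 1]) - 0.5), 0.05)

  mdl_small <- fit_elasticity(tbl, "stratified", strata = "urban",
                              min_n = 1000L)
  expect_warning(eh2 <- assign_eh(tbl, mdl_small), "pooled")
  expect_true(all(eh2 == max(mdl_small$pooled$beta_h, 0)))

  g <- fit_elasticity(tbl, "global")
  ehg <- assign_eh(tbl, g)
  expect_true(all(ehg == ehg[1]))  # constant assignment
})

test_that("stratified slopes recover the generator's stratum truths", {
  cfg <- pop_config(n_individuals = 20000, seed = 43)
  pop <- generate_population(cfg)
  mdl <- fit_elasticity(pop)
  dec <- healthvep:::decile_of(pop$age[pop$health_expenditure > 0 &
                                         pop$income > 0])
  sub <- pop[pop$health_expenditure > 0 & pop$income > 0, ]
  lab <- healthvep:::stratum_labels(sub, c("urban", "age_decile"))
  tru <- tapply(healthvep:::true_slope(cfg, sub$urban,
                                       healthvep:::decile_of(sub$age)),
                lab, mean)
  err <- mdl$beta_by_stratum[names(tru)] - tru
  expect_lt(max(abs(err)), 0.08)  # looser than the 50k acceptance bound
})
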
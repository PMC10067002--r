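test_that("design construction builds interactions, dummies and subgroups", {
  tbl <- data.frame(y = c(0L, 1L, 1L, 0L), gs = c(0, 1, 1, 0),
                    eh = c(0.2, 0.5, 0.0, 0.3),
                    province = c("P01", "P01", "P02", "P02"))
  spec <- regression_spec("y", "gs", second_layer = TRUE, eh_column = "eh",
                          interactions = "gs", fixed_effects = "province")
  d <- build_design(tbl, spec)
  expect_equal(unname(d$X[, "gs:eh"]), c(0, 0.5, 0, 0))
  expect_equal(sum(grepl("^province", colnames(d$X))), 1L)  # 2 levels -> 1

  # 30 balanced province levels with a mixed outcome -> 29 dummy columns
  tbl30 <- data.frame(y = rep(c(0L, 1L, 0L, 1L), times = 30),
                      gs = rep(c(0, 1), 60),
                      province = rep(sprintf("P%02d", 1:30), each = 4))
  d30 <- build_design(tbl30, regression_spec("y", "gs",
                                             fixed_effects = "province"))
  expect_equal(sum(grepl("^province", colnames(d30$X))), 29L)

  pop <- small_pop
  pop$pm_s <- pop$pm / 10
  pop$eh <- pop$eh_true
  spec_u <- regression_spec("vep", c("gs", "pm_s"), subgroup = list(urban = 1))
  expect_equal(build_design(pop, spec_u)$X |> nrow(), sum(pop$urban == 1))
  expect_error(build_design(pop, regression_spec("vep", "gs",
                                                 subgroup = list(urban = 7))),
               "empty subgroup")
  pop$const <- 1L
  expect_error(build_design(pop, regression_spec("const", "gs")),
               "constant outcome")
  expect_error(regression_spec("y", "gs", interactions = "gs"),
               "second-layer")
})

test_that("IRLS matches glm and the 2x2 closed form", {
  set.seed(12)
  n <- 1200
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 1.2 * x2))
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  f <- fit_logit(X, y)
  g <- stats::glm(y ~ x1 + x2, family = binomial)
  expect_lt(max(abs(f$coefficients$estimate - unname(coef(g)))), 1e-6)
  expect_lt(max(abs(f$coefficients$se - unname(sqrt(diag(vcov(g)))))), 1e-4)
  expect_equal(f$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-8)

  # printed 2x2 counts: beta equals the log odds ratio
  y2 <- c(rep(1, 40), rep(0, 60), rep(1, 60), rep(0, 40))
  x <- rep(c(0, 1), each = 100)
  f2 <- fit_logit(cbind(`(Intercept)` = 1, x = x), y2)
  expect_equal(f2$coefficients$estimate[2], log(2.25), tolerance = 1e-8)
})

test_that("separation and collinearity are detected", {
  x <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logit(cbind(i = 1, x = x), x), "separation.*x")
  set.seed(3)
  X <- cbind(i = 1, a = rnorm(40))
  X <- cbind(X, a2 = 2 * X[, "a"])
  f <- fit_logit(X, rbinom(40, 1, 0.5))
  expect_true("a2" %in% f$dropped_columns)
})

test_that("marginal effects match analytic and numerical oracles", {
  set.seed(15)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 1.2 * x2 + 0.5 * x1 * x2))
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, `x2:x1` = x2 * x1)
  f <- fit_logit(list(X = X, y = y, fe_levels = 0L,
                      interaction_map = list(`x2:x1` = c(parent = "x2",
                                                         modifier = "x1"))))
  me <- marginal_effects(f)
  b <- stats::setNames(f$coefficients$estimate, f$coefficients$term)
  pfun <- function(v1, v2)
    plogis(b[["(Intercept)"]] + b[["x1"]] * v1 + b[["x2"]] * v2 +
             b[["x2:x1"]] * v2 * v1)
  h <- 1e-6
  num <- mean((pfun(x1 + h, x2) - pfun(x1 - h, x2)) / (2 * h))
  expect_equal(me$dydx[me$term == "x1"], num, tolerance = 1e-6)
  # binary parent of an interaction: brute-force predict-and-difference
  expect_equal(me$dydx[me$term == "x2"], mean(pfun(x1, 1) - pfun(x1, 0)),
               tolerance = 1e-10)
  expect_true(me$discrete[me$term == "x2"])

  # continuous term without interactions: dydx == mean(p(1-p)) * beta
  f3 <- fit_logit(cbind(`(Intercept)` = 1, x1 = x1), y)
  me3 <- marginal_effects(f3)
  p3 <- f3$fitted
  expect_equal(me3$dydx, mean(p3 * (1 - p3)) * f3$coefficients$estimate[2],
               tolerance = 1e-10)

  # a zero coefficient gives a zero marginal effect
  fz <- f3
  fz$coefficients$estimate[2] <- 0
  fz$fitted <- plogis(fz$X %*% fz$coefficients$estimate)[, 1]
  expect_equal(marginal_effects(fz)$dydx, 0)
  expect_error(marginal_effects(f3, "ghost"), "absent")
})

test_that("Wald machinery: 1-df identity and error on singular blocks", {
  set.seed(19)
  n <- 800
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.4 * x))
  f <- fit_logit(cbind(`(Intercept)` = 1, x = x), y)
  w <- wald_joint(f, "x")
  expect_equal(w$statistic, f$coefficients$z[2]^2, tolerance = 1e-10)
  expect_equal(w$df, 1L)
  expect_error(wald_joint(f, "nope"), "absent")
  lr <- lr_test_null(f)
  expect_gt(lr$statistic, 0)
  expect_equal(lr$df, 1L)
})

test_that("the table suite returns all result blocks with bookkeeping", {
  pop <- small_pop
  pop$pm_s <- pop$pm / 10
  pop$eh <- pop$eh_true
  rep_ <- run_table_suite(pop)
  expect_s3_class(rep_, "vep_report")
  expect_setequal(names(rep_),
                  c("table4", "table5", "table6", "table7_urban",
                    "table7_rural", "table8_east", "table8_central",
                    "table8_west"))
  expect_null(rep_$table4$error)
  expect_true(all(c("dydx", "z", "stars") %in% names(rep_$table4$ame)))
  # exhaustive splits partition the full sample (counting rows set aside
  # in constant-outcome fixed-effect groups)
  used <- function(b) b$n + b$n_dropped + b$n_dropped_separated
  expect_equal(used(rep_$table7_urban) + used(rep_$table7_rural), nrow(pop))
  expect_equal(used(rep_$table8_east) + used(rep_$table8_central) +
                 used(rep_$table8_west), nrow(pop))
  expect_equal(used(rep_$table6), nrow(pop))
  expect_named(rep_$table5$per_term, c("gs:eh", "pm_s:eh"))
  expect_equal(rep_$table5$joint$df, 2L)
  # a failed subgroup is recorded, not fatal
  pop_bad <- pop[pop$region != "west", ]
  rep_bad <- run_table_suite(pop_bad, designs = c("table4", "table8"))
  expect_match(rep_bad$table8_west$error, "empty subgroup")
  expect_null(rep_bad$table4$error)
})
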
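test_that("builtin indicator systems have the documented structure", {
  specs <- builtin_specs()
  expect_length(specs$php, 7L)
  expect_length(specs$mhp, 10L)
  expect_true(all(vapply(specs$php, `[[`, numeric(1), "weight") == 1 / 7))
  expect_true(all(vapply(specs$mhp, `[[`, numeric(1), "weight") == 1 / 10))
  expect_equal(sum(vapply(specs$php, `[[`, numeric(1), "weight")), 1)
  expect_equal(sum(vapply(specs$mhp, `[[`, numeric(1), "weight")), 1)
  dims_php <- table(vapply(specs$php, `[[`, character(1), "dimension"))
  expect_equal(unname(dims_php[c("enabling", "need", "predisposing")]),
               c(1L, 5L, 1L), ignore_attr = TRUE)
  dims_mhp <- table(vapply(specs$mhp, `[[`, character(1), "dimension"))
  expect_equal(unname(dims_mhp[c("enabling", "need", "predisposing")]),
               c(1L, 8L, 1L), ignore_attr = TRUE)
})

test_that("deprivation rules follow the indicator tables", {
  specs <- builtin_specs()
  rec <- clean_record()
  expect_equal(unname(apply_deprivations(rec, specs$php)[1, ]), rep(0L, 7))
  expect_equal(unname(apply_deprivations(rec, specs$mhp)[1, ]), rep(0L, 10))

  # uninsured -> enabling deprivation in both indices
  rec$insurance <- 0L
  expect_equal(apply_deprivations(rec, specs$php)[1, "health insurance"], 1L,
               ignore_attr = TRUE)
  expect_equal(apply_deprivations(rec, specs$mhp)[1, "health insurance"], 1L,
               ignore_attr = TRUE)

  # psychometric score 3 -> deprived; 2 -> not
  rec <- clean_record()
  rec$dep_depress <- 3L
  d <- apply_deprivations(rec, specs$mhp)
  expect_equal(d[1, "degree of depression"], 1L, ignore_attr = TRUE)
  rec$dep_depress <- 2L
  expect_equal(apply_deprivations(rec, specs$mhp)[1, "degree of depression"],
               0L, ignore_attr = TRUE)

  # psychometric scores outside 1-4 are validation errors, not clamped
  rec$dep_depress <- 5L
  expect_error(apply_deprivations(rec, specs$mhp), "1-4")

  # missing raw field names the indicator
  rec <- clean_record(); rec$chronic <- NULL
  expect_error(apply_deprivations(rec, specs$php), "chronic illness")
})

test_that("scoring and identification match hand computations", {
  specs <- builtin_specs()
  expect_equal(score_and_classify(rep(0L, 7), specs$php),
               data.frame(weighted_score = 0, poor = 0L))
  p3 <- score_and_classify(c(1, 1, 1, 0, 0, 0, 0), specs$php, 0.30)
  expect_equal(p3$weighted_score, 3 / 7, tolerance = 1e-12)
  expect_identical(p3$poor, 1L)
  p2 <- score_and_classify(c(1, 1, 0, 0, 0, 0, 0), specs$php, 0.30)
  expect_equal(p2$weighted_score, 2 / 7, tolerance = 1e-12)
  expect_identical(p2$poor, 0L)
  # boundary inclusive: a score exactly at gamma is poor
  b <- score_and_classify(c(1, 1, 1, 0, 0, 0, 0), specs$php, 3 / 7)
  expect_identical(b$poor, 1L)
  expect_error(score_and_classify(rep(0L, 6), specs$php), "columns")
})

test_that("aggregation handles saturation, empty-poor and mixed cases", {
  specs <- builtin_specs()
  expect_error(af_aggregate(data.frame(weighted_score = numeric(0),
                                       poor = integer(0))), "empty")
  sat <- data.frame(weighted_score = c(1, 1), poor = c(1L, 1L))
  expect_equal(af_aggregate(sat),
               list(headcount_ratio = 1, mean_intensity_among_poor = 1,
                    adjusted_headcount = 1))
  none <- data.frame(weighted_score = c(0.1, 0.2), poor = c(0L, 0L))
  agg0 <- af_aggregate(none)
  expect_equal(agg0$headcount_ratio, 0)
  expect_true(is.na(agg0$mean_intensity_among_poor))
  expect_equal(agg0$adjusted_headcount, 0)
  mix <- data.frame(weighted_score = c(3 / 7, 4 / 7, 0.1, 0.2),
                    poor = c(1L, 1L, 0L, 0L))
  expect_equal(af_aggregate(mix),
               list(headcount_ratio = 0.5, mean_intensity_among_poor = 0.5,
                    adjusted_headcount = 0.25))
})

test_that("scoring is monotone and equals the ceiling rule for equal weights", {
  specs <- builtin_specs()
  set.seed(1)
  for (r in 1:50) {
    v <- rbinom(10, 1, 0.4)
    res <- score_and_classify(v, specs$mhp, 0.30)
    if (any(v == 0)) {
      v2 <- v; v2[which(v == 0)[1]] <- 1L
      res2 <- score_and_classify(v2, specs$mhp, 0.30)
      expect_gte(res2$weighted_score, res$weighted_score)
      expect_gte(res2$poor, res$poor)
    }
    # equal weights: poor iff count >= ceil(gamma * m) (gamma*m non-integer)
    expect_identical(res$poor, as.integer(sum(v) >= ceiling(0.30 * 10)))
  }
  expect_identical(min_deprivation_count(specs$php, 0.30), 3L)
  expect_identical(min_deprivation_count(specs$mhp, 0.30), 3L)
  # integer gamma*m stays boundary-inclusive
  expect_identical(min_deprivation_count(specs$mhp, 0.50), 5L)
})

test_that("index combination rules behave as documented", {
  php <- data.frame(weighted_score = c(3 / 7, 0, 3 / 7), poor = c(1L, 0L, 1L))
  mhp <- data.frame(weighted_score = c(0, 3 / 10, 3 / 10),
                    poor = c(0L, 1L, 1L))
  expect_equal(combine_indices(php, mhp, "either")$poor, c(1L, 1L, 1L))
  expect_equal(combine_indices(php, mhp, "both")$poor, c(0L, 0L, 1L))
  cs <- combine_indices(php, mhp, "score-union", 0.30)
  expect_equal(cs$weighted_score, (7 * php$weighted_score +
                                     10 * mhp$weighted_score) / 17)
  expect_equal(cs$poor, as.integer(cs$weighted_score >= 0.30))
})

test_that("indicator systems round-trip through spec files", {
  specs <- builtin_specs()
  path <- withr::local_tempfile(fileext = ".dcf")
  write_spec_file(specs$php, path)
  back <- read_spec_file(path)
  expect_equal(back, specs$php)
})
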
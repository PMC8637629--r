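test_that("leave-one-out on the bundled studies never moves the pool across 1", {
  loo <- leave_one_out(rs1564282_studies())
  expect_equal(nrow(loo), 7)
  expect_equal(loo$omitted_study_id, rs1564282_studies()$study_id)
  expect_true(all(loo$ci_low > 1))
  expect_true(all(loo$model == "fixed"))

  full <- pool_effects(study_effects(rs1564282_studies()))
  # every reduced pool overlaps the all-study interval
  expect_true(all(loo$ci_low < full$ci_high & loo$ci_high > full$ci_low))
  # the one study with OR < 1 (Tseng/Taiwan) pulls the pool down, so
  # omitting it must raise the estimate
  expect_gt(loo$or[loo$omitted_study_id == "tseng2013_t"], full$or)
})

test_that("leave-one-out over identical studies yields identical entries", {
  tab <- rs1564282_studies()[rep(2, 3), ]
  tab$study_id <- c("a", "b", "c")
  loo <- leave_one_out(tab)
  expect_equal(nrow(loo), 3)
  expect_equal(loo$or, rep(loo$or[1], 3))
  expect_equal(loo$ci_low, rep(loo$ci_low[1], 3))
  expect_error(leave_one_out(rs1564282_studies()[1:2, ]),
               class = "allelemeta_insufficient_studies")
})

test_that("funnel coordinates carry one point per study plus reference and boundary", {
  eff <- study_effects(rs1564282_studies())
  fp <- funnel_points(eff)
  expect_equal(nrow(fp), 7)
  expect_true(all(fp$se > 0.10 & fp$se < 0.19))
  expect_equal(attr(fp, "reference"),
               pool_effects(eff, model = "fixed")$or, tolerance = 1e-12)
  boundary <- attr(fp, "boundary")
  expect_equal(boundary$se[1], 0)
  expect_equal(max(boundary$se), max(eff$se))
  # at se = 0 both funnel limits meet at the reference
  expect_equal(boundary$low[1], attr(fp, "reference"))
  expect_equal(boundary$high[1], attr(fp, "reference"))

  # removing a study removes exactly its point
  fp6 <- funnel_points(eff[-3, ])
  expect_equal(fp6$study_id, setdiff(eff$study_id, "chen2013"))

  # single study is its own reference
  fp1 <- funnel_points(eff[1, ])
  expect_equal(nrow(fp1), 1)
  expect_equal(attr(fp1, "reference"), eff$or[1])

  # log scale option
  fl <- funnel_points(eff, scale = "log_or")
  expect_equal(fl$x, eff$log_or)
})

test_that("Egger regression matches closed-form OLS on the bundled studies", {
  eff <- study_effects(rs1564282_studies())
  eg <- egger_test(eff)
  orc <- oracle_ols_intercept(1 / eff$se, eff$log_or / eff$se)
  expect_equal(eg$intercept, orc$intercept, tolerance = 1e-9)
  expect_equal(eg$se_intercept, orc$se, tolerance = 1e-9)
  expect_equal(eg$t, orc$t, tolerance = 1e-9)
  expect_equal(eg$p, orc$p, tolerance = 1e-9)
  expect_equal(eg$df, 5)
  expect_equal(eg$intercept, -0.77, tolerance = 1e-2)
  expect_equal(eg$t, -0.3344, tolerance = 1e-3)
  expect_false(eg$significant)
  expect_gt(eg$p, 0.05)

  # order invariance
  set.seed(61)
  perm <- sample(7)
  eg2 <- egger_test(eff[perm, ])
  expect_equal(eg2$intercept, eg$intercept, tolerance = 1e-12)
  expect_equal(eg2$p, eg$p, tolerance = 1e-12)
})

test_that("constructed zero-bias data give a zero Egger intercept with p = 1", {
  # residuals (1, -2, 1) are orthogonal to both the intercept and x = (1, 2, 3),
  # so the fitted line through z = 0.4 x + e has intercept exactly 0 and t = 0
  x <- c(1, 2, 3)
  z <- 0.4 * x + 0.1 * c(1, -2, 1)
  eff <- tibble::tibble(study_id = sprintf("s%d", 1:3),
                        se = 1 / x, log_or = z / x)
  eg <- egger_test(eff)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  expect_equal(eg$slope, 0.4, tolerance = 1e-10)
  expect_equal(eg$t, 0, tolerance = 1e-8)
  expect_equal(eg$p, 1, tolerance = 1e-8)

  expect_error(egger_test(eff[1:2, ]),
               class = "allelemeta_insufficient_studies")
  degen <- tibble::tibble(study_id = c("a", "b", "c"), log_or = 0.2, se = 0.1)
  expect_error(egger_test(degen), class = "allelemeta_degenerate_error")
})

test_that("Egger test is approximately sized on simulated no-bias studies", {
  # k = 10 studies per table with a spread of precisions and no small-study
  # effect; the intercept test at level 0.1 should reject near its nominal
  # rate (Egger's test is known to be only approximately sized)
  reps <- 1000
  hits <- 0L
  sizes <- round(seq(150, 2000, length.out = 10))
  for (r in seq_len(reps)) {
    tab <- simulate_studies(10, n_case = sizes, n_control = sizes,
                            q = 0.15, psi = 1.2, seed = 7000 + r)
    eg <- egger_test(study_effects(tab), alpha = 0.1)
    if (eg$p < 0.1) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.06)
  expect_lte(hits / reps, 0.14)
})

test_that("tidy and glance views of the Egger fit are consistent", {
  eg <- egger_test(study_effects(rs1564282_studies()))
  td <- tidy(eg)
  expect_equal(td$estimate[td$term == "intercept"], eg$intercept)
  expect_equal(td$p.value[td$term == "intercept"], eg$p)
  gl <- glance(eg)
  expect_equal(gl$df, 5)
  expect_false(gl$significant)
})
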
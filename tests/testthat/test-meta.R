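bundled_effects <- function() study_effects(rs1564282_studies())

test_that("heterogeneity on the bundled studies: Q ~ 5.95, I2 floored at 0", {
  het <- heterogeneity(bundled_effects())
  expect_equal(het$k, 7)
  expect_equal(het$df, 6)
  expect_equal(het$q, 5.95, tolerance = 1e-2)
  expect_true(het$q < het$df)
  expect_equal(het$i2, 0)
  expect_equal(het$tau2, 0)
  expect_gt(het$p_q, 0.1)
})

test_that("two identical studies give Q = 0, I2 = 0, p_q = 1", {
  eff <- tibble::tibble(study_id = c("a", "b"), log_or = c(0.3, 0.3),
                        se = c(0.1, 0.1))
  het <- heterogeneity(eff)
  expect_equal(het$q, 0)
  expect_equal(het$i2, 0)
  expect_equal(het$p_q, 1)
  expect_equal(het$tau2, 0)
})

test_that("Q, I2 and tau2 match the brute-force oracle and are order-invariant", {
  set.seed(41)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    eff <- study_effects(random_study_table(k))
    het <- heterogeneity(eff)
    orc <- oracle_q(eff$log_or, eff$se)
    expect_equal(het$q, orc$q, tolerance = 1e-9)
    expect_equal(het$i2, oracle_i2(orc$q, k), tolerance = 1e-9)
    perm <- sample(k)
    expect_equal(heterogeneity(eff[perm, ])$q, het$q, tolerance = 1e-9)
  }
})

test_that("fixed-effect pooling reproduces the published rs1564282 estimate", {
  pooled <- pool_effects(bundled_effects())
  expect_equal(pooled$model, "fixed")
  expect_equal(round(pooled$or, 2), 1.28)
  expect_equal(round(pooled$ci_low, 2), 1.16)
  expect_equal(round(pooled$ci_high, 2), 1.42)
  expect_equal(pooled$z, 4.824, tolerance = 1e-3)
  expect_lt(pooled$p, 1e-4)
  expect_equal(sum(pooled$weights$weight), 1, tolerance = 1e-12)
  expect_true(all(pooled$weights$weight > 0))
})

test_that("pooling identities: single study, symmetric pair, range containment", {
  eff <- bundled_effects()
  single <- pool_effects(eff[1, ])
  expect_equal(single$log_or, eff$log_or[1])
  expect_equal(single$se, eff$se[1])

  pair <- tibble::tibble(study_id = c("a", "b"), log_or = c(0.1, 0.5),
                         se = c(0.2, 0.2))
  expect_equal(pool_effects(pair, model = "fixed")$log_or, 0.3)

  set.seed(51)
  for (rep in 1:20) {
    e <- study_effects(random_study_table(sample(2:8, 1)))
    p <- pool_effects(e, model = "fixed")
    expect_gte(p$log_or, min(e$log_or) - 1e-12)
    expect_lte(p$log_or, max(e$log_or) + 1e-12)
    expect_lt(p$se, min(e$se))
    expect_equal(p$p, 2 * pnorm(-abs(p$z)), tolerance = 1e-12)
  }
})

test_that("random-effects pooling collapses to fixed when tau2 = 0 and widens otherwise", {
  eff <- bundled_effects()
  fx <- pool_effects(eff, model = "fixed")
  rnd <- pool_effects(eff, model = "random")
  expect_equal(rnd$log_or, fx$log_or, tolerance = 1e-12)
  expect_equal(rnd$se, fx$se, tolerance = 1e-12)

  # inflate dispersion so tau2 > 0, then the random CI must be wider
  spread <- tibble::tibble(
    study_id = sprintf("s%d", 1:5),
    log_or = c(-0.8, -0.3, 0.1, 0.6, 1.1),
    se = rep(0.1, 5)
  )
  expect_gt(heterogeneity(spread)$tau2, 0)
  fx2 <- pool_effects(spread, model = "fixed")
  rnd2 <- pool_effects(spread, model = "random")
  expect_gt(rnd2$se, fx2$se)
  expect_gt(rnd2$ci_high - rnd2$ci_low, fx2$ci_high - fx2$ci_low)
})

test_that("model selection requires both a significant Q test and high I2", {
  het <- function(p_q, i2) tibble::tibble(p_q = p_q, i2 = i2)
  expect_equal(select_model(het(0.05, 80)), "random")
  expect_equal(select_model(het(0.05, 30)), "fixed")
  expect_equal(select_model(het(0.5, 80)), "fixed")
  expect_equal(select_model(het(0.5, 30)), "fixed")
  expect_equal(select_model(heterogeneity(bundled_effects())), "fixed")
})

test_that("IV pooling agrees with metafor and with the Mantel-Haenszel cross-check", {
  skip_if_not_installed("metafor")
  eff <- bundled_effects()
  fit <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "FE")
  pooled <- pool_effects(eff, model = "fixed")
  expect_equal(pooled$log_or, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(pooled$se, fit$se, tolerance = 1e-10)
  het <- heterogeneity(eff)
  expect_equal(het$q, fit$QE, tolerance = 1e-10)
  expect_equal(het$p_q, fit$QEp, tolerance = 1e-10)

  mh <- or_mantel_haenszel(eff)
  expect_equal(round(mh$or, 2), 1.28)
  expect_equal(mh$or, pooled$or, tolerance = 0.01)
})

test_that("pooled_or exposes broom-style tidy and glance views", {
  pooled <- pool_effects(bundled_effects())
  td <- tidy(pooled)
  expect_equal(nrow(td), 1)
  expect_equal(td$or, pooled$or)
  expect_equal(td$p.value, pooled$p)
  gl <- glance(pooled)
  expect_equal(gl$model, "fixed")
  expect_equal(gl$i2, 0)
  expect_equal(gl$k, 7)
})

test_that("insufficient studies and bad standard errors are rejected", {
  eff <- bundled_effects()
  expect_error(heterogeneity(eff[1, ]),
               class = "allelemeta_insufficient_studies")
  bad <- eff
  bad$se[2] <- 0
  expect_error(pool_effects(bad), class = "allelemeta_validation_error")
  expect_error(pool_effects(eff[1, ], model = "random"),
               class = "allelemeta_insufficient_studies")
})
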
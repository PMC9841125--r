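# Posterior summaries, HPD intervals, profile predictions.

test_that("HPD intervals are shortest and match central quantiles for symmetric draws", {
  set.seed(23)
  x <- rnorm(1e5)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  # agreement with the independent implementation in coda
  ci <- as.numeric(coda::HPDinterval(coda::mcmc(x), prob = 0.95))
  expect_lt(max(abs(h - ci)), 0.02)
  # skewed draws: HPD must be narrower than the equal-tailed interval
  y <- rexp(1e5)
  hy <- hpd_interval(y, 0.9)
  qy <- quantile(y, c(0.05, 0.95))
  expect_lt(diff(hy), diff(qy))
  expect_equal(hpd_interval(rep(3.3, 50), 0.95), c(3.3, 3.3))
})

test_that("the posterior summary follows the report layout", {
  fit <- cached_fit()
  s <- posterior_summary(fit)
  expect_equal(s$term[1:9],
               c("Intercept", "Strong", "Weak", "Nonbreeders present",
                 "Population density", "Male experience",
                 "Female experience", "Territory size", "Mean rainfall"))
  expect_equal(s$term[10:18],
               c("Intercept", "Strong", "Weak", "Nonbreeders present",
                 "Territory size", "Mean rainfall",
                 "Proportion strong in population",
                 "Supplemental food in population", "Population density"))
  expect_equal(s$submodel[19:22], rep("random effect", 4))
  expect_equal(s$term[23], "Deviance")
  # values are recomputable from the raw draws
  x <- draws_matrix(fit, "success.strong")[, 1]
  i <- match("success.strong", s$parameter)
  expect_equal(s$mean[i], mean(x))
  expect_equal(s$sd[i], sd(x))
  expect_equal(s$q2.5[i], quantile(x, 0.025, names = FALSE))
  expect_true(all(is.finite(s$rhat)) && all(s$n_eff > 0))
})

test_that("summary of a constant chain degenerates correctly", {
  fit <- cached_fit()
  fake <- fit
  for (k in seq_along(fake$draws)) fake$draws[[k]][, "success.strong"] <- 2
  s <- posterior_summary(fake)
  i <- match("success.strong", s$parameter)
  expect_equal(s$mean[i], 2)
  expect_equal(s$sd[i], 0)
  expect_equal(s$q2.5[i], 2)
  expect_equal(s$q97.5[i], 2)
})

test_that("profile predictions equal closed-form transforms of the draws", {
  # the reference-cell identity at posterior-mean coefficients
  expect_equal(round(plogis(-1.11 + 1.28 + 0.37), 3), 0.632)

  fit <- cached_fit()
  pred <- predict_profiles(fit)
  expect_equal(nrow(pred), 18)  # 6 profiles x 3 targets
  expect_setequal(unique(pred$target), c("success", "count", "fecundity"))

  b <- draws_matrix(fit, c("success.intercept", "success.strong",
                           "success.nonbreeders"))
  # sink, no nonbreeders -> p = invlogit(intercept) on every draw
  sink_row <- pred$target == "success" & pred$habitat_state == "sink" &
    pred$nonbreeders_present == 0
  expect_equal(pred$mean[sink_row], mean(plogis(b[, 1])), tolerance = 1e-10)
  # strong with nonbreeders -> intercept + strong + nonbreeders
  sr <- pred$target == "success" & pred$habitat_state == "strong" &
    pred$nonbreeders_present == 1
  expect_equal(pred$mean[sr], mean(plogis(rowSums(b))), tolerance = 1e-10)

  # fecundity is p * lambda draw by draw
  bc <- draws_matrix(fit, c("count.intercept", "count.strong",
                            "count.nonbreeders"))
  fr <- pred$target == "fecundity" & pred$habitat_state == "strong" &
    pred$nonbreeders_present == 1
  expect_equal(pred$mean[fr], mean(plogis(rowSums(b)) * exp(rowSums(bc))),
               tolerance = 1e-10)

  expect_error(predict_profiles(fit, data.frame(elevation = 1)),
               "unknown profile covariate")
  expect_error(predict_profiles(fit, data.frame(habitat_state = "medium")),
               "must be one of")
})

test_that("natural-scale profile values pass through the scaling report", {
  fit <- cached_fit()
  des <- fit$design
  rain_hi <- unstandardize_value(des, "rainfall", 0.5)
  pred <- predict_profiles(
    fit, data.frame(habitat_state = "sink", nonbreeders_present = 0,
                    rainfall = rain_hi))
  b <- draws_matrix(fit, c("success.intercept", "success.rainfall"))
  expect_equal(pred$mean[pred$target == "success"],
               mean(plogis(b[, 1] + 0.5 * b[, 2])), tolerance = 1e-10)
})

test_that("annual effect summaries cover every year in both submodels", {
  fit <- cached_fit()
  a <- annual_effects_summary(fit)
  expect_equal(nrow(a), 2 * length(fit$design$year_levels))
  expect_true(all(a$hpd95_lower <= a$hpd90_lower))
  expect_true(all(a$hpd90_upper <= a$hpd95_upper))
  expect_true(all(a$hpd90_lower < a$mean & a$mean < a$hpd90_upper))
})
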
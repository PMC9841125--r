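# Probability core: links, factorized likelihood, priors, marginal ZIP.

params_with <- function(success = NULL, count = NULL, sigma = NULL, ...) {
  p <- zeroed_params()
  if (!is.null(success)) p$beta_success[names(success)] <- success
  if (!is.null(count)) p$beta_count[names(count)] <- count
  if (!is.null(sigma)) p$sigma[names(sigma)] <- sigma
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  p
}

test_that("linear predictors obey the link identities", {
  des <- complete_design(standardize_covariates(tiny_table()))
  lp0 <- linear_predictors(zeroed_params(), des)
  expect_equal(lp0$p, rep(0.5, 6))
  expect_equal(lp0$lambda, rep(1, 6))

  # intercept-only success submodel at the reference posterior mean
  lp1 <- linear_predictors(params_with(success = c(intercept = -1.11)), des)
  expect_equal(unique(lp1$p), plogis(-1.11), tolerance = 1e-12)
  expect_equal(unique(round(lp1$p, 3)), 0.248)

  # adding c to a year effect multiplies lambda by exp(c) exactly
  base <- params_with(sigma = c(year_count = 1),
                      year_count = c(0, 0))
  bump <- params_with(sigma = c(year_count = 1),
                      year_count = c(0.7, 0))
  r <- linear_predictors(bump, des)$lambda / linear_predictors(base, des)$lambda
  expect_equal(r[des$year_index == 1], rep(exp(0.7), 3))
  expect_equal(r[des$year_index == 2], rep(1, 3))

  # missing experience must be imputed before pointwise evaluation
  expect_error(linear_predictors(zeroed_params(),
                                 standardize_covariates(tiny_table())),
               "missing covariate")
})

test_that("joint log-likelihood matches closed forms and rejects impossible rows", {
  des <- complete_design(standardize_covariates(tiny_table()))
  # collapse to known p and lambda
  p <- params_with(success = c(intercept = qlogis(0.3)))
  des0 <- des; des0$S <- rep(0L, 6); des0$C <- rep(0L, 6)
  expect_equal(joint_log_likelihood(p, des0), 6 * log(0.7), tolerance = 1e-12)

  # one successful row with C = 2, p = 0.5, lambda = 1:
  # log 0.5 - 1 - log 2, others at S=0 contribute log 0.5 each
  des1 <- des0; des1$S[1] <- 1L; des1$C[1] <- 2L
  expect_equal(joint_log_likelihood(zeroed_params(), des1),
               (log(0.5) - 1 - log(2)) + 5 * log(0.5), tolerance = 1e-12)

  desbad <- des0; desbad$C[2] <- 3L
  expect_error(joint_log_likelihood(zeroed_params(), desbad), "impossible")
})

test_that("exp(likelihood) sums to 1 over the outcome space of one row", {
  des <- complete_design(standardize_covariates(tiny_table()))
  params <- default_params()
  lp <- linear_predictors(params, des)
  # per-row log-likelihood of row 1 via differences of the joint
  base <- des; base$S[1] <- 0L; base$C[1] <- 0L
  ll_base <- joint_log_likelihood(params, base)
  ll_row1 <- function(S, C) {
    d <- des; d$S[1] <- S; d$C[1] <- C
    joint_log_likelihood(params, d) - ll_base + log(1 - lp$p[1])
  }
  total <- exp(ll_row1(0L, 0L)) +
    sum(vapply(0:200, function(c) exp(ll_row1(1L, c)), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("marginal ZIP pmf matches its definition and normalizes", {
  expect_equal(marginal_zip_pmf(0.5, log(2), 0), 0.75)
  expect_equal(marginal_zip_pmf(0, 3.7, 0), 1)
  expect_equal(marginal_zip_pmf(0, 3.7, 4), 0)
  for (p in c(0.2, 0.9)) for (lam in c(0.3, 5))
    expect_equal(sum(marginal_zip_pmf(p, lam, 0:200)), 1, tolerance = 1e-12)
})

test_that("summing the factorized likelihood over latent S recovers the marginal ZIP at C = 0", {
  des <- complete_design(standardize_covariates(tiny_table()))
  params <- default_params()
  lp <- linear_predictors(params, des)
  base <- des; base$S[1] <- 0L; base$C[1] <- 0L
  ll_base <- joint_log_likelihood(params, base)
  ll_row1 <- function(S, C) {
    d <- des; d$S[1] <- S; d$C[1] <- C
    joint_log_likelihood(params, d) - ll_base + log(1 - lp$p[1])
  }
  lhs <- exp(ll_row1(0L, 0L)) + exp(ll_row1(1L, 0L))
  expect_equal(lhs, marginal_zip_pmf(lp$p[1], lp$lambda[1], 0),
               tolerance = 1e-12)
})

test_that("the count factor reduces to a plain Poisson log-likelihood on successful rows", {
  des <- complete_design(standardize_covariates(tiny_table()))
  params <- default_params()
  lp <- linear_predictors(params, des)
  S <- des$S; C <- des$C
  manual_bern <- sum(S * log(lp$p) + (1 - S) * log(1 - lp$p))
  on <- S == 1
  manual_pois <- sum(C[on] * log(lp$lambda[on]) - lp$lambda[on] -
                       lgamma(C[on] + 1))
  expect_equal(joint_log_likelihood(params, des),
               manual_bern + manual_pois, tolerance = 1e-10)
})

test_that("likelihood is invariant to row order and group relabeling", {
  df <- tiny_table()
  params <- default_params()
  ll1 <- joint_log_likelihood(params,
                              complete_design(standardize_covariates(df)))
  ll2 <- joint_log_likelihood(
    params, complete_design(standardize_covariates(df[sample(6), ])))
  df3 <- df
  df3$population <- chartr("AB", "ZQ", df3$population)
  ll3 <- joint_log_likelihood(params,
                              complete_design(standardize_covariates(df3)))
  expect_equal(ll1, ll2, tolerance = 1e-12)
  expect_equal(ll1, ll3, tolerance = 1e-12)
})

test_that("log prior matches closed forms", {
  pr <- prior_spec()
  p0 <- zeroed_params()
  expected <- 18 * dnorm(0, 0, 10, log = TRUE) +
    4 * (log(2) + dnorm(0, 0, 2.24, log = TRUE))
  expect_equal(log_prior(p0, pr), expected, tolerance = 1e-12)

  # realized random effects contribute their Normal(0, sigma) densities
  p1 <- params_with(sigma = c(year_success = 2), year_success = c(0.5, -1))
  expect_equal(log_prior(p1, pr) - log_prior(params_with(
    sigma = c(year_success = 2), year_success = c(0, 0)), pr),
    dnorm(0.5, 0, 2, log = TRUE) + dnorm(-1, 0, 2, log = TRUE) -
      2 * dnorm(0, 0, 2, log = TRUE), tolerance = 1e-12)

  # a negative SD is a rejected state, not an error
  pbad <- zeroed_params()
  pbad$sigma[["year_count"]] <- -0.1
  expect_identical(log_prior(pbad, pr), -Inf)
})
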
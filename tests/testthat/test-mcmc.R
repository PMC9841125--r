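# Sampler contracts: determinism, prior recovery, boundary recovery, and
# agreement with an independent MCMC engine.

test_that("the same seed and data reproduce draws exactly", {
  df <- small_panel(seed = 55)
  f1 <- suppressWarnings(fit_zipfec(df, chains = 2, burnin = 200,
                                    block = 200, max_draws = 200, seed = 9))
  f2 <- suppressWarnings(fit_zipfec(df, chains = 2, burnin = 200,
                                    block = 200, max_draws = 200, seed = 9))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_zipfec(df, chains = 2, burnin = 200,
                                    block = 200, max_draws = 200, seed = 10))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("basic argument contracts hold", {
  df <- small_panel(seed = 56)
  expect_error(fit_zipfec(df, chains = 1), "at least 2 chains")
})

test_that("hitting the draw cap returns an unconverged flagged fit with a warning", {
  df <- small_panel(seed = 57)
  expect_warning(
    fit <- fit_zipfec(df, chains = 2, burnin = 100, block = 100,
                      max_draws = 100, rhat_tol = 1.0001, seed = 2),
    "cap reached")
  expect_false(fit$meta$converged)
  expect_gt(fit$meta$max_rhat, 1.0001)
  expect_equal(nrow(fit$draws[[1]]), 100)
})

test_that("with the likelihood disabled the sampler recovers the prior", {
  # posterior = prior: the marginal of each random-effect SD must be
  # half-normal(2.24), and coefficients Normal(0, 10)
  # long adaptation: the proposal scale must grow to the SD-10 prior
  fit <- suppressWarnings(
    fit_zipfec(tiny_table(), chains = 2, burnin = 4000, block = 8000,
               max_draws = 8000, seed = 31, prior_only = TRUE))
  sig <- draws_matrix(fit, "sigma.year_success")[, 1]
  # thin heavily: KS assumes independent draws, the slice/Gibbs chain on
  # sigma is autocorrelated
  thin <- sig[seq(1, length(sig), by = 25)]
  ks <- ks.test(thin, function(q) 2 * pnorm(q, 0, 2.24) - 1)
  expect_gt(ks$p.value, 0.01)
  b <- draws_matrix(fit, "count.strong")[, 1]
  expect_lt(abs(mean(b)) / (10 / sqrt(coda::effectiveSize(coda::mcmc(b)))), 4)
  expect_lt(abs(sd(b) - 10) / 10, 0.15)
})

test_that("a zero variance component is recovered near the boundary", {
  p <- default_params()
  p$sigma[["year_success"]] <- 0
  df <- small_panel(seed = 58, params = p)
  fit <- suppressWarnings(
    fit_zipfec(df, chains = 3, burnin = 1500, block = 1500,
               max_draws = 4500, seed = 12))
  post_med <- median(draws_matrix(fit, "sigma.year_success"))
  expect_lt(post_med, 0.3)
})

test_that("posterior means agree with an independent Gibbs engine (JAGS)", {
  skip_if_not_installed("rjags")
  cfg <- sim_config(schedule = uniform_schedule(8, 2, 12),
                    covariates = covariate_defaults(p_experience_missing = 0),
                    seed = 77)
  df <- simulate_panel(cfg)
  des <- standardize_covariates(df)

  fit <- suppressWarnings(
    fit_zipfec(des, chains = 3, burnin = 3000, block = 4000,
               max_draws = 8000, seed = 21))

  model <- "
  model {
    for (j in 1:9) { bs[j] ~ dnorm(0, 0.01); bc[j] ~ dnorm(0, 0.01) }
    sigS ~ dnorm(0, tau0) T(0,)
    sigC ~ dnorm(0, tau0) T(0,)
    sigP ~ dnorm(0, tau0) T(0,)
    sigT ~ dnorm(0, tau0) T(0,)
    for (y in 1:Y) {
      uS[y] ~ dnorm(0, pow(sigS, -2))
      uC[y] ~ dnorm(0, pow(sigC, -2))
    }
    for (p in 1:P) { vP[p] ~ dnorm(0, pow(sigP, -2)) }
    for (t in 1:T) { wT[t] ~ dnorm(0, pow(sigT, -2)) }
    for (i in 1:n) {
      logit(ps[i]) <- inprod(XS[i, ], bs) + uS[year[i]]
      S[i] ~ dbern(ps[i])
    }
    for (k in 1:n1) {
      log(lam[k]) <- inprod(XC1[k, ], bc) + uC[year1[k]] +
        vP[pop1[k]] + wT[terr1[k]]
      C1[k] ~ dpois(lam[k])
    }
  }"
  idx1 <- which(des$S == 1)
  jd <- list(XS = des$X_success, XC1 = des$X_count[idx1, ],
             S = des$S, C1 = des$C[idx1],
             year = des$year_index, year1 = des$year_index[idx1],
             pop1 = des$population_index[idx1],
             terr1 = des$territory_index[idx1],
             n = des$n, n1 = length(idx1),
             Y = length(des$year_levels), P = length(des$population_levels),
             T = length(des$territory_levels), tau0 = 1 / 2.24^2)
  jm <- rjags::jags.model(textConnection(model), data = jd, n.chains = 2,
                          n.adapt = 1000, quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 42))
  update(jm, 2000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("bs", "bc", "sigS", "sigC", "sigP", "sigT"),
                            n.iter = 6000, progress.bar = "none")
  jdraws <- as.matrix(js)

  mine <- colMeans(draws_matrix(fit))
  theirs <- colMeans(jdraws)
  map <- c(stats::setNames(paste0("bs[", 1:9, "]"),
                           paste0("success.", success_terms())),
           stats::setNames(paste0("bc[", 1:9, "]"),
                           paste0("count.", count_terms())),
           "sigma.year_success" = "sigS", "sigma.year_count" = "sigC",
           "sigma.territory" = "sigT", "sigma.population" = "sigP")
  mcse <- function(x) sd(x) / sqrt(max(coda::effectiveSize(coda::mcmc(x)), 10))
  for (p in names(map)) {
    x <- draws_matrix(fit, p)[, 1]
    y <- jdraws[, map[[p]]]
    tol <- max(0.05, 4 * sqrt(mcse(x)^2 + mcse(y)^2))
    expect_lt(abs(mean(x) - mean(y)), tol, label = p)
  }
})
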
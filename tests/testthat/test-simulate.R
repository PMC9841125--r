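# Synthetic panel generator: design layout, generative laws, determinism.

test_that("reference parameter values are wired correctly", {
  p <- default_params()
  expect_equal(p$beta_success[["strong"]], 1.28)
  expect_equal(p$sigma[["year_count"]], 0.26)
  z <- zeroed_params()
  expect_true(all(c(z$beta_success, z$beta_count, z$sigma) == 0))
  expect_error(parameter_set(p$beta_success, p$beta_count,
                             c(year_success = -1, year_count = 0,
                               territory = 0, population = 0)),
               ">= 0")
})

test_that("a one-population schedule yields one row per territory and a single rainfall", {
  cfg <- sim_config(schedule = uniform_schedule(1, 1, 20), seed = 3)
  panel <- build_panel(cfg)
  expect_equal(nrow(panel), 20)
  expect_equal(length(unique(panel$rainfall)), 1)
  expect_error(sim_config(schedule = data.frame(year = integer(),
                                                population = character(),
                                                n_territories = integer())),
               "empty")
  expect_error(sim_config(schedule = data.frame(year = 1, population = "A",
                                                n_territories = 0)),
               "at least one territory")
})

test_that("proportion_strong equals a brute-force recount per population-year", {
  cfg <- sim_config(schedule = uniform_schedule(6, 3, 15), seed = 8)
  panel <- build_panel(cfg)
  for (key in split(seq_len(nrow(panel)),
                    paste(panel$year, panel$population))) {
    expect_equal(unique(panel$proportion_strong[key]),
                 mean(panel$habitat_state[key] == "strong"))
  }
})

test_that("generation is bit-reproducible for a given seed", {
  cfg <- sim_config(schedule = uniform_schedule(5, 2, 10), seed = 21)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  cfg2 <- sim_config(schedule = uniform_schedule(5, 2, 10), seed = 22)
  expect_false(identical(simulate_panel(cfg), simulate_panel(cfg2)))
})

test_that("territory identifiers persist according to the turnover setting", {
  keep_all <- sim_config(schedule = uniform_schedule(4, 1, 25),
                         persistence = 1, seed = 5)
  p1 <- build_panel(keep_all)
  ids <- split(p1$territory, p1$year)
  for (k in 2:4) expect_setequal(ids[[k]], ids[[1]])

  churn <- sim_config(schedule = uniform_schedule(2, 1, 25),
                      persistence = 0, seed = 5)
  p2 <- build_panel(churn)
  ids2 <- split(p2$territory, p2$year)
  expect_length(intersect(ids2[[1]], ids2[[2]]), 0)
})

test_that("the 31-year study schedule has the published shape", {
  sched <- scrubjay_schedule()
  per_year <- aggregate(n_territories ~ year, sched, sum)
  expect_equal(nrow(per_year), 31)
  expect_equal(per_year$n_territories[per_year$year == 1988], 20)
  expect_equal(per_year$n_territories[per_year$year == 2002], 234)
  expect_equal(sum(sched$year == 2001), 14)
  quarter <- scrubjay_schedule(scale = 0.25)
  expect_equal(sum(quarter$n_territories[quarter$year == 1988]), 5)
})

# a flat 4-year design used for distributional checks
flat_panel <- function(seed, ...) {
  cfg <- sim_config(schedule = uniform_schedule(4, 1, 2500),
                    persistence = 0, seed = seed, ...)
  build_panel(cfg)
}

test_that("generative laws match their distributions at null parameters", {
  panel <- flat_panel(31)
  n <- nrow(panel)

  # p = 0 limit: nothing fledges
  sunk <- zeroed_params()
  sunk$beta_success[["intercept"]] <- -50
  d0 <- simulate_dataset(panel, sunk, "likelihood-exact", seed = 1)
  expect_true(all(d0$success == 0) && all(d0$count == 0))

  # null model: P(S) = 1/2, E[C | S=1] = 1 (Poisson(1))
  d1 <- simulate_dataset(panel, zeroed_params(), "likelihood-exact", seed = 2)
  expect_lt(abs(mean(d1$success) - 0.5), 3 * sqrt(0.25 / n))
  on <- d1$success == 1
  expect_lt(abs(mean(d1$count[on]) - 1), 3 / sqrt(sum(on)))

  # exact-likelihood mode produces successful-but-zero rows at p * exp(-lambda)
  s1c0 <- mean(d1$success == 1 & d1$count == 0)
  expect_lt(abs(s1c0 - 0.5 * exp(-1)), 3 * sqrt(0.5 * exp(-1) / n))

  # hurdle mode never does
  d2 <- simulate_dataset(panel, zeroed_params(), "hurdle", seed = 3)
  expect_equal(sum(d2$success == 1 & d2$count == 0), 0)
  expect_lt(abs(mean(d2$count[d2$success == 1]) - 1 / (1 - exp(-1))),
            3 * 0.8 / sqrt(sum(d2$success == 1)))

  # marginal mode hits the ZIP zero mass and defines S = 1(C > 0)
  d3 <- simulate_dataset(panel, zeroed_params(), "zip-marginal", seed = 4)
  expect_identical(d3$success, as.integer(d3$count > 0))
  p0 <- marginal_zip_pmf(0.5, 1, 0)
  expect_lt(abs(mean(d3$count == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("covariate marginals follow the configured distributions", {
  cv <- covariate_defaults()
  panel <- flat_panel(32)
  n <- nrow(panel)
  # habitat states: chi-square against the configured probabilities
  obs <- table(factor(panel$habitat_state,
                      levels = c("strong", "weak", "sink")))
  expect_gt(chisq.test(obs, p = cv$habitat_probs)$p.value, 0.01)
  # nonbreeder presence and experience missingness rates
  expect_lt(abs(mean(panel$nonbreeders_present) - cv$p_nonbreeder),
            3 * sqrt(0.25 / n))
  expect_lt(abs(mean(panel$mask_male) - cv$p_experience_missing),
            3 * sqrt(0.1 / n))
  # territory size: KS against the configured lognormal (iid by churn)
  expect_gt(ks.test(panel$territory_size, plnorm, cv$size_meanlog,
                    cv$size_sdlog)$p.value, 0.01)
})

test_that("a YAML simulation config round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "schedule:", "  n_years: 3", "  n_populations: 2",
    "  n_territories: 7",
    "covariates:", "  p_nonbreeder: 0.4",
    "persistence: 0.8", "mode: hurdle", "seed: 99"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "zipfec_sim_config")
  expect_equal(nrow(cfg$schedule), 6)
  expect_equal(cfg$covariates$p_nonbreeder, 0.4)
  expect_equal(cfg$mode, "hurdle")
  expect_equal(cfg$seed, 99L)
  df <- simulate_panel(cfg)
  expect_equal(sum(df$success == 1 & df$count == 0), 0)
})
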
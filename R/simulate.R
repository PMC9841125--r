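# Synthetic territory-year panel generator.
#
# Emulates the structure of a long-term multi-population monitoring panel:
# an unbalanced schedule of local populations over breeding seasons,
# territories that persist across years with some turnover, covariates drawn
# from configurable distributions, and outcomes drawn from the two-part
# success/count model at chosen true parameter values.

#' Covariate-model defaults for the panel generator
#'
#' Distributions used to populate covariates when simulating a panel.
#' Habitat states follow a categorical distribution with most territories in
#' the sink state, as in fire-suppressed scrub landscapes; rainfall is
#' lognormal with a 250 mm median (cumulative Dec-Feb); territory sizes are
#' lognormal around 10 ha; per-population-year pair density is Beta
#' distributed on `[0, 1]`.  Magnitudes are plausible placeholders, chosen
#' once so that a default panel reproduces the high (~3/4) zero fraction
#' typical of fecundity data, and are fully configurable.
#'
#' @param habitat_probs named probabilities for (strong, weak, sink).
#' @param p_nonbreeder probability a pair has nonbreeders present in April.
#' @param p_experience probability a breeder is experienced.
#' @param p_experience_missing fraction of experience values masked missing.
#' @param size_meanlog,size_sdlog lognormal parameters of territory size (m^2).
#' @param density_shape Beta shape parameters of pair density.
#' @param rain_meanlog,rain_sdlog lognormal parameters of rainfall (mm).
#' @param p_food probability a population is supplementally fed.
#' @return a named list of class `zipfec_covariate_model`.
#' @export
covariate_defaults <- function(habitat_probs = c(strong = 0.2, weak = 0.3,
                                                 sink = 0.5),
                               p_nonbreeder = 0.6,
                               p_experience = 0.75,
                               p_experience_missing = 0.1,
                               size_meanlog = log(1e5), size_sdlog = 0.4,
                               density_shape = c(8, 3),
                               rain_meanlog = log(250), rain_sdlog = 0.35,
                               p_food = 0.3) {
  habitat_probs <- habitat_probs[HABITAT_LEVELS]
  stopifnot(!anyNA(habitat_probs), all(habitat_probs >= 0),
            abs(sum(habitat_probs) - 1) < 1e-8,
            p_nonbreeder >= 0, p_nonbreeder <= 1,
            p_experience >= 0, p_experience <= 1,
            p_experience_missing >= 0, p_experience_missing <= 1,
            length(density_shape) == 2, all(density_shape > 0),
            p_food >= 0, p_food <= 1)
  structure(list(habitat_probs = habitat_probs, p_nonbreeder = p_nonbreeder,
                 p_experience = p_experience,
                 p_experience_missing = p_experience_missing,
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 density_shape = density_shape,
                 rain_meanlog = rain_meanlog, rain_sdlog = rain_sdlog,
                 p_food = p_food),
            class = "zipfec_covariate_model")
}

#' Uniform population schedule
#'
#' Every population is active in every year with the same territory count.
#'
#' @param n_years number of breeding seasons.
#' @param n_populations number of local populations.
#' @param n_territories territories per population per year.
#' @param first_year calendar year of the first season.
#' @return data.frame with columns `year`, `population`, `n_territories`.
#' @export
uniform_schedule <- function(n_years, n_populations, n_territories,
                             first_year = 1988) {
  stopifnot(n_years >= 1, n_populations >= 1, n_territories >= 1)
  expand.grid(year = first_year + seq_len(n_years) - 1,
              population = paste0("P", seq_len(n_populations)),
              n_territories = n_territories,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
                , c("year", "population", "n_territories")]
}

#' The 31-year scrub-jay study schedule
#'
#' Population and territory counts per year matching the published
#' monitoring design: 1 population of 20 territories in 1988 growing to a
#' peak of 14 populations and 234 territories around 2001-2002, then
#' contracting to 4 populations of ~110 territories by 2018.  Annual
#' territory totals are split as evenly as possible across the active
#' populations (the per-population breakdown was not published).
#'
#' @param scale multiply territory counts by this factor (rounded up),
#'   e.g. `0.25` for a quarter-size panel with the same shape.
#' @return data.frame with columns `year`, `population`, `n_territories`.
#' @export
scrubjay_schedule <- function(scale = 1) {
  years <- 1988:2018
  pops <- c(1, 2, 2, 2, 2, 2, 2, 2, 2, 5, 6, 8, 13, 14, 13, 7, 7, 7, 7, 7,
            11, 3, 4, 4, 4, 4, 4, 4, 4, 4, 4)
  terr <- c(20, 37, 37, 36, 49, 45, 48, 58, 59, 94, 93, 99, 168, 218, 234,
            190, 211, 182, 170, 185, 185, 91, 111, 104, 112, 121, 122, 116,
            116, 104, 107)
  terr <- pmax(ceiling(terr * scale), 1)
  out <- do.call(rbind, lapply(seq_along(years), function(i) {
    k <- pops[i]
    base <- terr[i] %/% k
    extra <- terr[i] %% k
    data.frame(year = years[i], population = paste0("P", seq_len(k)),
               n_territories = base + (seq_len(k) <= extra))
  }))
  out[out$n_territories > 0, ]
}

#' Simulation configuration for the panel generator
#'
#' @param schedule data.frame (`year`, `population`, `n_territories`)
#'   listing the active populations per season, e.g. from
#'   [uniform_schedule()] or [scrubjay_schedule()].
#' @param params true [parameter_set()] used for outcome generation.
#' @param covariates a [covariate_defaults()] list.
#' @param persistence probability a territory survives to the next active
#'   year of its population (replaced by a fresh territory otherwise).
#' @param mode generative law: `"likelihood-exact"` draws S ~ Bernoulli(p)
#'   and C ~ Poisson(S * lambda), recording both exactly as drawn (so
#'   success-without-young rows occur with probability p * exp(-lambda));
#'   `"hurdle"` draws counts from a zero-truncated Poisson when S = 1;
#'   `"zip-marginal"` draws C from the marginal ZIP pmf and defines
#'   S = 1(C > 0).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return object of class `zipfec_sim_config`.
#' @export
sim_config <- function(schedule = scrubjay_schedule(),
                       params = default_params(),
                       covariates = covariate_defaults(),
                       persistence = 0.9,
                       mode = c("likelihood-exact", "hurdle", "zip-marginal"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(schedule),
            all(c("year", "population", "n_territories") %in%
                  names(schedule)))
  if (nrow(schedule) == 0) stop_zipfec("empty population schedule")
  if (any(schedule$n_territories < 1))
    stop_zipfec("every schedule entry needs at least one territory")
  stopifnot(inherits(params, "zipfec_params"),
            inherits(covariates, "zipfec_covariate_model"),
            persistence >= 0, persistence <= 1)
  structure(list(schedule = schedule, params = params,
                 covariates = covariates, persistence = persistence,
                 mode = mode, seed = as.integer(seed)),
            class = "zipfec_sim_config")
}

#' Build the covariate panel (no outcomes) for a simulation configuration
#'
#' Lays out one row per territory-year following the schedule: territory
#' identifiers persist across consecutive active years of their population
#' with the configured survival probability; habitat states, nonbreeder
#' presence and breeder experience are drawn per territory-year; territory
#' size is a persistent property of the territory; density is drawn per
#' population-year; rainfall per year (broadcast to all rows of that year);
#' supplemental feeding per population.  `proportion_strong` is computed
#' per population-year as (# strong territories) / (# territories).
#' Experience columns are complete here; the missingness mask is stored in
#' logical columns `mask_male` / `mask_female` and applied by
#' [simulate_dataset()] after outcomes are drawn, so the generative model
#' always sees the true covariates.
#'
#' @param config a [sim_config()].
#' @return data.frame panel of covariate rows.
#' @export
build_panel <- function(config) {
  stopifnot(inherits(config, "zipfec_sim_config"))
  set.seed(config$seed)
  cv <- config$covariates
  sched <- config$schedule[order(config$schedule$year,
                                 config$schedule$population), ]
  years <- sort(unique(sched$year))
  pops <- sort(unique(sched$population))

  rainfall <- stats::setNames(
    stats::rlnorm(length(years), cv$rain_meanlog, cv$rain_sdlog), years)
  food <- stats::setNames(
    stats::rbinom(length(pops), 1, cv$p_food), pops)

  terr_counter <- stats::setNames(integer(length(pops)), pops)
  roster <- stats::setNames(vector("list", length(pops)), pops)
  size_of <- list()

  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    yr <- sched$year[i]
    pop <- sched$population[i]
    need <- sched$n_territories[i]
    old <- roster[[pop]]
    if (length(old)) {
      keep <- old[stats::runif(length(old)) < config$persistence]
      if (length(keep) > need) keep <- keep[seq_len(need)]
    } else keep <- character(0)
    n_new <- need - length(keep)
    new_ids <- character(0)
    if (n_new > 0) {
      new_ids <- paste0(pop, "-T", terr_counter[pop] + seq_len(n_new))
      terr_counter[pop] <- terr_counter[pop] + n_new
      for (id in new_ids)
        size_of[[id]] <- stats::rlnorm(1, cv$size_meanlog, cv$size_sdlog)
    }
    ids <- c(keep, new_ids)
    roster[[pop]] <- ids
    habitat <- sample(HABITAT_LEVELS, need, replace = TRUE,
                      prob = cv$habitat_probs)
    rows[[i]] <- data.frame(
      year = yr, population = pop, territory = ids,
      habitat_state = habitat,
      nonbreeders_present = stats::rbinom(need, 1, cv$p_nonbreeder),
      male_experience = stats::rbinom(need, 1, cv$p_experience),
      female_experience = stats::rbinom(need, 1, cv$p_experience),
      mask_male = stats::runif(need) < cv$p_experience_missing,
      mask_female = stats::runif(need) < cv$p_experience_missing,
      territory_size = unlist(size_of[ids], use.names = FALSE),
      density = stats::rbeta(1, cv$density_shape[1], cv$density_shape[2]),
      proportion_strong = mean(habitat == "strong"),
      supplemental_food = food[[pop]],
      rainfall = rainfall[[as.character(yr)]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate outcomes for a covariate panel
#'
#' Standardizes the panel covariates, draws any random effects not already
#' realized in `params` from Normal(0, sigma), forms the success
#' probability and expected count per row, and draws the outcome pair
#' (S, C) under the requested generative law (see [sim_config()] for the
#' three modes).  After outcomes are drawn, the experience missingness mask
#' is applied, so returned tables carry `NA` where experience was unknown.
#'
#' @param panel covariate panel from [build_panel()].
#' @param params true [parameter_set()].
#' @param mode one of `"likelihood-exact"`, `"hurdle"`, `"zip-marginal"`.
#' @param seed integer seed for the outcome draws.
#' @return a territory-year `data.frame` with `count` and `success` columns;
#'   attributes `true_effects` (the realized random-effect vectors),
#'   `true_params` and `mode` record the generating state.
#' @export
simulate_dataset <- function(panel, params = default_params(),
                             mode = c("likelihood-exact", "hurdle",
                                      "zip-marginal"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "zipfec_params"))
  set.seed(seed)
  tmp <- panel
  tmp$count <- 0L
  tmp$mask_male <- NULL
  tmp$mask_female <- NULL
  design <- standardize_covariates(tmp)

  draw_re <- function(u, n) if (length(u)) u else stats::rnorm(n, 0, 1)
  re <- list(
    year_success = draw_re(params$year_success, length(design$year_levels)) *
      if (length(params$year_success)) 1 else params$sigma[["year_success"]],
    year_count = draw_re(params$year_count, length(design$year_levels)) *
      if (length(params$year_count)) 1 else params$sigma[["year_count"]],
    population_count = draw_re(params$population_count,
                               length(design$population_levels)) *
      if (length(params$population_count)) 1 else
        params$sigma[["population"]],
    territory_count = draw_re(params$territory_count,
                              length(design$territory_levels)) *
      if (length(params$territory_count)) 1 else params$sigma[["territory"]])
  full <- parameter_set(params$beta_success, params$beta_count, params$sigma,
                        year_success = re$year_success,
                        year_count = re$year_count,
                        population_count = re$population_count,
                        territory_count = re$territory_count)
  lp <- linear_predictors(full, design)
  n <- design$n

  if (mode == "likelihood-exact") {
    S <- stats::rbinom(n, 1, lp$p)
    C <- stats::rpois(n, S * lp$lambda)
  } else if (mode == "hurdle") {
    S <- stats::rbinom(n, 1, lp$p)
    C <- integer(n)
    on <- which(S == 1)
    if (length(on)) {
      # zero-truncated Poisson via inversion restricted to u > P(0)
      u <- stats::runif(length(on), stats::dpois(0, lp$lambda[on]), 1)
      C[on] <- stats::qpois(u, lp$lambda[on])
    }
  } else { # zip-marginal
    Z <- stats::rbinom(n, 1, lp$p)
    C <- stats::rpois(n, Z * lp$lambda)
    S <- as.integer(C > 0)
  }

  out <- panel
  out$count <- as.integer(C)
  out$success <- as.integer(S)
  out$male_experience[out$mask_male] <- NA
  out$female_experience[out$mask_female] <- NA
  out$mask_male <- NULL
  out$mask_female <- NULL
  out <- out[, c("year", "population", "territory", "count", "success",
                 "habitat_state", "nonbreeders_present", "male_experience",
                 "female_experience", "territory_size", "density",
                 "proportion_strong", "supplemental_food", "rainfall")]
  attr(out, "true_effects") <- re
  attr(out, "true_params") <- full
  attr(out, "mode") <- mode
  out
}

#' Generate a complete synthetic territory-year table
#'
#' Convenience wrapper: [build_panel()] then [simulate_dataset()], with the
#' outcome seed derived deterministically from the configuration seed.
#'
#' @param config a [sim_config()].
#' @return a territory-year `data.frame` (see [simulate_dataset()]).
#' @export
simulate_panel <- function(config) {
  panel <- build_panel(config)
  simulate_dataset(panel, config$params, config$mode,
                   seed = config$seed + 500009L)
}

#' Write a territory-year table to CSV
#'
#' One header row; missing experience encoded as empty fields; the layout
#' matches what [read_territory_table()] expects.
#'
#' @param df a territory-year `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_territory_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a simulation configuration from a YAML/JSON file
#'
#' Recognized keys: `schedule` (either `{n_years, n_populations,
#' n_territories}` for a uniform design, `{preset: scrubjay, scale}` for the
#' 31-year study shape, or an explicit list of `{year, population,
#' n_territories}` rows), `params` (named `beta_success` / `beta_count` /
#' `sigma` lists; defaults to the reference values), `covariates` (any
#' [covariate_defaults()] argument), `persistence`, `mode`, `seed`.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sched <- raw$schedule
  schedule <-
    if (is.null(sched)) scrubjay_schedule()
    else if (!is.null(sched$preset) && sched$preset == "scrubjay")
      scrubjay_schedule(scale = sched$scale %||% 1)
    else if (!is.null(sched$n_years))
      uniform_schedule(sched$n_years, sched$n_populations %||% 1,
                       sched$n_territories %||% 20,
                       first_year = sched$first_year %||% 1988)
    else do.call(rbind, lapply(sched, as.data.frame))
  params <- if (is.null(raw$params)) default_params() else {
    d <- default_params()
    bs <- unlist(raw$params$beta_success %||% d$beta_success)
    bc <- unlist(raw$params$beta_count %||% d$beta_count)
    sg <- unlist(raw$params$sigma %||% d$sigma)
    parameter_set(bs[success_terms()], bc[count_terms()], sg)
  }
  covariates <- do.call(covariate_defaults,
                        lapply(raw$covariates %||% list(), unlist))
  sim_config(schedule = schedule, params = params, covariates = covariates,
             persistence = raw$persistence %||% 0.9,
             mode = raw$mode %||% "likelihood-exact",
             seed = raw$seed %||% 1L)
}
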
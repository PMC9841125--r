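# Shared fixtures: all data are generated in code at test time.

# A small deterministic territory-year table with known values.
tiny_table <- function() {
  data.frame(
    year = c(2000, 2000, 2000, 2001, 2001, 2001),
    population = c("A", "A", "B", "A", "A", "B"),
    territory = c("A-T1", "A-T2", "B-T1", "A-T1", "A-T2", "B-T1"),
    count = c(0L, 3L, 1L, 0L, 0L, 2L),
    habitat_state = c("strong", "weak", "sink", "strong", "sink", "weak"),
    nonbreeders_present = c(1, 0, 1, 0, 1, 0),
    male_experience = c(1, 0, NA, 1, 0, 1),
    female_experience = c(0, 1, 1, NA, 0, 1),
    territory_size = c(9e4, 1.1e5, 1.0e5, 9.5e4, 1.2e5, 8e4),
    density = c(0.7, 0.7, 0.5, 0.8, 0.8, 0.6),
    proportion_strong = c(0.5, 0.5, 0, 0.5, 0.5, 0),
    supplemental_food = c(0, 0, 1, 0, 0, 1),
    rainfall = c(250, 250, 250, 180, 180, 180),
    stringsAsFactors = FALSE)
}

# A medium likelihood-exact panel: 10 years x 3 populations x 20 territories.
small_panel <- function(seed = 1, params = default_params(),
                        mode = "likelihood-exact", ...) {
  cfg <- sim_config(schedule = uniform_schedule(10, 3, 20),
                    params = params, mode = mode, seed = seed, ...)
  simulate_panel(cfg)
}

# One short real fit, cached across tests that only need *a* fitted object.
.fit_cache <- new.env(parent = emptyenv())
cached_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    df <- small_panel(seed = 101)
    .fit_cache$data <- df
    .fit_cache$fit <- suppressWarnings(
      fit_zipfec(df, chains = 3, burnin = 1500, block = 1500,
                 max_draws = 4500, seed = 11))
  }
  .fit_cache$fit
}
cached_fit_data <- function() {
  cached_fit()
  .fit_cache$data
}
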
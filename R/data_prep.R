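# Ingest territory-year tables and build the model design.
#
# A territory-year table has one row per breeding pair per season:
#   year, population, territory, count, [success], habitat_state,
#   nonbreeders_present, male_experience, female_experience,
#   territory_size, density, proportion_strong, supplemental_food, rainfall
# Experience may be missing (empty field or "NA"); everything else must be
# complete.  Habitat is coded with sink as the reference state.

HABITAT_LEVELS <- c("strong", "weak", "sink")

REQUIRED_COLUMNS <- c(
  "year", "population", "territory", "count", "habitat_state",
  "nonbreeders_present", "male_experience", "female_experience",
  "territory_size", "density", "proportion_strong", "supplemental_food",
  "rainfall")

# Continuous / count-valued covariates scaled to mean 0, SD 0.5.
SCALED_COVARIATES <- c("territory_size", "density", "proportion_strong",
                       "rainfall")

#' Read a territory-year table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming the
#' documented columns (a `success` column is optional and, when present, is
#' kept rather than re-derived).  Missing breeder-experience values may be
#' encoded as empty fields or `NA`.
#'
#' @param path path to the CSV file.
#' @return a validated territory-year `data.frame`.
#' @export
read_territory_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  validate_territory_table(df)
}

#' Validate a territory-year table
#'
#' Checks column presence, types, value ranges (counts nonnegative, habitat
#' labels among strong/weak/sink, probabilities in `[0,1]`), consistency of
#' an optional success column with the counts, and that rainfall is constant
#' within each year.  Errors name the offending row and column.
#'
#' @param df a territory-year `data.frame`.
#' @return the table, invisibly unchanged apart from type coercion.
#' @export
validate_territory_table <- function(df) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols))
    stop_zipfec("missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  fail <- function(rows, col, msg) {
    stop_zipfec("invalid ", col, " at row(s) ",
                paste(utils::head(rows, 5), collapse = ", "), ": ", msg)
  }
  chk <- function(bad, col, msg) {
    bad <- which(bad)
    if (length(bad)) fail(bad, col, msg)
  }
  chk(is.na(df$count) | df$count < 0 | df$count != floor(df$count),
      "count", "must be a nonnegative integer")
  chk(!(df$habitat_state %in% HABITAT_LEVELS), "habitat_state",
      paste("allowed labels are", paste(HABITAT_LEVELS, collapse = ", ")))
  for (col in c("nonbreeders_present", "supplemental_food"))
    chk(!(df[[col]] %in% c(0, 1)), col, "must be 0 or 1")
  for (col in c("male_experience", "female_experience"))
    chk(!is.na(df[[col]]) & !(df[[col]] %in% c(0, 1)), col,
        "must be 0, 1 or missing")
  for (col in c("density", "proportion_strong"))
    chk(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] > 1, col,
        "must lie in [0, 1]")
  chk(is.na(df$territory_size) | df$territory_size <= 0, "territory_size",
      "must be positive")
  chk(is.na(df$rainfall) | df$rainfall < 0, "rainfall",
      "must be nonnegative")
  rain_by_year <- tapply(df$rainfall, df$year,
                         function(r) length(unique(r)))
  if (any(rain_by_year > 1))
    stop_zipfec("rainfall must be constant within a year; year(s) ",
                paste(names(rain_by_year)[rain_by_year > 1], collapse = ", "),
                " carry multiple values")
  if ("success" %in% names(df)) {
    chk(!(df$success %in% c(0, 1)), "success", "must be 0 or 1")
    chk(df$count > 0 & df$success == 0, "success",
        "success = 0 with count > 0 is impossible")
  }
  df
}

#' Derive the brood-success indicator from juvenile counts
#'
#' @param counts nonnegative integer vector of juvenile counts.
#' @return binary vector: 1 where `counts > 0`, else 0.
#' @export
derive_success <- function(counts) {
  if (any(counts < 0)) stop_zipfec("counts must be nonnegative")
  as.integer(counts > 0)
}

#' Build standardized design matrices and group index maps
#'
#' Converts a territory-year table into the design object the sampler
#' consumes: the success and count design matrices (leading intercept
#' column, sink as the habitat reference level), contiguous integer index
#' maps for year, population and territory, the outcome vectors, and a
#' scaling report.  Continuous and count-valued covariates (territory size,
#' density, proportion strong, rainfall) are centred and divided by **two**
#' standard deviations, placing them on a scale comparable with the 0/1
#' indicators; binary covariates are left untouched.  Scaling moments are
#' always recomputed from the rows being analysed (using all non-missing
#' values per column), so subsetting a table changes the standardized
#' values of the remaining rows.
#'
#' If the table carries a `success` column it is kept as-is (simulated
#' panels record the latent indicator exactly as drawn, including
#' success-without-young rows); otherwise success is derived from the
#' counts.  Missing experience values propagate as `NA` columns and are
#' imputed during fitting.
#'
#' @param df a validated territory-year `data.frame`.
#' @return an object of class `zipfec_design`.
#' @export
standardize_covariates <- function(df) {
  df <- validate_territory_table(df)
  n <- nrow(df)
  if (n == 0) stop_zipfec("empty table")
  S <- if ("success" %in% names(df)) as.integer(df$success)
       else derive_success(df$count)

  scaling <- data.frame(term = SCALED_COVARIATES,
                        mean = NA_real_, sd = NA_real_)
  scaled <- list()
  for (i in seq_along(SCALED_COVARIATES)) {
    term <- SCALED_COVARIATES[i]
    x <- df[[term]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_zipfec("covariate ", term, " has zero variance; cannot standardize")
    scaling$mean[i] <- m
    scaling$sd[i] <- s
    scaled[[term]] <- (x - m) / (2 * s)
  }

  strong <- as.numeric(df$habitat_state == "strong")
  weak <- as.numeric(df$habitat_state == "weak")
  X_success <- cbind(
    intercept = 1, strong = strong, weak = weak,
    nonbreeders = as.numeric(df$nonbreeders_present),
    density = scaled$density,
    male_experience = as.numeric(df$male_experience),
    female_experience = as.numeric(df$female_experience),
    territory_size = scaled$territory_size,
    rainfall = scaled$rainfall)
  X_count <- cbind(
    intercept = 1, strong = strong, weak = weak,
    nonbreeders = as.numeric(df$nonbreeders_present),
    territory_size = scaled$territory_size,
    rainfall = scaled$rainfall,
    proportion_strong = scaled$proportion_strong,
    supplemental_food = as.numeric(df$supplemental_food),
    density = scaled$density)

  year_levels <- sort(unique(df$year))
  population_levels <- sort(unique(df$population))
  territory_levels <- sort(unique(df$territory))
  structure(
    list(records = df, n = n, S = S, C = as.integer(df$count),
         X_success = X_success, X_count = X_count,
         year_index = match(df$year, year_levels),
         population_index = match(df$population, population_levels),
         territory_index = match(df$territory, territory_levels),
         year_levels = year_levels,
         population_levels = population_levels,
         territory_levels = territory_levels,
         scaling = scaling,
         missing_male = which(is.na(df$male_experience)),
         missing_female = which(is.na(df$female_experience))),
    class = "zipfec_design")
}

#' Fill missing experience covariates with fixed values
#'
#' Returns a copy of the design whose missing male/female experience cells
#' are replaced by `value` (default 0). The MCMC sampler imputes these cells
#' as latent Bernoulli variables instead; this helper supports pointwise
#' likelihood evaluation outside the sampler.
#'
#' @param design a `zipfec_design`.
#' @param value replacement value for missing experience cells.
#' @return the completed design.
#' @export
complete_design <- function(design, value = 0) {
  design$X_success[design$missing_male, "male_experience"] <- value
  design$X_success[design$missing_female, "female_experience"] <- value
  design
}

#' Map a natural-scale covariate value onto the fitted (standardized) scale
#'
#' @param design a `zipfec_design` carrying the scaling report.
#' @param term one of the scaled covariate names.
#' @param x natural-scale value(s).
#' @return standardized value(s) `(x - mean) / (2 * sd)`.
#' @export
standardize_value <- function(design, term, x) {
  i <- match(term, design$scaling$term)
  if (is.na(i)) stop_zipfec("not a scaled covariate: ", term)
  (x - design$scaling$mean[i]) / (2 * design$scaling$sd[i])
}

#' Back-transform a standardized covariate value onto its natural scale
#'
#' Inverse of [standardize_value()]; round-trips within numerical precision.
#'
#' @inheritParams standardize_value
#' @param z standardized value(s).
#' @export
unstandardize_value <- function(design, term, z) {
  i <- match(term, design$scaling$term)
  if (is.na(i)) stop_zipfec("not a scaled covariate: ", term)
  z * 2 * design$scaling$sd[i] + design$scaling$mean[i]
}

#' @export
print.zipfec_design <- function(x, ...) {
  cat("Territory-year model design:", x$n, "records |",
      length(x$year_levels), "years,",
      length(x$population_levels), "populations,",
      length(x$territory_levels), "territories\n")
  cat("  zero counts:", sprintf("%.1f%%", 100 * mean(x$C == 0)),
      "| success rate:", sprintf("%.1f%%", 100 * mean(x$S)), "\n")
  nmiss <- length(x$missing_male) + length(x$missing_female)
  if (nmiss) cat("  missing experience cells:", nmiss, "\n")
  invisible(x)
}
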
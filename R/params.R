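# Parameter container for the two-part fecundity model.
#
# The success (Bernoulli) submodel carries fixed effects for habitat state,
# nonbreeder presence, population density, breeder experience, territory size
# and pre-season rainfall, plus a year random effect.  The count (Poisson)
# submodel carries habitat state, nonbreeder presence, territory size,
# rainfall, proportion of strong territories, supplemental feeding and
# density, plus year, population and territory random effects.

#' Names of the success-submodel design columns, in design-matrix order
#' @keywords internal
success_terms <- function() {
  c("intercept", "strong", "weak", "nonbreeders", "density",
    "male_experience", "female_experience", "territory_size", "rainfall")
}

#' Names of the count-submodel design columns, in design-matrix order
#' @keywords internal
count_terms <- function() {
  c("intercept", "strong", "weak", "nonbreeders", "territory_size",
    "rainfall", "proportion_strong", "supplemental_food", "density")
}

#' Construct a parameter set for the zero-inflated fecundity model
#'
#' Bundles the regression coefficients of both submodels (on the logit and
#' log scales respectively), the four random-effect standard deviations, and
#' optionally realized random-effect vectors.  Coefficients refer to
#' covariates standardized to mean 0 / SD 0.5 (binary indicators stay 0/1),
#' so effect sizes are comparable across terms.
#'
#' @param beta_success named numeric vector of success-submodel coefficients;
#'   names and order must match [success_terms()].
#' @param beta_count named numeric vector of count-submodel coefficients;
#'   names and order must match [count_terms()].
#' @param sigma named numeric vector with elements `year_success`,
#'   `year_count`, `territory`, `population`; all must be nonnegative.
#' @param year_success,year_count,population_count,territory_count optional
#'   realized random-effect vectors (one element per group level). Empty
#'   vectors mean "draw from Normal(0, sigma) when simulating".
#' @return an object of class `zipfec_params`.
#' @seealso [default_params()], [zeroed_params()]
#' @export
parameter_set <- function(beta_success, beta_count, sigma,
                          year_success = numeric(0), year_count = numeric(0),
                          population_count = numeric(0),
                          territory_count = numeric(0)) {
  beta_success <- unlist(beta_success)
  beta_count <- unlist(beta_count)
  if (!identical(names(beta_success), success_terms()))
    stop_zipfec("beta_success must be named exactly: ",
                paste(success_terms(), collapse = ", "))
  if (!identical(names(beta_count), count_terms()))
    stop_zipfec("beta_count must be named exactly: ",
                paste(count_terms(), collapse = ", "))
  sig_names <- c("year_success", "year_count", "territory", "population")
  sigma <- unlist(sigma)[sig_names]
  if (anyNA(sigma))
    stop_zipfec("sigma must supply: ", paste(sig_names, collapse = ", "))
  if (any(sigma < 0)) stop_zipfec("random-effect SDs must be >= 0")
  structure(
    list(beta_success = beta_success, beta_count = beta_count, sigma = sigma,
         year_success = year_success, year_count = year_count,
         population_count = population_count,
         territory_count = territory_count),
    class = "zipfec_params")
}

#' Reference parameter values for the fecundity model
#'
#' Returns the parameter set used as the simulator default: posterior-mean
#' regression coefficients and random-effect SDs estimated from a 31-year
#' Florida scrub-jay monitoring panel. Habitat effects are relative to the
#' sink reference state. Notable values: strong habitat raises the log-odds
#' of brood success by 1.28 and log expected count by 0.26; supplemental
#' feeding raises log counts by 0.55; the year effect on success has SD 0.90
#' versus 0.26 on counts.
#'
#' @return a `zipfec_params` object with empty random-effect vectors.
#' @export
default_params <- function() {
  parameter_set(
    beta_success = stats::setNames(
      c(-1.11, 1.28, 0.34, 0.37, 0.12, -0.07, 0.07, 0.20, -0.22),
      success_terms()),
    beta_count = stats::setNames(
      c(-0.41, 0.26, 0.19, 0.10, 0.08, -0.01, 0.18, 0.55, -0.14),
      count_terms()),
    sigma = c(year_success = 0.90, year_count = 0.26,
              territory = 0.06, population = 0.18))
}

#' Null parameter set (all coefficients and SDs zero)
#'
#' Every beta and every random-effect SD is 0, so simulated panels have
#' p = 0.5 and lambda = 1 everywhere; used for calibration runs.
#'
#' @return a `zipfec_params` object.
#' @export
zeroed_params <- function() {
  parameter_set(
    beta_success = stats::setNames(rep(0, 9), success_terms()),
    beta_count = stats::setNames(rep(0, 9), count_terms()),
    sigma = c(year_success = 0, year_count = 0,
              territory = 0, population = 0))
}

#' @export
print.zipfec_params <- function(x, ...) {
  cat("Zero-inflated fecundity model parameters\n")
  cat("  success submodel (logit scale):\n")
  print(round(x$beta_success, 3))
  cat("  count submodel (log scale):\n")
  print(round(x$beta_count, 3))
  cat("  random-effect SDs:\n")
  print(round(x$sigma, 3))
  n_re <- lengths(x[c("year_success", "year_count",
                      "population_count", "territory_count")])
  if (any(n_re > 0))
    cat("  realized random effects:",
        paste(names(n_re)[n_re > 0], n_re[n_re > 0], collapse = ", "), "\n")
  invisible(x)
}
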
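# Probability core: linear predictors, the factorized success x count
# likelihood, priors, and the marginal ZIP pmf used as a validation oracle.
#
# The observation model for a territory-year is
#   S ~ Bernoulli(p),          logit(p)  = X_s b_s + Year_s[year]
#   C ~ Poisson(S * lambda),   log(lambda) = X_c b_c + Year_c[year]
#                                          + Population[pop] + Territory[terr]
# with S the brood-success indicator and C the July juvenile count.  S is
# observed (derived from C on real data), so the Poisson factor is *not*
# zero-truncated: a successful pair contributes Poisson(C | lambda) even at
# C = 0.  The marginal ZIP pmf below integrates S out and is kept as an
# independent cross-check of that factorization.

#' Prior specification for the fecundity model
#'
#' Coefficients get independent Normal(0, `beta_sd`) priors on the link
#' scale; random-effect SDs get half-normal priors, i.e. the right half of
#' Normal(0, `sigma_sd`) with density 2*phi(x; 0, sigma_sd) on x >= 0.  The
#' default half-normal SD of 2.24 gives a weakly informative prior with a
#' much shorter tail than a half-Cauchy, which speeds convergence because
#' the count submodel exponentiates its random effects.
#'
#' @param beta_sd prior SD for regression coefficients (default 10).
#' @param sigma_sd scale of the half-normal prior on random-effect SDs
#'   (default 2.24).
#' @return an object of class `zipfec_priors`.
#' @export
prior_spec <- function(beta_sd = 10, sigma_sd = 2.24) {
  stopifnot(beta_sd > 0, sigma_sd > 0)
  structure(list(beta_sd = beta_sd, sigma_sd = sigma_sd),
            class = "zipfec_priors")
}

# Random-effect vectors aligned to the design's group counts; empty vectors
# are promoted to zeros so fixed-effect-only evaluation works.
aligned_effects <- function(params, design) {
  align1 <- function(u, n, what) {
    if (length(u) == 0) return(rep(0, n))
    if (length(u) != n)
      stop_zipfec("length of ", what, " effects (", length(u),
                  ") does not match the number of groups (", n, ")")
    u
  }
  list(
    year_success = align1(params$year_success, length(design$year_levels),
                          "year_success"),
    year_count = align1(params$year_count, length(design$year_levels),
                        "year_count"),
    population = align1(params$population_count,
                        length(design$population_levels), "population"),
    territory = align1(params$territory_count,
                       length(design$territory_levels), "territory"))
}

#' Evaluate the success probability and expected count per record
#'
#' Applies the logit-linear success submodel and log-linear count submodel
#' to every row of a prepared design, adding the realized random effects
#' carried by `params` (missing/empty effect vectors count as zero).
#'
#' @param params a [parameter_set()].
#' @param design a `zipfec_design` from [standardize_covariates()].
#' @return list with components `p` (success probabilities in (0,1)) and
#'   `lambda` (expected counts, > 0), each of length `design$n`.
#' @export
linear_predictors <- function(params, design) {
  stopifnot(inherits(params, "zipfec_params"),
            inherits(design, "zipfec_design"))
  if (anyNA(design$X_success))
    stop_zipfec("design matrix has missing covariate values; ",
                "impute experience first (see complete_design())")
  re <- aligned_effects(params, design)
  eta_s <- drop(design$X_success %*% params$beta_success) +
    re$year_success[design$year_index]
  eta_c <- drop(design$X_count %*% params$beta_count) +
    re$year_count[design$year_index] +
    re$population[design$population_index] +
    re$territory[design$territory_index]
  list(p = invlogit(eta_s), lambda = exp(eta_c))
}

#' Joint log-likelihood of the factorized success/count model
#'
#' Sum over records of the Bernoulli log-likelihood of the success
#' indicator plus the Poisson log-likelihood of the count with mean
#' `S * lambda`; Poisson(0 | 0) contributes 0.  A positive count with
#' S = 0 is impossible under the model and raises an error.
#'
#' @inheritParams linear_predictors
#' @return scalar log-likelihood.
#' @export
joint_log_likelihood <- function(params, design) {
  lp <- linear_predictors(params, design)
  S <- design$S
  C <- design$C
  if (any(C > 0 & S == 0))
    stop_zipfec("impossible record: count > 0 with success = 0")
  eta_s <- stats::qlogis(lp$p)
  ll_s <- sum(bern_logit_ll(S, eta_s))
  on <- S == 1
  ll_c <- sum(stats::dpois(C[on], lp$lambda[on], log = TRUE))
  ll_s + ll_c
}

#' Marginal zero-inflated Poisson pmf
#'
#' Probability of observing count `c` once the latent success indicator is
#' integrated out: `(1-p) * 1(c = 0) + p * Poisson(c | lambda)`.  Vectorized
#' over all three arguments.
#'
#' @param p zero-inflation (success) probability in `[0, 1]`.
#' @param lambda Poisson mean, >= 0.
#' @param c nonnegative integer count.
#' @return probability of `C = c`.
#' @export
marginal_zip_pmf <- function(p, lambda, c) {
  stopifnot(all(p >= 0 & p <= 1), all(lambda >= 0), all(c >= 0))
  (1 - p) * (c == 0) + p * stats::dpois(c, lambda)
}

# log of the half-normal density 2*phi(x; 0, sd) on x >= 0
dhalfnorm_log <- function(x, sd) {
  ifelse(x < 0, -Inf, log(2) + stats::dnorm(x, 0, sd, log = TRUE))
}

#' Joint log prior density of a parameter set
#'
#' Normal(0, `beta_sd`) over all coefficients, half-normal(`sigma_sd`) over
#' the four random-effect SDs, and Normal(0, sigma_group) over each realized
#' random-effect vector carried by `params` (empty vectors contribute 0).
#' Any negative SD yields `-Inf` (a rejected state).
#'
#' @inheritParams linear_predictors
#' @param priors a [prior_spec()].
#' @return scalar log prior density.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  stopifnot(inherits(params, "zipfec_params"),
            inherits(priors, "zipfec_priors"))
  if (any(params$sigma < 0)) return(-Inf)
  lp <- sum(stats::dnorm(c(params$beta_success, params$beta_count),
                         0, priors$beta_sd, log = TRUE)) +
    sum(dhalfnorm_log(params$sigma, priors$sigma_sd))
  re <- list(year_success = params$year_success,
             year_count = params$year_count,
             population = params$population_count,
             territory = params$territory_count)
  sig <- params$sigma[c("year_success", "year_count",
                        "population", "territory")]
  for (k in seq_along(re)) {
    if (length(re[[k]]) == 0) next
    lp <- lp + sum(stats::dnorm(re[[k]], 0, sig[[k]], log = TRUE))
  }
  lp
}
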
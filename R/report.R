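# Posterior reporting: coefficient summary table, covariate-profile
# predictions, and annual random-effect HPD summaries.

TABLE_LABELS <- c(
  "success.intercept" = "Intercept",
  "success.strong" = "Strong",
  "success.weak" = "Weak",
  "success.nonbreeders" = "Nonbreeders present",
  "success.density" = "Population density",
  "success.male_experience" = "Male experience",
  "success.female_experience" = "Female experience",
  "success.territory_size" = "Territory size",
  "success.rainfall" = "Mean rainfall",
  "count.intercept" = "Intercept",
  "count.strong" = "Strong",
  "count.weak" = "Weak",
  "count.nonbreeders" = "Nonbreeders present",
  "count.territory_size" = "Territory size",
  "count.rainfall" = "Mean rainfall",
  "count.proportion_strong" = "Proportion strong in population",
  "count.supplemental_food" = "Supplemental food in population",
  "count.density" = "Population density",
  "sigma.year_success" = "sigma Year (success)",
  "sigma.year_count" = "sigma Year (count)",
  "sigma.territory" = "sigma Territory (count)",
  "sigma.population" = "sigma Population (count)",
  "deviance" = "Deviance")

#' Posterior summary table in the standard report layout
#'
#' One row per parameter with posterior mean, SD, central 95% credible
#' interval, split-chain Rhat and effective sample size.  Rows are ordered
#' success submodel, count submodel, random-effect SDs, then the deviance;
#' random effects and auxiliary parameters can be appended.
#'
#' @param fit a `zipfec_fit`.
#' @param include_random also list the individual random effects.
#' @return data.frame with columns `submodel`, `term`, `parameter`, `mean`,
#'   `sd`, `q2.5`, `q97.5`, `rhat`, `n_eff`.
#' @export
posterior_summary <- function(fit, include_random = FALSE) {
  conv <- convergence_summary(fit)
  m <- draws_matrix(fit)
  order_main <- names(TABLE_LABELS)
  pars <- if (include_random)
    c(order_main, setdiff(colnames(m), order_main)) else order_main
  stats_of <- function(p) {
    x <- m[, p]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    i <- match(p, conv$table$parameter)
    c(mean(x), stats::sd(x), q, conv$table$rhat[i], conv$table$ess[i])
  }
  vals <- t(vapply(pars, stats_of, numeric(6)))
  submodel <- ifelse(grepl("^success\\.", pars), "success",
              ifelse(grepl("^count\\.", pars), "count",
              ifelse(grepl("^sigma\\.", pars), "random effect",
                     "diagnostic")))
  term <- ifelse(pars %in% names(TABLE_LABELS),
                 TABLE_LABELS[pars], pars)
  out <- data.frame(submodel = submodel, term = unname(term),
                    parameter = pars, mean = vals[, 1], sd = vals[, 2],
                    q2.5 = vals[, 3], q97.5 = vals[, 4],
                    rhat = vals[, 5], n_eff = vals[, 6],
                    row.names = NULL)
  out
}

#' Shortest (highest posterior density) interval of a draw vector
#'
#' Computed as the shortest contiguous interval over the sorted draws that
#' contains a `prob` fraction of them.
#'
#' @param x numeric draws.
#' @param prob target probability mass (e.g. 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(prob > 0, prob <= 1)
  x <- sort(x)
  n <- length(x)
  k <- max(1, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Annual random-effect summary (mean and HPD intervals)
#'
#' Per year and submodel: posterior mean and the 90% and 95% highest
#' posterior density intervals of the year random effect.
#'
#' @param fit a `zipfec_fit`.
#' @return data.frame with one row per year x submodel.
#' @export
annual_effects_summary <- function(fit) {
  one <- function(submodel) {
    m <- year_effect_draws(fit, submodel)
    t(apply(m, 2, function(x)
      c(mean = mean(x), hpd90 = hpd_interval(x, 0.90),
        hpd95 = hpd_interval(x, 0.95))))
  }
  out <- do.call(rbind, lapply(c("success", "count"), function(sm) {
    v <- one(sm)
    data.frame(submodel = sm, year = fit$design$year_levels,
               mean = v[, 1], hpd90_lower = v[, 2], hpd90_upper = v[, 3],
               hpd95_lower = v[, 4], hpd95_upper = v[, 5],
               row.names = NULL)
  }))
  out
}

#' Default prediction profiles: habitat state x nonbreeder presence
#'
#' Six profiles covering every combination of the three habitat states and
#' nonbreeder presence/absence, with all other covariates at their
#' reference values (continuous covariates at the data means, experience
#' and supplemental feeding at 0).
#'
#' @return data.frame of profiles for [predict_profiles()].
#' @export
default_profiles <- function() {
  expand.grid(habitat_state = HABITAT_LEVELS,
              nonbreeders_present = c(0, 1),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Population-average predictions for covariate profiles
#'
#' For each profile (natural-scale covariate values; omitted covariates
#' default to the reference: data means for continuous terms, 0 for binary
#' indicators) and each posterior draw, computes the success probability
#' `p = invlogit(x_s' beta_s)`, the expected count given the linear
#' predictor `lambda = exp(x_c' beta_c)`, and the fecundity `p * lambda`
#' (expected juveniles per pair-year), with all random effects set to 0
#' (population-average prediction).  Continuous values are mapped onto the
#' fitted standardized scale through the stored scaling report.
#'
#' @param fit a `zipfec_fit`.
#' @param profiles data.frame of profiles; recognized columns are
#'   `habitat_state`, `nonbreeders_present`, `male_experience`,
#'   `female_experience`, `supplemental_food`, `territory_size`, `density`,
#'   `proportion_strong`, `rainfall`.  Unknown columns raise an error.
#' @return data.frame: one row per profile x target (`success`, `count`,
#'   `fecundity`) with posterior mean and central 95% CI.
#' @export
predict_profiles <- function(fit, profiles = default_profiles()) {
  des <- fit$design
  known <- c("habitat_state", "nonbreeders_present", "male_experience",
             "female_experience", "supplemental_food", "territory_size",
             "density", "proportion_strong", "rainfall")
  unknown <- setdiff(names(profiles), known)
  if (length(unknown))
    stop_zipfec("unknown profile covariate(s): ",
                paste(unknown, collapse = ", "))
  get_col <- function(col, default) {
    if (col %in% names(profiles)) profiles[[col]] else
      rep(default, nrow(profiles))
  }
  habitat <- get_col("habitat_state", "sink")
  if (!all(habitat %in% HABITAT_LEVELS))
    stop_zipfec("habitat_state must be one of ",
                paste(HABITAT_LEVELS, collapse = ", "))
  scaled <- function(term) {
    nat <- get_col(term, unstandardize_value(des, term, 0))
    standardize_value(des, term, nat)
  }
  xs <- cbind(intercept = 1,
              strong = as.numeric(habitat == "strong"),
              weak = as.numeric(habitat == "weak"),
              nonbreeders = get_col("nonbreeders_present", 0),
              density = scaled("density"),
              male_experience = get_col("male_experience", 0),
              female_experience = get_col("female_experience", 0),
              territory_size = scaled("territory_size"),
              rainfall = scaled("rainfall"))
  xc <- cbind(intercept = 1,
              strong = xs[, "strong"], weak = xs[, "weak"],
              nonbreeders = xs[, "nonbreeders"],
              territory_size = xs[, "territory_size"],
              rainfall = xs[, "rainfall"],
              proportion_strong = scaled("proportion_strong"),
              supplemental_food = get_col("supplemental_food", 0),
              density = xs[, "density"])
  BS <- draws_matrix(fit, paste0("success.", success_terms()))
  BC <- draws_matrix(fit, paste0("count.", count_terms()))
  P <- invlogit(BS %*% t(xs))       # draws x profiles
  Lam <- exp(BC %*% t(xc))
  Fec <- P * Lam
  summarize <- function(M, target) {
    data.frame(profile = seq_len(nrow(profiles)),
               habitat_state = habitat,
               nonbreeders_present = get_col("nonbreeders_present", 0),
               target = target,
               mean = colMeans(M),
               q2.5 = apply(M, 2, stats::quantile, 0.025),
               q97.5 = apply(M, 2, stats::quantile, 0.975),
               row.names = NULL)
  }
  rbind(summarize(P, "success"), summarize(Lam, "count"),
        summarize(Fec, "fecundity"))
}
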
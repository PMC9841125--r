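# Posterior-predictive and year-effect diagnostics.
#
# Three bespoke checks accompany the model:
#   * a Bayesian p-value from the Freeman-Tukey discrepancy between
#     observed juvenile counts and their marginal expectations p*lambda,
#     against replicate data simulated per posterior draw;
#   * a Bayesian runs test: per draw, the number of sign changes along the
#     sequence of annual random effects is compared with the sign changes
#     of a freshly drawn Bernoulli(1/2) sequence of the same length,
#     detecting runs of good or bad years;
#   * the posterior of the Pearson correlation between the success and
#     count year-effect vectors, asking whether the two processes share
#     their annual variation.

#' Freeman-Tukey discrepancy between counts and expected means
#'
#' `sum_i (sqrt(y_i) - sqrt(E_i))^2`, a variance-stabilized chi-square-type
#' discrepancy suited to small counts.
#'
#' @param observed nonnegative observed counts.
#' @param expected nonnegative expected means, same length.
#' @return scalar discrepancy.
#' @export
freeman_tukey <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop_zipfec("observed and expected lengths differ")
  stopifnot(all(observed >= 0), all(expected >= 0))
  sum((sqrt(observed) - sqrt(expected))^2)
}

# per-draw success/count linear predictors for a chunk of posterior draws;
# returns list(P, Lam): n x ndraw matrices.  Missing experience cells enter
# at the draw's experience prevalence (posterior-mean imputation).
draw_predictors <- function(fit, rows) {
  d <- draws_matrix(fit)[rows, , drop = FALSE]
  des <- fit$design
  BS <- d[, paste0("success.", success_terms()), drop = FALSE]
  colnames(BS) <- success_terms()
  BC <- d[, paste0("count.", count_terms()), drop = FALSE]
  colnames(BC) <- count_terms()
  US <- d[, grep("^year_success\\[", colnames(d)), drop = FALSE]
  UC <- d[, grep("^year_count\\[", colnames(d)), drop = FALSE]
  VP <- d[, grep("^population\\[", colnames(d)), drop = FALSE]
  WT <- d[, grep("^territory\\[", colnames(d)), drop = FALSE]

  XS0 <- des$X_success
  XS0[des$missing_male, "male_experience"] <- 0
  XS0[des$missing_female, "female_experience"] <- 0
  EtaS <- XS0 %*% t(BS) + t(US)[des$year_index, , drop = FALSE]
  if (length(des$missing_male))
    EtaS[des$missing_male, ] <- EtaS[des$missing_male, , drop = FALSE] +
      rep(d[, "p_male_experience"] * BS[, "male_experience"],
          each = length(des$missing_male))
  if (length(des$missing_female))
    EtaS[des$missing_female, ] <- EtaS[des$missing_female, , drop = FALSE] +
      rep(d[, "p_female_experience"] * BS[, "female_experience"],
          each = length(des$missing_female))
  EtaC <- des$X_count %*% t(BC) + t(UC)[des$year_index, , drop = FALSE] +
    t(VP)[des$population_index, , drop = FALSE] +
    t(WT)[des$territory_index, , drop = FALSE]
  list(P = invlogit(EtaS), Lam = exp(EtaC))
}

#' Posterior predictive p-value from the Freeman-Tukey discrepancy
#'
#' For each retained draw, the observed discrepancy compares the data
#' counts with their marginal expected values `E_i = p_i * lambda_i`; a
#' replicate data set is then drawn from the same state (S ~ Bernoulli(p),
#' C ~ Poisson(S * lambda), conditioning on the draw's random effects so
#' observed and replicate discrepancies are exchangeable) and scored
#' against the same expectations.  The p-value is the fraction of draws
#' whose replicate discrepancy exceeds the observed one; values near 0 or
#' 1 flag misfit.
#'
#' @param fit a `zipfec_fit`.
#' @param seed seed for the replicate draws.
#' @param counts optional count vector overriding the fitted data (used
#'   for sensitivity checks); defaults to the counts the model was fit to.
#' @param chunk draws processed per block (memory control).
#' @return the p-value, with attributes `ft_obs` and `ft_rep` carrying the
#'   per-draw discrepancies.
#' @export
ppc_pvalue <- function(fit, seed = 1L, counts = NULL, chunk = 500L) {
  set.seed(seed)
  C_obs <- counts %||% fit$design$C
  if (length(C_obs) != fit$design$n)
    stop_zipfec("counts length must match the fitted data")
  ndraw <- sum(vapply(fit$draws, nrow, integer(1)))
  n <- fit$design$n
  sqrtC <- sqrt(C_obs)
  ft_obs <- ft_rep <- numeric(ndraw)
  for (from in seq(1, ndraw, by = chunk)) {
    rows <- from:min(from + chunk - 1, ndraw)
    pr <- draw_predictors(fit, rows)
    E <- pr$P * pr$Lam
    ft_obs[rows] <- colSums((sqrtC - sqrt(E))^2)
    S_rep <- stats::rbinom(length(pr$P), 1, pr$P)
    C_rep <- stats::rpois(length(pr$P), S_rep * pr$Lam)
    ft_rep[rows] <- colSums((sqrt(matrix(C_rep, n)) - sqrt(E))^2)
  }
  structure(mean(ft_rep > ft_obs), ft_obs = ft_obs, ft_rep = ft_rep)
}

#' Count sign changes along a sequence
#'
#' Number of adjacent pairs with opposite signs.  Exact zeros (probability
#' zero for posterior draws) inherit the sign of the previous element; a
#' leading zero counts as positive.
#'
#' @param x numeric vector, length >= 1.
#' @return integer count in `0 .. length(x) - 1`.
#' @export
sign_changes <- function(x) {
  if (length(x) == 0) stop_zipfec("empty sequence")
  s <- sign(x)
  if (s[1] == 0) s[1] <- 1
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  sum(s[-1] != s[-length(s)])
}

#' Bayesian runs test on annual random-effect draws
#'
#' Per posterior draw, counts the sign changes of the year-effect sequence
#' and compares them with the sign changes of a freshly generated random
#' Bernoulli(1/2) sequence of the same length (mapped to signs).  The
#' returned p-value is the frequency with which the year effects show
#' *fewer* sign changes than the random reference -- i.e. the posterior
#' evidence for runs of consecutive good or bad years.  Strict inequality
#' is used; `midp = TRUE` counts ties as 1/2.
#'
#' @param year_draws draws matrix, iterations x years (e.g. from
#'   [year_effect_draws()]).
#' @param seed seed for the reference sequences.
#' @param midp use the mid-p tie convention (default `FALSE`).
#' @return scalar p-value in `[0, 1]`.
#' @export
runs_pvalue <- function(year_draws, seed = 1L, midp = FALSE) {
  year_draws <- as.matrix(year_draws)
  ny <- ncol(year_draws)
  if (ny < 2) stop_zipfec("need at least 2 years")
  set.seed(seed)
  s <- apply(year_draws, 1, sign_changes)
  ref <- matrix(stats::rbinom(nrow(year_draws) * ny, 1, 0.5),
                nrow(year_draws), ny)
  r <- rowSums(ref[, -1, drop = FALSE] != ref[, -ny, drop = FALSE])
  if (midp) mean(s < r) + 0.5 * mean(s == r) else mean(s < r)
}

#' Posterior correlation between success and count year effects
#'
#' Pearson correlation across years, computed within each posterior draw;
#' the draw-level correlations form the posterior of rho.  Draws where
#' either vector is constant have undefined correlation; they are dropped
#' and counted.
#'
#' @param success_draws,count_draws aligned draw matrices
#'   (iterations x years) for the two submodels.
#' @return list: `draws` (rho per retained draw), `mean`, `ci` (central
#'   95% interval), `n_excluded`.
#' @export
year_effect_correlation <- function(success_draws, count_draws) {
  success_draws <- as.matrix(success_draws)
  count_draws <- as.matrix(count_draws)
  if (!all(dim(success_draws) == dim(count_draws)))
    stop_zipfec("draw matrices must be aligned")
  if (ncol(success_draws) < 3)
    stop_zipfec("need at least 3 years to correlate")
  a <- success_draws - rowMeans(success_draws)
  b <- count_draws - rowMeans(count_draws)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  rho <- ifelse(den > 0, rowSums(a * b) / den, NA_real_)
  bad <- !is.finite(rho)
  rho <- rho[!bad]
  list(draws = rho, mean = mean(rho),
       ci = unname(stats::quantile(rho, c(0.025, 0.975))),
       n_excluded = sum(bad))
}

#' Full diagnostics report for a fitted model
#'
#' Bundles the Freeman-Tukey posterior predictive p-value, the runs-test
#' p-values for both submodels' year effects, the posterior of the
#' cross-submodel year-effect correlation, and a per-observation residual
#' table (observed count vs posterior-mean expected count).
#'
#' @param fit a `zipfec_fit`.
#' @param seed seed shared by the replicate and reference simulations.
#' @return an object of class `zipfec_diagnostics`.
#' @export
diagnostics_report <- function(fit, seed = 1L) {
  p_ft <- ppc_pvalue(fit, seed = seed)
  us <- year_effect_draws(fit, "success")
  uc <- year_effect_draws(fit, "count")
  rho <- year_effect_correlation(us, uc)
  # posterior-mean expected count per observation
  ndraw <- sum(vapply(fit$draws, nrow, integer(1)))
  Ebar <- numeric(fit$design$n)
  for (from in seq(1, ndraw, by = 500)) {
    rows <- from:min(from + 499, ndraw)
    pr <- draw_predictors(fit, rows)
    Ebar <- Ebar + rowSums(pr$P * pr$Lam)
  }
  Ebar <- Ebar / ndraw
  res <- data.frame(year = fit$design$records$year,
                    population = fit$design$records$population,
                    territory = fit$design$records$territory,
                    observed = fit$design$C, expected = Ebar,
                    pearson_residual = (fit$design$C - Ebar) / sqrt(Ebar))
  structure(
    list(bayesian_p_ft = as.numeric(p_ft),
         runs_p_success = runs_pvalue(us, seed = seed + 1L),
         runs_p_count = runs_pvalue(uc, seed = seed + 2L),
         rho_mean = rho$mean, rho_ci = rho$ci,
         rho_draws = rho$draws, rho_excluded = rho$n_excluded,
         residuals = res, seed = seed),
    class = "zipfec_diagnostics")
}

#' @export
print.zipfec_diagnostics <- function(x, ...) {
  cat("Posterior diagnostics\n")
  cat(sprintf("  Freeman-Tukey Bayesian p-value: %.3f\n", x$bayesian_p_ft))
  cat(sprintf("  runs test p (success year effects): %.3f\n",
              x$runs_p_success))
  cat(sprintf("  runs test p (count year effects):   %.3f\n",
              x$runs_p_count))
  cat(sprintf("  year-effect correlation: mean %.3f, 95%% CI (%.2f, %.2f)\n",
              x$rho_mean, x$rho_ci[1], x$rho_ci[2]))
  invisible(x)
}

#' Serialize a diagnostics report to JSON
#'
#' @param x a `zipfec_diagnostics`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(x, path) {
  jsonlite::write_json(
    list(bayesian_p_ft = x$bayesian_p_ft,
         runs_p_success = x$runs_p_success,
         runs_p_count = x$runs_p_count,
         rho_mean = x$rho_mean,
         rho_ci = as.numeric(x$rho_ci),
         rho_excluded = x$rho_excluded,
         seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
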
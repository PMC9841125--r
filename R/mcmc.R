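# Adaptive Metropolis-within-Gibbs sampler for the two-part fecundity model.
#
# The update sweep (compiled, see src/sampler.cpp) per iteration:
#   * each regression coefficient: scalar random-walk MH with cached linear
#     predictors and delta-likelihood evaluation;
#   * each random-effect block (year-success, year-count, population,
#     territory): jointly proposed, accepted/rejected per group -- groups
#     touch disjoint row sets, so the per-group decisions are exact;
#   * each random-effect SD: univariate slice sampler on its closed-form
#     conditional (no tuning, preserves the half-normal prior);
#   * ancillary likelihood-invariant moves that transfer mass between an
#     intercept (or a year/population-level slope: rainfall, supplemental
#     food) and the corresponding random-effect vector -- these break the
#     strong posterior correlations among year- and population-level
#     quantities that otherwise stall a random-walk sampler;
#   * latent missing experience covariates: exact Gibbs draws, with
#     Beta-conjugate updates of the population-level experience prevalence.
# Proposal scales adapt toward a 44% acceptance rate during burn-in only,
# so the post-burn-in chain has the correct stationary distribution.

restore_rng <- function(st) assign(".Random.seed", st$rng, envir = globalenv())
save_rng <- function(st) st$rng <- get(".Random.seed", envir = globalenv())

make_chain_state <- function(design, priors, chain_seed,
                             prior_only = FALSE) {
  st <- new.env(parent = emptyenv())
  set.seed(chain_seed)
  st$seed <- chain_seed
  st$prior_only <- prior_only

  st$S <- design$S
  st$XS <- design$X_success
  st$Y <- length(design$year_levels)
  st$P <- length(design$population_levels)
  st$T <- length(design$territory_levels)
  st$yi0 <- design$year_index - 1L

  idx1 <- which(design$S == 1)
  st$C1 <- design$C[idx1]
  st$XC1 <- design$X_count[idx1, , drop = FALSE]
  st$yi10 <- design$year_index[idx1] - 1L
  st$pi10 <- design$population_index[idx1] - 1L
  st$ti10 <- design$territory_index[idx1] - 1L
  st$lgamma_const <- sum(lgamma(st$C1 + 1))

  st$mi_m0 <- design$missing_male - 1L
  st$mi_f0 <- design$missing_female - 1L

  # year-level standardized rainfall and population-level food flag, for
  # the ancillary exchange moves
  first_of_year <- match(seq_len(st$Y), design$year_index)
  st$rainS_y <- design$X_success[first_of_year, "rainfall"]
  st$rainC_y <- design$X_count[first_of_year, "rainfall"]
  food_by_pop <- tapply(design$X_count[, "supplemental_food"],
                        design$population_index,
                        function(x) if (length(unique(x)) == 1) x[1] else NA)
  st$food_exchange_ok <- !anyNA(food_by_pop)
  st$food_p <- as.numeric(ifelse(is.na(food_by_pop), 0, food_by_pop))

  # initial values: coefficients ~ N(0, 0.5), SDs ~ |N(0, 0.5)|
  st$bs <- stats::rnorm(9, 0, 0.5)
  st$bc <- stats::rnorm(9, 0, 0.5)
  st$sig <- pmax(abs(stats::rnorm(4, 0, 0.5)), 0.02)
  names(st$sig) <- c("year_success", "year_count", "territory", "population")
  st$uS <- stats::rnorm(st$Y, 0, 0.1)
  st$uC <- stats::rnorm(st$Y, 0, 0.1)
  st$vP <- stats::rnorm(st$P, 0, 0.1)
  st$wT <- stats::rnorm(st$T, 0, 0.1)
  st$piM <- 0.5
  st$piF <- 0.5
  st$XS[design$missing_male, "male_experience"] <-
    stats::rbinom(length(design$missing_male), 1, 0.5)
  st$XS[design$missing_female, "female_experience"] <-
    stats::rbinom(length(design$missing_female), 1, 0.5)

  # cached linear predictors
  st$etaS <- drop(st$XS %*% st$bs) + st$uS[design$year_index]
  st$l1pS <- log1pexp(st$etaS)
  st$etaC1 <- drop(st$XC1 %*% st$bc) + st$uC[st$yi10 + 1L] +
    st$vP[st$pi10 + 1L] + st$wT[st$ti10 + 1L]
  st$expC1 <- exp(st$etaC1)

  # adaptive proposal scales (log) and acceptance counters
  st$ls_bs <- rep(log(0.1), 9)
  st$ls_bc <- rep(log(0.1), 9)
  st$ls_re <- rep(log(0.3), 4)
  st$ls_aux <- rep(log(0.2), 7)
  st$ls_sig <- rep(log(0.3), 4)
  st$acc_bs <- numeric(9); st$acc_bc <- numeric(9)
  st$acc_re <- numeric(4); st$acc_aux <- numeric(7)
  st$acc_sig <- numeric(4)
  st$batch <- 0L
  st$priors <- priors

  save_rng(st)
  st
}

chain_iterate <- function(st, n_iter, adapt = FALSE, record = TRUE,
                          param_names = NULL) {
  if (n_iter == 0) return(NULL)
  restore_rng(st)
  res <- zipfec_sweep(as.list(st), n_iter, adapt, record,
                      w = if (st$prior_only) 0 else 1,
                      b_prior_sd_ = st$priors$beta_sd,
                      sigma_prior_sd = st$priors$sigma_sd)
  save_rng(st)
  for (nm in c("bs", "bc", "uS", "uC", "vP", "wT", "piM", "piF",
               "XS", "etaS", "l1pS", "etaC1", "expC1",
               "ls_bs", "ls_bc", "ls_re", "ls_aux", "ls_sig",
               "acc_bs", "acc_bc", "acc_re", "acc_aux", "acc_sig",
               "batch"))
    st[[nm]] <- res[[nm]]
  st$sig <- stats::setNames(res$sig, names(st$sig))
  if (record) {
    out <- res$records
    colnames(out) <- param_names
    out
  }
}

fit_param_names <- function(design) {
  c(paste0("success.", success_terms()),
    paste0("count.", count_terms()),
    paste0("sigma.", c("year_success", "year_count", "territory",
                       "population")),
    paste0("year_success[", design$year_levels, "]"),
    paste0("year_count[", design$year_levels, "]"),
    paste0("population[", design$population_levels, "]"),
    paste0("territory[", design$territory_levels, "]"),
    "p_male_experience", "p_female_experience", "deviance")
}

# ---- public fitting interface ----------------------------------------

#' Fit the hierarchical zero-inflated fecundity model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler under a
#' run-until-converged protocol: each chain is adapted and burned in, then
#' sampling proceeds in blocks until the split-chain Gelman-Rubin
#' diagnostic of every monitored parameter (all regression coefficients
#' and random-effect SDs) drops below `rhat_tol`, or the per-chain draw
#' cap is reached (in which case the fit is returned with
#' `converged = FALSE` and a warning).  Draws are never thinned.  Missing
#' breeder-experience covariates are treated as latent Bernoulli variables
#' and imputed within the sampler.
#'
#' @param data a territory-year `data.frame` (see [read_territory_table()])
#'   or a prepared `zipfec_design`.
#' @param priors a [prior_spec()].
#' @param chains number of chains (>= 2), each with its own random
#'   initialization.
#' @param burnin iterations discarded (and used for proposal adaptation)
#'   per chain.
#' @param block post-burn-in iterations sampled per chain between
#'   convergence checks.
#' @param max_draws cap on retained draws per chain.
#' @param rhat_tol convergence gate on the split-chain Rhat (default 1.01).
#' @param seed master seed; per-chain seeds are derived from it, so the
#'   same seed and data reproduce the draws exactly.
#' @param prior_only if `TRUE` the likelihood is switched off and the
#'   sampler targets the prior (used for prior-recovery validation).
#' @return an object of class `zipfec_fit`: per-chain draw matrices
#'   (iterations x parameters, including the realized random effects, the
#'   experience-prevalence parameters and the deviance), the design, and a
#'   metadata record with seeds, settings and the convergence flag.
#' @export
fit_zipfec <- function(data, priors = prior_spec(), chains = 3,
                       burnin = 10000, block = 5000, max_draws = 200000,
                       rhat_tol = 1.01, seed = 1L, prior_only = FALSE) {
  design <- if (inherits(data, "zipfec_design")) data
            else standardize_covariates(data)
  if (chains < 2) stop_zipfec("at least 2 chains are required")
  stopifnot(burnin >= 0, block >= 1, max_draws >= block)
  t0 <- proc.time()[["elapsed"]]

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max %/% 2, chains)
  pn <- fit_param_names(design)
  monitored <- pn[1:22]

  states <- lapply(chain_seeds, function(s)
    make_chain_state(design, priors, s, prior_only = prior_only))
  for (st in states)
    chain_iterate(st, burnin, adapt = TRUE, record = FALSE,
                  param_names = pn)

  draws <- replicate(chains, NULL, simplify = FALSE)
  total <- 0L
  repeat {
    for (k in seq_len(chains)) {
      blk <- chain_iterate(states[[k]], block, adapt = FALSE,
                           record = TRUE, param_names = pn)
      draws[[k]] <- rbind(draws[[k]], blk)
    }
    total <- total + as.integer(block)
    rh <- vapply(monitored, function(p)
      split_rhat(sapply(draws, function(d) d[, p])), numeric(1))
    if (all(rh < rhat_tol, na.rm = TRUE) || total >= max_draws) break
  }
  converged <- all(rh < rhat_tol, na.rm = TRUE)
  if (!converged)
    warning("draw cap reached before convergence (max split-Rhat = ",
            round(max(rh, na.rm = TRUE), 3), ")", call. = FALSE)

  structure(
    list(draws = draws, param_names = pn, monitored = monitored,
         design = design, priors = priors,
         meta = list(seed = seed, chain_seeds = chain_seeds,
                     chains = chains, burnin = burnin, block = block,
                     n_draws = total, converged = converged,
                     max_rhat = max(rh, na.rm = TRUE),
                     prior_only = prior_only,
                     elapsed = proc.time()[["elapsed"]] - t0)),
    class = "zipfec_fit")
}

#' @export
print.zipfec_fit <- function(x, ...) {
  cat("Hierarchical zero-inflated Poisson fecundity fit\n")
  cat(sprintf("  %d records | %d chains x %d draws (burn-in %d, no thinning)\n",
              x$design$n, x$meta$chains, x$meta$n_draws, x$meta$burnin))
  cat(sprintf("  converged: %s (max split-Rhat %.3f over %d monitored parameters)\n",
              x$meta$converged, x$meta$max_rhat, length(x$monitored)))
  invisible(x)
}

#' Stack posterior draws across chains
#'
#' @param fit a `zipfec_fit`.
#' @param pars optional character vector of parameter names (or a regular
#'   expression when `regex = TRUE`).
#' @param regex interpret `pars` as a regular expression.
#' @return matrix with one row per retained draw (chains stacked) and one
#'   column per selected parameter.
#' @export
draws_matrix <- function(fit, pars = NULL, regex = FALSE) {
  m <- do.call(rbind, fit$draws)
  if (is.null(pars)) return(m)
  cols <- if (regex) grep(pars, colnames(m), value = TRUE) else pars
  missing <- setdiff(cols, colnames(m))
  if (length(missing))
    stop_zipfec("unknown parameter(s): ", paste(missing, collapse = ", "))
  m[, cols, drop = FALSE]
}

#' Extract year random-effect draws for one submodel
#'
#' @param fit a `zipfec_fit`.
#' @param submodel `"success"` or `"count"`.
#' @return draws matrix (stacked chains x years), columns named by year.
#' @export
year_effect_draws <- function(fit, submodel = c("success", "count")) {
  submodel <- match.arg(submodel)
  pre <- if (submodel == "success") "year_success\\[" else "year_count\\["
  m <- draws_matrix(fit, paste0("^", pre), regex = TRUE)
  colnames(m) <- fit$design$year_levels
  m
}

#' Export posterior draws in long format
#'
#' Writes one row per (chain, iteration, parameter) triple, the layout
#' used for archiving MCMC output as plain text.
#'
#' @param fit a `zipfec_fit`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(k) {
    d <- fit$draws[[k]]
    data.frame(chain = k, iteration = rep(seq_len(nrow(d)), ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Rebuild a fitted-model object from archived draws
#'
#' Reconstructs a `zipfec_fit` from a long-format draws CSV written by
#' [write_draws_csv()] together with the territory-year table the model
#' was fitted to, so diagnostics, summaries and predictions can be
#' recomputed without refitting.
#'
#' @param draws_path long-format draws CSV (chain, iteration, parameter,
#'   value).
#' @param data_path territory-year CSV the fit used.
#' @return a `zipfec_fit`.
#' @export
read_draws_csv <- function(draws_path, data_path) {
  design <- standardize_covariates(read_territory_table(data_path))
  long <- utils::read.csv(draws_path, stringsAsFactors = FALSE)
  pn <- fit_param_names(design)
  missing <- setdiff(pn, unique(long$parameter))
  if (length(missing))
    stop_zipfec("draws file lacks parameter(s): ",
                paste(utils::head(missing, 3), collapse = ", "))
  chains <- sort(unique(long$chain))
  draws <- lapply(chains, function(k) {
    d <- long[long$chain == k, ]
    m <- matrix(NA_real_, max(d$iteration), length(pn),
                dimnames = list(NULL, pn))
    for (p in pn) m[, p] <- d$value[d$parameter == p]
    m
  })
  structure(
    list(draws = draws, param_names = pn, monitored = pn[1:22],
         design = design, priors = prior_spec(),
         meta = list(chains = length(chains),
                     n_draws = nrow(draws[[1]]),
                     reloaded = TRUE, converged = NA)),
    class = "zipfec_fit")
}
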
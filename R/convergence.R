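# Convergence assessment: split-chain Gelman-Rubin diagnostic and
# effective sample sizes.

#' Split-chain Gelman-Rubin diagnostic for one parameter
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed over the resulting 2m half-chains; splitting also flags chains
#' that drift within themselves.  Constant chains return 1.
#'
#' @param x draws matrix, iterations x chains.
#' @return scalar Rhat (>= 1 up to numerical tolerance).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  h <- n %/% 2
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[(n - h + 1):n, , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  if (!is.finite(W) || W == 0) return(1)
  B <- h * stats::var(colMeans(halves))
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Per-parameter convergence summary of a fit
#'
#' Split-chain Rhat and effective sample size (via the spectral estimator
#' in \pkg{coda}) for every recorded parameter, plus an overall flag that
#' is `TRUE` iff all monitored parameters (regression coefficients and
#' random-effect SDs) have Rhat below `rhat_tol`.
#'
#' @param fit a `zipfec_fit`, or a list of per-chain draw matrices with
#'   identical column names (at least two chains).
#' @param rhat_tol convergence threshold (default 1.01).
#' @return list with `table` (data.frame: parameter, rhat, ess),
#'   `converged`, and `max_rhat` over the monitored set.
#' @export
convergence_summary <- function(fit, rhat_tol = 1.01) {
  if (inherits(fit, "zipfec_fit")) {
    draws <- fit$draws
    monitored <- fit$monitored
  } else {
    draws <- fit
    monitored <- colnames(draws[[1]])
  }
  if (!is.list(draws) || length(draws) < 2)
    stop_zipfec("convergence diagnostics require at least 2 chains")
  pn <- colnames(draws[[1]])
  rhat <- vapply(pn, function(p)
    split_rhat(sapply(draws, function(d) d[, p])), numeric(1))
  ess <- rowSums(matrix(vapply(
    draws, function(d) as.numeric(coda::effectiveSize(coda::mcmc(d))),
    numeric(length(pn))), nrow = length(pn)))
  names(ess) <- pn
  tab <- data.frame(parameter = pn, rhat = unname(rhat),
                    ess = unname(ess), row.names = NULL)
  mon <- rhat[monitored]
  list(table = tab,
       converged = all(mon < rhat_tol, na.rm = TRUE),
       max_rhat = max(mon, na.rm = TRUE))
}
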
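#' Split-Rhat for one parameter
#'
#' Potential-scale-reduction statistic computed on chains split in half, so
#' within-chain trends inflate the statistic.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Split-Rhat (scalar); `NA` with a single chain of length < 4 or
#'   zero variance.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  W <- mean(apply(sp, 2, stats::var))
  B <- nn * stats::var(mu)
  if (!is.finite(W) || W == 0) {
    return(if (stats::var(as.numeric(sp)) == 0) 1 else NA_real_)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size for one parameter
#'
#' Multi-chain effective sample size using combined autocorrelations with
#' Geyer's initial monotone positive sequence truncation, on split chains.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Estimated effective sample size, capped at the total draw count.
#' @export
effective_sample_size <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  mu <- colMeans(sp)
  B_over_n <- stats::var(mu)
  var_plus <- (nn - 1) / nn * W + B_over_n
  # chain-averaged autocovariances
  max_lag <- nn - 1
  acov <- matrix(0, max_lag + 1, m)
  for (j in seq_len(m)) {
    a <- stats::acf(sp[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)
    acov[, j] <- a$acf[, 1, 1]
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence on pair sums
  # (rho_0 + rho_1), (rho_2 + rho_3), ...; tau = -1 + 2 * sum of kept pairs
  pair0 <- rho[1] + if (length(rho) > 1) rho[2] else 0
  s2 <- pair0
  last_pair <- pair0
  k <- 1
  while (2 * k + 2 <= length(rho)) {
    pair <- rho[2 * k + 1] + rho[2 * k + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, last_pair)
    last_pair <- pair
    s2 <- s2 + pair
    k <- k + 1
  }
  tau <- max(-1 + 2 * s2, 1 / log10(nn * m + 10))
  min(nn * m / tau, nn * m)
}

#' Convergence diagnostics table
#'
#' Per-parameter split-Rhat and effective sample size with pass/fail flags
#' against the convergence gates (Rhat below 1.01 and effective sample size
#' above a floor).
#'
#' @param fit A `vb_fit`.
#' @param rhat_max Rhat gate (default 1.01).
#' @param neff_floor Effective-sample-size floor (default 1000, the reference
#'   gate; lower it for short desk-scale runs).
#' @return A tibble with columns `term`, `rhat`, `neff`, `rhat_ok`,
#'   `neff_ok`, `ok`.
#' @export
mcmc_diagnostics <- function(fit, rhat_max = 1.01, neff_floor = 1000) {
  stopifnot(inherits(fit, "vb_fit"))
  chains <- sort(unique(fit$chain))
  single <- length(chains) < 2
  per_chain <- lapply(chains, function(ch) fit$draws[fit$chain == ch, , drop = FALSE])
  K <- ncol(fit$draws)
  rhat <- numeric(K); neff <- numeric(K)
  for (k in seq_len(K)) {
    x <- vapply(per_chain, function(m) m[, k], numeric(nrow(per_chain[[1]])))
    rhat[k] <- if (single) NA_real_ else split_rhat(x)
    neff[k] <- effective_sample_size(x)
  }
  tibble::tibble(
    term = colnames(fit$draws), rhat = rhat, neff = neff,
    rhat_ok = !is.na(rhat) & rhat < rhat_max,
    neff_ok = !is.na(neff) & neff > neff_floor,
    ok = (!is.na(rhat) & rhat < rhat_max) & (!is.na(neff) & neff > neff_floor)
  )
}
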
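#' Gelman-Rubin potential scale reduction factor
#'
#' Brooks-Gelman corrected PSRF for one scalar parameter from two or more
#' chains: with m chains of length n, within-chain variance W, between-chain
#' variance B, and pooled variance estimate
#' \eqn{\hat V = (n-1)/n \, W + (1 + 1/m) B / n}, the statistic is
#' \eqn{\sqrt{(d+3)/(d+1) \cdot \hat V / W}} where d is the method-of-moments
#' degrees of freedom of the t-approximation to the pooled posterior.
#' Values near 1 indicate convergence; > 1.1 is the conventional flag.
#'
#' @param chains numeric matrix, one column per chain (>= 2 columns, >= 10
#'   rows), or a list of equal-length numeric vectors.
#' @return R-hat (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stop("diagnostic undefined: need at least 2 chains")
  if (n < 10) stop("diagnostic undefined: need at least 10 draws per chain")
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  W <- mean(vars)
  if (W <= 0) stop("diagnostic undefined: zero within-chain variance")
  B <- n * var(means)
  vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
  # method-of-moments df of the t-approximation (Brooks & Gelman 1998)
  var_vhat <- ((n - 1) / n)^2 / m * var(vars) +
    ((m + 1) / (m * n))^2 * 2 / (m - 1) * B^2 +
    2 * (m + 1) * (n - 1) / (m^2 * n) *
      (stats::cov(vars, means^2) - 2 * mean(means) * stats::cov(vars, means)) *
      n / m
  d <- 2 * vhat^2 / max(var_vhat, .Machine$double.eps)
  sqrt((d + 3) / (d + 1) * vhat / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence:
#' summation of lag-pair autocorrelations is truncated at the first
#' negative pair sum.
#'
#' @param x numeric vector of (stationary) draws.
#' @return effective sample size (scalar, capped at \code{length(x)}).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(n)
  max_lag <- min(n - 2, 10 * floor(sqrt(n)))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  tau <- 1
  k <- 1
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  min(n, n / tau)
}

#' Posterior summary table
#'
#' Mean, SD, central 95% interval bounds (2.5% and 97.5% empirical
#' quantiles, linear interpolation of order statistics), Gelman-Rubin
#' R-hat (when >= 2 chains are present) and effective sample size for each
#' parameter.
#'
#' @param draws a \code{posterior_draws} object from [run_mcmc()], or a
#'   numeric matrix of draws with named columns.
#' @param parameters optional character vector restricting the summary.
#' @return data.frame with one row per parameter.
#' @export
summarize_draws <- function(draws, parameters = NULL) {
  if (inherits(draws, "posterior_draws")) {
    params <- draws$params
    chain <- draws$chain
  } else {
    params <- as.matrix(draws)
    chain <- rep(1L, nrow(params))
  }
  if (nrow(params) == 0) stop("empty draw set")
  if (!is.null(parameters)) {
    bad <- setdiff(parameters, colnames(params))
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
    params <- params[, parameters, drop = FALSE]
  }
  n_chains <- length(unique(chain))
  out <- do.call(rbind, lapply(colnames(params), function(nm) {
    x <- params[, nm]
    q <- unname(quantile(x, c(0.025, 0.975), type = 7))
    rhat <- NA_real_
    if (n_chains >= 2 && var(x) > 1e-300) {
      m <- do.call(cbind, split(x, chain))
      rhat <- tryCatch(gelman_rubin(m), error = function(e) NA_real_)
    }
    data.frame(parameter = nm, mean = mean(x), sd = sd(x),
               q2.5 = q[1], q97.5 = q[2], rhat = rhat,
               ess = effective_size(x))
  }))
  rownames(out) <- NULL
  out
}
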
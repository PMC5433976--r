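# Shared fixture builders (all data generated in code).

# small hand-built capture table with a known mix of observed/missing labels
tiny_table <- function() {
  rec <- data.frame(
    id = sprintf("r%02d", 1:8),
    year = c(2000L, 2000L, 2001L, 2001L, 2002L, 2002L, 2003L, 2003L),
    day = c(280L, 282L, 284L, 281L, 283L, 285L, 280L, 284L),
    age = c(0L, 1L, NA, 0L, 1L, NA, 0L, NA),
    sex = c(0L, 1L, NA, 1L, NA, 0L, NA, 1L),
    weight_g = c(15.2, 16.8, 15.9, 16.1, 16.5, 15.4, 15.8, 16.2),
    primary_mm = c(62.5, 68.2, 65.0, 66.8, 67.5, 63.2, 64.1, 67.0),
    plumage = c("female_colored", NA, NA, "paradoxus", NA,
                "female_colored", "female_colored", NA),
    stringsAsFactors = FALSE)
  capture_table(rec, season_midpoint_day = 282L, reference_year = 2000L)
}

# random but valid model parameters for oracle comparisons
random_params <- function() {
  model_params(
    w0 = rnorm(4, 16, 1), w1 = rnorm(1, 0, 0.1), w2 = rnorm(1, 0, 0.1),
    p0 = rnorm(4, 65, 2), p1 = rnorm(1, 0, 0.1), p2 = rnorm(1, 0, 0.1),
    sigma_w = runif(4, 0.5, 2), sigma_p = runif(4, 0.5, 3),
    rho = runif(4, -0.9, 0.9),
    s0 = rnorm(1), s1 = rnorm(1, 0, 0.2), s2 = rnorm(1, 0, 0.2),
    a0 = rnorm(1), a1 = rnorm(1, 0, 0.2), a2 = rnorm(1, 0, 0.2))
}

# independent textbook oracle for the record log-density: univariate normal
# times conditional normal (regression form) times two Bernoulli masses
oracle_log_density <- function(params, age, sex, weight, primary,
                               day_c, year_c) {
  g <- 1 + sex + 2 * age
  mu_w <- params$w0[g] + params$w1 * day_c + params$w2 * year_c
  mu_p <- params$p0[g] + params$p1 * day_c + params$p2 * year_c
  sw <- params$sigma_w[g]; sp <- params$sigma_p[g]; r <- params$rho[g]
  cond_mean <- mu_p + r * sp / sw * (weight - mu_w)
  cond_sd <- sp * sqrt(1 - r^2)
  dnorm(weight, mu_w, sw, log = TRUE) +
    dnorm(primary, cond_mean, cond_sd, log = TRUE) +
    dbinom(sex, 1, plogis(params$s0 + params$s1 * day_c + params$s2 * year_c),
           log = TRUE) +
    dbinom(age, 1, plogis(params$a0 + params$a1 * day_c + params$a2 * year_c),
           log = TRUE)
}

# fabricate a posterior_draws object with given imputed-label matrix
fake_draws <- function(labels, miss_idx, n_params = 30) {
  n <- nrow(labels)
  params <- matrix(rnorm(n * n_params), n, n_params)
  colnames(params) <- names(ringmiss::params_to_vector(
    ringmiss:::default_truth()))
  structure(list(params = params, labels = labels,
                 miss_idx = as.integer(miss_idx),
                 chain = rep(1L, n), iter = seq_len(n),
                 max_rhat = NA_real_, converged = NA,
                 config = mcmc_config(n_chains = 1, n_iter = 2 * n,
                                      n_burn = 0, thin = 2)),
            class = "posterior_draws")
}
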
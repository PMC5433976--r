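#' Weakly informative prior specification
#'
#' Defaults: Normal(16, 5) for the class weight intercepts, Normal(65, 5)
#' for the class primary-length intercepts, Normal(0, 1) for all day/year
#' slopes, Normal(0, 2) for the logit intercepts s0 and a0, and an
#' inverse-Wishart with scale diag(1e-4) and 3 degrees of freedom for each
#' class weight-primary covariance matrix.  Under the shared-rho covariance
#' variant the class SDs get half-normal(\code{sigma_hn_sd}) priors and rho
#' a Uniform(-1, 1) prior instead.
#'
#' @param w0_mean,w0_sd,p0_mean,p0_sd intercept prior hyperparameters.
#' @param slope_sd SD for all day/year slope priors.
#' @param logit_intercept_sd SD for the s0/a0 priors.
#' @param iw_scale 2x2 inverse-Wishart scale matrix.
#' @param iw_df inverse-Wishart degrees of freedom (>= 3 for 2x2).
#' @param sigma_hn_sd half-normal SD for the shared-rho variant.
#' @return object of class \code{prior_spec}.
#' @export
prior_spec <- function(w0_mean = 16, w0_sd = 5, p0_mean = 65, p0_sd = 5,
                       slope_sd = 1, logit_intercept_sd = 2,
                       iw_scale = diag(1e-4, 2), iw_df = 3,
                       sigma_hn_sd = 5) {
  stopifnot(w0_sd > 0, p0_sd > 0, slope_sd > 0, logit_intercept_sd > 0,
            iw_df >= 3, all(diag(iw_scale) > 0))
  structure(list(
    beta_mean = c(rep(w0_mean, 4), 0, 0, rep(p0_mean, 4), 0, 0),
    beta_sd = c(rep(w0_sd, 4), slope_sd, slope_sd,
                rep(p0_sd, 4), slope_sd, slope_sd),
    s_sd = c(logit_intercept_sd, slope_sd, slope_sd),
    a_sd = c(logit_intercept_sd, slope_sd, slope_sd),
    iw_scale = iw_scale, iw_df = iw_df,
    sigma_hn_sd = sigma_hn_sd), class = "prior_spec")
}

#' MCMC run configuration
#'
#' The default schedule matches the study design: two parallel chains of
#' 6000 iterations, the first 2000 discarded as burn-in and the remainder
#' thinned by 2, giving 4000 saved posterior draws.
#'
#' @param n_chains number of chains (>= 2 for the Gelman-Rubin diagnostic).
#' @param n_iter iterations per chain.
#' @param n_burn burn-in iterations discarded per chain.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param seed master RNG seed.
#' @param target_accept Metropolis target acceptance rate for the adaptive
#'   random-walk updates (Robbins-Monro adaptation, frozen when burn-in
#'   ends).
#' @param cov_model \code{"iw"} for four independent inverse-Wishart class
#'   covariances (default), \code{"shared_rho"} for class SDs with a single
#'   shared weight-primary correlation.
#' @return object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 6000, n_burn = 2000,
                        thin = 2, seed = 1, target_accept = 0.35,
                        cov_model = c("iw", "shared_rho")) {
  cov_model <- match.arg(cov_model)
  stopifnot(n_iter > n_burn, thin >= 1, n_chains >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept,
                 cov_model = cov_model), class = "mcmc_config")
}

# Initial label assignment: admissible class nearest in standardized
# morphometric distance to complete-case class means (prior-free).
initial_labels <- function(rec, day_c, year_c) {
  complete <- !is.na(rec$sex) & !is.na(rec$age)
  g_obs <- rep(NA_integer_, nrow(rec))
  g_obs[complete] <- class_index(rec$age[complete], rec$sex[complete])
  mw <- tapply(rec$weight_g[complete], factor(g_obs[complete], levels = 1:4),
               mean)
  mp <- tapply(rec$primary_mm[complete], factor(g_obs[complete], levels = 1:4),
               mean)
  mw[is.na(mw)] <- mean(rec$weight_g)
  mp[is.na(mp)] <- mean(rec$primary_mm)
  sw <- max(sd(rec$weight_g), 1e-6)
  sp <- max(sd(rec$primary_mm), 1e-6)
  age <- rec$age; sex <- rec$sex
  par_flag <- !is.na(rec$plumage) & rec$plumage == "paradoxus"
  for (i in which(!complete)) {
    if (par_flag[i]) { age[i] <- 0L; sex[i] <- 1L; next }
    grid <- admissible_completions(rec$age[i], rec$sex[i], FALSE)
    g <- class_index(grid$age, grid$sex)
    dist <- ((rec$weight_g[i] - mw[g]) / sw)^2 +
      ((rec$primary_mm[i] - mp[g]) / sp)^2
    k <- which.min(dist)
    age[i] <- grid$age[k]; sex[i] <- grid$sex[k]
  }
  list(age = as.integer(age), sex = as.integer(sex))
}

# Complete-case slope fits for initialization and overdispersion scales.
initial_logit <- function(y_obs, day_c, year_c) {
  obs <- !is.na(y_obs)
  est <- c(0, 0, 0); se <- c(0.5, 0.1, 0.1)
  if (sum(obs) >= 10 && length(unique(y_obs[obs])) == 2) {
    fit <- suppressWarnings(
      glm(y_obs[obs] ~ day_c[obs] + year_c[obs], family = binomial()))
    if (all(is.finite(coef(fit)))) {
      est <- unname(coef(fit))
      se <- sqrt(diag(vcov(fit)))
      se[!is.finite(se)] <- 0.5
    }
  }
  list(est = est, se = se)
}

#' Fit the joint capture model by MCMC
#'
#' Alternates (i) imputation of every missing sex/age label from its full
#' conditional, (ii) a conjugate multivariate-normal draw of the twelve
#' mean-structure coefficients, (iii) conjugate inverse-Wishart draws of
#' the four class covariance matrices (or Metropolis updates of SDs and a
#' shared correlation under \code{cov_model = "shared_rho"}), and (iv)
#' adaptive random-walk Metropolis updates of the two logit-linear
#' coefficient blocks.  Chains are initialized from complete-case estimates
#' with the logistic coefficients jittered by +/- 2 complete-case standard
#' errors for overdispersion; missing labels start at the morphometrically
#' nearest admissible class.
#'
#' @param table a [capture_table()]; must contain at least one observed
#'   label of each sex and age value (anchoring), and every class must be
#'   attributable to at least one record.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return object of class \code{posterior_draws}: list with \code{params}
#'   (matrix, saved draws x 30 named parameters), \code{labels} (integer
#'   matrix of imputed class indices for records with missing labels),
#'   \code{miss_idx} (row indices of those records), \code{chain},
#'   \code{accept}, \code{config}, and the convergence flag
#'   \code{converged} (max split-free Gelman-Rubin <= 1.1 over all
#'   parameters, \code{NA} for single chains).
#' @export
run_mcmc <- function(table, priors = prior_spec(), config = mcmc_config()) {
  stopifnot(inherits(table, "capture_table"),
            inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  rec <- table$records
  day_c <- centered_day(table)
  year_c <- centered_year(table)
  n <- nrow(rec)
  par_flag <- !is.na(rec$plumage) & rec$plumage == "paradoxus"

  # anchoring: every class must be attributable to >= 1 record
  attributable <- matrix(FALSE, n, 4)
  for (i in seq_len(n)) {
    grid <- admissible_completions(rec$age[i], rec$sex[i], par_flag[i])
    attributable[i, class_index(grid$age, grid$sex)] <- TRUE
  }
  empty <- which(colSums(attributable) == 0)
  if (length(empty))
    stop("no attributable records for class(es) ",
         paste(empty, collapse = ", "))

  lab0 <- initial_labels(rec, day_c, year_c)
  g0 <- 1L + lab0$sex + 2L * lab0$age
  # complete-case mean-structure fit on the initial assignment
  fit_w <- lm(rec$weight_g ~ 0 + factor(g0, levels = 1:4) + day_c + year_c)
  fit_p <- lm(rec$primary_mm ~ 0 + factor(g0, levels = 1:4) + day_c + year_c)
  beta0 <- c(fill_coef(fit_w, priors$beta_mean[1:4]),
             fill_coef(fit_p, priors$beta_mean[7:10]))
  Sigma0 <- lapply(1:4, function(g) {
    idx <- g0 == g
    if (sum(idx) >= 8) {
      S <- stats::cov(cbind(resid(fit_w)[idx], resid(fit_p)[idx]))
      if (all(is.finite(S)) && det(S) > 1e-8) return(S)
    }
    matrix(c(1, 0.75, 0.75, 2.25), 2, 2)
  })
  s_cc <- initial_logit(rec$sex, day_c, year_c)
  a_cc <- initial_logit(rec$age, day_c, year_c)

  sex_obs <- ifelse(is.na(rec$sex), -1L, rec$sex)
  age_obs <- ifelse(is.na(rec$age), -1L, rec$age)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * (ch - 1L))
    jit_s <- runif(3, -1, 1) * 2 * pmax(s_cc$se, 0.05)
    jit_a <- runif(3, -1, 1) * 2 * pmax(a_cc$se, 0.05)
    init <- list(beta = beta0, Sigma = Sigma0,
                 s = s_cc$est + jit_s, a = a_cc$est + jit_a,
                 sex = lab0$sex, age = lab0$age,
                 lam_s = 0.1, lam_a = 0.1, lam_cov = rep(0.1, 9))
    chains[[ch]] <- mcmc_chain_cpp(
      day_c, year_c, rec$weight_g, rec$primary_mm,
      sex_obs, age_obs, as.integer(par_flag),
      init, unclass(priors),
      config$n_iter, config$n_burn, config$thin,
      config$target_accept, TRUE,
      if (config$cov_model == "shared_rho") 1L else 0L)
  }

  par_names <- names(params_to_vector(default_truth()))
  params <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(params) <- par_names
  n_save <- nrow(chains[[1]]$draws)
  chain_id <- rep(seq_len(config$n_chains), each = n_save)
  labels <- do.call(rbind, lapply(chains, `[[`, "labels"))
  rhat <- NA_real_
  if (config$n_chains >= 2) {
    per_par <- vapply(seq_len(ncol(params)), function(j) {
      m <- matrix(params[, j], ncol = config$n_chains)
      if (var(as.vector(m)) < 1e-12) return(1)
      gelman_rubin(m)
    }, numeric(1))
    rhat <- max(per_par, na.rm = TRUE)
  }
  structure(list(
    params = params,
    labels = labels,
    miss_idx = chains[[1]]$miss_idx + 1L,
    chain = chain_id,
    iter = rep(seq_len(n_save), config$n_chains),
    accept = data.frame(
      chain = seq_len(config$n_chains),
      accept_s = vapply(chains, `[[`, numeric(1), "accept_s"),
      accept_a = vapply(chains, `[[`, numeric(1), "accept_a")),
    max_rhat = rhat,
    converged = if (is.na(rhat)) NA else rhat <= 1.1,
    config = config), class = "posterior_draws")
}

fill_coef <- function(fit, fallback_intercepts) {
  cf <- coef(fit)
  out <- c(fallback_intercepts, 0, 0)
  ok <- is.finite(cf)
  out[which(ok)] <- cf[ok]
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws (%d chains), %d parameters, %d records with imputed labels\n",
              nrow(x$params), length(unique(x$chain)), ncol(x$params),
              length(x$miss_idx)))
  if (!is.na(x$max_rhat))
    cat(sprintf("  max Gelman-Rubin R-hat %.3f (%s)\n", x$max_rhat,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Write posterior draws to columnar CSV plus a JSON index
#'
#' One row per saved draw per parameter (columns \code{chain}, \code{iter},
#' \code{parameter}, \code{value}); the JSON index records the
#' configuration, acceptance rates and convergence flag.
#'
#' @param draws a \code{posterior_draws} object.
#' @param csv_path,json_path output paths.
#' @return \code{csv_path} invisibly.
#' @export
write_posterior_draws <- function(draws, csv_path, json_path = NULL) {
  long <- data.frame(
    chain = rep(draws$chain, times = ncol(draws$params)),
    iter = rep(draws$iter, times = ncol(draws$params)),
    parameter = rep(colnames(draws$params), each = nrow(draws$params)),
    value = as.vector(draws$params))
  write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    idx <- list(n_draws = nrow(draws$params),
                n_chains = length(unique(draws$chain)),
                parameters = colnames(draws$params),
                max_rhat = draws$max_rhat,
                converged = draws$converged,
                accept = draws$accept,
                config = unclass(draws$config))
    jsonlite::write_json(idx, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Advance the sampler by a single sweep from a given state
#'
#' Low-level access to the transition kernel (one full Gibbs/Metropolis
#' sweep, no adaptation), used for kernel-validation experiments such as
#' successive-conditional simulation.
#'
#' @param table a [capture_table()].
#' @param state list with elements \code{beta}, \code{Sigma}, \code{s},
#'   \code{a}, \code{sex}, \code{age} (full label vectors).
#' @param priors a [prior_spec()].
#' @param proposal_scales list with \code{lam_s}, \code{lam_a} (fixed).
#' @return updated state in the same format, plus \code{params} (named
#'   30-vector).
#' @export
mcmc_single_sweep <- function(table, state, priors = prior_spec(),
                              proposal_scales = list(lam_s = 0.1,
                                                     lam_a = 0.1)) {
  rec <- table$records
  par_flag <- !is.na(rec$plumage) & rec$plumage == "paradoxus"
  init <- list(beta = state$beta, Sigma = state$Sigma,
               s = state$s, a = state$a,
               sex = as.integer(state$sex), age = as.integer(state$age),
               lam_s = proposal_scales$lam_s, lam_a = proposal_scales$lam_a,
               lam_cov = rep(0.1, 9))
  out <- mcmc_chain_cpp(
    centered_day(table), centered_year(table),
    rec$weight_g, rec$primary_mm,
    ifelse(is.na(rec$sex), -1L, rec$sex),
    ifelse(is.na(rec$age), -1L, rec$age),
    as.integer(par_flag), init, unclass(priors),
    1L, 0L, 1L, 0.35, FALSE, 0L)
  v <- drop(out$draws)
  names(v) <- names(params_to_vector(default_truth()))
  sex <- as.integer(rec$sex); age <- as.integer(rec$age)
  if (length(out$miss_idx)) {
    g <- out$labels[1, ]
    sex[out$miss_idx + 1L] <- (g - 1L) %% 2L
    age[out$miss_idx + 1L] <- (g - 1L) %/% 2L
  }
  list(beta = unname(v[c(paste0("w0[", 1:4, "]"), "w1", "w2",
                         paste0("p0[", 1:4, "]"), "p1", "p2")]),
       Sigma = lapply(1:4, function(g) {
         sw <- v[paste0("sigma_w[", g, "]")]
         sp <- v[paste0("sigma_p[", g, "]")]
         r <- v[paste0("rho[", g, "]")]
         matrix(c(sw^2, r * sw * sp, r * sw * sp, sp^2), 2, 2)
       }),
       s = unname(v[c("s0", "s1", "s2")]),
       a = unname(v[c("a0", "a1", "a2")]),
       sex = sex, age = age, params = v)
}
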
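# One reduced-size scenario-1 fit shared by several blocks in this file.
scn <- scenario_preset(1, n_years = 8, mean_captures_per_year = 120)
tab_full <- simulate_captures(scn, seed = 31)
tab_masked <- apply_missingness(tab_full, scn, seed = 32)
cfg_short <- mcmc_config(n_chains = 2, n_iter = 1500, n_burn = 500,
                         thin = 2, seed = 77)
fit <- run_mcmc(tab_masked, prior_spec(), cfg_short)

test_that("the sampler is deterministic given config and seed", {
  fit2 <- run_mcmc(tab_masked, prior_spec(), cfg_short)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$labels, fit2$labels)
  cfg_other <- cfg_short; cfg_other$seed <- 78L
  fit3 <- run_mcmc(tab_masked, prior_spec(), cfg_other)
  expect_false(identical(fit$params, fit3$params))
})

test_that("draw bookkeeping matches the schedule", {
  expect_equal(nrow(fit$params), 2 * (1500 - 500) / 2)
  expect_equal(ncol(fit$params), 30)
  expect_equal(sort(unique(fit$chain)), 1:2)
  # imputed labels exist exactly for the records with missing labels
  rec <- tab_masked$records
  expect_setequal(fit$miss_idx, which(is.na(rec$sex) | is.na(rec$age)))
  expect_true(all(fit$labels %in% 1:4))
})

test_that("observed labels are never overridden by imputation", {
  rec <- tab_masked$records
  half_obs <- intersect(fit$miss_idx, which(!is.na(rec$sex)))
  k <- match(half_obs, fit$miss_idx)
  g <- fit$labels[, k, drop = FALSE]
  sex_imp <- (g - 1L) %% 2L
  expect_true(all(sex_imp == rep(rec$sex[half_obs], each = nrow(g))))
})

test_that("imputed-class marginals are stable across chains (no label switching)", {
  p_chain <- lapply(1:2, function(ch) {
    g <- fit$labels[fit$chain == ch, , drop = FALSE]
    vapply(1:4, function(cls) mean(g == cls), numeric(1))
  })
  expect_lt(max(abs(p_chain[[1]] - p_chain[[2]])), 0.03)
})

test_that("complete-label fits recover the generating slopes", {
  scn_big <- scenario_preset(1, n_years = 12, mean_captures_per_year = 400)
  tab <- simulate_captures(scn_big, seed = 41)   # no masking: labels observed
  cfg <- mcmc_config(n_chains = 2, n_iter = 1200, n_burn = 400, thin = 2,
                     seed = 42)
  d <- run_mcmc(tab, prior_spec(), cfg)
  truth <- params_to_vector(scn_big$truth)
  ss <- summarize_draws(d, parameters = c("w1", "w2", "p1", "p2",
                                          "s1", "s2", "a1", "a2"))
  z <- abs(ss$mean - truth[ss$parameter]) / ss$sd
  expect_true(all(z < 4), info = paste(ss$parameter, round(z, 2),
                                       collapse = "; "))
})

test_that("equal-class-mean data leave intercept differences near zero", {
  s3 <- scenario_preset(3, n_years = 8, mean_captures_per_year = 120)
  t3 <- apply_missingness(simulate_captures(s3, seed = 51), s3, seed = 52)
  d3 <- run_mcmc(t3, prior_spec(),
                 mcmc_config(n_chains = 2, n_iter = 1500, n_burn = 500,
                             thin = 2, seed = 53))
  w0 <- d3$params[, paste0("w0[", 1:4, "]")]
  diffs <- w0[, 2:4] - w0[, 1]
  z <- abs(colMeans(diffs)) / apply(diffs, 2, sd)
  expect_true(all(z < 4))
})

test_that("more observed labels never reduce precision (scenario 1 vs 2)", {
  s1 <- scenario_preset(1, n_years = 8, mean_captures_per_year = 120)
  s2 <- scenario_preset(2, n_years = 8, mean_captures_per_year = 120)
  base <- simulate_captures(s1, seed = 61)     # same generative truth
  cfg <- mcmc_config(n_chains = 2, n_iter = 1500, n_burn = 500, thin = 2,
                     seed = 63)
  d1 <- run_mcmc(apply_missingness(base, s1, seed = 62), prior_spec(), cfg)
  d2 <- run_mcmc(apply_missingness(base, s2, seed = 62), prior_spec(), cfg)
  sd1 <- sd(d1$params[, "s1"])
  sd2 <- sd(d2$params[, "s1"])
  expect_lt(sd1, sd2 * 1.15)   # allowance for Monte-Carlo error
})

test_that("anchoring is enforced at initialization", {
  rec <- tiny_table()$records
  rec$age <- 1L            # no young records attributable
  rec$sex <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  rec$plumage <- NA_character_
  t_ad <- capture_table(rec, 282L, 2000L)
  expect_error(run_mcmc(t_ad, prior_spec(),
                        mcmc_config(n_iter = 100, n_burn = 50, seed = 1)),
               "no attributable records")
})

test_that("each full sweep leaves the joint prior-data law invariant", {
  # successive-conditional simulation on a tiny instance: alternate one
  # transition-kernel sweep with a fresh data draw given the new
  # parameters; the sampled parameters must then keep their prior law.
  set.seed(71)
  n <- 3
  day_c <- c(-3, 0, 4); year_c <- c(-0.5, 0.5, 0.5)
  sex_obs <- c(1L, NA, NA); age_obs <- c(NA, 0L, NA)
  # numerically tame prior (kernel validity is prior-agnostic)
  priors <- prior_spec(w0_sd = 2, p0_sd = 2,
                       iw_scale = diag(0.5, 2), iw_df = 6)
  draw_prior <- function() {
    list(beta = rnorm(12, priors$beta_mean, priors$beta_sd),
         Sigma = lapply(1:4, function(g)
           solve(stats::rWishart(1, priors$iw_df,
                                 solve(priors$iw_scale))[, , 1])),
         s = rnorm(3, 0, priors$s_sd),
         a = rnorm(3, 0, priors$a_sd))
  }
  sim_data <- function(th) {
    sex <- rbinom(n, 1, plogis(th$s[1] + th$s[2] * day_c + th$s[3] * year_c))
    age <- rbinom(n, 1, plogis(th$a[1] + th$a[2] * day_c + th$a[3] * year_c))
    g <- 1L + sex + 2L * age
    w <- p <- numeric(n)
    for (i in 1:n) {
      S <- th$Sigma[[g[i]]]
      mu <- c(th$beta[g[i]] + th$beta[5] * day_c[i] + th$beta[6] * year_c[i],
              th$beta[6 + g[i]] + th$beta[11] * day_c[i] +
                th$beta[12] * year_c[i])
      x <- MASS::mvrnorm(1, mu, S)
      w[i] <- x[1]; p[i] <- x[2]
    }
    list(sex = sex, age = age, w = w, p = p)
  }
  make_table <- function(dat) {
    tab <- tiny_table()
    tab$records <- data.frame(
      id = as.character(1:n), year = 2000L + c(0L, 1L, 1L),
      day = 283L + c(-3L, 0L, 4L),
      age = ifelse(is.na(age_obs), NA_integer_, dat$age),
      sex = ifelse(is.na(sex_obs), NA_integer_, dat$sex),
      weight_g = dat$w, primary_mm = dat$p,
      plumage = NA_character_, stringsAsFactors = FALSE)
    tab$season_midpoint_day <- 283L
    tab$midpoint_year <- 2000.5
    tab
  }
  n_cycles <- 1500
  th <- draw_prior()
  dat <- sim_data(th)
  keep <- matrix(NA_real_, n_cycles, 4,
                 dimnames = list(NULL, c("w0[1]", "w1", "s1", "a0")))
  state <- c(th, list(sex = dat$sex, age = dat$age))
  for (cyc in seq_len(n_cycles)) {
    tab <- make_table(dat)
    state <- mcmc_single_sweep(tab, state, priors,
                               proposal_scales = list(lam_s = 1, lam_a = 1))
    keep[cyc, ] <- state$params[colnames(keep)]
    th <- state[c("beta", "Sigma", "s", "a")]
    dat <- sim_data(th)
    state$sex <- dat$sex; state$age <- dat$age
  }
  # marginal laws must match the priors (generous Monte-Carlo bounds)
  expect_lt(abs(mean(keep[, "w0[1]"]) - 16), 0.5)     # prior N(16, 2)
  expect_lt(abs(mean(keep[, "w1"])), 0.2)             # prior N(0, 1)
  expect_lt(abs(mean(keep[, "s1"])), 0.2)             # prior N(0, 1)
  expect_lt(abs(mean(keep[, "a0"])), 0.4)             # prior N(0, 2)
  expect_gt(var(keep[, "w1"]), 0.7)
  expect_lt(var(keep[, "w1"]), 1.4)
})

test_that("posterior draws serialize to CSV with a JSON index", {
  f_csv <- withr::local_tempfile(fileext = ".csv")
  f_json <- withr::local_tempfile(fileext = ".json")
  write_posterior_draws(fit, f_csv, f_json)
  long <- read.csv(f_csv)
  expect_equal(nrow(long), nrow(fit$params) * 30)
  idx <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  expect_equal(idx$n_draws, nrow(fit$params))
  expect_equal(idx$parameters, colnames(fit$params))
})
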
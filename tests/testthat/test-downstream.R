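# Young-male table with both plumage types across years, fully observed.
ym_table <- function(n_per_year = 40, n_years = 6, timing_effect = 0,
                     weight_effect = 0, primary_effect = 0, seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_years), function(y) {
    par <- rep(c(TRUE, FALSE), length.out = n_per_year)
    day <- 275L + sample(0:14, n_per_year, replace = TRUE)
    data.frame(year = 1999L + y, day = day + ifelse(par, timing_effect, 0),
               age = 0L, sex = 1L,
               weight_g = 16 + 0.1 * rnorm(n_per_year) +
                 ifelse(par, weight_effect, 0),
               primary_mm = 66 + 0.2 * rnorm(n_per_year) +
                 ifelse(par, primary_effect, 0),
               plumage = ifelse(par, "paradoxus", "female_colored"),
               stringsAsFactors = FALSE)
  }))
  rows$id <- sprintf("y%04d", seq_len(nrow(rows)))
  capture_table(rows, season_midpoint_day = 282L, reference_year = 2000L)
}

test_that("selection respects observed labels and imputed ones", {
  tab <- tiny_table()
  # records 3, 5, 7, 8 have missing labels (miss_idx), plus record 4 is an
  # observed paradoxus young male and record 2 an observed adult male
  miss_idx <- which(is.na(tab$records$sex) | is.na(tab$records$age))
  expect_identical(miss_idx, c(3L, 5L, 6L, 7L, 8L))
  set.seed(2)
  # fake imputations drawn uniformly over each record's admissible classes
  admissible <- list(`3` = 1:4, `5` = 3:4, `6` = c(1L, 3L),
                     `7` = 1:2, `8` = c(2L, 4L))
  labels <- vapply(as.character(miss_idx), function(k)
    sample(admissible[[k]], 200, replace = TRUE), integer(200))
  d <- fake_draws(labels, miss_idx)
  sel_frac <- vapply(seq_len(200), function(k) {
    sub <- select_young_males(tab, d, k)
    c("r01" %in% sub$id, "r02" %in% sub$id, "r04" %in% sub$id,
      "r03" %in% sub$id)
  }, logical(4))
  expect_false(any(sel_frac[1, ]))        # observed young female: never
  expect_false(any(sel_frac[2, ]))        # observed adult male: never
  expect_true(all(sel_frac[3, ]))         # observed paradoxus young male
  # all-missing record selected whenever its uniform label draw lands on
  # class 2, i.e. in about a quarter of the draws
  expect_lt(abs(mean(sel_frac[4, ]) - 0.25), 4 * sqrt(0.25 * 0.75 / 200))
})

test_that("timing model recovers exact effects on noise-free data", {
  tab <- ym_table(timing_effect = 0)
  tab$records$day <- 270L + 2L * (tab$records$year - 2000L)  # exact linear
  d <- fake_draws(matrix(integer(0), nrow = 5, ncol = 0), integer(0))
  sub <- select_young_males(tab, d, 1)
  fit <- suppressWarnings(fit_timing_model(sub))
  expect_equal(unname(fit$coef["paradoxusTRUE"]), 0, tolerance = 1e-8)
  sub2 <- sub
  sub2$day <- sub2$day + ifelse(sub2$paradoxus, 3, 0)
  fit2 <- suppressWarnings(fit_timing_model(sub2))
  expect_equal(unname(fit2$coef["paradoxusTRUE"]), 3, tolerance = 1e-8)
})

test_that("timing model equals the normal-equations oracle", {
  tab <- ym_table(timing_effect = 1.5, seed = 3)
  d <- fake_draws(matrix(integer(0), nrow = 2, ncol = 0), integer(0))
  sub <- select_young_males(tab, d, 1)
  fit <- fit_timing_model(sub)
  X <- cbind(1, sub$year_c, as.numeric(sub$paradoxus))
  ref <- solve(t(X) %*% X, t(X) %*% sub$day)
  expect_equal(unname(fit$coef), drop(ref), tolerance = 1e-10)
  e <- sub$day - X %*% ref
  s2 <- sum(e^2) / (nrow(X) - 3)
  expect_equal(unname(fit$vcov), s2 * solve(t(X) %*% X), tolerance = 1e-8)
})

test_that("condition model falls back to OLS when year variance is zero", {
  tab <- ym_table(weight_effect = 0.4, seed = 4)   # no year-level noise
  d <- fake_draws(matrix(integer(0), nrow = 2, ncol = 0), integer(0))
  sub <- select_young_males(tab, d, 1)
  mm <- fit_condition_model(sub, "weight")
  ols <- lm(weight_g ~ day_c + year_c + paradoxus, data = sub)
  expect_equal(unname(mm$coef), unname(coef(ols)), tolerance = 1e-4)
  # single plumage level is inestimable
  sub_one <- sub[sub$paradoxus, ]
  expect_error(fit_condition_model(sub_one, "weight"), "inestimable")
})

test_that("condition model recovers the generating plumage effects", {
  s <- scenario_preset("subigerberg", n_years = 12,
                       mean_captures_per_year = 400)
  tab <- simulate_captures(s, seed = 5)
  d <- fake_draws(matrix(integer(0), nrow = 1, ncol = 0), integer(0))
  sub <- select_young_males(tab, d, 1)   # true labels, no missingness
  for (spec in list(list("weight", 0.25), list("primary", 0.62))) {
    fit <- fit_condition_model(sub, spec[[1]])
    est <- unname(fit$coef["paradoxusTRUE"])
    se <- sqrt(fit$vcov["paradoxusTRUE", "paradoxusTRUE"])
    expect_lt(abs(est - spec[[2]]), 2 * se)
  }
})

test_that("pooling behaves in degenerate and counting cases", {
  f <- list(coef = c(a = 1, paradoxusTRUE = 2.5), vcov = diag(1e-20, 2),
            term = "paradoxusTRUE")
  pooled <- pool_over_draws(list(f, f, f), seed = 1)
  expect_equal(pooled$mean, 2.5, tolerance = 1e-8)
  expect_equal(pooled$q97.5 - pooled$q2.5, 0, tolerance = 1e-7)
  expect_true(pooled$support %in% c(0, 1))
  expect_equal(pooled$n_estimable, 3)

  # half positive, half negative samples give support one half
  fits <- lapply(c(rep(5, 10), rep(-5, 10)), function(m)
    list(coef = c(paradoxusTRUE = m), vcov = matrix(1e-12), term = "paradoxusTRUE"))
  pooled2 <- pool_over_draws(fits, seed = 2)
  expect_equal(pooled2$support, 0.5)

  expect_error(pool_over_draws(list(NULL, NULL)), "no estimable")
})

test_that("pooled spread obeys the law of total variance", {
  set.seed(6)
  mu <- rnorm(400, 0, 2)          # between-draw spread from label uncertainty
  fits <- lapply(mu, function(m)
    list(coef = c(paradoxusTRUE = m), vcov = matrix(0.5^2),
         term = "paradoxusTRUE"))
  pooled <- pool_over_draws(fits, seed = 7)
  within_var <- 0.5^2
  expect_gt(var(pooled$samples), within_var)
  expect_lt(abs(var(pooled$samples) - (var(mu) + within_var)), 0.8)
})

test_that("paradoxus trend flat case stays flat", {
  tab <- ym_table(n_per_year = 60, n_years = 8, seed = 8)  # 50% paradoxus
  d <- fake_draws(matrix(integer(0), nrow = 60, ncol = 0), integer(0))
  tr <- paradoxus_trend(tab, d, seed = 9)
  expect_lt(abs(tr$first_year$mean - 0.5), 0.1)
  expect_lt(abs(tr$last_year$mean - 0.5), 0.1)
  expect_gt(tr$slope_support, 0.05)
  expect_lt(tr$slope_support, 0.95)
  expect_equal(tr$n_estimable, 60)
})

test_that("full pipeline recovers null effects with complete labels", {
  # no plumage effects and no missing labels: pooled intervals near zero
  s <- scenario_preset(1, n_years = 6, mean_captures_per_year = 150)
  tab <- simulate_captures(s, seed = 10)
  d <- fake_draws(matrix(integer(0), nrow = 30, ncol = 0), integer(0))
  eff <- analyze_plumage(tab, d, seed = 11)
  expect_lt(abs(eff$weight$mean), 0.35)
  expect_true(eff$weight$q2.5 <= 0 && eff$weight$q97.5 >= 0)
  expect_lt(abs(eff$timing$mean), 3)
  # with no label uncertainty all draws give the same subset
  expect_equal(sd(eff$paradoxus_fraction), 0)
})
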
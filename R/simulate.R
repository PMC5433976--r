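#' Simulate a fully labelled capture table
#'
#' Generates captures year by year.  Individuals pass with day ~
#' Normal(passage_mean + shift * (year - midpoint), passage_sd); the yearly
#' number of passing birds is Poisson with intensity scaled by the normal
#' mass inside the fixed capture window, so the *expected number captured*
#' equals \code{mean_captures_per_year} in every year.  Retained birds (day
#' inside the window, after rounding to integer day of year) receive sex and
#' age from the logit-linear Bernoulli models evaluated at their centred day
#' and year, then (weight, primary) from the class-specific bivariate
#' normal.  Young males become paradoxus with a logit-linear-in-year
#' probability; paradoxus birds get the plumage effects added to weight,
#' primary and day.  Females and cairei young males are labelled
#' "female_colored" (the two cannot be told apart in the hand); adult males
#' get no plumage label.  All sex/age labels are fully observed at this
#' stage; use [apply_missingness()] to mask them.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer RNG seed.
#' @return a [capture_table()] whose records carry a logical
#'   \code{paradoxus} truth column in addition to the plumage label.
#' @export
simulate_captures <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$passage_sd <= 0 || spec$window_length < 1)
    stop("invalid scenario: degenerate passage law or empty window")
  set.seed(seed)
  wstart <- spec$window_start
  wend <- wstart + spec$window_length - 1L         # inclusive integer days
  years <- spec$start_year + seq_len(spec$n_years) - 1L
  midpoint_year <- mean(range(years))
  season_mid <- round(wstart + (spec$window_length - 1) / 2)
  tr <- spec$truth
  pl <- spec$plumage_truth

  per_year <- lapply(years, function(yr) {
    mu_y <- spec$passage_mean_day + spec$phenology_shift * (yr - midpoint_year)
    # capture probability = normal mass mapping to integer days in window
    p_window <- pnorm(wend + 0.5, mu_y, spec$passage_sd) -
      pnorm(wstart - 0.5, mu_y, spec$passage_sd)
    if (p_window <= 0) stop("invalid scenario: window has no passage mass")
    n_pass <- rpois(1, spec$mean_captures_per_year / p_window)
    day <- round(rnorm(n_pass, mu_y, spec$passage_sd))
    day <- day[day >= wstart & day <= wend]
    n <- length(day)
    if (n == 0) return(NULL)
    day_c <- day - season_mid
    year_c <- yr - midpoint_year
    sex <- rbinom(n, 1, plogis(tr$s0 + tr$s1 * day_c + tr$s2 * year_c))
    age <- rbinom(n, 1, plogis(tr$a0 + tr$a1 * day_c + tr$a2 * year_c))
    g <- 1L + sex + 2L * age
    z1 <- rnorm(n); z2 <- rnorm(n)
    sw <- tr$sigma_w[g]; sp <- tr$sigma_p[g]; r <- tr$rho[g]
    weight <- tr$w0[g] + tr$w1 * day_c + tr$w2 * year_c + sw * z1
    primary <- tr$p0[g] + tr$p1 * day_c + tr$p2 * year_c +
      sp * (r * z1 + sqrt(1 - r^2) * z2)
    paradoxus <- rep(FALSE, n)
    ym <- which(g == 2L)
    if (length(ym)) {
      p_par <- plogis(pl$baseline_logit + pl$year_slope * year_c)
      paradoxus[ym] <- runif(length(ym)) < p_par
    }
    weight[paradoxus] <- weight[paradoxus] + pl$weight_effect_g
    primary[paradoxus] <- primary[paradoxus] + pl$primary_effect_mm
    day[paradoxus] <- day[paradoxus] + pl$timing_effect_days
    plumage <- rep(NA_character_, n)
    plumage[sex == 0L | (g == 2L & !paradoxus)] <- "female_colored"
    plumage[paradoxus] <- "paradoxus"
    data.frame(year = yr, day = as.integer(day), age = age, sex = sex,
               weight_g = weight, primary_mm = primary,
               plumage = plumage, paradoxus = paradoxus,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, per_year)
  rec <- cbind(id = sprintf("b%06d", seq_len(nrow(rec))), rec)
  capture_table(rec, season_midpoint_day = season_mid,
                reference_year = spec$start_year)
}

#' Mask sex and age labels with class-dependent probabilities
#'
#' Hides each record's sex with probability \code{missing_sex_pct[g]/100}
#' and its age with probability \code{missing_age_pct[g]/100}, where g is
#' the record's true class — the informative missingness mechanism at the
#' heart of the problem.  Paradoxus birds are never unsexed (their adult
#' male-like feathers make sexing easy).  True labels are retained in
#' \code{true_age} / \code{true_sex} columns for evaluation only; weight,
#' primary and day are never altered.
#'
#' @param table a fully labelled [capture_table()] from
#'   [simulate_captures()].
#' @param spec the [scenario_spec()] holding the missingness design.
#' @param seed integer RNG seed.
#' @return a [capture_table()] with masked labels and truth columns.
#' @export
apply_missingness <- function(table, spec, seed) {
  stopifnot(inherits(table, "capture_table"), inherits(spec, "scenario_spec"))
  rec <- table$records
  if (anyNA(rec$sex) || anyNA(rec$age))
    stop("table already contains missing labels; refusing to double-mask")
  set.seed(seed)
  g <- class_index(rec$age, rec$sex)
  n <- nrow(rec)
  p_sex <- spec$missing_sex_pct[g] / 100
  if (!is.null(rec$paradoxus)) p_sex[rec$paradoxus] <- 0
  p_age <- spec$missing_age_pct[g] / 100
  hide_sex <- runif(n) < p_sex
  hide_age <- runif(n) < p_age
  rec$true_sex <- rec$sex
  rec$true_age <- rec$age
  rec$sex[hide_sex] <- NA_integer_
  rec$age[hide_age] <- NA_integer_
  out <- capture_table(rec, table$season_midpoint_day, table$reference_year)
  out$midpoint_year <- table$midpoint_year
  out
}
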
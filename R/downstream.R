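#' Young-male subset under one posterior draw
#'
#' Selects the records whose (observed-or-imputed) age is young and sex is
#' male at the given saved draw, tagging each as paradoxus (plumage =
#' "paradoxus") or cairei (any other plumage, including female-coloured and
#' unlabelled records imputed as young males).  Observed labels are never
#' overridden: a record observed as adult or female can never be selected.
#'
#' @param table the [capture_table()] the model was fitted to.
#' @param draws a \code{posterior_draws} object from [run_mcmc()].
#' @param draw_index saved-draw row index.
#' @return data.frame of the selected records with logical column
#'   \code{paradoxus} and covariate columns \code{day_c}, \code{year_c}.
#' @export
select_young_males <- function(table, draws, draw_index) {
  rec <- table$records
  age <- rec$age; sex <- rec$sex
  if (length(draws$miss_idx)) {
    g <- draws$labels[draw_index, ]
    age[draws$miss_idx] <- (g - 1L) %/% 2L
    sex[draws$miss_idx] <- (g - 1L) %% 2L
  }
  keep <- age == 0L & sex == 1L
  out <- rec[keep, , drop = FALSE]
  out$paradoxus <- !is.na(out$plumage) & out$plumage == "paradoxus"
  out$day_c <- centered_day(table)[keep]
  out$year_c <- centered_year(table)[keep]
  out
}

#' Migration-timing model for one young-male subset
#'
#' Ordinary least squares of capture day of year on centred year and
#' plumage type (0 = cairei, 1 = paradoxus).  With
#' \code{use_corrected_day = TRUE} the response is the phenology-corrected
#' day instead (both versions give quantitatively equivalent plumage
#' effects).
#'
#' @param subset data.frame from [select_young_males()].
#' @param use_corrected_day logical.
#' @param shift_per_year correction slope in days/year (default 0.2).
#' @param reference_year anchor for the correction.
#' @return list with \code{coef}, \code{vcov} and \code{term} (the plumage
#'   coefficient name).
#' @export
fit_timing_model <- function(subset, use_corrected_day = FALSE,
                             shift_per_year = 0.2, reference_year = NULL) {
  if (length(unique(subset$paradoxus)) < 2)
    stop("inestimable: single plumage level in this draw")
  y <- if (use_corrected_day) {
    if (is.null(reference_year)) reference_year <- min(subset$year)
    corrected_day(subset$day, subset$year, reference_year, shift_per_year)
  } else subset$day
  fit <- lm(y ~ year_c + paradoxus, data = subset)
  list(coef = coef(fit), vcov = vcov(fit), term = "paradoxusTRUE")
}

#' Body-condition model for one young-male subset
#'
#' Linear mixed model (REML) of weight or primary length on centred day,
#' centred year and plumage type with a random year intercept absorbing
#' year-to-year condition variation.  If the variance-component fit fails,
#' falls back to the fixed-effects-only OLS model with a warning.
#'
#' @param subset data.frame from [select_young_males()].
#' @param outcome \code{"weight"} or \code{"primary"}.
#' @return list with \code{coef} (fixed effects), \code{vcov} and
#'   \code{term}.
#' @export
fit_condition_model <- function(subset, outcome = c("weight", "primary")) {
  outcome <- match.arg(outcome)
  if (length(unique(subset$paradoxus)) < 2)
    stop("inestimable: single plumage level in this draw")
  if (length(unique(subset$year)) < 2)
    stop("inestimable: need >= 2 years")
  subset$y <- if (outcome == "weight") subset$weight_g else subset$primary_mm
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ day_c + year_c + paradoxus + (1 | year), data = subset,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed model failed to converge; using fixed-effects-only fit")
    fit <- lm(y ~ day_c + year_c + paradoxus, data = subset)
    return(list(coef = coef(fit), vcov = vcov(fit), term = "paradoxusTRUE"))
  }
  list(coef = lme4::fixef(fit), vcov = as.matrix(vcov(fit)),
       term = "paradoxusTRUE")
}

#' Pool per-draw model fits into one posterior effect distribution
#'
#' For every estimable draw, one coefficient vector is simulated from a
#' multivariate normal centred at the fit with the fit's covariance (the
#' per-draw parameter-simulation step), and the plumage coefficient is
#' collected; pooling these samples across draws propagates both the label
#' uncertainty (different subsets per draw) and the estimation uncertainty
#' of each fit.
#'
#' @param fits list of fit results (each with \code{coef}, \code{vcov},
#'   \code{term}); \code{NULL} entries mark inestimable draws and are
#'   skipped.
#' @param seed RNG seed for the simulation step.
#' @param direction \code{+1} or \code{-1}: the predicted sign; the support
#'   probability is the fraction of pooled samples with that sign.
#' @return list with \code{mean}, \code{q2.5}, \code{q97.5},
#'   \code{support}, \code{samples}, \code{n_estimable}, \code{n_skipped}.
#' @export
pool_over_draws <- function(fits, seed = 1, direction = 1) {
  est <- Filter(Negate(is.null), fits)
  if (!length(est)) stop("no estimable draws to pool")
  set.seed(seed)
  samples <- vapply(est, function(f) {
    sim <- MASS::mvrnorm(1, mu = f$coef, Sigma = f$vcov)
    unname(sim[f$term])
  }, numeric(1))
  list(mean = mean(samples),
       q2.5 = unname(quantile(samples, 0.025)),
       q97.5 = unname(quantile(samples, 0.975)),
       support = mean(sign(samples) == sign(direction)),
       samples = samples,
       n_estimable = length(est),
       n_skipped = length(fits) - length(est))
}

#' Plumage-type effects on timing and body condition
#'
#' Runs the full per-draw procedure over the saved posterior draws: select
#' the young males under each draw's imputed labels, fit the timing linear
#' model and the two condition mixed models, simulate one coefficient
#' vector per fit, and pool across draws.  The paradoxus fraction among
#' selected young males is recorded per draw.
#'
#' @param table the fitted [capture_table()].
#' @param draws a \code{posterior_draws} object.
#' @param draw_indices which saved draws to use (default: all).  A thinned
#'   subset trades a little Monte-Carlo precision for run time.
#' @param use_corrected_day passed to [fit_timing_model()].
#' @param seed RNG seed for the per-draw simulation step.
#' @return object of class \code{plumage_effects}: per-outcome pooled
#'   estimates (timing in days, weight in g, primary in mm; paradoxus minus
#'   cairei), support probabilities (timing: later passage; condition:
#'   positive difference) and the per-draw paradoxus fractions.
#' @export
analyze_plumage <- function(table, draws, draw_indices = NULL,
                            use_corrected_day = FALSE, seed = 1) {
  if (is.null(draw_indices)) draw_indices <- seq_len(nrow(draws$params))
  timing <- vector("list", length(draw_indices))
  weight <- vector("list", length(draw_indices))
  primary <- vector("list", length(draw_indices))
  frac <- numeric(length(draw_indices))
  for (k in seq_along(draw_indices)) {
    sub <- select_young_males(table, draws, draw_indices[k])
    frac[k] <- if (nrow(sub)) mean(sub$paradoxus) else NA_real_
    timing[[k]] <- tryCatch(
      fit_timing_model(sub, use_corrected_day = use_corrected_day),
      error = function(e) NULL)
    weight[[k]] <- tryCatch(fit_condition_model(sub, "weight"),
                            error = function(e) NULL)
    primary[[k]] <- tryCatch(fit_condition_model(sub, "primary"),
                             error = function(e) NULL)
  }
  structure(list(
    timing = pool_over_draws(timing, seed = seed, direction = 1),
    weight = pool_over_draws(weight, seed = seed + 1, direction = 1),
    primary = pool_over_draws(primary, seed = seed + 2, direction = 1),
    paradoxus_fraction = frac,
    n_draws = length(draw_indices)), class = "plumage_effects")
}

#' @export
print.plumage_effects <- function(x, ...) {
  cat("plumage-type effects (paradoxus - cairei), pooled over",
      x$n_draws, "posterior draws\n")
  for (nm in c("timing", "weight", "primary")) {
    e <- x[[nm]]
    unit <- c(timing = "days", weight = "g", primary = "mm")[nm]
    cat(sprintf("  %-8s %6.3f %s [%.3f to %.3f], support %.2f (%d draws, %d skipped)\n",
                nm, e$mean, unit, e$q2.5, e$q97.5, e$support,
                e$n_estimable, e$n_skipped))
  }
  cat(sprintf("  paradoxus fraction among young males: mean %.3f (range %.3f-%.3f)\n",
              mean(x$paradoxus_fraction, na.rm = TRUE),
              min(x$paradoxus_fraction, na.rm = TRUE),
              max(x$paradoxus_fraction, na.rm = TRUE)))
  invisible(x)
}

#' Trend in the paradoxus fraction among young males
#'
#' For each saved draw, a logistic regression of the paradoxus indicator on
#' centred year among the selected young males; one coefficient vector is
#' simulated per draw from the fit, and the implied paradoxus proportions
#' at the first and last study year are pooled across draws together with
#' the support probability for a positive year slope.  Draws in which the
#' subset is all-paradoxus or paradoxus-free are skipped and counted.
#'
#' @inheritParams analyze_plumage
#' @return list with pooled \code{first_year} and \code{last_year}
#'   proportion summaries (mean, q2.5, q97.5), \code{slope_support},
#'   \code{n_estimable}, \code{n_skipped}, and the yearly pooled proportion
#'   curve \code{curve} (data.frame year x mean proportion).
#' @export
paradoxus_trend <- function(table, draws, draw_indices = NULL, seed = 1) {
  if (is.null(draw_indices)) draw_indices <- seq_len(nrow(draws$params))
  years <- sort(unique(table$records$year))
  if (length(years) < 2) stop("multi-year data required")
  yr_c <- years - table$midpoint_year
  set.seed(seed)
  first <- last <- slope <- rep(NA_real_, length(draw_indices))
  curve_acc <- matrix(0, length(draw_indices), length(years))
  for (k in seq_along(draw_indices)) {
    sub <- select_young_males(table, draws, draw_indices[k])
    if (!nrow(sub) || length(unique(sub$paradoxus)) < 2) next
    fit <- suppressWarnings(
      glm(paradoxus ~ year_c, family = binomial(), data = sub))
    sim <- MASS::mvrnorm(1, mu = coef(fit), Sigma = vcov(fit))
    slope[k] <- sim["year_c"]
    pr <- plogis(sim["(Intercept)"] + sim["year_c"] * yr_c)
    first[k] <- pr[1]; last[k] <- pr[length(pr)]
    curve_acc[k, ] <- pr
  }
  ok <- !is.na(slope)
  if (!any(ok)) stop("no estimable draws for the paradoxus trend")
  summ <- function(x) list(mean = mean(x[ok]),
                           q2.5 = unname(quantile(x[ok], 0.025)),
                           q97.5 = unname(quantile(x[ok], 0.975)))
  list(first_year = summ(first),
       last_year = summ(last),
       slope_support = mean(slope[ok] > 0),
       n_estimable = sum(ok),
       n_skipped = sum(!ok),
       curve = data.frame(year = years,
                          proportion = colMeans(curve_acc[ok, , drop = FALSE])))
}

#' Write a plumage-effects report
#'
#' CSV table of pooled effects plus a JSON report with intervals and
#' support probabilities.
#'
#' @param effects a \code{plumage_effects} object.
#' @param csv_path,json_path output paths (either may be \code{NULL}).
#' @return invisibly, the summary data.frame.
#' @export
write_plumage_report <- function(effects, csv_path = NULL, json_path = NULL) {
  tab <- do.call(rbind, lapply(c("timing", "weight", "primary"), function(nm) {
    e <- effects[[nm]]
    data.frame(outcome = nm, estimate = e$mean, q2.5 = e$q2.5,
               q97.5 = e$q97.5, support = e$support,
               n_estimable = e$n_estimable, n_skipped = e$n_skipped)
  }))
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(tab, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
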
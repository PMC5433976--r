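#' Naive linear-model baselines
#'
#' The two traditional analyses the joint model is compared against:
#' \code{LM1} regresses a morphometric on centred day and year using *all*
#' records, ignoring the age-sex classes; \code{LM2} uses only the records
#' *observed* as young females (complete-case, one class).  Both return the
#' day and year slopes with 95% confidence intervals.
#'
#' @param table a [capture_table()].
#' @param outcome \code{"weight"} or \code{"primary"}.
#' @param which \code{"LM1"} or \code{"LM2"}.
#' @return data.frame with rows day/year: estimate, lower, upper.
#' @export
fit_baseline_lm <- function(table, outcome = c("weight", "primary"),
                            which = c("LM1", "LM2")) {
  outcome <- match.arg(outcome)
  which <- match.arg(which)
  rec <- table$records
  d <- data.frame(y = if (outcome == "weight") rec$weight_g else
                    rec$primary_mm,
                  day_c = centered_day(table),
                  year_c = centered_year(table))
  if (which == "LM2") {
    keep <- !is.na(rec$age) & !is.na(rec$sex) & rec$age == 0L & rec$sex == 0L
    d <- d[keep, , drop = FALSE]
  }
  if (nrow(d) < 10) stop("too few records for the baseline model")
  fit <- lm(y ~ day_c + year_c, data = d)
  ci <- confint(fit, level = 0.95)
  data.frame(term = c("day", "year"),
             estimate = unname(coef(fit)[c("day_c", "year_c")]),
             lower = unname(ci[c("day_c", "year_c"), 1]),
             upper = unname(ci[c("day_c", "year_c"), 2]))
}

#' Coverage and bias of interval estimates against generating truth
#'
#' @param summaries data.frame with columns \code{replicate},
#'   \code{parameter}, \code{mean}, \code{q2.5}, \code{q97.5} (one row per
#'   parameter per replicate).
#' @param truth named numeric vector of generating values; names must
#'   cover every parameter in \code{summaries}.
#' @return data.frame per parameter: \code{coverage} (proportion of
#'   replicates whose interval contains the truth), \code{bias} (mean of
#'   estimate minus truth), \code{bias_se} (Monte-Carlo SE of the bias),
#'   \code{mean_width}, \code{n}.
#' @export
coverage_and_bias <- function(summaries, truth) {
  pars <- unique(summaries$parameter)
  missing <- setdiff(pars, names(truth))
  if (length(missing))
    stop("no truth value for parameter(s): ", paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(pars, function(nm) {
    s <- summaries[summaries$parameter == nm, ]
    tv <- truth[[nm]]
    hit <- s$q2.5 <= tv & tv <= s$q97.5
    err <- s$mean - tv
    data.frame(parameter = nm,
               truth = tv,
               coverage = mean(hit),
               n_hit = sum(hit),
               bias = mean(err),
               bias_se = sd(err) / sqrt(length(err)),
               mean_width = mean(s$q97.5 - s$q2.5),
               n = nrow(s))
  }))
  rownames(out) <- NULL
  out
}

#' Replicate simulation study: simulate, mask, fit, evaluate
#'
#' For each replicate: generate a capture table from the scenario, mask
#' labels with the scenario's class-dependent missingness, fit the Bayesian
#' joint model, summarize the slope parameters, and fit the LM1/LM2
#' baselines for weight and primary length.  Replicate seeds are derived
#' from the master seed by a fixed counter scheme so each replicate is
#' independently reproducible.  Replicates whose maximum Gelman-Rubin
#' statistic exceeds 1.1 are recorded and excluded from the coverage/bias
#' aggregation (with disclosure in the result).
#'
#' @param scenario a [scenario_spec()].
#' @param n_reps number of replicates.
#' @param config an [mcmc_config()]; its seed field is overridden per
#'   replicate.
#' @param master_seed integer master seed.
#' @param parameters which parameters to track (default: the eight day and
#'   year slopes).
#' @return object of class \code{study_result}: \code{table} (per-parameter
#'   coverage/bias from [coverage_and_bias()]), \code{baselines}
#'   (LM1/LM2 per-term coverage, bias and width aggregated over
#'   replicates), \code{summaries} and \code{baseline_rows} (per-replicate
#'   detail), \code{n_excluded}, \code{scenario_id}, \code{master_seed}.
#' @export
run_study <- function(scenario, n_reps = 100,
                      config = mcmc_config(),
                      master_seed = 1,
                      parameters = SLOPE_PARAMS) {
  stopifnot(n_reps >= 1)
  truth <- params_to_vector(scenario$truth)
  summaries <- list()
  baseline_rows <- list()
  excluded <- integer(0)
  for (rep in seq_len(n_reps)) {
    seed_sim <- master_seed + 10000L * rep
    tab <- simulate_captures(scenario, seed = seed_sim)
    masked <- apply_missingness(tab, scenario, seed = seed_sim + 1L)
    cfg <- config
    cfg$seed <- seed_sim + 2L
    draws <- run_mcmc(masked, prior_spec(), cfg)
    if (isFALSE(draws$converged)) {
      excluded <- c(excluded, rep)
      next
    }
    ss <- summarize_draws(draws, parameters = parameters)
    ss$replicate <- rep
    summaries[[length(summaries) + 1L]] <- ss
    for (outcome in c("weight", "primary")) {
      for (bl in c("LM1", "LM2")) {
        b <- tryCatch(fit_baseline_lm(masked, outcome, bl),
                      error = function(e) NULL)
        if (is.null(b)) next
        b$outcome <- outcome
        b$model <- bl
        b$replicate <- rep
        baseline_rows[[length(baseline_rows) + 1L]] <- b
      }
    }
  }
  if (!length(summaries))
    stop("all replicates failed convergence")
  summaries <- do.call(rbind, summaries)
  baseline_rows <- do.call(rbind, baseline_rows)
  result <- coverage_and_bias(summaries, truth)

  baselines <- NULL
  if (!is.null(baseline_rows)) {
    key <- expand.grid(model = c("LM1", "LM2"),
                       outcome = c("weight", "primary"),
                       term = c("day", "year"), stringsAsFactors = FALSE)
    baselines <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
      b <- baseline_rows[baseline_rows$model == key$model[i] &
                           baseline_rows$outcome == key$outcome[i] &
                           baseline_rows$term == key$term[i], ]
      if (!nrow(b)) return(NULL)
      tv <- truth[[paste0(substr(key$outcome[i], 1, 1),
                          if (key$term[i] == "day") "1" else "2")]]
      data.frame(model = key$model[i], outcome = key$outcome[i],
                 term = key$term[i], truth = tv,
                 coverage = mean(b$lower <= tv & tv <= b$upper),
                 bias = mean(b$estimate - tv),
                 mean_width = mean(b$upper - b$lower),
                 prop_signif_positive = mean(b$lower > 0),
                 prop_signif_negative = mean(b$upper < 0),
                 n = nrow(b))
    }))
  }
  structure(list(table = result,
                 baselines = baselines,
                 summaries = summaries,
                 baseline_rows = baseline_rows,
                 n_reps = n_reps,
                 n_excluded = length(excluded),
                 excluded = excluded,
                 scenario_id = scenario$id,
                 master_seed = master_seed), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: scenario %s, %d replicates (%d excluded for non-convergence), master seed %d\n",
              x$scenario_id, x$n_reps, x$n_excluded, x$master_seed))
  print(x$table, digits = 3)
  if (!is.null(x$baselines)) {
    cat("\nbaseline linear models:\n")
    print(x$baselines, digits = 3)
  }
  invisible(x)
}

#' Write a study result as JSON plus per-replicate CSV
#' @param result a \code{study_result}.
#' @param json_path,csv_path output paths.
#' @return \code{json_path} invisibly.
#' @export
write_study_result <- function(result, json_path, csv_path = NULL) {
  obj <- list(scenario_id = result$scenario_id,
              n_reps = result$n_reps,
              n_excluded = result$n_excluded,
              master_seed = result$master_seed,
              table = result$table,
              baselines = result$baselines)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    write.csv(result$summaries, csv_path, row.names = FALSE)
  invisible(json_path)
}
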
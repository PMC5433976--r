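#' Joint log-density of one record under known labels
#'
#' The model's likelihood contribution for a single capture with (observed
#' or currently imputed) age and sex: bivariate-normal log-density of
#' (weight, primary) at the class-g mean plus the two Bernoulli log-masses
#' from the logit-linear sex and age models.
#'
#' @param params a [model_params()].
#' @param age,sex 0/1 labels (must be observed).
#' @param weight,primary morphometrics (g, mm).
#' @param day_c day centred at the middle of the capture period.
#' @param year_c year centred at the study midpoint.
#' @return log-density (scalar).
#' @export
record_log_density <- function(params, age, sex, weight, primary,
                               day_c, year_c) {
  g <- class_index(age, sex)
  mu_w <- params$w0[g] + params$w1 * day_c + params$w2 * year_c
  mu_p <- params$p0[g] + params$p1 * day_c + params$p2 * year_c
  sw <- params$sigma_w[g]; sp <- params$sigma_p[g]; r <- params$rho[g]
  if (any(sw <= 0) || any(sp <= 0) || any(abs(r) >= 1))
    stop("covariance not positive-definite")
  dw <- (weight - mu_w) / sw
  dp <- (primary - mu_p) / sp
  mvn <- -log(2 * pi) - log(sw) - log(sp) - 0.5 * log1p(-r^2) -
    (dw^2 - 2 * r * dw * dp + dp^2) / (2 * (1 - r^2))
  eta_s <- params$s0 + params$s1 * day_c + params$s2 * year_c
  eta_a <- params$a0 + params$a1 * day_c + params$a2 * year_c
  bern <- sex * eta_s - softplus(eta_s) + age * eta_a - softplus(eta_a)
  mvn + bern
}

# log(1 + exp(x)) without overflow
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Admissible (age, sex) completions for one record.  Observed labels fix
# their coordinate; paradoxus plumage forces young male.
admissible_completions <- function(age, sex, paradoxus = FALSE) {
  ages <- if (is.na(age)) 0:1 else age
  sexes <- if (is.na(sex)) 0:1 else sex
  grid <- expand.grid(age = ages, sex = sexes)
  if (isTRUE(paradoxus)) grid <- grid[grid$age == 0 & grid$sex == 1, ]
  if (nrow(grid) == 0)
    stop("empty admissible set: labels contradict the plumage constraint")
  grid
}

#' Posterior distribution over the missing labels of one record
#'
#' For a record with at least one missing label, the full-conditional
#' probability of each admissible (age, sex) completion given the current
#' model parameters: proportional to P(sex | day, year) * P(age | day,
#' year) * MVN(weight, primary | class), normalised over the admissible
#' set.  Records with paradoxus plumage are constrained to young male.
#'
#' @inheritParams record_log_density
#' @param age,sex 0/1 or \code{NA}; at least one must be \code{NA}.
#' @param paradoxus logical; plumage constraint.
#' @return data.frame with columns \code{age}, \code{sex}, \code{prob}
#'   (summing to 1).
#' @export
label_posterior <- function(params, age, sex, weight, primary,
                            day_c, year_c, paradoxus = FALSE) {
  if (!is.na(age) && !is.na(sex) && !paradoxus)
    stop("no missing label to impute")
  grid <- admissible_completions(age, sex, paradoxus)
  lp <- mapply(function(a, s)
    record_log_density(params, a, s, weight, primary, day_c, year_c),
    grid$age, grid$sex)
  w <- exp(lp - max(lp))
  grid$prob <- w / sum(w)
  rownames(grid) <- NULL
  grid
}
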
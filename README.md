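# ringmiss

Bayesian imputation of missing sex and age labels in bird-ringing capture
data, with a replicate simulation harness and a posterior-imputation
analysis of plumage-type effects in young male Black Redstarts.

## The problem

At autumn ringing stations many captures cannot be sexed or aged in the
hand, and the missingness is *informative*: first-year male Black Redstarts
with the dull *cairei* plumage look exactly like females, while the minority
with the adult-male-like *paradoxus* plumage are easy to sex.  Complete-case
analyses are therefore biased (the unsexed birds are not a random sample),
and all-data analyses that ignore sex and age confound seasonal and yearly
composition changes with real morphometric change.

`ringmiss` models each capture's body weight \(W_i\) and third-primary
length \(P_i\) jointly with its age-sex class \(g\) (young female, young
male, adult female, adult male):

```
(W_i, P_i) ~ MVN( (w0_g + w1*Day_i + w2*Year_i,
                   p0_g + p1*Day_i + p2*Year_i),  Sigma_g )
Sex_i ~ Bernoulli( invlogit(s0 + s1*Day_i + s2*Year_i) )
Age_i ~ Bernoulli( invlogit(a0 + a1*Day_i + a2*Year_i) )
```

with Day centred at the middle of the capture period and Year at the study
midpoint.  A Gibbs/Metropolis sampler (C++ core, fully seeded through R's
RNG) imputes every missing label from its full conditional at each
iteration, so label uncertainty propagates into every posterior summary and
into downstream models fitted per posterior draw.

## Worked example

```r
library(ringmiss)

# a campaign like simulation scenario 1, at desk scale
scn  <- scenario_preset(1, n_years = 10, mean_captures_per_year = 150)
tab  <- simulate_captures(scn, seed = 11)          # fully labelled truth
obs  <- apply_missingness(tab, scn, seed = 12)     # class-dependent masking
obs
#> capture_table: 1511 records, years 1980-1989
#>   day range 270-289 (midpoint day 280), midpoint year 1984.5
#>   missing sex 60.8%, missing age 32.7%, paradoxus 52

fit <- run_mcmc(obs, prior_spec(),
                mcmc_config(n_chains = 2, n_iter = 3000, n_burn = 1000,
                            thin = 2, seed = 7))
fit
#> posterior_draws: 2000 draws (2 chains), 30 parameters, 1077 records with imputed labels
#>   max Gelman-Rubin R-hat 1.018 (converged)

summarize_draws(fit, parameters = c("s1", "s2", "a1", "a2"))
#>   parameter    mean      sd     q2.5   q97.5  rhat   ess
#> 1        s1 0.02674 0.01140 0.003997 0.04849 1.009 208.4
#> 2        s2 0.07488 0.01969 0.039305 0.11355 1.002 226.9
#> 3        a1 0.11973 0.01529 0.091412 0.15229 1.018 152.9
#> 4        a2 0.04917 0.02274 0.004110 0.09478 1.001 293.5
```

Every 95% credible interval above contains its generating value (s1 =
0.032, s2 = 0.046, a1 = 0.122, a2 = 0.017): the day slopes say males and
especially adults pass later in the season, the year slopes capture the
composition trend across the study period, and the intervals are honest
about what ~1500 captures with three fifths of the sexes missing can
support.

Downstream, the plumage analysis pools per-draw model fits over the saved
draws (here a real-data-like preset; truth: paradoxus birds +0.25 g,
+0.62 mm, no timing difference):

```r
scn  <- scenario_preset("subigerberg", n_years = 10, mean_captures_per_year = 150)
obs  <- apply_missingness(simulate_captures(scn, 101), scn, 201)
fit  <- run_mcmc(obs, prior_spec(),
                 mcmc_config(n_iter = 3000, n_burn = 1000, seed = 301))
analyze_plumage(obs, fit, draw_indices = seq(1, 2000, by = 10))
#> plumage-type effects (paradoxus - cairei), pooled over 200 posterior draws
#>   timing    1.119 days [-0.828 to 2.976], support 0.88 (200 draws, 0 skipped)
#>   weight    0.197 g [-0.126 to 0.523], support 0.87 (200 draws, 0 skipped)
#>   primary   0.823 mm [0.310 to 1.330], support 1.00 (200 draws, 0 skipped)
#>   paradoxus fraction among young males: mean 0.081 (range 0.075-0.088)
```

All three pooled intervals contain their generating values (0, +0.25 g,
+0.62 mm).

The replicate simulation study (credible-interval coverage, bias, and the
LM1/LM2 naive-baseline comparison) is exposed as `run_study()`, and a thin
command-line front end lives at `inst/scripts/simstudy.R`.

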
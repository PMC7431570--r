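# wolfcr

Competing-risks survival analysis of policy effects on the fates of
radio-collared gray wolves.

## The problem

Known-fate telemetry studies follow collared animals from collaring to a
terminal *endpoint*. For Wisconsin wolves six endpoints compete: five causes
of death — vehicle collision, legal control kill, reported poaching, nonhuman
causes, uncertain cause — plus disappearance (lost-to-follow-up, LTF), an
aggregate of emigration, transmitter failure and *cryptic poaching* (illegal
kills with the evidence, collar included, destroyed). The scientific question
is whether periods of liberalized wolf-killing policy (ESA downlisting,
lethal-take sub-permits, delisting) changed the hazard and cumulative
incidence of each endpoint — especially LTF, whose cryptic-poaching component
is invisible to ordinary cause-of-death tallies. Discarding LTF animals as
uninformative censorings biases every cause-specific estimate, so the risk
set must account for all endpoints jointly.

`wolfcr` implements the full analysis pipeline for this design and a
synthetic cohort generator that emulates its statistical structure, so every
estimator can be exercised and validated against known truth.

## The models

Monitoring histories are split at every calendar date on which a
time-dependent covariate changes — liberalized killing (`lib_kill`), season
(`winter`), census-method era (`method_change`) — into counting-process
*spells* `(tstart, tstop]` in days since collaring. Cause-specific hazards
follow stratified proportional-hazards models fit jointly across endpoints
via Lunn–McNeil (Method B) augmentation: each spell is replicated once per
endpoint stratum *k* with an event indicator for that stratum, and

    h_k(t | x) = h_0k(t) * exp(beta_1k x_1 + ... + beta_jk x_j)

is maximized as one endpoint-stratified partial likelihood (Breslow ties,
day-resolution times), with robust variance from score residuals summed
within animal clusters. Time-varying coefficients enter as
`covariate * (t / 365.25)`, so `exp(beta_tvc)` is a multiplicative change in
the hazard ratio per year of monitoring.

Unconditional incidence uses the cumulative incidence function
`CIF_k(t) = Prob(T <= t, D = k)`, estimated three ways: nonparametrically
(Aalen–Johansen), by product-integral composition of the joint Cox fit's
per-stratum baseline hazards, and from Fine–Gray subdistribution-hazard
models, in which animals failing from competing endpoints remain in the risk
set with inverse-probability-of-censoring weights and coefficients
exponentiate to subhazard ratios (SHRs) acting on incidence. Published
hazard ratios are summarized as lognormal HR distributions (tail
probabilities beyond HR = 1), and animals with missing endpoints near the
study close are resolved by a Bernoulli-simulation imputation with MAIN /
LOW / HIGH threshold scenarios.

## Worked example

```r
library(wolfcr)

cohort <- generate_cohort(sim_config(), seed = 42)$cohort
validate_cohort(cohort)
#> Cohort validation: 513 records - OK
#> Endpoint mix:
#>   endpoint   n proportion
#>        ltf 234      45.6%
#>    poached  75      14.6%
#>      legal  38       7.4%
#>   nonhuman  82      16.0%
#>  collision  17       3.3%
#>  uncertain  23       4.5%
#>   censored  44       8.6%

spells <- split_spells(cohort, default_calendars())
aug    <- build_augmented(spells)
fit    <- cr_cox(aug, spec_m5())
summary(fit)
#>                term   coef    hr se_robust lower  upper      z     p
#>        lib_kill_ltf  0.497 1.643     0.169 1.179  2.289  2.935 0.003
#>    lib_kill_poached -0.265 0.768     0.407 0.346  1.705 -0.650 0.516
#>  ...
#>     census2_poached -1.017 0.362     0.400 0.165  0.793 -2.541 0.011
#>  tvc_lib_kill_legal  1.698 5.463     0.617 1.631 18.297  2.754 0.006
#>      tvc_winter_ltf -0.313 0.731     0.071 0.636  0.841 -4.401 0.000
#> LL = -2325.55, AIC = 4677.10, BIC = 4731.06, p = 13, events = 469
```

Each row is a covariate-by-endpoint interaction: `lib_kill_ltf` is the
hazard ratio for disappearance during liberalized-killing periods relative
to full protection (here 1.64 on this simulated cohort), with a 95% CI from
the cluster-robust SE. `tvc_winter_ltf` of 0.731 means the winter effect on
LTF shrinks by a factor 0.73 per monitored year, so

```r
tab <- summary(fit)$table
row <- tab[tab$term == "lib_kill_ltf", ]
prob_hr_side(hr_distribution(row$hr, se = row$se_robust), side = "above")$percent
#> [1] 100
hr_at_time(2.511, 0.731, years = 1)   # winter LTF HR one year after collaring
#> [1] 1.84
```

The published annotations are reproduced from printed table values alone:

```r
prob_hr_side(1.18, c(0.87, 1.60), side = "above")$percent  # LTF policy effect
#> [1] 86   # vs the published "85%", within rounded-input tolerance
prob_hr_side(0.81, c(0.48, 1.35), side = "below")$percent  # reported poached
#> [1] 79
hr_at_time(3.13, 0.69, 1:2)  # winter-on-LTF HR after 1 and 2 years
#> [1] 2.1597 1.4902
```

`run_pipeline(run_config(seed = 11))` chains every stage — simulation (or a
cohort CSV), validation, spells, augmentation, the model-selection ladder,
Fine–Gray fits, all three CIF families by policy level, HR distributions,
and the MAIN/LOW/HIGH imputation scenarios with per-scenario refits —
and `render_report()` formats the bundle as a single text report.

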
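# crgof — goodness-of-fit tests for the Compound Rayleigh distribution

`crgof` answers the question *"do these lifetimes follow a Compound
Rayleigh distribution?"* for complete and type-II right-censored samples,
the situation where the classical Kolmogorov–Smirnov / Cramér–von Mises /
Anderson–Darling tables are invalid twice over: the parameters are
estimated from the data, and censoring truncates the empirical
distribution function. It is aimed at reliability and survival analysts
working with Burr-type lifetime models.

## The model and the statistics

The Compound Rayleigh (CR) distribution has

$$F(x;\alpha,\beta)=1-\Big(1+\frac{x^2}{\beta}\Big)^{-\alpha},\qquad x>0,$$

with shape α and scale β (units of x²); equivalently X² is Lomax(α, β).
Given the r smallest order statistics of n items on test, the package:

* estimates (α, β) by censored maximum likelihood — closed form in α given
  β via the exponential identity $v_i=\log(1+x_i^2/\beta)\sim\mathrm{Exp}(\alpha)$,
  profile likelihood over β jointly (`cr_mle()`);
* computes the censored, estimated-parameter versions of the KS, CvM and
  AD statistics on $\hat u_{(i)}=F(x_{(i)};\hat\alpha,\hat\beta)$
  (`cr_gof_stats()`);
* calibrates them by Monte Carlo: reusable critical-value tables
  (`cr_critical_tables()`, `simulate_null()`) or per-dataset parametric
  bootstrap p-values with parameters re-estimated in every replicate
  (`cr_gof_test()`);
* measures power against exponential, gamma and chi-square alternatives
  (`power_table()`) and compares CR, Exponentiated Rayleigh and Rayleigh
  fits on a dataset (`compare_fits()`).

Three published datasets ship as plain-text fixtures with provenance
headers: 30 March precipitation values, 30 daily wind speeds, and 46
chemotherapy survival times (`load_precipitation()`, `load_wind_speed()`,
`load_chemotherapy()`).

## Worked example

Does the CR model fit the 46 chemotherapy survival times?

```r
library(crgof)
s <- censored_sample(load_chemotherapy()$values)   # complete: r = n = 46
cr_gof_test(s, level = 0.05, reps = 2000, seed = 42)
#> Compound Rayleigh goodness-of-fit test
#>   n = 46, r = 46, case = both_unknown, level = 0.05, bootstrap reps = 2000
#>   alpha = 0.6235, beta = 0.2827
#>  statistic   value critical p_value     decision
#>         ks 0.11601  0.11996 0.07046 not rejected
#>        cvm 0.10946  0.11437 0.05397 not rejected
#>         ad 0.68957  0.71955 0.05897 not rejected
```

The fitted model is CR(0.62, 0.28). Each statistic is below its bootstrap
5% critical value and every p-value is above 0.05, so the CR hypothesis is
not rejected for these survival times — though all three p-values sit
close to the level: the fit is acceptable, not comfortable.

Comparative fitting on the precipitation data ranks the candidate models
(smaller statistics = better fit):

```r
compare_fits(censored_sample(load_precipitation()$values))
#> Comparative fit (smaller statistic = better fit)
#>                  family                       estimates      ks     cvm      ad
#>       compound_rayleigh     alpha = 5.036, beta = 15.29 0.05533 0.01273 0.10311
#>  exponentiated_rayleigh lambda = 0.2476, theta = 0.9026 0.07530 0.03290 0.21974
#>                rayleigh                   sigma = 1.373 0.08349 0.05321 0.32492
```

The CR model fits best on all three statistics.

A command-line wrapper covers the same operations
(`inst/cli/crgof {fit|stats|test|tables|power|sample|datasets}`), e.g.
`inst/cli/crgof test mydata.txt --n 60 --reps 2000 --seed 7 --json`.

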
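# bnbpower

Simulation-based power and false-positive-rate estimation for RNA-Seq
differential expression with **paired or repeated measurements** — tumor
versus matched normal, before versus after treatment — where within-subject
correlation makes ordinary fixed-effects count models the wrong planning
tool. It is aimed at statisticians and bioinformaticians designing paired
sequencing studies: how many subject pairs are needed to detect a given
fold change in a gene of given expression level and dispersion, at a
stringent per-comparison error rate?

## Models and procedure

Paired counts are modeled by the **bivariate negative binomial (BNB)**
distribution: a subject effect G ~ Gamma(1/φ, φ) (mean 1, variance φ)
multiplies both members of a pair,

    X | G = g ~ Poisson(μ g),    Y | G = g ~ Poisson(γ μ g),

so X has marginal mean μ and variance μ + φμ², Y has mean γμ, and the
shared G induces the within-pair correlation (Cov(X, Y) = γφμ²). The fold
ratio γ is tested (H₀: γ = 1, two-sided) by the likelihood-ratio statistic
and by the Wald statistic on log γ̂ with the inverse observed information
as variance. The same data can be analyzed as **count GLMMs** — Poisson or
negative binomial family, log link, condition fixed effect, subject random
intercept, marginal likelihood by adaptive Gauss–Hermite quadrature — with
a likelihood-ratio test on the condition effect.

Power and false positive rates come from a six-step Monte Carlo procedure:
simulate T datasets under the null and T under the alternative, compute
the statistic on each, take the 100(1−α)th percentile of the null
statistics as the critical value (the **empirical parametric test**) or
use the asymptotic χ²₁ quantile, and report the alternative rejection
fraction. The empirical route controls the false positive rate at α by
construction — which matters, because the NB-GLMM LRT is visibly
conservative against χ²₁ and the Wald statistic drifts from it at low
expression.

## Worked example

Designing a study for genes at the 20th-percentile expression of a paired
tumor/normal pilot (baseline mean 14, dispersion 1), at α = 0.001:

```r
library(bnbpower)

sample_size_for_power(mu = 14, phi = 1, gamma = 2, alpha = 0.001,
                      target_power = 0.8, test = "bnb-lrt",
                      n_range = 3:20, T = 5000, seed = 1)
#> n = 5 pairs per condition reaches power 0.80 (estimated 0.8200)
#>   mu=14 phi=1 gamma=2 alpha=0.001, bnb-lrt (empirical critical values), T=5000
```

Five pairs suffice for a 2-fold up-regulation; the same call with
`gamma = 0.5` returns 9 pairs for a 2-fold down-regulation (down-regulated
genes yield fewer total counts, hence less information per pair).
Calibration of the LRT against the asymptotic χ²₁ critical value:

```r
false_positive_rate(n = 10, mu = 10, phi = 1, test = "bnb-lrt",
                    alpha = 0.001, T = 20000, seed = 1,
                    critical_source = "chi2")
#> FPR 0.00085 (MC SE 0.00021) for bnb-lrt at alpha 0.001 [chi2 critical value 10.8276]
#>   scenario n=10 mu=10 phi=1, T=20000, failed fits: 0 (crit) 0 (eval)
```

The estimated rate sits within Monte Carlo error of the nominal 0.001.
Scenario parameters are anchored in pilot data with `pilot_fit()`, which
fits the BNB model per gene of a paired count matrix and summarizes μ̂ and
φ̂ at their 20th/50th/80th percentiles; `generate_fixture()` creates a
synthetic pilot matrix for experimentation.

## Command line

A thin CLI wraps the same functions (`exec/bnbpower`):

```sh
exec/bnbpower samplesize --mu 14 --phi 1 --gamma 2 --alpha 0.001 --target 0.8
exec/bnbpower power --n 5,10,15 --mu 10 --phi 1 --gamma 0.5,1,2 --alpha 0.001 --out results/
exec/bnbpower fixture --n-genes 500 --n-pairs 50 --out pilot/
```

Every run writes CSV results plus `metadata.json` (version, seed, T,
percentile convention, failure counts) from which it can be reproduced
exactly; `--config file.yaml` supplies options from a config file.

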
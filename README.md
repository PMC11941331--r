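# coxshrink

Post-selection shrinkage estimation for high-dimensional Cox proportional
hazards models.

## The problem

In sparse survival regression with many covariates (gene-expression
predictors of time-to-event outcomes being the canonical case), penalized
selectors such as the LASSO and the Elastic Net recover covariates with
*strong* effects but shrink away *weak* ones — coefficients that are small
but genuinely nonzero. When weak signals are numerous, discarding them
biases the coefficients that are kept. `coxshrink` is for biostatisticians
and methods researchers who want to (a) detect strong and weak signal sets
separately, (b) correct the post-selection bias by Stein-type shrinkage,
and (c) study the estimators' risk behavior both by Monte Carlo and through
their asymptotic theory.

## The method

With hazard $\lambda(t\mid x)=\lambda_0(t)\exp(x^\top\beta)$ and log
partial likelihood $\ell(\beta)$ (Breslow ties), the index set splits into
strong signals $S_1$, weak signals $S_2$ and zeros:

1. **Step 1** — $\hat S_1$ = support of a cross-validated penalized Cox fit
   (LASSO or Elastic Net, via glmnet).
2. **Step 2** — weighted ridge
   $\hat\beta^r=\arg\min_\beta\,-\ell(\beta)+r_n\lVert\beta_{\hat S_1^c}\rVert_2^2$
   (penalty only outside $\hat S_1$), hard-thresholded at
   $a_n = c\,n^{-\kappa}$: surviving non-strong coordinates form
   $\hat S_2$, and the thresholded vector is the weighted-ridge estimator
   $\hat\beta^{WR}$.
3. **Shrinkage** — with $\hat s_2=|\hat S_2|>2$, the restricted MLE
   $\hat\beta^{RE}$ on $\hat S_1$ and the weak-signal statistic
   $T_n=\hat\beta^{WR\top}_{\hat S_2}(X_{\hat S_2}^\top M_{\hat S_1}X_{\hat S_2})\hat\beta^{WR}_{\hat S_2}$
   give the shrinkage estimator
   $\hat\beta^{SE}_{\hat S_1}=\hat\beta^{WR}_{\hat S_1}-\frac{\hat s_2-2}{T_n}(\hat\beta^{WR}_{\hat S_1}-\hat\beta^{RE})$
   and its positive part $\hat\beta^{PSE}$ (factor capped at 1, so the
   estimate stays between $\hat\beta^{WR}$ and $\hat\beta^{RE}$).

The package also evaluates the estimators' asymptotic distributional bias
and risk under local alternatives ($\beta_{S_2}=\delta/\sqrt n$) through
non-central chi-square inverse moments, and ships a seeded Monte Carlo
engine for relative-MSE and false-positive-rate studies on a calibrated
synthetic design (AR(1) covariates, exponential event times, uniform
censoring calibrated to a target rate). See the methods vignette
(`vignettes/postselection-shrinkage.Rmd`) for the model, defaults and
design decisions.

## Worked example

```r
library(coxshrink)

cfg <- sim_config(n = 150, p = 100, censor_rate = 0.15, seed = 42)
sim <- simulate_survival(cfg)          # truth: beta = (8, 9, 10, 1, 0.8, 0.5, 0.2 x4, 0, ...)
sel <- run_two_step(sim$data, family = "lasso", seed = 42)
sel
#> <selection_result>
#>   step 1 (lasso, lambda = 0.1569): |S1hat| = 6
#>   step 2 (r_n = 2.569 [theory], a_n = 0.2857): |S2hat| = 15
#>   S1hat: 1 2 3 4 5 7
shr <- post_selection_estimates(sim$data, sel)
shr
#> <shrinkage_result> |S1hat| = 6, s2 = 15, shrinkage applied (Tn = 227.5)
head(coefficient_table(sel, shr), 5)
#>    index beta_ple beta_re beta_pse
#> x1     1   1.2497  8.0849  11.9301
#> x2     2   1.4584  9.1788  13.9164
#> x3     3   1.6506 10.1194  15.2746
#> x4     4   0.1189  0.9929   1.3468
#> x5     5   0.1033  0.9623   1.6097
```

Step 1 found the three strong covariates plus three of the weak ones
(`S1hat = {1..5, 7}`); step 2 flagged 15 further coordinates as
weak-signal candidates. The penalized coefficients (`beta_ple`) are
heavily shrunk (1.2–1.7 against true values 8–10); the restricted MLE
(`beta_re`) recovers the strong block nearly unbiasedly. Because the
weak-signal evidence is strong here ($T_n = 227$, shrink factor
$(15-2)/227 \approx 0.06$), the positive-shrinkage estimate stays close to
the weighted-ridge fit — whose unpenalized block overfits at this extreme
signal strength, illustrating exactly the trade-off the simulation study
quantifies.

Risk theory, no simulation required:

```r
sg <- make_ar1_covariance(9, 0.5)
ti <- theory_inputs(sg[1:3, 1:3], sg[1:3, 4:9], sg[4:9, 4:9],
                    d1 = rep(1, 3) / sqrt(3), delta = rep(0.3, 6))
round(adr_values(ti), 4)
#>     wr     re     se    pse
#> 1.0000 0.8769 0.9166 0.8940
```

The weighted-ridge risk is 1 by normalization; at this mild weak-signal
level the restricted estimator is best and the positive-shrinkage
estimator dominates the plain shrinkage estimator, as the theory orders
them.

A command-line front end over the same functions ships in
`inst/cli/coxshrink.R` (subcommands `simulate`, `fit`, `study`, `theory`;
every run writes a JSON manifest of its resolved configuration).

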
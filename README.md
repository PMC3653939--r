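# seedlim

Seed and establishment limitation analysis for seed-addition experiments.

## The problem

Plant recruitment can fail for two very different reasons: seeds never
arrive (**seed limitation**), or seeds arrive but the site does not let
them establish (**establishment limitation**, decomposable into
density-independent and density-dependent mortality). Seed-addition
experiments — sowing seeds at a ladder of densities into replicated
quadrats and censusing seedlings repeatedly — are the standard way to
separate these processes. `seedlim` implements the complete analysis for
such experiments, together with a fully parameterised synthetic-data
generator so that every stage can be exercised and validated against known
ground truth.

Two complementary notions of limitation are computed:

**Realized limitation** via the per-seed recruitment effect size of a
treatment quadrat against its plot controls,

```
E_i = (T_i - C) / s_i
```

with `T_i` the seedling count after sowing `s_i` seeds, and `C` the mean
count of the matching control quadrats. `E` near 1 means seed-limited;
near 0 means establishment-limited. Hierarchical Bayesian GLMMs
(binomial–logit for `E`, lognormal-Poisson for counts, with crossed
species × plot random effects, fitted by an adaptive
Metropolis-within-Gibbs sampler with Gelman–Rubin diagnostics) quantify
how `E` varies with augmentation level, conspecific density, species and
site.

**Fundamental limitation** via the asymptotic Beverton–Holt recruitment
function

```
R(S) = P0 * S / (1 + P0 * S / Rmax)
```

where `S` is total seed input (sown + ambient rain), `P0` is per-seed
recruitment under density-independent mortality only, and `Rmax` is the
seedling density at seed saturation. Four nested variants (full DD model;
density-independent line `P0*S`; seed-only `S`; no-DI `S/(1+S/Rmax)`) are
fitted by maximum marginal likelihood with NB2 error, a log-normal plot
random effect integrated out by adaptive Gauss–Hermite quadrature, and
compared by AIC (a gap of 4 distinguishing models). From the fitted DD
model the recruitment shortfall is decomposed at any seed input into

- seed limitation `L_S = Rmax - R(S)`,
- density-independent limitation `L_DI = S/(1+S/Rmax) - R(S)`,
- density-dependent limitation `L_DD = P0*S - R(S)`,
- establishment limitation `L_E = S - R(S)`,

with closed-form crossovers `L_E = L_S` at `S = Rmax` and `L_DD = L_DI`
at `S = Rmax(1-P0)/P0`, reported both in seeds per quadrat and in
multiples of ambient seed rain, plus Pearson trend tests of each
component across censuses.

## Worked example

```r
library(seedlim)

design  <- experiment_design(n_plots = 8)   # 8 plots x 3 stations x 35 quadrats
records <- simulate_experiment(design, true_params(), rng_seed = 42)

effects <- plot_effect_sizes(records, census_month = 3)
mean(effects$E)
#> [1] 0.008

fit_dd <- fit_model(records, census_month = 3, model = "DD")
fit_di <- fit_model(records, census_month = 3, model = "DI")
fit_dd
#> Recruitment model DD at month 3: logLik = -408.359, AIC = 824.718 (840 obs)
#>   parameter estimate   ci_2_5 ci_97_5
#>          P0  0.01377 0.009173 0.02064
#>        Rmax  1.67916 0.961041 2.93388
#>           k  1.53284 0.815114 2.88255
#>  sigma_plot  0.38375 0.192852 0.76360

compare_models(list(fit_dd, fit_di))
#>   model    loglik n_free_params      aic delta_aic selected distinguished  tied
#> 1    DD -408.3591             4 824.7182   0.00000     TRUE          TRUE FALSE
#> 2    DI -418.7780             3 843.5560  18.83781    FALSE         FALSE FALSE

limitation_curve(fit_dd$estimates)
#> Limitation curve over 200 seed inputs [0.000835, 167] seeds/quadrat
#>   L_E overtakes L_S at S = 1.679 seeds/quadrat (20.11 x ambient)
#>   L_DD overtakes L_DI at S = 120.2 seeds/quadrat (1440 x ambient)
```

Reading the output: the mean per-seed effect size of 0.008 says that under
this generator truth the community is strongly establishment-limited (fewer
than 1% of added seeds recruit). The saturating (DD) model beats the
density-independent line by ΔAIC ≈ 19, clear evidence of density
dependence; the fitted `P0` of 0.014 and `Rmax` of 1.7 seedlings/quadrat
bracket the generating values (0.01 and 1.125). Establishment limitation
overtakes seed limitation once seed input exceeds ~1.7 seeds per quadrat
(~20× ambient rain), while density-dependent mortality only dominates
above ~1400× ambient — the two windows in which adding seed does and does
not pay.

The full pipeline (simulate → effects → GLMM → fits → decomposition →
trends, with a checksummed manifest) runs via

```r
cfg <- pipeline_config(rng_seed = 1)
run_pipeline(cfg, "out/")
```

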
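# healthvep

Health poverty vulnerability analysis for individual-level survey
microdata.

## What it is for

Health economists and epidemiologists studying whether policy levers —
government subsidies (GS) and public health-service provision (PM) —
reduce the risk that people fall into *physical and mental health
poverty* need three measurement layers before any regression can run:

1. **Multidimensional health poverty** via the Alkire–Foster (A-F)
   method: binary deprivations $\varphi_n$ on 7 physical-health and 10
   mental-health indicators (Andersen model dimensions: predisposing,
   enabling, need), weighted score $k=\sum_n w_n\varphi_n$, poor when
   $k \ge \gamma$ (default $\gamma = 0.30$, i.e. three or more of seven
   indicators).
2. **Vulnerability as expected poverty (VEP)**: model log welfare as
   $\ln C = X\alpha + e$, $\mathrm{Var}(e\mid X)=X\beta$ by three-stage
   feasible GLS (Chaudhuri/Amemiya), then
   $\mathrm{VUL}=\Phi\{(\ln z - X\hat\alpha)/\sqrt{X\hat\beta}\}$,
   binarized at a cutoff (default 0.5).
3. **Income elasticity of health demand** $E_H$: the slope of
   $\ln Q_{health} = \alpha + \beta_h \ln Y + \varepsilon$, estimated
   within urban/rural × age-decile strata and assigned per individual,
   truncated at zero.

The analysis layer is a **two-layer logistic regression** with province
fixed effects: first layer VEP ~ GS + PM + covariates; second layer adds
$E_H$ and the interactions $GS \times E_H$, $PM \times E_H$.  Results
are reported as average marginal effects (dy/dx) with delta-method
standard errors, joint Wald chi-square tests for the interaction block,
urban/rural and east/central/west subgroup contrasts, and
coefficient-of-variation / Theil-T inequality indices.

A calibrated synthetic microdata generator (`pop_config()`,
`generate_population()`) reproduces the analytic-sample structure of a
large household survey (n = 8831, 57% urban, subsidy rate 0.335, binary
vulnerability mean 0.953) with known ground truth, so the entire
pipeline is testable offline.

## Worked example

```r
library(healthvep)

cfg <- pop_config(n_individuals = 8831, seed = 7)
pop <- generate_population(cfg)

# A-F physical-health poverty aggregates
specs <- builtin_specs()
php <- score_and_classify(apply_deprivations(pop, specs$php), specs$php, 0.30)
unlist(af_aggregate(php))
#>           headcount_ratio mean_intensity_among_poor        adjusted_headcount
#>                0.19929793                0.48733766                0.09712539

# full pipeline: A-F -> elasticity -> FGLS vulnerability -> two-layer logit
res <- run_pipeline(pop, "results/demo", pipeline_config(seed = 7))
mean(res$table$vep)                 # share classified vulnerable: 0.338
res$elasticity$pooled$beta_h        # pooled income elasticity: 0.568

# second-layer average marginal effects (key variables)
a <- res$report$table6$ame
a[a$term %in% c("gs", "pm_s", "eh", "gs:eh", "pm_s:eh"),
  c("term", "dydx", "z", "stars")]
#>     term   dydx      z stars
#>       gs -0.116 -20.99   ***
#>     pm_s -0.136 -11.20   ***
#>       eh -0.629 -12.19   ***
#>    gs:eh  0.300  10.69   ***
#>  pm_s:eh -0.426  -6.21   ***
```

Reading the output: 19.9% of the simulated population is physically
health-poor, with a mean deprivation intensity of 0.49 among the poor
(adjusted headcount M0 = 0.097).  In the second-layer fit, receiving a
subsidy lowers the probability of being vulnerable by 11.6 points and a
one-unit rise in the rescaled service rating by 13.6 points; higher
health demand ($E_H$) is strongly protective, the positive
$GS \times E_H$ term says the subsidy effect weakens as demand rises,
and the negative $PM \times E_H$ term says service provision helps more
where demand is higher — the same sign pattern the generator encodes.

Every stage also writes artifacts (`population.csv`, `af_scores.csv`,
`elasticity.csv`, `vep.csv`, `regressions/`, `inequality.csv`) and a
`manifest.csv` recording rows in/out per stage.

## Command line

```sh
Rscript inst/cli/healthvep.R simulate --n 8831 --seed 7 --out pop.csv
Rscript inst/cli/healthvep.R af-score --in pop.csv --out af.csv --gamma 0.30
Rscript inst/cli/healthvep.R run-pipeline --simulate-n 8831 --seed 7 --out results/
```

Subcommands: `simulate`, `af-score`, `vep`, `elasticity`, `fit`,
`inequality`, `run-pipeline`.

## Package layout

* `R/synthetic_data.R`, `R/io.R` — generator and validated CSV I/O
* `R/af_index.R` — A-F indicator systems, scoring, aggregation
* `R/vep.R` — three-stage FGLS and vulnerability prediction
* `R/elasticity.R` — log-log elasticity, stratified E_H assignment
* `R/logit.R`, `R/suite.R` — IRLS logit, AMEs, Wald tests, table suite
* `R/inequality.R` — CV and Theil-T gap reports
* `R/pipeline.R` — orchestration, config files, manifests
* `vignettes/health-poverty-vulnerability.Rmd` — models, parameters,
  design decisions, known limitations
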
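# causalfoodq

Causal analysis of food quality tables: Bayesian-network structure
learning, d-separation-based deconfounding, do(x) intervention curves, and
double-machine-learning validation — with ground-truth synthetic generators
emulating three classic study designs (wheat baking quality, fermented
dairy consumer assessment, wine panel scores).

## The problem and the models

Food quality data mix objective physicochemical measurements with
subjective consumer grades, and the variables are heavily inter-correlated:
a regression coefficient of quality on temperature confounds the direct
effect with everything temperature also drives. This package implements the
graphical-causal workflow for such tables.

A structural causal model (SCM) over variables x_1..x_p is a directed
acyclic graph G = {V, E} with one mechanism per node,

    x_k = b_0k + Σ_{p ∈ Pa(x_k)} b_pk · g(x_p) + ε_k ,   ε_k ~ N(0, σ_k²),

so the joint density factorizes as Π_k p(x_k | Pa(x_k)). The stages:

- **Screening** (wide tables): elastic net minimizing
  `(1/2n)‖y − Xβ‖² + λ(α‖β‖₁ + (1−α)/2 ‖β‖₂²)` with λ chosen by
  cross-validation (glmnet backend).
- **Structure learning**: hill climbing on a decomposable penalized
  likelihood (BIC, `log L − (k/2) log n`), with logistic / cumulative-logit
  families for binary / ordinal nodes; structure MCMC gives posterior edge
  probabilities, validated against exact enumeration on small graphs.
- **Identification**: d-separation (Bayes-ball) and backdoor adjustment
  sets Z — non-descendants of the treatment that block every backdoor path.
- **Estimation**: path coefficients (OLS of each node on its parents,
  standardized), total effects as path-sums, the adjusted ACE
  `∂E[Y|do(x)]/∂x` from outcome-on-treatment+Z regression, and
  nonparametric do(x) curves from a bootstrap ensemble of small neural
  networks marginalized over the empirical covariate distribution.
- **Validation**: double machine learning — cross-fitted random-forest
  residuals of outcome and treatment on the covariates, and
  `θ = Cov(r_Y, r_T) / Var(r_T)` (the partially linear residual-ratio
  estimator), which should agree with the structural estimates when both
  are right.

## Worked example

The dairy template emulates a consumer study: pre-treatment `temperature`
and `fat` are exogenous; binary `odour`, `turbidity`, `taste` and a
3-level ordinal `grade` are sensory outcomes.

```r
library(causalfoodq)

scm <- food_template("dairy")      # ground-truth SCM preset
d   <- sample_dataset(scm, 5000, seed = 1)

hc <- hill_climb(d, n_restarts = 10, seed = 1)
dag_parents(hc$dag, "grade")
#> [1] "temperature" "fat"         "odour"       "turbidity"

cpdag_equal(cpdag_of(hc$dag), cpdag_of(scm$dag))
#> [1] TRUE

ace_adjusted(d, hc$dag, "temperature", "grade")
#> total effect of temperature on grade [adjusted-ols]: -0.0325 (se 0.0007, natural units)
#>   adjustment set: { odour }
```

The learned graph is in the generating Markov-equivalence class, the
quality grade's direct causes are recovered, and the deconfounded ACE of
temperature is about −0.03 grade per °C: heating lowers the expected
consumer grade. The do(temperature) curve
(`do_curve(d, hc$dag, "temperature", "grade", grid = seq(35, 75, 2.5))`)
shows the effect steepening near the planted 60 °C change point — ACE(x)
runs from −0.008 at the low end to −0.082 grade/°C just past 60 °C —
before flattening as the 3-level grade saturates.

On the wine template the structural and structure-free estimates agree per
predictor (standardized units; from `analysis/05_dml_validation.R`):

```
  alcohol                scm +0.336  dml +0.330 (se 0.018)
  sulphates              scm +0.167  dml +0.165 (se 0.013)
  volatile_acidity       scm -0.229  dml -0.233 (se 0.014)
  largest SCM-DML discrepancy: 1.29 combined se
```

Alcohol carries the strongest positive ACE on quality and volatile acidity
the strongest negative one, under both estimators.

## The analysis workflow

Numbered drivers under `analysis/` rerun the three case studies end to end,
writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the three template datasets + ground-truth DAGs |
| `02_feature_selection.R` | wheat: elastic-net screening (10/10 actives recovered, R² 0.91) + PCA |
| `03_structure_learning.R` | dairy: hill-climb DAG, CPDAG comparison, MCMC vs exact posterior |
| `04_causal_effects.R` | dairy: path coefficients, temperature/fat ACE, do(x) curves |
| `05_dml_validation.R` | wine: SCM path-sum vs DML per predictor |
| `06_quality_models.R` | bagged-forest baselines with out-of-bag metrics |

`run_pipeline()` executes the same stages from one YAML/JSON config with
deterministic per-stage seeding.

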
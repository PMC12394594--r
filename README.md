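# emotrans

Multi-study analysis of **emotion transition predictions** and their
relationship with **loneliness**, with an internal random-effects
meta-analysis and a fully synthetic test bench.

## The scientific problem

In the emotion transition task, participants rate on a 0–100% scale how
likely a target — themselves (*self*) or another person (*other*) — is to
move from one emotion state to another (e.g. *calm → irritable*), over all
ordered pairs of a study's emotion set. These ratings describe each
person's mental model of emotion dynamics. The package asks, across
several studies at once, whether people higher in trait loneliness
(20-item scale, scores 0–60):

* hold **atypical** models — per-participant typicality index
  `r_i = cor(ratings_i, group mean)`, correlated with standardized
  loneliness;
* are idiosyncratic in an **"Anna Karenina"** sense — intersubject
  similarity analysis (IS-RSA) comparing the participant-pair similarity
  matrix against a model matrix `M(i,j) = mean(L_i, L_j)` with Spearman's
  ρ and Mantel permutation inference;
* are less **accurate** predicting others — mixed model
  `ground truth ~ other_rating × loneliness` with crossed random
  intercepts (participant, from-state, to-state), where the ground truth
  is the per-transition mean of everyone's self-ratings;
* **anchor** less on themselves — `other_rating ~ self_rating × loneliness`;
* perceive more **volatility** / **anti-positivity** — per-category
  (PP/PN/NP/NN) simple slopes of loneliness on ratings;
* respond with less **confidence** — per-participant rating SD vs
  loneliness.

Study-level effects (standardized β, or Fisher-z correlations with
variance `1/(n−3)`) are pooled with a REML random-effects meta-analysis
(`y_j ~ N(μ, v_j + τ²)`), reporting the pooled estimate, 95% CI, τ² and
I². Studies without other-target data drop out of other-target families
(k = 6 instead of 7 in the default design).

Both workhorse estimators are implemented from scratch and validated
against independent oracles in the test suite: the crossed
random-intercept LMM uses profiled REML via the Woodbury identity on the
random-level crossproducts (checked against OLS, balanced-design closed
forms, and `lme4`), and the meta-analytic τ² uses the standard REML
fixed point (checked against a grid-search maximizer and
DerSimonian–Laird).

## Worked example

```r
library(emotrans)

## one synthetic study with the default planted effects
ds <- generate_study(synth_config(study_id = "demo", n_participants = 80, seed = 42))
ds
#> <study_dataset> demo
#>   states: 6 (same-state excluded)
#>   participants: 80; ratings: 4800; targets: self, other

## typicality: lonely raters deviate from the group-average model
eff <- typicality_effect(typicality_index(ds, "self"), ds)
round(attr(eff, "raw_r"), 3)
#> [1] -0.804

## Anna Karenina IS-RSA with Mantel permutations
S  <- similarity_matrix(ds, "self")
lz <- ds$participants$loneliness_z[match(rownames(S), ds$participants$participant_id)]
ak_isrsa(S, lz, n_perm = 1000, seed = 7)
#> <isrsa_result> model=ak_mean rho=-0.7266 p_perm=0.000999 (n=80, n_perm=1000)

## a seven-study suite (one study self-only), pooled
cfg <- pipeline_config(default_study_configs(master_seed = 1, n_scale = 0.15),
                       out_dir = "demo_out", master_seed = 1, n_perm = 500)
res <- run_pipeline(cfg)
res$meta$anchoring
#> <meta_result> anchoring: k=6 pooled=-0.0998 SE=0.0076 [-0.1146, -0.0849] p=1.19e-39 tau2=2.907e-05 I2=8.0%
res$meta$typicality_self
#> <meta_result> typicality_self: k=7 pooled=-1.0345 SE=0.0837 [-1.1985, -0.8705] p=4.13e-35 tau2=0.01126 I2=23.8%
#>   back-transformed r = -0.7757 [-0.8332, -0.7016]
```

Reading the numbers: the anchoring row pools six studies' interaction
coefficients — lonelier participants' other-ratings load about 0.10 SD
less on their own self-ratings per SD of loneliness, with little
between-study heterogeneity (I² = 8%). The typicality row pools Fisher-z
correlations from all seven studies and back-transforms the pooled value
to the correlation scale (r ≈ −0.78 under the deliberately strong
synthetic defaults; real-data effects are far smaller). `run_pipeline()`
also writes `effects.csv`, `meta.json`, per-family `forest_*.csv`, a
`manifest.json` (config hash + seeds), and a plain-text report whose
sign-pattern table compares every pooled direction with the expected
one.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "emotrans", package = "emotrans"))')
Rscript $CLI simulate --seed 1 --out sim_out          # synthetic suite -> CSVs + provenance
Rscript $CLI run-all  --seed 1 --out run_out          # simulate + analyze + pool + report
Rscript $CLI meta --effects run_out/effects.csv --out meta_out
```

Options: `--config PATH` (JSON/YAML study list, synthetic or file-backed),
`--n-perm INT`, `--n-scale FRAC`,
`--typicality-mode {include-self,loo}`, `--isrsa-model {ak-mean,ak-min,nn}`.

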
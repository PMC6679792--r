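# trajmtl

Parametric Bayesian multi-task learning for longitudinal biomarker
trajectories.

## The problem

Longitudinal studies of neurodegeneration (and many other slow processes)
typically record only a baseline and a handful of follow-up measurements per
subject. Fitting each subject's trajectory separately — ordinary least
squares (OLS) per subject — is then fragile: with two time points and
realistic measurement noise, per-subject slopes are dominated by error.
`trajmtl` treats the learning of each subject's polynomial trajectory as one
*task* and fits all tasks jointly, sharing statistical strength across
subjects through a structured parameter-covariance prior whose shape is
learned from the data. Subjects can additionally be coupled through
*kernels* built from auxiliary biomarkers (continuous measures such as
amyloid PET SUVR or CSF analytes, or APOE genotype similarity), so that
subjects who look alike in one modality are encouraged to have similar
trajectories in another.

The package is aimed at biostatisticians and imaging researchers who would
otherwise reach for a linear mixed effects model, and at anyone who wants a
fully worked, testable implementation of the method together with the
simulation machinery used to validate it.

## The model

Stack all subjects' observations as `y = [y_1' ... y_n']'` (m observations
total) and give each subject a polynomial design block, so the overall
design `X` is block diagonal and `w` holds all nd trajectory coefficients
(d = order + 1; intercept and slope for linear models). The model is
Bayesian linear regression with Gaussian noise of learned precision β:

    y | X, w ~ N(Xw, β⁻¹ I_m),     w ~ N(0, Σ_prior)

with a structured prior covariance built from inter-subject coupling
matrices, one per parameter type:

    Σ_prior = α₁ I_nd + Σᵢ (Σ_ci ⊗ M_ii)
    Σ_ci    = α_i1 I_n + α_i2 1_n + Σⱼ α_ij₊₂ K_j

`M_ii` is the d×d indicator of parameter type i, so intercept coupling and
slope coupling are learned independently. Each `Σ_ci` mixes a fully
independent term (`I_n`), a fully shared term (the all-ones matrix `1_n`,
which acts like a random-effects pooling term) and any number of
subject-similarity kernels `K_j`: linear (`b bᵀ`), squared-exponential
(`k_ij = exp(−σ ‖b_i − b_j‖²)`), binary group membership, or the
weighted/exponentiated identity-by-state genotype kernels. All
hyperparameters (the α's, kernel widths σ, and β) are tuned by **empirical
Bayes**: maximizing the log marginal likelihood with analytic gradients.
The posterior over `w` and the predictive distribution for held-out visits
are then available in closed form, and competing coupling structures are
compared via log Bayes factors (differences of log evidences).

## Worked example

Simulate a 50-subject cohort with group differences in intercept (five
intercept levels, fixed slope −1, noise SD 2), fit the biomarker-coupled
model on the first two visits per subject, and predict the held-out third
visit:

```r
library(trajmtl)

cfg    <- scenario_config("intercept_variation", n_subjects = 50,
                          sigma_m = 2, seed = 42)
cohort <- simulate_cohort(cfg)

fit <- mtl_fit(cohort$train, model = "gaussian_both",
               covariates = list(b = cohort$biomarker), seed = 42)
fit
#> Coupled Bayesian trajectory fit: model 'gaussian_both', 50 subjects, 100 observations
#>   log evidence: -81.3712   noise precision beta: 6.05
#>   covariance hyperparameters: 9

head(fit$parameters, 3)
#>   subject_id  intercept intercept_sd      slope  slope_sd
#> 1       s001 -10.524435    1.0201937 -0.9022735 0.1130964
#> 2       s002  -5.156104    1.0227949 -0.8978614 0.1137015
#> 3       s003 -10.238498    0.9586684 -0.8916171 0.1144850

pred <- predict(fit, cohort$heldout[, c("subject_id", "time")])
mae(pred$mean, cohort$heldout$value)          # 2.226
predict(ols_fit(cohort$train),
        cohort$heldout[, c("subject_id", "time")]) |>
  (\(p) mae(p$mean, cohort$heldout$value))()  # 3.618 — coupling wins

coverage(fit$parameters$slope, fit$parameters$slope_sd,
         cohort$true_slopes)$covered          # 1: true slope inside 2 SD
                                              # for every subject

plain <- mtl_fit(cohort$train, model = "plain", seed = 42)
log_bayes_factor(fit, plain)                  # 21.14 — strong evidence for
                                              # biomarker coupling
```

Reading the output: each subject gets a posterior mean and SD for its
intercept and slope; the posterior slopes are shrunk toward the shared
value −1 with honest uncertainties (the true slope is covered by the 2-SD
interval for every subject), and the coupled model predicts the held-out
visit with ~40% less error than per-subject OLS. The positive log Bayes
factor says the training data are far better explained with
biomarker-kernel coupling than without it.

A command-line interface wrapping the same functions (subcommands
`simulate`, `fit`, `compare`, `study`) is installed at
`system.file("cli", "trajmtl.R", package = "trajmtl")`.

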
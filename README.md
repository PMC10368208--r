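# ssdmodels

Observer models for the perception of object displacement across saccades.

Every saccade displaces the retinal image, yet the world looks stable. The
Saccadic Suppression of Displacement (SSD) paradigm probes how: a target
jumps (or not) while the eye is in flight, and the observer reports whether
— or by how much — it moved. Cue-signaled priors over the jump probability
and graded image blur make the task a testbed for a central question in
perceptual science: does the visual system weight its priors more when the
senses get noisier, as a Bayesian observer must?

`ssdmodels` is a simulation and analysis toolkit for that question, aimed at
psychophysicists and computational neuroscientists. It implements four
observer models and everything needed to exercise them without any
behavioral data:

- **Categorical Bayesian ideal observer.** The observer reports "jumped"
  when the posterior odds favor the broad jump likelihood over the narrow
  no-jump likelihood. With zero-mean likelihoods the rule reduces to a
  threshold on the squared perceived displacement,

  x̂² > x̂²_C = [log((σ²_J+σ²_t)/(σ²_¬J+σ²_t)) + 2·log((1−P(J))/P(J))] /
  [1/(σ²_¬J+σ²_t) − 1/(σ²_J+σ²_t)],

  and since x̂ ~ N(x, σ²_t), the decision curve is the survivor function of
  a noncentral chi-square: D(x) = 1 − F_χ²(x̂²_C/σ²_t; df = 1, λ = x²/σ²_t).
  A lapse-scaled version supports 14-parameter maximum-likelihood fitting
  (3 priors, 3 sensory noise SDs, 2 shared likelihood widths, per-noise
  lower bound and lapse), and a Monte-Carlo evaluator of the raw posterior
  odds serves as an independent oracle.

- **Continuous Bayesian observer.** For continuous reports, the posterior
  mean μ_post = (σ²_L·μ_prior + σ²_prior·μ_L)/(σ²_L + σ²_prior) — the
  reliability-weighted average — with least-squares fitting of the prior
  mean and per-noise likelihood SDs.

- **Discriminative (Perceptron) learner.** A two-layer network over 75
  input bins (0–7.5° at 0.1°), one weight matrix per cue context, trained
  with the delta rule Δw_ij = β·a_i·(d_j − o_j) at β = 0.5. It reproduces
  the overweighting of rare large displacements early in training and, with
  noise applied to its input encoding, a *decreasing* use of priors with
  image noise — the anti-Bayesian signature.

- **Combined model.** O_C = w_B·O_B + w_P·O_P with w_B + w_P = 1 (defaults
  0.1/0.9), the Bayesian component carrying motor-driven noise only (wide
  no-jump likelihood, fixed sensory noise).

Around the models: a synthetic trial-schedule generator with the exact
block structure of the categorical, control, continuous and motor-noise
experiment designs; timing-based trial exclusion; psychometric analysis
(4-parameter logistic fits, intercepts, d′ and Criterion, response-rate
differences, percentile bootstrap CIs); parameter-recovery harnesses; and
scenario drivers that write each model prediction as CSV tables with a JSON
manifest.

## Worked example

```r
library(ssdmodels)

# Bayesian prediction: prior use (high-minus-low intercept difference)
# grows with sensory noise
sapply(c(0.1, 0.25, 0.5), function(st)
  predict_intercept_difference(
    categorical_params(0.78, sigma_jump = 2, sigma_nojump = 0.017, sigma_t = st),
    categorical_params(0.22, sigma_jump = 2, sigma_nojump = 0.017, sigma_t = st)))
#> [1] 0.05674525 0.18708498 0.55474904

# Combined Bayesian + discriminative model: the trend reverses
sim <- simulate_combined_experiment(combined_config(), seed = 7, n_runs = 400)
sim$intercept_differences
#>     noise      diff
#> 0.1   0.1 0.4032862
#> 1     1.0 0.3961556
#> 2     2.0 0.3426002

# Simulate a full categorical session and analyze it
tab <- build_schedule(design_human_categorical(), seed = 1)
obs <- function(x, p, s) {
  out <- numeric(length(x))
  for (pp in unique(p)) {
    k <- p == pp
    out[k] <- decision_curve(x[k], categorical_params(pp, 1.5, 0.017, 0.1))
  }
  out
}
resp <- respond_categorical(tab, obs, seed = 2)
for (pr in c(0.9, 0.1)) {
  k <- resp$prior_label == pr
  print(fit_4pl(abs(resp$displacement_deg[k]), resp$response[k]))
}
#> 4PL fit: min = 0.241, max = 1.000, thresh = 0.104, slope = 3.041
#>   intercept (fitted_min) = 0.241, sse = 36.331
#> 4PL fit: min = 0.000, max = 1.000, thresh = 0.357, slope = 36.288
#>   intercept (fitted_min) = 0.000, sse = 0.770
```

The first block prints the ideal-observer intercept differences at the
three blob widths: the separation between high-prior and low-prior decision
curves grows roughly tenfold from low to high noise, i.e. a Bayesian
observer leans on its prior hardest when the image is least informative.
The combined model's ensemble shows the opposite, anti-Bayesian ordering
(0.40 → 0.34 as input noise goes 0.1° → 2°). The 4PL fits recover the
vertical separation the cued priors impose on the psychometric curves: the
0.9-prior observer's intercept is 0.24 while the 0.1-prior observer's is at
the floor.

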
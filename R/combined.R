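#' Configuration of the combined Bayesian + discriminative model
#'
#' The combined model's report probability is the convex mixture
#' `O_C = w_B * O_B + w_P * O_P` of the categorical Bayesian decision curve
#' and the perceptron output, with weights summing to 1. In the default
#' configuration the Bayesian component carries only motor-driven noise --
#' its no-jump likelihood width is tripled to 1.5 degrees to mimic saccadic
#' suppression while its sensory noise stays at the lowest level -- and all
#' image noise goes to the perceptron's input encoding.
#'
#' @param w_bayes Weight of the Bayesian component in \[0, 1\] (default
#'   0.1; the perceptron gets `1 - w_bayes`).
#' @param sigma_jump,sigma_nojump Likelihood widths of the Bayesian
#'   component (defaults 2.5 and 1.5 degrees).
#' @param sigma_t Sensory noise of the Bayesian component (fixed at the
#'   lowest image-noise level, 0.1 degrees).
#' @param priors Named-by-context prior probabilities the Bayesian component
#'   uses (defaults: the block priors 0.8/0.2 and baseline 0.5).
#' @param perceptron An `ssd_perceptron_config`; default covers contexts
#'   0.2/0.5/0.8.
#' @param protocol An `ssd_protocol` for training the discriminative
#'   component.
#' @return An object of class `ssd_combined_config`.
#' @export
combined_config <- function(w_bayes = 0.1, sigma_jump = 2.5,
                            sigma_nojump = 1.5, sigma_t = 0.1,
                            priors = c("0.2" = 0.2, "0.5" = 0.5,
                                       "0.8" = 0.8),
                            perceptron = perceptron_config(),
                            protocol = training_protocol()) {
  stopifnot(w_bayes >= 0, w_bayes <= 1,
            inherits(perceptron, "ssd_perceptron_config"),
            inherits(protocol, "ssd_protocol"))
  stop_if_not_prob(priors, "priors")
  bayes <- lapply(priors, function(p) {
    categorical_params(p, sigma_jump, sigma_nojump, sigma_t)
  })
  names(bayes) <- names(priors)
  structure(
    list(w_bayes = w_bayes, w_perceptron = 1 - w_bayes,
         bayes_params = bayes, perceptron = perceptron,
         protocol = protocol),
    class = "ssd_combined_config"
  )
}

#' Combined-model output for a displacement
#'
#' `w_B * D_Bayes(x) + w_P * o_jump(x)`: the Bayesian decision curve for the
#' context's prior (motor-noise parameters, fixed sensory noise) mixed with
#' the trained perceptron's jump output for the encoded displacement at the
#' requested image-noise level.
#'
#' @param x Absolute displacement(s), degrees.
#' @param config An `ssd_combined_config`.
#' @param state A trained `ssd_perceptron` state.
#' @param context Context label (must exist in both components).
#' @param sigma_noise Image noise SD used for the perceptron encoding
#'   (default: the protocol's training noise).
#' @return Combined report probabilities in \[0, 1\].
#' @export
combined_output <- function(x, config, state, context,
                            sigma_noise = config$protocol$train_noise) {
  stopifnot(inherits(config, "ssd_combined_config"),
            inherits(state, "ssd_perceptron"))
  ctx <- as.character(context)
  bp <- config$bayes_params[[ctx]]
  if (is.null(bp)) stop("unknown context: ", ctx, call. = FALSE)
  ob <- decision_curve(x, bp)
  act <- encode_inputs(x, sigma_noise, config$perceptron)
  op <- vapply(seq_len(nrow(act)), function(i) {
    unname(perceptron_forward(state, ctx, act[i, ])["jump"])
  }, numeric(1))
  config$w_bayes * ob + config$w_perceptron * op
}

#' Simulate the combined-model experiment over an ensemble of runs
#'
#' Trains the discriminative component through the protocol `n_runs` times.
#' Within each run the combined output of every trial is
#' `w_B * D_Bayes(|x|) + w_P * o_jump` -- the Bayesian component sees the
#' trial's displacement at its fixed (lowest) sensory noise, while the
#' perceptron input carries the trial's image noise. The psychometric
#' intercept per (prior context, image-noise level) is the mean combined
#' output over trials in the smallest displacement bin (`|x| <
#' intercept_bin`), averaged across the ensemble; the prior-use measure is
#' the high-minus-low prior intercept difference per noise level.
#'
#' @param config An `ssd_combined_config`.
#' @param seed Integer seed.
#' @param n_runs Ensemble size for the intercept measurements.
#' @param intercept_bin Half-width (degrees) of the displacement bin read
#'   as the intercept (default: the package's standard 0.5-degree display
#'   bin).
#' @param curves If `TRUE`, also compute early (short-protocol) and
#'   late-window (trials 3000-5000 of a long protocol) ensemble curves.
#' @param n_runs_curves Ensemble size for the curve summaries.
#' @return A list of class `ssd_combined_sim`: `intercepts` (data.frame
#'   `noise`, `context`, `mean_intercept`), `intercept_differences`
#'   (data.frame `noise`, `diff` = high minus low prior), and if requested
#'   `early_curves` / `late_curves` (combined-model ensemble curves).
#' @export
simulate_combined_experiment <- function(config, seed = 1, n_runs = 1000,
                                         intercept_bin = 0.5,
                                         curves = FALSE,
                                         n_runs_curves = 100) {
  stopifnot(inherits(config, "ssd_combined_config"), intercept_bin > 0)
  priors <- config$protocol$priors
  ctx_high <- as.character(max(priors))
  ctx_low <- as.character(min(priors))
  contexts <- as.character(c(0.5, priors))
  noise_levels <- sort(unique(c(config$protocol$train_noise,
                                config$protocol$test_noise)))
  pc <- config$perceptron
  seeds <- derive_seeds(seed, n_runs)
  sums <- counts <- matrix(
    0, length(noise_levels), length(contexts),
    dimnames = list(as.character(noise_levels), contexts)
  )
  for (r in seq_len(n_runs)) {
    run <- run_training(pc, config$protocol, seeds[r])
    tr <- run$trials[run$trials$x_abs < intercept_bin, , drop = FALSE]
    for (ctx in unique(tr$context)) {
      k <- tr$context == ctx
      bp <- config$bayes_params[[ctx]]
      ob <- cell_prob(tr$x_abs[k], bp$p_jump, bp$sigma_jump,
                      bp$sigma_nojump, bp$sigma_t, 0, 0)
      oc <- config$w_bayes * ob + config$w_perceptron * tr$o_jump[k]
      cell <- tapply(oc, as.character(tr$noise[k]), sum)
      ncell <- tapply(oc, as.character(tr$noise[k]), length)
      sums[names(cell), ctx] <- sums[names(cell), ctx] + cell
      counts[names(cell), ctx] <- counts[names(cell), ctx] + ncell
    }
  }
  acc <- sums / counts
  intercepts <- data.frame(
    noise = rep(noise_levels, times = length(contexts)),
    context = rep(contexts, each = length(noise_levels)),
    mean_intercept = as.vector(acc)
  )
  diffs <- data.frame(
    noise = noise_levels,
    diff = acc[, ctx_high] - acc[, ctx_low]
  )
  out <- list(intercepts = intercepts, intercept_differences = diffs,
              n_runs = n_runs)
  if (curves) {
    seeds2 <- derive_seeds(seed + 1, 2)
    early <- run_ensemble(pc, config$protocol, n_runs = n_runs_curves,
                          seed = seeds2[1])
    long_proto <- config$protocol
    long_proto$block_trials <- 5000L
    late <- run_ensemble(pc, long_proto, n_runs = n_runs_curves,
                         seed = seeds2[2], window = c(3000, 5000))
    add_bayes <- function(cv) {
      ob <- vapply(seq_len(nrow(cv)), function(i) {
        decision_curve(cv$bin_mid[i],
                       config$bayes_params[[cv$context[i]]])
      }, numeric(1))
      cv$mean_combined <- config$w_bayes * ob +
        config$w_perceptron * cv$mean_o_jump
      cv
    }
    out$early_curves <- add_bayes(early)
    out$late_curves <- add_bayes(late)
  }
  structure(out, class = "ssd_combined_sim")
}

#' Motor-noise (saccade vs no-saccade) Bayesian simulation
#'
#' Compares two categorical observers that share the jump likelihood width
#' and priors but differ in the no-jump width: wider with a saccade
#' (saccadic suppression makes moderate displacements look like no-jumps)
#' than without. Returns the decision-curve intercept `D(0)` per prior and
#' the high-minus-low prior intercept difference for each condition.
#'
#' @param sigma_jump Shared jump likelihood width (default 5 degrees).
#' @param sigma_nojump_saccade,sigma_nojump_nosaccade No-jump widths with
#'   and without a saccade (defaults 1 and 0.25 degrees).
#' @param sigma_t Sensory noise SD (default 0.5, the probe width used on
#'   all motor-noise trials).
#' @param priors Prior levels (default 0.2, 0.5, 0.8).
#' @return A list of class `ssd_exp5_sim`: `intercepts` (data.frame `prior`,
#'   `saccade`, `D0`) and `intercept_differences` (data.frame `saccade`,
#'   `diff` for the max-minus-min prior pair).
#' @export
simulate_experiment5 <- function(sigma_jump = 5,
                                 sigma_nojump_saccade = 1,
                                 sigma_nojump_nosaccade = 0.25,
                                 sigma_t = 0.5,
                                 priors = c(0.2, 0.5, 0.8)) {
  stopifnot(length(priors) >= 2)
  grid <- expand.grid(prior = priors, saccade = c(FALSE, TRUE))
  grid$D0 <- vapply(seq_len(nrow(grid)), function(i) {
    snj <- if (grid$saccade[i]) sigma_nojump_saccade else
      sigma_nojump_nosaccade
    decision_curve(0, categorical_params(grid$prior[i], sigma_jump, snj,
                                         sigma_t))
  }, numeric(1))
  hi <- max(priors)
  lo <- min(priors)
  diffs <- data.frame(
    saccade = c(FALSE, TRUE),
    diff = vapply(c(FALSE, TRUE), function(s) {
      grid$D0[grid$prior == hi & grid$saccade == s] -
        grid$D0[grid$prior == lo & grid$saccade == s]
    }, numeric(1))
  )
  structure(list(intercepts = grid, intercept_differences = diffs),
            class = "ssd_exp5_sim")
}
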
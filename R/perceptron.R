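#' Configuration of the two-layer discriminative (Perceptron) model
#'
#' The input layer codes absolute displacement as a binned population:
#' `(range_max - range_min) / bin_width` units (75 for the default 0 to 7.5
#' degree range at 0.1-degree bins). Two output units ("jump", "no jump")
#' receive weighted sums of the inputs; weights are learned with the delta
#' rule at learning rate `learning_rate`. Each cued prior gets its own
#' weight matrix ("context"), implementing the assumption that input-output
#' mappings are learned separately per cue color.
#'
#' @param bin_width Input bin width in degrees.
#' @param range_min,range_max Displacement range covered by the input layer.
#' @param learning_rate Delta-rule learning rate (beta > 0).
#' @param contexts Character vector of context labels (one per prior cue).
#' @return An object of class `ssd_perceptron_config` with an `n_bins`
#'   field.
#' @export
perceptron_config <- function(bin_width = 0.1, range_min = 0,
                              range_max = 7.5, learning_rate = 0.5,
                              contexts = c("0.2", "0.5", "0.8")) {
  stopifnot(bin_width > 0, range_max > range_min, learning_rate > 0,
            length(contexts) >= 1)
  n_bins <- (range_max - range_min) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) {
    stop("(range_max - range_min) / bin_width must be an integer",
         call. = FALSE)
  }
  structure(
    list(bin_width = bin_width, range_min = range_min,
         range_max = range_max, learning_rate = learning_rate,
         contexts = as.character(contexts), n_bins = as.integer(round(n_bins))),
    class = "ssd_perceptron_config"
  )
}

#' Initialize perceptron weights
#'
#' All weights start at 0; the forward pass's symmetric (0.5, 0.5) guard
#' makes the first-trial output well defined.
#'
#' @param config An `ssd_perceptron_config`.
#' @return An `ssd_perceptron` state: per-context `n_bins x 2` weight
#'   matrices (columns `jump`, `nojump`) and a trial counter.
#' @export
perceptron_init <- function(config) {
  stopifnot(inherits(config, "ssd_perceptron_config"))
  w <- lapply(config$contexts, function(ctx) {
    matrix(0, config$n_bins, 2, dimnames = list(NULL, c("jump", "nojump")))
  })
  names(w) <- config$contexts
  structure(list(weights = w, trial_count = 0L, config = config),
            class = "ssd_perceptron")
}

bin_edges <- function(config) {
  seq(config$range_min, config$range_max, by = config$bin_width)
}

#' Population encoding of a displacement
#'
#' The activation of input unit i is the probability mass of
#' `N(x_abs, sigma_noise^2)` falling in bin i, renormalized after truncation
#' to the input range so activations always sum to exactly 1. With
#' `sigma_noise = 0` all mass goes to the bin containing `x_abs` (bins are
#' left-closed; the top bin absorbs the upper edge). Displacements beyond
#' `range_max` are clamped to the top of the range with a warning -- draws
#' from the broad jump distribution occasionally exceed it.
#'
#' @param x_abs Absolute displacement, degrees (scalar; see
#'   [encode_inputs()] for the vectorized form).
#' @param sigma_noise Sensory noise SD, degrees.
#' @param config An `ssd_perceptron_config`.
#' @return Activation vector of length `n_bins` summing to 1.
#' @export
encode_input <- function(x_abs, sigma_noise, config) {
  stopifnot(length(x_abs) == 1)
  encode_inputs(x_abs, sigma_noise, config)[1, ]
}

#' @rdname encode_input
#' @param x Vector of absolute displacements.
#' @export
encode_inputs <- function(x, sigma_noise, config) {
  stopifnot(inherits(config, "ssd_perceptron_config"),
            all(x >= config$range_min | is.na(x)), sigma_noise >= 0)
  if (any(x > config$range_max, na.rm = TRUE)) {
    warning(sprintf("%d displacement(s) beyond range_max clamped to %.2f",
                    sum(x > config$range_max, na.rm = TRUE),
                    config$range_max), call. = FALSE)
    x <- pmin(x, config$range_max)
  }
  edges <- bin_edges(config)
  n <- length(x)
  if (sigma_noise == 0) {
    idx <- pmin(floor((x - config$range_min) / config$bin_width) + 1L,
                config$n_bins)
    act <- matrix(0, n, config$n_bins)
    act[cbind(seq_len(n), idx)] <- 1
    return(act)
  }
  # pnorm over the edge grid, differenced into per-bin masses
  cdf <- outer(x, edges, function(xx, e) pnorm(e, mean = xx, sd = sigma_noise))
  mass <- cdf[, -1, drop = FALSE] - cdf[, -length(edges), drop = FALSE]
  mass / rowSums(mass)
}

#' Forward pass of the perceptron
#'
#' Output-unit activations are the weighted input sums, normalized so the
#' two final outputs lie in \[0, 1\] and sum to 1. Weights are kept
#' nonnegative by [perceptron_update()], which is what guarantees the
#' bound; activations are additionally rectified at 0 here so that the
#' output stays well defined for hand-built states. If both activations are
#' (numerically) 0 -- e.g. at initialization -- the output is the
#' uninformative (0.5, 0.5).
#'
#' @param state An `ssd_perceptron` state.
#' @param context Context label (one of `config$contexts`).
#' @param activation Input activation vector (sums to 1).
#' @return Named numeric `c(jump = o_jump, nojump = o_nojump)`.
#' @export
perceptron_forward <- function(state, context, activation) {
  w <- state$weights[[as.character(context)]]
  if (is.null(w)) stop("unknown context: ", context, call. = FALSE)
  a <- c(crossprod(activation, w))
  a[a < 0] <- 0
  s <- sum(a)
  if (s <= 1e-12) return(c(jump = 0.5, nojump = 0.5))
  c(jump = a[1] / s, nojump = a[2] / s)
}

#' Delta-rule weight update
#'
#' `w_ij <- w_ij + beta * a_i * (d_j - o_j)` for both output units, applied
#' to the active context's weights only, then clamped at 0 from below. The
#' desired states are (1, 0) on jump trials and (0, 1) on no-jump trials,
#' so learning is driven by the output error; inactive input bins are
#' untouched. Keeping weights nonnegative makes the normalized outputs
#' provably stay in \[0, 1\] (the delta rule would otherwise drive weights
#' of frequently-wrong connections below zero).
#'
#' @param state An `ssd_perceptron` state.
#' @param context Context label.
#' @param activation Input activation vector.
#' @param desired_jump 1 if the trial's target jumped, else 0.
#' @return The updated state (with `trial_count` incremented).
#' @export
perceptron_update <- function(state, context, activation, desired_jump) {
  stopifnot(desired_jump %in% c(0, 1))
  ctx <- as.character(context)
  o <- perceptron_forward(state, ctx, activation)
  d <- c(desired_jump, 1 - desired_jump)
  beta <- state$config$learning_rate
  w <- state$weights[[ctx]]
  err <- d - o
  w[, 1] <- pmax(w[, 1] + beta * activation * err[1], 0)
  w[, 2] <- pmax(w[, 2] + beta * activation * err[2], 0)
  state$weights[[ctx]] <- w
  state$trial_count <- state$trial_count + 1L
  state
}

#' Training protocol for the perceptron simulations
#'
#' Mirrors the categorical experiment structure: a neutral baseline block
#' followed by one block per cued prior. Within every block 70% of trials
#' are low-noise trials whose jump probability matches the block's context
#' prior, and 30% are medium/high-noise testing trials with a neutral 0.5
#' jump statistic (split evenly). Displacements come from zero-mean
#' Gaussians with the simulated jump (`sigma_jump`) and no-jump
#' (`sigma_nojump`) widths; the model sees absolute displacements.
#'
#' @param priors Cued prior blocks, in order (baseline 0.5 is prepended).
#' @param baseline_trials,block_trials Trials in the baseline and each prior
#'   block.
#' @param train_noise Input noise SD for training trials (degrees).
#' @param test_noise Input noise SDs for the two testing cells.
#' @param sigma_jump,sigma_nojump Simulated displacement-distribution SDs.
#' @param train_frac Fraction of each block used as training trials.
#' @return A list of class `ssd_protocol`.
#' @export
training_protocol <- function(priors = c(0.8, 0.2), baseline_trials = 100L,
                              block_trials = 600L, train_noise = 0.1,
                              test_noise = c(1, 2), sigma_jump = 2.5,
                              sigma_nojump = 0.5, train_frac = 0.7) {
  stopifnot(all(priors > 0 & priors < 1), baseline_trials >= 0,
            block_trials > 0, train_frac > 0, train_frac <= 1,
            sigma_jump > sigma_nojump, sigma_nojump > 0,
            length(test_noise) >= 1)
  structure(
    list(priors = priors, baseline_trials = as.integer(baseline_trials),
         block_trials = as.integer(block_trials),
         train_noise = train_noise, test_noise = test_noise,
         sigma_jump = sigma_jump, sigma_nojump = sigma_nojump,
         train_frac = train_frac),
    class = "ssd_protocol"
  )
}

# exact per-block cell counts, shuffled order
protocol_block_trials <- function(prior, n, protocol) {
  n_train <- round(n * protocol$train_frac)
  n_test <- apportion(n - n_train, rep(1, length(protocol$test_noise)))
  data.frame(
    context = as.character(prior),
    phase = rep(c("training", rep("testing", length(protocol$test_noise))),
                c(n_train, n_test)),
    noise = rep(c(protocol$train_noise, protocol$test_noise),
                c(n_train, n_test)),
    p_jump = rep(c(prior, rep(0.5, length(protocol$test_noise))),
                 c(n_train, n_test))
  )
}

#' Run the perceptron through a training protocol
#'
#' Simulates one model run: trials are generated per the protocol's exact
#' cell counts (order randomized within blocks), each trial is encoded,
#' passed forward in its prior context, and the context's weights are
#' updated with the delta rule toward the trial's veridical jump state. The
#' recorded output is the pre-update `o_jump` -- the model's response on
#' that trial.
#'
#' @param config An `ssd_perceptron_config` whose contexts cover the
#'   protocol's priors plus baseline 0.5.
#' @param protocol An `ssd_protocol` from [training_protocol()].
#' @param seed Integer seed; fixed seed gives a bit-identical trajectory.
#' @return A list of class `ssd_perceptron_run`: `trials` (data.frame with
#'   per-trial context, phase, noise, abs displacement, jump flag, `o_jump`)
#'   and the final `state`, plus per-context weight snapshots taken at the
#'   end of each block (`block_states`).
#' @export
run_training <- function(config, protocol, seed) {
  stopifnot(inherits(config, "ssd_perceptron_config"),
            inherits(protocol, "ssd_protocol"))
  needed <- as.character(c(0.5, protocol$priors))
  if (!all(needed %in% config$contexts)) {
    stop("config contexts must include: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    blocks <- c(
      if (protocol$baseline_trials > 0) {
        list(protocol_block_trials(0.5, protocol$baseline_trials, protocol))
      },
      lapply(protocol$priors, protocol_block_trials,
             n = protocol$block_trials, protocol = protocol)
    )
    blocks <- lapply(blocks, function(b) b[sample.int(nrow(b)), ,
                                           drop = FALSE])
    trials <- do.call(rbind, blocks)
    n <- nrow(trials)
    trials$jumped <- as.numeric(runif(n) < trials$p_jump)
    trials$x_abs <- abs(ifelse(trials$jumped == 1,
                               rnorm(n, 0, protocol$sigma_jump),
                               rnorm(n, 0, protocol$sigma_nojump)))
    # clamp silently here: out-of-range draws are expected and rare
    trials$x_abs <- pmin(trials$x_abs, config$range_max)
    # encode all trials up front, grouped by noise level (vectorized pnorm)
    act <- matrix(0, n, config$n_bins)
    for (s in unique(trials$noise)) {
      i <- trials$noise == s
      act[i, ] <- encode_inputs(trials$x_abs[i], s, config)
    }
    state <- perceptron_init(config)
    beta <- config$learning_rate
    o_jump <- numeric(n)
    block_states <- list()
    row <- 0L
    for (b in seq_along(blocks)) {
      ctx <- blocks[[b]]$context[1]
      w <- state$weights[[ctx]]
      nb <- nrow(blocks[[b]])
      for (k in seq_len(nb)) {
        row <- row + 1L
        a <- act[row, ]
        aj <- c(a %*% w)
        s <- aj[1] + aj[2]
        o <- if (s <= 1e-12) c(0.5, 0.5) else aj / s
        o_jump[row] <- o[1]
        d1 <- trials$jumped[row]
        w[, 1] <- pmax(w[, 1] + beta * a * (d1 - o[1]), 0)
        w[, 2] <- pmax(w[, 2] + beta * a * ((1 - d1) - o[2]), 0)
      }
      state$weights[[ctx]] <- w
      block_states[[b]] <- state$weights
    }
    state$trial_count <- n
    trials$o_jump <- o_jump
    trials$trial_in_block <- unlist(lapply(blocks, function(b)
      seq_len(nrow(b))))
    rownames(trials) <- NULL
    structure(list(trials = trials, state = state,
                   block_states = block_states,
                   protocol = protocol),
              class = "ssd_perceptron_run")
  })
}

#' Binned response curves from a training run
#'
#' Mean `o_jump` per displacement bin and context over a chosen
#' trial-in-block window (e.g. the whole short protocol, or the 3000-5000
#' late-training window of a long run).
#'
#' @param run An `ssd_perceptron_run`.
#' @param window Length-2 inclusive range of trial indices *within each
#'   block*; `NULL` uses all trials.
#' @param bin_width Displacement bin width (degrees) for the summary curve.
#' @param phases Trial phases to include.
#' @return A data.frame with columns `context`, `bin_mid`, `mean_o_jump`,
#'   `n`.
#' @export
snapshot_curve <- function(run, window = NULL, bin_width = 0.5,
                           phases = c("training", "testing")) {
  tr <- run$trials
  keep <- tr$phase %in% phases
  if (!is.null(window)) {
    keep <- keep & tr$trial_in_block >= window[1] &
      tr$trial_in_block <= window[2]
  }
  tr <- tr[keep, , drop = FALSE]
  bin <- floor(tr$x_abs / bin_width) * bin_width + bin_width / 2
  agg <- stats::aggregate(tr$o_jump, list(context = tr$context,
                                          bin_mid = bin),
                          function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(context = agg$context, bin_mid = agg$bin_mid,
                    mean_o_jump = agg$x[, "mean"], n = agg$x[, "n"])
  out[order(out$context, out$bin_mid), ]
}

#' Ensemble of perceptron training runs
#'
#' Repeats [run_training()] across seeds and aggregates the binned response
#' curves with percentile confidence intervals across runs (middle 95% by
#' default), emulating the repeated-simulation summaries used for the model
#' figures.
#'
#' @inheritParams run_training
#' @param n_runs Number of independent runs.
#' @param window,bin_width,phases Passed to [snapshot_curve()].
#' @param conf Confidence level for the percentile interval.
#' @return A data.frame with `context`, `bin_mid`, `mean_o_jump`, `lo`,
#'   `hi`, `n_runs`.
#' @export
run_ensemble <- function(config, protocol, n_runs = 100, seed = 1,
                         window = NULL, bin_width = 0.5,
                         phases = c("training", "testing"), conf = 0.95) {
  seeds <- derive_seeds(seed, n_runs)
  curves <- lapply(seeds, function(s) {
    snapshot_curve(run_training(config, protocol, s), window = window,
                   bin_width = bin_width, phases = phases)
  })
  all <- do.call(rbind, curves)
  alpha <- (1 - conf) / 2
  agg <- stats::aggregate(
    all$mean_o_jump, list(context = all$context, bin_mid = all$bin_mid),
    function(v) c(mean = mean(v),
                  lo = unname(stats::quantile(v, alpha)),
                  hi = unname(stats::quantile(v, 1 - alpha)),
                  n = length(v))
  )
  out <- data.frame(context = agg$context, bin_mid = agg$bin_mid,
                    mean_o_jump = agg$x[, "mean"], lo = agg$x[, "lo"],
                    hi = agg$x[, "hi"], n_runs = agg$x[, "n"])
  out[order(out$context, out$bin_mid), ]
}
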
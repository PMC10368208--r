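#' Displacement distributions for jump and no-jump trials
#'
#' In the SSD paradigm the intrasaccadic displacement is drawn from one of two
#' overlapping zero-mean Gaussians: a broad "jump" distribution and a narrow
#' "no-jump" distribution. The overlap is what makes the task probabilistic
#' rather than a pure detection problem.
#'
#' @param sigma_jump SD (degrees) of the jump distribution; must exceed
#'   `sigma_nojump`.
#' @param sigma_nojump SD (degrees) of the no-jump distribution; must be > 0.
#' @param mu_jump,mu_nojump Means in degrees (0 in the standard paradigm).
#' @return An object of class `ssd_dists`.
#' @examples
#' displacement_distributions(1.5, 0.017)  # human paradigm
#' displacement_distributions(2.5, 0.2)    # macaque paradigm
#' @export
displacement_distributions <- function(sigma_jump, sigma_nojump,
                                       mu_jump = 0, mu_nojump = 0) {
  stopifnot(is.numeric(sigma_jump), is.numeric(sigma_nojump))
  if (!(sigma_jump > sigma_nojump && sigma_nojump > 0)) {
    stop("need sigma_jump > sigma_nojump > 0", call. = FALSE)
  }
  structure(
    list(mu_jump = mu_jump, sigma_jump = sigma_jump,
         mu_nojump = mu_nojump, sigma_nojump = sigma_nojump),
    class = "ssd_dists"
  )
}

# One block = exact per-cell trial counts. `cells` is a data.frame with
# columns phase, noise_sigma, p_jump, saccade, n. Counts are deterministic;
# only the within-block order and the draws themselves are random.
new_block <- function(prior_label, cells) {
  stopifnot(is.data.frame(cells),
            all(c("phase", "noise_sigma", "p_jump", "saccade", "n") %in%
                  names(cells)),
            all(cells$n >= 0), all(cells$n == round(cells$n)))
  list(prior_label = prior_label, cells = cells)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "ssd_design"))
  stop_if_not_prob(design$prior_levels, "prior_levels")
  for (b in design$blocks) {
    stop_if_not_prob(b$cells$p_jump[!is.na(b$cells$p_jump)], "p_jump")
    if (design$response_type == "binary" &&
        any(is.infinite(b$cells$noise_sigma))) {
      stop("infinite-noise trials exist only in the continuous design",
           call. = FALSE)
    }
  }
  if (!is.null(design$dists)) stopifnot(inherits(design$dists, "ssd_dists"))
  invisible(design)
}

new_design <- function(design_id, species, dists, prior_levels,
                       noise_levels_deg, blocks, frame_ms,
                       timing_mean_ms, timing_sd_ms,
                       response_type = c("binary", "continuous"),
                       continuous_prior = NULL) {
  design <- structure(
    list(design_id = design_id, species = species, dists = dists,
         prior_levels = prior_levels, noise_levels_deg = noise_levels_deg,
         blocks = blocks, frame_ms = frame_ms,
         timing_mean_ms = timing_mean_ms, timing_sd_ms = timing_sd_ms,
         response_type = match.arg(response_type),
         continuous_prior = continuous_prior),
    class = "ssd_design"
  )
  validate_design(design)
}

# standard 100-trial prior block: 70 low-noise training trials at the cued
# prior, 15 + 15 medium/high testing trials at the testing jump probability
prior_block <- function(prior, noise_levels, p_test) {
  new_block(prior, data.frame(
    phase = c("training", "testing", "testing"),
    noise_sigma = noise_levels,
    p_jump = c(prior, p_test, p_test),
    saccade = TRUE,
    n = c(70L, 15L, 15L)
  ))
}

categorical_blocks <- function(prior_levels, noise_levels, p_test,
                               n_blocks_per_prior = 6L) {
  baseline <- new_block(0.5, data.frame(
    phase = "baseline",
    noise_sigma = noise_levels,
    p_jump = 0.5,
    saccade = TRUE,
    n = c(90L, 5L, 5L)
  ))
  blocks <- list(baseline)
  for (p in prior_levels) {
    for (k in seq_len(n_blocks_per_prior)) {
      blocks[[length(blocks) + 1L]] <- prior_block(p, noise_levels, p_test)
    }
  }
  blocks
}

#' Preset experiment designs
#'
#' Constructors for the trial-schedule designs used throughout the package.
#' All counts per (prior, noise, phase) cell are exact; only trial order and
#' the stochastic draws (jump flag, displacement, timing) are randomized by
#' [build_schedule()].
#'
#' `design_human_categorical()` is the 1300-trial human schedule: one
#' 100-trial neutral baseline block followed by six 100-trial blocks per
#' cued prior (0.9 then 0.1 by default). Within each prior block 70% of
#' trials are low-noise training trials whose jump probability matches the
#' cue, and 30% are medium/high-noise testing trials with a neutral 0.5 jump
#' probability. Per prior, training trials are 420/1300 = 32.3% of the
#' experiment and each testing cell is 90/1300 = 6.9%.
#'
#' `design_monkey_categorical()` has the same relative frequencies with the
#' macaque parameters (priors 0.8/0.2, blob widths per animal, broader
#' displacement distributions). `design_monkey_control()` is its control
#' variant in which the true jump probability matches the cued prior at
#' every noise level.
#'
#' `design_continuous()` is the continuous-report schedule: 600 training
#' trials then 400 no-feedback testing trials, displacements drawn from the
#' N(0, 1 deg) prior, with 20% infinite-noise trials (target absent
#' postsaccadically, noise recorded as `Inf`) and testing noise levels
#' 0.1/0.5/1 deg.
#'
#' `design_motor_noise()` crosses priors {0.2, 0.5, 0.8} with a with-saccade
#' and a no-saccade condition at a fixed 0.5-deg blob width, all cells
#' interleaved with the jump probability equal to the cued prior.
#'
#' @param prior_order For the categorical designs, the order in which the two
#'   cued prior conditions are run.
#' @param monkey `"S"` or `"T"`; selects the animal's blob-width ladder.
#' @param n_per_cell Trials per (prior, saccade) cell in the motor-noise
#'   design.
#' @return An object of class `ssd_design`.
#' @seealso [build_schedule()]
#' @export
design_human_categorical <- function(prior_order = c(0.9, 0.1)) {
  new_design(
    design_id = "human_categorical", species = "human",
    dists = displacement_distributions(1.5, 0.017),
    prior_levels = prior_order,
    noise_levels_deg = c(0.1, 0.25, 0.5),
    blocks = categorical_blocks(prior_order, c(0.1, 0.25, 0.5), p_test = 0.5),
    frame_ms = 8.33, timing_mean_ms = -17.25, timing_sd_ms = 1.80,
    response_type = "binary"
  )
}

#' @rdname design_human_categorical
#' @export
design_monkey_categorical <- function(monkey = c("S", "T"),
                                      prior_order = c(0.8, 0.2)) {
  monkey <- match.arg(monkey)
  noise <- if (monkey == "S") c(0.5, 1.25, 2) else c(0.5, 1.25, 1.75)
  new_design(
    design_id = "monkey_categorical", species = "monkey",
    dists = displacement_distributions(2.5, 0.2),
    prior_levels = prior_order,
    noise_levels_deg = noise,
    blocks = categorical_blocks(prior_order, noise, p_test = 0.5),
    frame_ms = 7, timing_mean_ms = -7.63, timing_sd_ms = 5.07,
    response_type = "binary"
  )
}

#' @rdname design_human_categorical
#' @export
design_monkey_control <- function(monkey = c("S", "T"),
                                  prior_order = c(0.8, 0.2)) {
  monkey <- match.arg(monkey)
  noise <- if (monkey == "S") c(0.5, 1.25, 2) else c(0.5, 1.25, 1.75)
  blocks <- list(new_block(0.5, data.frame(
    phase = "baseline", noise_sigma = noise, p_jump = 0.5,
    saccade = TRUE, n = c(90L, 5L, 5L)
  )))
  for (p in prior_order) {
    for (k in 1:6) {
      # valid priors at every noise level: testing p_jump equals the cue
      blocks[[length(blocks) + 1L]] <- prior_block(p, noise, p_test = p)
    }
  }
  new_design(
    design_id = "monkey_control", species = "monkey",
    dists = displacement_distributions(2.5, 0.2),
    prior_levels = prior_order, noise_levels_deg = noise,
    blocks = blocks, frame_ms = 7,
    timing_mean_ms = -7.63, timing_sd_ms = 5.07,
    response_type = "binary"
  )
}

#' @rdname design_human_categorical
#' @export
design_continuous <- function() {
  # 20% of trials in each phase lack a postsaccadic target ("infinite noise");
  # the finite testing noise levels share the remainder as evenly as integer
  # counts allow (largest-remainder rounding).
  n_test_finite <- apportion(320L, c(1, 1, 1))
  training <- new_block(NA_real_, data.frame(
    phase = "training", noise_sigma = c(0.1, Inf), p_jump = NA_real_,
    saccade = TRUE, n = c(480L, 120L)
  ))
  testing <- new_block(NA_real_, data.frame(
    phase = "testing", noise_sigma = c(0.1, 0.5, 1, Inf), p_jump = NA_real_,
    saccade = TRUE, n = c(n_test_finite, 80L)
  ))
  new_design(
    design_id = "continuous", species = "human",
    dists = NULL, prior_levels = numeric(0),
    noise_levels_deg = c(0.1, 0.5, 1, Inf),
    blocks = list(training, testing),
    frame_ms = 16.7, timing_mean_ms = -17.25, timing_sd_ms = 1.80,
    response_type = "continuous",
    continuous_prior = list(mean = 0, sd = 1)
  )
}

#' @rdname design_human_categorical
#' @export
design_motor_noise <- function(n_per_cell = 1000L) {
  stopifnot(n_per_cell >= 1)
  priors <- c(0.2, 0.5, 0.8)
  cells <- expand.grid(p = priors, sac = c(TRUE, FALSE))
  blocks <- list(new_block(NA_real_, data.frame(
    phase = "testing", noise_sigma = 0.5, p_jump = cells$p,
    saccade = cells$sac, n = as.integer(n_per_cell),
    prior_override = cells$p
  )))
  new_design(
    design_id = "motor_noise", species = "monkey",
    dists = displacement_distributions(2.5, 0.2),
    prior_levels = priors, noise_levels_deg = 0.5,
    blocks = blocks, frame_ms = 7,
    timing_mean_ms = -7.63, timing_sd_ms = 5.07,
    response_type = "binary"
  )
}

#' @export
print.ssd_design <- function(x, ...) {
  n <- sum(vapply(x$blocks, function(b) sum(b$cells$n), numeric(1)))
  cat(sprintf("SSD experiment design '%s' (%s): %d blocks, %d trials\n",
              x$design_id, x$species, length(x$blocks), n))
  cat(sprintf("  priors: %s | noise SDs (deg): %s | %s report\n",
              paste(x$prior_levels, collapse = ", "),
              paste(x$noise_levels_deg, collapse = ", "),
              x$response_type))
  invisible(x)
}
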
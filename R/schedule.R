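TRIAL_COLUMNS <- c(
  "index", "block", "prior_label", "veridical_p_jump", "noise_sigma_deg",
  "jumped", "displacement_deg", "saccade_made", "direction_vs_saccade",
  "phase", "jump_cmd_to_saccade_end_ms", "response"
)

#' Build a randomized trial schedule from an experiment design
#'
#' Expands every design block into its exact per-cell trial counts, draws the
#' stochastic trial content (jump flag, displacement, displacement-command
#' timing) and randomizes trial order within each block. Responses are left
#' `NA` until a responder pass ([respond_categorical()] or
#' [respond_continuous()]) fills them in.
#'
#' The jump flag is Bernoulli with the cell's veridical jump probability;
#' displacements come from the design's jump distribution on jump trials and
#' from its no-jump distribution otherwise. In the continuous design there is
#' no jump dichotomy: displacements are drawn directly from the continuous
#' prior. The command-to-saccade-end timing is Gaussian with species-specific
#' mean/SD (humans: mean -17.25 ms, SD 1.80 ms; macaques: mean -7.63 ms,
#' SD 5.07 ms); negative values mean the displacement command preceded the
#' detected saccade end. Infinite-noise trials carry `Inf` in
#' `noise_sigma_deg`; arithmetic on them propagates to `Inf`/`NaN` rather
#' than producing silently plausible numbers.
#'
#' @param design An `ssd_design`, e.g. from [design_human_categorical()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A `data.frame` with one row per trial and the fixed column order
#'   `index, block, prior_label, veridical_p_jump, noise_sigma_deg, jumped,
#'   displacement_deg, saccade_made, direction_vs_saccade, phase,
#'   jump_cmd_to_saccade_end_ms, response`.
#' @examples
#' tab <- build_schedule(design_human_categorical(), seed = 1)
#' table(tab$phase, tab$noise_sigma_deg)
#' @export
build_schedule <- function(design, seed) {
  validate_design(design)
  with_seed(seed, {
    rows <- vector("list", length(design$blocks))
    for (bi in seq_along(design$blocks)) {
      b <- design$blocks[[bi]]
      cells <- b$cells
      prior <- if ("prior_override" %in% names(cells)) {
        rep(cells$prior_override, cells$n)
      } else {
        rep(b$prior_label, sum(cells$n))
      }
      tab <- data.frame(
        block = bi,
        prior_label = prior,
        veridical_p_jump = rep(cells$p_jump, cells$n),
        noise_sigma_deg = rep(cells$noise_sigma, cells$n),
        saccade_made = rep(cells$saccade, cells$n),
        phase = rep(cells$phase, cells$n)
      )
      n <- nrow(tab)
      if (design$response_type == "continuous") {
        tab$jumped <- NA
        tab$displacement_deg <- rnorm(n, design$continuous_prior$mean,
                                      design$continuous_prior$sd)
      } else {
        tab$jumped <- runif(n) < tab$veridical_p_jump
        d <- design$dists
        tab$displacement_deg <- ifelse(
          tab$jumped,
          rnorm(n, d$mu_jump, d$sigma_jump),
          rnorm(n, d$mu_nojump, d$sigma_nojump)
        )
      }
      tab$jump_cmd_to_saccade_end_ms <-
        rnorm(n, design$timing_mean_ms, design$timing_sd_ms)
      rows[[bi]] <- tab[sample.int(n), , drop = FALSE]
    }
    out <- do.call(rbind, rows)
    out$index <- seq_len(nrow(out))
    # sign convention: positive displacement = in the saccade direction
    out$direction_vs_saccade <- ifelse(out$displacement_deg >= 0,
                                       "with", "against")
    out$response <- NA_real_
    rownames(out) <- NULL
    out[, TRIAL_COLUMNS]
  })
}

#' Exclude trials whose displacement landed too late in the saccade
#'
#' Retains trials whose displacement command was issued no more than one
#' whole frame after the detected saccade end, i.e. with
#' `jump_cmd_to_saccade_end_ms >= -frame_ms`; later commands mean the target
#' may not have landed in its displaced location intrasaccadically.
#'
#' @param table A trial table with a populated
#'   `jump_cmd_to_saccade_end_ms` column.
#' @param frame_ms Frame duration in ms (8.33 for a 120 Hz display, 16.7 for
#'   60 Hz, 7 for the macaque photodiode criterion).
#' @return The filtered table; the number of removed trials is reported via
#'   `message()` and attached as attribute `n_removed`.
#' @export
filter_by_timing <- function(table, frame_ms) {
  stopifnot(is.data.frame(table), is.numeric(frame_ms), frame_ms > 0)
  if (!"jump_cmd_to_saccade_end_ms" %in% names(table) ||
      all(is.na(table$jump_cmd_to_saccade_end_ms))) {
    stop("timing field `jump_cmd_to_saccade_end_ms` is missing or empty",
         call. = FALSE)
  }
  keep <- table$jump_cmd_to_saccade_end_ms >= -frame_ms
  out <- table[keep, , drop = FALSE]
  message(sprintf("filter_by_timing: removed %d of %d trials",
                  sum(!keep), nrow(table)))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Fill in binary responses from a decision-curve observer
#'
#' Draws each trial's "jumped" report as Bernoulli with probability given by
#' the observer's decision curve at that trial's displacement, prior cue and
#' noise level.
#'
#' @param table A trial table from [build_schedule()].
#' @param observer `function(displacement, prior, noise_sigma)` returning a
#'   report probability in \[0, 1\] (vectorized over its arguments).
#' @param seed Integer seed for the Bernoulli draws.
#' @return The table with `response` set to 0/1.
#' @export
respond_categorical <- function(table, observer, seed) {
  stopifnot(is.data.frame(table), is.function(observer))
  p <- observer(table$displacement_deg, table$prior_label,
                table$noise_sigma_deg)
  if (length(p) != nrow(table)) stop("observer must be vectorized")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("observer returned probabilities outside [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    table$response <- as.numeric(runif(nrow(table)) < p)
    table
  })
}

#' Fill in continuous responses from the reliability-weighted observer
#'
#' The reported displacement is the posterior mean of the continuous Bayesian
#' observer plus Gaussian report noise. On infinite-noise trials (no
#' postsaccadic target) the default policy reports the presaccadic location,
#' i.e. displacement 0; `"prior_mean"` reports the observer's prior mean
#' instead.
#'
#' @param table Trial table from the continuous design.
#' @param params A `ssd_cont_params` object ([continuous_params()]).
#' @param report_noise_sd SD (degrees) of zero-mean Gaussian noise added to
#'   the report; 0 gives the noiseless posterior mean.
#' @param seed Integer seed.
#' @param infinite_policy Response policy for infinite-noise trials.
#' @return The table with continuous `response` values (degrees).
#' @export
respond_continuous <- function(table, params, report_noise_sd = 0, seed = 1,
                               infinite_policy = c("presaccadic",
                                                   "prior_mean")) {
  stopifnot(is.data.frame(table), inherits(params, "ssd_cont_params"),
            report_noise_sd >= 0)
  infinite_policy <- match.arg(infinite_policy)
  inf_resp <- switch(infinite_policy,
                     presaccadic = 0,
                     prior_mean = params$mu_prior)
  resp <- numeric(nrow(table))
  fin <- is.finite(table$noise_sigma_deg)
  for (lev in unique(table$noise_sigma_deg[fin])) {
    i <- fin & table$noise_sigma_deg == lev
    resp[i] <- posterior_mean(table$displacement_deg[i], params, lev)
  }
  resp[!fin] <- inf_resp
  with_seed(seed, {
    if (report_noise_sd > 0) {
      resp <- resp + rnorm(length(resp), 0, report_noise_sd)
    }
    table$response <- resp
    table
  })
}

#' Read and write trial tables as CSV
#'
#' Plain-text serialization with the fixed documented column order.
#'
#' @param table A trial table.
#' @param path File path.
#' @return `read_trial_table()` returns the table; `write_trial_table()`
#'   returns `path` invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(all(TRIAL_COLUMNS %in% names(table)))
  utils::write.csv(table[, TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(tab))
  if (length(missing)) {
    stop("not a trial table; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab[, TRIAL_COLUMNS]
}
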
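#' Parameters of the continuous reliability-weighted observer
#'
#' The continuous observer combines a Gaussian prior over displacements with
#' a Gaussian sensory likelihood whose SD depends on the blob noise level.
#' The sign convention for `mu_prior` is positive = opposite to the saccade
#' direction (the direction of the empirically observed bias).
#'
#' @param mu_prior Prior mean, degrees (signed).
#' @param sigma_prior Prior SD, degrees (> 0).
#' @param sigma_likelihood Named numeric vector of likelihood SDs (> 0), one
#'   per noise level; names are the noise levels (degrees) as strings.
#' @return An object of class `ssd_cont_params`.
#' @examples
#' continuous_params(0, 1, c("0.1" = 0.1, "0.5" = 0.5, "1" = 1))
#' @export
continuous_params <- function(mu_prior, sigma_prior, sigma_likelihood) {
  stopifnot(is.numeric(mu_prior), sigma_prior > 0,
            is.numeric(sigma_likelihood), all(sigma_likelihood > 0))
  if (is.null(names(sigma_likelihood))) {
    names(sigma_likelihood) <- as.character(sigma_likelihood)
  }
  structure(
    list(mu_prior = mu_prior, sigma_prior = sigma_prior,
         sigma_likelihood_by_noise = sigma_likelihood),
    class = "ssd_cont_params"
  )
}

lookup_sigma_l <- function(params, noise_level) {
  key <- as.character(noise_level)
  sl <- params$sigma_likelihood_by_noise
  if (!key %in% names(sl)) {
    stop(sprintf("noise level '%s' not present in params (have: %s)",
                 key, paste(names(sl), collapse = ", ")), call. = FALSE)
  }
  unname(sl[[key]])
}

#' Posterior mean of the continuous observer
#'
#' Reliability-weighted combination of prior and likelihood means,
#' \deqn{\mu_{post} = \frac{\sigma_L^2 \mu_{prior} + \sigma_{prior}^2 \mu_L}
#'   {\sigma_L^2 + \sigma_{prior}^2},}
#' i.e. the weights are the normalized inverse variances and sum to 1. As the
#' likelihood SD grows the estimate shrinks toward the prior mean.
#'
#' @param mu_likelihood Likelihood mean(s) (the presented displacement),
#'   degrees; vectorized.
#' @param params An `ssd_cont_params` object.
#' @param noise_level Noise level keying the likelihood SD.
#' @return Posterior mean(s), degrees.
#' @export
posterior_mean <- function(mu_likelihood, params, noise_level) {
  stopifnot(inherits(params, "ssd_cont_params"))
  sl2 <- lookup_sigma_l(params, noise_level)^2
  sp2 <- params$sigma_prior^2
  (sl2 * params$mu_prior + sp2 * mu_likelihood) / (sl2 + sp2)
}

#' Posterior variance of the continuous observer
#'
#' `1 / (1/sigma_L^2 + 1/sigma_prior^2)`: strictly smaller than both the
#' likelihood and prior variances, which is what makes the weighted estimate
#' Bayes optimal.
#'
#' @inheritParams posterior_mean
#' @return Posterior variance, degrees squared.
#' @export
posterior_variance <- function(params, noise_level) {
  stopifnot(inherits(params, "ssd_cont_params"))
  sl2 <- lookup_sigma_l(params, noise_level)^2
  1 / (1 / sl2 + 1 / params$sigma_prior^2)
}

#' Predicted deviation of the report from the presented displacement
#'
#' Returns `displacement - predicted response` for each presented
#' displacement. With a zero-mean prior the deviation is linear in the
#' displacement with slope `sigma_L^2 / (sigma_L^2 + sigma_prior^2)` (the
#' prior weight), so steeper deviation lines mean noisier sensory evidence.
#' `noise_level = Inf` models the no-target condition where the response is
#' the prior mean, so the deviation equals `displacement - mu_prior` (the
#' unity line for a zero-mean prior).
#'
#' @param displacements Presented displacements, signed degrees.
#' @param params An `ssd_cont_params` object.
#' @param noise_level Noise level; `Inf` for the no-target condition.
#' @return Numeric vector of deviations (degrees).
#' @export
deviation_curve <- function(displacements, params, noise_level) {
  stopifnot(inherits(params, "ssd_cont_params"))
  if (is.infinite(noise_level)) {
    return(displacements - params$mu_prior)
  }
  displacements - posterior_mean(displacements, params, noise_level)
}

#' Least-squares fit of the continuous observer
#'
#' Jointly fits the prior mean and one likelihood SD per finite noise level
#' by minimizing the summed squared error between the observed continuous
#' reports and the observer's posterior mean. The prior SD is held at its
#' experimental value (the observer model fits the noiseless posterior mean;
#' report noise lives in the generator, not the fitted model).
#' Infinite-noise trials are excluded as a distinct response strategy. SDs
#' are optimized on the log scale with multi-start `stats::nlminb`.
#'
#' @param table Trial table with continuous responses; at least 2 finite
#'   noise levels must be represented.
#' @param sigma_prior Fixed prior SD (degrees), default 1.
#' @param n_restarts Random restarts (default 5).
#' @param seed Integer seed for the restarts.
#' @return A list of class `ssd_cont_fit`: `params` (`ssd_cont_params` with
#'   fitted values), `sse`, `converged`.
#' @export
fit_continuous <- function(table, sigma_prior = 1, n_restarts = 5, seed = 1) {
  stopifnot(is.data.frame(table))
  fin <- is.finite(table$noise_sigma_deg) & !is.na(table$response)
  tab <- table[fin, , drop = FALSE]
  levels <- sort(unique(tab$noise_sigma_deg))
  if (length(levels) < 2) {
    stop("need at least 2 finite noise levels to fit", call. = FALSE)
  }
  lev_idx <- match(tab$noise_sigma_deg, levels)
  x <- tab$displacement_deg
  y <- tab$response
  sp2 <- sigma_prior^2
  sse <- function(theta) {
    mu <- theta[1]
    sl2 <- exp(theta[-1])[lev_idx]^2
    pred <- (sl2 * mu + sp2 * x) / (sl2 + sp2)
    sum((y - pred)^2)
  }
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(k) {
      c(runif(1, -0.5, 0.5), log(runif(length(levels), 0.05, 2)))
    })
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::nlminb(s, sse), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed", call. = FALSE)
  sl <- exp(best$par[-1])
  names(sl) <- as.character(levels)
  structure(
    list(params = continuous_params(best$par[1], sigma_prior, sl),
         sse = best$objective,
         converged = best$convergence == 0),
    class = "ssd_cont_fit"
  )
}

#' @export
print.ssd_cont_fit <- function(x, ...) {
  cat(sprintf("Continuous observer fit: sse = %.3f, converged = %s\n",
              x$sse, x$converged))
  cat(sprintf("  mu_prior = %.3f deg; sigma_likelihood: %s\n",
              x$params$mu_prior,
              paste(sprintf("%s -> %.3f",
                            names(x$params$sigma_likelihood_by_noise),
                            x$params$sigma_likelihood_by_noise),
                    collapse = ", ")))
  invisible(x)
}
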
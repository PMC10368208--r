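#' Four-parameter logistic psychometric function
#'
#' `y = max + (min - max) / (1 + (x / thresh)^slope)` with `x` the absolute
#' displacement. With the package's sign convention `slope > 0`, the curve
#' rises from `min` at `x = 0` to `max` as `x` grows, so the fitted `min` is
#' the intercept (the curve value at zero displacement).
#'
#' @param x Absolute displacement(s), degrees.
#' @param min,max Lower/upper asymptotes (probabilities).
#' @param thresh Inflection point, degrees (> 0).
#' @param slope Slope parameter (> 0 under the package convention).
#' @return Curve value(s).
#' @export
psychometric_4pl <- function(x, min, max, thresh, slope) {
  max + (min - max) / (1 + (x / thresh)^slope)
}

#' Fit the four-parameter logistic to binary responses
#'
#' Parameters are fit by minimizing mean squared error between the curve and
#' the 0/1 responses (matching the behavioral analysis convention; set
#' `method = "likelihood"` for a Bernoulli-likelihood fit instead). The
#' asymptotes are constrained to `0 <= min <= max <= 1` and `thresh`,
#' `slope` to be positive via an unconstrained reparametrization, with
#' multi-start optimization.
#'
#' @param x_abs Absolute displacements (>= 20 trials spanning >= 3 distinct
#'   values).
#' @param responses Binary responses (0/1).
#' @param method Objective: `"mse"` (default) or `"likelihood"`.
#' @param n_starts Number of optimizer starts.
#' @param seed Seed for the random starts.
#' @param intercept_mode How the `intercept` field is filled: the fitted
#'   `min` (continuous displacement designs) or the raw proportion at
#'   displacement zero (discretized designs with a 0 condition).
#' @return An object of class `ssd_4pl`: `min`, `max`, `thresh`, `slope`,
#'   `sse`, `intercept`, `intercept_mode`, `converged`.
#' @export
fit_4pl <- function(x_abs, responses, method = c("mse", "likelihood"),
                    n_starts = 8, seed = 1,
                    intercept_mode = c("fitted_min", "raw_at_zero")) {
  method <- match.arg(method)
  intercept_mode <- match.arg(intercept_mode)
  stopifnot(length(x_abs) == length(responses),
            all(responses %in% c(0, 1)), all(x_abs >= 0))
  if (length(x_abs) < 20) stop("need at least 20 trials", call. = FALSE)
  if (length(unique(round(x_abs, 8))) < 3) {
    stop("need responses at >= 3 distinct displacement values",
         call. = FALSE)
  }
  curve_theta <- function(theta) {
    mn <- plogis(theta[1])
    mx <- mn + (1 - mn) * plogis(theta[2])
    psychometric_4pl(x_abs, mn, mx, exp(theta[3]), exp(theta[4]))
  }
  obj <- if (method == "mse") {
    function(theta) mean((responses - curve_theta(theta))^2)
  } else {
    function(theta) {
      p <- clamp(curve_theta(theta), 1e-9, 1 - 1e-9)
      -sum(responses * log(p) + (1 - responses) * log(1 - p))
    }
  }
  med_x <- stats::median(x_abs[x_abs > 0])
  starts <- with_seed(seed, c(
    list(c(qlogis(0.2), qlogis(0.8), log(med_x), log(2))),
    lapply(seq_len(n_starts - 1), function(k) {
      c(qlogis(runif(1, 0.02, 0.5)), qlogis(runif(1, 0.5, 0.98)),
        log(runif(1, 0.2, 2) * med_x), log(runif(1, 0.5, 6)))
    })
  ))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::nlminb(s, obj), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("4PL fit failed on all starts", call. = FALSE)
  mn <- plogis(best$par[1])
  mx <- mn + (1 - mn) * plogis(best$par[2])
  intercept <- if (intercept_mode == "fitted_min") {
    mn
  } else {
    z <- responses[x_abs == 0]
    if (!length(z)) {
      stop("no displacement = 0 trials; use intercept_mode = 'fitted_min'",
           call. = FALSE)
    }
    mean(z)
  }
  structure(
    list(min = mn, max = mx, thresh = exp(best$par[3]),
         slope = exp(best$par[4]),
         sse = sum((responses - curve_theta(best$par))^2),
         intercept = intercept, intercept_mode = intercept_mode,
         converged = best$convergence == 0),
    class = "ssd_4pl"
  )
}

#' @export
print.ssd_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL fit: min = %.3f, max = %.3f, thresh = %.3f, slope = %.3f\n",
    x$min, x$max, x$thresh, x$slope))
  cat(sprintf("  intercept (%s) = %.3f, sse = %.3f\n",
              x$intercept_mode, x$intercept, x$sse))
  invisible(x)
}

#' Raw intercept for discretized designs
#'
#' The proportion of "moved" reports among displacement = 0 trials -- the
#' intercept convention for designs where displacements are discretized and
#' a zero-displacement condition exists.
#'
#' @param table Trial table with binary responses.
#' @return The proportion, with attribute `n` (trial count).
#' @export
intercept_at_zero <- function(table) {
  z <- table$response[table$displacement_deg == 0]
  z <- z[!is.na(z)]
  if (!length(z)) {
    stop("no displacement = 0 trials; use the fitted min of fit_4pl() ",
         "as the intercept", call. = FALSE)
  }
  structure(mean(z), n = length(z))
}

sdt_from_rates_ <- function(hit_rate, fa_rate) {
  list(hit_rate = hit_rate, fa_rate = fa_rate,
       dprime = qnorm(hit_rate) - qnorm(fa_rate),
       criterion = -0.5 * (qnorm(hit_rate) + qnorm(fa_rate)))
}

#' Signal detection theory measures
#'
#' Hit rate (proportion of "jumped" reports on true-jump trials) and false
#' alarm rate (on no-jump trials), with sensitivity `d' = Z(hit) - Z(fa)`
#' and bias `C = -0.5 * (Z(hit) + Z(fa))`; a lower Criterion means a more
#' liberal "jumped" reporter. Perfect rates are clamped to `1/(2N)` and
#' `1 - 1/(2N)` of their own trial count before the inverse-normal
#' transform.
#'
#' `sdt_from_rates()` applies the same identities to already-computed rates
#' (no clamping), which is convenient for analytic checks.
#'
#' @param table Trial table with logical/0-1 `jumped` and binary `response`.
#' @return An object of class `ssd_sdt` with `hit_rate`, `fa_rate`,
#'   `dprime`, `criterion`.
#' @export
sdt_measures <- function(table) {
  stopifnot(all(table$response %in% c(0, 1)))
  jumped <- as.logical(table$jumped)
  if (!any(jumped) || all(jumped)) {
    stop("table must contain both jump and no-jump trials", call. = FALSE)
  }
  n_sig <- sum(jumped)
  n_noise <- sum(!jumped)
  hit <- clamp(mean(table$response[jumped]),
               1 / (2 * n_sig), 1 - 1 / (2 * n_sig))
  fa <- clamp(mean(table$response[!jumped]),
              1 / (2 * n_noise), 1 - 1 / (2 * n_noise))
  structure(sdt_from_rates_(hit, fa), class = "ssd_sdt")
}

#' @rdname sdt_measures
#' @param hit_rate,fa_rate Rates in (0, 1).
#' @export
sdt_from_rates <- function(hit_rate, fa_rate) {
  stopifnot(hit_rate > 0, hit_rate < 1, fa_rate > 0, fa_rate < 1)
  structure(sdt_from_rates_(hit_rate, fa_rate), class = "ssd_sdt")
}

#' @export
print.ssd_sdt <- function(x, ...) {
  cat(sprintf("SDT: hit = %.3f, fa = %.3f, d' = %.3f, C = %.3f\n",
              x$hit_rate, x$fa_rate, x$dprime, x$criterion))
  invisible(x)
}

#' Raw response-rate difference between two prior conditions
#'
#' For discretized designs: the "jumped" report rate difference
#' (high minus low prior) at every displacement, plus the across-grid mean
#' -- the control-experiment measure of prior use that does not rely on a
#' curve fit.
#'
#' @param table_high,table_low Trial tables on identical displacement grids.
#' @return A list with `per_displacement` (data.frame `displacement`,
#'   `rate_high`, `rate_low`, `difference`) and `mean_difference`.
#' @export
response_rate_difference <- function(table_high, table_low) {
  gh <- sort(unique(table_high$displacement_deg))
  gl <- sort(unique(table_low$displacement_deg))
  if (length(gh) != length(gl) || any(gh != gl)) {
    stop("displacement grids do not match", call. = FALSE)
  }
  rate <- function(tab) {
    vapply(gh, function(d) {
      mean(tab$response[tab$displacement_deg == d], na.rm = TRUE)
    }, numeric(1))
  }
  rh <- rate(table_high)
  rl <- rate(table_low)
  list(
    per_displacement = data.frame(displacement = gh, rate_high = rh,
                                  rate_low = rl, difference = rh - rl),
    mean_difference = mean(rh - rl)
  )
}

#' Percentile bootstrap confidence interval
#'
#' Resamples trials (rows) with replacement and returns the percentile
#' interval of the statistic across resamples.
#'
#' @param statistic `function(table) -> scalar`.
#' @param table Trial table (any data.frame).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95: the 2.5-97.5 percentiles).
#' @return Named numeric `c(point, lo, hi)`.
#' @export
bootstrap_ci <- function(statistic, table, n_boot = 10000, seed = 1,
                         conf = 0.95) {
  stopifnot(is.function(statistic), is.data.frame(table), n_boot >= 100)
  n <- nrow(table)
  point <- statistic(table)
  stopifnot(length(point) == 1)
  with_seed(seed, {
    stats <- vapply(seq_len(n_boot), function(b) {
      statistic(table[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    q <- stats::quantile(stats, c(alpha, 1 - alpha), names = FALSE)
    c(point = point, lo = q[1], hi = q[2])
  })
}
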
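#' Parameters of the categorical Bayesian ideal observer
#'
#' Bundles everything the categorical observer needs: the prior probability
#' of a jump, the jump/no-jump likelihood widths (and means, normally 0),
#' the sensory noise SD induced by the blob width, and the lapse-scaling
#' parameters used when fitting behavioral data.
#'
#' @param p_jump Prior probability of a jump, in (0, 1).
#' @param sigma_jump,sigma_nojump SDs (degrees) of the jump and no-jump
#'   displacement distributions.
#' @param sigma_t Sensory noise SD (degrees) of the perceived displacement
#'   around the true displacement; >= 0.
#' @param mu_jump,mu_nojump Means of the two displacement distributions.
#' @param lower_bound,lapse Floor and 1-minus-ceiling of the lapse-scaled
#'   decision curve; must satisfy `lower_bound + lapse < 1`.
#' @return An object of class `ssd_cat_params`.
#' @examples
#' categorical_params(0.78, sigma_jump = 2, sigma_nojump = 0.017,
#'                    sigma_t = 0.1)
#' @export
categorical_params <- function(p_jump, sigma_jump, sigma_nojump, sigma_t,
                               mu_jump = 0, mu_nojump = 0,
                               lower_bound = 0, lapse = 0) {
  stopifnot(p_jump > 0, p_jump < 1,
            sigma_jump > 0, sigma_nojump >= 0, sigma_t >= 0,
            lower_bound >= 0, lapse >= 0, lower_bound + lapse < 1)
  structure(
    list(p_jump = p_jump, mu_jump = mu_jump, mu_nojump = mu_nojump,
         sigma_jump = sigma_jump, sigma_nojump = sigma_nojump,
         sigma_t = sigma_t, lower_bound = lower_bound, lapse = lapse),
    class = "ssd_cat_params"
  )
}

zero_means <- function(params) params$mu_jump == 0 && params$mu_nojump == 0

# Quadratic coefficients of the log posterior-odds condition in xhat:
# jump is reported when A*xhat^2 + B*xhat + C > 0.
log_odds_quadratic <- function(params) {
  vJ <- params$sigma_jump^2 + params$sigma_t^2
  vN <- params$sigma_nojump^2 + params$sigma_t^2
  list(
    A = 1 / vN - 1 / vJ,
    B = 2 * (params$mu_jump / vJ - params$mu_nojump / vN),
    C = params$mu_nojump^2 / vN - params$mu_jump^2 / vJ -
      log(vJ / vN) - 2 * log((1 - params$p_jump) / params$p_jump)
  )
}

#' Decision criterion of the categorical observer
#'
#' Derives the region of perceived displacements for which the observer
#' reports "jumped". With zero-mean likelihoods the condition reduces to a
#' threshold on the squared perceived displacement,
#' \deqn{\hat{x}^2 > \hat{x}_C^2 =
#'   \frac{\log\frac{\sigma_J^2+\sigma_t^2}{\sigma_{\neg J}^2+\sigma_t^2} +
#'         2\log\frac{1-P(J)}{P(J)}}
#'        {\frac{1}{\sigma_{\neg J}^2+\sigma_t^2} -
#'         \frac{1}{\sigma_J^2+\sigma_t^2}}.}
#' Degenerate corners are returned as explicit sentinels: a non-positive
#' criterion yields `"always_jump"`; when the no-jump likelihood is the wider
#' one the jump region is an inner interval around zero (or empty); equal
#' widths with equal means make the log-odds constant, decided by the prior
#' term alone (with a warning). With non-zero means the jump region is the
#' solution set of a quadratic inequality, returned as explicit intervals.
#'
#' @param params An `ssd_cat_params` object.
#' @return An object of class `ssd_criterion` with fields `type` (one of
#'   `"threshold"`, `"inner_interval"`, `"always_jump"`, `"never_jump"`,
#'   `"intervals"`), `xhat_crit_sq` (squared criterion, when defined) and
#'   `decision_region` (two-column matrix of intervals in perceived
#'   displacement).
#' @export
decision_criterion <- function(params) {
  stopifnot(inherits(params, "ssd_cat_params"))
  q <- log_odds_quadratic(params)
  mk <- function(type, xc2 = NA_real_, region = NULL) {
    structure(list(type = type, xhat_crit_sq = xc2,
                   decision_region = region),
              class = "ssd_criterion")
  }
  whole_line <- matrix(c(-Inf, Inf), 1)
  if (zero_means(params)) {
    if (q$A == 0) {
      warning("sigma_jump == sigma_nojump with equal means: decision is ",
              "constant, determined by the prior log-odds", call. = FALSE)
      return(if (q$C > 0) mk("always_jump", region = whole_line)
             else mk("never_jump", region = matrix(numeric(0), 0, 2)))
    }
    xc2 <- -q$C / q$A   # threshold on xhat^2
    if (q$A > 0) {
      if (xc2 <= 0) return(mk("always_jump", xc2, whole_line))
      r <- sqrt(xc2)
      return(mk("threshold", xc2,
                matrix(c(-Inf, -r, r, Inf), 2, 2, byrow = TRUE)))
    }
    # wider no-jump likelihood: jump region is an interval around zero
    if (xc2 <= 0) return(mk("never_jump", xc2, matrix(numeric(0), 0, 2)))
    r <- sqrt(xc2)
    return(mk("inner_interval", xc2, matrix(c(-r, r), 1)))
  }
  # general quadratic in xhat
  if (q$A == 0) {
    if (q$B == 0) {
      warning("degenerate criterion: constant log-odds", call. = FALSE)
      return(if (q$C > 0) mk("always_jump", region = whole_line)
             else mk("never_jump", region = matrix(numeric(0), 0, 2)))
    }
    root <- -q$C / q$B
    region <- if (q$B > 0) matrix(c(root, Inf), 1) else
      matrix(c(-Inf, root), 1)
    return(mk("intervals", region = region))
  }
  disc <- q$B^2 - 4 * q$A * q$C
  if (disc <= 0) {
    if (q$A > 0) return(mk("always_jump", region = whole_line))
    return(mk("never_jump", region = matrix(numeric(0), 0, 2)))
  }
  r <- sort(c((-q$B - sqrt(disc)) / (2 * q$A),
              (-q$B + sqrt(disc)) / (2 * q$A)))
  region <- if (q$A > 0) {
    matrix(c(-Inf, r[1], r[2], Inf), 2, 2, byrow = TRUE)
  } else {
    matrix(r, 1)
  }
  mk("intervals", region = region)
}

# P(|N(x, sigma_t)| > c) -- the Gaussian-interval identity for the
# noncentral chi-square survivor of decision_curve(); ~30x faster than
# pchisq(ncp=), used in fitting loops. Agreement is tested.
prob_sq_exceeds <- function(x, xc2, sigma_t) {
  if (sigma_t == 0) return(as.numeric(x^2 > xc2))
  r <- sqrt(xc2)
  1 - (pnorm((r - x) / sigma_t) - pnorm((-r - x) / sigma_t))
}

#' Closed-form decision curve of the categorical observer
#'
#' Probability that the observer reports "jumped" given the true displacement
#' `x`. Because the perceived displacement is \eqn{\hat{x} \sim N(x,
#' \sigma_t^2)}, \eqn{\hat{x}^2/\sigma_t^2} is noncentral chi-square with 1
#' degree of freedom and noncentrality \eqn{x^2/\sigma_t^2}, so for the
#' zero-mean criterion
#' \deqn{D(x) = 1 - F_{\chi^2}\!\left(\hat{x}_C^2/\sigma_t^2;\, df = 1,\,
#'   \lambda = x^2/\sigma_t^2\right).}
#' Sentinel criteria give the constant curves 1 or 0; `sigma_t = 0` gives the
#' noiseless indicator. Non-zero likelihood means have no closed form here;
#' use [mc_decision_oracle()] for that case.
#'
#' @param x True displacement(s), signed degrees.
#' @param params An `ssd_cat_params` object with zero likelihood means.
#' @return `D(x)` in \[0, 1\], vectorized over `x`.
#' @examples
#' p <- categorical_params(0.5, 2, 0.017, sigma_t = 0.1)
#' decision_curve(c(0, 0.5, 1), p)
#' @export
decision_curve <- function(x, params) {
  stopifnot(inherits(params, "ssd_cat_params"))
  if (!zero_means(params)) {
    stop("decision_curve requires zero likelihood means; ",
         "use mc_decision_oracle() for the non-zero-mean observer",
         call. = FALSE)
  }
  crit <- decision_criterion(params)
  decision_curve_at <- function(crit, x, sigma_t) {
    switch(crit$type,
      always_jump = rep(1, length(x)),
      never_jump = rep(0, length(x)),
      threshold = {
        if (sigma_t == 0) as.numeric(x^2 > crit$xhat_crit_sq)
        else pchisq(crit$xhat_crit_sq / sigma_t^2, df = 1,
                    ncp = x^2 / sigma_t^2, lower.tail = FALSE)
      },
      inner_interval = {
        if (sigma_t == 0) as.numeric(x^2 < crit$xhat_crit_sq)
        else pchisq(crit$xhat_crit_sq / sigma_t^2, df = 1,
                    ncp = x^2 / sigma_t^2)
      },
      stop("unsupported criterion type for the closed form")
    )
  }
  decision_curve_at(crit, x, params$sigma_t)
}

#' Lapse-scaled decision curve
#'
#' Affine rescaling of [decision_curve()] into
#' `[lower_bound, 1 - lapse]`, the form used when fitting behavioral data:
#' `lower_bound + (1 - lower_bound - lapse) * D(x)`.
#'
#' @inheritParams decision_curve
#' @return Probabilities in `[lower_bound, 1 - lapse]`.
#' @export
lapse_scaled_curve <- function(x, params) {
  params$lower_bound +
    (1 - params$lower_bound - params$lapse) * decision_curve(x, params)
}

#' Monte-Carlo evaluation of the categorical decision
#'
#' Independent stochastic route to the decision probability: draws perceived
#' displacements \eqn{\hat{x} \sim N(x, \sigma_t^2)} and evaluates the exact
#' posterior-odds indicator with Gaussian densities and the prior. Unlike the
#' closed form it supports non-zero likelihood means. Used as the oracle
#' against which [decision_curve()] is verified.
#'
#' @param x True displacement(s), signed degrees.
#' @param params An `ssd_cat_params` object.
#' @param n_samples Monte-Carlo draws per displacement (>= 1000).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `x`, `estimate`, `se`.
#' @export
mc_decision_oracle <- function(x, params, n_samples = 1e6, seed = 1) {
  stopifnot(inherits(params, "ssd_cat_params"), n_samples >= 1e3)
  vJ <- params$sigma_jump^2 + params$sigma_t^2
  vN <- params$sigma_nojump^2 + params$sigma_t^2
  indicator <- function(xhat) {
    lj <- dnorm(xhat, params$mu_jump, sqrt(vJ), log = TRUE) +
      log(params$p_jump)
    ln <- dnorm(xhat, params$mu_nojump, sqrt(vN), log = TRUE) +
      log(1 - params$p_jump)
    as.numeric(lj > ln)
  }
  with_seed(seed, {
    out <- lapply(x, function(xi) {
      if (params$sigma_t == 0) {
        return(c(estimate = indicator(xi), se = 0))
      }
      ind <- indicator(rnorm(n_samples, xi, params$sigma_t))
      c(estimate = mean(ind), se = stats::sd(ind) / sqrt(n_samples))
    })
    out <- as.data.frame(do.call(rbind, out))
    data.frame(x = x, estimate = out$estimate, se = out$se)
  })
}

#' High-minus-low prior intercept difference
#'
#' The model's measure of prior use: the difference between the lapse-scaled
#' decision curves of a high-prior and a low-prior observer evaluated at
#' displacement 0 (the psychometric intercept).
#'
#' @param params_high,params_low `ssd_cat_params` objects that differ only in
#'   `p_jump`.
#' @return A probability difference in \[-1, 1\].
#' @export
predict_intercept_difference <- function(params_high, params_low) {
  stopifnot(inherits(params_high, "ssd_cat_params"),
            inherits(params_low, "ssd_cat_params"))
  same <- setdiff(names(params_high), "p_jump")
  if (!isTRUE(all.equal(params_high[same], params_low[same]))) {
    stop("parameter sets must differ only in p_jump", call. = FALSE)
  }
  lapse_scaled_curve(0, params_high) - lapse_scaled_curve(0, params_low)
}

# Fast lapse-scaled curve for one (prior, noise) cell, covering the
# criterion sentinels; used inside the MLE objective.
cell_prob <- function(x, p_jump, sigma_jump, sigma_nojump, sigma_t,
                      lower_bound, lapse) {
  vJ <- sigma_jump^2 + sigma_t^2
  vN <- sigma_nojump^2 + sigma_t^2
  A <- 1 / vN - 1 / vJ
  C <- -log(vJ / vN) - 2 * log((1 - p_jump) / p_jump)
  d <- if (A == 0) {
    rep(as.numeric(C > 0), length(x))
  } else {
    xc2 <- -C / A
    if (A > 0) {
      if (xc2 <= 0) rep(1, length(x)) else prob_sq_exceeds(x, xc2, sigma_t)
    } else {
      if (xc2 <= 0) rep(0, length(x))
      else 1 - prob_sq_exceeds(x, xc2, sigma_t)
    }
  }
  lower_bound + (1 - lower_bound - lapse) * d
}

unpack_theta <- function(theta) {
  list(priors = plogis(theta[1:3]),
       sigma_t = exp(theta[4:6]),
       sigma_jump = exp(theta[7]),
       sigma_nojump = exp(theta[8]),
       lower_bound = 0.5 * plogis(theta[9:11]),
       lapse = 0.5 * plogis(theta[12:14]))
}

#' Maximum-likelihood fit of the categorical observer
#'
#' Fits the 14-parameter lapse-scaled categorical observer to binary
#' responses by minimizing Bernoulli negative log likelihood: one prior per
#' cued prior condition (3), one sensory noise SD per noise level (3), shared
#' jump and no-jump likelihood widths (2), and a lower bound and lapse rate
#' per noise level (6). The likelihood surface is multimodal, so the
#' optimizer (`stats::nlminb` on an unconstrained reparametrization: logit
#' for probabilities, log for SDs, lapse terms bounded to \[0, 0.5\]) is
#' restarted from `n_restarts` random initializations and the best solution
#' is kept.
#'
#' @param table Trial table with binary responses covering 3 prior conditions
#'   and 3 noise levels.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed for the restart draws.
#' @param max_iter Iteration cap per restart.
#' @return An object of class `ssd_cat_fit`: `params` (a `data.frame` of
#'   per-condition values), `theta` (raw parameter vector), `nll`,
#'   `converged`, `n_restarts_used`.
#' @export
fit_categorical_mle <- function(table, n_restarts = 10, seed = 1,
                                max_iter = 400) {
  stopifnot(is.data.frame(table), all(table$response %in% c(0, 1)))
  priors_lev <- sort(unique(table$prior_label))
  noise_lev <- sort(unique(table$noise_sigma_deg))
  if (length(priors_lev) != 3 || length(noise_lev) != 3) {
    stop("table must cover exactly 3 prior conditions and 3 noise levels",
         call. = FALSE)
  }
  cells <- list()
  for (i in 1:3) for (j in 1:3) {
    k <- table$prior_label == priors_lev[i] &
      table$noise_sigma_deg == noise_lev[j]
    if (any(k)) {
      cells[[length(cells) + 1L]] <-
        list(i = i, j = j, x = table$displacement_deg[k],
             r = table$response[k])
    }
  }
  nll <- function(theta) {
    p <- unpack_theta(theta)
    total <- 0
    for (cell in cells) {
      pr <- cell_prob(cell$x, p$priors[cell$i], p$sigma_jump,
                      p$sigma_nojump, p$sigma_t[cell$j],
                      p$lower_bound[cell$j], p$lapse[cell$j])
      pr <- clamp(pr, 1e-9, 1 - 1e-9)
      total <- total - sum(cell$r * log(pr) + (1 - cell$r) * log(1 - pr))
    }
    if (!is.finite(total)) total <- 1e10
    total
  }
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(k) {
      c(qlogis(runif(3, 0.05, 0.95)),          # priors
        log(runif(3, 0.05, 3)),                # sigma_t
        log(runif(1, 0.5, 5)),                 # sigma_jump
        log(runif(1, 0.005, 1)),               # sigma_nojump
        qlogis(runif(3, 0.02, 0.5)),           # lower bound (of 0.5 scale)
        qlogis(runif(3, 0.02, 0.5)))           # lapse (of 0.5 scale)
    })
  })
  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, nll, control = list(iter.max = max_iter,
                                           eval.max = 4 * max_iter)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_converged <- TRUE
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, theta = NULL, nll = Inf,
                          converged = FALSE,
                          n_restarts_used = n_restarts),
                     class = "ssd_cat_fit"))
  }
  est <- unpack_theta(best$par)
  params <- data.frame(
    prior_condition = priors_lev,
    prior_hat = est$priors,
    noise_level = noise_lev,
    sigma_t_hat = est$sigma_t,
    lower_bound_hat = est$lower_bound,
    lapse_hat = est$lapse
  )
  structure(
    list(params = params,
         sigma_jump_hat = est$sigma_jump,
         sigma_nojump_hat = est$sigma_nojump,
         theta = best$par, nll = best$objective,
         converged = any_converged, n_restarts_used = n_restarts),
    class = "ssd_cat_fit"
  )
}

#' @export
print.ssd_cat_fit <- function(x, ...) {
  cat(sprintf("Categorical observer MLE: nll = %.2f, converged = %s\n",
              x$nll, x$converged))
  if (!is.null(x$params)) {
    cat(sprintf("  shared widths: sigma_jump = %.3f, sigma_nojump = %.4f\n",
                x$sigma_jump_hat, x$sigma_nojump_hat))
    print(x$params, digits = 3)
  }
  invisible(x)
}
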
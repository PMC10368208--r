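test_that("zero-mean criterion matches an independent root-finding oracle", {
  cases <- list(
    fig3_observer(0.5, 0.1),
    fig3_observer(0.78, 0.25),
    fig3_observer(0.22, 0.5),
    categorical_params(0.8, 5, 1, 0.5),
    categorical_params(0.3, 2.5, 0.2, 1.25)
  )
  for (p in cases) {
    crit <- decision_criterion(p)
    expect_equal(crit$type, "threshold")
    expect_equal(crit$xhat_crit_sq, criterion_root_oracle(p),
                 tolerance = 1e-8)
  }
})

test_that("criterion sentinels cover the degenerate corners", {
  # overwhelming prior: criterion falls at or below zero -> always jump
  p_hi <- categorical_params(0.999, 2, 0.017, 0.1)
  expect_equal(decision_criterion(p_hi)$type, "always_jump")
  expect_true(all(decision_curve(c(0, 1, 3), p_hi) == 1))
  # wider no-jump than jump likelihood flips the decision region
  p_flip <- categorical_params(0.5, 2, 0.017, 0.1)
  p_flip$sigma_jump <- 0.017
  p_flip$sigma_nojump <- 2
  crit <- decision_criterion(p_flip)
  expect_equal(crit$type, "inner_interval")
  # equal widths and means: constant decision decided by the prior
  p_eq <- categorical_params(0.7, 1, 1 - 1e-12, 0.2)
  p_eq$sigma_nojump <- 1
  expect_warning(crit_eq <- decision_criterion(p_eq), "constant")
  expect_equal(crit_eq$type, "always_jump")
})

test_that("decision region is symmetric about zero for zero-mean
          likelihoods", {
  crit <- decision_criterion(fig3_observer(0.78, 0.25))
  r <- crit$decision_region
  expect_equal(r[1, ], -rev(r[2, ]))
  p <- fig3_observer(0.78, 0.25)
  x <- c(0.1, 0.7, 1.3, 4)
  expect_equal(decision_curve(x, p), decision_curve(-x, p))
})

test_that("closed-form decision curve agrees with the Monte-Carlo oracle", {
  cases <- list(c(0.5, 0.1), c(0.78, 0.25), c(0.22, 0.5))
  for (i in seq_along(cases)) {
    p <- fig3_observer(cases[[i]][1], cases[[i]][2])
    x <- c(0, 0.3, 1)
    dc <- decision_curve(x, p)
    # distinct seeds so sampling errors are independent across cases
    mc <- mc_decision_oracle(x, p, n_samples = 5e5, seed = 200 + i)
    expect_true(all(abs(dc - mc$estimate) <= 3 * mc$se + 1e-8))
  }
})

test_that("noiseless observer reduces to the indicator", {
  p <- categorical_params(0.5, 2, 0.017, sigma_t = 0)
  xc <- sqrt(decision_criterion(fig3_observer(0.5, 0))$xhat_crit_sq)
  expect_equal(decision_curve(c(xc / 2, 2 * xc), p), c(0, 1))
  mc <- mc_decision_oracle(c(xc / 2, 2 * xc), p, n_samples = 1e3)
  expect_equal(mc$estimate, c(0, 1))
  expect_equal(mc$se, c(0, 0))
})

test_that("noncentral chi-square form equals the Gaussian interval
          identity", {
  p <- fig3_observer(0.78, 0.25)
  xc2 <- decision_criterion(p)$xhat_crit_sq
  x <- seq(0, 5, by = 0.25)
  expect_equal(decision_curve(x, p),
               ssdmodels:::prob_sq_exceeds(x, xc2, p$sigma_t),
               tolerance = 1e-12)
})

test_that("lapse scaling is the documented affine map", {
  p0 <- fig3_observer(0.78, 0.25)
  expect_equal(lapse_scaled_curve(c(0, 1, 2), p0),
               decision_curve(c(0, 1, 2), p0))
  p <- categorical_params(0.999, 2, 0.017, 0.1,
                          lower_bound = 0.1, lapse = 0.2)
  # always-jump sentinel: D = 1 everywhere, scaled output is the ceiling
  expect_equal(lapse_scaled_curve(c(0, 3), p), c(0.8, 0.8))
  p_never <- categorical_params(1e-9, 2, 0.017, 0.1,
                                lower_bound = 0.1, lapse = 0.2)
  expect_equal(lapse_scaled_curve(0, p_never), 0.1)
})

test_that("non-zero likelihood means route to the Monte-Carlo oracle", {
  p <- categorical_params(0.5, 1 + 1e-9, 1 - 1e-9, 0.25,
                          mu_jump = 1, mu_nojump = 0)
  p$sigma_jump <- 1
  p$sigma_nojump <- 1
  expect_error(decision_curve(0.5, p), "mc_decision_oracle")
  # equal widths, shifted means: likelihood-ratio threshold at the midpoint
  mc <- mc_decision_oracle(c(0, 0.5, 1), p, n_samples = 2e5, seed = 5)
  analytic <- 1 - pnorm((0.5 - c(0, 0.5, 1)) / 0.25)
  expect_true(all(abs(mc$estimate - analytic) <= 3 * pmax(mc$se, 1e-4)))
  # the interval solver agrees on the region boundary
  crit <- decision_criterion(p)
  expect_equal(crit$type, "intervals")
  expect_equal(crit$decision_region[1, 1], 0.5, tolerance = 1e-8)
})

test_that("decision curve is monotone in displacement magnitude and prior", {
  x <- seq(0, 5, by = 0.5)
  for (st in c(0.1, 0.25, 0.5)) {
    for (pj in c(0.1, 0.5, 0.9)) {
      d <- decision_curve(x, fig3_observer(pj, st))
      expect_true(all(diff(d) >= -1e-12))
    }
    d_by_prior <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(pj) {
      decision_curve(1, fig3_observer(pj, st))
    }, numeric(1))
    expect_true(all(diff(d_by_prior) >= -1e-12))
  }
})

test_that("intercept difference behaves as a prior-use measure", {
  expect_equal(
    predict_intercept_difference(fig3_observer(0.5, 0.25),
                                 fig3_observer(0.5, 0.25)),
    0
  )
  d1 <- predict_intercept_difference(fig3_observer(0.78, 0.25),
                                     fig3_observer(0.22, 0.25))
  d2 <- predict_intercept_difference(fig3_observer(0.78, 0.5),
                                     fig3_observer(0.22, 0.5))
  expect_gt(d2, d1)
  expect_true(d1 >= -1 && d1 <= 1 && d2 >= -1 && d2 <= 1)
  expect_error(
    predict_intercept_difference(fig3_observer(0.78, 0.25),
                                 fig3_observer(0.22, 0.5)),
    "p_jump"
  )
})

test_that("MLE recovers the generating parameter orderings", {
  rec <- recover_categorical(n_per_cell = 800, seed = 4, n_restarts = 3)
  fit <- rec$fit
  expect_true(is.finite(fit$nll))
  # NLL at the generating parameter vector, via the same objective pieces
  expect_equal(order(fit$params$prior_hat), 1:3)
  expect_equal(order(fit$params$sigma_t_hat), 1:3)
  expect_gt(fit$sigma_jump_hat, fit$sigma_nojump_hat)
})

test_that("degenerate all-jump responses hit the parameter bounds without
          crashing", {
  tab <- expand.grid(prior_label = c(0.1, 0.5, 0.9),
                     noise_sigma_deg = c(0.1, 0.25, 0.5),
                     rep = 1:40)
  set.seed(1)
  tab$displacement_deg <- rnorm(nrow(tab))
  tab$response <- 1
  fit <- fit_categorical_mle(tab, n_restarts = 2, seed = 2, max_iter = 100)
  expect_s3_class(fit, "ssd_cat_fit")
  expect_true(is.finite(fit$nll))
  # the fitted curves must predict "jump" almost surely somewhere
  expect_gt(max(fit$params$prior_hat) + max(fit$params$lower_bound_hat), 0.5)
})
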
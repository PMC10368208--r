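test_that("input layer has 75 units for the standard configuration", {
  cfg <- perceptron_config()
  expect_equal(cfg$n_bins, 75L)
  expect_equal(length(encode_input(3, 0.1, cfg)), 75L)
  expect_error(perceptron_config(bin_width = 0.11), "integer")
})

test_that("encoding is a truncated, renormalized Gaussian mass", {
  cfg <- perceptron_config()
  for (x in c(0, 0.05, 3, 7.4)) {
    for (s in c(0, 0.1, 1, 2)) {
      expect_equal(sum(encode_input(x, s, cfg)), 1, tolerance = 1e-12)
    }
  }
  # bin-integral oracle at x = 3, sigma = 0.1: half-SD slices either side
  a <- encode_input(3, 0.1, cfg)
  total <- integrate(dnorm, 0, 7.5, mean = 3, sd = 0.1)$value
  m_left <- integrate(dnorm, 2.9, 3.0, mean = 3, sd = 0.1)$value / total
  m_right <- integrate(dnorm, 3.0, 3.1, mean = 3, sd = 0.1)$value / total
  expect_equal(a[30], m_left, tolerance = 1e-9)
  expect_equal(a[31], m_right, tolerance = 1e-9)
  expect_equal(m_left, pnorm(0) - pnorm(-1), tolerance = 1e-6)
  # noiseless encoding is a delta in the containing bin
  d <- encode_input(0.25, 0, cfg)
  expect_equal(which(d == 1), 3L)
  expect_equal(sum(d), 1)
  # out-of-range displacement clamps to the top bin with a warning
  expect_warning(top <- encode_input(8.2, 0, cfg), "clamped")
  expect_equal(which(top == 1), 75L)
})

test_that("forward pass normalizes and guards the zero state", {
  cfg <- perceptron_config(bin_width = 2.5, contexts = "0.5")
  st <- perceptron_init(cfg)
  expect_equal(perceptron_forward(st, "0.5", c(1, 0, 0)),
               c(jump = 0.5, nojump = 0.5))
  st$weights[["0.5"]] <- cbind(c(0.2, 0, 0), c(0.6, 0, 0))
  expect_equal(perceptron_forward(st, "0.5", c(1, 0, 0)),
               c(jump = 0.25, nojump = 0.75))
  st$weights[["0.5"]] <- cbind(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3))
  o <- perceptron_forward(st, "0.5", c(0.2, 0.5, 0.3))
  expect_equal(unname(o), c(0.5, 0.5))
  expect_equal(sum(o), 1)
  expect_error(perceptron_forward(st, "0.9", c(1, 0, 0)), "unknown context")
})

test_that("delta rule updates only active connections and clamps at zero", {
  cfg <- perceptron_config(bin_width = 7.5, contexts = "0.5")
  st <- perceptron_init(cfg)
  # single bin, zero state: o = (0.5, 0.5); desired jump
  st2 <- perceptron_update(st, "0.5", 1, desired_jump = 1)
  expect_equal(unname(st2$weights[["0.5"]][1, "jump"]), 0.25)  # 0.5 * 1 * 0.5
  expect_equal(unname(st2$weights[["0.5"]][1, "nojump"]), 0)   # clamped

  expect_equal(st2$trial_count, 1L)
  # zero error leaves weights untouched
  cfg3 <- perceptron_config(bin_width = 2.5, contexts = "0.5")
  st3 <- perceptron_init(cfg3)
  st3$weights[["0.5"]] <- cbind(c(1, 0, 0), c(0, 0, 0))   # o = (1, 0)
  st4 <- perceptron_update(st3, "0.5", c(1, 0, 0), desired_jump = 1)
  expect_equal(st4$weights, st3$weights)
  # inactive bins never move
  st5 <- perceptron_update(st3, "0.5", c(1, 0, 0), desired_jump = 0)
  expect_equal(st5$weights[["0.5"]][2:3, ], st3$weights[["0.5"]][2:3, ])
})

test_that("training runs are deterministic under a fixed seed", {
  cfg <- perceptron_config()
  proto <- training_protocol(block_trials = 200L)
  r1 <- run_training(cfg, proto, seed = 5)
  r2 <- run_training(cfg, proto, seed = 5)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$state$weights, r2$state$weights)
  r3 <- run_training(cfg, proto, seed = 6)
  expect_false(identical(r1$trials$x_abs, r3$trials$x_abs))
  # outputs are valid probabilities on every trial
  expect_true(all(r1$trials$o_jump >= 0 & r1$trials$o_jump <= 1))
  # run_training's inlined loop matches the exported update operator
  st <- perceptron_init(cfg)
  for (i in 1:50) {
    a <- encode_input(r1$trials$x_abs[i], r1$trials$noise[i], cfg)
    o <- perceptron_forward(st, r1$trials$context[i], a)
    expect_equal(unname(o["jump"]), r1$trials$o_jump[i], tolerance = 1e-12)
    st <- perceptron_update(st, r1$trials$context[i], a,
                            r1$trials$jumped[i])
  }
})

test_that("weights of never-activated bins stay at initialization", {
  cfg <- perceptron_config(contexts = c("0.5", "0.8"))
  proto <- training_protocol(priors = 0.8, baseline_trials = 50L,
                             block_trials = 300L, train_noise = 0,
                             test_noise = c(0, 0), sigma_jump = 0.4,
                             sigma_nojump = 0.1)
  run <- run_training(cfg, proto, seed = 9)
  # displacements are below ~2 degrees, so bins past 30 are never active
  expect_lt(max(run$trials$x_abs), 3)
  for (w in run$state$weights) expect_true(all(w[31:75, ] == 0))
})

test_that("ensemble error declines and plateaus with training", {
  cfg <- perceptron_config(contexts = c("0.5", "0.8"))
  proto <- training_protocol(priors = 0.8, baseline_trials = 0L,
                             block_trials = 2000L)
  err <- sapply(1:25, function(s) {
    run <- run_training(cfg, proto, seed = 400 + s)
    e <- abs(run$trials$jumped - run$trials$o_jump)
    vapply(split(e, ceiling(seq_along(e) / 500)), mean, numeric(1))
  })
  win <- rowMeans(err)
  expect_true(all(diff(win) <= 0.01))   # non-increasing up to sampling noise
  expect_lt(win[length(win)], win[1])
})

test_that("snapshot curves summarize the requested window", {
  cfg <- perceptron_config()
  run <- run_training(cfg, training_protocol(block_trials = 400L), seed = 2)
  cv <- snapshot_curve(run, bin_width = 1)
  expect_true(all(c("0.2", "0.5", "0.8") %in% cv$context))
  expect_true(all(cv$mean_o_jump >= 0 & cv$mean_o_jump <= 1))
  cv_late <- snapshot_curve(run, window = c(201, 400), bin_width = 1)
  expect_true(all(cv_late$n <= cv$n[match(
    paste(cv_late$context, cv_late$bin_mid),
    paste(cv$context, cv$bin_mid))]))
})
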
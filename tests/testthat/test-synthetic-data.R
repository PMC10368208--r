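test_that("human categorical schedule has exact design cell counts", {
  tab <- build_schedule(design_human_categorical(), seed = 42)
  expect_equal(nrow(tab), 1300L)
  for (p in c(0.9, 0.1)) {
    n_train <- sum(tab$phase == "training" & tab$prior_label == p)
    expect_equal(n_train, 420L)
    expect_equal(round(100 * n_train / nrow(tab), 1), 32.3)
    for (s in c(0.25, 0.5)) {
      n_test <- sum(tab$phase == "testing" & tab$prior_label == p &
                      tab$noise_sigma_deg == s)
      expect_equal(n_test, 90L)
      expect_equal(round(100 * n_test / nrow(tab), 1), 6.9)
    }
  }
  expect_equal(sum(tab$phase == "baseline"), 100L)
})

test_that("cell counts are exact for every design and invariant to seed", {
  designs <- list(design_human_categorical(),
                  design_monkey_categorical("S"),
                  design_monkey_control("T"),
                  design_continuous(),
                  design_motor_noise(200))
  for (d in designs) {
    t1 <- build_schedule(d, seed = 1)
    t2 <- build_schedule(d, seed = 2)
    c1 <- table(t1$phase, t1$noise_sigma_deg, t1$prior_label, useNA = "ifany")
    c2 <- table(t2$phase, t2$noise_sigma_deg, t2$prior_label, useNA = "ifany")
    expect_equal(c1, c2)
  }
})

test_that("schedules are reproducible under a fixed seed", {
  d <- design_monkey_categorical("T")
  expect_identical(build_schedule(d, seed = 7), build_schedule(d, seed = 7))
  t1 <- build_schedule(d, seed = 7)
  t2 <- build_schedule(d, seed = 8)
  expect_false(identical(t1$displacement_deg, t2$displacement_deg))
})

test_that("displacements follow the jump / no-jump distributions", {
  tab <- build_schedule(design_motor_noise(n_per_cell = 4000L), seed = 3)
  xj <- tab$displacement_deg[tab$jumped]
  xn <- tab$displacement_deg[!tab$jumped]
  expect_gt(length(xj), 10000)
  expect_gt(length(xn), 10000)
  expect_lt(abs(sd(xj) - 2.5) / 2.5, 0.05)
  expect_lt(abs(sd(xn) - 0.2) / 0.2, 0.05)
  expect_lt(abs(mean(xj)), 3 * 2.5 / sqrt(length(xj)))
})

test_that("empirical jump fraction matches the veridical probability", {
  tab <- build_schedule(design_human_categorical(), seed = 5)
  for (p in c(0.9, 0.1)) {
    k <- tab$phase == "training" & tab$prior_label == p
    se <- sqrt(p * (1 - p) / sum(k))
    expect_lt(abs(mean(tab$jumped[k]) - p), 3 * se)
    # testing trials of the hypothesis-test design are neutral
    kt <- tab$phase == "testing" & tab$prior_label == p
    se_t <- sqrt(0.25 / sum(kt))
    expect_lt(abs(mean(tab$jumped[kt]) - 0.5), 3 * se_t)
  }
})

test_that("infinite noise is rejected outside the continuous design", {
  d <- design_human_categorical()
  d$blocks[[2]]$cells$noise_sigma[1] <- Inf
  expect_error(build_schedule(d, seed = 1), "continuous")
  expect_silent(tab <- build_schedule(design_continuous(), seed = 1))
  expect_true(any(is.infinite(tab$noise_sigma_deg)))
})

test_that("timing filter keeps trials within one frame of saccade end", {
  tab <- data.frame(displacement_deg = 0,
                    jump_cmd_to_saccade_end_ms = c(-20, -10, -5))
  expect_equal(nrow(suppressMessages(filter_by_timing(tab, 8.33))), 1L)
  expect_equal(nrow(suppressMessages(filter_by_timing(tab, 16.7))), 2L)
  all_ok <- data.frame(jump_cmd_to_saccade_end_ms = rep(-5, 10))
  kept <- suppressMessages(filter_by_timing(all_ok, 8.33))
  expect_equal(nrow(kept), 10L)
  expect_equal(attr(kept, "n_removed"), 0L)
  expect_error(filter_by_timing(data.frame(x = 1), 8.33), "timing")
})

test_that("categorical responder draws Bernoulli from the decision curve", {
  tab <- build_schedule(design_motor_noise(n_per_cell = 2000L), seed = 1)
  # constant observers
  all1 <- respond_categorical(tab, function(x, p, s) rep(1, length(x)), 1)
  expect_true(all(all1$response == 1))
  half <- respond_categorical(tab, function(x, p, s) rep(0.5, length(x)), 2)
  se <- sqrt(0.25 / nrow(tab))
  expect_lt(abs(mean(half$response) - 0.5), 3 * se)
  expect_error(
    respond_categorical(tab, function(x, p, s) rep(1.2, length(x)), 1),
    "outside"
  )
})

test_that("categorical responder reproduces a model's psychometric curve", {
  tab <- build_schedule(design_motor_noise(n_per_cell = 2000L), seed = 2)
  obs <- function(x, p, s) {
    out <- numeric(length(x))
    for (pp in unique(p)) {
      k <- p == pp
      out[k] <- decision_curve(x[k], categorical_params(pp, 2.5, 0.2, 0.5))
    }
    out
  }
  resp <- respond_categorical(tab, obs, seed = 9)
  # binomial check per coarse displacement bin within one prior condition
  k <- resp$prior_label == 0.8
  bin <- cut(abs(resp$displacement_deg[k]), c(0, 0.5, 1, 2, 4, Inf))
  emp <- tapply(resp$response[k], bin, mean)
  mod <- tapply(obs(resp$displacement_deg[k], resp$prior_label[k],
                    resp$noise_sigma_deg[k]), bin, mean)
  n <- tapply(resp$response[k], bin, length)
  expect_true(all(abs(emp - mod) < 3 * sqrt(0.25 / n) + 0.02))
})

test_that("continuous responder returns posterior means and honors the
          infinite-noise policy", {
  par_eq <- continuous_params(0, 1, c("1" = 1))
  tab <- data.frame(noise_sigma_deg = rep(1, 5),
                    displacement_deg = c(-2, -1, 0, 1, 2),
                    response = NA_real_)
  out <- respond_continuous(tab, par_eq, report_noise_sd = 0)
  expect_equal(out$response, tab$displacement_deg / 2)
  # vanishing likelihood noise: report the displacement itself
  par_sharp <- continuous_params(0, 1, c("1" = 1e-6))
  out2 <- respond_continuous(tab, par_sharp, report_noise_sd = 0)
  expect_equal(out2$response, tab$displacement_deg, tolerance = 1e-9)
  # infinite noise: presaccadic location (0) by default, prior mean optionally
  tab_inf <- data.frame(noise_sigma_deg = Inf, displacement_deg = 1.3,
                        response = NA_real_)
  par_b <- continuous_params(0.4, 1, c("1" = 1))
  expect_equal(respond_continuous(tab_inf, par_b)$response, 0)
  expect_equal(
    respond_continuous(tab_inf, par_b, infinite_policy = "prior_mean")$response,
    0.4
  )
})

test_that("trial tables round-trip through CSV", {
  tab <- build_schedule(design_human_categorical(), seed = 13)
  path <- tempfile(fileext = ".csv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(back$displacement_deg, tab$displacement_deg, tolerance = 1e-12)
  expect_equal(back$phase, tab$phase)
  expect_error(read_trial_table({
    p2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p2, row.names = FALSE)
    p2
  }), "missing columns")
  unlink(path)
})

test_that("synthetic timing metadata has the species parameters", {
  th <- build_schedule(design_human_categorical(), seed = 2)
  tm <- build_schedule(design_monkey_categorical("S"), seed = 2)
  expect_lt(abs(mean(th$jump_cmd_to_saccade_end_ms) + 17.25),
            3 * 1.80 / sqrt(nrow(th)))
  expect_lt(abs(mean(tm$jump_cmd_to_saccade_end_ms) + 7.63),
            3 * 5.07 / sqrt(nrow(tm)))
})
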
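test_that("the log-scale loss matches a hand evaluation", {
  p <- default_params("three_state")
  sched <- exchange_schedule()
  # two times, one state, hand-picked observed counts
  obs <- tibble::tibble(time_day = c(1, 4), state = "LSK",
                        count = c(1000, 500))
  traj <- simulate_culture("three_state", p, sched,
                           sample_times = c(1, 4), grid_by = 0.25)
  model <- sample_trajectory(traj, c(1, 4))
  m <- model$count[model$state == "LSK"]
  by_hand <- (log(m[1] + 1) - log(1001))^2 + (log(m[2] + 1) - log(501))^2
  expect_equal(timeseries_loss(p, obs, sched), by_hand, tolerance = 1e-10)
})

test_that("noise-free self-generated data gives near-zero loss", {
  p <- default_params("three_state")
  obs <- generate_observations("three_state", p, noise = noise_model("none"))
  expect_lt(timeseries_loss(p, obs), 1e-10)
})

test_that("corrupting the observations increases the loss", {
  p <- default_params("three_state")
  obs <- generate_observations("three_state", p, noise = noise_model("none"))
  base <- timeseries_loss(p, obs)
  doubled <- dplyr::mutate(obs, count = 2 * count)
  expect_gt(timeseries_loss(p, doubled), base)
})

test_that("observations are validated against the model's state set", {
  p <- default_params("five_state")
  obs3 <- generate_observations("three_state",
                                noise = noise_model("none"))
  expect_error(timeseries_loss(p, obs3), "unknown LSK")
  expect_error(timeseries_loss(p, obs3[0, ]), "no rows")
})

test_that("a fully frozen fit returns the start unchanged", {
  p <- default_params("three_state")
  obs <- generate_observations("three_state", p,
                               noise = noise_model(cv = 0.2, seed = 3))
  fit <- fit_params(obs, "three_state", p, free = character())
  expect_identical(fit$params$values, p$values)
  expect_equal(fit$loss, timeseries_loss(p, obs))
  expect_true(fit$converged)
})

test_that("over-parameterized fits are refused without force", {
  p <- default_params("three_state")
  obs <- generate_observations("three_state", p, noise = noise_model("none"))
  free <- grep("^(PR|DR|f_max|m_)", names(p$values), value = TRUE)
  expect_gt(length(free), 10)
  expect_error(fit_params(obs, "three_state", p, free = free),
               "max_free")
})

test_that("fits are reproducible: same seed, bit-identical result", {
  p <- default_params("three_state")
  obs <- generate_observations("three_state", p,
                               noise = noise_model(cv = 0.1, seed = 5))
  start <- p
  start$values[["j_max_LSK"]] <- 0.35
  f1 <- fit_params(obs, "three_state", start, free = "j_max_LSK",
                   n_restarts = 2, seed = 99)
  f2 <- fit_params(obs, "three_state", start, free = "j_max_LSK",
                   n_restarts = 2, seed = 99)
  expect_identical(f1$params$values, f2$params$values)
  expect_identical(f1$loss, f2$loss)
})

test_that("tidy and glance summarize a fit", {
  p <- default_params("three_state")
  obs <- generate_observations("three_state", p, noise = noise_model("none"))
  fit <- fit_params(obs, "three_state", p, free = character())
  g <- glance(fit)
  expect_equal(g$n_obs, nrow(obs))
  expect_equal(g$n_free, 0)
  expect_equal(nrow(tidy(fit)), 0)
})
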
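test_that("exchange schedules produce the expected event times", {
  expect_equal(exchange_times(exchange_schedule(frequency = 2, horizon = 9)),
               c(2, 4, 6, 8))
  expect_equal(exchange_times(exchange_schedule(frequency = 5, horizon = 9)),
               5)
  expect_length(exchange_times(exchange_schedule(frequency = 10,
                                                 horizon = 9)), 0)
  expect_error(exchange_schedule(frequency = 0), "positive")
})

test_that("a media exchange refreshes stocks, clears pools, and is idempotent", {
  sched <- exchange_schedule()
  env <- culture_environment(scf_conc = 3, gc_conc = 1, pool_DiffS = 2,
                             pool_DiffI = 1, pool_ProS = 4, pool_ProI = 0.5)
  fresh <- apply_media_exchange(env, sched)
  expect_equal(fresh$scf_conc, 100)
  expect_equal(fresh$gc_conc, 10)
  expect_equal(
    unlist(fresh[1, c("pool_DiffS", "pool_DiffI", "pool_ProS", "pool_ProI")],
           use.names = FALSE),
    rep(0, 4))
  expect_equal(fresh$media_volume, env$media_volume)
  expect_equal(apply_media_exchange(fresh, sched), fresh)
})

test_that("zero-rate cultures stay frozen at the seeded populations", {
  p <- zero_params("three_state")
  tr <- simulate_culture("three_state", p, exchange_schedule(frequency = 2))
  expect_true(all(abs(tr$LSK - 1000) < 1e-6))
  expect_true(all(tr$CMP == 0) && all(tr$Terminal == 0))
})

test_that("an isolated proliferating compartment grows exponentially", {
  p <- exp_toy_params(rate = 0.3, n0 = 1000)
  tr <- simulate_culture("five_state", p, exchange_schedule(frequency = 10))
  expect_equal(tr$Terminal, 1000 * exp(0.3 * tr$time_day), tolerance = 1e-6)
})

test_that("trajectories satisfy their structural invariants", {
  tr <- simulate_culture("three_state")
  expect_true(all(diff(tr$time_day) > 0))
  states <- hsc_states("three_state")
  expect_true(all(as.matrix(tr[c(states, hscdyn:::env_fields())]) >= 0))
  # post-exchange rows carry the refreshed environment
  for (te in c(2, 4, 6, 8)) {
    row <- tr[tr$time_day == te, ]
    expect_equal(row$scf_conc, 100)
    expect_equal(row$gc_conc, 10)
    expect_equal(row$pool_DiffS + row$pool_DiffI +
                   row$pool_ProS + row$pool_ProI, 0)
  }
  # kernel columns are recorded alongside the state
  expect_true(all(c("f_LSK", "q_LSK", "j_LSK", "R_d") %in% names(tr)))
})

test_that("day-9 counts are stable under tolerance refinement", {
  base <- simulate_culture("three_state")
  fine <- simulate_culture("three_state", rtol = 5e-9, atol = 5e-5)
  states <- hsc_states("three_state")
  for (st in states) {
    a <- base[[st]][nrow(base)]; b <- fine[[st]][nrow(fine)]
    expect_lt(abs(a - b) / max(b, 1), 1e-3)
  }
})

test_that("trajectory sampling is exact on the grid and accurate off it", {
  tr <- simulate_culture("three_state", sample_times = c(0.5, 1, 2, 4, 7, 9))
  # grid times reproduce grid values exactly
  s <- sample_trajectory(tr, c(0, 4, 9))
  wide <- tidyr::pivot_wider(s, names_from = "state", values_from = "count")
  for (st in hsc_states("three_state")) {
    expect_equal(wide[[st]], tr[[st]][match(c(0, 4, 9), tr$time_day)])
  }
  # t = 0 returns the seeded populations
  s0 <- sample_trajectory(tr, 0)
  expect_equal(s0$count[s0$state == "LSK"], 5000)
  # midway between grid points: agree with a rerun whose grid contains it
  t_mid <- 3.025
  s_mid <- sample_trajectory(tr, t_mid)
  tr2 <- simulate_culture("three_state", sample_times = t_mid)
  ref <- tr2[tr2$time_day == t_mid, hsc_states("three_state")]
  expect_equal(s_mid$count, unlist(ref, use.names = FALSE),
               tolerance = 1e-3)
  expect_error(sample_trajectory(tr, 12), "within")
})

test_that("tidy/glance/autoplot views of a trajectory are consistent", {
  tr <- simulate_culture("three_state")
  long <- tidy(tr)
  expect_named(long, c("time_day", "state", "count"))
  expect_equal(nrow(long), 3 * nrow(tr))
  g <- glance(tr)
  expect_equal(g$terminal_peak, max(tr$Terminal))
  expect_s3_class(autoplot(tr), "ggplot")
})
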
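test_that("feedback ratios follow the zero-pool conventions", {
  expect_equal(feedback_ratios(
    culture_environment(pool_DiffS = 2, pool_DiffI = 1))$R_d, 2)
  expect_equal(feedback_ratios(
    culture_environment(pool_DiffS = 0, pool_DiffI = 5))$R_d, 0)
  # zero inhibitor: ratio capped by the 1e-9 ng floor
  expect_equal(feedback_ratios(
    culture_environment(pool_DiffS = 3, pool_DiffI = 0))$R_d, 3e9)
  # limit sweep: the floored ratio is the continuous limit of DiffI -> 0+
  sweep <- vapply(10^-(3:9), function(di) {
    feedback_ratios(culture_environment(pool_DiffS = 3,
                                        pool_DiffI = di))$R_d
  }, numeric(1))
  expect_true(all(diff(sweep) > 0))
  expect_equal(sweep[length(sweep)], 3e9)
  # fully empty culture (t = 0): both ratios zero, not 0/0
  r0 <- feedback_ratios(culture_environment())
  expect_equal(unlist(r0), c(R_d = 0, R_p = 0))
})

test_that("kernel closed forms match hand arithmetic", {
  expect_equal(secretion_rate(0.01, 0), 0.01)
  expect_equal(secretion_rate(0.01, 1, c_hat = 1), 0.01 * exp(-1))
  expect_equal(death_rate(0.2, 0, 10), 0.2)
  expect_equal(death_rate(0.2, 1, 0), 0.2)
  expect_equal(death_rate(0.2, 0.5, 10), 0.2 / 6)
  expect_equal(self_renewal_fraction(0.8, 0, R_d = 0, scf_conc = 0), 0.8)
  expect_equal(self_renewal_fraction(0.8, 0.01, R_d = 1, scf_conc = 100),
               0.8 / 3)
  expect_equal(proliferation_rate(1, scf_conc = 0, R_p = 5), 0)
  # half-maximum at scf * R_p = ln 2
  expect_equal(proliferation_rate(1, scf_conc = log(2), R_p = 1), 0.5)
  expect_equal(quiescent_fraction(0.3, 0), 0.3)
  expect_equal(quiescent_fraction(0.3, 1), 0.3 * exp(-1))
  expect_equal(jump_fraction(0.5, 0), 0.5)
  expect_equal(jump_fraction(0.5, 1), 0.5 * exp(-1))
  expect_equal(jump_fraction(0, 7), 0)  # jump-ablated model
})

test_that("kernels respect their bounds and monotonicity on random sweeps", {
  set.seed(42)
  for (i in 1:100) {
    f_max <- runif(1); q_max <- runif(1); j_max <- runif(1)
    pr_max <- runif(1, 0, 3); dr_max <- runif(1, 0, 3)
    rd <- runif(1, 0, 10); scf <- runif(1, 0, 200); gc <- runif(1, 0, 10)
    s <- runif(1, 0, 0.05); d <- runif(1, 0, 2); rp <- runif(1, 0, 10)
    td <- runif(1, 0, 5); m <- 10^runif(1, -7, -3); conc <- runif(1, 0, 20)

    f <- self_renewal_fraction(f_max, s, rd, scf)
    expect_lte(f, f_max); expect_gt(f, 0)
    q <- quiescent_fraction(q_max, rd)
    expect_lte(q, q_max); expect_gt(q, 0)
    j <- jump_fraction(j_max, td)
    expect_lte(j, j_max)
    pr <- proliferation_rate(pr_max, scf, rp)
    expect_lt(pr, pr_max + 1e-15); expect_gte(pr, 0)
    de <- death_rate(dr_max, d, gc)
    expect_lte(de, dr_max); expect_gte(de, 0)
    cs <- secretion_rate(m, conc)
    expect_lte(cs, m); expect_gte(cs, 0)

    # monotone feedback responses
    expect_lte(self_renewal_fraction(f_max, s, rd + 1, scf), f)
    expect_lte(self_renewal_fraction(f_max, s, rd, scf + 10), f)
    expect_lt(quiescent_fraction(q_max, rd + 1), q)
    expect_lte(jump_fraction(j_max, td + 1), j)
    expect_lte(death_rate(dr_max, d, gc + 1), de)
    expect_lte(secretion_rate(m, conc + 1), cs)
    expect_gte(proliferation_rate(pr_max, scf + 10, rp), pr)
  }
})

test_that("kernels reject out-of-domain inputs", {
  expect_error(secretion_rate(-0.01, 1), "non-negative")
  expect_error(death_rate(0.2, 1, -1), "non-negative")
  expect_error(self_renewal_fraction(1.2, 0, 0, 0), "\\[0, 1\\]")
  expect_error(quiescent_fraction(0.3, -1), "non-negative")
  expect_error(proliferation_rate(1, -5, 1), "non-negative")
  expect_error(culture_environment(pool_DiffS = -1), "non-negative")
})
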
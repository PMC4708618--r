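test_that("generated multiplier is the total-to-patient health ratio", {
  # annual utility losses averted: patient + one carer
  expect_equal(round_half_away(
    generated_multiplier(health_effect(-0.109, -0.030)), 2), 1.28)
  expect_equal(round_half_away(
    generated_multiplier(health_effect(-0.041, c(-0.023, -0.023))), 2), 2.12)
  expect_identical(generated_multiplier(health_effect(5)), 1)
  expect_equal(generated_multiplier(health_effect(1.0, -0.5)), 0.5)
})

test_that("displaced multiplier reproduces the displacement ratios", {
  expect_equal(displaced_multiplier(health_effect(100, 16)), 1.16)
  expect_equal(displaced_multiplier(health_effect(100, c(16, 16))), 1.32)
  expect_identical(displaced_multiplier(health_effect(100)), 1)
})

test_that("zero patient delta raises the undefined-multiplier error", {
  expect_error(generated_multiplier(health_effect(0, 1)),
               class = "spillcea_undefined_multiplier")
  expect_error(generated_multiplier(health_effect(0, 1)),
               "direct_spillover_decision")
})

test_that("health_effect validates inputs and aggregates additively", {
  eff <- health_effect(2, c(0.5, 0.25, 0.25))
  expect_equal(eff$network_delta, sum(eff$network_deltas))
  expect_error(health_effect(Inf), "finite")
  expect_error(health_effect(1, NaN), "finite")
})

test_that("conventional rule funds strictly below the threshold", {
  th <- threshold_spec(20000)
  fund <- conventional_decision(2e6, 120, th)
  expect_equal(fund$verdict, "FUND")
  expect_equal(fund$icer, 2e6 / 120)
  expect_equal(conventional_decision(2e6, 80, th)$verdict, "REJECT")
  # tie at the threshold is rejected
  expect_equal(conventional_decision(20000 * 100, 100, th)$verdict, "REJECT")
  dom <- conventional_decision(2e6, -5, th)
  expect_equal(dom$verdict, "DOMINATED")
  expect_match(dom$reason, "non-positive")
})

test_that("multiplier-adjusted rule scales the ICER by m_d/m_i", {
  th <- threshold_spec(20000)
  expect_equal(
    spillover_decision(2e6, 120, multiplier_pair(1.56, 1.32), th)$verdict,
    "FUND")
  expect_equal(
    spillover_decision(2e6, 120, multiplier_pair(1.04, 1.32), th)$verdict,
    "REJECT")
  expect_error(
    spillover_decision(2e6, 120, multiplier_pair(-0.2, 1.1), th),
    "direct_spillover_decision")
})

test_that("equal multipliers reduce the adjusted rule to the conventional one", {
  set.seed(11)
  th_pool <- c(1e3, 2e4, 5e4)
  for (i in 1:500) {
    cost <- runif(1, 1e4, 1e7)
    benefit <- runif(1, 1, 500)
    m <- runif(1, 0.2, 3)
    th <- threshold_spec(sample(th_pool, 1))
    expect_identical(
      spillover_decision(cost, benefit, multiplier_pair(m, m), th)$verdict,
      conventional_decision(cost, benefit, th)$verdict)
  }
})

test_that("direct rule compares cost per unit of total health across streams", {
  fund <- direct_spillover_decision(2e6, health_effect(120, 33.6),
                                    2e6, health_effect(100, 16))
  expect_equal(fund$verdict, "FUND")  # 153.6 total beats 116 displaced
  eq <- direct_spillover_decision(2e6, health_effect(100, 16),
                                  2e6, health_effect(100, 16))
  expect_equal(eq$verdict, "REJECT")  # strict inequality on equal ratios
  rej <- direct_spillover_decision(2e6, health_effect(120, c(2.4, 2.4)),
                                   2e6, health_effect(100, c(16, 16)))
  expect_equal(rej$verdict, "REJECT")  # 124.8 < 132
  expect_error(
    direct_spillover_decision(2e6, health_effect(10), 2e6, health_effect(0)),
    "threshold undefined")
  expect_equal(
    direct_spillover_decision(2e6, health_effect(-10, 2),
                              2e6, health_effect(100, 16))$verdict,
    "DOMINATED")
})

test_that("ratio form and direct form agree on consistent random streams", {
  set.seed(23)
  for (i in 1:500) {
    cs <- random_stream_case()
    direct <- direct_spillover_decision(cs$cost, cs$gen,
                                        cs$displaced_cost, cs$disp)
    mp <- multiplier_pair(generated_multiplier(cs$gen),
                          displaced_multiplier(cs$disp))
    ratio <- spillover_decision(cs$cost, cs$gen$patient_delta, mp,
                                threshold_spec(cs$k_p))
    expect_identical(ratio$verdict, direct$verdict)
  }
})

test_that("multiplier with n identical members is 1 + n * member/patient ratio", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(1, 0.05, 2)
    c_ <- runif(1, 0.001, 1)
    n <- sample(0:6, 1)
    expect_equal(generated_multiplier(health_effect(p, rep(c_, n))),
                 1 + n * c_ / p)
  }
  # monotone in n when member effect has the same sign as patient effect
  ms <- vapply(0:5, function(n)
    generated_multiplier(health_effect(0.1, rep(0.03, n))), numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("verdicts are invariant to joint currency rescaling", {
  set.seed(31)
  for (i in 1:100) {
    cost <- runif(1, 1e4, 1e7)
    benefit <- runif(1, 1, 500)
    k_p <- runif(1, 5e3, 5e4)
    scale <- runif(1, 0.01, 100)
    mp <- multiplier_pair(runif(1, 0.5, 2.5), runif(1, 0.5, 2.5))
    expect_identical(
      spillover_decision(cost, benefit, mp, threshold_spec(k_p))$verdict,
      spillover_decision(cost * scale, benefit, mp,
                         threshold_spec(k_p * scale))$verdict)
  }
})

test_that("net health benefit is generated minus displaced", {
  expect_equal(net_health_benefit(187, 132), 55)
  expect_equal(net_health_benefit(132, 132), 0)
  expect_equal(net_health_benefit(114, 132), -18)
})

test_that("threshold spec checks internal consistency", {
  expect_silent(threshold_spec(20000, 5e-5, 8e-6))
  expect_warning(threshold_spec(20000, 1e-4), "inconsistent")
  expect_error(threshold_spec(-1), "positive")
})

test_that("half-away-from-zero rounding matches the reporting convention", {
  expect_equal(round_half_away(c(153.6, 124.8, 169.6, 148.4, 122.4, 114.4)),
               c(154, 125, 170, 148, 122, 114))
  expect_equal(round_half_away(c(0.5, 1.5, -0.5, -1.5)), c(1, 2, -1, -2))
  expect_equal(round_half_away(2.125, 2), 2.13)
})
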
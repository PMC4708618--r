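pkgs <- meningitis_packages()
full <- scenario_spec(2)

test_that("reference package table carries the published 2-dp multipliers", {
  expect_equal(pkgs$multiplier_n1, c(1.28, 1.28, 1.56, 1.56, 1.02, 1.02))
  expect_equal(pkgs$multiplier_n2, c(1.56, 1.56, 2.12, 2.12, 1.04, 1.04))
  expect_equal(pkgs$patient_benefit, c(120, 80, 80, 70, 120, 110))
  expect_true(all(pkgs$cost == 2e6))
})

test_that("perceived benefits reproduce the published integer cells", {
  expect_equal(perceived_benefit(pkgs, scenario_spec(0)),
               c(120, 80, 80, 70, 120, 110))
  expect_equal(perceived_benefit(pkgs, scenario_spec(1)),
               c(154, 102, 125, 109, 122, 112))
  expect_equal(perceived_benefit(pkgs, scenario_spec(2)),
               c(187, 125, 170, 148, 125, 114))
})

test_that("rounding audit: published integers need the documented policy", {
  raw <- perceived_benefit(pkgs, scenario_spec(2), round_policy = "none")
  expect_equal(raw[1], 187.2)  # behavioral A before integer rounding
  expect_false(all(raw == perceived_benefit(pkgs, scenario_spec(2))))
})

test_that("missing multiplier column is a configuration error", {
  expect_error(perceived_benefit(pkgs, scenario_spec(3)), "multiplier_n3")
})

test_that("scenario thresholds add displaced member units per recognized carer", {
  expect_equal(scenario_threshold(scenario_spec(0)), 100)
  expect_equal(scenario_threshold(scenario_spec(1)), 116)
  expect_equal(scenario_threshold(scenario_spec(2)), 132)
  expect_equal(scenario_threshold(scenario_spec(2, 50, 10)), 70)
})

test_that("funding sets match the published scenario selections", {
  expect_setequal(select_funding(pkgs, scenario_spec(0)),
                  c("behavioral_A", "amputation_A", "amputation_B"))
  expect_setequal(select_funding(pkgs, scenario_spec(1)),
                  c("behavioral_A", "learning_A", "amputation_A"))
  expect_setequal(select_funding(pkgs, scenario_spec(2)),
                  c("behavioral_A", "learning_A", "learning_B"))
  empty <- pkgs[0, ]
  expect_length(select_funding(empty, scenario_spec(0)), 0)
})

test_that("realized net benefit values funding sets at full information", {
  expect_equal(realized_net_benefit(select_funding(pkgs, scenario_spec(0)),
                                    pkgs, full), 30)
  expect_equal(realized_net_benefit(select_funding(pkgs, full), pkgs, full),
               109)
  expect_equal(realized_net_benefit(character(0), pkgs, full), 0)
})

test_that("ignoring displaced spillovers costs 32 units on the reference set", {
  expect_equal(displaced_spillover_penalty(pkgs, full), 32)
})

test_that("penalty is zero when there are no spillovers", {
  no_spill <- generate_intervention_table(
    data.frame(condition = "x", patient_decrement = -0.1,
               carer_decrement = 0),
    list(x = c(A = 120, B = 80)), cost = 2e6)
  expect_equal(no_spill$multiplier_n1, c(1, 1))
  expect_equal(displaced_spillover_penalty(no_spill, scenario_spec(2, 100, 0)),
               0)
})

test_that("threshold rule selects the net-benefit-maximizing set (brute force)", {
  toy <- toy_packages()
  sc <- scenario_spec(2, 100, 16)
  oracle <- best_funding_set(toy, sc)
  chosen <- select_funding(toy, sc)
  expect_setequal(chosen, oracle$ids)
  expect_equal(realized_net_benefit(chosen, toy, sc), oracle$value)

  # and the full-information set dominates every other scenario's set
  for (n in 0:2) {
    other <- select_funding(toy, scenario_spec(n, 100, 16))
    expect_lte(realized_net_benefit(other, toy, sc), oracle$value)
  }
})

test_that("full-information selection dominates on randomized package sets", {
  set.seed(47)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    rnd <- care_packages(
      condition = paste0("c", seq_len(k)), arm = rep("A", k),
      cost = rep(2e6, k),
      patient_benefit = runif(k, 40, 200),
      multipliers = cbind(runif(k, 1, 1.8), runif(k, 1, 2.6)))
    sc <- scenario_spec(2, 100, 16)
    oracle <- best_funding_set(rnd, sc)
    expect_equal(realized_net_benefit(select_funding(rnd, sc), rnd, sc),
                 oracle$value)
  }
})

test_that("portfolio selection agrees with the multiplier decision rule", {
  # map the unit framing: budget 2e6 <-> 100 displaced patient units
  # <-> k_p = 20000; m_d at full information is 1.32
  th <- threshold_spec(20000, 5e-5, 8e-6)
  m_d <- displaced_multiplier(health_effect(100, c(16, 16)))
  raw <- perceived_benefit(pkgs, full, round_policy = "none")
  for (i in seq_len(nrow(pkgs))) {
    rule <- spillover_decision(pkgs$cost[i], pkgs$patient_benefit[i],
                               multiplier_pair(pkgs$multiplier_n2[i], m_d),
                               th)
    expect_identical(rule$verdict == "FUND",
                     raw[i] > scenario_threshold(full))
  }
})

test_that("run_portfolio assembles thresholds, sets and net benefits", {
  res <- run_portfolio(pkgs)
  expect_equal(unname(res$thresholds), c(100, 116, 132))
  expect_equal(unname(res$realized_net_benefit[c("n0", "n2")]), c(30, 109))
  expect_equal(res$benefits$perceived_n2, c(187, 125, 170, 148, 125, 114))
  expect_true(all(res$benefits$funded_n2 ==
                    (pkgs$id %in% res$funded$n2)))
})

test_that("care package validation rejects non-positive costs and benefits", {
  expect_error(care_packages("a", "A", -1, 10, 1.1), "positive")
  expect_error(care_packages("a", "A", 1e6, 0, 1.1), "positive")
})
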
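# Independent oracles used across test files.

# Trapezoidal quadrature; exact for linear integrands, which is what makes it
# an independent check on the closed-form triangle areas.
trapezoid <- function(f, a, b, n = 2000) {
  if (a == b) return(0)
  x <- seq(a, b, length.out = n + 1)
  y <- f(x)
  sum((y[-1] + y[-(n + 1)]) / 2) * (b - a) / n
}

# Brute-force search over all funding subsets for the one maximizing realized
# net benefit under full information.
best_funding_set <- function(packages, full_scenario) {
  ids <- packages$id
  best <- character(0)
  best_val <- 0
  for (mask in 0:(2^length(ids) - 1)) {
    subset <- ids[bitwAnd(mask, 2^(seq_along(ids) - 1)) > 0]
    val <- realized_net_benefit(subset, packages, full_scenario)
    if (val > best_val) {
      best <- subset
      best_val <- val
    }
  }
  list(ids = best, value = best_val)
}

# Random consistent generated/displaced streams for decision-rule
# equivalence checks: the threshold k_p is derived from the displaced stream
# so that the ratio form and the direct form describe the same problem.
random_stream_case <- function() {
  p <- runif(1, 1, 200)
  gen <- health_effect(p, runif(sample(0:3, 1), 0, 50))
  dp <- runif(1, 1, 200)
  disp <- health_effect(dp, runif(sample(0:3, 1), 0, 50))
  cost <- runif(1, 1e4, 5e6)
  displaced_cost <- runif(1, 1e4, 5e6)
  k_p <- displaced_cost / disp$patient_delta
  list(cost = cost, gen = gen, displaced_cost = displaced_cost, disp = disp,
       k_p = k_p)
}

# Small deterministic package table for toy portfolio checks.
toy_packages <- function() {
  care_packages(
    condition = c("x", "y", "z"),
    arm = c("A", "A", "A"),
    cost = rep(2e6, 3),
    patient_benefit = c(150, 110, 90),
    multipliers = cbind(c(1.10, 1.40, 1.60), c(1.20, 1.80, 2.20))
  )
}
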
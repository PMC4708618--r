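#' Incremental health effect of an intervention on a patient and their network
#'
#' A `health_effect` bundles the incremental health change experienced by the
#' patient (\eqn{\Delta h_p}) with the per-member incremental changes in the
#' patient's family network (the components of \eqn{\Delta h_n}). The aggregate
#' network effect is the sum of the components (additivity); the network may be
#' empty. The same container is used for health generated by a new intervention
#' and for health displaced elsewhere in the system when its budget is diverted.
#'
#' @param patient_delta Numeric scalar, incremental patient health in QALY-like
#'   units. Illness-induced losses are conventionally stored as negative
#'   decrements; benefits (losses averted) as positive values.
#' @param network_deltas Numeric vector of per-member incremental health
#'   changes; may be empty (no spillover).
#' @return An object of class `health_effect` with elements `patient_delta`,
#'   `network_deltas` and `network_delta` (their sum).
#' @examples
#' health_effect(120, c(33.6, 33.6))
#' health_effect(-0.109, -0.030)  # annual utility losses, patient + one carer
#' @export
health_effect <- function(patient_delta, network_deltas = numeric(0)) {
  stopifnot(is.numeric(patient_delta), length(patient_delta) == 1L,
            is.numeric(network_deltas))
  if (!is.finite(patient_delta) || !all(is.finite(network_deltas))) {
    stop("all health deltas must be finite", call. = FALSE)
  }
  structure(
    list(patient_delta = as.numeric(patient_delta),
         network_deltas = as.numeric(network_deltas),
         network_delta = sum(as.numeric(network_deltas))),
    class = "health_effect"
  )
}

#' @export
print.health_effect <- function(x, ...) {
  cat("<health_effect> patient:", x$patient_delta,
      " network (", length(x$network_deltas), " members):",
      x$network_delta, "\n", sep = "")
  invisible(x)
}

total_delta <- function(effect) effect$patient_delta + effect$network_delta

#' Cost-effectiveness threshold specification
#'
#' Describes the opportunity cost of health care spending: `k_p` is the cost
#' per unit of patient health displaced elsewhere in a fixed budget, and the
#' per-budget rates translate spending into displaced patient and network
#' health units. Internally consistent specifications satisfy
#' `k_p * displaced_patient_per_budget == 1` (spending `k_p` displaces exactly
#' one unit of patient health); a warning is raised otherwise.
#'
#' @param k_p Currency per unit of displaced patient health (> 0).
#' @param displaced_patient_per_budget Patient health units displaced per unit
#'   of currency spent. Defaults to `1 / k_p`.
#' @param displaced_network_per_member_per_budget Network health units
#'   displaced per affected member per unit of currency spent.
#' @return Object of class `threshold_spec`.
#' @examples
#' threshold_spec(20000)  # 2e6 spending displaces 100 patient units
#' threshold_spec(20000, displaced_network_per_member_per_budget = 8e-6)
#' @export
threshold_spec <- function(k_p,
                           displaced_patient_per_budget = 1 / k_p,
                           displaced_network_per_member_per_budget = 0) {
  stopifnot(is.numeric(k_p), length(k_p) == 1L, is.finite(k_p))
  if (k_p <= 0) stop("k_p must be positive", call. = FALSE)
  if (displaced_patient_per_budget <= 0) {
    stop("displaced_patient_per_budget must be positive", call. = FALSE)
  }
  if (abs(k_p * displaced_patient_per_budget - 1) > 1e-8) {
    warning("threshold_spec is internally inconsistent: ",
            "k_p * displaced_patient_per_budget != 1", call. = FALSE)
  }
  structure(
    list(k_p = as.numeric(k_p),
         displaced_patient_per_budget = as.numeric(displaced_patient_per_budget),
         displaced_network_per_member_per_budget =
           as.numeric(displaced_network_per_member_per_budget)),
    class = "threshold_spec"
  )
}

#' Pair of multiplier effects for generated and displaced health streams
#'
#' `m_i` is the ratio of total (patient + network) to patient health for the
#' stream of health generated by a new intervention; `m_d` the same ratio for
#' the stream displaced elsewhere when its budget is diverted. A multiplier of
#' exactly 1 means no network effect on that stream. Negative multipliers
#' (net-harmful spillovers exceeding the patient benefit) are representable,
#' but the ratio-form decision rule is only applicable when `m_i > 0`.
#'
#' @param m_i,m_d Finite dimensionless ratios.
#' @return Object of class `multiplier_pair`.
#' @examples
#' multiplier_pair(1.56, 1.32)
#' @export
multiplier_pair <- function(m_i, m_d) {
  stopifnot(is.numeric(m_i), is.numeric(m_d),
            length(m_i) == 1L, length(m_d) == 1L,
            is.finite(m_i), is.finite(m_d))
  structure(list(m_i = as.numeric(m_i), m_d = as.numeric(m_d)),
            class = "multiplier_pair")
}

stop_undefined_multiplier <- function() {
  stop(structure(
    class = c("spillcea_undefined_multiplier", "error", "condition"),
    list(message = paste0(
      "multiplier is undefined when the patient health delta is zero; ",
      "use direct_spillover_decision() on the raw health streams instead"),
      call = NULL)))
}

#' Multiplier effect on the stream of generated health benefits
#'
#' Computes \eqn{m_i = (\Delta h_p + \Delta h_n) / \Delta h_p}, the ratio of
#' total incremental health (patient plus family network) to incremental
#' patient health for an intervention. With `n` identical network members
#' each gaining `c` per patient unit `p`, this equals `1 + n * c / p`.
#'
#' @param effect A [health_effect()] with non-zero `patient_delta`.
#' @return Dimensionless multiplier (full double precision; round only for
#'   reporting).
#' @examples
#' generated_multiplier(health_effect(-0.109, -0.030))  # ~1.28
#' generated_multiplier(health_effect(-0.041, c(-0.023, -0.023)))  # ~2.12
#' @seealso [displaced_multiplier()], [multipliers_from_decrements()]
#' @export
generated_multiplier <- function(effect) {
  stopifnot(inherits(effect, "health_effect"))
  if (effect$patient_delta == 0) stop_undefined_multiplier()
  total_delta(effect) / effect$patient_delta
}

#' Multiplier effect on the stream of displaced health benefits
#'
#' Identical contract to [generated_multiplier()], applied to the health
#' displaced elsewhere in the system (\eqn{\Delta h_{dp}},
#' \eqn{\Delta h_{dn}}): \eqn{m_d = (\Delta h_{dp} + \Delta h_{dn}) /
#' \Delta h_{dp}}.
#'
#' @param displaced_effect A [health_effect()] describing the displaced
#'   stream; `patient_delta` must be non-zero.
#' @return Dimensionless multiplier.
#' @examples
#' displaced_multiplier(health_effect(100, 16))        # 1.16
#' displaced_multiplier(health_effect(100, c(16, 16))) # 1.32
#' @export
displaced_multiplier <- function(displaced_effect) {
  generated_multiplier(displaced_effect)
}

verdict_result <- function(verdict, icer = NA_real_, rule, reason = NA_character_) {
  structure(list(verdict = verdict, icer = icer, rule = rule, reason = reason),
            class = "funding_verdict")
}

#' @export
print.funding_verdict <- function(x, ...) {
  cat("<funding_verdict> ", x$verdict,
      if (is.finite(x$icer)) paste0("  ICER: ", format(x$icer)),
      "  [", x$rule, "]\n", sep = "")
  if (!is.na(x$reason)) cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Conventional cost-effectiveness decision rule
#'
#' Funds an intervention iff the incremental cost-effectiveness ratio on
#' patient health falls strictly below the threshold:
#' \eqn{\Delta c / \Delta h_p < k_p}. Ties at the threshold are rejected.
#'
#' @param cost Incremental cost (currency units, scalar).
#' @param patient_benefit Incremental patient health benefit
#'   (\eqn{\Delta h_p}, health units).
#' @param threshold A [threshold_spec()].
#' @return A `funding_verdict` with elements `verdict` (`"FUND"`, `"REJECT"`
#'   or `"DOMINATED"`), `icer` (currency per health unit) and `rule`. A
#'   non-positive patient benefit yields `"DOMINATED"` with an explanatory
#'   `reason` rather than an error.
#' @examples
#' conventional_decision(2e6, 120, threshold_spec(20000))  # FUND, ICER ~16667
#' conventional_decision(2e6, 80, threshold_spec(20000))   # REJECT
#' @export
conventional_decision <- function(cost, patient_benefit, threshold) {
  stopifnot(inherits(threshold, "threshold_spec"),
            is.numeric(cost), is.finite(cost),
            is.numeric(patient_benefit), is.finite(patient_benefit))
  if (patient_benefit <= 0) {
    return(verdict_result(
      "DOMINATED", rule = "conventional",
      reason = "non-positive patient benefit: intervention cannot be cost-effective at positive cost"))
  }
  icer <- cost / patient_benefit
  verdict_result(if (icer < threshold$k_p) "FUND" else "REJECT",
                 icer = icer, rule = "conventional")
}

#' Spillover-adjusted cost-effectiveness decision rule (ratio form)
#'
#' The multiplier-adjusted rule: fund iff
#' \eqn{(\Delta c / \Delta h_p) \times (m_d / m_i) < k_p} (strict). When
#' `m_i == m_d` this reduces exactly to [conventional_decision()]: constant
#' spillovers leave conventional decisions health-maximizing.
#'
#' @inheritParams conventional_decision
#' @param multipliers A [multiplier_pair()]; `m_i` must be positive (a
#'   non-positive total generated benefit invalidates the ratio form — use
#'   [direct_spillover_decision()] on the raw streams).
#' @return A `funding_verdict`; `icer` holds the adjusted ICER
#'   \eqn{(\Delta c/\Delta h_p)(m_d/m_i)}.
#' @examples
#' th <- threshold_spec(20000)
#' spillover_decision(2e6, 120, multiplier_pair(1.56, 1.32), th)  # FUND
#' spillover_decision(2e6, 120, multiplier_pair(1.04, 1.32), th)  # REJECT
#' @export
spillover_decision <- function(cost, patient_benefit, multipliers, threshold) {
  stopifnot(inherits(multipliers, "multiplier_pair"),
            inherits(threshold, "threshold_spec"))
  if (multipliers$m_i <= 0) {
    stop(paste0(
      "m_i <= 0: the ratio-form rule is invalid when total generated benefit ",
      "is non-positive; use direct_spillover_decision() on the raw streams"),
      call. = FALSE)
  }
  if (patient_benefit <= 0) {
    return(verdict_result(
      "DOMINATED", rule = "multiplier",
      reason = "non-positive patient benefit: ratio form inapplicable"))
  }
  adj_icer <- (cost / patient_benefit) * (multipliers$m_d / multipliers$m_i)
  verdict_result(if (adj_icer < threshold$k_p) "FUND" else "REJECT",
                 icer = adj_icer, rule = "multiplier")
}

#' Spillover decision rule on directly measured health streams
#'
#' When both the generated and the displaced health streams are measured
#' directly, the funding rule compares cost per unit of *total* health:
#' fund iff \eqn{\Delta c / (\Delta h_p + \Delta h_n) <
#' \Delta c_d / (\Delta h_{dp} + \Delta h_{dn})} (strict). Agrees with
#' [spillover_decision()] whenever both forms are applicable.
#'
#' @param cost Incremental cost of the proposed intervention.
#' @param generated [health_effect()] generated by the intervention.
#' @param displaced_cost Cost displaced elsewhere to fund it.
#' @param displaced [health_effect()] displaced elsewhere; its total must be
#'   positive (otherwise the implied threshold is undefined and an error is
#'   raised).
#' @return A `funding_verdict`. A non-positive total generated benefit yields
#'   `"DOMINATED"`.
#' @examples
#' direct_spillover_decision(2e6, health_effect(120, 33.6),
#'                           2e6, health_effect(100, 16))  # FUND: 153.6 > 116
#' @export
direct_spillover_decision <- function(cost, generated, displaced_cost, displaced) {
  stopifnot(inherits(generated, "health_effect"),
            inherits(displaced, "health_effect"))
  td <- total_delta(displaced)
  if (td <= 0) {
    stop("total displaced health must be positive: implied threshold undefined",
         call. = FALSE)
  }
  tg <- total_delta(generated)
  if (tg <= 0) {
    return(verdict_result(
      "DOMINATED", rule = "direct",
      reason = "non-positive total generated health at positive cost"))
  }
  fund <- cost / tg < displaced_cost / td
  verdict_result(if (fund) "FUND" else "REJECT",
                 icer = cost / tg, rule = "direct")
}

#' Net health benefit of a funding decision
#'
#' Total health generated minus total health displaced, in common health
#' units. Positive values mean the decision added health to the population.
#'
#' @param total_generated,total_displaced Finite health-unit totals.
#' @return `total_generated - total_displaced`.
#' @examples
#' net_health_benefit(187, 132)  # 55
#' @export
net_health_benefit <- function(total_generated, total_displaced) {
  stopifnot(is.numeric(total_generated), is.numeric(total_displaced),
            all(is.finite(total_generated)), all(is.finite(total_displaced)))
  total_generated - total_displaced
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds away from zero), as opposed to the
#' IEEE round-half-even used by [base::round()]. Used at the reporting layer
#' so that published integer tables are reproduced (e.g. 153.6 -> 154,
#' 124.8 -> 125, 114.4 -> 114).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
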
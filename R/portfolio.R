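#' Construct a table of candidate care packages
#'
#' A care-package table holds one row per candidate intervention: a condition
#' label, an arm label (e.g. "A" for the relatively more cost-effective
#' package, "B" for the less cost-effective one), its cost, its incremental
#' patient health benefit, and the generated-stream multipliers that apply
#' when 1, 2, ... network members are recognized (conventionally reported at
#' 2 decimal places).
#'
#' @param condition Character vector of condition labels.
#' @param arm Character vector of arm labels.
#' @param cost Positive costs (currency units).
#' @param patient_benefit Positive patient health benefits (health units).
#' @param multipliers Numeric matrix or data frame with one column per
#'   recognized network size (column `n` = multiplier with `n` members), one
#'   row per package; or a numeric vector if only one size is used.
#' @return A `data.frame` of class `care_packages` with columns `id`,
#'   `condition`, `arm`, `cost`, `patient_benefit`, `multiplier_n1`, ...
#' @examples
#' care_packages("behavioral", "A", 2e6, 120, cbind(1.28, 1.56))
#' @export
care_packages <- function(condition, arm, cost, patient_benefit, multipliers) {
  multipliers <- as.matrix(multipliers)
  n_pkg <- length(condition)
  stopifnot(length(arm) == n_pkg, length(cost) == n_pkg,
            length(patient_benefit) == n_pkg, nrow(multipliers) == n_pkg)
  if (any(!is.finite(cost)) || any(cost <= 0)) {
    stop("package costs must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(patient_benefit)) || any(patient_benefit <= 0)) {
    stop("patient benefits must be positive and finite", call. = FALSE)
  }
  out <- data.frame(
    id = paste(condition, arm, sep = "_"),
    condition = as.character(condition),
    arm = as.character(arm),
    cost = as.numeric(cost),
    patient_benefit = as.numeric(patient_benefit),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(multipliers))) {
    out[[paste0("multiplier_n", j)]] <- as.numeric(multipliers[, j])
  }
  class(out) <- c("care_packages", "data.frame")
  out
}

max_recognizable_n <- function(packages) {
  cols <- grep("^multiplier_n[0-9]+$", names(packages), value = TRUE)
  if (length(cols) == 0L) 0L else max(as.integer(sub("multiplier_n", "", cols)))
}

#' Specify an information scenario for portfolio funding
#'
#' A scenario states how many affected network members the decision maker
#' recognizes (`n_recognized` = 0 means patient-only information) and the
#' opportunity cost of one package's budget: the patient health units it
#' displaces elsewhere plus, per recognized member, the network health units
#' displaced.
#'
#' @param n_recognized Number of network members recognized (0, 1, 2, ...).
#' @param displaced_patient_units Patient health units displaced per package
#'   budget (> 0).
#' @param displaced_member_units Network health units displaced per recognized
#'   member per package budget.
#' @return Object of class `scenario_spec`.
#' @examples
#' scenario_spec(2)  # full two-carer information: threshold 132
#' @export
scenario_spec <- function(n_recognized,
                          displaced_patient_units = 100,
                          displaced_member_units = 16) {
  stopifnot(length(n_recognized) == 1L, n_recognized >= 0,
            n_recognized == as.integer(n_recognized))
  if (displaced_patient_units <= 0) {
    stop("displaced_patient_units must be positive", call. = FALSE)
  }
  structure(
    list(n_recognized = as.integer(n_recognized),
         displaced_patient_units = as.numeric(displaced_patient_units),
         displaced_member_units = as.numeric(displaced_member_units)),
    class = "scenario_spec"
  )
}

#' Perceived health benefit of each package under an information scenario
#'
#' With no spillover information the perceived benefit is the patient benefit
#' alone. With `n >= 1` recognized members, the patient benefit is scaled by
#' the package's `n`-member multiplier (taken at 2 decimal places) and the
#' result reported as an integer, rounding half away from zero. This
#' reporting policy (2-dp multiplier, then integer rounding) is what makes
#' published integer benefit tables reproducible; pass `round_policy =
#' "none"` to see the raw products.
#'
#' @param packages A [care_packages()] table.
#' @param scenario A [scenario_spec()].
#' @param round_policy `"published"` (default; 2-dp multipliers then integer
#'   half-away-from-zero rounding) or `"none"` (raw double precision).
#' @return Numeric vector of perceived benefits, one per package.
#' @examples
#' pkgs <- meningitis_packages()
#' perceived_benefit(pkgs, scenario_spec(2))  # 187 125 170 148 125 114
#' @export
perceived_benefit <- function(packages, scenario,
                              round_policy = c("published", "none")) {
  round_policy <- match.arg(round_policy)
  stopifnot(inherits(scenario, "scenario_spec"))
  n <- scenario$n_recognized
  if (n == 0L) return(packages$patient_benefit)
  col <- paste0("multiplier_n", n)
  if (!col %in% names(packages)) {
    stop("no multiplier configured for n_recognized = ", n,
         " (missing column ", col, ")", call. = FALSE)
  }
  m <- packages[[col]]
  if (round_policy == "published") {
    round_half_away(packages$patient_benefit * round_half_away(m, 2), 0)
  } else {
    packages$patient_benefit * m
  }
}

#' Perceived-benefit threshold implied by an information scenario
#'
#' The health a package's budget displaces, as perceived under the scenario:
#' displaced patient units plus `n_recognized` times the per-member displaced
#' units. A package is worth funding only if its perceived benefit strictly
#' exceeds this.
#'
#' @param scenario A [scenario_spec()].
#' @return Threshold in health units (100, 116, 132 for the default
#'   displacement rates at n = 0, 1, 2).
#' @export
scenario_threshold <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  scenario$displaced_patient_units +
    scenario$n_recognized * scenario$displaced_member_units
}

#' Select the packages funded under an information scenario
#'
#' Funds exactly the packages whose perceived benefit strictly exceeds the
#' scenario threshold (ties rejected). All packages are assumed to cost the
#' same per-package budget that the displacement rates refer to.
#'
#' @inheritParams perceived_benefit
#' @return Character vector of funded package ids.
#' @examples
#' select_funding(meningitis_packages(), scenario_spec(0))
#' @export
select_funding <- function(packages, scenario) {
  pb <- perceived_benefit(packages, scenario)
  packages$id[pb > scenario_threshold(scenario)]
}

#' Realized net health benefit of a funding set under full information
#'
#' Evaluates a funding set at face value: for each funded package, the
#' full-information perceived benefit minus the full-information threshold,
#' summed. This is the health the decisions actually add to (or remove from)
#' the population once all spillovers — generated and displaced — are counted.
#'
#' @param funded_ids Character vector of package ids (subset of
#'   `packages$id`).
#' @param packages A [care_packages()] table.
#' @param full_info_scenario A [scenario_spec()] with the maximum recognized
#'   `n` (the ground truth).
#' @return Net health benefit in health units (0 for an empty set).
#' @examples
#' pkgs <- meningitis_packages()
#' realized_net_benefit(select_funding(pkgs, scenario_spec(0)),
#'                      pkgs, scenario_spec(2))  # 30
#' @export
realized_net_benefit <- function(funded_ids, packages, full_info_scenario) {
  if (length(funded_ids) == 0L) return(0)
  stopifnot(all(funded_ids %in% packages$id))
  pb <- perceived_benefit(packages, full_info_scenario)
  thr <- scenario_threshold(full_info_scenario)
  sum(pb[match(funded_ids, packages$id)] - thr)
}

#' Health lost by ignoring displaced spillovers
#'
#' Compares the optimal full-information funding set against the set chosen
#' when the threshold is left unadjusted for displaced spillovers (m_d forced
#' to 1, i.e. the threshold stays at the displaced patient units only) while
#' generated spillovers are still counted. Both sets are valued at full
#' information. The difference is the additional health lost by failing to
#' lower the bar for what counts as "worth displacing".
#'
#' @param packages A [care_packages()] table.
#' @param full_info_scenario A [scenario_spec()] with the maximum `n`.
#' @return Health units lost relative to the optimal position (>= 0 under
#'   the default policy).
#' @examples
#' displaced_spillover_penalty(meningitis_packages(), scenario_spec(2))  # 32
#' @export
displaced_spillover_penalty <- function(packages, full_info_scenario) {
  stopifnot(inherits(full_info_scenario, "scenario_spec"))
  optimal <- select_funding(packages, full_info_scenario)
  naive_scenario <- scenario_spec(
    n_recognized = full_info_scenario$n_recognized,
    displaced_patient_units = full_info_scenario$displaced_patient_units,
    displaced_member_units = 0)
  naive <- select_funding(packages, naive_scenario)
  realized_net_benefit(optimal, packages, full_info_scenario) -
    realized_net_benefit(naive, packages, full_info_scenario)
}

#' Run the portfolio analysis across information scenarios
#'
#' For each requested number of recognized network members, computes every
#' package's perceived benefit, the scenario threshold, the funded set, and
#' the realized net health benefit of that set under full information
#' (largest configured `n`).
#'
#' @param packages A [care_packages()] table.
#' @param n_recognized Integer vector of scenarios to evaluate (default all
#'   of 0 .. max configured n).
#' @param displaced_patient_units,displaced_member_units Displacement rates
#'   per package budget, shared across scenarios.
#' @return A list with `benefits` (data frame: one row per package, one
#'   perceived-benefit column per scenario plus `funded_n<k>` logicals),
#'   `thresholds` (named vector), `funded` (list of id vectors) and
#'   `realized_net_benefit` (named vector, valued at full information).
#' @examples
#' run_portfolio(meningitis_packages())
#' @export
run_portfolio <- function(packages,
                          n_recognized = 0:max_recognizable_n(packages),
                          displaced_patient_units = 100,
                          displaced_member_units = 16) {
  n_full <- max(n_recognized)
  full <- scenario_spec(n_full, displaced_patient_units, displaced_member_units)
  benefits <- packages[, c("id", "condition", "arm", "patient_benefit")]
  thresholds <- numeric(0)
  funded <- list()
  rnb <- numeric(0)
  for (n in n_recognized) {
    sc <- scenario_spec(n, displaced_patient_units, displaced_member_units)
    key <- paste0("n", n)
    benefits[[paste0("perceived_", key)]] <- perceived_benefit(packages, sc)
    ids <- select_funding(packages, sc)
    benefits[[paste0("funded_", key)]] <- packages$id %in% ids
    thresholds[key] <- scenario_threshold(sc)
    funded[[key]] <- ids
    rnb[key] <- realized_net_benefit(ids, packages, full)
  }
  list(benefits = benefits, thresholds = thresholds, funded = funded,
       realized_net_benefit = rnb)
}

#' Reference utility decrements for three after-effects of meningitis
#'
#' Mean annual impact on the EQ-5D-5L utility index of three disabling
#' after-effects of meningitis, for the patient and for one carer, as
#' estimated in a family-impact study of meningitis survivors. These are the
#' reference decrements used throughout the package's worked examples.
#'
#' @return A data frame with columns `condition`, `patient_decrement`,
#'   `carer_decrement` (all decrements negative).
#' @examples
#' meningitis_decrements()
#' @export
meningitis_decrements <- function() {
  data.frame(
    condition = c("behavioral", "learning", "amputation"),
    patient_decrement = c(-0.109, -0.041, -0.226),
    carer_decrement = c(-0.030, -0.023, -0.005),
    stringsAsFactors = FALSE
  )
}

#' The six-package funding example built from the meningitis decrements
#'
#' Six hypothetical packages of care (a more and a less cost-effective arm
#' for each of three conditions), each costing 2 million currency units, with
#' generated-stream multipliers for 1 and 2 carers computed from
#' [meningitis_decrements()] and reported at 2 decimal places.
#'
#' @return A [care_packages()] table with 6 rows.
#' @examples
#' meningitis_packages()
#' @export
meningitis_packages <- function() {
  generate_intervention_table(
    decrements = meningitis_decrements(),
    patient_benefits = list(behavioral = c(A = 120, B = 80),
                            learning = c(A = 80, B = 70),
                            amputation = c(A = 120, B = 110)),
    cost = 2e6,
    n_members = 1:2,
    digits = 2
  )
}
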
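#' Specification for a synthetic patient-carer cohort
#'
#' Describes the data-generating process the estimation stage assumes: linked
#' patient-carer dyads where each condition, drawn independently by
#' prevalence, imposes a mean utility decrement on the patient and a smaller
#' one on each carer, plus linear covariate effects and additive Gaussian
#' noise on the utility index. Defaults emulate a meningitis after-effects
#' study: young survivors, adult family carers, three disabling conditions
#' with the reference decrements from [meningitis_decrements()].
#'
#' @param n_dyads Number of patient-carer family units (>= 1).
#' @param carers_per_patient Carers linked to each patient (default 2).
#' @param prevalence Named vector of per-condition prevalences in \[0, 1\].
#' @param patient_decrements,carer_decrements Named vectors of true utility
#'   effects per condition (same names as `prevalence`).
#' @param baseline Named vector: intercept utility for `patient` and `carer`
#'   before condition and covariate effects.
#' @param covariate_effects Named vector: `age` (per year), `male`
#'   (male vs female), `years_since_onset` (per year).
#' @param noise_sd Standard deviation of the additive Gaussian utility noise
#'   (>= 0).
#' @param cap_at_one Truncate utilities above 1 to 1? Off by default because
#'   censoring biases OLS recovery of the true decrements.
#' @param seed Integer base seed; the generator is bit-reproducible given the
#'   spec.
#' @return Object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_dyads = 500, noise_sd = 0.1, seed = 42)
#' @export
cohort_spec <- function(n_dyads = 2000,
                        carers_per_patient = 2,
                        prevalence = c(behavioral = 0.3, learning = 0.3,
                                       amputation = 0.2),
                        patient_decrements = c(behavioral = -0.109,
                                               learning = -0.041,
                                               amputation = -0.226),
                        carer_decrements = c(behavioral = -0.030,
                                             learning = -0.023,
                                             amputation = -0.005),
                        baseline = c(patient = 0.90, carer = 0.92),
                        covariate_effects = c(age = -0.002, male = 0.01,
                                              years_since_onset = 0.001),
                        noise_sd = 0.1,
                        cap_at_one = FALSE,
                        seed = 1L) {
  if (n_dyads < 1 || n_dyads != as.integer(n_dyads)) {
    stop("n_dyads must be a positive integer", call. = FALSE)
  }
  if (carers_per_patient < 0 || carers_per_patient != as.integer(carers_per_patient)) {
    stop("carers_per_patient must be a non-negative integer", call. = FALSE)
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  conds <- names(prevalence)
  if (is.null(conds) ||
      !setequal(conds, names(patient_decrements)) ||
      !setequal(conds, names(carer_decrements))) {
    stop("prevalence, patient_decrements and carer_decrements must share names",
         call. = FALSE)
  }
  structure(
    list(n_dyads = as.integer(n_dyads),
         carers_per_patient = as.integer(carers_per_patient),
         prevalence = prevalence,
         patient_decrements = patient_decrements[conds],
         carer_decrements = carer_decrements[conds],
         baseline = baseline,
         covariate_effects = covariate_effects,
         noise_sd = noise_sd,
         cap_at_one = isTRUE(cap_at_one),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Per-dyad substream seed: earlier dyads are unchanged when n_dyads grows.
dyad_seed <- function(base_seed, i) {
  (as.numeric(base_seed) * 1000003 + i) %% .Machine$integer.max
}

#' Generate a synthetic patient-carer cohort
#'
#' Draws one family unit per dyad: condition flags by prevalence, covariates
#' from documented distributions (patient age uniform on 1-40 years, carer
#' age uniform on 20-60, sex Bernoulli(0.5), dyad-level years since onset
#' uniform on 1-25), then utilities as baseline + condition decrements +
#' covariate effects + Gaussian noise. Carers inherit the linked patient's
#' condition flags as exposures, which is what makes the carer-side
#' regression well-posed. Each dyad uses its own RNG substream, so extending
#' `n_dyads` leaves earlier records bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of individual records: `person_id`, `dyad_id`,
#'   `role`, `utility`, `age`, `sex`, `years_since_onset` and one `cond_*`
#'   indicator column per condition.
#' @examples
#' head(generate_cohort(cohort_spec(n_dyads = 5, seed = 7)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  conds <- names(spec$prevalence)
  per_dyad <- 1L + spec$carers_per_patient
  n_total <- spec$n_dyads * per_dyad
  role <- character(n_total)
  utility <- age <- years <- numeric(n_total)
  sex <- character(n_total)
  dyad_id <- integer(n_total)
  flags <- matrix(0L, n_total, length(conds),
                  dimnames = list(NULL, paste0("cond_", conds)))
  ce <- spec$covariate_effects
  row <- 0L
  for (i in seq_len(spec$n_dyads)) {
    set.seed(dyad_seed(spec$seed, i))
    f <- stats::rbinom(length(conds), 1L, spec$prevalence)
    yrs <- stats::runif(1, 1, 25)
    members <- c("patient", rep("carer", spec$carers_per_patient))
    for (r in members) {
      row <- row + 1L
      dyad_id[row] <- i
      role[row] <- r
      age[row] <- if (r == "patient") stats::runif(1, 1, 40) else stats::runif(1, 20, 60)
      sex[row] <- if (stats::rbinom(1, 1, 0.5) == 1L) "male" else "female"
      years[row] <- yrs
      flags[row, ] <- f
      dec <- if (r == "patient") spec$patient_decrements else spec$carer_decrements
      mu <- spec$baseline[[r]] +
        sum(f * dec) +
        ce[["age"]] * age[row] +
        ce[["male"]] * (sex[row] == "male") +
        ce[["years_since_onset"]] * yrs
      utility[row] <- mu + if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
    }
  }
  if (spec$cap_at_one) utility <- pmin(utility, 1)
  out <- data.frame(
    person_id = seq_len(n_total),
    dyad_id = dyad_id,
    role = role,
    utility = utility,
    age = age,
    sex = sex,
    years_since_onset = years,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(flags))
}

#' Build a care-package table from condition decrements
#'
#' Constructs the funding-example fixture programmatically: one package per
#' condition and arm, with generated-stream multipliers computed from the
#' supplied decrements via [multipliers_from_decrements()] for each network
#' size.
#'
#' @param decrements Data frame with `condition`, `patient_decrement`,
#'   `carer_decrement` (e.g. [meningitis_decrements()]).
#' @param patient_benefits Named list: one element per condition, itself a
#'   named numeric vector of positive patient benefits per arm.
#' @param cost Per-package cost (shared; currency units).
#' @param n_members Network sizes to compute multipliers for (default 1:2).
#' @param digits Decimals for the stored multipliers (default 2, the
#'   published-table convention); `NULL` for full precision.
#' @return A [care_packages()] table.
#' @examples
#' generate_intervention_table(meningitis_decrements(),
#'   list(behavioral = c(A = 120), learning = c(A = 80),
#'        amputation = c(A = 120)), cost = 2e6)
#' @export
generate_intervention_table <- function(decrements, patient_benefits, cost,
                                        n_members = 1:2, digits = 2) {
  stopifnot(is.data.frame(decrements),
            all(c("condition", "patient_decrement", "carer_decrement") %in%
                  names(decrements)),
            all(names(patient_benefits) %in% decrements$condition))
  rows <- list()
  for (cond in names(patient_benefits)) {
    bens <- patient_benefits[[cond]]
    if (any(bens <= 0)) stop("patient benefits must be positive", call. = FALSE)
    d <- decrements[decrements$condition == cond, ]
    mult <- vapply(n_members, function(n) {
      multipliers_from_decrements(d$patient_decrement, d$carer_decrement, n,
                                  digits = digits)
    }, numeric(1))
    for (a in names(bens)) {
      rows[[length(rows) + 1L]] <- list(condition = cond, arm = a,
                                        benefit = bens[[a]], mult = mult)
    }
  }
  care_packages(
    condition = vapply(rows, `[[`, character(1), "condition"),
    arm = vapply(rows, `[[`, character(1), "arm"),
    cost = rep(cost, length(rows)),
    patient_benefit = vapply(rows, `[[`, numeric(1), "benefit"),
    multipliers = do.call(rbind, lapply(rows, `[[`, "mult"))
  )
}
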
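#' Estimate condition-specific utility decrements by OLS
#'
#' Fits one ordinary least squares regression per role: the health-utility
#' index regressed on the condition indicator columns jointly, adjusting for
#' age, sex and years since illness onset. The coefficient on each condition
#' indicator is the marginal utility impact of that condition on the chosen
#' role (expected negative for disabling after-effects). Carer records must
#' carry the linked patient's condition flags as exposures.
#'
#' @param records Data frame of individual records with columns `role`
#'   (`"patient"`/`"carer"`), `utility`, the covariates in `covariates`, and
#'   one 0/1 indicator column per condition (prefix `cond_` by default, as
#'   produced by [generate_cohort()]).
#' @param role Which role's model to fit: `"patient"` or `"carer"`.
#' @param conditions Character vector of condition indicator column names;
#'   defaults to every column starting with `cond_`.
#' @param covariates Adjustment covariates (default age, sex,
#'   years_since_onset).
#' @return A data frame of class `condition_effects` with columns
#'   `condition` (indicator name without the prefix), `estimate`
#'   (utility-unit decrement), `se`, `n` (records used) and attribute
#'   `role`; also carries the fitted `lm` in attribute `fit`.
#' @examples
#' rec <- generate_cohort(cohort_spec(n_dyads = 200, noise_sd = 0))
#' estimate_decrements(rec, "patient")
#' @export
estimate_decrements <- function(records, role = c("patient", "carer"),
                                conditions = NULL,
                                covariates = c("age", "sex", "years_since_onset")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(records),
            all(c("role", "utility") %in% names(records)))
  if (is.null(conditions)) {
    conditions <- grep("^cond_", names(records), value = TRUE)
  }
  if (length(conditions) == 0L) {
    stop("no condition indicator columns found", call. = FALSE)
  }
  missing_cols <- setdiff(c(conditions, covariates), names(records))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- records[records$role == role, , drop = FALSE]
  n_par <- length(conditions) + length(covariates) + 1L
  if (nrow(dat) < n_par + 2L) {
    stop("too few ", role, " records (", nrow(dat), ") for ", n_par,
         " parameters", call. = FALSE)
  }
  fml <- stats::reformulate(c(covariates, conditions), response = "utility")
  fit <- stats::lm(fml, data = dat)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    stop("singular design: collinear columns ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "), call. = FALSE)
  }
  # noise-free validation cohorts trip summary.lm's perfect-fit warning
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  est <- data.frame(
    condition = sub("^cond_", "", conditions),
    estimate = unname(coefs[conditions]),
    se = unname(sm[conditions, "Std. Error"]),
    n = nrow(dat),
    stringsAsFactors = FALSE
  )
  attr(est, "role") <- role
  attr(est, "fit") <- fit
  class(est) <- c("condition_effects", "data.frame")
  est
}

#' Multiplier implied by patient and carer utility decrements
#'
#' Converts condition-specific decrements into the generated-stream
#' multiplier for an intervention that averts them: the ratio of total
#' benefit (patient plus `n_members` identical network members) to patient
#' benefit, computed on benefit magnitudes so that negatively-coded
#' decrements and positively-coded benefits give the same answer:
#' `(|patient| + n * |carer|) / |patient|`.
#'
#' When `digits` is given, the per-member spillover ratio `|carer|/|patient|`
#' is rounded first and the multiplier reported as `1 + n * ratio`. Rounding
#' the ratio (rather than the finished multiplier) keeps the reported values
#' additive in `n` and is the policy under which published 2-dp multiplier
#' tables are internally consistent across network sizes.
#'
#' @param patient_dec Patient utility decrement (non-zero; sign ignored).
#' @param carer_dec Per-member carer utility decrement (sign ignored).
#' @param n_members Number of affected network members (>= 0).
#' @param digits Optional decimals for the reported per-member ratio
#'   (e.g. 2 for published tables); `NULL` keeps full precision.
#' @return Dimensionless multiplier >= 1 when decrements share a sign.
#' @examples
#' multipliers_from_decrements(-0.226, -0.005, 1, digits = 2)  # 1.02
#' multipliers_from_decrements(-0.041, -0.023, 2, digits = 2)  # 2.12
#' @export
multipliers_from_decrements <- function(patient_dec, carer_dec, n_members,
                                        digits = NULL) {
  stopifnot(is.numeric(patient_dec), is.numeric(carer_dec),
            all(is.finite(patient_dec)), all(is.finite(carer_dec)),
            all(n_members >= 0))
  if (any(patient_dec == 0)) stop_undefined_multiplier()
  ratio <- abs(carer_dec) / abs(patient_dec)
  if (!is.null(digits)) ratio <- round_half_away(ratio, digits)
  1 + n_members * ratio
}

#' Rank conditions by the magnitude of their utility impact
#'
#' Orders a set of condition-effect estimates by absolute decrement,
#' largest first. Patient and carer orderings can differ — a condition
#' mild for patients may weigh heavily on carers and vice versa — which is
#' exactly when spillover multipliers vary across interventions.
#'
#' @param estimates A `condition_effects` data frame (from
#'   [estimate_decrements()]) or any data frame with `condition` and
#'   `estimate` columns.
#' @return The input reordered by decreasing `abs(estimate)`.
#' @examples
#' dec <- meningitis_decrements()
#' rank_conditions(data.frame(condition = dec$condition,
#'                            estimate = dec$patient_decrement))
#' @export
rank_conditions <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("condition", "estimate") %in% names(estimates)),
            nrow(estimates) > 0)
  estimates[order(-abs(estimates$estimate)), , drop = FALSE]
}
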
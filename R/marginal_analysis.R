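#' Linear marginal health benefit schedule
#'
#' Marginal health benefit per unit of an intervention as a declining linear
#' function of quantity: `MHB(q) = intercept - slope * q`. The decline
#' reflects that some patients benefit more than others; the marginal health
#' *loss* schedule (opportunity cost per unit) is taken as a constant on the
#' assumption that each funding decision is small relative to the budget.
#'
#' @param intercept Benefit per unit at q = 0 (> 0 for a benefit schedule).
#' @param slope Decline per quantity unit (>= 0).
#' @return Object of class `linear_schedule`.
#' @examples
#' mhb <- linear_schedule(10, 1)
#' schedule_value(mhb, 4)  # 6
#' @export
linear_schedule <- function(intercept, slope) {
  stopifnot(is.numeric(intercept), is.numeric(slope),
            is.finite(intercept), is.finite(slope))
  if (slope < 0) stop("slope must be non-negative", call. = FALSE)
  structure(list(intercept = as.numeric(intercept), slope = as.numeric(slope)),
            class = "linear_schedule")
}

#' Evaluate a linear schedule at given quantities
#' @param schedule A [linear_schedule()].
#' @param q Numeric vector of quantities.
#' @return `intercept - slope * q`.
#' @export
schedule_value <- function(schedule, q) {
  stopifnot(inherits(schedule, "linear_schedule"))
  schedule$intercept - schedule$slope * q
}

#' Societal schedules implied by spillover multipliers
#'
#' Under proportional spillovers, the marginal health benefit to society is
#' the patient schedule scaled by the generated multiplier, and the marginal
#' health loss to society is the (constant) patient loss scaled by the
#' displaced multiplier: `MHB_S(q) = m_i * MHB_P(q)`, `MHL_S = m_d * MHL_P`.
#'
#' @param mhb_p Patient marginal-benefit [linear_schedule()].
#' @param mhl_p Constant patient marginal health loss (scalar).
#' @param multipliers A [multiplier_pair()] with both multipliers positive.
#' @return List with `mhb_s` (a `linear_schedule`) and `mhl_s` (scalar).
#' @examples
#' societal_schedules(linear_schedule(10, 1), 4, multiplier_pair(1.5, 1.1))
#' @export
societal_schedules <- function(mhb_p, mhl_p, multipliers) {
  stopifnot(inherits(mhb_p, "linear_schedule"),
            inherits(multipliers, "multiplier_pair"),
            is.numeric(mhl_p), is.finite(mhl_p))
  if (multipliers$m_i <= 0 || multipliers$m_d <= 0) {
    stop("both multipliers must be positive to scale the schedules",
         call. = FALSE)
  }
  list(mhb_s = linear_schedule(multipliers$m_i * mhb_p$intercept,
                               multipliers$m_i * mhb_p$slope),
       mhl_s = multipliers$m_d * mhl_p)
}

#' Health-maximizing funding quantity
#'
#' The quantity at which marginal health generated equals marginal health
#' displaced: `q* = (intercept - mhl) / slope`, clipped at 0 when the
#' schedule starts below the loss line (nothing is worth funding).
#'
#' @param mhb A [linear_schedule()] with positive slope.
#' @param mhl Constant marginal health loss.
#' @return Non-negative equilibrium quantity.
#' @examples
#' equilibrium_quantity(linear_schedule(10, 1), 4)  # 6
#' @export
equilibrium_quantity <- function(mhb, mhl) {
  stopifnot(inherits(mhb, "linear_schedule"), is.numeric(mhl), is.finite(mhl))
  if (mhb$slope == 0) {
    if (mhb$intercept > mhl) {
      stop("flat benefit schedule above the loss line: demand is unbounded",
           call. = FALSE)
    }
    return(0)
  }
  max(0, (mhb$intercept - mhl) / mhb$slope)
}

# Signed integral of (MHB(q) - mhl) over [q_from, q_to]; closed form for a
# linear gap function.
net_benefit_integral <- function(q_from, q_to, mhb, mhl) {
  g0 <- mhb$intercept - mhl
  antider <- function(q) g0 * q - mhb$slope * q^2 / 2
  antider(q_to) - antider(q_from)
}

#' Welfare triangle between societal benefit and loss schedules
#'
#' The health gained (or forgone) by moving the funded quantity between two
#' points: the absolute area between the societal marginal-benefit schedule
#' and the constant societal loss line over the interval. When one endpoint
#' is the crossing point the region is a triangle with area
#' `0.5 * |q_to - q_from| * |MHB_S(q_from) - MHL_S|`.
#'
#' @param q_from,q_to Interval endpoints (order irrelevant).
#' @param mhb_s Societal marginal-benefit [linear_schedule()].
#' @param mhl_s Constant societal marginal loss.
#' @return Area in health units (>= 0).
#' @examples
#' welfare_triangle(6, 8, linear_schedule(10, 1), 4)  # 2
#' @export
welfare_triangle <- function(q_from, q_to, mhb_s, mhl_s) {
  stopifnot(inherits(mhb_s, "linear_schedule"),
            is.numeric(q_from), is.numeric(q_to), is.numeric(mhl_s),
            is.finite(q_from), is.finite(q_to), is.finite(mhl_s))
  abs(net_benefit_integral(min(q_from, q_to), max(q_from, q_to), mhb_s, mhl_s))
}

#' Should an intervention with small spillovers be funded at all?
#'
#' In the small-spillover regime (societal loss exceeds societal benefit at
#' the patient-only equilibrium `q1`), scaling back from `q1` to the societal
#' equilibrium `q4` gains the triangle B; the net benefit still generated up
#' to `q4` is the triangle C. If B exceeds C, total health would be higher
#' with no funding at all. Equivalently, the verdict is the sign of the net
#' benefit integral of `MHB_S - MHL_S` over `[0, q1]`.
#'
#' @param mhb_s Societal marginal-benefit [linear_schedule()].
#' @param mhl_s Constant societal marginal loss. When `MHB_S(q1) >= mhl_s`
#'   the small-spillover regime does not bind: scaling back loses health,
#'   triangle B is zero and the verdict is trivially to keep funding.
#' @param q1 Patient-only equilibrium quantity.
#' @return List with `verdict` (`"FUND-TO-Q4"` if C >= B, else
#'   `"NO-FUNDING"`), `q4`, `triangle_B`, `triangle_C` and `net_benefit`
#'   (C - B).
#' @examples
#' corner_solution_check(linear_schedule(10, 2), 6, q1 = 6)
#' @export
corner_solution_check <- function(mhb_s, mhl_s, q1) {
  stopifnot(inherits(mhb_s, "linear_schedule"), q1 >= 0)
  q4 <- min(equilibrium_quantity(mhb_s, mhl_s), q1)
  triangle_B <- welfare_triangle(q4, q1, mhb_s, mhl_s)
  triangle_C <- welfare_triangle(0, q4, mhb_s, mhl_s)
  net <- net_benefit_integral(0, q1, mhb_s, mhl_s)
  list(verdict = if (net >= 0) "FUND-TO-Q4" else "NO-FUNDING",
       q4 = q4, triangle_B = triangle_B, triangle_C = triangle_C,
       net_benefit = net)
}

#' Full marginal-equilibrium analysis for one intervention
#'
#' Builds the societal schedules from patient schedules and a multiplier
#' pair, computes the patient-only equilibrium `q1` and the societal
#' equilibrium `q_star`, the welfare triangle between them, and a funding
#' verdict. With constant spillovers (`m_i == m_d`) the two equilibria
#' coincide; `m_i > m_d` widens provision, `m_i < m_d` narrows it, possibly
#' to zero.
#'
#' @param mhb_intercept,mhb_slope Patient marginal-benefit schedule
#'   parameters (slope > 0).
#' @param mhl Constant patient marginal health loss.
#' @param m_i,m_d Generated and displaced multipliers (> 0).
#' @return List with `q1`, `q_star`, `triangle` (health units between the
#'   two quantities), `mhb_s`, `mhl_s` and `verdict`
#'   (`"fund-to-equilibrium"` or `"fund-nothing"`).
#' @examples
#' marginal_equilibrium(10, 1, 4, m_i = 1.5, m_d = 1.1)
#' @export
marginal_equilibrium <- function(mhb_intercept, mhb_slope, mhl, m_i, m_d) {
  mhb_p <- linear_schedule(mhb_intercept, mhb_slope)
  soc <- societal_schedules(mhb_p, mhl, multiplier_pair(m_i, m_d))
  q1 <- equilibrium_quantity(mhb_p, mhl)
  q_star <- equilibrium_quantity(soc$mhb_s, soc$mhl_s)
  list(q1 = q1,
       q_star = q_star,
       triangle = welfare_triangle(q1, q_star, soc$mhb_s, soc$mhl_s),
       mhb_s = soc$mhb_s,
       mhl_s = soc$mhl_s,
       verdict = if (q_star > 0) "fund-to-equilibrium" else "fund-nothing")
}
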
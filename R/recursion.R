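#' Exact expected cost and QALYs by forward recursion
#'
#' Deterministic companion to [simulate_cohort()]: propagates occupancy
#' probabilities over the expanded state space (health state x number of
#' treatments used) cycle by cycle, accruing expected discounted cost and
#' QALYs with expected (rather than sampled) complication costs.  It is the
#' exact expectation of the per-patient stochastic process, so cohort means
#' from the microsimulation converge to it as the cohort grows; the package's
#' test suite uses it as the analytic oracle for the simulation engine.
#'
#' @inheritParams simulate_cohort
#' @return Named numeric vector with `cost` (expected discounted cost, USD),
#'   `qaly` (expected discounted QALYs) and `dly` (expected discounted
#'   life-years).
#' @export
#' @examples
#' expected_value_recursion("PNA-PNA-PNA", dc_scenario("MCP", "low"))
expected_value_recursion <- function(regimen, scenario,
                                     params = load_parameters(),
                                     mortality = NULL, perspective = NULL) {
  mortality <- mortality %||% mortality_from_params(params)
  econ <- params$economics
  societal <- (perspective %||% econ$perspective) == "societal"
  r <- econ$discount_rate

  real <- base_realization(params, 1L)
  inp <- slot_inputs(real, regimen, scenario)
  succ <- inp$succ3[1L, ]
  recur <- inp$recur3[1L, ]
  # expected cost of a treatment event per slot (wage handled per cycle)
  tcost <- inp$dcost3[1L, ] +
    vapply(1:3, function(s) sum(inp$comp_rate[1L, s, ] * inp$comp_cost[1L, s, ]),
           numeric(1))
  wage <- inp$wage3[1L, ]
  u_s <- inp$u_sympt[[1L]]
  u_f <- inp$u_free[[1L]]
  age0 <- real$start_age[[1L]]
  T <- sim_horizon(age0, mortality)

  mS <- c(1, 0, 0, 0)   # symptomatic, k = 0..3 treatments used
  mF <- c(0, 0, 0)      # symptom free, k = 1..3
  cost <- qaly <- dly <- 0
  for (t in 0:(T - 1L)) {
    df <- (1 + r)^(-t)
    h <- annual_mortality(age0 + t, mortality)
    nS <- numeric(4); nF <- numeric(3)
    pay_wage <- societal && (age0 + t) < econ$retirement_age
    for (k in 0:2) {                     # treated this cycle
      mass <- mS[[k + 1L]]
      if (mass > 0) {
        slot <- k + 1L
        ev <- tcost[[slot]] + if (pay_wage) wage[[slot]] else 0
        cost <- cost + mass * df * ev
        qaly <- qaly + mass * df * (succ[[slot]] * u_f + (1 - succ[[slot]]) * u_s)
        nF[[slot]] <- nF[[slot]] + mass * succ[[slot]]
        nS[[slot + 1L]] <- nS[[slot + 1L]] + mass * (1 - succ[[slot]])
      }
    }
    qaly <- qaly + mS[[4L]] * df * u_s   # out of treatments, symptomatic
    nS[[4L]] <- nS[[4L]] + mS[[4L]]
    for (k in 1:3) {                     # symptom free at cycle start
      mass <- mF[[k]]
      if (mass > 0) {
        qaly <- qaly + mass * df * ((1 - recur[[k]]) * u_f + recur[[k]] * u_s)
        nS[[k + 1L]] <- nS[[k + 1L]] + mass * recur[[k]]
        nF[[k]] <- nF[[k]] + mass * (1 - recur[[k]])
      }
    }
    dly <- dly + (sum(mS) + sum(mF)) * df
    mS <- nS * (1 - h)                   # death takes effect at cycle end
    mF <- nF * (1 - h)
  }
  c(cost = cost, qaly = qaly, dly = dly)
}
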
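#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Re-runs all requested regimens with the parameter set to its low and high
#' sensitivity bounds (base value in between for reference), using the same
#' seed so that the uniform streams — and hence the Monte Carlo noise — are
#' identical across settings, and records the NMB-optimal regimen and the
#' full NMB table at each setting.
#'
#' @param param_id Parameter id from [param_ids()].
#' @param params A `dc_parameters` set.
#' @param scenario A [dc_scenario()].
#' @param lambda Willingness-to-pay threshold (USD/QALY).
#' @param n Cohort size per setting.
#' @param seed Seed shared by all settings (common random numbers).
#' @param regimens Regimens to compare; default all 27.
#' @return A `dc_owsa` object: the low/high values, the NMB-optimal regimen
#'   at each setting, and an NMB matrix (regimen x setting).
#' @export
one_way_sweep <- function(param_id, params = load_parameters(), scenario,
                          lambda = 1e5, n = 2000L, seed = 1L,
                          regimens = enumerate_regimens()) {
  p <- tryCatch(get_param(params, param_id), error = function(e) NULL)
  if (!is_param(p)) stop("unknown parameter id: '", param_id, "'")
  settings <- c(low = p$low, base = p$base, high = p$high)
  nmb <- matrix(NA_real_, length(regimens), length(settings),
                dimnames = list(regimens, names(settings)))
  optimal <- character(length(settings))
  for (i in seq_along(settings)) {
    ps <- set_param(params, param_id, settings[[i]])
    g <- simulate_regimens(scenario, ps, n = n, seed = seed,
                           regimens = regimens)
    nmb[, i] <- net_monetary_benefit(g$table$mean_qaly, g$table$mean_cost,
                                     lambda)
    optimal[[i]] <- regimens[[which.max(nmb[, i])]]
  }
  names(optimal) <- names(settings)
  structure(list(param = param_id, low = p$low, base = p$base, high = p$high,
                 lambda = lambda, optimal = optimal, nmb = nmb,
                 scenario = scenario, n = n, seed = seed),
            class = "dc_owsa")
}

#' @export
print.dc_owsa <- function(x, ...) {
  cat(sprintf("<one-way sweep of %s over [%g, %g] (base %g)>\n",
              x$param, x$low, x$high, x$base))
  cat(sprintf("  NMB-optimal at low/base/high: %s / %s / %s\n",
              x$optimal[["low"]], x$optimal[["base"]], x$optimal[["high"]]))
  invisible(x)
}

#' NMB spread of a focal regimen pair across a one-way sweep
#'
#' The change in the NMB difference `alt - ref` between the parameter's low
#' and high settings; the tornado-diagram bar width for that parameter.
#'
#' @param x A `dc_owsa`.
#' @param ref,alt Regimen labels.
#' @return Named numeric: NMB difference at low, base, high, and the spread.
#' @export
owsa_spread <- function(x, ref, alt) {
  d <- x$nmb[alt, ] - x$nmb[ref, ]
  c(d, spread = unname(abs(d[["high"]] - d[["low"]])))
}

## --- probabilistic sensitivity analysis ----------------------------------

## Sample every non-fixed parameter once per draw, in the fixed traversal
## order of the defaults, and expand to patients_per_draw rows per draw.
sample_realization <- function(params, n_draws, patients_per_draw = 1L) {
  expand <- function(v) rep(v, each = patients_per_draw)
  draw_pv <- function(p, upper = Inf) {
    sample_dist(fit_distribution(p, upper = upper), n_draws)
  }
  n <- n_draws * patients_per_draw
  r <- list(n = n)
  sampled <- list()
  keep <- function(id, v) sampled[[id]] <<- v

  age <- draw_pv(params$age)
  keep("age", age)
  r$start_age <- expand(age)
  for (tr in treatments()) {
    for (j in c("MCP", "PIP")) for (s in c("low", "high")) {
      sv <- draw_pv(params$transitions$success[[tr]][[j]][[s]])
      rv <- draw_pv(params$transitions$recurrence[[tr]][[j]][[s]])
      keep(paste("transitions.success", tr, j, s, sep = "."), sv)
      keep(paste("transitions.recurrence", tr, j, s, sep = "."), rv)
      r[[paste("succ", tr, j, s, sep = ".")]] <- expand(sv)
      r[[paste("recur", tr, j, s, sep = ".")]] <- expand(rv)
    }
  }
  ## complication costs are shared across treatments: one draw per type
  comp_cost_draws <- lapply(params$complication_costs, draw_pv)
  for (lbl in names(comp_cost_draws)) {
    keep(paste0("complication_costs.", lbl), comp_cost_draws[[lbl]])
  }
  for (tr in treatments()) {
    total <- 0
    for (lbl in names(params$direct_costs[[tr]])) {
      v <- draw_pv(params$direct_costs[[tr]][[lbl]])
      keep(paste("direct_costs", tr, lbl, sep = "."), v)
      total <- total + v
    }
    r[[paste0("direct.", tr)]] <- expand(total)
    rates <- params$complication_rates[[tr]]
    cr <- matrix(0, n, MAX_COMP); cc <- matrix(0, n, MAX_COMP)
    for (i in seq_along(rates)) {
      lbl <- names(rates)[[i]]
      rv <- draw_pv(rates[[lbl]])
      keep(paste("complication_rates", tr, lbl, sep = "."), rv)
      cr[, i] <- expand(rv)
      cc[, i] <- expand(comp_cost_draws[[lbl]])
    }
    r[[paste0("comp_rate.", tr)]] <- cr
    r[[paste0("comp_cost.", tr)]] <- cc
    dv <- draw_pv(params$days_off_work[[tr]])
    keep(paste0("days_off_work.", tr), dv)
    r[[paste0("wage.", tr)]] <- expand(dv) *
      params$economics$annual_income / params$economics$working_days
  }
  for (j in c("MCP", "PIP")) for (s in c("low", "high")) {
    uv <- draw_pv(params$utilities$symptomatic[[j]][[s]], upper = 1)
    keep(paste("utilities.symptomatic", j, s, sep = "."), uv)
    r[[paste("usympt", j, s, sep = ".")]] <- expand(uv)
  }
  r$u_free <- rep(params$utilities$symptom_free, n)
  attr(r, "sampled") <- sampled
  r
}

#' Probabilistic sensitivity analysis
#'
#' Samples every non-fixed parameter from its fitted distribution (see
#' [fit_distribution()]) independently per draw — including the starting age,
#' drawn uniformly over its bounds, which shifts the whole mortality curve —
#' and evaluates all regimens on the same sampled patients with common random
#' numbers.  The default `patients_per_draw = 1` pairs each parameter draw
#' with a single simulated patient (10 000 draws then correspond to 10 000
#' simulated patients); larger values average several patients per draw,
#' which smooths acceptability curves.
#'
#' @inheritParams one_way_sweep
#' @param n_draws Number of parameter draws (default 10 000).
#' @param patients_per_draw Patients simulated per parameter draw (default 1).
#' @param regimens Regimens to evaluate; default all 27.
#' @param seed Seed covering parameter sampling and patient simulation.
#' @return A `dc_psa` object with per-draw mean `cost` and `qaly` matrices
#'   (draws x regimens), the sampled parameter draws (`$draws`), and the run
#'   settings.
#' @export
run_psa <- function(params = load_parameters(), scenario,
                    n_draws = 10000L, patients_per_draw = 1L, seed = NULL,
                    regimens = enumerate_regimens()) {
  stopifnot(n_draws >= 1L, patients_per_draw >= 1L)
  if (!is.null(seed)) set.seed(seed)
  real <- sample_realization(params, n_draws, patients_per_draw)
  mortality <- mortality_from_params(params)
  n <- real$n
  T <- sim_horizon(real$start_age, mortality)
  streams <- make_streams(n, T)          # after sampling, same RNG stream
  h_mat <- mortality_matrix(real$start_age, T, mortality)
  cost <- qaly <- matrix(NA_real_, n_draws, length(regimens),
                         dimnames = list(NULL, regimens))
  grp <- rep(seq_len(n_draws), each = patients_per_draw)
  for (i in seq_along(regimens)) {
    inp <- slot_inputs(real, regimens[[i]], scenario)
    inp$h_mat <- h_mat
    res <- sim_engine(inp, streams, params$economics)
    if (patients_per_draw == 1L) {
      cost[, i] <- res$cost
      qaly[, i] <- res$qaly
    } else {
      cost[, i] <- rowsum(res$cost, grp) / patients_per_draw
      qaly[, i] <- rowsum(res$qaly, grp) / patients_per_draw
    }
  }
  structure(list(scenario = scenario, n_draws = n_draws,
                 patients_per_draw = patients_per_draw, seed = seed,
                 regimens = regimens, cost = cost, qaly = qaly,
                 draws = attr(real, "sampled")),
            class = "dc_psa")
}

#' @export
print.dc_psa <- function(x, ...) {
  cat(sprintf("<dc_psa: %s %s severity, %d draws x %d patient(s), %d regimens>\n",
              x$scenario$joint, x$scenario$severity, x$n_draws,
              x$patients_per_draw, length(x$regimens)))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which each
#' regimen attains the maximal net monetary benefit (ties broken by regimen
#' enumeration order).  Probabilities sum to 1 across regimens at every
#' threshold.
#'
#' @param psa A `dc_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid in USD/QALY (default 0 to 300 000
#'   by 10 000).
#' @return A `dc_ceac` object with the probability matrix (`$probability`,
#'   thresholds x regimens) and the grid; `as.data.frame()` gives the long
#'   format (regimen, wtp, probability).
#' @export
ceac <- function(psa, wtp_grid = seq(0, 3e5, by = 1e4)) {
  stopifnot(inherits(psa, "dc_psa"), length(wtp_grid) >= 1L)
  nr <- length(psa$regimens)
  prob <- matrix(0, length(wtp_grid), nr,
                 dimnames = list(NULL, psa$regimens))
  for (i in seq_along(wtp_grid)) {
    nmb <- net_monetary_benefit(psa$qaly, psa$cost, wtp_grid[[i]])
    win <- max.col(nmb, ties.method = "first")
    prob[i, ] <- tabulate(win, nbins = nr) / psa$n_draws
  }
  structure(list(wtp = wtp_grid, probability = prob,
                 scenario = psa$scenario, n_draws = psa$n_draws),
            class = "dc_ceac")
}

#' @export
as.data.frame.dc_ceac <- function(x, ...) {
  data.frame(
    joint = x$scenario$joint, severity = x$scenario$severity,
    regimen = rep(colnames(x$probability), each = length(x$wtp)),
    wtp = rep(x$wtp, times = ncol(x$probability)),
    probability = as.vector(x$probability))
}

#' @export
print.dc_ceac <- function(x, ...) {
  cat(sprintf("<CEAC: %s %s severity, %d draws, wtp %g..%g>\n",
              x$scenario$joint, x$scenario$severity, x$n_draws,
              min(x$wtp), max(x$wtp)))
  top <- sort(x$probability[which.min(abs(x$wtp - 1e5)), ], decreasing = TRUE)
  cat("  at $100,000/QALY:",
      paste(sprintf("%s %.0f%%", names(top)[1:3], 100 * top[1:3]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dc_ceac <- function(x, top = 5L, ...) {
  keep <- order(apply(x$probability, 2, max), decreasing = TRUE)[seq_len(top)]
  graphics::matplot(x$wtp, x$probability[, keep], type = "l", lty = 1,
                    xlab = "Willingness to pay (USD/QALY)",
                    ylab = "P(most cost-effective)", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = colnames(x$probability)[keep],
                   col = seq_along(keep), lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
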
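# Shared builders for deterministic / degenerate model configurations.

# Mortality model that forces death at the end of a given cycle for a
# patient starting at `start_age` (probability 0 before, 1 from that age on).
death_at_cycle <- function(cycle, start_age = 60) {
  mortality_model(kind = "table",
                  table = data.frame(age = c(0, start_age + cycle),
                                     probability = c(0, 1)),
                  max_age = 200)
}

# Immortal-until-max-age mortality (all background mortality off).
no_mortality <- function(max_age = 200) {
  mortality_model(kind = "table",
                  table = data.frame(age = 0, probability = 0),
                  max_age = max_age)
}

# Set every success probability to `succ` and every recurrence probability
# to `recur`, across all treatments and scenarios.
set_all_transitions <- function(params, succ = NULL, recur = NULL) {
  clamp <- function(p, v) { p$base <- v; p$low <- min(v, p$low); p$high <- max(v, p$high); p }
  for (tr in treatments()) {
    for (j in c("MCP", "PIP")) for (s in c("low", "high")) {
      if (!is.null(succ)) {
        params$transitions$success[[tr]][[j]][[s]] <-
          clamp(params$transitions$success[[tr]][[j]][[s]], succ)
      }
      if (!is.null(recur)) {
        params$transitions$recurrence[[tr]][[j]][[s]] <-
          clamp(params$transitions$recurrence[[tr]][[j]][[s]], recur)
      }
    }
  }
  params
}

# Turn off complication draws entirely.
zero_complications <- function(params) {
  for (tr in treatments()) {
    for (lbl in names(params$complication_rates[[tr]])) {
      p <- params$complication_rates[[tr]][[lbl]]
      p$base <- 0; p$low <- 0
      params$complication_rates[[tr]][[lbl]] <- p
    }
  }
  params
}

# Collapse every sampled quantity to a point mass at its base value.
fix_all_parameters <- function(params) {
  fix <- function(x) {
    if (inherits(x, "dc_param")) { x$dist <- "fixed"; return(x) }
    if (is.list(x)) return(structure(lapply(x, fix), class = class(x)))
    x
  }
  fix(params)
}

# Frozen direct-cost components as printed, for independent re-summation.
printed_direct_components <- list(
  CCH = c(172.26, 5400.00, 209.02, 314.62),
  PNA = c(322.91, 673.57),
  LF  = c(1149.29, 245.00, 2623.34, 1394.35)
)

# Frozen (rate, cost) complication pairs as printed (rates as probabilities).
printed_complications <- list(
  CCH = cbind(rate = c(0.0038, 0.0156, 0.0026, 0.0397),
              cost = c(3479.56, 7987.00, 176.23, 75.32)),
  PNA = cbind(rate = c(0.0038, 0.0155, 0.0052, 0.0038, 0.0091),
              cost = c(3479.56, 2746.26, 2000.33, 5435.18, 3581.64)),
  LF  = cbind(rate = c(0.0017, 0.0113, 0.0128, 0.0216, 0.0095, 0.0128),
              cost = c(3479.56, 7987.00, 2746.26, 5435.18, 3581.64, 1658.78))
)

# The 24 printed transition-probability rows (base, low, high).
printed_transition_rows <- function(params) {
  out <- list()
  for (block in c("success", "recurrence")) {
    for (tr in treatments()) for (j in c("MCP", "PIP")) for (s in c("low", "high")) {
      out[[paste(block, tr, j, s, sep = ".")]] <-
        params$transitions[[block]][[tr]][[j]][[s]]
    }
  }
  out
}
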
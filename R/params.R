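#' Treatments for recurrent Dupuytren contracture
#'
#' The three interventions compared by the model, in the stable order used
#' for regimen enumeration: collagenase clostridium histolyticum injection
#' (`CCH`), percutaneous needle aponeurotomy (`PNA`) and limited fasciectomy
#' (`LF`).
#'
#' @return Character vector of the three treatment identifiers.
#' @export
#' @examples
#' treatments()
treatments <- function() c("CCH", "PNA", "LF")

#' Disease scenario (joint type and contracture severity)
#'
#' A scenario selects the transition-probability and utility entries used by
#' the simulation.  Contractures under 45 degrees from full extension are
#' "low" severity, above are "high" (the threshold is descriptive metadata;
#' contracture angle is not simulated).
#'
#' @param joint `"MCP"` (metacarpophalangeal) or `"PIP"`
#'   (proximal interphalangeal).
#' @param severity `"low"` or `"high"`.
#' @return An object of class `dc_scenario`.
#' @export
#' @examples
#' dc_scenario("MCP", "low")
dc_scenario <- function(joint = c("MCP", "PIP"), severity = c("low", "high")) {
  joint <- match.arg(joint)
  severity <- match.arg(severity)
  structure(list(joint = joint, severity = severity), class = "dc_scenario")
}

#' All four disease scenarios
#' @return List of the four `dc_scenario` objects (MCP/PIP x low/high).
#' @export
all_scenarios <- function() {
  out <- list()
  for (j in c("MCP", "PIP")) for (s in c("low", "high")) {
    out[[paste(j, s, sep = "_")]] <- dc_scenario(j, s)
  }
  out
}

#' @export
print.dc_scenario <- function(x, ...) {
  cat(sprintf("<scenario: %s joint, %s severity>\n", x$joint, x$severity))
  invisible(x)
}

## A single model input: base value with sensitivity bounds and the
## distribution family used for probabilistic sensitivity analysis.
param_value <- function(base, low, high, dist = c("beta", "normal", "uniform", "fixed")) {
  dist <- match.arg(dist)
  structure(list(base = base, low = low, high = high, dist = dist),
            class = "dc_param")
}

#' @export
print.dc_param <- function(x, ...) {
  cat(sprintf("%g [%g, %g] (%s)\n", x$base, x$low, x$high, x$dist))
  invisible(x)
}

is_param <- function(x) inherits(x, "dc_param")

pv <- param_value # internal shorthand for the defaults table

## Model defaults: every quantity of the published base-case input table.
## Percentages (complication rates, mortality) are stored as probabilities.
default_parameters <- function() {
  structure(list(
    age = pv(60, 45, 75, "uniform"),
    mortality = list(
      kind = "gompertz",
      h60 = 0.0087,      # annual all-cause mortality at age 60
      h45 = 0.0018,      # anchor at age 45 (printed low bound)
      high = 0.129,      # printed high bound (reached near age 86)
      max_age = 100,
      table = list()     # optional life-table override (age, probability)
    ),
    transitions = list(
      success = list(
        CCH = list(MCP = list(low = pv(0.61, 0.52, 0.71),
                              high = pv(0.39, 0.33, 0.45)),
                   PIP = list(low = pv(0.33, 0.28, 0.38),
                              high = pv(0.13, 0.11, 0.15))),
        PNA = list(MCP = list(low = pv(0.58, 0.49, 0.67),
                              high = pv(0.33, 0.28, 0.38)),
                   PIP = list(low = pv(0.37, 0.31, 0.43),
                              high = pv(0.21, 0.18, 0.24))),
        LF  = list(MCP = list(low = pv(0.71, 0.60, 0.82),
                              high = pv(0.61, 0.52, 0.70)),
                   PIP = list(low = pv(0.59, 0.50, 0.68),
                              high = pv(0.25, 0.21, 0.29)))
      ),
      recurrence = list(
        CCH = list(MCP = list(low = pv(0.25, 0.21, 0.29),
                              high = pv(0.25, 0.21, 0.29)),
                   PIP = list(low = pv(0.48, 0.41, 0.55),
                              high = pv(0.48, 0.41, 0.55))),
        PNA = list(MCP = list(low = pv(0.26, 0.22, 0.30),
                              high = pv(0.26, 0.22, 0.30)),
                   PIP = list(low = pv(0.40, 0.34, 0.46),
                              high = pv(0.40, 0.34, 0.46))),
        LF  = list(MCP = list(low = pv(0.18, 0.15, 0.21),
                              high = pv(0.18, 0.15, 0.21)),
                   PIP = list(low = pv(0.24, 0.20, 0.28),
                              high = pv(0.24, 0.20, 0.28)))
      )
    ),
    direct_costs = list(
      CCH = list(clinic_visit       = pv(172.26,  146.42,  198.10, "normal"),
                 medication         = pv(5400.00, 4590.00, 6210.00, "normal"),
                 manipulation_visit = pv(209.02,  177.67,  240.37, "normal"),
                 hand_therapy       = pv(314.62,  221.64,  407.60, "normal")),
      PNA = list(procedure          = pv(322.91,  274.47,  371.35, "normal"),
                 hand_therapy       = pv(673.57,  487.61,  859.53, "normal")),
      LF  = list(procedure          = pv(1149.29,  976.90, 1321.68, "normal"),
                 anesthesia         = pv(245.00,   208.25,  281.75, "normal"),
                 facility_fee       = pv(2623.34, 2229.84, 3016.84, "normal"),
                 hand_therapy       = pv(1394.35, 1115.41, 1859.25, "normal"))
    ),
    complication_costs = list(
      tendon_injury      = pv(3479.56, 2957.63, 4001.49, "normal"),
      admission          = pv(7987.00, 6788.95, 9185.05, "normal"),
      medication_allergy = pv(176.23,  149.80,  202.66,  "normal"),
      skin_tear          = pv(75.32,   64.02,   86.62,   "normal"),
      infection          = pv(2746.26, 2334.32, 3158.20, "normal"),
      crps               = pv(2000.33, 1700.28, 2300.38, "normal"),
      nerve_injury       = pv(5435.18, 4619.90, 6250.46, "normal"),
      artery_injury      = pv(3581.64, 3044.39, 4118.89, "normal"),
      hematoma           = pv(1658.78, 1409.96, 1907.60, "normal")
    ),
    complication_rates = list(
      CCH = list(tendon_injury      = pv(0.0038, 0.0034, 0.0046),
                 admission          = pv(0.0156, 0.0133, 0.0179),
                 medication_allergy = pv(0.0026, 0.0022, 0.0030),
                 skin_tear          = pv(0.0397, 0.0337, 0.0457)),
      PNA = list(tendon_injury      = pv(0.0038, 0.0032, 0.0044),
                 infection          = pv(0.0155, 0.0132, 0.0178),
                 crps               = pv(0.0052, 0.0044, 0.0060),
                 nerve_injury       = pv(0.0038, 0.0032, 0.0044),
                 artery_injury      = pv(0.0091, 0.0077, 0.0105)),
      LF  = list(tendon_injury      = pv(0.0017, 0.0014, 0.0020),
                 admission          = pv(0.0113, 0.0096, 0.0130),
                 infection          = pv(0.0128, 0.0109, 0.0147),
                 nerve_injury       = pv(0.0216, 0.0184, 0.0248),
                 artery_injury      = pv(0.0095, 0.0081, 0.0109),
                 hematoma           = pv(0.0128, 0.0109, 0.0147))
    ),
    days_off_work = list(
      CCH = pv(1,  0,  3,  "normal"),
      PNA = pv(1,  0,  14, "normal"),
      LF  = pv(37, 14, 60, "normal")
    ),
    utilities = list(
      symptomatic = list(
        MCP = list(low = pv(0.969, 0.824, 1.000),
                   high = pv(0.938, 0.891, 0.985)),
        PIP = list(low = pv(0.970, 0.922, 1.000),
                   high = pv(0.942, 0.895, 0.989))
      ),
      symptom_free = 1.0
    ),
    economics = list(
      discount_rate = 0.03,
      annual_income = 63179,   # 2018 US median income, USD
      working_days = 365,      # daily-wage divisor (calendar-day valuation)
      retirement_age = 65,     # wage loss applies below this age
      perspective = "societal",
      wtp = 1e5                # willingness-to-pay, USD/QALY
    ),
    severity_threshold_deg = 45
  ), class = "dc_parameters")
}

#' Load the model parameter set
#'
#' Returns the packaged base-case inputs (transition probabilities by
#' treatment, joint and severity; direct, indirect and complication costs;
#' utilities; discounting), optionally overridden by a YAML configuration
#' file whose keys mirror the parameter structure.  A scalar override
#' replaces a parameter's base value; a mapping with `base`/`low`/`high`
#' (and optionally `dist`) replaces those fields.  Unknown keys and
#' out-of-range values are rejected.
#'
#' @param config_path Optional path to a YAML override file.  See
#'   `system.file("extdata", "table1_defaults.yaml", package = "dupcea")` for
#'   the full schema with every default value.
#' @return A validated object of class `dc_parameters`.
#' @export
#' @examples
#' p <- load_parameters()
#' p$direct_costs$CCH$medication$base
load_parameters <- function(config_path = NULL) {
  params <- default_parameters()
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) {
      stop("config file not found: ", config_path)
    }
    overrides <- yaml::read_yaml(config_path)
    params <- apply_overrides(params, overrides)
  }
  validate_parameters(params)
  params
}

## Recursively merge a nested override list into the parameter set,
## rejecting keys that do not exist in the defaults.
apply_overrides <- function(params, overrides, path = character()) {
  if (!is.list(overrides)) stop("config overrides must be a mapping")
  for (key in names(overrides)) {
    here <- paste(c(path, key), collapse = ".")
    if (is.null(names(overrides)) || !nzchar(key)) {
      stop("config overrides must use named keys (at '",
           paste(path, collapse = "."), "')")
    }
    if (!key %in% names(params)) {
      stop("unknown configuration key: '", here, "'")
    }
    cur <- params[[key]]
    ov <- overrides[[key]]
    if (here == "mortality.table") {
      params[[key]] <- ov   # life table supplied wholesale
    } else if (is_param(cur)) {
      params[[key]] <- override_param(cur, ov, here)
    } else if (is.list(cur)) {
      params[[key]] <- apply_overrides(cur, ov, c(path, key))
    } else {
      if (!is.atomic(ov) || length(ov) != 1L) {
        stop("configuration key '", here, "' expects a single value")
      }
      params[[key]] <- ov
    }
  }
  params
}

override_param <- function(cur, ov, where) {
  if (is.numeric(ov) && length(ov) == 1L) {
    cur$base <- ov
    cur$low <- min(cur$low, ov)
    cur$high <- max(cur$high, ov)
  } else if (is.list(ov)) {
    bad <- setdiff(names(ov), c("base", "low", "high", "dist"))
    if (length(bad)) {
      stop("unknown field '", bad[[1L]], "' for parameter '", where, "'")
    }
    for (f in names(ov)) cur[[f]] <- ov[[f]]
  } else {
    stop("invalid override for parameter '", where, "'")
  }
  cur
}

## --- validation ---------------------------------------------------------

validate_parameters <- function(params) {
  stopifnot(inherits(params, "dc_parameters"))
  walk_params(params, function(p, path) {
    id <- paste(path, collapse = ".")
    if (!is.numeric(p$base) || !is.numeric(p$low) || !is.numeric(p$high)) {
      stop("parameter '", id, "' has non-numeric fields")
    }
    if (p$low > p$base || p$base > p$high) {
      stop("parameter '", id, "' violates low <= base <= high")
    }
    prob_like <- path[[1L]] %in% c("transitions", "complication_rates") ||
      (path[[1L]] == "utilities")
    if (prob_like) {
      if (p$base < 0 || p$base > 1 || p$low < 0 || p$high > 1) {
        stop("probability parameter '", id, "' outside [0, 1]")
      }
    }
    money_like <- path[[1L]] %in% c("direct_costs", "complication_costs")
    if (money_like && p$low < 0) {
      stop("cost parameter '", id, "' must be non-negative")
    }
    if (path[[1L]] == "days_off_work" && p$low < 0) {
      stop("days off work '", id, "' must be non-negative")
    }
  })
  econ <- params$economics
  for (key in c("discount_rate", "annual_income", "working_days",
                "retirement_age", "wtp")) {
    if (is.null(econ[[key]]) || !is.numeric(econ[[key]]) || econ[[key]] < 0) {
      stop("missing or invalid economics field: '", key, "'")
    }
  }
  if (!econ$perspective %in% c("societal", "health_sector")) {
    stop("perspective must be 'societal' or 'health_sector'")
  }
  m <- params$mortality
  if (is.null(m$kind) || !m$kind %in% c("gompertz", "table")) {
    stop("mortality kind must be 'gompertz' or 'table'")
  }
  u <- params$utilities
  for (j in c("MCP", "PIP")) for (s in c("low", "high")) {
    if (u$symptomatic[[j]][[s]]$base > u$symptom_free) {
      stop("symptomatic utility exceeds symptom-free utility (", j, "/", s, ")")
    }
  }
  invisible(params)
}

## Apply fn(param, path) to every dc_param leaf, depth first, in a fixed
## traversal order (list order of the defaults).
walk_params <- function(x, fn, path = character()) {
  if (is_param(x)) {
    fn(x, path)
  } else if (is.list(x)) {
    for (key in names(x)) walk_params(x[[key]], fn, c(path, key))
  }
  invisible(NULL)
}

#' Identifiers of all sweepable model parameters
#'
#' Dot-separated paths to every parameter that carries low/high sensitivity
#' bounds, usable with [set_param()] and [one_way_sweep()].
#'
#' @param params A `dc_parameters` object.
#' @return Character vector of parameter ids, in a fixed traversal order.
#' @export
#' @examples
#' head(param_ids(load_parameters()))
param_ids <- function(params) {
  ids <- character()
  walk_params(params, function(p, path) {
    ids[[length(ids) + 1L]] <<- paste(path, collapse = ".")
  })
  ids
}

#' Set a parameter's base value by id
#'
#' @param params A `dc_parameters` object.
#' @param id A dot-separated parameter id from [param_ids()].
#' @param value New base value (must respect the parameter's support).
#' @return The modified, re-validated parameter set.
#' @export
set_param <- function(params, id, value) {
  path <- strsplit(id, ".", fixed = TRUE)[[1L]]
  node <- params
  for (p in path) {
    if (!is.list(node) || !p %in% names(node)) {
      stop("unknown parameter id: '", id, "'")
    }
    node <- node[[p]]
  }
  if (!is_param(node)) stop("'", id, "' is not a sweepable parameter")
  node$base <- value
  node$low <- min(node$low, value)
  node$high <- max(node$high, value)
  params[[path]] <- node
  validate_parameters(params)
  params
}

get_param <- function(params, id) {
  path <- strsplit(id, ".", fixed = TRUE)[[1L]]
  node <- params
  for (p in path) node <- node[[p]]
  node
}

## --- derived cost aggregates -------------------------------------------

#' Direct cost of one treatment event
#'
#' Sum of a treatment's direct cost components at their base values (USD):
#' clinic visit, medication, manipulation visit and hand therapy for CCH;
#' procedure and hand therapy for PNA; procedure, anesthesia, facility fee
#' and hand therapy for LF.
#'
#' @param treatment `"CCH"`, `"PNA"` or `"LF"`.
#' @param params A `dc_parameters` object.
#' @return Direct cost in USD.
#' @export
#' @examples
#' direct_cost("LF", load_parameters())  # 5411.98
direct_cost <- function(treatment, params = load_parameters()) {
  treatment <- match.arg(treatment, treatments())
  sum(vapply(params$direct_costs[[treatment]], function(p) p$base, numeric(1)))
}

#' Expected complication cost of one treatment event
#'
#' Sum over the treatment's complication list of rate times cost, at base
#' values (USD).  Rates are stored as probabilities.
#'
#' @inheritParams direct_cost
#' @return Expected complication cost in USD.
#' @export
#' @examples
#' expected_complication_cost("CCH", load_parameters())  # about 141.27
expected_complication_cost <- function(treatment, params = load_parameters()) {
  treatment <- match.arg(treatment, treatments())
  rates <- params$complication_rates[[treatment]]
  sum(vapply(names(rates), function(lbl) {
    rates[[lbl]]$base * params$complication_costs[[lbl]]$base
  }, numeric(1)))
}

#' @export
print.dc_parameters <- function(x, ...) {
  cat("<dupcea parameter set>\n")
  cat(sprintf("  base age %g, discount rate %g, perspective %s\n",
              x$age$base, x$economics$discount_rate, x$economics$perspective))
  cat(sprintf("  annual income $%s over %g working days, retirement age %g\n",
              format(x$economics$annual_income, big.mark = ","),
              x$economics$working_days, x$economics$retirement_age))
  for (tr in treatments()) {
    cat(sprintf("  %s: direct $%.2f + expected complication $%.2f per event\n",
                tr, direct_cost(tr, x), expected_complication_cost(tr, x)))
  }
  cat(sprintf("  %d sweepable parameters\n", length(param_ids(x))))
  invisible(x)
}
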
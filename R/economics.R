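#' Net monetary benefit
#'
#' `NMB = lambda * e - c`: effectiveness valued at the willingness-to-pay
#' threshold minus cost.  The absolute form is used; differencing against any
#' common reference preserves the ranking.
#'
#' @param qaly Effectiveness (QALYs); vectorized.
#' @param cost Cost (USD); vectorized.
#' @param lambda Willingness-to-pay threshold in USD/QALY (default 100 000).
#' @return Net monetary benefit in USD.
#' @export
#' @examples
#' net_monetary_benefit(15.09, 3339)  # 1505661
net_monetary_benefit <- function(qaly, cost, lambda = 1e5) {
  stopifnot(lambda >= 0)
  lambda * qaly - cost
}

#' Efficiency frontier with extended dominance
#'
#' Classifies regimens on the cost-effectiveness plane: strictly dominated
#' options (another option costs no more and yields at least as many QALYs,
#' strictly better in one) and extended-dominated options (sequential ICERs
#' along the cost-sorted candidates fail to increase) are flagged; the
#' remaining frontier members get an ICER against the previous frontier
#' member, with the cheapest labeled the reference.  Net monetary benefit at
#' `lambda` is reported for every regimen so the NMB ranking can be compared
#' with the frontier.  Exact cost/QALY ties are broken by input order.
#'
#' @param x A `dc_grid` from [simulate_regimens()], or a data frame with
#'   columns `regimen`, `cost` (or `mean_cost`) and `qaly` (or `mean_qaly`).
#' @param lambda Willingness-to-pay threshold for the NMB column.
#' @return A `dc_frontier` data frame sorted by ascending cost with columns
#'   `regimen`, `cost`, `qaly`, `nmb`, `status`
#'   (`reference`/`frontier`/`dominated`/`extended_dominated`) and `icer`
#'   (USD/QALY; `NA` off the frontier and for the reference).
#' @export
#' @examples
#' toy <- data.frame(regimen = c("A", "B", "C"),
#'                   cost = c(0, 10, 5), qaly = c(0, 1, 0.2))
#' efficiency_frontier(toy)
efficiency_frontier <- function(x, lambda = 1e5) {
  if (inherits(x, "dc_grid")) {
    df <- data.frame(regimen = x$table$regimen, cost = x$table$mean_cost,
                     qaly = x$table$mean_qaly)
    scenario <- x$scenario
  } else {
    df <- as.data.frame(x)
    if (!"cost" %in% names(df)) df$cost <- df$mean_cost
    if (!"qaly" %in% names(df)) df$qaly <- df$mean_qaly
    df <- df[, c("regimen", "cost", "qaly")]
    scenario <- NULL
  }
  if (nrow(df) < 1L) stop("efficiency_frontier needs at least one regimen")
  n <- nrow(df)
  status <- rep("frontier", n)

  ## strict dominance (ties: first in input order wins)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dom <- df$cost[others] <= df$cost[i] & df$qaly[others] >= df$qaly[i] &
      (df$cost[others] < df$cost[i] | df$qaly[others] > df$qaly[i] |
         others < i)   # exact tie: earlier index dominates later
    if (any(dom)) status[i] <- "dominated"
  }

  ## extended dominance among remaining, sorted by ascending cost
  cand <- which(status == "frontier")
  cand <- cand[order(df$cost[cand], cand)]
  while (length(cand) > 2L) {
    ic <- diff(df$cost[cand]) / diff(df$qaly[cand])
    bad <- which(diff(ic) <= 0)          # ICER not strictly increasing
    if (!length(bad)) break
    drop <- cand[bad[[1L]] + 1L]         # the middle strategy of the triple
    status[drop] <- "extended_dominated"
    cand <- setdiff(cand, drop)
  }

  icer <- rep(NA_real_, n)
  if (length(cand) >= 1L) status[cand[[1L]]] <- "reference"
  if (length(cand) > 1L) {
    icer[cand[-1L]] <- diff(df$cost[cand]) / diff(df$qaly[cand])
  }
  out <- df
  out$nmb <- net_monetary_benefit(df$qaly, df$cost, lambda)
  out$status <- status
  out$icer <- icer
  out <- out[order(out$cost, seq_len(n)), ]
  rownames(out) <- NULL
  structure(out, class = c("dc_frontier", "data.frame"),
            lambda = lambda, scenario = scenario)
}

#' Regimen with the highest net monetary benefit
#' @param x A `dc_frontier` or `dc_grid`.
#' @param lambda Willingness-to-pay threshold.
#' @return The regimen label with maximal NMB (ties: first by input order).
#' @export
nmb_optimal <- function(x, lambda = 1e5) {
  if (inherits(x, "dc_grid")) x <- efficiency_frontier(x, lambda)
  nmb <- net_monetary_benefit(x$qaly, x$cost, lambda)
  x$regimen[[which.max(nmb)]]
}

#' @export
print.dc_frontier <- function(x, ...) {
  lam <- attr(x, "lambda") %||% 1e5
  cat(sprintf("<efficiency frontier, lambda = $%s/QALY>\n",
              format(lam, big.mark = ",")))
  df <- as.data.frame(x)
  for (col in intersect(c("cost", "nmb", "icer"), names(df))) {
    df[[col]] <- round(df[[col]])
  }
  print(df, row.names = FALSE)
  if (all(c("qaly", "cost") %in% names(df))) {
    cat("NMB-optimal:", nmb_optimal(x, lam), "\n")
  }
  invisible(x)
}

#' @export
plot.dc_frontier <- function(x, ...) {
  on_front <- x$status %in% c("reference", "frontier")
  graphics::plot(x$qaly, x$cost, xlab = "QALYs", ylab = "Cost (USD)",
                 pch = ifelse(on_front, 19, 1), ...)
  graphics::lines(x$qaly[on_front], x$cost[on_front], col = "grey40")
  graphics::text(x$qaly[on_front], x$cost[on_front], x$regimen[on_front],
                 pos = 4, cex = 0.7)
  invisible(x)
}

#' Monte Carlo standard error of an ICER by paired bootstrap
#'
#' Resamples patients (preserving the common-random-number pairing between
#' the two regimens), recomputes the ICER on each bootstrap replicate, and
#' reports the standard deviation of the replicates.  If the sign of the
#' QALY difference is unstable across replicates the ICER is poorly defined
#' and a warning is issued.
#'
#' @param ref,alt `dc_cohort` objects with retained patients, simulated with
#'   common random numbers, or a `dc_grid` as `ref` with `alt` and `alt2`
#'   naming the two regimen columns.
#' @param alt2 Second regimen label when `ref` is a `dc_grid`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @return List with `icer` (point estimate), `mcse`, `n_boot` and
#'   `dq_sign_stable`.
#' @export
icer_mcse <- function(ref, alt, alt2 = NULL, n_boot = 1000L, seed = NULL) {
  if (inherits(ref, "dc_grid")) {
    stopifnot(is.character(alt), is.character(alt2))
    cost_r <- ref$cost[, alt]; qaly_r <- ref$qaly[, alt]
    cost_a <- ref$cost[, alt2]; qaly_a <- ref$qaly[, alt2]
  } else {
    stopifnot(inherits(ref, "dc_cohort"), inherits(alt, "dc_cohort"),
              !is.null(ref$patients), !is.null(alt$patients),
              ref$n == alt$n)
    cost_r <- ref$patients$cost; qaly_r <- ref$patients$qaly
    cost_a <- alt$patients$cost; qaly_a <- alt$patients$qaly
  }
  n <- length(cost_r)
  dcst <- cost_a - cost_r
  dq <- qaly_a - qaly_r
  icer <- mean(dcst) / mean(dq)
  if (!is.null(seed)) set.seed(seed)
  reps <- numeric(n_boot)
  dq_means <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    dq_means[[b]] <- mean(dq[idx])
    reps[[b]] <- mean(dcst[idx]) / dq_means[[b]]
  }
  stable <- all(sign(dq_means) == sign(mean(dq)))
  if (!stable) {
    warning("bootstrap QALY difference changes sign; ICER MCSE is unreliable")
  }
  list(icer = icer, mcse = stats::sd(reps), n_boot = n_boot,
       dq_sign_stable = stable)
}
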
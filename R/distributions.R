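#' Fit a sampling distribution to a model parameter
#'
#' Builds the distribution used to propagate a parameter's uncertainty in
#' probabilistic sensitivity analysis.  Distributions are parameterized so
#' that approximately 95% of the mass lies between the parameter's low and
#' high bounds:
#'
#' * `beta`: mean fixed at the base value; the effective number of
#'   pseudo-observations is solved numerically so the central 95% interval
#'   width matches `high - low` (a normal-approximation start refined with
#'   [stats::uniroot()]).  For the transition-probability rows this yields
#'   roughly one hundred pseudo-observations.
#' * `normal`: mean equal to the base value, `sd = (high - low) / (2 * 1.96)`,
#'   truncated below at 0 (and above at 1 when the quantity is a probability
#'   or utility).
#' * `uniform`: supported on `[low, high]`.
#' * `fixed` (or degenerate bounds): a point mass at the base value.
#'
#' @param value A `dc_param` (base/low/high/dist), e.g. from
#'   [load_parameters()].
#' @param upper Optional upper truncation for the normal kind (e.g. 1 for a
#'   proportion); default `Inf`.
#' @return An object of class `dc_dist` with elements `kind` and the
#'   kind-specific parameters; query it with [dist_mean()], draw from it with
#'   [sample_dist()].
#' @export
#' @examples
#' p <- load_parameters()
#' d <- fit_distribution(p$transitions$success$CCH$MCP$low)
#' dist_mean(d)
fit_distribution <- function(value, upper = Inf) {
  stopifnot(inherits(value, "dc_param"))
  base <- value$base; low <- value$low; high <- value$high
  if (value$dist == "fixed" || low == high) {
    return(structure(list(kind = "fixed", value = base), class = "dc_dist"))
  }
  if (low > high) stop("low bound exceeds high bound")
  z95 <- 2 * stats::qnorm(0.975)   # central 95% width in sd units
  out <- switch(value$dist,
    beta = {
      if (base <= 0 || base >= 1) {
        stop("beta distribution requires base in (0, 1); got ", base)
      }
      width <- high - low
      m0 <- base * (1 - base) * (z95 / width)^2
      f <- function(m) {
        stats::qbeta(0.975, base * m, (1 - base) * m) -
          stats::qbeta(0.025, base * m, (1 - base) * m) - width
      }
      m <- tryCatch(
        stats::uniroot(f, lower = m0 / 64, upper = m0 * 64, tol = 1e-8)$root,
        error = function(e) m0)
      list(kind = "beta", shape1 = base * m, shape2 = (1 - base) * m)
    },
    normal = {
      sd <- (high - low) / z95
      list(kind = "truncnorm", mean = base, sd = sd, lower = 0, upper = upper)
    },
    uniform = list(kind = "uniform", min = low, max = high),
    stop("unsupported distribution kind: ", value$dist)
  )
  structure(out, class = "dc_dist")
}

#' Draw from a fitted parameter distribution
#'
#' Sampling is by inverse CDF, so supplying `u` makes draws a deterministic
#' function of the uniforms (used for common-random-number designs).
#'
#' @param dist A `dc_dist` from [fit_distribution()].
#' @param n Number of draws (ignored when `u` is given).
#' @param u Optional uniform(0,1) variates to transform.
#' @return Numeric vector of draws, guaranteed inside the support.
#' @export
sample_dist <- function(dist, n = 1L, u = NULL) {
  stopifnot(inherits(dist, "dc_dist"))
  if (is.null(u)) u <- stats::runif(n)
  switch(dist$kind,
    fixed = rep(dist$value, length(u)),
    beta = stats::qbeta(u, dist$shape1, dist$shape2),
    truncnorm = {
      plo <- stats::pnorm(dist$lower, dist$mean, dist$sd)
      phi <- stats::pnorm(dist$upper, dist$mean, dist$sd)
      stats::qnorm(plo + u * (phi - plo), dist$mean, dist$sd)
    },
    uniform = dist$min + u * (dist$max - dist$min),
    stop("unknown distribution kind")
  )
}

#' Mean of a fitted parameter distribution
#'
#' For the truncated normal this is the post-truncation mean.
#'
#' @inheritParams sample_dist
#' @return The distribution mean.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "dc_dist"))
  switch(dist$kind,
    fixed = dist$value,
    beta = dist$shape1 / (dist$shape1 + dist$shape2),
    truncnorm = {
      a <- (dist$lower - dist$mean) / dist$sd
      b <- (dist$upper - dist$mean) / dist$sd
      dist$mean + dist$sd * (stats::dnorm(a) - stats::dnorm(b)) /
        (stats::pnorm(b) - stats::pnorm(a))
    },
    uniform = (dist$min + dist$max) / 2
  )
}

#' Central interval of a fitted parameter distribution
#' @inheritParams sample_dist
#' @param level Coverage level, default 0.95.
#' @return Length-2 numeric vector (lower, upper).
#' @export
dist_interval <- function(dist, level = 0.95) {
  q <- c((1 - level) / 2, 1 - (1 - level) / 2)
  sample_dist(dist, u = q)   # inverse CDF at the central quantiles
}

#' @export
print.dc_dist <- function(x, ...) {
  cat("<dc_dist ", x$kind, ": ",
      paste(sprintf("%s=%g", setdiff(names(x), "kind"),
                    unlist(x[setdiff(names(x), "kind")])), collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}
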
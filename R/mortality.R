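#' Age-dependent background mortality model
#'
#' Annual probability of death from any cause, anchored to the model's
#' printed values: 0.87% per year at age 60, 0.18% at age 45.  The default is
#' a Gompertz curve through those two anchors,
#' `h(a) = h60 * exp(slope * (a - 60))` with
#' `slope = log(h60 / h45) / 15` (about 0.105 per year), clipped to 1 and
#' forced to 1 at `max_age`.  A user-supplied life table (columns `age`,
#' `probability`) can replace the curve; ages between table rows use the last
#' listed value.
#'
#' @param kind `"gompertz"` (default) or `"table"`.
#' @param h60,h45 Anchor annual mortality probabilities at ages 60 and 45.
#' @param table Data frame with columns `age` and `probability` (required for
#'   `kind = "table"`; may also be a path to a two-column CSV).
#' @param max_age Age at which death becomes certain (default 100).
#' @return An object of class `dc_mortality`.
#' @export
#' @examples
#' m <- mortality_model()
#' annual_mortality(60, m)  # 0.0087
mortality_model <- function(kind = c("gompertz", "table"),
                            h60 = 0.0087, h45 = 0.0018,
                            table = NULL, max_age = 100) {
  kind <- match.arg(kind)
  if (kind == "table") {
    if (is.character(table)) table <- utils::read.csv(table)
    if (is.null(table) || !all(c("age", "probability") %in% names(table))) {
      stop("a table mortality model needs columns 'age' and 'probability'")
    }
    table <- table[order(table$age), , drop = FALSE]
    if (any(table$probability < 0 | table$probability > 1)) {
      stop("life-table probabilities must be in [0, 1]")
    }
    if (is.unsorted(table$probability)) {
      stop("life-table probabilities must be non-decreasing with age")
    }
  }
  if (h60 <= 0 || h45 <= 0 || h45 > h60) {
    stop("anchors must satisfy 0 < h45 <= h60")
  }
  structure(list(kind = kind, h60 = h60, h45 = h45,
                 slope = log(h60 / h45) / 15,
                 table = table, max_age = max_age),
            class = "dc_mortality")
}

## Build a dc_mortality from the parameter set's mortality block.
mortality_from_params <- function(params) {
  m <- params$mortality
  tab <- m$table
  if (is.list(tab) && length(tab)) tab <- as.data.frame(tab) else tab <- NULL
  mortality_model(kind = if (!is.null(tab)) "table" else m$kind,
                  h60 = m$h60, h45 = m$h45, table = tab,
                  max_age = m$max_age)
}

#' Annual probability of death at a given age
#'
#' @param age Age in years (vectorized, must be non-negative).
#' @param model A `dc_mortality` from [mortality_model()].
#' @return Annual death probability, in `[0, 1]`, equal to 1 at and above the
#'   model's `max_age`.
#' @export
#' @examples
#' annual_mortality(c(45, 60, 85), mortality_model())
annual_mortality <- function(age, model = mortality_model()) {
  stopifnot(inherits(model, "dc_mortality"))
  if (any(age < 0)) stop("age must be non-negative")
  h <- if (model$kind == "gompertz") {
    pmin(1, model$h60 * exp(model$slope * (age - 60)))
  } else {
    tab <- model$table
    idx <- findInterval(age, tab$age)
    out <- numeric(length(age))
    out[idx >= 1] <- tab$probability[idx[idx >= 1]]
    out[idx < 1] <- tab$probability[1L]   # below table start: first row
    out
  }
  h[age >= model$max_age] <- 1
  h
}

## n x T matrix of annual death probabilities for patients with the given
## start ages over T cycles.
mortality_matrix <- function(start_age, T, model) {
  outer(start_age, seq_len(T) - 1L,
        function(a, t) annual_mortality(a + t, model))
}

#' Survival curve and life expectancy under a mortality model
#'
#' Probability of being alive at the start of each annual cycle, and the
#' implied (optionally discounted) expected life-years, under the package's
#' cycle accounting: everyone alive at the start of a cycle lives (and
#' accrues) that full year; the death draw takes effect at the cycle's end.
#'
#' @param model A `dc_mortality`.
#' @param start_age Starting age in years.
#' @param discount_rate Annual discount rate (0 for undiscounted).
#' @return List with `cycles`, `survival` (P(alive at cycle start)) and
#'   `life_years` (sum of discounted survival).
#' @export
life_expectancy <- function(model = mortality_model(), start_age = 60,
                            discount_rate = 0) {
  T <- max(1L, ceiling(model$max_age - start_age) + 1L)
  h <- annual_mortality(start_age + seq_len(T) - 1L, model)
  surv <- c(1, cumprod(1 - h))[seq_len(T)]
  df <- (1 + discount_rate)^-(seq_len(T) - 1L)
  list(cycles = seq_len(T) - 1L, survival = surv,
       life_years = sum(df * surv))
}

#' @export
print.dc_mortality <- function(x, ...) {
  if (x$kind == "gompertz") {
    cat(sprintf("<Gompertz mortality: h(60)=%.4f, slope=%.5f/yr, max age %g>\n",
                x$h60, x$slope, x$max_age))
  } else {
    cat(sprintf("<life-table mortality: %d rows, max age %g>\n",
                nrow(x$table), x$max_age))
  }
  invisible(x)
}
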
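test_that("net monetary benefit is lambda * e - c", {
  expect_equal(net_monetary_benefit(15.09, 3339, 1e5), 1505661)
  expect_equal(net_monetary_benefit(c(1, 1), c(5, 5), 0), c(-5, -5))
  # lambda = 0 ranks by cost alone
  q <- c(2, 9, 4); cst <- c(10, 30, 20)
  expect_identical(order(net_monetary_benefit(q, cst, 0), decreasing = TRUE),
                   order(cst))
  expect_error(net_monetary_benefit(1, 1, -5))
})

test_that("the toy frontier flags extended dominance correctly", {
  toy <- data.frame(regimen = c("A", "B", "C"),
                    cost = c(0, 10, 5), qaly = c(0, 1, 0.2))
  fr <- efficiency_frontier(toy, lambda = 1)
  expect_identical(fr$status[fr$regimen == "A"], "reference")
  expect_identical(fr$status[fr$regimen == "C"], "extended_dominated")
  expect_identical(fr$status[fr$regimen == "B"], "frontier")
  expect_equal(fr$icer[fr$regimen == "B"], 10)
  expect_true(is.na(fr$icer[fr$regimen == "C"]))
  # brute-force check of C's exclusion: its own ICER (25) exceeds the next step
  expect_gt((5 - 0) / (0.2 - 0), (10 - 5) / (1 - 0.2))
})

test_that("strict dominance and single-option edge cases", {
  fr <- efficiency_frontier(data.frame(regimen = "only", cost = 3, qaly = 1))
  expect_identical(fr$status, "reference")
  expect_true(is.na(fr$icer))
  expect_error(efficiency_frontier(data.frame(regimen = character(),
                                              cost = numeric(),
                                              qaly = numeric())),
               "at least one")
  dom <- data.frame(regimen = c("good", "bad"),
                    cost = c(5, 8), qaly = c(2, 1.5))
  fr2 <- efficiency_frontier(dom)
  expect_identical(fr2$status[fr2$regimen == "bad"], "dominated")
  # exact ties: first by input order wins
  tie <- data.frame(regimen = c("first", "twin"),
                    cost = c(5, 5), qaly = c(2, 2))
  fr3 <- efficiency_frontier(tie)
  expect_identical(fr3$status[fr3$regimen == "first"], "reference")
  expect_identical(fr3$status[fr3$regimen == "twin"], "dominated")
})

test_that("frontier ICERs increase strictly and NMB-optimal lies on the frontier", {
  set.seed(55)
  for (rep in 1:40) {
    k <- sample(3:12, 1)
    df <- data.frame(regimen = paste0("r", seq_len(k)),
                     cost = round(runif(k, 0, 3e4)),
                     qaly = round(runif(k, 10, 16), 2))
    lam <- sample(c(0, 5e4, 1e5, 3e5), 1)
    fr <- efficiency_frontier(df, lambda = lam)
    ic <- fr$icer[!is.na(fr$icer)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
    opt <- nmb_optimal(fr, lam)
    expect_true(fr$status[fr$regimen == opt] %in% c("reference", "frontier"))
    # independent NMB ranking agrees
    nmb_by_hand <- lam * df$qaly - df$cost
    expect_identical(opt, df$regimen[[which.max(nmb_by_hand)]])
  }
})

test_that("rounded published means give the expected step ICER", {
  step <- data.frame(regimen = c("PNA-PNA-PNA", "PNA-PNA-LF"),
                     cost = c(3512, 11225), qaly = c(14.64, 14.72))
  fr <- efficiency_frontier(step)
  expect_equal(fr$icer[fr$regimen == "PNA-PNA-LF"],
               (11225 - 3512) / (14.72 - 14.64), tolerance = 1e-9)
  expect_equal(fr$icer[fr$regimen == "PNA-PNA-LF"], 96412.5, tolerance = 1e-6)
})

test_that("ICER MCSE: zero-variance inputs give zero", {
  mk <- function(cost, qaly) {
    structure(list(n = length(cost),
                   patients = data.frame(cost = cost, qaly = qaly)),
              class = "dc_cohort")
  }
  a <- mk(rep(10, 6), rep(1, 6))
  b <- mk(rep(30, 6), rep(2, 6))
  out <- icer_mcse(a, b, n_boot = 200, seed = 1)
  expect_equal(out$icer, 20)
  expect_equal(out$mcse, 0)
  expect_true(out$dq_sign_stable)
})

test_that("ICER MCSE matches exhaustive resample enumeration at tiny n", {
  mk <- function(cost, qaly) {
    structure(list(n = length(cost),
                   patients = data.frame(cost = cost, qaly = qaly)),
              class = "dc_cohort")
  }
  cost_r <- c(10, 12, 9, 11, 10); qaly_r <- c(1.0, 1.2, 0.9, 1.1, 1.0)
  cost_a <- c(30, 29, 33, 31, 30); qaly_a <- c(2.1, 2.0, 2.4, 2.2, 2.1)
  # exhaustive bootstrap distribution: all 5^5 ordered resamples, equally likely
  idx <- as.matrix(expand.grid(rep(list(1:5), 5)))
  dcst <- cost_a - cost_r; dq <- qaly_a - qaly_r
  icers <- apply(idx, 1, function(ii) mean(dcst[ii]) / mean(dq[ii]))
  exact_sd <- sqrt(mean((icers - mean(icers))^2))
  out <- icer_mcse(mk(cost_r, qaly_r), mk(cost_a, qaly_a),
                   n_boot = 6000, seed = 42)
  expect_equal(out$mcse, exact_sd, tolerance = 0.1)
  # doubling the replicates moves the estimate by little
  out2 <- icer_mcse(mk(cost_r, qaly_r), mk(cost_a, qaly_a),
                    n_boot = 12000, seed = 43)
  expect_lt(abs(out2$mcse - out$mcse) / out$mcse, 0.1)
})

test_that("unstable QALY-difference signs raise a warning", {
  mk <- function(cost, qaly) {
    structure(list(n = length(cost),
                   patients = data.frame(cost = cost, qaly = qaly)),
              class = "dc_cohort")
  }
  set.seed(9)
  a <- mk(runif(40, 9, 11), rnorm(40, 1, 1))
  b <- mk(runif(40, 28, 32), rnorm(40, 1.02, 1))
  expect_warning(icer_mcse(a, b, n_boot = 400, seed = 2), "sign")
})
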
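test_that("sweeping a parameter no compared regimen uses changes nothing", {
  p <- load_parameters()
  sw <- one_way_sweep("complication_rates.CCH.skin_tear", p,
                      dc_scenario("MCP", "low"), n = 300, seed = 4,
                      regimens = c("PNA-PNA-PNA", "LF-LF-LF", "PNA-LF-PNA"))
  expect_equal(sw$nmb[, "low"], sw$nmb[, "base"], tolerance = 1e-12)
  expect_equal(sw$nmb[, "high"], sw$nmb[, "base"], tolerance = 1e-12)
})

test_that("the base setting of a sweep reproduces the base-case optimum", {
  p <- load_parameters()
  sc <- dc_scenario("PIP", "low")
  g <- simulate_regimens(sc, p, n = 1500, seed = 10)
  base_opt <- nmb_optimal(g)
  sw <- one_way_sweep("direct_costs.LF.facility_fee", p, sc,
                      n = 1500, seed = 10)
  expect_identical(sw$optimal[["base"]], base_opt)
  spread <- owsa_spread(sw, "PNA-PNA-PNA", "LF-LF-LF")
  expect_gt(spread[["spread"]], 0)   # LF-sensitive parameter moves the gap
})

test_that("a 5% lower symptomatic utility makes a PNA/LF combination cost-effective (low-severity MCP)", {
  p <- load_parameters()
  u <- p$utilities$symptomatic$MCP$low$base
  p2 <- set_param(p, "utilities.symptomatic.MCP.low", 0.95 * u)
  ev <- t(vapply(enumerate_regimens(), function(rg)
    expected_value_recursion(rg, dc_scenario("MCP", "low"), p2), numeric(3)))
  fr <- efficiency_frontier(data.frame(regimen = rownames(ev),
                                       cost = ev[, "cost"],
                                       qaly = ev[, "qaly"]))
  pl_only <- !grepl("CCH", fr$regimen) & fr$regimen != "PNA-PNA-PNA"
  expect_true(any(pl_only & !is.na(fr$icer) & fr$icer < 1e5))
})

test_that("raising LF success narrows the LF vs PNA gap in severe MCP disease", {
  p <- load_parameters()
  sw <- one_way_sweep("transitions.success.LF.MCP.high", p,
                      dc_scenario("MCP", "high"), n = 4000, seed = 6,
                      regimens = c("PNA-PNA-PNA", "LF-LF-LF", "PNA-PNA-LF"))
  gap <- function(setting) sw$nmb["LF-LF-LF", setting] -
    sw$nmb["PNA-PNA-PNA", setting]
  expect_gt(gap("high"), gap("base"))
  expect_gt(gap("base"), gap("low"))
})

test_that("point-mass distributions collapse the PSA onto the base case", {
  p <- fix_all_parameters(load_parameters())
  psa <- run_psa(p, dc_scenario("MCP", "low"), n_draws = 400,
                 patients_per_draw = 1, seed = 15,
                 regimens = c("PNA-PNA-PNA", "LF-LF-LF"))
  base <- load_parameters()
  for (id in names(psa$draws)) {
    expect_equal(unname(range(psa$draws[[id]])),
                 rep(dupcea:::get_param(base, if (id == "age") "age" else id)$base, 2),
                 tolerance = 1e-12, label = id)
  }
  # cohort means agree with the base-case expectation within Monte Carlo error
  ev <- expected_value_recursion("PNA-PNA-PNA", dc_scenario("MCP", "low"), base)
  se <- sd(psa$cost[, 1]) / sqrt(psa$n_draws)
  expect_lt(abs(mean(psa$cost[, 1]) - ev[["cost"]]), 4 * se)
})

test_that("sampled parameters stay in support with means near the fitted means", {
  p <- load_parameters()
  psa <- run_psa(p, dc_scenario("PIP", "low"), n_draws = 10000,
                 patients_per_draw = 1, seed = 16,
                 regimens = "PNA-PNA-PNA")
  draws <- psa$draws
  for (id in grep("transitions|complication_rates|utilities",
                  names(draws), value = TRUE)) {
    expect_true(all(draws[[id]] >= 0 & draws[[id]] <= 1), label = id)
  }
  for (id in grep("costs|days_off", names(draws), value = TRUE)) {
    expect_true(all(draws[[id]] >= 0), label = id)
  }
  expect_true(all(draws$age >= 45 & draws$age <= 75))
  for (id in names(draws)) {
    pv <- dupcea:::get_param(p, if (id == "age") "age" else id)
    d <- fit_distribution(pv, upper = if (grepl("utilities", id)) 1 else Inf)
    se <- sd(draws[[id]]) / sqrt(length(draws[[id]]))
    expect_lt(abs(mean(draws[[id]]) - dist_mean(d)), 4 * se, label = id)
  }
})

test_that("acceptability probabilities partition the draws at every threshold", {
  p <- load_parameters()
  psa <- run_psa(p, dc_scenario("MCP", "high"), n_draws = 1500,
                 patients_per_draw = 1, seed = 17)
  cc <- ceac(psa)
  expect_equal(unname(rowSums(cc$probability)), rep(1, length(cc$wtp)),
               tolerance = 1e-9)
  long <- as.data.frame(cc)
  expect_identical(nrow(long), length(cc$wtp) * 27L)
})

test_that("at lambda = 0 the cheapest regimen per draw wins", {
  p <- load_parameters()
  psa <- run_psa(p, dc_scenario("MCP", "low"), n_draws = 2000,
                 patients_per_draw = 1, seed = 18)
  cc <- ceac(psa, wtp_grid = 0)
  # independent cost-only oracle with the same tie rule
  win <- max.col(-psa$cost, ties.method = "first")
  oracle <- tabulate(win, nbins = 27) / psa$n_draws
  expect_equal(unname(cc$probability[1, ]), oracle, tolerance = 1e-12)
  expect_gt(cc$probability[1, "PNA-PNA-PNA"], 0.8)
})

test_that("the chance repeated PNA is optimal declines as willingness to pay rises", {
  p <- load_parameters()
  for (sc in all_scenarios()) {
    psa <- run_psa(p, sc, n_draws = 4000, patients_per_draw = 1, seed = 19)
    cc <- ceac(psa, wtp_grid = seq(0, 3e5, by = 5e4))
    ppp <- cc$probability[, "PNA-PNA-PNA"]
    # non-increasing up to small-sample wiggle
    expect_lt(max(diff(ppp)), 0.015,
              label = paste(sc$joint, sc$severity))
    expect_lt(ppp[[length(ppp)]], ppp[[1L]])
  }
})

test_that("two-level PSA averages patients within each draw", {
  p <- load_parameters()
  psa <- run_psa(p, dc_scenario("MCP", "low"), n_draws = 150,
                 patients_per_draw = 4, seed = 20,
                 regimens = c("PNA-PNA-PNA", "LF-LF-LF"))
  expect_identical(dim(psa$cost), c(150L, 2L))
  # averaging reduces between-draw spread relative to single patients
  psa1 <- run_psa(p, dc_scenario("MCP", "low"), n_draws = 150,
                  patients_per_draw = 1, seed = 20,
                  regimens = c("PNA-PNA-PNA", "LF-LF-LF"))
  expect_lt(sd(psa$qaly[, 1]), sd(psa1$qaly[, 1]))
})
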
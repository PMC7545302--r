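test_that("all 27 ordered regimens are enumerated exactly once", {
  regs <- enumerate_regimens()
  expect_length(regs, 27L)
  expect_false(anyDuplicated(regs) > 0)
  expect_true(all(c("PNA-PNA-PNA", "LF-LF-LF") %in% regs))
  # brute-force Cartesian product
  brute <- character()
  for (a in treatments()) for (b in treatments()) for (c in treatments()) {
    brute <- c(brute, paste(a, b, c, sep = "-"))
  }
  expect_setequal(regs, brute)
  expect_error(as_regimen("PNA-PNA"), "exactly 3")
  expect_error(as_regimen(c("PNA", "XXX", "LF")), "exactly 3")
})

test_that("degenerate probabilities give the hand-computable patient paths", {
  p <- zero_complications(load_parameters())
  p$economics$discount_rate <- 0
  sc <- dc_scenario("MCP", "low")

  # certain success, no recurrence, death at end of cycle 2:
  # one treatment, then symptom-free until death (3 accrued years)
  p1 <- set_all_transitions(p, succ = 1, recur = 0)
  r1 <- simulate_patient("PNA-PNA-PNA", sc, p1, seed = 5,
                         mortality = death_at_cycle(2))
  expect_identical(sum(r1$events$event == "treatment"), 1L)
  expect_equal(r1$qaly, 3 * p$utilities$symptom_free)
  expect_true(is.na(r1$time_to_first_recurrence))

  # certain failure, death at end of cycle 5: treatments at cycles 0,1,2;
  # every accrued year symptomatic
  p2 <- set_all_transitions(p, succ = 0, recur = 0)
  p2$economics$perspective <- "health_sector"   # isolate direct costs
  r2 <- simulate_patient("CCH-PNA-LF", sc, p2, seed = 5,
                         mortality = death_at_cycle(5))
  tr_ev <- r2$events[r2$events$event == "treatment", ]
  expect_equal(tr_ev$cycle, c(0, 1, 2))
  expect_identical(tr_ev$detail, c("CCH", "PNA", "LF"))
  expect_equal(r2$cost, direct_cost("CCH", p) + direct_cost("PNA", p) +
                 direct_cost("LF", p), tolerance = 1e-9)
  expect_equal(r2$qaly, 6 * p$utilities$symptomatic$MCP$low$base)
})

test_that("costs discount as (1+r)^-cycle with t = 0 for the first cycle", {
  p <- zero_complications(load_parameters())
  p$economics$perspective <- "health_sector"
  sc <- dc_scenario("MCP", "low")
  # success then certain recurrence: treatments land on cycles 0 and 2
  p3 <- set_all_transitions(p, succ = 1, recur = 1)
  r3 <- simulate_patient("PNA-LF-CCH", sc, p3, seed = 5,
                         mortality = death_at_cycle(2))
  expect_equal(r3$cost,
               direct_cost("PNA", p) + direct_cost("LF", p) / 1.03^2,
               tolerance = 1e-9)
})

test_that("the vectorized engine agrees exactly with the scalar reference", {
  p <- load_parameters()
  sc <- dc_scenario("PIP", "high")
  mort <- dupcea:::mortality_from_params(p)
  Tm <- dupcea:::sim_horizon(60, mort)
  n <- 40L
  st <- dupcea:::make_streams(n, Tm, seed = 7)
  co <- simulate_cohort("CCH-PNA-LF", sc, p, n = n, streams = st)
  for (i in seq_len(n)) {
    sti <- list(n = 1L, T = Tm,
                mort = st$mort[i, , drop = FALSE],
                event = st$event[i, , drop = FALSE],
                comp = array(st$comp[i, , ], c(1, 3, 6)))
    ri <- simulate_patient("CCH-PNA-LF", sc, p, streams = sti)
    expect_equal(ri$cost, co$patients$cost[i], tolerance = 1e-12)
    expect_equal(ri$qaly, co$patients$qaly[i], tolerance = 1e-12)
    expect_equal(ri$time_to_first_recurrence,
                 co$patients$time_to_first_recurrence[i])
  }
})

test_that("identical seeds give bit-identical cohort results", {
  sc <- dc_scenario("MCP", "high")
  a <- simulate_cohort("PNA-PNA-LF", sc, n = 500, seed = 99)
  b <- simulate_cohort("PNA-PNA-LF", sc, n = 500, seed = 99)
  expect_identical(a, b)
  c <- simulate_cohort("PNA-PNA-LF", sc, n = 500, seed = 100)
  expect_false(identical(a$mean_cost, c$mean_cost))
})

test_that("event logs are well-formed: bounded treatments, ordered times, absorbing death", {
  p <- load_parameters()
  set.seed(31)
  for (i in 1:25) {
    r <- simulate_patient("CCH-LF-PNA", dc_scenario("PIP", "low"), p)
    ev <- r$events
    expect_lte(sum(ev$event == "treatment"), 3L)
    expect_true(!is.unsorted(ev$cycle))
    if (any(ev$event == "death")) {
      expect_identical(which(ev$event == "death"), nrow(ev))
    }
    expect_lte(sum(ev$event == "success"), sum(ev$event == "treatment"))
  }
})

test_that("QALYs are bounded by discounted life-years and the annuity bound", {
  p <- load_parameters()
  co <- simulate_cohort("CCH-CCH-CCH", dc_scenario("PIP", "high"), p,
                        n = 2000, seed = 12)
  expect_true(all(co$patients$qaly <= co$patients$dly + 1e-9))
  r <- p$economics$discount_rate
  horizon <- 100 - 60 + 1
  annuity <- (1 - (1 + r)^-horizon) / (r / (1 + r))
  expect_true(all(co$patients$dly <= annuity + 1e-9))
  expect_true(all(co$patients$cost >= 0))
})

test_that("with all utilities at 1, QALYs equal discounted life-years for every regimen", {
  p <- load_parameters()
  for (j in c("MCP", "PIP")) for (s in c("low", "high")) {
    u <- p$utilities$symptomatic[[j]][[s]]
    u$base <- 1; u$high <- 1
    p$utilities$symptomatic[[j]][[s]] <- u
  }
  sc <- dc_scenario("MCP", "low")
  g <- simulate_regimens(sc, p, n = 400, seed = 8,
                         regimens = c("PNA-PNA-PNA", "LF-LF-LF", "CCH-LF-PNA"))
  # same mortality stream under common random numbers: identical QALY columns
  expect_equal(g$qaly[, 1], g$qaly[, 2], tolerance = 1e-12)
  expect_equal(g$qaly[, 1], g$qaly[, 3], tolerance = 1e-12)
})

test_that("raising a success probability never hurts QALYs or adds symptomatic years", {
  p <- load_parameters()
  sc <- dc_scenario("MCP", "high")
  lo <- simulate_cohort("PNA-PNA-PNA", sc, p, n = 3000, seed = 21)
  p_hi <- set_param(p, "transitions.success.PNA.MCP.high", 0.60)
  hi <- simulate_cohort("PNA-PNA-PNA", sc, p_hi, n = 3000, seed = 21)
  # common random numbers: the comparison holds patient by patient in bulk
  expect_gte(hi$mean_qaly, lo$mean_qaly)
  expect_lte(mean(hi$patients$sympt_years), mean(lo$patients$sympt_years))
})

test_that("health-sector perspective removes wage loss from costs", {
  p <- load_parameters()
  sc <- dc_scenario("MCP", "low")
  soc <- simulate_cohort("LF-LF-LF", sc, p, n = 800, seed = 14)
  hs <- simulate_cohort("LF-LF-LF", sc, p, n = 800, seed = 14,
                        perspective = "health_sector")
  expect_lt(hs$mean_cost, soc$mean_cost)
  expect_equal(hs$mean_qaly, soc$mean_qaly, tolerance = 1e-12)
  expect_true(all(hs$patients$cost <= soc$patients$cost + 1e-9))
})

test_that("event logs export to CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  log <- export_event_log("PNA-LF-CCH", dc_scenario("MCP", "low"),
                          n = 5, seed = 2, path = f)
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_identical(nrow(back), nrow(log))
  expect_true(all(c("patient_id", "cycle", "age", "event") %in% names(back)))
  expect_setequal(unique(back$patient_id), 1:5)
})
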
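---
title: "Model and methods behind dupcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind dupcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dupcea` simulates the lifetime management of recurrent Dupuytren contracture
of a single finger joint under every ordered sequence of three treatments
drawn from CCH (collagenase injection), PNA (needle aponeurotomy) and LF
(limited fasciectomy), and performs the complete cost-effectiveness analysis
on the results.  This vignette documents the model, its conventions, the
calibration choices that were genuinely open, and what the validation does
and does not establish.

## State-transition structure

Three health states: *symptomatic* (contracture present), *symptom-free*
(successful treatment, no recurrence yet) and *death*, an absorbing state
with no accrual.  Cycles are one year; the horizon is the patient's remaining
lifetime (capped at age 100).  One treatment may be given per year.  A
patient enters the model symptomatic, aged 60 in the base case, and attempts
the three treatments of the regimen in order, while symptomatic.  Treatment
success moves the patient to the symptom-free state; the probability of
immediate failure is one minus the success probability.  Each symptom-free
year carries an annual probability of recurrence determined by the treatment
that produced it.  After the third treatment slot is consumed, a symptomatic
patient remains symptomatic for life.  Success and recurrence probabilities
depend on the treatment, the affected joint (MCP/PIP) and contracture
severity (below/above 45°), and are assumed identical for first and repeat
treatments.

## Cycle accounting

Three conventions matter and are fixed as follows:

* **Accrue, then transition.**  Everyone alive at the start of a cycle
  accrues that full year's cost and utility; the mortality draw takes effect
  at the end of the cycle.  This is decisive: under the alternative
  (mortality resolved before accrual) the discounted life expectancy at age
  60 implied by the mortality model is 14.81 years, which is *below* the
  published lifetime QALYs of the best regimens (15.09–15.17) — impossible
  when utilities are at most 1.  With end-of-cycle deaths the model gives
  `life_expectancy(mortality_model(), 60, 0.03)$life_years` ≈ 15.38
  discounted life-years, which brackets the published values correctly.
* **Whole-year utility attribution.**  A year in which treatment fails, or a
  recurrence occurs, accrues the symptomatic utility for the entire year; a
  successful-treatment year accrues the symptom-free utility (1.0) for the
  entire year.  There is no half-cycle correction.
* **Discounting** uses factor $(1+r)^{-t}$ with $t = 0$ for the first cycle
  and $r = 0.03$ per year for both costs and QALYs.

A recurrence detected in year $t$ makes the patient symptomatic for year $t$;
the next treatment slot (if any) is attempted in year $t+1$.

## Inputs

All inputs ship as a validated default parameter set
(`load_parameters()`), every entry carrying a base value, low/high
sensitivity bounds and a distribution family; any entry can be overridden via
a YAML file (full schema with defaults:
`inst/extdata/table1_defaults.yaml`).

* **Transition probabilities** — 12 success and 12 annual recurrence entries
  (treatment × joint × severity), e.g. LF success 0.71 for low-severity MCP
  vs 0.25 for high-severity PIP.
* **Direct costs (USD)** — per treatment event: CCH $6,095.90 (clinic visit,
  medication, manipulation visit, hand therapy), PNA $996.48 (procedure,
  hand therapy), LF $5,411.98 (procedure, anesthesia, facility fee, hand
  therapy).  PNA and CCH are office procedures; LF is performed in the
  operating room (the facility fee can be attached to PNA via config to model
  operating-room PNA).
* **Complications** — per event, independent Bernoulli draws per
  complication type (rates 0.17%–3.97%) with type-specific costs
  ($75–$7,987); utilities are not reduced by complications.
* **Indirect costs** — days off work per treatment (CCH 1, PNA 1, LF 37)
  valued at a daily wage and charged at each treatment event while the
  patient is below the retirement age (default 65), under the societal
  perspective only.
* **Utilities** — symptomatic-state utilities by joint and severity
  (0.938–0.970); the symptom-free state has utility 1.

## Mortality

Annual all-cause mortality follows a Gompertz curve
$h(a) = h_{60}\exp(s\,(a-60))$ through two anchors, $h(60) = 0.0087$ and
$h(45) = 0.0018$, giving $s = \log(0.0087/0.0018)/15 \approx 0.105$ per year;
the curve reaches the documented upper value 0.129 near age 85.7 and is
forced to 1 at age 100.  A two-column life table (age, annual probability)
can replace the curve — via `mortality_model(kind = "table")` or the
`mortality: table:` config key — for users who want a specific national
table.  Sex- and cause-specific mortality are out of scope.

## Wage valuation — the calibrated knob

How days off work are monetized is the one economically material input the
source material leaves unspecified.  The package exposes both knobs in the
config (`economics: working_days`, `economics: retirement_age`) and sets the
defaults by calibration against the published lifetime costs: a daily wage of
`annual_income / 365` (calendar-day valuation of the $63,179 median income)
with wage losses charged below age 65.  Under a conventional 250-working-day
divisor the lifetime cost of LF-heavy regimens overshoots the published
values by roughly 20% and LF never becomes cost-effective for severe MCP
contractures; under the 365-day default the expected-value recursion
reproduces the published cost scale to within about 1% and the published
frontier structure exactly.  Users preferring the labor-economics convention
can set `working_days: 250`.

## Parameter-uncertainty distributions

Distributions are fitted (`fit_distribution()`) so that approximately 95% of
the mass lies between each parameter's low and high bounds:

* **Beta** (probabilities, utilities): mean fixed at the base value, with the
  effective number of pseudo-observations solved numerically so the central
  95% interval matches the bounds.  For the transition-probability rows this
  lands near 100 pseudo-observations (the 0.61 success row fits shapes
  ≈ (61, 39)); an unconditional 100-observation parameterization was
  rejected because it cannot reproduce the stated 95% bounds for rows far
  from 0.6.
* **Truncated normal** (costs, days off work): mean at base,
  `sd = (high − low)/3.92`, truncated below at 0 (and above at 1 for
  proportions).
* **Uniform**: starting age, sampled on 45–75.  The mortality row's
  uniform range (0.18%–12.9%) is interpreted as the *age-induced* span of
  the Gompertz curve: sampling the starting age shifts the whole mortality
  trajectory, rather than drawing an independent flat mortality rate.

All draws are independent across parameters, by inverse CDF so that draws
are a deterministic function of the underlying uniforms.

## Simulation design and random numbers

The engine is vectorized across patients with pre-generated uniform streams:
one per patient-cycle for mortality, one per patient-cycle for the
success-or-recurrence draw, and one per patient × treatment-slot ×
complication type.  Reusing the streams across regimens (the default in
`simulate_regimens()` and `run_psa()`) implements common random numbers:
patient *i*'s death year and luck are identical under every regimen, which
sharply reduces the variance of incremental comparisons.  A fixed seed makes
every result bit-identical on re-run.  A scalar reference implementation
(`simulate_patient()`, which also returns the event log) reproduces the
vectorized engine exactly on shared streams, and an exact forward recursion
over the state space (age × health × treatments used) supplies the analytic
expectation against which cohort means are tested on every scenario-regimen
pair.

## Economic analysis

The efficiency frontier removes strictly dominated options, then applies the
standard extended-dominance sweep (sequential ICERs along the cost-sorted
candidates must increase strictly); frontier members get an ICER against the
previous frontier member.  Net monetary benefit `λe − c` is reported for all
regimens so the NMB ranking — which coincides with the frontier comparisons
on the published table — can be read off directly; exact ties are broken by
regimen enumeration order.  ICER Monte Carlo standard errors come from a
paired patient-level bootstrap (default 1,000 replicates) that preserves the
common-random-number pairing; an unstable sign of the bootstrap QALY
difference triggers a warning, since the ICER is then ill-defined.

One-way sensitivity analysis re-runs all regimens at a parameter's low and
high bounds with the same streams, so the recorded NMB changes are due to
the parameter alone.

## PSA structure

The published description of the probabilistic analysis ("10,000 patients
with randomly selected model parameters") is ambiguous between one patient
per parameter draw and a cohort per draw.  `run_psa()` supports both; the
default and documented-reference mode is the literal one — 10,000 parameter
draws, one simulated patient each, all 27 regimens evaluated on the same
patient with common random numbers.  `patients_per_draw > 1` gives the
two-level design, which smooths acceptability curves and isolates
second-order (parameter) uncertainty as the cohort grows.  CEAC
probabilities are the fraction of draws in which a regimen attains maximal
NMB, ties to the first regimen in enumeration order; they sum to one at
every threshold.

## Validation: what matches and what does not

The test suite and `scripts/acceptance.R` verify, at base parameters with
10,000-patient cohorts:

* the qualitative frontier structure — repeated PNA is the unique
  cost-effective regimen at $100,000/QALY for low-severity MCP and both PIP
  phenotypes; for high-severity MCP, PNA-PNA-LF (and in most runs LF-LF-LF)
  reaches a frontier ICER below the threshold; no CCH-containing regimen is
  ever optimal; repeated PNA is always cheapest and repeated LF most
  expensive with at least equal QALYs;
* the published cost and QALY scale — e.g. the acceptance script computes a
  mean lifetime cost near $3,320 (published $3,339) and mean QALYs near
  15.11 (published 15.09) for repeated PNA in low-severity MCP disease;
* internal coherence — simulation means equal the exact recursion within
  Monte Carlo error on all 108 scenario × regimen pairs; fitted 95%
  intervals reproduce the stated bounds for all 24 transition rows;
  acceptability probabilities partition the draws; frontier ICERs increase
  strictly; fixed seeds reproduce results bit for bit.

Two published quantities are *not* reproduced and are flagged deliberately:

* **CEAC acceptability of repeated PNA at $100,000/QALY.**  The package
  computes ≈ 65–68% for high-severity PIP against a published 52% (and is
  similarly ~15 percentage points high elsewhere).  The scenario ordering
  and shape of the curves match, but the level depends on the unpublished
  pairing of patients with parameter draws and on tie handling among
  regimens that share a realized treatment path.  Every defensible variant
  examined (cohort-per-draw, independent streams per regimen, shared
  mortality only, truncated-normal utilities) either leaves this value
  unchanged or breaks the scenario ordering, so the literal design is
  retained and the corresponding acceptance check is expected to fail at
  its stated tolerance.
* **Mean time to first recurrence.**  The published text reports both 26
  months (high-severity MCP, after PNA) and 7.5 years (PNA, MCP joints) —
  mutually inconsistent under any single definition with annual cycles and
  a 0.26 annual recurrence probability (conditional geometric mean ≈ 3.5
  years, which is what the simulation reports as the interval from first
  successful treatment to first recurrence).  The quantity is exposed as a
  cohort output but not asserted against either published figure.

## What the synthetic cohorts do and do not represent

The generator produces exactly the study conditions: annual decision cycles,
a single affected joint, treatment-seeking patients who always accept the
next treatment, probabilities constant over episodes, and US costs.  It does
not emulate continuous-time recurrence, contracture-angle dynamics within
the severity strata, multi-finger disease, treatment deferral, or
non-US cost structures — so passing tests establish internal correctness
and fidelity to the published analysis, not transportability to other
settings.

## Problem sizes used by the tests

Unit and property tests run on cohorts of 40–4,000 patients; the acceptance
checks use the full design (10,000 patients per cohort, five seeds averaged
per scenario; 10,000 PSA draws).  The complete suite runs in about a minute
on one CPU.
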
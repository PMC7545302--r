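Package: dupcea
Title: Cost-Effectiveness Microsimulation of Treatment Sequences for
    Recurrent Dupuytren Contracture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level state-transition (Markov) microsimulation of
    recurrent Dupuytren contracture managed with up to three treatments drawn
    from collagenase clostridium histolyticum injection (CCH), percutaneous
    needle aponeurotomy (PNA), and limited fasciectomy (LF), over a lifetime
    horizon with annual cycles.  Simulates all 27 ordered three-treatment
    regimens for four disease phenotypes (MCP/PIP joint x low/high contracture
    severity), accrues discounted costs (societal or health-sector
    perspective) and quality-adjusted life-years, and turns cohort results
    into the standard health-economic outputs: incremental cost-effectiveness
    ratios on the efficiency frontier with extended dominance, net monetary
    benefit, one-way deterministic sensitivity analysis, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.  An
    exact expected-value recursion over the expanded state space is included
    as an analytic cross-check of the microsimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
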
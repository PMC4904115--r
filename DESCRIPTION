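Package: uhrconvert
Title: Diagnostic Rule Engines, Case Conversion and Agreement Statistics
    for Ultra-High-Risk Psychosis Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule engines for the CAARMS 12/2006 and SIPS 5.0 ultra-high-risk
    (UHR) psychosis diagnostic criteria (Psychosis threshold, BLIPS/BIPS, APS
    and GRD/Vulnerability subgroups, with onset, duration, functioning and
    exclusion gates), a pragmatic conversion engine that translates individual
    cases between the two instruments via subscale and frequency crosswalks,
    paired-outcome agreement statistics (percent agreement, Cohen's kappa with
    null-standard-error z and confidence interval, weighted kappa, prevalence-
    and bias-adjusted kappa, the McNemar-Bowker symmetry test, adjusted
    residuals), observed-score equipercentile linking of severity and frequency
    scales, diagnostic-accuracy metrics, a synthetic dual-instrument cohort
    generator with controllable discordance mechanisms, and tabular cohort
    input/output. All user-facing functions take data frames and return
    tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
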
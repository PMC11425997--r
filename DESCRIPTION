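Package: fhscreen
Title: Evidence Synthesis and Distributional Cost-Effectiveness of
    Familial Hypercholesterolemia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to synthesize published economic evaluations of familial
    hypercholesterolemia (FH) screening programmes and to assess their
    impact on health inequality.  Pools incremental costs and effects
    within screening-strategy/outcome groups into synthesized incremental
    cost-effectiveness ratios (ICERs), computes per-study net monetary
    benefit at study-specific willingness-to-pay thresholds, combines
    studies with comparative-efficiency (COMER) weights proportional to
    the inverse squared net benefit, and propagates uncertainty with
    either a fixed proportional interval rule or a delta-method ratio
    variance.  An aggregate distributional cost-effectiveness analysis
    (DCEA) module allocates net health benefit across socioeconomic (IMD
    quintile) groups, measures inequality with the Atkinson index, and
    reports the equally distributed equivalent health (EDEH) and
    population equity impact of a screening scenario.  Includes a
    synthetic evidence-base generator with known ground truth and
    hand-encoded fixtures of the published summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
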
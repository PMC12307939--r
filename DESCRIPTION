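Package: bioecon
Title: Input-Output Impact Modelling and Cost-Benefit Appraisal of Genomics Investments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Leontief input-output impact analysis and cost-benefit appraisal
    for national genomics investments, exercised on synthetic supply-use-derived
    flow tables. Generates balanced synthetic inter-industry economies, derives
    technical coefficients and the Leontief inverse, decomposes the impact of a
    final-demand injection into direct, indirect and induced components (Type I
    and Type II closures), models scenario adjustments (sector productivity
    gains, strengthened inter-sector linkages), calibrates multi-horizon
    cumulative benefit projections to printed anchor totals, and computes
    discounted cost-benefit metrics (NPV, benefit-cost ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
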
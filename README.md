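# bioecon

Economic appraisal of national genomics investments by Leontief input–output
modelling and cost–benefit analysis, exercisable entirely on synthetic
supply–use data.

## The problem

Proposals to sequence genomes locally (rather than outsourcing) are
increasingly justified economically: the injection of sequencing investment
into R&D and agriculture ripples through inter-industry purchases and
household spending, and the resulting benefit stream is set against the
investment cost. Appraisals of this kind rest on a national input–output
matrix that is often not redistributable, which makes the published numbers
hard to scrutinise. `bioecon` provides the full appraisal pipeline — economy
→ coefficients → impacts → projections → cost–benefit metrics — as tested,
reusable functions, together with a synthetic-economy generator that emulates
the structure of a real 27-sector supply–use-derived matrix (balanced
accounts, productive coefficients), so every step can be validated even
though the original table is unavailable.

It is written for analysts in development economics and science policy who
want to reproduce, stress-test or re-parameterise a genomics (or any other
sectoral) investment appraisal.

## The model

**Leontief input–output.** From an inter-industry flow matrix `Z` and gross
outputs `x`, the technical coefficients are

```
A_ij = Z_ij / x_j        (input from sector i per unit of sector j's output)
```

A productive economy (Hawkins–Simon: all leading principal minors of `I − A`
positive; equivalently spectral radius ρ(A) < 1) admits the Leontief inverse
`L = (I − A)⁻¹`. A final-demand injection `F` generates gross output
`x = L F`, decomposed into **direct** (`F`), **indirect** (`(L − I) F`) and,
under a Type II household closure, **induced** effects
(`(L_II − L_I) F` on the industry block of the household-augmented system).
Output multipliers are the column sums of `L`.

**Scenario adjustment.** A productivity gain `g` in a sector scales its input
column by `1/(1+g)` (same output from fewer intermediates); strengthened
linkages add a coefficient increment from a source sector (R&D) to target
sectors. Base and adjusted cases are evaluated at the same injection.

**Projection.** Cumulative benefits follow a geometric annual stream,
`cum(T) = Σ_{t=1..T} b (1+g)^(t−1)`; `(b, g)` are exactly identified by two
printed cumulative anchors and recovered by root-finding on the partial-sum
ratio.

**Cost–benefit.** With year-end discounting at rate `r`,
`NPV = Σ_{t=1..T} (Benefits_t − Costs_t)/(1+r)^t` and
`BCR = PV(benefits)/PV(costs)`.

## Worked example

```r
library(bioecon)

# a tiny 2-sector economy with balanced accounts
tb <- flow_table(Z = matrix(c(10, 30, 20, 40), 2, 2),
                 x = c(100, 200), f = c(70, 130), va = c(60, 140),
                 labels = c("agriculture", "R&D"))
A <- compute_technical_coefficients(tb)   # [[0.1, 0.1], [0.3, 0.2]]
L <- leontief_inverse(A)
output_multipliers(L)
#> agriculture         R&D
#>    1.594203    1.449275

decompose_impacts(A, demand_shock(c(agriculture = 10, `R&D` = 10)))
#>        sector direct indirect induced    total    share
#> 1 agriculture     10 3.043478       0 13.04348 42.85714
#> 2         R&D     10 7.391304       0 17.39130 57.14286
```

Each dollar of final demand for agriculture generates $1.59 of gross output
economy-wide; a $10M + $10M injection yields a $30.4M total impact, 43% of it
in agriculture.

The full pipeline on a synthetic 27-sector economy, with benefits calibrated
to cumulative anchors of $35M (5 yr) and $79M (20 yr):

```r
report <- run_pipeline(seed = 20240101,
                       projection = list(c(5, 35), c(20, 79)))
cat(render_summary(report), sep = "\n")
#> Total Cost: 20.00
#> Discounted Cost: 15.44
#> Total Benefit: 56.85
#> Discounted Benefit: 45.54
#> NPV: 30.10
#> BCR: 2.95
#> ...
#> Cumulative benefits by horizon:
#>   5 years: 35.00
#>   10 years: 56.85
#>   20 years: 79.00
```

The calibrated stream starts at b = 8.38 MUSD/yr and *decelerates* at
g ≈ −9%/yr — a structural implication of the 35 → 79 anchors that the
pipeline surfaces rather than hides. The $20M cost spread evenly over the
10-year window discounts to $15.44M; against the $45.54M discounted benefit
this gives NPV $30.10M and BCR 2.95.

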
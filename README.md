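# greysoft

Multi-criteria decision making over **fuzzy soft sets** — labelled tables
scoring `m` alternatives against `n` parameters with membership degrees in
`[0, 1]` — for analysts (e.g. in evidential medical diagnosis) who need a
ranking that does not hinge on an arbitrary cut-off.

Threshold-based fuzzy-soft-set methods binarise the table at a chosen
*level* and count surviving parameters per alternative; the winner can
change with the level. `greysoft`'s main pipeline (`gds_decide()`) removes
the threshold: each parameter is treated as a body of evidence, weighted by
how well it discriminates, and all evidence is fused with Dempster's rule.

1. **Grey relational analysis.** With `dbar_i` the row mean of alternative
   `i` and `Δ_ij = |d_ij − dbar_i|`, the grey mean relational degree is
   `r_ij = (a_j + ρ b_j)/(Δ_ij + ρ b_j)` with `a_j, b_j` the column
   min/max and distinguishing coefficient `ρ = 0.5`. The uncertainty
   degree of parameter `j` is `DOI(e_j) = (1/m)(Σ_i r_ij^q)^(1/q)`
   (`q = 2`): large when the parameter discriminates poorly.
2. **Mass construction.** Column-normalise the table
   (`image_ij = d_ij / Σ_i d_ij`) and set
   `m_j({x_i}) = image_ij (1 − DOI(e_j))`, `m_j(Θ) = DOI(e_j)` on the frame
   `Θ = {x_1, …, x_m}`.
3. **Dempster combination.** Fuse the `n` mass functions
   (`m = m_1 ⊕ ⋯ ⊕ m_n`, conflict renormalised by `1/(1−K)`) and rank the
   alternatives by combined singleton belief.

Also included: the **mean potentiality** baseline
(`mean_potentiality_decide()`, level soft sets at data-driven thresholds
with a spread-based tie-break), the performance measure
`Y = 1/Σ_{i<j}|F(e_i)(O_p) − F(e_j)(O_p)| + Σ_i F(e_i)(O_p)` for comparing
methods (`compare_methods()`), fuzzy-soft-set algebra (`and_product()`,
`is_fuzzy_subset()`, `level_soft_set()`), general Dempster–Shafer
mass/belief machinery, CSV I/O with significant-figure tracking, a seeded
random-table generator, and a CLI (`inst/cli/fse.R`).

## Worked example

The shipped 3×5 table is the classic case where the two methods disagree:

```r
library(greysoft)
fss <- read_fss(system.file("extdata", "table3.csv", package = "greysoft"))
gds_decide(fss)
#> Grey relational + Dempster-Shafer decision
#> Combined singleton masses:
#>     x1     x2     x3
#> 0.2690 0.3309 0.3218
#> Residual whole-frame mass: 0.0782 (mean input uncertainty 0.4723)
#> Ranking: x2 ≻ x3 ≻ x1
#> Optimal: x2
compare_methods(fss)
#> Method comparison
#>   grey/evidence:     optimum x2, performance 3.7202
#>   mean potentiality: optimum x3, performance 3.6462
#>   better: gds
```

Evidence combination concentrates belief: the mean input uncertainty
0.4723 collapses to a residual frame mass of 0.0782, and the grey/evidence
optimum x2 outscores the baseline's x3 on the performance measure.

A diagnosis example: restrict the symptom table to the patient's observed
symptoms, AND it with the examination-tool table (pointwise minima over all
symptom/tool pairs) and decide:

```r
symptoms <- select_parameters(
  read_fss(system.file("extdata", "table7.csv", package = "greysoft")),
  c("e1", "e2", "e4"))
tools <- read_fss(system.file("extdata", "table8.csv", package = "greysoft"))
gds_decide(and_product(symptoms, tools))
#> Combined singleton masses:
#>     d1     d2     d3     d4
#> 0.0827 0.0284 0.8349 0.0471
#> Residual whole-frame mass: 0.0069 (mean input uncertainty 0.3821)
#> Ranking: d3 ≻ d1 ≻ d4 ≻ d2
#> Optimal: d3
```

Belief 0.8349 lands on `d3` (acute sinusitis) with almost no residual
uncertainty. The same pipelines are available from a shell:

```sh
Rscript inst/cli/fse.R compare inst/extdata/table3.csv --json report.json
```

See `vignettes/greysoft-methods.Rmd` for the model details, conventions and
numerical edge cases.

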
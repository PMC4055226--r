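---
title: "Decision making over fuzzy soft sets: the grey relational / evidence pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision making over fuzzy soft sets: the grey relational / evidence pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greysoft)
```

## The problem

A fuzzy soft set is the standard container for a multi-criteria choice under
vague information: `m` alternatives (objects) are scored in `[0, 1]` against
`n` parameters, giving a membership matrix `D = (d_ij)`. Classical
fuzzy-soft-set decision procedures binarise `D` at some *level* and count,
per alternative, how many parameters survive (the choice values). The
well-known weakness is that the threshold is the analyst's to pick, and
different defensible thresholds pick different winners.

`greysoft` implements a pipeline that avoids thresholds altogether by
treating each parameter as an independent body of evidence about which
alternative is best, weighting that evidence by how well the parameter
actually discriminates, and fusing everything with Dempster's rule. The
package also implements the threshold-based *mean potentiality* baseline and
a performance measure so the two can be compared on the same table.

## The grey relational / evidence method (`gds_decide()`)

**Step 1 — uncertainty of each parameter by grey relational analysis.**
For each alternative compute its row mean `dbar_i`, and the difference
information `Delta_ij = |d_ij − dbar_i|`. Within each parameter column `j`,
with `a_j = min_i Delta_ij` and `b_j = max_i Delta_ij`, the grey mean
relational degree is

```
r_ij = (a_j + rho * b_j) / (Delta_ij + rho * b_j),    rho in (0, 1),
```

so `r_ij` is 1 where an alternative sits closest to its own mean and decays
toward `rho/(1+rho)` at the farthest. The distinguishing coefficient `rho`
(default 0.5, dimensionless) compresses or expands that range; 0.5 is the
conventional choice giving a strong distinguishing effect. The q-order
uncertainty degree of parameter `j` is the scaled q-norm of its column,

```
DOI(e_j) = (1/m) * (sum_i r_ij^q)^(1/q),    q >= 1 (default 2).
```

A parameter whose memberships all hug the row means has `r` near 1
everywhere and a large `DOI`: it discriminates poorly and should count for
little. Since `r_ij` lies in `(0, 1]`, `DOI` is bounded by `m^(1/q - 1)`
(for `q = 2`, `1/sqrt(m)`); the property suite asserts this bound on
generated inputs.

**Step 2 — masses from the column-normalised table.** The *information
structure image* divides each column by its sum, so each parameter's
memberships become a distribution over the alternatives. Parameter `j` then
induces a basic probability assignment on the frame `Theta = {x_1..x_m}`:

```
m_j({x_i}) = image_ij * (1 − DOI(e_j)),      m_j(Theta) = DOI(e_j).
```

The second equality holds because image columns sum to one, and the test
suite asserts it to `1e-9`. A maximally uncertain parameter contributes
vacuous evidence (all mass on `Theta`).

**Step 3 — Dempster combination and ranking.** The `n` mass functions are
fused with Dempster's rule: focal sets are intersected pairwise, the product
mass landing on the empty set is the conflict `K`, and the rest is rescaled
by `1/(1 − K)`. The rule is commutative and associative, so the package's
left fold is order-independent (asserted under permutations to `1e-9`).
Alternatives are ranked by combined singleton mass — equal to the belief of
each singleton — ties grouped; the optimal set collects every argmax. The
combined mass left on `Theta` is the residual whole-evidence uncertainty,
and on both shipped examples it falls far below every input `DOI`, which is
the method's selling point.

## The mean potentiality baseline (`mean_potentiality_decide()`)

The baseline picks its levels from the data rather than from the analyst,
in three escalating stages (the report records which stage resolved):

1. optionally delete a *normal parameter reduction* — a parameter subset
   whose per-object sums are constant, so removing it cannot reorder choice
   values (stage 0, search capped at subsets of size 3 by default);
2. threshold at the *mean potentiality* `m_p` (grand mean of all
   memberships) rounded to `rho` significant figures, where `rho` is the
   maximum number of significant decimal digits among the memberships *as
   written*; a unique maximal choice value decides (stage 4);
3. otherwise threshold at the rounded mean `alpha` of the per-parameter
   spreads (max − min per column); a unique maximum decides (stage 8);
4. otherwise the tie among the stage-8 leaders is broken by the smallest
   per-object spread `beta_i` — the flattest row wins (stage 9); if `beta`
   also ties, all minimal-`beta` objects are returned.

Two conventions are deliberate and locked by tests. Binarisation uses `>=`
(membership equal to the threshold counts), which is what the shipped
worked example requires. Rounding is half away from zero (`0.626 -> 0.63`,
`0.336 -> 0.34`): IEEE round-half-even would disagree on exact ties, so a
convention had to be fixed; `round_sig()` documents it. Significant figures
are a property of the *text* a table was read from, so `read_fss()` and
`synth_fss()` record per-cell digit counts and sets built from bare
numerics require an explicit override.

## The performance measure

`performance_measure()` scores a method by the alternative `O_p` it picks:

```
Y = 1 / sum_{i<j} |F(e_i)(O_p) − F(e_j)(O_p)|  +  sum_i F(e_i)(O_p),
```

the reciprocal of the optimum's summed pairwise membership spread plus its
total membership; larger is better. The pairwise sum runs over *unordered*
pairs. That reading was fixed by brute force: on the shipped 3x5 example it
reproduces both published scores (3.7202 for the grey/evidence winner x2,
3.6462 for the mean-potentiality winner x3) to all four printed decimals,
while the ordered-pair reading gives 3.4651 and matches nothing. `Y` is
undefined (an error) when the optimum's memberships are all equal, and a
tied optimum in either method makes `compare_methods()` error rather than
silently pick one.

On the medical table below, the literature attaches the score 4.1726 to the
same decision; evaluating the formula on that table's winning row gives
4.7163 under the convention validated above. The figure evidently
originates from a different worked example than the AND-product table
shipped here, so the package does not claim to reproduce it.

## Worked examples shipped as fixtures

`inst/extdata/table3.csv` is the 3-alternative, 5-parameter running
example on which the two methods famously disagree (x2 vs x3).
`table7.csv`/`table8.csv` describe four candidate diagnoses (acute dental
abscess, migraine, acute sinusitis, peritonsillar abscess) against seven
symptoms and three examination tools. The diagnosis pipeline restricts the
symptom table to the patient's observed symptoms (fever, running nose,
orofacial pain), forms the AND-product with the tools table — pointwise
minima over all symptom/tool pairs, 9 parameters — and runs `gds_decide()`.
The combined belief concentrates 0.8349 on acute sinusitis with residual
frame mass 0.0069, down from a mean input uncertainty of 0.3821:

```{r medical}
symptoms <- select_parameters(
  read_fss(system.file("extdata", "table7.csv", package = "greysoft")),
  c("e1", "e2", "e4"))
tools <- read_fss(system.file("extdata", "table8.csv", package = "greysoft"))
gds_decide(and_product(symptoms, tools))
```

(The surrounding literature quotes the post-combination uncertainty of this
case once as 0.0751 in prose while the printed combined masses, which sum
to 1.0000, give 0.0069; the package computes 0.0069.)

## Numerical choices and degenerate inputs

* **Degenerate grey column** (`b_j = 0`: every alternative equals its row
  mean at parameter `j`): the relational formula is 0/0; the package sets
  the whole column to 1, its continuous limit as `Delta -> 0` uniformly,
  which keeps the `DOI` bound intact. With a single alternative this makes
  every parameter maximally uncertain and all evidence vacuous.
* **Zero-support parameter** (column sum 0): no alternative satisfies it at
  all, so it carries no evidence and column normalisation is undefined.
  This is an error naming the parameter rather than a silent uniform fill —
  the caller must drop the parameter deliberately.
* **Total conflict** (`K = 1`) in combination is an error: the evidence is
  non-combinable. The pipeline's singleton-plus-frame masses can only reach
  it if some mass function is degenerate.
* Mass functions validate to a total of 1 within `1e-9` and never store the
  empty set; printed-value comparisons in the tests use the source's
  4-decimal precision.
* Focal sets may be arbitrary non-empty subsets, although the pipeline only
  produces singletons plus the frame; the general path is exercised against
  a brute-force bitmask oracle on frames of up to 4 alternatives.

## The random-table generator

`synth_fss(m, n, seed, decimals)` draws memberships independently and
uniformly on `[0, 1]`, rounded to `decimals` places (default 2, matching
the precision of typical published tables), with labels `x1..xm`, `e1..en`.
It exists to drive the property tests — normalisation, bounds,
monotonicity, round-trips — at sizes of 1–6 objects and parameters, and it
restores the caller's RNG state. Uniform independent memberships are a
deliberately structureless model: they contain no correlated parameters,
no dominated alternatives and no near-ties, so passing properties on them
demonstrates algebraic correctness of the pipeline, not decision quality on
any real screening or diagnosis data.

## Limitations

* Only Dempster's combination rule and the belief function are provided; no
  Yager/Dubois–Prade variants, plausibility, pignistic transforms or
  discounting, and no interval-valued or intuitionistic memberships.
* Grey analysis uses the row-mean reference only, not Deng's
  ideal-alternative reference sequence.
* Parameters are equally weighted throughout; the diagnosis example fuses
  symptom and tool evidence without weighting one class over the other.
* The normal-parameter-reduction search is exhaustive and therefore capped
  (default: dispensable sets of size at most 3); for wide tables raise the
  cap knowingly or switch the search off.
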
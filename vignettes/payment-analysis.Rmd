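---
title: "Methods: payments to general practices, from disclosure extract to company networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: payments to general practices, from disclosure extract to company networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paynet)
```

## The problem

UK drug companies disclose transfers of value to healthcare organisations
(Disclosure UK) as free text: a company name, an "institution name", an
"institution location", a payment category and a GBP amount, with no
recipient identifier. Turning that into an analysis of payments to English
general practices requires five steps, each of which this package
implements as a separately testable module:

1. **Ingest** — validated readers for the payments table and a practice
   registry, and VAT normalisation so amounts are comparable across
   companies.
2. **Linkage** — matching free-text recipients to unique practice codes,
   with full accounting of what could not be linked.
3. **Enrichment** — joining practice characteristics (region, list size,
   share of patients over 65, deprivation decile) and quartile groupings.
4. **Descriptives and comparisons** — concentration statistics (top-k
   donor shares, per-company and per-practice profiles) and stratified
   Wilcoxon rank-sum comparisons.
5. **Networks** — valued company-by-company graphs in which the weight of
   an edge is the number of practices both companies pay, under
   configurable payment thresholds.

A synthetic-data generator reproduces the *statistical shape* of the 2015
extract so that every stage runs, and is verified, without the original
data.

## VAT normalisation

Published methods for this kind of data adjust amounts for VAT using
company methodological notes, but do not state the arithmetic. The
package fixes a concrete, invertible contract: amounts reported
VAT-inclusive are divided by `1 + rate` (UK standard rate 0.20 by
default) and rounded half-up to pence; exclusive amounts pass through
unchanged; rows with unknown basis follow a configurable policy that
defaults to `assume_exclusive` (conservative: no alteration). Division
rather than subtraction makes the operation exactly invertible up to
pence rounding, and `normalize_vat()` is idempotent, so accidentally
running it twice cannot corrupt a dataset. All monetary arithmetic in the
package is done half-up at pence precision, and conservation identities
(total = linked + excluded) are asserted in integer pence, never in
floating-point pounds.

## Record linkage

No matching algorithm is published for this data, so the package uses a
deterministic two-stage design chosen for reproducibility and
auditability rather than maximum recall:

* **Normalization.** Both sides are casefolded, punctuation-stripped,
  whitespace-collapsed, and passed through a fixed abbreviation table
  (`rd`→road, `st`→street, `surg`→surgery, `dr`→doctor, `hc`→health
  centre, `med`→medical, `ave`→avenue, `ln`→lane). The street/saint
  ambiguity of "st" is resolved to street, the overwhelmingly more common
  use in practice addresses. The normalizer is idempotent.
* **Stage 1 (exact).** Each normalized candidate string (institution
  name first, then location) is looked up against four registry keys in
  decreasing order of specificity: name + postcode, unique name,
  normalized address + postcode, unique address. Keys that are ambiguous
  in the registry (two practices called "The Surgery") are simply not
  used as keys, which can never produce a wrong match.
* **Stage 2 (fuzzy).** For payments still unmatched that carry an
  extractable UK postcode, the best candidate is compared by token-set
  similarity (Levenshtein on sorted token strings, order-insensitive)
  against registry names in the same postcode district. The highest
  similarity at or above the threshold (default 0.90) wins; ties break
  to the lexicographically smallest practice code so reruns are
  identical. Payments without a postcode are never fuzzy-matched: a
  similarity score alone, with ~7,500 possible targets, is not evidence.

Lowering the threshold can only add matches (monotonicity), and on
synthetic data with only light noise the design achieves 100% recall
against the generator's truth table, which is what the noise model is
built to guarantee (see below). "Practices excluded" in the exclusion
report counts distinct unmatched recipient identities after
normalization, since without codes the true number of distinct excluded
practices is unknowable.

## Quartiles and stratified comparisons

All quantiles in the package — summary tables, IQRs, quartile groupings —
are type-7 sample quantiles (linear interpolation, the R default), with
quartile labels assigned by "value ≤ cut point, ties to the lower
quartile". Quartiles are computed over the payment-receiving practices,
the analysis population, not the whole registry. Deprivation quartiles
are derived from the postcode decile (1 = most deprived), so quartile 1
is the most deprived group.

Stratum comparisons use the two-sided Wilcoxon rank-sum test with the
per-practice total payment value as the unit of analysis (a per-payment
variant is available via `unit = "payment"`; published tables of this
kind are interpretable either way, and per-practice is the default
because the stratifying characteristics are practice-level). The test is
implemented from first principles:

* **Exact mode** evaluates the permutation null of
  `U = R_x − n_x(n_x+1)/2` by the standard counting recursion
  `c(u; m, n) = c(u−n; m−1, n) + c(u; m, n−1)`; it is valid only without
  ties and is selected automatically for `n ≤ 20`.
* **Normal mode** uses the tie-corrected variance
  `n_x n_y/12 · ((n+1) − Σ(t³−t)/(n(n−1)))` with a 0.5 continuity
  correction.

Both modes are cross-checked in the test suite against
`stats::wilcox.test`, and a permuted-labels simulation (1,000 replicates
on synthetic per-practice totals) confirms type-I calibration at
α = 0.05 ± 0.02. Raw p-values are reported per stratum with no
multiplicity adjustment, matching how such tables are conventionally
published; readers comparing many strata should keep that in mind.

## Valued company networks

From the linked table the package builds a company × practice incidence
under a threshold specification: a pair is *active* if the company made
at least one individual payment of at least the cutoff to that practice
(`single_payment_value`, the default reading of "payments over £X"), or
by pair-total value or pair payment count — the phrase is ambiguous in
the literature, so all three bases are selectable. The one-mode
projection weights each company pair by the number of shared active
practices. Statistics:

* **Strength** `s_i = Σ_j w_ij` and **binary degree**
  `d_i = #{j : w_ij > 0}`. Published descriptions of "centrality as the
  number of ties" are ambiguous between the two, so both are always
  reported side by side.
* **Valued density** = `Σ_{i<j} w_ij / (n(n−1)/2)`, the mean
  shared-practice count per unordered company pair (can exceed 1). An
  ordered-pair variant (half this value) is available for comparability
  with tools that count ordered dyads.
* **Centralization** = `Σ_i (c_max − c_i) / ((n−1)(n−2) · w_max)` with
  `c` = strength and `w_max` the largest observed edge weight. There is
  no universal normalization for valued centralization; this one is used
  because it reduces exactly to Freeman degree centralization on binary
  graphs (verified against igraph in the tests), equals 1 on a
  uniform-weight star, and 0 on a complete equal-weight graph.

Isolates (companies with at least one active practice but no shared
practice) are retained in node counts and reported separately. Strata
with fewer than the minimum nodes return `NA` statistics flagged
`degenerate` rather than an error, since small strata are a routine
occurrence in per-quartile networks. Projection weights are verified in
the tests against brute-force set intersection, exhaustively for all
3 × 3 incidences and on random incidences up to 6 × 8.

## The synthetic generator and its calibration

The generator emulates the 2015 extract's shape; its defaults are
calibrated to the published distribution summary and are treated as
fixed study conditions, not tuning knobs:

* **Scale.** 34 companies, 7,500 practices in 9 regions — the published
  final-sample company count and the approximate England practice
  population.
* **Values.** Single payments are drawn from a *split* (two-piece)
  lognormal: `exp(μ + σ_lower z)` for `z < 0`, `exp(μ + σ_upper z)`
  otherwise, with `μ = ln 320`, `σ_lower = ln(320/170)/0.6745`,
  `σ_upper = ln(869/320)/0.6745`, rounded half-up to pence and floored at
  £8. The published IQR is asymmetric on the log scale
  (`ln(320/170) = 0.63` versus `ln(869/320) = 1.00`), so no single-σ
  lognormal can match all three quartiles; the split form matches them
  exactly in distribution, and 50,000 pooled payments recover
  (170, 320, 869) within ±10% comfortably.
* **Donor structure.** One dominant donor makes 1,000 payments across
  780 distinct practices; the other 33 draw payment counts from a
  rounded lognormal with median 14.5 truncated to [1, 400] (so
  "three-quarters make no more than ~81 payments" holds qualitatively
  while total bundle size stays near the published ~2,900).
* **Practice selection.** Recipient practices are drawn with Zipf-like
  popularity `∝ rank^−α`. α = 0.8 was chosen by calibration: it yields a
  75th percentile of 2 payments per receiving practice (the published
  IQR upper bound) in 10/10 seeds, a maximum per-practice count of the
  right order (tens to ~100, published maximum 132), and ~1,700
  receiving practices (published 1,790). Steeper exponents (e.g. 1.3)
  concentrate far too hard — a top practice with 500+ payments and only
  ~1,000 receiving practices — and were rejected on those grounds.
* **Noise.** Each payment is independently heavily corrupted with
  probability `unmatchable_rate` (recipient strings replaced by tokens
  absent from the registry, postcode removed — guaranteeing exclusion),
  else lightly corrupted with probability `name_noise_rate` (case,
  punctuation, abbreviation swaps drawn from the normalizer's own table
  — guaranteeing recoverability). This makes linkage recall and the
  exclusion rate exactly testable: unmatched fraction → `unmatchable_rate`
  within binomial error.
* **VAT.** Amounts are generated VAT-exclusive; each company is flagged
  VAT-inclusive with probability 0.15, in which case its amounts are
  multiplied by 1.2 and labelled accordingly, exercising the VAT module
  end to end.
* **Characteristics.** Registered patients are lognormal (median 7,000,
  floored at 500); the over-65 share is Beta(5, 24) (mean ≈ 0.17,
  roughly the English practice average); deprivation deciles are uniform
  on 1–10. These are plausibility choices, not calibration targets.

What the generator deliberately does **not** emulate: geographic
correlation between deprivation, region and payment propensity; temporal
dynamics (one cross-sectional year); product-level marketing structure;
and the messy reality of practice mergers, branch surgeries and shared
premises that makes real linkage harder than synthetic linkage. Passing
tests therefore demonstrate that the pipeline's arithmetic, accounting
and algorithms are correct under realistic marginal distributions — not
that real-extract linkage would achieve the synthetic recall.

## Numerical conventions and problem sizes

Seeded RNG throughout; a bundle is bit-reproducible given its seed, and
the pipeline's written outputs are byte-identical across reruns.
Rounding is half-up at the stated precision (pence for amounts, 2
decimals for count percentages, 1 decimal for value percentages).
Ranking ties break lexicographically. The test suite runs at desk scale:
registries of 400–7,500 practices, bundles of ~500–3,000 payments,
50,000+ pooled values for distribution-recovery checks, 1,000
permutation replicates for test calibration, and exhaustive projection
checks on small incidences; the full suite completes in well under a
minute on one CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(simulate = generator_config(), seed = 1)
res <- run_pipeline(cfg)

res$linkage$report          # exclusion accounting
res$summary_table           # distribution summary across analysis levels
res$top_share               # top-10 donor share of value and count
res$comparisons$region      # stratified rank-sum comparison vs London
res$networks$value_1000$stats$centralization_valued
```

## Known limitations

* The fuzzy stage requires an extractable postcode; a badly misspelled
  name with no postcode is excluded rather than guessed.
* Valued centralization conventions differ across software; when
  comparing against other tools, check their normalization (the binary
  mode is the common ground and matches Freeman/igraph exactly).
* The exclusion report's "practices excluded" is a lower-bound-style
  estimate based on distinct normalized strings; spelling variants of
  the same unlinkable practice count once only if they normalize
  identically.
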
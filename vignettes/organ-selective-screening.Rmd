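---
title: "Screening organ-selective genes: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening organ-selective genes: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgsel)
```

## The screening model

`orgsel` asks, for every gene of a replicated multi-organ FPKM study,
whether its expression is *dominated* by a single organ. The procedure
combines one location test with one effect-size gate:

* Replicates are summarised by arithmetic per-organ means
  `m_1, ..., m_K` (`organ_means()`).
* The **max organ** holds the largest mean; the **median organ** holds
  the median of the K means. For odd K that is the `(K+1)/2`-th largest
  (the 6th of 11); for even K we take the lower of the two central
  values, so the comparison is never against an interpolated organ that
  does not exist. Comparing max against the *median* rather than the
  runner-up makes the test a proxy for "this organ versus a typical
  organ".
* The replicate FPKMs of those two organs are compared with a
  two-sample t-test (`two_sample_pvalue()`), pooled-variance Student by
  default with `df = n_a + n_b - 2`. Welch is available
  (`test_flavor = "welch"`) for unequal variances; with 3 replicates per
  organ the pooled test is the conventional default and the two rarely
  disagree on strong signals. Two-sided is the default sidedness — the
  conservative choice, since the max organ is selected *after* looking
  at the means.
* p-values are adjusted over **all tested genes jointly**
  (`fdr_qvalues()`): the screen runs one test per gene, so the natural
  multiple-testing family is the set of tested genes, not per-organ
  slices.
* The **MT ratio** `max(m) / sum(m)` measures dominance on a `(0, 1]`
  scale: `1/K` for uniform expression, 1 for single-organ expression.
  A gene is called `selective` when `p < alpha_p`, `q < alpha_q` and
  `MT > mt_min`; `interesting` (the enrichment foreground) needs only
  `p < alpha_p`.

The statistical caveat is worth stating plainly: because the two
compared organs are chosen from the same data (max vs median), the
t-test's null distribution is optimistic, and for genes with equal true
means across organs the realised type-I rate exceeds the nominal level.
The MT gate is what keeps the final selective calls clean — a flat gene
has MT near `1/K`, far from the 0.7 threshold — and the synthetic-data
recovery tests confirm that the *combined* screen, not the t-test
alone, controls false calls.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fpkm_min` | 5 | FPKM | genes whose maximum organ mean falls below this floor are too weakly expressed to test; strict `< 5` is ignored |
| `alpha_p`, `alpha_q` | 0.05 | — | strict `<` significance and FDR gates |
| `mt_min` | 0.7 | — | dominance threshold; strict `>`, so MT exactly 0.7 is not selective |
| `test_flavor` | `student` | — | pooled-variance t; `welch` optional |
| `tails` | `two_sided` | — | conservative reading of an unspecified sidedness |
| `fdr_method` | `bh` | — | BH is parameter-free and reproducible; `storey` rescales BH by an estimated null proportion |
| `filter_basis` | `organ_mean` | — | the floor applies to the max organ *mean*, consistent with every other organ-level summary; `sample_max` applies it to the largest single replicate |
| `interesting_requires_q` | `FALSE` | — | the enrichment foreground gates on p only; set `TRUE` to require the q-gate too |

The abundance filter is applied to organ means rather than individual
replicates because organs are summarised by means everywhere else in
the procedure; the alternative is still exposed because the phrase
"maximum FPKM value in any organ" is genuinely ambiguous between the
two readings.

## The synthetic-data generator

`sim_config()` / `simulate_study()` emulate the 11-organ × 3-replicate
design: a log-normal baseline of per-gene abundance, a planted fraction
of selective genes whose target organ holds an exact share `dominance`
of the summed true organ means (the remainder split uniformly over the
other organs), a fraction of genes forced below the abundance floor,
and multiplicative log-normal replicate noise with unit mean and
`CV = noise_cv` (`sigma^2 = log(1 + cv^2)`), which keeps abundances
positive and mimics FPKM dispersion without a count model. A count
mode additionally draws negative-binomial fragment counts with gene
lengths and library sizes, so FPKM computation can be round-trip
tested. One seeded stream is consumed in a fixed order (baselines,
class assignment, noise, count draws), so identical configurations are
bit-identical.

Defaults are the study conditions the package is validated under:
11 organs, 3 replicates, 10% planted markers at dominance 0.9, 10%
low-expressed genes, and `noise_cv = 0.1` — a replicate CV chosen once
as typical of well-controlled bulk RNA-seq organ panels (no published
dispersion estimate exists for the motivating design, so this is a
modeling choice). Two deliberate simplifications:

* baselines of expressed (non-low) genes are truncated below at
  1.2 × the abundance floor, so the planted truth classes stay
  unambiguous under noise — the generator plants *categories*, and a
  marker gene drifting under the filter would blur what "recovery"
  means;
* there are no batch effects, no organ-correlation structure beyond
  the planted dominance, and no heavy-tailed outliers.

Passing the recovery tests therefore shows the screen implements its
definition correctly and is well-behaved under realistic replicate
noise; it does not show robustness to the full messiness of real
organ panels.

## Numerical conventions and degenerate inputs

* **Ties** in organ means are broken by ascending organ code everywhere
  (max and median location, and the generator's labels are chosen so
  lexicographic order is numeric order), so runs are deterministic; a
  tie between the max and median *values* is flagged in the output.
* **Zero variance in both compared groups** leaves the t statistic
  undefined; the contract is `p = 1` when the group means are equal and
  `p = 0` otherwise — the limit of the test as the common variance
  shrinks. This arises routinely in noise-free synthetic data.
* **All-zero genes** (total 0) get an `NA` MT ratio; they are always
  `low_expression` under any positive floor.
* FPKM uses the column sums of the supplied count matrix as library
  sizes, making the operation self-contained; pre-scale the counts to
  use mapped-read totals instead.
* Expression TSVs are written with `%.17g`, so write → read round
  trips are bit-exact.
* The hypergeometric upper tail is `P(X >= k)` via `stats::phyper`,
  which works in log space internally and is accurate for the
  `1e-6`-scale tails that enrichment tables report.
* Storey's null-proportion estimate uses the λ grid 0.05–0.95 (step
  0.05) with a df-3 smoothing spline read off at λ = 0.95, falling back
  to the grid mean for short p-vectors; BH remains the default because
  it has no tuning at all.
* Organ clustering delegates agglomeration to `stats::hclust`; its
  deterministic merge order stands in for an explicit lexicographic
  tie-break rule. Newick branch lengths place each leaf at half its
  merge height (the `ape::as.phylo` convention for ultrametric trees).
* Enrichment backgrounds default to genes annotated in at least one
  set of the collection — the convention that produces fixed
  per-collection denominators (`K/N` with one N per collection) — and
  can be widened to a user universe with
  `restrict_to_annotated = FALSE`.

## Design choices that were genuinely open

* **Which genes feed the enrichment foreground**: interesting genes
  (p-gate only) by default, with `interesting_requires_q = TRUE` as the
  stricter reading.
* **Linkage**: no linkage is canonical for Bray–Curtis organ profiles;
  average (UPGMA) is the common companion and the default, with
  complete and single exposed. Distances are computed on per-organ
  mean profiles (one leaf per organ), over all genes in the matrix.
* **Report ordering**: per-organ tables sort by ascending q, then p,
  then gene id — a documented, stable convention.
* **Genes without description** are handled as an optional input
  attribute upstream of this package; the report tables do not model
  annotation status.

## Problem sizes in the test suite

The suite validates at desk scale: recovery studies of 300–2,000 genes
(11 organs × 3 replicates; ~200 planted markers at dominance 0.9,
noise CV 0.1), 20 randomised screen-vs-oracle studies of 100 genes
with 5–11 organs and 2–4 replicates, 1,000 random p-vectors of length
up to 500 for the BH oracle, and toy distance matrices with
hand-computed agglomerations. These sizes exercise every code path;
the implementation is vectorised and handles the ~33k-gene scale of a
full organ panel without special treatment.

## Known limitations

* The max-vs-median test inherits the selection effect discussed
  above; its p-values should be read as screening scores, not
  calibrated tail probabilities.
* One test per gene means a gene selective in *two* organs (e.g. a
  shared gut marker) can only ever be assigned to its single max
  organ.
* The MT ratio depends on the organ panel: adding organs dilutes the
  denominator, so thresholds are only comparable across studies with
  the same panel.
* Flat GMT over-representation ignores ontology structure; a
  graph-aware GO method will differ, most visibly for broad parent
  terms.
* The generator's uniform split of the non-dominant share is the
  simplest alternative model; real off-target expression is itself
  structured.
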
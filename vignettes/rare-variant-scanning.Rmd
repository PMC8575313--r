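---
title: "Homozygosity-aware prioritisation and rare-variant burden scanning with obscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity-aware prioritisation and rare-variant burden scanning with obscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obscan)
```

## The two analyses

`obscan` implements the computational core of a gene-discovery design used
for severe early-onset obesity, and applicable to recessive disease
generally. It has two arms.

**Arm 1 — consanguinity-aware prioritisation.** In probands from
consanguineous families, large tracts of the genome are identical by
descent, so a recessive causal allele is expected to sit as a *homozygote
inside a run of homozygosity* (ROH). The pipeline takes hard-filtered exome
calls, rare coding annotations and externally-called ROH intervals, and
emits every (individual, variant) pair where the call is hom-alt and the
position lies inside an ROH longer than 100 kb (strict, matching the
printed inequality). Genes are then selected when they carry a HIGH-impact
(stop-gain / frameshift) variant or when at least two affected individuals
carry a qualifying variant, and selected genes are mapped to *Drosophila*
orthologues by maximum DIOPT score for downstream functional screening.

**Arm 2 — case-control burden scanning.** In large case-control exome
panels, rare coding variants are collapsed per gene — or per sliding window
of the canonical transcript's protein — and tested for association with
case status. The burden statistic is the score test

$$ b_i = \sum_j w_j\, g_{ij}, \qquad
   U = \sum_i (y_i - \bar y)\, b_i, \qquad
   Q = \frac{U^2}{\bar y (1-\bar y) \sum_i (b_i - \bar b)^2} \sim \chi^2_1 $$

with $g_{ij} \in \{0,1,2\}$ the genotype code and weights
$w_j = \mathrm{Beta}(\mathrm{MAF}_j; 1, 25)$ by default (the convention of
the SKAT family of tests, whose binary-trait "burden, unadjusted
asymptotic" variant this reproduces; variance-component SKAT and SKAT-O are
deliberately out of scope). Carrier-level evidence is summarised by the
exact 2x2 machinery: the two-sided Fisher p (probability-mass criterion),
the conditional-MLE odds ratio under the noncentral hypergeometric
distribution, and the exact conditional CI. P-values are adjusted by
Benjamini-Hochberg and Holm, implemented from the step-up/step-down
formulas.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| ROH length floor | 100,000 (strict `>`) | bp | tracts shorter than ~100 kb are common in outbred genomes and carry little IBD signal |
| karyotype ROH floor | 4,000,000 (strict `>`) | bp | the "medium-to-large" tract class summarised in cohort coverage heatmaps |
| MAF tiers | 0.01 / 0.001 / 0.00025 (strict `<`) | fraction | the 1% pre-filter, "rare" and "very rare" tiers; all comparisons strict, matching every printed inequality |
| window / shift | 500 / 200 | aa | 1,500 bp / 600 bp on the transcript; windows overlap by 300 aa |
| burden weights | Beta(MAF; 1, 25) | — | strongly up-weights the rarest sites; `unit` available |
| kinship cut-off | 0.0442 (`>=` related) | — | third-degree-relative threshold for unrelated-subset selection |
| BMI cut-off | 40 (case strict `>`) | kg/m² | severe-obesity dichotomisation; missing BMI is excluded |

QC comes in three dialects: `ug2013` (`DP < 4` or `MQ0 >= 4 & MQ0/DP > 0.1`
excludes), `hc_hard` (GATK hard thresholds, separate SNV and indel rule
sets) and `gh` (site-level `PASS` + `FS < 30`, per-call `GQ > 10`). A
missing metric never fails a rule — filters act only on observed evidence —
and is logged as `untested`. The `gh` GQ rule is applied per call (the call
is masked to missing) because the source description does not fix the
level; this is a documented package decision.

## Design choices where the design was open

* **Tiling rule.** Only the window size and overlap are externally fixed.
  Candidate windows start on the 200 aa grid, are clipped at the protein
  length, and a window contained in an earlier one is dropped. This
  guarantees full coverage of `[1, L]`, no duplicate-subset windows, and an
  exact 300 aa overlap between consecutive full-width windows. Window
  counts depend on this rule, so it is stated prominently; other rules
  (e.g. anchoring the last window at `L - W + 1`) yield slightly different
  window families.
* **Adjustment scope.** Multiple-testing adjustment defaults to the whole
  scanned gene set; per-gene scope is available. Empty windows are reported
  but excluded from the number of tests, since a zero-marker window has no
  p-value. Note that step-up BH in a smaller family is *not* guaranteed to
  be smaller per window (Holm is); tests assert only the provable ordering.
* **Conditional MLE as the reported OR.** The published precedent prints an
  OR with an exact-looking CI without naming the estimator; the package
  reports the conditional MLE (the estimator Fisher's exact machinery
  yields) and its exact CI, solved by monotone bisection on log psi over
  `[1e-12, 1e12]` to relative tolerance `1e-8`. Support-edge tables give
  0 / infinity estimates and exact 0 / infinity CI endpoints.
* **Missing genotypes.** Missing is a first-class code (`-1`) at I/O;
  downstream, carriers treat missing as non-carrier evidence and the
  burden test codes missing as hom-ref by default (mean imputation
  optional). These follow the convention of the cited test family; the
  source is silent.
* **Greedy unrelated-subset selection.** Repeatedly remove the individual
  with the highest related-degree, ties broken by removing the
  lexicographically largest id. The contract is independence and
  determinism, not maximum cardinality.
* **Orthologue ties.** Equal DIOPT scores resolve to the lexicographically
  smallest fly symbol and are flagged; no external rule exists.
* **Prioritisation clause.** Two near-equivalent phrasings exist in the
  source material; the broader one (HIGH impact, or >= 2 carriers of any
  qualifying variant) is the default `methods` rule, the narrower
  frameshift/stop-gain + recurrent-missense reading ships as the
  `results` preset.

## What the synthetic cohorts emulate — and what they do not

The generator states one world and sticks to it: 73 probands of whom 57
are offspring of consanguineous unions (F = 1/16, first cousins; the rest
F = 0) for the discovery arm, and an outbred 4,984-person panel at case
prevalence 0.186 (a 927-case / 4,057-control split) for the case-control
arm. Sites get allele frequencies from a uniform law spanning the rare
tiers; VEP-like impacts are drawn from a fixed mixture
(5% HIGH / 60% MODERATE / 25% LOW / 10% MODIFIER); annotated population
frequencies equal the true simulation frequency unless noise is requested.

Autozygosity is simulated mechanically, not genealogically: per individual,
contiguous blocks with exponential lengths (mean 2 Mb) are placed uniformly
until a genome fraction F is covered; inside a block no heterozygote can be
drawn (hom-alt with probability p), outside blocks genotypes are
Hardy-Weinberg. Marginally this realises
`P(hom-alt) = p^2 + F p (1 - p)`, and the emitted ROH intervals are exactly
the placed blocks. Phenotypes are logistic:
`logit P(case) = beta0 + log(OR) * carrier`, with `beta0` solved against
the target marginal prevalence; BMI is a monotone noisy transform of the
case propensity, a convenience for exercising the dichotomiser only.

Not modelled: linkage disequilibrium, identity-by-descent pedigree
structure, sequencing error, annotation ascertainment bias, population
stratification. A green recovery test therefore establishes that the
pipeline's logic is correct on data satisfying its own assumptions — it
says nothing about robustness to stratification or call-quality artefacts
in real cohorts.

## Numerical conventions

* Two-sided Fisher p sums support probabilities `<= (1 + 1e-7) * P(obs)`,
  the same relative slack base R uses, so ties at machine precision count.
* Degenerate variation in the burden test (`Var(U) = 0`) returns
  `Q = 0, p = 1` rather than NaN.
* Internal allele frequency over an all-missing site is missing, never 0,
  and missing population frequencies pass the rarity filters by default
  ("below threshold or absent").
* All internal coordinates are 1-based inclusive (bp and amino acids); BED
  half-open input is converted once at the reader boundary. ROH length
  comparisons are strict.
* Writers emit fixed-precision floats and documented sort orders, so
  identical inputs give byte-identical outputs.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(simulation_config(
  seed = 1, n_individuals = 4984, n_consanguineous = 0, n_sites = 300,
  af_law = list(law = "uniform", lo = 1e-5, hi = 2.5e-4),
  causal_region = list(gene = "G03", aa_start = 601, aa_end = 700),
  n_causal_sites = 30, causal_af = 2.2e-4, carrier_or = 3))

ann <- consequence_filter(co$annotations, "exonic_nonsyn")
ann <- frequency_filter(ann, frequency_policy(
  0.00025, c("af_gnomAD_ALL", "af_gnomAD_SAS"), include_internal = FALSE))
res <- scan_gene_set(co$genotypes, co$phenotypes, ann, co$transcripts,
                     scan_config())
call_regions(res)
```

## Known limitations

* SKAT variance-component and SKAT-O statistics are out of scope; gene and
  window tests use the burden score statistic only, so signals spread over
  variants with opposing effect directions will be missed by design.
* Covariate adjustment is not implemented (the API reserves the slot); the
  null model is intercept-only, matching the precedent of testing without
  covariates.
* The published "approximately 3,200 windows" for the original gene list is
  not reproducible without that list's exact transcript lengths, and the
  original custom tiling at window boundaries may differ from the
  containment-drop rule here.
* ROH calling, kinship estimation and orthology prediction are consumed as
  inputs, never recomputed.
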
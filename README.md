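# obscan

Homozygosity-aware rare-variant prioritisation and case-control burden
scanning for gene discovery in severe obesity (and recessive disease
generally).

Two analyses share one toolbox:

1. **Consanguinity-aware prioritisation.** Probands from consanguineous
   families carry long runs of homozygosity (ROH), and a recessive causal
   allele is expected as a homozygote inside one. `obscan` applies
   hard-filter QC dialects to exome calls, tiered population-frequency
   filters (1% / 0.1% "rare" / 0.025% "very rare", all strict `<`) and
   consequence filters, restricts homozygous calls to ROH longer than
   100 kb, selects genes carrying a HIGH-impact variant or variants in two
   or more affected individuals, and maps the selection to *Drosophila*
   orthologues by maximum DIOPT score.

2. **Case-control burden scanning.** Rare coding variants are collapsed per
   gene or per sliding window of the canonical transcript protein (500 aa
   windows shifted by 200 aa) and tested with the binary-trait weighted
   burden score test

   `Q = U^2 / Var(U)`, with `U = sum_i (y_i - ybar) b_i` and
   `b_i = sum_j w_j g_ij`, `w_j = Beta(MAF_j; 1, 25)`, `Q ~ chi^2(1)`.

   Carrier-level evidence is summarised by exact 2x2 statistics: two-sided
   Fisher p, conditional-MLE odds ratio under the noncentral
   hypergeometric model, and the exact conditional CI. BH and Holm
   adjustments are applied across genes or windows, and significant
   windows (adjusted p < 0.05 and OR > 1) merge into region calls.

A synthetic-cohort generator emulates the statistical structure both arms
assume — rare site frequencies, inbreeding-driven homozygosity with
matching ROH intervals (`P(hom-alt) = p^2 + F p(1-p)`), VEP-like
annotations, and logistic case-control phenotypes with region-localised
carrier effects — so every stage is testable without protected human data.

## Worked example

The published TAOK2 carrier counts (14 of 925 severely obese cases vs 426
of 46,673 controls carrying a very rare coding variant) ship as a fixture:

```r
library(obscan)
tb <- taok2_carrier_table()
#  a     b     c     d
# 14   911   426 46247
fe <- fisher_exact(tb)
round(c(p = fe$p, or = fe$or, lo = fe$ci[1], hi = fe$ci[2]), 4)
#      p      or      lo      hi
# 0.0783  1.6683  0.9007  2.8450
```

That is the printed `OR = 1.6 (0.9 to 2.8), p = 0.08` at reporting
precision. Likewise the 27-row orthologue table dedups to its published 24
fly genes:

```r
ortho <- read_orthologues(obscan_fixture("orthologues_table1"))
mp <- map_orthologues(unique(ortho$human_gene), ortho)
length(mp$fly_genes)
# [1] 24
```

End-to-end on synthetic data:

```r
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
call_regions(res)[, c("gene", "aa_start", "aa_end", "tier", "best_p")]
#   gene aa_start aa_end    tier      best_p
# 1  G01     1601   2100 nominal 0.033614994
# 2  G03      201   1100 nominal 0.002199425
# 3  G06      201    800 nominal 0.002023700
```

The called G03 region spans the windows containing the planted 601-700 aa
causal segment (seed 1 happens to be a weaker draw that stays in the
nominal tier; across 100 replicates the planted region is recovered as the
top call in well over 80%, which is what the acceptance suite asserts).

## Command line

```sh
Rscript inst/cli/obscan.R simulate    --config cfg.json --seed 1 --out out/
Rscript inst/cli/obscan.R prioritize  --config cfg.json --out out/
Rscript inst/cli/obscan.R gene-test   --config cfg.json --out out/
Rscript inst/cli/obscan.R window-scan --config cfg.json --out out/
Rscript inst/cli/obscan.R regions     --config cfg.json --out out/
```

The JSON config is the single source of thresholds; unknown keys are
rejected by name. Every run writes a `log.txt` with the tool version,
config hash, seed, input checksums and the per-stage variant funnel.
Identical config and inputs give byte-identical outputs.

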
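test_that("simulate_sites honours the AF law and impact mixture", {
  set.seed(420)
  cfg <- simulation_config(seed = 420, n_individuals = 5,
                           af_law = list(law = "point_mass",
                                         af = c(0.001, 0.01)))
  ss <- simulate_sites(cfg)
  expect_equal(sort(ss$annotations$af_gnomAD_ALL), c(0.001, 0.01))
  expect_equal(sort(attr(ss$sites, "true_af")), c(0.001, 0.01))

  cfg2 <- simulation_config(seed = 421, n_individuals = 5, n_sites = 50,
                            impact_mix = c(HIGH = 1, MODERATE = 0, LOW = 0,
                                           MODIFIER = 0))
  set.seed(421)
  ss2 <- simulate_sites(cfg2)
  expect_true(all(ss2$annotations$impact == "HIGH"))

  set.seed(422)
  cfg3 <- simulation_config(seed = 422, n_individuals = 5, n_sites = 10000,
                            af_law = list(law = "uniform", lo = 1e-4, hi = 5e-4))
  ss3 <- simulate_sites(cfg3)
  m <- mean(attr(ss3$sites, "true_af"))
  se <- (5e-4 - 1e-4) / sqrt(12) / sqrt(10000)
  expect_lt(abs(m - 3e-4), 3 * se)
})

test_that("inbreeding model produces the expected homozygosity structure", {
  # F = 1: the whole genome is autozygous; no heterozygous calls
  cfg <- simulation_config(seed = 423, n_individuals = 10, f = rep(1, 10),
                           n_sites = 200,
                           af_law = list(law = "uniform", lo = 0.2, hi = 0.5),
                           per_call_metrics = FALSE)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$genotypes$calls == 1L), 0)
  expect_true(nrow(co$roh) > 0)

  # p = 0: everyone is hom-ref
  cfg0 <- simulation_config(seed = 424, n_individuals = 10,
                            af_law = list(law = "point_mass", af = rep(0, 20)),
                            per_call_metrics = FALSE)
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$genotypes$calls == 0L))

  # F = 0 at p = 0.5: HWE het probability is exactly 1/2
  cfg5 <- simulation_config(seed = 425, n_individuals = 50, f = rep(0, 50),
                            af_law = list(law = "point_mass",
                                          af = rep(0.5, 200)),
                            per_call_metrics = FALSE)
  co5 <- simulate_cohort(cfg5)
  ncalls <- length(co5$genotypes$calls)
  hf <- mean(co5$genotypes$calls == 1L)
  expect_lt(abs(hf - 0.5), 3 * sqrt(0.25 / ncalls))
  expect_equal(nrow(co5$roh), 0)

  # emitted ROH match the genotype constraint: no hets inside own intervals
  cfgr <- simulation_config(seed = 426, n_individuals = 20,
                            f = rep(0.3, 20), n_sites = 300,
                            af_law = list(law = "uniform", lo = 0.2, hi = 0.5),
                            per_call_metrics = FALSE)
  cor <- simulate_cohort(cfgr)
  for (i in seq_along(cor$genotypes$individuals)) {
    ind <- cor$genotypes$individuals[i]
    r <- cor$roh[cor$roh$individual == ind, ]
    het <- which(cor$genotypes$calls[i, ] == 1L)
    for (j in het) {
      s <- cor$sites[j, ]
      expect_false(any(r$chrom == s$chrom & r$start <= s$pos & s$pos <= r$end))
    }
  }
})

test_that("phenotype model hits the target prevalence and carrier effect", {
  cfg <- simulation_config(seed = 427, n_individuals = 5000,
                           n_consanguineous = 0, n_sites = 20,
                           carrier_or = 1, prevalence = 0.186,
                           per_call_metrics = FALSE)
  co <- simulate_cohort(cfg)
  prev <- mean(co$phenotypes$status == "case")
  expect_lt(abs(prev - 0.186), 3 * sqrt(0.186 * 0.814 / 5000))

  # with zero carriers the labels are genotype-independent by construction
  expect_equal(sum(co$truth$carrier), 0)

  # planted carrier effect: empirical carrier OR near the target
  cfg3 <- simulation_config(seed = 428, n_individuals = 4000,
                            n_consanguineous = 0, n_sites = 40,
                            causal_region = list(gene = "G03", aa_start = 1,
                                                 aa_end = 1235),
                            n_causal_sites = 20, causal_af = 0.02,
                            carrier_or = 3, per_call_metrics = FALSE)
  co3 <- simulate_cohort(cfg3)
  expect_gt(sum(co3$truth$carrier), 50)
  tb <- carrier_table(co3$genotypes, co3$phenotypes, co3$truth$causal_keys)
  fe <- fisher_exact(tb)
  expect_true(fe$ci[1] < 3 && 3 < fe$ci[2])  # CI covers the planted OR
  # prevalence is still matched marginally
  prev3 <- mean(co3$phenotypes$status == "case")
  expect_lt(abs(prev3 - 0.186), 3 * sqrt(0.186 * 0.814 / 4000))
})

test_that("causal sites always fall inside the planted region's windows", {
  cfg <- simulation_config(seed = 429, n_individuals = 10, n_sites = 30,
                           causal_region = list(gene = "G03", aa_start = 601,
                                                aa_end = 700),
                           per_call_metrics = FALSE)
  co <- simulate_cohort(cfg)
  ann <- co$annotations[variant_key(co$annotations) %in% co$truth$causal_keys, ]
  expect_equal(nrow(ann), 10)
  expect_true(all(ann$gene == "G03"))
  expect_true(all(ann$protein_start >= 601 & ann$protein_start <= 700))
  wins <- tile_windows(1235)
  asg <- assign_variants_to_windows(wins, ann)
  expect_true(all(variant_key(ann) %in% unlist(asg)))
})

test_that("the writer is deterministic for a fixed seed", {
  co1 <- simulate_cohort(simulation_config(seed = 430, n_individuals = 8,
                                           n_sites = 40))
  co2 <- simulate_cohort(simulation_config(seed = 430, n_individuals = 8,
                                           n_sites = 40))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_cohort(co1, d1); p2 <- write_cohort(co2, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
})

test_that("per-individual hom-excess regression recovers planted F (small)", {
  cfg <- simulation_config(seed = 431, n_individuals = 120,
                           f = seq(0, 0.25, length.out = 120), n_sites = 2000,
                           af_law = list(law = "uniform", lo = 0.05, hi = 0.3),
                           per_call_metrics = FALSE)
  co <- simulate_cohort(cfg)
  p <- co$truth$true_af
  het_exp <- sum(2 * p * (1 - p))
  fhat <- 1 - rowSums(co$genotypes$calls == 1L) / het_exp
  fit <- summary(lm(fhat ~ co$truth$f_planted))
  slope <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3 * se + 0.02)
})
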
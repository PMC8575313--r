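test_that("tile_windows follows the grid / clip / containment-drop rule", {
  expect_equal(tile_windows(400)[, c("aa_start", "aa_end")],
               data.frame(aa_start = 1, aa_end = 400))
  tw <- tile_windows(1000)
  expect_equal(tw$aa_start, c(1, 201, 401, 601))
  expect_equal(tw$aa_end, c(500, 700, 900, 1000))
  tw2 <- tile_windows(700)
  expect_equal(tw2$aa_start, c(1, 201))
  expect_equal(tw2$aa_end, c(500, 700))
})

test_that("tiling covers every position with the stated overlap", {
  set.seed(408)
  for (L in c(1, 2, 199, 200, 201, 499, 500, 501, sample(1:3000, 40))) {
    tw <- tile_windows(L)
    cov <- rep(FALSE, L)
    for (i in seq_len(nrow(tw))) cov[tw$aa_start[i]:tw$aa_end[i]] <- TRUE
    expect_true(all(cov))
    if (nrow(tw) > 1) {
      ov <- tw$aa_end[-nrow(tw)] - tw$aa_start[-1] + 1
      # full-width consecutive windows overlap by exactly W - S = 300
      full <- tw$aa_end[-nrow(tw)] - tw$aa_start[-nrow(tw)] + 1 == 500 &
        tw$aa_end[-1] - tw$aa_start[-1] + 1 == 500
      expect_true(all(ov[full] == 300))
      expect_true(all(ov >= 1))  # never disjoint
    }
  }
})

mk_scan_ann <- function(pos, ppos, gene = "G1", transcript = "T1") {
  data.frame(chrom = "1", pos = pos, ref = "A", alt = "T", gene = gene,
             transcript = transcript, consequence = "missense_variant",
             impact = "MODERATE", protein_start = ppos, protein_end = ppos,
             sift = NA, polyphen = NA, stringsAsFactors = FALSE)
}

test_that("variants are assigned to every window containing their position", {
  wins <- tile_windows(1000)
  ann <- mk_scan_ann(c(10L, 20L, 30L), c(250L, NA, 57L))
  asg <- assign_variants_to_windows(wins, ann)
  expect_equal(asg[["1"]], c("1:10:A:T", "1:30:A:T"))   # 250 and 57 in (1,500)
  expect_equal(asg[["2"]], "1:10:A:T")                  # 250 in (201,700)
  expect_equal(attr(asg, "unassigned"), "1:20:A:T")     # no protein position
  expect_error(assign_variants_to_windows(wins, mk_scan_ann(40L, 1001L),
                                          protein_length = 1000), "T1")
  # a variant appears in at least 1 and at most ceil(W/S) windows
  counts <- table(unlist(asg))
  expect_true(all(counts >= 1 & counts <= ceiling(500 / 200)))
})

scan_world <- function(seed, carrier_or = 1, n = 600) {
  cfg <- simulation_config(seed = seed, n_individuals = n,
                           n_consanguineous = 0, n_sites = 80,
                           af_law = list(law = "uniform", lo = 1e-3, hi = 2e-2),
                           causal_region = if (carrier_or != 1)
                             list(gene = "G03", aa_start = 601, aa_end = 700),
                           carrier_or = carrier_or, n_causal_sites = 10,
                           causal_af = 0.01, per_call_metrics = FALSE)
  simulate_cohort(cfg)
}

test_that("scan_gene_set tests non-empty windows and adjusts per scope", {
  co <- scan_world(409)
  ann <- consequence_filter(co$annotations, "exonic_nonsyn")
  res_set <- scan_gene_set(co$genotypes, co$phenotypes, ann, co$transcripts,
                           scan_config(scope = "gene_set"))
  res_gene <- scan_gene_set(co$genotypes, co$phenotypes, ann, co$transcripts,
                            scan_config(scope = "per_gene"))
  # identical raw statistics, different adjustment scope
  expect_identical(res_set$p, res_gene$p)
  expect_identical(res_set$Q, res_gene$Q)
  # Holm with a smaller test family is never larger (step-down theorem);
  # BH is rank-dependent, so it is checked by exact recomputation instead
  for (g in unique(res_set$gene)) {
    i <- res_set$gene == g & !is.na(res_set$p)
    expect_true(all(res_gene$p_holm[i] <= res_set$p_holm[i] + 1e-12))
    expect_equal(res_gene$p_bh[i], adjust_pvalues(res_set$p[i], "BH"))
  }
  # empty windows excluded from m: BH with the reduced m reproduces p_bh
  expect_equal(res_set$p_bh[!is.na(res_set$p)],
               adjust_pvalues(res_set$p[!is.na(res_set$p)], "BH"))
  expect_true(all(is.na(res_set$p_bh[is.na(res_set$p)])))
  # missing transcript is an error naming the gene
  expect_error(scan_gene_set(co$genotypes, co$phenotypes, ann,
                             co$transcripts[-3, ], scan_config()), "G03")
})

test_that("single-window gene adjusts to its own raw p under per_gene scope", {
  set.seed(410)
  gm <- tiny_gm(matrix(rbinom(200 * 2, 2, 0.03), 200, 2), pos = c(10L, 20L))
  ph <- tiny_pheno(gm$individuals, rep(c("case", "control"), 100))
  ann <- mk_scan_ann(c(10L, 20L), c(40L, 300L))   # one 450 aa protein
  tr <- data.frame(gene = "G1", transcript = "T1", protein_length = 450L)
  res <- scan_gene_set(gm, ph, ann, tr, scan_config(scope = "per_gene"))
  expect_equal(nrow(res), 1)
  expect_equal(res$p_bh, res$p)
  expect_equal(res$p_holm, res$p)
})

test_that("call_regions requires OR > 1 and merges overlapping windows", {
  res <- data.frame(gene = "G1", transcript = "T1", window_index = 1:3,
                    aa_start = c(1L, 201L, 601L), aa_end = c(500L, 700L, 1100L),
                    n_markers = 3L, n_case_carriers = 5L,
                    n_control_carriers = 1L, Q = 9, p = c(0.001, 0.002, 0.3),
                    or_cmle = c(3, 2.5, 0.7), ci_lo = 1, ci_hi = 9,
                    p_bh = c(0.01, 0.02, 0.6), p_holm = c(0.01, 0.02, 0.6))
  reg <- call_regions(res)
  adj <- reg[reg$tier == "adjusted", ]
  expect_equal(nrow(adj), 1)                       # windows 1-2 merge
  expect_equal(c(adj$aa_start, adj$aa_end), c(1, 700))
  expect_equal(adj$best_p, 0.001)
  expect_equal(adj$n_windows, 2)
  # OR <= 1 blocks a significant window
  res2 <- res; res2$or_cmle <- 0.7
  expect_equal(nrow(call_regions(res2)), 0)
  # nominal tier picks up raw-significant windows
  res3 <- res; res3$p_bh <- 0.9
  expect_true(all(call_regions(res3)$tier == "nominal"))
})

test_that("planted-effect detection is recovered and grows with OR", {
  hit <- function(seed, or) {
    co <- scan_world(seed, carrier_or = or)
    ann <- consequence_filter(co$annotations, "exonic_nonsyn")
    res <- scan_gene_set(co$genotypes, co$phenotypes, ann, co$transcripts,
                         scan_config())
    reg <- call_regions(res)
    nrow(reg) > 0 && {
      top <- reg[which.min(reg$best_p), ]
      top$gene == "G03" && top$aa_start <= 601 && top$aa_end >= 700
    }
  }
  # strong planted effect: recovered in most replicates (full-size study in
  # the acceptance suite; this is a fast smoke version)
  hits5 <- mean(vapply(1:8, function(s) hit(500 + s, 5), TRUE))
  hits1 <- mean(vapply(1:8, function(s) hit(500 + s, 1), TRUE))
  expect_gte(hits5, 0.75)
  expect_lte(hits1, hits5)
})
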
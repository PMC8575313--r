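#' Default autosome lengths (approximate human, bp)
#'
#' Twenty-two autosomes at their approximate physical lengths; the ROH
#' placement model and the karyotype binning operate on this genome unless a
#' custom one is supplied.
#'
#' @return named numeric vector ("1".."22").
#' @export
default_genome <- function() {
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
  setNames(mb * 1e6, as.character(1:22))
}

#' Default transcript plan
#'
#' Eight generic genes whose protein lengths span the range seen among
#' large cadherin-family and kinase candidates (a few hundred to ~5,000 aa),
#' so the 500/200 aa tiling produces between one and ~25 windows per gene.
#'
#' @return data frame: gene, transcript, protein_length.
#' @export
default_transcript_plan <- function() {
  data.frame(gene = sprintf("G%02d", 1:8),
             transcript = sprintf("T%02d", 1:8),
             protein_length = c(4981L, 3298L, 1235L, 2200L, 1500L, 800L,
                                600L, 450L),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The defaults state the discovery-cohort world the pipeline was designed
#' for: 73 individuals of whom 57 are offspring of consanguineous unions
#' (first-cousin inbreeding coefficient F = 1/16; the remainder F = 0), 500
#' rare coding sites with allele frequencies uniform on (0.0001, 0.005)
#' (populating the 1%/0.1%/0.025% tiers), ROH blocks with exponential
#' lengths of mean 2 Mb until the genome fraction F is covered, and a
#' baseline case prevalence of 0.186 (the case fraction of a 927-case /
#' 4,057-control exome case-control panel). A causal region, when given,
#' confers `log(carrier_or)` on the case log-odds of its carriers.
#'
#' @param seed mandatory integer seed; all draws flow from one generator
#'   stream seeded once per cohort.
#' @param n_individuals,n_consanguineous cohort size and its consanguineous
#'   subset (first `n_consanguineous` individuals; default: the 57/73
#'   fraction, rounded).
#' @param f_consanguineous,f_outbred inbreeding coefficients for the two
#'   subsets; alternatively supply `f` as a full per-individual vector.
#' @param f optional explicit per-individual F vector.
#' @param n_sites number of simulated sites (ignored for point-mass AF laws).
#' @param af_law `list(law = "uniform", lo, hi)` or
#'   `list(law = "point_mass", af = c(...))`.
#' @param genome named chromosome-length vector.
#' @param transcript_plan data frame gene/transcript/protein_length.
#' @param impact_mix named probabilities over HIGH/MODERATE/LOW/MODIFIER.
#' @param causal_region `list(gene, aa_start, aa_end)` or `NULL`.
#' @param n_causal_sites,causal_af sites planted inside the causal region.
#' @param carrier_or odds ratio for causal-region carriers (>= 0).
#' @param prevalence baseline marginal P(case).
#' @param roh_mean_bp mean exponential ROH block length.
#' @param af_noise_sd sd of multiplicative log-normal noise applied to the
#'   annotated population AFs (0 = annotate the true AF).
#' @param per_call_metrics emit per-call GQ/DP matrices.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_individuals = 73,
                              n_consanguineous = NULL,
                              f_consanguineous = 1 / 16,
                              f_outbred = 0,
                              f = NULL,
                              n_sites = 500,
                              af_law = list(law = "uniform", lo = 1e-4, hi = 5e-3),
                              genome = default_genome(),
                              transcript_plan = default_transcript_plan(),
                              impact_mix = c(HIGH = 0.05, MODERATE = 0.60,
                                             LOW = 0.25, MODIFIER = 0.10),
                              causal_region = NULL,
                              n_causal_sites = 10,
                              causal_af = 0.002,
                              carrier_or = 1,
                              prevalence = 0.186,
                              roh_mean_bp = 2e6,
                              af_noise_sd = 0,
                              per_call_metrics = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(f)) {
    # default consanguineous fraction mirrors a 57-of-73 discovery cohort
    n_consanguineous <- n_consanguineous %||% round(n_individuals * 57 / 73)
    stopifnot(n_consanguineous <= n_individuals)
    f <- c(rep(f_consanguineous, n_consanguineous),
           rep(f_outbred, n_individuals - n_consanguineous))
  }
  stopifnot(all(f >= 0 & f <= 1), length(f) == n_individuals,
            carrier_or >= 0, prevalence > 0, prevalence < 1,
            abs(sum(impact_mix) - 1) < 1e-8)
  if (!is.null(causal_region)) {
    stopifnot(all(c("gene", "aa_start", "aa_end") %in% names(causal_region)))
    if (!causal_region$gene %in% transcript_plan$gene)
      stop("causal_region gene is not in the transcript plan")
  }
  structure(list(seed = as.integer(seed), n_individuals = n_individuals,
                 f = f, n_sites = n_sites, af_law = af_law, genome = genome,
                 transcript_plan = transcript_plan, impact_mix = impact_mix,
                 causal_region = causal_region, n_causal_sites = n_causal_sites,
                 causal_af = causal_af, carrier_or = carrier_or,
                 prevalence = prevalence, roh_mean_bp = roh_mean_bp,
                 af_noise_sd = af_noise_sd,
                 per_call_metrics = per_call_metrics),
            class = "simulation_config")
}

sample_consequence <- function(impact, is_indel) {
  switch(impact,
         HIGH = if (is_indel) "frameshift_variant" else "stop_gained",
         MODERATE = "missense_variant",
         LOW = "splice_region_variant",
         MODIFIER = "intron_variant")
}

#' Simulate sites and their VEP-like annotations
#'
#' Draws site allele frequencies from the configured law, places sites
#' uniformly on the genome, assigns each to a gene with probability
#' proportional to protein length, gives HIGH/MODERATE sites a protein
#' position, draws impacts from the impact mixture and annotates population
#' AFs equal to the true AF (optionally log-normally perturbed). Causal
#' sites, when a causal region is configured, are appended inside that
#' region as missense sites at `causal_af`.
#'
#' Does not seed the RNG; call within [simulate_cohort()] or after
#' `set.seed()`.
#'
#' @param config a [simulation_config()].
#' @return list: `sites` (site-table schema), `annotations`, `truth`
#'   (causal site keys).
#' @export
simulate_sites <- function(config) {
  af <- if (config$af_law$law == "point_mass") config$af_law$af
  else runif(config$n_sites, config$af_law$lo, config$af_law$hi)
  n <- length(af)
  plan <- config$transcript_plan
  gidx <- sample.int(nrow(plan), n, replace = TRUE,
                     prob = plan$protein_length)
  impact <- sample(names(config$impact_mix), n, replace = TRUE,
                   prob = config$impact_mix)
  causal <- rep(FALSE, n)
  if (!is.null(config$causal_region)) {
    cr <- config$causal_region
    af <- c(af, rep(config$causal_af, config$n_causal_sites))
    gidx <- c(gidx, rep(match(cr$gene, plan$gene), config$n_causal_sites))
    impact <- c(impact, rep("MODERATE", config$n_causal_sites))
    causal <- c(causal, rep(TRUE, config$n_causal_sites))
    n <- length(af)
  }
  is_indel <- impact == "HIGH" & runif(n) < 0.5

  genome <- config$genome
  chrom <- sample(names(genome), n, replace = TRUE, prob = genome)
  pos <- floor(runif(n, 1, genome[chrom])) |> as.integer()
  while (anyDuplicated(paste(chrom, pos))) {
    dup <- duplicated(paste(chrom, pos))
    pos[dup] <- as.integer(floor(runif(sum(dup), 1, genome[chrom[dup]])))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  ref[is_indel] <- paste0(ref[is_indel], "A")
  alt[is_indel] <- substr(ref[is_indel], 1, 1)

  plen <- plan$protein_length[gidx]
  ppos <- ifelse(impact %in% c("HIGH", "MODERATE"),
                 1L + as.integer(floor(runif(n) * plen)), NA_integer_)
  if (!is.null(config$causal_region)) {
    cr <- config$causal_region
    ppos[causal] <- cr$aa_start +
      as.integer(floor(runif(sum(causal)) * (cr$aa_end - cr$aa_start + 1)))
  }
  consequence <- mapply(sample_consequence, impact, is_indel)
  mis <- consequence == "missense_variant"
  sift <- ifelse(mis, sample(c("deleterious", "tolerated"), n, TRUE,
                             prob = c(0.3, 0.7)), NA)
  polyphen <- ifelse(mis, sample(c("probably_damaging", "possibly_damaging",
                                   "benign"), n, TRUE,
                                 prob = c(0.3, 0.3, 0.4)), NA)

  o <- order(match(chrom, names(genome)), pos)
  af <- af[o]; gidx <- gidx[o]; impact <- impact[o]; causal <- causal[o]
  chrom <- chrom[o]; pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  ppos <- ppos[o]; consequence <- consequence[o]
  sift <- sift[o]; polyphen <- polyphen[o]

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      variant_class = ifelse(is_snv(ref, alt), "SNV", "indel"),
                      DP = as.integer(round(runif(n, 20, 80))),
                      MQ0 = 0, QD = round(runif(n, 10, 35), 2),
                      MQ = 60, FS = round(runif(n, 0, 10), 3),
                      SOR = round(runif(n, 0.3, 2), 3),
                      MQRankSum = round(rnorm(n), 3),
                      ReadPosRankSum = round(rnorm(n), 3),
                      InbreedingCoeff = round(runif(n, -0.1, 0.3), 3),
                      FILTER = "PASS", internal_af = NA_real_,
                      stringsAsFactors = FALSE)
  attr(sites, "dialect") <- "hc_hard"
  attr(sites, "true_af") <- af
  noise <- if (config$af_noise_sd > 0)
    exp(rnorm(n, 0, config$af_noise_sd)) else 1
  ann <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = config$transcript_plan$gene[gidx],
                    transcript = config$transcript_plan$transcript[gidx],
                    consequence = consequence, impact = impact,
                    protein_start = ppos, protein_end = ppos,
                    sift = sift, polyphen = polyphen,
                    af_gnomAD_ALL = pmin(1, af * noise),
                    af_gnomAD_SAS = pmin(1, af * noise),
                    stringsAsFactors = FALSE)
  attr(ann, "pop_afs") <- c("af_gnomAD_ALL", "af_gnomAD_SAS")
  list(sites = sites, annotations = ann,
       truth = list(causal_keys = variant_key(sites)[causal], true_af = af))
}

# ROH blocks for one individual: exponential lengths (mean roh_mean_bp)
# placed uniformly until the merged coverage reaches F * genome size.
place_roh_blocks <- function(f, genome, roh_mean_bp) {
  if (f <= 0) return(data.frame(chrom = character(), start = numeric(),
                                end = numeric()))
  if (f >= 0.999)  # fully autozygous: whole-chromosome blocks
    return(data.frame(chrom = names(genome), start = 1,
                      end = unname(genome), row.names = NULL))
  target <- f * sum(genome)
  blocks <- data.frame(chrom = character(), start = numeric(), end = numeric())
  covered <- 0
  guard <- 0L
  while (covered < target && guard < 1000L) {
    guard <- guard + 1L
    k <- max(2L, ceiling((target - covered) / roh_mean_bp * 1.2))
    chrom <- sample(names(genome), k, replace = TRUE, prob = genome)
    len <- pmax(1e4, rexp(k, rate = 1 / roh_mean_bp))
    start <- floor(runif(k, 1, genome[chrom]))
    end <- pmin(start + len - 1, genome[chrom])
    blocks <- rbind(blocks, data.frame(chrom = chrom, start = start, end = end))
    blocks <- do.call(rbind, lapply(split(blocks, blocks$chrom), function(g) {
      m <- merge_intervals(g$start, g$end)
      data.frame(chrom = g$chrom[1], start = m$start, end = m$end)
    }))
    covered <- sum(blocks$end - blocks$start + 1)
  }
  rownames(blocks) <- NULL
  blocks
}

#' Simulate genotypes with inbreeding-driven homozygosity and matching ROH
#'
#' Per individual, contiguous autozygous blocks are placed until the genome
#' fraction F is covered. Sites inside a block are drawn without
#' heterozygotes (hom-alt with probability p, else hom-ref); sites outside
#' follow Hardy-Weinberg at the site AF. Marginally this realises the
#' standard inbreeding model `P(hom-alt) = p^2 + F p(1-p)`,
#' `P(het) = 2p(1-p)(1-F)`. The emitted ROH intervals are exactly the
#' placed blocks.
#'
#' Does not seed the RNG (see [simulate_cohort()]).
#'
#' @param sites site table from [simulate_sites()] (needs `true_af` attr, or
#'   pass `af`).
#' @param config a [simulation_config()].
#' @param af optional per-site allele-frequency vector.
#' @return list: `genotypes` ([genotype_matrix()]), `roh` (1-based
#'   inclusive), `f_realized` (per-individual covered genome fraction).
#' @export
simulate_genotypes <- function(sites, config, af = NULL) {
  af <- af %||% attr(sites, "true_af")
  if (is.null(af)) stop("no allele frequencies available for sites")
  n_ind <- config$n_individuals
  n_site <- nrow(sites)
  ids <- sprintf("I%04d", seq_len(n_ind))
  calls <- matrix(0L, n_ind, n_site)
  roh_all <- list()
  f_real <- numeric(n_ind)
  G <- sum(config$genome)
  for (i in seq_len(n_ind)) {
    blocks <- place_roh_blocks(config$f[i], config$genome, config$roh_mean_bp)
    in_roh <- rep(FALSE, n_site)
    if (nrow(blocks)) {
      f_real[i] <- sum(blocks$end - blocks$start + 1) / G
      for (ch in unique(blocks$chrom)) {
        bc <- blocks[blocks$chrom == ch, , drop = FALSE]
        bc <- bc[order(bc$start), , drop = FALSE]
        j <- which(sites$chrom == ch)
        if (!length(j)) next
        hit <- findInterval(sites$pos[j], bc$start)
        ok <- hit > 0 & sites$pos[j] <= bc$end[pmax(hit, 1)]
        in_roh[j[ok]] <- TRUE
      }
      roh_all[[length(roh_all) + 1L]] <- data.frame(
        individual = ids[i], chrom = blocks$chrom,
        start = as.integer(blocks$start), end = as.integer(blocks$end),
        stringsAsFactors = FALSE)
    }
    g <- rbinom(n_site, 2L, af)             # HWE draw for all sites
    if (any(in_roh))                        # overridden inside ROH: no hets
      g[in_roh] <- 2L * rbinom(sum(in_roh), 1L, af[in_roh])
    calls[i, ] <- g
  }
  roh <- do.call(rbind, roh_all) %||% data.frame(
    individual = character(), chrom = character(), start = integer(),
    end = integer())
  if (nrow(roh)) {
    roh <- roh[order(roh$individual, match(roh$chrom, names(config$genome)),
                     roh$start), , drop = FALSE]
    rownames(roh) <- NULL
    roh$length <- roh$end - roh$start + 1L
  } else roh$length <- integer()
  gq <- dp <- NULL
  if (isTRUE(config$per_call_metrics)) {
    gq <- matrix(as.integer(pmin(99, 20 + rpois(n_ind * n_site, 45))),
                 n_ind, n_site)
    dp <- matrix(as.integer(1 + rpois(n_ind * n_site, 34)), n_ind, n_site)
  }
  gm <- genotype_matrix(calls, ids, sites[c("chrom", "pos", "ref", "alt")],
                        gq = gq, dp = dp)
  list(genotypes = gm, roh = roh, f_realized = f_real)
}

#' Simulate logistic case-control phenotypes
#'
#' Case status is Bernoulli with
#' `logit P(case_i) = beta0 + log(carrier_or) * carrier_i`, where carriers
#' hold at least one alternate allele at a causal site; `beta0` is solved
#' so the marginal prevalence matches the configuration. BMI is a monotone
#' noisy transform of the case propensity (convenience for exercising the
#' BMI dichotomiser, not a model of BMI genetics).
#'
#' Does not seed the RNG (see [simulate_cohort()]).
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [simulation_config()].
#' @param causal_keys site keys of the causal variants (may be empty).
#' @return list: `phenotypes` (individual, status, bmi), `carrier` (logical),
#'   `beta0`.
#' @export
simulate_phenotypes <- function(genotypes, config, causal_keys = character()) {
  n <- length(genotypes$individuals)
  carrier <- rep(FALSE, n)
  if (length(causal_keys)) {
    gm <- subset_genotypes(genotypes, keys = causal_keys)
    carrier <- rowSums(gm$calls == 1L | gm$calls == 2L) > 0
  }
  lor <- if (config$carrier_or > 0) log(config$carrier_or) else -Inf
  pi0 <- config$prevalence
  if (!any(carrier) || config$carrier_or == 1) {
    beta0 <- qlogis(pi0)
  } else {
    fr <- mean(carrier)
    beta0 <- uniroot(function(b0)
      (1 - fr) * plogis(b0) + fr * plogis(b0 + lor) - pi0,
      lower = -30, upper = 30, tol = 1e-10)$root
  }
  prob <- plogis(beta0 + ifelse(carrier, lor, 0))
  y <- rbinom(n, 1L, prob)
  bmi <- round(22 + 26 * prob + rnorm(n, 0, 2.5), 1)
  bmi <- pmax(bmi, 15)
  ph <- data.frame(individual = genotypes$individuals,
                   status = ifelse(y == 1L, "case", "control"),
                   bmi = bmi, stringsAsFactors = FALSE)
  list(phenotypes = ph, carrier = carrier, beta0 = beta0)
}

#' Simulate a complete synthetic cohort
#'
#' Seeds the RNG once from `config$seed` and draws, in documented order,
#' sites and annotations, then genotypes and ROH blocks, then phenotypes.
#' The returned truth record (causal site keys, planted and realised F,
#' carrier indicator, solved baseline log-odds) suffices to score any
#' recovery experiment.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_cohort`: sites, annotations,
#'   genotypes, roh, phenotypes, transcripts, truth.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ss <- simulate_sites(config)
  sg <- simulate_genotypes(ss$sites, config)
  sp <- simulate_phenotypes(sg$genotypes, config, ss$truth$causal_keys)
  structure(list(sites = ss$sites, annotations = ss$annotations,
                 genotypes = sg$genotypes, roh = sg$roh,
                 phenotypes = sp$phenotypes,
                 transcripts = config$transcript_plan,
                 truth = list(causal_keys = ss$truth$causal_keys,
                              true_af = ss$truth$true_af,
                              f_planted = config$f,
                              f_realized = sg$f_realized,
                              carrier = sp$carrier, beta0 = sp$beta0),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d individuals, %d sites, ",
                     "%d ROH intervals, %d causal sites\n"),
              length(x$genotypes$individuals), nrow(x$sites), nrow(x$roh),
              length(x$truth$causal_keys)))
  invisible(x)
}

#' Write a synthetic cohort as a VCF + BED + TSV file set
#'
#' Emits exactly the formats the readers consume: `cohort.vcf` (GT/GQ/DP
#' FORMAT, QC INFO fields), `roh.bed` (0-based half-open, name = individual),
#' `annotations.tsv`, `phenotypes.tsv` and `transcripts.tsv`. Writing then
#' reading reproduces genotype codes, QC metrics and intervals exactly, and
#' the file set is byte-identical across runs for the same cohort.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             bed = file.path(out_dir, "roh.bed"),
             annotations = file.path(out_dir, "annotations.tsv"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             transcripts = file.path(out_dir, "transcripts.tsv"))
  write_cohort_vcf(cohort, paths[["vcf"]])
  roh <- cohort$roh
  writeLines(if (nrow(roh)) sprintf("%s\t%d\t%d\t%s", roh$chrom,
                                    roh$start - 1L, roh$end, roh$individual)
             else character(), paths[["bed"]])
  ann <- cohort$annotations
  ann_out <- data.frame(chrom = ann$chrom, pos = ann$pos, ref = ann$ref,
                        alt = ann$alt, gene = ann$gene,
                        transcript = ann$transcript,
                        consequence = ann$consequence, impact = ann$impact,
                        protein_position = ifelse(is.na(ann$protein_start), "-",
                                                  as.character(ann$protein_start)),
                        sift = ifelse(is.na(ann$sift), "-", ann$sift),
                        polyphen = ifelse(is.na(ann$polyphen), "-", ann$polyphen),
                        af_gnomAD_ALL = sprintf("%.8g", ann$af_gnomAD_ALL),
                        af_gnomAD_SAS = sprintf("%.8g", ann$af_gnomAD_SAS),
                        stringsAsFactors = FALSE)
  write.table(ann_out, paths[["annotations"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$phenotypes, paths[["phenotypes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$transcripts, paths[["transcripts"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

write_cohort_vcf <- function(cohort, path) {
  s <- cohort$sites
  gm <- cohort$genotypes
  info_num <- function(x, int = FALSE)
    ifelse(is.na(x), NA, if (int) sprintf("%d", as.integer(x))
           else sprintf("%.6g", x))
  info <- paste0("DP=", info_num(s$DP, TRUE), ";MQ0=", info_num(s$MQ0, TRUE),
                 ";QD=", info_num(s$QD), ";MQ=", info_num(s$MQ),
                 ";FS=", info_num(s$FS), ";SOR=", info_num(s$SOR),
                 ";MQRankSum=", info_num(s$MQRankSum),
                 ";ReadPosRankSum=", info_num(s$ReadPosRankSum),
                 ";InbreedingCoeff=", info_num(s$InbreedingCoeff))
  gt_str <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  has_pc <- !is.null(gm$gq)
  fmt <- if (has_pc) "GT:GQ:DP" else "GT"
  sample_cols <- vapply(seq_len(nrow(s)), function(j) {
    g <- gt_str[as.character(gm$calls[, j])]
    cell <- if (has_pc) paste0(g, ":", gm$gq[, j], ":", gm$dp[, j]) else g
    paste(cell, collapse = "\t")
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(cohort$config$genome),
                   as.integer(cohort$config$genome)),
           sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
                   c("DP", "MQ0", "QD", "MQ", "FS", "SOR", "MQRankSum",
                     "ReadPosRankSum", "InbreedingCoeff"),
                   c("Integer", "Integer", rep("Float", 7)),
                   "site QC metric"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (has_pc) c(
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$individuals), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t100\t%s\t%s\t%s\t%s",
                  s$chrom, s$pos, s$ref, s$alt,
                  ifelse(is.na(s$FILTER), ".", s$FILTER), info, fmt,
                  sample_cols)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Built-in plain-text fixtures
#'
#' `"orthologues_table1"`: the 27-row human-to-fly orthologue table (DIOPT
#' scores and RNAi-line availability) used by the prioritisation worked
#' example. `"taok2_counts"`: the published carrier counts for the TAOK2
#' exact-test worked example (14/925 case carriers, 426/46,673 control
#' carriers).
#'
#' @param name fixture name.
#' @return file path.
#' @export
obscan_fixture <- function(name = c("orthologues_table1", "taok2_counts")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".tsv"), package = "obscan",
                   mustWork = TRUE)
  f
}

#' TAOK2 worked-example carrier table
#'
#' Builds the 2x2 carrier table from the shipped counts fixture.
#'
#' @return a `contingency_2x2` vector (a, b, c, d).
#' @export
taok2_carrier_table <- function() {
  df <- read.delim(obscan_fixture("taok2_counts"))
  a <- df$n_case_carriers; ca <- df$n_cases
  cc <- df$n_control_carriers; co <- df$n_controls
  structure(as.integer(c(a = a, b = ca - a, c = cc, d = co - cc)),
            names = c("a", "b", "c", "d"), class = "contingency_2x2")
}
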
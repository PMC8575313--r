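#' Site-level QC hard filters
#'
#' Applies one of three hard-filter dialects to a site table. Filters are
#' exclusion rules acting only on observed evidence: a missing metric never
#' fails its rule (it is logged as `"untested"`).
#'
#' Dialects:
#' \describe{
#'   \item{`ug2013`}{exclude if `DP < 4` or (`MQ0 >= 4` and `MQ0/DP > 0.1`)
#'     -- the classic UnifiedGenotyper-era depth/MQ0 rule.}
#'   \item{`hc_hard`}{GATK hard thresholds. SNVs: `QD >= 2`, `MQ >= 40`,
#'     `FS <= 60`, `SOR <= 3`, `MQRankSum >= -12.5`,
#'     `ReadPosRankSum >= -8`. Indels: `QD >= 2`,
#'     `ReadPosRankSum >= -20`, `InbreedingCoeff >= -0.8`, `FS <= 200`,
#'     `SOR <= 10`.}
#'   \item{`gh`}{site-level `FILTER == PASS` and `FS < 30`; per-call
#'     `GQ > 10`, applied as call-level masking (failing calls are set to
#'     missing in the returned genotype matrix).}
#' }
#'
#' @param sites site table as returned by [read_vcf()].
#' @param dialect `"ug2013"`, `"hc_hard"` or `"gh"` (default: the dialect
#'   recorded on `sites`).
#' @param genotypes optional [genotype_matrix()]; required by the `gh`
#'   dialect for GQ masking and returned (possibly masked, and subset to the
#'   kept sites) in all cases when supplied.
#' @return list with `kept` (site table), `log` (data frame: key, rule,
#'   value, status in fail/untested) and `genotypes` (or `NULL`).
#' @export
qc_filter <- function(sites, dialect = NULL, genotypes = NULL) {
  dialect <- dialect %||% attr(sites, "dialect") %||% "hc_hard"
  dialect <- match.arg(dialect, c("ug2013", "hc_hard", "gh"))
  n <- nrow(sites)
  key <- variant_key(sites)
  fails <- list(); untested <- list()

  # rule(): TRUE = fail; missing metric -> untested, never a failure
  apply_rule <- function(name, value, fail_mask, applies = rep(TRUE, n)) {
    miss <- applies & is.na(value)
    hit <- applies & !is.na(value) & fail_mask
    if (any(hit))
      fails[[length(fails) + 1L]] <<- data.frame(
        key = key[hit], rule = name, value = as.character(value[hit]),
        status = "fail", stringsAsFactors = FALSE)
    if (any(miss))
      untested[[length(untested) + 1L]] <<- data.frame(
        key = key[miss], rule = name, value = NA_character_,
        status = "untested", stringsAsFactors = FALSE)
    hit
  }

  excluded <- rep(FALSE, n)
  if (dialect == "ug2013") {
    excluded <- excluded | apply_rule("DP<4", sites$DP, sites$DP < 4)
    ratio_bad <- !is.na(sites$MQ0) & !is.na(sites$DP) &
      sites$MQ0 >= 4 & sites$MQ0 / sites$DP > 0.1
    mq0 <- ifelse(is.na(sites$MQ0) | is.na(sites$DP), NA_real_, sites$MQ0)
    excluded <- excluded | apply_rule("MQ0>=4&MQ0/DP>0.1", mq0, ratio_bad)
  } else if (dialect == "hc_hard") {
    snv <- sites$variant_class == "SNV"
    ind <- !snv
    excluded <- excluded |
      apply_rule("SNV:QD<2", sites$QD, sites$QD < 2, snv) |
      apply_rule("SNV:MQ<40", sites$MQ, sites$MQ < 40, snv) |
      apply_rule("SNV:FS>60", sites$FS, sites$FS > 60, snv) |
      apply_rule("SNV:SOR>3", sites$SOR, sites$SOR > 3, snv) |
      apply_rule("SNV:MQRankSum<-12.5", sites$MQRankSum,
                 sites$MQRankSum < -12.5, snv) |
      apply_rule("SNV:ReadPosRankSum<-8", sites$ReadPosRankSum,
                 sites$ReadPosRankSum < -8, snv) |
      apply_rule("indel:QD<2", sites$QD, sites$QD < 2, ind) |
      apply_rule("indel:ReadPosRankSum<-20", sites$ReadPosRankSum,
                 sites$ReadPosRankSum < -20, ind) |
      apply_rule("indel:InbreedingCoeff<-0.8", sites$InbreedingCoeff,
                 sites$InbreedingCoeff < -0.8, ind) |
      apply_rule("indel:FS>200", sites$FS, sites$FS > 200, ind) |
      apply_rule("indel:SOR>10", sites$SOR, sites$SOR > 10, ind)
  } else { # gh
    filt_bad <- !is.na(sites$FILTER) & sites$FILTER != "PASS"
    excluded <- excluded |
      apply_rule("FILTER!=PASS", sites$FILTER, filt_bad) |
      apply_rule("FS>=30", sites$FS, sites$FS >= 30)
    if (!is.null(genotypes) && !is.null(genotypes$gq)) {
      mask <- !is.na(genotypes$gq) & genotypes$gq <= 10
      genotypes$calls[mask] <- -1L
    }
  }

  log <- do.call(rbind, c(fails, untested)) %||%
    data.frame(key = character(), rule = character(), value = character(),
               status = character())
  kept <- sites[!excluded, , drop = FALSE]
  attr(kept, "dialect") <- dialect
  if (!is.null(genotypes))
    genotypes <- subset_genotypes(genotypes, keys = key[!excluded])
  list(kept = kept, log = log, genotypes = genotypes)
}

#' Internal (within-cohort) alternate allele frequency
#'
#' AF = (#het + 2 #hom-alt) / (2 #non-missing) per site; a site with only
#' missing calls has missing AF.
#'
#' @param genotypes a [genotype_matrix()].
#' @return named numeric vector (site key -> AF).
#' @export
internal_allele_frequency <- function(genotypes) {
  calls <- genotypes$calls
  nonmiss <- colSums(calls != -1L)
  alt <- colSums((calls == 1L) + 2L * (calls == 2L))
  af <- ifelse(nonmiss > 0L, alt / (2 * nonmiss), NA_real_)
  setNames(af, colnames(calls))
}

#' Frequency filter policy
#'
#' The tiers in routine use are 1% (rare-allele pre-filter), 0.1% ("rare")
#' and 0.025% ("very rare"). All comparisons are strict (`<`); a missing
#' population frequency passes by default (absence from a reference panel is
#' evidence of rarity, not of commonness).
#'
#' @param threshold MAF threshold, e.g. `0.01`, `0.001`, `0.00025`.
#' @param populations annotation AF column names that must all satisfy the
#'   threshold.
#' @param include_internal also require the within-cohort AF below threshold.
#' @param missing_passes does a missing population AF pass?
#' @return a `frequency_policy` object.
#' @export
frequency_policy <- function(threshold, populations,
                             include_internal = TRUE, missing_passes = TRUE) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  structure(list(threshold = threshold, populations = populations,
                 include_internal = include_internal,
                 missing_passes = missing_passes),
            class = "frequency_policy")
}

#' Apply a frequency policy to an annotation table
#'
#' @param annotations table from [read_annotations()].
#' @param policy a [frequency_policy()].
#' @param internal_af named vector from [internal_allele_frequency()];
#'   required when the policy includes the internal AF.
#' @return the kept annotation rows.
#' @export
frequency_filter <- function(annotations, policy, internal_af = NULL) {
  stopifnot(inherits(policy, "frequency_policy"))
  unknown <- setdiff(policy$populations, names(annotations))
  if (length(unknown))
    stop("unknown population AF column(s): ", paste(unknown, collapse = ", "))
  thr <- policy$threshold
  pass <- rep(TRUE, nrow(annotations))
  for (p in policy$populations) {
    af <- annotations[[p]]
    pass <- pass & ifelse(is.na(af), policy$missing_passes, af < thr)
  }
  if (policy$include_internal) {
    if (is.null(internal_af))
      stop("policy includes internal AF but internal_af was not supplied")
    af <- unname(internal_af[variant_key(annotations)])
    pass <- pass & ifelse(is.na(af), policy$missing_passes, af < thr)
  }
  annotations[pass, , drop = FALSE]
}

#' Consequence / impact category filter
#'
#' Categories:
#' \describe{
#'   \item{`nonsyn_or_splice`}{VEP filter "(Impact in HIGH,MODERATE) or
#'     (Consequence is splice_region_variant)" on the canonical transcript.}
#'   \item{`exonic_nonsyn`}{impact HIGH/MODERATE *and* an annotated protein
#'     position (the set the protein-coordinate sliding windows consume).}
#'   \item{`high_or_damaging`}{impact HIGH, plus SNVs called deleterious by
#'     SIFT *and* probably_damaging by PolyPhen2 (a conjunction).}
#' }
#'
#' @param annotations table from [read_annotations()].
#' @param category category name.
#' @return the kept annotation rows.
#' @export
consequence_filter <- function(annotations,
                               category = c("nonsyn_or_splice", "exonic_nonsyn",
                                            "high_or_damaging")) {
  category <- match.arg(category)
  imp <- annotations$impact
  keep <- switch(category,
    nonsyn_or_splice = imp %in% c("HIGH", "MODERATE") |
      grepl("splice_region_variant", annotations$consequence, fixed = TRUE),
    exonic_nonsyn = imp %in% c("HIGH", "MODERATE") &
      !is.na(annotations$protein_start),
    high_or_damaging = imp == "HIGH" |
      (is_snv(annotations$ref, annotations$alt) &
         !is.na(annotations$sift) & annotations$sift == "deleterious" &
         !is.na(annotations$polyphen) &
         annotations$polyphen == "probably_damaging"))
  annotations[keep, , drop = FALSE]
}
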
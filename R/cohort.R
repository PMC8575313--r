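#' Select an unrelated subset by kinship threshold
#'
#' Builds the relatedness graph over pairs with kinship at or above the
#' threshold and greedily removes the individual with the highest
#' related-degree until no edge remains. Ties are broken by removing the
#' lexicographically largest id, so the result is deterministic. The
#' contract is independence (no kept pair at or above the threshold) and
#' determinism, not maximum-cardinality.
#'
#' @param ids all candidate individual ids.
#' @param kinship_pairs data frame `id1`, `id2`, `kinship` (undirected).
#' @param threshold kinship cut-off; pairs with `kinship >= threshold` are
#'   treated as related. The conventional third-degree cut-off is 0.0442.
#' @return character vector of kept ids (input order).
#' @export
select_unrelated <- function(ids, kinship_pairs, threshold = 0.0442) {
  if (any(kinship_pairs$id1 == kinship_pairs$id2))
    stop("kinship table contains self-pair(s)")
  e <- kinship_pairs[kinship_pairs$kinship >= threshold &
                       kinship_pairs$id1 %in% ids &
                       kinship_pairs$id2 %in% ids, , drop = FALSE]
  removed <- character()
  while (nrow(e)) {
    deg <- table(c(e$id1, e$id2))
    worst <- names(deg)[deg == max(deg)]
    victim <- max(worst)  # lexicographically largest removed on ties
    removed <- c(removed, victim)
    e <- e[e$id1 != victim & e$id2 != victim, , drop = FALSE]
  }
  ids[!ids %in% removed]
}

#' Dichotomise BMI into severe-obesity cases and controls
#'
#' Case iff `BMI > cutoff` (strict; the severe-obesity convention is
#' 40 kg/m^2), control iff `BMI <= cutoff`; missing BMI is excluded.
#'
#' @param phenotypes phenotype table with `individual` and `bmi`.
#' @param cutoff BMI threshold in kg/m^2.
#' @return list: `cases`, `controls`, `excluded` (data frame id, reason),
#'   and `phenotypes` (the input with `status` re-derived from BMI for the
#'   retained individuals).
#' @export
dichotomize_bmi <- function(phenotypes, cutoff = 40) {
  bmi <- phenotypes$bmi
  if (any(!is.na(bmi) & bmi <= 0)) stop("non-positive BMI value(s)")
  case <- !is.na(bmi) & bmi > cutoff
  ctrl <- !is.na(bmi) & bmi <= cutoff
  excl <- is.na(bmi)
  ph <- phenotypes[!excl, , drop = FALSE]
  ph$status <- ifelse(ph$bmi > cutoff, "case", "control")
  list(cases = phenotypes$individual[case],
       controls = phenotypes$individual[ctrl],
       excluded = data.frame(individual = phenotypes$individual[excl],
                             reason = if (any(excl)) "missing_bmi" else character(),
                             stringsAsFactors = FALSE),
       phenotypes = ph)
}
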
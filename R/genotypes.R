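#' Genotype matrix container
#'
#' Holds an individuals x sites matrix of genotype codes together with the
#' decomposed site table. Codes are `0` hom-ref, `1` het, `2` hom-alt and
#' `-1` missing. One column per (variant, alt) pair: multi-allelic VCF rows
#' are decomposed at ingest and a `1/2` call contributes code 1 to each alt.
#'
#' @param calls integer matrix, one row per individual, one column per site;
#'   values restricted to -1, 0, 1, 2.
#' @param individuals character vector of individual ids (row order).
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (column order of `calls`).
#' @param gq,dp optional matrices of per-call genotype quality / depth with
#'   the same shape as `calls`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individuals, sites, gq = NULL, dp = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  assert_columns(sites, c("chrom", "pos", "ref", "alt"), "sites")
  if (nrow(calls) != length(individuals))
    stop("calls must have one row per individual")
  if (ncol(calls) != nrow(sites))
    stop("calls must have one column per site")
  bad <- !(calls %in% c(-1L, 0L, 1L, 2L))
  if (any(bad))
    stop("genotype codes must be -1, 0, 1 or 2")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt must differ")
  key <- variant_key(sites)
  dimnames(calls) <- list(individuals, key)
  for (m in list(gq, dp))
    if (!is.null(m) && !identical(dim(m), dim(calls)))
      stop("gq/dp must match the shape of calls")
  structure(list(individuals = as.character(individuals),
                 sites = sites, calls = calls, gq = gq, dp = dp),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites (%d missing calls)\n",
              length(x$individuals), nrow(x$sites), sum(x$calls == -1L)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by site keys and/or individuals
#'
#' @param gm a [genotype_matrix()].
#' @param keys character vector of site keys to retain (default all).
#' @param individuals ids to retain (default all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, keys = NULL, individuals = NULL) {
  ck <- colnames(gm$calls)
  j <- if (is.null(keys)) seq_along(ck) else {
    miss <- setdiff(keys, ck)
    if (length(miss)) stop("unknown site key(s): ", paste(miss, collapse = ", "))
    match(keys, ck)
  }
  i <- if (is.null(individuals)) seq_along(gm$individuals) else {
    miss <- setdiff(individuals, gm$individuals)
    if (length(miss)) stop("unknown individual(s): ", paste(miss, collapse = ", "))
    match(individuals, gm$individuals)
  }
  genotype_matrix(gm$calls[i, j, drop = FALSE], gm$individuals[i],
                  gm$sites[j, , drop = FALSE],
                  gq = if (!is.null(gm$gq)) gm$gq[i, j, drop = FALSE],
                  dp = if (!is.null(gm$dp)) gm$dp[i, j, drop = FALSE])
}
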
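#' Carrier 2x2 contingency table for a variant set
#'
#' A carrier is an individual with at least one alternate allele (code 1 or
#' 2) at any variant in the set. Missing calls count as non-carrier evidence
#' under the default policy (set `missing_as_noncarrier = FALSE` to drop
#' individuals whose calls are all missing across the set).
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype table with `individual` and `status` in
#'   case/control (individuals with other status are ignored).
#' @param variant_set character vector of site keys (`chrom:pos:ref:alt`).
#' @param missing_as_noncarrier see above.
#' @return named integer vector `c(a, b, c, d)` of class `contingency_2x2`:
#'   case carriers, case non-carriers, control carriers, control
#'   non-carriers.
#' @export
carrier_table <- function(genotypes, phenotypes, variant_set,
                          missing_as_noncarrier = TRUE) {
  if (!length(variant_set)) stop("variant_set must be non-empty")
  ph <- phenotypes[phenotypes$status %in% c("case", "control"), , drop = FALSE]
  ph <- ph[ph$individual %in% genotypes$individuals, , drop = FALSE]
  if (!any(ph$status == "case") || !any(ph$status == "control"))
    stop("need at least one case and one control")
  gm <- subset_genotypes(genotypes, keys = variant_set,
                         individuals = ph$individual)
  carrier <- rowSums(gm$calls == 1L | gm$calls == 2L) > 0
  if (!missing_as_noncarrier) {
    all_missing <- rowSums(gm$calls != -1L) == 0
    keep <- !all_missing
    carrier <- carrier[keep]; ph <- ph[keep, , drop = FALSE]
  }
  case <- ph$status == "case"
  tab <- c(a = sum(case & carrier), b = sum(case & !carrier),
           c = sum(!case & carrier), d = sum(!case & !carrier))
  structure(as.integer(tab), names = names(tab), class = "contingency_2x2")
}

# --- noncentral hypergeometric machinery ------------------------------------
# X = count in cell a, conditional on margins (n1 = a+b cases, n2 = c+d
# controls, k = a+c carriers). Support lo..hi; log binomial weights logdc.
nchg_setup <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, n1)
  x <- lo:hi
  list(n1 = n1, n2 = n2, k = k, lo = lo, hi = hi, x = x,
       logdc = lchoose(n1, x) + lchoose(n2, k - x))
}

nchg_pmf <- function(sup, log_psi) {
  w <- sup$logdc + sup$x * log_psi
  w <- exp(w - max(w))
  w / sum(w)
}

nchg_mean <- function(sup, log_psi) sum(sup$x * nchg_pmf(sup, log_psi))

#' Fisher's exact test with conditional-MLE odds ratio and exact CI
#'
#' Two-sided p-value by the probability-mass criterion: the sum over the
#' hypergeometric support of probabilities not exceeding that of the
#' observed table (with `1e-7` relative slack). The odds-ratio estimate is
#' the conditional MLE under the noncentral hypergeometric distribution
#' (solves `E[X | psi] = a`); the CI endpoints solve
#' `P(X >= a | psi_lo) = alpha/2` and `P(X <= a | psi_hi) = alpha/2`. When
#' `a` sits at the support minimum/maximum the estimate is 0 / `Inf` and
#' the corresponding CI endpoint is exact at 0 / `Inf`. All root finding is
#' monotone bisection on `log(psi)` over `[1e-12, 1e12]` to relative
#' tolerance `1e-8`. Conventions match `stats::fisher.test`.
#'
#' @param table a `contingency_2x2` or numeric vector/matrix with counts
#'   a (case carriers), b, c, d.
#' @param alpha two-sided CI level is `1 - alpha`.
#' @param conf compute the exact CI (set `FALSE` to skip the two extra root
#'   finds when only p and the estimate are needed, e.g. in large sweeps).
#' @return list: `p`, `or` (conditional MLE), `ci` (length-2, `NA` when
#'   `conf = FALSE`), `table`.
#' @export
fisher_exact <- function(table, alpha = 0.05, conf = TRUE) {
  tb <- as.integer(table)
  if (length(tb) != 4L) stop("table must have four cells")
  if (any(tb < 0L)) stop("negative cell count")
  a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
  sup <- nchg_setup(a, b, cc, d)

  # central (psi = 1) two-sided p
  dens <- dhyper(sup$x, sup$k, sup$n1 + sup$n2 - sup$k, sup$n1)
  p <- min(1, sum(dens[dens <= dens[match(a, sup$x)] * (1 + 1e-7)]))

  solve_logpsi <- function(f, increasing) {
    # f monotone in log-psi; find the root by bisection
    loB <- log(1e-12); hiB <- log(1e12)
    flo <- f(loB); fhi <- f(hiB)
    if (increasing) { if (flo >= 0) return(loB); if (fhi <= 0) return(hiB) }
    else { if (flo <= 0) return(loB); if (fhi >= 0) return(hiB) }
    for (i in 1:200) {
      mid <- (loB + hiB) / 2
      fm <- f(mid)
      pos <- if (increasing) fm > 0 else fm < 0
      if (pos) hiB <- mid else loB <- mid
      if ((hiB - loB) < 1e-8 * max(1, abs(mid))) break
    }
    (loB + hiB) / 2
  }

  if (sup$lo == sup$hi) {
    or <- NA_real_; ci <- c(0, Inf)
  } else {
    or <- if (a == sup$lo) 0
    else if (a == sup$hi) Inf
    else exp(solve_logpsi(function(lp) nchg_mean(sup, lp) - a, increasing = TRUE))
    if (conf) {
      p_ge <- function(lp) sum(nchg_pmf(sup, lp)[sup$x >= a]) # increasing in psi
      p_le <- function(lp) sum(nchg_pmf(sup, lp)[sup$x <= a]) # decreasing in psi
      ci_lo <- if (a == sup$lo) 0
      else exp(solve_logpsi(function(lp) p_ge(lp) - alpha / 2, increasing = TRUE))
      ci_hi <- if (a == sup$hi) Inf
      else exp(solve_logpsi(function(lp) alpha / 2 - p_le(lp), increasing = TRUE))
      ci <- c(ci_lo, ci_hi)
    } else ci <- c(NA_real_, NA_real_)
  }
  list(p = p, or = or, ci = ci,
       table = structure(c(a = a, b = b, c = cc, d = d),
                         class = "contingency_2x2"))
}

#' Burden weights
#'
#' The default follows the convention of the SKAT family of tests:
#' `Beta(MAF; 1, 25)` density evaluated at the (internal) minor allele
#' frequency, strongly up-weighting rare sites. `"unit"` gives equal
#' weights.
#'
#' @param maf numeric vector of allele frequencies.
#' @param scheme `"beta"` or `"unit"`.
#' @return numeric weights.
#' @export
burden_weights <- function(maf, scheme = c("beta", "unit")) {
  scheme <- match.arg(scheme)
  if (scheme == "unit") return(rep(1, length(maf)))
  dbeta(pmin(pmax(maf, 0), 1), 1, 25)
}

#' Binary-trait weighted burden score test
#'
#' Collapses the variant set into a per-individual weighted genotype sum
#' `b_i = sum_j w_j g_ij`, then score-tests its association with case
#' status under an intercept-only binomial null:
#' `U = sum_i (y_i - ybar) b_i`,
#' `Var(U) = ybar (1 - ybar) sum_i (b_i - bbar)^2`,
#' `Q = U^2 / Var`, with p from the upper tail of chi-square(1). This is the
#' unadjusted asymptotic burden test (the `method.bin = "UA"` burden variant
#' of the SKAT binary machinery). Degenerate variation (`Var = 0`) yields
#' `Q = 0`, `p = 1`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype table (case/control rows used).
#' @param variant_set site keys to collapse.
#' @param weights `"beta"` (default; Beta(1,25) on the internal MAF),
#'   `"unit"`, or a numeric vector of per-site weights.
#' @param missing_policy `-1` codes become 0 (`"as_ref"`, default) or the
#'   per-site mean of observed codes (`"mean_impute"`).
#' @return list: `Q`, `p`, `n_markers`, `U`, `var_u`.
#' @export
burden_score_test <- function(genotypes, phenotypes, variant_set,
                              weights = "beta",
                              missing_policy = c("as_ref", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  if (!length(variant_set)) stop("variant_set must be non-empty")
  ph <- phenotypes[phenotypes$status %in% c("case", "control"), , drop = FALSE]
  ph <- ph[ph$individual %in% genotypes$individuals, , drop = FALSE]
  if (!any(ph$status == "case") || !any(ph$status == "control"))
    stop("need at least one case and one control")
  gm <- subset_genotypes(genotypes, keys = variant_set,
                         individuals = ph$individual)
  g <- gm$calls
  miss <- g == -1L
  g[miss] <- 0L
  g <- matrix(as.numeric(g), nrow = nrow(g), dimnames = dimnames(g))
  if (missing_policy == "mean_impute" && any(miss)) {
    mu <- colSums(g) / pmax(colSums(!miss), 1L)
    g[miss] <- mu[col(g)[miss]]
  }
  w <- if (is.numeric(weights)) {
    if (length(weights) != ncol(g)) stop("weights length must match variant_set")
    weights
  } else {
    maf <- internal_allele_frequency(gm)
    maf[is.na(maf)] <- 0
    burden_weights(pmin(maf, 1 - maf), scheme = weights)
  }
  b <- as.vector(g %*% w)
  y <- as.numeric(ph$status == "case")
  ybar <- mean(y)
  u <- sum((y - ybar) * b)
  var_u <- ybar * (1 - ybar) * sum((b - mean(b))^2)
  if (var_u <= 0) {
    q <- 0; p <- 1
  } else {
    q <- u^2 / var_u
    p <- pchisq(q, df = 1, lower.tail = FALSE)
  }
  list(Q = q, p = p, n_markers = length(variant_set), U = u, var_u = var_u)
}

#' Benjamini-Hochberg and Holm p-value adjustment
#'
#' BH (step-up): `adj_(i) = min_{j >= i} min(1, m p_(j) / j)`. Holm
#' (step-down): `adj_(i) = max_{j <= i} min(1, (m - j + 1) p_(j))`. The
#' original order is restored. Implemented from the step formulas;
#' equivalent to `stats::p.adjust`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs are passed through
#'   and do not count towards `m`).
#' @param method `"BH"` or `"Holm"`.
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv)
    ps <- pv[o]
    adj <- if (method == "BH") {
      rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
    } else {
      pmin(1, cummax(pmin(1, (m - seq_len(m) + 1) * ps)))
    }
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

#' Assemble association results for named variant sets
#'
#' Runs the burden score test and the exact carrier 2x2 machinery for each
#' variant set (typically genes), then adjusts p-values across the sets.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype table.
#' @param sets named list of site-key vectors.
#' @param weights forwarded to [burden_score_test()].
#' @param alpha CI level for [fisher_exact()].
#' @return data frame in the `gene_test` results schema.
#' @export
association_results <- function(genotypes, phenotypes, sets,
                                weights = "beta", alpha = 0.05) {
  rows <- lapply(names(sets), function(id) {
    vs <- sets[[id]]
    bt <- burden_score_test(genotypes, phenotypes, vs, weights = weights)
    tb <- carrier_table(genotypes, phenotypes, vs)
    fe <- fisher_exact(tb, alpha = alpha)
    data.frame(unit_id = id, n_markers = bt$n_markers,
               n_case_carriers = tb[["a"]], n_control_carriers = tb[["c"]],
               Q = bt$Q, p = bt$p, or_cmle = fe$or,
               ci_lo = fe$ci[1], ci_hi = fe$ci[2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- adjust_pvalues(res$p, "BH")
  res$p_holm <- adjust_pvalues(res$p, "Holm")
  res
}
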
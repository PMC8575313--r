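# Shared builders and independent oracles.

tiny_gm <- function(calls, ids = NULL, chrom = "1", pos = NULL) {
  calls <- as.matrix(calls)
  ids <- ids %||% sprintf("P%d", seq_len(nrow(calls)))
  pos <- pos %||% (seq_len(ncol(calls)) * 100L)
  genotype_matrix(calls, ids,
                  data.frame(chrom = chrom, pos = pos,
                             ref = "A", alt = "T", stringsAsFactors = FALSE))
}

tiny_pheno <- function(ids, status, bmi = NA_real_) {
  data.frame(individual = ids, status = status, bmi = bmi,
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A hand-written VCF fixture, independent of the package writer.
hand_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "1\t100\t.\tA\tT\t50\tPASS\tQD=3.2;MQ=55;DP=40;MQ0=1;FS=2.5\tGT:GQ\t0/1:99\t1/1:45",
    "1\t200\t.\tG\tA,C\t50\tPASS\tQD=12;MQ=60;DP=30\tGT:GQ\t1/2:60\t./.:.",
    "2\t300\t.\tT\tTA\t50\tLowQual\tQD=1.5\tGT:GQ\t0/0:8\t1/1:99"),
    ext = ".vcf")
}

# Full hypergeometric enumeration p-value (independent of fisher_exact).
enum_fisher_p <- function(a, b, cc, d) {
  n1 <- a + b; n2 <- cc + d; k <- a + cc
  lo <- max(0, k - n2); hi <- min(k, n1)
  dens <- dhyper(lo:hi, k, n1 + n2 - k, n1)
  min(1, sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)]))
}

# Conditional-MLE oracle by likelihood maximisation (golden-section on the
# conditional log-likelihood) -- a different route than the moment-equation
# bisection in fisher_exact.
cmle_loglik <- function(a, b, cc, d) {
  n1 <- a + b; n2 <- cc + d; k <- a + cc
  lo <- max(0, k - n2); hi <- min(k, n1)
  if (lo == hi) return(NA_real_)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  x <- lo:hi
  logdc <- lchoose(n1, x) + lchoose(n2, k - x)
  ll <- function(lp) {
    w <- logdc + x * lp
    a * lp - (max(w) + log(sum(exp(w - max(w)))))
  }
  exp(optimize(ll, c(log(1e-12), log(1e12)), maximum = TRUE, tol = 1e-9)$maximum)
}

# Random small contingency tables with at least one case and control.
random_tables <- function(n, max_margin = 40) {
  lapply(seq_len(n), function(i) {
    n1 <- sample(1:max_margin, 1); n2 <- sample(1:max_margin, 1)
    a <- sample(0:n1, 1); cc <- sample(0:n2, 1)
    c(a, n1 - a, cc, n2 - cc)
  })
}
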
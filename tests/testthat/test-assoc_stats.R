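test_that("carrier_table counts carriers and respects the missing policy", {
  gm <- tiny_gm(matrix(c(1L, 0L, 0L, 2L), 4, 1),
                ids = c("A", "B", "C", "D"))
  ph <- tiny_pheno(c("A", "B", "C", "D"),
                   c("case", "case", "control", "control"))
  tb <- carrier_table(gm, ph, "1:100:A:T")
  expect_equal(unname(unclass(tb)), c(1L, 1L, 1L, 1L))

  # an all-missing individual is a non-carrier under the default policy
  gm2 <- tiny_gm(matrix(c(-1L, 0L, 0L, 2L), 4, 1),
                 ids = c("A", "B", "C", "D"))
  tb2 <- carrier_table(gm2, ph, "1:100:A:T")
  expect_equal(tb2[["b"]], 2L)
  expect_equal(carrier_table(gm2, ph, "1:100:A:T",
                             missing_as_noncarrier = FALSE)[["b"]], 1L)

  expect_error(carrier_table(gm, tiny_pheno(c("A", "B"), c("case", "case")),
                             "1:100:A:T"), "control")

  # set-union invariance: a multi-site set equals the OR of its singletons
  set.seed(402)
  g <- matrix(sample(c(-1L, 0L, 1L, 2L), 50 * 6, TRUE, c(.05, .7, .15, .1)),
              50, 6)
  gm3 <- tiny_gm(g)
  ph3 <- tiny_pheno(gm3$individuals, rep(c("case", "control"), 25))
  keys <- colnames(gm3$calls)
  whole <- carrier_table(gm3, ph3, keys)
  carrier_by_one <- Reduce(`|`, lapply(keys, function(k) {
    m <- subset_genotypes(gm3, k)$calls
    rowSums(m == 1L | m == 2L) > 0
  }))
  expect_equal(whole[["a"]], sum(carrier_by_one & ph3$status == "case"))
  expect_equal(whole[["c"]], sum(carrier_by_one & ph3$status == "control"))
})

test_that("fisher_exact reproduces frozen oracle values", {
  # full-enumeration oracle values (see helpers): note (3,0,1,4) -> 1/7
  expect_equal(fisher_exact(c(3, 0, 1, 4))$p, 1 / 7, tolerance = 1e-12)
  expect_equal(fisher_exact(c(3, 2, 0, 5))$p, 1 / 6, tolerance = 1e-12)
  sym <- fisher_exact(c(5, 95, 5, 95))
  expect_equal(sym$p, 1)
  expect_equal(sym$or, 1, tolerance = 1e-6)
  # degenerate support: no carriers at all
  deg <- fisher_exact(c(0, 10, 0, 10))
  expect_equal(deg$p, 1)
  expect_true(is.na(deg$or))
  expect_error(fisher_exact(c(-1, 1, 1, 1)), "negative")
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(403)
  for (tb in random_tables(60)) {
    fe <- fisher_exact(tb)
    ft <- stats::fisher.test(matrix(tb, 2, 2, byrow = TRUE))
    expect_equal(fe$p, ft$p.value, tolerance = 1e-9)
    # fisher.test solves its roots to ~1e-4 on psi, so compare on the log
    # scale with slack; the tight (1e-6) check is against the independent
    # likelihood oracle in the acceptance suite
    if (is.finite(fe$or) && fe$or > 0)
      expect_lt(abs(log(fe$or) - log(unname(ft$estimate))), 0.01)
    ci_ft <- as.numeric(ft$conf.int)
    both <- is.finite(fe$ci) & fe$ci > 0 & is.finite(ci_ft) & ci_ft > 0
    if (any(both))
      expect_lt(max(abs(log(fe$ci[both]) - log(ci_ft[both]))), 0.05)
    expect_identical(is.finite(fe$ci), is.finite(ci_ft))
  }
})

test_that("fisher_exact has the expected symmetries", {
  set.seed(404)
  for (tb in random_tables(40)) {
    fe <- fisher_exact(tb, conf = FALSE)
    # transpose (swap the roles of rows and columns)
    ft <- fisher_exact(tb[c(1, 3, 2, 4)], conf = FALSE)
    expect_equal(fe$p, ft$p, tolerance = 1e-10)
    # swapping rows inverts the odds ratio
    fs <- fisher_exact(tb[c(3, 4, 1, 2)], conf = FALSE)
    if (is.finite(fe$or) && fe$or > 0)
      expect_equal(fs$or, 1 / fe$or, tolerance = 1e-5)
  }
})

test_that("burden score test matches hand computation and degenerates safely", {
  gm <- tiny_gm(matrix(c(1L, 0L, 0L, 0L), 4, 1), ids = c("A", "B", "C", "D"))
  ph <- tiny_pheno(c("A", "B", "C", "D"),
                   c("case", "case", "control", "control"))
  bt <- burden_score_test(gm, ph, "1:100:A:T", weights = "unit")
  expect_equal(bt$Q, 4 / 3, tolerance = 1e-12)   # U = 0.5, Var = 0.1875
  expect_equal(bt$p, pchisq(4 / 3, 1, lower.tail = FALSE))

  gm0 <- tiny_gm(matrix(0L, 4, 2), ids = c("A", "B", "C", "D"))
  bt0 <- burden_score_test(gm0, ph, colnames(gm0$calls))
  expect_equal(c(bt0$Q, bt0$p), c(0, 1))
})

test_that("burden p agrees with a permutation oracle", {
  # continuous weights keep the permutation null off a coarse lattice, so
  # the asymptotic and permutation tails are comparable at MC precision
  set.seed(405)
  n <- 500; m <- 10
  g <- matrix(rbinom(n * m, 2, 0.2), n, m)
  w <- runif(m, 0.5, 1.5)
  gm <- tiny_gm(g)
  y <- rep(c(1, 0), each = n / 2)
  ph <- tiny_pheno(gm$individuals, ifelse(y == 1, "case", "control"))
  bt <- burden_score_test(gm, ph, colnames(gm$calls), weights = w)
  b <- as.vector(g %*% w)
  stat <- function(yy) {
    u <- sum((yy - mean(yy)) * b)
    u^2 / (mean(yy) * (1 - mean(yy)) * sum((b - mean(b))^2))
  }
  expect_equal(bt$Q, stat(y), tolerance = 1e-12)
  nperm <- 10000
  qs <- replicate(nperm, stat(sample(y)))
  p_perm <- mean(qs >= bt$Q - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(bt$p - p_perm), 3 * se + 0.01)

  # with one variant and unit weights Q is the standard trend-type score
  g1 <- g[, 1, drop = FALSE]
  bt1 <- burden_score_test(tiny_gm(g1), ph, "1:100:A:T", weights = "unit")
  ybar <- mean(y)
  q_trend <- sum((y - ybar) * g1)^2 /
    (ybar * (1 - ybar) * sum((g1 - mean(g1))^2))
  expect_equal(bt1$Q, q_trend, tolerance = 1e-12)
})

test_that("BH and Holm adjustments match hand-derived vectors and p.adjust", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "BH"), c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(p, "Holm"), c(0.04, 0.06, 0.06, 0.06))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "Holm"), 0.03)
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")

  set.seed(406)
  for (i in 1:10) {
    pr <- runif(sample(2:40, 1))
    bh <- adjust_pvalues(pr, "BH"); hm <- adjust_pvalues(pr, "Holm")
    expect_equal(bh, p.adjust(pr, "BH"))
    expect_equal(hm, p.adjust(pr, "holm"))
    expect_true(all(hm >= bh - 1e-12 & bh >= pr - 1e-12))
  }
})

test_that("association_results assembles the gene-test schema", {
  set.seed(407)
  g <- matrix(rbinom(200 * 4, 2, 0.05), 200, 4)
  gm <- tiny_gm(g)
  ph <- tiny_pheno(gm$individuals, rep(c("case", "control"), 100))
  sets <- list(GA = colnames(gm$calls)[1:2], GB = colnames(gm$calls)[3:4])
  res <- association_results(gm, ph, sets)
  expect_equal(res$unit_id, c("GA", "GB"))
  expect_true(all(res$p_holm >= res$p_bh & res$p_bh >= res$p))
  expect_true(all(res$ci_lo <= res$or_cmle & res$or_cmle <= res$ci_hi))
})
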
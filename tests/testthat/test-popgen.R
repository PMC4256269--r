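# Allele counting, heterogeneity G tests, swept-allele identification,
# F_ST, diversity indices, LD significance and multiple testing.

make_sample <- function(geno_list, id = "s") {
  # geno_list: per locus, a 2-column matrix of allele labels
  loci <- names(geno_list)
  n <- nrow(geno_list[[1]])
  g <- array(NA_character_, c(n, length(loci), 2),
             dimnames = list(NULL, loci, c("allele1", "allele2")))
  for (l in loci) {
    g[, l, 1] <- geno_list[[l]][, 1]
    g[, l, 2] <- geno_list[[l]][, 2]
  }
  hap_sample(g, sample_id = id)
}

test_that("allele counting respects missing slots", {
  g <- matrix(c("x", "y", "x", "x"), 2, 2)
  s <- make_sample(list(L = g))
  expect_equal(allele_counts(s, "L"), c(x = 3L, y = 1L))
  g[1, 2] <- NA
  s <- make_sample(list(L = g))
  expect_equal(sum(allele_counts(s, "L")), 3)
  expect_error(allele_counts(s, "nope"), "not present")
  # an empty sample counts zero copies, with a warning
  s0 <- make_sample(list(L = matrix(NA_character_, 2, 2)))
  expect_warning(cnt <- allele_counts(s0, "L", alleles = c("x", "y")),
                 "no scored")
  expect_equal(unname(cnt), c(0L, 0L))
})

test_that("the G statistic matches hand computation and its invariances", {
  # identical distributions: G = 0, p = 1
  g <- g_heterogeneity(c(a = 12, b = 24), c(a = 12, b = 24),
                       method = "both", B = 200, seed = 1)
  expect_equal(g$G, 0)
  expect_equal(g$p_asymptotic, 1)
  expect_equal(g$p_mc, 1)
  # complete separation of a 2x2: G = 4 * 10 * ln 2
  g <- g_heterogeneity(c(a = 10, b = 0), c(a = 0, b = 10),
                       method = "both", B = 5000, seed = 1)
  expect_equal(g$G, 40 * log(2), tolerance = 1e-12)
  expect_lt(g$p_asymptotic, 0.001)
  expect_lt(g$p_mc, 0.001)
  # invariant under column permutation
  x <- c(a = 5, b = 9, c = 2); y <- c(a = 1, b = 4, c = 8)
  g1 <- g_heterogeneity(x, y, method = "asymptotic")
  g2 <- g_heterogeneity(x[c(3, 1, 2)], y[c(3, 1, 2)],
                        method = "asymptotic")
  expect_equal(g1$G, g2$G)
  # proportional rows are homogeneous
  g3 <- g_heterogeneity(c(a = 10, b = 20, c = 30),
                        c(a = 5, b = 10, c = 15), method = "asymptotic")
  expect_equal(g3$G, 0, tolerance = 1e-12)
  expect_error(g_heterogeneity(c(a = 3), c(a = 5), method = "asymptotic"),
               ">= 2 alleles")
  expect_error(g_heterogeneity(c(a = 0, b = 0), c(a = 1, b = 1),
                               method = "asymptotic"), "at least one")
})

test_that("Monte-Carlo p-values agree with exact enumeration", {
  cases <- list(list(x = c(a = 8, b = 4), y = c(a = 2, b = 10)),
                list(x = c(a = 6, b = 6), y = c(a = 5, b = 7)),
                list(x = c(a = 12, b = 2), y = c(a = 7, b = 7)))
  B <- 20000
  for (cs in cases) {
    p_exact <- exact_g_test_p(cs$x, cs$y)
    p_mc <- g_heterogeneity(cs$x, cs$y, B = B, seed = 99)$p_mc
    tol <- 3 * sqrt(p_exact * (1 - p_exact) / B) + 2 / B
    expect_lt(abs(p_mc - p_exact), tol)
  }
})

test_that("swept alleles are identified by their standardized residuals", {
  # one allele rises 0.10 -> 0.60 while four fall proportionally
  pre <- c(a1 = 10, a2 = 30, a3 = 25, a4 = 20, a5 = 15)
  post <- c(a1 = 60, a2 = 13, a3 = 12, a4 = 9, a5 = 6)
  r <- identify_swept_alleles(pre, post, alpha = 0.05,
                              method = "asymptotic")
  expect_equal(r$swept[1], "a1")
  expect_true(r$homogeneous)
  # removal of the swept column never increases G (direct recomputation)
  g_all <- g_heterogeneity(pre, post, method = "asymptotic")$G
  g_rm <- g_heterogeneity(pre[-1], post[-1], method = "asymptotic")$G
  expect_lte(g_rm, g_all)
  # two independently inflated alleles need two rounds
  pre2 <- c(a1 = 20, a2 = 20, a3 = 20, a4 = 20, a5 = 20)
  post2 <- c(a1 = 40, a2 = 34, a3 = 9, a4 = 9, a5 = 8)
  r2 <- identify_swept_alleles(pre2, post2, alpha = 0.05,
                               method = "asymptotic")
  expect_true(all(c("a1", "a2") %in% r2$swept))
  # every reported swept allele increased in frequency
  for (al in r2$swept)
    expect_gt(post2[[al]] / sum(post2), pre2[[al]] / sum(pre2))
  # the procedure is undefined for two alleles, and inapplicable when
  # the samples are already homogeneous
  expect_error(identify_swept_alleles(c(a = 30, b = 10), c(a = 10, b = 30)),
               "undefined")
  expect_error(identify_swept_alleles(pre, pre, method = "asymptotic"),
               "homogeneous")
})

test_that("F_ST matches the variance-components formula", {
  # identical distributions: estimator ~ 0 (the unbiased variance-
  # components form is mildly negative when MSA < MSW), permutation p ~ 1
  f0 <- fst(c(a = 30, b = 30), c(a = 30, b = 30), B = 500, seed = 1)
  expect_lt(abs(f0$fst), 0.05)
  expect_lte(f0$fst, 0)
  expect_gt(f0$p, 0.9)
  # fixed alternative alleles: maximal differentiation
  f1 <- fst(c(a = 200, b = 0), c(a = 0, b = 200), B = 500, seed = 1)
  expect_equal(f1$fst, 1, tolerance = 1e-3)
  expect_lt(f1$p, 0.01)
  # the worked two-allele case equals the hand formula to 1e-12
  x <- c(a = 60, b = 36); y <- c(a = 30, b = 66)
  f <- fst(x, y, B = 0)
  expect_equal(f$fst, oracle_fst_2pop(x, y), tolerance = 1e-12)
  # multi-allelic case against the same oracle
  x3 <- c(a = 40, b = 30, c = 26); y3 <- c(a = 70, b = 10, c = 16)
  expect_equal(fst(x3, y3, B = 0)$fst, oracle_fst_2pop(x3, y3),
               tolerance = 1e-12)
  # monomorphic pooled locus is flagged, not computed
  expect_true(fst(c(a = 10), c(a = 12), B = 0)$monomorphic)
})

test_that("F_ST permutation p-values are calibrated under the null", {
  # draw paired samples from one pool; the rejection rate at 5% stays
  # within Monte-Carlo error of 5%
  set.seed(11)
  R <- 200
  rej <- 0
  for (i in 1:R) {
    pool <- c(0.5, 0.3, 0.2)
    x <- table(factor(sample(3, 60, TRUE, pool), levels = 1:3))
    y <- table(factor(sample(3, 60, TRUE, pool), levels = 1:3))
    f <- fst(setNames(as.numeric(x), c("a", "b", "c")),
             setNames(as.numeric(y), c("a", "b", "c")),
             B = 200, seed = i)
    if (!is.na(f$p) && f$p < 0.05) rej <- rej + 1
  }
  expect_lt(rej / R, 0.05 + 3 * sqrt(0.05 * 0.95 / R))
})

test_that("effective allele number behaves as a diversity index", {
  expect_equal(effective_allele_number(rep(1 / 7, 7)), 7)
  expect_equal(effective_allele_number(c(1)), 1)
  expect_equal(effective_allele_number(c(0.5, 0.25, 0.25)), 1 / 0.375)
  # counts normalize internally
  expect_equal(effective_allele_number(c(50, 25, 25)), 1 / 0.375)
  # never exceeds the observed allele count; drops when one allele
  # inflates at the others' proportional expense
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_lte(effective_allele_number(p), 4)
  inflate <- function(p, q) c(q, p[-1] * (1 - q) / sum(p[-1]))
  expect_lt(effective_allele_number(inflate(p, 0.8)),
            effective_allele_number(p))
  expect_error(effective_allele_number(numeric(0)), "positive")
})

test_that("Holm decisions match hand-worked cases and control FWER", {
  d <- sequential_bonferroni(c(0.001, 0.04), alpha = 0.05)
  expect_equal(d$reject, c(TRUE, TRUE))
  d <- sequential_bonferroni(c(0.03, 0.04), alpha = 0.05)
  expect_equal(d$reject, c(FALSE, FALSE))
  expect_equal(nrow(sequential_bonferroni(numeric(0))), 0)
  # uniformly no less powerful than plain Bonferroni
  set.seed(3)
  for (i in 1:50) {
    p <- runif(8)^2
    holm <- sequential_bonferroni(p, 0.05)$reject
    bonf <- p <= 0.05 / length(p)
    expect_true(all(holm | !bonf))
  }
  # FWER on global nulls
  set.seed(4)
  R <- 400
  fam_err <- mean(vapply(1:R, function(i)
    any(sequential_bonferroni(runif(10), 0.05)$reject), logical(1)))
  expect_lt(fam_err, 0.05 + 3 * sqrt(0.05 * 0.95 / R))
})

test_that("LD significance detects association and stays calibrated", {
  # perfectly associated biallelic loci across 25 diploids (50 haplotypes)
  al <- rep(c("x", "y"), each = 25)
  g <- list(L1 = cbind(al[1:25], al[26:50]),
            L2 = cbind(toupper(al[1:25]), toupper(al[26:50])))
  s <- make_sample(g)
  r <- ld_significance(s, "L1", "L2", B = 2000, seed = 5)
  expect_lt(r$p, 0.001)
  # determinism
  r2 <- ld_significance(s, "L1", "L2", B = 2000, seed = 5)
  expect_identical(r$p, r2$p)
  # monomorphic locus: not applicable
  g$L3 <- cbind(rep("z", 25), rep("z", 25))
  s <- make_sample(g)
  expect_true(ld_significance(s, "L1", "L3", B = 100, seed = 1)$monomorphic)
  # independently shuffled loci: uniform p-values
  set.seed(6)
  R <- 300
  ps <- vapply(1:R, function(i) {
    a <- sample(c("x", "y"), 60, TRUE)
    b <- sample(c("u", "v", "w"), 60, TRUE)
    s <- make_sample(list(L1 = cbind(a[1:30], a[31:60]),
                          L2 = cbind(b[1:30], b[31:60])))
    ld_significance(s, "L1", "L2", B = 300, seed = i)$p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / R) + 1 / 300)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})
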
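# Informative-cross analysis: co-segregation, recombinant exclusion,
# map distances, survival.

test_that("co-segregation probabilities follow the halving rule", {
  fam <- cross_family(matrix(1L, 16, 1, dimnames = list(NULL, "A")),
                      rep("son", 16))
  r <- cosegregation_test(fam, "A")
  expect_equal(r$p, 0.5^16)
  expect_true(r$cosegregating)
  expect_lt(r$p, 1e-4)
  # 60 sons: 9e-19 to one significant figure
  fam60 <- cross_family(matrix(1L, 60, 1, dimnames = list(NULL, "A")),
                        rep("son", 60))
  expect_equal(signif(cosegregation_test(fam60, "A")$p, 1), 9e-19)
  # mixed alleles: verdict not co-segregating, p = 1
  inh <- matrix(c(rep(1L, 10), rep(2L, 6)), ncol = 1,
                dimnames = list(NULL, "A"))
  fam2 <- cross_family(inh, rep("son", 16))
  r2 <- cosegregation_test(fam2, "A")
  expect_false(r2$cosegregating)
  expect_equal(r2$p, 1)
  # daughters segregate ~1:1 and are reported as a sanity check
  inh3 <- matrix(c(rep(1L, 8), rep(1L, 4), rep(2L, 4)), ncol = 1,
                 dimnames = list(NULL, "A"))
  fam3 <- cross_family(inh3, c(rep("son", 8), rep("daughter", 8)))
  expect_equal(cosegregation_test(fam3, "A")$daughter_p, 1)
  expect_error(cosegregation_test(
    cross_family(matrix(1L, 2, 1, dimnames = list(NULL, "A")),
                 rep("daughter", 2)), "A"), "no sons")
})

test_that("recombinant exclusion localizes the suppressor region", {
  # the mapped configuration: 1 recombinant at C, none at D/E/F, 2 at G
  rec <- c(A = 2, B = 1, C = 1, D = 0, E = 0, F = 0,
           G = 2, H = 3, I = 4, J = 5, K = 6, L = 7)
  fam <- sons_only_family(rec)
  loc <- localize_region(fam)
  expect_equal(loc$retained, c("D", "E", "F"))
  expect_equal(loc$interval, c("C", "G"))
  expect_equal(unname(loc$recombinants[c("C", "D", "G")]), c(1, 0, 2))
  # no recombinants anywhere: whole chromosome retained, open interval
  fam_all <- sons_only_family(setNames(rep(0, 5), LETTERS[1:5]))
  loc_all <- localize_region(fam_all)
  expect_equal(loc_all$retained, LETTERS[1:5])
  expect_true(all(is.na(loc_all$interval)))
  # recombinants everywhere: empty localization
  fam_none <- sons_only_family(setNames(rep(1, 4), LETTERS[1:4]))
  expect_length(localize_region(fam_none)$retained, 0)
  # a marker with zero recombinants is never excluded
  set.seed(2)
  for (i in 1:10) {
    rec <- setNames(rpois(8, 1), LETTERS[1:8])
    loc <- localize_region(sons_only_family(rec, n_sons = 30))
    expect_true(all(loc$recombinants[loc$retained] == 0))
  }
})

test_that("recombination fractions count discordant meioses", {
  inh <- cbind(A = rep(1:2, each = 10), B = rep(1:2, each = 10))
  fam <- cross_family(inh, rep("daughter", 20), type = "male-informative")
  expect_equal(recombination_fraction(fam, "A", "B")$r, 0)
  # complementary vectors: flagged as unlinked-or-phase-error
  inh2 <- cbind(A = rep(1:2, each = 10), B = rep(2:1, each = 10))
  fam2 <- cross_family(inh2, rep("daughter", 20),
                       type = "male-informative")
  rf <- recombination_fraction(fam2, "A", "B")
  expect_equal(rf$r, 1)
  expect_true(rf$phase_warning)
  # 31 recombinants of 307 meioses
  inh3 <- cbind(A = rep(1L, 307),
                B = c(rep(2L, 31), rep(1L, 276)))
  fam3 <- cross_family(inh3, rep("daughter", 307),
                       type = "male-informative")
  expect_equal(recombination_fraction(fam3, "A", "B")$r, 31 / 307)
  expect_error(recombination_fraction(
    cross_family(cbind(A = 1L, B = 1L), "daughter",
                 type = "male-informative"), "A", "B"), "fewer than 2")
})

test_that("the Haldane map function and its inverse are consistent", {
  expect_equal(haldane_cm(0), 0)
  expect_equal(haldane_cm(0.1), -50 * log(0.8))
  expect_equal(haldane_cm(0.1), 11.157, tolerance = 1e-4)
  expect_equal(haldane_r(haldane_cm(0.25)), 0.25, tolerance = 1e-12)
  expect_equal(haldane_cm(haldane_r(41)), 41, tolerance = 1e-9)
  expect_error(haldane_cm(0.5), "infinite")
  # strictly increasing and convex on [0, 0.5)
  r <- seq(0, 0.49, by = 0.01)
  d <- haldane_cm(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
})

test_that("map estimation recovers the simulated intervals", {
  map <- linkage_map(LETTERS[1:5], positions = c(0, 10, 20, 30, 41))
  attr(map, "suppressor_cm") <- 11.5
  fam <- simulate_cross_family("male-informative", 4000, map, seed = 31)
  est <- estimate_map(fam, map)
  truth <- diff(map$positions)
  got <- diff(est$positions)
  for (i in seq_along(truth)) {
    r_true <- haldane_r(truth[i])
    n <- attr(est, "estimates")$n[i]
    tol_r <- 3 * sqrt(r_true * (1 - r_true) / n)
    expect_lt(abs(haldane_r(got[i]) - r_true), tol_r)
  }
})

test_that("survival estimates follow the sexed offspring counts", {
  expect_equal(survival_estimate(60, n_expected = 150)$survival, 0.4)
  # the cross's raw counts: 60 sons vs 307 daughters
  expect_equal(survival_estimate(60, 307)$survival, 60 / 153.5)
  expect_equal(round(survival_estimate(60, 307)$survival, 1), 0.4)
  expect_equal(survival_estimate(50, 100)$survival, 1)
  expect_equal(survival_estimate(0, 100)$survival, 0)
  expect_error(survival_estimate(10, 0), "positive")
})

test_that("simulated cross families honour the meiosis and survival rules", {
  map <- linkage_map(LETTERS[1:6], positions = c(0, 8, 11, 12, 17, 41))
  attr(map, "suppressor_cm") <- 11.5
  # female-informative: no recombination, so surviving sons carry the
  # complete maternal suppressor haplotype
  ff <- simulate_cross_family("female-informative", 400, map, seed = 21)
  sons <- ff$inherited[ff$sex == "son", , drop = FALSE]
  expect_true(all(sons == 1L))
  # daughters segregate both haplotypes
  dau <- ff$inherited[ff$sex == "daughter", 1]
  expect_true(all(c(1L, 2L) %in% dau))
  # same seed, same family
  ff2 <- simulate_cross_family("female-informative", 400, map, seed = 21)
  expect_identical(ff$inherited, ff2$inherited)
  # male-informative: daughter recombinant fraction matches the map
  mf <- simulate_cross_family("male-informative", 3000, map,
                              survival = 0.4, seed = 22)
  rf <- recombination_fraction(mf, "A", "E")
  r_true <- haldane_r(17)
  expect_lt(abs(rf$r - r_true), 3 * sqrt(r_true * (1 - r_true) / rf$n))
  # son:daughter ratio ~ survival / 2
  ratio <- sum(mf$sex == "son") / sum(mf$sex == "daughter")
  expect_lt(abs(ratio - 0.2), 0.05)
})

test_that("localization covers the true position across replicates", {
  # marker geometry of the mapped chromosome: a cluster of three markers
  # within 1 cM of the suppressor, flanked at 3 and 5 cM
  map <- linkage_map(LETTERS[1:12],
                     positions = c(0, 4, 8, 11, 11.5, 12, 17, 22, 27, 32,
                                   36.5, 41))
  attr(map, "suppressor_cm") <- 11.3
  hits <- 0
  R <- 40
  for (i in 1:R) {
    fam <- simulate_cross_family("male-informative", 600, map,
                                 survival = 0.4, seed = 100 + i)
    loc <- localize_region(fam, map)
    if (length(loc$retained) == 0) next
    lo <- if (is.na(loc$interval[1])) 0 else
      map$positions[loc$interval[1]]
    hi <- if (is.na(loc$interval[2])) 41 else
      map$positions[loc$interval[2]]
    if (lo <= 11.3 && 11.3 <= hi) hits <- hits + 1
  }
  expect_gte(hits / R, 0.95)
})
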
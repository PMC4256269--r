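# The deterministic recursion: gamete formation, selection, hitchhiking.

test_that("gamete distributions reflect male-limited recombination", {
  # homozygote: a single gamete regardless of r
  g <- gamete_distribution("SA", "SA", 0.3, sex = "male")
  expect_equal(unname(g["SA"]), 1)
  # heterozygote at r = 0.1: parental 0.45 each, recombinant 0.05 each
  g <- gamete_distribution("SA", "sa", 0.1, sex = "male")
  expect_equal(unname(g[c("SA", "sa", "Sa", "sA")]),
               c(0.45, 0.45, 0.05, 0.05))
  # female meiosis is achiasmatic: the same diplotype ignores r entirely
  g <- gamete_distribution("SA", "sa", 0.1, sex = "female")
  expect_equal(unname(g[c("SA", "sa", "Sa", "sA")]), c(0.5, 0.5, 0, 0))
  # distributions are proper across random diplotypes and rates
  haps2 <- c("SA", "Sa", "sA", "sa")
  set.seed(1)
  for (rep in 1:20) {
    h <- sample(haps2, 2, replace = TRUE)
    r <- runif(1, 0, 0.5)
    for (sx in c("male", "female"))
      expect_equal(sum(gamete_distribution(h[1], h[2], r, sx)), 1)
  }
  # three-locus male gametes: independent crossovers across intervals
  g <- gamete_distribution("SAB", "sab", c(0.1, 0.2), sex = "male")
  expect_equal(unname(g["SAB"]), 0.9 * 0.8 / 2)
  expect_equal(unname(g["SAb"]), 0.9 * 0.2 / 2)
  expect_equal(unname(g["Sab"]), 0.1 * 0.8 / 2)
  expect_equal(unname(g["SaB"]), 0.1 * 0.2 / 2)
})

test_that("initial state carries the prescribed masses", {
  p <- sweep_params(prevalence = 0.99, immigrant_fraction = 0.01)
  st <- initial_state(p)
  expect_equal(sum(st$female[, , 2]), 0.99)
  expect_equal(sum(st$female), 1)
  expect_equal(sum(st$male), 1)
  # S frequency in the male pool equals the immigrant fraction
  f <- mksweep:::allele_freq_state(st)
  expect_equal(f["S", "male"], 0.01)
  expect_equal(f["S", "female"], 0)
  # invalid configurations are rejected
  expect_error(sweep_params(rec_fractions = 0.7), "0.5")
  expect_error(sweep_params(immigrant_fraction = 1.2), "proportion")
  expect_error(sweep_sim(sweep_params(), 0), ">= 1")
})

test_that("absence of the suppressor is absorbing", {
  p <- sweep_params(immigrant_fraction = 0)
  sim <- sweep_sim(p, 10)
  expect_equal(unname(allele_freq(sim, "S")), rep(0, 11))
})

test_that("without infection or CI the model is neutral Hardy-Weinberg", {
  # no infected females, no CI: allele frequencies constant from gen 1
  p <- sweep_params(prevalence = 0, ci_level = 0, rec_fractions = 0.2,
                    immigrant_fraction = 0.3, resident_freqs = 0.4)
  sim <- sweep_sim(p, 10)
  for (loc in c("S", "A")) {
    tr <- unname(allele_freq(sim, loc))
    expect_equal(tr[-1], rep(tr[2], 10), tolerance = 1e-12)
  }
  # same neutrality limit with infection present but harmless
  p <- sweep_params(survival = c(ss = 1, Ss = 1, SS = 1), ci_level = 0,
                    rec_fractions = 0.1)
  sim <- sweep_sim(p, 8)
  tr <- unname(allele_freq(sim, "S"))
  expect_equal(tr[-1], rep(tr[2], 8), tolerance = 1e-12)
})

test_that("male killing selects on infected male zygotes as specified", {
  p <- sweep_params()
  st <- next_generation(initial_state(p), p)
  haps <- rownames(st$haps)
  # infected ss males have adult frequency 0
  ss <- outer(st$haps[, "S"] == 0, st$haps[, "S"] == 0)
  expect_equal(sum(st$male[, , 2][ss]), 0)
  # heterozygous infected male zygotes survive at exactly half their
  # zygotic mass (the female pool, rescaled by its own surviving mass,
  # is the unselected zygote distribution)
  Ss <- outer(st$haps[, "S"], st$haps[, "S"], `+`) == 1
  expect_equal(sum(st$male[, , 2][Ss]) * st$mass[["male"]],
               0.5 * sum(st$female[, , 2][Ss]) * st$mass[["female"]])
})

test_that("frequency vectors stay on the simplex and infection is maternal", {
  p <- sweep_params(rec_fractions = 0.1, resident_freqs = 0.3)
  st <- initial_state(p)
  for (g in 1:25) {
    st <- next_generation(st, p)
    expect_equal(sum(st$female), 1, tolerance = 1e-12)
    expect_equal(sum(st$male), 1, tolerance = 1e-12)
    expect_true(all(st$female >= 0) && all(st$male >= 0))
  }
  # a fully uninfected maternal pool produces no infected offspring
  p0 <- sweep_params(prevalence = 0)
  st0 <- next_generation(initial_state(p0), p0)
  expect_equal(sum(st0$female[, , 2]), 0)
  expect_equal(sum(st0$male[, , 2]), 0)
})

test_that("complete linkage means perfect hitchhiking", {
  p <- sweep_params(rec_fractions = 0)
  sim <- sweep_sim(p, 30)
  expect_equal(allele_freq(sim, "A"), allele_freq(sim, "S"))
})

test_that("an irrelevant third locus does not perturb the two-locus model", {
  p2 <- sweep_params(rec_fractions = 0.05)
  p3 <- sweep_params(rec_fractions = c(0.05, 0.5),
                     resident_freqs = c(0, 0.5))
  s2 <- sweep_sim(p2, 25)$summary
  s3 <- sweep_sim(p3, 25)$summary
  expect_equal(s2$freq_S_pop, s3$freq_S_pop, tolerance = 1e-9)
  expect_equal(s2$freq_A_pop, s3$freq_A_pop, tolerance = 1e-9)
})

test_that("the first-generation jump approaches its bounds from below", {
  sim <- sweep_sim(sweep_params(), 2)
  # adult-male S frequency: close to, but not exceeding, one half
  m1 <- allele_freq(sim, "S", "m")[["1"]]
  expect_lt(m1, 0.5)
  expect_gt(m1, 0.35)
  # population frequency of the immigrant chromosome: near one quarter
  p1 <- allele_freq(sim, "S")[["1"]]
  expect_lt(p1, 0.25)
  expect_gt(p1, 0.2)
  # as prevalence -> 1 every surviving son is heterozygous Ss, so the
  # adult-male frequency attains the 1/2 bound exactly
  sim <- sweep_sim(sweep_params(prevalence = 1 - 1e-9), 1)
  expect_equal(allele_freq(sim, "S", "m")[["1"]], 0.5, tolerance = 1e-6)
})

test_that("equilibrium hitchhiking frequency is monotone in r", {
  eq <- equilibrium_profile(sweep_params(), seq(0, 0.5, by = 0.05))
  expect_true(all(eq$converged))
  expect_true(all(diff(eq$eq_freq) <= 1e-9))
  expect_equal(eq$eq_freq[eq$r == 0], 1, tolerance = 1e-6)
  expect_error(equilibrium_profile(sweep_params(), 0.1, tol = 0), "tol")
})

test_that("extinction is signalled, not silently normalized", {
  # every mother infected, no suppressor anywhere: all sons die
  p <- sweep_params(prevalence = 1, immigrant_fraction = 0)
  expect_error(sweep_sim(p, 2), "extinction")
})

test_that("LD metrics behave at the boundaries and during the sweep", {
  # resident population in linkage equilibrium: D = 0 between neutral
  # loci at generation 0 (no immigrant present)
  p <- sweep_params(rec_fractions = c(0.1, 0.2), immigrant_fraction = 0,
                    resident_freqs = c(0.3, 0.6))
  expect_equal(ld_metrics(initial_state(p), c("A", "B"))$D, 0)
  # complete association at r = 0: normalized LD attains its maximum
  sim <- sweep_sim(sweep_params(rec_fractions = 0), 5)
  ld <- ld_metrics(sim$states[[4]], c("S", "A"))
  expect_equal(ld$r_corr, 1, tolerance = 1e-12)
  # monomorphic locus: defined as 0 and flagged
  ld0 <- ld_metrics(initial_state(sweep_params(immigrant_fraction = 0)),
                    c("S", "A"))
  expect_true(ld0$monomorphic)
  expect_equal(ld0$D, 0)
})

test_that("local LD between linked neutral loci rises then decays", {
  p <- sweep_params(rec_fractions = c(0.05, 0.01))
  sim <- sweep_sim(p, 40)
  D <- abs(sim$summary$D_AB)
  at <- function(g) D[sim$summary$generation == g]
  expect_gt(at(10), 0.05)            # sweep generates local LD
  peak <- which.max(D) - 1           # generations are 0-indexed
  expect_gt(peak, 0)                 # it first rises
  expect_lt(peak, 15)                # peaking during the sweep
  expect_lt(at(40), max(D))          # and later decays
  # tightly linked pair: LD retained even after 40 generations
  expect_gt(at(40), 0.25 * max(D))
  # later-generation decay is slower than the early change
  expect_lt(abs(at(40) - at(20)), abs(at(20) - at(5)) + 1e-12)
})

test_that("sampling individuals is seeded and consistent with the state", {
  sim <- sweep_sim(sweep_params(rec_fractions = 0.05), 15)
  st <- sim$final
  # the simulate() method draws seeded replicate samples from a generation
  reps <- simulate(sim, nsim = 2, seed = 3, n = 20, generation = 10)
  expect_length(reps, 2)
  expect_false(identical(reps[[1]]$geno, reps[[2]]$geno))
  expect_identical(simulate(sim, 1, seed = 3, n = 20, generation = 10)[[1]],
                   reps[[1]])
  expect_error(simulate(sim, 1, n = 5), "seed")
  expect_error(sample_individuals(st, 0, seed = 1), ">= 1")
  s1 <- sample_individuals(st, 100, seed = 42)
  s2 <- sample_individuals(st, 100, seed = 42)
  expect_identical(s1$geno, s2$geno)
  # law of large numbers: sampled frequencies approach state frequencies
  big <- sample_individuals(st, 1e5, seed = 7)
  truth <- mksweep:::allele_freq_state(st)
  for (loc in c("S", "A")) {
    cnt <- allele_counts(big, loc)
    p_hat <- cnt[[toupper(loc)]] / sum(cnt)
    p_true <- truth[loc, "population"]
    tol <- 3 * sqrt(p_true * (1 - p_true) / (2 * 1e5))
    expect_lt(abs(p_hat - p_true), tol)
  }
})
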
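## Deterministic recursion for suppressor spread.
##
## State representation: for each sex an array F[h1, h2, inf] of frequencies
## over ordered pairs of gametic haplotypes (maternal, paternal) crossed with
## infection status (1 = uninfected, 2 = infected).  Each sex's array sums
## to 1.  Infection is part of the genotype because it is maternally
## transmitted and determines both male killing and CI.

#' Gamete distribution of a diplotype
#'
#' Probability distribution over gametic haplotypes produced by an
#' individual carrying haplotypes `h1` and `h2`.  In males, crossovers occur
#' independently in each adjacent interval with probability
#' `rec_fractions[i]` (no interference).  Female meiosis is achiasmatic:
#' the two parental haplotypes are transmitted unchanged, 1/2 each, and
#' `rec_fractions` is ignored.
#'
#' @param h1,h2 Haplotype labels, e.g. `"SA"`, `"sa"` (two loci) or
#'   `"SAb"` (three loci).  Uppercase = immigrant/suppressor allele.
#' @param rec_fractions Per-interval male recombination fractions.
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector of gamete probabilities (sums to 1).
#' @examples
#' gamete_distribution("SA", "sa", 0.1, sex = "male")
#' gamete_distribution("SA", "sa", 0.1, sex = "female")
#' @export
gamete_distribution <- function(h1, h2, rec_fractions,
                                sex = c("male", "female")) {
  sex <- match.arg(sex)
  n_loci <- length(rec_fractions) + 1L
  haps <- hap_table(n_loci)
  i1 <- match(h1, rownames(haps)); i2 <- match(h2, rownames(haps))
  if (is.na(i1) || is.na(i2))
    stop_("unknown haplotype label; expected one of: %s",
          paste(rownames(haps), collapse = ", "))
  r <- if (sex == "male") rec_fractions else rep(0, n_loci - 1L)
  G <- gamete_matrix(n_loci, r)
  setNames(G[(i2 - 1L) * nrow(haps) + i1, ], rownames(haps))
}

## Transmission matrix: rows index ordered diplotypes (h1 + (h2-1)*n_hap,
## i.e. column-major vec of F[,,inf]), columns index gamete haplotypes.
## Memoized: the recursion requests the same matrix every generation.
gamete_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(n_loci, rec_fractions) {
    key <- paste(n_loci, paste(format(rec_fractions, digits = 17),
                               collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- gamete_matrix_build(n_loci, rec_fractions)
    cache[[key]] <- val
    val
  }
})

gamete_matrix_build <- function(n_loci, rec_fractions) {
  haps <- hap_table(n_loci)
  n_hap <- nrow(haps)
  ## crossover patterns: which parental chromosome each locus is read from
  pat <- hap_table(n_loci)  # reuse binary enumeration, 0/1 = chromosome
  ppat <- apply(pat, 1, function(cfg) {
    pr <- 0.5
    if (n_loci > 1L) for (i in seq_len(n_loci - 1L))
      pr <- pr * if (cfg[i] == cfg[i + 1L]) 1 - rec_fractions[i] else
        rec_fractions[i]
    pr
  })
  G <- matrix(0, n_hap * n_hap, n_hap)
  for (i1 in seq_len(n_hap)) for (i2 in seq_len(n_hap)) {
    row <- (i2 - 1L) * n_hap + i1
    for (k in seq_len(nrow(pat))) {
      gam <- ifelse(pat[k, ] == 0L, haps[i1, ], haps[i2, ])
      g <- sum(gam * 2L^((n_loci - 1L):0)) + 1L
      G[row, g] <- G[row, g] + ppat[k] + 0  # chromosome roles symmetric
      ## pattern read with chromosomes swapped
      gam2 <- ifelse(pat[k, ] == 0L, haps[i2, ], haps[i1, ])
      g2 <- sum(gam2 * 2L^((n_loci - 1L):0)) + 1L
      G[row, g2] <- G[row, g2] + ppat[k]
    }
  }
  G / 2  # the two chromosome assignments above each carried full weight
}

#' Initial population state for the sweep model
#'
#' Constructs the generation-0 state: a resident population fixed for the
#' non-suppressor allele `s` (with neutral-locus alleles at their resident
#' frequencies, in linkage equilibrium), into which a single infected `SS`
#' immigrant male carrying the complete immigrant haplotype contributes
#' `immigrant_fraction` of the male gamete pool.  Females are infected with
#' probability `prevalence`.
#'
#' @param params A [sweep_params()] object.
#' @return An object of class `"sweep_state"`: list with per-sex frequency
#'   arrays (`female`, `male`), the generation counter, and haplotype
#'   bookkeeping.
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "sweep_params"))
  n_loci <- params$n_loci
  haps <- hap_table(n_loci)
  n_hap <- nrow(haps)
  ## resident chromosome pool: allele 1 at neutral locus l w.p. resident
  ## frequency, never S
  res <- apply(haps, 1, function(b) {
    if (b[1] == 1L) return(0)
    pr <- 1
    if (n_loci > 1L) for (l in 2:n_loci) {
      p <- params$resident_freqs[l - 1L]
      pr <- pr * if (b[l] == 1L) p else 1 - p
    }
    pr
  })
  female <- array(0, c(n_hap, n_hap, 2L),
                  dimnames = list(rownames(haps), rownames(haps),
                                  c("uninfected", "infected")))
  male <- female
  female[, , 2L] <- outer(res, res) * params$prevalence
  female[, , 1L] <- outer(res, res) * (1 - params$prevalence)
  i <- params$immigrant_fraction
  male[n_hap, n_hap, 2L] <- i      # immigrant: homozygous full haplotype
  male[, , 1L] <- male[, , 1L] + outer(res, res) * (1 - i)
  new_state(female, male, 0L, params, mass = c(female = 1, male = 1))
}

new_state <- function(female, male, generation, params, mass) {
  structure(list(female = female, male = male,
                 generation = as.integer(generation),
                 mass = mass, n_loci = params$n_loci,
                 haps = hap_table(params$n_loci)),
            class = "sweep_state")
}

#' @export
print.sweep_state <- function(x, ...) {
  cat("Sweep model state, generation", x$generation, "\n")
  f <- allele_freq_state(x)
  print(round(f, 4))
  invisible(x)
}

## male-survival multiplier array over (h1, h2, inf)
survival_array <- function(params) {
  haps <- hap_table(params$n_loci)
  n_hap <- nrow(haps)
  nS <- outer(haps[, 1L], haps[, 1L], `+`)
  sv <- array(1, c(n_hap, n_hap, 2L))
  sv[, , 2L] <- params$survival[nS + 1L]
  sv
}

#' Advance the sweep model by one generation
#'
#' Zygotes are formed by random union of female gametes (carrying the
#' mother's infection status) and male gametes; CI mortality removes a
#' fraction `ci_level` of offspring of uninfected mothers sired by infected
#' fathers; infected male zygotes then survive according to their
#' suppressor genotype; each sex's adult distribution is renormalized.
#' The primary (zygotic) sex ratio is 1:1.
#'
#' @param state A `"sweep_state"`.
#' @param params The [sweep_params()] used to create it.
#' @return The next `"sweep_state"`; its `mass` element records each sex's
#'   surviving fraction of zygotes (before renormalization), from which the
#'   adult sex ratio follows.
#' @export
next_generation <- function(state, params) {
  stopifnot(inherits(state, "sweep_state"), inherits(params, "sweep_params"))
  n_loci <- params$n_loci
  n_hap <- 2L^n_loci
  Gf <- gamete_matrix(n_loci, rep(0, n_loci - 1L))
  Gm <- gamete_matrix(n_loci, params$rec_fractions)
  gf <- vapply(1:2, function(inf)
    as.vector(crossprod(Gf, as.vector(state$female[, , inf]))),
    numeric(n_hap))
  gm <- vapply(1:2, function(inf)
    as.vector(crossprod(Gm, as.vector(state$male[, , inf]))),
    numeric(n_hap))
  ## zygotes by (maternal hap, paternal hap, mother inf), CI applied on the
  ## uninfected-mother x infected-father union
  Z <- array(0, c(n_hap, n_hap, 2L), dimnames = dimnames(state$female))
  Z[, , 1L] <- outer(gf[, 1L], gm[, 1L]) +
    outer(gf[, 1L], gm[, 2L]) * (1 - params$ci_level)
  Z[, , 2L] <- outer(gf[, 2L], gm[, 1L] + gm[, 2L])
  female <- Z
  male <- Z * survival_array(params)
  mf <- sum(female); mm <- sum(male)
  if (mf <= 0 || mm <= 0)
    stop_("population extinction: surviving %s mass is zero at generation %d",
          if (mf <= 0) "female" else "male", state$generation + 1L)
  new_state(female / mf, male / mm, state$generation + 1L, params,
            mass = c(female = mf, male = mm))
}

## Allele frequencies from a state: matrix loci x subsets
allele_freq_state <- function(state) {
  haps <- state$haps
  freq_of <- function(F3, w = NULL) {
    m <- apply(F3, 3, function(M) {
      wh <- rowSums(M) + colSums(M)  # chromosome-pool weights, sums to 2
      as.vector(t(haps) %*% wh / 2)
    })                                # loci x inf
    m
  }
  ff <- freq_of(state$female); fm <- freq_of(state$male)
  pf_inf <- sum(state$female[, , 2L]); pm_inf <- sum(state$male[, , 2L])
  f_f <- rowSums(ff); f_m <- rowSums(fm)
  out <- cbind(female = f_f, male = f_m, population = (f_f + f_m) / 2)
  rownames(out) <- colnames(haps)
  attr(out, "prevalence") <- c(female = pf_inf, male = pm_inf)
  out
}

#' Run the deterministic sweep model
#'
#' Iterates the recursion for `generations` generations from the initial
#' state implied by `params` and records per-generation summaries: allele
#' frequencies by sex and population-wide (sexes weighted equally, since
#' each sex contributes half of the genes), infection prevalence by sex,
#' the adult sex ratio, and linkage disequilibrium of each neutral locus
#' with the suppressor (plus the local pair for the three-locus model).
#'
#' @param params A [sweep_params()] object.
#' @param generations Number of generations to iterate (>= 1).
#' @param keep_states Keep the full state sequence (default `TRUE`); with
#'   `FALSE` only the final state and the summary table are retained.
#' @return An object of class `"sweep_sim"` with elements `params`,
#'   `summary` (data frame, one row per generation 0..T), `states` (list of
#'   `"sweep_state"`, if kept) and `final` (last state).
#' @examples
#' sim <- sweep_sim(sweep_params(rec_fractions = 0.05), 20)
#' head(summary(sim))
#' @export
sweep_sim <- function(params, generations, keep_states = TRUE) {
  stopifnot(inherits(params, "sweep_params"))
  if (!is.numeric(generations) || length(generations) != 1L ||
      generations < 1)
    stop_("`generations` must be a single integer >= 1")
  generations <- as.integer(generations)
  state <- initial_state(params)
  states <- if (keep_states) vector("list", generations + 1L)
  rows <- vector("list", generations + 1L)
  for (g in 0:generations) {
    if (keep_states) states[[g + 1L]] <- state
    rows[[g + 1L]] <- summarize_state(state)
    if (g < generations) state <- next_generation(state, params)
  }
  out <- structure(list(params = params,
                        summary = do.call(rbind, rows),
                        states = states, final = state),
                   class = "sweep_sim")
  out
}

summarize_state <- function(state) {
  f <- allele_freq_state(state)
  prev <- attr(f, "prevalence")
  loci <- rownames(f)
  row <- data.frame(generation = state$generation)
  for (l in loci) {
    row[[paste0("freq_", l, "_pop")]] <- f[l, "population"]
    row[[paste0("freq_", l, "_f")]] <- f[l, "female"]
    row[[paste0("freq_", l, "_m")]] <- f[l, "male"]
  }
  row$prevalence_f <- prev[["female"]]
  row$prevalence_m <- prev[["male"]]
  m <- state$mass
  row$sex_ratio_male <- m[["male"]] / (m[["male"]] + m[["female"]])
  if (state$n_loci >= 2L) {
    ld <- ld_metrics(state, c("S", "A"))
    row$D_SA <- ld$D; row$r_SA <- ld$r_corr
  }
  if (state$n_loci == 3L) {
    ld <- ld_metrics(state, c("S", "B"))
    row$D_SB <- ld$D; row$r_SB <- ld$r_corr
    ld <- ld_metrics(state, c("A", "B"))
    row$D_AB <- ld$D; row$r_AB <- ld$r_corr
  }
  row
}

#' @export
print.sweep_sim <- function(x, ...) {
  T <- max(x$summary$generation)
  cat("Deterministic suppressor-sweep simulation, generations 0..",
      T, "\n", sep = "")
  print(x$params)
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("  final S frequency (population): %.4f\n", last$freq_S_pop))
  if (!is.null(last$freq_A_pop))
    cat(sprintf("  final A frequency (population): %.4f\n", last$freq_A_pop))
  invisible(x)
}

#' @export
summary.sweep_sim <- function(object, ...) object$summary

#' @export
as.data.frame.sweep_sim <- function(x, ...) x$summary

#' Plot allele-frequency trajectories of a sweep simulation
#'
#' @param x A `"sweep_sim"` object.
#' @param what Columns of the summary table to draw (default: population
#'   frequencies of every locus).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sweep_sim <- function(x, what = NULL, ...) {
  s <- x$summary
  if (is.null(what))
    what <- grep("^freq_.*_pop$", names(s), value = TRUE)
  cols <- hcl.colors(max(3L, length(what)), "Dark 3")[seq_along(what)]
  matplot(s$generation, as.matrix(s[, what, drop = FALSE]), type = "l",
          lty = 1, lwd = 2, col = cols, xlab = "generation",
          ylab = "allele frequency", ylim = c(0, 1), ...)
  legend("bottomright", legend = what, col = cols, lty = 1, lwd = 2,
         bty = "n")
  invisible(x)
}

#' Simulate finite samples from a sweep trajectory
#'
#' Draws `nsim` independent samples of `n` diploid individuals from the
#' adult population at a chosen generation of the trajectory (see
#' [sample_individuals()]).
#'
#' @param object A `"sweep_sim"` with its states kept.
#' @param nsim Number of samples.
#' @param seed Integer seed.
#' @param n Individuals per sample.
#' @param generation Generation to sample from (default: the last).
#' @param ... Unused.
#' @return A list of [hap_sample()] objects.
#' @importFrom stats simulate
#' @export
simulate.sweep_sim <- function(object, nsim = 1, seed = NULL, n = 48,
                               generation = NULL, ...) {
  if (is.null(object$states))
    stop_("rerun sweep_sim() with keep_states = TRUE to sample states")
  if (is.null(generation))
    generation <- max(object$summary$generation)
  st <- object$states[[generation + 1L]]
  if (is.null(st)) stop_("generation %s not in the trajectory", generation)
  if (is.null(seed)) stop_("an explicit integer `seed` is required")
  lapply(seq_len(nsim), function(k)
    sample_individuals(st, n, seed = child_seed(seed, k)))
}

#' Extract an allele-frequency trajectory
#'
#' @param sim A `"sweep_sim"` object.
#' @param locus `"S"`, `"A"` or `"B"`.
#' @param subset `"pop"` (sexes weighted equally), `"f"` or `"m"`.
#' @return Numeric vector indexed by generation 0..T.
#' @export
allele_freq <- function(sim, locus = "S", subset = c("pop", "f", "m")) {
  stopifnot(inherits(sim, "sweep_sim"))
  subset <- match.arg(subset)
  col <- paste0("freq_", locus, "_", subset)
  if (is.null(sim$summary[[col]])) stop_("no such locus: %s", locus)
  setNames(sim$summary[[col]], sim$summary$generation)
}

#' Equilibrium frequency of a hitchhiking allele across recombination
#' distances
#'
#' For each recombination fraction in `r_grid`, runs the two-locus model
#' with a neutral allele initially in complete association with the
#' suppressor and iterates until the per-generation change in its
#' population frequency falls below `tol`, reporting the equilibrium
#' frequency reached.
#'
#' @param params A [sweep_params()] object; its `rec_fractions` entry is
#'   replaced by each grid value in turn.
#' @param r_grid Recombination fractions in `[0, 0.5]`.
#' @param tol Convergence tolerance on the per-generation change of every
#'   tracked frequency (default `1e-10`).
#' @param max_gen Generation cap; non-convergence is flagged, never
#'   silently truncated.
#' @return Data frame (class `"sweep_equilibrium"`) with columns `r`,
#'   `eq_freq` (equilibrium frequency of the hitchhiking allele),
#'   `eq_freq_S`, `generations`, `converged`.
#' @export
equilibrium_profile <- function(params, r_grid, tol = 1e-10,
                                max_gen = 5000L) {
  stopifnot(inherits(params, "sweep_params"))
  if (tol <= 0) stop_("`tol` must be > 0")
  if (any(r_grid < 0 | r_grid > 0.5)) stop_("each r must lie in [0, 0.5]")
  res <- lapply(r_grid, function(r) {
    p <- params; p$rec_fractions <- r; p$n_loci <- 2L
    p$resident_freqs <- params$resident_freqs[1L]
    state <- initial_state(p)
    prevA <- prevS <- -1
    conv <- FALSE; g <- 0L
    repeat {
      state <- next_generation(state, p)
      g <- g + 1L
      f <- allele_freq_state(state)
      if (max(abs(f["A", "population"] - prevA),
              abs(f["S", "population"] - prevS)) < tol) {
        conv <- TRUE
        break
      }
      prevA <- f["A", "population"]; prevS <- f["S", "population"]
      if (g >= max_gen) break
    }
    f <- allele_freq_state(state)
    data.frame(r = r, eq_freq = f["A", "population"],
               eq_freq_S = f["S", "population"],
               generations = g, converged = conv)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (any(!out$converged))
    warn_("no convergence within %d generations for r = %s", max_gen,
          paste(out$r[!out$converged], collapse = ", "))
  class(out) <- c("sweep_equilibrium", "data.frame")
  out
}

#' @export
plot.sweep_equilibrium <- function(x, ...) {
  plot(x$r, x$eq_freq, type = "b", pch = 16, xlab = "recombination fraction",
       ylab = "equilibrium frequency of linked allele", ylim = c(0, 1), ...)
  invisible(x)
}

#' Linkage disequilibrium between two loci of a model state
#'
#' Computed on the adult chromosome pool with the sexes pooled at equal
#' weight (each sex contributes half of the genes).  `D` is the classical
#' coefficient `f(11) - p1 p2` for the immigrant-carried alleles, and
#' `r_corr = D / sqrt(p1 q1 p2 q2)` the correlation-style normalization.
#'
#' @param state A `"sweep_state"`.
#' @param loci Two locus names among `"S"`, `"A"`, `"B"`; local LD between
#'   the two neutral loci requires the three-locus model.
#' @return List with `D`, `r_corr`, allele frequencies `p1`, `p2` and a
#'   `monomorphic` flag (when a locus is monomorphic both measures are 0).
#' @export
ld_metrics <- function(state, loci = c("S", "A")) {
  stopifnot(inherits(state, "sweep_state"))
  ln <- locus_names(state$n_loci)
  if (length(loci) != 2L || !all(loci %in% ln))
    stop_("`loci` must name two of: %s (is the model three-locus?)",
          paste(ln, collapse = ", "))
  haps <- state$haps
  pool_of <- function(F3) {
    M <- F3[, , 1L] + F3[, , 2L]
    (rowSums(M) + colSums(M)) / 2
  }
  pool <- (pool_of(state$female) + pool_of(state$male)) / 2
  i1 <- match(loci[1L], ln); i2 <- match(loci[2L], ln)
  p1 <- sum(pool[haps[, i1] == 1L]); p2 <- sum(pool[haps[, i2] == 1L])
  p12 <- sum(pool[haps[, i1] == 1L & haps[, i2] == 1L])
  D <- p12 - p1 * p2
  mono <- p1 %in% c(0, 1) || p2 %in% c(0, 1) ||
    min(p1, 1 - p1, p2, 1 - p2) < 1e-14
  r_corr <- if (mono) 0 else D / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  list(D = if (mono) 0 else D, r_corr = r_corr, p1 = p1, p2 = p2,
       monomorphic = mono)
}

#' Draw diploid individuals from a model state
#'
#' Samples `n` diploid individuals multinomially from the sex-pooled adult
#' diplotype distribution (sexes at equal weight), retaining phase.
#'
#' @param state A `"sweep_state"`.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed (required: every stochastic entry point in the
#'   package is explicitly seeded).
#' @return A [hap_sample()] whose loci are the model's loci; allele labels
#'   are the per-locus letters (uppercase = immigrant allele).
#' @export
sample_individuals <- function(state, n, seed) {
  stopifnot(inherits(state, "sweep_state"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_("`n` must be a single integer >= 1")
  n <- as.integer(n)
  pool <- (state$female[, , 1L] + state$female[, , 2L] +
             state$male[, , 1L] + state$male[, , 2L]) / 2
  haps <- state$haps
  n_hap <- nrow(haps)
  counts <- with_seed(seed,
                      rmultinom(1L, n, prob = as.vector(pool))[, 1L])
  idx <- rep(seq_along(counts), counts)
  h1 <- (idx - 1L) %% n_hap + 1L
  h2 <- (idx - 1L) %/% n_hap + 1L
  perm <- with_seed(child_seed(seed, 1L), sample.int(n))
  h1 <- h1[perm]; h2 <- h2[perm]
  loci <- colnames(haps)
  geno <- array(NA_character_, c(n, length(loci), 2L),
                dimnames = list(paste0("ind", seq_len(n)), loci,
                                c("allele1", "allele2")))
  upper <- c(S = "S", A = "A", B = "B"); lower <- c(S = "s", A = "a", B = "b")
  for (l in seq_along(loci)) {
    geno[, l, 1L] <- ifelse(haps[h1, l] == 1L, upper[[loci[l]]],
                            lower[[loci[l]]])
    geno[, l, 2L] <- ifelse(haps[h2, l] == 1L, upper[[loci[l]]],
                            lower[[loci[l]]])
  }
  hap_sample(geno, sample_id = sprintf("generation%d", state$generation))
}
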
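#' Parameters of the deterministic suppressor-sweep model
#'
#' Bundles and validates every rate and frequency entering the deterministic
#' recursion for the spread of a dominant, zygotically acting suppressor of
#' Wolbachia-induced male killing.  The model tracks one selected locus
#' (alleles `S`/`s`) together with one or two linked, selectively neutral
#' loci (`A`/`a`, and `B`/`b` when present).  Infection is maternally
#' transmitted; male killing acts on infected male zygotes according to
#' their suppressor genotype; cytoplasmic incompatibility (CI) kills the
#' offspring of uninfected mothers sired by infected fathers; recombination
#' occurs in male meiosis only (female Lepidoptera are achiasmatic).
#'
#' @param prevalence Initial fraction of females infected with the
#'   male killer.  Default 0.99, the prevalence observed in Samoa before the
#'   sweep.
#' @param survival Named numeric vector `c(ss=, Ss=, SS=)`: viability of
#'   *infected* male zygotes by suppressor genotype.  Default
#'   `c(ss = 0, Ss = 0.5, SS = 1)`: a fully penetrant male killer with
#'   partially dominant rescue.  Uninfected males and all females are
#'   unaffected.
#' @param ci_level Fraction of offspring of uninfected-mother x
#'   infected-father pairings that die during embryogenesis. Default 1
#'   (complete CI).
#' @param rec_fractions Recombination fraction(s) in male meiosis for each
#'   adjacent interval along the locus order `S, A[, B]`.  Length 1 gives
#'   the two-locus model, length 2 the three-locus model.  Each value must
#'   lie in `[0, 0.5]`.
#' @param immigrant_fraction Share of the generation-0 male gamete pool
#'   contributed by the infected `SS` immigrant male that introduces the
#'   suppressor (his gametes carry the full immigrant haplotype).  Default
#'   0.1: with the pre-sweep sex ratio near 100 females per male, a single
#'   immigrant male lands in a resident male pool of order ten, and this
#'   value reproduces the first-generation frequencies the scenario implies
#'   (see the package vignette for the sensitivity sweep).
#' @param resident_freqs Frequency of the immigrant-carried allele among
#'   *resident* chromosomes at each neutral locus (length `n_loci - 1`).
#'   Default 0: the immigrant marks the locus with an allele novel to the
#'   resident population.
#'
#' @return An object of class `"sweep_params"`.
#' @seealso [sweep_sim()], [initial_state()], [equilibrium_profile()]
#' @examples
#' p <- sweep_params(rec_fractions = 0.05)
#' p
#' @export
sweep_params <- function(prevalence = 0.99,
                         survival = c(ss = 0, Ss = 0.5, SS = 1),
                         ci_level = 1,
                         rec_fractions = 0,
                         immigrant_fraction = 0.1,
                         resident_freqs = NULL) {
  if (!is_prob(prevalence) || length(prevalence) != 1L)
    stop_("`prevalence` must be a single proportion in [0, 1]")
  if (length(survival) != 3L || !is_prob(survival))
    stop_("`survival` must be three proportions, one per suppressor genotype")
  if (is.null(names(survival))) names(survival) <- c("ss", "Ss", "SS")
  survival <- survival[c("ss", "Ss", "SS")]
  if (anyNA(survival))
    stop_("`survival` must be named with genotypes ss, Ss, SS")
  if (!is_prob(ci_level) || length(ci_level) != 1L)
    stop_("`ci_level` must be a single proportion in [0, 1]")
  if (!is.numeric(rec_fractions) || !length(rec_fractions) %in% c(1L, 2L))
    stop_("`rec_fractions` must have length 1 (two loci) or 2 (three loci)")
  if (any(!is.finite(rec_fractions)) || any(rec_fractions < 0) ||
      any(rec_fractions > 0.5))
    stop_("each element of `rec_fractions` must lie in [0, 0.5]")
  if (!is_prob(immigrant_fraction) || length(immigrant_fraction) != 1L)
    stop_("`immigrant_fraction` must be a single proportion in [0, 1]")
  n_loci <- length(rec_fractions) + 1L
  if (is.null(resident_freqs)) resident_freqs <- rep(0, n_loci - 1L)
  if (length(resident_freqs) != n_loci - 1L || !is_prob(resident_freqs))
    stop_("`resident_freqs` must give one proportion per neutral locus")
  structure(list(prevalence = prevalence,
                 survival = survival,
                 ci_level = ci_level,
                 rec_fractions = as.numeric(rec_fractions),
                 immigrant_fraction = immigrant_fraction,
                 resident_freqs = as.numeric(resident_freqs),
                 n_loci = n_loci),
            class = "sweep_params")
}

#' @export
print.sweep_params <- function(x, ...) {
  cat("Suppressor-sweep model parameters (", x$n_loci, " loci)\n", sep = "")
  cat(sprintf("  female infection prevalence : %.4g\n", x$prevalence))
  cat(sprintf("  infected-male survival      : ss=%.3g Ss=%.3g SS=%.3g\n",
              x$survival[["ss"]], x$survival[["Ss"]], x$survival[["SS"]]))
  cat(sprintf("  CI mortality                : %.4g\n", x$ci_level))
  cat(sprintf("  male recombination fractions: %s\n",
              paste(signif(x$rec_fractions, 4), collapse = ", ")))
  cat(sprintf("  immigrant gamete fraction   : %.4g\n", x$immigrant_fraction))
  cat(sprintf("  resident immigrant-allele frequencies: %s\n",
              paste(signif(x$resident_freqs, 4), collapse = ", ")))
  invisible(x)
}

## Locus and haplotype bookkeeping.  Allele 1 denotes the immigrant-carried
## variant (S at the selected locus), allele 0 the resident one.
locus_names <- function(n_loci) c("S", "A", "B")[seq_len(n_loci)]

hap_table <- function(n_loci) {
  n <- 2L^n_loci
  bits <- matrix(0L, n, n_loci)
  for (l in seq_len(n_loci))
    bits[, l] <- (0:(n - 1L)) %/% 2L^(n_loci - l) %% 2L
  colnames(bits) <- locus_names(n_loci)
  upper <- c("S", "A", "B"); lower <- c("s", "a", "b")
  rownames(bits) <- apply(bits, 1, function(b)
    paste0(ifelse(b == 1L, upper[seq_len(n_loci)],
                  lower[seq_len(n_loci)]), collapse = ""))
  bits
}
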
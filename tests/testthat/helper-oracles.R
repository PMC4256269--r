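# Independent oracle implementations used across test files.  These are
# deliberately naive (enumeration / brute force / textbook formulas) and
# share no code with the package internals they check.

# All 2xK tables with the margins of rbind(x, y), with their probabilities
# under the null of independence conditional on both margins
# (multivariate hypergeometric), and the exact G-test p-value.
exact_g_test_p <- function(x, y) {
  k <- length(x)
  n1 <- sum(x)
  cols <- x + y
  g_of <- function(tab) {
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    keep <- tab > 0
    2 * sum(tab[keep] * log(tab[keep] / e[keep]))
  }
  g_obs <- g_of(rbind(x, y))
  # enumerate first-row cell counts recursively
  p_total <- 0
  enumerate <- function(i, remaining, row1) {
    if (i == k) {
      if (remaining > cols[k]) return()
      row1 <- c(row1, remaining)
      tab <- rbind(row1, cols - row1)
      lp <- sum(lchoose(cols, row1)) - lchoose(sum(cols), n1)
      if (g_of(tab) >= g_obs - 1e-9)
        p_total <<- p_total + exp(lp)
      return()
    }
    for (v in 0:min(cols[i], remaining))
      enumerate(i + 1L, remaining - v, c(row1, v))
  }
  enumerate(1L, n1, integer(0))
  p_total
}

# Brute-force nucleotide diversity: expand the haplotype counts into the
# full set of n sequences and average differences over all n(n-1)/2 pairs.
brute_pi <- function(seqs, counts) {
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap <- apply(M == "-", 2, any)
  M <- M[, !gap, drop = FALSE]
  idx <- rep(seq_along(seqs), counts)
  n <- length(idx)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(M[idx[i], ] != M[idx[j], ])
  k <- tot / (n * (n - 1) / 2)
  list(k = k, pi = k / ncol(M))
}

# Textbook Tajima's D written out directly from its defining constants.
oracle_tajima_d <- function(n, S, k_hat) {
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k_hat - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# Hand evaluation of the haploid variance-components F_ST for two samples:
# one-way ANOVA of 0/1 allele indicators, summed over alleles.
oracle_fst_2pop <- function(x, y) {
  ni <- c(sum(x), sum(y))
  ntot <- sum(ni); r <- 2
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  num <- den <- 0
  for (a in seq_along(x)) {
    p <- c(x[a] / ni[1], y[a] / ni[2])
    pbar <- (x[a] + y[a]) / ntot
    msa <- sum(ni * (p - pbar)^2) / (r - 1)
    msw <- sum(ni * p * (1 - p)) / (ntot - r)
    s2a <- (msa - msw) / nc
    num <- num + s2a
    den <- den + s2a + msw
  }
  num / den
}

# Deterministic per-(replicate, marker) seed for Monte-Carlo subtests.
child_seed_for_test <- function(i, m) {
  (i * 131 + sum(utf8ToInt(m))) %% 100000 + 1
}

# All-sons male-informative family: n sons all carrying the informative
# allele except for the given per-marker recombinant counts.
sons_only_family <- function(rec_counts, n_sons = 60) {
  mk <- names(rec_counts)
  inh <- matrix(1L, n_sons, length(mk), dimnames = list(NULL, mk))
  for (m in mk) if (rec_counts[[m]] > 0)
    inh[seq_len(rec_counts[[m]]), m] <- 2L
  cross_family(inh, rep("son", n_sons), type = "male-informative")
}
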
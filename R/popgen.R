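## Sweep-detection statistics: heterogeneity tests with swept-allele
## identification, differentiation, diversity, and LD significance.

#' Phased multi-locus haplotype sample
#'
#' Container for a population sample of `n` diploid individuals scored at a
#' set of loci.  Each individual carries exactly two allele slots per locus
#' (phased); either slot may be `NA` (missing).  Allele labels are
#' arbitrary strings, consistent within a locus across samples.
#'
#' @param geno A 3-d character array `[individuals, loci, 2]` (dimnames:
#'   individual ids, locus names, `c("allele1","allele2")`), or a data
#'   frame in long format with columns `individual`, `locus`, `allele1`,
#'   `allele2`.
#' @param sample_id Label for the sample (e.g. the time point).
#' @param sequences Optional named list: for each locus, a named character
#'   vector mapping allele labels to aligned sequences (enables
#'   [sequence_diversity()] through [sweep_report()]).
#' @return An object of class `"hap_sample"`.
#' @export
hap_sample <- function(geno, sample_id = "sample", sequences = NULL) {
  if (is.data.frame(geno)) {
    need <- c("individual", "locus", "allele1", "allele2")
    if (!all(need %in% names(geno)))
      stop_("long-format input needs columns: %s", paste(need, collapse = ", "))
    inds <- unique(geno$individual); loci <- unique(geno$locus)
    arr <- array(NA_character_, c(length(inds), length(loci), 2L),
                 dimnames = list(inds, loci, c("allele1", "allele2")))
    arr[cbind(match(geno$individual, inds), match(geno$locus, loci), 1L)] <-
      as.character(geno$allele1)
    arr[cbind(match(geno$individual, inds), match(geno$locus, loci), 2L)] <-
      as.character(geno$allele2)
    geno <- arr
  }
  if (!is.array(geno) || length(dim(geno)) != 3L || dim(geno)[3L] != 2L)
    stop_("`geno` must be an [n, loci, 2] array or a long-format data frame")
  storage.mode(geno) <- "character"
  structure(list(geno = geno, sample_id = sample_id, sequences = sequences),
            class = "hap_sample")
}

#' @export
print.hap_sample <- function(x, ...) {
  d <- dim(x$geno)
  cat(sprintf("Haplotype sample '%s': %d individuals x %d loci\n",
              x$sample_id, d[1L], d[2L]))
  miss <- mean(is.na(x$geno))
  if (miss > 0) cat(sprintf("  missing allele slots: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.hap_sample <- function(x) dim(x$geno)

sample_loci <- function(x) dimnames(x$geno)[[2L]]

#' Allele copy counts at one locus
#'
#' Counts non-missing allele copies (up to `2n`) at a locus of a
#' [hap_sample()].
#'
#' @param sample A `"hap_sample"`.
#' @param locus Locus name.
#' @param alleles Optional allele universe; counts are returned in this
#'   order (zeros filled in).
#' @return Named integer vector of allele-copy counts.
#' @export
allele_counts <- function(sample, locus, alleles = NULL) {
  stopifnot(inherits(sample, "hap_sample"))
  if (!locus %in% sample_loci(sample))
    stop_("locus '%s' not present in sample '%s'", locus, sample$sample_id)
  obs <- c(sample$geno[, locus, 1L], sample$geno[, locus, 2L])
  obs <- obs[!is.na(obs)]
  if (length(obs) == 0L)
    warn_("no scored allele copies at locus '%s' in sample '%s'",
          locus, sample$sample_id)
  if (is.null(alleles)) alleles <- sort(unique(obs))
  tab <- table(factor(obs, levels = alleles))
  setNames(as.integer(tab), alleles)
}

## G statistic of a contingency table (2 sum obs log(obs/exp), zero cells
## contribute nothing); shared by the heterogeneity and LD tests.
g_stat <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / e[keep]))
}

## Adjusted standardized residuals (cell deviation divided by its standard
## error under independence): (o - e) / sqrt(e (1 - row/n) (1 - col/n)).
adjusted_residuals <- function(tab) {
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  e <- outer(rs, cs) / n
  se <- sqrt(e * outer(1 - rs / n, 1 - cs / n))
  res <- (tab - e) / se
  res[!is.finite(res)] <- 0
  res
}

#' G test of allele-frequency heterogeneity between two samples
#'
#' Log-likelihood-ratio (G) test of homogeneity of the allele frequency
#' distributions of two samples at one locus.  The Monte-Carlo p-value
#' resamples tables with both margins fixed (Patefield algorithm); the
#' asymptotic p-value uses the chi-square distribution on
#' `(rows - 1)(cols - 1)` degrees of freedom.  Alleles unobserved in both
#' samples are dropped.
#'
#' @param t1_row,t2_row Named allele-count vectors (see [allele_counts()]);
#'   names are matched, missing alleles count 0.
#' @param method `"monte-carlo"` (default), `"asymptotic"`, or `"both"`.
#' @param B Monte-Carlo replicates (default 1e5).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @return Object of class `"g_test"`: `G`, `df`, `p` (the p-value of the
#'   requested method), `p_asymptotic`, `p_mc`, adjusted standardized
#'   `residuals`, and the `table` tested.
#' @examples
#' g_heterogeneity(c(a = 10, b = 0), c(a = 0, b = 10), seed = 1)
#' @export
g_heterogeneity <- function(t1_row, t2_row,
                            method = c("monte-carlo", "asymptotic", "both"),
                            B = 1e5, seed = NULL) {
  method <- match.arg(method)
  alleles <- union(names(t1_row), names(t2_row))
  if (is.null(alleles))
    stop_("allele-count vectors must be named")
  x <- setNames(rep(0, length(alleles)), alleles)
  y <- x
  x[names(t1_row)] <- t1_row; y[names(t2_row)] <- t2_row
  keep <- x + y > 0
  x <- x[keep]; y <- y[keep]
  if (sum(x) == 0 || sum(y) == 0)
    stop_("each sample must contain at least one scored allele copy")
  if (length(x) < 2L)
    stop_("need >= 2 alleles pooled across the samples")
  tab <- rbind(t1 = x, t2 = y)
  G <- g_stat(tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p_asym <- pchisq(G, df, lower.tail = FALSE)
  p_mc <- NA_real_
  if (method %in% c("monte-carlo", "both")) {
    if (is.null(seed))
      stop_("Monte-Carlo p-values require an explicit `seed`")
    sims <- with_seed(seed, r2dtable(B, rowSums(tab), colSums(tab)))
    gs <- vapply(sims, g_stat, numeric(1))
    p_mc <- (1 + sum(gs >= G - 1e-12)) / (B + 1)
  }
  p <- switch(method, `monte-carlo` = p_mc, asymptotic = p_asym,
              both = p_mc)
  structure(list(G = G, df = df, p = p, p_asymptotic = p_asym, p_mc = p_mc,
                 method = method, residuals = adjusted_residuals(tab),
                 table = tab),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G heterogeneity test: G = %.4f, df = %d\n", x$G, x$df))
  cat(sprintf("  p (asymptotic) = %.4g", x$p_asymptotic))
  if (!is.na(x$p_mc)) cat(sprintf("   p (Monte-Carlo) = %.4g", x$p_mc))
  cat("\n")
  invisible(x)
}

#' Iterative identification of swept alleles
#'
#' During a sweep, the allele initially associated with the target of
#' selection rises while all others fall proportionally, so the swept
#' allele is the largest contributor to heterogeneity between time points:
#' it carries the largest adjusted standardized residual.  This procedure
#' iterates: test heterogeneity; among alleles whose frequency increased,
#' pick the one with the largest residual; drop its column; retest.  It
#' stops when the samples are homogeneous at `alpha` or fewer than three
#' alleles remain.  With only two alleles the procedure is undefined (each
#' allele contributes equally to heterogeneity) and an error is raised.
#'
#' @inheritParams g_heterogeneity
#' @param alpha Significance level for the homogeneity stopping rule.
#' @param method,B,seed Passed to [g_heterogeneity()] for each round.
#' @return List: `swept` (ordered allele labels), `steps` (per-round
#'   `g_test` objects), `homogeneous` (was homogeneity restored?),
#'   `final_p`.
#' @export
identify_swept_alleles <- function(t1_row, t2_row, alpha = 0.05,
                                   method = "monte-carlo", B = 1e5,
                                   seed = NULL) {
  alleles <- union(names(t1_row), names(t2_row))
  x <- setNames(rep(0, length(alleles)), alleles)
  y <- x
  x[names(t1_row)] <- t1_row; y[names(t2_row)] <- t2_row
  keep <- x + y > 0; x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop_("swept-allele identification is undefined with %d alleles ",
          length(x))
  g0 <- g_heterogeneity(x, y, method = method, B = B, seed = seed)
  if (g0$p >= alpha)
    stop_("samples are homogeneous at alpha = %g (p = %.4g); nothing to identify",
          alpha, g0$p)
  swept <- character(0)
  steps <- list()
  k <- 0L
  g <- g0
  repeat {
    k <- k + 1L
    steps[[k]] <- g
    if (g$p >= alpha) break
    p1 <- x / sum(x); p2 <- y / sum(y)
    increased <- names(x)[p2 > p1]
    if (length(increased) == 0L) break
    res2 <- g$residuals["t2", increased]
    pick <- increased[which.max(res2)]
    swept <- c(swept, pick)
    x <- x[names(x) != pick]; y <- y[names(y) != pick]
    if (length(x) < 2L || sum(x) == 0 || sum(y) == 0) break
    g <- g_heterogeneity(x, y, method = method, B = B,
                         seed = child_seed(seed, k))
    if (length(x) < 3L) { k <- k + 1L; steps[[k]] <- g; break }
  }
  final <- steps[[length(steps)]]
  list(swept = swept, steps = steps,
       homogeneous = final$p >= alpha, final_p = final$p)
}

#' F_ST between two allele-count samples
#'
#' Variance-components estimator of Weir-Cockerham type for haploid allele
#' counts: a one-way analysis of variance of the 0/1 allele indicators
#' with samples as groups, combined over alleles.  Nei's G_ST is reported
#' alongside for comparison.  The permutation p-value shuffles allele
#' copies between the samples (preserving sample sizes).
#'
#' @inheritParams g_heterogeneity
#' @param B Permutations (default 1e4).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `"fst_test"`: `fst`, `gst`, `p` (permutation,
#'   `NA` if `B = 0`), `monomorphic` flag.
#' @export
fst <- function(t1_row, t2_row, B = 1e4, seed = NULL) {
  alleles <- union(names(t1_row), names(t2_row))
  x <- setNames(rep(0, length(alleles)), alleles)
  y <- x
  x[names(t1_row)] <- t1_row; y[names(t2_row)] <- t2_row
  keep <- x + y > 0; x <- x[keep]; y <- y[keep]
  n1 <- sum(x); n2 <- sum(y)
  if (n1 == 0 || n2 == 0) stop_("both samples must contain allele copies")
  if (length(x) < 2L)
    return(structure(list(fst = NA_real_, gst = NA_real_, p = NA_real_,
                          monomorphic = TRUE), class = "fst_test"))
  est <- fst_estimate(rbind(x, y))
  p <- NA_real_
  if (B > 0) {
    if (is.null(seed)) stop_("permutation p-values require an explicit `seed`")
    copies <- rep(seq_along(x), x + y)  # pooled allele copies (as codes)
    k <- length(x)
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(B)) {
        perm <- sample(copies)
        c1 <- tabulate(perm[seq_len(n1)], k)
        c2 <- tabulate(perm[(n1 + 1L):(n1 + n2)], k)
        if (fst_estimate(rbind(c1, c2))$fst >= est$fst - 1e-12)
          hits <- hits + 1L
      }
      (1 + hits) / (B + 1)
    })
  }
  structure(list(fst = est$fst, gst = est$gst, p = p, monomorphic = FALSE),
            class = "fst_test")
}

## rows = samples, cols = alleles; haploid-count variance components
fst_estimate <- function(tab) {
  ni <- rowSums(tab)
  r <- nrow(tab); ntot <- sum(ni)
  nbar <- mean(ni)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  p <- tab / ni
  pbar <- colSums(tab) / ntot
  msa <- colSums(ni * (p - rep(pbar, each = r))^2) / (r - 1)
  msw <- colSums(ni * p * (1 - p)) / (ntot - r)
  s2a <- (msa - msw) / nc
  denom <- sum(s2a + msw)
  fst_val <- if (denom <= 0) 0 else sum(s2a) / denom
  ## Nei's G_ST on the same counts
  hs <- sum(ni / ntot * (1 - rowSums(p^2)))
  ht <- 1 - sum(pbar^2)
  gst <- if (ht <= 0) 0 else (ht - hs) / ht
  list(fst = fst_val, gst = gst)
}

#' @export
print.fst_test <- function(x, ...) {
  if (x$monomorphic) {
    cat("F_ST undefined: locus monomorphic in the pooled sample\n")
  } else {
    cat(sprintf("F_ST = %.4f (Nei G_ST = %.4f)", x$fst, x$gst))
    if (!is.na(x$p)) cat(sprintf(", permutation p = %.4g", x$p))
    cat("\n")
  }
  invisible(x)
}

#' Effective number of alleles
#'
#' `A_E = 1 / sum(p_i^2)`: the number of equifrequent alleles producing the
#' same expected homozygosity; a diversity measure bounded by the observed
#' allele count.
#'
#' @param freqs Allele frequencies (summing to 1) or counts (normalized
#'   internally).
#' @return A single number in `[1, k]`.
#' @examples
#' effective_allele_number(c(0.5, 0.25, 0.25))  # 2.667
#' @export
effective_allele_number <- function(freqs) {
  if (length(freqs) == 0L || sum(freqs) <= 0)
    stop_("`freqs` must contain at least one positive entry")
  p <- freqs / sum(freqs)
  1 / sum(p^2)
}

#' Holm step-down ("sequential Bonferroni") decisions
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param alpha Family-wise error rate.
#' @return Data frame with `p`, `p_adjusted` (Holm) and logical `reject`.
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L)
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      reject = logical(0)))
  if (!is_prob(pvals)) stop_("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "holm")
  data.frame(p = pvals, p_adjusted = adj, reject = adj <= alpha)
}

#' Significance of linkage disequilibrium between two loci
#'
#' Log-likelihood-ratio (G) test of independence on the two-locus haplotype
#' count table of a phased sample, with the p-value obtained by Monte-Carlo
#' permutation of the haplotype alleles at one locus.  Only significance is
#' reported: the magnitude of LD is not a standardized measure, being
#' dependent on the allele frequency distributions.
#'
#' @param sample A [hap_sample()].
#' @param locusA,locusB Locus names.
#' @param B Permutations (default 1e4).
#' @param seed Integer seed.
#' @return List: `p`, `G`, `n_haplotypes` used, `monomorphic` flag (when a
#'   locus is monomorphic the test is not applicable and `p` is `NA`).
#' @export
ld_significance <- function(sample, locusA, locusB, B = 1e4, seed = NULL) {
  stopifnot(inherits(sample, "hap_sample"))
  for (l in c(locusA, locusB)) if (!l %in% sample_loci(sample))
    stop_("locus '%s' not present", l)
  a <- c(sample$geno[, locusA, 1L], sample$geno[, locusA, 2L])
  b <- c(sample$geno[, locusB, 1L], sample$geno[, locusB, 2L])
  keep <- !is.na(a) & !is.na(b)
  a <- factor(a[keep]); b <- factor(b[keep])
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    return(list(p = NA_real_, G = NA_real_, n_haplotypes = length(a),
                monomorphic = TRUE))
  if (is.null(seed)) stop_("permutation p-values require an explicit `seed`")
  ai <- as.integer(a); bi <- as.integer(b)
  ka <- nlevels(a); kb <- nlevels(b)
  count2 <- function(ai, bi) {
    tab <- matrix(tabulate((bi - 1L) * ka + ai, ka * kb), ka, kb)
    tab
  }
  G <- g_stat(count2(ai, bi))
  p <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(B)) {
      if (g_stat(count2(ai, sample(bi))) >= G - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (B + 1)
  })
  list(p = p, G = G, n_haplotypes = length(ai), monomorphic = FALSE)
}
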
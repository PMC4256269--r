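## DNA polymorphism statistics on aligned haplotype (allele) sequences.

#' Polymorphism and diversity statistics of aligned haplotypes
#'
#' Computes the standard per-locus summaries from a set of distinct
#' aligned haplotype sequences and their sample counts: segregating sites
#' `S`, number of haplotypes, haplotype diversity `Hd` (with sample-size
#' correction), mean pairwise difference `k`, nucleotide diversity per site
#' `pi`, Watterson's `theta` (per site), effective allele number `A_E`, and
#' Tajima's `D`.  Alignment columns containing a gap (`-`) in any sequence
#' are excluded before any site is counted, so indel variation never
#' enters the statistics.
#'
#' @param seqs Character vector of equal-length aligned sequences, one per
#'   distinct haplotype.
#' @param counts Integer vector: copies of each haplotype in the sample.
#' @return Object of class `"diversity_stats"`; fields `n`, `sites`, `S`,
#'   `n_haplotypes`, `Hd`, `k`, `pi`, `theta_w`, `A_E`, `tajima_D`
#'   (`NA` when `S = 0`).
#' @examples
#' sequence_diversity(c("ACGT", "ACGA"), counts = c(2, 2))
#' @export
sequence_diversity <- function(seqs, counts = rep(1L, length(seqs))) {
  if (length(seqs) == 0L) stop_("no sequences supplied")
  if (length(counts) != length(seqs))
    stop_("`counts` must match `seqs` in length")
  keep <- counts > 0
  seqs <- toupper(seqs[keep]); counts <- as.integer(counts[keep])
  L0 <- unique(nchar(seqs))
  if (length(L0) != 1L)
    stop_("sequences must be aligned to equal length (got lengths %s)",
          paste(sort(L0), collapse = ", "))
  M <- do.call(rbind, strsplit(seqs, ""))
  gap_col <- apply(M == "-", 2, any)
  M <- M[, !gap_col, drop = FALSE]
  L <- ncol(M)
  n <- sum(counts)
  seg <- apply(M, 2, function(col) length(unique(col)) > 1L)
  S <- sum(seg)
  h <- length(seqs)
  p <- counts / n
  Hd <- if (n > 1) n / (n - 1) * (1 - sum(p^2)) else 0
  ## mean pairwise differences over the n*(n-1)/2 sequence pairs
  dmat <- matrix(0, h, h)
  if (h > 1) for (i in 1:(h - 1)) for (j in (i + 1):h)
    dmat[i, j] <- dmat[j, i] <- sum(M[i, ] != M[j, ])
  npairs <- n * (n - 1) / 2
  k <- if (npairs > 0)
    sum(outer(counts, counts) * dmat) / 2 / npairs else 0
  pi <- if (L > 0) k / L else 0
  a1 <- if (n > 1) sum(1 / seq_len(n - 1)) else NA_real_
  theta_w <- if (L > 0 && n > 1) S / a1 / L else NA_real_
  D <- tajima_d(n, S, k)
  structure(list(n = n, sites = L, S = S, n_haplotypes = h, Hd = Hd,
                 k = k, pi = pi, theta_w = theta_w,
                 A_E = effective_allele_number(counts), tajima_D = D),
            class = "diversity_stats")
}

## Tajima's D from sample size, segregating sites and mean pairwise
## differences (standard variance normalization).
tajima_d <- function(n, S, k) {
  if (S == 0 || n < 4) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d sequences, %d sites | S = %d, haplotypes = %d, Hd = %.4f\n",
    x$n, x$sites, x$S, x$n_haplotypes, x$Hd))
  cat(sprintf("pi = %.6f, theta_w = %.6f, k = %.4f, A_E = %.3f, Tajima D = %s\n",
              x$pi, x$theta_w, x$k, x$A_E,
              if (is.na(x$tajima_D)) "NA" else sprintf("%.4f", x$tajima_D)))
  invisible(x)
}
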
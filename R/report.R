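## The full pre/post-sweep comparison: per-locus heterogeneity with swept
## alleles, F_ST, diversity, LD matrices, multiple-testing correction.

#' Compare two time-point samples for signatures of a selective sweep
#'
#' Runs the whole detection pipeline on a shared locus panel: per-locus
#' G-test heterogeneity (Monte-Carlo p-values) with iterative
#' standardized-residual identification of swept alleles, F_ST with a
#' permutation test, effective allele numbers per sample, nucleotide
#' diversity when allele sequences are attached to the samples, pairwise
#' LD significance matrices within each sample, and Holm-corrected
#' decisions across loci.  Alleles present in the later sample but absent
#' from the earlier one are flagged as migration candidates.
#'
#' @param pre,post [hap_sample()] objects sharing a locus panel (e.g. the
#'   2001 pre-sweep and 2006 post-sweep samples).
#' @param panel Optional character vector restricting the loci analysed;
#'   default: all loci shared by both samples.
#' @param alpha Significance level for Holm-corrected decisions and for
#'   the swept-allele stopping rule.
#' @param seed Integer seed governing every Monte-Carlo draw.
#' @param B_het,B_fst,B_ld Resampling sizes for the heterogeneity,
#'   F_ST and LD tests.
#' @param ld Compute the pairwise LD matrices (default `TRUE`; the
#'   quadratic number of permutation tests dominates the runtime).
#' @return Object of class `"sweep_report"`: `loci` (per-locus data
#'   frame), `het` (per-locus `g_test`s), `swept` (per-locus swept-allele
#'   lists), `ld_pre`, `ld_post` (p-value matrices), `alpha`, sample ids.
#' @export
sweep_report <- function(pre, post, panel = NULL, alpha = 0.05, seed = 1L,
                         B_het = 1e4, B_fst = 1e4, B_ld = 2000, ld = TRUE) {
  stopifnot(inherits(pre, "hap_sample"), inherits(post, "hap_sample"))
  shared <- intersect(sample_loci(pre), sample_loci(post))
  if (is.null(panel)) panel <- shared
  if (length(intersect(panel, shared)) == 0L)
    stop_("the samples share no locus of the requested panel")
  if (!all(panel %in% shared))
    stop_("loci absent from both samples: %s",
          paste(setdiff(panel, shared), collapse = ", "))
  het <- list(); swept <- list()
  rows <- vector("list", length(panel))
  for (i in seq_along(panel)) {
    loc <- panel[i]
    alleles <- union(names(allele_counts(pre, loc)),
                     names(allele_counts(post, loc)))
    x <- allele_counts(pre, loc, alleles = alleles)
    y <- allele_counts(post, loc, alleles = alleles)
    g <- g_heterogeneity(x, y, method = "monte-carlo", B = B_het,
                         seed = child_seed(seed, i))
    het[[loc]] <- g
    f <- fst(x, y, B = B_fst, seed = child_seed(seed, 1000L + i))
    novel <- names(y)[x == 0 & y > 0]
    pi_pre <- pi_post <- NA_real_
    if (!is.null(pre$sequences[[loc]])) {
      sq <- pre$sequences[[loc]]
      use <- intersect(names(sq), names(x)[x > 0])
      if (length(use) > 0)
        pi_pre <- sequence_diversity(sq[use], x[use])$pi
    }
    if (!is.null(post$sequences[[loc]])) {
      sq <- post$sequences[[loc]]
      use <- intersect(names(sq), names(y)[y > 0])
      if (length(use) > 0)
        pi_post <- sequence_diversity(sq[use], y[use])$pi
    }
    rows[[i]] <- data.frame(
      locus = loc, n_pre = sum(x), n_post = sum(y),
      k_alleles = sum(x + y > 0),
      G = g$G, p_het = g$p,
      fst = f$fst, p_fst = f$p, gst = f$gst,
      A_E_pre = if (sum(x) > 0) effective_allele_number(x) else NA_real_,
      A_E_post = if (sum(y) > 0) effective_allele_number(y) else NA_real_,
      pi_pre = pi_pre, pi_post = pi_post,
      novel_alleles = paste(novel, collapse = ","))
  }
  loci <- do.call(rbind, rows)
  holm <- sequential_bonferroni(loci$p_het, alpha)
  loci$p_het_holm <- holm$p_adjusted
  loci$het_significant <- holm$reject
  ## swept-allele identification at the loci where heterogeneity stands
  ## after correction (needs >= 3 alleles: with 2, each allele contributes
  ## equally to heterogeneity and the procedure is undefined)
  loci$swept_alleles <- ""
  for (i in seq_along(panel)) {
    loc <- panel[i]
    if (!loci$het_significant[i] || loci$k_alleles[i] < 3L) next
    alleles <- union(names(allele_counts(pre, loc)),
                     names(allele_counts(post, loc)))
    sw <- tryCatch(
      identify_swept_alleles(allele_counts(pre, loc, alleles),
                             allele_counts(post, loc, alleles),
                             alpha = alpha, B = B_het,
                             seed = child_seed(seed, 2000L + i))$swept,
      error = function(e) character(0))
    swept[[loc]] <- sw
    loci$swept_alleles[i] <- paste(sw, collapse = ",")
  }
  out <- list(loci = loci, het = het, swept = swept,
              alpha = alpha,
              pre_id = pre$sample_id, post_id = post$sample_id)
  if (ld) {
    out$ld_pre <- ld_matrix(pre, panel, B = B_ld,
                            seed = child_seed(seed, 3000L))
    out$ld_post <- ld_matrix(post, panel, B = B_ld,
                             seed = child_seed(seed, 4000L))
  }
  structure(out, class = "sweep_report")
}

#' Pairwise LD significance matrix of a sample
#'
#' Applies [ld_significance()] to every locus pair of the panel.
#'
#' @inheritParams sweep_report
#' @param sample A [hap_sample()].
#' @param B Permutations per pair.
#' @param seed Integer seed.
#' @return Symmetric matrix of permutation p-values (`NA` on the diagonal
#'   and for pairs involving a monomorphic locus).
#' @export
ld_matrix <- function(sample, panel = NULL, B = 2000, seed = 1L) {
  stopifnot(inherits(sample, "hap_sample"))
  if (is.null(panel)) panel <- sample_loci(sample)
  k <- length(panel)
  M <- matrix(NA_real_, k, k, dimnames = list(panel, panel))
  idx <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    idx <- idx + 1L
    r <- ld_significance(sample, panel[i], panel[j], B = B,
                         seed = child_seed(seed, idx))
    M[i, j] <- M[j, i] <- r$p
  }
  M
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("Sweep report: '%s' vs '%s' (%d loci, alpha = %g)\n",
              x$pre_id, x$post_id, nrow(x$loci), x$alpha))
  sig <- x$loci$het_significant
  cat(sprintf("  heterogeneous loci after Holm correction: %d of %d\n",
              sum(sig), length(sig)))
  cols <- c("locus", "G", "p_het", "p_het_holm", "fst", "p_fst",
            "A_E_pre", "A_E_post", "swept_alleles")
  df <- x$loci[, cols]
  df[, c("G", "fst")] <- round(df[, c("G", "fst")], 3)
  df[, c("A_E_pre", "A_E_post")] <- round(df[, c("A_E_pre", "A_E_post")], 2)
  df$p_het <- signif(df$p_het, 3); df$p_het_holm <- signif(df$p_het_holm, 3)
  df$p_fst <- signif(df$p_fst, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.sweep_report <- function(object, ...) object$loci

#' Write a sweep report to disk
#'
#' Emits the per-locus table as TSV, the LD matrices as TSV with
#' significance strata (`<0.001`, `<0.01`, `<0.05`, `ns`), and the whole
#' report as JSON.
#'
#' @param report A `"sweep_report"`.
#' @param prefix Output path prefix; files `<prefix>_loci.tsv`,
#'   `<prefix>_ld_pre.tsv`, `<prefix>_ld_post.tsv`, `<prefix>.json`.
#' @return Invisibly, the paths written.
#' @export
write_sweep_report <- function(report, prefix) {
  stopifnot(inherits(report, "sweep_report"))
  paths <- character(0)
  p <- paste0(prefix, "_loci.tsv")
  write.table(report$loci, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  strat <- function(M) {
    S <- matrix("ns", nrow(M), ncol(M), dimnames = dimnames(M))
    S[!is.na(M) & M < 0.05] <- "<0.05"
    S[!is.na(M) & M < 0.01] <- "<0.01"
    S[!is.na(M) & M < 0.001] <- "<0.001"
    S[is.na(M)] <- "NA"
    S
  }
  for (side in c("ld_pre", "ld_post")) {
    if (is.null(report[[side]])) next
    p <- paste0(prefix, "_", side, ".tsv")
    write.table(strat(report[[side]]), p, sep = "\t", quote = FALSE,
                col.names = NA)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(pre = report$pre_id, post = report$post_id, alpha = report$alpha,
         loci = report$loci,
         ld_pre = report$ld_pre, ld_post = report$ld_post),
    p, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
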
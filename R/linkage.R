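## Informative-cross analysis.  Female Lepidoptera are achiasmatic, so a
## heterozygous mother transmits whole haplotypes (female-informative
## families detect co-segregation with male survival), while a heterozygous
## father recombines (male-informative families map loci and localize the
## suppressor by recombinant exclusion).

#' Informative cross family
#'
#' A backcross family in which one parent is heterozygous at every scored
#' marker (the informative parent, with known phase: allele `1` lies on
#' the suppressor-bearing haplotype, allele `2` on the other) and the
#' other parent is homozygous.  Offspring are scored for the informative
#' parent's transmitted allele at each marker.
#'
#' @param inherited Integer matrix `[offspring, markers]` with entries 1
#'   (suppressor-haplotype allele), 2 (other allele) or `NA` (missing).
#' @param sex Character vector, `"son"`/`"daughter"` per offspring.
#' @param type `"female-informative"` or `"male-informative"`.
#' @param markers Optional marker names (default from column names).
#' @return Object of class `"cross_family"`.
#' @export
cross_family <- function(inherited, sex,
                         type = c("female-informative", "male-informative"),
                         markers = colnames(inherited)) {
  type <- match.arg(type)
  inherited <- as.matrix(inherited)
  if (!all(inherited %in% c(1L, 2L, NA)))
    stop_("`inherited` entries must be 1, 2 or NA")
  if (length(sex) != nrow(inherited))
    stop_("`sex` must have one entry per offspring")
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("son", "daughter")))
    stop_("`sex` entries must be 'son' or 'daughter'")
  if (is.null(markers)) markers <- paste0("M", seq_len(ncol(inherited)))
  colnames(inherited) <- markers
  structure(list(inherited = inherited, sex = sex, type = type,
                 markers = markers),
            class = "cross_family")
}

#' @export
print.cross_family <- function(x, ...) {
  cat(sprintf("%s family: %d offspring (%d sons, %d daughters), %d markers\n",
              x$type, nrow(x$inherited), sum(x$sex == "son"),
              sum(x$sex == "daughter"), length(x$markers)))
  invisible(x)
}

#' Co-segregation of a marker with male survival
#'
#' In a female-informative family the mother transmits whole haplotypes,
#' so a marker linked to the suppressor is carried by *every* surviving
#' son.  If all `n` scored sons share the same maternal allele the
#' probability of that pattern under the null of no association is
#' `0.5^n`.  Daughters are checked for ~1:1 segregation (two-sided
#' binomial test) as a sanity report.
#'
#' @param family A [cross_family()] of type `"female-informative"`.
#' @param marker Marker name.
#' @return List: `p` (the all-same-allele probability; 1 when sons carry
#'   mixed alleles), `cosegregating`, `n_sons`, `shared_allele`,
#'   `daughter_p` (binomial segregation check, `NA` without daughters).
#' @examples
#' fam <- cross_family(matrix(1L, 16, 1, dimnames = list(NULL, "A")),
#'                     sex = rep("son", 16))
#' cosegregation_test(fam, "A")$p  # 0.5^16
#' @export
cosegregation_test <- function(family, marker) {
  stopifnot(inherits(family, "cross_family"))
  if (family$type != "female-informative")
    stop_("co-segregation testing requires a female-informative family")
  if (!marker %in% family$markers) stop_("unknown marker '%s'", marker)
  sons <- family$inherited[family$sex == "son", marker]
  sons <- sons[!is.na(sons)]
  if (length(sons) == 0L) stop_("no sons scored at marker '%s'", marker)
  same <- length(unique(sons)) == 1L
  p <- if (same) 0.5^length(sons) else 1
  dau <- family$inherited[family$sex == "daughter", marker]
  dau <- dau[!is.na(dau)]
  daughter_p <- if (length(dau) > 0)
    binom.test(sum(dau == 1L), length(dau), 0.5)$p.value else NA_real_
  list(p = p, cosegregating = same, n_sons = length(sons),
       shared_allele = if (same) sons[1L] else NA_integer_,
       daughter_p = daughter_p)
}

#' Localize the suppressor by recombinant exclusion
#'
#' In a male-informative family every surviving son must carry the genomic
#' region required for male survival, so markers where one or more sons
#' lack the informative parent's suppressor-haplotype allele are excluded.
#' The candidate region is the run of markers with zero recombinant sons,
#' bounded (exclusively) by the nearest flanking markers showing at least
#' one recombinant.
#'
#' @param family A [cross_family()] of type `"male-informative"`.
#' @param map Optional [linkage_map()] giving marker order and positions;
#'   defaults to the family's marker order with unknown positions.
#' @return List: `retained` (marker names with zero recombinants),
#'   `interval` (flanking markers, `NA` at an unflanked end),
#'   `recombinants` (named counts over sons), `n_sons`, and `interval_cM`
#'   when positions are known.
#' @export
localize_region <- function(family, map = NULL) {
  stopifnot(inherits(family, "cross_family"))
  if (family$type != "male-informative")
    stop_("recombinant exclusion requires a male-informative family")
  order_markers <- if (!is.null(map)) map$markers else family$markers
  if (!all(order_markers %in% family$markers))
    stop_("map and family marker sets differ")
  sons <- family$inherited[family$sex == "son", order_markers, drop = FALSE]
  rec <- apply(sons, 2, function(v) sum(v == 2L, na.rm = TRUE))
  retained <- names(rec)[rec == 0L]
  if (length(retained) == 0L)
    return(list(retained = character(0),
                interval = c(NA_character_, NA_character_),
                recombinants = rec, n_sons = nrow(sons)))
  idx <- which(rec == 0L)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  core <- runs[[which.max(lengths(runs))]]   # longest zero-recombinant run
  lo <- min(core); hi <- max(core)
  left <- if (lo > 1L) order_markers[lo - 1L] else NA_character_
  right <- if (hi < length(order_markers)) order_markers[hi + 1L] else
    NA_character_
  out <- list(retained = order_markers[core], interval = c(left, right),
              recombinants = rec, n_sons = nrow(sons))
  if (!is.null(map) && !is.na(left) && !is.na(right))
    out$interval_cM <- unname(map$positions[right] - map$positions[left])
  out
}

#' Recombination fraction between two markers of a cross
#'
#' Counts recombinant offspring (those inheriting discordant informative
#' parent alleles at the two markers) among offspring scored at both.
#' Only offspring of a male-informative family are informative for
#' recombination; by default daughters are used (sons are
#' survival-selected around the suppressor).
#'
#' @param family A [cross_family()] of type `"male-informative"`.
#' @param markerA,markerB Marker names.
#' @param use `"daughters"` (default), `"sons"`, or `"all"`.
#' @param conf_level Level of the exact binomial confidence interval.
#' @return List: `r`, `recombinants`, `n`, `ci`, and a `phase_warning`
#'   flag set when `r > 0.5` (unlinked or phase error).
#' @export
recombination_fraction <- function(family, markerA, markerB,
                                   use = c("daughters", "sons", "all"),
                                   conf_level = 0.95) {
  stopifnot(inherits(family, "cross_family"))
  if (family$type != "male-informative")
    stop_("recombination fractions require a male-informative family")
  use <- match.arg(use)
  keep <- switch(use, daughters = family$sex == "daughter",
                 sons = family$sex == "son",
                 all = rep(TRUE, length(family$sex)))
  a <- family$inherited[keep, markerA]
  b <- family$inherited[keep, markerB]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 2L) stop_("fewer than 2 offspring scored at both markers")
  rec <- sum(a[ok] != b[ok])
  bt <- binom.test(rec, n, conf.level = conf_level)
  list(r = rec / n, recombinants = rec, n = n,
       ci = unname(bt$conf.int), phase_warning = rec / n > 0.5)
}

#' Haldane map function
#'
#' Converts a recombination fraction to map distance assuming no crossover
#' interference: `d = -50 ln(1 - 2r)` centimorgans, with inverse
#' `r = (1 - exp(-d / 50)) / 2`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance in cM.
#' @examples
#' haldane_cm(0.1)        # 11.157 cM
#' haldane_r(haldane_cm(0.1))
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop_("`r` must lie in [0, 0.5): r = 0.5 maps to infinite distance")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @param d Map distance(s) in cM (>= 0).
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop_("map distances must be >= 0")
  (1 - exp(-d / 50)) / 2
}

#' Ordered linkage map
#'
#' Marker order is taken as given (ordering algorithms are external);
#' positions are cumulative Haldane distances.
#'
#' @param markers Marker names in map order.
#' @param positions Positions in cM (non-decreasing), or `NULL` to derive
#'   them from `rec_fractions`.
#' @param rec_fractions Adjacent-interval recombination fractions (length
#'   `length(markers) - 1`), used when `positions` is `NULL`.
#' @return Object of class `"linkage_map"` with `markers`, `positions`
#'   (named, cM) and `rec_fractions`.
#' @export
linkage_map <- function(markers, positions = NULL, rec_fractions = NULL) {
  if (is.null(positions)) {
    if (is.null(rec_fractions) ||
        length(rec_fractions) != length(markers) - 1L)
      stop_("supply `positions`, or one recombination fraction per interval")
    positions <- cumsum(c(0, haldane_cm(rec_fractions)))
  }
  if (length(positions) != length(markers))
    stop_("one position per marker required")
  if (is.unsorted(positions))
    stop_("positions must be non-decreasing along the map")
  if (is.null(rec_fractions))
    rec_fractions <- haldane_r(diff(positions))
  structure(list(markers = markers,
                 positions = setNames(as.numeric(positions), markers),
                 rec_fractions = as.numeric(rec_fractions)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("Linkage map,", length(x$markers), "markers spanning",
      sprintf("%.1f cM\n", diff(range(x$positions))))
  print(round(x$positions, 2))
  invisible(x)
}

#' Estimate adjacent-interval map distances from a cross
#'
#' Computes recombination fractions between consecutive markers of `map`
#' from a male-informative family and converts them to Haldane cM.
#'
#' @param family A male-informative [cross_family()].
#' @param map A [linkage_map()] fixing the marker order.
#' @param use Offspring subset passed to [recombination_fraction()].
#' @return A new `"linkage_map"` with estimated positions, plus an
#'   `estimates` data frame attribute (interval, r, n, recombinants).
#' @export
estimate_map <- function(family, map, use = "daughters") {
  mk <- map$markers
  est <- lapply(seq_len(length(mk) - 1L), function(i) {
    rf <- recombination_fraction(family, mk[i], mk[i + 1L], use = use)
    data.frame(from = mk[i], to = mk[i + 1L], r = rf$r, n = rf$n,
               recombinants = rf$recombinants)
  })
  est <- do.call(rbind, est)
  r <- pmin(est$r, 0.499)  # cap: r >= 0.5 has no finite Haldane distance
  out <- linkage_map(mk, positions = cumsum(c(0, haldane_cm(r))))
  attr(out, "estimates") <- est
  out
}

#' Suppressor-male survival estimate from a cross
#'
#' In a male-informative family half of the zygotes of each sex inherit
#' the suppressor; daughters all survive while infected sons survive only
#' with the suppressor.  The survival of suppressor-bearing males is thus
#' the ratio of surviving sons to the expected number of
#' suppressor-bearing male zygotes, estimated as half the daughter count
#' (1:1 primary sex ratio).
#'
#' @param n_sons Surviving sons.
#' @param n_daughters Daughters (used as `n_daughters / 2` expected
#'   suppressor-bearing sons), or `NULL` when `n_expected` is given.
#' @param n_expected Expected suppressor-bearing male zygotes, overriding
#'   the daughter-based estimate.
#' @param conf_level Level of the exact binomial confidence interval.
#' @return List: `survival`, `expected`, `ci`.
#' @examples
#' survival_estimate(60, n_expected = 150)$survival  # 0.40
#' @export
survival_estimate <- function(n_sons, n_daughters = NULL, n_expected = NULL,
                              conf_level = 0.95) {
  if (is.null(n_expected)) {
    if (is.null(n_daughters) || n_daughters <= 0)
      stop_("need a positive daughter count (or `n_expected`)")
    n_expected <- n_daughters / 2
  }
  if (n_expected <= 0) stop_("expected count must be positive")
  surv <- n_sons / n_expected
  bt <- binom.test(min(n_sons, round(n_expected)), round(n_expected),
                   conf.level = conf_level)
  list(survival = surv, expected = n_expected, ci = unname(bt$conf.int))
}
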
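## Seeded generator for every input the pipeline consumes: a marker panel
## emulating the field study's design (12 linked markers spanning ~41 cM
## plus 9 unlinked controls), pre/post-sweep population samples with the
## hitchhiking structure the analysis assumes, and informative-cross
## families.

#' Synthetic marker panel
#'
#' Builds a marker panel: `n_linked` multi-allelic markers on one linkage
#' group spanning `map_length` cM (positions evenly spread, with the
#' suppressor located at `suppressor_cm`), plus `n_unlinked` markers on
#' distinct linkage groups.  Pre-sweep allele frequencies are drawn from a
#' broken-stick distribution; a configurable subset of linked markers
#' carries an immigrant allele novel to the resident population, the rest
#' have the immigrant haplotype tagging an existing resident allele.  Each
#' allele also receives a SNP-bearing sequence template so that nucleotide
#' diversity can be computed downstream.
#'
#' @param n_linked,n_unlinked Marker counts (defaults 12 and 9).
#' @param map_length Linked-group map length in cM (default 41).
#' @param positions Marker positions (cM) on the linked group.  The
#'   default for the 12-marker, 41-cM design mirrors the mapped
#'   chromosome's geometry: three markers clustered within 1 cM of the
#'   suppressor and the rest spread to the ends; other designs space the
#'   markers evenly.
#' @param suppressor_cm Suppressor position on the linked group (default
#'   11.5 cM, inside the proximal third as in the mapped region).
#' @param n_novel Number of linked markers whose immigrant allele is novel
#'   (default 4).
#' @param novel_at Indices (along the linked markers) carrying the novel
#'   immigrant alleles.  The default for the 12-marker design places them
#'   at markers 1, 6, 7 and 9 (A, F, G, I) — the field configuration:
#'   three genomic locations spread over ~17 cM, one of them inside the
#'   co-segregating cluster.  Other designs draw `n_novel` positions at
#'   random.
#' @param allele_range Range of allele counts per marker (default 2:8).
#' @param seq_length Length of the per-allele sequence templates (nt).
#' @param n_snps SNP positions segregating per marker (default 8).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return Object of class `"marker_panel"`: data frame `markers` (name,
#'   group, position_cM, linked flag), list `alleles` (per marker: named
#'   pre-sweep frequency vector), `immigrant` (per linked marker: the
#'   allele carried on the sweeping haplotype), `novel` (logical per
#'   linked marker), `sequences` (per marker: allele -> sequence),
#'   `suppressor_cm`.
#' @export
make_panel <- function(n_linked = 12, n_unlinked = 9, map_length = 41,
                       positions = NULL, suppressor_cm = 11.5, n_novel = 4,
                       novel_at = NULL, allele_range = 2:8,
                       seq_length = 500, n_snps = 8, seed = 1L) {
  if (n_linked < 2L) stop_("need at least two linked markers")
  if (suppressor_cm < 0 || suppressor_cm > map_length)
    stop_("`suppressor_cm` must lie within [0, map_length]")
  if (n_novel > n_linked) stop_("`n_novel` cannot exceed `n_linked`")
  if (is.null(positions)) {
    positions <- if (n_linked == 12 && map_length == 41)
      c(0, 4, 8, 11, 11.5, 12, 17, 22, 27, 32, 36.5, 41)
    else seq(0, map_length, length.out = n_linked)
  }
  if (length(positions) != n_linked || is.unsorted(positions) ||
      any(positions < 0 | positions > map_length))
    stop_("`positions` must be %d non-decreasing values in [0, map_length]",
          n_linked)
  with_seed(seed, {
    linked_names <- LETTERS[seq_len(n_linked)]
    unlinked_names <- LETTERS[n_linked + seq_len(n_unlinked)]
    pos <- positions
    markers <- data.frame(
      marker = c(linked_names, unlinked_names),
      group = c(rep("SLG", n_linked),
                paste0("LG", 1 + seq_len(n_unlinked) %% max(1, n_unlinked - 1))),
      position_cM = c(pos, rep(NA_real_, n_unlinked)),
      linked = rep(c(TRUE, FALSE), c(n_linked, n_unlinked)))
    alleles <- list(); sequences <- list()
    for (m in markers$marker) {
      k <- sample(allele_range, 1L)
      ## broken stick: ordered uniform spacings give exchangeable segment
      ## lengths summing to 1
      w <- sort(diff(c(0, sort(runif(k - 1L)), 1)), decreasing = TRUE)
      names(w) <- paste0(m, seq_len(k))
      alleles[[m]] <- w
      sequences[[m]] <- allele_sequences(k, seq_length, n_snps,
                                         prefix = m)
    }
    ## immigrant haplotype: for n_novel linked markers append a novel
    ## allele (resident frequency 0); otherwise tag a resident allele
    if (is.null(novel_at)) {
      novel_at <- if (n_linked == 12 && n_novel == 4) c(1L, 6L, 7L, 9L)
      else sort(sample(seq_len(n_linked), n_novel))
    }
    if (length(novel_at) != n_novel || any(novel_at > n_linked))
      stop_("`novel_at` must give %d indices within the linked markers",
            n_novel)
    novel_at <- sort(as.integer(novel_at))
    immigrant <- character(n_linked); novel <- logical(n_linked)
    names(immigrant) <- names(novel) <- linked_names
    for (i in seq_len(n_linked)) {
      m <- linked_names[i]
      if (i %in% novel_at) {
        lab <- paste0(m, length(alleles[[m]]) + 1L)
        alleles[[m]] <- c(alleles[[m]], setNames(0, lab))
        sequences[[m]] <- c(sequences[[m]],
                            setNames(mutate_sequence(sequences[[m]][1L]),
                                     lab))
        immigrant[i] <- lab; novel[i] <- TRUE
      } else {
        immigrant[i] <- sample(names(alleles[[m]]), 1L,
                               prob = alleles[[m]])
      }
    }
    structure(list(markers = markers, alleles = alleles,
                   immigrant = immigrant, novel = novel,
                   sequences = sequences, suppressor_cm = suppressor_cm,
                   map_length = map_length, seed = seed),
              class = "marker_panel")
  })
}

## k aligned allele sequences differing at n_snps sites
allele_sequences <- function(k, len, n_snps, prefix = "") {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  snp_pos <- sample(len, min(n_snps, len))
  out <- character(k)
  for (i in seq_len(k)) {
    s <- base
    for (p in snp_pos) {
      alt <- setdiff(c("A", "C", "G", "T"), base[p])
      ## each allele takes the base or one fixed alternative at each SNP
      s[p] <- if (rbinom(1L, 1L, 0.5) == 1L) alt[1L] else base[p]
    }
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- paste0(prefix, seq_len(k))
  ## ensure all alleles distinct: flip a private site per duplicate
  while (anyDuplicated(out)) {
    d <- which(duplicated(out))[1L]
    p <- sample(snp_pos, 1L)
    ch <- strsplit(out[d], "")[[1L]]
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    out[d] <- paste(ch, collapse = "")
  }
  out
}

mutate_sequence <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  p <- sample(length(ch), 1L)
  ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf(
    "Marker panel: %d linked (%.0f cM, suppressor at %.1f cM) + %d unlinked\n",
    sum(x$markers$linked), x$map_length, x$suppressor_cm,
    sum(!x$markers$linked)))
  cat("  novel immigrant alleles at:",
      paste(names(x$novel)[x$novel], collapse = ", "), "\n")
  invisible(x)
}

#' Simulate pre/post-sweep population samples
#'
#' Evolves every linked marker of a panel against the suppressor with the
#' deterministic two-locus model (at the recombination fraction implied by
#' its map distance via the inverse Haldane function), then draws `n`
#' diploid individuals per requested generation.  Within an individual the
#' two chromosomes are drawn from the model's suppressor diplotype
#' distribution; each chromosome's marker alleles are then generated as a
#' Markov chain outward from the suppressor, with the transition between
#' consecutive markers taken from a three-locus model run (suppressor plus
#' the marker pair), so that local linkage disequilibrium between linked
#' markers rises and decays exactly as the recursion dictates.  Markers on
#' opposite sides of the suppressor are associated through the suppressor
#' only.  Unlinked markers stay at their pre-sweep frequencies throughout.
#' The generation-0 sample is drawn at linkage equilibrium.
#'
#' @param panel A [make_panel()] object.
#' @param model_params A [sweep_params()] object; its `rec_fractions` and
#'   `resident_freqs` entries are replaced per marker.
#' @param sample_times Generations at which samples are drawn.  The
#'   default `c(0, 25)` emulates the field design: a pre-sweep sample and
#'   one taken shortly after the ~10-15-generation sweep has run to
#'   completion (the butterfly completes ~10 generations per year, so a
#'   couple of years separate onset and the post-sweep collection).
#' @param n Diploid individuals per sample (default 48).
#' @param seed Integer seed.
#' @return List with `samples` (list of [hap_sample()], named
#'   `t<generation>`, each carrying per-locus allele sequences) and
#'   `truth` (class `"simulation_truth"`: every generating parameter
#'   needed to reproduce the draw, including the per-marker model
#'   trajectories' final immigrant-allele frequencies).
#' @export
simulate_sweep_samples <- function(panel, model_params = sweep_params(),
                                   sample_times = c(0, 25), n = 48,
                                   seed = 1L) {
  stopifnot(inherits(panel, "marker_panel"),
            inherits(model_params, "sweep_params"))
  if (any(sample_times < 0)) stop_("sample times must be >= 0")
  T <- max(sample_times)
  linked <- panel$markers$marker[panel$markers$linked]
  pos <- setNames(panel$markers$position_cM[panel$markers$linked], linked)
  dist_cm <- abs(pos - panel$suppressor_cm)
  r_marker <- setNames(haldane_r(dist_cm), linked)
  res_freq <- vapply(linked, function(m)
    unname(panel$alleles[[m]][panel$immigrant[[m]]]), numeric(1))
  ## per-marker two-locus runs (marginals and truth record)
  runs <- list()
  for (m in linked) {
    p <- model_params
    p$rec_fractions <- min(r_marker[[m]], 0.5)
    p$n_loci <- 2L
    p$resident_freqs <- res_freq[[m]]
    runs[[m]] <- sweep_sim(p, max(T, 1L), keep_states = TRUE)
  }
  ## chains outward from the suppressor, one per side; consecutive markers
  ## get a three-locus run (S, nearer marker, farther marker)
  left <- linked[pos < panel$suppressor_cm]
  left <- left[order(pos[left], decreasing = TRUE)]
  right <- linked[pos >= panel$suppressor_cm]
  right <- right[order(pos[right])]
  chains <- Filter(function(ch) length(ch) > 0, list(left, right))
  triples <- list()
  for (ch in chains) {
    if (length(ch) < 2L) next
    for (j in seq_len(length(ch) - 1L)) {
      a <- ch[j]; b <- ch[j + 1L]
      p <- model_params
      p$rec_fractions <- c(min(r_marker[[a]], 0.5),
                           min(haldane_r(abs(pos[b] - pos[a])), 0.5))
      p$n_loci <- 3L
      p$resident_freqs <- c(res_freq[[a]], res_freq[[b]])
      triples[[paste(a, b, sep = ":")]] <-
        sweep_sim(p, max(T, 1L), keep_states = TRUE)
    }
  }
  samples <- list()
  truth_freq <- list()
  for (ti in seq_along(sample_times)) {
    t <- sample_times[ti]
    samples[[paste0("t", t)]] <-
      draw_multilocus_sample(panel, runs, triples, chains, t, n,
                             seed = child_seed(seed, 7L * ti))
    truth_freq[[paste0("t", t)]] <- as.list(vapply(linked, function(m)
      allele_freq(runs[[m]], "A")[[as.character(t)]], numeric(1)))
  }
  truth <- structure(list(
    panel_seed = panel$seed, seed = seed, n = n,
    sample_times = sample_times,
    model_params = unclass(model_params),
    suppressor_cm = panel$suppressor_cm,
    r_marker = r_marker,
    immigrant_allele = panel$immigrant,
    novel = panel$novel,
    immigrant_allele_freq = truth_freq), class = "simulation_truth")
  list(samples = samples, truth = truth)
}

## chromosome pool of a model state (sexes at equal weight)
chromosome_pool <- function(state) {
  M <- state$female[, , 1L] + state$female[, , 2L] +
    state$male[, , 1L] + state$male[, , 2L]
  (rowSums(M) + colSums(M)) / 4
}

## draw one multi-marker diploid sample at generation t; marker states per
## chromosome form a Markov chain outward from the suppressor, with
## transitions taken from the three-locus runs
draw_multilocus_sample <- function(panel, runs, triples, chains, t, n,
                                   seed) {
  linked <- names(runs)
  unlinked <- panel$markers$marker[!panel$markers$linked]
  loci <- c(linked, unlinked)
  geno <- array(NA_character_, c(n, length(loci), 2L),
                dimnames = list(sprintf("ind%03d", seq_len(n)), loci,
                                c("allele1", "allele2")))
  clamp <- function(p) pmin(pmax(p, 0), 1)
  if (t == 0) {
    ## the pre-sweep sample is the resident population before the
    ## immigrant's arrival: every marker at its pre-sweep frequencies, in
    ## linkage equilibrium
    with_seed(seed, {
      for (m in loci) {
        freqs <- panel$alleles[[m]]
        for (k in 1:2)
          geno[, m, k] <- sample(names(freqs), n, replace = TRUE,
                                 prob = freqs)
      }
    })
    return(hap_sample(geno, sample_id = "t0",
                      sequences = panel$sequences))
  }
  with_seed(seed, {
    ## suppressor diplotypes from the sex-pooled adult distribution of the
    ## first linked marker's run (the S marginal is identical across runs)
    st <- runs[[1L]]$states[[t + 1L]]
    pool <- (st$female[, , 1L] + st$female[, , 2L] +
               st$male[, , 1L] + st$male[, , 2L]) / 2
    hapS <- st$haps[, "S"]
    pS <- matrix(0, 2, 2)  # P(S allele on chrom1, chrom2)
    for (h1 in seq_along(hapS)) for (h2 in seq_along(hapS))
      pS[hapS[h1] + 1L, hapS[h2] + 1L] <-
        pS[hapS[h1] + 1L, hapS[h2] + 1L] + pool[h1, h2]
    dip <- rmultinom(1L, n, as.vector(pS))[, 1L]
    Schrom <- matrix(0L, n, 2L)
    idx <- rep(seq_len(4L), dip)
    Schrom[, 1L] <- (idx - 1L) %% 2L
    Schrom[, 2L] <- (idx - 1L) %/% 2L
    Schrom <- Schrom[sample.int(n), , drop = FALSE]
    ## immigrant-allele state (0/1) per chromosome and linked marker
    state01 <- array(0L, c(n, 2L, length(linked)),
                     dimnames = list(NULL, NULL, linked))
    for (ch in chains) {
      ## head of the chain: P(A | S) from its two-locus run
      head <- ch[1L]
      stm <- runs[[head]]$states[[t + 1L]]
      chrom <- chromosome_pool(stm) * 2
      hp <- stm$haps
      pA_S <- vapply(0:1, function(s) {
        tot <- sum(chrom[hp[, "S"] == s])
        if (tot <= 0) return(0)
        sum(chrom[hp[, "S"] == s & hp[, "A"] == 1L]) / tot
      }, numeric(1))
      for (k in 1:2)
        state01[, k, head] <-
          rbinom(n, 1L, clamp(pA_S[Schrom[, k] + 1L]))
      if (length(ch) < 2L) next
      for (j in seq_len(length(ch) - 1L)) {
        a <- ch[j]; b <- ch[j + 1L]
        st3 <- triples[[paste(a, b, sep = ":")]]$states[[t + 1L]]
        chrom3 <- chromosome_pool(st3) * 2
        hp3 <- st3$haps
        ## P(B = 1 | S = s, A = x), falling back on P(B = 1 | S = s)
        cond <- array(0, c(2, 2))
        for (s in 0:1) {
          tot_s <- sum(chrom3[hp3[, "S"] == s])
          pB_s <- if (tot_s > 0)
            sum(chrom3[hp3[, "S"] == s & hp3[, "B"] == 1L]) / tot_s else 0
          for (x in 0:1) {
            sel <- hp3[, "S"] == s & hp3[, "A"] == x
            tot <- sum(chrom3[sel])
            cond[s + 1L, x + 1L] <- if (tot > 1e-14)
              sum(chrom3[sel & hp3[, "B"] == 1L]) / tot else pB_s
          }
        }
        for (k in 1:2)
          state01[, k, b] <- rbinom(n, 1L, clamp(
            cond[cbind(Schrom[, k] + 1L, state01[, k, a] + 1L)]))
      }
    }
    ## immigrant-state chromosomes get the immigrant-tagged allele label;
    ## the rest draw resident alleles (renormalized without the tag)
    for (m in linked) {
      freqs <- panel$alleles[[m]]
      imm <- panel$immigrant[[m]]
      other <- setdiff(names(freqs), imm)
      p_other <- freqs[other]
      p_other <- if (sum(p_other) > 0) p_other / sum(p_other) else
        setNames(rep(1 / length(other), length(other)), other)
      for (k in 1:2) {
        is_imm <- state01[, k, m] == 1L
        lab <- character(n)
        lab[is_imm] <- imm
        if (any(!is_imm))
          lab[!is_imm] <- sample(other, sum(!is_imm), replace = TRUE,
                                 prob = p_other)
        geno[, m, k] <- lab
      }
    }
    for (m in unlinked) {
      freqs <- panel$alleles[[m]]
      for (k in 1:2)
        geno[, m, k] <- sample(names(freqs), n, replace = TRUE,
                               prob = freqs)
    }
  })
  hap_sample(geno, sample_id = sprintf("t%d", t),
             sequences = panel$sequences)
}

#' Simulate an informative cross family
#'
#' Generates the offspring of a backcross between a suppressor
#' heterozygote (`Ss`, Wolbachia-infected) and a non-suppressor homozygote
#' (`ss`), with the heterozygous (informative) parent's phase known:
#' allele 1 at every marker lies on the suppressor haplotype.  In a
#' female-informative family the mother is heterozygous and transmits
#' whole haplotypes (achiasmatic meiosis); in a male-informative family
#' the father is heterozygous and recombines, with crossovers independent
#' across intervals (no interference).  All offspring inherit the
#' mother's infection, so sons survive only when carrying the suppressor,
#' with probability `survival`; daughters always survive.
#'
#' @param type `"female-informative"` or `"male-informative"`.
#' @param n_offspring Number of zygotes to generate (surviving offspring
#'   are returned, so expect roughly `n_offspring/2 (1 + survival/2)`
#'   survivors).
#' @param map A [linkage_map()] for the scored markers.
#' @param survival Survival of suppressor-bearing infected males (default
#'   0.4, the empirical estimate from the mapping cross).
#' @param seed Integer seed.
#' @return A [cross_family()] of the surviving, sexed, genotyped
#'   offspring.
#' @export
simulate_cross_family <- function(type = c("female-informative",
                                           "male-informative"),
                                  n_offspring, map, survival = 0.4,
                                  seed = 1L) {
  type <- match.arg(type)
  stopifnot(inherits(map, "linkage_map"))
  k <- length(map$markers)
  ## the suppressor locus enters the crossover chain as a pseudo-marker
  ## at its own map position (default: the first marker's position), so
  ## strand switches across it carry their proper Haldane probability
  s_cm <- attr(map, "suppressor_cm")
  if (is.null(s_cm)) s_cm <- unname(map$positions[1L])
  aug_pos <- c(map$positions, suppressor = s_cm)
  ord <- order(aug_pos)
  aug_pos <- aug_pos[ord]
  idx_s <- which(names(aug_pos) == "suppressor")
  rf_aug <- haldane_r(diff(aug_pos))
  marker_at <- match(map$markers, names(aug_pos))
  with_seed(seed, {
    sexes <- ifelse(rbinom(n_offspring, 1L, 0.5) == 1L, "son", "daughter")
    inherited <- matrix(NA_integer_, n_offspring, k,
                        dimnames = list(NULL, map$markers))
    has_S <- logical(n_offspring)
    ka <- length(aug_pos)
    for (o in seq_len(n_offspring)) {
      if (type == "female-informative") {
        gam <- rep(rbinom(1L, 1L, 0.5), ka)  # whole maternal haplotype
      } else {
        gam <- integer(ka)
        gam[1L] <- rbinom(1L, 1L, 0.5)
        if (ka > 1L) for (j in 2:ka)
          gam[j] <- if (rbinom(1L, 1L, rf_aug[j - 1L]) == 1L)
            1L - gam[j - 1L] else gam[j - 1L]
      }
      ## strand 0 carries the suppressor haplotype (marker allele 1)
      inherited[o, ] <- ifelse(gam[marker_at] == 0L, 1L, 2L)
      has_S[o] <- gam[idx_s] == 0L
    }
    survive <- ifelse(sexes == "daughter", TRUE,
                      has_S & runif(n_offspring) < survival)
    cross_family(inherited[survive, , drop = FALSE], sexes[survive],
                 type = type)
  })
}
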
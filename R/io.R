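## Readers and writers for the plain-text interchange formats: phased
## haplotype TSV, IUPAC diploid genotype tables, FASTA allele sequences,
## segregation tables for mapping crosses, and simulation-truth JSON.

#' Read/write phased haplotype samples as TSV
#'
#' Long format with columns `individual`, `locus`, `allele1`, `allele2`;
#' missing allele slots are written as `NA`.
#'
#' @param sample A [hap_sample()].
#' @param path Output file.
#' @return `write_hap_tsv` invisibly returns `path`; `read_hap_tsv`
#'   returns a [hap_sample()].
#' @export
write_hap_tsv <- function(sample, path) {
  stopifnot(inherits(sample, "hap_sample"))
  g <- sample$geno
  long <- expand.grid(individual = dimnames(g)[[1L]],
                      locus = dimnames(g)[[2L]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$allele1 <- g[cbind(match(long$individual, dimnames(g)[[1L]]),
                          match(long$locus, dimnames(g)[[2L]]), 1L)]
  long$allele2 <- g[cbind(match(long$individual, dimnames(g)[[1L]]),
                          match(long$locus, dimnames(g)[[2L]]), 2L)]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hap_tsv
#' @param sample_id Sample label for the object read back.
#' @export
read_hap_tsv <- function(path, sample_id = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = "NA")
  hap_sample(df, sample_id = sample_id)
}

## IUPAC ambiguity codes for unordered nucleotide pairs
iupac_code <- local({
  codes <- c(AA = "A", CC = "C", GG = "G", TT = "T",
             AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
  full <- codes
  for (nm in names(codes)) {
    rev <- paste0(substr(nm, 2, 2), substr(nm, 1, 1))
    full[rev] <- codes[[nm]]
  }
  full
})

iupac_decode <- local({
  m <- list(A = c("A", "A"), C = c("C", "C"), G = c("G", "G"),
            T = c("T", "T"), R = c("A", "G"), Y = c("C", "T"),
            S = c("C", "G"), W = c("A", "T"), K = c("G", "T"),
            M = c("A", "C"))
  m
})

## IUPAC genotype string of a diploid at one locus from its two allele
## sequences
iupac_genotype <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1L]]
  b <- strsplit(toupper(seq2), "")[[1L]]
  if (length(a) != length(b)) stop_("allele sequences differ in length")
  paste(iupac_code[paste0(a, b)], collapse = "")
}

#' Write/read diploid genotypes as an IUPAC-coded table
#'
#' One row per individual, one column per locus; each cell is the
#' individual's diploid genotype collapsed to a single IUPAC-coded
#' sequence (heterozygous positions become ambiguity codes, e.g. A/G =
#' `R`).  Missing genotypes are written as the empty string.  Reading
#' back requires the panel's allele-sequence catalog and recovers the
#' allele pair only where it is unambiguous (a naive counting-based
#' phaser); ambiguous cells are returned as missing with a warning.
#'
#' @param sample A [hap_sample()] whose samples carry `sequences`.
#' @param path Output file.
#' @return `write_iupac_genotypes` invisibly returns `path`.
#' @export
write_iupac_genotypes <- function(sample, path) {
  stopifnot(inherits(sample, "hap_sample"))
  if (is.null(sample$sequences))
    stop_("sample carries no allele-sequence catalog")
  g <- sample$geno
  loci <- dimnames(g)[[2L]]
  out <- matrix("", nrow(g), length(loci),
                dimnames = list(dimnames(g)[[1L]], loci))
  for (l in loci) {
    sq <- sample$sequences[[l]]
    for (i in seq_len(nrow(g))) {
      a1 <- g[i, l, 1L]; a2 <- g[i, l, 2L]
      if (is.na(a1) || is.na(a2)) next
      out[i, l] <- iupac_genotype(sq[[a1]], sq[[a2]])
    }
  }
  df <- data.frame(individual = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_iupac_genotypes
#' @param sequences Per-locus allele-sequence catalog (as in
#'   [make_panel()]'s `sequences`).
#' @param sample_id Label for the sample read back.
#' @export
read_iupac_genotypes <- function(path, sequences,
                                 sample_id = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  loci <- setdiff(names(df), "individual")
  geno <- array(NA_character_, c(nrow(df), length(loci), 2L),
                dimnames = list(df$individual, loci,
                                c("allele1", "allele2")))
  n_ambiguous <- 0L
  for (l in loci) {
    sq <- toupper(sequences[[l]])
    labs <- names(sequences[[l]])
    ## genotype string for every unordered allele pair
    pairs <- expand.grid(i = seq_along(labs), j = seq_along(labs))
    pairs <- pairs[pairs$i <= pairs$j, ]
    keys <- vapply(seq_len(nrow(pairs)), function(r)
      iupac_genotype(sq[pairs$i[r]], sq[pairs$j[r]]), character(1))
    for (row in seq_len(nrow(df))) {
      cell <- toupper(df[row, l])
      if (is.na(cell) || !nzchar(cell)) next
      hit <- which(keys == cell)
      if (length(hit) == 1L) {
        geno[row, l, 1L] <- labs[pairs$i[hit]]
        geno[row, l, 2L] <- labs[pairs$j[hit]]
      } else {
        n_ambiguous <- n_ambiguous + 1L
      }
    }
  }
  if (n_ambiguous > 0L)
    warn_("%d genotype cells were ambiguous or unmatched and left missing",
          n_ambiguous)
  hap_sample(geno, sample_id = sample_id, sequences = sequences)
}

#' Write/read allele sequences as FASTA
#'
#' Sequence names are `<locus>|<allele>`.
#'
#' @param sequences Per-locus allele-sequence catalog.
#' @param path Output file.
#' @export
write_allele_fasta <- function(sequences, path) {
  seqs <- unlist(lapply(names(sequences), function(l) {
    s <- sequences[[l]]
    setNames(s, paste0(l, "|", names(s)))
  }))
  bin <- ape::as.DNAbin(lapply(seqs, function(s)
    strsplit(tolower(s), "")[[1L]]))
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' @rdname write_allele_fasta
#' @export
read_allele_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(bin), paste, character(1),
                         collapse = ""))
  loci <- sub("\\|.*$", "", names(seqs))
  alleles <- sub("^.*\\|", "", names(seqs))
  out <- split(setNames(seqs, alleles), loci)
  out[unique(loci)]
}

#' Write/read a cross-family segregation table
#'
#' Simple TSV with columns `offspring`, `sex`, then one column per marker
#' coded `a` (informative parent's suppressor-haplotype allele), `b` (the
#' other allele) or `-` (missing) — one offspring row per meiosis.
#'
#' @param family A [cross_family()].
#' @param path Output file.
#' @export
write_segregation_tsv <- function(family, path) {
  stopifnot(inherits(family, "cross_family"))
  code <- matrix(c("a", "b")[family$inherited], nrow(family$inherited),
                 dimnames = dimnames(family$inherited))
  code[is.na(code)] <- "-"
  df <- data.frame(offspring = sprintf("off%04d",
                                       seq_len(nrow(code))),
                   sex = family$sex, code, check.names = FALSE)
  header <- sprintf("# type=%s", family$type)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_segregation_tsv
#' @export
read_segregation_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  type <- if (grepl("^# type=", first)) sub("^# type=", "", first) else
    "male-informative"
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  markers <- setdiff(names(df), c("offspring", "sex"))
  inherited <- as.matrix(df[, markers, drop = FALSE])
  m <- matrix(NA_integer_, nrow(inherited), ncol(inherited),
              dimnames = list(NULL, markers))
  m[inherited == "a"] <- 1L
  m[inherited == "b"] <- 2L
  cross_family(m, df$sex, type = type, markers = markers)
}

#' Write/read the simulation truth record
#'
#' @param truth A `"simulation_truth"` object from
#'   [simulate_sweep_samples()].
#' @param path Output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "simulation_truth")
}
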
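# shared fixtures, memoised so expensive objects are built once per run

sl_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_reference(seed = 7)
    cache
  }
})

sl_maps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_ortholog_maps(sl_ref())
    cache
  }
})

sl_cohort7 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(sim_config(seed = 7), sl_ref())
    cache
  }
})

sl_result7 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_pipeline(sl_cohort7(), ortholog_maps = sl_maps())
    cache
  }
})

# a tiny handmade two-exon gene on each strand for exact annotation checks.
# CDS (coding orientation): ATG CAT GCC TTA GAC AAA = M H A L D K
toy_transcripts <- function() {
  cds <- "ATGCATGCCTTAGACAAA"
  # plus gene: exon1 = first 10 bases at 101..110, intron 111..160,
  # exon2 = last 8 bases at 161..168
  plus_chrom <- paste0(strrep("T", 100), substr(cds, 1, 10),
                       strrep("A", 50), substr(cds, 11, 18), strrep("T", 100))
  # minus gene with the same coding sequence: genomic = revcomp
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  minus_chrom <- paste0(strrep("T", 100), substr(rc, 1, 8),
                        strrep("A", 50), substr(rc, 9, 18), strrep("T", 100))
  genome <- Biostrings::DNAStringSet(c(chrP = plus_chrom, chrM = minus_chrom))
  prot <- "MHALDK"
  tab <- data.frame(
    gene = c("PLUSG", "MINUSG"),
    chrom = c("chrP", "chrM"),
    strand = c("+", "-"),
    exons = c("101-110;161-168", "101-108;159-168"),
    stringsAsFactors = FALSE)
  transcript_set(tab, genome, c(PLUSG = prot, MINUSG = prot))
}

# exhaustive local-alignment oracle: enumerates every monotone set of
# matched residue pairs (no dynamic programming); gaps between
# consecutive matched pairs are charged affinely per run. Feasible for
# sequences up to ~6 residues.
brute_force_local <- function(a, b, mat, gap_open, gap_extend) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B)
  best <- 0
  rec <- function(i, j, score) {
    best <<- max(best, score)
    if (i < m && j < n) {
      for (ii in (i + 1):m) for (jj in (j + 1):n) {
        gi <- ii - i - 1L; gj <- jj - j - 1L
        pen <- (gi > 0) * (gap_open + gi * gap_extend) +
          (gj > 0) * (gap_open + gj * gap_extend)
        rec(ii, jj, score + mat[A[ii], B[jj]] - pen)
      }
    }
  }
  for (i in seq_len(m)) for (j in seq_len(n)) rec(i, j, mat[A[i], B[j]])
  best
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}

blosum62_fixture <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# random variant tables for filter-property tests
random_variants <- function(n, seed) {
  set.seed(seed)
  data.frame(
    case = sample(sprintf("case%02d", 1:5), n, replace = TRUE),
    chrom = sample(c("chr01", "chr02"), n, replace = TRUE),
    pos = sample.int(5000, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    region_class = sample(c("coding", "intronic", "intergenic", "UTR"), n,
                          replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
    consequence = sample(c("missense", "synonymous", "nonsense", "none",
                           "essential_splice"), n, replace = TRUE),
    db_maf = ifelse(runif(n) < 0.3, runif(n, 0, 0.5), NA_real_),
    tumor_depth = sample(1:120, n, replace = TRUE),
    tumor_alt = integer(n),
    stringsAsFactors = FALSE)
}
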
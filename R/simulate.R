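#' Default planted driver spectrum
#'
#' Hotspot drivers planted by the cohort simulator, with per-case
#' carrier fractions mirroring a 20-case hemangiosarcoma-like cohort:
#' a PIK3CA codon-1047 hotspot in ~45% of cases, a TP53
#' DNA-binding-domain hotspot in ~35%, and rare PTEN and PLCG1 events.
#'
#' @return data.frame with columns `gene`, `change`, `fraction`
#' @export
default_driver_spectrum <- function() {
  data.frame(
    gene = c("PIK3CA", "TP53", "PTEN", "PLCG1"),
    change = c("H1047R", "R248W", "I79T", "S273F"),
    fraction = c(0.45, 0.35, 0.10, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the tumor/normal cohort simulator. Per-case event
#' counts are Poisson with the given rates; sequencing depth is
#' negative binomial around the configured means with tumor coverage
#' designed at twice the normal coverage, and overdispersion fixed at
#' `depth_dispersion` (variance = mu + dispersion * mu^2), reflecting
#' the uneven coverage of FFPE exomes.
#'
#' @param n_cases number of tumor/normal pairs (>= 1)
#' @param driver_spectrum data.frame (gene, change, fraction) of hotspot
#'   drivers and their per-case carrier probabilities
#' @param passenger_rate mean nonsynonymous passenger mutations per case
#' @param indel_fraction fraction of passengers planted as 1 bp
#'   frameshift deletions rather than SNVs
#' @param synonymous_rate mean synonymous coding mutations per case
#' @param germline_snp_rate mean shared tumor+normal polymorphisms per case
#' @param artifact_rate mean low-VAF deamination artifacts per case
#' @param mean_depth_normal mean normal read depth (tumor mean is 2x this)
#' @param depth_dispersion negative binomial overdispersion of depth
#' @param target_region_size captured territory in bases, used for
#'   mutation burden per megabase
#' @param seed integer seed; identical config and seed give identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_cases = 20, driver_spectrum = default_driver_spectrum(),
                       passenger_rate = 8, indel_fraction = 0.10,
                       synonymous_rate = 3,
                       germline_snp_rate = 12, artifact_rate = 15,
                       mean_depth_normal = 37, depth_dispersion = 0.3,
                       target_region_size = 15e6, seed = 1) {
  stopifnot_scalar_prob(indel_fraction, "indel_fraction")
  if (n_cases < 1) stop("n_cases must be >= 1")
  rates <- c(passenger_rate, synonymous_rate, germline_snp_rate, artifact_rate)
  if (any(rates < 0)) stop("event rates must be >= 0")
  if (mean_depth_normal <= 0) stop("mean_depth_normal must be > 0")
  if (depth_dispersion <= 0) stop("depth_dispersion must be > 0")
  if (target_region_size <= 0) stop("target region must have positive size")
  if (nrow(driver_spectrum) > 0) {
    stopifnot(all(c("gene", "change", "fraction") %in% names(driver_spectrum)))
    if (any(driver_spectrum$fraction < 0 | driver_spectrum$fraction > 1))
      stop("driver case fractions must be in [0, 1]")
  }
  structure(list(n_cases = as.integer(n_cases), driver_spectrum = driver_spectrum,
                 passenger_rate = passenger_rate, indel_fraction = indel_fraction,
                 synonymous_rate = synonymous_rate,
                 germline_snp_rate = germline_snp_rate, artifact_rate = artifact_rate,
                 mean_depth_normal = mean_depth_normal,
                 depth_dispersion = depth_dispersion,
                 target_region_size = target_region_size,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# gene models emulated by the reference simulator. Hotspot codons are
# pinned so that a single-base substitution yields the classic residue
# change (e.g. CAT -> CGT is His -> Arg at PIK3CA 1047); human
# counterparts diverge by point substitutions plus, for PTEN / PLCG1 /
# DSCAM, the N-terminal extensions or internal insertion that make the
# human residue numbering run ahead of the canine one (PTEN +22,
# PLCG1 +72 upstream of the kinase-domain hotspot, DSCAM +236).
driver_gene_specs <- function() {
  list(
    PIK3CA = list(length = 1068, strand = "+", n_exons = 5, divergence = 0.002,
                  human_ext = 0, human_ins = NULL,
                  codons = c("350" = "GAT", "1047" = "CAT")),
    TP53 = list(length = 393, strand = "-", n_exons = 4, divergence = 0.10,
                human_ext = 0, human_ins = NULL,
                codons = c("111" = "TTA", "126" = "TAT", "179" = "CAT",
                           "241" = "TCT", "248" = "CGG", "274" = "GTT")),
    PTEN = list(length = 381, strand = "+", n_exons = 6, divergence = 0.01,
                human_ext = 22, human_ins = NULL,
                codons = c("56" = "ACT", "79" = "ATT")),
    PLCG1 = list(length = 1215, strand = "-", n_exons = 8, divergence = 0.02,
                 human_ext = 0, human_ins = list(after = 150, len = 72),
                 codons = c("273" = "TCT")),
    DSCAM = list(length = 1700, strand = "+", n_exons = 7, divergence = 0.05,
                 human_ext = 236, human_ins = NULL,
                 codons = c("1562" = "CGA", "1679" = "GGC")),
    TTN = list(length = 2000, strand = "+", n_exons = 10, divergence = 0.08,
               human_ext = 0, human_ins = NULL, codons = character(0))
  )
}

aa_alphabet <- function() setdiff(sort(unique(Biostrings::GENETIC_CODE)), "*")

codons_for_aa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- split(names(Biostrings::GENETIC_CODE),
                                        Biostrings::GENETIC_CODE)
    cache
  }
})

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate the reference bundle
#'
#' Builds the companion reference data the pipeline consumes: a toy
#' genome with one gene per chromosome, validated transcript models
#' (multi-exon, both strands), canine and human protein pairs with
#' configurable divergence, a population SNP table with minor allele
#' frequencies, the human cancer-phenotype hotspot table and local gene
#' sets for over-representation tests.
#'
#' @param genes named list of gene specs (see the package defaults);
#'   driver genes carry pinned hotspot codons and human offsets
#' @param n_passenger_genes number of additional anonymous genes that
#'   absorb passenger mutations
#' @param passenger_gene_length protein length of the anonymous genes
#' @param divergence_override optional single substitution divergence in
#'   [0, 1] applied to every gene pair instead of the per-gene defaults
#' @param n_snp_sites number of population polymorphism sites
#' @param seed integer seed
#' @return an `sl_reference` bundle
#' @export
simulate_reference <- function(genes = driver_gene_specs(),
                               n_passenger_genes = 30,
                               passenger_gene_length = 300,
                               divergence_override = NULL,
                               n_snp_sites = 400, seed = 1) {
  if (length(genes) == 0) stop("gene set must be non-empty")
  if (!is.null(divergence_override) &&
      (divergence_override < 0 || divergence_override > 1))
    stop("divergence must be in [0, 1]")
  set.seed(seed)
  if (n_passenger_genes > 0) {
    anon <- lapply(seq_len(n_passenger_genes), function(i)
      list(length = passenger_gene_length,
           strand = sample(c("+", "-"), 1), n_exons = sample(1:3, 1),
           divergence = 0.10, human_ext = 0, human_ins = NULL,
           codons = character(0)))
    names(anon) <- sprintf("GENE%03d", seq_len(n_passenger_genes))
    genes <- c(genes, anon)
  }

  chroms <- character(0); chrom_seqs <- character(0)
  tab <- list(); prot_can <- character(0); prot_hum <- character(0)
  coding <- list()
  for (k in seq_along(genes)) {
    g <- genes[[k]]; name <- names(genes)[k]
    if (!is.null(divergence_override)) g$divergence <- divergence_override
    built <- build_gene(name, g, chrom = sprintf("chr%02d", k))
    chroms <- c(chroms, built$chrom)
    chrom_seqs <- c(chrom_seqs, built$chrom_seq)
    tab[[k]] <- built$row
    prot_can[name] <- built$protein
    prot_hum[name] <- built$human_protein
    coding[[k]] <- built$coding
  }
  transcript_table <- do.call(rbind, tab)
  genome <- Biostrings::DNAStringSet(stats::setNames(chrom_seqs, chroms))
  txs <- transcript_set(transcript_table, genome, prot_can)

  coding_positions <- do.call(rbind, coding)
  snp <- simulate_snp_table(genome, n_snp_sites)

  structure(list(
    genome = genome, transcript_table = transcript_table, transcripts = txs,
    proteins_canine = prot_can, proteins_human = prot_hum,
    coding_positions = coding_positions, snp_table = snp,
    phenotype = build_phenotype_table(),
    gene_sets = build_gene_sets(names(genes)),
    seed = as.integer(seed)
  ), class = "sl_reference")
}

build_gene <- function(name, g, chrom) {
  aa <- aa_alphabet()
  protein <- c("M", sample(aa, g$length - 1, replace = TRUE))
  for (r in names(g$codons)) {
    res <- translate_codon(g$codons[[r]])
    protein[as.integer(r)] <- res
  }
  cod_sets <- codons_for_aa()
  codons <- character(length(protein))
  for (a in unique(protein)) {
    idx <- which(protein == a)
    cs <- cod_sets[[a]]
    codons[idx] <- if (length(cs) == 1) cs else sample(cs, length(idx),
                                                       replace = TRUE)
  }
  for (r in names(g$codons)) codons[as.integer(r)] <- g$codons[[r]]
  cds <- paste(codons, collapse = "")
  protein <- paste(protein, collapse = "")

  # split CDS into exons (each >= 30 bp), interleave random introns
  len <- nchar(cds)
  n_ex <- min(g$n_exons, max(1L, len %/% 60L))
  repeat {
    if (n_ex == 1L) { sizes <- len; break }
    cuts <- sort(sample(seq_len(len - 1L), n_ex - 1L))
    sizes <- diff(c(0L, cuts, len))
    if (all(sizes >= 30L)) break
  }
  pieces <- substring(cds, cumsum(c(1L, utils::head(sizes, -1L))),
                      cumsum(sizes))
  genomic_pieces <- if (g$strand == "+") pieces else rev(dna_revcomp(pieces))
  introns <- if (n_ex > 1L) vapply(sample(80:400, n_ex - 1L, replace = TRUE),
                                   random_dna, character(1)) else character(0)
  flank5 <- random_dna(1000); flank3 <- random_dna(1000)
  seq_parts <- character(0); starts <- integer(0); ends <- integer(0)
  cursor <- nchar(flank5)
  seq_parts <- flank5
  for (i in seq_len(n_ex)) {
    starts[i] <- cursor + 1L
    ends[i] <- cursor + nchar(genomic_pieces[i])
    seq_parts <- c(seq_parts, genomic_pieces[i])
    cursor <- ends[i]
    if (i < n_ex) {
      seq_parts <- c(seq_parts, introns[i])
      cursor <- cursor + nchar(introns[i])
    }
  }
  chrom_seq <- paste(c(seq_parts, flank3), collapse = "")

  # human counterpart: point substitutions away from pinned hotspots,
  # then the insertion / N-terminal extension that shifts numbering
  prot_vec <- strsplit(protein, "", fixed = TRUE)[[1]]
  protected <- unique(c(1L, as.integer(names(g$codons))))
  hum <- prot_vec
  subs <- which(stats::runif(length(hum)) < g$divergence)
  subs <- setdiff(subs, protected)
  for (i in subs) hum[i] <- sample(setdiff(aa, hum[i]), 1)
  if (!is.null(g$human_ins))
    hum <- append(hum, sample(aa, g$human_ins$len, replace = TRUE),
                  after = g$human_ins$after)
  if (g$human_ext > 0)
    hum <- c(sample(aa, g$human_ext, replace = TRUE), hum)
  human_protein <- paste(hum, collapse = "")

  gpos <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
  coding <- data.frame(gene = name, chrom = chrom, pos = gpos,
                       ref = strsplit(paste(genomic_pieces, collapse = ""),
                                      "", fixed = TRUE)[[1]],
                       stringsAsFactors = FALSE)

  list(chrom = chrom, chrom_seq = chrom_seq, protein = protein,
       human_protein = human_protein, coding = coding,
       row = data.frame(gene = name, chrom = chrom, strand = g$strand,
                        exons = paste(paste0(starts, "-", ends), collapse = ";"),
                        stringsAsFactors = FALSE))
}

simulate_snp_table <- function(genome, n_sites) {
  lens <- Biostrings::width(genome)
  chrom <- sample(names(genome), n_sites, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(chrom, function(ch)
    sample.int(lens[match(ch, names(genome))], 1), integer(1))
  ref <- vapply(seq_len(n_sites), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i], pos[i])),
    character(1))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  common <- stats::runif(n_sites) < 0.6
  maf <- ifelse(common, stats::runif(n_sites, 0.05, 0.5),
                stats::runif(n_sites, 0.005, 0.05))
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, maf = maf,
                    stringsAsFactors = FALSE)
  out[!duplicated(out[c("chrom", "pos")]), ]
}

#' Curated human cancer-phenotype hotspot table
#'
#' A small synthetic lookup table of human hotspot annotations
#' (gain-of-function, loss-of-function, dominant-negative, predicted
#' pathogenic), in human protein coordinates, emulating the role of
#' COSMIC/ClinVar-style resources for the genes the simulator plants.
#' It is a fixture curated from well-known hotspot literature labels,
#' not a mirror of any database.
#'
#' @return data.frame with columns `gene`, `change`, `label`, `source`
#' @export
build_phenotype_table <- function() {
  data.frame(
    gene = c("PIK3CA", "PIK3CA", "PIK3CA",
             "TP53", "TP53", "TP53", "TP53", "TP53", "TP53",
             "PTEN", "PLCG1", "DSCAM"),
    change = c("H1047R", "H1047L", "D350G",
               "L111*", "Y126N", "H179Y", "S241F", "R248W", "V274L",
               "I101T", "S345F", "R1798*"),
    label = c("GOF", "GOF", "GOF",
              "LOF", "LOF", "GOF", "GOF+DN", "GOF", "dominant_negative",
              "predicted_pathogenic", "GOF", "predicted_pathogenic"),
    source = c("cosmic_like", "cosmic_like", "literature",
               "cosmic_like", "cosmic_like", "literature", "literature",
               "literature", "literature",
               "clinvar_like", "literature", "literature"),
    stringsAsFactors = FALSE
  )
}

build_gene_sets <- function(symbols) {
  sets <- list(
    pi3k_signaling = c("PIK3CA", "PTEN", "PLCG1"),
    tp53_pathway = c("TP53"),
    cell_adhesion = c("DSCAM", "TTN")
  )
  if (any(grepl("^GENE0", symbols)))
    sets$housekeeping <- utils::head(sort(grep("^GENE0", symbols, value = TRUE)), 8)
  lapply(sets, function(s) intersect(s, symbols))
}
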
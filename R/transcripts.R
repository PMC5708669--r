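#' Build a transcript set from gene models and a genome
#'
#' One transcript per gene. Each model carries the gene symbol,
#' chromosome, strand, ordered CDS intervals (1-based inclusive,
#' ascending genomic order) and the protein it encodes. At construction
#' the CDS is extracted from the genome (reverse-complemented for minus
#' strand genes), checked to be a multiple of 3 in length, and
#' translated; a model whose translation does not reproduce its stated
#' protein is rejected.
#'
#' @param table data.frame with columns `gene`, `chrom`, `strand`
#'   (`"+"`/`"-"`) and `exons` (CDS intervals as `"start-end;start-end"`)
#' @param genome a named [Biostrings::DNAStringSet] of chromosome sequences
#' @param proteins a named [Biostrings::AAStringSet] (or named character
#'   vector) of protein sequences keyed by gene symbol
#' @return an `sl_transcripts` named list of transcript models
#' @export
transcript_set <- function(table, genome, proteins) {
  stopifnot(is.data.frame(table),
            all(c("gene", "chrom", "strand", "exons") %in% names(table)))
  proteins <- stats::setNames(as.character(proteins), names(proteins))
  models <- lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    exons <- parse_exons(row$exons)
    if (!row$chrom %in% names(genome))
      stop(sprintf("chromosome %s of gene %s absent from genome", row$chrom, row$gene))
    chrom_seq <- genome[[row$chrom]]
    pieces <- vapply(seq_len(nrow(exons)), function(k) {
      as.character(Biostrings::subseq(chrom_seq, exons$start[k], exons$end[k]))
    }, character(1))
    cds <- paste(pieces, collapse = "")
    if (row$strand == "-") cds <- dna_revcomp(cds)
    if (nchar(cds) %% 3 != 0)
      stop(sprintf("CDS length of %s (%d) is not a multiple of 3", row$gene, nchar(cds)))
    if (!row$gene %in% names(proteins))
      stop(sprintf("no protein sequence for gene %s", row$gene))
    prot <- proteins[[row$gene]]
    observed <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    if (!identical(observed, prot))
      stop(sprintf("translated CDS of %s does not match its stated protein", row$gene))
    list(gene = row$gene, chrom = row$chrom, strand = row$strand,
         exons = exons, cds = cds, protein = prot,
         cds_len = nchar(cds), span = c(min(exons$start), max(exons$end)))
  })
  names(models) <- table$gene
  structure(models, class = "sl_transcripts")
}

parse_exons <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  se <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
  exons <- data.frame(start = as.integer(se[, 1]), end = as.integer(se[, 2]))
  if (any(exons$end < exons$start) || is.unsorted(exons$start, strictly = TRUE))
    stop("CDS intervals must be valid and in ascending genomic order")
  exons
}

#' Load a transcript set from files
#'
#' Reads the tab-separated transcript table, a genome FASTA and a protein
#' FASTA keyed by gene symbol, and builds a validated [transcript_set()].
#'
#' @param transcript_table path to the transcript table (TSV with columns
#'   gene, chrom, strand, exons)
#' @param genome_fasta path to the genome FASTA
#' @param protein_fasta path to the protein FASTA
#' @return an `sl_transcripts` object
#' @export
load_transcripts <- function(transcript_table, genome_fasta, protein_fasta) {
  tab <- utils::read.delim(transcript_table, stringsAsFactors = FALSE)
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  prot <- Biostrings::readAAStringSet(protein_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  transcript_set(tab, genome, prot)
}

# 1-based CDS offset of a genomic position, NA when not exonic.
# Plus strand: offsets run with the genome; minus strand: against it.
cds_offset <- function(tx, pos) {
  ex <- tx$exons
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  lens <- ex$end - ex$start + 1L
  if (tx$strand == "+") {
    before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
    as.integer(before + (pos - ex$start[hit] + 1L))
  } else {
    after <- if (hit < nrow(ex)) sum(lens[(hit + 1L):nrow(ex)]) else 0L
    as.integer(after + (ex$end[hit] - pos + 1L))
  }
}

# genomic position of a 1-based CDS offset (inverse of cds_offset)
genomic_pos <- function(tx, offset) {
  ex <- tx$exons
  lens <- ex$end - ex$start + 1L
  if (offset < 1L || offset > sum(lens)) stop("CDS offset outside transcript")
  if (tx$strand == "+") {
    cum <- cumsum(lens)
    k <- which(offset <= cum)[1]
    prior <- if (k > 1L) cum[k - 1L] else 0L
    ex$start[k] + (offset - prior - 1L)
  } else {
    cum <- cumsum(rev(lens))
    kr <- which(offset <= cum)[1]
    prior <- if (kr > 1L) cum[kr - 1L] else 0L
    k <- nrow(ex) - kr + 1L
    ex$end[k] - (offset - prior - 1L)
  }
}

# essential splice check: intronic position within 2 bases of an internal
# exon boundary. Returns NA (not a splice site) or the genomic position of
# the nearest exonic base.
splice_boundary <- function(tx, pos) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(NA_integer_)
  donors <- ex$end[-n]      # intron starts at end+1
  acceptors <- ex$start[-1] # intron ends at start-1
  if (any(pos >= donors + 1L & pos <= donors + 2L))
    return(donors[pos >= donors + 1L & pos <= donors + 2L][1])
  if (any(pos >= acceptors - 2L & pos <= acceptors - 1L))
    return(acceptors[pos >= acceptors - 2L & pos <= acceptors - 1L][1])
  NA_integer_
}

#' @export
print.sl_transcripts <- function(x, ...) {
  cat(sprintf("sl_transcripts: %d gene models\n", length(x)))
  for (tx in x)
    cat(sprintf("  %s %s%s, %d CDS intervals, %d aa\n", tx$gene, tx$chrom,
                tx$strand, nrow(tx$exons), nchar(tx$protein)))
  invisible(x)
}
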
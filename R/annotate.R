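#' Annotate the coding consequence of a variant
#'
#' Classifies a variant against a transcript set into one of
#' `missense`, `nonsense`, `synonymous`, `frameshift`, `inframe_indel`,
#' `essential_splice`, or `none` (no coding consequence).
#'
#' SNVs inside a CDS are classified by translating the reference and
#' alternate codon (standard genetic code, strand-aware); the residue
#' index is `ceiling(cds_offset / 3)` (1-based). Indels whose length
#' change is not a multiple of 3 are frameshifts, annotated at the first
#' affected residue (`"T56fs"` style); in-frame indels are reported as
#' `inframe_indel`. An intronic position within 2 bases of an internal
#' CDS boundary (the canonical GT/AG dinucleotides) is an essential
#' splice variant, as is any indel spanning a CDS/intron boundary (most
#' severe class wins); splice records carry the residue index of the
#' nearest exonic base.
#'
#' @param tx_set an `sl_transcripts` set (one transcript per gene)
#' @param chrom,pos,ref,alt the variant (VCF conventions: 1-based `pos`,
#'   anchored indel alleles)
#' @return one-row data.frame: `gene`, `consequence`, `residue`,
#'   `ref_res`, `alt_res`, `label`
#' @export
annotate_variant <- function(tx_set, chrom, pos, ref, alt) {
  none <- data.frame(gene = NA_character_, consequence = "none",
                     residue = NA_integer_, ref_res = NA_character_,
                     alt_res = NA_character_, label = NA_character_,
                     stringsAsFactors = FALSE)
  tx <- find_transcript(tx_set, chrom, pos)
  if (is.null(tx)) return(none)
  if (is_snv(ref, alt)) annotate_snv(tx, pos, ref, alt, none)
  else annotate_indel(tx, pos, ref, alt, none)
}

find_transcript <- function(tx_set, chrom, pos) {
  for (tx in tx_set) {
    if (tx$chrom == chrom && pos >= tx$span[1] - 2L && pos <= tx$span[2] + 2L)
      return(tx)
  }
  NULL
}

annotate_snv <- function(tx, pos, ref, alt, none) {
  off <- cds_offset(tx, pos)
  if (is.na(off)) {
    boundary <- splice_boundary(tx, pos)
    if (is.na(boundary)) return(none)
    res <- codon_of(cds_offset(tx, boundary))
    return(consequence_row(tx$gene, "essential_splice", res,
                           substr(tx$protein, res, res), NA, "splice"))
  }
  res <- codon_of(off)
  cpos <- off - 3L * (res - 1L)
  ref_codon <- substr(tx$cds, 3L * res - 2L, 3L * res)
  cds_ref <- if (tx$strand == "+") toupper(ref) else dna_complement(toupper(ref))
  if (substr(ref_codon, cpos, cpos) != cds_ref)
    stop(sprintf("reference allele mismatch for %s at %s:%d", tx$gene, tx$chrom, pos))
  cds_alt <- if (tx$strand == "+") toupper(alt) else dna_complement(toupper(alt))
  alt_codon <- ref_codon
  substr(alt_codon, cpos, cpos) <- cds_alt
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  if (aa_ref == aa_alt)
    consequence_row(tx$gene, "synonymous", res, aa_ref, aa_alt,
                    paste0(aa_ref, res, aa_alt))
  else if (aa_alt == "*")
    consequence_row(tx$gene, "nonsense", res, aa_ref, "*",
                    paste0(aa_ref, res, "*"))
  else if (res == 1L && aa_ref == "M")
    # start-loss: no initiator, folded into the nonsense (inactivating) class
    consequence_row(tx$gene, "nonsense", res, aa_ref, aa_alt,
                    paste0(aa_ref, res, aa_alt))
  else
    consequence_row(tx$gene, "missense", res, aa_ref, aa_alt,
                    paste0(aa_ref, res, aa_alt))
}

annotate_indel <- function(tx, pos, ref, alt, none) {
  ref <- toupper(ref); alt <- toupper(alt)
  len_diff <- nchar(alt) - nchar(ref)
  if (len_diff == 0L) return(none)  # MNVs not supported at toy scale
  if (len_diff < 0L) {
    changed <- (pos + 1L):(pos + nchar(ref) - 1L)
  } else {
    changed <- c(pos, pos + 1L)     # insertion between the two flanks
  }
  offs <- vapply(changed, function(p) cds_offset(tx, p), integer(1))
  splice <- any(vapply(changed, function(p) !is.na(splice_boundary(tx, p)), logical(1)))
  exonic <- !is.na(offs)
  if (len_diff < 0L) {
    if (!any(exonic)) {
      if (!splice) return(none)
      b <- splice_boundary(tx, changed[1])
      res <- codon_of(cds_offset(tx, b))
      return(consequence_row(tx$gene, "essential_splice", res,
                             substr(tx$protein, res, res), NA, "splice"))
    }
    if (!all(exonic) || splice) {
      res <- codon_of(min(offs[exonic]))
      return(consequence_row(tx$gene, "essential_splice", res,
                             substr(tx$protein, res, res), NA, "splice"))
    }
    first_off <- min(offs)
  } else {
    if (!all(exonic)) {
      if (!any(exonic)) return(none)
      res <- codon_of(offs[exonic][1])
      return(consequence_row(tx$gene, "essential_splice", res,
                             substr(tx$protein, res, res), NA, "splice"))
    }
    first_off <- max(offs)  # first coding base shifted by the insertion
  }
  res <- codon_of(first_off)
  aa_ref <- substr(tx$protein, res, res)
  if (abs(len_diff) %% 3L != 0L)
    consequence_row(tx$gene, "frameshift", res, aa_ref, "fs",
                    paste0(aa_ref, res, "fs"))
  else
    consequence_row(tx$gene, "inframe_indel", res, aa_ref,
                    if (len_diff < 0) "del" else "ins",
                    paste0(aa_ref, res, if (len_diff < 0) "del" else "ins"))
}

codon_of <- function(off) as.integer(ceiling(off / 3))

consequence_row <- function(gene, consequence, residue, ref_res, alt_res, label) {
  data.frame(gene = gene, consequence = consequence, residue = as.integer(residue),
             ref_res = as.character(ref_res), alt_res = as.character(alt_res),
             label = label, stringsAsFactors = FALSE)
}

#' Annotate a table of variants
#'
#' Row-wise [annotate_variant()] over a variant data.frame.
#'
#' @param tx_set an `sl_transcripts` set
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#' @return `variants` with annotation columns appended
#' @export
annotate_variants <- function(tx_set, variants) {
  ann <- lapply(seq_len(nrow(variants)), function(i)
    annotate_variant(tx_set, variants$chrom[i], variants$pos[i],
                     variants$ref[i], variants$alt[i]))
  ann <- if (length(ann)) do.call(rbind, ann) else
    consequence_row(character(0), character(0), integer(0),
                    character(0), character(0), character(0))
  cbind(variants, ann)
}

#' Reverse-strand codon in coding orientation
#'
#' For a minus-strand transcript, the genomic bases of a codon read in
#' ascending genomic order must be reverse-complemented to obtain the
#' codon in coding orientation.
#'
#' @param genomic_codon 3-base genomic sequence (ascending genomic order)
#' @param strand transcript strand; must be `"-"`
#' @return the codon in coding orientation
#' @export
reverse_strand_codon <- function(genomic_codon, strand) {
  if (!identical(strand, "-"))
    stop("reverse_strand_codon applies to minus-strand transcripts only")
  dna_revcomp(genomic_codon)
}
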
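#' Write a simulated cohort as paired VCF files
#'
#' Emits one tumor and one normal VCF v4.2 per case
#' (`<case>_tumor.vcf`, `<case>_normal.vcf`), plus the truth table as
#' `truth.tsv`. The tumor file carries every emitted record with tumor
#' depth/alt in the sample column (`DP:AD`) and, in INFO, the region
#' class (`RC`), the population minor allele frequency when the site is
#' a known polymorphism (`MAF`), and the matched-normal depth and alt
#' count at the site (`NDP`, `NAD`). The normal file lists the records
#' with read support in the normal sample (the germline component); its
#' union across cases is the panel of normals. Output is plain text and
#' byte-identical across reruns of the same cohort. Column semantics
#' are documented in the `schema.md` file shipped with the package.
#'
#' @param cohort an [simulate_cohort()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_cohort_vcfs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- sprintf("##contig=<ID=%s,length=%d>",
                     names(cohort$reference$genome),
                     Biostrings::width(cohort$reference$genome))
  files <- character(0)
  for (id in cohort$cases) {
    cc <- cohort$calls[cohort$calls$case == id, , drop = FALSE]
    cc <- cc[order(cc$chrom, cc$pos), , drop = FALSE]
    tfile <- file.path(dir, paste0(id, "_tumor.vcf"))
    nfile <- file.path(dir, paste0(id, "_normal.vcf"))
    info <- paste0("RC=", cc$region_class,
                   ifelse(is.na(cc$db_maf), "",
                          sprintf(";MAF=%.10g", cc$db_maf)),
                   sprintf(";NDP=%d;NAD=%d", cc$normal_depth, cc$normal_alt))
    write_vcf(tfile, contigs, paste0(id, "_T"), cc, info,
              sprintf("%d:%d,%d", cc$tumor_depth,
                      cc$tumor_depth - cc$tumor_alt, cc$tumor_alt))
    nn <- cc[cc$in_normal, , drop = FALSE]
    write_vcf(nfile, contigs, paste0(id, "_N"), nn,
              paste0("RC=", nn$region_class,
                     ifelse(is.na(nn$db_maf), "", sprintf(";MAF=%.10g", nn$db_maf))),
              sprintf("%d:%d,%d", nn$normal_depth,
                      nn$normal_depth - nn$normal_alt, nn$normal_alt))
    files <- c(files, tfile, nfile)
  }
  truth_file <- file.path(dir, "truth.tsv")
  utils::write.table(cohort$truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, truth_file))
}

vcf_header <- function(contigs, sample) {
  c("##fileformat=VCFv4.2",
    "##source=somaticlift",
    contigs,
    '##INFO=<ID=RC,Number=1,Type=String,Description="Region class">',
    '##INFO=<ID=MAF,Number=1,Type=Float,Description="Population minor allele frequency">',
    '##INFO=<ID=NDP,Number=1,Type=Integer,Description="Matched normal depth at site">',
    '##INFO=<ID=NAD,Number=1,Type=Integer,Description="Matched normal alt count at site">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref,alt read depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

write_vcf <- function(path, contigs, sample, rows, info, gt) {
  lines <- vcf_header(contigs, sample)
  if (nrow(rows) > 0)
    lines <- c(lines, paste(rows$chrom, rows$pos, ".", rows$ref, rows$alt,
                            ".", "PASS", info, "DP:AD", gt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a paired-VCF cohort directory
#'
#' Rebuilds the cohort call table from `<case>_tumor.vcf` /
#' `<case>_normal.vcf` pairs written by [write_cohort_vcfs()] (or any
#' files following the same schema). Multi-allelic records are
#' decomposed into one biallelic variant per alternate allele, with
#' the matching component of the `AD` field.
#'
#' @param dir directory of paired VCFs
#' @return data.frame in the same layout as `simulate_cohort()$calls`
#' @export
read_cohort_vcfs <- function(dir) {
  tumor_files <- sort(list.files(dir, pattern = "_tumor\\.vcf$", full.names = TRUE))
  if (length(tumor_files) == 0) stop("no *_tumor.vcf files in ", dir)
  out <- lapply(tumor_files, function(tf) {
    id <- sub("_tumor\\.vcf$", "", basename(tf))
    v <- vcfR::read.vcfR(tf, verbose = FALSE)
    if (nrow(v@fix) == 0) return(NULL)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- t(fx)  # single-record files
    fix <- as.data.frame(fx, stringsAsFactors = FALSE)
    dp <- as.integer(vcfR::extract.gt(v, "DP")[, 1])
    ad <- strsplit(vcfR::extract.gt(v, "AD")[, 1], ",", fixed = TRUE)
    maf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MAF")))
    # decompose multi-allelic records into biallelic variants
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    n_alt <- lengths(alts)
    idx <- rep(seq_len(nrow(fix)), n_alt)
    which_alt <- sequence(n_alt)
    fix <- fix[idx, , drop = FALSE]
    fix$ALT <- unlist(alts)
    dp <- dp[idx]
    maf <- maf[idx]
    alt_reads <- as.integer(mapply(function(counts, k) counts[k + 1L],
                                   ad[idx], which_alt))
    normal_keys <- character(0)
    nf <- file.path(dir, paste0(id, "_normal.vcf"))
    if (file.exists(nf)) {
      nv <- vcfR::read.vcfR(nf, verbose = FALSE)
      if (nrow(nv@fix) > 0) {
        nfx <- vcfR::getFIX(nv)
        if (is.null(dim(nfx))) nfx <- t(nfx)
        nfix <- as.data.frame(nfx, stringsAsFactors = FALSE)
        normal_keys <- variant_key(nfix$CHROM, as.integer(nfix$POS),
                                   nfix$REF, nfix$ALT)
      }
    }
    pos <- as.integer(fix$POS)
    data.frame(case = id, chrom = fix$CHROM, pos = pos,
               ref = fix$REF, alt = fix$ALT,
               tumor_depth = dp, tumor_alt = alt_reads,
               normal_depth = as.integer(vcfR::extract.info(v, "NDP"))[idx],
               normal_alt = as.integer(vcfR::extract.info(v, "NAD"))[idx],
               region_class = vcfR::extract.info(v, "RC")[idx],
               db_maf = maf,
               in_normal = variant_key(fix$CHROM, pos, fix$REF, fix$ALT) %in%
                 normal_keys,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Write the reference bundle as fixture files
#'
#' Serializes a simulated reference to plain-text files: transcript
#' table (`transcripts.tsv`), genome and protein FASTA
#' (`genome.fa`, `proteins_canine.fa`, `proteins_human.fa`), the
#' population SNP table (`snp_table.tsv`), the phenotype hotspot table
#' (`phenotype_table.tsv`) and gene sets (`gene_sets.tsv`, long format).
#'
#' @param reference an `sl_reference`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_reference_fixtures <- function(reference, dir) {
  stopifnot(inherits(reference, "sl_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(reference$transcript_table,
                     file.path(dir, "transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(reference$genome, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(reference$proteins_canine),
    file.path(dir, "proteins_canine.fa"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(reference$proteins_human),
    file.path(dir, "proteins_human.fa"))
  utils::write.table(reference$snp_table, file.path(dir, "snp_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(reference$phenotype, file.path(dir, "phenotype_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gs <- do.call(rbind, lapply(names(reference$gene_sets), function(s)
    data.frame(set = s, gene = reference$gene_sets[[s]],
               stringsAsFactors = FALSE)))
  utils::write.table(gs, file.path(dir, "gene_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
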
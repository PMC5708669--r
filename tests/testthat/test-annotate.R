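# toy gene (both strands): CDS = ATG CAT GCC TTA GAC AAA -> MHALDK,
# split across two exons with a 50 bp intron

test_that("transcript models validate translation at load", {
  txs <- toy_transcripts()
  expect_s3_class(txs, "sl_transcripts")
  expect_equal(txs$PLUSG$protein, "MHALDK")
  expect_equal(txs$MINUSG$cds, txs$PLUSG$cds)
  # a wrong protein is rejected
  tab <- data.frame(gene = "PLUSG", chrom = "chrP", strand = "+",
                    exons = "101-110;161-168", stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(c(chrP = paste0(
    strrep("T", 100), "ATGCATGCCT", strrep("A", 50), "TAGACAAA", strrep("T", 100))))
  expect_error(transcript_set(tab, genome, c(PLUSG = "MHALDY")),
               "does not match")
})

test_that("SNV consequences on the plus strand: missense, synonymous, nonsense", {
  txs <- toy_transcripts()
  # codon 2 CAT -> CGT (A>G at genomic 105): His2Arg
  ann <- annotate_variant(txs, "chrP", 105, "A", "G")
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$label, "H2R")
  expect_equal(ann$residue, 2L)
  # codon 3 GCC -> GCA (C>A at genomic 109): synonymous
  ann <- annotate_variant(txs, "chrP", 109, "C", "A")
  expect_equal(ann$consequence, "synonymous")
  # codon 4 TTA spans the intron; TTA -> TGA (T>G at genomic 161): Leu4*
  ann <- annotate_variant(txs, "chrP", 161, "T", "G")
  expect_equal(ann$consequence, "nonsense")
  expect_equal(ann$label, "L4*")
})

test_that("minus-strand SNVs are annotated through the reverse complement", {
  txs <- toy_transcripts()
  # H2R on the minus gene: CDS offset 5 sits at genomic 164; the coding
  # A>G change reads T>C on the genome strand
  ann <- annotate_variant(txs, "chrM", 164, "T", "C")
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$label, "H2R")
  # a wrong reference allele is an error
  expect_error(annotate_variant(txs, "chrM", 164, "A", "C"), "mismatch")
})

test_that("essential splice sites are the two intronic bases at CDS boundaries", {
  txs <- toy_transcripts()
  for (pos in c(111, 112, 159, 160)) {
    ann <- annotate_variant(txs, "chrP", pos, "A", "G")
    expect_equal(ann$consequence, "essential_splice", info = pos)
  }
  # deeper intronic positions have no coding consequence
  for (pos in c(113, 135, 158)) {
    ann <- annotate_variant(txs, "chrP", pos, "A", "G")
    expect_equal(ann$consequence, "none", info = pos)
  }
  # outside the transcript entirely
  expect_equal(annotate_variant(txs, "chrP", 50, "T", "C")$consequence, "none")
})

test_that("indels classify as frameshift, inframe, or splice by span", {
  txs <- toy_transcripts()
  # delete genomic 105 (codon 2, base 2): frameshift at His2
  ann <- annotate_variant(txs, "chrP", 104, "CA", "C")
  expect_equal(ann$consequence, "frameshift")
  expect_equal(ann$label, "H2fs")
  # delete codon 2 entirely (offsets 4-6): in-frame deletion
  ann <- annotate_variant(txs, "chrP", 103, "GCAT", "G")
  expect_equal(ann$consequence, "inframe_indel")
  expect_equal(ann$residue, 2L)
  # 1 bp insertion inside codon 3: frameshift
  ann <- annotate_variant(txs, "chrP", 107, "G", "GT")
  expect_equal(ann$consequence, "frameshift")
  # deletion running from the exon into the intron: essential splice
  ann <- annotate_variant(txs, "chrP", 109, "CTA", "C")
  expect_equal(ann$consequence, "essential_splice")
})

test_that("start-loss folds into the nonsense (inactivating) class", {
  txs <- toy_transcripts()
  # ATG -> ATC (G>C at genomic 103): Met1Ile, no initiator
  ann <- annotate_variant(txs, "chrP", 103, "G", "C")
  expect_equal(ann$consequence, "nonsense")
  expect_equal(ann$residue, 1L)
})

test_that("reverse_strand_codon reverse-complements and enforces strand", {
  expect_equal(reverse_strand_codon("ATG", "-"), "CAT")
  expect_equal(reverse_strand_codon("GAC", "-"), "GTC")
  expect_error(reverse_strand_codon("ATG", "+"), "minus-strand")
})

test_that("annotation is a pure function with mutually exclusive classes", {
  txs <- toy_transcripts()
  a1 <- annotate_variant(txs, "chrP", 105, "A", "G")
  a2 <- annotate_variant(txs, "chrP", 105, "A", "G")
  expect_identical(a1, a2)
  classes <- c("missense", "nonsense", "synonymous", "frameshift",
               "inframe_indel", "essential_splice", "none")
  expect_true(a1$consequence %in% classes)
  expect_length(a1$consequence, 1)
})

test_that("planted drivers annotate back to their planted labels", {
  coh <- sl_cohort7()
  drv <- coh$truth[coh$truth$category == "driver", , drop = FALSE]
  expect_gt(nrow(drv), 0)
  ann <- annotate_variants(coh$reference$transcripts, drv)
  expect_true(all(ann$label == drv$planted_change))
  expect_true(all(ann$gene == drv$gene))
})
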
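test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(passenger_rate = -1), "rates")
  expect_error(sim_config(target_region_size = 0), "positive size")
  spec <- default_driver_spectrum()
  spec$fraction[1] <- 1.5
  expect_error(sim_config(driver_spectrum = spec), "\\[0, 1\\]")
  expect_error(simulate_reference(genes = list()), "non-empty")
  expect_error(simulate_reference(divergence_override = 1.2), "\\[0, 1\\]")
})

test_that("a driver gene missing from the transcript set is an error", {
  spec <- data.frame(gene = "NOSUCHGENE", change = "A1V", fraction = 1,
                     stringsAsFactors = FALSE)
  expect_error(simulate_cohort(sim_config(driver_spectrum = spec, seed = 1),
                               sl_ref()),
               "absent from transcript set")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_cases = 4, seed = 33)
  c1 <- simulate_cohort(cfg, sl_ref())
  c2 <- simulate_cohort(cfg, sl_ref())
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$truth, c2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort_vcfs(c1, d1); write_cohort_vcfs(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("all rates zero and no drivers yields empty tumor call sets", {
  cfg <- sim_config(n_cases = 3,
                    driver_spectrum = default_driver_spectrum()[0, ],
                    passenger_rate = 0, synonymous_rate = 0,
                    germline_snp_rate = 0, artifact_rate = 0, seed = 2)
  coh <- simulate_cohort(cfg, sl_ref())
  expect_equal(nrow(coh$calls), 0)
  expect_equal(nrow(coh$truth), 0)
  d <- tempfile()
  write_cohort_vcfs(coh, d)
  for (f in list.files(d, pattern = "vcf$", full.names = TRUE)) {
    lines <- readLines(f)
    expect_true(all(startsWith(lines, "#")), info = f)
  }
})

test_that("every emitted variant has exactly one truth record", {
  coh <- sl_cohort7()
  expect_equal(nrow(coh$calls), nrow(coh$truth))
  k1 <- paste(coh$calls$case, coh$calls$chrom, coh$calls$pos)
  k2 <- paste(coh$truth$case, coh$truth$chrom, coh$truth$pos)
  expect_identical(sort(k1), sort(k2))
  expect_false(any(duplicated(k1)))
})

test_that("germline records are shared by tumor and normal at het/hom VAF", {
  coh <- sl_cohort7()
  germ_keys <- with(coh$truth[coh$truth$category == "germline", ],
                    paste(case, chrom, pos))
  calls_keys <- paste(coh$calls$case, coh$calls$chrom, coh$calls$pos)
  g <- coh$calls[calls_keys %in% germ_keys, , drop = FALSE]
  expect_true(all(g$in_normal))
  tvaf <- g$tumor_alt / g$tumor_depth
  nvaf <- g$normal_alt / g$normal_depth
  # each observed VAF lies near 0.5 or near 1.0
  near <- function(v) abs(v - 0.5) < 0.35 | v > 0.75
  expect_gt(mean(near(tvaf)), 0.95)
  expect_gt(mean(near(nvaf)), 0.95)
  # non-germline records are absent from normals
  ng <- coh$calls[!(calls_keys %in% germ_keys), , drop = FALSE]
  expect_false(any(ng$in_normal))
  expect_true(all(ng$normal_alt == 0))
})

test_that("planted driver counts follow the configured case fractions", {
  coh <- sl_cohort7()
  drv <- coh$truth[coh$truth$category == "driver", , drop = FALSE]
  counts <- table(factor(drv$gene, levels = default_driver_spectrum()$gene))
  # binomial(20, f): within 4 SD of the mean
  f <- default_driver_spectrum()$fraction
  expect_true(all(abs(as.integer(counts) - 20 * f) <=
                    4 * sqrt(20 * f * (1 - f)) + 1))
  # per-case uniqueness of each planted driver
  expect_false(any(duplicated(drv[c("case", "gene")])))
})

test_that("artifacts are tumor-only low-VAF deamination changes", {
  coh <- sl_cohort7()
  keys <- paste(coh$truth$case, coh$truth$chrom, coh$truth$pos)
  ckeys <- paste(coh$calls$case, coh$calls$chrom, coh$calls$pos)
  art <- coh$calls[ckeys %in% keys[coh$truth$category == "artifact"], ]
  expect_true(all((art$ref == "C" & art$alt == "T") |
                    (art$ref == "G" & art$alt == "A")))
  expect_true(all(art$normal_alt == 0))
  # drawn VAFs concentrate below the somatic-call threshold
  expect_gt(mean(art$tumor_alt / art$tumor_depth < 0.10), 0.85)
})

test_that("tumor depth is designed at twice the normal depth", {
  coh <- sl_cohort7()
  expect_lt(abs(mean(coh$calls$tumor_depth) /
                  mean(coh$calls$normal_depth) - 2), 0.2)
})

test_that("zero divergence gives identical protein pairs", {
  ref0 <- simulate_reference(genes = driver_gene_specs()[c("PIK3CA", "TP53")],
                             n_passenger_genes = 0,
                             divergence_override = 0, seed = 9)
  expect_identical(ref0$proteins_canine[["PIK3CA"]],
                   ref0$proteins_human[["PIK3CA"]])
  expect_identical(ref0$proteins_canine[["TP53"]],
                   ref0$proteins_human[["TP53"]])
})

test_that("reference fixtures round-trip through their file formats", {
  ref <- sl_ref()
  d <- tempfile()
  write_reference_fixtures(ref, d)
  expect_true(all(file.exists(file.path(d, c(
    "transcripts.tsv", "genome.fa", "proteins_canine.fa", "proteins_human.fa",
    "snp_table.tsv", "phenotype_table.tsv", "gene_sets.tsv")))))
  # reload validates translation of every transcript
  txs <- load_transcripts(file.path(d, "transcripts.tsv"),
                          file.path(d, "genome.fa"),
                          file.path(d, "proteins_canine.fa"))
  expect_equal(sort(names(txs)), sort(names(ref$transcripts)))
  expect_equal(txs$PIK3CA$cds, ref$transcripts$PIK3CA$cds)
})

test_that("cohort VCFs round-trip through a VCF reader", {
  cfg <- sim_config(n_cases = 3, seed = 12)
  coh <- simulate_cohort(cfg, sl_ref())
  d <- tempfile()
  write_cohort_vcfs(coh, d)
  back <- read_cohort_vcfs(d)
  orig <- coh$calls[order(coh$calls$case, coh$calls$chrom, coh$calls$pos), ]
  rownames(orig) <- NULL
  expect_equal(back, orig)
})

test_that("multi-allelic records decompose into biallelic variants on read", {
  d <- tempfile(); dir.create(d)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=1000>",
    '##INFO=<ID=RC,Number=1,Type=String,Description="Region class">',
    '##INFO=<ID=NDP,Number=1,Type=Integer,Description="x">',
    '##INFO=<ID=NAD,Number=1,Type=Integer,Description="x">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="x">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="x">',
    paste("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT","s_T",
          sep = "\t"),
    paste("chr01","100",".","A","G,T",".","PASS","RC=coding;NDP=30;NAD=0",
          "DP:AD","50:30,12,8", sep = "\t"))
  writeLines(lines, file.path(d, "caseX_tumor.vcf"))
  calls <- read_cohort_vcfs(d)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$alt, c("G", "T"))
  expect_equal(calls$tumor_alt, c(12L, 8L))
  expect_equal(calls$tumor_depth, c(50L, 50L))
  expect_equal(calls$normal_depth, c(30L, 30L))
})
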
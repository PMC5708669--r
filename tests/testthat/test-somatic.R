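test_that("somatic discrimination separates clear somatic, germline and reference calls", {
  cfg <- filter_config()
  expect_equal(call_somatic(30, 100, 0, 40, cfg), "somatic")
  expect_equal(call_somatic(20, 40, 19, 38, cfg), "germline")
  # VAF 0.03 below the tumor threshold: not somatic
  expect_equal(call_somatic(3, 100, 0, 50, cfg), "reference")
  expect_equal(call_somatic(0, 0, 5, 30, cfg), "ambiguous")
  expect_equal(call_somatic(5, 30, 0, 0, cfg), "ambiguous")
  # vectorized
  expect_equal(call_somatic(c(30, 20), c(100, 40), c(0, 19), c(40, 38), cfg),
               c("somatic", "germline"))
  expect_error(call_somatic(10, 5, 0, 10, cfg), "exceed")
})

test_that("the Fisher statistic matches fisher.test by exact enumeration", {
  set.seed(3)
  for (i in 1:40) {
    td <- sample(1:60, 1); ta <- sample(0:td, 1)
    nd <- sample(1:60, 1); na <- sample(0:nd, 1)
    expected <- stats::fisher.test(
      matrix(c(ta, td - ta, na, nd - na), 2, byrow = TRUE),
      alternative = "greater")$p.value
    expect_equal(somatic_fisher_p(ta, td, na, nd), expected, tolerance = 1e-12)
  }
})

test_that("filters remove variants in the documented order", {
  cfg <- filter_config()
  v <- data.frame(
    chrom = "chr01", pos = 1:5, ref = "A", alt = "G",
    region_class = c("intronic", "coding", "coding", "coding", "coding"),
    consequence = c("none", "missense", "missense", "missense", "missense"),
    db_maf = c(NA, 0.04, NA, NA, 0.20),
    tumor_depth = c(100, 50, 9, 60, 9),
    tumor_alt = c(20, 10, 4, 20, 4),
    stringsAsFactors = FALSE)
  pon <- variant_key("chr01", 4, "A", "G")
  fl <- apply_filters(v, pon, cfg)
  expect_equal(fl$final,
               c("region_or_synonymous", "pass", "min_depth",
                 "panel_of_normals", "population_maf"))
  # a variant failing MAF and depth is charged to the earlier filter only
  expect_equal(fl$final[5], "population_maf")
  expect_equal(nrow(fl$pass), 1)
  expect_equal(fl$pass$pos, 2)  # MAF 0.04 < 0.05 is retained
})

test_that("MAF boundary at exactly the threshold is removed, just below retained", {
  cfg <- filter_config()
  v <- data.frame(chrom = "chr01", pos = 1:2, ref = "A", alt = "G",
                  region_class = "coding", consequence = "missense",
                  db_maf = c(0.05, 0.049999), tumor_depth = 50, tumor_alt = 10,
                  stringsAsFactors = FALSE)
  fl <- apply_filters(v, character(0), cfg)
  expect_equal(fl$final, c("population_maf", "pass"))
})

test_that("synonymous and non-coding calls fail filter 1 but essential splice survives", {
  cfg <- filter_config()
  v <- data.frame(chrom = "chr01", pos = 1:3, ref = "A", alt = "G",
                  region_class = c("coding", "intronic", "intronic"),
                  consequence = c("synonymous", "essential_splice", "missense"),
                  db_maf = NA_real_, tumor_depth = 50, tumor_alt = 10,
                  stringsAsFactors = FALSE)
  fl <- apply_filters(v, character(0), cfg)
  expect_equal(fl$final,
               c("region_or_synonymous", "pass", "region_or_synonymous"))
})

test_that("filter trace stops at the first failing filter and covers every variant", {
  v <- random_variants(60, seed = 21)
  fl <- apply_filters(v, character(0), filter_config())
  key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  for (i in seq_len(nrow(v))) {
    tr <- fl$trace[fl$trace$variant == key[i], , drop = FALSE]
    expect_gte(nrow(tr), 1)
    fails <- which(tr$verdict == "fail")
    if (fl$final[i] == "pass") expect_length(fails, 0)
    else {
      expect_equal(fails, nrow(tr))  # only the last evaluated filter fails
      expect_equal(tr$filter[fails], fl$final[i])
    }
  }
})

test_that("filter chain is idempotent and monotone in min_depth", {
  for (seed in c(5, 17, 29)) {
    v <- random_variants(120, seed = seed)
    fl1 <- apply_filters(v, character(0), filter_config())
    # idempotence: re-filtering the passing set changes nothing
    fl2 <- apply_filters(fl1$pass, character(0), filter_config())
    expect_identical(fl2$pass, fl1$pass)
    # subset monotonicity
    expect_true(all(rownames(fl1$pass) %in% rownames(v)))
    # raising min_depth never enlarges the passing set
    prev <- NULL
    for (d in c(1, 10, 30, 60)) {
      p <- apply_filters(v, character(0), filter_config(min_depth = d))$pass
      if (!is.null(prev))
        expect_true(all(rownames(p) %in% rownames(prev)))
      prev <- p
    }
  }
})

test_that("artifact surrogate drops only low-support deamination calls", {
  v <- data.frame(ref = c("C", "A", "C", "G", "C"),
                  alt = c("T", "G", "T", "A", "T"),
                  tumor_alt = c(3, 3, 40, 2, 6),
                  tumor_depth = c(80, 80, 80, 60, 80),
                  stringsAsFactors = FALSE)
  expect_equal(artifact_filter(v), c(FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("empty input passes through the filter chain", {
  fl <- apply_filters(random_variants(0, seed = 1), character(0), filter_config())
  expect_equal(nrow(fl$pass), 0)
  expect_equal(nrow(fl$trace), 0)
})
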
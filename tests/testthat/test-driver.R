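test_that("phenotype matching distinguishes exact, site and no hits", {
  db <- build_phenotype_table()
  hit <- match_phenotype("PIK3CA", 1047L, "R", db)
  expect_equal(hit$tier, "exact")
  expect_equal(hit$label, "GOF")
  # a different alternate at an annotated residue is a site match
  db2 <- db[db$change != "H1047L", ]
  hit <- match_phenotype("PIK3CA", 1047L, "W", db2)
  expect_equal(unique(hit$tier), "site")
  # unannotated gene or residue: no match
  expect_equal(nrow(match_phenotype("GENE001", 10L, "A", db)), 0)
  expect_equal(nrow(match_phenotype("PIK3CA", 999L, "A", db)), 0)
  # stop and frameshift markers match their records
  expect_equal(match_phenotype("DSCAM", 1798L, "*", db)$tier, "exact")
})

test_that("recurrence ranks genes by distinct mutated cases", {
  gc <- data.frame(
    gene = c(rep("PIK3CA", 9), rep("TP53", 8), rep("PTEN", 2), "PLCG1"),
    case = c(sprintf("c%02d", 1:9), sprintf("c%02d", c(1:7, 7)),
             c("c10", "c11"), "c12"),
    stringsAsFactors = FALSE)
  r <- recurrence(gc, min_cases = 2)
  # TP53 has 8 mutations but 7 distinct cases
  expect_equal(r$gene, c("PIK3CA", "TP53", "PTEN"))
  expect_equal(r$n_cases, c(9L, 7L, 2L))
  # all-singleton input yields an empty table
  solo <- data.frame(gene = c("A", "B"), case = c("c1", "c2"))
  expect_equal(nrow(recurrence(solo)), 0)
})

test_that("recurrence equals a direct recount and ignores case labels", {
  set.seed(8)
  gc <- data.frame(gene = sample(LETTERS[1:6], 80, replace = TRUE),
                   case = sample(sprintf("c%02d", 1:10), 80, replace = TRUE),
                   stringsAsFactors = FALSE)
  r <- recurrence(gc, min_cases = 2)
  for (i in seq_len(nrow(r)))
    expect_equal(r$n_cases[i],
                 length(unique(gc$case[gc$gene == r$gene[i]])))
  # permuting case labels leaves the table unchanged
  perm <- setNames(sample(sprintf("c%02d", 1:10)), sprintf("c%02d", 1:10))
  gc2 <- transform(gc, case = perm[case])
  expect_equal(recurrence(gc2, min_cases = 2), r)
})

test_that("case frequencies and per-case means use half-up rounding", {
  expect_equal(case_frequency(9, 20), 45.0)
  expect_equal(case_frequency(7, 20), 35.0)
  expect_equal(case_frequency(0, 20), 0.0)
  expect_equal(case_frequency(1, 3), 33.3)
  expect_equal(mutations_per_case(171, 20), 8.6)  # 8.55 rounds up
  expect_error(case_frequency(5, 0), "> 0")
  expect_error(case_frequency(21, 20), "between")
})

test_that("mutation burden is mutations per megabase", {
  expect_equal(mutation_burden(20, 40), 0.5)
  expect_equal(mutation_burden(0, 40), 0)
  expect_equal(mutation_burden(c(3, 30), 15), c(0.2, 2))
  expect_error(mutation_burden(5, 0), "> 0")
})

test_that("display classes follow the inactivating / non-truncating convention", {
  expect_equal(classify_display(c("frameshift", "missense", "essential_splice",
                                  "nonsense", "inframe_indel", "synonymous")),
               c("black", "green", "black", "black", "green", "green"))
})

test_that("over-representation p equals exhaustive enumeration of draws", {
  universe <- letters[1:10]
  gene_set <- letters[1:5]
  mutated <- letters[1:3]
  p <- overrepresentation(mutated, gene_set, 10)
  # enumerate all C(10,3) draws and count those with overlap >= 3
  draws <- utils::combn(universe, 3)
  overlap3 <- mean(apply(draws, 2, function(d) sum(d %in% gene_set) >= 3))
  expect_equal(p, overlap3)
  expect_equal(round(p, 4), 0.0833)
  # degenerate cases
  expect_equal(overrepresentation(character(0), gene_set, 10), 1.0)
  expect_equal(overrepresentation(mutated, universe, 10), 1.0)
  expect_error(overrepresentation(mutated, gene_set, 0), "non-empty")
})

test_that("coverage summary computes mean and threshold fractions", {
  cs <- coverage_summary(rep(37, 50))
  expect_equal(cs$mean_depth, 37)
  expect_equal(cs$frac_ge_10x, 1.0)
  expect_equal(cs$frac_ge_20x, 1.0)
  cs <- coverage_summary(c(rep(0, 25), rep(40, 25)))
  expect_equal(cs$mean_depth, 20)
  expect_equal(cs$frac_ge_10x, 0.5)
  expect_gte(cs$frac_ge_10x, cs$frac_ge_20x)
  expect_error(coverage_summary(numeric(0)), "empty")
})

test_that("hotspot tallies group by residue across cases", {
  final <- data.frame(
    gene = "PIK3CA", residue = 1047L, case = sprintf("c%02d", 1:8),
    label = c(rep("H1047R", 6), rep("H1047L", 2)),
    human_residue = 1047L,
    human_label = c(rep("H1047R", 6), rep("H1047L", 2)),
    stringsAsFactors = FALSE)
  tal <- hotspot_tally(final)
  expect_equal(nrow(tal), 1)
  expect_equal(tal$n_cases, 8L)
  expect_match(tal$changes, "H1047R:6")
  expect_match(tal$changes, "H1047L:2")
})
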
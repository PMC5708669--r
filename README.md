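# somaticlift

Cohort-level somatic mutation analysis for paired tumor/normal exomes of
a non-human species, interpreted against human cancer knowledge.

The package is aimed at comparative oncogenomics: studies that sequence
tumor/normal pairs in a model species (the motivating setting is canine
hemangiosarcoma, a common splenic endothelial tumor in dogs that
resembles the rare human angiosarcoma) and ask whether the somatic
mutations land on known human cancer drivers. Because the species'
variant databases and annotation resources are thinner than human ones,
the analysis has to do three things carefully: separate somatic from
germline and artifact calls without a deep population resource, annotate
coding consequences against transcript models, and translate mutated
residue positions into human protein coordinates before comparing
against human hotspot catalogs.

## What it implements

* **Somatic discrimination** from paired read counts: a call is somatic
  when the tumor variant allele fraction (VAF) reaches a threshold
  (default 0.10), the normal VAF stays at or below 0.05, and a one-sided
  Fisher exact test on the 2x2 table of alt/ref reads in tumor vs
  normal is significant at 0.05.
* **A decision-tree filter chain**, applied in a fixed order: (1) drop
  non-coding (intergenic, intronic, UTR) and synonymous calls —
  essential splice-site variants are kept; (2) drop known population
  polymorphisms with minor allele frequency >= 0.05; (3) drop anything
  seen in any cohort normal (panel of normals); (4) drop calls with
  tumor depth < 10x. A surrogate for manual read review then removes
  FFPE deamination artifacts: C>T / G>A calls with tumor VAF < 0.10 and
  fewer than 5 supporting reads.
* **Consequence annotation** on toy-scale transcript models (strand
  aware, standard genetic code): missense, nonsense, synonymous,
  frameshift, in-frame indel, and essential splice (the +/-2 intronic
  bases at CDS boundaries).
* **Cross-species ortholog lifting**: an affine-gap Smith-Waterman
  aligner (Gotoh algorithm, BLOSUM62, gap open 11 / extend 1, written in
  C++) aligns each mutated protein to its human counterpart; the pair is
  accepted as orthologous when the Karlin-Altschul E-value
  `E = K m n exp(-lambda * S)` is <= 1e-4, gene symbols match, and
  alignment identity exceeds 70%. Mutated residues are then mapped
  through the aligned columns into human coordinates and looked up in a
  local hotspot phenotype table (gain/loss-of-function labels).
* **Cohort statistics**: per-case mutation loads, recurrently mutated
  genes, per-residue hotspot tallies, mutation burden per megabase
  (including synonymous calls), an oncoprint-style genes x cases matrix
  (green = non-truncating, black = inactivating), coverage summaries,
  and a hypergeometric gene-set over-representation test.
* **A seeded cohort simulator** that generates paired tumor/normal VCFs
  with planted hotspot drivers (PIK3CA-1047-like at 45% of cases,
  TP53 DNA-binding-domain at 35%, rare PTEN/PLCG1 events), Poisson
  passenger and synonymous load, shared germline polymorphisms, low-VAF
  deamination artifacts, and negative-binomial depths with tumor
  coverage designed at twice the normal — so the entire chain is
  testable end to end with a known ground truth.

## Worked example

```r
library(somaticlift)

ref    <- simulate_reference(seed = 7)          # genome, transcripts, protein pairs
cohort <- simulate_cohort(sim_config(seed = 7), ref)
result <- run_pipeline(cohort)
result
#> sl_result: 20 cases, 172 nonsynonymous somatic mutations (160 SNVs, 12 indels)
#>   mean 8.6 per case (range 4-13); burden 0.40-1.53 /Mb incl. synonymous
#>   recurrent genes: DSCAM(14), PIK3CA(13), PLCG1(13), TTN(12), TP53(9)

head(result$hotspots, 4)
#>     gene residue human_residue n_cases         changes
#> 1 PIK3CA    1047          1047       8        H1047R:8
#> 2   TP53     248           248       6         R248W:6
#> 3   PTEN      79           101       3         I101T:3
#> 4 GENE026     184          184       2 M184L:1,M184V:1
```

The hotspot table reads: 8 of 20 tumors carry the planted PIK3CA
codon-1047 change; the PTEN hotspot at canine residue 79 lifts to human
residue 101 (the human protein carries a 22-residue N-terminal
extension), where it matches a `predicted_pathogenic` phenotype record.
The ortholog map behind such a lift:

```r
result$ortholog_maps$PLCG1
#> ortholog_map PLCG1 (canine, 1215 aa) ~ PLCG1 (human, 1287 aa)
#>   score 6738, identity 0.976 (1186/1215 aligned columns), E = 0
#>   accepted
lift_position(result$ortholog_maps$PLCG1, 273L)
#> [1] 345
```

A command-line wrapper with `simulate` and `run` subcommands is
installed under `cli/somaticlift.R` in the package directory:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "somaticlift.R", package = "somaticlift"))')" \
    simulate --outdir demo --seed 5 --cases 4
Rscript ".../cli/somaticlift.R" run --vcf-dir demo/vcf \
    --reference demo/reference --outdir demo/reports
```

## Package layout

* `R/` — simulator, filters, annotation, alignment/lifting, cohort
  statistics, pipeline orchestration
* `src/` — the affine-gap local aligner (Rcpp)
* `inst/cli/` — command-line wrapper; `inst/extdata/` — file-format
  schema and the synthetic phenotype hotspot fixture
* `vignettes/` — methods vignette with the model, parameter and design
  rationale
* `tests/testthat/` — unit, property and acceptance suites
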
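# File schemas

## Paired cohort VCFs (`<case>_tumor.vcf`, `<case>_normal.vcf`)

VCF v4.2, one sample column per file (`<case>_T` / `<case>_N`),
coordinates 1-based inclusive, indels as anchored alleles.

Tumor-file INFO keys:

| key | type | meaning |
|-----|------|---------|
| RC  | String | region class: `coding`, `intronic`, `UTR`, `intergenic` |
| MAF | Float  | population minor allele frequency; absent when the site is not a known polymorphism |
| NDP | Integer | matched-normal read depth at the site |
| NAD | Integer | matched-normal alt read count at the site |

FORMAT: `DP` (depth), `AD` (ref,alt read counts).

The normal file lists only records with read support in the normal
sample; the union of normal files across cases is the panel of normals.

## `truth.tsv`

One row per emitted variant record: `case`, `chrom`, `pos`, `ref`,
`alt`, `category` (`driver` / `passenger` / `synonymous` / `germline` /
`artifact`), `gene` (when coding), `planted_change` (drivers only,
e.g. `H1047R`).

## Reference fixtures

* `transcripts.tsv`: `gene`, `chrom`, `strand` (`+`/`-`), `exons`
  (CDS intervals, ascending genomic order, `start-end;start-end`, 1-based
  inclusive).
* `genome.fa`, `proteins_canine.fa`, `proteins_human.fa`: FASTA keyed by
  chromosome / gene symbol.
* `snp_table.tsv`: `chrom`, `pos`, `ref`, `alt`, `maf`.
* `phenotype_table.tsv`: `gene`, `change` (human coordinates, e.g.
  `H1047R`, `R1798*`), `label` (`GOF`, `LOF`, `dominant_negative`,
  `GOF+DN`, `predicted_pathogenic`), `source`.
* `gene_sets.tsv`: long format, `set`, `gene`.

## Reports

* `audit_trace.tsv`: every input variant with its final verdict
  (`germline`, `reference`, `ambiguous`, `filtered:<filter>`,
  `artifact`, `pass`).
* `filter_trace.tsv`: per variant, the filters evaluated in order with
  `pass`/`fail`; a variant is charged to the first failing filter.
* `per_case_counts.tsv`: per case, nonsynonymous count, coding count
  including synonymous, burden per Mb.
* `recurrence.tsv`, `hotspot_tallies.tsv`, `gene_case_matrix.tsv`
  (values `.` / `green` / `black`), `coverage.tsv`,
  `final_mutations.tsv`, `ortholog_map_<gene>.tsv`, `summary.tsv`.
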
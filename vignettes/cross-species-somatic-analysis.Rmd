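---
title: "Cross-species somatic mutation analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species somatic mutation analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticlift)
```

# The analysis problem

Comparative oncogenomics studies sequence paired tumor/normal exomes in
a model species — here, a canine cohort of hemangiosarcoma, a splenic
endothelial malignancy histologically similar to the rare human
angiosarcoma — and interpret the somatic mutations against human cancer
knowledge. Archival FFPE tissue and a thin population-variant resource
shape the whole analysis: depths are uneven, formalin fixation produces
spurious low-frequency C>T calls, and germline removal leans on the
cohort's own normal samples as much as on SNP databases. Once a curated
somatic set exists, the informative step is cross-species: mutated
residue positions are translated into human protein coordinates by
pairwise alignment, so that canine mutations can be matched against
human hotspot catalogs (a canine PIK3CA His1047Arg is only meaningful
as a driver claim once position 1047 is shown to be the same residue as
the human hotspot).

`somaticlift` implements that chain as testable components: somatic
discrimination, a fixed-order filter chain, consequence annotation,
ortholog lifting, and cohort statistics, plus a seeded simulator that
generates cohorts with known truth so the pipeline's operating
characteristics can be measured rather than assumed.

# Somatic discrimination

For each variant record with tumor counts $(a_T, d_T)$ and normal
counts $(a_N, d_N)$, the caller emulation classifies:

* **somatic** if $a_T/d_T \ge v_T$ and $a_N/d_N \le v_N$ and the
  one-sided Fisher exact test of alt enrichment in tumor
  ($P[X \ge a_T]$ under the hypergeometric distribution of the pooled
  2x2 table) has $p \le \alpha$;
* **germline** if both VAFs are at least $v_T$;
* **reference** if the tumor VAF is below $v_T$;
* **ambiguous** otherwise, including any record with zero depth in
  either sample (not an error — such records simply cannot be judged).

Defaults $v_T = 0.10$, $v_N = 0.05$, $\alpha = 0.05$ sit near the
customary defaults of paired tumor/normal callers; "standard settings"
of such callers are not a published parameter list, so all three are
exposed in `filter_config()`. The Fisher statistic is computed as a
vectorized hypergeometric tail and is tested against `fisher.test()` by
exact enumeration.

# The filter chain

Filters run in a fixed order, and a variant is charged to the first
filter it fails (the audit trace records exactly the filters
evaluated):

1. **region/synonymous** — drop calls outside coding sequence
   (intergenic, intronic, UTR; "intragenic" in input region labels is
   treated as non-coding gene body) and synonymous calls. Essential
   splice-site variants are intronic by position but are *kept*: they
   are part of the inactivating class the analysis reports.
2. **population MAF** — drop calls at known polymorphic sites with
   minor allele frequency $\ge 0.05$. The boundary is excluded at
   exactly 0.05 (a "threshold of 0.05" is read as a removal criterion);
   the convention is configurable.
3. **panel of normals** — drop any variant identity observed in *any*
   cohort normal. This is what guarantees complete germline removal on
   simulated cohorts: every emitted germline record is present in its
   own case's normal by construction.
4. **minimum depth** — drop calls with tumor depth below 10 reads.

The chain is a pure set operation: output is a subset of input,
applying it twice equals applying it once, and tightening any threshold
never enlarges the passing set. These properties are asserted on
randomized inputs in the test suite.

**Artifact surrogate.** The original curation step this replaces is
manual read review in a genome viewer, which cannot be reproduced
offline. The surrogate drops somatic calls that look like FFPE
deamination: C>T or G>A, tumor VAF < 0.10 *and* fewer than 5 supporting
reads. Against the simulator's artifact model the surrogate plus the
caller's VAF threshold remove >= 95% of planted artifacts while never
touching a clonal driver (a call at or above VAF 0.10 is never dropped
by the rule).

# Consequence annotation

Transcript models carry one transcript per gene: ordered CDS intervals
(1-based inclusive, ascending genomic order), strand, and the protein.
At load time every model is validated by translating its CDS
(reverse-complemented for minus-strand genes) and comparing to the
stated protein; a mismatching model is rejected rather than silently
trusted. For an exonic SNV the reference and alternate codons are
translated with the standard genetic code; the residue index is
$\lceil \text{CDS offset}/3 \rceil$. Indels whose length change is not
a multiple of 3 are frameshifts annotated at the first affected residue
(`T56fs` style); in-frame indels are reported separately. The essential
splice class is the canonical +/-2 intronic dinucleotide at each
internal CDS boundary; an indel spanning a CDS/intron boundary is also
classified essential splice (most severe wins). Start-loss (a
substitution removing the initiator methionine) is folded into the
nonsense class for reporting: both predict an inactivated product, and
the display convention (below) only distinguishes inactivating from
non-truncating. Stop-loss cannot arise at toy scale because the stored
CDS excludes the terminal stop codon.

# Ortholog lifting

The aligner is an affine-gap Smith-Waterman (Gotoh) implemented in C++:
a gap of length $g$ costs $o + g e$ with BLOSUM62 and $o = 11$,
$e = 1$ (classic protein-search defaults). Traceback is deterministic
— ties resolve diagonal > up > left and the best cell is the first in
row-major order — so identical inputs always give identical column
pairs. Significance uses the Karlin-Altschul form
$E = K m n e^{-\lambda S}$ with the published gapped parameters for
this scheme ($\lambda = 0.267$, $K = 0.041$); only the E-value
*threshold* (1e-4) is a fixed analysis choice, the statistic's
parameters are configurable.

A protein pair is accepted as orthologous when, checked in order: the
E-value is at most 1e-4; the gene symbols match; and identity is
*strictly* greater than 0.70 ("more than 70%"). Identity is
matches / aligned residue-residue columns — gap columns are excluded
from the denominator. An alternative convention (denominator = full
sequence length) exists in the literature; the aligned-columns choice
is documented here and encoded in one place, because for
high-divergence pairs the two differ materially.

Position lifting maps a canine residue through the aligned columns to
its human partner. Residues aligned opposite a gap, or outside the
local alignment, are reported unmapped rather than extrapolated — a
local alignment asserts homology only where it aligns. The map is
strictly increasing on both sides and is a bijection on its domain
(lifting and reverse lookup round-trip), both asserted at construction
and in tests. On the simulated reference pairs this machinery
reproduces the expected cross-species offsets: the PTEN-like pair
carries a 22-residue human N-terminal extension (canine 79 -> human
101), the PLCG1-like pair a 72-residue internal insertion upstream of
the kinase-domain hotspot (canine 273 -> human 345), and the DSCAM-like
pair a 236-residue offset (canine 1562 -> human 1798).

# Driver annotation and cohort statistics

Lifted changes are looked up in a local phenotype table (gene, human
protein change, functional label, source). An exact hit — same gene,
residue and alternate — returns the record; a hit at the annotated
residue with a different alternate is returned as a `site` tier, which
captures the common situation of a different substitution at a known
hotspot codon. The shipped table is a small synthetic curation of
well-known hotspot labels (PIK3CA 1047/350, a TP53 DNA-binding-domain
set, PTEN 101, PLCG1 345, DSCAM 1798); it is a lookup fixture standing
in for COSMIC/ClinVar-class resources, not a database mirror.

Recurrence ranks genes by the number of *distinct* mutated cases
(minimum 2 by default), ties alphabetical; it is invariant under case
relabeling. Case frequencies and per-case means are rounded half-up at
one decimal (8.55 -> 8.6), matching how such cohort figures are
conventionally printed. Mutation burden divides the per-case coding
mutation count *including synonymous calls* by the captured territory
in megabases — synonymous calls are removed from the driver analysis by
filter 1 but retained for burden, which is why the pipeline reports
both a nonsynonymous total and a with-synonymous total. The
genes-by-cases display matrix uses the oncoprint convention: black for
predicted inactivating classes (nonsense, frameshift, essential
splice), green for other nonsynonymous classes; where a gene/case cell
holds both, black wins. Gene-set over-representation is a plain
hypergeometric upper tail against user-supplied local gene sets;
web-database pathway services are deliberately out of scope because
they are neither offline-reproducible nor versioned.

# The simulator: what it emulates, and what it does not

`sim_config()` defaults define the study conditions the package is
validated under, chosen once to mirror a 20-case FFPE exome cohort:

| parameter | default | rationale |
|---|---|---|
| `n_cases` | 20 | cohort size of the motivating study design |
| `driver_spectrum` | PIK3CA H1047R 0.45; TP53 R248W 0.35; PTEN I79T 0.10; PLCG1 S273F 0.05 | hotspot drivers at the case fractions the analysis is meant to recover |
| `passenger_rate` | 8 /case (Poisson) | with planted drivers, yields a mean nonsynonymous load near 8.6/case and a 0-21 style range |
| `indel_fraction` | 0.10 | minority of passengers as 1 bp frameshift deletions, so indel handling is exercised end to end |
| `synonymous_rate` | 3 /case | roughly the 1:3 synonymous:nonsynonymous ratio of coding SNVs |
| `germline_snp_rate` | 12 /case | shared tumor+normal polymorphisms, 70% drawn from the SNP table (carrying its MAF), 30% private |
| `artifact_rate` | 15 /case | FFPE deamination load; C>T/G>A only, tumor-only, true VAF uniform(0.01, 0.08) |
| `mean_depth_normal` | 37 reads | tumor mean is fixed at twice this (74x), the 2:1 design of tumor-heavy sequencing |
| `depth_dispersion` | 0.3 | negative binomial (var = mu + 0.3 mu^2): FFPE exome coverage is strongly overdispersed; a fixture choice, not an empirical claim |
| `target_region_size` | 15 Mb | effective well-covered callable exome territory; with the default load this puts per-case burden in the 0.1-2 /Mb band typical of low-burden sarcomas. No published per-case target size exists for the motivating design, so this is exposed rather than fixed |

Drivers are planted as the actual codon edit producing the configured
residue change (the first single-base edit, in deterministic order,
that reaches the target residue under the genetic code), with clonal
tumor VAF uniform(0.30, 0.55) and zero normal support. Germline records
are heterozygous (VAF 0.5) or homozygous (VAF 1.0) in both samples. Alt
counts are binomial in the drawn depth; a record is emitted only with
read support (tumor alt > 0; for germline, support in both samples),
and every emitted record has exactly one truth-table row.

The simulator works at the *variant-call* level: it does not model
reads, mapping, base qualities, tumor purity gradients, subclonal
structure, copy number, or multi-nucleotide variants. Consequently,
passing tests demonstrate that the decision logic is correct under the
stated statistical structure — they do not demonstrate robustness to
alignment artifacts, contamination, or purity collapse, which real
FFPE cohorts exhibit and which sit upstream of this package's scope.
One deliberate scale concession matters for interpretation: the toy
transcript set is ~0.15 Mb of coding territory versus ~30 Mb in a real
exome, so passenger mutations hit driver genes far more often than they
would in reality. Driver recovery is therefore measured by the planted
gene *and* protein change (hotspot identity), not by gene-level
mutation presence.

# Validation design and problem sizes

The suite validates at three levels, with sizes chosen to keep the
default run in the low minutes:

* **Oracle equivalence**: the aligner is checked against a brute-force
  enumeration oracle (all monotone matched-pair sets, no dynamic
  programming) on random pairs up to length 6, where enumeration is
  tractable, and against an established local aligner
  (`Biostrings::pairwiseAlignment`) on 1,000 random pairs up to length
  12. The hypergeometric and Fisher statistics are checked against
  exhaustive enumeration and `fisher.test()` respectively.
* **Property suites**: filter idempotence/monotonicity on randomized
  variant tables; alignment symmetry; position-map monotonicity and
  bijectivity; annotation purity and class exclusivity; byte-identical
  reruns of the simulator, pipeline and reports under a fixed seed.
* **Parameter recovery**: 50 seeded 20-case cohorts at the defaults
  above. Expected behavior, all measured in the acceptance suite:
  100% of germline records removed; >= 95% of artifacts removed; 100%
  of planted coding drivers that enter the filter chain with tumor
  depth >= 10 survive it (retention through the chain is structural;
  the discrimination stage in front of it has binomial sensitivity
  < 1 at marginal depth, exactly as a read-count-based caller does, and
  that sensitivity is absorbed by the frequency-recovery criterion);
  and mean recovered driver case frequencies within 3 binomial
  standard errors of the planted fractions.

# Known limitations

* One transcript per gene; no isoform precedence, no UTR-aware
  annotation, no MNVs.
* Ortholog pairing is symbol-driven (as in symbol-matched ortholog
  pipelines); there is no database search step, and paralog confusion
  is out of scope.
* The E-value parameters are fixed constants for the default scoring
  scheme; changing the matrix or gap penalties without updating
  lambda/K makes E-values nominal.
* The phenotype table is a versioned fixture; conclusions about real
  tumors require a real, current hotspot resource.
* Multi-allelic records should be decomposed to biallelic form before
  input; the simulator only emits biallelic records.
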
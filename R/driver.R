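#' Match a lifted mutation against the phenotype table
#'
#' Looks up a human-coordinate protein change in the cancer-phenotype
#' table. An exact hit (same gene, residue and alternate residue)
#' returns the record at tier `"exact"`; a hit at the same residue with
#' a different alternate returns tier `"site"` (a hotspot-position
#' match); otherwise a zero-row frame.
#'
#' @param gene human gene symbol
#' @param residue human residue index (1-based)
#' @param alt_res alternate residue, `"*"` for stop, `"fs"` for frameshift
#' @param db phenotype table (columns `gene`, `change`, `label`, `source`),
#'   e.g. [build_phenotype_table()]
#' @return data.frame rows with `tier`, `change`, `label`, `source`
#' @export
match_phenotype <- function(gene, residue, alt_res, db = build_phenotype_table()) {
  empty <- data.frame(tier = character(0), change = character(0),
                      label = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(gene) || is.na(residue)) return(empty)
  hits <- db[db$gene == gene, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  parsed <- lapply(hits$change, parse_change)
  res <- vapply(parsed, `[[`, integer(1), "residue")
  alt <- vapply(parsed, `[[`, character(1), "alt")
  exact <- res == residue & alt == alt_res
  site <- res == residue & !exact
  if (any(exact))
    data.frame(tier = "exact", change = hits$change[exact],
               label = hits$label[exact], source = hits$source[exact],
               stringsAsFactors = FALSE)
  else if (any(site))
    data.frame(tier = "site", change = hits$change[site],
               label = hits$label[site], source = hits$source[site],
               stringsAsFactors = FALSE)
  else empty
}

#' Recurrently mutated genes
#'
#' Genes mutated in at least `min_cases` distinct cases, ranked by case
#' count (descending), ties broken alphabetically.
#'
#' @param gene_case data.frame with columns `gene` and `case` (one row
#'   per mutation; repeated gene/case pairs count once)
#' @param min_cases minimum number of distinct mutated cases
#' @return data.frame `gene`, `n_cases`
#' @export
recurrence <- function(gene_case, min_cases = 2) {
  gc <- unique(gene_case[!is.na(gene_case$gene), c("gene", "case")])
  counts <- table(gc$gene)
  counts <- counts[counts >= min_cases]
  out <- data.frame(gene = names(counts), n_cases = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0)
    out <- out[order(-out$n_cases, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Case frequency as a percentage
#'
#' @param n_mutated number of mutated cases
#' @param n_cases cohort size (> 0)
#' @return percentage, rounded half-up to one decimal
#' @export
case_frequency <- function(n_mutated, n_cases) {
  if (any(n_cases <= 0)) stop("n_cases must be > 0")
  if (any(n_mutated < 0 | n_mutated > n_cases))
    stop("n_mutated must be between 0 and n_cases")
  round_half_up(100 * n_mutated / n_cases, 1)
}

#' Mean mutations per case
#'
#' @param n_mutations total mutation count
#' @param n_cases cohort size (> 0)
#' @return mean per case, rounded half-up to one decimal
#' @export
mutations_per_case <- function(n_mutations, n_cases) {
  if (any(n_cases <= 0)) stop("n_cases must be > 0")
  round_half_up(n_mutations / n_cases, 1)
}

#' Mutation burden per megabase
#'
#' Mutations (nonsynonymous plus synonymous) divided by the captured
#' territory in megabases.
#'
#' @param n_mutations mutation count (vectorized, e.g. per case)
#' @param target_mb captured territory in megabases (> 0)
#' @return mutations per Mb
#' @export
mutation_burden <- function(n_mutations, target_mb) {
  if (any(target_mb <= 0)) stop("target territory must be > 0 Mb")
  n_mutations / target_mb
}

#' Display class of a mutation (oncoprint convention)
#'
#' `black` marks predicted inactivating mutations — truncating
#' (frameshift), nonsense, and essential splice-site variants; `green`
#' marks non-truncating nonsynonymous variants (possible
#' gain-of-function).
#'
#' @param consequence consequence class vector
#' @return `"black"` or `"green"` per element
#' @export
classify_display <- function(consequence) {
  ifelse(consequence %in% c("nonsense", "frameshift", "essential_splice"),
         "black", "green")
}

#' Gene-set over-representation (hypergeometric tail)
#'
#' Probability of observing at least the seen overlap between the
#' mutated genes and a gene set, drawing `|mutated|` genes without
#' replacement from the universe.
#'
#' @param mutated_genes character vector of mutated gene symbols
#'   (must lie within the universe)
#' @param gene_set character vector, subset of the universe
#' @param universe_size number of genes in the universe (> 0)
#' @return upper-tail hypergeometric p-value
#' @export
overrepresentation <- function(mutated_genes, gene_set, universe_size) {
  if (universe_size <= 0) stop("universe must be non-empty")
  mutated_genes <- unique(mutated_genes)
  gene_set <- unique(gene_set)
  if (length(gene_set) > universe_size || length(mutated_genes) > universe_size)
    stop("gene set and mutated genes must lie within the universe")
  overlap <- length(intersect(mutated_genes, gene_set))
  stats::phyper(overlap - 1, m = length(gene_set),
                n = universe_size - length(gene_set),
                k = length(mutated_genes), lower.tail = FALSE)
}

#' Coverage summary of a depth vector
#'
#' @param depths non-empty vector of per-position read depths
#' @return list: `mean_depth`, `frac_ge_10x`, `frac_ge_20x`
#' @export
coverage_summary <- function(depths) {
  if (length(depths) == 0) stop("empty depth vector")
  list(mean_depth = mean(depths),
       frac_ge_10x = mean(depths >= 10),
       frac_ge_20x = mean(depths >= 20))
}
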
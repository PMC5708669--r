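#' Somatic filter configuration
#'
#' Thresholds for somatic discrimination and the downstream filter
#' chain. Discrimination emulates a paired tumor/normal caller: a call
#' is somatic when the tumor VAF reaches `tumor_vaf_min`, the normal VAF
#' is at most `normal_vaf_max`, and a one-sided Fisher exact test of alt
#' read enrichment in tumor versus normal is significant at
#' `fisher_alpha`. The filter chain then removes non-coding and
#' synonymous calls, known population polymorphisms with minor allele
#' frequency at or above `maf_threshold` (a site at exactly the
#' threshold is removed), anything seen in any cohort normal, and calls
#' with tumor depth below `min_depth`.
#'
#' @param min_depth minimum tumor read depth retained (default 10)
#' @param maf_threshold population MAF at/above which a site is removed
#' @param tumor_vaf_min,normal_vaf_max,fisher_alpha somatic-call thresholds
#' @return a `filter_config` list
#' @export
filter_config <- function(min_depth = 10, maf_threshold = 0.05,
                          tumor_vaf_min = 0.10, normal_vaf_max = 0.05,
                          fisher_alpha = 0.05) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  stopifnot_scalar_prob(maf_threshold, "maf_threshold")
  stopifnot_scalar_prob(tumor_vaf_min, "tumor_vaf_min")
  stopifnot_scalar_prob(normal_vaf_max, "normal_vaf_max")
  stopifnot_scalar_prob(fisher_alpha, "fisher_alpha")
  structure(list(min_depth = min_depth, maf_threshold = maf_threshold,
                 tumor_vaf_min = tumor_vaf_min, normal_vaf_max = normal_vaf_max,
                 fisher_alpha = fisher_alpha),
            class = "filter_config")
}

#' One-sided Fisher exact p for tumor alt-read enrichment
#'
#' Hypergeometric tail probability of observing at least the tumor alt
#' count given the pooled 2x2 table of alt/ref reads in tumor and
#' normal; identical to `fisher.test(..., alternative = "greater")` on
#' the table with rows (tumor, normal) and columns (alt, ref).
#'
#' @param tumor_alt,tumor_depth,normal_alt,normal_depth read counts
#'   (vectorized)
#' @return p-values
#' @export
somatic_fisher_p <- function(tumor_alt, tumor_depth, normal_alt, normal_depth) {
  stats::phyper(tumor_alt - 1,
                m = tumor_alt + normal_alt,
                n = (tumor_depth - tumor_alt) + (normal_depth - normal_alt),
                k = tumor_depth, lower.tail = FALSE)
}

#' Discriminate somatic from germline calls in a tumor/normal pair
#'
#' @param tumor_alt,tumor_depth,normal_alt,normal_depth read counts
#'   (vectorized)
#' @param cfg a [filter_config()]
#' @return character vector: `"somatic"`, `"germline"`, `"reference"` or
#'   `"ambiguous"`. Zero depth in either sample yields `"ambiguous"`.
#' @export
call_somatic <- function(tumor_alt, tumor_depth, normal_alt, normal_depth,
                         cfg = filter_config()) {
  if (any(tumor_alt > tumor_depth | normal_alt > normal_depth, na.rm = TRUE))
    stop("alt counts cannot exceed depths")
  tvaf <- ifelse(tumor_depth > 0, tumor_alt / tumor_depth, NA_real_)
  nvaf <- ifelse(normal_depth > 0, normal_alt / normal_depth, NA_real_)
  p <- somatic_fisher_p(tumor_alt, tumor_depth, normal_alt, normal_depth)
  status <- rep("ambiguous", length(tumor_alt))
  zero <- tumor_depth == 0 | normal_depth == 0
  germ <- !zero & tvaf >= cfg$tumor_vaf_min & nvaf >= cfg$tumor_vaf_min
  som <- !zero & !germ & tvaf >= cfg$tumor_vaf_min &
    nvaf <= cfg$normal_vaf_max & p <= cfg$fisher_alpha
  refc <- !zero & !germ & !som & tvaf < cfg$tumor_vaf_min
  status[germ] <- "germline"
  status[som] <- "somatic"
  status[refc] <- "reference"
  status
}

# fixed filter order of the decision tree
filter_names <- c("region_or_synonymous", "population_maf",
                  "panel_of_normals", "min_depth")

#' Apply the somatic filter chain
#'
#' Runs the four filters in their fixed order on annotated somatic
#' calls: (1) remove calls outside coding regions and synonymous calls
#' (essential splice variants, though intronic, are retained); (2)
#' remove known population polymorphisms with `db_maf >=
#' maf_threshold`; (3) remove any variant identity observed in any
#' cohort normal (panel of normals); (4) remove calls with tumor depth
#' below `min_depth`. A variant is charged to the first filter it
#' fails; later filters are not evaluated for it.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `region_class`, `consequence`, `db_maf` (NA when the site is not a
#'   known polymorphism) and `tumor_depth`
#' @param panel_of_normals character vector of `chrom:pos:ref:alt`
#'   identities seen in cohort normals (see [panel_of_normals()])
#' @param cfg a [filter_config()]
#' @return list with `pass` (surviving rows of `variants`), `trace`
#'   (long data.frame: variant, filter, verdict) and `final`
#'   (per-variant final status: `"pass"` or the failing filter)
#' @export
apply_filters <- function(variants, panel_of_normals = character(0),
                          cfg = filter_config()) {
  n <- nrow(variants)
  if (n == 0L) {
    return(list(pass = variants,
                trace = data.frame(variant = character(0), filter = character(0),
                                   verdict = character(0)),
                final = character(0)))
  }
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  noncoding <- !(variants$region_class %in% "coding") &
    !(variants$consequence %in% "essential_splice")
  fails <- cbind(
    region_or_synonymous = noncoding |
      variants$consequence %in% c("synonymous", "none"),
    population_maf = !is.na(variants$db_maf) & variants$db_maf >= cfg$maf_threshold,
    panel_of_normals = key %in% panel_of_normals,
    min_depth = variants$tumor_depth < cfg$min_depth
  )
  first_fail <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w)) w[1] else NA_integer_
  })
  final <- ifelse(is.na(first_fail), "pass", filter_names[first_fail])
  evaluated <- ifelse(is.na(first_fail), length(filter_names), first_fail)
  trace <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- evaluated[i]
    data.frame(variant = key[i], filter = filter_names[seq_len(k)],
               verdict = c(rep("pass", k - (final[i] != "pass")),
                           if (final[i] != "pass") "fail"),
               stringsAsFactors = FALSE)
  }))
  list(pass = variants[final == "pass", , drop = FALSE],
       trace = trace, final = final)
}

#' Deamination artifact surrogate filter
#'
#' FFPE fixation deaminates cytosine, producing spurious low-VAF C>T
#' (and, read on the other strand, G>A) calls. This rule stands in for
#' manual read review: a somatic call is dropped when it is a C>T or
#' G>A substitution supported by fewer than `alt_min` tumor reads at a
#' tumor VAF below `vaf_min`.
#'
#' @param variants data.frame with `ref`, `alt`, `tumor_alt`, `tumor_depth`
#' @param vaf_min tumor VAF at/above which a call is never dropped
#' @param alt_min tumor alt read count at/above which a call is never dropped
#' @return logical vector, `TRUE` = keep
#' @export
artifact_filter <- function(variants, vaf_min = 0.10, alt_min = 5) {
  deamination <- (variants$ref == "C" & variants$alt == "T") |
    (variants$ref == "G" & variants$alt == "A")
  tvaf <- ifelse(variants$tumor_depth > 0,
                 variants$tumor_alt / variants$tumor_depth, 0)
  !(deamination & tvaf < vaf_min & variants$tumor_alt < alt_min)
}

#' Panel of normals from a cohort
#'
#' The union of variant identities observed in any normal sample of the
#' cohort; any somatic candidate matching the panel is removed by
#' filter 3 (this removes all shared germline polymorphisms, including
#' those below the population-MAF threshold).
#'
#' @param calls cohort call data.frame with logical column `in_normal`
#' @return character vector of `chrom:pos:ref:alt` identities
#' @export
panel_of_normals <- function(calls) {
  normals <- calls[calls$in_normal, , drop = FALSE]
  unique(variant_key(normals$chrom, normals$pos, normals$ref, normals$alt))
}
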
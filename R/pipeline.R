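#' Run the somatic analysis pipeline on a cohort
#'
#' Executes the full chain on paired tumor/normal calls: somatic
#' discrimination, consequence annotation, the four-step filter chain,
#' the deamination-artifact surrogate, cross-species ortholog lifting of
#' mutated residues into human coordinates, phenotype-table annotation,
#' and cohort summaries (per-case loads, recurrence, hotspot tallies,
#' burden per megabase, oncoprint-style display classes, coverage).
#'
#' @param cohort an [simulate_cohort()] object; alternatively pass
#'   `vcf_dir` plus `reference`
#' @param vcf_dir directory of paired VCFs (see [read_cohort_vcfs()])
#' @param reference an `sl_reference` bundle; taken from `cohort` when omitted
#' @param fcfg a [filter_config()]
#' @param scoring an [alignment_scoring()] for the ortholog alignments
#' @param criteria an [ortholog_acceptance()]
#' @param artifact_vaf_min,artifact_alt_min [artifact_filter()] thresholds
#' @param min_recurrence minimum cases for the recurrence table
#' @param ortholog_maps optional precomputed list of [ortholog_map()]s
#'   keyed by gene symbol (they depend only on the reference, so they
#'   can be shared across cohorts); computed when omitted
#' @param target_region_size captured territory (bases) for burden;
#'   taken from the cohort config when omitted
#' @param outdir if non-NULL, reports are written there ([write_reports()])
#' @return an `sl_result` list: `final` (passing mutations with canine
#'   and human annotation), `audit`, `filter_trace`, `per_case`,
#'   `recurrence`, `hotspots`, `matrix`, `ortholog_maps`, `coverage`,
#'   `summary`
#' @export
run_pipeline <- function(cohort = NULL, vcf_dir = NULL, reference = NULL,
                         fcfg = filter_config(),
                         scoring = alignment_scoring(),
                         criteria = ortholog_acceptance(),
                         artifact_vaf_min = 0.10, artifact_alt_min = 5,
                         min_recurrence = 2, target_region_size = NULL,
                         ortholog_maps = NULL, outdir = NULL) {
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "sl_cohort"))
    calls <- cohort$calls
    reference <- reference %||% cohort$reference
    target_region_size <- target_region_size %||%
      cohort$config$target_region_size
    cases <- cohort$cases
  } else {
    if (is.null(vcf_dir) || is.null(reference))
      stop("supply either `cohort`, or `vcf_dir` together with `reference`")
    calls <- read_cohort_vcfs(vcf_dir)
    target_region_size <- target_region_size %||% 15e6
    cases <- sort(unique(calls$case))
  }
  target_mb <- target_region_size / 1e6

  status <- call_somatic(calls$tumor_alt, calls$tumor_depth,
                         calls$normal_alt, calls$normal_depth, fcfg)
  verdict <- ifelse(status == "somatic", NA_character_, status)

  som <- calls[status == "somatic", , drop = FALSE]
  ann <- annotate_variants(reference$transcripts, som)
  pon <- panel_of_normals(calls)
  fl <- apply_filters(ann, pon, fcfg)
  keep <- rep(FALSE, nrow(ann))
  passed <- fl$final == "pass"
  keep[passed] <- artifact_filter(ann[passed, , drop = FALSE],
                                  artifact_vaf_min, artifact_alt_min)
  som_verdict <- ifelse(passed,
                        ifelse(keep, "pass", "artifact"),
                        paste0("filtered:", fl$final))
  verdict[status == "somatic"] <- som_verdict
  audit <- data.frame(calls[c("case", "chrom", "pos", "ref", "alt")],
                      verdict = verdict, stringsAsFactors = FALSE)

  final <- ann[keep, , drop = FALSE]

  # burden set: coding calls including synonymous, subject to the
  # population-MAF, panel-of-normals, depth and artifact rules
  akey <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  burden_keep <- (ann$region_class %in% "coding" |
                    ann$consequence %in% "essential_splice") &
    !(ann$consequence %in% "none") &
    !(!is.na(ann$db_maf) & ann$db_maf >= fcfg$maf_threshold) &
    !(akey %in% pon) &
    ann$tumor_depth >= fcfg$min_depth &
    artifact_filter(ann, artifact_vaf_min, artifact_alt_min)
  burden_set <- ann[burden_keep, , drop = FALSE]

  # ortholog lifting for mutated genes
  genes <- sort(unique(final$gene[!is.na(final$gene)]))
  maps <- ortholog_maps %||% list()
  for (g in genes) {
    if (is.null(maps[[g]]) &&
        g %in% names(reference$proteins_canine) &&
        g %in% names(reference$proteins_human))
      maps[[g]] <- ortholog_map(reference$proteins_canine[[g]],
                                reference$proteins_human[[g]],
                                g, g, scoring, criteria)
  }
  final$human_residue <- rep(NA_integer_, nrow(final))
  for (i in seq_len(nrow(final))) {
    g <- final$gene[i]
    if (!is.na(g) && !is.null(maps[[g]]) && isTRUE(maps[[g]]$accepted) &&
        !is.na(final$residue[i]))
      final$human_residue[i] <- lift_position(maps[[g]], final$residue[i])
  }
  final$human_label <- ifelse(
    is.na(final$human_residue), NA_character_,
    ifelse(final$consequence == "essential_splice", "splice",
           paste0(final$ref_res, final$human_residue, final$alt_res)))
  final$display <- classify_display(final$consequence)

  ph <- lapply(seq_len(nrow(final)), function(i) {
    hit <- match_phenotype(final$gene[i], final$human_residue[i],
                           final$alt_res[i], reference$phenotype)
    if (nrow(hit) == 0)
      data.frame(pheno_tier = NA_character_, pheno_label = NA_character_,
                 pheno_source = NA_character_, stringsAsFactors = FALSE)
    else
      data.frame(pheno_tier = hit$tier[1], pheno_label = hit$label[1],
                 pheno_source = hit$source[1], stringsAsFactors = FALSE)
  })
  final <- cbind(final, if (length(ph)) do.call(rbind, ph) else
    data.frame(pheno_tier = character(0), pheno_label = character(0),
               pheno_source = character(0)))
  rownames(final) <- NULL

  per_case <- data.frame(
    case = cases,
    n_nonsynonymous = as.integer(table(factor(final$case, levels = cases))),
    n_coding_total = as.integer(table(factor(burden_set$case, levels = cases))),
    stringsAsFactors = FALSE)
  per_case$burden_per_mb <- mutation_burden(per_case$n_coding_total, target_mb)

  rec <- recurrence(final, min_cases = min_recurrence)

  hot <- hotspot_tally(final)
  mat <- display_matrix(final, cases)
  cov <- cohort_coverage(calls, cases)

  n_snv <- sum(is_snv(final$ref, final$alt))
  summary <- list(
    n_cases = length(cases),
    n_nonsynonymous = nrow(final),
    n_snv = n_snv,
    n_indel = nrow(final) - n_snv,
    n_coding_incl_synonymous = nrow(burden_set),
    mean_per_case = mutations_per_case(nrow(final), length(cases)),
    load_range = range(per_case$n_nonsynonymous),
    burden_range = range(per_case$burden_per_mb),
    target_region_mb = target_mb)

  res <- structure(list(final = final, audit = audit, filter_trace = fl$trace,
                        burden_set = burden_set, per_case = per_case,
                        recurrence = rec, hotspots = hot, matrix = mat,
                        ortholog_maps = maps, coverage = cov,
                        summary = summary, cases = cases),
                   class = "sl_result")
  if (!is.null(outdir)) write_reports(res, outdir)
  res
}

#' Precompute ortholog maps for a reference
#'
#' Aligns every canine/human protein pair of the reference once;
#' the resulting list can be passed to [run_pipeline()] and shared
#' across cohorts built on the same reference.
#'
#' @param reference an `sl_reference`
#' @param scoring an [alignment_scoring()]
#' @param criteria an [ortholog_acceptance()]
#' @param genes gene symbols to align (default: all shared symbols)
#' @return named list of [ortholog_map()]s
#' @export
build_ortholog_maps <- function(reference, scoring = alignment_scoring(),
                                criteria = ortholog_acceptance(), genes = NULL) {
  genes <- genes %||% intersect(names(reference$proteins_canine),
                                names(reference$proteins_human))
  maps <- lapply(genes, function(g)
    ortholog_map(reference$proteins_canine[[g]], reference$proteins_human[[g]],
                 g, g, scoring, criteria))
  stats::setNames(maps, genes)
}

#' Per-residue hotspot tallies across cases
#'
#' Groups mutations by gene and (canine) residue and counts distinct
#' mutated cases, listing the observed protein changes (in human
#' coordinates where lifted).
#'
#' @param final data.frame with columns `gene`, `residue`, `case`,
#'   `label` and optionally `human_residue` / `human_label`
#' @return data.frame `gene`, `residue`, `human_residue`, `n_cases`,
#'   `changes`, ranked by case count
#' @export
hotspot_tally <- function(final) {
  if (is.null(final$human_label)) final$human_label <- NA_character_
  if (is.null(final$human_residue)) final$human_residue <- NA_integer_
  f <- final[!is.na(final$gene), , drop = FALSE]
  if (nrow(f) == 0)
    return(data.frame(gene = character(0), residue = integer(0),
                      human_residue = integer(0), n_cases = integer(0),
                      changes = character(0), stringsAsFactors = FALSE))
  key <- paste(f$gene, f$residue, sep = ":")
  out <- do.call(rbind, lapply(split(f, key), function(d) {
    lab <- table(ifelse(is.na(d$human_label), d$label, d$human_label))
    data.frame(gene = d$gene[1], residue = d$residue[1],
               human_residue = d$human_residue[1],
               n_cases = length(unique(d$case)),
               changes = paste(sprintf("%s:%d", names(lab), as.integer(lab)),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_cases, out$gene, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# genes x cases character matrix: "." / "green" / "black" (black wins)
display_matrix <- function(final, cases) {
  genes <- sort(unique(final$gene[!is.na(final$gene)]))
  mat <- matrix(".", nrow = length(genes), ncol = length(cases),
                dimnames = list(genes, cases))
  for (i in seq_len(nrow(final))) {
    g <- final$gene[i]
    if (is.na(g)) next
    cur <- mat[g, final$case[i]]
    mat[g, final$case[i]] <-
      if (cur == "black" || final$display[i] == "black") "black" else "green"
  }
  mat
}

cohort_coverage <- function(calls, cases) {
  out <- do.call(rbind, lapply(cases, function(id) {
    cc <- calls[calls$case == id, , drop = FALSE]
    if (nrow(cc) == 0)
      return(data.frame(case = id, tumor_mean_depth = NA_real_,
                        normal_mean_depth = NA_real_,
                        tumor_frac_ge_10x = NA_real_, tumor_frac_ge_20x = NA_real_,
                        stringsAsFactors = FALSE))
    tc <- coverage_summary(cc$tumor_depth)
    nc <- coverage_summary(cc$normal_depth)
    data.frame(case = id, tumor_mean_depth = tc$mean_depth,
               normal_mean_depth = nc$mean_depth,
               tumor_frac_ge_10x = tc$frac_ge_10x,
               tumor_frac_ge_20x = tc$frac_ge_20x,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write pipeline reports
#'
#' Tab-separated reports: audit trace (`audit_trace.tsv`, every input
#' variant with its final verdict), filter trace, per-case counts and
#' burden, recurrence table, hotspot tallies, the genes-by-cases display
#' matrix, coverage summary, per-gene ortholog maps, and a key-value
#' `summary.tsv`.
#'
#' @param result an `sl_result`
#' @param outdir output directory (created if needed)
#' @return invisibly, `outdir`
#' @export
write_reports <- function(result, outdir) {
  stopifnot(inherits(result, "sl_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(result$audit, "audit_trace.tsv")
  wt(result$filter_trace, "filter_trace.tsv")
  wt(result$per_case, "per_case_counts.tsv")
  wt(result$recurrence, "recurrence.tsv")
  wt(result$hotspots, "hotspot_tallies.tsv")
  wt(result$final, "final_mutations.tsv")
  wt(result$coverage, "coverage.tsv")
  mat <- data.frame(gene = rownames(result$matrix), result$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wt(mat, "gene_case_matrix.tsv")
  for (g in names(result$ortholog_maps))
    write_ortholog_map(result$ortholog_maps[[g]],
                       file.path(outdir, sprintf("ortholog_map_%s.tsv", g)))
  s <- result$summary
  kv <- data.frame(
    key = c("n_cases", "n_nonsynonymous", "n_snv", "n_indel",
            "n_coding_incl_synonymous", "mean_per_case", "load_min", "load_max",
            "burden_min_per_mb", "burden_max_per_mb", "target_region_mb"),
    value = c(s$n_cases, s$n_nonsynonymous, s$n_snv, s$n_indel,
              s$n_coding_incl_synonymous, s$mean_per_case, s$load_range,
              s$burden_range, s$target_region_mb),
    stringsAsFactors = FALSE)
  wt(kv, "summary.tsv")
  invisible(outdir)
}

#' @export
print.sl_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("sl_result: %d cases, %d nonsynonymous somatic mutations (%d SNVs, %d indels)\n",
              s$n_cases, s$n_nonsynonymous, s$n_snv, s$n_indel))
  cat(sprintf("  mean %.1f per case (range %d-%d); burden %.2f-%.2f /Mb incl. synonymous\n",
              s$mean_per_case, s$load_range[1], s$load_range[2],
              s$burden_range[1], s$burden_range[2]))
  if (nrow(x$recurrence)) {
    top <- utils::head(x$recurrence, 5)
    cat("  recurrent genes:",
        paste(sprintf("%s(%d)", top$gene, top$n_cases), collapse = ", "), "\n")
  }
  invisible(x)
}
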
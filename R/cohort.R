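#' Simulate a paired tumor/normal variant cohort
#'
#' Generates per-case tumor/normal variant call sets with the
#' statistical structure the downstream analysis assumes:
#'
#' * hotspot drivers planted as the exact codon change yielding the
#'   configured residue change, in a Bernoulli-sampled case subset,
#'   with clonal tumor VAF and no normal support;
#' * Poisson passenger (nonsynonymous) and synonymous coding mutations;
#' * germline polymorphisms shared by tumor and normal at VAF ~0.5
#'   (heterozygous) or ~1.0 (homozygous), partly drawn from the
#'   population SNP table (carrying its MAF), partly private;
#' * FFPE deamination artifacts: tumor-only C>T / G>A calls with true
#'   VAF uniform on (0.01, 0.08), below the somatic-call VAF threshold.
#'
#' Read depths are negative binomial (tumor mean twice the normal
#' mean); alt counts are binomial in the drawn depth around the true
#' VAF. A record is emitted only when it has read support (alt > 0 in
#' tumor; for germline, in both samples), and every emitted record has
#' exactly one truth-table row.
#'
#' @param config a [sim_config()]
#' @param reference an [simulate_reference()] bundle; built from
#'   `config$seed` when omitted
#' @return an `sl_cohort`: list with `calls` (one row per emitted
#'   tumor-side record), `truth` (case, locus, alleles, category, gene,
#'   planted protein change), `config`, `reference`
#' @export
simulate_cohort <- function(config = sim_config(), reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(reference)) reference <- simulate_reference(seed = config$seed)
  spectrum <- config$driver_spectrum
  if (nrow(spectrum) > 0) {
    missing <- setdiff(spectrum$gene, names(reference$transcripts))
    if (length(missing))
      stop(sprintf("driver gene(s) absent from transcript set: %s",
                   paste(missing, collapse = ", ")))
  }
  set.seed(config$seed)
  cases <- sprintf("case%02d", seq_len(config$n_cases))

  rows <- list()
  for (ci in seq_along(cases)) {
    id <- cases[ci]
    ev <- list()
    if (nrow(spectrum) > 0) {
      carry <- stats::runif(nrow(spectrum)) < spectrum$fraction
      for (k in which(carry)) {
        tx <- reference$transcripts[[spectrum$gene[k]]]
        v <- plant_protein_change(tx, spectrum$change[k])
        ev[[length(ev) + 1L]] <- data.frame(
          case = id, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          category = "driver", gene = tx$gene, planted_change = spectrum$change[k],
          region_class = "coding", db_maf = NA_real_,
          true_vaf = stats::runif(1, 0.30, 0.55), germline_vaf = 0,
          stringsAsFactors = FALSE)
      }
    }
    ev[[length(ev) + 1L]] <- draw_coding_events(
      reference, id, stats::rpois(1, config$passenger_rate),
      want = c("missense", "nonsense", "frameshift"), category = "passenger",
      indel_fraction = config$indel_fraction)
    ev[[length(ev) + 1L]] <- draw_coding_events(
      reference, id, stats::rpois(1, config$synonymous_rate),
      want = "synonymous", category = "synonymous")
    ev[[length(ev) + 1L]] <- draw_germline(reference, id,
                                           stats::rpois(1, config$germline_snp_rate))
    ev[[length(ev) + 1L]] <- draw_artifacts(reference, id,
                                            stats::rpois(1, config$artifact_rate))
    ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
    if (!is.null(ev) && nrow(ev) > 0) {
      ev <- ev[!duplicated(ev[c("chrom", "pos")]), , drop = FALSE]
      rows[[ci]] <- ev
    }
  }
  events <- do.call(rbind, rows)
  if (is.null(events)) events <- empty_events()

  n <- nrow(events)
  size <- 1 / config$depth_dispersion
  tumor_depth <- stats::rnbinom(n, size = size, mu = 2 * config$mean_depth_normal)
  normal_depth <- stats::rnbinom(n, size = size, mu = config$mean_depth_normal)
  tumor_alt <- stats::rbinom(n, tumor_depth, events$true_vaf)
  normal_alt <- stats::rbinom(n, normal_depth, events$germline_vaf)

  calls <- data.frame(
    case = events$case, chrom = events$chrom, pos = events$pos,
    ref = events$ref, alt = events$alt,
    tumor_depth = tumor_depth, tumor_alt = tumor_alt,
    normal_depth = normal_depth, normal_alt = normal_alt,
    region_class = events$region_class, db_maf = events$db_maf,
    in_normal = events$category == "germline" & normal_alt > 0,
    stringsAsFactors = FALSE)
  emitted <- ifelse(events$category == "germline",
                    tumor_alt > 0 & normal_alt > 0, tumor_alt > 0)
  calls <- calls[emitted, , drop = FALSE]
  truth <- data.frame(case = events$case, chrom = events$chrom, pos = events$pos,
                      ref = events$ref, alt = events$alt,
                      category = events$category, gene = events$gene,
                      planted_change = events$planted_change,
                      stringsAsFactors = FALSE)[emitted, , drop = FALSE]
  rownames(calls) <- rownames(truth) <- NULL

  structure(list(calls = calls, truth = truth, config = config,
                 reference = reference, cases = cases),
            class = "sl_cohort")
}

empty_events <- function() {
  data.frame(case = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), category = character(0),
             gene = character(0), planted_change = character(0),
             region_class = character(0), db_maf = numeric(0),
             true_vaf = numeric(0), germline_vaf = numeric(0),
             stringsAsFactors = FALSE)
}

# parse "H1047R" / "R1562*" / "T56fs" into components
parse_change <- function(change) {
  m <- regmatches(change, regexec("^([A-Z])([0-9]+)(fs|\\*|[A-Z])$", change))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse protein change '%s'", change))
  list(ref = m[2], residue = as.integer(m[3]), alt = m[4])
}

# construct the VCF record that produces `change` on transcript `tx`.
# For substitutions the first single-base codon edit (position, then
# A<C<G<T) reaching the target residue is used; frameshifts are planted
# as a 1 bp deletion in the target codon.
plant_protein_change <- function(tx, change) {
  pc <- parse_change(change)
  if (pc$residue < 1 || pc$residue > nchar(tx$protein))
    stop(sprintf("residue %d outside %s protein", pc$residue, tx$gene))
  if (substr(tx$protein, pc$residue, pc$residue) != pc$ref)
    stop(sprintf("%s residue %d is %s, not %s", tx$gene, pc$residue,
                 substr(tx$protein, pc$residue, pc$residue), pc$ref))
  chrom_len <- NULL
  if (pc$alt == "fs") {
    off <- 3L * (pc$residue - 1L) + 2L
    g <- genomic_pos(tx, off)
    # anchored 1 bp deletion; anchor is the genomically previous base
    return(list(chrom = tx$chrom, pos = g - 1L,
                ref = paste0(base_at(tx, g - 1L), base_at(tx, g)),
                alt = base_at(tx, g - 1L)))
  }
  codon <- substr(tx$cds, 3L * pc$residue - 2L, 3L * pc$residue)
  for (cpos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, cpos, cpos) == b) next
      cand <- codon
      substr(cand, cpos, cpos) <- b
      if (translate_codon(cand) == pc$alt) {
        off <- 3L * (pc$residue - 1L) + cpos
        g <- genomic_pos(tx, off)
        ref_b <- substr(codon, cpos, cpos)
        if (tx$strand == "-") { ref_b <- dna_complement(ref_b); b <- dna_complement(b) }
        return(list(chrom = tx$chrom, pos = g, ref = ref_b, alt = b))
      }
    }
  }
  stop(sprintf("no single-base edit of %s codon %d yields %s",
               tx$gene, pc$residue, pc$alt))
}

# genomic base from the stored exon content (exonic) — used for anchors
base_at <- function(tx, pos) {
  off <- cds_offset(tx, pos)
  if (is.na(off)) stop("base_at needs an exonic position")
  b <- substr(tx$cds, off, off)
  if (tx$strand == "-") b <- dna_complement(b)
  b
}

draw_coding_events <- function(reference, id, n, want, category,
                               indel_fraction = 0, max_try = 50L) {
  if (n == 0) return(NULL)
  cp <- reference$coding_positions
  out <- vector("list", n)
  for (i in seq_len(n)) {
    as_indel <- stats::runif(1) < indel_fraction
    for (t in seq_len(max_try)) {
      j <- sample.int(nrow(cp), 1)
      if (as_indel) {
        # anchored 1 bp deletion of the base after the sampled position
        chrom_seq <- reference$genome[[cp$chrom[j]]]
        if (cp$pos[j] + 1L > length(chrom_seq)) next
        ref <- as.character(Biostrings::subseq(chrom_seq, cp$pos[j], cp$pos[j] + 1L))
        alt <- substr(ref, 1L, 1L)
      } else {
        ref <- cp$ref[j]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      }
      ann <- annotate_variant(reference$transcripts, cp$chrom[j], cp$pos[j],
                              ref, alt)
      ok <- if (as_indel) ann$consequence == "frameshift"
            else ann$consequence %in% setdiff(want, "frameshift")
      if (ok) {
        out[[i]] <- data.frame(case = id, chrom = cp$chrom[j], pos = cp$pos[j],
                               ref = ref, alt = alt, category = category,
                               gene = ann$gene, planted_change = NA_character_,
                               region_class = "coding", db_maf = NA_real_,
                               true_vaf = stats::runif(1, 0.15, 0.50),
                               germline_vaf = 0, stringsAsFactors = FALSE)
        break
      }
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

draw_germline <- function(reference, id, n) {
  if (n == 0) return(NULL)
  from_db <- stats::runif(n) < 0.7
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (from_db[i]) {
      s <- reference$snp_table[sample.int(nrow(reference$snp_table), 1), ]
      chrom <- s$chrom; pos <- s$pos; ref <- s$ref; alt <- s$alt; maf <- s$maf
    } else {
      chrom <- sample(names(reference$genome), 1)
      pos <- sample.int(Biostrings::width(reference$genome)[
        match(chrom, names(reference$genome))], 1)
      ref <- as.character(Biostrings::subseq(reference$genome[[chrom]], pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      maf <- NA_real_
    }
    vaf <- if (stats::runif(1) < 0.8) 0.5 else 1.0
    out[[i]] <- data.frame(case = id, chrom = chrom, pos = pos, ref = ref,
                           alt = alt, category = "germline", gene = NA_character_,
                           planted_change = NA_character_,
                           region_class = classify_position(reference, chrom, pos),
                           db_maf = maf, true_vaf = vaf, germline_vaf = vaf,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

draw_artifacts <- function(reference, id, n) {
  if (n == 0) return(NULL)
  cp <- reference$coding_positions
  eligible <- which(cp$ref %in% c("C", "G"))
  j <- sample(eligible, n, replace = TRUE)
  data.frame(case = id, chrom = cp$chrom[j], pos = cp$pos[j], ref = cp$ref[j],
             alt = ifelse(cp$ref[j] == "C", "T", "A"), category = "artifact",
             gene = cp$gene[j], planted_change = NA_character_,
             region_class = "coding", db_maf = NA_real_,
             true_vaf = stats::runif(n, 0.01, 0.08), germline_vaf = 0,
             stringsAsFactors = FALSE)
}

#' Region class of a genomic position
#'
#' `coding` inside a CDS interval, `intronic` between CDS intervals of a
#' gene, `UTR` within 200 bp of the gene's CDS span, else `intergenic`.
#'
#' @param reference an `sl_reference`
#' @param chrom,pos position
#' @return one of `"coding"`, `"intronic"`, `"UTR"`, `"intergenic"`
#' @export
classify_position <- function(reference, chrom, pos) {
  for (tx in reference$transcripts) {
    if (tx$chrom != chrom) next
    if (!is.na(cds_offset(tx, pos))) return("coding")
    if (pos >= tx$span[1] && pos <= tx$span[2]) return("intronic")
    if (pos >= tx$span[1] - 200L && pos <= tx$span[2] + 200L) return("UTR")
  }
  "intergenic"
}
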
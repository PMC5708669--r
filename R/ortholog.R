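#' Ortholog acceptance criteria
#'
#' A candidate canine/human protein pair is accepted as an ortholog when
#' its best local alignment has E-value at or below `evalue_max`, the two
#' gene symbols match (case-insensitive), and alignment identity is
#' strictly greater than `identity_min`. Identity is computed as
#' matches / aligned residue-residue columns (gap columns excluded).
#'
#' @param evalue_max maximum E-value for a significant match
#' @param identity_min identity fraction that must be exceeded (strict)
#' @param require_symbol_match require identical gene symbols
#' @return an `ortholog_acceptance` list
#' @export
ortholog_acceptance <- function(evalue_max = 1e-4, identity_min = 0.70,
                                require_symbol_match = TRUE) {
  if (evalue_max <= 0) stop("evalue_max must be > 0")
  if (identity_min <= 0 || identity_min > 1) stop("identity_min must be in (0, 1]")
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 require_symbol_match = isTRUE(require_symbol_match)),
            class = "ortholog_acceptance")
}

#' Build a cross-species ortholog map for one protein pair
#'
#' Aligns a canine protein against its human counterpart
#' (Smith-Waterman, affine gaps), scores the pair against the acceptance
#' criteria, and derives the residue-level position map used to lift
#' mutated canine positions into human coordinates. Only
#' residue-residue columns of the local alignment enter the position
#' map; canine residues aligned opposite a gap, or outside the local
#' alignment, are unmappable.
#'
#' @param canine_seq,human_seq protein sequences (character strings)
#' @param canine_symbol,human_symbol gene symbols of the two proteins
#' @param scoring an [alignment_scoring()] scheme
#' @param criteria an [ortholog_acceptance()] object
#' @return an `ortholog_map`: symbols, alignment columns, `identity`,
#'   `score`, `evalue`, `accepted`, `reject_reason`, and `map`, a
#'   data.frame of (`canine_pos`, `human_pos`) pairs
#' @export
ortholog_map <- function(canine_seq, human_seq, canine_symbol, human_symbol,
                         scoring = alignment_scoring(),
                         criteria = ortholog_acceptance()) {
  aln <- smith_waterman(canine_seq, human_seq, scoring)
  cols <- aln$columns
  paired <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  ca <- strsplit(toupper(canine_seq), "", fixed = TRUE)[[1]]
  hu <- strsplit(toupper(human_seq), "", fixed = TRUE)[[1]]
  n_paired <- sum(paired)
  n_match <- if (n_paired > 0)
    sum(ca[cols$a_pos[paired]] == hu[cols$b_pos[paired]]) else 0L
  identity <- if (n_paired > 0) n_match / n_paired else 0
  ev <- evalue(aln$score, nchar(canine_seq), nchar(human_seq), scoring)

  map <- data.frame(canine_pos = cols$a_pos[paired],
                    human_pos = cols$b_pos[paired])
  # aligned columns are emitted in increasing order on both sequences
  stopifnot(!is.unsorted(map$canine_pos, strictly = TRUE),
            !is.unsorted(map$human_pos, strictly = TRUE))

  out <- structure(list(
    canine_symbol = canine_symbol, human_symbol = human_symbol,
    canine_length = nchar(canine_seq), human_length = nchar(human_seq),
    columns = cols, identity = identity, n_matches = n_match,
    n_aligned = n_paired, score = aln$score, evalue = ev,
    map = map, accepted = NA, reject_reason = NA_character_
  ), class = "ortholog_map")
  verdict <- accept_ortholog(out, criteria)
  out$accepted <- verdict$accepted
  out$reject_reason <- verdict$reason
  out
}

#' Apply ortholog acceptance criteria
#'
#' Criteria are checked in a fixed order (E-value, symbol, identity) and
#' a rejection reports the first failing criterion. The identity bound
#' is strict: a pair at exactly `identity_min` is rejected.
#'
#' @param map an [ortholog_map()] object
#' @param criteria an [ortholog_acceptance()] object
#' @return list with `accepted` (logical) and `reason`
#'   (`NA` when accepted; otherwise `"evalue"`, `"symbol"` or `"identity"`)
#' @export
accept_ortholog <- function(map, criteria = ortholog_acceptance()) {
  stopifnot(inherits(map, "ortholog_map"))
  if (map$evalue > criteria$evalue_max)
    return(list(accepted = FALSE, reason = "evalue"))
  if (criteria$require_symbol_match &&
      toupper(map$canine_symbol) != toupper(map$human_symbol))
    return(list(accepted = FALSE, reason = "symbol"))
  if (map$identity <= criteria$identity_min)
    return(list(accepted = FALSE, reason = "identity"))
  list(accepted = TRUE, reason = NA_character_)
}

#' Lift a canine residue position into human coordinates
#'
#' @param map an accepted [ortholog_map()]
#' @param canine_pos 1-based residue index (vectorized) in the canine protein
#' @return integer vector of human residue indices; `NA` where the canine
#'   residue is aligned to a gap or falls outside the local alignment
#' @export
lift_position <- function(map, canine_pos) {
  stopifnot(inherits(map, "ortholog_map"))
  if (!isTRUE(map$accepted))
    stop(sprintf("ortholog pair %s/%s was not accepted (%s); positions cannot be lifted",
                 map$canine_symbol, map$human_symbol, map$reject_reason))
  if (any(canine_pos < 1 | canine_pos > map$canine_length))
    stop("canine residue index outside the protein")
  map$map$human_pos[match(canine_pos, map$map$canine_pos)]
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map %s (canine, %d aa) ~ %s (human, %d aa)\n",
              x$canine_symbol, x$canine_length, x$human_symbol, x$human_length))
  cat(sprintf("  score %.0f, identity %.3f (%d/%d aligned columns), E = %.3g\n",
              x$score, x$identity, x$n_matches, x$n_aligned, x$evalue))
  cat(if (isTRUE(x$accepted)) "  accepted\n"
      else sprintf("  rejected (%s)\n", x$reject_reason))
  invisible(x)
}

# write one map as the tab-separated exchange format:
# a summary line then (canine_pos, human_pos) pairs
write_ortholog_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#summary\tscore=%g\tidentity=%g\tevalue=%g\taccepted=%s",
                     map$score, map$identity, map$evalue, map$accepted), con)
  writeLines("canine_pos\thuman_pos", con)
  if (nrow(map$map))
    writeLines(paste(map$map$canine_pos, map$map$human_pos, sep = "\t"), con)
  invisible(path)
}
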
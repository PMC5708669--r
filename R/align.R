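#' Protein alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw local-alignment scores
#' into E-values. Defaults are the classic BLASTp scheme: BLOSUM62 with
#' gap open 11 / extend 1, and the gapped Karlin-Altschul parameters
#' lambda = 0.267, K = 0.041 published for that scheme.
#'
#' A gap of length g is charged `gap_open + g * gap_extend`.
#'
#' @param matrix symmetric substitution matrix with residue dimnames;
#'   defaults to BLOSUM62 as shipped with Biostrings
#' @param gap_open,gap_extend positive gap penalties
#' @param lambda,K positive Karlin-Altschul parameters for [evalue()]
#' @return an `alignment_scoring` list
#' @export
alignment_scoring <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                              lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- blosum62()
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must be square with identical row/col names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "alignment_scoring")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two protein sequences under an affine gap
#' model (Gotoh algorithm, implemented in C++). Traceback is
#' deterministic: ties resolve diagonal > up > left, and the
#' highest-scoring cell is the first reached in row-major order.
#'
#' @param a,b protein sequences (single character strings, residues drawn
#'   from the scoring matrix alphabet)
#' @param scoring an [alignment_scoring()] scheme
#' @return a list with `score` and `columns`, a data.frame of aligned
#'   column pairs (`a_pos`, `b_pos`, 1-based; `NA` marks a gap)
#' @export
smith_waterman <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(inherits(scoring, "alignment_scoring"))
  ai <- encode_residues(a, scoring$matrix, "a")
  bi <- encode_residues(b, scoring$matrix, "b")
  res <- .sw_align_cpp(ai, bi, scoring$matrix,
                       as.numeric(scoring$gap_open),
                       as.numeric(scoring$gap_extend))
  cols <- data.frame(
    a_pos = ifelse(res$a_pos == 0L, NA_integer_, res$a_pos),
    b_pos = ifelse(res$b_pos == 0L, NA_integer_, res$b_pos)
  )
  list(score = res$score, columns = cols)
}

encode_residues <- function(x, mat, arg) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop(sprintf("sequence `%s` must be a non-empty character string", arg))
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, rownames(mat))
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stop(sprintf("sequence `%s` contains characters outside the scoring alphabet: %s",
                 arg, paste(bad, collapse = ", ")))
  }
  idx
}

#' Karlin-Altschul expectation value
#'
#' E-value of a local alignment score for a search space of an
#' m-residue query against an n-residue subject:
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score raw alignment score (>= 0)
#' @param m,n sequence lengths
#' @param scoring an [alignment_scoring()] scheme supplying lambda and K
#' @return the expectation value (numeric scalar)
#' @export
evalue <- function(score, m, n, scoring = alignment_scoring()) {
  if (any(score < 0)) stop("score must be >= 0")
  scoring$K * m * n * exp(-scoring$lambda * score)
}
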
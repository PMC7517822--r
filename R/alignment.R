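#' @importFrom Biostrings pairwiseAlignment score pattern subject
#' @importFrom methods as
NULL

.check_alpha <- function(x, type) {
  if (type == "dna") {
    bad <- grepl("[^ACGTN]", x)
    if (any(bad)) stop("sequence contains characters outside {A,C,G,T,N}")
  }
}

.new_alignment <- function(aligned_a, aligned_b, score,
                           a_start, a_end, b_start, b_end, a_len, b_len) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  mm <- which(both & ca != cb)
  structure(list(
    aligned_a = aligned_a, aligned_b = aligned_b, score = score,
    a_start = a_start, a_end = a_end, b_start = b_start, b_end = b_end,
    a_len = a_len, b_len = b_len,
    mismatch_columns = data.frame(column = mm - 1L, base_a = ca[mm],
                                  base_b = cb[mm], stringsAsFactors = FALSE)
  ), class = "dgr_alignment")
}

#' @export
print.dgr_alignment <- function(x, ...) {
  cat(sprintf("<dgr_alignment> score %s, %d columns, %d mismatches\n",
              format(x$score), nchar(x$aligned_a), nrow(x$mismatch_columns)))
  invisible(x)
}

.pa_to_alignment <- function(pa, a, b) {
  .new_alignment(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    a_start = BiocGenerics::start(Biostrings::pattern(pa)) - 1L,
    a_end = BiocGenerics::end(Biostrings::pattern(pa)),
    b_start = BiocGenerics::start(Biostrings::subject(pa)) - 1L,
    b_end = BiocGenerics::end(Biostrings::subject(pa)),
    a_len = nchar(a), b_len = nchar(b))
}

.align <- function(a, b, scheme, type) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  .check_alpha(c(a, b), scheme$type)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = type,
    substitutionMatrix = scheme$matrix,
    gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend))
  .pa_to_alignment(pa, a, b)
}

#' Optimal global (Needleman-Wunsch) pairwise alignment
#'
#' Affine-gap global alignment of two sequences. A gap run of length L costs
#' `gap_open + L * gap_extend`. Mismatch columns (gap-free columns where the
#' two residues differ) are reported with 0-based column indices.
#'
#' @param a,b nonempty character scalars (DNA over A/C/G/T/N, or protein).
#' @param scheme a [scoring_scheme()]; default [dna_scheme()].
#' @return a `dgr_alignment` with elements `aligned_a`, `aligned_b`, `score`,
#'   0-based half-open spans `a_start`..`b_end`, input lengths and
#'   `mismatch_columns`.
#' @export
global_align <- function(a, b, scheme = dna_scheme()) {
  .align(a, b, scheme, "global")
}

#' Optimal local (Smith-Waterman) pairwise alignment
#'
#' Local counterpart of [global_align()]. When no positive-scoring pair of
#' substrings exists, an empty alignment with score 0 is returned.
#' @inheritParams global_align
#' @return a `dgr_alignment`; `score >= 0` always.
#' @export
local_align <- function(a, b, scheme = dna_scheme()) {
  aln <- .align(a, b, scheme, "local")
  if (aln$score <= 0) {
    aln <- .new_alignment("", "", 0, 0L, 0L, 0L, 0L, nchar(a), nchar(b))
    aln$aligned_a <- ""
    aln$aligned_b <- ""
  }
  aln
}

.aln_counts <- function(alignment) {
  ca <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  list(gapfree = sum(both), matches = sum(both & ca == cb))
}

#' Percent identity of an alignment
#'
#' Two denominator conventions are exposed: `"columns"` divides matches by the
#' number of gap-free columns (used for TR/VR and remote-target identity);
#' `"shorter"` divides by the length of the shorter input sequence (the CD-HIT
#' convention, used for clustering).
#'
#' @param alignment a `dgr_alignment`.
#' @param mode `"columns"` or `"shorter"`.
#' @return fraction in [0, 1].
#' @export
percent_identity <- function(alignment, mode = c("columns", "shorter")) {
  mode <- match.arg(mode)
  cnt <- .aln_counts(alignment)
  den <- if (mode == "columns") cnt$gapfree else min(alignment$a_len,
                                                     alignment$b_len)
  if (den == 0) stop("zero denominator in percent_identity")
  cnt$matches / den
}

#' Reverse complement of a DNA string
#' @param x DNA character scalar.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
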
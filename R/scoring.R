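#' Scoring schemes for pairwise alignment
#'
#' A scoring scheme bundles match/mismatch scores (or a substitution matrix)
#' with affine gap penalties. A gap run of length L costs
#' `gap_open + L * gap_extend` (both stored as non-positive integers).
#'
#' @param match positive match score (DNA schemes only).
#' @param mismatch negative mismatch score (DNA schemes only).
#' @param gap_open non-positive gap opening penalty.
#' @param gap_extend non-positive per-base gap extension penalty.
#' @param type `"dna"` or `"protein"`.
#' @param matrix substitution matrix for protein schemes (defaults to BLOSUM62).
#' @return an object of class `dgr_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, type = c("dna", "protein"),
                           matrix = NULL) {
  type <- match.arg(type)
  stopifnot(gap_open <= 0, gap_extend <= 0)
  if (type == "dna") {
    stopifnot(match > mismatch)
    letters5 <- c("A", "C", "G", "T", "N")
    mat <- base::matrix(as.numeric(mismatch), 5, 5,
                        dimnames = list(letters5, letters5))
    diag(mat) <- as.numeric(match)
    # N never counts as a match
    mat["N", "N"] <- as.numeric(mismatch)
  } else {
    if (is.null(matrix)) {
      mat <- .blosum62()
    } else {
      mat <- matrix
    }
  }
  structure(list(type = type, match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 matrix = mat),
            class = "dgr_scheme")
}

.blosum62_env <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_env$m <- e$BLOSUM62
  }
  .blosum62_env$m
}

#' Default DNA scoring scheme (BLAST-like: +2/-3, gaps -5/-2)
#' @export
dna_scheme <- function() scoring_scheme(2L, -3L, -5L, -2L, "dna")

#' Default protein scoring scheme (BLOSUM62, gaps -11/-1)
#' @export
protein_scheme <- function() scoring_scheme(type = "protein",
                                            gap_open = -11L, gap_extend = -1L)

#' Mild DNA scheme used for remote-homology scans (+1/-1, gaps -2/-1)
#'
#' With this scheme a local alignment has positive expected score exactly when
#' identity exceeds 50%, matching the remote-VP designation threshold.
#' @export
remote_scheme <- function() scoring_scheme(1L, -1L, -2L, -1L, "dna")
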
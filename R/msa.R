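# Center-star progressive multiple alignment and threshold consensus.
# A lightweight stand-in for an external multiple aligner: adequate for the
# small, highly similar sets (RT/CLec paralogs) this package handles.

#' Center-star multiple sequence alignment
#'
#' Picks the sequence with the highest summed pairwise identity to all others
#' as the center, aligns every other sequence to it globally, and merges the
#' pairwise alignments by the "once a gap, always a gap" rule.
#'
#' @param seqs character vector (optionally named) of >= 1 sequence.
#' @param scheme scoring scheme; default [dna_scheme()] for DNA input,
#'   pass [protein_scheme()] for proteins.
#' @return character vector of equal-length aligned rows, same order and names
#'   as the input; removing `-` from row i reproduces `seqs[i]`.
#' @export
star_msa <- function(seqs, scheme = NULL) {
  if (length(seqs) == 0) stop("star_msa: empty sequence set")
  if (any(!nzchar(seqs))) stop("star_msa: empty sequence")
  if (is.null(scheme)) {
    scheme <- if (all(!grepl("[^ACGTN]", seqs))) dna_scheme() else protein_scheme()
  }
  n <- length(seqs)
  if (n == 1) return(stats::setNames(as.character(seqs), names(seqs)))
  # center choice by summed pairwise identity
  idsum <- numeric(n)
  alns <- vector("list", n * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(seqs[[i]], seqs[[j]], scheme)
      pid <- percent_identity(aln, "columns")
      idsum[i] <- idsum[i] + pid
      idsum[j] <- idsum[j] + pid
    }
  }
  center <- which.max(idsum)
  L <- nchar(seqs[[center]])
  others <- setdiff(seq_len(n), center)
  pair <- lapply(others, function(i) global_align(seqs[[center]], seqs[[i]],
                                                  scheme))
  # ins[[k]][p] = gap columns inserted before center position p (p = 1..L+1)
  ins_of <- function(aln) {
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    ins <- integer(L + 1L)
    p <- 1L
    for (ch in ca) {
      if (ch == "-") ins[p] <- ins[p] + 1L else p <- p + 1L
    }
    ins
  }
  ins_list <- lapply(pair, ins_of)
  master <- Reduce(pmax, ins_list, integer(L + 1L))
  pad <- function(block, width) paste0(block, strrep("-", width - nchar(block)))
  center_chars <- strsplit(seqs[[center]], "", fixed = TRUE)[[1]]
  build_center <- paste0(
    paste0(strrep("-", master[seq_len(L)]), center_chars, collapse = ""),
    strrep("-", master[L + 1L]))
  build_row <- function(aln, ins) {
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    out <- character(L + 1L)
    blocks <- character(L + 1L)  # residues of b in the insertion block before p
    col <- 1L
    p <- 1L
    buf <- ""
    body <- character(L)
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        buf <- paste0(buf, cb[k])
      } else {
        blocks[p] <- buf
        buf <- ""
        body[p] <- cb[k]
        p <- p + 1L
      }
    }
    blocks[L + 1L] <- buf
    paste0(paste0(vapply(seq_len(L), function(p)
      paste0(pad(blocks[p], master[p]), body[p]), ""), collapse = ""),
      pad(blocks[L + 1L], master[L + 1L]))
  }
  rows <- character(n)
  rows[center] <- build_center
  for (k in seq_along(others)) {
    rows[others[k]] <- build_row(pair[[k]], ins_list[[k]])
  }
  stats::setNames(rows, names(seqs))
}

#' Threshold consensus of a multiple alignment
#'
#' Per column: if the gap fraction is >= `threshold` the column is dropped;
#' otherwise the residue whose frequency among non-gap symbols is >=
#' `threshold` is emitted, or `"X"` when no residue reaches it.
#'
#' @param msa character vector of equal-length aligned rows.
#' @param threshold fraction in (0.5, 1]; default 0.75.
#' @return consensus sequence (character scalar).
#' @export
consensus_sequence <- function(msa, threshold = 0.75) {
  if (length(msa) == 0) stop("consensus of empty alignment")
  if (length(unique(nchar(msa))) != 1) stop("alignment rows differ in length")
  stopifnot(threshold > 0.5, threshold <= 1)
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gap_frac <- mean(col == "-")
    if (gap_frac >= threshold) next
    res <- col[col != "-"]
    tab <- sort(table(res), decreasing = TRUE)
    out <- c(out, if (tab[1] / length(res) >= threshold) names(tab)[1] else "X")
  }
  paste0(out, collapse = "")
}

#' Read an aligned FASTA file (gap character `-`)
#' @param path file path.
#' @return named character vector of equal-length rows.
#' @export
read_aligned_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(toupper(as.character(x)), names(x))
  if (length(rows) && length(unique(nchar(rows))) != 1)
    stop("aligned FASTA rows differ in length")
  rows
}

#' Write an aligned FASTA file
#' @param msa named character vector of aligned rows.
#' @param path output path.
#' @export
write_aligned_fasta <- function(msa, path) {
  x <- Biostrings::BStringSet(msa)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
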
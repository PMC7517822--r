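# Near-repeat discovery around an RT anchor: exact k-mer seeding, colinear
# chaining, then local realignment of the padded candidate intervals. An
# exhaustive all-substring-pair scan exists in the test suite as the oracle.

.overlap_len <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- .overlap_len(s1, e1, s2, e2)
  if (ov == 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# chain seed hits (i, j) lying on nearby diagonals into candidate blocks.
# i, j are 0-based offsets; diag = j - i is constant along an ungapped repeat
# in either orientation (see .find_pairs_orient).
.chain_hits <- function(i, j, k, max_gap = 120L) {
  if (length(i) == 0) return(list())
  d <- j - i
  o <- order(d, i)
  i <- i[o]; j <- j[o]; d <- d[o]
  # seeds of a substitution-driven repeat share one exact diagonal in either
  # orientation; chain runs of seeds per diagonal, breaking on gaps > max_gap.
  # Small indels shift the diagonal and simply yield several chains whose
  # padded realignments converge on the same pair (de-duplicated later).
  chains <- list()
  for (g in split(seq_along(i), d)) {
    gi <- i[g]; gj <- j[g]
    sub <- cumsum(c(TRUE, diff(gi) > max_gap))
    for (s in split(seq_along(gi), sub)) {
      chains[[length(chains) + 1L]] <- list(
        i0 = gi[s[1]], i1 = gi[s[length(s)]] + k,
        j0 = min(gj[s]), j1 = max(gj[s]) + k)
    }
  }
  chains
}

.kmer_hits <- function(qseq, sseq, k, max_occ = 25L) {
  nq <- nchar(qseq); ns <- nchar(sseq)
  if (nq < k || ns < k) return(list(i = integer(), j = integer()))
  kq <- substring(qseq, 1:(nq - k + 1), k:nq)
  ks <- if (identical(qseq, sseq)) kq else substring(sseq, 1:(ns - k + 1), k:ns)
  keep_q <- !grepl("N", kq, fixed = TRUE)
  idx_s <- split(seq_along(ks), ks)
  occ <- lengths(idx_s)
  idx_s <- idx_s[occ <= max_occ]
  qpos <- which(keep_q)
  hit <- idx_s[kq[qpos]]
  nh <- lengths(hit)
  ii <- rep.int(qpos, nh)
  jj <- unlist(hit, use.names = FALSE)
  if (is.null(jj)) jj <- integer(0)
  list(i = ii - 1L, j = jj - 1L)  # 0-based offsets
}

# candidate repeat pairs in one orientation within a window sequence.
# orient "+": both copies on the forward strand; hits are (i, j) with j > i.
# orient "-": copy2 is the reverse complement; j indexes revcomp(wseq), and
# j - i is again constant along a repeat.
.find_pairs_orient <- function(wseq, orient, config, pad = 30L) {
  n <- nchar(wseq)
  k <- as.integer(config$seed_k)
  if (orient == "+") {
    h <- .kmer_hits(wseq, wseq, k)
    keep <- h$j > h$i
    h$i <- h$i[keep]; h$j <- h$j[keep]
  } else {
    h <- .kmer_hits(wseq, revcomp(wseq), k)
  }
  chains <- .chain_hits(h$i, h$j, k)
  min_span <- max(4L * k, as.integer(0.4 * config$min_repeat_len))
  out <- list()
  for (ch in chains) {
    if (ch$i1 - ch$i0 < min_span) next
    a0 <- max(0L, ch$i0 - pad); a1 <- min(n, ch$i1 + pad)
    if (orient == "+") {
      b0 <- max(0L, ch$j0 - pad); b1 <- min(n, ch$j1 + pad)
    } else {
      # map revcomp offsets back to forward coordinates
      b0 <- max(0L, n - (ch$j1) - pad); b1 <- min(n, n - ch$j0 + pad)
    }
    if (a0 >= b0) next  # canonical order: copy1 before copy2
    a_seq <- substr(wseq, a0 + 1L, a1)
    b_fwd <- substr(wseq, b0 + 1L, b1)
    b_seq <- if (orient == "+") b_fwd else revcomp(b_fwd)
    if (!nzchar(a_seq) || !nzchar(b_seq)) next
    aln <- local_align(a_seq, b_seq, dna_scheme())
    if (aln$score <= 0) next
    c1 <- c(a0 + aln$a_start, a0 + aln$a_end)
    c2 <- if (orient == "+") c(b0 + aln$b_start, b0 + aln$b_end)
          else c(b1 - aln$b_end, b1 - aln$b_start)
    out[[length(out) + 1L]] <- list(c1 = c1, c2 = c2, orient = orient,
                                    alignment = aln)
  }
  out
}

#' Find near-identical repeat pairs in the proximal region of an RT gene
#'
#' Scans the window `anchor +/- window_bp` (clipped at contig ends) for pairs
#' of near-identical intervals in either relative orientation, by exact
#' k-mer seeding, colinear chaining and local realignment. Overlapping
#' candidates are de-duplicated keeping the longest; windows of >10% N are
#' skipped.
#'
#' @param genome assembly ([Biostrings::DNAStringSet]).
#' @param anchor one-row gene feature (the RT candidate gene).
#' @param config [detect_config()].
#' @return list of `dgr_repeat_pair` objects with elements contig,
#'   `copy1`/`copy2` (0-based half-open contig intervals, copy1 leftmost),
#'   orient (`"+"` forward/forward, `"-"` forward/reverse-complement),
#'   alignment, identity ("columns" mode) and length (aligned columns).
#' @export
find_near_repeats <- function(genome, anchor, config = detect_config()) {
  contig <- anchor$contig
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  clen <- Biostrings::width(genome)[match(contig, names(genome))]
  ws <- max(0L, anchor$start - config$window_bp)
  we <- min(clen, anchor$end + config$window_bp)
  wseq <- as.character(Biostrings::subseq(genome[[contig]], ws + 1L, we))
  cands <- c(.find_pairs_orient(wseq, "+", config),
             .find_pairs_orient(wseq, "-", config))
  pairs <- list()
  for (cd in cands) {
    w1 <- cd$c1[2] - cd$c1[1]; w2 <- cd$c2[2] - cd$c2[1]
    if (min(w1, w2) < config$min_repeat_len) next
    if (min(w1, w2) > config$max_repeat_len) next
    if (.overlap_len(cd$c1[1], cd$c1[2], cd$c2[1], cd$c2[2]) > 0) next
    s1 <- substr(wseq, cd$c1[1] + 1L, cd$c1[2])
    s2 <- substr(wseq, cd$c2[1] + 1L, cd$c2[2])
    nfrac <- function(s) {
      n <- nchar(s)
      if (n == 0) 1 else (n - nchar(gsub("N", "", s, fixed = TRUE))) / n
    }
    if (nfrac(s1) > 0.1 || nfrac(s2) > 0.1) next
    pid <- percent_identity(cd$alignment, "columns")
    if (pid < config$near_identity_range[1]) next
    pairs[[length(pairs) + 1L]] <- structure(list(
      contig = contig,
      copy1 = c(ws + cd$c1[1], ws + cd$c1[2]),
      copy2 = c(ws + cd$c2[1], ws + cd$c2[2]),
      orient = cd$orient, alignment = cd$alignment, identity = pid,
      length = nchar(cd$alignment$aligned_a)), class = "dgr_repeat_pair")
  }
  if (length(pairs) <= 1) return(pairs)
  # de-duplicate: keep the longest among mutually overlapping pairs
  ord <- order(-vapply(pairs, function(p) p$length, numeric(1)))
  kept <- list()
  for (p in pairs[ord]) {
    dup <- any(vapply(kept, function(q)
      .reciprocal_overlap(p$copy1[1], p$copy1[2], q$copy1[1], q$copy1[2]) >= 0.5 &&
      .reciprocal_overlap(p$copy2[1], p$copy2[2], q$copy2[1], q$copy2[2]) >= 0.5,
      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept[order(vapply(kept, function(p) p$copy1[1], numeric(1)))]
}
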
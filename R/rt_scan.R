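#' Detection configuration
#'
#' Thresholds of the cassette-detection procedure. The printed thresholds of
#' the method are the 10-kbp proximal window (RT +/- 5 kbp), the > 80%
#' TR-adenine mismatch rule, and repeat lengths of roughly 100-200 bp; the
#' remaining knobs are package defaults documented in the methods vignette.
#'
#' @param window_bp bases scanned on each side of the RT gene (default 5000).
#' @param min_repeat_len,max_repeat_len accepted repeat copy lengths (bp).
#' @param near_identity_range identity interval regarded as "near-identical";
#'   exact repeats are retained but cannot pass the mismatch floor.
#' @param adenine_fraction_min TR-adenine mismatch fraction; pass is strict `>`.
#' @param codon12_fraction_min 1st+2nd codon-position fraction; pass is `>=`.
#' @param min_mismatches minimum mismatch count for the signature to be
#'   meaningful (exact repeats therefore never pass).
#' @param three_prime_fraction terminal fraction of a CDS counted as "near 3'".
#' @param seed_k exact seed length for the repeat search.
#' @param rt_min_score minimum local-alignment score (BLOSUM62, gaps -11/-1)
#'   of a translated CDS against the RT consensus to call an RT candidate.
#' @param clec_min_score minimum C-terminal score against the CLec consensus
#'   for remote-target candidacy when no domain annotation is supplied.
#' @param remote_identity_min TR identity at/above which a dispersed CLec gene
#'   is a remote VP (below: VP homolog).
#' @param remote_coverage_min minimum aligned fraction of TR length for a
#'   remote hit to be scored directly from the local alignment.
#' @return a `dgr_detect_config` list.
#' @export
detect_config <- function(window_bp = 5000L, min_repeat_len = 80L,
                          max_repeat_len = 250L,
                          near_identity_range = c(0.75, 0.995),
                          adenine_fraction_min = 0.8,
                          codon12_fraction_min = 2 / 3,
                          min_mismatches = 4L,
                          three_prime_fraction = 0.25,
                          seed_k = 8L, rt_min_score = 200,
                          clec_min_score = 60,
                          remote_identity_min = 0.5,
                          remote_coverage_min = 0.5) {
  stopifnot(window_bp > max_repeat_len, min_repeat_len > 0,
            max_repeat_len >= min_repeat_len,
            near_identity_range[1] >= 0.5, near_identity_range[2] <= 1,
            adenine_fraction_min >= 0, adenine_fraction_min <= 1,
            codon12_fraction_min >= 0, codon12_fraction_min <= 1,
            min_mismatches >= 1, three_prime_fraction > 0,
            three_prime_fraction <= 1, seed_k >= 4)
  structure(as.list(environment()), class = "dgr_detect_config")
}

.extdata <- function(file) {
  system.file("extdata", file, package = "dgrscan", mustWork = TRUE)
}

.read_single_faa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  toupper(as.character(x[[1]]))
}

#' Bundled reverse-transcriptase consensus (synthetic stand-in)
#'
#' A synthetic consensus protein standing in for a cyanobacterial DGR-RT
#' consensus; it carries canonical RT motif blocks (NTP-binding lysine,
#' \code{[LIVM]PQG}, catalytic \code{[YF]xDD}). Supply your own consensus for
#' real-genome scans via the `consensus` argument of [scan_rt_candidates()].
#' @return protein character scalar.
#' @export
rt_consensus <- function() .read_single_faa(.extdata("rt_consensus_synthetic.faa"))

#' Bundled C-terminal CLec-like consensus (synthetic stand-in)
#' @return protein character scalar.
#' @export
clec_consensus <- function() .read_single_faa(.extdata("clec_consensus_synthetic.faa"))

.rt_motifs <- c(ntp_binding = "KG[A-Z]{2}R",
                domain_b = "[LIVM]PQG",
                catalytic = "[YF][A-Z]DD")

#' Count RT core motif blocks in a protein
#'
#' Counts how many of the bundled NTP-binding / polymerase motif blocks match
#' the protein (0-3). Reported per candidate as a quick plausibility check.
#' @param protein protein character scalar.
#' @return integer count.
#' @export
count_rt_motifs <- function(protein) {
  sum(vapply(.rt_motifs, function(p) grepl(p, protein), logical(1)))
}

# translate a CDS feature tolerantly: trailing partial codon dropped (flagged)
.translate_feature <- function(genome, feature) {
  s <- extract_cds(genome, feature)
  flag <- nchar(s) %% 3 != 0
  if (flag) s <- substr(s, 1L, nchar(s) - nchar(s) %% 3)
  p <- translate_dna(s)
  list(protein = sub("\\*$", "", p), partial = flag)
}

# batch variant: translate many CDS features in one Biostrings call
.translate_features <- function(genome, features) {
  n <- nrow(features)
  if (n == 0) return(list(protein = character(0), partial = logical(0)))
  seqs <- vapply(seq_len(n), function(i)
    extract_cds(genome, features[i, ]), "")
  partial <- nchar(seqs) %% 3 != 0
  seqs <- substr(seqs, 1L, nchar(seqs) - nchar(seqs) %% 3)
  ok <- nzchar(seqs)
  prots <- character(n)
  if (any(ok)) {
    prots[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(seqs[ok]), if.fuzzy.codon = "X"))
  }
  list(protein = sub("\\*$", "", prots), partial = partial)
}

#' Scan annotated CDS features for DGR reverse-transcriptase candidates
#'
#' Each CDS is translated and locally aligned (BLOSUM62, gaps -11/-1) against
#' an RT consensus; genes scoring at least `config$rt_min_score` are returned
#' sorted by descending score, each with its RT motif-block count.
#'
#' @param genes gene feature table.
#' @param genome assembly ([Biostrings::DNAStringSet]).
#' @param config [detect_config()].
#' @param consensus RT consensus protein (default the bundled synthetic one).
#' @return data.frame with columns gene_id, contig, start, end, strand,
#'   score, motif_hits, partial_cds; zero rows when nothing scores.
#' @export
scan_rt_candidates <- function(genes, genome, config = detect_config(),
                               consensus = rt_consensus()) {
  empty <- data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), motif_hits = integer(),
                      partial_cds = logical(), stringsAsFactors = FALSE)
  cds <- genes[genes$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(empty)
  scheme <- protein_scheme()
  tr <- .translate_features(genome, cds)
  ok <- nzchar(tr$protein)
  if (!any(ok)) return(empty)
  scores <- rep(-Inf, nrow(cds))
  scores[ok] <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(tr$protein[ok]), consensus, type = "local",
    substitutionMatrix = scheme$matrix, gapOpening = abs(scheme$gap_open),
    gapExtension = abs(scheme$gap_extend), scoreOnly = TRUE)
  hit <- which(scores >= config$rt_min_score)
  if (length(hit) == 0) return(empty)
  out <- data.frame(gene_id = cds$id[hit], contig = cds$contig[hit],
                    start = cds$start[hit], end = cds$end[hit],
                    strand = cds$strand[hit], score = scores[hit],
                    motif_hits = vapply(tr$protein[hit], count_rt_motifs,
                                        integer(1), USE.NAMES = FALSE),
                    partial_cds = tr$partial[hit], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
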
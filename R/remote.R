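# Dispersed-target discovery: CLec-candidate genes scanned for TR homology.
# Genes with >= 50% nucleotide identity to the cassette TR over at least half
# the TR length are remote VPs; CLec candidates below that are VP homologs.

.is_clec_domain <- function(domain_name) {
  grepl("clec|lectin", domain_name, ignore.case = TRUE)
}

#' Classify a remote-target candidate by TR identity
#'
#' @param identity best TR nucleotide identity (fraction).
#' @param threshold designation threshold (default 0.5).
#' @param inclusive use `>=` (the default, the operative definition) or
#'   strict `>`.
#' @return `"remote_VP"` or `"VP_homolog"`.
#' @export
classify_remote <- function(identity, threshold = 0.5, inclusive = TRUE) {
  hit <- if (inclusive) identity >= threshold else identity > threshold
  if (hit) "remote_VP" else "VP_homolog"
}

# best TR hit inside a CDS. A permissive local alignment (match +1,
# mismatch -1) only locates the homologous region; the reported identity is
# then the ungapped base-by-base identity of the full TR laid on the hit
# diagonal. Mutagenic retrohoming substitutes bases without indels, and any
# optimal gapped alignment of ~40%-identical DNA inflates "columns" identity
# well past 50%, so the ungapped diagonal is the faithful measure for the
# remote-VP designation. Both TR orientations are tried.
.tr_hit_in_cds <- function(tr_seq, cds_seq, config) {
  tr_len <- nchar(tr_seq)
  best <- NULL
  for (orient in c("+", "-")) {
    tr <- if (orient == "+") tr_seq else revcomp(tr_seq)
    loc <- local_align(cds_seq, tr, remote_scheme())
    if (loc$score <= 0) next
    # the local alignment may harbor small indels that shift its start off the
    # dominant diagonal; test anchors from both ends of the hit, with jitter
    anchors <- unique(as.vector(outer(
      c(loc$a_start - loc$b_start, loc$a_end - loc$b_end), -3:3, "+")))
    tr_all <- strsplit(tr, "", fixed = TRUE)[[1]]
    for (anchor in anchors) {
      s <- max(0L, anchor)
      e <- min(nchar(cds_seq), anchor + tr_len)
      ov <- e - s
      if (ov < config$remote_coverage_min * tr_len) next
      tr_chars <- tr_all[(s - anchor + 1L):(e - anchor)]
      cds_chars <- strsplit(substr(cds_seq, s + 1L, e), "", fixed = TRUE)[[1]]
      hit <- list(identity = sum(tr_chars == cds_chars) / ov,
                  cds_span = c(s, e),
                  orient = orient, coverage = ov / tr_len)
      if (is.null(best) || hit$identity > best$identity) best <- hit
    }
  }
  best
}

#' Find remote variable proteins and VP homologs for a cassette
#'
#' Candidate genes are CDS features carrying a CLec-like domain annotation,
#' or whose C-terminal 200 aa align to the bundled CLec consensus above
#' `config$clec_min_score`. Each candidate (excluding the cassette's own
#' targets) is scanned for local TR homology in both orientations; the best
#' identity ("columns" mode, alignment covering at least half the TR)
#' classifies the gene as remote VP (>= 50%) or VP homolog (< 50%).
#'
#' @param genome assembly.
#' @param genes gene feature table.
#' @param cassette a `dgr_cassette`.
#' @param domain_annotations optional data.frame from [import_domain_hits()].
#' @param config [detect_config()].
#' @param clec CLec consensus protein for annotation-free candidacy.
#' @return data.frame: gene_id, contig, best_tr_identity, coverage,
#'   hit_start, hit_end (genomic), near_3prime, klass, cassette.
#' @export
find_remote_targets <- function(genome, genes, cassette,
                                domain_annotations = NULL,
                                config = detect_config(),
                                clec = clec_consensus()) {
  empty <- data.frame(gene_id = character(), contig = character(),
                      best_tr_identity = numeric(), coverage = numeric(),
                      hit_start = integer(), hit_end = integer(),
                      near_3prime = logical(), klass = character(),
                      cassette = character(), stringsAsFactors = FALSE)
  cds <- genes[genes$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(empty)
  own <- stats::na.omit(cassette$vrs$target_gene)
  annotated <- if (is.null(domain_annotations) || nrow(domain_annotations) == 0)
    character(0) else
    unique(domain_annotations$gene_id[
      .is_clec_domain(domain_annotations$domain_name)])
  tr_seq <- extract_cds(genome, list(contig = cassette$contig,
                                     start = cassette$tr[1],
                                     end = cassette$tr[2], strand = "+"))
  scheme <- protein_scheme()
  rows <- list()
  for (i in seq_len(nrow(cds))) {
    f <- cds[i, ]
    if (f$id %in% own) next
    is_cand <- f$id %in% annotated
    if (!is_cand) {
      prot <- .translate_feature(genome, f)$protein
      if (!nzchar(prot)) next
      cterm <- substr(prot, max(1L, nchar(prot) - 199L), nchar(prot))
      is_cand <- local_align(cterm, clec, scheme)$score >= config$clec_min_score
    }
    if (!is_cand) next
    cds_seq <- extract_cds(genome, f)
    hit <- .tr_hit_in_cds(tr_seq, cds_seq, config)
    identity <- if (is.null(hit)) 0 else hit$identity
    if (is.null(hit)) {
      gs <- c(NA_integer_, NA_integer_)
      near3 <- NA
    } else {
      # CDS offsets back to genomic coordinates, strand-aware
      if (identical(f$strand, "-")) {
        gs <- c(f$end - hit$cds_span[2], f$end - hit$cds_span[1])
      } else {
        gs <- c(f$start + hit$cds_span[1], f$start + hit$cds_span[2])
      }
      near3 <- is_near_3prime(gs[1], gs[2], f, config)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = f$id, contig = f$contig, best_tr_identity = identity,
      coverage = if (is.null(hit)) 0 else hit$coverage,
      hit_start = gs[1], hit_end = gs[2], near_3prime = near3,
      klass = classify_remote(identity, config$remote_identity_min),
      cassette = cassette$id, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$contig, out$gene_id), , drop = FALSE]
}
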
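# Cassette assembly: signature-passing TR/VR pairs grouped per RT anchor.

.pair_key <- function(contig, c1, c2) {
  paste(contig, c1[1], c1[2], c2[1], c2[2], sep = ":")
}

.interval_gene_dist <- function(s, e, gs, ge) {
  if (.overlap_len(s, e, gs, ge) > 0) 0L else max(gs - e, s - ge)
}

#' Detect DGR cassettes in one annotated genome
#'
#' Runs the full per-genome procedure: RT candidate scan, near-repeat search
#' in each RT's proximal window, TR/VR role assignment, the adenine-mutagenesis
#' signature test, and cassette assembly. A repeat pair discovered in the
#' windows of several RTs is attributed to the nearest RT.
#'
#' @param genome assembly ([Biostrings::DNAStringSet]).
#' @param genes gene feature table (see [read_gff3()]).
#' @param config [detect_config()].
#' @param consensus RT consensus protein for the candidate scan.
#' @return list with elements `rt_candidates` (data.frame), `pairs`
#'   (data.frame of every evaluated oriented pair with its signature),
#'   `ambiguous` (diagnostics), `cassettes` (list of `dgr_cassette`) and
#'   `remnants` (RT candidates with no signature-passing pair).
#' @export
detect_dgrs <- function(genome, genes, config = detect_config(),
                        consensus = rt_consensus()) {
  rts <- scan_rt_candidates(genes, genome, config, consensus)
  pair_rows <- list()
  ambiguous <- list()
  seen <- new.env(parent = emptyenv())
  if (nrow(rts) > 0) {
    # collect pairs per RT, attributing duplicates to the nearest anchor
    found <- list()
    for (i in seq_len(nrow(rts))) {
      rt <- rts[i, ]
      for (p in find_near_repeats(genome, rt, config)) {
        key <- .pair_key(p$contig, p$copy1, p$copy2)
        d <- .interval_gene_dist(min(p$copy1[1], p$copy2[1]),
                                 max(p$copy1[2], p$copy2[2]),
                                 rt$start, rt$end)
        prev <- found[[key]]
        if (is.null(prev) || d < prev$dist)
          found[[key]] <- list(pair = p, rt = rt, dist = d)
      }
    }
    for (f in found) {
      p <- f$pair
      oriented <- assign_tr_vr(p, genes)
      if (!identical(oriented$status, "ok")) {
        ambiguous[[length(ambiguous) + 1L]] <- data.frame(
          rt_gene = f$rt$gene_id, contig = p$contig,
          copy1_start = p$copy1[1], copy1_end = p$copy1[2],
          copy2_start = p$copy2[1], copy2_end = p$copy2[2],
          identity = p$identity, reason = oriented$reason,
          stringsAsFactors = FALSE)
        next
      }
      sig <- mutagenesis_signature(oriented, genome, config)
      vr_gene <- oriented$vr_gene
      near3 <- if (is.null(vr_gene)) NA else
        is_near_3prime(oriented$vr[1], oriented$vr[2], vr_gene, config)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        rt_gene = f$rt$gene_id, contig = p$contig,
        tr_start = oriented$tr[1], tr_end = oriented$tr[2],
        vr_start = oriented$vr[1], vr_end = oriented$vr[2],
        target_gene = if (is.null(vr_gene)) NA_character_ else vr_gene$id,
        identity = p$identity, aligned_length = p$length,
        n_mismatch = sig$n_mismatch,
        adenine_fraction = sig$adenine_fraction,
        codon12_fraction = sig$codon12_fraction,
        pass_adenine = sig$pass_adenine, pass_codon = sig$pass_codon,
        fail_reason = sig$fail_reason, near_3prime = near3,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(rt_gene = character(), contig = character(),
               tr_start = integer(), tr_end = integer(),
               vr_start = integer(), vr_end = integer(),
               target_gene = character(), identity = numeric(),
               aligned_length = integer(), n_mismatch = integer(),
               adenine_fraction = numeric(), codon12_fraction = numeric(),
               pass_adenine = logical(), pass_codon = logical(),
               fail_reason = character(), near_3prime = logical(),
               stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$contig, pairs$tr_start, pairs$vr_start), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  asm <- assemble_cassettes(rts, pairs, genes, config)
  list(rt_candidates = rts, pairs = pairs,
       ambiguous = if (length(ambiguous)) do.call(rbind, ambiguous) else NULL,
       cassettes = asm$cassettes, remnants = asm$remnants)
}

#' Assemble cassettes from signature-passing TR/VR pairs
#'
#' Pairs attributed to the same RT whose TR intervals reciprocally overlap by
#' at least 0.5 are merged into one cassette carrying multiple VRs (one TR can
#' serve several target genes). RT candidates with no passing pair are
#' reported as RT-only remnants.
#'
#' @param rt_candidates data.frame from [scan_rt_candidates()].
#' @param pairs data.frame of evaluated pairs (see [detect_dgrs()]).
#' @param genes gene feature table.
#' @param config [detect_config()].
#' @return list(cassettes = list of `dgr_cassette`, remnants = data.frame).
#' @export
assemble_cassettes <- function(rt_candidates, pairs, genes,
                               config = detect_config()) {
  cassettes <- list()
  with_cassette <- character(0)
  ok <- pairs[!is.na(pairs$pass_adenine) & pairs$pass_adenine &
                pairs$pass_codon, , drop = FALSE]
  if (nrow(ok) > 0) {
    for (rt_id in unique(ok$rt_gene)) {
      sub <- ok[ok$rt_gene == rt_id, , drop = FALSE]
      groups <- list()  # each: list(tr = c(s,e), rows = integer())
      for (r in seq_len(nrow(sub))) {
        placed <- FALSE
        for (g in seq_along(groups)) {
          if (.reciprocal_overlap(sub$tr_start[r], sub$tr_end[r],
                                  groups[[g]]$tr[1],
                                  groups[[g]]$tr[2]) >= 0.5) {
            groups[[g]]$rows <- c(groups[[g]]$rows, r)
            if (sub$tr_end[r] - sub$tr_start[r] >
                groups[[g]]$tr[2] - groups[[g]]$tr[1])
              groups[[g]]$tr <- c(sub$tr_start[r], sub$tr_end[r])
            placed <- TRUE
            break
          }
        }
        if (!placed)
          groups[[length(groups) + 1L]] <-
            list(tr = c(sub$tr_start[r], sub$tr_end[r]), rows = r)
      }
      rt <- rt_candidates[rt_candidates$gene_id == rt_id, , drop = FALSE]
      for (g in groups) {
        vrs <- sub[g$rows, , drop = FALSE]
        cassettes[[length(cassettes) + 1L]] <- structure(list(
          id = sprintf("DGR_%s_%02d", rt_id, length(cassettes) + 1L),
          rt = rt, contig = vrs$contig[1], tr = g$tr, vrs = vrs),
          class = "dgr_cassette")
      }
      with_cassette <- c(with_cassette, rt_id)
    }
  }
  remnants <- rt_candidates[!rt_candidates$gene_id %in% with_cassette, ,
                            drop = FALSE]
  rownames(remnants) <- NULL
  list(cassettes = cassettes, remnants = remnants)
}

#' @export
print.dgr_cassette <- function(x, ...) {
  cat(sprintf("<dgr_cassette %s> RT %s, TR [%d,%d), %d VR(s) on %s\n",
              x$id, x$rt$gene_id, x$tr[1], x$tr[2], nrow(x$vrs), x$contig))
  invisible(x)
}

#' One row per VR cassette report
#'
#' @param cassettes list of `dgr_cassette`.
#' @param genome_id genome label for the first column.
#' @return data.frame (the cassette report table).
#' @export
cassette_report <- function(cassettes, genome_id = "genome") {
  if (length(cassettes) == 0) {
    return(data.frame(genome = character(), cassette = character(),
                      contig = character(), rt_gene = character(),
                      tr_start = integer(), tr_end = integer(),
                      vr_start = integer(), vr_end = integer(),
                      target_gene = character(), n_mismatch = integer(),
                      adenine_fraction = numeric(),
                      codon12_fraction = numeric(), near_3prime = logical(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(cassettes, function(cs) {
    data.frame(genome = genome_id, cassette = cs$id, contig = cs$contig,
               rt_gene = cs$rt$gene_id, tr_start = cs$tr[1],
               tr_end = cs$tr[2], vr_start = cs$vrs$vr_start,
               vr_end = cs$vrs$vr_end, target_gene = cs$vrs$target_gene,
               n_mismatch = cs$vrs$n_mismatch,
               adenine_fraction = cs$vrs$adenine_fraction,
               codon12_fraction = cs$vrs$codon12_fraction,
               near_3prime = cs$vrs$near_3prime, identity = cs$vrs$identity,
               stringsAsFactors = FALSE)
  }))
}

#' Cassette features as a GFF3-ready gene table (RT/TR/VR rows)
#' @param cassettes list of `dgr_cassette`.
#' @return gene feature data.frame with types RT, TR and VR.
#' @export
cassette_track <- function(cassettes) {
  if (length(cassettes) == 0) return(.empty_genes())
  do.call(rbind, lapply(cassettes, function(cs) {
    rbind(
      data.frame(id = paste0(cs$id, "_RT"), contig = cs$contig,
                 start = cs$rt$start, end = cs$rt$end, strand = cs$rt$strand,
                 type = "RT", product = "DGR reverse transcriptase",
                 stringsAsFactors = FALSE),
      data.frame(id = paste0(cs$id, "_TR"), contig = cs$contig,
                 start = cs$tr[1], end = cs$tr[2], strand = "+",
                 type = "TR", product = "DGR template repeat",
                 stringsAsFactors = FALSE),
      data.frame(id = sprintf("%s_VR%d", cs$id, seq_len(nrow(cs$vrs))),
                 contig = cs$contig, start = cs$vrs$vr_start,
                 end = cs$vrs$vr_end, strand = "+", type = "VR",
                 product = paste0("DGR variable region in ",
                                  cs$vrs$target_gene),
                 stringsAsFactors = FALSE))
  }))
}
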
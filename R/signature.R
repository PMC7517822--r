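# TR/VR role assignment and the adenine-mutagenesis signature test.

# CDS feature (row index into genes) best overlapping an interval, or NA.
# "in CDS" requires at least half the interval inside a single CDS.
.best_cds_overlap <- function(genes, contig, s, e) {
  cds <- which(genes$type == "CDS" & genes$contig == contig)
  if (length(cds) == 0) return(list(idx = NA_integer_, frac = 0))
  ov <- vapply(cds, function(i)
    as.numeric(.overlap_len(s, e, genes$start[i], genes$end[i])), numeric(1))
  b <- which.max(ov)
  list(idx = cds[b], frac = ov[b] / (e - s))
}

# adenine fraction of one aligned row at the mismatch columns of an alignment
.mismatch_adenine_fraction <- function(alignment, row = c("a", "b")) {
  row <- match.arg(row)
  mm <- alignment$mismatch_columns
  if (nrow(mm) == 0) return(NA_real_)
  mean(mm[[paste0("base_", row)]] == "A")
}

#' Assign template-repeat (TR) and variable-region (VR) roles to a repeat pair
#'
#' The copy lying inside a CDS is the VR and the other copy the TR. When both
#' or neither copy overlaps a CDS, the copy with the higher adenine fraction
#' at mismatch positions is the TR, provided the margin is at least 0.2;
#' otherwise the pair is flagged ambiguous (excluded from cassettes, retained
#' for diagnostics).
#'
#' @param pair a `dgr_repeat_pair` from [find_near_repeats()].
#' @param genes gene feature table.
#' @return list with `status` ("ok" or "ambiguous"), `tr`, `vr` (0-based
#'   half-open intervals), `vr_gene` (one-row data.frame or NULL), `contig`,
#'   and `reason` for ambiguous pairs.
#' @export
assign_tr_vr <- function(pair, genes) {
  o1 <- .best_cds_overlap(genes, pair$contig, pair$copy1[1], pair$copy1[2])
  o2 <- .best_cds_overlap(genes, pair$contig, pair$copy2[1], pair$copy2[2])
  in1 <- o1$frac >= 0.5
  in2 <- o2$frac >= 0.5
  res <- function(tr, vr, vr_idx) {
    list(status = "ok", contig = pair$contig, tr = tr, vr = vr,
         vr_gene = if (is.na(vr_idx)) NULL else genes[vr_idx, , drop = FALSE],
         pair = pair, reason = NA_character_)
  }
  if (in1 && !in2) return(res(pair$copy2, pair$copy1, o1$idx))
  if (in2 && !in1) return(res(pair$copy1, pair$copy2, o2$idx))
  # both or neither coding: adenine-margin rule
  fa1 <- .mismatch_adenine_fraction(pair$alignment, "a")
  fa2 <- .mismatch_adenine_fraction(pair$alignment, "b")
  if (is.na(fa1) || abs(fa1 - fa2) < 0.2) {
    return(list(status = "ambiguous", contig = pair$contig,
                tr = NULL, vr = NULL, vr_gene = NULL, pair = pair,
                reason = if (is.na(fa1)) "no_mismatches" else "adenine_margin"))
  }
  if (fa1 > fa2) res(pair$copy1, pair$copy2, if (in2) o2$idx else NA_integer_)
  else res(pair$copy2, pair$copy1, if (in1) o1$idx else NA_integer_)
}

# offset of a genomic position within a CDS in coding orientation
.cds_offset <- function(gpos, cds) {
  if (identical(cds$strand, "-")) cds$end - 1L - gpos else gpos - cds$start
}

#' Compute the adenine-mutagenesis signature of an oriented TR/VR pair
#'
#' The VR is extracted in the coding orientation of its gene and globally
#' aligned against the TR in whichever TR orientation scores best. Gap
#' columns and columns adjacent to a gap are excluded from all counts.
#' The pair passes the adenine criterion when it has at least
#' `config$min_mismatches` mismatches of which strictly more than
#' `config$adenine_fraction_min` sit at TR adenines, and the codon criterion
#' when at least `config$codon12_fraction_min` of mismatches fall at 1st or
#' 2nd codon positions of the target ORF.
#'
#' @param oriented result of [assign_tr_vr()] with status "ok".
#' @param genome assembly.
#' @param config [detect_config()].
#' @return a `dgr_signature` list: n_mismatch, n_tr_adenine, adenine_fraction,
#'   codon_pos_counts (c1, c2, c3), codon12_fraction, pass_adenine,
#'   pass_codon, fail_reason.
#' @export
mutagenesis_signature <- function(oriented, genome, config = detect_config()) {
  if (!identical(oriented$status, "ok"))
    stop("mutagenesis_signature requires an unambiguous TR/VR assignment")
  contig <- oriented$contig
  cds <- oriented$vr_gene
  vr_strand <- if (is.null(cds)) "+" else cds$strand
  vr_seq <- extract_cds(genome, list(contig = contig,
                                     start = oriented$vr[1],
                                     end = oriented$vr[2],
                                     strand = vr_strand))
  tr_f <- extract_cds(genome, list(contig = contig, start = oriented$tr[1],
                                   end = oriented$tr[2], strand = "+"))
  aln_f <- global_align(vr_seq, tr_f, dna_scheme())
  aln_r <- global_align(vr_seq, revcomp(tr_f), dna_scheme())
  aln <- if (aln_r$score > aln_f$score) aln_r else aln_f
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  gap <- ca == "-" | cb == "-"
  near_gap <- gap | c(FALSE, gap[-length(gap)]) | c(gap[-1], FALSE)
  no_cds <- is.null(cds)
  cds_len <- if (no_cds) 0L else cds$end - cds$start
  vr_off_all <- cumsum(ca != "-") - 1L  # offset in vr_seq per column
  count_on <- function(counted) {
    mm_cols <- which(counted & !near_gap & ca != cb)
    n_mismatch <- length(mm_cols)
    n_tr_adenine <- sum(cb[mm_cols] == "A")
    c123 <- c(0L, 0L, 0L)
    if (!no_cds && n_mismatch > 0) {
      for (col in mm_cols) {
        off <- vr_off_all[col]
        gpos <- if (identical(vr_strand, "-")) oriented$vr[2] - 1L - off
                else oriented$vr[1] + off
        co <- .cds_offset(gpos, cds)
        if (co >= 0 && co < cds_len) {
          p <- co %% 3 + 1
          c123[p] <- c123[p] + 1L
        }
      }
    }
    adenine_fraction <- if (n_mismatch > 0) n_tr_adenine / n_mismatch
                        else NA_real_
    codon12_fraction <- if (n_mismatch > 0) (c123[1] + c123[2]) / n_mismatch
                        else NA_real_
    pass_adenine <- n_mismatch >= config$min_mismatches &&
      !is.na(adenine_fraction) &&
      adenine_fraction > config$adenine_fraction_min
    pass_codon <- !no_cds && n_mismatch > 0 &&
      codon12_fraction >= config$codon12_fraction_min
    list(n_mismatch = n_mismatch, n_tr_adenine = n_tr_adenine,
         adenine_fraction = adenine_fraction, codon_pos_counts = c123,
         codon12_fraction = codon12_fraction, pass_adenine = pass_adenine,
         pass_codon = pass_codon)
  }
  # Boundary-robust evaluation on two supports. The full alignment can be
  # diluted by a few chance-similar flank columns that local realignment
  # appended; the seed-anchored core (between the first and last run of
  # >= seed_k consecutive matches) excludes such flanks but can chop genuine
  # terminal mismatches when they cluster more densely than seed_k. The two
  # errors are complementary, so the criteria are tested on both supports and
  # a pair is accepted when either support passes.
  full <- count_on(rep(TRUE, length(ca)))
  match_col <- !gap & ca == cb
  r <- rle(match_col)
  rends <- cumsum(r$lengths)
  long <- which(r$values & r$lengths >= config$seed_k)
  core <- NULL
  if (length(long) > 0) {
    core0 <- rends[long[1]] - r$lengths[long[1]] + 1L
    core1 <- rends[long[length(long)]]
    if (core0 > 1L || core1 < length(ca))
      core <- count_on(seq_along(ca) >= core0 & seq_along(ca) <= core1)
  }
  chosen <- full
  support <- "full"
  if (!(full$pass_adenine && full$pass_codon) && !is.null(core) &&
      core$pass_adenine && core$pass_codon) {
    chosen <- core
    support <- "core"
  }
  fail_reason <- if (no_cds) "vr_not_in_cds"
    else if (chosen$n_mismatch < config$min_mismatches) "below_min_mismatches"
    else if (!chosen$pass_adenine) "adenine_fraction"
    else if (!chosen$pass_codon) "codon_positions"
    else NA_character_
  structure(c(chosen,
              list(support = support, fail_reason = fail_reason,
                   alignment = aln)),
            class = "dgr_signature")
}

#' Does a variable region sit near the 3' terminus of its target gene?
#'
#' TRUE when the VR's 3'-most base that overlaps the CDS (in coding
#' orientation) lies within the final `three_prime_fraction` of the CDS
#' length; the boundary position is inclusive.
#'
#' @param vr_start,vr_end VR interval, 0-based half-open genomic.
#' @param cds one-row CDS feature overlapping the VR.
#' @param config [detect_config()].
#' @return logical scalar.
#' @export
is_near_3prime <- function(vr_start, vr_end, cds, config = detect_config()) {
  if (.overlap_len(vr_start, vr_end, cds$start, cds$end) == 0)
    stop("VR does not overlap the CDS")
  len <- cds$end - cds$start
  if (identical(cds$strand, "-")) {
    g <- max(vr_start, cds$start)            # 3'-most base on minus strand
    off <- cds$end - 1L - g
  } else {
    g <- min(vr_end, cds$end) - 1L
    off <- g - cds$start
  }
  (off + 1) >= (1 - config$three_prime_fraction) * len
}
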
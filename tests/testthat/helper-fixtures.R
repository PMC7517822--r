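# In-code fixtures: miniature genomes with a TR and a VR-bearing CDS built
# base by base, so expected signature counts are known by construction.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_sense_codons <- function(n_codons, gc = 0.45) {
  out <- character(0)
  while (length(out) < n_codons) {
    cod <- replicate(n_codons - length(out),
                     random_dna_str(3, gc))
    out <- c(out, cod[!cod %in% STOP_CODONS])
  }
  paste0(out, collapse = "")
}

mk_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

mk_gene <- function(id, contig, start, end, strand = "+", type = "CDS",
                    product = "hypothetical protein") {
  data.frame(id = id, contig = contig, start = start, end = end,
             strand = strand, type = type, product = product,
             stringsAsFactors = FALSE)
}

rc <- function(x) dgrscan::revcomp(x)

#' Build a one-contig genome holding a TR and a CDS whose tail carries a VR
#' copy of the TR with mismatches at chosen 0-based repeat offsets.
#'
#' mm is a data.frame(pos0 = 0-based offset in the repeat, base = VR base);
#' the TR base at each mm position is set via tr_base (default "A") so the
#' expected adenine count is controlled exactly.
make_tr_vr_case <- function(L = 99, mm = NULL, tr_base = "A",
                            vr_cds_off = 123, t_strand = "+",
                            tr_strand = "+", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(vr_cds_off %% 1 == 0)
  tr <- strsplit(random_sense_codons(ceiling(L / 3)), "", fixed = TRUE)[[1]][1:L]
  # keep anchor runs clean at both repeat ends
  if (!is.null(mm)) {
    stopifnot(all(mm$pos0 >= 8), all(mm$pos0 <= L - 9))
    for (r in seq_len(nrow(mm))) {
      p <- mm$pos0[r] + 1L
      tr[p] <- if (!is.null(mm$tr_base)) mm$tr_base[r] else tr_base
      stopifnot(mm$base[r] != tr[p])
    }
  }
  vr <- tr
  if (!is.null(mm)) vr[mm$pos0 + 1L] <- mm$base
  n_fill <- vr_cds_off  # bases between ATG+filler start and VR (vr_cds_off total)
  stopifnot(n_fill >= 3)
  cds <- paste0("ATG", random_sense_codons(ceiling((n_fill - 3) / 3)))
  cds <- substr(cds, 1, n_fill)  # any frame offset for the VR is permitted
  cds <- paste0(cds, paste0(vr, collapse = ""), random_sense_codons(3), "TAA")
  pad1 <- random_dna_str(60)
  pad2 <- random_dna_str(80)
  pad3 <- random_dna_str(60)
  tr_seg <- if (tr_strand == "-") rc(paste0(tr, collapse = "")) else
    paste0(tr, collapse = "")
  cds_seg <- if (t_strand == "-") rc(cds) else cds
  contig_seq <- paste0(pad1, tr_seg, pad2, cds_seg, pad3)
  tr_iv <- c(nchar(pad1), nchar(pad1) + L)
  cds_iv <- c(nchar(pad1) + L + nchar(pad2),
              nchar(pad1) + L + nchar(pad2) + nchar(cds))
  vr_iv <- if (t_strand == "+") cds_iv[1] + vr_cds_off + c(0L, L) else
    cds_iv[2] - vr_cds_off - L + c(0L, L)
  genome <- mk_genome(chr1 = contig_seq)
  genes <- mk_gene("vp1", "chr1", cds_iv[1], cds_iv[2], t_strand)
  oriented <- list(status = "ok", contig = "chr1", tr = tr_iv, vr = vr_iv,
                   vr_gene = genes[1, , drop = FALSE], reason = NA_character_)
  list(genome = genome, genes = genes, oriented = oriented,
       tr_chars = tr, vr_chars = vr, L = L, vr_cds_off = vr_cds_off,
       cds_iv = cds_iv, tr_iv = tr_iv, vr_iv = vr_iv)
}

# simple deterministic back-translation (first codon of each amino acid)
back_translate_str <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste0(vapply(aas, function(a) names(gc)[gc == a][1], ""), collapse = "")
}

# small cached bank of synthetic genomes at default study conditions
.sims_env <- new.env(parent = emptyenv())
acceptance_sims <- function(seeds = 1:20) {
  key <- paste(range(seeds), collapse = "_")
  if (is.null(.sims_env[[key]])) {
    .sims_env[[key]] <- lapply(seeds, function(sd)
      dgrscan::generate_genome(dgrscan::synth_params(), seed = sd))
  }
  .sims_env[[key]]
}

reciprocal_overlap_ok <- function(s, e, ts, te, frac = 0.9) {
  ov <- pmin(e, te) - pmax(s, ts)
  any(ov / (e - s) >= frac & ov / (te - ts) >= frac)
}
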
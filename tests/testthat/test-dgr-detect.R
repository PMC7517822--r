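# exhaustive forward-diagonal repeat scan, used as oracle for the seeded search
exhaustive_diag_pairs <- function(wchars, L, min_id = 0.8) {
  n <- length(wchars)
  out <- list()
  for (d in seq_len(n - L)) {
    eq <- wchars[seq_len(n - d)] == wchars[(1 + d):n]
    if (length(eq) < L) next
    cum <- c(0L, cumsum(eq))
    idv <- (cum[(L + 1):length(cum)] - cum[seq_len(length(cum) - L)]) / L
    hit <- which(idv >= min_id)
    for (i in hit) {
      out[[length(out) + 1L]] <- c(start1 = i - 1L, end1 = i - 1L + L,
                                   start2 = i - 1L + d, end2 = i - 1L + d + L)
    }
  }
  out
}

test_that("RT candidate scan finds planted RTs and nothing in random CDS", {
  set.seed(31)
  prot <- rt_consensus()
  # plant an RT at ~90% aa identity
  aas <- strsplit(prot, "")[[1]]
  idx <- sample(length(aas), 33)
  alpha <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (p in idx) aas[p] <- sample(setdiff(alpha, aas[p]), 1)
  rt_cds <- paste0("ATG", back_translate_str(paste0(aas, collapse = "")), "TAA")
  decoy_cds <- paste0("ATG", random_sense_codons(320), "TAA")
  contig <- paste0(random_dna_str(100), rt_cds, random_dna_str(100),
                   decoy_cds, random_dna_str(100))
  g <- mk_genome(chr1 = contig)
  genes <- rbind(
    mk_gene("rt1", "chr1", 100L, 100L + nchar(rt_cds)),
    mk_gene("dec", "chr1", 200L + nchar(rt_cds),
            200L + nchar(rt_cds) + nchar(decoy_cds)))
  cand <- scan_rt_candidates(genes, g)
  expect_equal(cand$gene_id, "rt1")
  expect_gte(cand$score, detect_config()$rt_min_score)
  expect_gte(cand$motif_hits, 1)
  # random CDS only -> nothing
  cand2 <- scan_rt_candidates(genes[2, , drop = FALSE], g)
  expect_equal(nrow(cand2), 0)
  expect_equal(nrow(scan_rt_candidates(genes[0, ], g)), 0)
})

test_that("near-repeat search recovers a planted pair, matching the exhaustive scan", {
  set.seed(32)
  L <- 134L
  tr <- strsplit(random_dna_str(L), "")[[1]]
  vr <- tr
  pos <- sort(sample(8:(L - 9), 11))
  for (p in pos) vr[p + 1] <- sample(setdiff(c("A", "C", "G", "T"),
                                             tr[p + 1]), 1)
  contig <- paste0(random_dna_str(300), strrep("G", 0),
                   paste0(tr, collapse = ""), random_dna_str(250),
                   paste0(vr, collapse = ""), random_dna_str(300))
  anchor <- mk_gene("rt", "chr1", 0L, 120L)  # window covers everything
  g <- mk_genome(chr1 = contig)
  cfg <- detect_config(window_bp = 1500L)
  pairs <- find_near_repeats(g, anchor, cfg)
  expect_equal(length(pairs), 1)
  p <- pairs[[1]]
  expect_true(reciprocal_overlap_ok(p$copy1[1], p$copy1[2], 300, 300 + L))
  expect_true(reciprocal_overlap_ok(p$copy2[1], p$copy2[2], 300 + L + 250,
                                    300 + 2 * L + 250))
  expect_gte(p$identity, 0.85)
  # oracle: exhaustive diagonal scan finds the same repeat and no other
  oracle <- exhaustive_diag_pairs(strsplit(contig, "")[[1]], L, 0.85)
  expect_gte(length(oracle), 1)
  # the seeded search result coincides with an exhaustive-scan hit
  starts <- vapply(oracle, `[[`, 0, "start1")
  expect_lte(min(abs(starts - p$copy1[1])), 5)
  # and every exhaustive hit is a (near-threshold) shift of the one planted
  # repeat, not an unrelated pair elsewhere in the window
  expect_true(all(abs(starts - 300) <= 20))
})

test_that("exact tandem duplications are reported with identity 1", {
  set.seed(33)
  s <- random_dna_str(120)
  contig <- paste0(random_dna_str(200), s, random_dna_str(40), s,
                   random_dna_str(200))
  g <- mk_genome(chr1 = contig)
  pairs <- find_near_repeats(g, mk_gene("rt", "chr1", 0L, 100L),
                             detect_config(window_bp = 1000L))
  expect_equal(length(pairs), 1)
  expect_equal(pairs[[1]]$identity, 1)
  # window with no repeat
  g2 <- mk_genome(chr1 = random_dna_str(2000))
  expect_length(find_near_repeats(g2, mk_gene("rt", "chr1", 0L, 100L),
                                  detect_config(window_bp = 900L)), 0)
})

test_that("reverse-orientation repeat copies are found", {
  set.seed(34)
  L <- 120L
  tr <- random_dna_str(L)
  contig <- paste0(random_dna_str(300), tr, random_dna_str(220), rc(tr),
                   random_dna_str(300))
  g <- mk_genome(chr1 = contig)
  pairs <- find_near_repeats(g, mk_gene("rt", "chr1", 0L, 100L),
                             detect_config(window_bp = 1200L))
  expect_equal(length(pairs), 1)
  expect_equal(pairs[[1]]$orient, "-")
  expect_true(reciprocal_overlap_ok(pairs[[1]]$copy1[1], pairs[[1]]$copy1[2],
                                    300, 300 + L))
})

mk_pair <- function(contig, c1, c2, s1, s2, genes) {
  aln <- global_align(s1, s2)
  structure(list(contig = contig, copy1 = c1, copy2 = c2, orient = "+",
                 alignment = aln,
                 identity = percent_identity(aln, "columns"),
                 length = nchar(aln$aligned_a)), class = "dgr_repeat_pair")
}

test_that("TR/VR role assignment follows CDS overlap then the adenine margin", {
  genes <- mk_gene("vp", "chr1", 500L, 700L)
  s1 <- random_dna_str(100)
  p <- mk_pair("chr1", c(100L, 200L), c(520L, 620L), s1, s1, genes)
  r <- assign_tr_vr(p, genes)
  expect_equal(r$status, "ok")
  expect_equal(r$tr, c(100L, 200L))
  expect_equal(r$vr, c(520L, 620L))
  expect_equal(r$vr_gene$id, "vp")

  # both intergenic: adenine fractions 0.9 vs ~0 resolve roles
  set.seed(35)
  base <- strsplit(random_dna_str(100), "")[[1]]
  s_tr <- base; s_vr <- base
  pos <- seq(10, 91, by = 9)  # 10 mismatches
  for (k in seq_along(pos)) {
    s_tr[pos[k]] <- if (k <= 9) "A" else "C"
    s_vr[pos[k]] <- if (k <= 9) "G" else "T"
  }
  p2 <- mk_pair("chr1", c(100L, 200L), c(300L, 400L),
                paste0(s_tr, collapse = ""), paste0(s_vr, collapse = ""),
                genes)
  r2 <- assign_tr_vr(p2, genes)
  expect_equal(r2$status, "ok")
  expect_equal(r2$tr, c(100L, 200L))  # copy1 carries the adenines

  # margin below 0.2 -> ambiguous
  s_tr2 <- base; s_vr2 <- base
  for (k in seq_along(pos)) {
    s_tr2[pos[k]] <- if (k <= 5) "A" else "C"
    s_vr2[pos[k]] <- if (k <= 6) "G" else "A"   # fractions 0.5 vs ~0.4
  }
  p3 <- mk_pair("chr1", c(100L, 200L), c(300L, 400L),
                paste0(s_tr2, collapse = ""), paste0(s_vr2, collapse = ""),
                genes)
  r3 <- assign_tr_vr(p3, genes)
  expect_equal(r3$status, "ambiguous")
  expect_equal(r3$reason, "adenine_margin")

  # exact repeats cannot be oriented
  p4 <- mk_pair("chr1", c(100L, 200L), c(300L, 400L), s1, s1, genes)
  expect_equal(assign_tr_vr(p4, genes)$status, "ambiguous")
  expect_equal(assign_tr_vr(p4, genes)$reason, "no_mismatches")
})

test_that("the mutagenesis signature counts adenines and codon positions", {
  # 10 mismatches, 9 at TR adenines -> adenine fraction 0.9, pass
  mm <- data.frame(pos0 = c(9, 18, 27, 36, 45, 54, 63, 72, 81, 90),
                   base = c(rep("G", 9), "T"),
                   tr_base = c(rep("A", 9), "C"))
  cs <- make_tr_vr_case(L = 99, mm = mm, vr_cds_off = 123, seed = 36)
  sig <- mutagenesis_signature(cs$oriented, cs$genome)
  expect_equal(sig$n_mismatch, 10L)
  expect_equal(sig$n_tr_adenine, 9L)
  expect_equal(sig$adenine_fraction, 0.9)
  expect_true(sig$pass_adenine)
  # offsets 9,18,... are codon-aligned with vr_cds_off 123 (multiple of 3)
  expect_equal(sum(sig$codon_pos_counts), 10L)
  expect_equal(sig$codon_pos_counts[1],
               sum((mm$pos0 + 123) %% 3 == 0))

  # 3 mismatches, all at TR adenines -> below the mismatch floor
  mm3 <- data.frame(pos0 = c(20, 40, 60), base = "G", tr_base = "A")
  cs3 <- make_tr_vr_case(L = 99, mm = mm3, vr_cds_off = 123, seed = 37)
  sig3 <- mutagenesis_signature(cs3$oriented, cs3$genome)
  expect_equal(sig3$n_mismatch, 3L)
  expect_false(sig3$pass_adenine)
  expect_equal(sig3$fail_reason, "below_min_mismatches")
})

test_that("codon-position rule: (5,4,1) passes, (1,1,4) fails", {
  # choose repeat offsets by desired codon position (vr_cds_off = 123 = 0 mod 3)
  pos_for <- function(codon_pos, k) {
    cand <- seq(9, 88)[(seq(9, 88) %% 3) == (codon_pos - 1)]
    cand[seq_len(k) * 3]
  }
  mm <- data.frame(pos0 = c(pos_for(1, 5), pos_for(2, 4), pos_for(3, 1)),
                   base = "G", tr_base = "A")
  cs <- make_tr_vr_case(L = 99, mm = mm, vr_cds_off = 123, seed = 38)
  sig <- mutagenesis_signature(cs$oriented, cs$genome)
  expect_equal(sig$codon_pos_counts, c(5L, 4L, 1L))
  expect_equal(sig$codon12_fraction, 0.9)
  expect_true(sig$pass_codon)

  mm2 <- data.frame(pos0 = c(pos_for(1, 1), pos_for(2, 1), pos_for(3, 4)),
                    base = "G", tr_base = "A")
  cs2 <- make_tr_vr_case(L = 99, mm = mm2, vr_cds_off = 123, seed = 39)
  sig2 <- mutagenesis_signature(cs2$oriented, cs2$genome)
  expect_equal(sig2$codon_pos_counts, c(1L, 1L, 4L))
  expect_equal(sig2$codon12_fraction, 1 / 3)
  expect_false(sig2$pass_codon)
})

test_that("signature counts are identical for minus-strand targets and TRs", {
  mm <- data.frame(pos0 = seq(9, 90, by = 9), base = "G", tr_base = "A")
  for (ts in c("+", "-")) {
    for (trs in c("+", "-")) {
      cs <- make_tr_vr_case(L = 99, mm = mm, vr_cds_off = 123,
                            t_strand = ts, tr_strand = trs, seed = 40)
      sig <- mutagenesis_signature(cs$oriented, cs$genome)
      expect_equal(sig$n_mismatch, 10L)
      expect_equal(sig$adenine_fraction, 1)
      expect_true(sig$pass_adenine)
      expect_true(sig$pass_codon)
    }
  }
})

test_that("raising the adenine threshold never accepts more pairs", {
  sims <- acceptance_sims(1:3)
  af <- unlist(lapply(sims, function(sim) {
    det <- detect_dgrs(sim$genome, sim$genes)
    det$pairs$adenine_fraction
  }))
  nm <- unlist(lapply(sims, function(sim) {
    det <- detect_dgrs(sim$genome, sim$genes)
    det$pairs$n_mismatch
  }))
  accepted <- vapply(seq(0.5, 0.95, by = 0.05), function(th)
    sum(nm >= 4 & !is.na(af) & af > th), numeric(1))
  expect_true(all(diff(accepted) <= 0))
})

test_that("near-3' localization uses the coding 3' terminus, boundary inclusive", {
  cds <- mk_gene("vp", "chr1", 100L, 500L, "+")
  expect_true(is_near_3prime(470L, 500L, cds))
  expect_false(is_near_3prime(105L, 135L, cds))
  # VR end exactly at the 75% boundary is near-3' (inclusive)
  expect_true(is_near_3prime(370L, 400L, cds))
  expect_false(is_near_3prime(369L, 399L, cds))
  # minus strand: the 3' terminus is the interval start
  cdsm <- mk_gene("vp", "chr1", 100L, 500L, "-")
  expect_true(is_near_3prime(100L, 130L, cdsm))
  expect_false(is_near_3prime(470L, 500L, cdsm))
  expect_error(is_near_3prime(600L, 650L, cds), "overlap")
})

test_that("cassette assembly groups VRs by shared TR and reports remnants", {
  rts <- data.frame(gene_id = c("rt1", "rt2"), contig = "chr1",
                    start = c(0L, 5000L), end = c(900L, 5900L),
                    strand = "+", score = c(1500, 1400),
                    motif_hits = 3L, partial_cds = FALSE,
                    stringsAsFactors = FALSE)
  pairs <- data.frame(
    rt_gene = c("rt1", "rt1"), contig = "chr1",
    tr_start = c(1000L, 1002L), tr_end = c(1150L, 1148L),
    vr_start = c(2000L, 2400L), vr_end = c(2150L, 2546L),
    target_gene = c("vpA", "vpB"), identity = 0.9, aligned_length = 150L,
    n_mismatch = 12L, adenine_fraction = 0.95, codon12_fraction = 0.9,
    pass_adenine = TRUE, pass_codon = TRUE, fail_reason = NA_character_,
    near_3prime = TRUE, stringsAsFactors = FALSE)
  genes <- rbind(mk_gene("vpA", "chr1", 1900L, 2200L),
                 mk_gene("vpB", "chr1", 2300L, 2600L))
  asm <- assemble_cassettes(rts, pairs, genes)
  expect_length(asm$cassettes, 1)
  expect_equal(nrow(asm$cassettes[[1]]$vrs), 2)
  expect_equal(asm$remnants$gene_id, "rt2")
})

test_that("a generator cassette with two targets yields one cassette, two VRs", {
  sim <- generate_genome(synth_params(n_cassettes = 1L,
                                      n_targets_per_cassette = 2L,
                                      n_remote_vps = 0L, n_homologs = 0L,
                                      n_transposases = 0L,
                                      genome_len = 60000L), seed = 7L)
  det <- detect_dgrs(sim$genome, sim$genes)
  expect_length(det$cassettes, 1)
  expect_equal(nrow(det$cassettes[[1]]$vrs), 2)
  expect_setequal(det$cassettes[[1]]$vrs$target_gene,
                  c("vp_cassette_1_1", "vp_cassette_1_2"))
})

test_that("an RT flanked only by an exact duplication is an RT-only remnant", {
  set.seed(41)
  rt_cds <- paste0("ATG", back_translate_str(rt_consensus()), "TAA")
  s <- random_dna_str(130)
  contig <- paste0(random_dna_str(200), rt_cds, random_dna_str(400), s,
                   random_dna_str(150), s, random_dna_str(200))
  g <- mk_genome(chr1 = contig)
  genes <- mk_gene("rt1", "chr1", 200L, 200L + nchar(rt_cds))
  det <- detect_dgrs(g, genes)
  expect_equal(det$rt_candidates$gene_id, "rt1")
  expect_length(det$cassettes, 0)
  expect_equal(det$remnants$gene_id, "rt1")
})
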
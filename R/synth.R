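# Synthetic genomes with planted DGR cassettes, remote targets, transposases
# and decoy repeats, plus a machine-readable truth table. The generator is the
# package's benchmark surface: every planted feature is recorded with its
# realized mismatch statistics so detection can be scored without external
# data.

.STOPS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

#' Parameters of the synthetic-genome generator
#'
#' Defaults encode the study conditions the detector is built for: two
#' cassettes per 200-kbp genome, repeat copies of 100-200 bp at 90% identity,
#' planted mismatches sitting at TR adenines with probability 0.95 and at
#' 1st/2nd codon positions with probability 0.9, remote VPs at 70% and VP
#' homologs at 40% TR identity, transposases within 10 kbp of a cassette and
#' one decoy repeat of each class.
#'
#' @param genome_len contig length in bp.
#' @param n_cassettes planted cassettes.
#' @param n_targets_per_cassette VR-bearing target genes per cassette.
#' @param repeat_len_range TR length range in bp (rounded to codons).
#' @param pair_identity target TR/VR identity.
#' @param p_A probability a planted mismatch sits at a TR adenine.
#' @param p_12 probability a planted mismatch sits at codon position 1 or 2.
#' @param n_remote_vps,remote_identity dispersed remote VPs and their TR
#'   identity.
#' @param n_homologs,homolog_identity dispersed VP homologs and their TR
#'   identity.
#' @param n_transposases transposase genes planted within 10 kbp of cassettes.
#' @param n_filler_genes unrelated background CDS.
#' @param n_decoys decoy repeats per class (exact duplication, non-adenine
#'   mismatches, far from any RT).
#' @param gc_content background GC fraction.
#' @param seed default seed used when [generate_genome()] gets none.
#' @return a `dgr_synth_params` list.
#' @export
synth_params <- function(genome_len = 200000L, n_cassettes = 2L,
                         n_targets_per_cassette = 1L,
                         repeat_len_range = c(100L, 200L),
                         pair_identity = 0.90, p_A = 0.95, p_12 = 0.9,
                         n_remote_vps = 2L, remote_identity = 0.70,
                         n_homologs = 2L, homolog_identity = 0.40,
                         n_transposases = 2L, n_filler_genes = 8L,
                         n_decoys = 1L, gc_content = 0.45, seed = 1L) {
  stopifnot(p_A >= 0, p_A <= 1, p_12 >= 0, p_12 <= 1,
            repeat_len_range[1] >= 50, repeat_len_range[2] <= 300,
            pair_identity > 0, pair_identity <= 1,
            remote_identity > 0, remote_identity <= 1,
            homolog_identity > 0, homolog_identity <= 1,
            gc_content > 0, gc_content < 1, genome_len >= 20000,
            n_cassettes >= 0, n_targets_per_cassette >= 1)
  structure(as.list(environment()), class = "dgr_synth_params")
}

# one pseudo-random stream per (seed, item); item indices are fixed so adding
# decoys never perturbs cassette sequences
.item_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) %% 100000) * 20011 + idx * 7919) %% 2147483647L
}

.with_stream <- function(seed, idx, f) {
  set.seed(.item_seed(seed, idx))
  f()
}

.random_dna <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# n random sense codons (no stops), as a flat character vector of bases
.random_codons <- function(n, gc) {
  out <- character(0)
  while (length(out) < 3 * n) {
    chunk <- .random_dna(3 * (n - length(out) / 3), gc)
    cod <- apply(matrix(chunk, nrow = 3), 2, paste0, collapse = "")
    keep <- !cod %in% .STOPS
    out <- c(out, unlist(strsplit(cod[keep], "", fixed = TRUE)))
  }
  out
}

.codon_table_env <- new.env(parent = emptyenv())
.codons_for <- function(aa) {
  if (is.null(.codon_table_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_table_env$tab <- split(names(gc), unname(gc))
  }
  .codon_table_env$tab[[aa]]
}

.back_translate <- function(protein) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  unlist(lapply(aas, function(a) {
    cods <- .codons_for(a)
    if (is.null(cods)) cods <- .codons_for("A")
    strsplit(sample(cods, 1), "", fixed = TRUE)[[1]]
  }))
}

.mutate_protein <- function(protein, rate) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  n <- max(1L, round(rate * length(aas)))
  pos <- sample(length(aas), n)
  for (p in pos) aas[p] <- sample(setdiff(alphabet, aas[p]), 1)
  paste0(aas, collapse = "")
}

# substitute one base, avoiding stop codons in frame 0 of `chars`
.substitute_base <- function(chars, p) {
  ci <- ((p - 1L) %/% 3L) * 3L + 1L
  for (b in sample(setdiff(.BASES, chars[p]))) {
    tmp <- chars
    tmp[p] <- b
    if (ci + 2L <= length(tmp) &&
        paste0(tmp[ci:(ci + 2L)], collapse = "") %in% .STOPS) next
    return(tmp)
  }
  NULL
}

# plant n_mm mismatches into a TR copy. The number of mismatches sitting at
# TR adenines is Binomial(n_mm, p_A) and the number at 1st/2nd codon
# positions Binomial(n_mm, p_12); when p_A (p_12) itself exceeds the
# signature threshold the draw is conditioned on clearing that threshold with
# margin, so that a planted cassette is a true positive by construction while
# the pooled realized fractions stay at p_A / p_12. The substituted base is
# uniform among the three alternatives, resampled if it would create an
# in-frame stop.
.plant_mismatches <- function(tr, n_mm, p_A, p_12) {
  vr <- tr
  L <- length(tr)
  pos12 <- ((seq_len(L) - 1L) %% 3L) < 2L
  n_A <- stats::rbinom(1, n_mm, p_A)
  if (p_A > 0.8) n_A <- max(n_A, min(n_mm, floor(0.8 * n_mm) + 2L))
  n_12 <- stats::rbinom(1, n_mm, p_12)
  if (p_12 > 2 / 3) n_12 <- max(n_12, min(n_mm, floor(2 / 3 * n_mm) + 2L))
  a_flag <- sample(c(rep(TRUE, n_A), rep(FALSE, n_mm - n_A)))
  c_flag <- sample(c(rep(TRUE, n_12), rep(FALSE, n_mm - n_12)))
  chosen <- integer(0)
  for (m in seq_len(n_mm)) {
    pool <- list(
      which(pos12 == c_flag[m] & (tr == "A") == a_flag[m]),
      which((tr == "A") == a_flag[m]),   # relax codon class
      which(pos12 == c_flag[m]),         # relax adenine class
      seq_len(L))                        # any position
    done <- FALSE
    for (cand in pool) {
      cand <- setdiff(cand, chosen)
      while (length(cand) > 0) {
        p <- if (length(cand) == 1) cand else sample(cand, 1)
        tmp <- .substitute_base(vr, p)
        if (is.null(tmp)) {
          cand <- setdiff(cand, p)
          next
        }
        vr <- tmp
        chosen <- c(chosen, p)
        done <- TRUE
        break
      }
      if (done) break
    }
  }
  list(vr = vr, pos = sort(chosen),
       n_mismatch = length(chosen),
       n_tr_adenine = sum(tr[chosen] == "A"),
       n_codon12 = sum(pos12[chosen]))
}

# mutate a TR copy down to roughly `identity`, stop-free in frame 0
.mutate_to_identity <- function(tr, identity) {
  n_sub <- round((1 - identity) * length(tr))
  out <- tr
  chosen <- integer(0)
  guard <- 0L
  while (length(chosen) < n_sub && guard < 10000L) {
    guard <- guard + 1L
    p <- sample(setdiff(seq_along(tr), chosen), 1)
    tmp <- .substitute_base(out, p)
    if (is.null(tmp)) next
    out <- tmp
    chosen <- c(chosen, p)
  }
  list(seq = out, identity = 1 - length(chosen) / length(tr))
}

.seq_of <- function(chars) paste0(chars, collapse = "")

# ---- item builders -------------------------------------------------------
# each returns list(seq, genes, domains, truth) with block-relative 0-based
# half-open coordinates; absolute coordinates are filled in after placement.

.strand_seg <- function(chars, strand) {
  if (strand == "-") strsplit(revcomp(.seq_of(chars)), "", fixed = TRUE)[[1]]
  else chars
}

.gene_row <- function(id, start, end, strand, product) {
  data.frame(id = id, contig = NA_character_, start = start, end = end,
             strand = strand, type = "CDS", product = product,
             stringsAsFactors = FALSE)
}

.truth_row <- function(item_id, kind, start, end, strand, cassette = NA,
                       gene_id = NA, identity = NA, n_mismatch = NA,
                       n_tr_adenine = NA, n_codon12 = NA,
                       copy2_start = NA, copy2_end = NA,
                       hit_start = NA, hit_end = NA) {
  data.frame(item_id = item_id, kind = kind, contig = NA_character_,
             start = start, end = end, strand = strand,
             cassette = as.character(cassette), gene_id = as.character(gene_id),
             identity = as.numeric(identity),
             n_mismatch = as.integer(n_mismatch),
             n_tr_adenine = as.integer(n_tr_adenine),
             n_codon12 = as.integer(n_codon12),
             copy2_start = as.integer(copy2_start),
             copy2_end = as.integer(copy2_end),
             hit_start = as.integer(hit_start),
             hit_end = as.integer(hit_end), stringsAsFactors = FALSE)
}

.build_cassette <- function(ci, params, rt_cons) {
  cid <- sprintf("cassette_%d", ci)
  gc <- params$gc_content
  rt_prot <- .mutate_protein(rt_cons, 0.10)
  rt_cds <- c(strsplit("ATG", "")[[1]], .back_translate(rt_prot),
              strsplit("TAA", "")[[1]])
  lc <- round(params$repeat_len_range / 3)
  L <- 3L * sample(seq(lc[1], lc[2]), 1)
  tr <- .random_codons(L / 3L, gc)
  rt_strand <- sample(c("+", "-"), 1)
  tr_strand <- sample(c("+", "-"), 1)
  parts <- character(0)
  genes <- list(); truth <- list(); domains <- list()
  at <- 0L
  push <- function(chars) {
    parts[[length(parts) + 1L]] <<- .seq_of(chars)
    s <- at
    at <<- at + length(chars)
    s
  }
  rt_s <- push(.strand_seg(rt_cds, rt_strand))
  rt_id <- sprintf("rt_%s", cid)
  genes[[1]] <- .gene_row(rt_id, rt_s, at, rt_strand, "reverse transcriptase")
  truth[[1]] <- .truth_row(rt_id, "RT", rt_s, at, rt_strand, cid, rt_id)
  push(.random_dna(sample(200:600, 1), gc))
  tr_s <- push(.strand_seg(tr, tr_strand))
  truth[[length(truth) + 1L]] <-
    .truth_row(paste0("tr_", cid), "TR", tr_s, at, tr_strand, cid)
  for (t in seq_len(params$n_targets_per_cassette)) {
    push(.random_dna(sample(200:600, 1), gc))
    n_mm <- max(8L, round((1 - params$pair_identity) * L))
    pl <- .plant_mismatches(tr, n_mm, params$p_A, params$p_12)
    nf <- sample(100:160, 1)
    tail_cod <- sample(2:4, 1)
    cds <- c(strsplit("ATG", "")[[1]], .random_codons(nf, gc), pl$vr,
             .random_codons(tail_cod, gc), strsplit("TAA", "")[[1]])
    vr_off <- 3L + 3L * nf
    t_strand <- sample(c("+", "-"), 1)
    t_s <- push(.strand_seg(cds, t_strand))
    t_e <- at
    gid <- sprintf("vp_%s_%d", cid, t)
    vr_s <- if (t_strand == "+") t_s + vr_off else t_e - vr_off - L
    genes[[length(genes) + 1L]] <-
      .gene_row(gid, t_s, t_e, t_strand, "hypothetical protein")
    prot_len <- length(cds) / 3L - 1L
    domains[[length(domains) + 1L]] <- data.frame(
      gene_id = gid, domain_name = "CLec-like",
      aa_start = max(1L, nf - 20L), aa_end = prot_len, score = 50,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <-
      .truth_row(gid, "target_CDS", t_s, t_e, t_strand, cid, gid)
    truth[[length(truth) + 1L]] <- .truth_row(
      sprintf("vr_%s_%d", cid, t), "VR", vr_s, vr_s + L, t_strand, cid, gid,
      identity = 1 - pl$n_mismatch / L, n_mismatch = pl$n_mismatch,
      n_tr_adenine = pl$n_tr_adenine, n_codon12 = pl$n_codon12)
  }
  list(id = cid, seq = paste0(parts, collapse = ""),
       genes = do.call(rbind, genes), truth = do.call(rbind, truth),
       domains = do.call(rbind, domains),
       rt_rel = c(rt_s, rt_s + length(rt_cds)), tr = tr)
}

.build_dispersed_vp <- function(kind, k, tr, cassette_id, identity, params) {
  gc <- params$gc_content
  mut <- .mutate_to_identity(tr, identity)
  nf <- sample(80:140, 1)
  cds <- c(strsplit("ATG", "")[[1]], .random_codons(nf, gc), mut$seq,
           strsplit("TAA", "")[[1]])
  strand <- sample(c("+", "-"), 1)
  gid <- sprintf("%s_%d", if (kind == "remote_VP") "rvp" else "hom", k)
  L <- length(mut$seq)
  hit_s <- if (strand == "+") 3L + 3L * nf else length(cds) - 3L * nf - 3L - L
  prot_len <- length(cds) / 3L - 1L
  list(seq = .seq_of(.strand_seg(cds, strand)),
       genes = .gene_row(gid, 0L, length(cds), strand, "hypothetical protein"),
       domains = data.frame(gene_id = gid, domain_name = "CLec-like",
                            aa_start = max(1L, nf - 10L), aa_end = prot_len,
                            score = 45, stringsAsFactors = FALSE),
       truth = .truth_row(gid, kind, 0L, length(cds), strand, cassette_id,
                          gid, identity = mut$identity,
                          hit_start = hit_s, hit_end = hit_s + L))
}

.build_simple_cds <- function(id, n_codons, product, gc) {
  cds <- c(strsplit("ATG", "")[[1]], .random_codons(n_codons, gc),
           strsplit("TAA", "")[[1]])
  strand <- sample(c("+", "-"), 1)
  list(seq = .seq_of(.strand_seg(cds, strand)),
       genes = .gene_row(id, 0L, length(cds), strand, product),
       truth = NULL, strand = strand, len = length(cds))
}

.build_decoy <- function(kind, k, params) {
  gc <- params$gc_content
  L <- 3L * sample(40:60, 1)
  c1 <- .random_codons(L / 3L, gc)
  if (kind == "decoy_exact") {
    c2 <- c1
    stats_ <- list(n_mismatch = 0L, n_tr_adenine = 0L, n_codon12 = 0L)
  } else if (kind == "decoy_nonA") {
    pl <- .plant_mismatches(c1, max(8L, round(0.1 * L)), p_A = 0, p_12 = 2 / 3)
    c2 <- pl$vr
    stats_ <- pl
  } else {  # decoy_far: a true-looking pair, just outside any RT window
    pl <- .plant_mismatches(c1, max(8L, round(0.1 * L)), params$p_A,
                            params$p_12)
    c2 <- pl$vr
    stats_ <- pl
  }
  spacer <- .random_dna(sample(150:250, 1), gc)
  seqs <- paste0(.seq_of(c1), .seq_of(spacer), .seq_of(c2))
  s2 <- L + length(spacer)
  iid <- sprintf("%s_%d", kind, k)
  list(seq = seqs,
       genes = NULL,
       truth = .truth_row(iid, kind, 0L, L, "+",
                          identity = 1 - stats_$n_mismatch / L,
                          n_mismatch = stats_$n_mismatch,
                          n_tr_adenine = stats_$n_tr_adenine,
                          n_codon12 = stats_$n_codon12,
                          copy2_start = s2, copy2_end = s2 + L))
}

# ---- placement -----------------------------------------------------------

.forbid_zones <- function(iv, pad) {
  if (nrow(iv) == 0) return(NULL)
  cbind(iv, pad = pad)
}

.overlaps_any <- function(s, e, occ, margin = 300L) {
  if (nrow(occ) == 0) return(FALSE)
  any(occ$start - margin < e & occ$end + margin > s)
}

.place_free <- function(len, lo, hi, occ, margin = 300L, tries = 1000L,
                        forbid = NULL) {
  for (t in seq_len(tries)) {
    if (hi - len <= lo) break
    s <- lo + sample.int(hi - len - lo, 1)
    if (.overlaps_any(s, s + len, occ, margin)) next
    if (!is.null(forbid) &&
        any(forbid$start < s + len + forbid$pad & forbid$end + forbid$pad > s))
      next
    return(s)
  }
  stop("could not place a synthetic feature without overlap after ", tries,
       " attempts")
}

#' Generate a synthetic genome with planted DGR features and a truth table
#'
#' Produces an i.i.d.-background contig carrying, per cassette, an RT CDS
#' derived from the bundled consensus, a non-coding TR, and one or more target
#' CDS whose 3'-terminal VR copies the TR with mismatches drawn per
#' `p_A`/`p_12`; plus dispersed remote VPs and VP homologs at configured TR
#' identities, transposase genes within 10 kbp of cassettes, unrelated filler
#' genes, and three decoy classes (exact duplication; near-repeat with
#' non-adenine mismatches; near-repeat farther than 5 kbp from any RT).
#' Identical `params`/`seed` yield byte-identical output.
#'
#' @param params [synth_params()].
#' @param seed integer seed (default `params$seed`).
#' @return list(genome = [Biostrings::DNAStringSet], genes, domains, truth,
#'   params, seed); `truth` holds realized per-item statistics.
#' @export
generate_genome <- function(params = synth_params(), seed = params$seed) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  contig <- "synth_contig_1"
  gl <- params$genome_len
  rt_cons <- rt_consensus()
  background <- .with_stream(seed, 0L, function()
    .seq_of(.random_dna(gl, params$gc_content)))
  items <- list()
  add <- function(x, idx, constraint) {
    items[[length(items) + 1L]] <<- c(x, list(idx = idx,
                                              constraint = constraint))
  }
  cassettes <- list()
  for (ci in seq_len(params$n_cassettes)) {
    b <- .with_stream(seed, 100L + ci, function()
      .build_cassette(ci, params, rt_cons))
    cassettes[[ci]] <- b
    add(b, 100L + ci, list(kind = "free"))
  }
  pick_cas <- function(k) ((k - 1L) %% max(1L, params$n_cassettes)) + 1L
  if (params$n_cassettes > 0) {
    for (k in seq_len(params$n_remote_vps)) {
      cc <- pick_cas(k)
      add(.with_stream(seed, 200L + k, function()
        .build_dispersed_vp("remote_VP", k, cassettes[[cc]]$tr,
                            cassettes[[cc]]$id, params$remote_identity,
                            params)), 200L + k, list(kind = "away_from_rt"))
    }
    for (k in seq_len(params$n_homologs)) {
      cc <- pick_cas(k)
      add(.with_stream(seed, 300L + k, function()
        .build_dispersed_vp("VP_homolog", k, cassettes[[cc]]$tr,
                            cassettes[[cc]]$id, params$homolog_identity,
                            params)), 300L + k, list(kind = "away_from_rt"))
    }
    for (k in seq_len(params$n_transposases)) {
      b <- .with_stream(seed, 400L + k, function()
        .build_simple_cds(sprintf("tnp_%d", k), sample(250:350, 1),
                          "IS200/IS605 family transposase",
                          params$gc_content))
      b$truth <- .truth_row(sprintf("tnp_%d", k), "transposase", 0L,
                            b$len, b$strand,
                            cassettes[[pick_cas(k)]]$id,
                            sprintf("tnp_%d", k))
      add(b, 400L + k, list(kind = "near_cassette", cassette = pick_cas(k)))
    }
  }
  for (k in seq_len(params$n_filler_genes)) {
    add(.with_stream(seed, 500L + k, function()
      .build_simple_cds(sprintf("fil_%d", k), sample(150:300, 1),
                        "hypothetical protein", params$gc_content)),
      500L + k, list(kind = "away_from_rt"))
  }
  if (params$n_cassettes > 0) {
    for (k in seq_len(params$n_decoys)) {
      add(.with_stream(seed, 600L + k, function()
        .build_decoy("decoy_exact", k, params)), 600L + k,
        list(kind = "in_window", cassette = pick_cas(k)))
      add(.with_stream(seed, 700L + k, function()
        .build_decoy("decoy_nonA", k, params)), 700L + k,
        list(kind = "in_window", cassette = pick_cas(k + 1L)))
      add(.with_stream(seed, 800L + k, function()
        .build_decoy("decoy_far", k, params)), 800L + k,
        list(kind = "far_from_rt"))
    }
  }
  # ---- placement (its own stream; cassettes first, decoys last) ----
  set.seed(.item_seed(seed, 900L))
  occ <- data.frame(start = integer(), end = integer())
  pos <- numeric(length(items))
  cass_pos <- integer(length(cassettes))
  order_kind <- function(kind) match(kind, c("free", "away_from_rt",
                                             "near_cassette", "in_window",
                                             "far_from_rt"))
  ord <- order(vapply(items, function(x) order_kind(x$constraint$kind),
                      numeric(1)),
               vapply(items, function(x) x$idx, numeric(1)))
  rt_abs <- data.frame(start = integer(), end = integer())
  for (t in ord) {
    it <- items[[t]]
    len <- nchar(it$seq)
    con <- it$constraint
    if (con$kind == "free") {
      s <- .place_free(len, 6000L, gl - 1000L, occ)
    } else if (con$kind == "away_from_rt") {
      s <- .place_free(len, 1000L, gl - 1000L, occ,
                       forbid = .forbid_zones(rt_abs, 6000L))
    } else if (con$kind == "near_cassette") {
      cp <- cass_pos[con$cassette]
      clen <- nchar(cassettes[[con$cassette]]$seq)
      s <- NA
      for (tries in 1:200) {
        d <- sample(500:8000, 1)
        cand <- if (stats::runif(1) < 0.5) cp + clen + d else cp - d - len
        if (cand < 500 || cand + len > gl - 500) next
        if (.overlaps_any(cand, cand + len, occ)) next
        s <- cand
        break
      }
      if (is.na(s)) stop("could not place a transposase near cassette")
    } else if (con$kind == "in_window") {
      cp <- cass_pos[con$cassette]
      rtr <- cassettes[[con$cassette]]$rt_rel
      rt_start <- cp + rtr[1]
      s <- NA
      for (tries in 1:200) {
        d <- sample(300:(4800 - len), 1)
        cand <- rt_start - d - len
        if (cand < 0) next
        if (.overlaps_any(cand, cand + len, occ, margin = 100L)) next
        s <- cand
        break
      }
      if (is.na(s)) stop("could not place a decoy inside an RT window")
    } else {  # far_from_rt
      s <- .place_free(len, 1000L, gl - 1000L, occ,
                       forbid = .forbid_zones(rt_abs, 5500L))
    }
    pos[t] <- s
    occ <- rbind(occ, data.frame(start = s, end = s + len))
    ic <- which(vapply(seq_along(cassettes), function(ci)
      items[[t]]$idx == 100L + ci, logical(1)))
    if (length(ic) == 1) {
      cass_pos[ic] <- s
      rtr <- cassettes[[ic]]$rt_rel
      rt_abs <- rbind(rt_abs, data.frame(start = s + rtr[1], end = s + rtr[2]))
    }
  }
  # ---- assemble sequence and absolute tables ----
  chars <- strsplit(background, "", fixed = TRUE)[[1]]
  genes <- list(); truth <- list(); domains <- list()
  for (t in seq_along(items)) {
    it <- items[[t]]
    s <- pos[t]
    chars[(s + 1):(s + nchar(it$seq))] <-
      strsplit(it$seq, "", fixed = TRUE)[[1]]
    shift <- function(df) {
      if (is.null(df) || nrow(df) == 0) return(NULL)
      df$start <- df$start + s
      df$end <- df$end + s
      df$contig <- contig
      for (col in c("copy2_start", "copy2_end", "hit_start", "hit_end")) {
        if (col %in% names(df)) df[[col]] <- df[[col]] + as.integer(s)
      }
      df
    }
    if (!is.null(it$genes)) genes[[length(genes) + 1L]] <- shift(it$genes)
    if (!is.null(it$truth)) truth[[length(truth) + 1L]] <- shift(it$truth)
    if (!is.null(it$domains)) domains[[length(domains) + 1L]] <- it$domains
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(.seq_of(chars), contig))
  genes <- if (length(genes)) do.call(rbind, genes) else .empty_genes()
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth)) {
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  }
  domains <- if (length(domains)) do.call(rbind, domains) else
    data.frame(gene_id = character(), domain_name = character(),
               aa_start = integer(), aa_end = integer(), score = numeric(),
               stringsAsFactors = FALSE)
  # planted CDS must translate cleanly
  for (i in seq_len(nrow(genes))) {
    p <- translate_dna(extract_cds(genome, genes[i, ]))
    stopifnot(!grepl("\\*", substr(p, 1, nchar(p) - 1)))
  }
  list(genome = genome, genes = genes, domains = domains, truth = truth,
       params = params, seed = seed)
}

#' Recompute realized mismatch statistics from the truth table
#'
#' Independent of the detection code path: planted TR/VR (and decoy) pairs are
#' re-extracted from the emitted genome at their recorded coordinates and
#' compared base by base.
#'
#' @param sim result of [generate_genome()].
#' @return data.frame(item_id, kind, cassette, n_mismatch, adenine_fraction,
#'   codon12_fraction) with one row per planted pair.
#' @export
realized_signature <- function(sim) {
  truth <- sim$truth
  genome <- sim$genome
  if (is.null(truth)) return(data.frame())
  rows <- list()
  cmp <- function(tr_chars, vr_chars, frame_known) {
    stopifnot(length(tr_chars) == length(vr_chars))
    mm <- which(tr_chars != vr_chars)
    data.frame(n_mismatch = length(mm),
               adenine_fraction = if (length(mm)) mean(tr_chars[mm] == "A")
                 else NA_real_,
               codon12_fraction = if (length(mm) && frame_known)
                 mean(((mm - 1L) %% 3L) < 2L) else NA_real_)
  }
  get_chars <- function(start, end, strand) {
    strsplit(extract_cds(genome, list(contig = truth$contig[1], start = start,
                                      end = end, strand = strand)),
             "", fixed = TRUE)[[1]]
  }
  vrs <- truth[truth$kind == "VR", , drop = FALSE]
  for (i in seq_len(nrow(vrs))) {
    v <- vrs[i, ]
    tr_row <- truth[truth$kind == "TR" & truth$cassette == v$cassette, ,
                    drop = FALSE]
    tr_chars <- get_chars(tr_row$start, tr_row$end, tr_row$strand)
    vr_chars <- get_chars(v$start, v$end, v$strand)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(item_id = v$item_id, kind = "VR", cassette = v$cassette,
                 stringsAsFactors = FALSE),
      cmp(tr_chars, vr_chars, TRUE))
  }
  dec <- truth[truth$kind %in% c("decoy_exact", "decoy_nonA", "decoy_far"), ,
               drop = FALSE]
  for (i in seq_len(nrow(dec))) {
    d <- dec[i, ]
    c1 <- get_chars(d$start, d$end, "+")
    c2 <- get_chars(d$copy2_start, d$copy2_end, "+")
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(item_id = d$item_id, kind = d$kind, cassette = NA_character_,
                 stringsAsFactors = FALSE),
      cmp(c1, c2, TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic genome bundle to disk
#'
#' Emits genome.fasta, genes.gff3, domains.tsv and truth.tsv into `dir`.
#' @param sim result of [generate_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  utils::write.table(sim$domains, file.path(dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
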
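# Independent oracles used across the suite. These deliberately avoid the
# package's alignment/counting code paths: the aligner oracle enumerates all
# gapped alignments recursively (with caching), the signature oracle recounts
# columns with a plain loop, and the clustering oracle is a direct transcription
# of the greedy rule.

# -- exhaustive affine-gap alignment oracle --------------------------------
# A gap run of length L costs gap_open + L * gap_extend (the package's
# convention). States: "d" = last column consumed both, "ga" = last column was
# a gap in b (consumed a), "gb" = gap in a (consumed b).
enum_global_score <- function(a, b, match = 2, mismatch = -3, gap_open = -5,
                              gap_extend = -2) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  na_ <- length(ca); nb <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > na_ && j > nb) return(0)
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= na_ && j <= nb) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "d"))
    }
    if (i <= na_) {
      g <- if (state == "ga") gap_extend else gap_open + gap_extend
      best <- max(best, g + rec(i + 1L, j, "ga"))
    }
    if (j <= nb) {
      g <- if (state == "gb") gap_extend else gap_open + gap_extend
      best <- max(best, g + rec(i, j + 1L, "gb"))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "d")
}

.enum_cache <- new.env(parent = emptyenv())
enum_global_cached <- function(a, b, ...) {
  key <- paste(a, b, sep = "|")
  hit <- .enum_cache[[key]]
  if (is.null(hit)) {
    hit <- enum_global_score(a, b, ...)
    .enum_cache[[key]] <- hit
  }
  hit
}

# brute-force local score: best global score over all substring pairs, or 0
enum_local_score <- function(a, b, ...) {
  best <- 0
  for (i1 in seq_len(nchar(a))) {
    for (i2 in i1:nchar(a)) {
      sa <- substr(a, i1, i2)
      for (j1 in seq_len(nchar(b))) {
        for (j2 in j1:nchar(b)) {
          best <- max(best, enum_global_cached(sa, substr(b, j1, j2), ...))
        }
      }
    }
  }
  best
}

# all sequences over an alphabet up to a length
all_seqs <- function(alphabet, max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(grid, 1, paste0, collapse = ""))
  }
  out
}

# -- naive signature recount ------------------------------------------------
# Recounts a signature alignment column by column with the documented rules:
# gap and gap-adjacent columns excluded; counting evaluated on the full
# alignment and on the seed-anchored core (between the first and last run of
# >= seed_k consecutive matches), with the core adopted only when the full
# support fails the criteria and the core passes; codon position from the VR
# (row a) offset within its CDS.
recount_signature <- function(aligned_a, aligned_b, vr_cds_offset0 = NULL,
                              seed_k = 8L, min_mismatches = 4L,
                              adenine_min = 0.8, codon12_min = 2 / 3) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  n <- length(ca)
  is_gap <- function(t) ca[t] == "-" || cb[t] == "-"
  # core bounds from match runs
  run <- 0L; core0 <- NA; core1 <- NA; run_start <- NA
  for (t in seq_len(n)) {
    if (!is_gap(t) && ca[t] == cb[t]) {
      if (run == 0L) run_start <- t
      run <- run + 1L
      if (run >= seed_k) {
        if (is.na(core0)) core0 <- run_start
        core1 <- t
      }
    } else run <- 0L
  }
  count_between <- function(lo, hi) {
    n_mm <- 0L; n_a <- 0L; c123 <- c(0L, 0L, 0L)
    off <- -1L
    for (t in seq_len(n)) {
      if (ca[t] != "-") off <- off + 1L
      if (t < lo || t > hi) next
      if (is_gap(t)) next
      if (t > 1 && is_gap(t - 1)) next
      if (t < n && is_gap(t + 1)) next
      if (ca[t] == cb[t]) next
      n_mm <- n_mm + 1L
      if (cb[t] == "A") n_a <- n_a + 1L
      if (!is.null(vr_cds_offset0)) {
        co <- vr_cds_offset0 + off
        p <- co %% 3 + 1
        c123[p] <- c123[p] + 1L
      }
    }
    list(n_mismatch = n_mm, n_tr_adenine = n_a, codon_pos_counts = c123)
  }
  passes <- function(x) {
    if (x$n_mismatch < min_mismatches) return(FALSE)
    af <- x$n_tr_adenine / x$n_mismatch
    cf <- (x$codon_pos_counts[1] + x$codon_pos_counts[2]) / x$n_mismatch
    af > adenine_min && cf >= codon12_min
  }
  full <- count_between(1L, n)
  if (passes(full) || is.na(core0) || (core0 == 1L && core1 == n))
    return(full)
  core <- count_between(core0, core1)
  if (passes(core)) core else full
}

# -- greedy clustering oracle ----------------------------------------------
# direct transcription of the clustering rule: longest-first (ties by id),
# join the first cluster whose representative matches at identity
# (matches / shorter) >= idt with coverage (gap-free columns / shorter) >= cov
brute_greedy <- function(seqs, idt, cov, scheme = NULL) {
  if (is.null(scheme)) {
    scheme <- if (all(!grepl("[^ACGTN]", seqs))) dgrscan::dna_scheme()
      else dgrscan::protein_scheme()
  }
  ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
  clusters <- list()
  for (id in ids) {
    joined <- FALSE
    for (k in seq_along(clusters)) {
      rep_id <- clusters[[k]][1]
      aln <- dgrscan::global_align(seqs[[id]], seqs[[rep_id]], scheme)
      ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
      cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
      both <- ca != "-" & cb != "-"
      shorter <- min(nchar(seqs[[id]]), nchar(seqs[[rep_id]]))
      if (sum(both & ca == cb) / shorter >= idt &&
          sum(both) / shorter >= cov) {
        clusters[[k]] <- c(clusters[[k]], id)
        joined <- TRUE
        break
      }
    }
    if (!joined) clusters[[length(clusters) + 1L]] <- id
  }
  lapply(clusters, sort)
}

# canonical form of a clustering for comparison
partition_of <- function(clusters) {
  sets <- lapply(clusters, function(cl)
    sort(if (is.list(cl)) cl$members else cl))
  sets[order(vapply(sets, function(s) s[1], ""))]
}

# -- misc -------------------------------------------------------------------
random_dna_str <- function(n, gc = 0.45) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

random_protein <- function(n) {
  paste0(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
         collapse = "")
}
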
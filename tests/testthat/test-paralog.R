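test_that("remote targets are classified by the 50% TR-identity rule", {
  expect_equal(classify_remote(0.7), "remote_VP")
  expect_equal(classify_remote(0.45), "VP_homolog")
  # the boundary is inclusive: exactly 50% designates a remote VP
  expect_equal(classify_remote(0.5), "remote_VP")
  expect_equal(classify_remote(0.5, inclusive = FALSE), "VP_homolog")
})

test_that("generator remote VPs and homologs are recovered and classified", {
  sim <- acceptance_sims(1:2)[[1]]
  det <- detect_dgrs(sim$genome, sim$genes)
  own <- unlist(lapply(det$cassettes, function(cs) cs$vrs$target_gene))
  remote <- do.call(rbind, lapply(det$cassettes, function(cs)
    find_remote_targets(sim$genome, sim$genes, cs, sim$domains)))
  remote <- remote[!remote$gene_id %in% own, , drop = FALSE]
  # best row per gene across cassettes
  remote <- remote[order(-remote$best_tr_identity), ]
  remote <- remote[!duplicated(remote$gene_id), ]
  truth <- sim$truth
  for (k in which(truth$kind == "remote_VP")) {
    row <- remote[remote$gene_id == truth$gene_id[k], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$klass, "remote_VP")
    expect_gte(row$best_tr_identity, 0.5)
    expect_true(row$near_3prime)
  }
  for (k in which(truth$kind == "VP_homolog")) {
    row <- remote[remote$gene_id == truth$gene_id[k], ]
    expect_equal(row$klass, "VP_homolog")
    expect_lt(row$best_tr_identity, 0.5)
  }
  # unrelated filler genes without CLec evidence are absent
  expect_false(any(grepl("^fil_", remote$gene_id)))
})

test_that("consensus-similarity fallback admits CLec genes lacking annotations", {
  set.seed(51)
  # gene whose C-terminus is a back-translated CLec consensus and whose tail
  # carries a 70%-identity TR segment
  sim <- generate_genome(synth_params(n_cassettes = 1L, n_remote_vps = 0L,
                                      n_homologs = 0L, n_transposases = 0L,
                                      n_filler_genes = 0L, n_decoys = 0L,
                                      genome_len = 50000L), seed = 9L)
  det <- detect_dgrs(sim$genome, sim$genes)
  cs <- det$cassettes[[1]]
  tr_seq <- extract_cds(sim$genome,
                        list(contig = cs$contig, start = cs$tr[1],
                             end = cs$tr[2], strand = "+"))
  trc <- strsplit(tr_seq, "")[[1]]
  pos <- sample(length(trc), round(0.3 * length(trc)))
  for (p in pos) trc[p] <- sample(setdiff(c("A", "C", "G", "T"), trc[p]), 1)
  cds <- paste0("ATG", back_translate_str(clec_consensus()),
                paste0(trc, collapse = ""), "TAA")
  glen <- Biostrings::width(sim$genome)[1]
  contig2 <- paste0(as.character(sim$genome[[1]]), cds, random_dna_str(100))
  genome2 <- mk_genome(synth_contig_1 = contig2)
  genes2 <- rbind(sim$genes,
                  mk_gene("clec_new", "synth_contig_1", glen,
                          glen + nchar(cds)))
  out <- find_remote_targets(genome2, genes2, cs, domain_annotations = NULL)
  row <- out[out$gene_id == "clec_new", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$klass, "remote_VP")
  # an unrelated gene with neither annotation nor consensus match is absent
  expect_false("fil_x" %in% out$gene_id)
})

test_that("greedy clustering degenerate cases", {
  seqs <- stats::setNames(rep(random_dna_str(60), 5), paste0("s", 1:5))
  cl <- greedy_cluster(seqs, 0.95, 0.9)
  expect_length(cl, 1)
  expect_length(cl[[1]]$members, 5)
  expect_equal(cl[[1]]$representative, "s1")

  set.seed(52)
  dis <- c(a = random_dna_str(60), b = random_dna_str(60),
           c = random_dna_str(60))
  cl2 <- greedy_cluster(dis, 0.95, 0.9)
  expect_length(cl2, 3)
  expect_error(greedy_cluster(character(0)), "empty")
})

test_that("greedy clustering matches the brute-force rule and partitions input", {
  set.seed(53)
  for (rep in 1:8) {
    base <- random_dna_str(40)
    n <- sample(4:8, 1)
    seqs <- stats::setNames(vapply(seq_len(n), function(i) {
      ch <- strsplit(base, "")[[1]]
      nmut <- sample(0:12, 1)
      for (p in sample(40, nmut))
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste0(ch, collapse = "")
    }, ""), paste0("q", seq_len(n)))
    for (thr in c(0.95, 0.8, 0.5)) {
      got <- greedy_cluster(seqs, thr, 0.9)
      expect_equal(partition_of(got), partition_of(brute_greedy(seqs, thr, 0.9)))
      expect_setequal(unlist(lapply(got, `[[`, "members")), names(seqs))
      expect_equal(sum(lengths(lapply(got, `[[`, "members"))), n)
    }
  }
})

test_that("cluster count is non-increasing as the identity threshold drops", {
  set.seed(54)
  base <- random_dna_str(50)
  seqs <- stats::setNames(vapply(1:10, function(i) {
    ch <- strsplit(base, "")[[1]]
    for (p in sample(50, sample(0:20, 1)))
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste0(ch, collapse = "")
  }, ""), paste0("m", 1:10))
  counts <- vapply(c(0.99, 0.9, 0.8, 0.6, 0.4, 0.2),
                   function(t) length(greedy_cluster(seqs, t, 0.5)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identity statistics summarize the pairwise matrix", {
  s <- c(x = "ACGTACGTAC", y = "ACGTACGTAC")
  st <- identity_stats(s)
  expect_equal(st$mean, 1)
  expect_equal(st$min, 1)
  st2 <- identity_stats(c(x = "ACGT", y = "ACGA"))
  expect_equal(st2$mean, 0.75)
  expect_error(identity_stats(c(x = "ACGT")), "two")
  set.seed(55)
  s5 <- stats::setNames(vapply(1:5, function(i) random_dna_str(30), ""),
                        paste0("r", 1:5))
  st5 <- identity_stats(s5)
  expect_equal(st5$mean, mean(st5$matrix[upper.tri(st5$matrix)]))
  expect_true(isSymmetric(st5$matrix))
})

test_that("neighbor joining recovers additive trees and validates input", {
  # three taxa: closed-form branch lengths
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- nj_tree(d)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # x = (5+9-10)/2 = 2, y = 3, z = 7
  bl <- stats::setNames(tr$edge.length[tr$edge[, 2] <= 3],
                        tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))

  set.seed(56)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    true <- ape::rtree(n)
    dd <- cophenetic(true)
    nwk2 <- nj_tree(dd)
    est <- ape::read.tree(text = nwk2)
    expect_equal(phangorn::RF.dist(ape::unroot(true), ape::unroot(est)), 0)
  }

  dna <- matrix(1, 4, 4) - diag(4)
  rownames(dna) <- colnames(dna) <- letters[1:4]
  nwk3 <- nj_tree(dna)
  est3 <- ape::read.tree(text = nwk3)
  expect_equal(length(unique(round(
    est3$edge.length[est3$edge[, 2] <= 4], 8))), 1)

  bad <- matrix(c(0, 1, 2, 0, 0, 1, 0, 0, 0), 3, 3)
  expect_error(nj_tree(bad), "symmetric")
})
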
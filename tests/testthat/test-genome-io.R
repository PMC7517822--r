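test_that("read_fasta handles wrapping, case, order and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 first", "acgt", "ACGT", ">g2", "GGGTTT"), f)
  g <- read_fasta(f)
  expect_equal(names(g), c("g1", "g2"))
  expect_equal(as.character(g[["g1"]]), "ACGTACGT")
  expect_equal(Biostrings::width(g), c(8L, 6L))

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty), 0)
})

test_that("read_fasta rejects duplicate ids and non-IUPAC characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT", ">g1", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate id")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">bad", "AC9T"), f2)
  expect_error(read_fasta(f2), "bad")
})

test_that("FASTA write/read round-trip preserves sequences", {
  g <- mk_genome(c1 = random_dna_str(200), c2 = random_dna_str(157))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g, f)
  g2 <- read_fasta(f)
  expect_equal(as.character(g2), as.character(g))
})

test_that("read_gff3 converts 1-based inclusive to 0-based half-open", {
  fa <- mk_genome(g1 = random_dna_str(100))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g1\t.\tCDS\t1\t9\t.\t+\t0\tID=cds1;product=thing A",
               "g1\t.\tCDS\t11\t40\t.\t-\t0\tID=cds2",
               "g1\t.\tgene\t50\t70\t.\t+\t.\tID=gene3"), f)
  genes <- read_gff3(f, fa)
  expect_equal(nrow(genes), 3)
  expect_equal(genes$start[1], 0L)
  expect_equal(genes$end[1], 9L)
  expect_equal(genes$id, c("cds1", "cds2", "gene3"))
  expect_equal(genes$strand, c("+", "-", "+"))
  expect_equal(genes$product[1], "thing A")
})

test_that("read_gff3 rejects features on unknown contigs", {
  fa <- mk_genome(g1 = random_dna_str(100))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "gX\t.\tCDS\t1\t9\t.\t+\t0\tID=cds1"), f)
  expect_error(read_gff3(f, fa), "unknown contig")
})

test_that("GFF3 coordinate round-trip is the identity", {
  genes <- rbind(mk_gene("a", "c1", 0L, 9L, "+"),
                 mk_gene("b", "c1", 10L, 43L, "-"),
                 mk_gene("c", "c1", 99L, 150L, "+"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  back <- read_gff3(f)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$id, genes$id)
})

test_that("extract_cds is strand-aware with half-open coordinates", {
  g <- mk_genome(c1 = "AACGTT")
  expect_equal(extract_cds(g, mk_gene("x", "c1", 2L, 5L, "+")), "CGT")
  expect_equal(extract_cds(g, mk_gene("x", "c1", 2L, 5L, "-")), "ACG")
  expect_equal(extract_cds(g, mk_gene("x", "c1", 0L, 6L, "+")), "AACGTT")
  expect_error(extract_cds(g, mk_gene("x", "c1", 2L, 9L, "+")), "bounds")
  # minus-strand extraction is the reverse complement of plus-strand
  g2 <- mk_genome(c1 = random_dna_str(80))
  plus <- extract_cds(g2, mk_gene("x", "c1", 13L, 61L, "+"))
  minus <- extract_cds(g2, mk_gene("x", "c1", 13L, 61L, "-"))
  expect_equal(minus, revcomp(plus))
})

test_that("translate_dna follows the standard code with X for fuzzy codons", {
  expect_equal(translate_dna("ATGAAATAA"), "MK*")
  expect_equal(translate_dna(""), "")
  expect_equal(translate_dna("ATN"), "X")
  expect_error(translate_dna("ATGA"), "divisible")
})

test_that("import_domain_hits validates rows and gene references", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\tdomain_name\taa_start\taa_end\tscore", f)
  expect_equal(nrow(import_domain_hits(f)), 0)

  writeLines(c("gene_id\tdomain_name\taa_start\taa_end\tscore",
               "g7\tCLec-like\t120\t260\t41.5"), f)
  d <- import_domain_hits(f)
  expect_equal(d$gene_id, "g7")
  expect_equal(d$aa_end, 260L)

  writeLines(c("gene_id\tdomain_name\taa_start\taa_end\tscore",
               "g7\tCLec-like\t260\t120\t41.5"), f)
  expect_error(import_domain_hits(f), "line 2")

  writeLines(c("gene_id\tdomain_name\taa_start\taa_end\tscore",
               "g9\tkinase\t1\t100\t10"), f)
  genes <- mk_gene("g7", "c1", 0L, 300L)
  expect_error(import_domain_hits(f, genes), "unknown gene")
})
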
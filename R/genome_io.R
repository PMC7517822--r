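#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and validated against the IUPAC nucleotide
#' alphabet; record order is preserved.
#'
#' @param path FASTA file (records may be line-wrapped; lowercase permitted).
#' @return a [Biostrings::DNAStringSet] named by record id (first token of
#'   each header). An empty file yields an empty set.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate id in FASTA: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(raw))
  iupac <- "[^ACGTNRYSWKMBDHV]"
  bad <- grepl(iupac, seqs)
  if (any(bad))
    stop("non-IUPAC characters in record '", ids[bad][1], "'")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a genome assembly to FASTA (wrapped at 70 columns)
#' @param genome a named [Biostrings::DNAStringSet] (or named character).
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

.empty_genes <- function() {
  data.frame(id = character(), contig = character(), start = integer(),
             end = integer(), strand = character(), type = character(),
             product = character(), stringsAsFactors = FALSE)
}

#' Read gene annotations from GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package-internal
#' 0-based half-open convention. Only the conversion happens here; every other
#' function assumes 0-based half-open intervals.
#'
#' @param path GFF3 file.
#' @param genomes optional [Biostrings::DNAStringSet]; when supplied, features
#'   on unknown contigs or out of contig bounds raise an error.
#' @return data.frame with columns id, contig, start, end, strand, type,
#'   product (gene feature table), in file order.
#' @export
read_gff3 <- function(path, genomes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(.empty_genes())
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (col %in% colnames(mc)) {
      v <- mc[[col]]
      if (methods::is(v, "CharacterList") || is.list(v))
        v <- vapply(v, function(x) if (length(x)) paste(x, collapse = ";")
                    else NA_character_, "")
      as.character(v)
    } else rep(NA_character_, length(gr))
  }
  id <- pick("ID")
  parent <- pick("Parent")
  id <- ifelse(is.na(id) | !nzchar(id), parent, id)
  if (any(is.na(id)))
    id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  genes <- data.frame(
    id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    product = pick("product"),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (any(genes$end < genes$start + 1L))
    stop("GFF3 feature with end < start")
  if (!is.null(genomes)) {
    unknown <- !genes$contig %in% names(genomes)
    if (any(unknown))
      stop("feature on unknown contig: ", genes$contig[unknown][1])
    len <- Biostrings::width(genomes)[match(genes$contig, names(genomes))]
    if (any(genes$end > len))
      stop("feature beyond contig end: ", genes$id[genes$end > len][1])
  }
  rownames(genes) <- NULL
  genes
}

#' Write a gene feature table to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive on output.
#'
#' @param genes gene feature data.frame (see [read_gff3()]).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @export
write_gff3 <- function(genes, path, source = "dgrscan") {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- genes$type
  gr$ID <- genes$id
  if (!is.null(genes$product)) gr$product <- genes$product
  gr$source <- source
  gr$phase <- ifelse(genes$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the genomic sequence of a feature, strand-aware
#'
#' @param genome [Biostrings::DNAStringSet] assembly.
#' @param feature one-row gene feature data.frame (or list) with contig,
#'   start, end (0-based half-open) and strand.
#' @return DNA character scalar; reverse-complemented for `-` strand features.
#' @export
extract_cds <- function(genome, feature) {
  contig <- feature$contig
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- Biostrings::width(genome)[match(contig, names(genome))]
  if (feature$start < 0 || feature$end > len || feature$start >= feature$end)
    stop("feature out of contig bounds: [", feature$start, ",", feature$end,
         ") on ", contig, " of length ", len)
  s <- as.character(Biostrings::subseq(genome[[contig]],
                                       start = feature$start + 1L,
                                       end = feature$end))
  if (identical(feature$strand, "-")) s <- revcomp(s)
  s
}

#' Translate a coding sequence (standard genetic code)
#'
#' Stops are rendered `*`; codons containing N translate to `X`.
#'
#' @param dna DNA character scalar with length divisible by 3 (may be empty).
#' @return protein character scalar.
#' @export
translate_dna <- function(dna) {
  if (!nzchar(dna)) return("")
  if (nchar(dna) %% 3 != 0)
    stop("CDS length ", nchar(dna), " not divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     if.fuzzy.codon = "X"))
}

#' Import protein-domain annotations from TSV
#'
#' Expects a tab-separated table with header
#' `gene_id  domain_name  aa_start  aa_end  score` (1-based inclusive protein
#' coordinates), e.g. exported from an external domain caller.
#'
#' @param path TSV file.
#' @param genes optional gene feature table; rows naming unknown genes error.
#' @return data.frame of domain annotations (possibly empty).
#' @export
import_domain_hits <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  need <- c("gene_id", "domain_name", "aa_start", "aa_end", "score")
  lines <- readLines(path)
  empty <- data.frame(gene_id = character(), domain_name = character(),
                      aa_start = integer(), aa_end = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(need %in% names(d)))
    stop("domain TSV missing columns: ", paste(setdiff(need, names(d)),
                                               collapse = ", "))
  if (nrow(d) == 0) return(empty)
  d <- d[, need]
  bad <- which(is.na(d$aa_start) | is.na(d$aa_end) | d$aa_start < 1 |
                 d$aa_end < d$aa_start)
  if (length(bad))
    stop("malformed domain row at line ", bad[1] + 1L)
  if (!is.null(genes)) {
    unknown <- !d$gene_id %in% genes$id
    if (any(unknown))
      stop("domain hit for unknown gene at line ",
           which(unknown)[1] + 1L, ": ", d$gene_id[unknown][1])
  }
  d
}
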
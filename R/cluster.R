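# CD-HIT-style greedy incremental clustering, pairwise identity statistics,
# and a neighbor-joining convenience wrapper.

#' Greedy incremental sequence clustering (CD-HIT style)
#'
#' Sequences are sorted longest-first (ties broken lexicographically by id)
#' and each sequence joins the first existing cluster whose representative it
#' matches at identity (`"shorter"` denominator) at least `identity_thr` with
#' aligned coverage of the shorter sequence at least `coverage_thr`; otherwise
#' it founds a new cluster. Representatives are therefore the longest members.
#'
#' @param seqs named character vector (>= 1 sequence; DNA or protein).
#' @param identity_thr identity threshold in (0, 1], e.g. 0.95 for RT
#'   de-redundancy, 0.99 for de-replication, 0.30 for CLec families.
#' @param coverage_thr aligned-coverage threshold in (0, 1], e.g. 0.9 or 0.3.
#' @param scheme scoring scheme; defaults to DNA/protein by alphabet.
#' @return list of clusters, each `list(representative, members,
#'   identity_to_rep)`; every input appears in exactly one cluster.
#' @export
greedy_cluster <- function(seqs, identity_thr = 0.95, coverage_thr = 0.9,
                           scheme = NULL) {
  if (length(seqs) == 0) stop("greedy_cluster: empty input")
  stopifnot(identity_thr > 0, identity_thr <= 1,
            coverage_thr > 0, coverage_thr <= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("greedy_cluster: sequences must have unique names")
  if (is.null(scheme)) {
    scheme <- if (all(!grepl("[^ACGTN]", seqs))) dna_scheme() else protein_scheme()
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  clusters <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    id <- names(seqs)[i]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_seq <- seqs[[clusters[[ci]]$representative]]
      aln <- global_align(s, rep_seq, scheme)
      cnt <- .aln_counts(aln)
      shorter <- min(nchar(s), nchar(rep_seq))
      pid <- cnt$matches / shorter
      cov <- cnt$gapfree / shorter
      if (pid >= identity_thr && cov >= coverage_thr) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, id)
        clusters[[ci]]$identity_to_rep <- c(clusters[[ci]]$identity_to_rep, pid)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <-
        list(representative = id, members = id, identity_to_rep = 1)
  }
  clusters
}

#' Clusters as a tidy table
#' @param clusters result of [greedy_cluster()].
#' @return data.frame(cluster_id, representative, member, identity_to_rep).
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0)
    return(data.frame(cluster_id = integer(), representative = character(),
                      member = character(), identity_to_rep = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, representative = cl$representative,
               member = cl$members, identity_to_rep = cl$identity_to_rep,
               stringsAsFactors = FALSE)
  }))
}

#' Pairwise global identity statistics of a sequence set
#'
#' All pairwise global alignments are computed and summarized over the strict
#' upper triangle — the statistic behind "average global sequence identity"
#' figures for RT or CLec sets.
#'
#' @param seqs named character vector of >= 2 sequences.
#' @param mode identity denominator, `"columns"` or `"shorter"`.
#' @param scheme scoring scheme; defaults by alphabet.
#' @return list(mean, min, max, matrix) — matrix is symmetric with unit
#'   diagonal.
#' @export
identity_stats <- function(seqs, mode = c("columns", "shorter"),
                           scheme = NULL) {
  mode <- match.arg(mode)
  n <- length(seqs)
  if (n < 2) stop("identity_stats needs at least two sequences")
  if (is.null(scheme)) {
    scheme <- if (all(!grepl("[^ACGTN]", seqs))) dna_scheme() else protein_scheme()
  }
  m <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- percent_identity(global_align(seqs[[i]], seqs[[j]], scheme), mode)
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  up <- m[upper.tri(m)]
  list(mean = mean(up), min = min(up), max = max(up), matrix = m)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()]: validates the matrix, clamps negative
#' branch lengths to zero and returns a newick string. A lightweight utility —
#' not a substitute for maximum-likelihood phylogenetics.
#'
#' @param d symmetric numeric matrix with zero diagonal, size >= 3.
#' @param labels optional tip labels (default rownames of `d`).
#' @return newick character scalar (terminated by `;`).
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (!is.null(labels)) rownames(d) <- colnames(d) <- labels
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::write.tree(tree)
}
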
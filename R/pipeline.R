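# Orchestration: QC -> detection -> remote targets -> neighborhoods ->
# pooled clustering -> summaries, with plain-text reports (TSV/GFF3/JSON).

#' Pipeline run configuration
#'
#' @param detect [detect_config()].
#' @param radius neighborhood radius in bp.
#' @param qc_max_scaffolds assemblies with more scaffolds are excluded.
#' @param rt_cluster_identity,rt_cluster_coverage RT clustering thresholds
#'   (0.95 identity / 0.9 coverage).
#' @param derep_identity de-replication identity (0.99).
#' @param clec_cluster_identity,clec_cluster_coverage CLec-domain clustering
#'   thresholds (0.30 / 0.3).
#' @param seed seed recorded in the manifest and used for any randomized step.
#' @param strict treat ambiguous TR/VR assignments as errors.
#' @return a `dgr_run_config` list.
#' @export
run_config <- function(detect = detect_config(), radius = 10000L,
                       qc_max_scaffolds = 50L,
                       rt_cluster_identity = 0.95, rt_cluster_coverage = 0.9,
                       derep_identity = 0.99,
                       clec_cluster_identity = 0.30,
                       clec_cluster_coverage = 0.3,
                       seed = 1L, strict = FALSE) {
  structure(as.list(environment()), class = "dgr_run_config")
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys are rejected; nested `detect` keys map to [detect_config()].
#' @param path YAML file.
#' @return a `dgr_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$detect)) {
    badd <- setdiff(names(y$detect), names(formals(detect_config)))
    if (length(badd))
      stop("unknown detect config keys: ", paste(badd, collapse = ", "))
    y$detect <- do.call(detect_config, y$detect)
  }
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a `dgr_run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$detect <- unclass(x$detect)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Assembly quality filter
#'
#' Draft assemblies composed of more than `max_scaffolds` scaffolds are
#' excluded (50 scaffolds are kept; 51 are excluded).
#'
#' @param assemblies named list; each element has a `genome`
#'   ([Biostrings::DNAStringSet]).
#' @param max_scaffolds inclusive threshold (default 50).
#' @return list(kept = names, excluded = data.frame(genome, n_scaffolds,
#'   reason)).
#' @export
qc_filter <- function(assemblies, max_scaffolds = 50L) {
  n <- vapply(assemblies, function(a) length(a$genome), integer(1))
  keep <- n <= max_scaffolds
  list(kept = names(assemblies)[keep],
       excluded = data.frame(genome = names(assemblies)[!keep],
                             n_scaffolds = n[!keep],
                             reason = rep(sprintf("more than %d scaffolds",
                                                  max_scaffolds), sum(!keep)),
                             stringsAsFactors = FALSE))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cassette_hull <- function(cs) {
  c(min(cs$rt$start, cs$tr[1], cs$vrs$vr_start),
    max(cs$rt$end, cs$tr[2], cs$vrs$vr_end))
}

# best remote-target row per gene across cassettes
.aggregate_remote <- function(remote) {
  if (nrow(remote) == 0) return(remote)
  remote <- remote[order(-remote$best_tr_identity, remote$cassette), ,
                   drop = FALSE]
  remote <- remote[!duplicated(remote$gene_id), , drop = FALSE]
  remote[order(remote$gene_id), , drop = FALSE]
}

#' Run the full DGR discovery pipeline over one or more genomes
#'
#' Executes QC, RT scanning, near-repeat detection, the mutagenesis signature,
#' cassette assembly, remote-target mapping, neighborhood scans, pooled
#' RT/CLec clustering and summaries, writing every stage's report under
#' `outdir` before the next stage starts. Reruns with identical inputs and
#' configuration produce byte-identical reports.
#'
#' @param inputs named list of assemblies: each element a list with `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (feature table) and optional
#'   `domains` (domain-annotation data.frame).
#' @param outdir output directory, created if needed.
#' @param config [run_config()].
#' @return invisibly, a list with summaries, cassette report, remote targets,
#'   neighborhood summary and cluster tables.
#' @export
run_pipeline <- function(inputs, outdir, config = run_config()) {
  if (length(inputs) == 0) stop("no inputs")
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    stop("inputs must be a named list of assemblies")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(outdir, "config.yaml"))

  qc <- qc_filter(inputs, config$qc_max_scaffolds)
  .write_tsv(qc$excluded, file.path(outdir, "qc_excluded.tsv"))

  all_cassettes <- list()
  all_reports <- list()
  all_rt <- list()
  all_remnants <- list()
  all_pairs <- list()
  all_remote <- list()
  nb_reports <- list()
  summaries <- list()
  rt_prot <- character(0)
  clec_prot <- character(0)

  for (g in qc$kept) {
    inp <- inputs[[g]]
    genome <- inp$genome
    genes <- inp$genes
    det <- detect_dgrs(genome, genes, config$detect)
    if (config$strict && !is.null(det$ambiguous) && nrow(det$ambiguous) > 0)
      stop("ambiguous TR/VR assignment in genome ", g)
    own_targets <- unique(stats::na.omit(unlist(
      lapply(det$cassettes, function(cs) cs$vrs$target_gene))))
    remote <- list()
    for (cs in det$cassettes) {
      r <- find_remote_targets(genome, genes, cs, inp$domains, config$detect)
      r <- r[!r$gene_id %in% own_targets, , drop = FALSE]
      remote[[length(remote) + 1L]] <- r
    }
    remote <- if (length(remote)) do.call(rbind, remote) else
      data.frame(gene_id = character(), contig = character(),
                 best_tr_identity = numeric(), coverage = numeric(),
                 hit_start = integer(), hit_end = integer(),
                 near_3prime = logical(), klass = character(),
                 cassette = character(), stringsAsFactors = FALSE)
    remote <- .aggregate_remote(remote)
    remote <- cbind(genome = rep(g, nrow(remote)), remote)

    # neighborhoods around cassettes and dispersed targets
    reps <- list()
    for (cs in det$cassettes) {
      hull <- .cassette_hull(cs)
      excl <- c(cs$rt$gene_id, stats::na.omit(cs$vrs$target_gene))
      reps[[length(reps) + 1L]] <- neighborhood_report(
        genes, paste0(g, ":", cs$id), cs$contig, hull[1], hull[2],
        config$radius,
        Biostrings::width(genome)[match(cs$contig, names(genome))], excl)
    }
    for (i in seq_len(nrow(remote))) {
      r <- remote[i, ]
      gene <- genes[genes$id == r$gene_id, , drop = FALSE][1, ]
      reps[[length(reps) + 1L]] <- neighborhood_report(
        genes, paste0(g, ":", r$gene_id), gene$contig, gene$start, gene$end,
        config$radius,
        Biostrings::width(genome)[match(gene$contig, names(genome))],
        gene$id)
    }
    nb_reports[[g]] <- reps

    # pooled sequences for cohort clustering
    for (cs in det$cassettes) {
      rt_gene <- genes[genes$id == cs$rt$gene_id, , drop = FALSE][1, ]
      rt_prot[paste0(g, ":", cs$rt$gene_id)] <-
        .translate_feature(genome, rt_gene)$protein
    }
    for (gid in c(own_targets,
                  remote$gene_id[remote$klass == "remote_VP"])) {
      gene <- genes[genes$id == gid, , drop = FALSE][1, ]
      p <- .translate_feature(genome, gene)$protein
      clec_prot[paste0(g, ":", gid)] <-
        substr(p, max(1L, nchar(p) - 199L), nchar(p))
    }

    rep_df <- cassette_report(det$cassettes, g)
    all_reports[[g]] <- rep_df
    all_cassettes[[g]] <- det$cassettes
    all_rt[[g]] <- if (nrow(det$rt_candidates))
      cbind(genome = g, det$rt_candidates) else NULL
    all_remnants[[g]] <- if (nrow(det$remnants))
      cbind(genome = g, det$remnants) else NULL
    all_pairs[[g]] <- if (nrow(det$pairs)) cbind(genome = g, det$pairs)
      else NULL
    all_remote[[g]] <- remote

    targets_per_dgr <- vapply(det$cassettes, function(cs) nrow(cs$vrs),
                              integer(1))
    summaries[[g]] <- data.frame(
      genome = g, n_scaffolds = length(genome), qc_pass = TRUE,
      n_dgrs = length(det$cassettes), n_vps = sum(targets_per_dgr),
      n_remote_vps = sum(remote$klass == "remote_VP"),
      n_vp_homologs = sum(remote$klass == "VP_homolog"),
      n_rt_only_remnants = nrow(det$remnants),
      targets_per_dgr = paste(targets_per_dgr, collapse = ";"),
      stringsAsFactors = FALSE)
    write_gff3(cassette_track(det$cassettes),
               file.path(outdir, paste0(g, "_cassettes.gff3")))
  }
  for (g in qc$excluded$genome) {
    summaries[[g]] <- data.frame(
      genome = g, n_scaffolds = length(inputs[[g]]$genome), qc_pass = FALSE,
      n_dgrs = NA_integer_, n_vps = NA_integer_, n_remote_vps = NA_integer_,
      n_vp_homologs = NA_integer_, n_rt_only_remnants = NA_integer_,
      targets_per_dgr = NA_character_, stringsAsFactors = FALSE)
  }

  bindw <- function(lst, path) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    df <- if (length(lst)) do.call(rbind, lst) else data.frame()
    rownames(df) <- NULL
    .write_tsv(df, path)
    df
  }
  cassette_tbl <- bindw(all_reports, file.path(outdir, "cassettes.tsv"))
  bindw(all_rt, file.path(outdir, "rt_candidates.tsv"))
  bindw(all_remnants, file.path(outdir, "rt_only_remnants.tsv"))
  bindw(all_pairs, file.path(outdir, "repeat_pairs.tsv"))
  remote_tbl <- bindw(all_remote, file.path(outdir, "remote_targets.tsv"))

  nb_tbl <- summarize_neighborhoods(nb_reports)
  .write_tsv(nb_tbl, file.path(outdir, "neighborhood_summary.tsv"))
  nb_feat <- list()
  for (g in names(nb_reports)) {
    for (r in nb_reports[[g]]) {
      f <- r$features
      if (nrow(f) == 0) next
      nb_feat[[length(nb_feat) + 1L]] <- data.frame(
        genome = g, focus_id = r$focus_id, gene_id = f$id,
        distance_bp = f$distance_bp, product = f$product,
        mobile_flag = f$mobile_flag, keyword = f$keyword,
        stringsAsFactors = FALSE)
    }
  }
  nb_feat <- if (length(nb_feat)) do.call(rbind, nb_feat) else
    data.frame(genome = character(), focus_id = character(),
               gene_id = character(), distance_bp = integer(),
               product = character(), mobile_flag = logical(),
               keyword = character(), stringsAsFactors = FALSE)
  .write_tsv(nb_feat, file.path(outdir, "neighborhood_features.tsv"))

  # cohort clustering: de-replication at 0.99, RT clusters at 0.95/0.9,
  # CLec C-terminal clusters at 0.30/0.3
  clusters <- list(rt_derep = NULL, rt = NULL, clec = NULL)
  if (length(rt_prot) > 0) {
    derep <- greedy_cluster(rt_prot, config$derep_identity,
                            config$rt_cluster_coverage)
    .write_tsv(cluster_table(derep), file.path(outdir, "clusters_rt_derep.tsv"))
    reps <- rt_prot[vapply(derep, function(cl) cl$representative, "")]
    rtcl <- greedy_cluster(reps, config$rt_cluster_identity,
                           config$rt_cluster_coverage)
    .write_tsv(cluster_table(rtcl), file.path(outdir, "clusters_rt.tsv"))
    clusters$rt_derep <- derep
    clusters$rt <- rtcl
  }
  if (length(clec_prot) > 0) {
    clcl <- greedy_cluster(clec_prot, config$clec_cluster_identity,
                           config$clec_cluster_coverage)
    .write_tsv(cluster_table(clcl), file.path(outdir, "clusters_clec.tsv"))
    clusters$clec <- clcl
  }

  summary_tbl <- do.call(rbind, summaries[order(names(summaries))])
  rownames(summary_tbl) <- NULL
  .write_tsv(summary_tbl, file.path(outdir, "genome_summaries.tsv"))
  cohort <- summarize_run(summary_tbl)
  .write_tsv(cohort, file.path(outdir, "cohort_summary.tsv"))

  manifest <- list(
    package = "dgrscan",
    version = as.character(utils::packageVersion("dgrscan")),
    seed = config$seed,
    genomes = sort(names(inputs)),
    qc_kept = sort(qc$kept),
    config_md5 = unname(tools::md5sum(file.path(outdir, "config.yaml"))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summaries = summary_tbl, cohort = cohort,
                 cassettes = cassette_tbl, remote = remote_tbl,
                 neighborhoods = nb_tbl, clusters = clusters,
                 cassette_objects = all_cassettes, outdir = outdir))
}

#' Cohort summary: totals and per-genome-normalized feature occurrence
#'
#' Totals and means of DGRs, cassette VPs, remote VPs and VP homologs over
#' QC-passing genomes. Two denominators are reported: all kept genomes
#' (`per_genome`) and only genomes where the feature occurs
#' (`per_genome_present`).
#'
#' @param summaries data.frame of per-genome summaries (see [run_pipeline()]).
#' @return data.frame(feature, total, per_genome, per_genome_present).
#' @export
summarize_run <- function(summaries) {
  if (nrow(summaries) == 0) stop("no summaries")
  kept <- summaries[summaries$qc_pass, , drop = FALSE]
  feat <- c(dgrs = "n_dgrs", vps = "n_vps", remote_vps = "n_remote_vps",
            vp_homologs = "n_vp_homologs", rt_only_remnants = "n_rt_only_remnants")
  rows <- lapply(names(feat), function(f) {
    v <- kept[[feat[[f]]]]
    data.frame(feature = f, total = sum(v),
               per_genome = if (nrow(kept)) sum(v) / nrow(kept) else NA_real_,
               per_genome_present = if (any(v > 0)) sum(v) / sum(v > 0)
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
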
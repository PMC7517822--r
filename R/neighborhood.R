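# Neighborhood inventories: genes within +/- 10 kbp of a cassette or remote
# target, flagged for mobile-element annotations.

#' Genes in the neighborhood of a focus interval
#'
#' Returns features overlapping `[focus_start - radius, focus_end + radius)`
#' (clipped to the contig, 0-based half-open; a gene abutting the window edge
#' is excluded), sorted by start. Focus features themselves are excluded by id.
#'
#' @param genes gene feature table.
#' @param contig contig of the focus.
#' @param focus_start,focus_end focus interval (0-based half-open).
#' @param radius bases scanned on each side (default 10000).
#' @param contig_length optional contig length for clipping the right edge.
#' @param exclude_ids feature ids to drop (the focus genes).
#' @return data.frame of features with an added `distance_bp` column (0 when
#'   overlapping the focus itself).
#' @export
neighborhood_features <- function(genes, contig, focus_start, focus_end,
                                  radius = 10000L, contig_length = NULL,
                                  exclude_ids = character(0)) {
  known <- unique(genes$contig)
  if (!contig %in% known)
    stop("unknown contig: ", contig)
  ws <- max(0L, focus_start - radius)
  we <- focus_end + radius
  if (!is.null(contig_length)) we <- min(we, contig_length)
  sel <- genes$contig == contig & genes$start < we & genes$end > ws &
    !genes$id %in% exclude_ids
  out <- genes[sel, , drop = FALSE]
  out <- out[order(out$start, out$id), , drop = FALSE]
  out$distance_bp <- pmax(0L, pmax(out$start - focus_end,
                                   focus_start - out$end))
  rownames(out) <- NULL
  out
}

#' Flag mobile-element annotations among features
#'
#' Case-insensitive substring match of mobile-element keywords against the
#' product annotation; each feature receives the first matching keyword.
#'
#' @param features gene feature data.frame.
#' @param keywords keywords to match (defaults: transposase, integrase,
#'   mobile element).
#' @return `features` with added logical `mobile_flag` and character
#'   `keyword` columns.
#' @export
flag_mobile_elements <- function(features,
                                 keywords = c("transposase", "integrase",
                                              "mobile element")) {
  prod <- tolower(ifelse(is.na(features$product), "", features$product))
  kw <- rep(NA_character_, nrow(features))
  for (k in keywords) {
    hit <- is.na(kw) & grepl(tolower(k), prod, fixed = TRUE)
    kw[hit] <- k
  }
  features$mobile_flag <- !is.na(kw)
  features$keyword <- kw
  features
}

#' Build a neighborhood report for one focus
#'
#' @param genes gene feature table.
#' @param focus_id label of the focus (cassette or remote-target id).
#' @param contig,focus_start,focus_end focus location.
#' @inheritParams neighborhood_features
#' @param keywords mobile-element keywords.
#' @return list(focus_id, contig, radius, features) with flagged features.
#' @export
neighborhood_report <- function(genes, focus_id, contig, focus_start,
                                focus_end, radius = 10000L,
                                contig_length = NULL,
                                exclude_ids = character(0),
                                keywords = c("transposase", "integrase",
                                             "mobile element")) {
  f <- neighborhood_features(genes, contig, focus_start, focus_end, radius,
                             contig_length, exclude_ids)
  f <- flag_mobile_elements(f, keywords)
  list(focus_id = focus_id, contig = contig, radius = radius, features = f)
}

#' Summarize neighborhood reports per genome and keyword
#'
#' Produces deterministic per-genome totals of flagged features and
#' per-keyword counts, both with and without de-duplication of features shared
#' between overlapping neighborhoods.
#'
#' @param reports named list: `reports[[genome]]` is a list of reports from
#'   [neighborhood_report()].
#' @return data.frame(genome, keyword, n_flagged, n_flagged_unique); zero rows
#'   (with header) when no reports are given. Counts are invariant to the
#'   input order of reports.
#' @export
summarize_neighborhoods <- function(reports) {
  empty <- data.frame(genome = character(), keyword = character(),
                      n_flagged = integer(), n_flagged_unique = integer(),
                      stringsAsFactors = FALSE)
  if (length(reports) == 0) return(empty)
  rows <- list()
  for (g in sort(names(reports))) {
    feats <- lapply(reports[[g]], function(r)
      r$features[r$features$mobile_flag, , drop = FALSE])
    feats <- feats[vapply(feats, nrow, integer(1)) > 0]
    if (length(feats) == 0) next
    all_f <- do.call(rbind, feats)
    for (k in sort(unique(all_f$keyword))) {
      sub <- all_f[all_f$keyword == k, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, keyword = k, n_flagged = nrow(sub),
        n_flagged_unique = length(unique(sub$id)), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
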
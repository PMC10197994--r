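# Duplicate-gene detection and tandem/segmental classification.
#
# A pair of family genes is a duplicate when the local alignment covers
# more than 80% of the longer protein AND exceeds 80% identity. Tightly
# linked same-chromosome copies collapse into one cluster so each cluster
# contributes a single event; events are tandem when the partners sit on
# one chromosome within the tight-linkage window (or within 100 kb), and
# segmental otherwise.

#' Find duplicate gene pairs
#'
#' All unordered member pairs whose optimal local alignment passes both the
#' coverage-of-longer and identity thresholds (strict `>`).
#'
#' @param members Character vector of member gene ids.
#' @param proteins Named [Biostrings::AAStringSet] containing the members.
#' @param min_identity,min_coverage Strict lower bounds (default 0.8 both).
#' @param scoring An [align_scoring()] object.
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `identity`,
#'   `coverage_of_longer`, `score`.
#' @export
find_duplicate_pairs <- function(members, proteins, min_identity = 0.8,
                                 min_coverage = 0.8,
                                 scoring = align_scoring()) {
  missing <- setdiff(members, names(proteins))
  if (length(missing)) {
    stop("find_duplicate_pairs: members without sequence: ",
         paste(missing, collapse = ", "))
  }
  out <- list()
  for (i in seq_along(members)) {
    for (j in seq_len(i - 1L)) {
      a <- members[j]; b <- members[i]
      al <- local_align(proteins[[a]], proteins[[b]], scoring,
                        query_id = a, target_id = b)
      if (al$identity > min_identity && al$coverage > min_coverage) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = a, gene_b = b, identity = al$identity,
          coverage_of_longer = al$coverage, score = al$score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), coverage_of_longer = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

gene_rank_on_chromosome <- function(gene_records) {
  rec <- gene_records[order(gene_records$chromosome, gene_records$start), ]
  rank <- stats::ave(seq_len(nrow(rec)), rec$chromosome, FUN = seq_along)
  stats::setNames(rank, rec$gene_id)
}

#' Collapse tightly linked duplicate pairs into clusters
#'
#' Same-chromosome partners separated by at most `max_intervening` genes
#' (in chromosome coordinate order over all annotated genes) are merged
#' transitively into one cluster; every other gene of a reported pair forms
#' its own cluster. Each cluster contributes one duplication event
#' downstream.
#'
#' @param pairs Pair `data.frame` from [find_duplicate_pairs()].
#' @param gene_records Gene record `data.frame` (all genes, for gene order).
#' @param max_intervening Maximum intervening gene count (default 1).
#' @return `pairs` with an added `cluster_a`/`cluster_b` column pair plus a
#'   `clusters` attribute (named vector gene id -> cluster id).
#' @export
collapse_tight_clusters <- function(pairs, gene_records, max_intervening = 1) {
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  rank <- gene_rank_on_chromosome(gene_records)
  chrom <- stats::setNames(gene_records$chromosome, gene_records$gene_id)
  # union-find over tightly linked reported pairs
  parent <- stats::setNames(genes, genes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[k]; b <- pairs$gene_b[k]
    if (chrom[[a]] == chrom[[b]] &&
        abs(rank[[a]] - rank[[b]]) - 1L <= max_intervening) {
      parent[[find(a)]] <- find(b)
    }
  }
  cluster <- vapply(genes, find, character(1))
  ids <- stats::setNames(sprintf("C%02d", seq_along(unique(cluster))),
                         unique(cluster))
  cluster <- stats::setNames(unname(ids[cluster]), genes)
  pairs$cluster_a <- unname(cluster[pairs$gene_a])
  pairs$cluster_b <- unname(cluster[pairs$gene_b])
  attr(pairs, "clusters") <- cluster
  pairs
}

#' Classify duplication events as tandem or segmental
#'
#' One event per unordered cluster pair (intra-cluster pairs are tandem
#' events by construction: the cluster's copies are tightly linked).
#' A two-cluster event is tandem when the representative partners share a
#' chromosome and lie within `max_span_bp`, segmental otherwise. Every
#' reported event re-asserts the >0.8 identity and coverage thresholds.
#'
#' @param pairs Clustered pair `data.frame` from [collapse_tight_clusters()].
#' @param gene_records Gene record `data.frame`.
#' @param max_span_bp Same-chromosome midpoint distance below which a
#'   two-cluster event still counts as tandem (default 100 kb).
#' @return A `data.frame` of events: `gene_a`, `gene_b`, `identity`,
#'   `coverage_of_longer`, `kind` (`tandem`/`segmental`), `cluster_id`.
#' @export
classify_events <- function(pairs, gene_records, max_span_bp = 1e5) {
  if (nrow(pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), coverage_of_longer = numeric(),
                      kind = character(), cluster_id = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(pairs$identity > 0.8), all(pairs$coverage_of_longer > 0.8))
  chrom <- stats::setNames(gene_records$chromosome, gene_records$gene_id)
  mid <- stats::setNames((gene_records$start + gene_records$end) / 2,
                         gene_records$gene_id)
  key <- ifelse(pairs$cluster_a < pairs$cluster_b,
                paste(pairs$cluster_a, pairs$cluster_b),
                paste(pairs$cluster_b, pairs$cluster_a))
  events <- list()
  for (k in unique(key)) {
    sub <- pairs[key == k, , drop = FALSE]
    best <- sub[which.max(sub$identity), , drop = FALSE]
    a <- best$gene_a; b <- best$gene_b
    same_cluster <- best$cluster_a == best$cluster_b
    kind <- if (same_cluster) "tandem"
            else if (chrom[[a]] == chrom[[b]] &&
                     abs(mid[[a]] - mid[[b]]) <= max_span_bp) "tandem"
            else "segmental"
    events[[length(events) + 1L]] <- data.frame(
      gene_a = a, gene_b = b, identity = best$identity,
      coverage_of_longer = best$coverage_of_longer, kind = kind,
      cluster_id = k, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, events)
}

#' Write duplication events and a circular-plot link file
#'
#' @param events Event `data.frame` from [classify_events()].
#' @param gene_records Gene record `data.frame` (for link coordinates).
#' @param event_path,link_path Output TSV paths (either may be `NULL`).
#' @return Invisibly, a list of the written paths.
#' @export
write_duplication_events <- function(events, gene_records,
                                     event_path = NULL, link_path = NULL) {
  if (!is.null(event_path)) {
    utils::write.table(events, event_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(link_path)) {
    idx_a <- match(events$gene_a, gene_records$gene_id)
    idx_b <- match(events$gene_b, gene_records$gene_id)
    links <- data.frame(
      chrom_a = gene_records$chromosome[idx_a],
      start_a = gene_records$start[idx_a],
      end_a = gene_records$end[idx_a],
      chrom_b = gene_records$chromosome[idx_b],
      start_b = gene_records$start[idx_b],
      end_b = gene_records$end[idx_b]
    )
    utils::write.table(links, link_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(list(events = event_path, links = link_path))
}
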
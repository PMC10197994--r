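# Cross-species projection of a reference co-functional network.
#
# Target and reference proteomes are searched against each other with the
# package's local aligner; the highest-scoring qualifying hit in each
# direction defines a homolog, a reciprocal best-hit pair defines an
# operational ortholog, and a reference edge is transferred whenever both
# endpoints have ortholog counterparts in the target species.

#' Best-hit map between two proteomes
#'
#' For every query protein, the single highest-scoring subject protein with
#' an e-value proxy at or below the cutoff. Score ties are broken towards
#' the lexicographically smaller subject id, with a warning.
#'
#' @param queries,subjects Named [Biostrings::AAStringSet]s.
#' @param evalue_cutoff Maximum e-value proxy (default 1e-5).
#' @param scoring An [align_scoring()] object.
#' @param stats Optional precomputed [align_stats_matrix()] result
#'   (queries x subjects).
#' @return Named character vector query id -> best subject id (queries with
#'   no qualifying hit are absent).
#' @export
best_hit_map <- function(queries, subjects, evalue_cutoff = 1e-5,
                         scoring = align_scoring(), stats = NULL) {
  stopifnot(length(queries) > 0L, length(subjects) > 0L)
  if (is.null(stats)) stats <- align_stats_matrix(queries, subjects, scoring)
  score <- stats$score
  score[stats$evalue > evalue_cutoff] <- -Inf
  out <- character(0)
  tied <- character(0)
  ord <- order(colnames(score))  # lexicographic tie-break
  score <- score[, ord, drop = FALSE]
  for (q in rownames(score)) {
    s <- score[q, ]
    if (all(!is.finite(s))) next
    best <- which.max(s)
    if (sum(s == s[best]) > 1L) tied <- c(tied, q)
    out[q] <- colnames(score)[best]
  }
  if (length(tied)) {
    warning("best_hit_map: score ties broken lexicographically for: ",
            paste(tied, collapse = ", "))
  }
  out
}

#' Reciprocal best-hit ortholog pairs
#'
#' `(a, b)` is kept iff `map_ab[a] == b` and `map_ba[b] == a`.
#'
#' @param map_ab,map_ba Named best-hit maps from [best_hit_map()].
#' @return A `data.frame` with columns `target_id`, `reference_id`.
#' @export
reciprocal_pairs <- function(map_ab, map_ba) {
  keep <- !is.na(map_ba[map_ab]) & map_ba[map_ab] == names(map_ab)
  keep[is.na(keep)] <- FALSE
  data.frame(target_id = names(map_ab)[keep],
             reference_id = unname(map_ab[keep]),
             stringsAsFactors = FALSE)
}

#' Project a reference network onto the target species
#'
#' A target edge `(t1, t2)` exists iff a reference edge `(r1, r2)` exists
#' with `t1 <-> r1` and `t2 <-> r2` in the ortholog pairing. Self-loops are
#' dropped and duplicate edges merged, so the result is a simple undirected
#' graph.
#'
#' @param reference_edges Two-column `data.frame` (or matrix) of reference
#'   gene pairs.
#' @param pairs Ortholog pairs from [reciprocal_pairs()] (unique per target
#'   and per reference id).
#' @return An [igraph::igraph] undirected simple graph over target ids.
#' @export
project_network <- function(reference_edges, pairs) {
  stopifnot(!anyDuplicated(pairs$target_id), !anyDuplicated(pairs$reference_id))
  ref2tgt <- stats::setNames(pairs$target_id, pairs$reference_id)
  e1 <- ref2tgt[as.character(reference_edges[[1L]])]
  e2 <- ref2tgt[as.character(reference_edges[[2L]])]
  keep <- !is.na(e1) & !is.na(e2) & e1 != e2
  g <- igraph::graph_from_data_frame(
    data.frame(from = e1[keep], to = e2[keep]),
    directed = FALSE,
    vertices = data.frame(name = sort(unique(pairs$target_id)))
  )
  igraph::simplify(g)
}

#' Extract a family-centred subnetwork
#'
#' Induced subgraph on the seed genes and their neighbourhoods up to `hops`
#' edges away, with the number of distinct interactors of each seed.
#'
#' @param net An [igraph::igraph] graph from [project_network()].
#' @param seed_ids Seed gene ids (missing seeds are dropped with a warning).
#' @param hops Neighbourhood radius in edges (default 1; 0 = seeds only).
#' @return A list with `graph` (the subnetwork), `degree`
#'   (`data.frame`: `seed`, `interactors` counted in the full network) and
#'   `nodes`/`edges` counts.
#' @export
extract_subnetwork <- function(net, seed_ids, hops = 1) {
  present <- intersect(seed_ids, igraph::V(net)$name)
  missing <- setdiff(seed_ids, present)
  if (length(missing)) {
    warning("extract_subnetwork: seed(s) absent from network: ",
            paste(missing, collapse = ", "))
  }
  if (!length(present)) {
    stop("extract_subnetwork: no seed is present in the network")
  }
  nb <- igraph::ego(net, order = hops, nodes = present)
  keep <- unique(c(present, unlist(lapply(nb, function(v) v$name))))
  sub <- igraph::induced_subgraph(net, keep)
  deg <- data.frame(
    seed = present,
    interactors = as.integer(igraph::degree(net, present)),
    stringsAsFactors = FALSE
  )
  list(graph = sub, degree = deg,
       nodes = igraph::vcount(sub), edges = igraph::ecount(sub))
}

#' Write a network as an edge-list TSV (and optional GraphML)
#'
#' @param net An [igraph::igraph] graph.
#' @param edge_path Output TSV path for the two-column edge list.
#' @param graphml_path Optional GraphML path for viewer import.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  el <- igraph::as_edgelist(net)
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(net, graphml_path, format = "graphml")
  }
  invisible(list(edges = edge_path, graphml = graphml_path))
}
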
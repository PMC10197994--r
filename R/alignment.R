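# Local protein alignment with BLAST-like scoring semantics.
#
# Scores come from exact Smith-Waterman dynamic programming with affine gaps
# (via Biostrings); significance is summarised by a Karlin-Altschul e-value
# proxy K*m*n*exp(-lambda*score) so the familiar 1e-5 cutoff keeps its
# meaning without a BLAST dependency.

#' Alignment scoring parameters
#'
#' @param matrix Substitution matrix name (passed to Biostrings).
#' @param gap_open Gap opening penalty; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend Gap extension penalty per gapped residue.
#' @param lambda,K Karlin-Altschul constants used by the e-value proxy
#'   (defaults are the gapped BLOSUM62/11/1 values).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041) {
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "align_scoring")
}

#' Karlin-Altschul e-value proxy
#'
#' `K * m * n * exp(-lambda * score)` for a local alignment of score `score`
#' between sequences of lengths `m` and `n`.
#'
#' @param score Alignment score(s).
#' @param m,n Sequence lengths.
#' @param scoring An [align_scoring()] object.
#' @return Numeric e-value proxy, decreasing in `score`.
#' @export
evalue_proxy <- function(score, m, n, scoring = align_scoring()) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}

as_aa <- function(x, arg) {
  if (methods::is(x, "AAString")) return(x)
  if (is.character(x) && length(x) == 1L) return(Biostrings::AAString(x))
  stop("expected a single AAString or character sequence for ", arg)
}

#' Optimal local alignment of two proteins
#'
#' Exact Smith-Waterman alignment with affine gap penalties. Identity is the
#' fraction of alignment columns (gap columns included) with identical
#' residues; coverage is the alignment length divided by the length of the
#' longer input, matching the "covered >80% of the longer gene" convention
#' used for both identification and duplication calling. When no positive
#' scoring alignment exists the result is an empty hit with score 0.
#'
#' @param a,b Sequences ([Biostrings::AAString] or character).
#' @param scoring An [align_scoring()] object.
#' @param query_id,target_id Optional identifiers carried into the result.
#' @return A list of class `alignment_result` with fields `query_id`,
#'   `target_id`, `score`, `identity`, `coverage`, `evalue_proxy`,
#'   `alignment_length`.
#' @export
local_align <- function(a, b, scoring = align_scoring(),
                        query_id = NA_character_, target_id = NA_character_) {
  a <- as_aa(a, "a"); b <- as_aa(b, "b")
  if (length(a) == 0L || length(b) == 0L) stop("local_align: empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  sc <- Biostrings::score(pa)
  m <- length(a); n <- length(b)
  if (sc <= 0) {
    res <- list(query_id = query_id, target_id = target_id, score = 0,
                identity = 0, coverage = 0,
                evalue_proxy = evalue_proxy(0, m, n, scoring),
                alignment_length = 0L)
  } else {
    len <- Biostrings::nchar(pa)
    res <- list(query_id = query_id, target_id = target_id, score = sc,
                identity = Biostrings::nmatch(pa) / len,
                coverage = min(1, len / max(m, n)),
                evalue_proxy = evalue_proxy(sc, m, n, scoring),
                alignment_length = len)
  }
  class(res) <- "alignment_result"
  res
}

#' All-vs-all local alignment statistics between two proteomes
#'
#' Vectorised Smith-Waterman of every query against every target. Used by
#' candidate screening, duplicate detection and reciprocal-best-hit mapping
#' so that one scoring contract covers the whole pipeline.
#'
#' @param queries,targets Named [Biostrings::AAStringSet]s.
#' @param scoring An [align_scoring()] object.
#' @return A list of matrices (`score`, `identity`, `coverage`, `evalue`)
#'   with one row per query and one column per target.
#' @export
align_stats_matrix <- function(queries, targets, scoring = align_scoring()) {
  stopifnot(length(queries) > 0L, length(targets) > 0L)
  nq <- length(queries); nt <- length(targets)
  score <- matrix(0, nq, nt, dimnames = list(names(queries), names(targets)))
  ident <- score; cover <- score
  qlen <- Biostrings::width(queries)
  for (j in seq_len(nt)) {
    pa <- Biostrings::pairwiseAlignment(
      queries, targets[[j]], type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
    )
    sc <- Biostrings::score(pa)
    len <- Biostrings::nchar(pa)
    nm <- Biostrings::nmatch(pa)
    pos <- sc > 0
    score[, j] <- ifelse(pos, sc, 0)
    ident[, j] <- ifelse(pos, nm / len, 0)
    cover[, j] <- ifelse(pos, pmin(1, len / pmax(qlen, Biostrings::width(targets)[j])), 0)
  }
  ev <- evalue_proxy(score, outer(qlen, Biostrings::width(targets)), n = 1, scoring)
  # outer() above already carries m*n, so pass n = 1
  list(score = score, identity = ident, coverage = cover, evalue = ev)
}

#' Screen a target proteome for family candidates
#'
#' A target protein is a candidate when at least one reference protein aligns
#' to it with coverage of the longer sequence at or above `min_coverage` and
#' an e-value proxy at or below `evalue_cutoff`. The returned ids are
#' deduplicated and keep the input order of the target proteome.
#'
#' @param references Reference family proteins ([Biostrings::AAStringSet]).
#' @param targets Target proteome ([Biostrings::AAStringSet]).
#' @param min_coverage Minimum coverage fraction (default 0.80).
#' @param evalue_cutoff Maximum e-value proxy (default 1e-5).
#' @param scoring An [align_scoring()] object.
#' @param stats Optional precomputed [align_stats_matrix()] result.
#' @return Character vector of candidate target ids.
#' @export
screen_candidates <- function(references, targets, min_coverage = 0.80,
                              evalue_cutoff = 1e-5, scoring = align_scoring(),
                              stats = NULL) {
  stopifnot(length(references) > 0L, length(targets) > 0L)
  if (is.null(stats)) stats <- align_stats_matrix(references, targets, scoring)
  ok <- stats$coverage >= min_coverage & stats$evalue <= evalue_cutoff
  hit <- colnames(stats$score)[colSums(ok) > 0L]
  names(targets)[names(targets) %in% hit]
}
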
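# Consensus-block domain scanning.
#
# Family membership requires both the serine/threonine protein kinase domain
# and at least one EF-hand calcium-binding motif. Profile HMM scanning is
# replaced by ungapped consensus-block scoring: a window scores the summed
# BLOSUM62 similarity to a fixed consensus block, and a hit requires at
# least a stated fraction of the block's self-score.

# Fixed consensus blocks. The kinase block carries the hallmark VAIK / HRD /
# DFG catalytic anchors of the Ser/Thr kinase domain; the EF-hand block is a
# canonical helix-loop-helix with the DxDxDG calcium-binding loop.
KINASE_CONSENSUS <- paste0(
  "GKVYLAREKGSGKFYALKVLKKATIVKLGVEHVHRDLKPENFLFADGSELKVIDFGLSAK"
)
EFHAND_CONSENSUS <- "ELKEAFRVFDKDGDGFISAAELRHVMTNL"

#' Domain models used by the family filter
#'
#' Each model is a fixed amino-acid consensus block plus a score threshold
#' expressed as a fraction of the block's self-alignment score.
#'
#' @param min_score_frac Fraction of the maximal (self) block score a window
#'   must reach to count as a hit (default 0.6).
#' @return A named list of models, one per domain label (`kinase`,
#'   `EF-hand`), each with `consensus`, `width`, `max_score`, `threshold`.
#' @export
domain_models <- function(min_score_frac = 0.6) {
  build <- function(consensus) {
    res <- strsplit(consensus, "")[[1]]
    mx <- blosum62_matrix()
    max_score <- sum(mx[cbind(res, res)])
    list(consensus = consensus, width = length(res),
         max_score = max_score, threshold = min_score_frac * max_score)
  }
  list("kinase" = build(KINASE_CONSENSUS), "EF-hand" = build(EFHAND_CONSENSUS))
}

blosum62_cache <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

#' Scan a protein for consensus-block domain hits
#'
#' Slides each domain's consensus block along the protein, scoring every
#' ungapped window by summed BLOSUM62 similarity. Windows at or above the
#' model threshold are reported greedily best-first, discarding windows that
#' overlap an already accepted hit of the same domain.
#'
#' @param protein A single sequence ([Biostrings::AAString] or character).
#' @param models Domain models from [domain_models()].
#' @param protein_id Identifier carried into the hits.
#' @return A `data.frame` with columns `protein_id`, `domain`, `start`,
#'   `end`, `score` (best hit first per domain); zero rows when nothing
#'   reaches threshold.
#' @export
scan_domains <- function(protein, models = domain_models(),
                         protein_id = NA_character_) {
  seq <- strsplit(as.character(protein), "")[[1]]
  L <- length(seq)
  mx <- blosum62_matrix()
  out <- list()
  for (label in names(models)) {
    mod <- models[[label]]
    w <- mod$width
    if (L < w) next
    cons <- strsplit(mod$consensus, "")[[1]]
    nwin <- L - w + 1L
    sc <- numeric(nwin)
    for (j in seq_len(w)) {
      sc <- sc + mx[cbind(cons[j], seq[j:(j + nwin - 1L)])]
    }
    cand <- which(sc >= mod$threshold)
    cand <- cand[order(-sc[cand], cand)]
    taken_start <- integer(0)
    for (s in cand) {
      if (any(abs(taken_start - s) < w)) next
      taken_start <- c(taken_start, s)
      out[[length(out) + 1L]] <- data.frame(
        protein_id = protein_id, domain = label,
        start = s, end = s + w - 1L, score = sc[s],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(), domain = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Scan a whole proteome for domain hits
#'
#' @param proteins A named [Biostrings::AAStringSet].
#' @param models Domain models from [domain_models()].
#' @return A `data.frame` of hits across all proteins (see [scan_domains()]).
#' @export
scan_proteome_domains <- function(proteins, models = domain_models()) {
  hits <- lapply(names(proteins), function(id) {
    scan_domains(proteins[[id]], models, protein_id = id)
  })
  do.call(rbind, hits)
}

#' Confirm family members by the dual-domain rule
#'
#' A candidate is confirmed when its domain hits include at least one
#' `kinase` and at least one `EF-hand` label.
#'
#' @param candidates Character vector of candidate protein ids.
#' @param domain_hits A hit `data.frame` as from [scan_proteome_domains()].
#' @param require_both Keep the dual-domain requirement (default `TRUE`);
#'   with `FALSE` a single domain of either label suffices.
#' @return Character vector of confirmed member ids (a subset of
#'   `candidates`, input order preserved).
#' @export
confirm_members <- function(candidates, domain_hits, require_both = TRUE) {
  if (length(candidates) == 0L) return(character(0))
  has <- function(label) {
    unique(domain_hits$protein_id[domain_hits$domain == label])
  }
  kin <- has("kinase"); ef <- has("EF-hand")
  keep <- if (require_both) candidates %in% kin & candidates %in% ef
          else candidates %in% kin | candidates %in% ef
  candidates[keep]
}

#' Assemble a family table for confirmed members
#'
#' Members are ordered by chromosome label and start coordinate, named with
#' a zero-padded rank (`TrCDPK01`, ...), and joined with their gene records
#' and protein lengths.
#'
#' @param members Character vector of confirmed member gene ids.
#' @param gene_records Gene record `data.frame` from [read_gff3()].
#' @param proteins Named [Biostrings::AAStringSet] containing the members.
#' @param groups Optional named character vector gene id -> group label;
#'   missing ids are reported as `ungrouped`.
#' @param prefix Name prefix for the rank-based member names.
#' @return A family table `data.frame` (see [load_family_table()]).
#' @export
build_family_table <- function(members, gene_records, proteins, groups = NULL,
                               prefix = "TrCDPK") {
  missing_ann <- setdiff(members, gene_records$gene_id)
  if (length(missing_ann)) {
    stop("build_family_table: members without annotation: ",
         paste(missing_ann, collapse = ", "))
  }
  missing_seq <- setdiff(members, names(proteins))
  if (length(missing_seq)) {
    stop("build_family_table: members without protein sequence: ",
         paste(missing_seq, collapse = ", "))
  }
  rec <- gene_records[match(members, gene_records$gene_id), ]
  ord <- order(rec$chromosome, rec$start)
  rec <- rec[ord, ]
  ids <- rec$gene_id
  grp <- if (is.null(groups)) rep("ungrouped", length(ids)) else {
    g <- unname(groups[ids])
    g[is.na(g)] <- "ungrouped"
    g
  }
  width <- max(2L, nchar(length(ids)))
  data.frame(
    name = sprintf("%s%0*d", prefix, width, seq_along(ids)),
    locus = ids,
    chromosome = rec$chromosome,
    start = rec$start,
    end = rec$end,
    group = grp,
    intron = rec$intron_count,
    length_aa = Biostrings::width(proteins)[match(ids, names(proteins))],
    stringsAsFactors = FALSE
  )
}
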
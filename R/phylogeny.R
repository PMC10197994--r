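# Distance-based phylogeny: p-distances, neighbor joining, nonparametric
# column bootstrap, and clade-based assignment of members to reference
# groups I-IV.

aln_to_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- aln
  } else {
    if (methods::is(aln, "AAStringSet")) {
      chars <- strsplit(as.character(aln), "")
      ids <- names(aln)
    } else if (is.character(aln)) {
      chars <- strsplit(aln, "")
      ids <- names(aln)
    } else stop("unsupported alignment representation")
    w <- lengths(chars)
    if (length(unique(w)) != 1L) stop("alignment rows differ in length")
    m <- do.call(rbind, chars)
    rownames(m) <- ids
  }
  if (is.null(rownames(m))) stop("alignment must carry sequence ids")
  m
}

#' Uncorrected p-distance matrix from a multiple alignment
#'
#' `d(i, j)` is the fraction of mismatching residues over the columns where
#' both rows carry a residue (pairwise deletion of gap positions).
#'
#' @param aln Aligned sequences: an [Biostrings::AAStringSet] of equal-width
#'   rows, a named character vector, or a character matrix (gap = `-`).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  m <- aln_to_matrix(aln)
  if (nrow(m) < 3L) stop("p_distance_matrix: need at least 3 sequences")
  nongap <- (m != "-" & m != ".") * 1
  comp <- nongap %*% t(nongap)
  match <- matrix(0, nrow(m), nrow(m))
  for (ch in setdiff(unique(as.vector(m)), c("-", "."))) {
    x <- (m == ch) * 1
    match <- match + x %*% t(x)
  }
  off <- comp == 0 & row(comp) != col(comp)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1L, ]
    stop("p_distance_matrix: no comparable columns between ",
         rownames(m)[bad[1L]], " and ", rownames(m)[bad[2L]])
  }
  d <- (comp - match) / pmax(comp, 1)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration. Negative branch-length estimates are
#' clamped to zero with the deficit shifted to the sister edge, so the path
#' length between the joined pair is preserved. On tree-additive matrices
#' the generating topology and branch lengths are recovered exactly.
#'
#' @param D Symmetric distance matrix with zero diagonal, `n >= 3`, with
#'   row/column names.
#' @return An unrooted [ape::phylo] tree (basal trifurcation).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D)
  if (is.null(rownames(D))) rownames(D) <- paste0("t", seq_len(nrow(D)))
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("neighbor_joining: distance matrix must be symmetric")
  }
  n0 <- nrow(D)
  if (n0 < 3L) stop("neighbor_joining: need at least 3 taxa")

  # every active node is a Newick fragment string
  frag <- rownames(D)
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)[1L, ]
    i <- min(idx); j <- max(idx)
    dij <- D[i, j]
    li <- 0.5 * dij + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    l <- clamp_pair(li, lj)
    new_frag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], l[1L], frag[j], l[2L])
    dnew <- 0.5 * (D[i, ] + D[j, ] - dij)
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  ls <- c(l1, l2, l3)
  for (k in seq_len(3L)) {
    if (ls[k] < 0) {
      sis <- if (k == 3L) 1L else k + 1L
      ls[sis] <- ls[sis] + ls[k]
      ls[k] <- 0
    }
  }
  ls <- pmax(ls, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1L], ls[1L], frag[2L], ls[2L], frag[3L], ls[3L])
  ape::read.tree(text = nwk)
}

tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (k in seq_along(pp)) {
    side <- sort(labs[pp[[k]]])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and scores each internal edge of the full-data tree by the
#' percentage of replicates containing its bipartition. Supports are stored
#' as internal node labels (0-100); with `n_replicates = 0` the topology is
#' returned without supports.
#'
#' @param aln Alignment accepted by [p_distance_matrix()].
#' @param n_replicates Bootstrap replicate count (study default 1000).
#' @param seed Integer seed for the column resampling.
#' @return An [ape::phylo] tree; internal node labels carry supports.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000, seed = 1) {
  m <- aln_to_matrix(aln)
  if (ncol(m) < 2L) stop("bootstrap_support: need at least 2 columns")
  main <- neighbor_joining(p_distance_matrix(m))
  if (n_replicates <= 0) return(main)
  set.seed(seed)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    tr <- try(neighbor_joining(p_distance_matrix(m[, idx, drop = FALSE])),
              silent = TRUE)
    if (inherits(tr, "try-error")) next
    for (k in tree_bipartitions(tr)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
    }
  }
  tips <- sort(main$tip.label)
  pp <- ape::prop.part(main)
  labs <- attr(pp, "labels")
  node_lab <- character(main$Nnode)
  for (k in seq_along(pp)) {
    side <- sort(labs[pp[[k]]])
    if (length(side) >= length(tips) - 1L) { node_lab[k] <- ""; next }
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    hits <- if (is.null(counts[[key]])) 0 else counts[[key]]
    node_lab[k] <- format(round(100 * hits / n_replicates, 1))
  }
  main$node.label <- node_lab
  main
}

#' Assign family members to reference groups from a phylogeny
#'
#' For every non-reference leaf the smallest bipartition side containing it
#' together with at least one labelled reference leaf is located; the member
#' inherits the reference group when all reference leaves in that side agree,
#' and is `ungrouped` otherwise.
#'
#' @param tree An [ape::phylo] tree containing member and reference leaves.
#' @param reference_labels Named character vector: reference leaf ->
#'   group label.
#' @return Named character vector: member leaf -> group (or `ungrouped`).
#' @export
assign_groups <- function(tree, reference_labels) {
  refs <- intersect(tree$tip.label, names(reference_labels))
  if (!length(refs)) stop("assign_groups: tree contains no reference leaves")
  members <- setdiff(tree$tip.label, refs)
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(s) labs[s])
  sides <- c(sides, as.list(tips))  # pendant edges
  all_sides <- list()
  for (s in sides) {
    all_sides[[length(all_sides) + 1L]] <- s
    all_sides[[length(all_sides) + 1L]] <- setdiff(tips, s)
  }
  out <- stats::setNames(rep("ungrouped", length(members)), members)
  for (mber in members) {
    best <- NULL
    for (s in all_sides) {
      if (!(mber %in% s)) next
      if (!any(refs %in% s)) next
      if (is.null(best) || length(s) < length(best)) best <- s
    }
    if (is.null(best)) next
    g <- unique(reference_labels[intersect(best, refs)])
    if (length(g) == 1L) out[mber] <- g
  }
  out
}

#' Multiple alignment of protein sequences
#'
#' Aligns a protein set with MAFFT (default parameters, deterministic) and
#' returns the aligned rows. A pre-computed alignment can be supplied to any
#' downstream function instead, so the aligner itself stays replaceable.
#'
#' @param seqs Named [Biostrings::AAStringSet] of unaligned proteins.
#' @return A named [Biostrings::AAStringSet] of equal-width aligned rows.
#' @export
align_proteins <- function(seqs) {
  if (Sys.which("mafft") == "") {
    stop("align_proteins: the 'mafft' executable is required on the PATH")
  }
  tin <- tempfile(fileext = ".faa")
  tout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  write_fasta(seqs, tin)
  status <- system2("mafft", c("--quiet", "--anysymbol", tin), stdout = tout)
  if (status != 0L) stop("align_proteins: mafft failed with status ", status)
  aln <- Biostrings::readAAStringSet(tout)
  aln <- Biostrings::AAStringSet(toupper(as.character(aln)))
  aln[match(names(seqs), names(aln))]
}

#' Write a tree to Newick
#'
#' Internal node labels (bootstrap supports) are preserved.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
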
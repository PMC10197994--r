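# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results by brute force and stay independent
# of the code paths they verify.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Naive Smith-Waterman with affine gaps (Gotoh three-state recursion),
# written directly from the recurrences. A gap of length L costs
# open + L * ext, matching BLAST's gap-existence/extension convention.
naive_sw_affine <- function(a, b, open = 11, ext = 1, mx = blosum62()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mx[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Hypergeometric upper tail by direct summation of the pmf.
brute_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Random additive distance matrix from a random tree with known branch
# lengths; the generating tree is the oracle.
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Exhaustive re-derivation of a projected edge set.
brute_project <- function(edges, pairs) {
  r2t <- stats::setNames(pairs$target_id, pairs$reference_id)
  out <- character(0)
  for (k in seq_len(nrow(edges))) {
    t1 <- r2t[edges[[1]][k]]; t2 <- r2t[edges[[2]][k]]
    if (is.na(t1) || is.na(t2) || t1 == t2) next
    out <- c(out, paste(min(t1, t2), max(t1, t2)))
  }
  sort(unique(out))
}

graph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# Breadth-first re-derivation of an <=hops neighbourhood from an edge list.
brute_neighbourhood <- function(edges, seeds, hops) {
  frontier <- seeds
  seen <- seeds
  for (h in seq_len(hops)) {
    nxt <- c(edges$to[edges$from %in% frontier],
             edges$from[edges$to %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  sort(seen)
}

# Unrooted topology + branch length agreement via path-length matrices.
same_unrooted_tree <- function(a, b, tol = 1e-8) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  da <- ape::cophenetic.phylo(a)
  db <- ape::cophenetic.phylo(b)[rownames(da), colnames(da)]
  if (max(abs(da - db)) > tol) return(FALSE)
  ape::dist.topo(ape::unroot(a), ape::unroot(b)) == 0
}
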
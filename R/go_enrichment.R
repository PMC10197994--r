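# GO term enrichment with an elim-style hierarchy correction.
#
# Each term is tested by the hypergeometric upper tail (one-sided Fisher);
# the elim pass walks the ontology leaves-to-root and, whenever a term is
# significant at alpha, removes its genes from all ancestor terms before
# they are tested, so parents are not called significant merely by
# inheriting a child's signal.

#' Upper-tail hypergeometric test
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes in a study set of `n`, when `K` of the `N`
#' population genes are annotated.
#'
#' @param k Study genes annotated to the term.
#' @param n Study set size.
#' @param K Population genes annotated to the term.
#' @param N Population size.
#' @return The p-value in (0, 1].
#' @export
hypergeometric_test <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || k > min(n, K) || n > N || K > N) {
    stop("hypergeometric_test: inconsistent counts")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read an ontology from a child-parent pair list
#'
#' @param path TSV with columns `term`, `parent`, `namespace`.
#' @return A `data.frame` ontology usable by [annotate_up_propagate()].
#' @export
read_ontology <- function(path) {
  ont <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("term", "parent", "namespace"), names(ont))
  if (length(missing)) {
    stop("ontology ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ont
}

#' Read gene-to-term annotations
#'
#' @param path TSV with columns `gene`, `term`.
#' @return A `data.frame` with one row per direct annotation.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "term"), names(ann))
  if (length(missing)) {
    stop("annotations ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ann
}

ancestors_map <- function(ontology) {
  parents <- split(ontology$parent, ontology$term)
  terms <- unique(c(ontology$term, ontology$parent))
  anc <- stats::setNames(vector("list", length(terms)), terms)
  visit <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    ps <- parents[[t]]
    out <- character(0)
    for (p in ps) out <- union(out, c(p, visit(p)))
    anc[[t]] <<- out
    out
  }
  for (t in terms) visit(t)
  anc
}

#' Close annotations under ontology ancestors (true-path rule)
#'
#' Every gene annotated to a term is also annotated to all of that term's
#' ancestors. Annotations to terms absent from the ontology are skipped
#' with a warning.
#'
#' @param annotations `data.frame` with columns `gene`, `term` (direct
#'   annotations).
#' @param ontology `data.frame` with columns `term`, `parent`, `namespace`.
#' @return Named list gene -> character vector of terms (closed upward).
#' @export
annotate_up_propagate <- function(annotations, ontology) {
  known <- unique(c(ontology$term, ontology$parent))
  bad <- !annotations$term %in% known
  if (any(bad)) {
    warning("annotate_up_propagate: unknown term(s) skipped: ",
            paste(unique(annotations$term[bad]), collapse = ", "))
    annotations <- annotations[!bad, , drop = FALSE]
  }
  anc <- ancestors_map(ontology)
  lapply(split(annotations$term, annotations$gene), function(terms) {
    out <- unique(terms)
    for (t in terms) out <- union(out, anc[[t]])
    out
  })
}

term_depths <- function(ontology) {
  anc <- ancestors_map(ontology)
  vapply(anc, length, integer(1))
}

#' GO enrichment with the elim hierarchy correction
#'
#' Hypergeometric enrichment of the study set against the population for
#' every ontology term with at least one annotated population gene, within
#' each namespace independently. Terms are processed deepest-first; when a
#' term's elim p-value falls below `alpha`, its annotated genes are removed
#' from all of its ancestors before those are tested. Both the uncorrected
#' (`p_raw`) and elim (`p_elim`) p-values are reported, unadjusted, per the
#' topGO convention.
#'
#' @param study Character vector of study gene ids (subset of `population`).
#' @param population Character vector of background gene ids.
#' @param annotations Direct annotations (`data.frame`: `gene`, `term`).
#' @param ontology Ontology pair list (`data.frame`: `term`, `parent`,
#'   `namespace`).
#' @param alpha Elimination threshold on the elim p-value (default 0.05).
#' @return A `data.frame`: `term`, `namespace`, `study_count`,
#'   `population_count`, `study_size`, `population_size`, `p_raw`,
#'   `p_elim`, sorted by `p_elim`.
#' @export
elim_enrichment <- function(study, population, annotations, ontology,
                            alpha = 0.05) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population)) {
    stop("elim_enrichment: study set must be a subset of the population")
  }
  gene_terms <- annotate_up_propagate(
    annotations[annotations$gene %in% population, , drop = FALSE], ontology)
  term_genes <- split(rep(names(gene_terms), lengths(gene_terms)),
                      unlist(gene_terms))
  ns_of <- c(stats::setNames(ontology$namespace, ontology$term),
             stats::setNames(ontology$namespace, ontology$parent))
  depth <- term_depths(ontology)
  anc <- ancestors_map(ontology)
  N <- length(population)
  n <- length(study)

  terms <- names(term_genes)
  terms <- terms[order(-depth[terms], terms)]  # leaves first, stable
  removed <- stats::setNames(vector("list", length(terms)), terms)
  rows <- list()
  for (t in terms) {
    genes <- term_genes[[t]]
    K_raw <- length(genes)
    k_raw <- length(intersect(genes, study))
    p_raw <- hypergeometric_test(k_raw, n, K_raw, N)
    kept <- setdiff(genes, removed[[t]])
    K <- length(kept)
    k <- length(intersect(kept, study))
    p_elim <- hypergeometric_test(k, n, K, N)
    if (p_elim < alpha) {
      for (a in intersect(anc[[t]], terms)) {
        removed[[a]] <- union(removed[[a]], genes)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      term = t, namespace = unname(ns_of[t]),
      study_count = k_raw, population_count = K_raw,
      study_size = n, population_size = N,
      p_raw = p_raw, p_elim = p_elim,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out[order(out$p_elim, out$term), ]
}

#' Write enrichment results with a -log10(p) column
#'
#' @param results `data.frame` from [elim_enrichment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  results$neg_log10_p <- -log10(results$p_elim)
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
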
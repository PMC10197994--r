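toy_dag <- function() {
  # 3-level chain per namespace root: root <- mid <- leaf, plus a sibling
  data.frame(
    term = c("MID", "LEAF", "SIB"),
    parent = c("ROOT", "MID", "ROOT"),
    namespace = "BP",
    stringsAsFactors = FALSE
  )
}

test_that("hypergeometric p-values match brute-force tail enumeration", {
  expect_equal(hypergeometric_test(0, 10, 20, 100), 1)
  expect_equal(hypergeometric_test(5, 5, 5, 5), 1)
  expect_equal(hypergeometric_test(6, 10, 20, 100),
               brute_hyper_tail(6, 10, 20, 100), tolerance = 1e-12)
  set.seed(81)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_test(k, n, K, N), brute_hyper_tail(k, n, K, N),
                 tolerance = 1e-12, info = paste(k, n, K, N))
  }
  expect_error(hypergeometric_test(6, 5, 10, 100), "inconsistent")
  expect_error(hypergeometric_test(2, 5, 1, 100), "inconsistent")
})

test_that("annotations propagate to every ancestor", {
  ann <- data.frame(gene = c("g1", "g2"), term = c("LEAF", "SIB"))
  closed <- annotate_up_propagate(ann, toy_dag())
  expect_setequal(closed$g1, c("LEAF", "MID", "ROOT"))
  expect_setequal(closed$g2, c("SIB", "ROOT"))
  expect_warning(
    closed2 <- annotate_up_propagate(
      data.frame(gene = "g3", term = c("LEAF", "NOPE")), toy_dag()),
    "NOPE")
  expect_setequal(closed2$g3, c("LEAF", "MID", "ROOT"))

  # closure equals reachability on a larger random DAG
  set.seed(82)
  terms <- sprintf("T%02d", 1:20)
  dag <- do.call(rbind, lapply(2:20, function(i) {
    parents <- sample(terms[seq_len(i - 1)], min(i - 1, sample(1:2, 1)))
    data.frame(term = terms[i], parent = parents, namespace = "BP")
  }))
  reach <- matrix(FALSE, 20, 20, dimnames = list(terms, terms))
  for (k in seq_len(nrow(dag))) reach[dag$term[k], dag$parent[k]] <- TRUE
  for (m in terms) for (i in terms) for (j in terms) {
    if (reach[i, m] && reach[m, j]) reach[i, j] <- TRUE
  }
  ann <- data.frame(gene = "g", term = sample(terms, 5))
  closed <- annotate_up_propagate(ann, dag)
  oracle <- unique(c(ann$term, unlist(lapply(ann$term, function(t)
    terms[reach[t, ]]))))
  expect_setequal(closed$g, oracle)
})

test_that("elim matches a hand-stepped sequence of hypergeometric tests", {
  # population of 20 genes; the leaf term carries a planted signal
  population <- sprintf("g%02d", 1:20)
  leaf_genes <- population[1:5]
  mid_extra <- population[6:8]
  sib_genes <- population[9:12]
  ann <- rbind(
    data.frame(gene = leaf_genes, term = "LEAF"),
    data.frame(gene = mid_extra, term = "MID"),
    data.frame(gene = sib_genes, term = "SIB")
  )
  study <- c(leaf_genes[1:4], "g09")
  res <- elim_enrichment(study, population, ann, toy_dag(), alpha = 0.05)
  res <- res[match(c("LEAF", "MID", "SIB", "ROOT"), res$term), ]

  N <- 20; n <- 5
  # step 1 (deepest): LEAF has 5 population genes, 4 in the study
  p_leaf <- stats::phyper(4 - 1, 5, N - 5, n, lower.tail = FALSE)
  expect_equal(res$p_raw[1], p_leaf, tolerance = 1e-12)
  expect_equal(res$p_elim[1], p_leaf, tolerance = 1e-12)
  expect_lt(p_leaf, 0.05)  # significant -> its genes leave the ancestors
  # step 2: MID raw = 8 genes / 4 study hits; elim drops the 5 LEAF genes
  expect_equal(res$p_raw[2],
               stats::phyper(4 - 1, 8, N - 8, n, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p_elim[2],
               stats::phyper(0 - 1, 3, N - 3, n, lower.tail = FALSE),
               tolerance = 1e-12)
  # SIB is untouched by the elimination
  expect_equal(res$p_elim[3], res$p_raw[3], tolerance = 1e-12)
  # ROOT raw = all 12 annotated genes; elim drops the LEAF genes
  expect_equal(res$p_raw[4],
               stats::phyper(5 - 1, 12, N - 12, n, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p_elim[4],
               stats::phyper(1 - 1, 7, N - 7, n, lower.tail = FALSE),
               tolerance = 1e-12)
  # the parent's elim p is never smaller than its raw p here
  expect_gte(res$p_elim[2], res$p_raw[2])
})

test_that("a flat ontology leaves elim equal to the raw test", {
  population <- sprintf("g%02d", 1:30)
  flat <- data.frame(term = c("A", "B", "C"), parent = "ROOT",
                     namespace = "BP")
  ann <- data.frame(gene = population[1:12],
                    term = rep(c("A", "B", "C"), each = 4))
  study <- population[c(1:4, 13)]
  res <- elim_enrichment(study, population, ann, flat)
  leaves <- res[res$term != "ROOT", ]
  expect_equal(leaves$p_elim, leaves$p_raw, tolerance = 1e-12)
  # elim never reports more significant terms than the raw pass
  expect_lte(sum(res$p_elim < 0.05), sum(res$p_raw < 0.05))
})

test_that("enrichment is invariant to gene order and validates inputs", {
  population <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene = population[1:8],
                    term = rep(c("LEAF", "SIB"), each = 4))
  study <- population[c(1, 2, 3, 9)]
  r1 <- elim_enrichment(study, population, ann, toy_dag())
  r2 <- elim_enrichment(rev(study), sample(population), ann, toy_dag())
  expect_equal(r1, r2)
  expect_error(elim_enrichment(c("zz"), population, ann, toy_dag()),
               "subset")
})

test_that("planted enrichment is detected in the synthetic annotations", {
  bundle <- small_bundle()
  study <- bundle$manifest$go$partner_genes
  population <- unique(bundle$annotations$gene)
  res <- elim_enrichment(intersect(study, population), population,
                         bundle$annotations, bundle$ontology)
  top <- res$term[which.min(res$p_elim)]
  expect_equal(top, bundle$manifest$go$planted_term)
  expect_lt(res$p_elim[res$term == top], 0.05)
})
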
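test_that("FPKM follows its closed form and algebraic identities", {
  counts <- matrix(10, 1, 1, dimnames = list("g", "0H_r1"))
  expect_equal(unname(fpkm(counts, c(g = 1000), library_sizes = 1e6)[1, 1]), 10)
  expect_equal(unname(fpkm(counts * 0, c(g = 1000), library_sizes = 1e6)[1, 1]), 0)

  set.seed(91)
  cm <- matrix(rpois(20, 50), 4, 5,
               dimnames = list(paste0("g", 1:4), paste0("0H_r", 1:5)))
  lens <- stats::setNames(sample(500:2000, 4), rownames(cm))
  libs <- stats::setNames(sample(1e5:1e6, 5), colnames(cm))
  fp <- fpkm(cm, lens, libs)
  # element-wise recomputation oracle
  for (i in 1:4) for (j in 1:5) {
    expect_equal(fp[i, j], 1e9 * cm[i, j] / (libs[[j]] * lens[[i]]))
  }
  # linear in counts, inversely proportional to length
  expect_equal(fpkm(2 * cm, lens, libs), 2 * fp)
  expect_equal(fpkm(cm, 2 * lens, libs), fp / 2)
  expect_error(fpkm(cm, lens, library_sizes = rep(0, 5)), "library")
})

test_that("the expressed filter is strict and monotone", {
  fp <- matrix(c(1, 1, 1, 1,
                 0.2, 5, 0.1, 0.3,
                 0.5, 0.5, 0.9, 0.2), 3, 4, byrow = TRUE,
               dimnames = list(c("border", "burst", "low"),
                               c("0H_r1", "0H_r2", "30M_r1", "30M_r2")))
  expect_equal(filter_expressed(fp), "burst")      # strict > 1
  expect_equal(filter_expressed(fp, 0.15), c("border", "burst", "low"))
  # raising the threshold never adds genes
  for (thr in c(0.1, 0.5, 1, 2, 10)) {
    expect_true(all(filter_expressed(fp, thr * 2) %in% filter_expressed(fp, thr)))
  }
})

test_that("log2 centring/scaling standardises every informative row", {
  set.seed(92)
  fp <- matrix(rexp(40, 0.01), 5, 8,
               dimnames = list(paste0("g", 1:5),
                               paste0(rep(c("0H", "30M"), 4), "_r",
                                      rep(1:4, each = 2))))
  fp[3, ] <- 7  # constant row
  expect_warning(z <- log2_center_scale(fp), "zero-variance")
  expect_true(all(z[3, ] == 0))
  keep <- setdiff(1:5, 3)
  expect_equal(unname(rowMeans(z[keep, ])), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z[keep, ], 1, sd)), rep(1, 4), tolerance = 1e-9)
  # two-pass oracle
  lg <- log2(fp[1, ] + 1)
  expect_equal(z[1, ], (lg - mean(lg)) / sd(lg))
})

test_that("gene clustering merges identical rows first and is order-invariant", {
  set.seed(93)
  block1 <- matrix(rnorm(3 * 8, mean = rep(c(2, -2), each = 4)), 3, 8,
                   byrow = TRUE)
  block2 <- -block1 + rnorm(24, sd = 0.1)
  m <- rbind(block1, block2)
  rownames(m) <- paste0("g", 1:6)
  colnames(m) <- paste0(rep(c("0H", "30M"), each = 4), "_r", rep(1:4, 2))
  m["g2", ] <- m["g1", ]  # identical pair merges at height 0
  cl <- cluster_genes(m)
  h <- cl$hclust
  first <- sort(rownames(m)[-h$merge[1, ]])
  expect_equal(first, c("g1", "g2"))
  expect_equal(h$height[1], 0, tolerance = 1e-12)
  # anti-correlated blocks split at the top
  top <- stats::cutree(h, 2)
  expect_equal(length(unique(top[c("g1", "g2", "g3")])), 1L)
  expect_equal(length(unique(top[c("g4", "g5", "g6")])), 1L)
  # permutation invariance up to relabeling
  perm <- sample(rownames(m))
  cl2 <- cluster_genes(m[perm, ])
  expect_equal(as.matrix(stats::cophenetic(cl$hclust))[rownames(m), rownames(m)],
               as.matrix(stats::cophenetic(cl2$hclust))[rownames(m), rownames(m)],
               tolerance = 1e-12)
})

test_that("response calls use replicate-mean fold changes with a pseudocount", {
  fp <- matrix(c(10, 10, 40, 40,
                 10, 10, 10, 10,
                 40, 40, 10, 10), 3, 4, byrow = TRUE,
               dimnames = list(c("up", "flat", "down"),
                               c("0H_r1", "0H_r2", "30M_r1", "30M_r2")))
  calls <- call_responses(fp, control = "0H", lfc_threshold = 1)
  at30 <- calls[calls$timepoint == "30M", ]
  expect_equal(at30$lfc[at30$gene == "up"], log2(41 / 11))
  expect_equal(at30$direction[at30$gene == "up"], "up")
  expect_equal(at30$direction[at30$gene == "flat"], "flat")
  expect_equal(at30$direction[at30$gene == "down"], "down")
  ctrl <- calls[calls$timepoint == "0H", ]
  expect_true(all(ctrl$direction == "flat"))
  expect_true(all(ctrl$lfc == 0))
})

test_that("planted cold responses are recovered at the study conditions", {
  bundle <- default_bundle()
  fp <- fpkm(bundle$counts, bundle$lengths, bundle$library_sizes)
  expressed <- filter_expressed(fp)
  expect_setequal(expressed, bundle$manifest$expression$expressed_genes)

  calls <- call_responses(fp[expressed, ])
  up30 <- calls$gene[calls$timepoint == "30M" & calls$direction == "up"]
  truth <- bundle$manifest$expression$upregulated_30M
  expect_gte(mean(truth %in% up30), 0.95)
  fdr <- if (length(up30)) mean(!up30 %in% truth) else 0
  expect_lte(fdr, 0.05)
})

test_that("2^-ddCt follows its closed forms and recovers noisy planted folds", {
  ct <- data.frame(
    gene = "g", timepoint = rep(c("0H", "30M", "1H"), each = 2),
    replicate = rep(1:2, 3),
    ct_target = c(25, 25, 20, 20, 26, 26),
    ct_reference = c(18, 18, 18, 18, 19, 19)
  )
  res <- delta_delta_ct(ct, control = "0H")
  expect_equal(res$fold_change[res$timepoint == "0H"], 1.0)
  expect_equal(res$fold_change[res$timepoint == "30M"], 32.0)  # ddCt = -5
  expect_equal(res$fold_change[res$timepoint == "1H"], 1.0)    # ddCt = 0
  expect_error(delta_delta_ct(ct[ct$timepoint != "0H", ], control = "0H"),
               "control")

  # noisy recovery: the tolerance band comes from Monte-Carlo propagation of
  # the Ct noise through 2^-ddCt (same noise model as the generator)
  bundle <- default_bundle()
  cfg <- bundle$config
  set.seed(94)
  mc <- replicate(4000, {
    d <- mean(rnorm(cfg$replicates, 0, cfg$ct_noise_sd * sqrt(2))) -
      mean(rnorm(cfg$replicates, 0, cfg$ct_noise_sd * sqrt(2)))
    abs(2^d - 1) <= 0.2
  })
  expected_within <- mean(mc)  # chance a fold lands within 20% of truth
  folds <- delta_delta_ct(bundle$ct_table)
  planted <- bundle$manifest$qpcr$planted
  mg <- merge(folds, planted, by = c("gene", "timepoint"))
  within <- abs(mg$fold_change / 2^(-mg$ddct.y) - 1) <= 0.2
  # observed coverage within binomial noise of the Monte-Carlo expectation
  margin <- 3 * sqrt(expected_within * (1 - expected_within) / nrow(mg))
  expect_gte(mean(within), expected_within - margin)
})
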
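test_that("generator is deterministic and honours planted structure", {
  cfg <- small_config(seed = 5)
  a <- generate_survey_inputs(cfg)
  b <- generate_survey_inputs(cfg)
  expect_identical(as.character(a$target), as.character(b$target))
  expect_identical(a$manifest$genes, b$manifest$genes)
  expect_identical(a$counts, b$counts)
  expect_identical(a$ct_table, b$ct_table)
  expect_identical(a$network, b$network)

  m <- a$manifest
  expect_equal(sum(m$genes$role == "member"), cfg$n_family_members)
  expect_equal(sum(m$genes$role == "decoy"), cfg$n_decoys)
  expect_equal(unclass(table(m$genes$group[m$genes$role == "member"])),
               unclass(cfg$groups[sort(names(cfg$groups))]),
               ignore_attr = TRUE)

  # every manifest id exists in the emitted sequences and annotation
  expect_true(all(m$genes$gene_id %in% names(a$target)))
  expect_true(all(m$genes$gene_id %in% a$records$gene_id))
  expect_true(all(m$orthologs$ref_id %in% names(a$reference)))
})

test_that("written bundles are byte-identical under a fixed seed", {
  cfg <- small_config(seed = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_survey_inputs(cfg, dir = d1)
  generate_survey_inputs(cfg, dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("tandem clusters are consecutive same-chromosome genes within 100 kb", {
  bundle <- small_bundle()
  m <- bundle$manifest
  tandem_units <- m$units$unit[m$units$kind == "tandem"]
  ord <- bundle$records[order(bundle$records$chromosome, bundle$records$start), ]
  for (u in tandem_units) {
    g <- m$genes[m$genes$unit == u, ]
    expect_equal(length(unique(g$chromosome)), 1L)
    expect_lte(max(g$start) - min(g$start), 1e5)
    # consecutive: no other gene intervenes
    pos <- match(g$gene_id, ord$gene_id)
    expect_equal(sort(pos), seq(min(pos), max(pos)))
  }
  # segmental partners sit on homoeologous chromosomes at mirrored slots
  for (u in m$units$unit[m$units$kind == "segmental"]) {
    g <- m$genes[m$genes$unit == u, ]
    expect_equal(nrow(g), 2L)
    expect_equal(sub("[OP]$", "", g$chromosome[1]), sub("[OP]$", "", g$chromosome[2]))
    expect_false(g$chromosome[1] == g$chromosome[2])
    expect_equal(g$start[1], g$start[2])
  }
})

test_that("decoys miss exactly one planted domain and members carry both", {
  bundle <- small_bundle()
  m <- bundle$manifest
  dom <- m$domains
  for (i in seq_len(nrow(m$genes))) {
    g <- m$genes[i, ]
    labels <- unique(dom$domain[dom$protein_id == g$gene_id])
    if (g$role == "member") {
      expect_setequal(labels, c("kinase", "EF-hand"))
    } else {
      expect_equal(labels, g$decoy_domain)
    }
  }
  # domain intervals stay within the protein
  len <- stats::setNames(m$genes$protein_length, m$genes$gene_id)
  expect_true(all(dom$start >= 1))
  expect_true(all(dom$end <= len[dom$protein_id]))
})

test_that("planted domain blocks match the consensus at the configured rate", {
  cfg <- small_config(seed = 9)
  # no noise: planted blocks equal the consensus exactly
  cfg0 <- cfg; cfg0$domain_mutation_rate <- 0
  b0 <- generate_survey_inputs(cfg0)
  m0 <- b0$manifest
  kin <- m0$domains[m0$domains$domain == "kinase" &
                      m0$domains$protein_id %in% manifest_members(b0), ]
  blocks <- substr(as.character(b0$target[kin$protein_id]), kin$start, kin$end)
  expect_true(all(blocks == cdpkfam:::KINASE_CONSENSUS))

  # rate 0.1: mean identity to the consensus near the binomial expectation
  b1 <- small_bundle()  # domain_mutation_rate = 0.1
  m1 <- b1$manifest
  kin1 <- m1$domains[m1$domains$domain == "kinase" &
                       m1$domains$protein_id %in% manifest_members(b1), ]
  cons <- strsplit(cdpkfam:::KINASE_CONSENSUS, "")[[1]]
  ident <- vapply(seq_len(nrow(kin1)), function(i) {
    blk <- strsplit(substr(as.character(b1$target[[kin1$protein_id[i]]]),
                           kin1$start[i], kin1$end[i]), "")[[1]]
    mean(blk == cons)
  }, numeric(1))
  expect_lt(abs(mean(ident) - 0.9), 0.03)
})

test_that("reference network is a simple graph touching every family ortholog", {
  bundle <- small_bundle()
  net <- bundle$network
  expect_true(all(net$from != net$to))
  keys <- paste(pmin(net$from, net$to), pmax(net$from, net$to))
  expect_false(anyDuplicated(keys) > 0)
  fam <- bundle$manifest$reference_family$ref_id
  expect_true(all(fam %in% c(net$from, net$to)))

  # forced triangle when the edge budget equals the capacity
  cfg <- small_config(seed = 3)
  cfg$orthology_fraction <- 3 / (cfg$n_family_members + cfg$n_decoys)
  cfg$network_edges <- 3
  g <- generate_genome(cfg)
  p <- generate_proteomes(cfg, g$manifest)
  n <- generate_reference_network(cfg, p$manifest)
  expect_equal(nrow(n$edges), 3L)
  expect_equal(length(unique(c(n$edges$from, n$edges$to))), 3L)
  cfg$network_edges <- 4
  expect_error(generate_reference_network(cfg, p$manifest), "possible")
})

test_that("expression generator plants the configured induction", {
  bundle <- default_bundle()
  cfg <- bundle$config
  m <- bundle$manifest
  expect_length(m$expression$upregulated_30M, cfg$n_upregulated_30M)

  # mean 30M/0H FPKM ratio over the planted set is near the planted fold
  fp <- fpkm(bundle$counts, bundle$lengths, bundle$library_sizes)
  avg <- average_replicates(fp)
  up <- m$expression$upregulated_30M
  ratio <- mean(avg[up, "30M"] / avg[up, "0H"])
  expect_lt(abs(ratio / cfg$fold_change - 1), 0.25)

  # fold_change = 1 plants no up-regulated genes
  cfg1 <- small_config(seed = 8)
  cfg1$fold_change <- 1
  b1 <- generate_survey_inputs(cfg1)
  expect_length(b1$manifest$expression$upregulated_30M, 0L)

  # library sizes vary at most two-fold
  libs <- unlist(bundle$manifest$expression$library_sizes)
  expect_lt(max(libs) / min(libs), 2)
})

test_that("noiseless Ct tables reproduce planted fold changes exactly", {
  cfg <- small_config(seed = 4)
  cfg$ct_noise_sd <- 0
  b <- generate_survey_inputs(cfg)
  folds <- delta_delta_ct(b$ct_table, control = "0H")
  planted <- b$manifest$qpcr$planted
  mg <- merge(folds, planted, by = c("gene", "timepoint"))
  expect_equal(mg$fold_change, 2^(-mg$ddct.y), tolerance = 1e-9)
  ctrl <- folds$fold_change[folds$timepoint == "0H"]
  expect_true(all(ctrl == 1))
})
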
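make_records <- function(ids, chrom, start, width = 3000) {
  data.frame(gene_id = ids, chromosome = chrom, start = start,
             end = start + width, strand = "+", exon_count = 2L,
             intron_count = 1L, stringsAsFactors = FALSE)
}

test_that("duplicate pairs require >80% identity and coverage of the longer gene", {
  set.seed(61)
  base <- paste(sample(cdpkfam:::AA_ALPHABET[1:20], 300, replace = TRUE),
                collapse = "")
  copy <- paste(cdpkfam:::mutate_residues(strsplit(base, "")[[1]], 0.02),
                collapse = "")
  diverged <- paste(cdpkfam:::mutate_residues(strsplit(base, "")[[1]], 0.35),
                    collapse = "")
  prot <- Biostrings::AAStringSet(c(g1 = base, g2 = copy, g3 = diverged))
  pairs <- find_duplicate_pairs(c("g1", "g2", "g3"), prot)
  expect_equal(nrow(pairs), 1L)
  expect_equal(sort(c(pairs$gene_a, pairs$gene_b)), c("g1", "g2"))
  expect_gt(pairs$identity, 0.8)
  expect_gt(pairs$coverage_of_longer, 0.8)

  ident <- find_duplicate_pairs(c("g1", "g1b"),
                                Biostrings::AAStringSet(c(g1 = base, g1b = base)))
  expect_equal(ident$identity, 1.0)
  expect_error(find_duplicate_pairs(c("g1", "gx"), prot), "gx")
})

test_that("tight clusters merge and distant copies stay separate", {
  rec <- rbind(
    make_records(paste0("g", 1:6), "Tr1O",
                 c(1e6, 1.01e6, 1.02e6, 5e6, 9e6, 9.5e6)),
    # filler genes separate the distant copies, as in a real annotation
    make_records(paste0("f", 1:8), "Tr1O", seq(5.5e6, 8.8e6, length.out = 8))
  )
  pairs <- data.frame(
    gene_a = c("g1", "g1", "g2", "g4"),
    gene_b = c("g2", "g3", "g3", "g5"),
    identity = 0.95, coverage_of_longer = 0.95, score = 500,
    stringsAsFactors = FALSE
  )
  cl <- collapse_tight_clusters(pairs, rec, max_intervening = 1)
  clusters <- attr(cl, "clusters")
  # three consecutive copies collapse into one cluster
  expect_equal(length(unique(clusters[c("g1", "g2", "g3")])), 1L)
  # copies far apart on the chromosome are not merged
  expect_false(clusters[["g4"]] == clusters[["g5"]])

  ev <- classify_events(cl, rec)
  expect_equal(sum(ev$cluster_id == paste(clusters[["g1"]], clusters[["g1"]])), 1L)
})

test_that("events classify by chromosome and distance", {
  # filler genes sit between a1 and a2, as non-family genes would in a
  # real annotation, so the pair is not tightly linked by gene rank
  rec <- rbind(make_records(c("a1", "a2"), "Tr8O", c(1e6, 2e7)),
               make_records(paste0("f", 1:10), "Tr8O", seq(2e6, 1.1e7, 1e6)),
               make_records("b1", "Tr8P", 1e6),
               make_records(c("c1", "c2"), "Tr2O", c(3e6, 3.001e6)))
  mk_pairs <- function(a, b) data.frame(
    gene_a = a, gene_b = b, identity = 0.93, coverage_of_longer = 0.92,
    score = 400, stringsAsFactors = FALSE)
  # different chromosomes (homoeologs) -> segmental
  p1 <- collapse_tight_clusters(mk_pairs("a1", "b1"), rec)
  expect_equal(classify_events(p1, rec)$kind, "segmental")
  # same chromosome but 19 Mb apart -> segmental
  p2 <- collapse_tight_clusters(mk_pairs("a1", "a2"), rec)
  expect_equal(classify_events(p2, rec)$kind, "segmental")
  # adjacent genes ~1 kb apart -> tandem
  p3 <- collapse_tight_clusters(mk_pairs("c1", "c2"), rec)
  expect_equal(classify_events(p3, rec)$kind, "tandem")
  # classify_events asserts the >0.8 thresholds on its input
  bad <- p3; bad$identity <- 0.7
  expect_error(classify_events(bad, rec))
})

test_that("synthetic manifests are reproduced and tandem counts are monotone", {
  bundle <- small_bundle()
  members <- manifest_members(bundle)
  pairs <- find_duplicate_pairs(members, bundle$target)

  # every reported pair is a planted duplication-unit pair and vice versa
  unit <- stats::setNames(bundle$manifest$genes$unit,
                          bundle$manifest$genes$gene_id)
  expect_true(all(unit[pairs$gene_a] == unit[pairs$gene_b]))
  multi <- table(unit[members])
  expected_pairs <- sum(choose(multi[multi > 1], 2))
  expect_equal(nrow(pairs), unname(expected_pairs))

  cl <- collapse_tight_clusters(pairs, bundle$records)
  ev <- classify_events(cl, bundle$records)
  expect_equal(sum(ev$kind == "tandem"), bundle$manifest$n_tandem_events)
  expect_equal(sum(ev$kind == "segmental"), bundle$manifest$n_segmental_events)
  # events partition into the two kinds
  expect_equal(nrow(ev), sum(ev$kind == "tandem") + sum(ev$kind == "segmental"))

  # tightening max_intervening never increases the tandem count
  tandem_at <- function(k) {
    c2 <- collapse_tight_clusters(pairs, bundle$records, max_intervening = k)
    sum(classify_events(c2, bundle$records)$kind == "tandem")
  }
  expect_lte(tandem_at(0), tandem_at(1))
  expect_lte(tandem_at(1), tandem_at(5))
})

test_that("event and link files are written", {
  bundle <- small_bundle()
  members <- manifest_members(bundle)
  pairs <- collapse_tight_clusters(find_duplicate_pairs(members, bundle$target),
                                   bundle$records)
  ev <- classify_events(pairs, bundle$records)
  ef <- withr::local_tempfile(fileext = ".tsv")
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_duplication_events(ev, bundle$records, ef, lf)
  expect_equal(nrow(utils::read.delim(ef)), nrow(ev))
  links <- utils::read.delim(lf, header = FALSE)
  expect_equal(nrow(links), nrow(ev))
  expect_equal(ncol(links), 6L)
})
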
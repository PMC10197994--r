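test_that("local alignment matches closed-form and degenerate expectations", {
  a <- paste(rep("MKVLQDRHEW", 5), collapse = "")
  r <- local_align(a, a)
  expect_equal(r$identity, 1.0)
  expect_equal(r$coverage, 1.0)
  expect_gt(r$score, 0)

  # disjoint residue alphabets with no positive substitution scores
  r0 <- local_align(strrep("A", 30), strrep("W", 30))
  expect_equal(r0$score, 0)
  expect_equal(r0$identity, 0)
  expect_equal(r0$coverage, 0)
  expect_equal(r0$alignment_length, 0L)

  expect_error(local_align("", "MKV"), "empty|non amino|sequence")
})

test_that("alignment scores are symmetric and e-value proxy decreases in score", {
  set.seed(31)
  for (i in 1:5) {
    a <- paste(sample(LETTERS[c(1, 3:9, 11:14, 16:20, 22:23, 25)], 40,
                      replace = TRUE), collapse = "")
    b <- paste(sample(LETTERS[c(1, 3:9, 11:14, 16:20, 22:23, 25)], 40,
                      replace = TRUE), collapse = "")
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
  ev <- evalue_proxy(c(50, 100, 200), 400, 400)
  expect_true(all(diff(ev) < 0))
})

test_that("candidate screening applies the coverage and e-value rules", {
  bundle <- small_bundle()
  ref <- bundle$reference[names(bundle$reference) %in%
                            names(bundle$reference_groups)]
  # a target identical to a reference is always a candidate
  probe <- Biostrings::AAStringSet(c(probe = as.character(ref[[1]])))
  expect_equal(screen_candidates(ref[1], probe), "probe")

  # a short shared fragment fails the 80% coverage rule
  frag <- Biostrings::AAStringSet(
    c(frag = substr(as.character(ref[[1]]), 1, 40)))
  expect_length(screen_candidates(ref[1], frag), 0L)

  # monotonicity: raising min_coverage never enlarges the candidate set
  stats <- align_stats_matrix(ref, bundle$target)
  c50 <- screen_candidates(ref, bundle$target, min_coverage = 0.5, stats = stats)
  c80 <- screen_candidates(ref, bundle$target, min_coverage = 0.8, stats = stats)
  c95 <- screen_candidates(ref, bundle$target, min_coverage = 0.95, stats = stats)
  expect_true(all(c80 %in% c50))
  expect_true(all(c95 %in% c80))
})

test_that("domain scanning finds planted consensus blocks and rejects noise", {
  models <- domain_models()
  protein <- paste0(strrep("A", 25), cdpkfam:::KINASE_CONSENSUS, strrep("G", 30))
  hits <- scan_domains(protein, models, protein_id = "p1")
  kin <- hits[hits$domain == "kinase", ]
  expect_equal(nrow(kin), 1L)
  expect_equal(kin$start, 26L)
  expect_equal(kin$end, 25L + nchar(cdpkfam:::KINASE_CONSENSUS))

  expect_equal(nrow(scan_domains(strrep("A", 200), models)), 0L)
})

test_that("dual-domain confirmation recovers the planted family exactly", {
  bundle <- small_bundle()
  ref <- bundle$reference[names(bundle$reference) %in%
                            names(bundle$reference_groups)]
  candidates <- screen_candidates(ref, bundle$target)
  truth <- manifest_members(bundle)
  expect_true(all(truth %in% candidates))

  hits <- scan_proteome_domains(bundle$target[candidates])
  members <- confirm_members(candidates, hits)
  # members are a subset of candidates, and recover the manifest exactly
  expect_true(all(members %in% candidates))
  expect_setequal(members, truth)

  # kinase-only evidence is rejected; either-domain mode accepts it
  kin_only <- hits[hits$domain == "kinase", ]
  decoy_kin <- setdiff(unique(kin_only$protein_id), truth)
  expect_length(confirm_members(decoy_kin, hits[hits$domain == "kinase", ]), 0L)
  expect_equal(confirm_members(decoy_kin, kin_only, require_both = FALSE),
               decoy_kin)
  expect_length(confirm_members(character(0), hits), 0L)
})

test_that("family tables are chromosome-ordered with copied annotations", {
  bundle <- small_bundle()
  members <- manifest_members(bundle)
  groups <- stats::setNames(
    bundle$manifest$genes$group[match(members, bundle$manifest$genes$gene_id)],
    members)
  tab <- build_family_table(members, bundle$records, bundle$target, groups)
  expect_equal(nrow(tab), length(members))
  expect_equal(tab$name, sprintf("TrCDPK%02d", seq_along(members)))
  expect_false(is.unsorted(order(tab$chromosome, tab$start)))
  expect_equal(tab$length_aa,
               unname(Biostrings::width(bundle$target)[
                 match(tab$locus, names(bundle$target))]))
  rec <- bundle$records[match(tab$locus, bundle$records$gene_id), ]
  expect_equal(tab$intron, rec$intron_count)

  expect_error(build_family_table(c(members, "ghost"), bundle$records,
                                  bundle$target),
               "ghost")
})

test_that("a family table round-trips through a pseudo-annotation", {
  fixture <- load_family_table()
  rec <- data.frame(
    gene_id = fixture$locus, chromosome = fixture$chromosome,
    start = fixture$start, end = fixture$end, strand = "+",
    exon_count = fixture$intron + 1L, intron_count = fixture$intron,
    stringsAsFactors = FALSE
  )
  prot <- Biostrings::AAStringSet(stats::setNames(
    strrep("A", fixture$length_aa), fixture$locus))
  groups <- stats::setNames(fixture$group, fixture$locus)
  rebuilt <- build_family_table(fixture$locus, rec, prot, groups)
  # chromosome-order naming differs from the published order, so compare
  # row content keyed by locus
  rebuilt <- rebuilt[match(fixture$locus, rebuilt$locus), ]
  expect_equal(rebuilt$chromosome, fixture$chromosome)
  expect_equal(rebuilt$start, fixture$start)
  expect_equal(rebuilt$group, fixture$group)
  expect_equal(rebuilt$intron, fixture$intron)
  expect_equal(rebuilt$length_aa, fixture$length_aa)
})
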
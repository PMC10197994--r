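# Seeded generators for every input the survey consumes, with a manifest of
# planted truth so recovery tests never re-infer truth from the emitted
# files.
#
# The emulated study system: an allotetraploid genome with eight pairs of
# homoeologous chromosomes (labels Tr1O..Tr8O / Tr1P..Tr8P), a ~50-member
# kinase family carrying both a planted kinase-like block and EF-hand-like
# blocks, single-domain decoys, tandem clusters and cross-homoeolog
# segmental copies, a reference proteome with known orthology and a
# co-functional network, an 8-point cold time course with three replicates
# and a planted early-up-regulated subset, and qPCR Ct tables with planted
# fold changes.
#
# Mutations are substitutions only (no indels), so planted domain blocks
# keep their coordinates and coverage of full-length alignments stays near
# one; group structure comes from group-specific core sequences.

#' Configuration for the synthetic survey inputs
#'
#' Defaults describe the emulated study conditions: 16 chromosomes in O/P
#' homoeologous pairs, 50 family members split over groups I-IV with the
#' published group sizes, two tandem clusters and five segmental pairs, a
#' 10% domain mutation rate, 80% orthology coverage, an eight-point cold
#' time course (0H control) with three replicates, and an eight-fold
#' planted early induction with a 32-fold qPCR peak gene.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_chromosomes Even count of chromosomes (O/P pairs).
#' @param n_family_members True family size.
#' @param n_decoys Proteins carrying exactly one of the two domains.
#' @param groups Named counts of members per group (must sum to
#'   `n_family_members`).
#' @param tandem_clusters List of `list(chromosome=, size=)` tandem clusters
#'   (consecutive near-identical copies within 100 kb).
#' @param segmental_pairs Number of cross-homoeolog duplicate pairs.
#' @param domain_mutation_rate Per-residue substitution rate applied to the
#'   planted domain blocks.
#' @param member_mutation_rate Divergence of each duplication unit from its
#'   group core sequence.
#' @param duplicate_mutation_rate Divergence of each copy within a
#'   duplication unit from the unit ancestor.
#' @param ortholog_mutation_rate Divergence of a reference ortholog from its
#'   target gene.
#' @param orthology_fraction Fraction of target genes given a reference
#'   ortholog.
#' @param network_edges Edge count of the reference co-functional network.
#' @param timepoints Ordered time-course labels; first entry is the control.
#' @param replicates Replicates per timepoint.
#' @param n_upregulated_30M Members planted as induced at the first
#'   post-control timepoint.
#' @param fold_change Planted induction factor at the first post-control
#'   timepoint (decaying geometrically afterwards).
#' @param n_silent Members planted as unexpressed (fail the FPKM filter).
#' @param mean_expression Baseline negative-binomial mean count.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param n_qpcr_genes Genes carried into the qPCR table.
#' @param qpcr_peak_fold Planted fold change of the single qPCR peak gene at
#'   the first post-control timepoint.
#' @param ct_noise_sd Gaussian noise on every Ct value, in cycles.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_chromosomes = 16,
                             n_family_members = 50,
                             n_decoys = 30,
                             groups = c(I = 17, II = 15, III = 13, IV = 5),
                             tandem_clusters = list(
                               list(chromosome = "Tr5O", size = 2),
                               list(chromosome = "Tr1P", size = 2)
                             ),
                             segmental_pairs = 5,
                             domain_mutation_rate = 0.1,
                             member_mutation_rate = 0.2,
                             duplicate_mutation_rate = 0.02,
                             ortholog_mutation_rate = 0.05,
                             orthology_fraction = 0.8,
                             network_edges = 200,
                             timepoints = c("0H", "30M", "1H", "3H", "6H", "12H", "24H", "72H"),
                             replicates = 3,
                             n_upregulated_30M = 15,
                             fold_change = 8,
                             n_silent = 5,
                             mean_expression = 200,
                             nb_dispersion = 0.1,
                             n_qpcr_genes = 10,
                             qpcr_peak_fold = 32,
                             ct_noise_sd = 0.2) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$seed == round(cfg$seed),
    cfg$n_chromosomes >= 2, cfg$n_chromosomes %% 2 == 0,
    cfg$n_family_members >= 1, cfg$n_decoys >= 0,
    sum(cfg$groups) == cfg$n_family_members,
    all(names(cfg$groups) %in% c("I", "II", "III", "IV")),
    cfg$segmental_pairs >= 0,
    cfg$domain_mutation_rate >= 0, cfg$domain_mutation_rate <= 1,
    cfg$orthology_fraction >= 0, cfg$orthology_fraction <= 1,
    cfg$network_edges >= 0,
    length(cfg$timepoints) >= 1, cfg$replicates >= 1,
    cfg$n_upregulated_30M >= 0, cfg$fold_change > 0,
    cfg$ct_noise_sd >= 0
  )
  labs <- chromosome_labels(cfg$n_chromosomes)
  for (cl in cfg$tandem_clusters) {
    stopifnot(cl$chromosome %in% labs, cl$size >= 2)
  }
  n_dup_slots <- sum(vapply(cfg$tandem_clusters, function(cl) cl$size, numeric(1))) +
    2L * cfg$segmental_pairs
  if (n_dup_slots > cfg$n_family_members) {
    stop("generator_config: duplication structure needs more members than available")
  }
  class(cfg) <- "generator_config"
  cfg
}

#' O/P chromosome labels
#' @param n Even chromosome count.
#' @return Character vector `Tr1O..Tr<k>O, Tr1P..Tr<k>P`.
#' @export
chromosome_labels <- function(n) {
  k <- n / 2
  c(paste0("Tr", seq_len(k), "O"), paste0("Tr", seq_len(k), "P"))
}

homoeolog_partner <- function(chrom) {
  ifelse(endsWith(chrom, "O"),
         sub("O$", "P", chrom),
         sub("P$", "O", chrom))
}

random_residues <- function(n) {
  sample(AA_ALPHABET[1:20], n, replace = TRUE)
}

mutate_residues <- function(res, rate) {
  if (rate <= 0) return(res)
  hit <- which(stats::runif(length(res)) < rate)
  for (i in hit) {
    res[i] <- sample(setdiff(AA_ALPHABET[1:20], res[i]), 1L)
  }
  res
}

# Per-group protein architecture: fixed-position kinase block and two
# EF-hand blocks, flanked by group-specific regions.
group_architectures <- function(group_names) {
  lapply(stats::setNames(group_names, group_names), function(g) {
    nterm <- sample(50:90, 1L)
    junc <- sample(20:40, 1L)
    cterm <- sample(120:250, 1L)
    kw <- nchar(KINASE_CONSENSUS)
    ew <- nchar(EFHAND_CONSENSUS)
    len <- nterm + kw + junc + ew + 10L + ew + cterm
    list(length = len,
         kinase_start = nterm + 1L,
         ef_starts = c(nterm + kw + junc + 1L,
                       nterm + kw + junc + ew + 10L + 1L))
  })
}

#' Generate the synthetic genome annotation
#'
#' Places family members and decoys on the O/P chromosome grid, honouring
#' tandem clusters (consecutive copies within 100 kb) and segmental pairs
#' (mirrored slots on homoeologous chromosomes), assigns groups, exon
#' counts and per-group protein architectures, and writes a GFF3 file when
#' a path is given.
#'
#' @param config A [generator_config()].
#' @param gff_path Optional output path for the GFF3 annotation.
#' @return A list with `records` (gene record `data.frame` as from
#'   [read_gff3()]) and `manifest` (planted truth so far).
#' @export
generate_genome <- function(config, gff_path = NULL) {
  set.seed(config$seed + 101L)
  labs <- chromosome_labels(config$n_chromosomes)
  slot_bp <- 250000L
  n_slots <- 200L
  cluster_spacing <- 25000L

  # duplication units: tandem clusters, segmental pairs, singles
  units <- list()
  for (cl in config$tandem_clusters) {
    if ((cl$size - 1L) * cluster_spacing > 100000L) {
      stop("generate_genome: tandem cluster of size ", cl$size,
           " exceeds the 100 kb chromosome window")
    }
    units[[length(units) + 1L]] <- list(kind = "tandem", size = cl$size,
                                        chromosome = cl$chromosome)
  }
  for (i in seq_len(config$segmental_pairs)) {
    units[[length(units) + 1L]] <- list(kind = "segmental", size = 2L)
  }
  n_single <- config$n_family_members -
    sum(vapply(units, function(u) u$size, numeric(1)))
  for (i in seq_len(n_single)) {
    units[[length(units) + 1L]] <- list(kind = "single", size = 1L)
  }

  # assign groups to units without splitting a unit across groups
  remaining <- config$groups
  unit_group <- character(length(units))
  ord <- order(-vapply(units, function(u) u$size, numeric(1)))
  for (i in ord) {
    ok <- names(remaining)[remaining >= units[[i]]$size]
    if (!length(ok)) stop("generate_genome: group counts cannot host duplication units")
    g <- if (length(ok) == 1L) ok else sample(ok, 1L)
    unit_group[i] <- g
    remaining[g] <- remaining[g] - units[[i]]$size
  }

  arch <- group_architectures(names(config$groups))

  # slot bookkeeping per chromosome
  used <- stats::setNames(lapply(labs, function(x) integer(0)), labs)
  take_slot <- function(chrom) {
    free <- setdiff(seq_len(n_slots), used[[chrom]])
    if (!length(free)) stop("generate_genome: chromosome ", chrom, " is full")
    s <- if (length(free) == 1L) free else sample(free, 1L)
    used[[chrom]] <<- c(used[[chrom]], s)
    s
  }

  genes <- list()
  unit_rows <- list()
  add_gene <- function(chrom, pos, group, unit_id, role, decoy_domain = NA_character_) {
    genes[[length(genes) + 1L]] <<- list(
      chromosome = chrom, start = pos, group = group, unit = unit_id,
      role = role, decoy_domain = decoy_domain
    )
  }

  for (i in seq_along(units)) {
    u <- units[[i]]
    uid <- sprintf("U%02d", i)
    g <- unit_group[i]
    if (u$kind == "tandem") {
      s <- take_slot(u$chromosome)
      base <- 1000000L + (s - 1L) * slot_bp
      for (k in seq_len(u$size)) {
        add_gene(u$chromosome, base + (k - 1L) * cluster_spacing, g, uid, "member")
      }
      unit_rows[[length(unit_rows) + 1L]] <-
        data.frame(unit = uid, kind = "tandem", size = u$size,
                   chromosome = u$chromosome, stringsAsFactors = FALSE)
    } else if (u$kind == "segmental") {
      chrom_a <- sample(labs[endsWith(labs, "O")], 1L)
      chrom_b <- homoeolog_partner(chrom_a)
      s <- take_slot(chrom_a)
      used[[chrom_b]] <- c(used[[chrom_b]], s)  # mirror the slot
      base <- 1000000L + (s - 1L) * slot_bp
      add_gene(chrom_a, base, g, uid, "member")
      add_gene(chrom_b, base, g, uid, "member")
      unit_rows[[length(unit_rows) + 1L]] <-
        data.frame(unit = uid, kind = "segmental", size = 2L,
                   chromosome = chrom_a, stringsAsFactors = FALSE)
    } else {
      chrom <- sample(labs, 1L)
      s <- take_slot(chrom)
      add_gene(chrom, 1000000L + (s - 1L) * slot_bp, g, uid, "member")
    }
  }

  for (i in seq_len(config$n_decoys)) {
    chrom <- sample(labs, 1L)
    s <- take_slot(chrom)
    donor <- sample(names(config$groups), 1L)
    keep <- if (i %% 2L == 0L) "kinase" else "EF-hand"
    add_gene(chrom, 1000000L + (s - 1L) * slot_bp, donor,
             sprintf("D%02d", i), "decoy", keep)
  }

  tab <- do.call(rbind, lapply(genes, function(g) {
    data.frame(chromosome = g$chromosome, start = g$start, group = g$group,
               unit = g$unit, role = g$role, decoy_domain = g$decoy_domain,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$chromosome, tab$start), ]
  tab$gene_id <- sprintf("tg%03d", seq_len(nrow(tab)))
  tab$strand <- sample(c("+", "-"), nrow(tab), replace = TRUE)
  tab$protein_length <- vapply(tab$group, function(g) arch[[g]]$length, numeric(1))

  # copies in a unit share exon structure
  intron_pool <- 4:12
  intron_prob <- c(1, 2, 6, 6, 2, 1, 1, 1, 1)
  unit_introns <- stats::setNames(
    sample(intron_pool, length(unique(tab$unit)), replace = TRUE,
           prob = intron_prob),
    unique(tab$unit)
  )
  tab$intron_count <- as.integer(unit_introns[tab$unit])
  tab$exon_count <- tab$intron_count + 1L
  intron_bp <- 400L
  tab$end <- tab$start + 3L * tab$protein_length + intron_bp * tab$intron_count - 1L

  records <- data.frame(
    gene_id = tab$gene_id, chromosome = tab$chromosome,
    start = tab$start, end = tab$end, strand = tab$strand,
    exon_count = tab$exon_count, intron_count = tab$intron_count,
    stringsAsFactors = FALSE
  )

  manifest <- list(
    config = unclass(config),
    architectures = arch,
    genes = tab[, c("gene_id", "role", "group", "unit", "decoy_domain",
                    "chromosome", "start", "end", "strand",
                    "exon_count", "intron_count", "protein_length")],
    units = if (length(unit_rows)) do.call(rbind, unit_rows) else
      data.frame(unit = character(), kind = character(), size = integer(),
                 chromosome = character()),
    n_tandem_events = length(config$tandem_clusters),
    n_segmental_events = config$segmental_pairs
  )
  rownames(manifest$genes) <- NULL

  if (!is.null(gff_path)) write_synthetic_gff3(records, gff_path)
  list(records = records, manifest = manifest)
}

write_synthetic_gff3 <- function(records, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    lines <- c(lines, sprintf(
      "%s\tcdpkfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      r$chromosome, r$start, r$end, r$strand, r$gene_id
    ), sprintf(
      "%s\tcdpkfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.m1;Parent=%s",
      r$chromosome, r$start, r$end, r$strand, r$gene_id, r$gene_id
    ))
    n_exon <- r$exon_count
    cds_total <- (r$end - r$start + 1L) - 400L * (n_exon - 1L)
    base <- cds_total %/% n_exon
    lens <- rep(base, n_exon)
    extra <- cds_total - base * n_exon
    if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
    pos <- r$start
    for (k in seq_len(n_exon)) {
      lines <- c(lines, sprintf(
        "%s\tcdpkfam\texon\t%d\t%d\t.\t%s\t.\tID=%s.m1.exon%d;Parent=%s.m1",
        r$chromosome, pos, pos + lens[k] - 1L, r$strand, r$gene_id, k, r$gene_id
      ))
      pos <- pos + lens[k] + 400L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate target and reference proteomes
#'
#' Every true member carries one planted kinase-like block and two
#' EF-hand-like blocks (each substituted at `domain_mutation_rate`); decoys
#' carry exactly one of the two. The reference proteome consists of planted
#' orthologs of a seeded `orthology_fraction` of target genes; orthologs of
#' family members carry the member's group label and double as the labelled
#' reference family.
#'
#' @param config A [generator_config()].
#' @param manifest Manifest from [generate_genome()].
#' @return A list with `target` and `reference` ([Biostrings::AAStringSet]),
#'   `reference_groups` (named character vector for reference family
#'   members) and the extended `manifest` (domain intervals, ortholog
#'   pairs).
#' @export
generate_proteomes <- function(config, manifest) {
  set.seed(config$seed + 202L)
  genes <- manifest$genes
  arch <- manifest$architectures
  cores <- lapply(arch, function(a) random_residues(a$length))

  unit_ids <- unique(genes$unit)
  unit_anc <- list()
  for (u in unit_ids) {
    g <- genes$group[genes$unit == u][1L]
    unit_anc[[u]] <- mutate_residues(cores[[g]], config$member_mutation_rate)
  }

  kin <- strsplit(KINASE_CONSENSUS, "")[[1]]
  ef <- strsplit(EFHAND_CONSENSUS, "")[[1]]
  plant <- function(res, block, start, rate) {
    res[start:(start + length(block) - 1L)] <- mutate_residues(block, rate)
    res
  }

  target <- character(nrow(genes))
  dom_rows <- list()
  for (i in seq_len(nrow(genes))) {
    gr <- genes[i, ]
    a <- arch[[gr$group]]
    res <- unit_anc[[gr$unit]]
    multi <- sum(genes$unit == gr$unit) > 1L
    if (multi) res <- mutate_residues(res, config$duplicate_mutation_rate)
    plant_kinase <- gr$role == "member" || identical(gr$decoy_domain, "kinase")
    plant_ef <- gr$role == "member" || identical(gr$decoy_domain, "EF-hand")
    if (plant_kinase) {
      res <- plant(res, kin, a$kinase_start, config$domain_mutation_rate)
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        protein_id = gr$gene_id, domain = "kinase",
        start = a$kinase_start, end = a$kinase_start + length(kin) - 1L,
        stringsAsFactors = FALSE)
    } else {
      res[a$kinase_start:(a$kinase_start + length(kin) - 1L)] <-
        random_residues(length(kin))
    }
    if (plant_ef) {
      for (es in a$ef_starts) {
        res <- plant(res, ef, es, config$domain_mutation_rate)
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = gr$gene_id, domain = "EF-hand",
          start = es, end = es + length(ef) - 1L, stringsAsFactors = FALSE)
      }
    } else {
      for (es in a$ef_starts) {
        res[es:(es + length(ef) - 1L)] <- random_residues(length(ef))
      }
    }
    target[i] <- paste(res, collapse = "")
  }
  names(target) <- genes$gene_id

  n_orth <- round(config$orthology_fraction * nrow(genes))
  orth_targets <- sort(sample(genes$gene_id, n_orth))
  ref <- character(n_orth)
  ref_ids <- sprintf("ref%03d", seq_len(n_orth))
  for (i in seq_len(n_orth)) {
    res <- strsplit(target[[orth_targets[i]]], "")[[1]]
    ref[i] <- paste(mutate_residues(res, config$ortholog_mutation_rate),
                    collapse = "")
  }
  names(ref) <- ref_ids

  orth <- data.frame(
    target_id = orth_targets, ref_id = ref_ids,
    role = genes$role[match(orth_targets, genes$gene_id)],
    group = genes$group[match(orth_targets, genes$gene_id)],
    stringsAsFactors = FALSE
  )
  fam <- orth$role == "member"
  reference_groups <- stats::setNames(orth$group[fam], orth$ref_id[fam])

  manifest$domains <- do.call(rbind, dom_rows)
  manifest$orthologs <- orth
  manifest$reference_family <- data.frame(
    ref_id = orth$ref_id[fam], group = orth$group[fam], stringsAsFactors = FALSE
  )
  list(target = Biostrings::AAStringSet(target),
       reference = Biostrings::AAStringSet(ref),
       reference_groups = reference_groups,
       manifest = manifest)
}

#' Generate the reference co-functional network
#'
#' A simple undirected graph (no loops, no duplicate edges) over the
#' reference gene ids, with every reference family member guaranteed at
#' least one edge when the requested edge budget allows.
#'
#' @param config A [generator_config()].
#' @param manifest Manifest from [generate_proteomes()].
#' @return A list with `edges` (two-column `data.frame`, canonical
#'   lexicographic order within each edge) and the extended `manifest`.
#' @export
generate_reference_network <- function(config, manifest) {
  set.seed(config$seed + 303L)
  nodes <- manifest$orthologs$ref_id
  n <- length(nodes)
  capacity <- n * (n - 1) / 2
  if (config$network_edges > capacity) {
    stop("generate_reference_network: requested ", config$network_edges,
         " edges but only ", capacity, " are possible on ", n, " genes")
  }
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keys <- character(0)
  from <- character(0); to <- character(0)
  add_edge <- function(a, b) {
    k <- canon(a, b)
    if (a == b || k %in% keys) return(FALSE)
    keys <<- c(keys, k)
    from <<- c(from, min(a, b)); to <<- c(to, max(a, b))
    TRUE
  }
  fam <- manifest$reference_family$ref_id
  for (f in fam) {
    if (length(keys) >= config$network_edges) break
    repeat {
      if (add_edge(f, sample(setdiff(nodes, f), 1L))) break
    }
  }
  while (length(keys) < config$network_edges) {
    pair <- sample(nodes, 2L)
    add_edge(pair[1L], pair[2L])
  }
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  manifest$network <- edges
  list(edges = edges, manifest = manifest)
}

#' Generate the cold time-course count matrix
#'
#' Negative-binomial counts for every family member across the configured
#' timepoints and replicates, with per-sample depth factors varying at most
#' two-fold, a planted up-regulated subset (induction `fold_change` at the
#' first post-control timepoint, decaying geometrically back to baseline)
#' and a planted silent subset that fails the FPKM filter.
#'
#' @param config A [generator_config()].
#' @param manifest Manifest from [generate_proteomes()].
#' @return A list with `counts` (gene x sample matrix; samples labelled
#'   `<timepoint>_r<rep>`), `lengths` (named effective transcript lengths,
#'   bp) and the extended `manifest`.
#' @export
generate_expression <- function(config, manifest) {
  set.seed(config$seed + 404L)
  genes <- manifest$genes
  members <- genes$gene_id[genes$role == "member"]
  n <- length(members)
  tps <- config$timepoints
  reps <- config$replicates
  samples <- as.vector(outer(tps, seq_len(reps),
                             function(t, r) paste0(t, "_r", r)))

  silent <- sort(sample(members, min(config$n_silent, n)))
  expressed <- setdiff(members, silent)
  up <- sort(sample(expressed, min(config$n_upregulated_30M, length(expressed))))

  base_mu <- stats::setNames(
    stats::rlnorm(n, log(config$mean_expression), 0.6), members)
  base_mu[silent] <- 0

  # log2 induction decays by half per subsequent timepoint
  lfc <- matrix(0, n, length(tps), dimnames = list(members, tps))
  if (config$fold_change > 1 && length(tps) > 1L && length(up)) {
    for (k in 2:length(tps)) {
      lfc[up, k] <- log2(config$fold_change) * 0.5^(k - 2L)
    }
  } else {
    up <- character(0)
  }

  depth <- stats::runif(length(samples), 0.75, 1.5)
  names(depth) <- samples
  counts <- matrix(0L, n, length(samples), dimnames = list(members, samples))
  size <- 1 / config$nb_dispersion
  for (j in seq_along(samples)) {
    tp <- sub("_r\\d+$", "", samples[j])
    mu <- base_mu * 2^lfc[, tp] * depth[j]
    counts[, j] <- ifelse(mu <= 0, 0L,
                          stats::rnbinom(n, mu = pmax(mu, 1e-8), size = size))
  }
  # whole-library totals: the family panel is a negligible slice of the
  # transcriptome, so the per-sample total is depth alone, not the panel sum
  library_sizes <- round(2e6 * depth)

  lengths <- stats::setNames(3L * genes$protein_length[match(members, genes$gene_id)] + 200L,
                             members)
  manifest$expression <- list(
    expressed_genes = expressed,
    silent_genes = silent,
    upregulated_30M = up,
    fold_change = config$fold_change,
    library_sizes = as.list(library_sizes)
  )
  list(counts = counts, lengths = lengths, library_sizes = library_sizes,
       manifest = manifest)
}

#' Generate a qPCR Ct table
#'
#' Builds Ct rows (gene, timepoint, replicate, target and reference Ct) for
#' the first four timepoints of the time course. Planted log2 fold changes
#' enter the target Ct with the opposite sign; the reference gene is
#' constant in expectation; Gaussian noise of `ct_noise_sd` cycles is added
#' to every Ct value.
#'
#' @param config A [generator_config()].
#' @param manifest Manifest from [generate_expression()].
#' @return A list with `ct_table` (`data.frame`: `gene`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`) and the extended `manifest`
#'   (planted per-gene/timepoint ddCt values).
#' @export
generate_ct_table <- function(config, manifest) {
  set.seed(config$seed + 505L)
  tps <- config$timepoints[seq_len(min(4L, length(config$timepoints)))]
  up <- manifest$expression$upregulated_30M
  expressed <- manifest$expression$expressed_genes
  n_genes <- min(config$n_qpcr_genes, length(expressed))
  qpcr_genes <- sort(c(
    utils::head(up, min(length(up), ceiling(n_genes / 2))),
    utils::head(setdiff(expressed, up), n_genes - min(length(up), ceiling(n_genes / 2)))
  ))

  planted <- expand.grid(gene = qpcr_genes, timepoint = tps,
                         stringsAsFactors = FALSE)
  planted$ddct <- 0
  peak_gene <- if (length(up)) utils::head(intersect(qpcr_genes, up), 1L) else character(0)
  for (k in seq_along(tps)[-1]) {
    idx_up <- planted$timepoint == tps[k] & planted$gene %in% up
    planted$ddct[idx_up] <- -log2(config$fold_change) * 0.5^(k - 2L)
    if (length(peak_gene)) {
      idx_peak <- planted$timepoint == tps[k] & planted$gene == peak_gene
      planted$ddct[idx_peak] <- -log2(config$qpcr_peak_fold) * 0.5^(k - 2L)
    }
  }

  base_ct <- stats::setNames(stats::runif(length(qpcr_genes), 22, 28), qpcr_genes)
  ref_ct <- 18
  rows <- list()
  for (i in seq_len(nrow(planted))) {
    g <- planted$gene[i]; tp <- planted$timepoint[i]
    for (r in seq_len(config$replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, timepoint = tp, replicate = r,
        ct_target = base_ct[[g]] + planted$ddct[i] +
          stats::rnorm(1, 0, config$ct_noise_sd),
        ct_reference = ref_ct + stats::rnorm(1, 0, config$ct_noise_sd),
        stringsAsFactors = FALSE
      )
    }
  }
  ct <- do.call(rbind, rows)
  manifest$qpcr <- list(planted = planted, peak_gene = peak_gene,
                        peak_fold = config$qpcr_peak_fold)
  list(ct_table = ct, manifest = manifest)
}

# Compact built-in ontology used by the synthetic annotations: true GO ids
# and is-a links for a dozen terms across the three namespaces.
TOY_ONTOLOGY <- data.frame(
  term = c("GO:0050896", "GO:0006950", "GO:0009409",
           "GO:0023052", "GO:0007165",
           "GO:0065007", "GO:0050794",
           "GO:0016301", "GO:0005515",
           "GO:0005737", "GO:0005634"),
  parent = c("GO:0008150", "GO:0050896", "GO:0006950",
             "GO:0008150", "GO:0023052",
             "GO:0008150", "GO:0065007",
             "GO:0003674", "GO:0003674",
             "GO:0005575", "GO:0005575"),
  namespace = c("BP", "BP", "BP", "BP", "BP", "BP", "BP",
                "MF", "MF", "CC", "CC"),
  stringsAsFactors = FALSE
)

#' Generate synthetic GO annotations
#'
#' Annotates target genes over a compact built-in ontology. Genes whose
#' reference ortholog shares a network edge with a reference family member
#' (the expected network partners of the family) are enriched for the
#' planted term `GO:0007165` (signal transduction); all other genes carry it
#' at a low background rate. Every gene receives 1-2 additional random
#' terms.
#'
#' @param config A [generator_config()].
#' @param manifest Manifest from [generate_reference_network()].
#' @return A list with `annotations` (`data.frame`: `gene`, `term`),
#'   `ontology` (`data.frame`: `term`, `parent`, `namespace`) and the
#'   extended `manifest` (planted enriched term).
#' @export
generate_go_annotations <- function(config, manifest) {
  set.seed(config$seed + 606L)
  orth <- manifest$orthologs
  fam_refs <- manifest$reference_family$ref_id
  net <- manifest$network
  partner_refs <- unique(c(net$to[net$from %in% fam_refs],
                           net$from[net$to %in% fam_refs]))
  partner_refs <- setdiff(partner_refs, fam_refs)
  partner_genes <- orth$target_id[orth$ref_id %in% partner_refs]
  all_genes <- manifest$genes$gene_id
  planted_term <- "GO:0007165"
  leaf_terms <- setdiff(TOY_ONTOLOGY$term, TOY_ONTOLOGY$parent)

  rows <- list()
  for (g in all_genes) {
    p <- if (g %in% partner_genes) 0.7 else 0.1
    terms <- character(0)
    if (stats::runif(1) < p) terms <- planted_term
    terms <- unique(c(terms, sample(setdiff(leaf_terms, planted_term),
                                    sample(1:2, 1L))))
    rows[[length(rows) + 1L]] <- data.frame(gene = g, term = terms,
                                            stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  manifest$go <- list(planted_term = planted_term,
                      partner_genes = partner_genes)
  list(annotations = ann, ontology = TOY_ONTOLOGY, manifest = manifest)
}

#' Generate every synthetic survey input
#'
#' Runs all generators in order and (optionally) writes the complete input
#' bundle: GFF3 annotation, target/reference proteome FASTAs, reference
#' group labels, reference network edge list, count and length TSVs, Ct
#' table, GO annotation and ontology TSVs, and the JSON truth manifest.
#' All output is byte-identical across runs with the same config.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if missing); `NULL` to skip writing.
#' @return A list with all generated objects plus the complete `manifest`
#'   and, when `dir` is given, a `paths` list of written files.
#' @export
generate_survey_inputs <- function(config = generator_config(), dir = NULL) {
  gen <- generate_genome(config)
  prot <- generate_proteomes(config, gen$manifest)
  net <- generate_reference_network(config, prot$manifest)
  expr <- generate_expression(config, net$manifest)
  ct <- generate_ct_table(config, expr$manifest)
  go <- generate_go_annotations(config, ct$manifest)
  manifest <- go$manifest

  out <- list(
    config = config,
    records = gen$records,
    target = prot$target,
    reference = prot$reference,
    reference_groups = prot$reference_groups,
    network = net$edges,
    counts = expr$counts,
    lengths = expr$lengths,
    library_sizes = expr$library_sizes,
    ct_table = ct$ct_table,
    annotations = go$annotations,
    ontology = go$ontology,
    manifest = manifest
  )

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- list(
      gff3 = file.path(dir, "genome.gff3"),
      target = file.path(dir, "target_proteome.faa"),
      reference = file.path(dir, "reference_proteome.faa"),
      reference_groups = file.path(dir, "reference_groups.tsv"),
      network = file.path(dir, "reference_network.tsv"),
      counts = file.path(dir, "counts.tsv"),
      library_sizes = file.path(dir, "library_sizes.tsv"),
      lengths = file.path(dir, "gene_lengths.tsv"),
      ct_table = file.path(dir, "ct_table.tsv"),
      annotations = file.path(dir, "go_annotations.tsv"),
      ontology = file.path(dir, "go_ontology.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    write_synthetic_gff3(gen$records, p$gff3)
    write_fasta(out$target, p$target)
    write_fasta(out$reference, p$reference)
    utils::write.table(
      data.frame(ref_id = names(out$reference_groups),
                 group = unname(out$reference_groups)),
      p$reference_groups, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$network, p$network, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(gene = rownames(out$counts), out$counts,
                                  check.names = FALSE),
                       p$counts, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = names(out$library_sizes),
                                  total = unname(out$library_sizes)),
                       p$library_sizes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(gene = names(out$lengths),
                                  length = unname(out$lengths)),
                       p$lengths, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$ct_table, p$ct_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(out$annotations, p$annotations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$ontology, p$ontology, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(manifest_for_json(manifest), p$manifest,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- p
  }
  out
}

manifest_for_json <- function(manifest) {
  manifest$config$groups <- as.list(manifest$config$groups)
  manifest
}
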
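# End-to-end survey orchestration: identify -> phylogeny -> motifs ->
# duplications -> network projection -> GO enrichment -> expression ->
# qPCR, from one input bundle, with per-stage logging and a consolidated
# report bundle on disk.

#' Survey parameters
#'
#' The analysis thresholds, with the study's values as defaults: alignment
#' coverage 0.80 at e-value 1e-5 for identification, a 0.6-of-maximum
#' consensus-block score for domain hits, 1000 bootstrap replicates, up to
#' 10 motifs of width 6-50, duplication thresholds 0.8/0.8, enrichment
#' alpha 0.05, and the FPKM > 1 expression filter.
#'
#' @param min_coverage,evalue_cutoff Identification screen thresholds.
#' @param domain_score_frac Fraction of the maximal consensus-block score
#'   required for a domain hit.
#' @param bootstrap Bootstrap replicate count for the phylogeny.
#' @param max_motifs,w_min,w_max Motif discovery controls.
#' @param dup_identity,dup_coverage Duplication thresholds (strict `>`).
#' @param max_intervening,max_span_bp Tight-linkage window for tandem calls.
#' @param go_alpha Elim enrichment threshold.
#' @param min_fpkm Expressed-gene filter (strict `>`).
#' @param lfc_threshold Response-call log2 fold-change threshold.
#' @param control Control timepoint label.
#' @param name_prefix Member naming prefix for the family table.
#' @return A list of class `survey_params`.
#' @export
survey_params <- function(min_coverage = 0.80, evalue_cutoff = 1e-5,
                          domain_score_frac = 0.6, bootstrap = 1000,
                          max_motifs = 10, w_min = 6, w_max = 50,
                          dup_identity = 0.8, dup_coverage = 0.8,
                          max_intervening = 1, max_span_bp = 1e5,
                          go_alpha = 0.05, min_fpkm = 1, lfc_threshold = 1,
                          control = "0H", name_prefix = "TrCDPK") {
  structure(as.list(environment()), class = "survey_params")
}

#' Load a survey input bundle from a directory
#'
#' Reads the standard bundle layout written by [generate_survey_inputs()]:
#' `genome.gff3`, `target_proteome.faa`, `reference_proteome.faa`,
#' `reference_groups.tsv`, `reference_network.tsv`, `counts.tsv`,
#' `gene_lengths.tsv`, `ct_table.tsv`, `go_annotations.tsv`,
#' `go_ontology.tsv`.
#'
#' @param dir Input directory.
#' @return A named list of loaded inputs.
#' @export
load_survey_inputs <- function(dir) {
  path <- function(x) file.path(dir, x)
  grp <- utils::read.delim(path("reference_groups.tsv"),
                           stringsAsFactors = FALSE)
  lens <- utils::read.delim(path("gene_lengths.tsv"), stringsAsFactors = FALSE)
  libs <- if (file.exists(path("library_sizes.tsv"))) {
    tab <- utils::read.delim(path("library_sizes.tsv"), stringsAsFactors = FALSE)
    stats::setNames(tab$total, tab$sample)
  } else NULL
  net <- utils::read.delim(path("reference_network.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(net) <- c("from", "to")
  list(
    records = read_gff3(path("genome.gff3")),
    target = read_fasta(path("target_proteome.faa")),
    reference = read_fasta(path("reference_proteome.faa")),
    reference_groups = stats::setNames(grp$group, grp$ref_id),
    network = net,
    counts = read_expression_matrix(path("counts.tsv")),
    lengths = stats::setNames(lens$length, lens$gene),
    library_sizes = libs,
    ct_table = read_ct_table(path("ct_table.tsv")),
    annotations = read_annotations(path("go_annotations.tsv")),
    ontology = read_ontology(path("go_ontology.tsv"))
  )
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

transpose_stats <- function(stats) {
  lapply(stats, t)
}

#' Run the full family survey
#'
#' Executes every stage in dependency order on an input bundle (either the
#' list returned by [generate_survey_inputs()] / [load_survey_inputs()] or
#' a directory path), writes the per-stage outputs into `out_dir` (family
#' table and summary, Newick tree, motif text and occurrence matrix,
#' duplication events and links, projected and family subnetwork edge
#' lists, enrichment table, expression tables, qPCR fold changes, and a
#' provenance echo of every parameter), and returns the report as a list.
#' A stage failure halts with the stage name and offending input.
#'
#' @param inputs Input bundle list or a directory path.
#' @param out_dir Output directory for the report bundle (`NULL` = no
#'   files).
#' @param params A [survey_params()] object.
#' @param seed Integer seed for the bootstrap and motif stages.
#' @return A list of class `survey_report`.
#' @export
run_survey <- function(inputs, out_dir = NULL, params = survey_params(),
                       seed = 1) {
  if (is.character(inputs) && length(inputs) == 1L) {
    inputs <- load_survey_inputs(inputs)
  }
  required <- c("records", "target", "reference", "reference_groups",
                "network", "counts", "lengths", "ct_table")
  for (r in required) {
    if (is.null(inputs[[r]])) {
      stage <- switch(r,
                      records = "family_identification",
                      target = "family_identification",
                      reference = "family_identification",
                      reference_groups = "phylogeny",
                      network = "grn_projection",
                      counts = "expression", lengths = "expression",
                      ct_table = "qpcr")
      stop("run_survey: stage '", stage, "' is missing input '", r, "'")
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  out <- function(x) if (is.null(out_dir)) NULL else file.path(out_dir, x)
  report <- list(params = params, seed = seed)

  # -- identification ------------------------------------------------------
  stage_log("identify", length(inputs$reference), " reference x ",
            length(inputs$target), " target proteins")
  scoring <- align_scoring()
  stats_rt <- align_stats_matrix(inputs$reference, inputs$target, scoring)
  ref_family <- inputs$reference[names(inputs$reference) %in%
                                   names(inputs$reference_groups)]
  fam_stats <- lapply(stats_rt, function(m)
    m[names(ref_family), , drop = FALSE])
  candidates <- screen_candidates(ref_family, inputs$target,
                                  min_coverage = params$min_coverage,
                                  evalue_cutoff = params$evalue_cutoff,
                                  scoring = scoring, stats = fam_stats)
  models <- domain_models(params$domain_score_frac)
  hits <- scan_proteome_domains(inputs$target[candidates], models)
  members <- confirm_members(candidates, hits)
  stage_log("identify", length(candidates), " candidates, ",
            length(members), " confirmed members")
  if (length(members) < 3L) {
    stop("run_survey: stage 'family_identification' confirmed fewer than 3 members")
  }
  report$candidates <- candidates
  report$members <- members
  report$domain_hits <- hits

  # -- phylogeny -----------------------------------------------------------
  stage_log("phylo", "aligning ", length(members), " members + ",
            length(ref_family), " references")
  aln <- align_proteins(c(inputs$target[members], ref_family))
  tree <- bootstrap_support(aln, n_replicates = params$bootstrap, seed = seed)
  groups <- assign_groups(tree, inputs$reference_groups)
  report$tree <- tree
  report$groups <- groups[members]
  if (!is.null(out_dir)) write_tree_newick(tree, out("tree.nwk"))

  # -- family table --------------------------------------------------------
  fam_table <- build_family_table(members, inputs$records, inputs$target,
                                  groups = report$groups,
                                  prefix = params$name_prefix)
  report$family_table <- fam_table
  report$summary <- summarize_family_table(fam_table)
  if (!is.null(out_dir)) write_family_table(fam_table, out("family_table.tsv"))
  if (!is.null(out_dir)) {
    utils::write.table(hits, out("domain_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # -- motifs --------------------------------------------------------------
  stage_log("motifs", "EM discovery over ", length(members), " proteins")
  motifs <- discover_motifs(inputs$target[members],
                            max_motifs = params$max_motifs,
                            w_min = params$w_min, w_max = params$w_max,
                            seed = seed)
  occ <- occurrence_matrix(motifs, inputs$target[members])
  report$motifs <- motifs
  report$occurrence <- occ
  report$shared_motifs <- if (length(motifs)) shared_motifs(occ) else character(0)
  stage_log("motifs", length(motifs), " motifs, ",
            length(report$shared_motifs), " shared by all members")
  if (!is.null(out_dir) && length(motifs)) {
    write_meme_txt(motifs, out("motifs_meme.txt"))
    utils::write.table(data.frame(protein = rownames(occ), occ,
                                  check.names = FALSE),
                       out("motif_occurrence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # -- duplications --------------------------------------------------------
  stage_log("dups", "screening ", length(members), " members for duplicates")
  pairs <- find_duplicate_pairs(members, inputs$target,
                                min_identity = params$dup_identity,
                                min_coverage = params$dup_coverage,
                                scoring = scoring)
  pairs <- collapse_tight_clusters(pairs, inputs$records,
                                   max_intervening = params$max_intervening)
  events <- classify_events(pairs, inputs$records,
                            max_span_bp = params$max_span_bp)
  report$duplicate_pairs <- pairs
  report$duplication_events <- events
  stage_log("dups", sum(events$kind == "tandem"), " tandem + ",
            sum(events$kind == "segmental"), " segmental events")
  if (!is.null(out_dir)) {
    write_duplication_events(events, inputs$records,
                             out("duplication_events.tsv"),
                             out("duplication_links.tsv"))
  }

  # -- network projection --------------------------------------------------
  stage_log("grn", "reciprocal best hits over ", length(inputs$target),
            " x ", length(inputs$reference), " proteins")
  map_tr <- best_hit_map(inputs$target, inputs$reference,
                         evalue_cutoff = params$evalue_cutoff,
                         scoring = scoring,
                         stats = transpose_stats(stats_rt))
  map_rt <- best_hit_map(inputs$reference, inputs$target,
                         evalue_cutoff = params$evalue_cutoff,
                         scoring = scoring, stats = stats_rt)
  rbh <- reciprocal_pairs(map_tr, map_rt)
  net <- project_network(inputs$network, rbh)
  subnet <- extract_subnetwork(net, intersect(members, igraph::V(net)$name))
  report$rbh <- rbh
  report$network <- net
  report$subnetwork <- subnet
  stage_log("grn", nrow(rbh), " ortholog pairs; projected ",
            igraph::ecount(net), " edges; family subnetwork ",
            subnet$nodes, " nodes / ", subnet$edges, " edges")
  if (!is.null(out_dir)) {
    write_network(net, out("projected_network.tsv"))
    write_network(subnet$graph, out("family_subnetwork.tsv"),
                  out("family_subnetwork.graphml"))
    utils::write.table(subnet$degree, out("family_degrees.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # -- GO enrichment -------------------------------------------------------
  if (!is.null(inputs$annotations) && !is.null(inputs$ontology)) {
    partners <- setdiff(igraph::V(subnet$graph)$name, members)
    population <- unique(inputs$annotations$gene)
    study <- intersect(partners, population)
    stage_log("enrich", length(study), " partner genes vs ",
              length(population), " background genes")
    enr <- elim_enrichment(study, population, inputs$annotations,
                           inputs$ontology, alpha = params$go_alpha)
    report$enrichment <- enr
    if (!is.null(out_dir)) write_enrichment(enr, out("go_enrichment.tsv"))
  }

  # -- expression ----------------------------------------------------------
  stage_log("express", nrow(inputs$counts), " genes x ",
            ncol(inputs$counts), " samples")
  libs <- if (is.null(inputs$library_sizes)) colSums(inputs$counts) else
    inputs$library_sizes[colnames(inputs$counts)]
  fp <- fpkm(inputs$counts, inputs$lengths, library_sizes = libs)
  expressed <- filter_expressed(fp, params$min_fpkm)
  if (length(expressed) < 2L) {
    stop("run_survey: stage 'expression' kept fewer than 2 expressed genes")
  }
  z <- suppressWarnings(log2_center_scale(fp[expressed, , drop = FALSE]))
  cl <- cluster_genes(z)
  calls <- call_responses(fp[expressed, , drop = FALSE],
                          control = params$control,
                          lfc_threshold = params$lfc_threshold)
  report$fpkm <- fp
  report$expressed <- expressed
  report$leaf_order <- cl$order
  report$response_calls <- calls
  up30 <- calls$gene[calls$direction == "up" &
                       calls$timepoint == colnames(average_replicates(fp))[2L]]
  stage_log("express", length(expressed), " expressed genes, ",
            length(up30), " up-regulated at the first stress timepoint")
  if (!is.null(out_dir)) {
    utils::write.table(data.frame(gene = rownames(z), z, check.names = FALSE),
                       out("expression_scaled.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(cl$order, out("heatmap_leaf_order.txt"))
    utils::write.table(calls, out("response_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(timepoint_distributions(fp[expressed, , drop = FALSE]),
                       out("timepoint_distributions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # -- qPCR ----------------------------------------------------------------
  folds <- delta_delta_ct(inputs$ct_table, control = params$control)
  report$qpcr <- folds
  stage_log("qpcr", length(unique(folds$gene)), " genes quantified")
  if (!is.null(out_dir)) {
    utils::write.table(folds, out("qpcr_fold_changes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(out_dir)) {
    prm <- c(list(seed = seed), unclass(params))
    writeLines(paste0(names(prm), ": ", vapply(prm, function(x)
      paste(format(x), collapse = " "), character(1))),
      out("parameters.txt"))
    writeLines(utils::capture.output(print(report$summary)),
               out("summary.txt"))
  }
  class(report) <- "survey_report"
  report
}

#' @export
print.survey_report <- function(x, ...) {
  cat("Survey report\n")
  cat("  members   :", length(x$members), "\n")
  cat("  motifs    :", length(x$motifs), "\n")
  cat("  dup events:", nrow(x$duplication_events), "\n")
  cat("  network   :", igraph::vcount(x$network), "nodes /",
      igraph::ecount(x$network), "edges\n")
  cat("  expressed :", length(x$expressed), "\n")
  invisible(x)
}

#' Compare two family summaries field by field
#'
#' @param a,b Family tables (`data.frame`s sharing the family-table schema).
#' @return A `data.frame` with columns `field`, `a`, `b`, `equal`; zero
#'   `equal = FALSE` rows means the summaries agree.
#' @export
validate_against_fixture <- function(a, b) {
  for (tab in list(a, b)) {
    missing <- setdiff(FAMILY_TABLE_COLS, names(tab))
    if (length(missing)) {
      stop("validate_against_fixture: table missing column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  sa <- summarize_family_table(a)
  sb <- summarize_family_table(b)
  flatten <- function(s) {
    out <- c(
      n_members = s$n_members,
      max_length = unname(s$max_length),
      max_length_name = names(s$max_length),
      min_length = unname(s$min_length),
      min_length_name = names(s$min_length),
      max_introns = unname(s$max_introns),
      max_introns_name = names(s$max_introns),
      min_introns = s$min_introns
    )
    for (g in names(s$per_group)) out[paste0("group_", g)] <- s$per_group[[g]]
    for (ch in names(s$per_chromosome)) {
      out[paste0("chrom_", ch)] <- s$per_chromosome[[ch]]
    }
    out
  }
  fa <- flatten(sa); fb <- flatten(sb)
  fields <- union(names(fa), names(fb))
  data.frame(
    field = fields,
    a = unname(fa[fields]),
    b = unname(fb[fields]),
    equal = !is.na(fa[fields]) & !is.na(fb[fields]) &
      unname(fa[fields]) == unname(fb[fields]),
    stringsAsFactors = FALSE
  )
}
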
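# Domain containers and readers/writers for the formats the survey touches.
# Coordinates follow GFF3 throughout: 1-based, inclusive on both ends.

#' Amino-acid alphabet accepted by the pipeline
#'
#' The twenty standard residues plus `X` for an unknown residue.
#' @keywords internal
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

FAMILY_GROUPS <- c("I", "II", "III", "IV", "ungrouped")

#' Read a protein FASTA file
#'
#' Thin validating wrapper around [Biostrings::readAAStringSet()]. Residues
#' are uppercased and restricted to the 20 standard amino-acid letters plus
#' `X`; record order is preserved.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A named [Biostrings::AAStringSet] with one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) == 0L) {
    stop("FASTA format error in ", path, ": file is empty (line 1)")
  }
  first <- non_blank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA format error in ", path, ": expected '>' header at line ", first)
  }
  # validate residue characters on the raw lines (the Biostrings reader
  # silently drops invalid one-letter codes)
  is_seq <- !startsWith(trimws(lines), ">") & nzchar(trimws(lines))
  for (i in which(is_seq)) {
    ch <- strsplit(toupper(trimws(lines[i])), "")[[1]]
    if (any(!ch %in% AA_ALPHABET)) {
      stop("FASTA format error in ", path,
           ": non amino-acid residues at line ", i)
    }
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (any(!nzchar(names(seqs)))) {
    stop("FASTA format error in ", path, ": empty header name")
  }
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  if (any(Biostrings::width(seqs) < 1L)) {
    stop("FASTA format error in ", path, ": zero-length record")
  }
  seqs
}

#' Write a protein FASTA file
#'
#' @param seqs A named [Biostrings::AAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`, `mRNA` and `exon` features and returns one record per gene.
#' When a gene carries several mRNAs the one with the largest summed exon
#' length is used, matching the "longest transcript" convention behind
#' protein-length reporting. Intron counts are `exon_count - 1` for the
#' chosen mRNA.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`, `exon_count`, `intron_count`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  exons <- gr[type == "exon"]
  if (length(genes) == 0L) stop("GFF3 file ", path, " contains no gene features")
  exon_parent <- unlist_parent(exons$Parent)
  # drop duplicated exon lines (same parent + identical interval)
  exon_key <- paste(exon_parent, GenomicRanges::start(exons), GenomicRanges::end(exons))
  if (anyDuplicated(exon_key)) {
    warning("read_gff3: duplicate exon lines deduplicated in ", path)
    keep <- !duplicated(exon_key)
    exons <- exons[keep]
    exon_parent <- exon_parent[keep]
  }
  exon_w <- GenomicRanges::width(exons)
  mrna_id <- as.character(mrnas$ID)
  mrna_parent <- unlist_parent(mrnas$Parent)
  exon_n <- tapply(exon_w, factor(exon_parent, levels = mrna_id), length)
  exon_len <- tapply(exon_w, factor(exon_parent, levels = mrna_id), sum)
  exon_n[is.na(exon_n)] <- 0L
  exon_len[is.na(exon_len)] <- 0L
  if (any(exon_n == 0L)) {
    stop("read_gff3: mRNA without exons in ", path, ": ",
         paste(mrna_id[exon_n == 0L], collapse = ", "))
  }
  recs <- lapply(seq_along(genes), function(i) {
    gid <- as.character(genes$ID[i])
    idx <- which(mrna_parent == gid)
    if (length(idx) == 0L) stop("read_gff3: gene without mRNA in ", path, ": ", gid)
    best <- idx[which.max(exon_len[idx])]
    data.frame(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(genes))[i],
      start = GenomicRanges::start(genes)[i],
      end = GenomicRanges::end(genes)[i],
      strand = as.character(GenomicRanges::strand(genes))[i],
      exon_count = as.integer(exon_n[best]),
      intron_count = as.integer(exon_n[best]) - 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  stopifnot(all(out$start <= out$end), all(out$intron_count >= 0L))
  out
}

unlist_parent <- function(p) {
  vapply(as.list(p), function(x) if (length(x)) as.character(x)[1L] else NA_character_,
         character(1))
}

#' Path to the packaged white clover family table
#'
#' A 50-row transcription of the published summary of the white clover CDPK
#' family (name, locus, chromosome, coordinates, group, intron count,
#' protein length).
#'
#' @return Path to the TSV fixture.
#' @export
family_table_fixture <- function() {
  system.file("extdata", "family_table_clover.tsv", package = "cdpkfam",
              mustWork = TRUE)
}

FAMILY_TABLE_COLS <- c("name", "locus", "chromosome", "start", "end",
                       "group", "intron", "length_aa")

#' Load a family summary table
#'
#' Reads a TSV with columns `name`, `locus`, `chromosome`, `start`, `end`,
#' `group`, `intron`, `length_aa`. Group labels must come from
#' `I`/`II`/`III`/`IV`/`ungrouped`.
#'
#' @param path Path to the TSV (defaults to the packaged white clover table).
#' @return A `data.frame`, one row per family member.
#' @export
load_family_table <- function(path = family_table_fixture()) {
  if (!file.exists(path)) stop("family table not found: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    warning("load_family_table: empty file ", path)
    return(empty_family_table())
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(FAMILY_TABLE_COLS, names(tab))
  if (length(missing)) {
    stop("family table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, FAMILY_TABLE_COLS]
  if (nrow(tab) == 0L) {
    warning("load_family_table: no rows in ", path)
    return(tab)
  }
  bad <- !tab$group %in% FAMILY_GROUPS
  if (any(bad)) {
    stop("family table ", path, " has unknown group label(s): ",
         paste(unique(tab$group[bad]), collapse = ", "))
  }
  stopifnot(all(tab$length_aa >= 1), all(tab$intron >= 0),
            all(tab$start <= tab$end))
  tab
}

empty_family_table <- function() {
  data.frame(name = character(), locus = character(), chromosome = character(),
             start = numeric(), end = numeric(), group = character(),
             intron = integer(), length_aa = integer(),
             stringsAsFactors = FALSE)
}

#' Write a family table TSV
#'
#' @param tab A family table `data.frame` as from [load_family_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(tab, path) {
  utils::write.table(tab[, FAMILY_TABLE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a "chrom:start-end" locus string
#'
#' Accepts both an ASCII hyphen and the typographic en-dash between the two
#' coordinates.
#'
#' @param x Character vector of locus strings, e.g. `"Tr5O:6993561-7004058"`.
#' @return A `data.frame` with columns `chromosome`, `start`, `end`.
#' @export
parse_locus_range <- function(x) {
  m <- regexec("^([^:]+):(\\d+)[-–](\\d+)$", x, perl = TRUE)
  parts <- regmatches(x, m)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("unparseable locus string(s): ", paste(x[bad], collapse = ", "))
  data.frame(
    chromosome = vapply(parts, `[`, character(1), 2L),
    start = as.numeric(vapply(parts, `[`, character(1), 3L)),
    end = as.numeric(vapply(parts, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
}

#' Summarise a family table
#'
#' Computes the membership count, protein-length and intron-count extrema
#' (with the member names achieving them), and per-chromosome / per-group
#' tallies.
#'
#' @param tab A family table `data.frame` as from [load_family_table()].
#' @return An object of class `family_summary`.
#' @export
summarize_family_table <- function(tab) {
  if (!is.data.frame(tab) || nrow(tab) == 0L) {
    stop("summarize_family_table: empty family table")
  }
  per_chromosome <- table(tab$chromosome)
  per_group <- table(factor(tab$group, levels = intersect(FAMILY_GROUPS, unique(tab$group))))
  out <- list(
    n_members = nrow(tab),
    max_length = c(stats::setNames(max(tab$length_aa), tab$name[which.max(tab$length_aa)])),
    min_length = c(stats::setNames(min(tab$length_aa), tab$name[which.min(tab$length_aa)])),
    max_introns = c(stats::setNames(max(tab$intron), tab$name[which.max(tab$intron)])),
    min_introns = min(tab$intron),
    per_chromosome = per_chromosome,
    per_group = per_group
  )
  stopifnot(sum(out$per_chromosome) == out$n_members,
            sum(out$per_group) == out$n_members)
  class(out) <- "family_summary"
  out
}

#' @export
print.family_summary <- function(x, ...) {
  cat("Family summary:", x$n_members, "members\n")
  cat("  longest protein :", x$max_length, "aa (", names(x$max_length), ")\n")
  cat("  shortest protein:", x$min_length, "aa (", names(x$min_length), ")\n")
  cat("  introns         :", x$min_introns, "-", x$max_introns,
      "( max in", names(x$max_introns), ")\n")
  cat("  per group       :",
      paste(names(x$per_group), as.integer(x$per_group), sep = "=", collapse = " "), "\n")
  cat("  chromosomes     :", length(x$per_chromosome), "occupied\n")
  invisible(x)
}
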
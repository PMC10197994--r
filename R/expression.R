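# Cold-stress expression quantification and response calling, plus qPCR
# relative quantification.
#
# Counts -> FPKM -> expressed-gene filter (FPKM > 1 in at least one
# sample) -> log2(x+1) -> per-gene centring/scaling -> hierarchical
# clustering for heatmap ordering -> per-timepoint fold-change calls
# against the control; Ct tables are quantified by 2^-ddCt.

TIMEPOINT_LEVELS <- c("0H", "30M", "1H", "3H", "6H", "12H", "24H", "72H")

sample_timepoint <- function(samples) sub("_r\\d+$", "", samples)

#' Read a count (or FPKM) matrix TSV
#'
#' First column `gene`, remaining columns samples labelled
#' `<timepoint>_r<replicate>`.
#'
#' @param path TSV path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene") stop("expression matrix ", path,
                                     " must start with a 'gene' column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("expression matrix ", path, " has negative values")
  m
}

#' FPKM normalisation
#'
#' `FPKM(g, s) = 1e9 * count(g, s) / (library_size(s) * length(g))`.
#'
#' @param counts Gene x sample count matrix.
#' @param lengths Named effective transcript lengths in bp.
#' @param library_sizes Named per-sample totals; defaults to column sums.
#' @return FPKM matrix with the same dimnames.
#' @export
fpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("fpkm: every gene needs a positive length")
  }
  if (any(library_sizes <= 0)) stop("fpkm: zero library size")
  sweep(sweep(counts, 2, library_sizes, "/"), 1, lengths, "/") * 1e9
}

#' Filter to expressed genes
#'
#' Keeps genes with FPKM strictly above `min_fpkm` in at least one sample.
#'
#' @param mat FPKM matrix.
#' @param min_fpkm Strict threshold (default 1).
#' @return Character vector of surviving gene ids.
#' @export
filter_expressed <- function(mat, min_fpkm = 1) {
  rownames(mat)[apply(mat, 1, function(x) any(x > min_fpkm))]
}

#' log2 transform then centre/scale per gene
#'
#' `x -> log2(x + 1)` entrywise, then each gene row is centred to mean 0
#' and scaled to standard deviation 1 across samples. Zero-variance rows
#' become all-zero with a warning.
#'
#' @param mat FPKM matrix.
#' @return Transformed matrix.
#' @export
log2_center_scale <- function(mat) {
  lg <- log2(mat + 1)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning("log2_center_scale: zero-variance gene(s) set to zero: ",
            paste(rownames(mat)[flat], collapse = ", "))
    sdv[flat] <- 1
  }
  out <- (lg - mu) / sdv
  out[flat, ] <- 0
  out
}

#' Hierarchical clustering of genes for heatmap ordering
#'
#' Average-linkage agglomeration on `1 - Pearson` correlation distances.
#'
#' @param mat Transformed matrix (genes x samples).
#' @return A list with `order` (gene ids in leaf order) and `hclust` (the
#'   dendrogram object).
#' @export
cluster_genes <- function(mat) {
  if (nrow(mat) < 2L) stop("cluster_genes: need at least 2 genes")
  cc <- suppressWarnings(stats::cor(t(mat)))
  cc[is.na(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  list(order = rownames(mat)[hc$order], hclust = hc)
}

#' Average replicates per timepoint
#'
#' @param mat Gene x sample matrix with `<timepoint>_r<rep>` sample labels.
#' @return Gene x timepoint matrix of replicate means, timepoints in
#'   time-course order.
#' @export
average_replicates <- function(mat) {
  tp <- sample_timepoint(colnames(mat))
  levels <- unique(c(intersect(TIMEPOINT_LEVELS, tp), setdiff(tp, TIMEPOINT_LEVELS)))
  out <- sapply(levels, function(t) rowMeans(mat[, tp == t, drop = FALSE]))
  rownames(out) <- rownames(mat)
  out
}

#' Call expression responses against the control timepoint
#'
#' Per gene and non-control timepoint,
#' `LFC = log2((mean FPKM_t + 1) / (mean FPKM_control + 1))` on
#' replicate-averaged values; `up` iff `LFC >= lfc_threshold`, `down` iff
#' `LFC <= -lfc_threshold`, else `flat`. The control timepoint is always
#' `flat`.
#'
#' @param mat FPKM matrix (genes x samples, replicate sample labels).
#' @param control Control timepoint label (default `"0H"`).
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @return A `data.frame`: `gene`, `timepoint`, `lfc`, `direction`.
#' @export
call_responses <- function(mat, control = "0H", lfc_threshold = 1) {
  avg <- average_replicates(mat)
  if (!control %in% colnames(avg)) {
    stop("call_responses: control timepoint ", control, " absent")
  }
  rows <- list()
  for (tp in colnames(avg)) {
    lfc <- log2((avg[, tp] + 1) / (avg[, control] + 1))
    dir <- ifelse(lfc >= lfc_threshold, "up",
                  ifelse(lfc <= -lfc_threshold, "down", "flat"))
    if (tp == control) { lfc[] <- 0; dir[] <- "flat" }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rownames(avg), timepoint = tp, lfc = unname(lfc),
      direction = unname(dir), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Per-timepoint expression distribution summaries
#'
#' Quartiles (and mean) of the expressed genes' FPKM per timepoint, the
#' numbers behind a violin-plot view of the time course.
#'
#' @param mat FPKM matrix.
#' @return A `data.frame`: `timepoint`, `q0`, `q25`, `q50`, `q75`, `q100`,
#'   `mean`.
#' @export
timepoint_distributions <- function(mat) {
  avg <- average_replicates(mat)
  out <- lapply(colnames(avg), function(tp) {
    q <- stats::quantile(avg[, tp], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(timepoint = tp, q0 = q[1], q25 = q[2], q50 = q[3],
               q75 = q[4], q100 = q[5], mean = mean(avg[, tp]))
  })
  do.call(rbind, out)
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `gene`, `timepoint`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @return A validated `data.frame`.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "timepoint", "replicate", "ct_target",
                       "ct_reference"), names(ct))
  if (length(missing)) {
    stop("Ct table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45) ||
      any(ct$ct_reference <= 0 | ct$ct_reference >= 45)) {
    stop("Ct table ", path, " has Ct values outside (0, 45)")
  }
  ct
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per gene and timepoint,
#' `ddCt = mean dCt(t) - mean dCt(control)` and the relative fold change is
#' `2^-ddCt`. The control timepoint's fold change is exactly 1.
#'
#' @param ct Ct table (`data.frame` as from [read_ct_table()]).
#' @param control Control timepoint label (default `"0H"`).
#' @return A `data.frame`: `gene`, `timepoint`, `ddct`, `fold_change`.
#' @export
delta_delta_ct <- function(ct, control = "0H") {
  ct$dct <- ct$ct_target - ct$ct_reference
  genes <- unique(ct$gene)
  no_ctrl <- genes[!genes %in% ct$gene[ct$timepoint == control]]
  if (length(no_ctrl)) {
    stop("delta_delta_ct: no control (", control, ") rows for gene(s): ",
         paste(no_ctrl, collapse = ", "))
  }
  rows <- list()
  for (g in genes) {
    sub <- ct[ct$gene == g, ]
    ctrl_mean <- mean(sub$dct[sub$timepoint == control])
    for (tp in unique(sub$timepoint)) {
      ddct <- if (tp == control) 0 else
        mean(sub$dct[sub$timepoint == tp]) - ctrl_mean
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, timepoint = tp, ddct = ddct, fold_change = 2^(-ddct),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
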
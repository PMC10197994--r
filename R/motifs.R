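# EM-based conserved-motif discovery over protein sequences.
#
# A finite mixture over fixed-width sequence windows: each window is either
# a motif site (position weight matrix, PWM) or background (0-order residue
# frequencies estimated from the input set). EM alternates posterior site
# probabilities with PWM/abundance updates; sites are called wherever the
# posterior odds against background reach a threshold, any number of times
# per sequence (ANR). Motifs are found sequentially, masking the sites of
# each motif before searching for the next, so site sets are disjoint.

MOTIF_WIDTH_GRID <- c(6, 8, 10, 15, 20, 29, 50)

encode_seqs <- function(seqs) {
  chars <- strsplit(as.character(seqs), "")
  lapply(chars, function(ch) {
    i <- match(ch, AA_ALPHABET[1:20])
    i[is.na(i)] <- 0L  # X / masked
    i
  })
}

# flat window table for one width: sequence index, start, and the nwin x w
# residue matrix (only windows free of masked residues)
window_table <- function(enc, w) {
  seq_id <- list(); start <- list(); res <- list()
  for (s in seq_along(enc)) {
    v <- enc[[s]]
    L <- length(v)
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    idx <- outer(starts, 0:(w - 1L), "+")
    res[[length(res) + 1L]] <- matrix(v[idx], nrow = length(starts))
    seq_id[[length(seq_id) + 1L]] <- rep.int(s, length(starts))
    start[[length(start) + 1L]] <- starts
  }
  if (!length(res)) return(NULL)
  res <- do.call(rbind, res)
  seq_id <- unlist(seq_id); start <- unlist(start)
  ok <- rowSums(res == 0L) == 0L
  list(seq = seq_id[ok], start = start[ok], res = res[ok, , drop = FALSE])
}

# Per-position scores for how often the 4-mer starting at each position
# recurs across the whole sequence set; conserved blocks light up even at
# 10-20% per-residue divergence because most of their 4-mers are intact
# somewhere in every carrier sequence.
kmer_repeat_scores <- function(enc, k = 4L) {
  codes <- lapply(enc, function(v) {
    L <- length(v)
    if (L < k) return(integer(0))
    code <- rep(0, L - k + 1L)
    ok <- rep(TRUE, L - k + 1L)
    for (j in seq_len(k)) {
      seg <- v[j:(L - k + j)]
      ok <- ok & seg > 0L
      code <- code * 20 + pmax(seg - 1L, 0L)
    }
    code[!ok] <- -1
    code
  })
  all_codes <- unlist(codes)
  tab <- table(all_codes[all_codes >= 0])
  counts <- stats::setNames(as.integer(tab), names(tab))
  lapply(codes, function(code) {
    s <- rep(0L, length(code))
    pos <- code >= 0
    s[pos] <- counts[as.character(code[pos])] - 1L
    s
  })
}

window_logprob <- function(res, ltheta) {
  lp <- numeric(nrow(res))
  for (j in seq_len(ncol(res))) lp <- lp + ltheta[res[, j], j]
  lp
}

em_fit <- function(wt, theta, lbg_res, max_iter = 200, tol = 1e-4,
                   gamma = 0.05) {
  w <- ncol(wt$res)
  nwin <- nrow(wt$res)
  lbg <- numeric(nwin)
  for (j in seq_len(w)) lbg <- lbg + lbg_res[wt$res[, j]]
  z <- NULL
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- window_logprob(wt$res, log(theta))
    # mixture log-likelihood at the current parameters
    hi <- pmax(lp + log(gamma), lbg + log(1 - gamma))
    loglik <- c(loglik, sum(hi + log(exp(lp + log(gamma) - hi) +
                                       exp(lbg + log(1 - gamma) - hi))))
    logit <- log(gamma / (1 - gamma)) + lp - lbg
    z <- 1 / (1 + exp(-logit))
    gamma <- min(max(mean(z), 1 / nwin), 0.3)
    new_theta <- matrix(0.1, 20, w)
    for (j in seq_len(w)) {
      new_theta[, j] <- new_theta[, j] +
        unname(tapply(z, factor(wt$res[, j], levels = 1:20), sum, default = 0))
    }
    new_theta <- sweep(new_theta, 2, colSums(new_theta), "/")
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    if (delta < tol) break
  }
  lp <- window_logprob(wt$res, log(theta))
  list(theta = theta, z = z, gamma = gamma, lp = lp, lbg = lbg,
       iterations = it, loglik = loglik)
}

# A sharp seed keeps the EM in the phase of the seeding substring: softer
# seeds let windows shifted by one or two positions reach posterior one on
# low-complexity backgrounds, and the PWM then smears across phases.
seed_theta <- function(res_row, w) {
  theta <- matrix(0.2 / 19, 20, w)
  theta[cbind(res_row, seq_len(w))] <- 0.8
  theta
}

# Re-anchor a converged motif: EM can lock onto a phase shifted by a few
# positions from the true site (especially when the width exceeds the true
# motif). Try small shifts of the called site set, re-estimate the PWM from
# the shifted windows, and keep the phase with the highest site
# log-likelihood ratio; then re-call sites under the winning PWM.
refine_phase <- function(wt, fit, idx, w, odds_threshold, shifts = -3:3) {
  key <- wt$seq * 10000000 + wt$start
  best <- NULL
  for (d in shifts) {
    tgt <- match(wt$seq[idx] * 10000000 + (wt$start[idx] + d), key)
    tgt <- tgt[!is.na(tgt)]
    if (length(tgt) < 2L) next
    theta <- matrix(0.1, 20, w)
    for (j in seq_len(w)) {
      theta[, j] <- theta[, j] +
        tabulate(wt$res[tgt, j], nbins = 20)
    }
    theta <- sweep(theta, 2, colSums(theta), "/")
    lp <- window_logprob(wt$res[tgt, , drop = FALSE], log(theta))
    lbg <- fit$lbg[tgt]
    llr <- sum(lp - lbg)
    if (is.null(best) || llr > best$llr) {
      best <- list(llr = llr, theta = theta, d = d)
    }
  }
  if (is.null(best)) return(list(fit = fit, idx = idx))
  new_fit <- fit
  new_fit$theta <- best$theta
  new_fit$lp <- window_logprob(wt$res, log(best$theta))
  new_idx <- call_sites(wt, new_fit, odds_threshold, w)
  if (length(new_idx) < 2L) return(list(fit = fit, idx = idx))
  list(fit = new_fit, idx = new_idx)
}

call_sites <- function(wt, fit, odds_threshold, w) {
  post_odds <- fit$z / pmax(1 - fit$z, 1e-12)
  cand <- which(post_odds >= odds_threshold)
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-fit$z[cand], wt$seq[cand], wt$start[cand])]
  taken <- list()
  keep <- integer(0)
  for (i in cand) {
    s <- wt$seq[i]; st <- wt$start[i]
    prev <- taken[[as.character(s)]]
    if (!is.null(prev) && any(abs(prev - st) < w)) next
    taken[[as.character(s)]] <- c(prev, st)
    keep <- c(keep, i)
  }
  sort(keep)
}

#' Discover conserved motifs by expectation-maximisation
#'
#' Sequential EM motif discovery with the survey's parameterisation: up to
#' `max_motifs` motifs of width `w_min`-`w_max`, any number of occurrences
#' per sequence. For each motif, EM runs at every candidate width from a
#' small set of seeded substring starts; the width maximising a
#' penalised log-likelihood-ratio criterion (`LLR - 19 w`) is kept, its
#' sites are called at posterior odds `odds_threshold` and masked, and the
#' search repeats. Discovery stops early when no further motif reaches the
#' odds threshold in at least two sequences.
#'
#' @param seqs Named [Biostrings::AAStringSet] (or character vector).
#' @param max_motifs Maximum number of motifs (default 10).
#' @param w_min,w_max Width bounds in residues (defaults 6 and 50).
#' @param seed Integer seed for substring seeding.
#' @param odds_threshold Posterior odds against background required to call
#'   a site (default 10).
#' @param n_starts Seeded substring starts per width (default 8).
#' @param max_iter,tol EM convergence controls (PWM sup-change below `tol`,
#'   default `1e-4`, or `max_iter` iterations, default 200).
#' @return A list of motifs; each motif is a list with `motif_id`, `width`,
#'   `pwm` (20 x width, columns sum to one), `sites` (`data.frame`:
#'   `protein_id`, `start`, `end`, `score`), and `llr`.
#' @export
discover_motifs <- function(seqs, max_motifs = 10, w_min = 6, w_max = 50,
                            seed = 1, odds_threshold = 10, n_starts = 8,
                            max_iter = 200, tol = 1e-4) {
  if (max_motifs <= 0) return(list())
  seq_chars <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seq_chars))
  if (length(seq_chars) < 2L) stop("discover_motifs: need at least 2 sequences")
  if (all(nchar(seq_chars) < w_min)) {
    stop("discover_motifs: all sequences shorter than the minimum width")
  }
  widths <- MOTIF_WIDTH_GRID[MOTIF_WIDTH_GRID >= w_min & MOTIF_WIDTH_GRID <= w_max]
  if (!length(widths)) widths <- w_min

  enc <- encode_seqs(seq_chars)
  all_res <- unlist(enc)
  bg <- tabulate(all_res[all_res > 0L], nbins = 20) + 1
  bg <- bg / sum(bg)
  lbg_res <- log(bg)

  motifs <- list()
  for (m in seq_len(max_motifs)) {
    rep_scores <- kmer_repeat_scores(enc)
    best <- NULL
    for (w in widths) {
      wt <- window_table(enc, w)
      if (is.null(wt) || nrow(wt$res) < 2L) next
      set.seed(seed + 1000L * m + w)
      # seeds: windows dense in cross-sequence repeated 4-mers (conserved
      # blocks) and the most background-improbable windows, both taken
      # greedily without overlap, plus random draws
      lbg_w <- numeric(nrow(wt$res))
      for (j in seq_len(w)) lbg_w <- lbg_w + lbg_res[wt$res[, j]]
      kscore <- vapply(seq_along(wt$seq), function(i) {
        s <- rep_scores[[wt$seq[i]]]
        j <- wt$start[i]:min(wt$start[i] + w - 4L, length(s))
        sum(s[j])
      }, numeric(1))
      greedy_top <- function(ord, n_top) {
        sel <- integer(0)
        for (i in ord) {
          if (length(sel) >= n_top) break
          if (any(wt$seq[sel] == wt$seq[i] &
                  abs(wt$start[sel] - wt$start[i]) < w)) next
          sel <- c(sel, i)
        }
        sel
      }
      n_top <- ceiling(min(n_starts, nrow(wt$res)) / 2)
      starts <- unique(c(greedy_top(order(-kscore), n_top),
                         greedy_top(order(lbg_w), ceiling(n_top / 2)),
                         sample.int(nrow(wt$res),
                                    min(n_starts, nrow(wt$res)))))
      # short EM per seed; full EM from the two most promising seeds (the
      # short-run ranking is not always the converged ranking)
      # penalised criterion: LLR minus a BIC-style cost of 19 free
      # parameters per column at the realised site count
      crit_of <- function(fit, idx) {
        if (length(idx) < 2L) return(-Inf)
        sum(fit$lp[idx] - fit$lbg[idx]) - 0.5 * 19 * w * log(length(idx))
      }
      seed_scores <- vapply(starts, function(i) {
        f <- em_fit(wt, seed_theta(wt$res[i, ], w), lbg_res, max_iter = 5)
        crit_of(f, call_sites(wt, f, odds_threshold, w))
      }, numeric(1))
      top <- starts[order(-seed_scores)][seq_len(min(2L, length(starts)))]
      for (i0 in top) {
        if (!is.finite(seed_scores[match(i0, starts)])) next
        fit <- em_fit(wt, seed_theta(wt$res[i0, ], w), lbg_res,
                      max_iter = max_iter, tol = tol)
        idx <- call_sites(wt, fit, odds_threshold, w)
        if (length(idx) < 2L) next
        ref <- refine_phase(wt, fit, idx, w, odds_threshold)
        crit <- crit_of(ref$fit, ref$idx)
        if (!is.finite(crit)) next
        if (is.null(best) || crit > best$crit) {
          best <- list(crit = crit,
                       llr = sum(ref$fit$lp[ref$idx] - ref$fit$lbg[ref$idx]),
                       w = w, wt = wt, fit = ref$fit, idx = ref$idx)
        }
      }
    }
    if (is.null(best)) break
    sites <- data.frame(
      protein_id = ids[best$wt$seq[best$idx]],
      start = best$wt$start[best$idx],
      end = best$wt$start[best$idx] + best$w - 1L,
      score = best$fit$lp[best$idx] - best$fit$lbg[best$idx],
      stringsAsFactors = FALSE
    )
    if (length(unique(sites$protein_id)) < 2L) break
    motifs[[length(motifs) + 1L]] <- list(
      motif_id = length(motifs) + 1L,
      width = best$w,
      pwm = best$fit$theta,
      sites = sites,
      llr = best$llr
    )
    # mask called sites before searching for the next motif
    for (k in seq_len(nrow(sites))) {
      s <- match(sites$protein_id[k], ids)
      enc[[s]][sites$start[k]:sites$end[k]] <- 0L
    }
  }
  motifs
}

#' Motif occurrence matrix
#'
#' Counts the called sites of each motif per protein.
#'
#' @param motifs Motif list from [discover_motifs()].
#' @param seqs The sequence set the motifs were discovered on (supplies the
#'   full protein id universe, including zero-occurrence rows).
#' @return Integer matrix, proteins x motifs.
#' @export
occurrence_matrix <- function(motifs, seqs) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  mat <- matrix(0L, length(ids), length(motifs),
                dimnames = list(ids, vapply(motifs, function(m)
                  paste0("motif", m$motif_id), character(1))))
  for (k in seq_along(motifs)) {
    tab <- table(motifs[[k]]$sites$protein_id)
    mat[names(tab), k] <- as.integer(tab)
  }
  mat
}

#' Motifs present in every protein
#'
#' @param mat Occurrence matrix from [occurrence_matrix()].
#' @return Character vector of motif ids with at least one site in every
#'   row.
#' @export
shared_motifs <- function(mat) {
  if (!length(mat)) stop("shared_motifs: empty occurrence matrix")
  colnames(mat)[apply(mat, 2, min) >= 1L]
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs Motif list from [discover_motifs()].
#' @param path Output path.
#' @param bg Optional named background frequencies (20 residues).
#' @return `path`, invisibly.
#' @export
write_meme_txt <- function(motifs, path, bg = NULL) {
  lines <- c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "")
  if (!is.null(bg)) {
    lines <- c(lines, "Background letter frequencies",
               paste(names(bg), sprintf("%.5f", bg), collapse = " "), "")
  }
  # PWM rows follow MEME's A..Y alphabet ordering
  ord <- match(sort(AA_ALPHABET[1:20]), AA_ALPHABET[1:20])
  for (m in motifs) {
    nsites <- nrow(m$sites)
    lines <- c(lines, sprintf("MOTIF motif%d", m$motif_id),
               sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                       m$width, nsites))
    pwm <- m$pwm[ord, , drop = FALSE]
    for (j in seq_len(m$width)) {
      lines <- c(lines, paste(sprintf("%.6f", pwm[, j]), collapse = " "))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate sequences with planted motifs
#'
#' Builds a seeded set of random protein sequences carrying mutated copies
#' of planted consensus motifs: `n_universal` motifs occur in every
#' sequence and `n_partial` motifs each occur in a random
#' `partial_fraction` of sequences. Placement is non-overlapping with
#' random spacing; the manifest records every planted site.
#'
#' @param n_seqs Number of sequences (default 50).
#' @param seq_length Approximate sequence length before insertions.
#' @param widths Widths of the universal motifs (recycled as needed).
#' @param n_universal,n_partial Motif counts.
#' @param partial_fraction Fraction of sequences carrying each partial
#'   motif.
#' @param mutation_rate Per-residue substitution rate applied to each
#'   planted copy (default 0.1).
#' @param seed Integer seed.
#' @return A list with `seqs` ([Biostrings::AAStringSet]), `consensus`
#'   (character vector per motif) and `sites` (`data.frame`: `seq_id`,
#'   `motif`, `start`, `end`).
#' @export
generate_motif_sequences <- function(n_seqs = 50, seq_length = 300,
                                     widths = c(10, 15, 20),
                                     n_universal = 3, n_partial = 0,
                                     partial_fraction = 0.5,
                                     mutation_rate = 0.1, seed = 1) {
  set.seed(seed)
  n_motifs <- n_universal + n_partial
  w <- rep_len(widths, n_motifs)
  consensus <- vapply(w, function(k) paste(random_residues(k), collapse = ""),
                      character(1))
  names(consensus) <- paste0("planted", seq_len(n_motifs))
  carrier <- matrix(TRUE, n_seqs, n_motifs)
  if (n_partial > 0) {
    for (k in (n_universal + 1):n_motifs) {
      carrier[, k] <- stats::runif(n_seqs) < partial_fraction
      if (!any(carrier[, k])) carrier[sample.int(n_seqs, 1L), k] <- TRUE
    }
  }
  ids <- sprintf("mseq%03d", seq_len(n_seqs))
  seqs <- character(n_seqs)
  sites <- list()
  for (s in seq_len(n_seqs)) {
    present <- which(carrier[s, ])
    order_k <- sample(present)
    res <- random_residues(sample(20:40, 1L))
    for (k in order_k) {
      block <- mutate_residues(strsplit(consensus[[k]], "")[[1]], mutation_rate)
      sites[[length(sites) + 1L]] <- data.frame(
        seq_id = ids[s], motif = names(consensus)[k],
        start = length(res) + 1L, end = length(res) + w[k],
        stringsAsFactors = FALSE
      )
      res <- c(res, block, random_residues(sample(20:60, 1L)))
    }
    pad <- seq_length - length(res)
    if (pad > 0) res <- c(res, random_residues(pad))
    seqs[s] <- paste(res, collapse = "")
  }
  list(seqs = Biostrings::AAStringSet(stats::setNames(seqs, ids)),
       consensus = consensus,
       sites = do.call(rbind, sites))
}
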
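# Hexamer splicing-enhancer density in the DNA encoding codons 2-34 from
# each exon edge (the same residues used by the distance-correlation
# analysis), compared between exon classes and splicing statuses, plus the
# flanking-intron length comparison.

#' Extract junction-proximal DNA windows
#'
#' For each retained exon (see [filter_for_correlation()]) returns the DNA
#' of the codons at distance `d_min`..`d_max` from each edge, with codons
#' of short exons assigned to the nearer edge only (midpoint codons to
#' neither). Start-side and end-side windows are kept separate: no hexamer
#' window ever spans the gap between them or crosses into the junction
#' codon (d = 1) or beyond `d_max`.
#'
#' @param fexons Retained-exon table (`$exons` of [filter_for_correlation()]).
#' @param d_min,d_max Codon-distance window (defaults 2 and 34).
#' @return Data frame: `transcript_id`, `exon_id`, `rank`, `side`, `seq`,
#'   `width`.
#' @export
junction_windows <- function(fexons, d_min = 2L, d_max = 34L) {
  rows <- list()
  if (nrow(fexons)) {
    m <- fexons$n_codons
    hi <- pmin(d_max, m %/% 2L)  # farthest distance assigned to each side
    has <- hi >= d_min
    if (any(has)) {
      f <- fexons[has, , drop = FALSE]
      h <- hi[has]
      mm <- f$n_codons
      start_seq <- substr(f$codons, 3L * (d_min - 1L) + 1L, 3L * h)
      end_seq <- substr(f$codons, 3L * (mm - h) + 1L, 3L * (mm - d_min + 1L))
      rows <- list(
        data.frame(transcript_id = f$transcript_id, exon_id = f$exon_id,
                   rank = f$rank, side = "start", seq = start_seq,
                   width = nchar(start_seq), stringsAsFactors = FALSE),
        data.frame(transcript_id = f$transcript_id, exon_id = f$exon_id,
                   rank = f$rank, side = "end", seq = end_seq,
                   width = nchar(end_seq), stringsAsFactors = FALSE))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), exon_id = character(0),
               rank = integer(0), side = character(0), seq = character(0),
               width = integer(0))
  rownames(out) <- NULL
  out
}

#' Count hexamer windows and motif matches in DNA sequences
#'
#' Slides a 6-nt window with stride 1 over each sequence; overlapping
#' matches are each counted. Windows containing an uncertain base (`N`)
#' are skipped and excluded from the window count. Sequences shorter than
#' 6 nt contribute no windows.
#'
#' @param seqs Character vector of DNA sequences.
#' @param motifs `jx_motif_set` (or character vector of hexamers); may be
#'   empty, in which case all match counts are 0.
#' @return Data frame: `n_windows`, `n_matches`, one row per sequence.
#' @export
scan_windows <- function(seqs, motifs) {
  seqs <- toupper(as.character(seqs))
  w <- nchar(seqs)
  nw <- pmax(w - 5L, 0L)
  # exclude windows containing N
  has_n <- grepl("N", seqs, fixed = TRUE)
  for (i in which(has_n)) {
    if (nw[i] == 0L) next
    npos <- gregexpr("N", seqs[i], fixed = TRUE)[[1L]]
    excluded <- logical(nw[i])
    for (p in npos) {
      lo <- max(1L, p - 5L)
      hi <- min(nw[i], p)
      if (lo <= hi) excluded[lo:hi] <- TRUE
    }
    nw[i] <- nw[i] - sum(excluded)
  }
  n_matches <- integer(length(seqs))
  motifs <- as.character(motifs)
  scanable <- w >= 6L
  if (length(motifs) && any(scanable)) {
    pd <- Biostrings::PDict(motifs)
    subj <- Biostrings::DNAStringSet(seqs[scanable])
    cnt <- Biostrings::vcountPDict(pd, subj)
    n_matches[scanable] <- as.integer(colSums(cnt))
  }
  data.frame(n_windows = nw, n_matches = n_matches)
}

#' Hexamer scan of a single window
#'
#' @param dna_window DNA string.
#' @param motif_set Motif set (see [read_motifs()]).
#' @return Named numeric vector `c(n_windows, n_matches)`.
#' @export
scan_exon <- function(dna_window, motif_set) {
  r <- scan_windows(dna_window, motif_set)
  c(n_windows = r$n_windows[1L], n_matches = r$n_matches[1L])
}

#' ESE density per exon class (and splicing status)
#'
#' Pools hexamer windows and motif matches over all junction-proximal
#' windows of each stratum and reports the percentage of windows matching
#' a motif, plus the 2x2 chi-square (match vs non-match windows, df = 1,
#' no continuity correction) comparing structure- and disorder-encoding
#' exons within each splicing-status level.
#'
#' @param windows Window table from [junction_windows()].
#' @param classes Classification from [classify_exons()] (joined on
#'   transcript + exon id).
#' @param motifs `jx_motif_set`.
#' @param statuses Optional splicing-status table from
#'   [classify_splicing_status()] (joined on exon id); when given, strata
#'   are additionally split by constituent/alternative.
#' @return List of class `jx_density`: `density` (stratum table with
#'   `n_windows`, `n_matches`, `density_pct`) and `tests` (chi-square
#'   structured-vs-disordered rows).
#' @export
ese_density <- function(windows, classes, motifs, statuses = NULL) {
  if (!nrow(windows)) stop("no windows to scan")
  key <- paste(windows$transcript_id, windows$exon_id)
  ckey <- paste(classes$transcript_id, classes$exon_id)
  category <- classes$category[match(key, ckey)]
  category[is.na(category)] <- "other"
  status <- rep("all", nrow(windows))
  if (!is.null(statuses)) {
    status <- statuses$status[match(windows$exon_id, statuses$exon_id)]
    status[is.na(status)] <- "all"
  }
  sc <- scan_windows(windows$seq, motifs)

  level_status <- if (is.null(statuses)) "all" else
    c("all", intersect(c("constituent", "alternative"), unique(status)))
  dens_rows <- list()
  test_rows <- list()
  for (st in level_status) {
    sel_st <- if (st == "all") rep(TRUE, nrow(windows)) else status == st
    for (cl in c("all", "structured", "disordered", "other")) {
      sel <- sel_st & (cl == "all" | category == cl)
      if (!any(sel)) next
      nw <- sum(sc$n_windows[sel])
      nm <- sum(sc$n_matches[sel])
      dens_rows[[length(dens_rows) + 1L]] <- data.frame(
        motif_set = attr(motifs, "name") %||% "motifs",
        status = st, category = cl, n_windows = nw, n_matches = nm,
        density_pct = if (nw > 0) 100 * nm / nw else NA_real_,
        stringsAsFactors = FALSE)
    }
    s_sel <- sel_st & category == "structured"
    d_sel <- sel_st & category == "disordered"
    ws <- sum(sc$n_windows[s_sel]); ms <- sum(sc$n_matches[s_sel])
    wd <- sum(sc$n_windows[d_sel]); md <- sum(sc$n_matches[d_sel])
    if (ws > 0 && wd > 0) {
      mat <- matrix(c(ms, ws - ms, md, wd - md), nrow = 2, byrow = TRUE,
                    dimnames = list(c("structured", "disordered"),
                                    c("match", "no_match")))
      ht <- suppressWarnings(stats::chisq.test(mat, correct = FALSE))
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        motif_set = attr(motifs, "name") %||% "motifs", status = st,
        density_structured_pct = 100 * ms / ws,
        density_disordered_pct = 100 * md / wd,
        statistic = unname(ht$statistic), df = 1L,
        p_value = unname(ht$p.value), stringsAsFactors = FALSE)
    }
  }
  structure(list(density = do.call(rbind, dens_rows),
                 tests = if (length(test_rows)) do.call(rbind, test_rows) else NULL),
            class = "jx_density")
}

#' @export
print.jx_density <- function(x, ...) {
  cat("<jx_density>\n")
  print(x$density, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("structured vs disordered:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flanking-intron length comparison between exon classes
#'
#' Computes each internal exon's mean flanking-intron length (the gap in
#' genomic coordinates between consecutive exons of the transcript) and
#' compares structure- vs disorder-encoding exons with a Welch t-test
#' (two-sided, Welch-Satterthwaite df). The reported t statistic is
#' structured minus disordered.
#'
#' @param txs A `jx_transcript_set`.
#' @param classes Classification from [classify_exons()].
#' @return List of class `jx_intron_test`: `statistic`, `df`, `p_value`,
#'   `means` (per class), `n` (per class), `data` (per-exon table).
#' @export
flanking_intron_comparison <- function(txs, classes) {
  rows <- list()
  for (tx in txs) {
    ex <- tx$exons
    n <- nrow(ex)
    if (n < 3L) next
    introns <- if (tx$strand == "+") {
      ex$genomic_start[-1L] - ex$genomic_end[-n] - 1L
    } else {
      ex$genomic_start[-n] - ex$genomic_end[-1L] - 1L
    }
    for (r in 2L:(n - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id, exon_id = ex$exon_id[r],
        rank = r, mean_flanking_intron = mean(introns[c(r - 1L, r)]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no internal exons with two flanking introns")
  df <- do.call(rbind, rows)
  key <- paste(df$transcript_id, df$exon_id)
  ckey <- paste(classes$transcript_id, classes$exon_id)
  df$category <- classes$category[match(key, ckey)]
  df$category[is.na(df$category)] <- "other"
  xs <- df$mean_flanking_intron[df$category == "structured"]
  xd <- df$mean_flanking_intron[df$category == "disordered"]
  if (length(xs) < 2L || length(xd) < 2L) {
    stop("need at least two structured and two disordered internal exons")
  }
  ht <- stats::t.test(xs, xd, var.equal = FALSE)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value),
         means = c(structured = mean(xs), disordered = mean(xd)),
         n = c(structured = length(xs), disordered = length(xd)),
         data = df),
    class = "jx_intron_test")
}

#' @export
print.jx_intron_test <- function(x, ...) {
  cat(sprintf("<jx_intron_test> structured %.1f nt (n=%d) vs disordered %.1f nt (n=%d)\n",
              x$means["structured"], x$n["structured"],
              x$means["disordered"], x$n["disordered"]))
  cat(sprintf("  Welch t = %.4g, df = %.1f, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
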
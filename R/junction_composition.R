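# Amino-acid (and nucleotide) composition at splice junctions: last-codon
# composition per stratum, fold changes against the proteome background,
# and chi-square enrichment statistics over the disorder-promoting half of
# the amino-acid alphabet.

#' Build a composition table from residues or counts
#'
#' @param x Character vector of 1-letter amino-acid codes (letters outside
#'   the 20 standard ones, e.g. `X` or `*`, are dropped), or a named numeric
#'   vector of counts.
#' @param label Stratum label (e.g. `"junction:disordered:phase2"`).
#' @param alphabet Letters the table is defined over (default: the 20 amino
#'   acids in disorder-propensity order).
#' @return List of class `jx_composition`: `label`, `counts`, `freqs`,
#'   `total`.
#' @export
composition_table <- function(x, label = "composition", alphabet = AA_ORDER) {
  if (is.numeric(x)) {
    counts <- stats::setNames(numeric(length(alphabet)), alphabet)
    x <- x[names(x) %in% alphabet]
    counts[names(x)] <- x
  } else {
    x <- x[x %in% alphabet]
    counts <- table(factor(x, levels = alphabet))
    counts <- stats::setNames(as.numeric(counts), alphabet)
  }
  total <- sum(counts)
  freqs <- if (total > 0) counts / total else counts * 0
  structure(list(label = label, counts = counts, freqs = freqs, total = total),
            class = "jx_composition")
}

#' @export
print.jx_composition <- function(x, ...) {
  cat(sprintf("<jx_composition> %s: %d residues\n", x$label, round(x$total)))
  print(round(x$freqs, 4))
  invisible(x)
}

#' Background amino-acid composition of a proteome
#'
#' Counts every residue of every protein sequence in scope; non-standard
#' letters are excluded. When comparing taxonomic groups, recompute the
#' background from that group's genomes only by subsetting `proteins`.
#'
#' @param proteins A `jx_transcript_set` (protein sequences are taken from
#'   it) or a character vector of protein sequences.
#' @param label Table label.
#' @return `jx_composition`.
#' @export
background_composition <- function(proteins, label = "background:all") {
  if (inherits(proteins, "jx_transcript_set")) {
    proteins <- vapply(proteins, `[[`, "", "protein")
  }
  proteins <- proteins[nzchar(proteins)]
  if (!length(proteins)) stop("empty protein scope for background composition")
  aa <- Biostrings::AAStringSet(proteins)
  counts <- colSums(Biostrings::letterFrequency(aa, letters = AA_ORDER))
  composition_table(counts, label = label)
}

#' Junction amino-acid composition, stratified
#'
#' Tabulates the amino acids encoded by each exon's last codon (split
#' codons attributed to the upstream exon, counted once), optionally
#' stratified by exon class, end phase, or both. Codons translating to `X`
#' are excluded. Strata with zero junctions are flagged empty.
#'
#' @param jr Junction-residue table from [junction_residues()].
#' @param by `"all"`, `"phase"`, `"class"` or `"class_phase"`.
#' @param classes Optional exon classification from [classify_exons()]
#'   (required for class strata); joined on `transcript_id` + `exon_id`.
#' @return Named list of `jx_composition` tables, one per stratum.
#' @export
junction_composition <- function(jr, by = c("all", "phase", "class", "class_phase"),
                                 classes = NULL) {
  by <- match.arg(by)
  if (by %in% c("class", "class_phase")) {
    if (is.null(classes)) stop("`classes` is required for class strata")
    key <- paste(jr$transcript_id, jr$exon_id)
    ckey <- paste(classes$transcript_id, classes$exon_id)
    jr$category <- classes$category[match(key, ckey)]
    jr$category[is.na(jr$category)] <- "other"
  }
  strata <- switch(by,
    all = rep("all", nrow(jr)),
    phase = paste0("phase", jr$end_phase),
    class = jr$category,
    class_phase = paste0(jr$category, ":phase", jr$end_phase))
  out <- lapply(split(jr$amino_acid, strata), function(aa) aa)
  tabs <- lapply(names(out), function(s) {
    composition_table(out[[s]], label = paste0("junction:", s))
  })
  names(tabs) <- names(out)
  tabs
}

#' Nucleotide composition at splice junctions
#'
#' Counts the last two exonic nucleotides before each 5' splice site
#' (positions -2, -1) and the first nucleotide after the 3' splice site
#' (position +1), per exon class. Under the canonical splice-site
#' consensus these are biased towards A, G and G respectively.
#'
#' @param txs A `jx_transcript_set`.
#' @param classes Optional classification from [classify_exons()]; when
#'   given, counts are additionally stratified by exon category.
#' @return Data frame: `stratum`, `position` (-2, -1, +1), `nucleotide`,
#'   `count`, `freq` (within stratum x position; `N` excluded).
#' @export
junction_nucleotide_composition <- function(txs, classes = NULL) {
  jr <- junction_residues(txs)
  if (!nrow(jr)) stop("no junctions in transcript set")
  cds <- vapply(txs, `[[`, "", "cds")[jr$transcript_id]
  cend <- integer(nrow(jr))
  for (k in seq_len(nrow(jr))) {
    tx <- txs[[jr$transcript_id[k]]]
    cend[k] <- tx$exons$coding_end_offset[match(jr$rank[k], tx$exons$rank)]
  }
  nt <- data.frame(
    m2 = substring(cds, cend - 1L, cend - 1L),
    m1 = substring(cds, cend, cend),
    p1 = substring(cds, cend + 1L, cend + 1L),
    stringsAsFactors = FALSE)
  strat <- rep("all", nrow(jr))
  if (!is.null(classes)) {
    key <- paste(jr$transcript_id, jr$exon_id)
    ckey <- paste(classes$transcript_id, classes$exon_id)
    strat <- classes$category[match(key, ckey)]
    strat[is.na(strat)] <- "other"
  }
  posmap <- c("-2" = "m2", "-1" = "m1", "+1" = "p1")
  rows <- list()
  for (s in unique(strat)) {
    sel <- strat == s
    for (pn in names(posmap)) {
      v <- nt[[posmap[[pn]]]][sel]
      v <- v[v %in% c("A", "C", "G", "T")]
      tab <- table(factor(v, levels = c("A", "C", "G", "T")))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, position = pn,
        nucleotide = names(tab), count = as.integer(tab),
        freq = as.numeric(tab) / max(sum(tab), 1L), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fold change of junction vs background composition
#'
#' For each amino acid, the ratio of its frequency among last-codon
#' residues to its background frequency. Amino acids absent from junctions
#' get fold 0; a zero background frequency with nonzero junction usage is
#' an error (the ratio would be infinite).
#'
#' @param junction_tab,background_tab `jx_composition` tables.
#' @return Data frame (class `jx_fold`): `amino_acid` (in disorder-propensity
#'   order), `junction_freq`, `background_freq`, `fold`.
#' @export
fold_change <- function(junction_tab, background_tab) {
  if (junction_tab$total == 0) stop("empty junction composition table")
  if (background_tab$total == 0) stop("empty background composition table")
  jf <- junction_tab$freqs
  bf <- background_tab$freqs
  bad <- bf == 0 & jf > 0
  if (any(bad)) {
    stop("background frequency is zero for amino acid(s) present at junctions: ",
         paste(names(jf)[bad], collapse = ", "))
  }
  fold <- ifelse(jf == 0, 0, jf / bf)
  df <- data.frame(amino_acid = names(jf), junction_freq = as.numeric(jf),
                   background_freq = as.numeric(bf), fold = as.numeric(fold),
                   stringsAsFactors = FALSE)
  class(df) <- c("jx_fold", "data.frame")
  df
}

#' Amino acids enriched at junctions
#'
#' @param fold A `jx_fold` table from [fold_change()].
#' @param threshold Enrichment is fold change strictly greater than this
#'   (default 1).
#' @return Character vector of enriched amino acids.
#' @export
enriched_amino_acids <- function(fold, threshold = 1) {
  fold$amino_acid[fold$fold > threshold]
}

# shared 2x2 chi-square machinery: counts in/out of a set for two samples.
# Pearson chi-square on raw counts, df = 1, no continuity correction.
.set_enrichment <- function(counts1, counts2, set, labels) {
  in1 <- sum(counts1[set]); out1 <- sum(counts1) - in1
  in2 <- sum(counts2[set]); out2 <- sum(counts2) - in2
  mat <- matrix(c(in1, out1, in2, out2), nrow = 2, byrow = TRUE,
                dimnames = list(labels, c("in_set", "out_set")))
  ht <- suppressWarnings(stats::chisq.test(mat, correct = FALSE))
  low_expected <- any(ht$expected < 5)
  if (low_expected) {
    warning("chi-square expected cell count below 5; statistic may be unreliable")
  }
  structure(
    list(set = set,
         pct = stats::setNames(100 * c(in1 / (in1 + out1), in2 / (in2 + out2)),
                               labels),
         statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value), table = mat,
         low_expected = low_expected),
    class = "jx_enrichment")
}

#' @export
print.jx_enrichment <- function(x, ...) {
  cat(sprintf("<jx_enrichment> set of %d amino acids {%s}\n",
              length(x$set), paste(x$set, collapse = "")))
  cat(sprintf("  %s: %.1f%%  vs  %s: %.1f%%\n",
              names(x$pct)[1], x$pct[1], names(x$pct)[2], x$pct[2]))
  cat(sprintf("  chi-square = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Disorder-set enrichment of junction composition
#'
#' Splits the 20 amino acids into the ten most and ten least
#' disorder-promoting (TOP-IDP scale by default) and compares the fraction
#' falling in the disorder-promoting half between junction residues and
#' the background, with a 2x2 chi-square on raw counts (df = 1, no
#' continuity correction). A warning is attached when any expected cell
#' count is below 5.
#'
#' @param junction_tab,background_tab `jx_composition` tables.
#' @param scale Disorder-propensity scale (default [top_idp_scale()]);
#'   other published orderings can be substituted.
#' @return `jx_enrichment`: percentages in the top-10 set for both samples,
#'   chi-square statistic, df and p-value.
#' @export
disorder_set_enrichment <- function(junction_tab, background_tab,
                                    scale = top_idp_scale()) {
  sets <- disorder_sets(scale)
  .set_enrichment(junction_tab$counts, background_tab$counts, sets$top10,
                  labels = c("junction", "background"))
}

#' Enriched-set usage compared between exon classes
#'
#' Given the set of amino acids enriched at junctions across all exons
#' (fold change above 1 by default; see [enriched_amino_acids()]),
#' compares the fraction of last-codon residues falling in that set
#' between structure-encoding and disorder-encoding exons (2x2 chi-square
#' on raw counts, df = 1, no continuity correction).
#'
#' @param structured_tab,disordered_tab `jx_composition` tables of junction
#'   residues in the two exon classes.
#' @param enriched_set Character vector of enriched amino acids.
#' @return `jx_enrichment`.
#' @export
enriched_set_comparison <- function(structured_tab, disordered_tab,
                                    enriched_set) {
  .set_enrichment(structured_tab$counts, disordered_tab$counts, enriched_set,
                  labels = c("structured", "disordered"))
}
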
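# Phase annotation and exon -> residue mapping, including attribution of
# codons split across a junction.
#
# The end phase of an exon is the cumulative number of coding nucleotides
# from the translation start to the exon's 3' end, modulo 3; the start phase
# of exon k+1 equals the end phase of exon k, and the first coding exon has
# start phase 0. A phase 1 or 2 junction splits a codon across the two
# flanking exons; that codon's amino acid is attributed to the junction of
# the upstream exon (it is the "last codon" of that exon).

#' Compute start/end phases and residue spans for a transcript's exons
#'
#' @param tx A `jx_transcript`.
#' @return Data frame (class `jx_phases`) with one row per coding exon:
#'   `exon_id`, `rank`, `coding_len`, `start_phase`, `end_phase`,
#'   `res_start`/`res_end` (0-based half-open span of residues any of whose
#'   codon nucleotides lie in the exon; the terminal stop codon is never a
#'   residue), `first_partial`/`last_partial` (edge residue only partially
#'   encoded here), and `owns_split_codon_at_end`.
#' @export
compute_phases <- function(tx) {
  ex <- tx$exons
  cstart <- ex$coding_start_offset
  cend <- ex$coding_end_offset
  n_res <- nchar(tx$protein)
  nr <- nrow(ex)
  df <- fast_df(
    transcript_id = rep(tx$transcript_id, nr),
    exon_id = ex$exon_id,
    rank = ex$rank,
    coding_len = cend - cstart,
    start_phase = cstart %% 3L,
    end_phase = cend %% 3L,
    res_start = cstart %/% 3L,
    res_end = pmin(as.integer(ceiling(cend / 3)), n_res),
    first_partial = cstart %% 3L != 0L,
    last_partial = cend %% 3L != 0L)
  df$res_end <- pmax(df$res_end, df$res_start)  # guard: stop-only tail exon
  df$owns_split_codon_at_end <- df$end_phase != 0L & df$rank < nrow(ex)
  class(df) <- c("jx_phases", "data.frame")
  df
}

#' Residue interval and edge flags for one phased exon
#'
#' @param phases Result of [compute_phases()].
#' @param rank Exon rank within the transcript.
#' @return List with `res_start`, `res_end` (0-based half-open) and
#'   `first_partial`/`last_partial` flags.
#' @export
map_exon_to_residues <- function(phases, rank) {
  i <- match(rank, phases$rank)
  if (is.na(i)) stop("no exon with rank ", rank)
  list(res_start = phases$res_start[i], res_end = phases$res_end[i],
       first_partial = phases$first_partial[i],
       last_partial = phases$last_partial[i])
}

#' The amino acid encoded by an exon's last codon
#'
#' For an end phase of 0 the codon is the exon's final three coding
#' nucleotides; for phase 1 it is the last nucleotide plus the next exon's
#' first two; for phase 2 the last two plus the next exon's first one. The
#' final coding exon has no 3' splice junction and is an error.
#'
#' @param tx A `jx_transcript`.
#' @param rank Exon rank (must not be the final coding exon).
#' @return List (class `jx_junction_residue`): `transcript_id`, `rank`,
#'   `end_phase`, `codon`, `amino_acid` (`X` if the codon has uncertain
#'   bases), `split`, `residue_index` (0-based position in the protein).
#' @export
last_codon_residue <- function(tx, rank) {
  ex <- tx$exons
  i <- match(rank, ex$rank)
  if (is.na(i)) stop("no exon with rank ", rank)
  if (i == nrow(ex)) {
    stop(sprintf("exon rank %d is the final coding exon of %s: no 3' junction",
                 rank, tx$transcript_id))
  }
  cend <- ex$coding_end_offset[i]
  e <- cend %% 3L
  ci <- if (e == 0L) cend %/% 3L - 1L else cend %/% 3L
  codon <- substr(tx$cds, 3L * ci + 1L, 3L * ci + 3L)
  structure(
    list(transcript_id = tx$transcript_id, rank = rank, end_phase = e,
         codon = codon, amino_acid = translate_codons(codon),
         split = e != 0L, residue_index = ci),
    class = "jx_junction_residue")
}

#' Junction residues for every 3' splice junction in a transcript set
#'
#' Applies [last_codon_residue()] to every exon except each transcript's
#' final coding exon (whose 3' end is the stop, not a junction).
#'
#' @param txs A `jx_transcript_set`.
#' @return Data frame: `transcript_id`, `gene_id`, `exon_id`, `rank`,
#'   `end_phase`, `codon`, `amino_acid`, `split`, `residue_index`.
#' @export
junction_residues <- function(txs) {
  out <- vector("list", length(txs))
  for (k in seq_along(txs)) {
    tx <- txs[[k]]
    n <- nrow(tx$exons)
    if (n < 2L) next
    cend <- tx$exons$coding_end_offset[-n]
    e <- cend %% 3L
    ci <- ifelse(e == 0L, cend %/% 3L - 1L, cend %/% 3L)
    codon <- substring(tx$cds, 3L * ci + 1L, 3L * ci + 3L)
    out[[k]] <- data.frame(
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      exon_id = tx$exons$exon_id[-n], rank = tx$exons$rank[-n],
      end_phase = e, codon = codon, amino_acid = translate_codons(codon),
      split = e != 0L, residue_index = ci, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      exon_id = character(0), rank = integer(0),
                      end_phase = integer(0), codon = character(0),
                      amino_acid = character(0), split = logical(0),
                      residue_index = integer(0)))
  }
  do.call(rbind, out)
}

#' Phase table for a whole transcript set
#'
#' @param txs A `jx_transcript_set`.
#' @return Row-bound [compute_phases()] tables for all transcripts.
#' @export
phase_table <- function(txs) {
  do.call(rbind, lapply(unclass(txs), function(tx) {
    df <- compute_phases(tx)
    class(df) <- "data.frame"
    df
  }))
}
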
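# Classify exons as structure-encoding, disorder-encoding or other, and
# flag exons as constituent vs alternative across a gene's transcripts.
#
# An exon is disorder-encoding if at least 75% of the residues it encodes
# carry a consensus disorder prediction AND none of them lie in a predicted
# domain; structure-encoding if at least 75% lie in a predicted domain AND
# none carry a disorder prediction. Everything else is "other". Residues
# of codons split across a junction are (partially) encoded by both
# flanking exons and count toward both.

#' Classify a single exon from its residue span and annotation track
#'
#' @param res_start,res_end 0-based half-open residue span of the exon
#'   (from [compute_phases()]).
#' @param track A per-protein track: list with `length`, `disorder`,
#'   `domain` logical vectors (one element of a `jx_track_set`), or `NULL`.
#' @param threshold Fraction threshold (default 0.75, applied as `>=`).
#' @return List: `category` (`"structured"`, `"disordered"` or `"other"`),
#'   `frac_disorder`, `frac_domain`, `n_disorder`, `n_domain`, `n_residues`.
#' @export
classify_exon <- function(res_start, res_end, track, threshold = 0.75) {
  if (is.null(track) || res_end <= res_start) {
    return(list(category = "other", frac_disorder = NA_real_,
                frac_domain = NA_real_, n_disorder = NA_integer_,
                n_domain = NA_integer_, n_residues = res_end - res_start))
  }
  if (res_end > track$length) stop("residue span exceeds track length")
  idx <- (res_start + 1L):res_end
  n <- length(idx)
  nd <- sum(track$disorder[idx])
  nm <- sum(track$domain[idx])
  fd <- nd / n
  fm <- nm / n
  category <- if (fm >= threshold && nd == 0L) "structured"
  else if (fd >= threshold && nm == 0L) "disordered"
  else "other"
  list(category = category, frac_disorder = fd, frac_domain = fm,
       n_disorder = nd, n_domain = nm, n_residues = n)
}

#' Classify every exon of every transcript
#'
#' @param txs A `jx_transcript_set`.
#' @param tracks A `jx_track_set` keyed by transcript/protein id. A missing
#'   track yields category `"other"` (logged via warning once).
#' @param threshold Fraction threshold (default 0.75).
#' @return Data frame: `transcript_id`, `exon_id`, `rank`, `category`,
#'   `frac_disorder`, `frac_domain`, `n_disorder`, `n_domain`, `n_residues`.
#' @export
classify_exons <- function(txs, tracks, threshold = 0.75) {
  missing_tracks <- setdiff(names(txs), names(tracks))
  if (length(missing_tracks)) {
    warning(sprintf("%d transcript(s) without residue track; their exons are 'other'",
                    length(missing_tracks)))
  }
  out <- lapply(unclass(txs), function(tx) {
    ph <- compute_phases(tx)
    tr <- tracks[[tx$transcript_id]]
    cls <- lapply(seq_len(nrow(ph)), function(i) {
      classify_exon(ph$res_start[i], ph$res_end[i], tr, threshold)
    })
    data.frame(
      transcript_id = tx$transcript_id,
      exon_id = ph$exon_id, rank = ph$rank,
      category = vapply(cls, `[[`, "", "category"),
      frac_disorder = vapply(cls, `[[`, 0, "frac_disorder"),
      frac_domain = vapply(cls, `[[`, 0, "frac_domain"),
      n_disorder = vapply(cls, function(x) as.integer(x$n_disorder), 0L),
      n_domain = vapply(cls, function(x) as.integer(x$n_domain), 0L),
      n_residues = vapply(cls, function(x) as.integer(x$n_residues), 0L),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Constituent vs alternative status of each exon of a gene set
#'
#' An exon is constituent if it contributes the same coding sequence from
#' the same genetic locus (identical chromosome, strand and coding genomic
#' interval) in every transcript of its gene; otherwise alternative.
#' Single-transcript genes therefore have all exons constituent. An exon
#' sharing its genomic span but not its coding sub-interval across
#' transcripts (e.g. through UTR overlap) is alternative.
#'
#' @param txs A `jx_transcript_set` (all transcripts of the genes of
#'   interest must be present).
#' @return Data frame: `gene_id`, `exon_id`, `chrom`, `strand`,
#'   `coding_genomic_start`, `coding_genomic_end`, `status`
#'   (`"constituent"`/`"alternative"`), `n_transcripts` (of the gene).
#' @export
classify_splicing_status <- function(txs) {
  gene_ids <- vapply(txs, `[[`, "", "gene_id")
  out <- list()
  for (g in unique(gene_ids)) {
    gtx <- unclass(txs)[gene_ids == g]
    keys_by_tx <- lapply(gtx, function(tx) {
      paste(tx$chrom, tx$strand, tx$exons$coding_genomic_start,
            tx$exons$coding_genomic_end, sep = ":")
    })
    all_keys <- unique(unlist(keys_by_tx))
    in_all <- vapply(all_keys, function(k) {
      all(vapply(keys_by_tx, function(ks) k %in% ks, TRUE))
    }, TRUE)
    # representative exon record per key (first transcript carrying it)
    rows <- lapply(seq_along(all_keys), function(i) {
      k <- all_keys[i]
      for (tx in gtx) {
        j <- match(k, paste(tx$chrom, tx$strand, tx$exons$coding_genomic_start,
                            tx$exons$coding_genomic_end, sep = ":"))
        if (!is.na(j)) {
          return(data.frame(
            gene_id = g, exon_id = tx$exons$exon_id[j], chrom = tx$chrom,
            strand = tx$strand,
            coding_genomic_start = tx$exons$coding_genomic_start[j],
            coding_genomic_end = tx$exons$coding_genomic_end[j],
            status = if (in_all[i]) "constituent" else "alternative",
            n_transcripts = length(gtx), stringsAsFactors = FALSE))
        }
      }
    })
    out[[g]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
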
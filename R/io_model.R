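# Domain types and readers/writers for gene models, sequences, residue
# tracks and motif lists.
#
# A transcript is a list with:
#   transcript_id, gene_id, chrom, strand ("+"/"-")
#   exons: data.frame with one row per coding exon, in transcript (5'->3')
#     rank order: exon_id, rank, genomic_start, genomic_end (1-based inclusive
#     exon bounds), coding_genomic_start, coding_genomic_end (1-based inclusive
#     bounds of the coding part), coding_start_offset, coding_end_offset
#     (0-based half-open offsets within the CDS)
#   cds: CDS DNA including the terminal stop codon (never mapped to a residue)
#   protein: amino-acid sequence
#   utr5, utr3: untranslated cDNA flanks (possibly "")

new_transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                           cds, protein, utr5 = "", utr3 = "") {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons))
  clen <- exons$coding_end_offset - exons$coding_start_offset
  if (any(clen <= 0L)) stop("exon with non-positive coding length")
  if (nrow(exons) > 1L) {
    if (any(diff(exons$coding_start_offset) <= 0L) ||
        any(exons$coding_start_offset[-1L] !=
            exons$coding_end_offset[-nrow(exons)])) {
      stop("coding offsets must be contiguous and strictly increasing")
    }
  }
  if (exons$coding_start_offset[1L] != 0L) stop("CDS must start at offset 0")
  if (sum(clen) != nchar(cds)) stop("CDS length != sum of exon coding lengths")
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds, protein = protein,
         utr5 = utr5, utr3 = utr3),
    class = "jx_transcript")
}

#' @export
print.jx_transcript <- function(x, ...) {
  cat(sprintf("<jx_transcript> %s (gene %s, %s%s): %d coding exon(s), CDS %d nt, protein %d aa\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nchar(x$cds), nchar(x$protein)))
  invisible(x)
}

#' Bundle transcripts into a set keyed by transcript id
#' @param transcripts List of `jx_transcript` objects.
#' @return `jx_transcript_set`.
#' @export
transcript_set <- function(transcripts) {
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(transcripts, class = "jx_transcript_set")
}

#' @export
print.jx_transcript_set <- function(x, ...) {
  cat(sprintf("<jx_transcript_set> %d transcripts, %d genes, %d coding exons\n",
              length(x),
              length(unique(vapply(x, `[[`, "", "gene_id"))),
              sum(vapply(x, function(t) nrow(t$exons), 0L))))
  invisible(x)
}

#' @export
`[.jx_transcript_set` <- function(x, i) {
  transcript_set(unclass(x)[i])
}

cdna_of <- function(tx) paste0(tx$utr5, tx$cds, tx$utr3)

#' Read gene models from GTF plus cDNA and protein FASTA
#'
#' Builds transcript records from `exon` and `CDS` features. Only coding
#' exons are returned (exons entirely within the 5'/3' UTR are dropped);
#' exons are ordered 5'->3' in transcript orientation, so minus-strand
#' transcripts read in the direction of translation. The CDS sequence is
#' sliced out of the cDNA using the exon/CDS geometry and kept with its
#' terminal stop codon.
#'
#' Transcripts with a missing cDNA or protein sequence, or whose CDS cannot
#' be reconstructed from the annotated exons, are skipped with a warning.
#'
#' @param gtf_path GTF file with `exon` and `CDS` features carrying
#'   `gene_id`/`transcript_id` (and optionally `exon_id`) attributes.
#' @param cdna_fasta,protein_fasta FASTA files whose headers (first token)
#'   are transcript ids.
#' @param verbose Emit progress messages.
#' @return A `jx_transcript_set`.
#' @export
read_gene_models <- function(gtf_path, cdna_fasta, protein_fasta,
                             verbose = FALSE) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  cdna <- Biostrings::readDNAStringSet(cdna_fasta)
  names(cdna) <- sub("\\s.*$", "", names(cdna))
  prot <- Biostrings::readAAStringSet(protein_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))

  feat <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    exon_id = if (!is.null(gr$exon_id)) gr$exon_id else NA_character_,
    stringsAsFactors = FALSE)
  feat <- feat[feat$type %in% c("exon", "CDS"), , drop = FALSE]

  out <- list()
  for (tid in unique(feat$transcript_id)) {
    f <- feat[feat$transcript_id == tid, , drop = FALSE]
    tx <- .build_transcript(tid, f, cdna, prot, verbose)
    if (!is.null(tx)) out[[tid]] <- tx
  }
  transcript_set(out)
}

.build_transcript <- function(tid, f, cdna, prot, verbose) {
  skip <- function(why) {
    warning(sprintf("skipping transcript %s: %s", tid, why), call. = FALSE)
    NULL
  }
  if (!tid %in% names(cdna)) return(skip("no cDNA sequence"))
  if (!tid %in% names(prot)) return(skip("no protein sequence"))
  ex <- f[f$type == "exon", , drop = FALSE]
  cd <- f[f$type == "CDS", , drop = FALSE]
  if (nrow(ex) == 0L || nrow(cd) == 0L) return(skip("no exon/CDS features"))
  strand <- ex$strand[1L]
  ord <- if (strand == "+") order(ex$start) else order(-ex$start)
  ex <- ex[ord, , drop = FALSE]

  cdna_seq <- as.character(cdna[[tid]])
  prot_seq <- as.character(prot[[tid]])

  rows <- list()
  cdna_cursor <- 0L   # nt of cDNA consumed by previous exons
  cds_cursor <- 0L    # nt of CDS consumed so far
  cds_pieces <- character(0)
  utr5_len <- NA_integer_
  rank <- 0L
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    exon_w <- e$end - e$start + 1L
    hit <- which(cd$chrom == e$chrom & cd$start >= e$start & cd$end <= e$end)
    if (length(hit) > 1L) return(skip("multiple CDS features in one exon"))
    if (length(hit) == 1L) {
      cc <- cd[hit, ]
      # offset of the coding part from the exon's 5' end (transcript sense)
      off5 <- if (strand == "+") cc$start - e$start else e$end - cc$end
      w <- cc$end - cc$start + 1L
      piece_start <- cdna_cursor + off5  # 0-based within cDNA
      if (piece_start + w > nchar(cdna_seq)) {
        return(skip("CDS extends beyond cDNA"))
      }
      if (is.na(utr5_len)) utr5_len <- piece_start
      rank <- rank + 1L
      rows[[rank]] <- data.frame(
        exon_id = if (!is.na(e$exon_id)) e$exon_id
                  else sprintf("%s_e%d", tid, rank),
        rank = rank,
        genomic_start = e$start, genomic_end = e$end,
        coding_genomic_start = cc$start, coding_genomic_end = cc$end,
        coding_start_offset = cds_cursor,
        coding_end_offset = cds_cursor + w,
        stringsAsFactors = FALSE)
      cds_pieces[[rank]] <- substr(cdna_seq, piece_start + 1L, piece_start + w)
      attr(rows[[rank]], "cdna_piece") <- c(piece_start, piece_start + w)
      cds_cursor <- cds_cursor + w
      cdna_cursor <- cdna_cursor + exon_w
    } else {
      cdna_cursor <- cdna_cursor + exon_w
    }
  }
  if (rank == 0L) return(skip("no coding exons"))
  exdf <- do.call(rbind, rows)
  # contiguity check: coding pieces must abut in the cDNA
  pieces <- t(vapply(rows, function(r) attr(r, "cdna_piece"), c(0L, 0L)))
  starts_ok <- rank == 1L || all(pieces[-1L, 1L] == pieces[-rank, 2L])
  cds_seq <- paste(cds_pieces, collapse = "")
  if (!starts_ok || nchar(cds_seq) != exdf$coding_end_offset[rank]) {
    return(skip("CDS not reconstructible from exons"))
  }
  utr5_len <- pieces[1L, 1L]
  utr5 <- if (utr5_len > 0L) substr(cdna_seq, 1L, utr5_len) else ""
  utr3_start <- utr5_len + nchar(cds_seq)
  utr3 <- if (utr3_start < nchar(cdna_seq)) {
    substr(cdna_seq, utr3_start + 1L, nchar(cdna_seq))
  } else ""
  jx_msg("read transcript ", tid, verbose = verbose)
  new_transcript(tid, f$gene_id[1L], ex$chrom[1L], strand, exdf,
                 cds_seq, prot_seq, utr5 = utr5, utr3 = utr3)
}

#' Write gene models as GTF + cDNA/protein FASTA
#'
#' Inverse of [read_gene_models()]: emits one `exon` and one `CDS` feature
#' per coding exon (plus `exon` features for pure-UTR exons recorded in
#' `utr_exons`), a cDNA FASTA (UTRs + CDS) and a protein FASTA.
#'
#' @param txs A `jx_transcript_set`.
#' @param dir Output directory (created if needed).
#' @param utr_exons Optional data.frame of non-coding exons
#'   (`transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `exon_id`, `before_coding`) to interleave into the GTF.
#' @return Invisibly, named vector of written file paths.
#' @export
write_gene_models <- function(txs, dir, utr_exons = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gtf <- file.path(dir, "genes.gtf")
  lines <- character(0)
  for (tx in txs) {
    ex <- tx$exons
    utr_rows_before <- utr_rows_after <- NULL
    if (!is.null(utr_exons)) {
      u <- utr_exons[utr_exons$transcript_id == tx$transcript_id, , drop = FALSE]
      if (nrow(u)) {
        utr_rows_before <- u[u$before_coding, , drop = FALSE]
        utr_rows_after <- u[!u$before_coding, , drop = FALSE]
      }
    }
    attr_str <- function(eid) sprintf(
      'gene_id "%s"; transcript_id "%s"; exon_id "%s";',
      tx$gene_id, tx$transcript_id, eid)
    fmt <- function(start, end, type, eid, frame = ".") sprintf(
      "%s\tjunctionscape\t%s\t%d\t%d\t.\t%s\t%s\t%s",
      tx$chrom, type, start, end, tx$strand, frame, attr_str(eid))
    if (!is.null(utr_rows_before)) for (j in seq_len(nrow(utr_rows_before))) {
      u <- utr_rows_before[j, ]
      lines <- c(lines, fmt(u$start, u$end, "exon", u$exon_id))
    }
    for (i in seq_len(nrow(ex))) {
      frame <- as.character((3L - ex$coding_start_offset[i] %% 3L) %% 3L)
      lines <- c(lines,
                 fmt(ex$genomic_start[i], ex$genomic_end[i], "exon", ex$exon_id[i]),
                 fmt(ex$coding_genomic_start[i], ex$coding_genomic_end[i],
                     "CDS", ex$exon_id[i], frame))
    }
    if (!is.null(utr_rows_after)) for (j in seq_len(nrow(utr_rows_after))) {
      u <- utr_rows_after[j, ]
      lines <- c(lines, fmt(u$start, u$end, "exon", u$exon_id))
    }
  }
  writeLines(lines, gtf)

  cdna_fa <- file.path(dir, "cdna.fa")
  prot_fa <- file.path(dir, "protein.fa")
  cdna <- Biostrings::DNAStringSet(vapply(txs, cdna_of, ""))
  names(cdna) <- names(txs)
  Biostrings::writeXStringSet(cdna, cdna_fa, width = 70L)
  prot <- Biostrings::AAStringSet(vapply(txs, `[[`, "", "protein"))
  names(prot) <- names(txs)
  Biostrings::writeXStringSet(prot, prot_fa, width = 70L)
  invisible(c(gtf = gtf, cdna = cdna_fa, protein = prot_fa))
}

#' Read per-residue annotation tracks
#'
#' Reads a BED-like TSV of per-protein residue intervals (columns
#' `protein_id`, `start`, `end`, `track`; 0-based half-open residue
#' coordinates; `track` is `disorder` or `domain`, emulating a disorder
#' consensus and predicted-domain assignments) and rasterises it to boolean
#' vectors. Overlapping intervals union; rows exceeding the protein length
#' are rejected with a warning. Proteins with no rows get all-`FALSE`
#' tracks of their length.
#'
#' @param tsv_path Path to the TSV (header required).
#' @param protein_lengths Named integer vector of protein lengths (residues).
#' @return Named list (by protein id) of lists with `length`, `disorder`,
#'   `domain`; class `jx_track_set`.
#' @export
read_residue_tracks <- function(tsv_path, protein_lengths) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "track")
  if (!all(need %in% names(df))) {
    stop("track file must have columns: ", paste(need, collapse = ", "))
  }
  tracks <- lapply(protein_lengths, function(n) {
    list(length = as.integer(n),
         disorder = rep(FALSE, n), domain = rep(FALSE, n))
  })
  names(tracks) <- names(protein_lengths)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$protein_id %in% names(tracks)) {
      warning(sprintf("track row %d: unknown protein %s; rejected", i, r$protein_id))
      next
    }
    n <- tracks[[r$protein_id]]$length
    if (r$start < 0L || r$end > n || r$end <= r$start) {
      warning(sprintf("track row %d: interval [%d,%d) outside protein %s (len %d); rejected",
                      i, r$start, r$end, r$protein_id, n))
      next
    }
    if (!r$track %in% c("disorder", "domain")) {
      warning(sprintf("track row %d: unknown track '%s'; rejected", i, r$track))
      next
    }
    idx <- (r$start + 1L):r$end
    tracks[[r$protein_id]][[r$track]][idx] <- TRUE
  }
  structure(tracks, class = "jx_track_set")
}

#' Write residue tracks as interval TSV
#'
#' @param tracks `jx_track_set` (or compatible named list).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_residue_tracks <- function(tracks, path) {
  rows <- list()
  for (pid in names(tracks)) {
    for (tr in c("disorder", "domain")) {
      v <- tracks[[pid]][[tr]]
      if (!any(v)) next
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, start = starts[keep] - 1L, end = ends[keep],
        track = tr, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), track = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hexamer motif set
#'
#' One motif per line, case-insensitive; deduplicated and uppercased. Any
#' line that is not a 6-mer over A/C/G/T is a hard error reporting the line
#' number.
#'
#' @param path Plain-text motif file.
#' @param name Label for the set (defaults to the file name).
#' @return Character vector of unique uppercase hexamers, class
#'   `jx_motif_set` with a `name` attribute.
#' @export
read_motifs <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  keep <- nzchar(lines)
  bad <- which(keep & !grepl("^[ACGTacgt]{6}$", lines))
  if (length(bad)) {
    stop(sprintf("invalid motif at line %d of %s: '%s' (need a 6-mer over ACGT)",
                 bad[1L], path, lines[bad[1L]]))
  }
  motif_set(toupper(lines[keep]), name = name)
}

#' Construct a motif set from character hexamers
#' @param motifs Character vector of DNA 6-mers (deduplicated, uppercased).
#' @param name Label for the set.
#' @return `jx_motif_set`.
#' @export
motif_set <- function(motifs, name = "motifs") {
  motifs <- unique(toupper(motifs))
  if (length(motifs) && any(!grepl("^[ACGT]{6}$", motifs))) {
    stop("motifs must be 6-mers over ACGT")
  }
  structure(motifs, name = name, class = "jx_motif_set")
}

#' @export
print.jx_motif_set <- function(x, ...) {
  cat(sprintf("<jx_motif_set> %s: %d hexamers\n", attr(x, "name"), length(x)))
  invisible(x)
}

#' Write a motif set to a plain-text file
#' @param motifs `jx_motif_set` or character vector of hexamers.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motifs <- function(motifs, path) {
  writeLines(as.character(motifs), path)
  invisible(path)
}

#' Read a genome-to-group map
#'
#' TSV with columns `genome_id` and `group` (e.g. Chordates, Fungi). Every
#' genome must have exactly one label.
#'
#' @param path TSV path (header required).
#' @return Named character vector: genome id -> group label.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "group") %in% names(df))) {
    stop("group map must have columns genome_id, group")
  }
  if (anyDuplicated(df$genome_id)) stop("duplicate genome_id in group map")
  stats::setNames(df$group, df$genome_id)
}
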
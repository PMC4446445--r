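# Independent oracles and fixture builders. Oracles deliberately use the
# dumbest possible algorithm (per-nucleotide walks, per-position loops,
# substring enumeration) so they share no code path with the package.

GC_TABLE <- Biostrings::GENETIC_CODE  # reference translation table

# Per-nucleotide codon walk over exon coding lengths: phases and the span
# of codon indices touched by each exon.
oracle_phase_walk <- function(coding_lens) {
  n <- length(coding_lens)
  out <- data.frame(rank = seq_len(n), start_phase = NA_integer_,
                    end_phase = NA_integer_, res_start = NA_integer_,
                    res_end = NA_integer_)
  pos <- 0L  # 0-based nucleotide index within CDS
  for (k in seq_len(n)) {
    out$start_phase[k] <- pos %% 3L
    codons <- integer(0)
    for (j in seq_len(coding_lens[k])) {
      codons <- c(codons, pos %/% 3L)
      pos <- pos + 1L
    }
    out$end_phase[k] <- pos %% 3L
    out$res_start[k] <- min(codons)
    out$res_end[k] <- max(codons) + 1L
  }
  out
}

# residue-by-residue translation of a CDS, one codon at a time
oracle_translate <- function(cds) {
  n <- nchar(cds)
  aa <- character(0)
  for (i in seq(1L, n - 2L, by = 3L)) {
    codon <- substr(cds, i, i + 2L)
    a <- if (codon %in% names(GC_TABLE)) unname(GC_TABLE[codon]) else "X"
    aa <- c(aa, a)
  }
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# brute-force sliding-window hexamer scan (N windows skipped)
oracle_scan <- function(seq, motifs) {
  n <- nchar(seq)
  nw <- 0L; nm <- 0L
  if (n >= 6L) {
    for (i in 1:(n - 5L)) {
      w <- substr(seq, i, i + 5L)
      if (grepl("N", w, fixed = TRUE)) next
      nw <- nw + 1L
      if (w %in% motifs) nm <- nm + 1L
    }
  }
  c(n_windows = nw, n_matches = nm)
}

# per-residue interval membership test
oracle_rasterize <- function(intervals, len) {
  v <- logical(len)
  for (r in seq_len(nrow(intervals))) {
    for (p in seq_len(len)) {
      if (p - 1L >= intervals$start[r] && p - 1L < intervals$end[r]) {
        v[p] <- TRUE
      }
    }
  }
  v
}

SENSE <- setdiff(names(GC_TABLE), c("TAA", "TAG", "TGA"))

# Build a minimal valid transcript from per-exon coding lengths. The CDS is
# random sense codons (ATG start, stop end) unless given; exon genomic
# coordinates are laid out left to right with 100-nt introns.
make_tx <- function(coding_lens, cds = NULL, transcript_id = "t1",
                    gene_id = "g1", chrom = "chrT", strand = "+",
                    utr5 = "", utr3 = "") {
  total <- sum(coding_lens)
  stopifnot(total %% 3L == 0L)
  if (is.null(cds)) {
    codons <- sample(SENSE, total / 3L, replace = TRUE)
    codons[1L] <- "ATG"
    codons[length(codons)] <- "TAA"
    cds <- paste(codons, collapse = "")
  }
  stopifnot(nchar(cds) == total)
  ends <- cumsum(coding_lens)
  starts <- c(0L, ends[-length(ends)])
  gstart <- integer(length(coding_lens))
  cursor <- 1000L
  for (k in seq_along(coding_lens)) {
    gstart[k] <- cursor
    cursor <- cursor + coding_lens[k] + 100L
  }
  exons <- data.frame(
    exon_id = sprintf("%s_e%d", transcript_id, seq_along(coding_lens)),
    rank = seq_along(coding_lens),
    genomic_start = gstart, genomic_end = gstart + coding_lens - 1L,
    coding_genomic_start = gstart, coding_genomic_end = gstart + coding_lens - 1L,
    coding_start_offset = starts, coding_end_offset = ends,
    stringsAsFactors = FALSE)
  protein <- tryCatch(translate_cds(cds), error = function(e) "")
  junctionscape:::new_transcript(transcript_id, gene_id, chrom, strand, exons,
                                 cds, protein, utr5 = utr5, utr3 = utr3)
}

# random multi-exon transcript: exon coding lengths >= 4 nt, total CDS a
# multiple of 3, random phases
fuzz_tx <- function(id = "t1", n_exons = NULL) {
  if (is.null(n_exons)) n_exons <- sample(2:8, 1L)
  lens <- sample(4:60, n_exons, replace = TRUE)
  excess <- sum(lens) %% 3L
  lens[n_exons] <- lens[n_exons] + (3L - excess) %% 3L
  make_tx(lens, transcript_id = id, gene_id = paste0("g", id))
}

# small track object
make_track <- function(disorder, domain) {
  stopifnot(length(disorder) == length(domain))
  list(length = length(disorder), disorder = disorder, domain = domain)
}

lean_config <- function(...) {
  # generator config with every optional signal off; individual tests turn
  # on exactly the mechanism they probe (overrides win over the lean defaults)
  defaults <- list(splice_bias = 0,
                   ese_rates = c(structured = 0, disordered = 0, other = 0),
                   gradient_slopes = numeric(0),
                   alt_rate = 0, utr5_rate = 0, utr3_rate = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(gen_config, args)
}
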
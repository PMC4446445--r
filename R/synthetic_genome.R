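# Seeded generator of synthetic gene models with planted, recorded signal:
# multi-exon genes with configurable splice-site nucleotide bias, planted
# enhancer hexamers at class-specific per-window rates, exon-aligned
# disorder/domain tracks, optional amino-acid composition gradients near
# junctions, and alternative transcripts by exon skipping. Every planted
# quantity is recorded in a ground-truth table so each pipeline stage has
# a recoverable target.

#' Configuration for the synthetic genome generator
#'
#' Defaults describe the emulated study conditions: ~8 coding exons per
#' gene, internal exons of ~50 codons, canonical splice-site bias (exonic
#' AG before the 5' splice site, G after the 3' splice site) realised at
#' 60% of junctions, enhancer-hexamer window match rates of 10% in
#' structure-encoding and 13.5% in disorder-encoding exons, flanking
#' introns shorter around disorder-encoding exons, and a mild planted
#' decrease of Lysine usage with distance from the junction.
#'
#' @param n_genes Number of genes.
#' @param seed RNG seed (mandatory; generation is deterministic given it).
#' @param genome_id Label for this genome.
#' @param exons_per_gene_mean,exons_per_gene_dispersion Negative-binomial
#'   exon count per gene (1 + NB(mu = mean - 1, size = dispersion)).
#' @param exon_len_mean,exon_len_sd,exon_len_min Exon length in codons
#'   (rounded normal, floored at `exon_len_min`).
#' @param class_probs Stationary probabilities of planting each exon as
#'   structured / disordered / other.
#' @param class_switch_rate Probability that an exon's planted class is
#'   redrawn (from `class_probs`) rather than copied from its upstream
#'   neighbour; classes therefore come in blocks, as domains and
#'   disordered regions span consecutive exons in real genes.
#' @param intron_mean,intron_sd Named per-class intron length parameters
#'   (nt); an intron's mean is the average over its two flanking exons'
#'   classes.
#' @param intron_min Minimum intron length in nt (floors every draw).
#' @param splice_bias Probability beta that a junction carries the
#'   canonical exonic signal: the 2 nt before the 5' splice site forced to
#'   AG and the nt after the 3' splice site forced to G.
#' @param ese_rates Named per-class target hexamer match rate per 6-nt
#'   window inside the scanned codon 2-34 blocks. Planting uses stochastic
#'   rounding of rate x windows and keeps the background inside scanned
#'   windows motif-free, so the realised match rate equals the target.
#' @param gradient_slopes Named per-amino-acid slopes of the junction
#'   composition gradient: at codon distance d in 2..34 from the nearer
#'   exon edge, amino acid a is drawn with weight proportional to
#'   `bg_a * exp(slope_a * (d - 2))`. Negative slope = usage decreasing
#'   with distance (enriched near the junction). Default: K at -0.015.
#' @param phase_probs Distribution of junction phases 0/1/2.
#' @param alt_rate Probability a gene gains a second transcript skipping
#'   one frame-preserving (phase 0/0) internal exon.
#' @param utr5_rate,utr5_exon_rate,utr3_rate Probability of a 5' UTR, of it
#'   being a separate pure-UTR exon, and of a 3' UTR.
#' @param codon_usage Optional named probability vector over the 61 sense
#'   codons (default uniform, which makes null composition tests exact).
#' @param n_motifs,n_motifs_int3 Sizes of the generated synthetic enhancer
#'   motif sets (RESCUE-like and INT3-like consensus subset).
#' @param force_terminal_codons Force ATG start and a stop codon (default
#'   TRUE). Setting FALSE yields a junction sample exactly
#'   distribution-matched to the background, for null calibration.
#' @return List of class `jx_gen_config`.
#' @export
gen_config <- function(n_genes = 300L, seed = 1L, genome_id = "synthA",
                       exons_per_gene_mean = 8, exons_per_gene_dispersion = 6,
                       exon_len_mean = 50, exon_len_sd = 15, exon_len_min = 6L,
                       class_probs = c(structured = 0.4, disordered = 0.3, other = 0.3),
                       class_switch_rate = 0.4,
                       intron_mean = c(structured = 1000, disordered = 600, other = 800),
                       intron_sd = c(structured = 200, disordered = 150, other = 175),
                       intron_min = 60L,
                       splice_bias = 0.6,
                       ese_rates = c(structured = 0.10, disordered = 0.135, other = 0.11),
                       gradient_slopes = c(K = -0.015),
                       phase_probs = c(0.47, 0.30, 0.23),
                       alt_rate = 0.3,
                       utr5_rate = 0.5, utr5_exon_rate = 0.4, utr3_rate = 0.5,
                       codon_usage = NULL,
                       n_motifs = 238L, n_motifs_int3 = 84L,
                       force_terminal_codons = TRUE) {
  probs <- c(splice_bias, ese_rates, alt_rate, utr5_rate, utr5_exon_rate,
             utr3_rate, class_probs, phase_probs, class_switch_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(class_probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (!setequal(names(class_probs), c("structured", "disordered", "other"))) {
    stop("class_probs needs names structured/disordered/other")
  }
  for (nm in list(ese_rates, intron_mean, intron_sd)) {
    if (!all(c("structured", "disordered", "other") %in% names(nm))) {
      stop("per-class parameters need names structured/disordered/other")
    }
  }
  if (exon_len_min < 4L) stop("exon_len_min must be at least 4 codons")
  if (exon_len_mean < exon_len_min) stop("infeasible exon length configuration")
  if (is.null(codon_usage)) {
    codon_usage <- stats::setNames(rep(1 / length(SENSE_CODONS),
                                       length(SENSE_CODONS)), SENSE_CODONS)
  } else {
    if (!setequal(names(codon_usage), SENSE_CODONS)) {
      stop("codon_usage must be named over the 61 sense codons")
    }
    codon_usage <- codon_usage[SENSE_CODONS] / sum(codon_usage)
  }
  slopes <- stats::setNames(numeric(20), AA_ORDER)
  if (length(gradient_slopes)) {
    if (is.null(names(gradient_slopes)) ||
        !all(names(gradient_slopes) %in% AA_ORDER)) {
      stop("gradient_slopes must be named by 1-letter amino-acid codes")
    }
    slopes[names(gradient_slopes)] <- gradient_slopes
  }
  if (n_motifs_int3 > n_motifs) stop("INT3-like set cannot exceed the full set")
  structure(
    list(n_genes = as.integer(n_genes), seed = as.integer(seed),
         genome_id = genome_id,
         exons_per_gene_mean = exons_per_gene_mean,
         exons_per_gene_dispersion = exons_per_gene_dispersion,
         exon_len_mean = exon_len_mean, exon_len_sd = exon_len_sd,
         exon_len_min = as.integer(exon_len_min),
         class_probs = class_probs[c("structured", "disordered", "other")],
         class_switch_rate = class_switch_rate,
         intron_mean = intron_mean, intron_sd = intron_sd,
         intron_min = as.integer(intron_min),
         splice_bias = splice_bias, ese_rates = ese_rates,
         gradient_slopes = slopes, phase_probs = phase_probs,
         alt_rate = alt_rate, utr5_rate = utr5_rate,
         utr5_exon_rate = utr5_exon_rate, utr3_rate = utr3_rate,
         codon_usage = codon_usage,
         n_motifs = as.integer(n_motifs),
         n_motifs_int3 = as.integer(n_motifs_int3),
         force_terminal_codons = isTRUE(force_terminal_codons)),
    class = "jx_gen_config")
}

#' Generate a synthetic enhancer motif set
#'
#' Draws `n` distinct hexamers uniformly from the 4096 possible ones.
#' Note this samples the current RNG stream; [generate_genome()] calls it
#' internally under the config seed.
#'
#' @param n Number of motifs.
#' @param name Set label.
#' @return `jx_motif_set`.
#' @export
synthetic_motif_set <- function(n, name = "synthetic-ese") {
  idx <- sample.int(length(ALL_CODONS)^2, n) - 1L
  m1 <- ALL_CODONS[idx %/% 64L + 1L]
  m2 <- ALL_CODONS[idx %% 64L + 1L]
  motif_set(paste0(m1, m2), name = name)
}

# amino-acid frequencies implied by a codon usage table (stops excluded)
.aa_freq_from_usage <- function(codon_usage) {
  aa <- translate_codons(names(codon_usage))
  f <- tapply(codon_usage, aa, sum)
  out <- stats::setNames(numeric(20), AA_ORDER)
  out[names(f)] <- f
  out / sum(out)
}

# padded amino-acid -> codon lookup for vectorised codon draws
.aa_codon_matrix <- function() {
  aa <- translate_codons(SENSE_CODONS)
  by_aa <- split(SENSE_CODONS, aa)[AA_ORDER]
  ncod <- lengths(by_aa)
  mat <- matrix(NA_character_, nrow = 20, ncol = max(ncod),
                dimnames = list(AA_ORDER, NULL))
  for (i in seq_along(by_aa)) mat[i, seq_len(ncod[i])] <- by_aa[[i]]
  list(mat = mat, ncod = ncod)
}

#' Generate a synthetic genome bundle
#'
#' Produces an in-memory bundle of transcripts, residue tracks, motif sets
#' and ground truth under the planted-signal model of [gen_config()].
#' Deterministic given `config$seed`. Use [write_genome_bundle()] to emit
#' the on-disk formats ([read_gene_models()] and friends read back).
#'
#' @param config A `jx_gen_config`.
#' @return List of class `jx_genome_bundle`: `transcripts`
#'   (`jx_transcript_set`), `tracks` (`jx_track_set`), `motifs` (list with
#'   `rescue` and `int3` sets), `truth` (per-exon data frame), `truth_ese`
#'   (per exon-side enhancer planting table), `utr_exons`, `loci` (per-gene
#'   chromosome sequences), `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "jx_gen_config"))
  set.seed(config$seed)
  cfg <- config
  rescue <- synthetic_motif_set(cfg$n_motifs, name = "rescue-like-synthetic")
  int3 <- motif_set(sample(rescue, cfg$n_motifs_int3),
                    name = "int3-like-synthetic")
  aa_bg <- .aa_freq_from_usage(cfg$codon_usage)
  aacod <- .aa_codon_matrix()
  # gradient weight matrix: aa x distance 2..34
  use_gradient <- any(cfg$gradient_slopes != 0)
  grad_w <- NULL
  if (use_gradient) {
    dd <- 2:34
    grad_w <- vapply(dd, function(d) {
      w <- aa_bg * exp(cfg$gradient_slopes * (d - 2))
      w / sum(w)
    }, numeric(20))
    colnames(grad_w) <- dd
  }

  genes <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    genes[[g]] <- .generate_gene(cfg, g, rescue, int3, aa_bg, aacod, grad_w)
  }
  txs <- unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE)
  tracks <- unlist(lapply(genes, `[[`, "tracks"), recursive = FALSE)
  truth <- lapply(genes, `[[`, "truth")
  truth_ese <- Filter(Negate(is.null), lapply(genes, `[[`, "truth_ese"))
  utr_rows <- Filter(Negate(is.null), lapply(genes, `[[`, "utr_exons"))
  loci <- lapply(genes, `[[`, "locus")
  names(loci) <- vapply(loci, `[[`, "", "chrom")
  structure(
    list(transcripts = transcript_set(txs),
         tracks = structure(tracks, class = "jx_track_set"),
         motifs = list(rescue = rescue, int3 = int3),
         truth = do.call(rbind, truth),
         truth_ese = if (length(truth_ese)) do.call(rbind, truth_ese) else NULL,
         utr_exons = if (length(utr_rows)) do.call(rbind, utr_rows) else NULL,
         loci = loci, config = cfg),
    class = "jx_genome_bundle")
}

#' @export
print.jx_genome_bundle <- function(x, ...) {
  cat(sprintf("<jx_genome_bundle> %s: %d transcripts, %d genes (seed %d)\n",
              x$config$genome_id, length(x$transcripts), x$config$n_genes,
              x$config$seed))
  invisible(x)
}

.generate_gene <- function(cfg, g, rescue, int3, aa_bg, aacod, grad_w) {
  gene_id <- sprintf("%s_g%04d", cfg$genome_id, g)
  n_ex <- 1L + stats::rnbinom(1L, size = cfg$exons_per_gene_dispersion,
                              mu = max(cfg$exons_per_gene_mean - 1, 0.01))
  classes <- character(n_ex)
  classes[1L] <- sample(names(cfg$class_probs), 1L, prob = cfg$class_probs)
  if (n_ex > 1L) {
    redraw <- stats::runif(n_ex - 1L) < cfg$class_switch_rate
    for (k in 2:n_ex) {
      classes[k] <- if (redraw[k - 1L])
        sample(names(cfg$class_probs), 1L, prob = cfg$class_probs)
      else classes[k - 1L]
    }
  }
  L <- pmax(as.integer(round(stats::rnorm(n_ex, cfg$exon_len_mean,
                                          cfg$exon_len_sd))),
            cfg$exon_len_min)
  # junction phases; class changes are pinned to phase 0 so that residue
  # tracks can be exactly exon-aligned (a split codon never straddles two
  # planted classes)
  p <- if (n_ex > 1L) sample(0:2, n_ex - 1L, TRUE, cfg$phase_probs) else integer(0)
  if (n_ex > 1L) p[classes[-n_ex] != classes[-1L]] <- 0L
  pfull <- c(0L, p, 0L)
  nk <- 3L * L + pfull[-1L] - pfull[-(n_ex + 1L)]
  cend <- cumsum(nk)
  cstart <- c(0L, cend[-n_ex])
  N <- sum(L)

  cod <- sample(SENSE_CODONS, N, TRUE, cfg$codon_usage)
  if (cfg$force_terminal_codons) {
    cod[1L] <- "ATG"
    cod[N] <- sample(STOP_CODONS, 1L)
  }

  # complete-codon geometry per exon (0-based codon counts before exon)
  c0 <- as.integer(ceiling(cstart / 3))
  c1 <- cend %/% 3L
  m <- c1 - c0

  # --- planted composition gradient (codon-level, before nt assembly) ---
  if (!is.null(grad_w)) {
    pos_all <- integer(0); d_all <- integer(0)
    for (k in seq_len(n_ex)) {
      if (m[k] < 1L) next
      i <- seq_len(m[k])
      ds <- i; de <- m[k] + 1L - i
      near <- pmin(ds, de)
      sel <- ds != de & near >= 2L & near <= 34L
      if (!any(sel)) next
      gpos <- c0[k] + i[sel]  # 1-based global codon index
      keep <- gpos != 1L & gpos != N
      pos_all <- c(pos_all, gpos[keep])
      d_all <- c(d_all, near[sel][keep])
    }
    if (length(pos_all)) {
      for (dgrp in split(seq_along(pos_all), d_all)) {
        d <- d_all[dgrp[1L]]
        aa <- sample(AA_ORDER, length(dgrp), TRUE, grad_w[, as.character(d)])
        ai <- match(aa, AA_ORDER)
        ci <- 1L + floor(stats::runif(length(dgrp)) * aacod$ncod[ai])
        cod[pos_all[dgrp]] <- aacod$mat[cbind(ai, ci)]
      }
    }
  }

  nt <- unlist(CODON_LETTERS[cod], use.names = FALSE)

  # --- canonical splice-site bias at junctions ---
  junction_forced <- logical(max(n_ex - 1L, 0L))
  realized_last2 <- realized_next1 <- rep(NA_character_, max(n_ex - 1L, 0L))
  if (n_ex > 1L) {
    junction_forced <- stats::runif(n_ex - 1L) < cfg$splice_bias
    forced_pos <- logical(3L * N)
    for (k in which(junction_forced)) {
      J <- cend[k]  # 0-based CDS offset of first nt after the junction
      nt[J - 1L] <- "A"; nt[J] <- "G"; nt[J + 1L] <- "G"
      forced_pos[c(J - 1L, J, J + 1L)] <- TRUE
    }
    # repair any stop codon created by the forced nucleotides
    for (k in which(junction_forced)) {
      J <- cend[k]
      cfrom <- max(1L, (J - 3L) %/% 3L + 1L)
      cto <- min(N - 1L, J %/% 3L + 1L)
      for (cc in cfrom:cto) {
        if (cc == 1L) next
        idx <- (3L * (cc - 1L) + 1L):(3L * cc)
        codon <- paste(nt[idx], collapse = "")
        if (!codon %in% STOP_CODONS) next
        free <- idx[!forced_pos[idx]]
        for (try in 1:50) {
          nt[free] <- sample(c("A", "C", "G", "T"), length(free), TRUE)
          if (!paste(nt[idx], collapse = "") %in% STOP_CODONS) break
        }
      }
    }
    realized_last2 <- paste0(nt[cend[-n_ex] - 1L], nt[cend[-n_ex]])
    realized_next1 <- nt[cend[-n_ex] + 1L]
  }

  # --- enhancer planting inside the scanned codon 2..34 windows ---
  ese_rows <- NULL
  rates <- cfg$ese_rates[classes]
  if (any(rates > 0)) {
    ese_list <- list()
    for (k in seq_len(n_ex)) {
      r <- rates[k]
      if (r <= 0 || m[k] < 1L) next
      hi <- min(34L, m[k] %/% 2L)
      if (hi < 3L) next  # window shorter than one hexamer
      for (side in c("start", "end")) {
        if (side == "start") {
          a <- 3L * (c0[k] + 1L) + 1L; b <- 3L * (c0[k] + hi)
        } else {
          a <- 3L * (c0[k] + m[k] - hi) + 1L; b <- 3L * (c0[k] + m[k] - 1L)
        }
        res <- .plant_window(nt, a, b, r, rescue)
        nt <- res$nt
        ese_list[[length(ese_list) + 1L]] <- data.frame(
          gene_id = gene_id, exon_index = k, side = side,
          n_windows = res$n_windows, k_planted = res$k_planted,
          realized_matches = res$realized,
          offsets = paste(res$offsets, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    if (length(ese_list)) ese_rows <- do.call(rbind, ese_list)
  }

  cds <- paste(nt, collapse = "")
  codons_final <- split_codons(cds)
  aa_final <- translate_codons(codons_final)
  if (cfg$force_terminal_codons) {
    if (any(aa_final[-N] == "*")) stop("internal stop codon survived repair")
    protein <- paste(aa_final[-N], collapse = "")
  } else {
    if (any(aa_final == "*")) stop("unexpected stop codon")
    protein <- paste(aa_final, collapse = "")
  }

  # --- UTRs and genomic layout ---
  rand_dna <- function(n) if (n > 0L)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "") else ""
  u5 <- ""; u5_separate <- FALSE
  if (stats::runif(1) < cfg$utr5_rate) {
    u5 <- rand_dna(sample(30:200, 1L))
    u5_separate <- stats::runif(1) < cfg$utr5_exon_rate
  }
  u3 <- if (stats::runif(1) < cfg$utr3_rate) rand_dna(sample(20:150, 1L)) else ""

  strand <- sample(c("+", "-"), 1L)
  clen <- cend - cstart
  exon_lens <- clen
  if (!u5_separate && nchar(u5)) exon_lens[1L] <- exon_lens[1L] + nchar(u5)
  exon_lens[n_ex] <- exon_lens[n_ex] + nchar(u3)
  cls_mean <- cfg$intron_mean; cls_sd <- cfg$intron_sd
  n_introns <- n_ex - 1L
  intron_len <- integer(0)
  if (n_introns > 0L) {
    imean <- (cls_mean[classes[-n_ex]] + cls_mean[classes[-1L]]) / 2
    isd <- (cls_sd[classes[-n_ex]] + cls_sd[classes[-1L]]) / 2
    intron_len <- pmax(cfg$intron_min,
                       as.integer(round(stats::rnorm(n_introns, imean, isd))))
  }
  u5_intron <- if (u5_separate)
    max(cfg$intron_min,
        as.integer(round(stats::rnorm(1, cls_mean["other"], cls_sd["other"]))))
  else 0L

  cursor <- 1L
  u5_locus <- NULL
  if (u5_separate) {
    u5_locus <- c(cursor, cursor + nchar(u5) - 1L)
    cursor <- cursor + nchar(u5) + u5_intron
  }
  ex_locus <- matrix(0L, nrow = n_ex, ncol = 2L)
  for (k in seq_len(n_ex)) {
    ex_locus[k, ] <- c(cursor, cursor + exon_lens[k] - 1L)
    cursor <- cursor + exon_lens[k] + if (k < n_ex) intron_len[k] else 0L
  }
  span <- ex_locus[n_ex, 2L]
  flank <- 500L
  chrom <- paste0("chr_", gene_id)
  to_genomic <- function(a, b) {
    if (strand == "+") cbind(flank + a, flank + b)
    else cbind(flank + span - b + 1L, flank + span - a + 1L)
  }
  coding_locus <- ex_locus
  if (!u5_separate && nchar(u5)) coding_locus[1L, 1L] <- coding_locus[1L, 1L] + nchar(u5)
  coding_locus[n_ex, 2L] <- coding_locus[n_ex, 2L] - nchar(u3)

  ge <- to_genomic(ex_locus[, 1L], ex_locus[, 2L])
  gc <- to_genomic(coding_locus[, 1L], coding_locus[, 2L])
  exdf <- fast_df(
    exon_id = sprintf("%s_e%d", gene_id, seq_len(n_ex)), rank = seq_len(n_ex),
    genomic_start = ge[, 1L], genomic_end = ge[, 2L],
    coding_genomic_start = gc[, 1L], coding_genomic_end = gc[, 2L],
    coding_start_offset = cstart, coding_end_offset = cend)

  tid1 <- paste0(gene_id, "_t1")
  tx1 <- new_transcript(tid1, gene_id, chrom, strand, exdf, cds, protein,
                        utr5 = u5, utr3 = u3)
  transcripts <- list(tx1)
  tracks <- list()
  tracks[[tid1]] <- .class_track(tx1, classes)

  utr_exons <- NULL
  if (u5_separate) {
    gu <- to_genomic(u5_locus[1L], u5_locus[2L])
    utr_exons <- data.frame(
      transcript_id = tid1, gene_id = gene_id, chrom = chrom, strand = strand,
      start = gu[1L, 1L], end = gu[1L, 2L], exon_id = paste0(gene_id, "_u5"),
      before_coding = TRUE, stringsAsFactors = FALSE)
  }

  # --- alternative transcript by frame-preserving exon skipping ---
  skipped <- NA_integer_
  if (n_ex >= 3L && stats::runif(1) < cfg$alt_rate) {
    cand <- which(cstart %% 3L == 0L & cend %% 3L == 0L)
    cand <- cand[cand > 1L & cand < n_ex]
    if (length(cand)) {
      skipped <- if (length(cand) == 1L) cand else sample(cand, 1L)
      keep <- setdiff(seq_len(n_ex), skipped)
      ex2 <- exdf[keep, , drop = FALSE]
      w <- clen[keep]
      ends2 <- cumsum(w)
      ex2$coding_start_offset <- c(0L, ends2[-length(w)])
      ex2$coding_end_offset <- ends2
      ex2$rank <- seq_along(keep)
      rownames(ex2) <- NULL
      cds2 <- paste(vapply(keep, function(k)
        substr(cds, cstart[k] + 1L, cend[k]), ""), collapse = "")
      protein2 <- translate_cds(cds2)
      tid2 <- paste0(gene_id, "_t2")
      tx2 <- new_transcript(tid2, gene_id, chrom, strand, ex2, cds2, protein2,
                            utr5 = u5, utr3 = u3)
      transcripts[[2L]] <- tx2
      tracks[[tid2]] <- .class_track(tx2, classes[keep])
      if (u5_separate) {
        u2 <- utr_exons[1L, ]; u2$transcript_id <- tid2
        utr_exons <- rbind(utr_exons, u2)
      }
    }
  }

  status <- rep("constituent", n_ex)
  if (!is.na(skipped)) status[skipped] <- "alternative"
  truth <- fast_df(
    genome_id = rep(cfg$genome_id, n_ex), gene_id = rep(gene_id, n_ex),
    transcript_id = rep(tid1, n_ex),
    exon_id = exdf$exon_id, rank = seq_len(n_ex), class = classes,
    status = status,
    junction_forced = c(junction_forced, NA),
    realized_last2 = c(realized_last2, NA_character_),
    realized_next1 = c(realized_next1, NA_character_))
  if (!is.null(ese_rows)) {
    ese_rows$exon_id <- exdf$exon_id[ese_rows$exon_index]
    ese_rows$class <- classes[ese_rows$exon_index]
  }

  list(transcripts = transcripts, tracks = tracks, truth = truth,
       truth_ese = ese_rows, utr_exons = utr_exons,
       # layout spec; the chromosome sequence itself is built lazily at
       # write time (intron/flank fill is not needed in-memory)
       locus = list(chrom = chrom, strand = strand, span = span,
                    flank = flank, transcript_id = tid1,
                    u5_separate = u5_separate, u5_intron = u5_intron,
                    intron_len = intron_len))
}

# Rebuild one chromosome's sequence from its layout spec and the primary
# transcript: exon sequences (with UTR flanks) interleaved with GT..AG
# introns (splice-site dinucleotides only; no branch-point or
# polypyrimidine model), reverse-complemented for minus-strand genes.
.build_chrom_seq <- function(locus, txs) {
  tx <- txs[[locus$transcript_id]]
  ex <- tx$exons
  n_ex <- nrow(ex)
  rand_dna <- function(n) if (n > 0L)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "") else ""
  intron_seq <- function(len) paste0("GT", rand_dna(len - 4L), "AG")
  pieces <- character(0)
  if (locus$u5_separate) {
    pieces <- c(tx$utr5, intron_seq(locus$u5_intron))
  }
  for (k in seq_len(n_ex)) {
    s <- substr(tx$cds, ex$coding_start_offset[k] + 1L, ex$coding_end_offset[k])
    if (k == 1L && !locus$u5_separate && nchar(tx$utr5)) s <- paste0(tx$utr5, s)
    if (k == n_ex) s <- paste0(s, tx$utr3)
    pieces <- c(pieces, s, if (k < n_ex) intron_seq(locus$intron_len[k]) else NULL)
  }
  locus_seq <- paste(pieces, collapse = "")
  stopifnot(nchar(locus_seq) == locus$span)
  paste0(rand_dna(locus$flank),
         if (locus$strand == "+") locus_seq else revcomp(locus_seq),
         rand_dna(locus$flank))
}

# exon-aligned disorder/domain track for one transcript
.class_track <- function(tx, classes) {
  ph <- compute_phases(tx)
  n <- nchar(tx$protein)
  cls <- rep(NA_character_, n)
  for (i in seq_len(nrow(ph))) {
    if (ph$res_end[i] > ph$res_start[i]) {
      cls[(ph$res_start[i] + 1L):ph$res_end[i]] <- classes[i]
    }
  }
  cls[is.na(cls)] <- "other"
  list(length = n, disorder = cls == "disordered", domain = cls == "structured")
}

# Plant hexamer motifs in the CDS window nt[a..b] (1-based, codon-aligned)
# at a target per-window match rate r, and scrub incidental background
# matches so the realised rate equals the planted one. Tiles are the
# non-overlapping codon-pair slots of the window; the planted count is the
# stochastic rounding of r * n_windows (capped by the tile count).
# Matching here is plain substring hashing, independent of the
# Biostrings-based scanner the analysis side uses.
.plant_window <- function(nt, a, b, r, rescue) {
  Lw <- b - a + 1L
  nw <- Lw - 5L
  if (nw < 1L) {
    return(list(nt = nt, n_windows = max(nw, 0L), k_planted = 0L,
                realized = 0L, offsets = integer(0)))
  }
  n_tiles <- Lw %/% 6L
  k_exact <- nw * r
  k <- as.integer(floor(k_exact)) + (stats::runif(1) < (k_exact - floor(k_exact)))
  k <- min(k, n_tiles)
  tiles <- if (k > 0L) sort(sample.int(n_tiles, k) - 1L) else integer(0)

  draw_motif <- function() {
    for (try in 1:50) {
      mo <- sample(rescue, 1L)
      if (!substr(mo, 1L, 3L) %in% STOP_CODONS &&
          !substr(mo, 4L, 6L) %in% STOP_CODONS) return(mo)
    }
    NA_character_
  }
  write6 <- function(nt, off, mo) {
    nt[(a + off):(a + off + 5L)] <- strsplit(mo, "")[[1L]]
    nt
  }
  kept <- logical(length(tiles))
  for (t in seq_along(tiles)) {
    mo <- draw_motif()
    if (is.na(mo)) next
    nt <- write6(nt, 6L * tiles[t], mo)
    kept[t] <- TRUE
  }
  planted_offsets <- 6L * tiles[kept]
  planted_codons <- sort(c(2L * tiles[kept], 2L * tiles[kept] + 1L))
  k <- sum(kept)

  realized <- k
  for (iter in 1:40) {
    win <- paste(nt[a:b], collapse = "")
    sub6 <- substring(win, seq_len(nw), seq_len(nw) + 5L)
    starts <- which(sub6 %in% rescue) - 1L  # 0-based window offsets
    extra <- setdiff(starts, planted_offsets)
    realized <- length(starts)
    if (!length(extra)) break
    e <- extra[1L]
    cods <- (e %/% 3L):((e + 5L) %/% 3L)  # 0-based window codons touched
    free <- setdiff(cods, planted_codons)
    free <- free[free < Lw %/% 3L]
    if (length(free)) {
      fc <- free[sample.int(length(free), 1L)]
      newc <- sample(SENSE_CODONS, 1L)
      nt[(a + 3L * fc):(a + 3L * fc + 2L)] <- strsplit(newc, "")[[1L]]
    } else {
      # match lies entirely within planted motifs; redraw one of them
      hit <- which(planted_offsets %in% (6L * (cods %/% 2L)))
      if (!length(hit)) break
      mo <- draw_motif()
      if (is.na(mo)) break
      nt <- write6(nt, planted_offsets[hit[1L]], mo)
    }
  }
  list(nt = nt, n_windows = nw, k_planted = k, realized = realized,
       offsets = planted_offsets)
}

#' Write a genome bundle to disk
#'
#' Emits exactly the formats the readers consume: `genes.gtf`, `genome.fa`,
#' `cdna.fa`, `protein.fa`, `tracks.tsv`, `motifs_rescue.txt`,
#' `motifs_int3.txt`, `truth_exons.tsv`, `truth_ese.tsv`, `config.yaml`.
#'
#' @param bundle A `jx_genome_bundle`.
#' @param dir Output directory.
#' @return Invisibly, named vector of file paths.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_gene_models(bundle$transcripts, dir,
                             utr_exons = bundle$utr_exons)
  # chromosome sequences: exon sequences are fixed by the transcripts;
  # intron/flank fill is drawn under a seed derived from the config seed
  # (global RNG state is preserved), so writes are reproducible
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed((bundle$config$seed + 77003L) %% .Machine$integer.max)
  genome <- Biostrings::DNAStringSet(vapply(names(bundle$loci), function(ch) {
    .build_chrom_seq(bundle$loci[[ch]], bundle$transcripts)
  }, ""))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  genome_fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_fa, width = 70L)
  tracks_tsv <- file.path(dir, "tracks.tsv")
  write_residue_tracks(bundle$tracks, tracks_tsv)
  rescue_txt <- file.path(dir, "motifs_rescue.txt")
  int3_txt <- file.path(dir, "motifs_int3.txt")
  write_motifs(bundle$motifs$rescue, rescue_txt)
  write_motifs(bundle$motifs$int3, int3_txt)
  truth_tsv <- file.path(dir, "truth_exons.tsv")
  utils::write.table(bundle$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ese_tsv <- file.path(dir, "truth_ese.tsv")
  if (!is.null(bundle$truth_ese)) {
    utils::write.table(bundle$truth_ese, ese_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cfg_yaml <- file.path(dir, "config.yaml")
  cfg <- bundle$config
  cfg_plain <- lapply(unclass(cfg), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(cfg_plain, cfg_yaml)
  invisible(c(paths, genome = genome_fa, tracks = tracks_tsv,
              motifs_rescue = rescue_txt, motifs_int3 = int3_txt,
              truth = truth_tsv, truth_ese = ese_tsv, config = cfg_yaml))
}

#' Generate and write a synthetic genome in one step
#'
#' @param config A `jx_gen_config`.
#' @param dir Output directory.
#' @return The bundle, invisibly; files are written to `dir`.
#' @export
generate <- function(config, dir) {
  bundle <- generate_genome(config)
  write_genome_bundle(bundle, dir)
  invisible(bundle)
}

#' Inject filter-rule defects into transcripts
#'
#' Each transcript receives at most one defect: a mutated start codon, a
#' destroyed stop codon, a premature internal stop, one uncertain base, or
#' one inserted nucleotide that throws the CDS length off a multiple of 3
#' (placed so that the length rule — not an earlier rule — is the first to
#' fail). The injected truth is returned so filter output can be compared
#' label-for-label.
#'
#' @param txs A `jx_transcript_set`.
#' @param rates Named defect rates (`no_start`, `no_stop`, `premature_stop`,
#'   `uncertain_base`, `length_not_multiple_of_3`); remaining probability
#'   mass leaves a transcript clean.
#' @param assign Optional named character vector transcript id -> defect
#'   (overrides random assignment; use `"none"` to force clean).
#' @return List: `transcripts` (modified set), `truth` (data frame
#'   `transcript_id`, `defect`).
#' @export
corrupt_for_filters <- function(txs,
                                rates = c(no_start = 0.05, no_stop = 0.05,
                                          premature_stop = 0.05,
                                          uncertain_base = 0.05,
                                          length_not_multiple_of_3 = 0.05),
                                assign = NULL) {
  stopifnot(all(names(rates) %in% FILTER_RULES))
  if (sum(rates) > 1) stop("defect rates sum above 1")
  defects <- character(length(txs))
  for (i in seq_along(txs)) {
    tid <- names(txs)[i]
    if (!is.null(assign) && tid %in% names(assign)) {
      defects[i] <- assign[[tid]]
    } else {
      defects[i] <- sample(c(names(rates), "none"), 1L,
                           prob = c(rates, 1 - sum(rates)))
    }
  }
  out <- unclass(txs)
  for (i in seq_along(out)) {
    if (defects[i] == "none") next
    out[[i]] <- .inject_defect(out[[i]], defects[i])
  }
  list(transcripts = transcript_set(out),
       truth = data.frame(transcript_id = names(txs), defect = defects,
                          stringsAsFactors = FALSE))
}

.inject_defect <- function(tx, defect) {
  cds <- tx$cds
  n <- nchar(cds)
  N <- n %/% 3L
  if (defect == "no_start") {
    substr(cds, 1L, 3L) <- "CTG"
  } else if (defect == "no_stop") {
    substr(cds, n - 2L, n) <- "GCC"
  } else if (defect == "premature_stop") {
    j <- max(2L, N %/% 2L)
    substr(cds, 3L * (j - 1L) + 1L, 3L * j) <- "TAA"
  } else if (defect == "uncertain_base") {
    p <- 3L * max(1L, N %/% 2L - 1L) + 2L
    substr(cds, p, p) <- "N"
  } else if (defect == "length_not_multiple_of_3") {
    # insert a non-T base just before the stop codon: start/stop/premature
    # checks still pass, so the length rule is the first to fail
    cds <- paste0(substr(cds, 1L, n - 3L), "C", substr(cds, n - 2L, n))
    last <- nrow(tx$exons)
    tx$exons$coding_end_offset[last] <- tx$exons$coding_end_offset[last] + 1L
    if (tx$strand == "+") {
      tx$exons$coding_genomic_end[last] <- tx$exons$coding_genomic_end[last] + 1L
      tx$exons$genomic_end[last] <- tx$exons$genomic_end[last] + 1L
    } else {
      tx$exons$coding_genomic_start[last] <- tx$exons$coding_genomic_start[last] - 1L
      tx$exons$genomic_start[last] <- tx$exons$genomic_start[last] - 1L
    }
  } else {
    stop("unknown defect: ", defect)
  }
  tx$cds <- cds
  tx
}
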
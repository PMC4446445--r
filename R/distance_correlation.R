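# Correlation of amino-acid usage with distance from splice junctions
# (codon positions 2-34 from each exon edge), with the upstream filtering
# rules: transcripts must begin with a start codon, end with a stop codon,
# contain no premature stop, no uncertain base, and have length a multiple
# of three; each protein's first and last exons are discarded; incomplete
# codons at exon edges are trimmed.

FILTER_RULES <- c("no_start", "no_stop", "premature_stop",
                  "uncertain_base", "length_not_multiple_of_3")

.first_failing_rule <- function(cds) {
  n <- nchar(cds)
  if (n < 6L) return("no_start")
  if (substr(cds, 1L, 3L) != "ATG") return("no_start")
  k <- n %/% 3L
  last_full <- substr(cds, 3L * (k - 1L) + 1L, 3L * k)
  # "ends with a stop codon" read on the final in-frame codon
  if (n %% 3L == 0L && !last_full %in% STOP_CODONS) return("no_stop")
  if (n %% 3L != 0L && !substr(cds, n - 2L, n) %in% STOP_CODONS) return("no_stop")
  if (k > 1L) {
    internal <- substring(cds, 3L * (seq_len(k - 1L) - 1L) + 1L,
                          3L * seq_len(k - 1L))
    if (any(internal %in% STOP_CODONS)) return("premature_stop")
  }
  if (grepl("[^ACGT]", cds)) return("uncertain_base")
  if (n %% 3L != 0L) return("length_not_multiple_of_3")
  NA_character_
}

#' Filter transcripts and exons for the distance-correlation analysis
#'
#' Applies, in order: start-codon, stop-codon, premature-stop,
#' uncertain-base and length-multiple-of-3 checks on the CDS (the first
#' failing rule is recorded per transcript); then discards the first and
#' last exon of each surviving protein; then trims incomplete codons from
#' each retained exon (an exon with start phase s sheds its leading 3-s
#' nucleotides, one with end phase e its trailing e nucleotides — exactly
#' the nucleotides of codons shared with neighbouring exons).
#'
#' @param txs A `jx_transcript_set`.
#' @return List of class `jx_filter`: `exons` (data frame of retained
#'   internal exons: `transcript_id`, `gene_id`, `exon_id`, `rank`,
#'   `start_phase`, `end_phase`, `nt_trimmed_lead`, `nt_trimmed_trail`,
#'   `n_codons`, `codons` — the exon's complete codons as one string),
#'   `report` (per transcript: `pass`, `first_fail`), `n_input`,
#'   `n_retained_transcripts`, `n_retained_exons`.
#' @export
filter_for_correlation <- function(txs) {
  fails <- vapply(txs, function(tx) .first_failing_rule(tx$cds), "")
  report <- data.frame(
    transcript_id = names(txs),
    pass = is.na(fails),
    first_fail = unname(fails),
    stringsAsFactors = FALSE)
  parts <- lapply(which(report$pass), function(i) {
    tx <- txs[[i]]
    ex <- tx$exons
    n <- nrow(ex)
    if (n < 3L) return(NULL)  # dropping first and last exon leaves nothing
    r <- 2L:(n - 1L)
    cstart <- ex$coding_start_offset[r]
    cend <- ex$coding_end_offset[r]
    c0 <- as.integer(ceiling(cstart / 3))
    c1 <- cend %/% 3L
    m <- c1 - c0
    keep <- m >= 1L
    if (!any(keep)) return(NULL)
    list(transcript_id = rep(tx$transcript_id, sum(keep)),
         gene_id = rep(tx$gene_id, sum(keep)),
         exon_id = ex$exon_id[r][keep], rank = r[keep],
         start_phase = (cstart %% 3L)[keep], end_phase = (cend %% 3L)[keep],
         n_codons = m[keep],
         codons = substring(tx$cds, 3L * c0[keep] + 1L, 3L * c1[keep]))
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  exons <- if (length(parts)) {
    cols <- names(parts[[1L]])
    df <- lapply(cols, function(cl) unlist(lapply(parts, `[[`, cl), use.names = FALSE))
    names(df) <- cols
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df$nt_trimmed_lead <- (3L - df$start_phase) %% 3L
    df$nt_trimmed_trail <- df$end_phase
    df
  } else {
    data.frame(transcript_id = character(0), gene_id = character(0),
               exon_id = character(0), rank = integer(0),
               start_phase = integer(0), end_phase = integer(0),
               n_codons = integer(0), codons = character(0),
               nt_trimmed_lead = integer(0), nt_trimmed_trail = integer(0))
  }
  structure(list(exons = exons, report = report,
                 n_input = length(txs),
                 n_retained_transcripts = sum(report$pass),
                 n_retained_exons = nrow(exons)),
            class = "jx_filter")
}

#' @export
print.jx_filter <- function(x, ...) {
  cat(sprintf("<jx_filter> %d/%d transcripts pass; %d internal exons retained\n",
              x$n_retained_transcripts, x$n_input, x$n_retained_exons))
  if (any(!x$report$pass)) {
    print(table(x$report$first_fail[!x$report$pass]))
  }
  invisible(x)
}

#' Positional amino-acid composition near splice junctions
#'
#' Counts amino-acid usage at codon distances `d_min`..`d_max` (default
#' 2..34) from the chosen exon edge, pooled over all retained exons. The
#' junction codon itself (d = 1) is excluded. Codons of short exons are
#' assigned to their nearer edge only (midpoint ties to neither side), so
#' no residue contributes to both the start-side and end-side composition
#' of the same exon.
#'
#' @param fexons Retained-exon table (`$exons` of [filter_for_correlation()]),
#'   optionally pre-subset to a stratum (class, phase, genome...).
#' @param side `"start"` or `"end"`.
#' @param d_min,d_max Distance window in codons (defaults 2 and 34).
#' @return List of class `jx_positional`: `counts` and `fractions`
#'   (amino acid x distance matrices; fractions normalised within each
#'   distance), `side`, `d`, `available` (TRUE when every distance in the
#'   window is populated).
#' @export
positional_composition <- function(fexons, side = c("start", "end"),
                                   d_min = 2L, d_max = 34L) {
  side <- match.arg(side)
  dd <- d_min:d_max
  empty <- matrix(0, nrow = length(AA_ORDER), ncol = length(dd),
                  dimnames = list(AA_ORDER, dd))
  if (!nrow(fexons)) {
    return(structure(list(counts = empty, fractions = empty, side = side,
                          d = dd, available = FALSE),
                     class = "jx_positional"))
  }
  m <- fexons$n_codons
  codons <- split_codons(paste(fexons$codons, collapse = ""))
  i <- sequence(m)
  mrep <- rep.int(m, m)
  d_start <- i
  d_end <- mrep + 1L - i
  if (side == "start") {
    keep <- d_start < d_end & d_start >= d_min & d_start <= d_max
    d <- d_start[keep]
  } else {
    keep <- d_end < d_start & d_end >= d_min & d_end <= d_max
    d <- d_end[keep]
  }
  aa <- translate_codons(codons[keep])
  ok <- aa %in% AA_ORDER
  counts <- table(factor(aa[ok], levels = AA_ORDER),
                  factor(d[ok], levels = dd))
  counts <- matrix(as.numeric(counts), nrow = length(AA_ORDER),
                   dimnames = list(AA_ORDER, dd))
  totals <- colSums(counts)
  fractions <- sweep(counts, 2L, pmax(totals, 1), "/")
  structure(list(counts = counts, fractions = fractions, side = side,
                 d = dd, available = all(totals > 0)),
            class = "jx_positional")
}

# Spearman rho with two-sided p from the large-sample t approximation.
.spearman_rho_p <- function(x, y) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(c(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Spearman correlation profile of usage vs distance
#'
#' For each amino acid, Spearman's rank correlation between codon distance
#' from the splice junction and the amino acid's fraction of usage at that
#' distance, over the 33 positions of the window. p-values use the
#' two-sided large-sample t approximation; significance is declared at
#' p <= `alpha` (default 0.001). A constant fraction vector has undefined
#' rho and is reported as not significant.
#'
#' @param pos A `jx_positional` from [positional_composition()].
#' @param alpha Significance level (default 0.001).
#' @return Data frame (class `jx_profile`): `amino_acid`, `rho`, `p`,
#'   `significant`, plus attributes `side` and `n` (window length). If the
#'   window is not fully populated (`available = FALSE`) all values are NA.
#' @export
spearman_profile <- function(pos, alpha = 0.001) {
  stopifnot(inherits(pos, "jx_positional"))
  n <- length(pos$d)
  if (!pos$available) {
    df <- data.frame(amino_acid = AA_ORDER, rho = NA_real_, p = NA_real_,
                     significant = FALSE, stringsAsFactors = FALSE)
  } else {
    rp <- t(vapply(AA_ORDER, function(a) {
      .spearman_rho_p(pos$d, pos$fractions[a, ])
    }, c(rho = 0, p = 0)))
    df <- data.frame(amino_acid = AA_ORDER, rho = rp[, "rho"], p = rp[, "p"],
                     significant = !is.na(rp[, "p"]) & rp[, "p"] <= alpha,
                     stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  attr(df, "side") <- pos$side
  attr(df, "n") <- n
  class(df) <- c("jx_profile", "data.frame")
  df
}

#' Pool per-genome correlation profiles by taxonomic group
#'
#' @param profiles Named list (genome id -> profile data frame from
#'   [spearman_profile()], or any data frame with `amino_acid` and `rho`).
#' @param group_map Named character vector genome id -> group label
#'   (see [read_group_map()]). Genomes absent from the map are skipped
#'   with a warning.
#' @return List: `values` (long data frame genome/group/amino_acid/rho) and
#'   `summary` (per group x amino acid: n, median and quartiles of rho).
#' @export
group_profiles <- function(profiles, group_map) {
  known <- names(profiles) %in% names(group_map)
  if (any(!known)) {
    warning("genomes missing from group map, skipped: ",
            paste(names(profiles)[!known], collapse = ", "))
  }
  profiles <- profiles[known]
  if (!length(profiles)) stop("no genomes left after group-map matching")
  vals <- do.call(rbind, lapply(names(profiles), function(g) {
    p <- profiles[[g]]
    data.frame(genome_id = g, group = unname(group_map[g]),
               amino_acid = p$amino_acid, rho = p$rho,
               stringsAsFactors = FALSE)
  }))
  rownames(vals) <- NULL
  spl <- split(vals$rho, list(vals$group, vals$amino_acid), sep = ":")
  summ <- do.call(rbind, lapply(names(spl), function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1L]]
    r <- spl[[k]][!is.na(spl[[k]])]
    data.frame(group = parts[1L], amino_acid = parts[2L], n = length(r),
               median_rho = if (length(r)) stats::median(r) else NA_real_,
               q25 = if (length(r)) unname(stats::quantile(r, 0.25)) else NA_real_,
               q75 = if (length(r)) unname(stats::quantile(r, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(values = vals, summary = summ)
}
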
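# Genetic-code tables, amino-acid constants and small sequence utilities
# shared across the package. All coordinates in this package follow one
# dialect: genomic coordinates are 1-based inclusive (GTF), everything
# internal (CDS offsets, residue spans) is 0-based half-open.

STOP_CODONS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- as.character(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3))

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' TOP-IDP disorder propensity scale
#'
#' Per-amino-acid intrinsic disorder propensities on the TOP-IDP scale,
#' ordered from most to least disorder-promoting. Positive values indicate
#' disorder-promoting residues (Proline, Glutamic acid, Lysine, ...), strongly
#' negative values order-promoting ones (Tryptophan, Phenylalanine, ...).
#'
#' @return Named numeric vector of length 20 (1-letter amino-acid codes),
#'   sorted by decreasing disorder propensity.
#' @examples
#' head(top_idp_scale(), 3)
#' @export
top_idp_scale <- function() {
  c(P =  0.987, E =  0.736, K =  0.586, S =  0.341, Q =  0.318,
    H =  0.303, D =  0.192, R =  0.180, G =  0.166, A =  0.060,
    T =  0.059, N =  0.007, C = -0.020, V = -0.121, L = -0.326,
    M = -0.397, I = -0.486, Y = -0.510, F = -0.697, W = -0.884)
}

# Canonical amino-acid ordering used for all composition tables and reports:
# most to least disorder-promoting, matching the figure layout convention.
AA_ORDER <- names(top_idp_scale())

#' Split the 20 amino acids into disorder- and order-promoting halves
#'
#' @param scale Named numeric disorder-propensity scale over the 20 standard
#'   amino acids; defaults to [top_idp_scale()]. Alternative published
#'   orderings can be supplied to check robustness.
#' @return List with `top10` (ten most disorder-promoting) and `bottom10`
#'   (ten least) character vectors.
#' @export
disorder_sets <- function(scale = top_idp_scale()) {
  if (length(scale) != 20L || is.null(names(scale)) ||
      !setequal(names(scale), AA_ORDER)) {
    stop("`scale` must be a named numeric vector over the 20 standard amino acids")
  }
  ord <- names(sort(scale, decreasing = TRUE))
  list(top10 = ord[1:10], bottom10 = ord[11:20])
}

# codon -> amino acid lookup; names are DNA codons, values 1-letter codes,
# "*" for stop.
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}
CODON_AA <- NULL  # filled in .onLoad to avoid load-order surprises

.get_codon_aa <- function() {
  if (is.null(CODON_AA)) .codon_table() else CODON_AA
}

# codon -> its three letters, precomputed for fast CDS assembly
CODON_LETTERS <- NULL

.onLoad <- function(libname, pkgname) {
  ns <- asNamespace(pkgname)
  assign("CODON_AA", .codon_table(), envir = ns)
  letters3 <- strsplit(ALL_CODONS, "", fixed = TRUE)
  names(letters3) <- ALL_CODONS
  assign("CODON_LETTERS", letters3, envir = ns)
  invisible()
}

#' Translate a vector of codons
#'
#' Codons containing any non-ACGT character (e.g. `N`) translate to `"X"`;
#' stop codons translate to `"*"`. Composition counts downstream ignore both.
#'
#' @param codons Character vector of DNA 3-mers.
#' @return Character vector of 1-letter amino-acid codes.
#' @export
translate_codons <- function(codons) {
  aa <- unname(.get_codon_aa()[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a CDS string
#'
#' @param cds DNA string whose length is a multiple of 3. A terminal stop
#'   codon, if present, is dropped from the returned protein.
#' @return Protein string (1-letter codes; `X` for codons with uncertain bases).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- translate_codons(codons)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}

# reverse complement for plain character vectors (N preserved)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a concatenation of codons into 3-mers
split_codons <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# data.frame constructor without coercion/checking overhead; columns must
# be equal-length atomic vectors (hot generator paths only)
fast_df <- function(...) {
  l <- list(...)
  structure(l, class = "data.frame",
            row.names = c(NA_integer_, -length(l[[1L]])))
}

jx_msg <- function(..., verbose = getOption("junctionscape.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[junctionscape] ", ...)
  invisible()
}
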
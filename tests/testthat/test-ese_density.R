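test_that("hexamer scanning counts overlapping matches and skips N windows", {
  m <- motif_set("GAAGAA")
  expect_equal(scan_exon("GAAGAAGAA", m),
               c(n_windows = 4, n_matches = 2))  # offsets 0 and 3 match
  expect_equal(scan_exon("GAAGAAGAA", motif_set(character(0))),
               c(n_windows = 4, n_matches = 0))
  expect_equal(scan_exon("GAAGA", m), c(n_windows = 0, n_matches = 0))
  # one N knocks out every window overlapping it
  expect_equal(scan_exon("GAANAAGAA", m), c(n_windows = 0, n_matches = 0))
  expect_equal(scan_exon("GAAGAAGAAN", m),
               c(n_windows = 4, n_matches = 2))
})

test_that("scan counts equal the brute-force substring oracle on fuzzed inputs", {
  set.seed(40)
  motifs <- motif_set(unique(vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""), ""))[1:25])
  alph <- c("A", "C", "G", "T", "N")
  seqs <- vapply(1:500, function(i) {
    paste(sample(alph, sample(1:45, 1L), TRUE, prob = c(rep(0.245, 4), 0.02)),
          collapse = "")
  }, "")
  got <- scan_windows(seqs, motifs)
  want <- t(vapply(seqs, oracle_scan, c(n_windows = 0L, n_matches = 0L),
                   motifs = as.character(motifs)))
  expect_equal(got$n_windows, unname(want[, "n_windows"]))
  expect_equal(got$n_matches, unname(want[, "n_matches"]))
})

test_that("windows never cross the junction codon, the far boundary, or sides", {
  set.seed(41)
  b <- generate_genome(lean_config(n_genes = 15, seed = 41))
  fl <- filter_for_correlation(b$transcripts)
  win <- junction_windows(fl$exons)
  fx <- fl$exons[match(paste(win$transcript_id, win$exon_id),
                       paste(fl$exons$transcript_id, fl$exons$exon_id)), ]
  hi <- pmin(34L, fx$n_codons %/% 2L)
  expect_true(all(win$width == 3L * (hi - 1L)))
  st <- win$side == "start"
  expect_equal(win$seq[st], substr(fx$codons[st], 4L, 3L * hi[st]))
  en <- !st
  expect_equal(win$seq[en],
               substr(fx$codons[en], 3L * (fx$n_codons[en] - hi[en]) + 1L,
                      3L * (fx$n_codons[en] - 1L)))
})

test_that("density is invariant to exon order and monotone in the motif set", {
  set.seed(42)
  b <- generate_genome(gen_config(n_genes = 20, seed = 42, alt_rate = 0))
  fl <- filter_for_correlation(b$transcripts)
  win <- junction_windows(fl$exons)
  cls <- classify_exons(b$transcripts, b$tracks)
  d1 <- ese_density(win, cls, b$motifs$rescue)
  d2 <- ese_density(win[sample(nrow(win)), ], cls, b$motifs$rescue)
  expect_equal(d1$density[d1$density$category == "all", ],
               d2$density[d2$density$category == "all", ],
               ignore_attr = TRUE)
  # INT3-like subset can only match fewer windows on identical sequences
  d3 <- ese_density(win, cls, b$motifs$int3)
  expect_true(all(d3$density$n_matches <= d1$density$n_matches))
})

test_that("uniform random DNA matches the i.i.d. expectation for a motif set", {
  set.seed(43)
  motifs <- synthetic_motif_set(100)
  seqs <- vapply(1:12000, function(i)
    paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = ""), "")
  sc <- scan_windows(seqs, motifs)
  nw <- sum(sc$n_windows)
  expect_gt(nw, 1e6 - 1)
  p <- length(motifs) / 4^6
  phat <- sum(sc$n_matches) / nw
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nw) + 2e-4)
})

test_that("planted equal enhancer rates give a null class comparison", {
  cfg <- gen_config(n_genes = 60, seed = 44,
                    ese_rates = c(structured = 0.12, disordered = 0.12,
                                  other = 0.12),
                    gradient_slopes = numeric(0), alt_rate = 0,
                    utr5_rate = 0, utr3_rate = 0)
  b <- generate_genome(cfg)
  fl <- filter_for_correlation(b$transcripts)
  win <- junction_windows(fl$exons)
  cls <- classify_exons(b$transcripts, b$tracks)
  de <- ese_density(win, cls, b$motifs$rescue)
  expect_gt(de$tests$p_value, 0.001)
  expect_lt(abs(de$tests$density_structured_pct -
                de$tests$density_disordered_pct), 1)
})

test_that("Welch comparison flags shorter introns around disorder-encoding exons", {
  b <- generate_genome(gen_config(n_genes = 80, seed = 45, alt_rate = 0))
  cls <- classify_exons(b$transcripts, b$tracks)
  it <- flanking_intron_comparison(b$transcripts, cls)
  expect_gt(it$statistic, 0)  # structured minus disordered
  expect_lt(it$p_value, 1e-4)
  expect_gt(it$means["structured"], it$means["disordered"])
})

test_that("identical intron samples give t = 0 and p = 1", {
  set.seed(46)
  # both classes see the same multiset of mean flanking intron lengths
  ivals <- c(100L, 150L, 100L, 150L)
  classes <- c("structured", "structured", "disordered", "disordered")
  txs <- lapply(1:4, function(i) {
    tx <- make_tx(c(9L, 12L, 9L), transcript_id = paste0("t", i),
                  gene_id = paste0("g", i))
    lens <- tx$exons$genomic_end - tx$exons$genomic_start + 1L
    gs <- c(1000L,
            1000L + lens[1L] + ivals[i],
            1000L + lens[1L] + ivals[i] + lens[2L] + ivals[i])
    tx$exons$genomic_start <- gs
    tx$exons$genomic_end <- gs + lens - 1L
    tx$exons$coding_genomic_start <- gs
    tx$exons$coding_genomic_end <- gs + lens - 1L
    tx
  })
  cls <- data.frame(transcript_id = paste0("t", 1:4),
                    exon_id = paste0("t", 1:4, "_e2"),
                    category = classes, stringsAsFactors = FALSE)
  it <- flanking_intron_comparison(transcript_set(txs), cls)
  expect_equal(unname(it$statistic), 0)
  expect_equal(unname(it$p_value), 1)
})
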
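test_that("each filter rule fires in the stated order on constructed defects", {
  set.seed(30)
  clean1 <- make_tx(c(9L, 12L, 9L), transcript_id = "ok1")
  clean2 <- make_tx(c(9L, 9L, 12L), transcript_id = "ok2")
  no_start <- make_tx(c(9L, 9L), transcript_id = "d1")
  substr(no_start$cds, 1, 3) <- "CTG"
  with_stop <- make_tx(c(9L, 9L), transcript_id = "d2")
  substr(with_stop$cds, 7, 9) <- "TAA"  # internal stop
  with_n <- make_tx(c(9L, 9L), transcript_id = "d3")
  substr(with_n$cds, 8, 8) <- "N"
  # off-frame: 10 coding nt in exon 2 (total 19, not a multiple of 3), but
  # still ATG..stop at the string edges
  off <- make_tx(c(9L, 9L), transcript_id = "d4")
  off$cds <- paste0(substr(off$cds, 1, 15), "C", substr(off$cds, 16, 18))
  off$exons$coding_end_offset[2] <- 19L
  off$exons$genomic_end[2] <- off$exons$genomic_end[2] + 1L
  off$exons$coding_genomic_end[2] <- off$exons$coding_genomic_end[2] + 1L

  fl <- filter_for_correlation(transcript_set(
    list(clean1, clean2, no_start, with_stop, with_n, off)))
  rep <- fl$report
  expect_equal(sum(rep$pass), 2L)
  expect_equal(rep$first_fail[rep$transcript_id == "d1"], "no_start")
  expect_equal(rep$first_fail[rep$transcript_id == "d2"], "premature_stop")
  expect_equal(rep$first_fail[rep$transcript_id == "d3"], "uncertain_base")
  expect_equal(rep$first_fail[rep$transcript_id == "d4"],
               "length_not_multiple_of_3")
  # first and last exons discarded: each clean 3-exon transcript
  # contributes only its middle exon
  expect_equal(nrow(fl$exons), 2L)
  expect_true(all(fl$exons$rank == 2L))
})

test_that("incomplete codons are trimmed to the exon's complete codons", {
  set.seed(31)
  tx <- make_tx(c(7L, 11L, 6L))  # middle exon: offsets [7,18), phases 1 -> 0
  fl <- filter_for_correlation(transcript_set(list(tx)))
  ex <- fl$exons
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$start_phase, 1L)
  expect_equal(ex$end_phase, 0L)
  expect_equal(ex$nt_trimmed_lead, 2L)
  expect_equal(ex$nt_trimmed_trail, 0L)
  expect_equal(ex$n_codons, 3L)          # 11 nt -> 9 nt of complete codons
  expect_equal(ex$codons, substr(tx$cds, 10L, 18L))
  expect_equal(nchar(ex$codons) %% 3L, 0L)
})

test_that("positional composition assigns codons to the nearer edge only", {
  set.seed(32)
  # one long exon: 70 complete codons; both sides fully populated at 2..34
  tx <- make_tx(c(9L, 210L, 9L))
  fl <- filter_for_correlation(transcript_set(list(tx)))
  ps <- positional_composition(fl$exons, side = "start")
  pe <- positional_composition(fl$exons, side = "end")
  expect_true(ps$available && pe$available)
  expect_true(all(colSums(ps$counts) == 1))
  expect_true(all(colSums(pe$counts) == 1))

  # 40 codons: start side gets d 2..20, end side d 2..20; nothing beyond
  tx2 <- make_tx(c(9L, 120L, 9L))
  fl2 <- filter_for_correlation(transcript_set(list(tx2)))
  ps2 <- positional_composition(fl2$exons, side = "start")
  expect_false(ps2$available)
  expect_true(all(colSums(ps2$counts)[as.character(2:20)] == 1))
  expect_true(all(colSums(ps2$counts)[as.character(21:34)] == 0))

  # 41 codons: midpoint codon 21 belongs to neither side
  tx3 <- make_tx(c(9L, 123L, 9L))
  fl3 <- filter_for_correlation(transcript_set(list(tx3)))
  ps3 <- positional_composition(fl3$exons, side = "start")
  pe3 <- positional_composition(fl3$exons, side = "end")
  expect_equal(sum(ps3$counts) + sum(pe3$counts), 38)  # 2*(20-1) codons
})

test_that("no residue is counted on both sides of one exon", {
  set.seed(33)
  b <- generate_genome(lean_config(n_genes = 20, seed = 33))
  fl <- filter_for_correlation(b$transcripts)
  m <- fl$exons$n_codons
  i <- sequence(m)
  mrep <- rep.int(m, m)
  start_sel <- i < mrep + 1L - i & i >= 2L & i <= 34L
  end_sel <- (mrep + 1L - i) < i & (mrep + 1L - i) >= 2L & (mrep + 1L - i) <= 34L
  expect_false(any(start_sel & end_sel))
})

test_that("all-Lysine exons give K fraction 1 at every distance", {
  k_codons <- paste(rep("AAA", 80L), collapse = "")
  cds <- paste0("ATG", "GCA", k_codons, "GCC", "TAA")
  tx <- make_tx(c(6L, nchar(k_codons), 6L), cds = cds)
  fl <- filter_for_correlation(transcript_set(list(tx)))
  ps <- positional_composition(fl$exons, side = "start")
  expect_true(all(ps$fractions["K", ] == 1))
})

test_that("Spearman rho matches the closed-form rank statistic on tie-free data", {
  set.seed(34)
  for (rep in 1:50) {
    y <- sample(seq_len(33))  # tie-free
    pos <- structure(list(
      counts = matrix(0, 20, 33, dimnames = list(names(top_idp_scale()), 2:34)),
      fractions = matrix(rep(y, each = 20), 20, 33,
                         dimnames = list(names(top_idp_scale()), 2:34)),
      side = "start", d = 2:34, available = TRUE), class = "jx_positional")
    pos$fractions[1, ] <- y
    pr <- spearman_profile(pos)
    d2 <- sum((rank(2:34) - rank(y))^2)
    rho_ref <- 1 - 6 * d2 / (33 * (33^2 - 1))
    expect_equal(pr$rho[pr$amino_acid == names(top_idp_scale())[1]], rho_ref,
                 tolerance = 1e-12)
  }
})

test_that("monotone fractions give rho = +1 and constants are not significant", {
  f <- matrix(seq(0.01, 0.33, length.out = 33), nrow = 20, ncol = 33,
              byrow = TRUE, dimnames = list(names(top_idp_scale()), 2:34))
  f["W", ] <- 0.05  # constant: rho undefined
  pos <- structure(list(counts = f, fractions = f, side = "end", d = 2:34,
                        available = TRUE), class = "jx_positional")
  pr <- spearman_profile(pos)
  expect_equal(pr$rho[pr$amino_acid == "K"], 1)
  expect_equal(pr$p[pr$amino_acid == "K"], 0)
  expect_true(pr$significant[pr$amino_acid == "K"])
  expect_true(is.na(pr$rho[pr$amino_acid == "W"]))
  expect_false(pr$significant[pr$amino_acid == "W"])
})

test_that("a planted decreasing Lysine gradient yields negative significant rho", {
  cfg <- lean_config(n_genes = 150, seed = 35, gradient_slopes = c(K = -0.03))
  b <- generate_genome(cfg)
  fl <- filter_for_correlation(b$transcripts)
  for (side in c("start", "end")) {
    pr <- spearman_profile(positional_composition(fl$exons, side = side))
    expect_lt(pr$rho[pr$amino_acid == "K"], 0)
    expect_true(pr$significant[pr$amino_acid == "K"])
  }
})

test_that("group profiles pool per-genome rho values and separate planted signs", {
  cfgA <- lean_config(n_genes = 100, seed = 36, genome_id = "gA",
                      gradient_slopes = c(K = -0.03))
  cfgB <- lean_config(n_genes = 100, seed = 37, genome_id = "gB",
                      gradient_slopes = c(K = 0.03))
  profs <- lapply(list(gA = cfgA, gB = cfgB), function(cf) {
    b <- generate_genome(cf)
    fl <- filter_for_correlation(b$transcripts)
    spearman_profile(positional_composition(fl$exons, side = "end"))
  })
  gm <- c(gA = "GroupDown", gB = "GroupUp")
  gp <- group_profiles(profs, gm)
  kv <- gp$values[gp$values$amino_acid == "K", ]
  expect_lt(kv$rho[kv$group == "GroupDown"], 0)
  expect_gt(kv$rho[kv$group == "GroupUp"], 0)
  # single-genome groups: the distribution is that genome's rho
  ks <- gp$summary[gp$summary$amino_acid == "K", ]
  expect_equal(ks$n, c(1L, 1L))
  expect_equal(sort(ks$median_rho), sort(kv$rho))
  # pooling all groups reproduces the all-genome rho multiset
  expect_setequal(gp$values$rho, c(profs$gA$rho, profs$gB$rho))
  expect_warning(group_profiles(profs, c(gA = "GroupDown")), "skipped")
})
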
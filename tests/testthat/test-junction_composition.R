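test_that("background composition counts every residue of every protein", {
  bg <- background_composition(c("KK", "QQ"))
  expect_equal(unname(bg$freqs["K"]), 0.5)
  expect_equal(unname(bg$freqs["Q"]), 0.5)
  expect_equal(bg$total, 4)
  expect_error(background_composition(character(0)), "empty")
})

test_that("background composition matches a naive letter-count oracle", {
  set.seed(20)
  for (rep in 1:10) {
    prots <- vapply(1:8, function(i) {
      paste(sample(AA_ORDER <- names(top_idp_scale()),
                   sample(5:80, 1L), replace = TRUE), collapse = "")
    }, "")
    bg <- background_composition(prots)
    naive <- table(factor(unlist(strsplit(prots, "")),
                          levels = names(top_idp_scale())))
    expect_equal(unname(bg$counts), as.numeric(naive))
  }
})

test_that("junction tables stratify and conserve counts across phases", {
  b <- generate_genome(gen_config(n_genes = 30, seed = 21))
  jr <- junction_residues(b$transcripts)
  all_tab <- junction_composition(jr, by = "all")$all
  by_phase <- junction_composition(jr, by = "phase")
  summed <- Reduce(`+`, lapply(by_phase, `[[`, "counts"))
  expect_equal(summed, all_tab$counts)

  jr_k <- jr
  jr_k$amino_acid <- "K"
  expect_equal(unname(junction_composition(jr_k, by = "all")$all$freqs["K"]), 1)
})

test_that("junction nucleotides under full bias are all AG|G and match substring tallies", {
  b <- generate_genome(lean_config(n_genes = 15, seed = 22, splice_bias = 1))
  ntc <- junction_nucleotide_composition(b$transcripts)
  m2 <- ntc[ntc$position == "-2", ]
  m1 <- ntc[ntc$position == "-1", ]
  p1 <- ntc[ntc$position == "+1", ]
  expect_equal(m2$freq[m2$nucleotide == "A"], 1)
  expect_equal(m1$freq[m1$nucleotide == "G"], 1)
  expect_equal(p1$freq[p1$nucleotide == "G"], 1)

  # counts equal a brute-force substring tally on an unbiased genome
  b0 <- generate_genome(lean_config(n_genes = 10, seed = 23))
  ntc0 <- junction_nucleotide_composition(b0$transcripts)
  tally <- c(A = 0, C = 0, G = 0, T = 0)
  for (tx in b0$transcripts) {
    n <- nrow(tx$exons)
    if (n < 2L) next
    for (k in 1:(n - 1L)) {
      ce <- tx$exons$coding_end_offset[k]
      nt <- substr(tx$cds, ce - 1L, ce - 1L)
      tally[nt] <- tally[nt] + 1
    }
  }
  got <- ntc0[ntc0$position == "-2", ]
  expect_equal(got$count[match(names(tally), got$nucleotide)],
               unname(as.integer(tally)))
})

test_that("junction nucleotides are near-uniform without splice bias", {
  b <- generate_genome(lean_config(n_genes = 120, seed = 24))
  ntc <- junction_nucleotide_composition(b$transcripts)
  p1 <- ntc[ntc$position == "+1", ]
  n <- sum(p1$count)
  # each base within a 3-SD binomial band around 1/4 (the -2/-1 exon
  # positions are mildly codon-structured; the +1 position is clean)
  band <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(p1$freq - 0.25) <= band + 0.02))
})

test_that("fold changes behave as ratios with guarded zeros", {
  t1 <- composition_table(c(K = 30, Q = 30, W = 40), label = "a")
  fc0 <- fold_change(t1, t1)
  present <- fc0$amino_acid %in% c("K", "Q", "W")
  expect_true(all(fc0$fold[present] == 1))
  expect_true(all(fc0$fold[!present] == 0))  # absent everywhere -> fold 0

  j <- composition_table(c(K = 12, W = 88))
  bg <- composition_table(c(K = 6, W = 94))
  fc <- fold_change(j, bg)
  expect_equal(fc$fold[fc$amino_acid == "K"], 2, tolerance = 1e-12)
  expect_equal(fc$fold[fc$amino_acid == "A"], 0)  # absent from junctions

  bg0 <- composition_table(c(W = 100))
  expect_error(fold_change(j, bg0), "zero")
})

test_that("fold changes recover planted canonical-bias enrichment of K", {
  b <- generate_genome(lean_config(n_genes = 60, seed = 25, splice_bias = 0.6))
  jr <- junction_residues(b$transcripts)
  fc <- fold_change(junction_composition(jr, by = "all")$all,
                    background_composition(b$transcripts))
  expect_gt(fc$fold[fc$amino_acid == "K"], 1.5)
  expect_gt(fc$fold[fc$amino_acid == "R"], 1.2)
})

test_that("disorder-set enrichment is a plain 2x2 chi-square on counts", {
  tab <- composition_table(c(K = 25, P = 25, W = 30, F = 20))
  enr <- disorder_set_enrichment(tab, tab)
  expect_equal(enr$statistic, 0)
  expect_equal(enr$p_value, 1)
  expect_equal(enr$df, 1L)

  # monotonicity: a larger planted excess of disorder-promoting residues
  # gives a larger statistic
  bg <- composition_table(c(K = 100, W = 100))
  s1 <- disorder_set_enrichment(composition_table(c(K = 110, W = 90)), bg)
  s2 <- disorder_set_enrichment(composition_table(c(K = 130, W = 70)), bg)
  expect_gt(s2$statistic, s1$statistic)

  small <- composition_table(c(K = 2, W = 2))
  expect_warning(disorder_set_enrichment(small, small), "below 5")
})

test_that("the TOP-IDP split is a disjoint 10/10 partition", {
  sets <- disorder_sets()
  expect_length(sets$top10, 10L)
  expect_length(intersect(sets$top10, sets$bottom10), 0L)
  expect_setequal(c(sets$top10, sets$bottom10), names(top_idp_scale()))
  expect_true(all(c("P", "E", "K", "S", "Q") %in% sets$top10))
  expect_true(all(c("W", "F", "Y", "I", "M") %in% sets$bottom10))
  # an alternative ordering reshuffles the split
  rev_scale <- -top_idp_scale()
  expect_equal(disorder_sets(rev_scale)$top10, sets$bottom10[10:1])
})

test_that("enriched-set comparison is null on identical compositions and the
           canonical-bias enriched set contains K, Q and E", {
  b <- generate_genome(lean_config(n_genes = 120, seed = 26, splice_bias = 0.9))
  jr <- junction_residues(b$transcripts)
  cls <- classify_exons(b$transcripts, b$tracks)
  tabs <- junction_composition(jr, by = "class", classes = cls)
  ident <- enriched_set_comparison(tabs$structured, tabs$structured,
                                   c("K", "Q", "E"))
  expect_equal(ident$p_value, 1)
  bg <- background_composition(b$transcripts)
  enriched <- enriched_amino_acids(fold_change(
    junction_composition(jr, by = "all")$all, bg))
  expect_true(all(c("K", "Q", "E") %in% enriched))
})
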
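test_that("generation is deterministic given the seed", {
  cfg <- gen_config(n_genes = 12, seed = 99)
  b1 <- generate_genome(cfg)
  b2 <- generate_genome(cfg)
  expect_identical(vapply(b1$transcripts, `[[`, "", "cds"),
                   vapply(b2$transcripts, `[[`, "", "cds"))
  expect_identical(b1$truth, b2$truth)
  expect_identical(as.character(b1$motifs$rescue),
                   as.character(b2$motifs$rescue))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_bundle(b1, d1)
  write_genome_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("full splice bias realises AG|G at every junction of the emitted CDS", {
  b <- generate_genome(lean_config(n_genes = 15, seed = 50, splice_bias = 1))
  for (tx in b$transcripts) {
    n <- nrow(tx$exons)
    if (n < 2L) next
    for (k in 1:(n - 1L)) {
      ce <- tx$exons$coding_end_offset[k]
      expect_equal(substr(tx$cds, ce - 1L, ce), "AG")
      expect_equal(substr(tx$cds, ce + 1L, ce + 1L), "G")
    }
  }
  tr <- b$truth[!is.na(b$truth$junction_forced), ]
  expect_true(all(tr$junction_forced))
  expect_true(all(tr$realized_last2 == "AG"))
  expect_true(all(tr$realized_next1 == "G"))
})

test_that("emitted CDS are translatable with the planted structure", {
  b <- generate_genome(gen_config(n_genes = 20, seed = 51))
  for (tx in b$transcripts) {
    expect_equal(nchar(tx$cds) %% 3L, 0L)
    expect_equal(translate_cds(tx$cds), tx$protein)
    expect_equal(nchar(tx$cds),
                 sum(tx$exons$coding_end_offset - tx$exons$coding_start_offset))
  }
})

test_that("exon count distribution matches the configured mean", {
  cfg <- lean_config(n_genes = 800, seed = 52, exon_len_mean = 10,
                     exon_len_sd = 2, exon_len_min = 6)
  b <- generate_genome(cfg)
  counts <- table(b$truth$gene_id)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - cfg$exons_per_gene_mean), 3 * se)
})

test_that("planted enhancer truth is re-derivable from the emitted sequences", {
  cfg <- gen_config(n_genes = 25, seed = 53, alt_rate = 0,
                    utr5_rate = 0, utr3_rate = 0, gradient_slopes = numeric(0))
  b <- generate_genome(cfg)
  fl <- filter_for_correlation(b$transcripts)
  win <- junction_windows(fl$exons)
  sc <- scan_windows(win$seq, b$motifs$rescue)
  key <- paste(win$exon_id, win$side)
  te <- b$truth_ese
  tkey <- paste(te$exon_id, te$side)
  hit <- match(key, tkey)
  ok <- !is.na(hit)
  expect_gt(sum(ok), 0)
  expect_equal(sc$n_windows[ok], te$n_windows[hit[ok]])
  expect_equal(sc$n_matches[ok], te$realized_matches[hit[ok]])
})

test_that("alternative transcripts skip one frame-preserving internal exon", {
  b <- generate_genome(gen_config(n_genes = 40, seed = 54, alt_rate = 1))
  n_alt <- 0L
  for (g in unique(b$truth$gene_id)) {
    tids <- names(which(vapply(b$transcripts, `[[`, "", "gene_id") == g))
    if (length(tids) < 2L) next
    n_alt <- n_alt + 1L
    t1 <- b$transcripts[[grep("_t1$", tids, value = TRUE)]]
    t2 <- b$transcripts[[grep("_t2$", tids, value = TRUE)]]
    expect_equal(nrow(t2$exons), nrow(t1$exons) - 1L)
    skipped <- setdiff(t1$exons$exon_id, t2$exons$exon_id)
    expect_length(skipped, 1L)
    i <- match(skipped, t1$exons$exon_id)
    expect_equal(t1$exons$coding_start_offset[i] %% 3L, 0L)
    expect_equal(t1$exons$coding_end_offset[i] %% 3L, 0L)
    expect_equal(translate_cds(t2$cds), t2$protein)
    # skipped exon flagged alternative in truth, all others constituent
    tr <- b$truth[b$truth$gene_id == g, ]
    expect_equal(tr$status[match(skipped, tr$exon_id)], "alternative")
    expect_true(all(tr$status[tr$exon_id != skipped] == "constituent"))
    # and the classifier agrees
    st <- classify_splicing_status(b$transcripts[tids])
    expect_equal(st$status[match(skipped, st$exon_id)], "alternative")
  }
  expect_gt(n_alt, 10L)
})

test_that("defect injection is recovered label-for-label by the filter", {
  b <- generate_genome(lean_config(n_genes = 30, seed = 55,
                                   exons_per_gene_mean = 4))
  ids <- names(b$transcripts)
  # zero rates: everything passes
  clean <- corrupt_for_filters(b$transcripts, rates = c(no_start = 0))
  expect_true(all(filter_for_correlation(clean$transcripts)$report$pass))

  # named premature-stop injection hits exactly the named transcripts
  pick <- ids[1:10]
  cr <- corrupt_for_filters(b$transcripts, rates = c(no_start = 0),
                            assign = setNames(rep("premature_stop", 10), pick))
  rep <- filter_for_correlation(cr$transcripts)$report
  expect_setequal(rep$transcript_id[!rep$pass], pick)
  expect_true(all(rep$first_fail[!rep$pass] == "premature_stop"))

  # random rates: the filter/truth confusion matrix is diagonal
  set.seed(56)
  cr2 <- corrupt_for_filters(b$transcripts,
                             rates = c(no_start = 0.1, no_stop = 0.1,
                                       premature_stop = 0.1,
                                       uncertain_base = 0.1,
                                       length_not_multiple_of_3 = 0.1))
  rep2 <- filter_for_correlation(cr2$transcripts)$report
  truth <- cr2$truth$defect
  called <- ifelse(rep2$pass, "none", rep2$first_fail)
  expect_equal(called, truth)
})
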
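# Stage orchestration: runs the analysis end to end on a (synthetic or
# user-supplied) genome directory, writing TSV reports and a JSON run
# manifest. Every threshold is a config default, never hard-coded, so
# sensitivity analyses are one-argument changes.

#' Default pipeline run configuration
#'
#' @param gen Generator configuration ([gen_config()]) used by the `synth`
#'   stage.
#' @param class_threshold Exon classification fraction (default 0.75).
#' @param alpha Significance level for correlation profiles (default 0.001).
#' @param enrich_fold Fold-change threshold defining the enriched
#'   amino-acid set (default 1).
#' @param d_min,d_max Codon-distance window (defaults 2 and 34).
#' @return List of class `jx_run_config`.
#' @export
run_config <- function(gen = gen_config(), class_threshold = 0.75,
                       alpha = 0.001, enrich_fold = 1,
                       d_min = 2L, d_max = 34L) {
  stopifnot(class_threshold > 0, class_threshold <= 1,
            alpha > 0, alpha < 1, d_min >= 1L, d_max > d_min)
  structure(list(gen = gen, class_threshold = class_threshold, alpha = alpha,
                 enrich_fold = enrich_fold, d_min = as.integer(d_min),
                 d_max = as.integer(d_max)),
            class = "jx_run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.need_artifacts <- function(out_dir, files, stage, needed_by) {
  paths <- file.path(out_dir, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(sprintf("stage '%s' requires artifacts from stage '%s'; missing: %s",
                 needed_by, stage, paste(files[missing], collapse = ", ")),
         call. = FALSE)
  }
  invisible(paths)
}

.load_inputs <- function(out_dir) {
  synth <- file.path(out_dir, "synth")
  txs <- read_gene_models(file.path(synth, "genes.gtf"),
                          file.path(synth, "cdna.fa"),
                          file.path(synth, "protein.fa"))
  plen <- vapply(txs, function(t) nchar(t$protein), 0L)
  tracks <- read_residue_tracks(file.path(synth, "tracks.tsv"), plen)
  motifs <- list(
    rescue = read_motifs(file.path(synth, "motifs_rescue.txt"),
                         name = "rescue-like-synthetic"),
    int3 = read_motifs(file.path(synth, "motifs_int3.txt"),
                       name = "int3-like-synthetic"))
  list(transcripts = txs, tracks = tracks, motifs = motifs)
}

#' Run the analysis pipeline
#'
#' Subcommands: `synth` (generate + write the synthetic genome), `map`
#' (exon phases), `classify` (exon classes and splicing status), `junction`
#' (junction composition, fold changes, enrichment, junction nucleotides),
#' `correlate` (filter report and Spearman profiles), `ese` (enhancer
#' densities and intron-length comparison), or `all`. Stage outputs are
#' TSVs under `out_dir`; a machine-readable manifest accompanies every
#' run. Stages after `synth` read their inputs back from the `synth`
#' artifacts, so later stages error clearly when earlier ones are missing.
#'
#' @param subcommand One of `synth`, `map`, `classify`, `junction`,
#'   `correlate`, `ese`, `all`.
#' @param config A `jx_run_config` (or NULL for defaults).
#' @param out_dir Output directory.
#' @param seed Optional override of the generator seed.
#' @param verbose Emit progress messages.
#' @return Invisibly, named vector of artifact paths written by this call.
#' @export
run_pipeline <- function(subcommand = c("all", "synth", "map", "classify",
                                        "junction", "correlate", "ese"),
                         config = NULL, out_dir, seed = NULL,
                         verbose = FALSE) {
  subcommand <- match.arg(subcommand)
  if (is.null(config)) config <- run_config()
  stopifnot(inherits(config, "jx_run_config"))
  if (!is.null(seed)) config$gen$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- if (subcommand == "all") {
    c("synth", "map", "classify", "junction", "correlate", "ese")
  } else subcommand
  written <- character(0)
  for (st in stages) {
    jx_msg("stage: ", st, verbose = verbose)
    written <- c(written, switch(st,
      synth = .stage_synth(config, out_dir),
      map = .stage_map(config, out_dir),
      classify = .stage_classify(config, out_dir),
      junction = .stage_junction(config, out_dir),
      correlate = .stage_correlate(config, out_dir),
      ese = .stage_ese(config, out_dir)))
  }
  manifest <- .write_manifest(config, out_dir, stages, written)
  invisible(c(written, manifest = manifest))
}

.stage_synth <- function(config, out_dir) {
  bundle <- generate_genome(config$gen)
  paths <- write_genome_bundle(bundle, file.path(out_dir, "synth"))
  unname(paths)
}

.stage_map <- function(config, out_dir) {
  .need_artifacts(out_dir, file.path("synth", c("genes.gtf", "cdna.fa", "protein.fa")),
                  "synth", "map")
  inp <- .load_inputs(out_dir)
  ph <- phase_table(inp$transcripts)
  .write_tsv(ph, file.path(out_dir, "exon_phases.tsv"))
}

.stage_classify <- function(config, out_dir) {
  .need_artifacts(out_dir, "exon_phases.tsv", "map", "classify")
  inp <- .load_inputs(out_dir)
  cls <- classify_exons(inp$transcripts, inp$tracks,
                        threshold = config$class_threshold)
  status <- classify_splicing_status(inp$transcripts)
  c(.write_tsv(cls, file.path(out_dir, "exon_classes.tsv")),
    .write_tsv(status, file.path(out_dir, "splicing_status.tsv")))
}

.stage_junction <- function(config, out_dir) {
  .need_artifacts(out_dir, c("exon_classes.tsv"), "classify", "junction")
  inp <- .load_inputs(out_dir)
  cls <- utils::read.delim(file.path(out_dir, "exon_classes.tsv"),
                           stringsAsFactors = FALSE)
  jr <- junction_residues(inp$transcripts)
  bg <- background_composition(inp$transcripts)

  comp_rows <- list(); fold_rows <- list()
  tabs <- c(junction_composition(jr, by = "all"),
            junction_composition(jr, by = "phase"),
            junction_composition(jr, by = "class", classes = cls),
            junction_composition(jr, by = "class_phase", classes = cls))
  for (s in names(tabs)) {
    tab <- tabs[[s]]
    comp_rows[[s]] <- data.frame(stratum = s, amino_acid = names(tab$counts),
                                 count = as.numeric(tab$counts),
                                 freq = as.numeric(tab$freqs),
                                 stringsAsFactors = FALSE)
    if (tab$total > 0) {
      fc <- fold_change(tab, bg)
      fold_rows[[s]] <- cbind(stratum = s, fc)
    }
  }
  comp <- do.call(rbind, c(comp_rows,
    list(data.frame(stratum = "background", amino_acid = names(bg$counts),
                    count = as.numeric(bg$counts),
                    freq = as.numeric(bg$freqs), stringsAsFactors = FALSE))))

  enr <- disorder_set_enrichment(tabs[["all"]], bg)
  enriched <- enriched_amino_acids(fold_change(tabs[["all"]], bg),
                                   threshold = config$enrich_fold)
  enr_rows <- data.frame(
    comparison = "top10_junction_vs_background",
    set = paste(enr$set, collapse = ""),
    pct_1 = enr$pct[1L], pct_2 = enr$pct[2L], statistic = enr$statistic,
    df = enr$df, p_value = enr$p_value, stringsAsFactors = FALSE)
  if (!is.null(tabs[["structured"]]) && !is.null(tabs[["disordered"]]) &&
      tabs[["structured"]]$total > 0 && tabs[["disordered"]]$total > 0) {
    cmp <- enriched_set_comparison(tabs[["structured"]], tabs[["disordered"]],
                                   enriched)
    enr_rows <- rbind(enr_rows, data.frame(
      comparison = "enriched_set_structured_vs_disordered",
      set = paste(cmp$set, collapse = ""),
      pct_1 = cmp$pct[1L], pct_2 = cmp$pct[2L], statistic = cmp$statistic,
      df = cmp$df, p_value = cmp$p_value, stringsAsFactors = FALSE))
  }
  ntc <- junction_nucleotide_composition(inp$transcripts, classes = cls)

  c(.write_tsv(comp, file.path(out_dir, "junction_composition.tsv")),
    .write_tsv(do.call(rbind, fold_rows), file.path(out_dir, "fold_change.tsv")),
    .write_tsv(enr_rows, file.path(out_dir, "enrichment.tsv")),
    .write_tsv(ntc, file.path(out_dir, "junction_nucleotides.tsv")))
}

.stage_correlate <- function(config, out_dir) {
  .need_artifacts(out_dir, c("exon_phases.tsv", "exon_classes.tsv"),
                  "map/classify", "correlate")
  inp <- .load_inputs(out_dir)
  cls <- utils::read.delim(file.path(out_dir, "exon_classes.tsv"),
                           stringsAsFactors = FALSE)
  fl <- filter_for_correlation(inp$transcripts)
  fex <- fl$exons
  key <- paste(fex$transcript_id, fex$exon_id)
  fex$category <- cls$category[match(key, paste(cls$transcript_id, cls$exon_id))]
  fex$category[is.na(fex$category)] <- "other"

  prof_rows <- list()
  for (side in c("start", "end")) {
    phase_col <- if (side == "start") "start_phase" else "end_phase"
    for (cl in c("all", "structured", "disordered")) {
      for (phs in c("all", "0", "1", "2")) {
        sel <- rep(TRUE, nrow(fex))
        if (cl != "all") sel <- sel & fex$category == cl
        if (phs != "all") sel <- sel & fex[[phase_col]] == as.integer(phs)
        pc <- positional_composition(fex[sel, , drop = FALSE], side = side,
                                     d_min = config$d_min, d_max = config$d_max)
        pr <- spearman_profile(pc, alpha = config$alpha)
        prof_rows[[length(prof_rows) + 1L]] <- data.frame(
          side = side, category = cl, phase = phs,
          amino_acid = pr$amino_acid, rho = pr$rho, p = pr$p,
          significant = pr$significant, available = pc$available,
          stringsAsFactors = FALSE)
      }
    }
  }
  c(.write_tsv(fl$report, file.path(out_dir, "filter_report.tsv")),
    .write_tsv(do.call(rbind, prof_rows),
               file.path(out_dir, "correlation_profiles.tsv")))
}

.stage_ese <- function(config, out_dir) {
  .need_artifacts(out_dir, c("exon_classes.tsv", "splicing_status.tsv"),
                  "classify", "ese")
  inp <- .load_inputs(out_dir)
  cls <- utils::read.delim(file.path(out_dir, "exon_classes.tsv"),
                           stringsAsFactors = FALSE)
  status <- utils::read.delim(file.path(out_dir, "splicing_status.tsv"),
                              stringsAsFactors = FALSE)
  fl <- filter_for_correlation(inp$transcripts)
  win <- junction_windows(fl$exons, d_min = config$d_min, d_max = config$d_max)
  dens_rows <- list(); test_rows <- list()
  for (ms in names(inp$motifs)) {
    de <- ese_density(win, cls, inp$motifs[[ms]], statuses = status)
    dens_rows[[ms]] <- de$density
    if (!is.null(de$tests)) test_rows[[ms]] <- de$tests
  }
  introns <- tryCatch(flanking_intron_comparison(inp$transcripts, cls),
                      error = function(e) NULL)
  intron_df <- if (is.null(introns)) {
    data.frame(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
               mean_structured = NA_real_, mean_disordered = NA_real_,
               n_structured = NA_integer_, n_disordered = NA_integer_)
  } else {
    data.frame(statistic = introns$statistic, df = introns$df,
               p_value = introns$p_value,
               mean_structured = introns$means["structured"],
               mean_disordered = introns$means["disordered"],
               n_structured = introns$n["structured"],
               n_disordered = introns$n["disordered"])
  }
  c(.write_tsv(do.call(rbind, dens_rows), file.path(out_dir, "ese_density.tsv")),
    .write_tsv(do.call(rbind, test_rows), file.path(out_dir, "ese_tests.tsv")),
    .write_tsv(intron_df, file.path(out_dir, "intron_lengths.tsv")))
}

.write_manifest <- function(config, out_dir, stages, written) {
  written <- written[file.exists(written)]
  manifest <- list(
    package = "junctionscape",
    version = as.character(utils::packageVersion("junctionscape")),
    stages = stages,
    seed = config$gen$seed,
    config_hash = .config_hash(config),
    artifacts = lapply(stats::setNames(written, basename(written)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    }))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(lapply(unclass(config$gen), unclass), tmp)
  unname(tools::md5sum(tmp))
}
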
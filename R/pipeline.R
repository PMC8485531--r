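#' Run the full analysis pipeline on a synthetic metastudy
#'
#' Chains every stage through files in `out_dir`, the way the
#' command-line driver does: simulate (per-experiment count TSVs,
#' taxonomy, metadata), ingest (read back, rarefy, merge), core-index
#' (class-level CI/NorCI partition and shared classes), indicator screen
#' (level scan, repeated-CV importance, indicator ranking, train/test
#' prediction, random-effects meta-analysis), stability (co-occurrence
#' network, topology, cohesion ratios), resistome (chip detection,
#' copy numbers, ARG-taxon correlation) and phenotype (locomotion HAA
#' and slopes). Every stage is seeded from the single `seed`, so two
#' runs with the same seed produce byte-identical output files.
#'
#' @param out_dir output directory (created).
#' @param config a [synth_config()]; its own seed is overridden by
#'   `seed` so one integer drives the whole run.
#' @param seed master integer seed.
#' @param depth rarefaction depth (default 2000).
#' @param levels taxonomic levels for the OOB scan.
#' @param null_iters permutations for the cohesion null model.
#' @param cv_folds,cv_repeats importance cross-validation design.
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(out_dir, config = synth_config(), seed = 1,
                         depth = 2000,
                         levels = c("phylum", "class", "genus"),
                         null_iters = 200, cv_folds = 10, cv_repeats = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)

  # -- simulate ------------------------------------------------------------
  sim_dir <- file.path(out_dir, "simulated")
  sim <- simulate_metastudy(config)
  write_metastudy(sim, sim_dir, config = config)

  # -- ingest: read back from disk, rarefy, merge --------------------------
  meta <- read_sample_meta(file.path(sim_dir, "metadata.tsv"))
  tax <- read_taxonomy(file.path(sim_dir, "taxonomy.tsv"))
  paths <- sort(list.files(sim_dir, pattern = "^counts_.*\\.tsv$",
                           full.names = TRUE))
  tables <- lapply(paths, read_count_table, format = "tsv",
                   sample_meta = meta, taxonomy = tax,
                   sample_ids = meta$sample_id)
  merged <- merge_experiments(tables)
  merged <- rarefy_counts(merged, depth = depth, seed = seed + 1L)
  write_count_table(merged, file.path(out_dir, "merged.tsv"))

  # -- core index at class level -------------------------------------------
  classes <- collapse_taxa(merged, "class")
  part <- core_partition(classes)
  shared <- shared_taxa(classes)
  write_tsv(part$stats, file.path(out_dir, "taxon_stats.tsv"))
  write_tsv(shared$edges, file.path(out_dir, "shared_edges.tsv"))
  write_tsv(data.frame(category = names(part$category_abundance),
                       abundance_pct = as.numeric(part$category_abundance)),
            file.path(out_dir, "category_abundance.tsv"))

  # -- indicator screen at genus level -------------------------------------
  genus <- collapse_taxa(merged, "genus")
  x <- rel_abundance(genus)
  y <- genus$sample_meta$group
  scan <- scan_taxonomic_levels(merged, levels = levels, seed = seed + 2L)
  imp <- cv_importance(x, y, folds = cv_folds, repeats = cv_repeats,
                       seed = seed + 3L)
  gstats <- taxon_stats(genus)
  indic <- select_indicator(imp, gstats, taxonomy = genus$taxonomy)
  pred <- train_test_predict(x, y, seed = seed + 4L)
  cls_rel <- rel_abundance(classes)
  ind_class <- sim$truth$indicator_class
  meta_df <- data.frame(experiment_id = classes$sample_meta$experiment_id,
                        group = classes$sample_meta$group,
                        value = cls_rel[, ind_class])
  meta_res <- random_effects_meta(meta_df)
  write_tsv(scan, file.path(out_dir, "oob_by_level.tsv"))
  write_tsv(imp, file.path(out_dir, "importance.tsv"))
  write_tsv(indic, file.path(out_dir, "indicator_ranking.tsv"))
  write_tsv(as.data.frame(pred$confusion),
            file.path(out_dir, "confusion.tsv"))
  write_tsv(meta_res$studies, file.path(out_dir, "meta_forest.tsv"))
  write_tsv(meta_res$loo, file.path(out_dir, "meta_leave1out.tsv"))

  # -- stability: network + cohesion ---------------------------------------
  net <- cooccurrence_network(classes)
  topo <- network_topology(net)
  conn <- connectedness(classes, null_iters = null_iters, seed = seed + 5L)
  coh <- cohesion(classes, conn, groups = classes$sample_meta$group)
  sub <- subcommunity_cohesion(classes, focal = ind_class,
                               null_iters = null_iters, seed = seed + 6L,
                               groups = classes$sample_meta$group)
  write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
  write_tsv(topo, file.path(out_dir, "network_topology.tsv"))
  write_tsv(coh$samples, file.path(out_dir, "cohesion_samples.tsv"))
  write_tsv(data.frame(community = c(rep("whole", length(coh$ratio)),
                                     rep("indicator_sub", length(sub$ratio))),
                       group = c(names(coh$ratio), names(sub$ratio)),
                       neg_pos_ratio = c(as.numeric(coh$ratio),
                                         as.numeric(sub$ratio))),
            file.path(out_dir, "cohesion_ratio.tsv"))

  # -- resistome ------------------------------------------------------------
  chip <- simulate_ct_chip(n_genes = 96, n_bio = 3, n_tech = 3,
                           detected_fraction = 0.4, seed = seed + 7L)
  detected <- detect_genes(chip$ct)
  abund <- gene_abundance(chip$ct, detected)
  burden <- simulate_arg_burden(cls_rel, ind_class, seed = seed + 8L)
  argcor <- arg_taxon_correlation(cls_rel, burden)
  utils::write.csv(chip$ct, file.path(out_dir, "ct_matrix.csv"),
                   row.names = FALSE)
  write_tsv(data.frame(gene_id = detected),
            file.path(out_dir, "detected_genes.tsv"))
  write_tsv(abund, file.path(out_dir, "gene_abundance.tsv"))
  write_tsv(argcor, file.path(out_dir, "arg_taxon_correlation.tsv"))

  # -- phenotype: locomotion under a control > AZ > OTC > AO drift order ----
  drifts <- c(Control = 0.45, AZ = 0.30, OTC = 0.20, AO = 0.12)
  loco <- lapply(seq_along(drifts), function(i) {
    simulate_locomotion(drift = drifts[i], seed = seed + 10L + i)
  })
  names(loco) <- names(drifts)
  summaries <- lapply(loco, locomotion_summary)
  haa_df <- do.call(rbind, lapply(names(summaries), function(g) {
    data.frame(group = g, timepoint = names(summaries[[g]]$haa),
               haa = as.numeric(summaries[[g]]$haa),
               stringsAsFactors = FALSE)
  }))
  slopes <- data.frame(group = names(summaries),
                       k = vapply(summaries, `[[`, numeric(1), "k"),
                       r2 = vapply(summaries, `[[`, numeric(1), "r2"))
  write_tsv(haa_df, file.path(out_dir, "haa.tsv"))
  write_tsv(slopes, file.path(out_dir, "motility_slopes.tsv"))

  invisible(list(sim = sim, merged = merged, partition = part,
                 shared = shared, scan = scan, indicator = indic,
                 prediction = pred, meta = meta_res, network = net,
                 topology = topo, cohesion = coh, subcommunity = sub,
                 detected_genes = detected, gene_abundance = abund,
                 arg_correlation = argcor, locomotion = summaries))
}
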
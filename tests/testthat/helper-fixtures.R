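# small seeded fixtures shared across test files

tiny_config <- function(seed = 1, ...) {
  args <- list(n_experiments = 3, samples_per_experiment = 4,
               library_size = 500, n_classes = 8, genera_per_class = 2,
               core_classes = 1:2, transient_classes = 3:4,
               indicator_class = 1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# a small merged genus-level table with a pollution signal
tiny_merged <- function(seed = 1, fold = 2.5, ...) {
  sim <- simulate_metastudy(tiny_config(seed = seed,
                                        pollution_fold_change = fold, ...))
  merge_experiments(sim$tables)
}

# hand-built 3 samples x 4 taxa table with metadata
toy_table <- function() {
  m <- matrix(c(5, 0, 2, 3,
                1, 4, 0, 5,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("taxA", "taxB", "taxC", "taxD")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     experiment_id = c("E1", "E1", "E2"),
                     group = c("Control", "Pollution", "Control"))
  tax <- data.frame(
    taxon_id = c("taxA", "taxB", "taxC", "taxD"),
    lineage = c("d__Bacteria;p__P1;c__C1;o__O1;f__F1;g__taxA",
                "d__Bacteria;p__P1;c__C1;o__O1;f__F1;g__taxB",
                "d__Bacteria;p__P1;c__C2;o__O2;f__F2;g__taxC",
                "d__Bacteria;p__P2;c__C3;o__O3;f__F3;g__taxD"))
  count_table(m, meta, tax)
}
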
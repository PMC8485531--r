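test_that("TSV and BIOM serializations round-trip to the same object", {
  tab <- toy_table()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  biom <- withr::local_tempfile(fileext = ".biom")
  write_count_table(tab, tsv, "tsv")
  write_count_table(tab, biom, "biom")
  meta <- tab$sample_meta
  tax <- tab$taxonomy[, c("taxon_id", "lineage")]
  from_tsv <- read_count_table(tsv, "tsv", meta, tax,
                               sample_ids = meta$sample_id)
  from_biom <- read_count_table(biom, "biom", meta, tax)
  expect_equal(from_tsv$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
  expect_equal(from_biom$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
  expect_equal(from_tsv$counts[, colnames(from_biom$counts)],
               from_biom$counts[rownames(from_tsv$counts), ])
})

test_that("editing one count changes exactly one cell on read-back", {
  tab <- toy_table()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, tsv, "tsv")
  lines <- readLines(tsv)
  lines[2] <- sub("\t5\t", "\t6\t", lines[2])
  writeLines(lines, tsv)
  back <- read_count_table(tsv, "tsv", tab$sample_meta,
                           tab$taxonomy[, c("taxon_id", "lineage")],
                           sample_ids = tab$sample_meta$sample_id)
  diff <- back$counts[rownames(tab$counts), colnames(tab$counts)] != tab$counts
  expect_equal(sum(diff), 1)
})

test_that("degenerate inputs are rejected at construction", {
  expect_error(count_table(matrix(nrow = 0, ncol = 0), NULL), "empty")
  m <- matrix(c(-1, 2, 3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  meta <- data.frame(sample_id = c("a", "b"), experiment_id = "E1",
                     group = "Control")
  expect_error(count_table(m, meta), "negative")
  m2 <- abs(m) + 0.5
  expect_error(count_table(m2, meta), "non-integer")
})

test_that("rarefaction drops shallow samples and equalizes retained ones", {
  m <- matrix(c(1500, 500,      # 2000 exactly: retained
                1999, 0,        # below depth: dropped
                3000, 1000), nrow = 3, byrow = TRUE,
              dimnames = list(c("ok", "shallow", "deep"), c("A", "B")))
  meta <- data.frame(sample_id = rownames(m), experiment_id = "E1",
                     group = "Control")
  tab <- count_table(m, meta)
  expect_message(rar <- rarefy_counts(tab, depth = 2000, seed = 1),
                 "shallow")
  expect_setequal(rownames(rar$counts), c("ok", "deep"))
  expect_true(all(rowSums(rar$counts) == 2000))
  # a sample at exactly the depth passes through unchanged
  expect_equal(rar$counts["ok", ], c(A = 1500, B = 500))
  expect_error(rarefy_counts(tab, depth = 5000), "no samples survive")
})

test_that("rarefied counts match the hypergeometric expectation", {
  m <- matrix(c(3000, 1000), nrow = 1,
              dimnames = list("s1", c("A", "B")))
  meta <- data.frame(sample_id = "s1", experiment_id = "E1",
                     group = "Control")
  tab <- count_table(m, meta)
  reps <- 4000
  draws <- vapply(seq_len(reps), function(s) {
    rarefy_counts(tab, depth = 2000, seed = s)$counts[1, "A"]
  }, numeric(1))
  # hypergeometric oracle: E = 2000 * 3000/4000, var from the standard formula
  e <- 2000 * 3000 / 4000
  v <- 2000 * (3000 / 4000) * (1000 / 4000) * (4000 - 2000) / (4000 - 1)
  se <- sqrt(v / reps)
  expect_lt(abs(mean(draws) - e), 3 * se)
})

test_that("taxonomic collapse is additive, conservative and identity at genus", {
  tab <- toy_table()
  cls <- collapse_taxa(tab, "class")
  # taxA + taxB share class C1
  expect_equal(cls$counts[, "C1"],
               tab$counts[, "taxA"] + tab$counts[, "taxB"])
  expect_equal(sum(cls$counts), sum(tab$counts))
  gen <- collapse_taxa(tab, "genus")
  expect_equal(sort(colnames(gen$counts)), sort(colnames(tab$counts)))
  expect_equal(gen$counts[, colnames(tab$counts)], tab$counts)
})

test_that("taxa with no label at the target rank are pooled, not dropped", {
  m <- matrix(c(5, 7), 1, dimnames = list("s1", c("t1", "t2")))
  meta <- data.frame(sample_id = "s1", experiment_id = "E1",
                     group = "Control")
  tax <- data.frame(taxon_id = c("t1", "t2"),
                    lineage = c("d__Bacteria;p__P1;c__C1",
                                "d__Bacteria;p__P1"))
  cls <- collapse_taxa(count_table(m, meta, tax), "class")
  expect_setequal(colnames(cls$counts), c("C1", "unclassified_P1"))
  expect_equal(sum(cls$counts), 12)
})

test_that("merging is lossless, order-invariant and rejects duplicate ids", {
  sim <- simulate_metastudy(tiny_config(seed = 2))
  merged <- merge_experiments(sim$tables)
  expect_equal(nrow(merged$counts),
               sum(vapply(sim$tables, n_samples, numeric(1))))
  # round-trip: slicing reproduces each input
  for (t in sim$tables) {
    e <- t$sample_meta$experiment_id[1]
    back <- subset_experiment(merged, e, drop_absent = FALSE)
    expect_equal(back$counts[rownames(t$counts), colnames(t$counts)],
                 t$counts)
  }
  # order invariance
  merged_rev <- merge_experiments(rev(sim$tables))
  expect_equal(merged_rev$counts[rownames(merged$counts),
                                 colnames(merged$counts)],
               merged$counts)
  expect_error(merge_experiments(list(sim$tables[[1]], sim$tables[[1]])),
               "duplicate sample id")
})

test_that("merging disjoint taxon sets sums the widths", {
  t1 <- toy_table()
  m2 <- matrix(c(1, 2, 3, 4), 2, 2,
               dimnames = list(c("x1", "x2"), c("taxE", "taxF")))
  meta2 <- data.frame(sample_id = c("x1", "x2"), experiment_id = "E9",
                      group = "Control")
  t2 <- count_table(m2, meta2)
  merged <- merge_experiments(list(t1, t2))
  expect_equal(ncol(merged$counts), ncol(t1$counts) + ncol(t2$counts))
  expect_true(all(merged$counts[c("x1", "x2"), c("taxA", "taxB")] == 0))
})
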
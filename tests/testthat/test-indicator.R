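make_separable <- function(n = 30, p = 6, gap = 5, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("Control", "Pollution"), each = n / 2))
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
    x[y == "Pollution", 1] <- x[y == "Pollution", 1] + gap
    list(x = x, y = y)
  })
}

test_that("all three classifiers separate linearly separable features perfectly", {
  d <- make_separable(gap = 10)
  res <- compare_classifiers(d$x, d$y, folds = 5, seed = 1)
  for (m in c("RF", "SVM", "LR")) {
    expect_equal(res[[m]]$auc, 1.0)
    expect_true(all(diff(res[[m]]$roc_points$tpr) >= 0))
    expect_true(all(diff(res[[m]]$roc_points$fpr) >= 0))
  }
})

test_that("cross-validated probabilities are reproducible under a fixed seed", {
  d <- make_separable(gap = 1)
  a <- compare_classifiers(d$x, d$y, folds = 5, seed = 9, models = "RF")
  b <- compare_classifiers(d$x, d$y, folds = 5, seed = 9, models = "RF")
  expect_identical(a$RF$prob, b$RF$prob)
  expect_error(compare_classifiers(d$x, rep("Control", 30)), "two classes")
})

test_that("OOB level scan prefers the level carrying the planted signal", {
  # signal planted at class level (indicator enrichment); class-level
  # OOB should not exceed phylum-level OOB on average
  wins <- 0
  for (s in 1:10) {
    merged <- tiny_merged(seed = s, fold = 3,
                          samples_per_experiment = 8)
    scan <- scan_taxonomic_levels(merged, levels = c("phylum", "class"),
                                  seed = s)
    oob <- stats::setNames(scan$oob_error, scan$level)
    wins <- wins + (oob["class"] <= oob["phylum"] + 1e-9)
  }
  expect_gte(wins, 6)
})

test_that("pure-noise features give OOB near the majority-class error", {
  withr::with_seed(4, {
    m <- matrix(rpois(40 * 12, 50), 40, 12,
                dimnames = list(paste0("s", 1:40), paste0("t", 1:12)))
  })
  meta <- data.frame(sample_id = paste0("s", 1:40),
                     experiment_id = "E1",
                     group = rep(c("Control", "Pollution"), 20))
  tax <- data.frame(taxon_id = paste0("t", 1:12),
                    lineage = sprintf("d__B;p__P1;c__C1;o__O1;f__F1;g__t%d",
                                      1:12))
  tab <- count_table(m, meta, tax)
  scan <- scan_taxonomic_levels(tab, levels = "genus", seed = 4)
  expect_lt(abs(scan$oob_error[1] - 0.5), 0.2)
})

test_that("a perfectly discriminating genus ranks first in repeated-CV importance", {
  d <- make_separable(n = 40, gap = 8, seed = 3)
  colnames(d$x) <- paste0("genus", 1:6)
  imp <- cv_importance(d$x, d$y, folds = 5, repeats = 2, seed = 3)
  expect_equal(imp$taxon[1], "genus1")
  # uninformative genera sit in the noise band around zero
  expect_lt(max(abs(imp$importance[imp$taxon != "genus1"])),
            imp$importance[1] / 2)
  imp2 <- cv_importance(d$x, d$y, folds = 5, repeats = 2, seed = 3)
  expect_identical(imp$importance, imp2$importance)
  expect_error(cv_importance(d$x, d$y, folds = 25), "smallest class")
})

test_that("indicator score combines importance with occupancy", {
  # a moderate-importance high-frequency genus can outrank a
  # high-importance genus seen in 1% of samples (product rule)
  imp2 <- data.frame(taxon = c("rare_strong", "common_mid", "baseline"),
                     importance = c(1.0, 0.95, 0))
  freq <- data.frame(taxon = c("rare_strong", "common_mid", "baseline"),
                     f = c(0.01, 0.9, 0.5))
  out2 <- select_indicator(imp2, freq)
  expect_equal(out2$taxon[1], "common_mid")
  # equal frequencies reduce the ranking to the importance ranking
  freq_eq <- data.frame(taxon = c("a", "b", "c"), f = 0.7)
  imp3 <- data.frame(taxon = c("a", "b", "c"),
                     importance = c(0.2, 0.9, 0.5))
  expect_equal(select_indicator(imp3, freq_eq)$taxon, c("b", "c", "a"))
  expect_error(select_indicator(imp3, data.frame(taxon = "z", f = 1)),
               "no taxa shared")
})

test_that("the selected indicator genus reports its class lineage", {
  merged <- tiny_merged(seed = 5, fold = 3)
  g <- collapse_taxa(merged, "genus")
  imp <- cv_importance(rel_abundance(g), g$sample_meta$group,
                       folds = 5, repeats = 1, seed = 5)
  out <- select_indicator(imp, taxon_stats(g), taxonomy = g$taxonomy)
  expect_true(all(grepl("^C\\d\\d$", out$class)))
})

test_that("train/test prediction is perfect on separable data and conserves counts", {
  d <- make_separable(n = 40, gap = 10, seed = 2)
  res <- train_test_predict(d$x, d$y, split = 0.7, seed = 2)
  expect_equal(unname(res$class_accuracy), c(1, 1))
  expect_equal(sum(res$confusion), res$n_test)
  expect_equal(res$auc, 1.0)
})

test_that("meta-analysis of identical studies returns the common effect with tau2 = 0", {
  one <- data.frame(group = rep(c("Control", "Pollution"), each = 6),
                    value = c(1, 2, 3, 4, 5, 6, 3, 4, 5, 6, 7, 8))
  dat <- do.call(rbind, lapply(1:4, function(e) {
    cbind(experiment_id = paste0("E", e), one)
  }))
  res <- random_effects_meta(dat)
  expect_equal(res$tau2, 0)
  expect_equal(res$pooled, res$studies$g[1])
  expect_equal(nrow(res$loo), 4)
  # with tau2 = 0 the pooled estimate equals the fixed-effect
  # inverse-variance mean
  fe <- sum(res$studies$g / res$studies$var) / sum(1 / res$studies$var)
  expect_equal(res$pooled, fe)
  expect_error(random_effects_meta(one_study <- cbind(experiment_id = "E1",
                                                      one)),
               ">= 2 studies")
})

test_that("meta-analysis recovers a planted standardized mean difference", {
  pooled <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      dat <- do.call(rbind, lapply(1:5, function(e) {
        data.frame(experiment_id = paste0("E", e),
                   group = rep(c("Control", "Pollution"), each = 20),
                   value = c(rnorm(20, 0, 1), rnorm(20, 0.8, 1)))
      }))
    })
    random_effects_meta(dat)$pooled
  }, numeric(1))
  expect_lt(abs(mean(pooled) - 0.8), 0.25)
})

test_that("zero-variance studies are floored with a warning", {
  dat <- rbind(
    data.frame(experiment_id = "E1",
               group = rep(c("Control", "Pollution"), each = 3),
               value = c(1, 1, 1, 1, 1, 1)),
    data.frame(experiment_id = "E2",
               group = rep(c("Control", "Pollution"), each = 3),
               value = c(1, 2, 3, 2, 3, 4)))
  expect_warning(res <- random_effects_meta(dat), "floored")
  expect_true(is.finite(res$pooled))
})
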
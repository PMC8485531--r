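#' Stratified cross-validation folds
#'
#' @param labels factor of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments (1..k), stratified by class.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < k) stop("fewer than ", k, " samples in class ", lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

fit_predict_prob <- function(model, x_tr, y_tr, x_te) {
  df_tr <- data.frame(x_tr, check.names = FALSE)
  df_te <- data.frame(x_te, check.names = FALSE)
  pos <- levels(y_tr)[2]
  switch(model,
    RF = {
      fit <- randomForest::randomForest(x = df_tr, y = y_tr, ntree = 500)
      stats::predict(fit, df_te, type = "prob")[, pos]
    },
    SVM = {
      fit <- e1071::svm(x = as.matrix(x_tr), y = y_tr, probability = TRUE)
      pr <- stats::predict(fit, as.matrix(x_te), probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    LR = {
      d <- data.frame(.y = y_tr, x_tr, check.names = TRUE)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d,
                                         family = stats::binomial()))
      suppressWarnings(stats::predict(
        fit, data.frame(x_te, check.names = TRUE), type = "response"))
    },
    stop("unknown model: ", model))
}

#' Compare RF, SVM and logistic-regression classifiers by cross-validated ROC
#'
#' All three models are evaluated on identical stratified folds; per-model
#' out-of-fold class probabilities give one ROC curve and AUC each, and
#' models are ranked by AUC.
#'
#' @param features samples x taxa numeric matrix (relative abundances).
#' @param labels two-level grouping (e.g. Control / Pollution).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment and model fits.
#' @param models subset of `c("RF", "SVM", "LR")`.
#' @return named list per model: `auc`, `roc_points` (data.frame
#'   `fpr`, `tpr`), `prob` (out-of-fold probabilities), plus attribute
#'   `ranking` (models by decreasing AUC).
#' @export
compare_classifiers <- function(features, labels, folds = 5, seed = 1,
                                models = c("RF", "SVM", "LR")) {
  features <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  if (length(y) < 10) stop("need at least 10 samples")
  fold_id <- stratified_folds(y, folds, seed)
  out <- list()
  for (m in models) {
    prob <- numeric(length(y))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      prob[te] <- withr::with_seed(
        seed + 1000L * f,
        fit_predict_prob(m, features[!te, , drop = FALSE], y[!te],
                         features[te, , drop = FALSE]))
    }
    roc <- pROC::roc(response = y, predictor = prob, quiet = TRUE,
                     levels = levels(y), direction = "<")
    out[[m]] <- list(
      auc = as.numeric(pROC::auc(roc)),
      roc_points = {
        pts <- data.frame(fpr = 1 - roc$specificities,
                          tpr = roc$sensitivities)
        pts[order(pts$fpr, pts$tpr), , drop = FALSE]
      },
      prob = prob)
  }
  attr(out, "ranking") <- names(sort(vapply(out, `[[`, numeric(1), "auc"),
                                     decreasing = TRUE))
  out
}

#' Scan taxonomic levels by random-forest out-of-bag error
#'
#' Collapses the merged table to each requested level, transforms to
#' relative abundances, fits a random forest with default hyperparameters
#' (500 trees, sqrt(p) candidate features per split) and records the OOB
#' misclassification rate. The level with the lowest OOB error is the
#' natural level at which to build the indicator model.
#'
#' @param merged a merged [count_table()] with `group` metadata.
#' @param levels taxonomic levels to scan; `"otu"` means no collapsing.
#' @param seed integer seed.
#' @return data.frame `level`, `oob_error`, with attribute `best`
#'   (the argmin level).
#' @export
scan_taxonomic_levels <- function(merged,
                                  levels = c("phylum", "class", "order",
                                             "family", "genus", "otu"),
                                  seed = 1) {
  y <- droplevels(as.factor(merged$sample_meta$group))
  oob <- vapply(levels, function(lv) {
    tab <- collapse_taxa(merged, lv)
    x <- rel_abundance(tab)
    fit <- withr::with_seed(
      seed, randomForest::randomForest(x = data.frame(x, check.names = FALSE),
                                       y = y, ntree = 500))
    unname(fit$err.rate[fit$ntree, "OOB"])
  }, numeric(1))
  res <- data.frame(level = levels, oob_error = unname(oob),
                    stringsAsFactors = FALSE)
  attr(res, "best") <- levels[which.min(oob)]
  res
}

#' Repeated cross-validated random-forest importance per taxon
#'
#' Tenfold cross-validation with five repeats (defaults): in each
#' train fold a random forest is fitted with permutation importance, and
#' the per-taxon mean decrease in accuracy is averaged over all
#' folds x repeats, with its dispersion.
#'
#' @param features samples x taxa matrix (relative abundances).
#' @param labels two-level grouping.
#' @param folds,repeats cross-validation design (default 10 x 5).
#' @param seed integer seed.
#' @return data.frame `taxon`, `importance` (mean decrease in accuracy),
#'   `sd`, sorted by decreasing importance.
#' @export
cv_importance <- function(features, labels, folds = 10, repeats = 5,
                          seed = 1) {
  features <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  if (min(table(y)) < folds) stop("folds exceed the smallest class size")
  imp <- matrix(NA_real_, nrow = ncol(features), ncol = folds * repeats,
                dimnames = list(colnames(features), NULL))
  k <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds, seed + r)
    for (f in seq_len(folds)) {
      k <- k + 1L
      tr <- fold_id != f
      fit <- withr::with_seed(
        seed + 7777L * r + f,
        randomForest::randomForest(
          x = data.frame(features[tr, , drop = FALSE], check.names = FALSE),
          y = y[tr], ntree = 500, importance = TRUE))
      imp[, k] <- randomForest::importance(
        fit, type = 1, scale = FALSE)[colnames(features), 1]
    }
  }
  res <- data.frame(taxon = rownames(imp),
                    importance = rowMeans(imp),
                    sd = apply(imp, 1, stats::sd),
                    stringsAsFactors = FALSE)
  res[order(-res$importance, res$taxon), , drop = FALSE]
}

#' Select indicator taxa by importance x occupancy
#'
#' Combines min-max-normalized cross-validated importance with each
#' taxon's occupancy `f` (fraction of samples in which it is detected)
#' into the score `norm(importance) * f`, and ranks taxa by it
#' (lexicographic tie-break). Each taxon's class lineage is reported so
#' class-level claims about the top indicator are checkable.
#'
#' @param importance data.frame from [cv_importance()].
#' @param frequency data.frame with columns `taxon` and `f` (e.g. from
#'   [taxon_stats()] at genus level).
#' @param taxonomy optional taxonomy data.frame (`taxon_id`, `lineage`)
#'   used to annotate each taxon's class.
#' @return data.frame `taxon`, `importance`, `f`, `score`, `class`,
#'   ranked by decreasing score.
#' @export
select_indicator <- function(importance, frequency, taxonomy = NULL) {
  common <- intersect(importance$taxon, frequency$taxon)
  if (!length(common)) stop("no taxa shared between importance and frequency")
  imp <- importance$importance[match(common, importance$taxon)]
  f <- frequency$f[match(common, frequency$taxon)]
  rng <- range(imp)
  norm <- if (diff(rng) > 0) (imp - rng[1]) / diff(rng) else rep(1, length(imp))
  cls <- rep(NA_character_, length(common))
  if (!is.null(taxonomy)) {
    ranks <- parse_lineage(taxonomy$lineage[match(common, taxonomy$taxon_id)])
    cls <- ranks$class
  }
  res <- data.frame(taxon = common, importance = imp, f = f,
                    score = norm * f, class = cls,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$score, res$taxon), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Train/test random-forest prediction with per-class accuracy
#'
#' Stratified split (default 70/30), random forest on the training part,
#' confusion matrix and per-class accuracies on the held-out part, plus
#' the held-out AUC.
#'
#' @param features samples x taxa matrix.
#' @param labels two-level grouping.
#' @param split training fraction (default 0.7).
#' @param seed integer seed.
#' @return list: `confusion` (observed x predicted), `class_accuracy`,
#'   `auc`, `n_test`.
#' @export
train_test_predict <- function(features, labels, split = 0.7, seed = 1) {
  features <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  tr <- logical(length(y))
  withr::with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_tr <- round(split * length(idx))
      if (n_tr < 1 || n_tr >= length(idx)) stop("degenerate split")
      tr[sample(idx, n_tr)] <- TRUE
    }
  })
  fit <- withr::with_seed(
    seed + 1L,
    randomForest::randomForest(
      x = data.frame(features[tr, , drop = FALSE], check.names = FALSE),
      y = y[tr], ntree = 500))
  te_df <- data.frame(features[!tr, , drop = FALSE], check.names = FALSE)
  pred <- stats::predict(fit, te_df)
  prob <- stats::predict(fit, te_df, type = "prob")[, levels(y)[2]]
  confusion <- table(observed = y[!tr], predicted = pred)
  acc <- diag(prop.table(confusion, 1))
  roc <- pROC::roc(response = y[!tr], predictor = prob, quiet = TRUE,
                   levels = levels(y), direction = "<")
  list(confusion = confusion, class_accuracy = acc,
       auc = as.numeric(pROC::auc(roc)), n_test = sum(!tr))
}

#' Random-effects meta-analysis of a taxon across experiments
#'
#' Per experiment, the Pollution-vs-Control standardized mean difference
#' (Hedges' g) of the taxon's abundance is computed with its sampling
#' variance; studies are pooled with the DerSimonian-Laird
#' random-effects estimator, and a leave-one-out sensitivity analysis
#' reports the pooled effect with each study removed.
#'
#' @param data data.frame with columns `experiment_id`, `group`
#'   (`Control` / `Pollution`) and `value` (e.g. relative abundance).
#' @return list: `studies` (per-study `g`, `var`, `weight`), `pooled`,
#'   `se`, `ci_lb`, `ci_ub`, `tau2`, `p`, `loo` (leave-one-out pooled
#'   effects).
#' @export
random_effects_meta <- function(data) {
  stopifnot(all(c("experiment_id", "group", "value") %in% names(data)))
  exps <- unique(data$experiment_id)
  rows <- lapply(exps, function(e) {
    d <- data[data$experiment_id == e, ]
    a <- d$value[d$group == "Pollution"]
    b <- d$value[d$group == "Control"]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    data.frame(experiment_id = e,
               m1i = mean(a), sd1i = stats::sd(a), n1i = length(a),
               m2i = mean(b), sd2i = stats::sd(b), n2i = length(b))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 2) {
    stop("random-effects meta-analysis needs >= 2 studies with both groups")
  }
  zero_var <- rows$sd1i == 0 & rows$sd2i == 0
  if (any(zero_var)) {
    warning("zero-variance study variance floored: ",
            paste(rows$experiment_id[zero_var], collapse = ", "))
    eps <- 1e-6 * max(abs(c(rows$m1i, rows$m2i)), 1)
    rows$sd1i[zero_var] <- eps
  }
  es <- metafor::escalc(measure = "SMD", m1i = m1i, sd1i = sd1i, n1i = n1i,
                        m2i = m2i, sd2i = sd2i, n2i = n2i, data = rows)
  fit <- metafor::rma(yi, vi, data = es, method = "DL")
  loo <- metafor::leave1out(fit)
  list(studies = data.frame(experiment_id = rows$experiment_id,
                            g = as.numeric(es$yi), var = es$vi,
                            weight = stats::weights(fit)),
       pooled = as.numeric(fit$beta), se = fit$se,
       ci_lb = fit$ci.lb, ci_ub = fit$ci.ub,
       tau2 = fit$tau2, p = fit$pval,
       loo = data.frame(excluded = rows$experiment_id,
                        pooled = as.numeric(loo$estimate),
                        ci_lb = as.numeric(loo$ci.lb),
                        ci_ub = as.numeric(loo$ci.ub)))
}
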
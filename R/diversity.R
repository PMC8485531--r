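#' Alpha diversity (Shannon and Chao1) per sample
#'
#' Shannon uses natural logarithms on relative abundances
#' (via [vegan::diversity()]); Chao1 is the bias-corrected estimator
#' `S_obs + f1(f1-1)/(2(f2+1))` (via [vegan::estimateR()]).
#'
#' @param x a [count_table()] or samples x taxa count matrix.
#' @return data.frame with `sample_id`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (any(rowSums(m) == 0)) stop("all-zero sample: diversity undefined")
  est <- vegan::estimateR(round(m))
  data.frame(sample_id = rownames(m),
             shannon = unname(vegan::diversity(m, index = "shannon")),
             chao1 = unname(est["S.chao1", ]),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computed on per-sample relative abundances so that depth-equalized
#' (rarefied) samples are compared compositionally. Values lie in [0, 1].
#'
#' @param x a [count_table()] or samples x taxa matrix.
#' @return a `dist` object.
#' @export
bray_curtis <- function(x) {
  vegan::vegdist(rel_abundance(x), method = "bray")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA for a single grouping factor, the
#' Adonis test of vegan. The p-value is `(1 + #{perm F >= obs F}) /
#' (1 + n_perm)`.
#'
#' @param dist a `dist` or square symmetric matrix of dissimilarities.
#' @param labels grouping vector, one value per sample; at least two
#'   distinct groups required.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return list with `f` (pseudo-F), `r2`, `p`, `n_perm`.
#' @export
permanova_test <- function(dist, labels, n_perm = 9999, seed = 1) {
  d <- stats::as.dist(dist)
  labels <- as.factor(labels)
  n <- attr(d, "Size")
  if (length(labels) != n) stop("labels do not match the distance matrix")
  if (nlevels(droplevels(labels)) < 2) {
    stop("PERMANOVA needs at least two groups")
  }
  fit <- withr::with_seed(
    seed,
    vegan::adonis2(d ~ grp, data = data.frame(grp = labels),
                   permutations = n_perm)
  )
  list(f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}
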
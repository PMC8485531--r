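#' Null-corrected connectedness of each taxon
#'
#' Implements the cohesion framework's connectedness statistic. For each
#' taxon pair, the observed Pearson correlation of relative abundances is
#' corrected by subtracting the mean of null correlations obtained from a
#' taxa-shuffle null: one taxon's abundances are permuted across samples
#' `null_iters` times and the pair correlation recomputed. A taxon's
#' positive connectedness is the mean of its positive corrected pair
#' correlations (0 if none); its negative connectedness the mean of the
#' negative ones (0 if none). Taxa below the persistence (occupancy)
#' filter are removed first, since correlations of near-absent taxa are
#' unstable.
#'
#' The permutation stream is fully determined by `seed` and the fixed
#' pair order (j < k, iterations innermost), so independent
#' implementations consuming the same stream agree exactly.
#'
#' @param x a [count_table()] or samples x taxa matrix of counts or
#'   relative abundances (rows are renormalized internally).
#' @param null_iters permutations per pair (default 200).
#' @param persistence_min minimum occupancy for a taxon to enter
#'   (default 0.05).
#' @param seed integer seed.
#' @return data.frame `taxon`, `connectedness_pos` (>= 0),
#'   `connectedness_neg` (<= 0), with attribute `corrected` (the full
#'   corrected correlation matrix).
#' @export
connectedness <- function(x, null_iters = 200, persistence_min = 0.05,
                          seed = 1) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (nrow(m) < 4) stop("need at least 4 samples")
  m <- rel_abundance(m)
  keep <- colMeans(m > 0) >= persistence_min
  if (!any(keep)) stop("persistence filter removed all taxa")
  m <- m[, keep, drop = FALSE]
  T_ <- ncol(m); n <- nrow(m)
  corrected <- matrix(0, T_, T_, dimnames = list(colnames(m), colnames(m)))
  obs <- suppressWarnings(stats::cor(m))
  obs[is.na(obs)] <- 0
  withr::with_seed(seed, {
    if (T_ >= 2) {
      for (j in seq_len(T_ - 1L)) {
        xj <- m[, j]
        for (k in seq.int(j + 1L, T_)) {
          xk <- m[, k]
          null_sum <- 0
          for (it in seq_len(null_iters)) {
            null_sum <- null_sum +
              suppressWarnings(stats::cor(xj, xk[sample.int(n)]))
          }
          null_mean <- null_sum / null_iters
          if (is.na(null_mean)) null_mean <- 0
          corrected[j, k] <- corrected[k, j] <- obs[j, k] - null_mean
        }
      }
    }
  })
  pos <- neg <- numeric(T_)
  for (j in seq_len(T_)) {
    v <- corrected[j, -j]
    pv <- v[v > 0]; nv <- v[v < 0]
    pos[j] <- if (length(pv)) mean(pv) else 0
    neg[j] <- if (length(nv)) mean(nv) else 0
  }
  res <- data.frame(taxon = colnames(m), connectedness_pos = pos,
                    connectedness_neg = neg, stringsAsFactors = FALSE)
  attr(res, "corrected") <- corrected
  res
}

#' Positive and negative cohesion per sample
#'
#' Cohesion weights each sample's taxon relative abundances by the
#' taxon-level connectedness: for sample i,
#' `cohesion_pos(i) = sum_j a_ij * connectedness_pos(j)` and likewise for
#' the negative part, so `cohesion_pos >= 0 >= cohesion_neg` always. The
#' group-level stability index is the ratio
#' `|mean cohesion_neg| / mean cohesion_pos`.
#'
#' @param x the [count_table()] or matrix the connectedness was computed
#'   on.
#' @param conn result of [connectedness()].
#' @param groups optional grouping vector (one value per sample) for
#'   group-level ratios.
#' @return list with `samples` (data.frame `sample_id`, `cohesion_pos`,
#'   `cohesion_neg`) and `ratio` (overall, or per group when `groups`
#'   given; `NA` when mean positive cohesion is 0).
#' @export
cohesion <- function(x, conn, groups = NULL) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  m <- rel_abundance(m)
  taxa <- conn$taxon
  if (!all(taxa %in% colnames(m))) stop("connectedness taxa not in table")
  a <- m[, taxa, drop = FALSE]
  pos <- as.numeric(a %*% conn$connectedness_pos)
  neg <- as.numeric(a %*% conn$connectedness_neg)
  samples <- data.frame(sample_id = rownames(m), cohesion_pos = pos,
                        cohesion_neg = neg, stringsAsFactors = FALSE)
  ratio_of <- function(idx) {
    mp <- mean(pos[idx])
    if (mp == 0) return(NA_real_)
    abs(mean(neg[idx])) / mp
  }
  ratio <- if (is.null(groups)) {
    ratio_of(seq_along(pos))
  } else {
    vapply(split(seq_along(pos), groups), ratio_of, numeric(1))
  }
  list(samples = samples, ratio = ratio)
}

#' Cohesion of the subcommunity associated with a focal class
#'
#' Restricts the community to the focal class's taxa plus every taxon
#' with a significant co-occurrence edge to any focal member, then
#' recomputes connectedness and cohesion on that subset. This isolates
#' the stability contribution of a hub taxon's neighborhood.
#'
#' @param x a [count_table()] collapsed to the rank at which the focal
#'   taxa are named (typically class).
#' @param focal character vector of focal taxon labels (e.g. one class).
#' @param r_threshold,p_threshold edge thresholds passed to
#'   [cooccurrence_network()].
#' @param null_iters,persistence_min,seed passed to [connectedness()].
#' @param groups optional grouping for the ratio.
#' @return as [cohesion()], plus `members` (the subcommunity taxa).
#' @export
subcommunity_cohesion <- function(x, focal, r_threshold = 0.6,
                                  p_threshold = 0.05, null_iters = 200,
                                  persistence_min = 0.05, seed = 1,
                                  groups = NULL) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  focal <- intersect(focal, colnames(m))
  if (!length(focal)) stop("focal taxa absent from the table")
  net <- cooccurrence_network(m, r_threshold, p_threshold)
  touching <- unique(c(net$edges$from[net$edges$to %in% focal],
                       net$edges$to[net$edges$from %in% focal]))
  members <- union(focal, touching)
  sub <- m[, members, drop = FALSE]
  conn <- connectedness(sub, null_iters = null_iters,
                        persistence_min = persistence_min, seed = seed)
  res <- cohesion(sub, conn, groups = groups)
  res$members <- members
  res
}
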
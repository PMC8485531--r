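#' Per-taxon occupancy and abundance statistics
#'
#' For every taxon in a merged metastudy table, computes the ingredients
#' of the core index: occupancy `f` (fraction of all samples in which the
#' taxon is detected, detection = count > 0 after rarefaction), `n`
#' (number of experiments in which it is detected), `N` (total
#' experiments), `s` (total reads assigned to the taxon), `S` (total
#' reads in the table) and the mean per-sample relative abundance.
#'
#' @param merged a merged [count_table()] with `experiment_id` metadata.
#' @return data.frame, one row per taxon, columns `taxon`, `f`, `n`, `N`,
#'   `s`, `S`, `mean_rel_abund`.
#' @export
taxon_stats <- function(merged) {
  stopifnot(inherits(merged, "count_table"))
  m <- merged$counts
  if (nrow(m) == 0) stop("empty table")
  exps <- unique(merged$sample_meta$experiment_id)
  present <- m > 0
  f <- colMeans(present)
  n <- integer(ncol(m))
  for (e in exps) {
    rows <- merged$sample_meta$experiment_id == e
    n <- n + as.integer(colSums(present[rows, , drop = FALSE]) > 0)
  }
  s <- colSums(m)
  S <- sum(m)
  rel <- rel_abundance(m)
  data.frame(taxon = colnames(m), f = unname(f), n = n,
             N = length(exps), s = unname(s), S = S,
             mean_rel_abund = unname(colMeans(rel)),
             stringsAsFactors = FALSE)
}

#' Taxa shared by all experiments
#'
#' Returns the taxa whose per-experiment detection rate exceeds
#' `min_detect_fraction` in every experiment, together with the bipartite
#' experiment-taxon detection edge list used for shared-network
#' reporting.
#'
#' @param merged a merged [count_table()].
#' @param min_detect_fraction minimum within-experiment detection rate;
#'   the default 0 requires presence in at least one sample per
#'   experiment.
#' @return list with `shared` (character vector of taxa, in table order)
#'   and `edges` (data.frame `experiment_id`, `taxon`, `detect_rate`).
#' @export
shared_taxa <- function(merged, min_detect_fraction = 0) {
  stopifnot(inherits(merged, "count_table"))
  exps <- unique(merged$sample_meta$experiment_id)
  present <- merged$counts > 0
  rates <- sapply(exps, function(e) {
    rows <- merged$sample_meta$experiment_id == e
    colMeans(present[rows, , drop = FALSE])
  })
  rates <- matrix(rates, ncol = length(exps),
                  dimnames = list(colnames(merged$counts), exps))
  shared <- rownames(rates)[apply(rates > min_detect_fraction, 1, all)]
  edges <- data.frame(
    experiment_id = rep(exps, each = nrow(rates)),
    taxon = rep(rownames(rates), times = length(exps)),
    detect_rate = as.vector(rates),
    stringsAsFactors = FALSE)
  edges <- edges[edges$detect_rate > min_detect_fraction, , drop = FALSE]
  rownames(edges) <- NULL
  list(shared = shared, edges = edges)
}

#' Core index (CI) of each taxon
#'
#' The core index scores a taxon's symbiotic potential across a
#' metastudy by multiplicatively combining its three occupancy-abundance
#' ingredients: sample occupancy `f`, cross-experiment ubiquity `n/N`,
#' and aggregate read share `s/S`:
#' \deqn{CI = f \cdot (n/N) \cdot (s/S)}
#' The index is zero exactly for undetected taxa and strictly increasing
#' in each ingredient. An alternative formula (e.g. a transcription of a
#' published variant) can be supplied via `formula`.
#'
#' @param stats data.frame from [taxon_stats()].
#' @param formula function of `(f, n, N, s, S)` returning the index;
#'   defaults to the product form above.
#' @return `stats` with a `CI` column appended.
#' @export
core_index <- function(stats, formula = NULL) {
  if (any(stats$S <= 0)) stop("S must be positive")
  if (is.null(formula)) {
    formula <- function(f, n, N, s, S) f * (n / N) * (s / S)
  }
  stats$CI <- formula(stats$f, stats$n, stats$N, stats$s, stats$S)
  stopifnot(all(stats$CI >= 0))
  stats
}

#' Normalized core index (NorCI)
#'
#' Scales CI by its maximum over all detected taxa, so the top-ranked
#' taxon has NorCI = 1 and thresholds on a 0-1 scale are meaningful.
#' Sum-normalization (`method = "sum"`) is available as an alternative.
#'
#' @param stats data.frame with a `CI` column (see [core_index()]).
#' @param method `"max"` (default) or `"sum"`.
#' @return `stats` with a `NorCI` column appended.
#' @export
normalize_ci <- function(stats, method = c("max", "sum")) {
  method <- match.arg(method)
  if (all(stats$CI == 0)) stop("all CI values are zero")
  denom <- if (method == "max") max(stats$CI) else sum(stats$CI)
  stats$NorCI <- stats$CI / denom
  stats
}

#' Partition taxa into core, transient and rare fractions
#'
#' Applies the NorCI thresholds: core when `NorCI >= hi`, transient when
#' `lo <= NorCI < hi`, rare otherwise (both bounds closed from below).
#' Also reports each category's total share of reads, which sums to 100%.
#'
#' @param stats data.frame with `NorCI` and `s`, `S` columns.
#' @param thresholds numeric `(hi, lo)`; defaults `c(0.83, 0.3)`.
#' @return list with `stats` (a `category` column appended) and
#'   `category_abundance` (named percentages summing to 100).
#' @export
classify_taxa <- function(stats, thresholds = c(0.83, 0.3)) {
  hi <- thresholds[1]; lo <- thresholds[2]
  stopifnot(hi > lo, hi > 0, hi <= 1, lo > 0)
  cat <- ifelse(stats$NorCI >= hi, "core",
                ifelse(stats$NorCI >= lo, "transient", "rare"))
  stats$category <- cat
  share <- tapply(stats$s, factor(cat, levels = c("core", "transient",
                                                  "rare")), sum)
  share[is.na(share)] <- 0
  abund <- 100 * share / stats$S[1]
  list(stats = stats, category_abundance = abund)
}

#' Full core-partition analysis of a merged metastudy table
#'
#' Convenience wrapper chaining [taxon_stats()], [core_index()],
#' [normalize_ci()] and [classify_taxa()].
#'
#' @param merged a merged [count_table()].
#' @inheritParams classify_taxa
#' @inheritParams core_index
#' @param norm normalization method for [normalize_ci()].
#' @return list with `stats` (full per-taxon table including `CI`,
#'   `NorCI`, `category`) and `category_abundance`.
#' @export
core_partition <- function(merged, thresholds = c(0.83, 0.3),
                           formula = NULL, norm = "max") {
  st <- taxon_stats(merged)
  st <- core_index(st, formula = formula)
  st <- normalize_ci(st, method = norm)
  classify_taxa(st, thresholds = thresholds)
}
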
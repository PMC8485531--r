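#' High-area-activity (HAA) index of one locomotion timepoint
#'
#' Scores how far out on the concentric-ring test map the individuals
#' are: with per-ring weights `w` (default the ring index 1..5,
#' increasing outward), `HAA = sum_i w_i c_i / (max(w) * n)`. All
#' individuals in the innermost ring give the minimum `w_1/max(w)`
#' (0.2 under default weights); all in the outermost ring give 1.
#' Moving any individual outward strictly increases the index. A custom
#' weighting can be supplied to register an alternative published form.
#'
#' @param counts integer vector of individuals per ring (innermost
#'   first).
#' @param weights strictly increasing per-ring weights (default
#'   `seq_along(counts)`).
#' @param n_individuals expected column total; defaults to
#'   `sum(counts)`, and a mismatch is an error.
#' @return HAA value in `[weights[1]/max(weights), 1]`.
#' @export
haa_index <- function(counts, weights = seq_along(counts),
                      n_individuals = sum(counts)) {
  stopifnot(length(weights) == length(counts), all(diff(weights) > 0),
            all(counts >= 0))
  if (sum(counts) != n_individuals) {
    stop("ring counts do not sum to n_individuals")
  }
  sum(weights * counts) / (max(weights) * n_individuals)
}

#' Motility slope K from an HAA time series
#'
#' Ordinary least-squares slope of the HAA index against time in
#' minutes; K summarizes how quickly the cohort spreads outward.
#'
#' @param haa numeric HAA values.
#' @param timepoints times in minutes (same length).
#' @return list `k` (slope), `intercept`, `r2`.
#' @export
motility_slope <- function(haa, timepoints) {
  stopifnot(length(haa) == length(timepoints), length(haa) >= 2)
  if (stats::sd(timepoints) == 0) stop("constant time vector")
  fit <- stats::lm(haa ~ timepoints)
  # summary.lm warns on an exact fit; the r-squared is still valid
  r2 <- if (stats::sd(haa) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  list(k = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r2 = r2)
}

#' HAA series and slope for a simulated or measured locomotion table
#'
#' @param loco ring x timepoint count matrix (see
#'   [simulate_locomotion()]); column names `t<minutes>`.
#' @param weights per-ring weights (default ring index).
#' @return list `haa` (per-timepoint index), `k`, `intercept`, `r2`.
#' @export
locomotion_summary <- function(loco, weights = seq_len(nrow(loco))) {
  tp <- as.numeric(sub("^t", "", colnames(loco)))
  haa <- apply(loco, 2, haa_index, weights = weights)
  c(list(haa = haa), motility_slope(haa, tp))
}

#' Welch's two-sample t test
#'
#' Two-tailed Welch statistic with Satterthwaite degrees of freedom, the
#' group-comparison test used throughout phenotype analyses. Identical
#' constant groups return `t = 0, p = 1` rather than an error.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' OLS regression of a phenotype on taxon abundance
#'
#' Ordinary least-squares fit of a phenotype value on a taxon's relative
#' abundance. Reported as the signed coefficient of determination
#' `sign(slope) * R^2` (the convention under which a negative value
#' encodes a negative association), alongside the unsigned `R^2` and the
#' slope t-test p-value.
#'
#' @param x taxon relative abundance per replicate.
#' @param y phenotype value per replicate.
#' @return list `slope`, `intercept`, `r2`, `signed_r2`, `p`.
#' @export
taxon_phenotype_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("constant abundance vector")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a summary warning
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared, signed_r2 = sign(slope) * sm$r.squared,
       p = sm$coefficients[2, 4])
}
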
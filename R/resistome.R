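#' Read an HT-qPCR CT matrix from CSV
#'
#' Expected columns: `gene_id`, `gene_class` (ARG / MGE / 16S),
#' `bio_rep`, `tech_rep`, `ct` (empty = no amplification). Each
#' (gene, bio, tech) well may appear at most once.
#'
#' @param path CSV file.
#' @return data.frame in the long CT-matrix layout.
#' @export
read_ct_matrix <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "gene_class", "bio_rep", "tech_rep", "ct")
  if (!all(req %in% names(ct))) {
    stop("CT matrix needs columns: ", paste(req, collapse = ", "))
  }
  ct$ct <- suppressWarnings(as.numeric(ct$ct))
  validate_ct(ct)
  ct
}

validate_ct <- function(ct) {
  key <- paste(ct$gene_id, ct$bio_rep, ct$tech_rep)
  if (anyDuplicated(key)) stop("duplicate (gene, bio, tech) wells")
  if (any(!is.na(ct$ct) & (ct$ct <= 0 | ct$ct > 40))) {
    stop("CT values must lie in (0, 40]")
  }
  invisible(ct)
}

#' Detect genes under the replicate amplification rule
#'
#' A gene is detected iff at least `min_bio` biological replicates each
#' have at least `min_tech` technical replicates amplified below the
#' threshold cycle (strictly `ct < ct_threshold`; non-amplified wells,
#' encoded `NA`, never count). This is the standard 3 technical + 3
#' biological replicate rule with a cycle-31 threshold.
#'
#' @param ct long CT data.frame (see [read_ct_matrix()]).
#' @param ct_threshold detection threshold cycle (default 31).
#' @param min_tech,min_bio replicate requirements (default 3 + 3).
#' @param strict if `FALSE`, wells at exactly the threshold also count.
#' @return character vector of detected gene ids.
#' @export
detect_genes <- function(ct, ct_threshold = 31, min_tech = 3, min_bio = 3,
                         strict = TRUE) {
  validate_ct(ct)
  if (any(ct$bio_rep < 1 | ct$tech_rep < 1 |
          ct$bio_rep != round(ct$bio_rep) | ct$tech_rep != round(ct$tech_rep))) {
    stop("malformed replicate indices")
  }
  amp <- !is.na(ct$ct) &
    (if (strict) ct$ct < ct_threshold else ct$ct <= ct_threshold)
  per_bio <- stats::aggregate(amp, by = list(gene_id = ct$gene_id,
                                             bio_rep = ct$bio_rep), FUN = sum)
  ok_bio <- per_bio$x >= min_tech
  per_gene <- tapply(ok_bio, per_bio$gene_id, sum)
  sort(names(per_gene)[per_gene >= min_bio])
}

#' Relative copy number from a threshold cycle
#'
#' The chip's relative quantification: `10^((31 - CT) / (10/3))`, so a
#' gene amplifying exactly at cycle 31 has copy number 1 and every 10/3
#' cycles earlier multiplies it tenfold. Log-linear:
#' `log10(copy_number) = 0.3 * (31 - CT)` exactly.
#'
#' @param ct_value numeric CT value(s).
#' @param ct_threshold reference cycle (default 31).
#' @return relative copy number(s), strictly decreasing in CT.
#' @export
copy_number <- function(ct_value, ct_threshold = 31) {
  if (!is.numeric(ct_value)) stop("ct_value must be numeric")
  10^((ct_threshold - ct_value) / (10 / 3))
}

#' Per-sample gene abundance, raw and normalized to 16S
#'
#' For each detected gene and biological replicate (the sample unit of
#' the chip), the copy number is averaged over amplified technical
#' replicates; division by the 16S reference copy number of the same
#' replicate gives the per-16S relative abundance (the standard chip
#' convention). Both scales are reported.
#'
#' @param ct long CT data.frame.
#' @param detected gene ids passing [detect_genes()]; default recomputed.
#' @param ct_threshold threshold cycle used for amplification and the
#'   copy-number transform.
#' @param reference_gene id of the 16S reference (default `"16S"`).
#' @return data.frame `gene_id`, `bio_rep`, `copy_number`,
#'   `per_16s` (`NA` with a warning when the reference is missing).
#' @export
gene_abundance <- function(ct, detected = NULL, ct_threshold = 31,
                           reference_gene = "16S") {
  validate_ct(ct)
  if (is.null(detected)) detected <- detect_genes(ct, ct_threshold)
  amp <- ct[!is.na(ct$ct) & ct$ct < ct_threshold, , drop = FALSE]
  ref <- amp[amp$gene_id == reference_gene, , drop = FALSE]
  ref16 <- tapply(copy_number(ref$ct, ct_threshold), ref$bio_rep, mean)
  d <- amp[amp$gene_id %in% detected & amp$gene_id != reference_gene, ,
           drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(gene_id = character(), bio_rep = integer(),
                      copy_number = numeric(), per_16s = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(copy_number(d$ct, ct_threshold),
                          by = list(gene_id = d$gene_id,
                                    bio_rep = d$bio_rep), FUN = mean)
  names(agg)[3] <- "copy_number"
  agg$per_16s <- agg$copy_number / as.numeric(ref16[as.character(agg$bio_rep)])
  if (anyNA(agg$per_16s)) {
    warning("16S reference missing for some replicates; ",
            "per-16S abundance reported as NA")
  }
  agg[order(agg$gene_id, agg$bio_rep), , drop = FALSE]
}

#' Correlate taxon abundance with resistance-gene abundance
#'
#' Correlates each taxon's per-sample relative abundance with a summary
#' ARG abundance per sample (total, or per drug class), with
#' Benjamini-Hochberg adjusted q-values across taxa. Constant taxon
#' vectors have undefined correlation and are excluded with a warning.
#'
#' @param taxon_abund samples x taxa matrix of relative abundances, or a
#'   data.frame of per-sample taxon abundances.
#' @param arg_abund numeric vector of ARG abundance, one value per
#'   sample (same order as rows of `taxon_abund`).
#' @param method correlation method (default `"spearman"`).
#' @return data.frame `taxon`, `r`, `p`, `q`, sorted by q.
#' @export
arg_taxon_correlation <- function(taxon_abund, arg_abund,
                                  method = "spearman") {
  m <- as.matrix(taxon_abund)
  if (nrow(m) != length(arg_abund)) stop("unpaired samples")
  if (nrow(m) < 4) stop("need at least 4 paired samples")
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("excluding constant taxa: ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  res <- do.call(rbind, lapply(colnames(m), function(tx) {
    ct <- suppressWarnings(
      stats::cor.test(m[, tx], arg_abund, method = method, exact = FALSE))
    data.frame(taxon = tx, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$q, res$taxon), , drop = FALSE]
}
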
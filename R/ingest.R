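#' Rarefy a count table to even depth
#'
#' Subsamples every sample without replacement (hypergeometric subsampling,
#' via [vegan::rrarefy()]) to exactly `depth` reads. Samples whose total is
#' below `depth` are dropped with a message, matching the usual
#' minimum-depth filter applied before merging heterogeneous studies.
#'
#' @param x a [count_table()].
#' @param depth target reads per sample (default 2000, the depth used to
#'   harmonize multi-study gut amplicon data).
#' @param seed integer seed; subsampling is reproducible.
#' @return a rarefied `count_table`; every retained row sums to `depth`.
#' @export
rarefy_counts <- function(x, depth = 2000, seed = 1) {
  stopifnot(inherits(x, "count_table"), depth >= 1)
  totals <- rowSums(x$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no samples survive rarefaction at depth ", depth)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(x$counts)[!keep], collapse = ", "))
  }
  m <- x$counts[keep, , drop = FALSE]
  rar <- withCallingHandlers(
    withr::with_seed(seed, vegan::rrarefy(m, depth)),
    warning = function(w) {
      # vegan heuristically warns when the smallest count exceeds 1;
      # irrelevant for already-validated integer tables
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  rar <- as.matrix(rar)
  dimnames(rar) <- dimnames(m)
  count_table(rar,
              x$sample_meta[keep, , drop = FALSE],
              x$taxonomy[, c("taxon_id", "lineage")])
}

#' Collapse a count table to a taxonomic rank
#'
#' Sums counts over taxa sharing the same label at `rank`. Taxa whose
#' lineage is empty at that rank are pooled into
#' `unclassified_<nearest named parent rank label>` so no reads are lost.
#'
#' @param x a [count_table()].
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, or `"otu"` (identity: no collapsing).
#' @return a `count_table` at the requested rank; total reads are
#'   conserved.
#' @export
collapse_taxa <- function(x, rank = "class") {
  stopifnot(inherits(x, "count_table"))
  if (rank == "otu") return(x)
  ranks <- tax_ranks()
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  ri <- match(rank, ranks)
  labels <- x$taxonomy[[rank]]
  # pool unknown-rank taxa under their nearest classified parent
  for (i in which(is.na(labels) | labels == "")) {
    parent <- ""
    for (j in rev(seq_len(ri - 1L))) {
      v <- x$taxonomy[[ranks[j]]][i]
      if (!is.na(v) && nzchar(v)) { parent <- v; break }
    }
    labels[i] <- paste0("unclassified_", if (nzchar(parent)) parent else "root")
  }
  groups <- factor(labels, levels = unique(labels))
  collapsed <- t(rowsum(t(x$counts), groups))
  colnames(collapsed) <- levels(groups)

  # retain the lineage prefix shared within each collapsed group
  keep_ranks <- ranks[seq_len(ri)]
  lin <- vapply(levels(groups), function(g) {
    idx <- which(groups == g)[1]
    row <- x$taxonomy[idx, keep_ranks, drop = FALSE]
    if (startsWith(g, "unclassified_")) row[[rank]] <- g
    make_lineage(row)
  }, character(1))
  taxonomy <- data.frame(taxon_id = levels(groups), lineage = unname(lin),
                         stringsAsFactors = FALSE)
  count_table(collapsed, x$sample_meta, taxonomy)
}

#' Merge per-experiment count tables into one metastudy table
#'
#' Takes the union of taxa, zero-filling absences, and concatenates
#' samples. Sample ids must be unique across experiments; experiment
#' labels in the metadata are preserved. The merge is lossless: slicing
#' the merged table back to one experiment's samples and taxa reproduces
#' the input.
#'
#' @param tables list of [count_table()] objects with compatible rank
#'   labels.
#' @return a merged `count_table`.
#' @export
merge_experiments <- function(tables) {
  stopifnot(length(tables) >= 1)
  all_ids <- unlist(lapply(tables, function(t) rownames(t$counts)))
  if (anyDuplicated(all_ids)) {
    stop("duplicate sample id across experiments: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  taxa <- unique(unlist(lapply(tables, function(t) colnames(t$counts))))
  m <- matrix(0, nrow = length(all_ids), ncol = length(taxa),
              dimnames = list(all_ids, taxa))
  for (t in tables) {
    m[rownames(t$counts), colnames(t$counts)] <- t$counts
  }
  meta <- do.call(rbind, lapply(tables, function(t) {
    t$sample_meta[, intersect(names(t$sample_meta),
                              c("sample_id", "experiment_id", "group",
                                "host")), drop = FALSE]
  }))
  tax <- do.call(rbind, lapply(tables, function(t) {
    t$taxonomy[, c("taxon_id", "lineage")]
  }))
  tax <- tax[!duplicated(tax$taxon_id), , drop = FALSE]
  count_table(m, meta, tax)
}

#' Slice a merged table to one experiment
#' @param x merged `count_table`.
#' @param experiment_id experiment label.
#' @param drop_absent drop taxa with zero counts in the slice.
#' @return a `count_table` restricted to that experiment's samples.
#' @export
subset_experiment <- function(x, experiment_id, drop_absent = TRUE) {
  keep <- x$sample_meta$experiment_id == experiment_id
  if (!any(keep)) stop("unknown experiment: ", experiment_id)
  m <- x$counts[keep, , drop = FALSE]
  if (drop_absent) m <- m[, colSums(m) > 0, drop = FALSE]
  count_table(m, x$sample_meta[keep, , drop = FALSE],
              x$taxonomy[x$taxonomy$taxon_id %in% colnames(m),
                         c("taxon_id", "lineage")])
}
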
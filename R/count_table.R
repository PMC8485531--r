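#' Analysis-ready taxon count table
#'
#' `count_table()` bundles a samples x taxa matrix of non-negative integer
#' counts with per-sample metadata and per-taxon lineages. It is the
#' substrate of every community-level stage: rarefaction, taxonomic
#' collapse, merging, diversity, core-index and stability analyses.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   unique row and column names. Counts must be non-negative integers.
#' @param sample_meta data.frame with at least `sample_id`,
#'   `experiment_id` and `group` (values `"Control"` / `"Pollution"`);
#'   an optional `host` column is carried through. One row per sample.
#' @param taxonomy data.frame with columns `taxon_id` and `lineage`
#'   (QIIME-style `d__;p__;c__;o__;f__;g__` string). Taxa missing from
#'   the table get a warning and an empty lineage.
#'
#' @return An object of class `count_table`: a list with elements
#'   `counts`, `sample_meta`, `taxonomy` (taxonomy expanded into rank
#'   columns `domain` ... `genus`).
#' @export
count_table <- function(counts, sample_meta, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("no samples: count table is empty")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample (row) and taxon (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("non-integer counts are not allowed")
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)

  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "experiment_id", "group")
  if (!all(req %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(req, collapse = ", "))
  }
  if (!setequal(sample_meta$sample_id, rownames(counts))) {
    stop("sample_meta does not match the samples in `counts`")
  }
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL

  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = colnames(counts), lineage = "",
                           stringsAsFactors = FALSE)
  }
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(taxonomy))) {
    stop("taxonomy needs columns taxon_id and lineage")
  }
  missing_tax <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(missing_tax)) {
    warning("no taxonomy for ", length(missing_tax),
            " taxa; assigning empty lineages")
    taxonomy <- rbind(taxonomy[, c("taxon_id", "lineage")],
                      data.frame(taxon_id = missing_tax, lineage = "",
                                 stringsAsFactors = FALSE))
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ,
                       drop = FALSE]
  rownames(taxonomy) <- NULL
  taxonomy <- cbind(taxonomy[, c("taxon_id", "lineage")],
                    parse_lineage(taxonomy$lineage))

  structure(list(counts = counts, sample_meta = sample_meta,
                 taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa\n", sep = "")
  cat("experiments: ", length(unique(x$sample_meta$experiment_id)),
      "; groups: ", paste(sort(unique(x$sample_meta$group)), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

# canonical rank order used throughout
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

#' Parse QIIME-style lineage strings into rank columns
#'
#' Splits `d__...;p__...;c__...;o__...;f__...;g__...` strings into a
#' data.frame with columns `domain` through `genus`. Missing or empty
#' ranks become `""`.
#'
#' @param lineage character vector of lineage strings.
#' @return data.frame with one column per rank.
#' @export
parse_lineage <- function(lineage) {
  prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  out <- matrix("", nrow = length(lineage), ncol = length(prefixes),
                dimnames = list(NULL, names(prefixes)))
  parts <- strsplit(ifelse(is.na(lineage), "", lineage), ";")
  for (i in seq_along(parts)) {
    for (p in trimws(parts[[i]])) {
      hit <- which(startsWith(p, prefixes))
      if (length(hit) == 1L) {
        out[i, hit] <- substring(p, 4L)
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Build a lineage string from rank labels
#' @param ranks data.frame or named character vector with entries for
#'   `domain` ... `genus` (missing ranks allowed).
#' @return character vector of `d__;p__;...` strings.
#' @export
make_lineage <- function(ranks) {
  if (!is.data.frame(ranks)) ranks <- as.data.frame(as.list(ranks))
  prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__")
  cols <- sapply(names(prefixes), function(r) {
    v <- if (r %in% names(ranks)) as.character(ranks[[r]]) else ""
    paste0(prefixes[[r]], v)
  })
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1)
  apply(cols, 1, paste, collapse = ";")
}

#' Per-sample relative abundances
#' @param x a `count_table` or a samples x taxa matrix.
#' @return matrix of row-normalized abundances.
#' @export
rel_abundance <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("all-zero sample: relative abundance undefined")
  sweep(m, 1, rs, "/")
}

#' Number of samples / taxa in a count table
#' @param x a `count_table`.
#' @return integer.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname n_samples
#' @export
n_taxa <- function(x) ncol(x$counts)
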
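#' Read a taxon count table from TSV or BIOM
#'
#' TSV tables are taxa x samples (first column the taxon id), the layout
#' most amplicon pipelines emit; BIOM 1.0 (JSON) tables follow the BIOM
#' convention of observations in rows. Orientation is normalized to
#' samples x taxa on read. A TSV whose id column is named `sample_id`
#' is taken to be samples x taxa already; `sample_ids` (e.g. from the
#' metadata file) disambiguates any other layout.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param sample_meta optional data.frame (`sample_id`, `experiment_id`,
#'   `group`, ...). When omitted a minimal placeholder is built so the
#'   fragment can still be inspected before merging.
#' @param taxonomy optional taxonomy data.frame (`taxon_id`, `lineage`).
#' @param sample_ids optional character vector used to detect orientation.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             sample_meta = NULL, taxonomy = NULL,
                             sample_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    raw <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(raw) == 0L || ncol(raw) < 2L) stop("no samples: empty table")
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids)) stop("duplicate taxon ids in ", path)
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- ids
    idcol <- names(raw)[1]
    samples_in_rows <- identical(tolower(idcol), "sample_id")
    if (!is.null(sample_ids)) {
      row_hits <- length(intersect(rownames(m), sample_ids))
      col_hits <- length(intersect(colnames(m), sample_ids))
      samples_in_rows <- row_hits > col_hits
    }
    counts <- if (samples_in_rows) m else t(m)
  } else {
    b <- biomformat::read_biom(path)
    counts <- t(as.matrix(biomformat::biom_data(b)))
  }
  if (!is.numeric(counts)) stop("non-numeric counts in ", path)
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = rownames(counts),
                              experiment_id = "unknown", group = NA_character_,
                              stringsAsFactors = FALSE)
  } else {
    sample_meta <- sample_meta[sample_meta$sample_id %in% rownames(counts), ,
                               drop = FALSE]
  }
  count_table(counts, sample_meta, taxonomy)
}

#' Write a count table to TSV and/or BIOM
#'
#' TSV output is taxa x samples with the taxon id in the first column,
#' mirroring [read_count_table()].
#'
#' @param x a `count_table`.
#' @param path output file.
#' @param format `"tsv"` or `"biom"`.
#' @export
write_count_table <- function(x, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon_id = colnames(x$counts),
                     t(x$counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    b <- biomformat::make_biom(t(x$counts))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read / write sample metadata and taxonomy TSVs
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "experiment_id", "group")
  if (!all(req %in% names(meta))) {
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  }
  meta
}

#' @rdname read_sample_meta
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(tax))) {
    stop("taxonomy needs columns taxon_id and lineage")
  }
  tax
}

#' @rdname read_sample_meta
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
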
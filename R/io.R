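# Text I/O. Dialect: tab-separated, UTF-8, "." decimal, one header row,
# no quoting of numeric fields (matches the obitools/metabarcoding ecosystem).

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8", na.strings = "NA",
                    colClasses = NA)
}

write_tsv_strict <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  path
}

#' Read a MOTU table from its TSV trio
#'
#' Reads the canonical three-file representation — a counts table
#' (`motu_id` column plus one column per sample), a taxonomy table
#' (`motu_id`, `rank`, `kingdom` ... `species`, `best_identity`) and a sample
#' metadata table (`sample_id`, `sample_type`, `site`, `estuary`, `country`,
#' `pool_size`) — and joins them into a validated [motu_table()]. Samples or
#' MOTUs present in one file but absent from another raise an error naming the
#' offending id; nothing is silently dropped.
#'
#' Deposited archives from other pipelines may use different column names;
#' rename columns to this layout before reading (a one-line adapter in most
#' cases).
#'
#' @param counts_path,taxonomy_path,metadata_path Paths to the three
#'   tab-separated files.
#' @return A validated `motu_table`.
#' @seealso [write_motu_table()]
#' @export
read_motu_table <- function(counts_path, taxonomy_path, metadata_path) {
  cnt <- read_tsv_strict(counts_path)
  tax <- read_tsv_strict(taxonomy_path)
  meta <- read_tsv_strict(metadata_path)

  if (!"motu_id" %in% names(cnt))
    stop_validation("counts file lacks a motu_id column: ", counts_path)
  ids <- as.character(cnt$motu_id)
  m <- as.matrix(cnt[, setdiff(names(cnt), "motu_id"), drop = FALSE])
  if (length(m) && !is.numeric(m))
    stop_validation("non-numeric count in ", counts_path)
  rownames(m) <- ids
  for (col in TAX_RANKS) {
    if (col %in% names(tax)) {
      tax[[col]] <- as.character(tax[[col]])
      tax[[col]][is.na(tax[[col]])] <- ""
    }
  }
  if ("best_identity" %in% names(tax))
    tax$best_identity <- as.numeric(tax$best_identity)
  motu_table(m, tax, meta)
}

#' Write a MOTU table as its TSV trio
#'
#' Writes `<prefix>_counts.tsv`, `<prefix>_taxonomy.tsv` and
#' `<prefix>_metadata.tsv`. Reading the trio back with [read_motu_table()]
#' reproduces the table exactly (bit-identical counts, identical metadata).
#'
#' @param table A `motu_table`.
#' @param out_prefix Path prefix for the three output files.
#' @return Named character vector of the written paths (`counts`, `taxonomy`,
#'   `metadata`), invisibly.
#' @export
write_motu_table <- function(table, out_prefix) {
  stopifnot(inherits(table, "motu_table"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop_validation("output directory does not exist: ", dir)
  paths <- c(counts = paste0(out_prefix, "_counts.tsv"),
             taxonomy = paste0(out_prefix, "_taxonomy.tsv"),
             metadata = paste0(out_prefix, "_metadata.tsv"))
  ids <- rownames(table$counts)
  if (is.null(ids)) ids <- character(0)
  cnt <- data.frame(motu_id = ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  storage <- table$counts
  storage.mode(storage) <- "integer"
  cnt <- cbind(cnt, as.data.frame(storage, check.names = FALSE))
  write_tsv_strict(cnt, paths[["counts"]])
  write_tsv_strict(table$taxonomy, paths[["taxonomy"]])
  write_tsv_strict(table$samples, paths[["metadata"]])
  invisible(paths)
}
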
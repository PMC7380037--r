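#' @keywords internal
"_PACKAGE"

# Canonical enumerations used throughout the package.
SAMPLE_TYPES <- c("stomach", "sediment", "empty_stomach", "negative_control")
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
RANK_LEVELS <- c(TAX_RANKS[length(TAX_RANKS):1], "unassigned") # species..kingdom, unassigned

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("trophodiet_validation_error", "error")))
}

#' Construct a MOTU-by-sample read-count table
#'
#' The single currency of the pipeline: a non-negative integer read-count
#' matrix (MOTUs in rows, samples in columns) joined to per-MOTU taxonomy and
#' per-sample metadata. All components are validated on construction; malformed
#' input raises a condition of class `trophodiet_validation_error` rather than
#' producing a partially built object.
#'
#' @param counts Integer matrix with MOTU ids as row names and sample ids as
#'   column names. All entries must be non-negative whole numbers.
#' @param taxonomy Data frame with columns `motu_id`, `rank` (one of species,
#'   genus, family, order, class, phylum, kingdom, unassigned), the seven
#'   Linnaean rank columns `kingdom` ... `species` (empty string for
#'   unassigned levels) and `best_identity` (alignment identity of the best
#'   reference match, in \[0, 1\]).
#' @param samples Data frame with columns `sample_id`, `sample_type` (stomach,
#'   sediment, empty_stomach or negative_control), `site`, `estuary`,
#'   `country` and `pool_size` (number of stomachs pooled, 1-8; `NA` for
#'   non-stomach samples).
#' @return An object of class `motu_table`.
#' @examples
#' tab <- motu_table(
#'   counts = matrix(c(5L, 0L, 3L, 7L), 2, 2,
#'     dimnames = list(c("M1", "M2"), c("S1", "S2"))),
#'   taxonomy = data.frame(
#'     motu_id = c("M1", "M2"), rank = "species",
#'     kingdom = "Metazoa", phylum = "Arthropoda", class = "", order = "",
#'     family = "", genus = "", species = c("A a", "B b"), best_identity = 1),
#'   samples = data.frame(
#'     sample_id = c("S1", "S2"), sample_type = c("stomach", "sediment"),
#'     site = "X", estuary = "E", country = "NL", pool_size = c(8L, NA)))
#' tab
#' @export
motu_table <- function(counts, taxonomy, samples) {
  counts <- as.matrix(counts)
  # plain double matrix: strip any table/array subclass picked up upstream
  counts <- matrix(as.numeric(counts), nrow = nrow(counts), ncol = ncol(counts),
                   dimnames = dimnames(counts))
  x <- structure(
    list(counts = counts, taxonomy = as.data.frame(taxonomy),
         samples = as.data.frame(samples)),
    class = "motu_table")
  validate_motu_table(x)
}

#' Validate a `motu_table`
#'
#' Checks every structural invariant of the container: integral non-negative
#' counts, exact agreement between the count matrix indices and the taxonomy /
#' metadata keys, no duplicate ids, sample types within the enumeration,
#' `best_identity` in \[0, 1\], pool sizes in 1-8, species-rank MOTUs carrying a
#' species name, and a one-to-one site-to-estuary mapping.
#'
#' @param x A `motu_table` (or list with the same components).
#' @return `x`, invisibly coerced to class `motu_table`, if valid; otherwise an
#'   error of class `trophodiet_validation_error`.
#' @export
validate_motu_table <- function(x) {
  counts <- x$counts
  tax <- x$taxonomy
  meta <- x$samples

  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    stop_validation("count matrix must have MOTU ids as row names")
  if (is.null(colnames(counts)) && ncol(counts) > 0L)
    stop_validation("count matrix must have sample ids as column names")
  if (anyNA(counts)) stop_validation("missing value in count matrix")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop_validation("negative count for MOTU '", rownames(counts)[bad[1L]],
                    "' in sample '", colnames(counts)[bad[2L]], "'")
  }
  if (any(counts != floor(counts)))
    stop_validation("non-integer count in count matrix")
  if (anyDuplicated(rownames(counts)))
    stop_validation("duplicate motu_id in count matrix: ",
                    rownames(counts)[anyDuplicated(rownames(counts))])
  if (anyDuplicated(colnames(counts)))
    stop_validation("duplicate sample_id in count matrix: ",
                    colnames(counts)[anyDuplicated(colnames(counts))])

  need_tax <- c("motu_id", "rank", TAX_RANKS, "best_identity")
  miss <- setdiff(need_tax, names(tax))
  if (length(miss)) stop_validation("taxonomy lacks column(s): ",
                                    paste(miss, collapse = ", "))
  if (anyDuplicated(tax$motu_id))
    stop_validation("duplicate motu_id in taxonomy")
  only_tax <- setdiff(tax$motu_id, rownames(counts))
  only_cnt <- setdiff(rownames(counts), tax$motu_id)
  if (length(only_tax)) stop_validation("MOTU in taxonomy but not in counts: ",
                                        paste(only_tax, collapse = ", "))
  if (length(only_cnt)) stop_validation("MOTU in counts but not in taxonomy: ",
                                        paste(only_cnt, collapse = ", "))
  if (!all(tax$rank %in% RANK_LEVELS))
    stop_validation("taxonomy rank outside {",
                    paste(RANK_LEVELS, collapse = ", "), "}")
  bi <- tax$best_identity
  if (any(!is.na(bi) & (bi < 0 | bi > 1)))
    stop_validation("best_identity outside [0, 1]")
  sp <- tax$rank == "species"
  if (any(sp & (is.na(tax$species) | tax$species == "")))
    stop_validation("species-rank MOTU without a species name: ",
                    paste(tax$motu_id[sp & (is.na(tax$species) | tax$species == "")],
                          collapse = ", "))

  need_meta <- c("sample_id", "sample_type", "site", "estuary", "country",
                 "pool_size")
  miss <- setdiff(need_meta, names(meta))
  if (length(miss)) stop_validation("metadata lacks column(s): ",
                                    paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop_validation("duplicate sample_id in metadata")
  only_meta <- setdiff(meta$sample_id, colnames(counts))
  only_col <- setdiff(colnames(counts), meta$sample_id)
  if (length(only_meta)) stop_validation("sample in metadata but not in counts: ",
                                         paste(only_meta, collapse = ", "))
  if (length(only_col)) stop_validation("sample in counts but not in metadata: ",
                                        paste(only_col, collapse = ", "))
  if (!all(meta$sample_type %in% SAMPLE_TYPES))
    stop_validation("sample_type outside {",
                    paste(SAMPLE_TYPES, collapse = ", "), "}: ",
                    paste(unique(setdiff(meta$sample_type, SAMPLE_TYPES)),
                          collapse = ", "))
  ps <- meta$pool_size[meta$sample_type %in% c("stomach", "empty_stomach")]
  ps <- ps[!is.na(ps)]
  if (any(ps < 1 | ps > 8))
    stop_validation("pool_size outside [1, 8]")
  s2e <- unique(meta[, c("site", "estuary")])
  if (anyDuplicated(s2e$site))
    stop_validation("site mapped to more than one estuary: ",
                    s2e$site[anyDuplicated(s2e$site)])

  # canonical ordering: taxonomy and metadata follow the matrix indices
  x$taxonomy <- tax[match(rownames(counts), tax$motu_id), , drop = FALSE]
  rownames(x$taxonomy) <- NULL
  x$samples <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(x$samples) <- NULL
  class(x) <- "motu_table"
  x
}

#' @export
print.motu_table <- function(x, ...) {
  tt <- table(factor(x$samples$sample_type, levels = SAMPLE_TYPES))
  cat(sprintf("motu_table: %d MOTUs x %d samples, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat("  samples: ", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "),
      "\n", sep = "")
  cat("  sites: ", length(unique(x$samples$site)),
      " in ", length(unique(x$samples$estuary)), " estuaries\n", sep = "")
  invisible(x)
}

#' @export
dim.motu_table <- function(x) dim(x$counts)

#' Total read count of a `motu_table`
#' @param x A `motu_table`.
#' @return Total number of reads across all cells.
#' @export
total_reads <- function(x) sum(x$counts)

#' Subset a `motu_table` by sample type and/or site
#'
#' Restricts the table to samples matching the requested types and sites. MOTU
#' rows are always retained, even when all-zero in the subset: dropping MOTUs
#' is an explicit filtering step, never a side effect of subsetting.
#'
#' @param x A `motu_table`.
#' @param sample_types Character vector of sample types to keep, or `NULL` for
#'   all.
#' @param sites Character vector of sites to keep, or `NULL` for all.
#' @param ... Ignored.
#' @return A `motu_table` restricted to the matching samples.
#' @export
subset.motu_table <- function(x, sample_types = NULL, sites = NULL, ...) {
  meta <- x$samples
  if (!is.null(sample_types)) {
    unknown <- setdiff(sample_types, meta$sample_type)
    if (length(unknown))
      stop_validation("sample_type not present in table: ",
                      paste(unknown, collapse = ", "))
  }
  if (!is.null(sites)) {
    unknown <- setdiff(sites, meta$site)
    if (length(unknown))
      stop_validation("site not present in table: ",
                      paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(sample_types)) keep <- keep & meta$sample_type %in% sample_types
  if (!is.null(sites)) keep <- keep & meta$site %in% sites
  if (!any(keep))
    stop_validation("subset selects no samples")
  motu_table(x$counts[, meta$sample_id[keep], drop = FALSE],
             x$taxonomy, meta[keep, , drop = FALSE])
}
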
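# Prey selectivity against paired environmental DNA: Jacobs' index,
# trophic-significance scoring, and Table-style diet summaries.

#' Jacobs' selectivity index
#'
#' Electivity measure comparing a resource's relative abundance in the diet
#' (`r`) to its relative abundance in the environment (`p`):
#' \deqn{D = (r - p) / (r + p - 2 r p)}
#' `D` ranges from -1 (total avoidance) through 0 (consumption proportional to
#' availability) to +1 (exclusive selection), and corrects for item depletion.
#' Vectorised over `r` and `p`.
#'
#' @param r Relative read abundance in the diet, in \[0, 1\].
#' @param p Relative read abundance in the environment, in \[0, 1\].
#' @return `D` in \[-1, 1\]; `NA` where the index is undefined (`r == p` with
#'   both 0 or both 1), for the caller to exclude.
#' @examples
#' jacobs_index(0.5, 0.5)   # 0: neutral
#' jacobs_index(0.2, 0)     # +1: exclusive selection
#' jacobs_index(0, 0.3)     # -1: total avoidance
#' @export
jacobs_index <- function(r, p) {
  if (any(r < 0 | r > 1, na.rm = TRUE) || any(p < 0 | p > 1, na.rm = TRUE))
    stop_validation("relative abundances must lie in [0, 1]")
  denom <- r + p - 2 * r * p
  out <- ifelse(denom == 0, NA_real_, (r - p) / denom)
  out
}

#' Per-sample relative read abundances
#'
#' @param table A `motu_table`.
#' @param sample_id Sample column to normalise.
#' @return Named numeric vector of per-MOTU fractions summing to 1.
#' @export
relative_abundance <- function(table, sample_id) {
  if (!sample_id %in% colnames(table$counts))
    stop_validation("unknown sample: ", sample_id)
  v <- table$counts[, sample_id]
  tot <- sum(v)
  if (tot <= 0) stop_validation("zero-depth sample: ", sample_id)
  v / tot
}

rel_abundance_matrix <- function(table) {
  depth <- colSums(table$counts)
  if (any(depth <= 0))
    stop_validation("zero-depth sample: ",
                    paste(colnames(table$counts)[depth <= 0], collapse = ", "))
  sweep(table$counts, 2L, depth, "/")
}

#' Presence fraction of a MOTU within a sample group
#'
#' @param table A `motu_table`.
#' @param motu_id MOTU row.
#' @param sample_ids Character vector of sample columns forming the group.
#' @return Fraction of group samples in which the MOTU has count > 0.
#' @export
presence_fraction <- function(table, motu_id, sample_ids) {
  if (!length(sample_ids)) stop_validation("empty sample group")
  if (!motu_id %in% rownames(table$counts))
    stop_validation("unknown MOTU: ", motu_id)
  unknown <- setdiff(sample_ids, colnames(table$counts))
  if (length(unknown)) stop_validation("unknown sample(s): ",
                                       paste(unknown, collapse = ", "))
  mean(table$counts[motu_id, sample_ids] > 0)
}

#' Trophic-significance score
#'
#' Composite importance score of a prey taxon:
#' \deqn{TS = a \cdot f \cdot (D + 1)}
#' where `a` is the mean relative read abundance in the diet, `f` the fraction
#' of diet samples containing the taxon, and `D` Jacobs' selectivity index.
#' TS lies in \[0, 2\] and is monotone non-decreasing in each argument; total
#' avoidance (`D = -1`) nullifies the score.
#'
#' @param a Mean relative abundance in \[0, 1\].
#' @param f Presence fraction in \[0, 1\].
#' @param D Jacobs' index in \[-1, 1\].
#' @return TS in \[0, 2\]. Vectorised.
#' @export
trophic_significance <- function(a, f, D) {
  if (any(a < 0 | a > 1, na.rm = TRUE) || any(f < 0 | f > 1, na.rm = TRUE))
    stop_validation("a and f must lie in [0, 1]")
  if (any(abs(D) > 1, na.rm = TRUE))
    stop_validation("D must lie in [-1, 1]")
  a * f * (D + 1)
}

#' Pair stomach samples with their site's sediment sample
#'
#' Builds the within-site pairing used for all selectivity evaluations: each
#' retained stomach sample maps to the (single, pooled) sediment eDNA sample
#' of its collection site.
#'
#' @param diet_table `motu_table` whose stomach samples need pairing (or any
#'   table carrying the stomach metadata).
#' @param env_table `motu_table` carrying the sediment samples; defaults to
#'   `diet_table`.
#' @return Data frame with columns `stomach`, `sediment`, `site`
#'   (class `site_pairing`).
#' @export
site_pairing <- function(diet_table, env_table = diet_table) {
  sm <- diet_table$samples
  em <- env_table$samples
  stom <- sm[sm$sample_type == "stomach", , drop = FALSE]
  sed <- em[em$sample_type == "sediment", , drop = FALSE]
  if (!nrow(stom)) stop_validation("no stomach samples to pair")
  out <- lapply(seq_len(nrow(stom)), function(i) {
    hit <- sed$sample_id[sed$site == stom$site[i]]
    if (length(hit) == 0L)
      stop_validation("no sediment sample for site ", stom$site[i])
    if (length(hit) > 1L)
      stop_validation("site ", stom$site[i],
                      " has several sediment samples; combine them first")
    data.frame(stomach = stom$sample_id[i], sediment = hit,
               site = stom$site[i], stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("site_pairing", "data.frame"))
}

#' Paired Jacobs' selectivity per MOTU
#'
#' Evaluates Jacobs' `D` for every MOTU on every (stomach, paired sediment)
#' pair from the pair's relative read abundances, then summarises per MOTU as
#' the mean and standard error over informative pairs. Pairs where the MOTU is
#' absent from both members (`r = p = 0`) carry no electivity information and
#' are excluded (`pair_inclusion = "either"`, the default); with
#' `pair_inclusion = "stomach"` only pairs where the MOTU occurs in the
#' stomach sample are used.
#'
#' @param diet_table `motu_table` containing the stomach samples.
#' @param env_table `motu_table` containing the sediment samples.
#' @param pairing A [site_pairing()] covering the stomach samples.
#' @param pair_inclusion Which pairs inform a MOTU's mean `D`.
#' @return Data frame: `motu_id`, `mean_D`, `se_D`, `n_pairs`, `no_data`
#'   (TRUE when no pair was informative; `mean_D` is `NA` there, never the
#'   result of NaN arithmetic).
#' @export
paired_selectivity <- function(diet_table, env_table, pairing,
                               pair_inclusion = c("either", "stomach")) {
  pair_inclusion <- match.arg(pair_inclusion)
  stopifnot(inherits(pairing, "site_pairing"))
  missing_pairs <- setdiff(
    diet_table$samples$sample_id[diet_table$samples$sample_type == "stomach"],
    pairing$stomach)
  if (length(missing_pairs))
    stop_validation("pairing does not cover stomach sample(s): ",
                    paste(missing_pairs, collapse = ", "))
  ids <- rownames(diet_table$counts)
  ra_d <- rel_abundance_matrix(diet_table)
  ra_e <- rel_abundance_matrix(env_table)
  # align environment rows to the diet MOTU universe; absent = 0
  e_aligned <- matrix(0, nrow = length(ids), ncol = nrow(pairing),
                      dimnames = list(ids, pairing$stomach))
  common <- intersect(ids, rownames(ra_e))
  e_aligned[common, ] <- ra_e[common, pairing$sediment, drop = FALSE]
  d_aligned <- ra_d[ids, pairing$stomach, drop = FALSE]

  use <- if (pair_inclusion == "either") d_aligned > 0 | e_aligned > 0
         else d_aligned > 0
  D <- jacobs_index(d_aligned, e_aligned)
  D[!use] <- NA
  n_pairs <- rowSums(!is.na(D))
  mean_D <- ifelse(n_pairs > 0, rowMeans(D, na.rm = TRUE), NA_real_)
  se_D <- vapply(seq_along(ids), function(i) {
    v <- D[i, !is.na(D[i, ])]
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else
      if (length(v) == 1L) 0 else NA_real_
  }, numeric(1))
  data.frame(motu_id = ids, mean_D = mean_D, se_D = se_D,
             n_pairs = n_pairs, no_data = n_pairs == 0L,
             stringsAsFactors = FALSE)
}

#' Assign relative trophic significance and categories
#'
#' Normalises each record's TS by the total over the record set
#' (`relative_TS = TS / sum(TS)`) and bins it: High when `relative_TS`
#' exceeds `thresholds$high` (default 10%), Low when below `thresholds$low`
#' (default 1%), Medium otherwise. The Medium bin is the closed interval
#' between the two thresholds, so the partition is exhaustive.
#'
#' @param records Data frame with a `TS` column.
#' @param thresholds List with elements `high` and `low` (fractions of the
#'   TS total).
#' @return `records` with `relative_TS` and `category` columns added.
#' @export
categorize <- function(records, thresholds = list(high = 0.10, low = 0.01)) {
  ts <- records$TS
  tot <- sum(ts, na.rm = TRUE)
  if (!any(!is.na(ts) & ts > 0)) stop_validation("all trophic significances are zero")
  records$relative_TS <- ts / tot
  records$category <- ifelse(is.na(records$relative_TS), NA_character_,
                      ifelse(records$relative_TS > thresholds$high, "High",
                      ifelse(records$relative_TS < thresholds$low, "Low",
                             "Medium")))
  records
}

summarise_records <- function(diet_table, env_table, pairing, taxonomy,
                              pair_inclusion, ts_thresholds) {
  stom_ids <- diet_table$samples$sample_id[diet_table$samples$sample_type == "stomach"]
  if (!length(stom_ids)) stop_validation("no stomach samples in diet table")
  ra <- rel_abundance_matrix(diet_table)[, stom_ids, drop = FALSE]
  n <- length(stom_ids)
  # zero-inclusive mean over all retained stomach samples
  a <- rowMeans(ra)
  se_a <- if (n >= 2L) apply(ra, 1L, stats::sd) / sqrt(n) else rep(0, nrow(ra))
  f <- rowMeans(ra > 0)
  sel <- paired_selectivity(diet_table, env_table, pairing, pair_inclusion)
  rec <- data.frame(motu_id = rownames(ra),
                    mean_rel_abundance = a, se_rel_abundance = se_a,
                    presence_fraction = f,
                    mean_D = sel$mean_D, se_D = sel$se_D,
                    n_pairs = sel$n_pairs, stringsAsFactors = FALSE)
  rec$TS <- ifelse(is.na(rec$mean_D), NA_real_,
                   trophic_significance(rec$mean_rel_abundance,
                                        rec$presence_fraction,
                                        rec$mean_D))
  rec <- categorize(rec, ts_thresholds)
  cbind(rec, taxonomy[match(rec$motu_id, taxonomy$motu_id),
                      c("phylum", "order", "family", "species",
                        "best_identity"), drop = FALSE])
}

#' Diet summary: per-MOTU selectivity records
#'
#' Produces the per-MOTU diet table: zero-inclusive mean relative read
#' abundance (with SE) over all retained stomach samples, presence fraction,
#' paired Jacobs' `D` (mean with SE over informative pairs), the
#' trophic-significance score `TS = a f (D + 1)`, its share of the TS total
#' and the High/Medium/Low category. Relative TS is normalised over *all*
#' MOTUs; the reporting threshold then restricts which records are shown.
#'
#' @param diet_table Refined `motu_table` with the stomach samples (output of
#'   [run_cascade()]).
#' @param env_table `motu_table` with the sediment eDNA samples.
#' @param pairing A [site_pairing()]; built automatically when `NULL`.
#' @param report_threshold Minimum mean relative abundance for a record to be
#'   reported (default 0.005, i.e. 0.5%). Use 0 to report every MOTU. The
#'   full record set is always available in `attr(, "full")`.
#' @param pair_inclusion Passed to [paired_selectivity()].
#' @param ts_thresholds Passed to [categorize()].
#' @return A `diet_summary` data frame, sorted by phylum then taxonomy.
#' @export
diet_summary <- function(diet_table, env_table, pairing = NULL,
                         report_threshold = 0.005,
                         pair_inclusion = c("either", "stomach"),
                         ts_thresholds = list(high = 0.10, low = 0.01)) {
  pair_inclusion <- match.arg(pair_inclusion)
  if (is.null(pairing)) pairing <- site_pairing(diet_table, env_table)
  rec <- summarise_records(diet_table, env_table, pairing, diet_table$taxonomy,
                           pair_inclusion, ts_thresholds)
  ord <- order(rec$phylum == "", rec$phylum, rec$order, rec$family, rec$species,
               rec$motu_id)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  shown <- rec[rec$mean_rel_abundance >= report_threshold, , drop = FALSE]
  rownames(shown) <- NULL
  structure(shown,
            full = rec,
            n_stomach_samples = sum(diet_table$samples$sample_type == "stomach"),
            report_threshold = report_threshold,
            class = c("diet_summary", "data.frame"))
}

#' Per-phylum selectivity summary
#'
#' Aggregates read counts to phylum level (MOTUs without a phylum assignment
#' grouped as `"unassigned"`) in both the diet and environment tables, then
#' computes the same descriptors as [diet_summary()]: presence, zero-inclusive
#' mean relative abundance in the diet and in the environment, paired Jacobs'
#' `D` and trophic significance.
#'
#' @inheritParams diet_summary
#' @return Data frame with one row per phylum.
#' @export
phylum_summary <- function(diet_table, env_table, pairing = NULL,
                           pair_inclusion = c("either", "stomach"),
                           ts_thresholds = list(high = 0.10, low = 0.01)) {
  pair_inclusion <- match.arg(pair_inclusion)
  if (is.null(pairing)) pairing <- site_pairing(diet_table, env_table)
  dt <- aggregate_phyla(diet_table)
  et <- aggregate_phyla(env_table)
  rec <- summarise_records(dt, et, pairing, dt$taxonomy, pair_inclusion,
                           ts_thresholds)
  env_ra <- rel_abundance_matrix(et)
  sed_ids <- et$samples$sample_id[et$samples$sample_type == "sediment"]
  env_mean <- if (length(sed_ids))
    rowMeans(env_ra[, sed_ids, drop = FALSE]) else rep(NA_real_, nrow(env_ra))
  rec$mean_env_abundance <- env_mean[match(rec$motu_id, rownames(env_ra))]
  rec$mean_env_abundance[is.na(rec$mean_env_abundance)] <- 0
  rec$phylum <- rec$motu_id
  rec <- rec[order(-rec$TS, rec$phylum),
             c("phylum", "presence_fraction", "mean_rel_abundance",
               "se_rel_abundance", "mean_env_abundance", "mean_D", "se_D",
               "n_pairs", "TS", "relative_TS", "category")]
  rownames(rec) <- NULL
  rec
}

aggregate_phyla <- function(table) {
  phy <- table$taxonomy$phylum
  phy[is.na(phy) | phy == ""] <- "unassigned"
  counts <- rowsum(table$counts, group = phy)
  tax <- data.frame(motu_id = rownames(counts), rank = "phylum",
                    kingdom = "", phylum = rownames(counts), class = "",
                    order = "", family = "", genus = "", species = "",
                    best_identity = NA_real_, stringsAsFactors = FALSE)
  tax$phylum[tax$motu_id == "unassigned"] <- ""
  tax$rank[tax$motu_id == "unassigned"] <- "unassigned"
  motu_table(counts, tax, table$samples)
}

# half-up rounding to `digits` decimals, for percent display only
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

fmt_pct <- function(x, se = NULL) {
  v <- sprintf("%.1f", round_half_up(100 * x, 1L))
  if (!is.null(se)) v <- paste0(v, " ± ", sprintf("%.1f", round_half_up(100 * se, 1L)))
  v
}

#' @export
print.diet_summary <- function(x, ...) {
  cat(sprintf("diet_summary: %d MOTU(s) reported (threshold %.2g mean rel. abundance) of %d; %d stomach samples\n",
              nrow(x), attr(x, "report_threshold"), nrow(attr(x, "full")),
              attr(x, "n_stomach_samples")))
  if (!nrow(x)) return(invisible(x))
  df <- data.frame(
    Phylum = x$phylum, Species = ifelse(x$species == "", "Unassigned", x$species),
    `Presence (%)` = fmt_pct(x$presence_fraction),
    `Abundance (%)` = fmt_pct(x$mean_rel_abundance, x$se_rel_abundance),
    `Selectivity (D)` = paste0(sprintf("%.1f", round_half_up(x$mean_D, 1L)),
                               " ± ", sprintf("%.1f", round_half_up(x$se_D, 1L))),
    TS = signif(x$TS, 3), Category = x$category, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot a diet summary
#'
#' Horizontal bar chart of relative trophic significance, coloured by
#' category, mirroring the usual phylum/taxon importance display.
#'
#' @param x A `diet_summary`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.diet_summary <- function(x, ...) {
  lab <- ifelse(x$species == "", paste0(x$family, " sp."), x$species)
  cols <- c(High = "firebrick", Medium = "goldenrod", Low = "grey70")
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(100 * x$relative_TS), names.arg = rev(lab), horiz = TRUE,
                    las = 1, col = rev(cols[x$category]),
                    xlab = "Relative trophic significance (%)", ...)
  invisible(x)
}
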
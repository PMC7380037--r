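# The data-refinement cascade. Each stage takes a motu_table and returns
# list(table = <motu_table>, report = <filter_report>) so that stages can be
# invoked individually or chained by run_cascade() with full provenance.

DEFAULT_STAGE_ORDER <- c("merge_species_motus", "renormalize_tag_switching",
                         "remove_contaminants", "min_reads_filter",
                         "negative_control_filter", "remove_focal_taxa",
                         "sample_depth_filter")

#' Configuration of the MOTU-table refinement cascade
#'
#' Bundles every tunable threshold of the cascade. Defaults follow the
#' standard COI metabarcoding refinement: tag-switching cells below 1% of a
#' MOTU's total reads are zeroed, MOTUs with more than 10% of their reads in
#' PCR-negative controls are discarded, cells with four or fewer reads are
#' zeroed sample-by-sample, and samples with fewer than 1,000 diet reads after
#' focal-taxon removal are dropped.
#'
#' @param tag_switch_threshold Fraction of a MOTU's total reads below which a
#'   cell is treated as tag-switching leakage and zeroed (strict `<`).
#'   Default 0.01.
#' @param negctrl_max_fraction Maximum tolerated fraction of a MOTU's reads in
#'   negative controls (strict `>` removes). Default 0.10.
#' @param min_reads_per_cell Minimum reads for a cell to be kept; cells with
#'   fewer are zeroed (default 5, i.e. cells of four or fewer reads removed).
#' @param min_reads_mode `"cell"` (default) zeroes individual cells below the
#'   threshold and then drops all-zero MOTUs; `"motu"` drops any MOTU whose
#'   row maximum is below the threshold.
#' @param min_sample_depth Minimum post-focal-removal column sum for a sample
#'   to be retained (strict `<` drops). Default 1000.
#' @param depth_scope Sample types subject to the depth filter. Default
#'   `c("stomach", "empty_stomach")`: sediment eDNA samples are kept
#'   regardless of depth.
#' @param focal_taxa Species names removed before diet analysis (the consumer
#'   itself and any pervasive non-diet taxon such as an endoparasitic fungus).
#' @param contaminant_rules List of single-field taxonomy predicates, each a
#'   named list such as `list(kingdom = "Bacteria")` or
#'   `list(species = "Homo sapiens")`; a MOTU matching any rule is removed.
#' @param stage_order Character vector giving the order in which
#'   [run_cascade()] applies the stages.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(tag_switch_threshold = 0.01,
                          negctrl_max_fraction = 0.10,
                          min_reads_per_cell = 5L,
                          min_reads_mode = c("cell", "motu"),
                          min_sample_depth = 1000L,
                          depth_scope = c("stomach", "empty_stomach"),
                          focal_taxa = c("Crangon crangon",
                                         "Purpureocillium lilacinum"),
                          contaminant_rules = list(
                            list(kingdom = "Bacteria"),
                            list(species = "Homo sapiens")),
                          stage_order = DEFAULT_STAGE_ORDER) {
  min_reads_mode <- match.arg(min_reads_mode)
  stopifnot(tag_switch_threshold > 0, tag_switch_threshold < 1,
            negctrl_max_fraction > 0, negctrl_max_fraction < 1,
            min_reads_per_cell >= 1, min_sample_depth >= 0,
            all(stage_order %in% DEFAULT_STAGE_ORDER))
  structure(list(tag_switch_threshold = tag_switch_threshold,
                 negctrl_max_fraction = negctrl_max_fraction,
                 min_reads_per_cell = as.integer(min_reads_per_cell),
                 min_reads_mode = min_reads_mode,
                 min_sample_depth = as.integer(min_sample_depth),
                 depth_scope = depth_scope,
                 focal_taxa = focal_taxa,
                 contaminant_rules = contaminant_rules,
                 stage_order = stage_order),
            class = "filter_config")
}

new_stage_report <- function(stage, before, after, removed, extra = NULL) {
  rec <- list(stage = stage,
              motus_in = nrow(before$counts), motus_out = nrow(after$counts),
              samples_in = ncol(before$counts), samples_out = ncol(after$counts),
              reads_in = sum(before$counts), reads_out = sum(after$counts),
              removed = removed, extra = extra)
  structure(list(rec), class = "filter_report")
}

removed_frame <- function(id = character(), kind = character(),
                          reads = numeric(), reason = character()) {
  data.frame(id = id, kind = kind, reads = reads, reason = reason,
             stringsAsFactors = FALSE)
}

#' Combine filter reports
#' @param ... `filter_report` objects.
#' @return A single `filter_report` with the stage records concatenated.
#' @export
c.filter_report <- function(...) {
  structure(do.call(c, lapply(list(...), unclass)), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", length(x), "stage(s)\n")
  for (rec in x) {
    cat(sprintf("  %-26s MOTUs %d -> %d | samples %d -> %d | reads %s -> %s (removed %s)\n",
                rec$stage, rec$motus_in, rec$motus_out, rec$samples_in,
                rec$samples_out, format(rec$reads_in, big.mark = ","),
                format(rec$reads_out, big.mark = ","),
                format(rec$reads_in - rec$reads_out, big.mark = ",")))
  }
  invisible(x)
}

#' Summarise a filter report as a data frame
#' @param object A `filter_report`.
#' @param ... Ignored.
#' @return Data frame with one row per stage (MOTUs, samples and reads in/out).
#' @export
summary.filter_report <- function(object, ...) {
  do.call(rbind, lapply(object, function(rec)
    data.frame(stage = rec$stage, motus_in = rec$motus_in,
               motus_out = rec$motus_out, samples_in = rec$samples_in,
               samples_out = rec$samples_out, reads_in = rec$reads_in,
               reads_out = rec$reads_out,
               reads_removed = rec$reads_in - rec$reads_out)))
}

#' Merge MOTUs assigned to the same species
#'
#' All MOTUs of rank `species` sharing a species name are summed cell-wise
#' into a single record; the representative keeps the member with the highest
#' `best_identity`. MOTUs assigned above species rank are never merged. Total
#' reads are conserved exactly.
#'
#' @param table A `motu_table`.
#' @return `list(table, report)`.
#' @export
merge_species_motus <- function(table) {
  tax <- table$taxonomy
  sp <- tax$rank == "species"
  key <- ifelse(sp, tax$species, paste0("\r__motu__", tax$motu_id))
  removed <- removed_frame()
  if (anyDuplicated(key[sp])) {
    counts <- table$counts
    keep <- rep(TRUE, nrow(counts))
    for (s in unique(tax$species[sp][duplicated(tax$species[sp])])) {
      members <- which(sp & tax$species == s)
      rep_i <- members[which.max(tax$best_identity[members])]
      others <- setdiff(members, rep_i)
      counts[rep_i, ] <- colSums(counts[members, , drop = FALSE])
      keep[others] <- FALSE
      removed <- rbind(removed, removed_frame(
        id = tax$motu_id[others], kind = "motu", reads = 0,
        reason = sprintf("merged into %s (%s)", tax$motu_id[rep_i], s)))
    }
    out <- motu_table(counts[keep, , drop = FALSE],
                      tax[keep, , drop = FALSE], table$samples)
  } else out <- table
  list(table = out,
       report = new_stage_report("merge_species_motus", table, out, removed))
}

#' Renormalization filter for tag-switching artefacts
#'
#' For each MOTU, every cell whose count is strictly below
#' `threshold` times that MOTU's total reads across all samples is set to
#' zero. Low-frequency occurrences of a MOTU outside the samples where it is
#' genuinely abundant are the signature of tag-jumps (sample mis-assignment
#' during library multiplexing); this row-wise fraction rule removes them.
#' All-zero rows are retained (dropping is left to [min_reads_filter()]).
#'
#' @param table A `motu_table`.
#' @param threshold Fraction of the MOTU's total reads (default 0.01).
#' @return `list(table, report)`.
#' @export
renormalize_tag_switching <- function(table, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  counts <- table$counts
  tot <- rowSums(counts)
  zero <- counts < threshold * tot & counts > 0
  zeroed_reads <- rowSums(counts * zero)
  counts[zero] <- 0
  out <- motu_table(counts, table$taxonomy, table$samples)
  hit <- zeroed_reads > 0
  removed <- removed_frame(id = rownames(counts)[hit],
                           kind = rep("cells", sum(hit)),
                           reads = zeroed_reads[hit],
                           reason = sprintf("cells < %g of MOTU total zeroed",
                                            threshold)[rep(1, sum(hit))])
  list(table = out,
       report = new_stage_report("renormalize_tag_switching", table, out, removed))
}

match_rule <- function(tax, rule) {
  if (length(rule) != 1L || is.null(names(rule)))
    stop_validation("contaminant rule must be a single named field=value pair")
  field <- names(rule)
  if (!field %in% c(TAX_RANKS, "rank", "motu_id"))
    stop_validation("contaminant rule references unknown taxonomy field: ", field)
  !is.na(tax[[field]]) & tax[[field]] == rule[[1L]]
}

#' Remove contaminant MOTUs by taxonomy rule
#'
#' Removes every MOTU matching any of the supplied taxonomy predicates
#' (e.g. bacterial reads, human DNA, designated terrestrial taxa). Each removed
#' MOTU is reported with the rule that matched it.
#'
#' @param table A `motu_table`.
#' @param rules List of single-field predicates, e.g.
#'   `list(list(kingdom = "Bacteria"), list(species = "Homo sapiens"))`.
#' @return `list(table, report)`.
#' @export
remove_contaminants <- function(table, rules) {
  tax <- table$taxonomy
  drop <- rep(FALSE, nrow(tax))
  removed <- removed_frame()
  for (rule in rules) {
    hit <- match_rule(tax, rule) & !drop
    if (any(hit)) {
      removed <- rbind(removed, removed_frame(
        id = tax$motu_id[hit], kind = "motu",
        reads = rowSums(table$counts)[hit],
        reason = sprintf("contaminant rule %s=%s", names(rule), rule[[1L]])))
    }
    drop <- drop | match_rule(tax, rule)
  }
  out <- if (any(drop))
    motu_table(table$counts[!drop, , drop = FALSE],
               tax[!drop, , drop = FALSE], table$samples)
  else table
  list(table = out,
       report = new_stage_report("remove_contaminants", table, out, removed))
}

#' Minimum-reads-per-cell filter
#'
#' Zeroes, sample by sample, every cell with fewer than `min_reads_per_cell`
#' reads (the default of 5 removes cells with four or fewer reads — PCR and
#' sequencing noise). MOTUs whose rows become all-zero are dropped and listed.
#' With `mode = "motu"` the whole MOTU is instead dropped when its row maximum
#' falls below the threshold.
#'
#' @param table A `motu_table`.
#' @param min_reads_per_cell Minimum cell count retained (default 5).
#' @param mode `"cell"` (default) or `"motu"`; see Details.
#' @return `list(table, report)`.
#' @export
min_reads_filter <- function(table, min_reads_per_cell = 5L,
                             mode = c("cell", "motu")) {
  mode <- match.arg(mode)
  stopifnot(min_reads_per_cell >= 1)
  counts <- table$counts
  removed <- removed_frame()
  if (mode == "motu") {
    drop <- apply(counts, 1L, max) < min_reads_per_cell
  } else {
    zero <- counts < min_reads_per_cell & counts > 0
    zeroed_reads <- rowSums(counts * zero)
    counts[zero] <- 0
    hit <- zeroed_reads > 0
    removed <- removed_frame(id = rownames(counts)[hit],
                             kind = rep("cells", sum(hit)),
                             reads = zeroed_reads[hit],
                             reason = rep(sprintf("cells with < %d reads zeroed",
                                                  min_reads_per_cell), sum(hit)))
    drop <- rowSums(counts) == 0
  }
  if (any(drop)) {
    removed <- rbind(removed, removed_frame(
      id = rownames(counts)[drop], kind = "motu",
      reads = rowSums(counts)[drop],
      reason = rep(if (mode == "motu") "row maximum below threshold"
                   else "all cells below threshold", sum(drop))))
  }
  out <- motu_table(counts[!drop, , drop = FALSE],
                    table$taxonomy[!drop, , drop = FALSE], table$samples)
  list(table = out,
       report = new_stage_report("min_reads_filter", table, out, removed))
}

#' Negative-control filter
#'
#' Removes every MOTU whose read abundance summed over PCR-negative-control
#' samples is strictly greater than `max_fraction` of its total reads
#' (reagent or cross-contamination signature). The negative-control columns
#' themselves are consumed by this stage and dropped from the output, so they
#' never reach diet statistics. With no control samples present the stage is a
#' logged no-op.
#'
#' @param table A `motu_table`.
#' @param max_fraction Maximum tolerated control fraction (default 0.10).
#' @return `list(table, report)`.
#' @export
negative_control_filter <- function(table, max_fraction = 0.10) {
  stopifnot(max_fraction > 0, max_fraction < 1)
  meta <- table$samples
  is_ctrl <- meta$sample_type == "negative_control"
  if (!any(is_ctrl)) {
    return(list(table = table,
                report = new_stage_report("negative_control_filter", table,
                                          table, removed_frame(),
                                          extra = list(note = "no negative controls present"))))
  }
  counts <- table$counts
  ctrl_reads <- rowSums(counts[, meta$sample_id[is_ctrl], drop = FALSE])
  tot <- rowSums(counts)
  drop <- tot > 0 & ctrl_reads > max_fraction * tot
  removed <- removed_frame(id = rownames(counts)[drop], kind = rep("motu", sum(drop)),
                           reads = tot[drop],
                           reason = rep(sprintf("> %g of reads in negative controls",
                                                max_fraction), sum(drop)))
  kept <- counts[!drop, , drop = FALSE]
  ctrl_cols <- meta$sample_id[is_ctrl]
  leak <- colSums(kept[, ctrl_cols, drop = FALSE])
  if (any(leak > 0) || length(ctrl_cols)) {
    removed <- rbind(removed, removed_frame(
      id = ctrl_cols, kind = rep("sample", length(ctrl_cols)),
      reads = as.numeric(leak),
      reason = rep("negative-control column dropped after stage", length(ctrl_cols))))
  }
  out <- motu_table(kept[, meta$sample_id[!is_ctrl], drop = FALSE],
                    table$taxonomy[!drop, , drop = FALSE],
                    meta[!is_ctrl, , drop = FALSE])
  list(table = out,
       report = new_stage_report("negative_control_filter", table, out, removed))
}

#' Remove focal (consumer and other non-diet) taxa
#'
#' Removes MOTUs whose species name matches one of `focal_taxa` — typically
#' the consumer itself, whose own DNA dominates stomach amplicons, and any
#' pervasive non-diet taxon (e.g. an endoparasitic fungus). The report records,
#' per sample and per focal taxon, the pre-removal proportion of focal reads
#' (the standard "proportion of consumer reads" summary). A focal name that
#' matches nothing raises a warning, not an error.
#'
#' @param table A `motu_table`.
#' @param focal_taxa Character vector of species names.
#' @return `list(table, report)`.
#' @export
remove_focal_taxa <- function(table, focal_taxa) {
  tax <- table$taxonomy
  counts <- table$counts
  depth <- colSums(counts)
  drop <- rep(FALSE, nrow(tax))
  removed <- removed_frame()
  props <- list()
  for (nm in focal_taxa) {
    hit <- !is.na(tax$species) & tax$species == nm
    if (!any(hit)) {
      warning("focal taxon not present in table: ", nm, call. = FALSE)
      next
    }
    focal_reads <- colSums(counts[hit, , drop = FALSE])
    props[[nm]] <- data.frame(
      sample_id = colnames(counts), taxon = nm,
      proportion = ifelse(depth > 0, focal_reads / depth, 0),
      stringsAsFactors = FALSE)
    removed <- rbind(removed, removed_frame(
      id = tax$motu_id[hit], kind = rep("motu", sum(hit)),
      reads = rowSums(counts)[hit],
      reason = rep(sprintf("focal taxon %s", nm), sum(hit))))
    drop <- drop | hit
  }
  out <- if (any(drop))
    motu_table(counts[!drop, , drop = FALSE], tax[!drop, , drop = FALSE],
               table$samples)
  else table
  focal_proportions <- if (length(props)) do.call(rbind, props) else NULL
  if (!is.null(focal_proportions)) rownames(focal_proportions) <- NULL
  list(table = out,
       report = new_stage_report("remove_focal_taxa", table, out, removed,
                                 extra = list(focal_proportions = focal_proportions)))
}

#' Sample read-depth filter
#'
#' Drops in-scope samples whose column sum is strictly below
#' `min_sample_depth`. Run after [remove_focal_taxa()] so that the depth
#' reflects diet-related reads only. Sediment samples are outside the default
#' scope and kept regardless of depth.
#'
#' @param table A `motu_table`.
#' @param min_sample_depth Minimum retained depth (default 1000; strict `<`
#'   drops).
#' @param scope Sample types the filter applies to.
#' @return `list(table, report)`.
#' @export
sample_depth_filter <- function(table, min_sample_depth = 1000L,
                                scope = c("stomach", "empty_stomach")) {
  meta <- table$samples
  depth <- colSums(table$counts)
  drop <- meta$sample_type %in% scope & depth < min_sample_depth
  if (sum(!drop) == 0)
    stop_validation("no samples survive depth filter")
  removed <- removed_frame(id = meta$sample_id[drop], kind = rep("sample", sum(drop)),
                           reads = as.numeric(depth[drop]),
                           reason = rep(sprintf("read depth < %d", min_sample_depth),
                                        sum(drop)))
  out <- if (any(drop))
    motu_table(table$counts[, !drop, drop = FALSE], table$taxonomy,
               meta[!drop, , drop = FALSE])
  else table
  list(table = out,
       report = new_stage_report("sample_depth_filter", table, out, removed))
}

#' Run the full refinement cascade
#'
#' Applies the configured stages in `config$stage_order` and concatenates the
#' per-stage provenance into one [filter_config()]-driven `filter_report`.
#' Chain consistency holds by construction: stage *k*'s input equals stage
#' *k-1*'s output, and no stage ever increases a cell.
#'
#' @param table A `motu_table` (raw, with negative-control columns present).
#' @param config A [filter_config()].
#' @return `list(table, report)` — the refined diet table and the full report.
#' @examples
#' sim <- simulate_diet_dataset(sim_config(n_estuaries = 2, sites_per_estuary = 2,
#'                                         stomach_depth = 5000, sediment_depth = 5000),
#'                              seed = 1)
#' res <- run_cascade(sim$table, filter_config(min_sample_depth = 100))
#' summary(res$report)
#' @export
run_cascade <- function(table, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  reports <- list()
  for (stage in config$stage_order) {
    res <- switch(stage,
      merge_species_motus = merge_species_motus(table),
      renormalize_tag_switching =
        renormalize_tag_switching(table, config$tag_switch_threshold),
      remove_contaminants = remove_contaminants(table, config$contaminant_rules),
      min_reads_filter = min_reads_filter(table, config$min_reads_per_cell,
                                          config$min_reads_mode),
      negative_control_filter =
        negative_control_filter(table, config$negctrl_max_fraction),
      remove_focal_taxa = remove_focal_taxa(table, config$focal_taxa),
      sample_depth_filter = sample_depth_filter(table, config$min_sample_depth,
                                                config$depth_scope),
      stop_validation("unknown stage: ", stage))
    table <- res$table
    reports[[stage]] <- res$report
  }
  list(table = table, report = do.call(c.filter_report, unname(reports)))
}
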
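# Synthetic paired stomach/sediment metabarcoding data with known ground
# truth, for end-to-end validation and parameter-recovery studies.

#' Configuration of the synthetic diet-metabarcoding generator
#'
#' The generator emulates the sampling design of a multi-estuary diet study
#' of a benthic generalist: per site one pooled sediment eDNA sample and
#' several pooled-stomach replicates, a dominant focal-consumer read
#' fraction, a ubiquitous fungal taxon, taxon-specific consumption
#' preference, tag-switching leakage into other samples and negative
#' controls, and reagent contamination of the PCR-negative controls.
#'
#' The community model draws a per-taxon base abundance from a log-normal
#' species-abundance distribution and perturbs it per site with a Dirichlet
#' draw whose concentration controls spatial patchiness (estuarine benthic
#' communities are strongly patchy: a taxon can dominate locally while its
#' study-wide mean abundance stays modest). Diet composition at a site is
#' availability times preference, renormalised: \eqn{r_s \propto p_s w}.
#'
#' @param n_estuaries,sites_per_estuary,stomach_pools_per_site Sampling
#'   design (defaults 6, 4, 3: 24 sites, 72 stomach pools).
#' @param pool_size Stomachs pooled per stomach sample (default 8).
#' @param n_taxa Number of prey taxa (default 30).
#' @param phyla Phylum labels recycled across prey taxa.
#' @param lognormal_meanlog,lognormal_sdlog Log-normal species-abundance
#'   parameters for the base community (defaults 0, 1.5).
#' @param site_concentration Dirichlet concentration multiplier for
#'   between-site variation (default 4; smaller = patchier). The default is
#'   calibrated so that abundant prey taxa occur in roughly 20-55% of stomach
#'   samples while remaining locally dominant, the aggregation typical of
#'   estuarine benthos.
#' @param preference_weights Non-negative per-taxon consumption preferences;
#'   default spans 0.02-50 on a log scale (strong avoidance to strong
#'   selection).
#' @param focal_read_fraction Mean fraction of stomach reads belonging to the
#'   consumer itself (default 0.28).
#' @param fungal_read_fraction Mean fraction of stomach reads belonging to
#'   the ubiquitous fungus (default 0.36).
#' @param sediment_focal_fraction,sediment_fungal_fraction The same two
#'   fractions in sediment samples (defaults 0.01 and 0.001).
#' @param contaminant_read_fraction Fraction of reads from environmental
#'   contaminants (a bacterial MOTU and human DNA) in every sample (default
#'   0.003); set to 0 to disable.
#' @param stomach_depth,sediment_depth Read depth per sample type (defaults
#'   50000 and 18000). The sediment default approximately matches the
#'   expected number of diet-informative reads per stomach pool
#'   (`stomach_depth` net of the focal, fungal and contaminant fractions), so
#'   both communities are observed with equal effort and selectivity
#'   estimates are calibrated around zero under neutral consumption.
#' @param n_empty_stomach,empty_stomach_depth Number and depth of pooled
#'   visually-empty-stomach samples (defaults 3 and 200; their reads are
#'   almost entirely focal and fungal).
#' @param n_negctrl Number of PCR-negative controls (default 3).
#' @param tag_switch_rate Fraction of each sample's reads reassigned to
#'   uniformly chosen other samples, emulating library cross-talk (default
#'   0.002).
#' @param negctrl_contam_rate Expected reagent-contaminant reads per control,
#'   as a fraction of `stomach_depth` (default 0.001).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_estuaries = 6L, sites_per_estuary = 4L,
                       stomach_pools_per_site = 3L, pool_size = 8L,
                       n_taxa = 30L,
                       phyla = c("Arthropoda", "Annelida", "Mollusca",
                                 "Chordata", "Bacillariophyta", "Cnidaria",
                                 "Rhodophyta", "Nematoda"),
                       lognormal_meanlog = 0, lognormal_sdlog = 1.5,
                       site_concentration = 4,
                       preference_weights = NULL,
                       focal_read_fraction = 0.28,
                       fungal_read_fraction = 0.36,
                       sediment_focal_fraction = 0.01,
                       sediment_fungal_fraction = 0.001,
                       contaminant_read_fraction = 0.003,
                       stomach_depth = 50000L, sediment_depth = 18000L,
                       n_empty_stomach = 3L, empty_stomach_depth = 200L,
                       n_negctrl = 3L,
                       tag_switch_rate = 0.002,
                       negctrl_contam_rate = 0.001) {
  if (is.null(preference_weights))
    preference_weights <- 10^seq(log10(0.02), log10(50), length.out = n_taxa)
  stopifnot(length(preference_weights) == n_taxa,
            all(preference_weights >= 0), any(preference_weights > 0),
            focal_read_fraction >= 0, focal_read_fraction < 1,
            fungal_read_fraction >= 0, fungal_read_fraction < 1,
            focal_read_fraction + fungal_read_fraction +
              contaminant_read_fraction < 1,
            tag_switch_rate >= 0, tag_switch_rate < 1,
            stomach_depth > 0, sediment_depth > 0)
  structure(as.list(environment()), class = "sim_config")
}

FOCAL_SPECIES <- "Crangon crangon"
FUNGAL_SPECIES <- "Purpureocillium lilacinum"

sim_taxonomy <- function(cfg) {
  prey_ids <- sprintf("MOTU_%03d", seq_len(cfg$n_taxa))
  prey <- data.frame(
    motu_id = prey_ids, rank = "species", kingdom = "Metazoa",
    phylum = rep_len(cfg$phyla, cfg$n_taxa), class = "", order = "",
    family = "", genus = "",
    species = sprintf("Prey taxon %03d", seq_len(cfg$n_taxa)),
    best_identity = 1, stringsAsFactors = FALSE)
  extra <- data.frame(
    motu_id = c("MOTU_FOCAL", "MOTU_FUNGUS", "MOTU_BACT", "MOTU_HUMAN",
                "MOTU_REAGENT"),
    rank = c("species", "species", "kingdom", "species", "unassigned"),
    kingdom = c("Metazoa", "Fungi", "Bacteria", "Metazoa", ""),
    phylum = c("Arthropoda", "Ascomycota", "", "Chordata", ""),
    class = "", order = "", family = "", genus = "",
    species = c(FOCAL_SPECIES, FUNGAL_SPECIES, "", "Homo sapiens", ""),
    best_identity = c(1, 1, 0.95, 1, 0.7), stringsAsFactors = FALSE)
  rbind(prey, extra)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a paired stomach/sediment metabarcoding dataset
#'
#' Draws per-site community proportions, composes stomach pools as
#' availability-times-preference multinomials on top of configured focal,
#' fungal and contaminant read fractions, injects tag-switching leakage
#' (read-conserving, destination-uniform over all other samples including
#' negative controls) and reagent contamination of the controls, and returns
#' a validated [motu_table()] together with the generator's ground truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(config, seed)` gives bit-identical
#'   tables.
#' @return `list(table = motu_table, truth = sim_truth)`. The truth carries
#'   the per-site community proportions `p` (taxa x sites), expected diet
#'   proportions `r`, preference weights `w`, the per-sample focal/fungal
#'   read counts, every injected tag-jump and contamination event, and the
#'   ids of the non-prey MOTUs.
#' @export
simulate_diet_dataset <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  tax <- sim_taxonomy(cfg)
  n_taxa <- cfg$n_taxa
  prey_ids <- sprintf("MOTU_%03d", seq_len(n_taxa))
  all_ids <- tax$motu_id

  estuaries <- sprintf("E%d", seq_len(cfg$n_estuaries))
  countries <- rep_len(c("NL", "UK", "PT"), cfg$n_estuaries)
  sites <- unlist(lapply(seq_len(cfg$n_estuaries), function(e)
    sprintf("E%dS%d", e, seq_len(cfg$sites_per_estuary))))
  site_estuary <- rep(estuaries, each = cfg$sites_per_estuary)
  site_country <- rep(countries, each = cfg$sites_per_estuary)

  # base community (log-normal SAD) and per-site Dirichlet perturbation
  base <- stats::rlnorm(n_taxa, cfg$lognormal_meanlog, cfg$lognormal_sdlog)
  base <- base / sum(base)
  p <- vapply(seq_along(sites), function(s)
    rdirichlet1(cfg$site_concentration * n_taxa * base), numeric(n_taxa))
  dimnames(p) <- list(prey_ids, sites)
  w <- cfg$preference_weights
  names(w) <- prey_ids
  r <- apply(p, 2L, function(ps) {
    x <- ps * w
    x / sum(x)
  })
  dimnames(r) <- dimnames(p)

  meta <- list(); cols <- list()
  draw_sample <- function(prey_probs, depth, focal_f, fungal_f, contam_f) {
    pr <- c(prey_probs * (1 - focal_f - fungal_f - contam_f),
            focal_f, fungal_f, contam_f * 0.6, contam_f * 0.4, 0)
    stats::rmultinom(1L, depth, pr)[, 1L]
  }
  for (s in seq_along(sites)) {
    sed_id <- paste0(sites[s], "_SED")
    cols[[sed_id]] <- draw_sample(p[, s], cfg$sediment_depth,
                                  cfg$sediment_focal_fraction,
                                  cfg$sediment_fungal_fraction,
                                  cfg$contaminant_read_fraction)
    meta[[sed_id]] <- data.frame(sample_id = sed_id, sample_type = "sediment",
                                 site = sites[s], estuary = site_estuary[s],
                                 country = site_country[s],
                                 pool_size = NA_integer_)
    for (k in seq_len(cfg$stomach_pools_per_site)) {
      st_id <- sprintf("%s_ST%d", sites[s], k)
      cols[[st_id]] <- draw_sample(r[, s], cfg$stomach_depth,
                                   cfg$focal_read_fraction,
                                   cfg$fungal_read_fraction,
                                   cfg$contaminant_read_fraction)
      meta[[st_id]] <- data.frame(sample_id = st_id, sample_type = "stomach",
                                  site = sites[s], estuary = site_estuary[s],
                                  country = site_country[s],
                                  pool_size = cfg$pool_size)
    }
  }
  if (cfg$n_empty_stomach > 0) {
    empty_sites <- sample(seq_along(sites), cfg$n_empty_stomach, replace = TRUE)
    for (k in seq_len(cfg$n_empty_stomach)) {
      s <- empty_sites[k]
      id <- sprintf("EMPTY%d", k)
      cols[[id]] <- draw_sample(p[, s], cfg$empty_stomach_depth, 0.45, 0.50,
                                cfg$contaminant_read_fraction)
      meta[[id]] <- data.frame(sample_id = id, sample_type = "empty_stomach",
                               site = sites[s], estuary = site_estuary[s],
                               country = site_country[s],
                               pool_size = cfg$pool_size)
    }
  }
  for (k in seq_len(cfg$n_negctrl)) {
    id <- sprintf("NEG%d", k)
    cols[[id]] <- rep(0, length(all_ids))
    meta[[id]] <- data.frame(sample_id = id, sample_type = "negative_control",
                             site = "lab", estuary = "lab", country = "lab",
                             pool_size = NA_integer_)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- all_ids
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL

  focal_counts <- counts["MOTU_FOCAL", ]
  fungal_counts <- counts["MOTU_FUNGUS", ]

  # reagent contamination of the PCR-negative controls
  contam_events <- NULL
  if (cfg$n_negctrl > 0 && cfg$negctrl_contam_rate > 0) {
    lambda <- cfg$negctrl_contam_rate * cfg$stomach_depth
    reads <- stats::rpois(cfg$n_negctrl, lambda)
    ctrl_ids <- sprintf("NEG%d", seq_len(cfg$n_negctrl))
    counts["MOTU_REAGENT", ctrl_ids] <- counts["MOTU_REAGENT", ctrl_ids] + reads
    contam_events <- data.frame(sample_id = ctrl_ids, motu_id = "MOTU_REAGENT",
                                reads = reads, stringsAsFactors = FALSE)
  }

  # tag-switching: read-conserving reassignment, destination uniform over the
  # other samples (negative controls included)
  jump_events <- NULL
  if (cfg$tag_switch_rate > 0 && ncol(counts) > 1L) {
    events <- list()
    sample_ids <- colnames(counts)
    for (j in seq_along(sample_ids)) {
      tot <- sum(counts[, j])
      if (tot == 0) next
      n_jump <- stats::rbinom(1L, tot, cfg$tag_switch_rate)
      if (n_jump == 0) next
      moved <- stats::rmultinom(1L, n_jump, counts[, j])[, 1L]
      dest <- sample(sample_ids[-j], n_jump, replace = TRUE)
      motu_of_read <- rep(rownames(counts), moved)
      dest_per_motu <- table(factor(motu_of_read, levels = rownames(counts)),
                             factor(dest, levels = sample_ids))
      add <- matrix(as.numeric(dest_per_motu), nrow = nrow(dest_per_motu),
                    dimnames = dimnames(dest_per_motu))
      counts[, j] <- counts[, j] - moved
      counts <- counts + add[rownames(counts), sample_ids]
      ev <- as.data.frame(dest_per_motu, stringsAsFactors = FALSE)
      names(ev) <- c("motu_id", "to_sample", "reads")
      ev <- ev[ev$reads > 0, , drop = FALSE]
      if (nrow(ev)) {
        ev$from_sample <- sample_ids[j]
        events[[length(events) + 1L]] <- ev[, c("from_sample", "to_sample",
                                                "motu_id", "reads")]
      }
    }
    if (length(events)) jump_events <- do.call(rbind, events)
  }

  table <- motu_table(counts, tax, samples)
  truth <- structure(list(p = p, r = r, w = w, base = base,
                          focal_counts = focal_counts,
                          fungal_counts = fungal_counts,
                          tag_jump_events = jump_events,
                          contam_events = contam_events,
                          non_prey_motus = c("MOTU_FOCAL", "MOTU_FUNGUS",
                                             "MOTU_BACT", "MOTU_HUMAN",
                                             "MOTU_REAGENT"),
                          config = cfg),
                     class = "sim_truth")
  list(table = table, truth = truth)
}

#' Parameter-recovery report
#'
#' Joins the estimated selectivity records against the generator's ground
#' truth: per prey taxon the true preference weight, the estimated mean
#' Jacobs' `D`, and the expected per-sample diet read count (which governs
#' how well the taxon can be estimated). Taxa present in the truth but
#' filtered out of the estimates are reported with `NA` estimates, never
#' dropped silently. The report's attributes carry the Spearman rank
#' correlation between preference and estimated `D` (over taxa whose expected
#' diet count reaches `min_expected_count`) and the mean `D` of neutral
#' (`w = 1`) taxa — the estimator's bias under proportional consumption.
#'
#' @param estimates A [diet_summary()] computed on a simulated dataset (use
#'   `report_threshold = 0` to keep every MOTU).
#' @param truth The `sim_truth` from [simulate_diet_dataset()].
#' @param min_expected_count Expected diet reads per sample below which a
#'   taxon is excluded from the rank correlation (default 50).
#' @return Data frame (one row per prey taxon) with attributes
#'   `spearman_rho` and `neutral_mean_D`.
#' @export
recovery_report <- function(estimates, truth, min_expected_count = 50) {
  stopifnot(inherits(truth, "sim_truth"))
  full <- attr(estimates, "full")
  if (is.null(full)) full <- as.data.frame(estimates)
  cfg <- truth$config
  diet_depth <- cfg$stomach_depth *
    (1 - cfg$focal_read_fraction - cfg$fungal_read_fraction -
       cfg$contaminant_read_fraction)
  expected_count <- diet_depth * rowMeans(truth$r)
  ids <- rownames(truth$r)
  i <- match(ids, full$motu_id)
  rep_df <- data.frame(motu_id = ids, true_w = truth$w[ids],
                       expected_count = expected_count,
                       mean_D = full$mean_D[i], TS = full$TS[i],
                       retained = !is.na(i), stringsAsFactors = FALSE)
  rep_df$true_rank <- rank(rep_df$true_w)
  rep_df$D_rank <- rank(rep_df$mean_D, na.last = "keep")
  use <- rep_df$expected_count >= min_expected_count & !is.na(rep_df$mean_D)
  rho <- if (sum(use) >= 3L)
    stats::cor(rep_df$true_w[use], rep_df$mean_D[use], method = "spearman")
  else NA_real_
  neutral <- rep_df$mean_D[use & abs(rep_df$true_w - 1) < 1e-12]
  structure(rep_df, spearman_rho = rho,
            neutral_mean_D = if (length(neutral)) mean(neutral) else NA_real_,
            n_rank_taxa = sum(use))
}
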
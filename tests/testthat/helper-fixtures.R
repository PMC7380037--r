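# Fixture builders shared across the test files. Everything is constructed in
# code; no binary fixtures.

make_taxonomy <- function(motu_id, species = motu_id,
                          rank = rep("species", length(motu_id)),
                          kingdom = rep("Metazoa", length(motu_id)),
                          phylum = rep("Arthropoda", length(motu_id)),
                          best_identity = rep(1, length(motu_id))) {
  data.frame(motu_id = motu_id, rank = rank, kingdom = kingdom,
             phylum = phylum, class = "", order = "", family = "", genus = "",
             species = ifelse(rank == "species", species, ""),
             best_identity = best_identity, stringsAsFactors = FALSE)
}

make_meta <- function(sample_id, sample_type, site = rep("A", length(sample_id)),
                      estuary = NULL, country = "NL") {
  if (is.null(estuary)) estuary <- sub("[0-9]*$", "", site)
  data.frame(sample_id = sample_id, sample_type = sample_type, site = site,
             estuary = estuary, country = country,
             pool_size = ifelse(sample_type %in% c("stomach", "empty_stomach"),
                                8L, NA_integer_),
             stringsAsFactors = FALSE)
}

# 3 MOTUs x 4 samples, one of each sample type, well formed
tiny_table <- function() {
  counts <- matrix(c(10, 5, 0, 0,
                     2, 0, 8, 0,
                     1, 1, 1, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("M1", "M2", "M3"),
                                   c("ST1", "SED1", "EMPTY1", "NEG1")))
  motu_table(counts,
             make_taxonomy(c("M1", "M2", "M3"),
                           species = c("Carcinus maenas", "Hediste diversicolor",
                                       "Corophium volutator")),
             make_meta(c("ST1", "SED1", "EMPTY1", "NEG1"),
                       c("stomach", "sediment", "empty_stomach",
                         "negative_control"),
                       site = c("A", "A", "A", "lab")))
}

# the 20-cell worked fixture for the full cascade: one tag-jump cell, one
# MOTU over-represented in the negative control, cells of 4 and 5 reads, and
# one stomach sample that drops below 1,000 diet reads
cascade_fixture <- function() {
  counts <- matrix(c(
    # ST1, ST2, SED1, NEG1
     800, 900,  10, 0,   # M_FOCAL  consumer reads (sediment cell is leakage)
    2000, 150, 300, 0,   # M_PREY1  genuine prey, present everywhere
     985,   5,  10, 0,   # M_JUMP   5-read tag-jump cell in ST2; SED1 exactly 1%
      30,   5,   0, 5,   # M_CTRL   5/40 = 12.5% of reads in the control
       4,   4,   4, 0,   # M_LOW    all cells at 4 reads
       0,  50,   0, 0),  # M_BACT   bacterial contaminant
    nrow = 6, byrow = TRUE,
    dimnames = list(c("M_FOCAL", "M_PREY1", "M_JUMP", "M_CTRL", "M_LOW",
                      "M_BACT"),
                    c("ST1", "ST2", "SED1", "NEG1")))
  tax <- make_taxonomy(rownames(counts),
                       species = c("Crangon crangon", "Prey one", "Prey two",
                                   "Prey three", "Prey four", ""),
                       rank = c(rep("species", 5), "kingdom"),
                       kingdom = c(rep("Metazoa", 5), "Bacteria"))
  meta <- make_meta(colnames(counts),
                    c("stomach", "stomach", "sediment", "negative_control"),
                    site = c("A", "A", "A", "lab"))
  motu_table(counts, tax, meta)
}

# paired diet/env tables realising chosen per-pair (r, p) values for MOTU "T"
# by padding with a filler MOTU, at depth `scale` reads per sample
paired_fixture <- function(r, p, scale = 1000) {
  stopifnot(length(r) == length(p))
  n <- length(r)
  st <- sprintf("ST%d", seq_len(n))
  sed <- sprintf("SED%d", seq_len(n))
  diet_counts <- rbind(T = round(r * scale), FILL = scale - round(r * scale))
  env_counts <- rbind(T = round(p * scale), FILL = scale - round(p * scale))
  colnames(diet_counts) <- st
  colnames(env_counts) <- sed
  tax <- make_taxonomy(c("T", "FILL"), species = c("Target sp", "Filler sp"))
  diet <- motu_table(diet_counts, tax,
                     make_meta(st, rep("stomach", n), site = sprintf("S%d", seq_len(n))))
  env <- motu_table(env_counts, tax,
                    make_meta(sed, rep("sediment", n), site = sprintf("S%d", seq_len(n))))
  list(diet = diet, env = env,
       pairing = site_pairing(diet, env))
}

expect_reconciles <- function(report) {
  for (rec in report) {
    expect_equal(rec$reads_in - rec$reads_out, sum(rec$removed$reads),
                 info = paste("stage", rec$stage))
  }
}
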
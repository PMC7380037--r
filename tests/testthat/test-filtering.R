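two_sample_table <- function(counts, species = rownames(counts),
                             rank = rep("species", nrow(counts)),
                             types = c("stomach", "sediment"), ...) {
  motu_table(counts,
             make_taxonomy(rownames(counts), species = species, rank = rank, ...),
             make_meta(colnames(counts), types))
}

test_that("species-level MOTU merging sums cells, keeps the best identity, conserves reads", {
  counts <- matrix(c(10, 5,
                     2, 0,
                     7, 7), nrow = 3, byrow = TRUE,
                   dimnames = list(c("Ma", "Mb", "Mc"), c("ST1", "SED1")))
  tax <- make_taxonomy(c("Ma", "Mb", "Mc"),
                       species = c("Carcinus maenas", "Carcinus maenas", "Other sp"),
                       best_identity = c(0.97, 0.99, 1))
  tab <- motu_table(counts, tax, make_meta(c("ST1", "SED1"),
                                           c("stomach", "sediment")))
  res <- merge_species_motus(tab)
  expect_equal(nrow(res$table$counts), 2L)
  expect_equal(unname(res$table$counts["Mb", ]), c(12, 5))  # cell-wise sum
  expect_false("Ma" %in% rownames(res$table$counts))        # 0.99 wins
  expect_equal(total_reads(res$table), total_reads(tab))
  expect_reconciles(res$report)

  # genus-rank MOTUs with the same name are never merged
  g <- two_sample_table(counts[1:2, ], rank = c("genus", "genus"))
  g$taxonomy$genus <- "Carcinus"
  expect_equal(nrow(merge_species_motus(g)$table$counts), 2L)

  # all-distinct species: identity, empty removal list
  res <- merge_species_motus(two_sample_table(counts,
                                              species = c("A a", "B b", "C c")))
  expect_identical(res$table$counts, counts)
  expect_equal(nrow(res$report[[1]]$removed), 0L)
})

test_that("tag-switching renormalization zeroes cells strictly below the row-total fraction", {
  counts <- matrix(c(990, 5, 5,
                     0, 60, 0,
                     50, 1, 50), nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("ST1", "ST2", "SED1")))
  tab <- two_sample_table(counts, types = c("stomach", "stomach", "sediment"))
  res <- renormalize_tag_switching(tab, 0.01)
  # A totals 1000: cells of 5 < 10 are zeroed
  expect_equal(unname(res$table$counts["A", ]), c(990, 0, 0))
  # B has a single occupied cell: 100% of its total, never zeroed
  expect_equal(unname(res$table$counts["B", ]), c(0, 60, 0))
  # C totals 101: the 1-read cell (below 1.01) is zeroed; the rest stay
  expect_equal(unname(res$table$counts["C", ]), c(50, 0, 50))
  expect_reconciles(res$report)

  # boundary: a cell exactly at the threshold fraction is retained
  b <- matrix(c(10, 990), 1, 2, dimnames = list("X", c("ST1", "SED1")))
  res <- renormalize_tag_switching(two_sample_table(b), 0.01)
  expect_equal(unname(res$table$counts["X", ]), c(10, 990))
})

test_that("contaminant rules remove matching MOTUs and report the rule", {
  counts <- matrix(c(5, 5, 9, 0, 8, 8), nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "H"), c("ST1", "SED1")))
  tab <- two_sample_table(counts, species = c("Prey sp", "", "Homo sapiens"),
                          rank = c("species", "kingdom", "species"),
                          kingdom = c("Metazoa", "Bacteria", "Metazoa"))
  rules <- list(list(kingdom = "Bacteria"), list(species = "Homo sapiens"))
  res <- remove_contaminants(tab, rules)
  expect_equal(rownames(res$table$counts), "A")
  expect_match(res$report[[1]]$removed$reason[
    res$report[[1]]$removed$id == "B"], "Bacteria")
  expect_reconciles(res$report)

  # empty rule list is the identity
  expect_identical(remove_contaminants(tab, list())$table$counts, counts)
  # unknown taxonomy field is an error
  expect_error(remove_contaminants(tab, list(list(color = "red"))),
               "unknown taxonomy field", class = "trophodiet_validation_error")
})

test_that("minimum-reads filter zeroes four-or-fewer cells and drops emptied MOTUs", {
  counts <- matrix(c(4, 5,
                     4, 3,
                     100, 4), nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("ST1", "SED1")))
  tab <- two_sample_table(counts)
  res <- min_reads_filter(tab, 5L)
  expect_equal(unname(res$table$counts["A", ]), c(0, 5))   # 4 zeroed, 5 kept
  expect_false("B" %in% rownames(res$table$counts))        # (4,3) all below
  expect_equal(unname(res$table$counts["C", ]), c(100, 0))
  expect_reconciles(res$report)

  # threshold 1 is the identity
  expect_identical(min_reads_filter(tab, 1L)$table$counts, counts)

  # whole-MOTU mode keys on the row maximum
  res <- min_reads_filter(tab, 5L, mode = "motu")
  expect_setequal(rownames(res$table$counts), c("A", "C"))
  expect_equal(unname(res$table$counts["A", ]), c(4, 5))
})

test_that("negative-control filter applies the strict 10% rule and consumes control columns", {
  counts <- matrix(c(35, 0, 5,    # 5/40 = 12.5% in control -> removed
                     90, 0, 10,   # exactly 10% -> retained
                     50, 50, 0),  # absent from controls -> retained
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("ST1", "SED1", "NEG1")))
  tab <- motu_table(counts, make_taxonomy(c("A", "B", "C")),
                    make_meta(c("ST1", "SED1", "NEG1"),
                              c("stomach", "sediment", "negative_control"),
                              site = c("A", "A", "lab")))
  res <- negative_control_filter(tab, 0.10)
  expect_setequal(rownames(res$table$counts), c("B", "C"))
  expect_false("NEG1" %in% colnames(res$table$counts))
  expect_reconciles(res$report)

  # without control samples the stage is a logged no-op
  no_ctrl <- subset(tab, sample_types = c("stomach", "sediment"))
  res <- negative_control_filter(no_ctrl, 0.10)
  expect_identical(res$table$counts, no_ctrl$counts)
  expect_match(res$report[[1]]$extra$note, "no negative controls")
})

test_that("focal-taxon removal reports per-sample pre-removal proportions", {
  counts <- matrix(c(28, 10,
                     50, 40,
                     22, 50), nrow = 3, byrow = TRUE,
                   dimnames = list(c("F", "A", "B"), c("ST1", "SED1")))
  tab <- two_sample_table(counts, species = c("Crangon crangon", "A a", "B b"))
  res <- remove_focal_taxa(tab, "Crangon crangon")
  expect_false("F" %in% rownames(res$table$counts))
  props <- res$report[[1]]$extra$focal_proportions
  expect_equal(props$proportion[props$sample_id == "ST1"], 0.28)
  expect_equal(props$proportion[props$sample_id == "SED1"], 0.10)
  expect_reconciles(res$report)

  # absent focal taxon: identity plus a warning
  expect_warning(res2 <- remove_focal_taxa(tab, "Nessiteras rhombopteryx"),
                 "not present")
  expect_identical(res2$table$counts, counts)

  # two focal taxa: both removed, proportions reported per taxon
  res3 <- suppressWarnings(remove_focal_taxa(tab, c("Crangon crangon", "A a")))
  expect_equal(nrow(res3$table$counts), 1L)
  props <- res3$report[[1]]$extra$focal_proportions
  expect_equal(sort(unique(props$taxon)), c("A a", "Crangon crangon"))
  expect_equal(sum(props$proportion[props$sample_id == "ST1"]), 0.78)
})

test_that("sample depth filter drops in-scope samples strictly below the threshold", {
  counts <- matrix(c(999, 1000, 999), 1, 3,
                   dimnames = list("A", c("ST1", "ST2", "SED1")))
  tab <- motu_table(counts, make_taxonomy("A"),
                    make_meta(c("ST1", "ST2", "SED1"),
                              c("stomach", "stomach", "sediment")))
  res <- sample_depth_filter(tab, 1000L, scope = "stomach")
  expect_setequal(colnames(res$table$counts), c("ST2", "SED1"))  # 999 sediment kept
  expect_reconciles(res$report)

  # depth 0 is the identity
  expect_identical(sample_depth_filter(tab, 0L)$table$counts, counts)

  # all in-scope and out-of-scope samples dropping is an error
  solo <- subset(tab, sample_types = "stomach", sites = "A")
  solo <- motu_table(solo$counts[, "ST1", drop = FALSE], solo$taxonomy,
                     solo$samples[solo$samples$sample_id == "ST1", ])
  expect_error(sample_depth_filter(solo, 100000L),
               "no samples survive", class = "trophodiet_validation_error")
})

test_that("threshold stages are idempotent and the cascade never increases a cell", {
  sim <- simulate_diet_dataset(
    sim_config(n_estuaries = 2, sites_per_estuary = 2, n_taxa = 12,
               stomach_depth = 4000, sediment_depth = 3000,
               tag_switch_rate = 0.01), seed = 42)
  tab <- sim$table
  cfg <- filter_config(min_sample_depth = 200L)

  stages <- list(
    function(t) min_reads_filter(t, 5L),
    function(t) negative_control_filter(t, 0.10),
    function(t) remove_contaminants(t, cfg$contaminant_rules),
    function(t) suppressWarnings(remove_focal_taxa(t, cfg$focal_taxa)),
    function(t) sample_depth_filter(t, 200L))
  for (f in stages) {
    once <- f(tab)$table
    twice <- f(once)$table
    expect_identical(twice$counts, once$counts)
  }

  res <- run_cascade(tab, cfg)
  expect_reconciles(res$report)
  # chain consistency and monotone reads
  for (k in seq_along(res$report)) {
    rec <- res$report[[k]]
    expect_lte(rec$reads_out, rec$reads_in)
    if (k > 1) expect_equal(rec$reads_in, res$report[[k - 1]]$reads_out)
  }
  # surviving cells never exceed their original value
  surv <- res$table$counts
  orig <- tab$counts[rownames(surv), colnames(surv)]
  expect_true(all(surv <= orig))
})

test_that("commuting stages (contaminant and focal removal) give identical output", {
  tab <- cascade_fixture()
  cfg1 <- filter_config(stage_order = c("remove_contaminants", "remove_focal_taxa"),
                        focal_taxa = "Crangon crangon")
  cfg2 <- filter_config(stage_order = c("remove_focal_taxa", "remove_contaminants"),
                        focal_taxa = "Crangon crangon")
  expect_identical(run_cascade(tab, cfg1)$table$counts,
                   run_cascade(tab, cfg2)$table$counts)
})

test_that("a no-op configuration leaves the table unchanged", {
  tab <- subset(cascade_fixture(), sample_types = c("stomach", "sediment"))
  cfg <- filter_config(tag_switch_threshold = 1e-9, min_reads_per_cell = 1L,
                       min_sample_depth = 0L, focal_taxa = "No such species",
                       contaminant_rules = list())
  res <- suppressWarnings(run_cascade(tab, cfg))
  expect_identical(res$table$counts, tab$counts)
})
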
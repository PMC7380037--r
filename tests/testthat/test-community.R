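# Independent oracles used here: direct Bray-Curtis arithmetic, full
# enumeration of label permutations for Mantel/PERMANOVA, and the
# hypergeometric closed form for rarefaction — all written out below, never
# delegated to the library that backs the implementation.

random_community <- function(n_motu, samples, seed, type = "stomach") {
  set.seed(seed)
  counts <- matrix(rpois(n_motu * length(samples), 30) + 1, nrow = n_motu,
                   dimnames = list(sprintf("M%02d", seq_len(n_motu)), samples))
  motu_table(counts, make_taxonomy(rownames(counts)),
             make_meta(samples, rep(type, length(samples)),
                       site = paste0("S", seq_along(samples))))
}

bray_oracle <- function(x, y) {
  x <- x / sum(x); y <- y / sum(y)
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

test_that("Bray-Curtis dissimilarities match the direct formula and its range", {
  tab <- random_community(6, paste0("ST", 1:6), seed = 21)
  d <- bray_curtis(tab)
  m <- as.matrix(d)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], bray_oracle(tab$counts[, i], tab$counts[, j]))
  }

  # hand-computed case on raw counts x=(1,0,3), y=(1,2,1): 1 - 2*2/8 = 0.5
  counts <- cbind(ST1 = c(1, 0, 3) * 4, ST2 = c(1, 2, 1) * 4)  # equal depths
  rownames(counts) <- c("A", "B", "C")
  two <- motu_table(counts, make_taxonomy(rownames(counts)),
                    make_meta(colnames(counts), c("stomach", "stomach"),
                              site = c("S1", "S2")))
  expect_equal(as.numeric(bray_curtis(two)), 0.5)

  # identical samples -> 0; disjoint supports -> 1
  same <- motu_table(matrix(c(5, 5, 10, 10), 2, 2,
                            dimnames = list(c("A", "B"), c("ST1", "ST2"))),
                     make_taxonomy(c("A", "B")),
                     make_meta(c("ST1", "ST2"), c("stomach", "stomach"),
                               site = c("S1", "S2")))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disj <- motu_table(matrix(c(5, 0, 0, 7), 2, 2,
                            dimnames = list(c("A", "B"), c("ST1", "ST2"))),
                     make_taxonomy(c("A", "B")),
                     make_meta(c("ST1", "ST2"), c("stomach", "stomach"),
                               site = c("S1", "S2")))
  expect_equal(as.numeric(bray_curtis(disj)), 1)

  # square-root transform operates on relative abundances (no re-closure)
  d2 <- bray_curtis(tab, transform = "sqrt")
  ra <- sweep(tab$counts, 2, colSums(tab$counts), "/")
  bc_raw <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
  expect_equal(as.matrix(d2)[1, 2], bc_raw(sqrt(ra[, 1]), sqrt(ra[, 2])))
})

test_that("Mantel r and p match trivial identities and full enumeration at n = 5", {
  tab <- random_community(8, paste0("ST", 1:5), seed = 31)
  d1 <- bray_curtis(tab)
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$statistic, 1)
  # positive affine transform leaves r = 1
  d_aff <- d1 * 0.5 + 0.1
  attr(d_aff, "Labels") <- labels(d1)
  expect_equal(mantel_test(d1, d_aff, n_perm = 99, seed = 1)$statistic, 1)

  tab2 <- random_community(8, paste0("ST", 1:5), seed = 32)
  d2 <- bray_curtis(tab2)
  attr(d2, "Labels") <- labels(d1)
  fit <- mantel_test(d1, d2, n_perm = 999, seed = 4)
  expect_gte(fit$p_value, 1 / 1000)
  expect_lte(fit$p_value, 1)

  # enumeration oracle: permute rows+columns of d2 over all 120 orderings
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  low <- lower.tri(m1)
  obs <- cor(m1[low], m2[low])
  expect_equal(fit$statistic, obs)
  perms <- perm_all(1:5)
  rs <- vapply(perms, function(pm) cor(m1[low], m2[pm, pm][low]), numeric(1))
  p_exact <- mean(rs >= obs - 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(fit$p_value - p_exact), 3 * mc_se + 2 / 1000)

  # label mismatch and degenerate matrices are rejected
  d_bad <- d2; attr(d_bad, "Labels") <- paste0("X", 1:5)
  expect_error(mantel_test(d1, d_bad), "labels",
               class = "trophodiet_validation_error")
  d_const <- d1; d_const[] <- 0.5
  expect_error(mantel_test(d1, d_const), "constant",
               class = "trophodiet_validation_error")
})

test_that("PERMANOVA pseudo-F and p match full enumeration on a 6-sample fixture", {
  tab <- random_community(10, paste0("ST", 1:6), seed = 41)
  d <- bray_curtis(tab)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  fit <- permanova(d, g, n_perm = 999, seed = 2)
  m <- as.matrix(d)
  expect_equal(fit$statistic, pseudo_F_oracle(m, as.character(g)),
               tolerance = 1e-10)

  perms <- perm_all(1:6)
  Fs <- vapply(perms, function(pm) pseudo_F_oracle(m, as.character(g)[pm]),
               numeric(1))
  p_exact <- mean(Fs >= fit$statistic - 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(fit$p_value - p_exact), 3 * mc_se + 2 / 1000)

  # maximally separated groups attain the minimal p
  m2 <- matrix(1, 6, 6) - diag(6)
  m2[1:3, 1:3] <- 0; m2[4:6, 4:6] <- 0; diag(m2) <- 0
  rownames(m2) <- colnames(m2) <- paste0("ST", 1:6)
  d2 <- as.dist(m2)
  fit2 <- permanova(d2, g, n_perm = 999, seed = 3)
  expect_lte(fit2$p_value, 0.11)  # only 20 distinct relabelings at n=6
  expect_error(permanova(d, factor(rep("a", 6))), "2 groups",
               class = "trophodiet_validation_error")
})

test_that("nested PERMANOVA uses sequential SS and validates the nesting", {
  sim <- simulate_diet_dataset(
    sim_config(n_estuaries = 2, sites_per_estuary = 2, n_taxa = 10,
               stomach_depth = 3000, sediment_depth = 2000), seed = 8)
  diet <- subset(sim$table, sample_types = "stomach")
  d <- bray_curtis(diet, transform = "sqrt")
  grp <- diet$samples[, c("estuary", "site")]
  fit <- permanova(d, grp, n_perm = 199, seed = 5)
  expect_s3_class(fit$detail, "anova")
  expect_equal(rownames(fit$detail)[1:2], c("outer", "nested"))
  # a site assigned to two estuaries is rejected
  bad <- grp; bad$estuary[bad$site == bad$site[1]][1] <- "other"
  expect_error(permanova(d, bad, n_perm = 99), "several outer",
               class = "trophodiet_validation_error")
})

test_that("rarefied richness matches the hypergeometric closed form and resampling agrees", {
  # closed-form oracle written out directly
  hurlbert <- function(counts, depth) {
    N <- sum(counts)
    sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
  }
  expect_equal(rarefy_richness(c(5, 5), depth = 2), 14 / 9, tolerance = 1e-12)
  expect_equal(rarefy_richness(c(5, 5), depth = 2), hurlbert(c(5, 5), 2),
               tolerance = 1e-12)

  set.seed(13)
  for (i in 1:5) {
    counts <- rpois(12, 20) + 1
    depth <- 50
    exp_S <- rarefy_richness(counts, depth)
    expect_equal(exp_S, hurlbert(counts, depth), tolerance = 1e-10)
    res_S <- rarefy_richness(counts, depth, method = "resample",
                             n_perm = 500, seed = i)
    # Monte-Carlo SE of the resampling mean, estimated from fresh draws
    pool <- rep.int(seq_along(counts), counts)
    draws <- replicate(300, length(unique(pool[sample.int(sum(counts), depth)])))
    se <- max(sd(draws) / sqrt(500), 1e-3)
    expect_lt(abs(res_S - exp_S), 3 * se + 0.05)
  }

  # boundary behaviour
  expect_equal(rarefy_richness(c(3, 2, 9), depth = 14), 3)
  expect_equal(rarefy_richness(c(3, 2, 9), depth = 1), 1)
  expect_error(rarefy_richness(c(3, 2), depth = 6), "depth",
               class = "trophodiet_validation_error")
  # monotone in depth
  counts <- c(40, 10, 5, 1)
  rich <- sapply(seq(1, 56, by = 5), function(d) rarefy_richness(counts, d))
  expect_true(all(diff(rich) >= 0))
})

test_that("accumulation curves are monotone, flat for identical samples, linear for disjoint ones", {
  # identical samples: flat at the common richness
  counts <- matrix(rep(c(300, 400, 300), 4), nrow = 3,
                   dimnames = list(c("A", "B", "C"), paste0("ST", 1:4)))
  tab <- motu_table(counts, make_taxonomy(c("A", "B", "C")),
                    make_meta(colnames(counts), rep("stomach", 4),
                              site = paste0("S", 1:4)))
  curve <- accumulation_curve(tab, rarefy_depth = 500, n_perm = 50, seed = 1)
  expect_equal(curve$richness, rep(3, 4))

  # disjoint supports: mean at k equals k x per-sample richness
  counts <- rbind(diag(c(600, 600, 600)), diag(c(600, 600, 600)))
  rownames(counts) <- paste0("M", 1:6)
  colnames(counts) <- paste0("ST", 1:3)
  tab <- motu_table(counts, make_taxonomy(rownames(counts)),
                    make_meta(colnames(counts), rep("stomach", 3),
                              site = paste0("S", 1:3)))
  curve <- accumulation_curve(tab, rarefy_depth = 1000, n_perm = 50, seed = 2)
  expect_equal(curve$richness, 2 * (1:3))

  # monotone, and shallow samples are excluded with a warning
  sim <- simulate_diet_dataset(
    sim_config(n_estuaries = 2, sites_per_estuary = 2, n_taxa = 15,
               stomach_depth = 3000, sediment_depth = 2000,
               n_empty_stomach = 1, empty_stomach_depth = 100), seed = 3)
  expect_warning(
    curve <- accumulation_curve(sim$table,
                                sample_ids = sim$table$samples$sample_id[
                                  sim$table$samples$sample_type %in%
                                    c("stomach", "empty_stomach")],
                                rarefy_depth = 1000, n_perm = 100, seed = 4),
    "below rarefaction depth")
  expect_true(all(diff(curve$richness) >= -1e-9))
})

test_that("permutation results are reproducible from their seed", {
  tab <- random_community(8, paste0("ST", 1:8), seed = 51)
  tab2 <- random_community(8, paste0("ST", 1:8), seed = 52)
  d1 <- bray_curtis(tab); d2 <- bray_curtis(tab2)
  attr(d2, "Labels") <- labels(d1)
  f1 <- mantel_test(d1, d2, n_perm = 199, seed = 7)
  f2 <- mantel_test(d1, d2, n_perm = 199, seed = 7)
  expect_identical(f1$p_value, f2$p_value)
  g <- factor(rep(c("a", "b"), each = 4))
  p1 <- permanova(d1, g, n_perm = 199, seed = 7)
  p2 <- permanova(d1, g, n_perm = 199, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
})
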
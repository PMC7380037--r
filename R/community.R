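# Distance-based comparison of consumed vs. available communities and
# richness estimation. Standard computations are delegated to vegan
# (vegdist, mantel, adonis2, rarefy, rrarefy, specaccum) behind this module's
# interface; results are returned in the package's own containers.

#' Bray-Curtis dissimilarity matrix between samples
#'
#' Computes pairwise Bray-Curtis dissimilarities
#' \eqn{d(x, y) = 1 - 2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)}
#' on per-sample relative read abundances, optionally square-root-transformed
#' first (the usual variance-stabilising choice for ordination-style
#' analyses).
#'
#' @param table A `motu_table`; every sample must have a positive total.
#' @param transform `"none"` (default) or `"sqrt"` (applied to the relative
#'   abundances).
#' @return A [stats::dist] object labelled by sample id, values in \[0, 1\].
#' @export
bray_curtis <- function(table, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  ra <- rel_abundance_matrix(table)
  if (transform == "sqrt") ra <- sqrt(ra)
  vegan::vegdist(t(ra), method = "bray")
}

# vegan emits a heuristic advisory whenever the smallest count exceeds 1;
# our inputs are validated integer read counts, so muffle that one warning.
quiet_vegan <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("observed count data|should be used for observed counts",
              conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

new_perm_test <- function(method, statistic, statistic_name, p_value, n_perm,
                          seed, detail = NULL) {
  structure(list(method = method, statistic = statistic,
                 statistic_name = statistic_name, p_value = p_value,
                 n_perm = n_perm, seed = seed, detail = detail),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (%d permutations%s)\n",
              x$method, x$statistic_name, x$statistic, x$p_value, x$n_perm,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  if (!is.null(x$detail)) print(x$detail)
  invisible(x)
}

check_dist_labels <- function(d1, d2) {
  l1 <- labels(d1); l2 <- labels(d2)
  if (is.null(l1) || is.null(l2) || !identical(l1, l2))
    stop_validation("distance matrices must carry identical sample labels ",
                    "in identical order")
}

#' Mantel test between two distance matrices
#'
#' Pearson product-moment correlation between the lower triangles of two
#' distance matrices, with significance by joint row/column permutation of
#' the second matrix. The p-value uses the add-one estimator
#' `(1 + b) / (1 + m)`.
#'
#' @param d1,d2 [stats::dist] objects with identical labels (e.g. paired
#'   stomach and sediment Bray-Curtis matrices with samples relabelled by
#'   site).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed making the permutation stream reproducible.
#' @return A `perm_test` with the correlation `r` and its p-value.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL) {
  check_dist_labels(d1, d2)
  if (attr(d1, "Size") < 4L) stop_validation("Mantel test needs at least 4 samples")
  if (stats::sd(as.vector(d1)) == 0 || stats::sd(as.vector(d2)) == 0)
    stop_validation("constant distance matrix: Mantel r is undefined")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = n_perm)
  new_perm_test("Mantel test", statistic = unname(fit$statistic),
                statistic_name = "r", p_value = fit$signif,
                n_perm = n_perm, seed = seed)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total sum
#' of squared dissimilarities among one grouping factor, or among an outer
#' factor with a second factor nested within it (sequential sums of squares,
#' outer factor fitted first), with significance by unrestricted label
#' permutation.
#'
#' @param dist A [stats::dist] object.
#' @param groups A factor (one-way design), or a data frame with two columns
#'   — outer factor first, nested factor second (e.g. estuary, site). Each
#'   nested level must belong to exactly one outer level.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `perm_test`; `statistic` is the pseudo-F of the first term and
#'   `detail` the full `adonis2` table.
#' @export
permanova <- function(dist, groups, n_perm = 1000L, seed = NULL) {
  n <- attr(dist, "Size")
  if (is.data.frame(groups)) {
    if (ncol(groups) != 2L)
      stop_validation("nested design needs exactly two factors (outer, nested)")
    if (nrow(groups) != n)
      stop_validation("groups length must match the distance matrix")
    outer_f <- factor(groups[[1L]]); nested_f <- factor(groups[[2L]])
    map <- unique(data.frame(o = outer_f, s = nested_f))
    if (anyDuplicated(map$s))
      stop_validation("nested level assigned to several outer levels: ",
                      map$s[anyDuplicated(map$s)])
    dat <- data.frame(outer = outer_f, nested = nested_f)
    if (!is.null(seed)) set.seed(seed)
    fit <- vegan::adonis2(dist ~ outer + nested, data = dat,
                          permutations = n_perm, by = "terms")
    new_perm_test("PERMANOVA (nested)", statistic = fit$F[1L],
                  statistic_name = "pseudo-F", p_value = fit$`Pr(>F)`[1L],
                  n_perm = n_perm, seed = seed, detail = fit)
  } else {
    g <- factor(groups)
    if (length(g) != n)
      stop_validation("groups length must match the distance matrix")
    if (nlevels(droplevels(g)) < 2L)
      stop_validation("PERMANOVA needs at least 2 groups")
    dat <- data.frame(g = g)
    if (!is.null(seed)) set.seed(seed)
    fit <- vegan::adonis2(dist ~ g, data = dat, permutations = n_perm)
    new_perm_test("PERMANOVA", statistic = fit$F[1L],
                  statistic_name = "pseudo-F", p_value = fit$`Pr(>F)`[1L],
                  n_perm = n_perm, seed = seed, detail = fit)
  }
}

#' Rarefied MOTU richness of one sample
#'
#' Expected number of MOTUs in a random subsample of `depth` reads drawn
#' without replacement. `method = "expected"` evaluates the hypergeometric
#' closed form
#' \eqn{E[S] = \sum_i (1 - \binom{N - N_i}{depth} / \binom{N}{depth})};
#' `method = "resample"` averages the observed richness of `n_perm` random
#' draws, which converges to the closed form.
#'
#' @param counts Integer vector of per-MOTU read counts for one sample.
#' @param depth Rarefaction depth (default 1000); must not exceed the sample
#'   total.
#' @param method `"expected"` (default) or `"resample"`.
#' @param n_perm Number of draws for the resampling method (default 500).
#' @param seed Integer seed (resampling only).
#' @return Expected richness (numeric scalar).
#' @examples
#' rarefy_richness(c(5, 5), depth = 2) # 2 - 2 * choose(5,2)/choose(10,2) = 14/9
#' @export
rarefy_richness <- function(counts, depth = 1000L,
                            method = c("expected", "resample"),
                            n_perm = 500L, seed = NULL) {
  method <- match.arg(method)
  counts <- counts[counts > 0]
  tot <- sum(counts)
  if (depth > tot) stop_validation("rarefaction depth exceeds sample total")
  if (method == "expected")
    return(as.numeric(quiet_vegan(vegan::rarefy(round(counts), sample = depth))))
  if (!is.null(seed)) set.seed(seed)
  pool <- rep.int(seq_along(counts), counts)
  mean(vapply(seq_len(n_perm), function(i)
    length(unique(pool[sample.int(tot, depth)])), numeric(1)))
}

#' Sample-based MOTU accumulation curve after read rarefaction
#'
#' Each sample in the group is first rarefied (one random draw without
#' replacement) to `rarefy_depth` reads; samples below that depth are
#' excluded with a warning. The curve then gives, for k = 1..n samples, the
#' mean (and sd) cumulative MOTU richness over `n_perm` random orderings of
#' the rarefied samples. The curve is monotone non-decreasing and its
#' endpoint equals the pooled richness of the rarefied samples.
#'
#' @param table A `motu_table`.
#' @param sample_ids Samples forming the group (default: all stomach
#'   samples).
#' @param rarefy_depth Per-sample read depth (default 1000).
#' @param n_perm Number of random orderings (default 1000).
#' @param seed Integer seed.
#' @return Data frame with columns `k`, `richness`, `sd`.
#' @export
accumulation_curve <- function(table, sample_ids = NULL, rarefy_depth = 1000L,
                               n_perm = 1000L, seed = NULL) {
  if (is.null(sample_ids))
    sample_ids <- table$samples$sample_id[table$samples$sample_type == "stomach"]
  unknown <- setdiff(sample_ids, colnames(table$counts))
  if (length(unknown)) stop_validation("unknown sample(s): ",
                                       paste(unknown, collapse = ", "))
  depth <- colSums(table$counts[, sample_ids, drop = FALSE])
  shallow <- sample_ids[depth < rarefy_depth]
  if (length(shallow)) {
    warning("excluding sample(s) below rarefaction depth: ",
            paste(shallow, collapse = ", "), call. = FALSE)
    sample_ids <- setdiff(sample_ids, shallow)
  }
  if (length(sample_ids) < 2L)
    stop_validation("accumulation curve needs at least 2 samples at depth")
  if (!is.null(seed)) set.seed(seed)
  m <- t(table$counts[, sample_ids, drop = FALSE])
  storage.mode(m) <- "integer"
  rar <- quiet_vegan(vegan::rrarefy(m, rarefy_depth))
  acc <- quiet_vegan(vegan::specaccum(rar, method = "random",
                                      permutations = n_perm))
  data.frame(k = acc$sites, richness = acc$richness,
             sd = ifelse(is.na(acc$sd), 0, acc$sd))
}
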
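# Independent oracles: enumeration and first-principles formulas used to
# cross-check the community statistics. Deliberately naive implementations.

perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# distance-based pseudo-F for a one-way design, from first principles
pseudo_F_oracle <- function(m, g) {
  n <- nrow(m); k <- length(unique(g))
  ss_t <- sum(m[lower.tri(m)]^2) / n
  ss_w <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    sub <- m[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}
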
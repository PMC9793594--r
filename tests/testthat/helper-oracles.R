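# Shared fixtures and independent oracles used across the suite.

# Tiny cohort for fast end-to-end checks: 5 networks, 40 ROIs.
tiny_spec <- function(seed = 5, ...) {
  cohort_spec(n_asd_subtype1 = 10, n_asd_subtype2 = 12, n_tc = 16,
              n_roi = 40, network_sizes = c(10, 12, 8, 6, 4),
              network_names = c("A", "B", "C", "D", "E"),
              behavior = default_behavior(c("A", "B", "C", "D", "E")),
              site_levels = paste0("s", 1:3), seed = seed, ...)
}

# Random small set of nonneg connectivity matrices (valid correlations).
random_fc_set <- function(n_subj, n_roi, seed, nonneg = TRUE) {
  set.seed(seed)
  lapply(seq_len(n_subj), function(i) {
    m <- matrix(rnorm(n_roi^2, 0.3, 0.3), n_roi)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m <- nearest_correlation(pmin(pmax(m, -0.99), 0.99))
    cm <- idfc:::new_connectivity_matrix(m, paste0("roi", seq_len(n_roi)), "raw")
    if (nonneg) zero_negatives(cm) else cm
  })
}

# Brute-force IDFC: triple loop over subjects x subjects x ROIs.
oracle_idfc <- function(asd_fc, tc_fc, drop_self = TRUE) {
  r <- nrow(asd_fc[[1]])
  out <- matrix(0, length(asd_fc), r)
  for (i in seq_along(asd_fc)) for (k in seq_len(r)) {
    d <- 0
    for (j in seq_along(tc_fc)) {
      a <- unclass(asd_fc[[i]])[k, ]
      b <- unclass(tc_fc[[j]])[k, ]
      if (drop_self) { a <- a[-k]; b <- b[-k] }
      d <- d + (1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    }
    out[i, k] <- d / length(tc_fc)
  }
  out
}

# Brute-force within-group deviation (i != j).
oracle_within <- function(fc, drop_self = TRUE) {
  r <- nrow(fc[[1]])
  n <- length(fc)
  out <- matrix(0, n, r)
  for (i in seq_len(n)) for (k in seq_len(r)) {
    d <- 0
    for (j in setdiff(seq_len(n), i)) {
      a <- unclass(fc[[i]])[k, ]; b <- unclass(fc[[j]])[k, ]
      if (drop_self) { a <- a[-k]; b <- b[-k] }
      d <- d + (1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    }
    out[i, k] <- d / (n - 1)
  }
  out
}

# Textbook pooled two-sample t per column.
oracle_pooled_t <- function(ya, yb) {
  na <- nrow(ya); nb <- nrow(yb)
  vapply(seq_len(ncol(ya)), function(j) {
    a <- ya[, j]; b <- yb[, j]
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }, numeric(1))
}

# Per-point silhouette by direct definition.
oracle_mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}
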
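zify <- function(fc_list) lapply(fc_list, fisher_z)

test_that("edge and block counts follow the combinatorial formulas", {
  expect_equal(count_region_edges(264), 34716L)
  expect_equal(count_region_edges(2), 1L)
  expect_equal(count_region_edges(10), 45L)
  expect_error(count_region_edges(1), "2 ROIs")
  expect_equal(count_network_blocks(11), 66L)
  expect_equal(count_network_blocks(1), 1L)
  expect_equal(count_network_blocks(4), 10L)
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 3), 0.05 / 3)
  expect_equal(round(bonferroni_threshold(0.05, 3), 3), 0.017)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
})

test_that("BH step-up matches hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(rep(0.9, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr(0.04, 0.05), TRUE)
  expect_equal(bh_fdr(numeric(0)), logical(0))
  # step-up: a late small p rescues earlier ones
  p <- c(0.001, 0.013, 0.04, 0.9)
  expect_equal(bh_fdr(p, 0.05), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("covariate-free edgewise t equals the pooled two-sample t", {
  za <- zify(random_fc_set(9, 10, seed = 71, nonneg = FALSE))
  zb <- zify(random_fc_set(11, 10, seed = 72, nonneg = FALSE))
  names(za) <- paste0("a", 1:9); names(zb) <- paste0("b", 1:11)
  res <- edgewise_test(za, zb, covariates = NULL)
  expect_equal(nrow(res), count_region_edges(10))
  ut <- upper.tri(matrix(0, 10, 10))
  ya <- t(sapply(za, function(m) unclass(m)[ut]))
  yb <- t(sapply(zb, function(m) unclass(m)[ut]))
  expect_equal(unname(res$t), oracle_pooled_t(ya, yb), tolerance = 1e-10)
  # identical groups give all-zero t
  r0 <- edgewise_test(za, za)
  expect_true(all(abs(r0$t) < 1e-12))
  expect_true(!any(r0$significant))
})

test_that("network block averages match hand arithmetic", {
  z <- matrix(0, 4, 4)
  z[1, 2] <- z[2, 1] <- 0.6          # within A
  z[3, 4] <- z[4, 3] <- 0.4          # within B
  z[1, 3] <- z[3, 1] <- 0.1; z[1, 4] <- z[4, 1] <- 0.2
  z[2, 3] <- z[3, 2] <- 0.3; z[2, 4] <- z[4, 2] <- 0.4
  zc <- idfc:::new_connectivity_matrix(z, paste0("roi", 1:4), "fisher_z")
  parc <- generate_parcellation(4, c(2, 2), c("A", "B"))
  b <- network_block_average(zc, parc)
  expect_equal(unname(b["A-A"]), 0.6)
  expect_equal(unname(b["B-B"]), 0.4)
  expect_equal(unname(b["A-B"]), mean(c(0.1, 0.2, 0.3, 0.4)))
  # constant matrix -> every block equals the constant
  zc2 <- idfc:::new_connectivity_matrix(matrix(0.7, 4, 4),
                                        paste0("roi", 1:4), "fisher_z")
  expect_true(all(network_block_average(zc2, parc) == 0.7))
  # 11-network parcellation yields 66 blocks
  z11 <- zify(random_fc_set(1, 264, seed = 73, nonneg = FALSE))[[1]]
  expect_length(network_block_average(z11, generate_parcellation(264)), 66)
})

test_that("a planted uniform shift is reproduced in every block mean", {
  parc <- generate_parcellation(12, c(5, 4, 3), c("A", "B", "C"))
  base <- random_fc_set(6, 12, seed = 74, nonneg = FALSE)
  names(base) <- paste0("s", 1:6)
  shifted <- lapply(base, function(m) {
    v <- unclass(m); v <- v + 0.2; diag(v) <- 1
    idfc:::new_connectivity_matrix(v, rownames(m), "raw")
  })
  delta <- 0.2
  bb <- network_block_average(lapply(base, function(m) {
    z <- unclass(m); diag(z) <- 0
    idfc:::new_connectivity_matrix(z, rownames(m), "fisher_z") }), parc)
  bs <- network_block_average(lapply(shifted, function(m) {
    z <- unclass(m) ; diag(z) <- 0
    idfc:::new_connectivity_matrix(z, rownames(m), "fisher_z") }), parc)
  expect_equal(unname(colMeans(bs) - colMeans(bb)), rep(delta, 6),
               tolerance = 1e-12)
})

test_that("network test flags a planted global shift with positive t", {
  parc <- generate_parcellation(12, c(5, 4, 3), c("A", "B", "C"))
  za <- zify(random_fc_set(10, 12, seed = 75, nonneg = FALSE))
  zb <- zify(random_fc_set(10, 12, seed = 76, nonneg = FALSE))
  names(za) <- paste0("a", 1:10); names(zb) <- paste0("b", 1:10)
  za_shift <- lapply(za, function(m) {
    v <- unclass(m) + 0.5; diag(v) <- 0
    idfc:::new_connectivity_matrix(v, rownames(m), "fisher_z")
  })
  ba <- network_block_average(za_shift, parc)
  bb <- network_block_average(zb, parc)
  res <- network_test(ba, bb, comparison = c("shifted", "null"))
  expect_true(all(res$t[res$significant] > 0))
  expect_gt(sum(res$significant), 0)
  expect_true(all(res$mean_diff > 0))
  # identical groups -> nothing significant
  r0 <- network_test(ba, ba)
  expect_true(!any(r0$significant))
})

test_that("whole-brain comparisons apply the Bonferroni rule", {
  za <- zify(random_fc_set(8, 8, seed = 77, nonneg = FALSE))
  zb <- zify(random_fc_set(8, 8, seed = 78, nonneg = FALSE))
  zc <- zify(random_fc_set(8, 8, seed = 79, nonneg = FALSE))
  names(za) <- paste0("a", 1:8); names(zb) <- paste0("b", 1:8)
  names(zc) <- paste0("c", 1:8)
  res <- wholebrain_test(list(g1 = za, g2 = zb, tc = zc))
  expect_equal(nrow(res), 3)
  expect_equal(res$threshold, rep(0.05 / 3, 3))
  r0 <- wholebrain_test(list(g1 = za, g2 = za, tc = za))
  expect_true(!any(r0$significant))
})

test_that("significant-edge fractions partition the region-level count", {
  parc <- generate_parcellation(10, c(6, 4), c("A", "B"))
  za <- zify(random_fc_set(12, 10, seed = 80, nonneg = FALSE))
  zb <- zify(random_fc_set(12, 10, seed = 81, nonneg = FALSE))
  names(za) <- paste0("a", 1:12); names(zb) <- paste0("b", 1:12)
  et <- edgewise_test(za, zb)
  fr <- significant_edge_fraction(et, parc)
  expect_equal(sum(fr$n_edges), count_region_edges(10))
  expect_equal(sum(fr$n_significant), sum(et$significant))
  expect_true(all(fr$pct >= 0 & fr$pct <= 100, na.rm = TRUE))
  # hand-built toy: 1 of 4 inter-block edges significant -> 25%
  toy <- et[0, ]
  toy <- data.frame(roi_a = c("roi1", "roi1", "roi2", "roi2"),
                    roi_b = c("roi3", "roi4", "roi3", "roi4"),
                    t = c(3, 0, 0, 0), p = c(0.001, 0.9, 0.9, 0.9),
                    significant = c(TRUE, FALSE, FALSE, FALSE),
                    direction = c(1, 0, 0, 0))
  parc2 <- generate_parcellation(4, c(2, 2), c("A", "B"))
  fr2 <- significant_edge_fraction(toy, parc2)
  expect_equal(fr2$pct[fr2$block == "A-B"], 25)
})

test_that("within-group deviation contrast detects inflated heterogeneity", {
  set.seed(82)
  fa <- random_fc_set(14, 10, seed = 83)
  ft <- random_fc_set(14, 10, seed = 84)
  va <- unclass(compute_within_group_deviation(fa))
  vt <- unclass(compute_within_group_deviation(ft))
  rownames(va) <- paste0("a", 1:14); rownames(vt) <- paste0("t", 1:14)
  parc <- generate_parcellation(10, c(6, 4), c("A", "B"))
  colnames(va) <- colnames(vt) <- parc$roi_id
  r0 <- within_group_deviation_test(va, vt, parcellation = parc)
  expect_true(all(c("roi", "network", "t", "p", "significant") %in% names(r0)))
  # identical groups -> nothing significant
  ri <- within_group_deviation_test(va, va, parcellation = parc)
  expect_true(!any(ri$significant))
  expect_equal(attr(ri, "n_higher") + attr(ri, "n_lower"), 0)
  # a group with 3x the connectivity jitter shows higher heterogeneity
  mk <- function(noise, seed) {
    co <- generate_cohort(cohort_spec(
      n_asd_subtype1 = 1, n_asd_subtype2 = 1, n_tc = 14, n_roi = 12,
      network_sizes = c(8, 4), network_names = c("A", "B"),
      noise_sd = noise, site_levels = paste0("s", 1:2), seed = seed))
    ids <- co$phenotype$subject_id[co$phenotype$group == "tc"]
    unclass(compute_within_group_deviation(
      lapply(co$fc[ids], zero_negatives)))
  }
  v_hi <- mk(0.15, 3); v_lo <- mk(0.05, 4)
  rownames(v_hi) <- paste0("h", 1:14); rownames(v_lo) <- paste0("l", 1:14)
  parc3 <- generate_parcellation(12, c(8, 4), c("A", "B"))
  colnames(v_hi) <- colnames(v_lo) <- parc3$roi_id
  rh <- within_group_deviation_test(v_hi, v_lo, parcellation = parc3)
  expect_gt(attr(rh, "n_higher"), attr(rh, "n_lower"))
  expect_gt(attr(rh, "n_higher"), 0)
})
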
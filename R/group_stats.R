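#' Covariate-adjusted group comparisons of connectivity
#'
#' Two-group connectivity differences are tested at three spatial scales —
#' every region-level edge, every network block (within- and
#' between-network), and a single whole-brain mean — on Fisher
#' z-transformed matrices. The "two-sample t test with covariates" is the t
#' statistic of the group coefficient in a per-unit ordinary least-squares
#' model (intercept + group indicator + encoded covariates). Region- and
#' network-scale p values are Benjamini-Hochberg corrected; the three
#' whole-brain comparisons use Bonferroni.
#'
#' @name group_stats
NULL

#' Number of region-level edges
#'
#' @param n_roi number of ROIs (>= 2).
#' @return n_roi * (n_roi - 1) / 2.
#' @export
count_region_edges <- function(n_roi) {
  if (n_roi < 2L) stop("need at least 2 ROIs")
  as.integer(n_roi * (n_roi - 1) / 2)
}

#' Number of network blocks (within- plus between-network)
#'
#' @param n_net number of networks (>= 1).
#' @return n_net + n_net * (n_net - 1) / 2.
#' @export
count_network_blocks <- function(n_net) {
  if (n_net < 1L) stop("need at least 1 network")
  as.integer(n_net + n_net * (n_net - 1) / 2)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha familywise level.
#' @param m number of comparisons.
#' @return alpha / m (stored at full precision).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3L) alpha / m

#' Benjamini-Hochberg significance mask
#'
#' Standard step-up procedure at level `q`.
#'
#' @param p vector of p values in \[0, 1\].
#' @param q false discovery rate level.
#' @return logical mask, TRUE where the hypothesis is rejected.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}

# t statistic, p and df of the group coefficient in Y ~ 1 + group + covars,
# vectorized over the columns of Y.
group_lm_t <- function(y, group, covariates = NULL, columns = NULL) {
  y <- as.matrix(y)
  g <- as.numeric(group)
  x <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates) && nrow(covariates) > 0L) {
    columns <- columns %||% intersect(covariate_columns, names(covariates))
    x <- cbind(x, encode_covariates(covariates, columns))
  }
  n <- nrow(y); pcol <- ncol(x)
  if (n <= pcol + 1L)
    stop("combined sample size (", n, ") too small for ", pcol, " regressors")
  qx <- qr(x)
  if (qx$rank < pcol)
    stop("rank-deficient design in group comparison")
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - pcol
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtxinv[2L, 2L])
  tval <- coefs[2L, ] / se
  tval[se == 0] <- 0
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(t = tval, p = p, df = df)
}

upper_tri_index <- function(rois) {
  r <- length(rois)
  idx <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  data.frame(roi_a = rois[idx[, 1L]], roi_b = rois[idx[, 2L]],
             stringsAsFactors = FALSE)
}

# Stack upper-triangle edges of a list of z matrices into subjects x edges.
edge_matrix <- function(z_list) {
  a <- fc_array(z_list)
  r <- length(a$rois)
  ut <- upper.tri(matrix(0, r, r))
  m <- t(apply(a$arr, 1L, function(s) s[ut]))
  if (length(z_list) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- names(z_list)
  list(values = m, edges = upper_tri_index(a$rois), rois = a$rois)
}

new_stats_table <- function(df, scale, comparison, correction, level) {
  attr(df, "scale") <- scale
  attr(df, "comparison") <- comparison
  attr(df, "correction") <- correction
  attr(df, "level") <- level
  class(df) <- c("edgewise_stats", class(df))
  df
}

#' Edgewise group comparison
#'
#' Tests every upper-triangle edge between two groups of Fisher z matrices
#' with covariate adjustment and BH correction. Positive t means group A >
#' group B.
#'
#' @param z_a,z_b named lists of `fisher_z` connectivity matrices.
#' @param covariates data frame for the stacked subjects (rows of `z_a`
#'   first), or NULL for an unadjusted test.
#' @param q FDR level.
#' @param comparison label pair, e.g. `c("subtype1", "tc")`.
#' @return data frame (class `edgewise_stats`) with roi_a, roi_b, t, p,
#'   significant, direction.
#' @export
edgewise_test <- function(z_a, z_b, covariates = NULL, q = 0.05,
                          comparison = c("a", "b")) {
  ea <- edge_matrix(z_a); eb <- edge_matrix(z_b)
  if (!identical(ea$rois, eb$rois)) stop("groups do not share roi_order")
  y <- rbind(ea$values, eb$values)
  g <- rep(c(1, 0), c(nrow(ea$values), nrow(eb$values)))
  fit <- group_lm_t(y, g, covariates)
  out <- cbind(ea$edges,
               data.frame(t = fit$t, p = fit$p,
                          significant = bh_fdr(fit$p, q),
                          direction = sign(fit$t)))
  new_stats_table(out, "region", comparison, "BH", q)
}

#' Per-subject network block averages
#'
#' For one z matrix, the mean z over the edges of every network block:
#' between-network blocks use all cross edges, within-network blocks the
#' block's upper triangle (self edges excluded). A singleton network's
#' diagonal block has no edges and is returned as NA with a warning.
#'
#' @param z a `fisher_z` connectivity matrix, or a named list of them.
#' @param parcellation a parcellation covering all ROIs.
#' @return named vector of block means (blocks "A-B" in network order), or a
#'   subjects x blocks matrix for a list input.
#' @export
network_block_average <- function(z, parcellation) {
  parcellation <- as_parcellation(parcellation)
  if (is.list(z) && !is.matrix(z)) {
    out <- t(vapply(z, network_block_average, parcellation = parcellation,
                    numeric(count_network_blocks(nlevels(parcellation$network)))))
    rownames(out) <- names(z)
    return(out)
  }
  if (!identical(as.character(parcellation$roi_id), rownames(z)))
    stop("parcellation does not match matrix roi_order")
  nets <- levels(parcellation$network)
  memb <- parcellation$network
  nn <- length(nets)
  vals <- numeric(0); labs <- character(0)
  for (i in seq_len(nn)) for (j in i:nn) {
    sub <- unclass(z)[memb == nets[i], memb == nets[j], drop = FALSE]
    if (i == j) {
      if (nrow(sub) < 2L) {
        warning("singleton network ", nets[i], ": within-block mean undefined")
        v <- NA_real_
      } else v <- mean(sub[upper.tri(sub)])
    } else v <- mean(sub)
    vals <- c(vals, v); labs <- c(labs, paste0(nets[i], "-", nets[j]))
  }
  stats::setNames(vals, labs)
}

#' Network-block group comparison
#'
#' As [edgewise_test()], over the block-average vectors (66 units for 11
#' networks), with BH correction. A signed mean-difference column mirrors
#' the +/- display of network-level results.
#'
#' @param blocks_a,blocks_b subjects x blocks matrices from
#'   [network_block_average()].
#' @inheritParams edgewise_test
#' @return data frame (class `edgewise_stats`) with block, t, p,
#'   significant, direction, mean_diff.
#' @export
network_test <- function(blocks_a, blocks_b, covariates = NULL, q = 0.05,
                         comparison = c("a", "b")) {
  if (!identical(colnames(blocks_a), colnames(blocks_b)))
    stop("block vectors do not align")
  y <- rbind(blocks_a, blocks_b)
  g <- rep(c(1, 0), c(nrow(blocks_a), nrow(blocks_b)))
  fit <- group_lm_t(y, g, covariates)
  out <- data.frame(block = colnames(blocks_a), t = fit$t, p = fit$p,
                    significant = bh_fdr(fit$p, q),
                    direction = sign(fit$t),
                    mean_diff = colMeans(blocks_a) - colMeans(blocks_b),
                    row.names = NULL)
  new_stats_table(out, "network", comparison, "BH", q)
}

#' Whole-brain mean connectivity per subject
#'
#' @param z a `fisher_z` connectivity matrix.
#' @return mean of the upper-triangle z values.
#' @export
wholebrain_mean <- function(z) {
  v <- unclass(z)
  mean(v[upper.tri(v)])
}

#' Whole-brain group comparisons with Bonferroni control
#'
#' One covariate-adjusted t per listed comparison on the subject-level
#' whole-brain mean z; significance at p < alpha / (number of comparisons).
#'
#' @param z_groups named list of groups, each a named list of `fisher_z`
#'   matrices.
#' @param comparisons list of 2-vectors of group names (default: the three
#'   pairwise comparisons of the listed groups, if exactly three).
#' @param covariate_table data frame indexed by subject id (rownames or a
#'   `subject_id` column) supplying covariates, or NULL.
#' @param alpha familywise level.
#' @return data frame (class `edgewise_stats`, scale `whole_brain`) with one
#'   row per comparison: group_a, group_b, t, p, threshold, significant.
#' @export
wholebrain_test <- function(z_groups, comparisons = NULL,
                            covariate_table = NULL, alpha = 0.05) {
  if (is.null(comparisons)) {
    gn <- names(z_groups)
    comparisons <- utils::combn(gn, 2L, simplify = FALSE)
  }
  m <- length(comparisons)
  thr <- bonferroni_threshold(alpha, m)
  rows <- lapply(comparisons, function(cmp) {
    za <- z_groups[[cmp[1L]]]; zb <- z_groups[[cmp[2L]]]
    y <- c(vapply(za, wholebrain_mean, numeric(1)),
           vapply(zb, wholebrain_mean, numeric(1)))
    g <- rep(c(1, 0), c(length(za), length(zb)))
    cov <- NULL
    if (!is.null(covariate_table)) {
      ids <- c(names(za), names(zb))
      cov <- covariate_table[match(ids, covariate_table$subject_id), ,
                             drop = FALSE]
    }
    fit <- group_lm_t(matrix(y, ncol = 1L), g, cov)
    data.frame(group_a = cmp[1L], group_b = cmp[2L],
               t = unname(fit$t), p = unname(fit$p), threshold = thr,
               significant = unname(fit$p < thr),
               direction = unname(sign(fit$t)), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  new_stats_table(out, "whole_brain", "all", "bonferroni", alpha)
}

#' Fraction of significant edges per network block
#'
#' For every network block, the percentage of its region-level edges whose
#' group difference is significant, out of the block's total edge count.
#'
#' @param edge_table an [edgewise_test()] result.
#' @param parcellation a parcellation covering the tested ROIs.
#' @return data frame with block, n_edges, n_significant, pct (0-100; NA
#'   for a block with no edges).
#' @export
significant_edge_fraction <- function(edge_table, parcellation) {
  parcellation <- as_parcellation(parcellation)
  net <- stats::setNames(as.character(parcellation$network),
                         parcellation$roi_id)
  na <- net[edge_table$roi_a]; nb <- net[edge_table$roi_b]
  nets <- levels(parcellation$network)
  ord <- function(x, y) {
    i <- match(x, nets); j <- match(y, nets)
    paste0(nets[pmin(i, j)], "-", nets[pmax(i, j)])
  }
  blk <- ord(na, nb)
  labs <- character(0)
  nn <- length(nets)
  for (i in seq_len(nn)) for (j in i:nn)
    labs <- c(labs, paste0(nets[i], "-", nets[j]))
  n_edges <- as.integer(table(factor(blk, levels = labs)))
  n_sig <- as.integer(tapply(edge_table$significant,
                             factor(blk, levels = labs), sum, default = 0L))
  n_sig[is.na(n_sig)] <- 0L
  data.frame(block = labs, n_edges = n_edges, n_significant = n_sig,
             pct = ifelse(n_edges > 0L, 100 * n_sig / n_edges, NA_real_))
}

#' Compare within-group deviation maps between groups
#'
#' Region-wise covariate-adjusted t tests of two within-group deviation
#' matrices (e.g. ASD vs TC heterogeneity), BH corrected, with signed
#' counts and network memberships reported per ROI.
#'
#' @param v_aa,v_tt within-group deviation matrices over the same ROI set.
#' @param covariates stacked covariates (rows of `v_aa` first), or NULL.
#' @param parcellation a parcellation for the ROI-network lookup.
#' @param q FDR level.
#' @return data frame with roi, network, t, p, significant, direction, plus
#'   attributes `n_higher` / `n_lower` (significant ROI counts by sign).
#' @export
within_group_deviation_test <- function(v_aa, v_tt, covariates = NULL,
                                        parcellation = NULL, q = 0.05) {
  if (!identical(colnames(v_aa), colnames(v_tt)))
    stop("deviation matrices do not share an ROI set")
  y <- rbind(v_aa, v_tt)
  g <- rep(c(1, 0), c(nrow(v_aa), nrow(v_tt)))
  fit <- group_lm_t(y, g, covariates)
  network <- NA_character_
  if (!is.null(parcellation)) {
    parcellation <- as_parcellation(parcellation)
    network <- as.character(parcellation$network)[
      match(colnames(v_aa), parcellation$roi_id)]
  }
  out <- data.frame(roi = colnames(v_aa), network = network,
                    t = fit$t, p = fit$p,
                    significant = bh_fdr(fit$p, q),
                    direction = sign(fit$t), row.names = NULL)
  attr(out, "n_higher") <- sum(out$significant & out$t > 0)
  attr(out, "n_lower") <- sum(out$significant & out$t < 0)
  new_stats_table(out, "region", c("within_a", "within_b"), "BH", q)
}
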
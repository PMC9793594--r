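#' Connectome subtyping by k-means over network-level deviations
#'
#' Network-level IDFC is residualized against nuisance covariates, k is
#' selected by the mean silhouette over a scanned range, and subjects are
#' clustered by multi-restart k-means. Subtype balance on demographics and
#' symptom scores is then tested.
#'
#' @name subtype
NULL

covariate_columns <- c("age", "fiq", "mean_fd", "handedness", "eye_status",
                       "site")

#' Encode a covariate table as a design matrix
#'
#' Continuous covariates are standardized; categorical ones are one-hot
#' encoded with the first level dropped. No intercept column is included
#' (callers add it). Constant covariates are dropped with a warning only when
#' categorical with a single level; a constant continuous covariate is an
#' error (rank-deficient design).
#'
#' @param covariates data frame of per-subject covariates.
#' @param columns which columns to use (default: the standard six).
#' @return numeric matrix, one row per subject.
#' @export
encode_covariates <- function(covariates, columns = intersect(
                                covariate_columns, names(covariates))) {
  if (length(columns) == 0L)
    return(matrix(numeric(0), nrow = nrow(covariates), ncol = 0L))
  if (anyNA(covariates[columns]))
    stop("missing values among modeled covariates: ",
         paste(columns[colSums(is.na(covariates[columns])) > 0], collapse = ", "))
  blocks <- list()
  for (cn in columns) {
    x <- covariates[[cn]]
    if (is.numeric(x)) {
      s <- stats::sd(x)
      if (s == 0) stop("constant continuous covariate: ", cn)
      blocks[[cn]] <- matrix((x - mean(x)) / s, ncol = 1L,
                             dimnames = list(NULL, cn))
    } else {
      f <- factor(x)
      f <- droplevels(f)
      if (nlevels(f) < 2L) next
      mm <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(cn, "_", levels(f)[-1L])
      blocks[[cn]] <- mm
    }
  }
  do.call(cbind, blocks) %||% matrix(numeric(0), nrow(covariates), 0L)
}

design_with_intercept <- function(covariates, columns) {
  x <- encode_covariates(covariates, columns)
  cbind(`(Intercept)` = 1, x)
}

#' Residualize features against covariates
#'
#' Each feature column is replaced by the residuals of an ordinary
#' least-squares fit on an intercept plus the encoded covariates, making the
#' residuals orthogonal to every regressor. Idempotent.
#'
#' @param features numeric matrix (e.g. network-level deviations), rows
#'   aligned with `covariates`.
#' @param covariates data frame of covariates for the same subjects.
#' @param columns covariate columns to regress out.
#' @return matrix of residuals with the same shape and dimnames.
#' @export
residualize <- function(features, covariates,
                        columns = intersect(covariate_columns,
                                            names(covariates))) {
  f <- as.matrix(features)
  if (nrow(f) != nrow(covariates))
    stop("features and covariates have different numbers of subjects")
  x <- design_with_intercept(covariates, columns)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  r <- qr.resid(qx, f)
  dimnames(r) <- dimnames(f)
  r
}

#' Mean silhouette of a clustering
#'
#' Euclidean silhouette of each point, averaged. Computed with
#' \pkg{cluster}'s silhouette routine.
#'
#' @param features numeric matrix.
#' @param labels integer cluster labels (at least 2 clusters).
#' @return mean silhouette width in \[-1, 1\].
#' @export
mean_silhouette <- function(features, labels) {
  sil <- cluster::silhouette(as.integer(labels),
                             stats::dist(as.matrix(features)))
  mean(sil[, "sil_width"])
}

best_kmeans <- function(features, k, n_restarts, iter_max = 300L) {
  suppressWarnings(stats::kmeans(features, centers = k, nstart = n_restarts,
                                 iter.max = iter_max))
}

#' Scan k by mean silhouette
#'
#' For each k in `k_range`, fits the best of `n_restarts` k-means solutions
#' and scores it by the mean Euclidean silhouette. Deterministic given
#' `seed`.
#'
#' @param features numeric subjects x features matrix.
#' @param k_range candidate cluster counts (default 2:20, i.e. 19 values).
#' @param seed RNG seed.
#' @param n_restarts k-means restarts per k.
#' @return data frame with columns `k` and `silhouette`; attribute `k_star`
#'   holds the smallest k attaining the maximum.
#' @export
silhouette_scan <- function(features, k_range = 2:20, seed = 1L,
                            n_restarts = 100L) {
  features <- as.matrix(features)
  if (max(k_range) >= nrow(features))
    stop("k_range extends to ", max(k_range), " but only ",
         nrow(features), " subjects are available")
  set.seed(seed)
  sil <- vapply(k_range, function(k) {
    fit <- best_kmeans(features, k, n_restarts)
    mean_silhouette(features, fit$cluster)
  }, numeric(1))
  out <- data.frame(k = as.integer(k_range), silhouette = sil)
  attr(out, "k_star") <- out$k[which.max(out$silhouette)]
  out
}

#' Cluster subjects into subtypes
#'
#' Best-of-restarts k-means (lowest within-cluster sum of squares); label
#' ids are canonicalized by descending cluster size, so subtype 1 is always
#' the largest cluster.
#'
#' @inheritParams silhouette_scan
#' @param k number of clusters (>= 2).
#' @return list (class `subtype_solution`) with `labels` (named integer
#'   vector), `k`, `centers`, `tot_withinss`, `seed`, `n_restarts`.
#' @export
cluster_subtypes <- function(features, k, seed = 1L, n_restarts = 100L) {
  features <- as.matrix(features)
  if (k < 2L) stop("k must be at least 2")
  if (k >= nrow(features)) stop("k must be below the number of subjects")
  set.seed(seed)
  fit <- best_kmeans(features, k, n_restarts)
  sizes <- tabulate(fit$cluster, nbins = k)
  if (any(sizes == 0L)) stop("degenerate clustering: empty cluster")
  remap <- order(order(-sizes, seq_len(k)))
  labels <- remap[fit$cluster]
  names(labels) <- rownames(features)
  structure(list(labels = labels, k = as.integer(k),
                 centers = fit$centers[order(-sizes, seq_len(k)), , drop = FALSE],
                 tot_withinss = fit$tot.withinss,
                 seed = seed, n_restarts = n_restarts),
            class = "subtype_solution")
}

#' Test subtype balance on demographics and symptoms
#'
#' Two-sample t tests for continuous variables (age, FIQ, mean FD, and the
#' ADOS subscores, the latter restricted to subjects with scores present)
#' and chi-squared tests for handedness and eye status; the site x subtype
#' contingency table is reported alongside its chi-squared test.
#'
#' @param labels per-subject subtype labels (exactly 2 subtypes).
#' @param phenotype phenotype rows for the same subjects, in order.
#' @param continuous,categorical variable names to test.
#' @return list with `tests` (data frame: variable, type, statistic, df, p,
#'   n1, n2) and `site_table` (contingency table).
#' @export
compare_subtype_profiles <- function(labels, phenotype,
                                     continuous = c("age", "fiq", "mean_fd",
                                                    "ados_comm", "ados_social",
                                                    "ados_rrb"),
                                     categorical = c("handedness",
                                                     "eye_status")) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L)
    stop("pairwise balance tests need exactly 2 subtypes")
  if (min(table(labels)) < 2L) stop("a subtype has fewer than 2 members")
  if (length(labels) != nrow(phenotype))
    stop("labels and phenotype are misaligned")
  rows <- list()
  for (v in intersect(continuous, names(phenotype))) {
    x <- phenotype[[v]]
    keep <- !is.na(x)
    g <- labels[keep]; xv <- x[keep]
    if (length(unique(g)) < 2L || min(table(g)) < 2L) next
    tt <- stats::t.test(xv[g == 1L], xv[g == 2L], var.equal = TRUE)
    rows[[v]] <- data.frame(variable = v, type = "t",
                            statistic = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value,
                            n1 = sum(g == 1L), n2 = sum(g == 2L))
  }
  for (v in intersect(categorical, names(phenotype))) {
    tab <- table(phenotype[[v]], labels)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[v]] <- data.frame(variable = v, type = "chisq",
                            statistic = unname(ct$statistic),
                            df = unname(ct$parameter), p = ct$p.value,
                            n1 = sum(labels == 1L), n2 = sum(labels == 2L))
  }
  site_table <- NULL
  if ("site" %in% names(phenotype)) {
    site_table <- table(site = phenotype$site, subtype = labels)
    ct <- suppressWarnings(stats::chisq.test(site_table, correct = FALSE))
    rows[["site"]] <- data.frame(variable = "site", type = "chisq",
                                 statistic = unname(ct$statistic),
                                 df = unname(ct$parameter), p = ct$p.value,
                                 n1 = sum(labels == 1L), n2 = sum(labels == 2L))
  }
  list(tests = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       site_table = site_table)
}
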
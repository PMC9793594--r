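#' Inter-individual deviation of functional connectivity (IDFC)
#'
#' The IDFC of subject i at ROI k is the mean, over all reference subjects j,
#' of the cosine distance between the two subjects' connectivity profiles at
#' ROI k:
#'
#'   V_ik = mean_j ( 1 - F_ik . F_jk / (||F_ik|| ||F_jk||) )
#'
#' where F_ik is row k of subject i's (nonnegative) correlation matrix, the
#' correlations of region k with the other regions. With nonnegative profiles
#' every deviation lies in \[0, 1\]; with negatives retained, \[0, 2\].
#'
#' @name deviation
NULL

new_deviation_matrix <- function(values, unit_kind, reference) {
  stopifnot(is.matrix(values))
  attr(values, "unit_kind") <- unit_kind
  attr(values, "reference") <- reference
  class(values) <- c("deviation_matrix", class(values))
  values
}

#' Cosine distance between two connectivity profiles
#'
#' @param a,b numeric vectors of equal length, both with positive norm.
#' @return 1 - cos(a, b), in \[0, 2\] (\[0, 1\] for nonnegative profiles).
#' @export
cosine_deviation <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("zero-norm connectivity profile")
  1 - sum(a * b) / (na * nb)
}

# Stack a list of connectivity matrices into a subjects x R x R array,
# checking a shared ROI order.
fc_array <- function(fc_list) {
  if (length(fc_list) == 0L) stop("empty connectivity set")
  rois <- rownames(fc_list[[1L]])
  r <- length(rois)
  for (m in fc_list) {
    if (!identical(rownames(m), rois))
      stop("connectivity matrices do not share roi_order")
  }
  arr <- array(NA_real_, dim = c(length(fc_list), r, r))
  for (i in seq_along(fc_list)) arr[i, , ] <- unclass(fc_list[[i]])
  list(arr = arr, rois = rois)
}

# Profiles of every subject at ROI k (self entry optionally dropped),
# rows normalized to unit norm. Zero-norm rows either error or are mapped to
# the zero vector, which yields the maximum cosine distance 1.
profile_rows <- function(arr, k, drop_self, zero_norm, who) {
  p <- arr[, k, , drop = FALSE]
  dim(p) <- dim(arr)[c(1L, 3L)]
  if (drop_self) p <- p[, -k, drop = FALSE]
  nrm <- sqrt(rowSums(p * p))
  if (any(nrm == 0)) {
    if (zero_norm == "error")
      stop(sprintf("zero-norm profile at ROI index %d for %s subject(s) %s",
                   k, who, paste(which(nrm == 0), collapse = ", ")))
    nrm[nrm == 0] <- Inf
  }
  p / nrm
}

#' Region-level IDFC of a group against a reference cohort
#'
#' Entry (i, k) is the mean cosine distance between subject i's profile at
#' ROI k and the corresponding profile of every reference subject.
#'
#' @param asd_fc list of nonneg-variant connectivity matrices (evaluated group).
#' @param tc_fc list of nonneg-variant connectivity matrices (reference group).
#' @param drop_self drop the self-correlation entry from each profile
#'   (default TRUE), so the constant diagonal cannot compress distances.
#' @param zero_norm `"error"` (default) to fail on an all-zero profile, or
#'   `"max"` to assign such profiles the maximum distance 1.
#' @return subjects x ROI deviation matrix (`unit_kind = "roi"`).
#' @export
compute_idfc_roi <- function(asd_fc, tc_fc, drop_self = TRUE,
                             zero_norm = c("error", "max")) {
  zero_norm <- match.arg(zero_norm)
  if (length(tc_fc) == 0L) stop("reference (TC) set is empty")
  a <- fc_array(asd_fc)
  t_ <- fc_array(tc_fc)
  if (!identical(a$rois, t_$rois)) stop("groups do not share roi_order")
  r <- length(a$rois)
  out <- matrix(NA_real_, nrow = length(asd_fc), ncol = r,
                dimnames = list(names(asd_fc), a$rois))
  for (k in seq_len(r)) {
    pa <- profile_rows(a$arr, k, drop_self, zero_norm, "evaluated")
    pt <- profile_rows(t_$arr, k, drop_self, zero_norm, "reference")
    out[, k] <- 1 - rowMeans(pa %*% t(pt))
  }
  new_deviation_matrix(out, "roi", "between_group")
}

#' Within-group inter-individual deviation
#'
#' Entry (i, k) is the mean cosine distance at ROI k between subject i and
#' every *other* subject of the same group (i != j).
#'
#' @inheritParams compute_idfc_roi
#' @param fc list of at least two nonneg-variant connectivity matrices.
#' @return subjects x ROI deviation matrix (`reference = "within_group"`).
#' @export
compute_within_group_deviation <- function(fc, drop_self = TRUE,
                                           zero_norm = c("error", "max")) {
  zero_norm <- match.arg(zero_norm)
  if (length(fc) < 2L) stop("within-group deviation needs at least 2 subjects")
  a <- fc_array(fc)
  n <- length(fc); r <- length(a$rois)
  out <- matrix(NA_real_, nrow = n, ncol = r,
                dimnames = list(names(fc), a$rois))
  for (k in seq_len(r)) {
    p <- profile_rows(a$arr, k, drop_self, zero_norm, "group")
    s <- p %*% t(p)
    out[, k] <- 1 - (rowSums(s) - diag(s)) / (n - 1)
  }
  new_deviation_matrix(out, "roi", "within_group")
}

#' Aggregate region-level deviations to network level
#'
#' Each network's value is the unweighted mean of the ROI deviations of its
#' member regions, yielding the subjects x networks matrix used as the
#' clustering feature space.
#'
#' @param v a region-level deviation matrix.
#' @param parcellation a parcellation (see [generate_parcellation()]).
#' @return subjects x networks deviation matrix (`unit_kind = "network"`).
#' @export
aggregate_to_network <- function(v, parcellation) {
  stopifnot(inherits(v, "deviation_matrix"),
            attr(v, "unit_kind") == "roi")
  parcellation <- as_parcellation(parcellation)
  if (!identical(as.character(parcellation$roi_id), colnames(v)))
    stop("parcellation roi ids do not match deviation matrix columns")
  nets <- levels(parcellation$network)
  sizes <- table(parcellation$network)
  if (any(sizes == 0L))
    stop("network(s) with zero ROIs: ",
         paste(nets[sizes == 0L], collapse = ", "))
  out <- sapply(nets, function(g) {
    rowMeans(v[, parcellation$network == g, drop = FALSE])
  })
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(v), nets))
  new_deviation_matrix(out, "network", attr(v, "reference"))
}
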
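#' Synthetic connectome cohorts with planted deviation subtypes
#'
#' Generates two-group cohorts with the statistical structure the IDFC
#' analysis assumes: block-structured network connectivity, two planted ASD
#' subtypes that shift all connections down (hypoconnectivity) or up
#' (hyperconnectivity), demographic covariates, and symptom scores linearly
#' linked to each subject's true (noise-free) network deviations.
#'
#' @name synthetic_data
NULL

#' Network names of the 264-region parcellation
#'
#' Ten functional networks — somatosensory-motor (SMN), cingulo-opercular
#' (CO), auditory (AN), default-mode (DMN), visual (VN), fronto-parietal
#' (FPN), salience (SAN), subcortical (SUB), ventral and dorsal attention
#' (VAN, DAN) — plus the uncertain network (UND) holding unassigned regions.
#' @export
default_network_names <- c("SMN", "CO", "AN", "DMN", "VN", "FPN",
                           "SAN", "SUB", "VAN", "DAN", "UND")

#' ROI counts per network for the default 264-region scheme
#' @export
default_network_sizes <- c(SMN = 35L, CO = 14L, AN = 13L, DMN = 58L,
                           VN = 31L, FPN = 25L, SAN = 18L, SUB = 13L,
                           VAN = 9L, DAN = 11L, UND = 37L)

#' Build a parcellation assigning ROIs to named networks
#'
#' @param n_roi total number of ROIs.
#' @param network_sizes integer vector summing to `n_roi`.
#' @param network_names unique names, one per entry of `network_sizes`.
#' @return data frame (class `parcellation`) with columns `roi_id` and
#'   `network` (factor with levels in the given order); ROI ordering is
#'   stable: consecutive blocks in network order.
#' @export
generate_parcellation <- function(n_roi = 264L,
                                  network_sizes = default_network_sizes,
                                  network_names = names(network_sizes) %||%
                                    default_network_names) {
  network_sizes <- as.integer(network_sizes)
  if (any(network_sizes <= 0L)) stop("network sizes must be positive")
  if (sum(network_sizes) != n_roi)
    stop("network sizes sum to ", sum(network_sizes), ", not n_roi = ", n_roi)
  if (length(network_names) != length(network_sizes))
    stop("need one name per network")
  if (anyDuplicated(network_names)) stop("network names must be unique")
  p <- data.frame(
    roi_id = paste0("roi", seq_len(n_roi)),
    network = factor(rep(network_names, network_sizes),
                     levels = network_names),
    stringsAsFactors = FALSE
  )
  class(p) <- c("parcellation", "data.frame")
  p
}

#' Coerce a data frame to a parcellation
#'
#' @param x object with `roi_id` and `network` columns.
#' @return a `parcellation` data frame.
#' @export
as_parcellation <- function(x) {
  if (inherits(x, "parcellation")) return(x)
  if (!all(c("roi_id", "network") %in% names(x)))
    stop("a parcellation needs roi_id and network columns")
  x <- as.data.frame(x)
  if (!is.factor(x$network)) x$network <- factor(x$network, levels = unique(x$network))
  class(x) <- c("parcellation", "data.frame")
  x
}

#' Project a symmetric matrix to the nearest correlation matrix
#'
#' Alternating-projections (Higham-style) nearest-correlation repair:
#' the result is symmetric, unit-diagonal and positive semidefinite, and is
#' idempotent on valid correlation matrices.
#'
#' @param m symmetric numeric matrix.
#' @param tol convergence tolerance (default 1e-8).
#' @return the projected matrix (plain numeric matrix).
#' @export
nearest_correlation <- function(m, tol = 1e-8) {
  if (!isSymmetric(unclass(m), tol = 1e-10)) stop("input must be symmetric")
  m <- unclass(m)
  # already a valid correlation matrix -> return as is
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (all(abs(diag(m) - 1) < tol) && min(ev) > -tol) return(m)
  out <- as.matrix(Matrix::nearPD(m, corr = TRUE, eig.tol = tol,
                                  conv.tol = tol, maxit = 200L)$mat)
  dimnames(out) <- dimnames(m)
  out
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the study cohort this generator emulates: 105 ASD children
#' split into a hypoconnected subtype (shift below the base connectivity) and
#' a hyperconnected subtype (shift above it), 102 typical controls, 264 ROIs
#' in 11 networks, and ADOS-like symptom subscores available for a subset of
#' ASD subjects. Symptom scores are a planted linear map from each subject's
#' *true* (noise-free) network deviation vector, restricted to the driving
#' subtype, plus noise.
#'
#' @param n_asd_subtype1,n_asd_subtype2,n_tc group sizes.
#' @param n_roi number of ROIs.
#' @param network_sizes,network_names parcellation layout.
#' @param n_timepoints time-series length when `mode = "time_series"`.
#' @param base_within_network_corr,base_between_network_corr block values of
#'   the shared base correlation structure, both in (0, 1).
#' @param subtype1_shift,subtype2_shift additive offsets applied to every
#'   off-diagonal correlation for subjects of each subtype (negative = hypo-,
#'   positive = hyperconnectivity).
#' @param shift_sd subject-level standard deviation of the shift, giving
#'   subjects of one subtype graded deviation magnitudes (needed for a
#'   recoverable brain-behavior link). Length 1 or 2 (per subtype): the
#'   deviation metric responds much more steeply to hypo- than to
#'   hyperconnectivity once negatives are zeroed, so the hypoconnected
#'   subtype gets a tighter spread by default.
#' @param noise_sd sd of the symmetric edgewise jitter added per subject.
#' @param behavior list of per-score specs, each `list(subtype =, weights =)`
#'   with one weight per network (or NULL for a pure-noise score).
#' @param behavior_noise_sd sd of the score noise.
#' @param ados_fraction fraction of ASD subjects with symptom scores.
#' @param site_levels site labels for the categorical site covariate.
#' @param mode `"fc"` (default: connectivity matrices generated directly) or
#'   `"time_series"` (multivariate normal draws whose sample correlation
#'   converges to the target as `n_timepoints` grows).
#' @param seed RNG seed; the cohort is deterministic given the spec.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_asd_subtype1 = 47L, n_asd_subtype2 = 58L,
                        n_tc = 102L, n_roi = 264L,
                        network_sizes = default_network_sizes,
                        network_names = names(network_sizes) %||%
                          default_network_names,
                        n_timepoints = 150L,
                        base_within_network_corr = 0.5,
                        base_between_network_corr = 0.15,
                        subtype1_shift = -0.12, subtype2_shift = 0.12,
                        shift_sd = c(0.005, 0.05), noise_sd = 0.06,
                        behavior = default_behavior(network_names),
                        behavior_noise_sd = 0.5,
                        ados_fraction = 82 / 105,
                        site_levels = paste0("site", 1:6),
                        mode = c("fc", "time_series"),
                        seed = 1L) {
  mode <- match.arg(mode)
  spec <- list(n_asd_subtype1 = as.integer(n_asd_subtype1),
               n_asd_subtype2 = as.integer(n_asd_subtype2),
               n_tc = as.integer(n_tc), n_roi = as.integer(n_roi),
               network_sizes = as.integer(network_sizes),
               network_names = network_names,
               n_timepoints = as.integer(n_timepoints),
               base_within_network_corr = base_within_network_corr,
               base_between_network_corr = base_between_network_corr,
               subtype1_shift = subtype1_shift,
               subtype2_shift = subtype2_shift,
               shift_sd = rep(shift_sd, length.out = 2L),
               noise_sd = noise_sd,
               behavior = behavior, behavior_noise_sd = behavior_noise_sd,
               ados_fraction = ados_fraction, site_levels = site_levels,
               mode = mode, seed = as.integer(seed))
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

#' Default planted brain-behavior links
#'
#' Communication severity is driven by the hypoconnected subtype's network
#' deviations, restricted/repetitive behavior by the hyperconnected
#' subtype's; the social score carries no planted signal. A handful of
#' networks get nonzero weights so weight-recovery is testable.
#' @param network_names network labels the weights attach to.
#' @export
default_behavior <- function(network_names = default_network_names) {
  n <- length(network_names)
  w1 <- stats::setNames(numeric(n), network_names)
  w2 <- w1
  nz1 <- intersect(c("DMN", "FPN", "VN"), network_names)
  nz2 <- intersect(c("SUB", "SMN", "DAN"), network_names)
  if (length(nz1) == 0L) nz1 <- network_names[seq_len(min(2L, n))]
  if (length(nz2) == 0L) nz2 <- network_names[seq_len(min(2L, n))]
  w1[nz1] <- 1
  w2[nz2] <- 1
  list(ados_comm = list(subtype = 1L, weights = w1),
       ados_social = NULL,
       ados_rrb = list(subtype = 2L, weights = w2))
}

validate_cohort_spec <- function(s) {
  counts <- c(s$n_asd_subtype1, s$n_asd_subtype2, s$n_tc, s$n_roi,
              s$n_timepoints)
  if (any(counts <= 0L)) stop("all counts must be positive")
  if (sum(s$network_sizes) != s$n_roi)
    stop("network_sizes must sum to n_roi")
  base <- c(s$base_within_network_corr, s$base_between_network_corr)
  if (any(base <= 0 | base >= 1)) stop("base correlations must lie in (0,1)")
  for (sh in c(s$subtype1_shift, s$subtype2_shift)) {
    lo <- min(base) + sh; hi <- max(base) + sh
    if (lo <= -1 || hi >= 1)
      stop("subtype shift ", sh, " pushes target correlations out of (-1,1)")
  }
  if (any(c(s$noise_sd, s$shift_sd, s$behavior_noise_sd) < 0))
    stop("standard deviations must be nonnegative")
  if (s$ados_fraction < 0 || s$ados_fraction > 1)
    stop("ados_fraction must lie in [0,1]")
  invisible(s)
}

# Stratified draw of a continuous covariate: within each group, uniforms are
# taken one per equal-width stratum (shuffled), then pushed through the
# quantile function, so every group samples the same distribution with
# near-identical empirical moments.
matched_continuous <- function(groups, qfun) {
  u <- numeric(length(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    m <- length(idx)
    u[idx] <- (sample(m) - stats::runif(m)) / m
  }
  qfun(u)
}

# Largest-remainder allocation of category counts within each group, then
# shuffled, so category frequencies are balanced across groups.
matched_categorical <- function(groups, probs) {
  out <- character(length(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    m <- length(idx)
    raw <- probs * m
    cnt <- floor(raw)
    rem <- m - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    out[idx] <- sample(rep(names(probs), cnt))
  }
  out
}

# Base block correlation structure shared by every subject.
base_block_matrix <- function(spec) {
  net <- rep(seq_along(spec$network_sizes), spec$network_sizes)
  b <- matrix(spec$base_between_network_corr, spec$n_roi, spec$n_roi)
  for (g in seq_along(spec$network_sizes))
    b[net == g, net == g] <- spec$base_within_network_corr
  diag(b) <- 1
  b
}

# Noise-free target matrix for one subject: base shifted off-diagonally.
shifted_matrix <- function(base, shift) {
  m <- base + shift
  diag(m) <- 1
  m
}

# True (noise-free) network deviation vector of one subject vs the base
# reference, on the nonnegative-profile path used by the analysis.
true_network_deviation <- function(subject_true, base, net_factor) {
  a <- pmax(subject_true, 0); b <- pmax(base, 0)
  r <- nrow(base)
  v <- vapply(seq_len(r), function(k) {
    cosine_deviation(a[k, -k], b[k, -k])
  }, numeric(1))
  tapply(v, net_factor, mean)
}

#' Generate a synthetic cohort
#'
#' Each subject's connectivity is the base block matrix, plus that subject's
#' subtype shift (drawn around the subtype mean shift), plus symmetric
#' edgewise noise, projected to the nearest valid correlation matrix. In
#' `"time_series"` mode, multivariate normal series with that correlation as
#' covariance are drawn instead, so the sample FC converges to the target as
#' the series lengthens.
#'
#' @param spec a [cohort_spec()].
#' @return list with `fc` (named list of raw connectivity matrices; in
#'   time-series mode also `time_series`), `parcellation`, `phenotype`
#'   (data frame with group, subtype_truth, covariates and symptom scores)
#'   and `truth` (per-subject drawn shifts and true network deviations).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  parc <- generate_parcellation(spec$n_roi, spec$network_sizes,
                                spec$network_names)
  base <- base_block_matrix(spec)
  n1 <- spec$n_asd_subtype1; n2 <- spec$n_asd_subtype2; nt <- spec$n_tc
  n <- n1 + n2 + nt
  group <- c(rep("asd", n1 + n2), rep("tc", nt))
  subtype <- c(rep(1L, n1), rep(2L, n2), rep(NA_integer_, nt))
  ids <- sprintf("sub%03d", seq_len(n))
  mean_shift <- ifelse(is.na(subtype), 0,
                       ifelse(subtype == 1L, spec$subtype1_shift,
                              spec$subtype2_shift))
  sub_sd <- ifelse(is.na(subtype), 0, spec$shift_sd[pmax(subtype, 1L)])
  shift <- mean_shift + stats::rnorm(n, 0, 1) * sub_sd
  lim <- 0.999 - max(spec$base_within_network_corr,
                     spec$base_between_network_corr)
  shift <- pmin(pmax(shift, -spec$base_between_network_corr + 1e-3 - 1),
                lim)

  fc <- vector("list", n); names(fc) <- ids
  ts_list <- if (spec$mode == "time_series") stats::setNames(vector("list", n), ids)
  vtrue <- matrix(NA_real_, n, length(spec$network_names),
                  dimnames = list(ids, spec$network_names))
  for (i in seq_len(n)) {
    target <- shifted_matrix(base, shift[i])
    e <- matrix(stats::rnorm(spec$n_roi^2, 0, spec$noise_sd), spec$n_roi)
    e <- (e + t(e)) / 2; diag(e) <- 0
    m <- pmin(pmax(target + e, -0.999), 0.999)
    diag(m) <- 1
    m <- nearest_correlation(m)
    if (spec$mode == "time_series") {
      x <- MASS::mvrnorm(spec$n_timepoints, mu = rep(0, spec$n_roi), Sigma = m)
      colnames(x) <- parc$roi_id
      ts_list[[i]] <- x
      fc[[i]] <- compute_fc(x)
    } else {
      fc[[i]] <- new_connectivity_matrix(m, parc$roi_id, "raw")
    }
    vtrue[i, ] <- true_network_deviation(target, base, parc$network)
  }

  # Covariates are matched across the planted groups (stratified draws per
  # group), emulating a demographically matched cohort: each group receives
  # a stratified sample of the same covariate distribution, so covariates
  # are balanced across subtypes by construction, as in a matched study.
  strat <- factor(ifelse(is.na(subtype), "tc", paste0("s", subtype)))
  pheno <- data.frame(
    subject_id = ids, group = group, subtype_truth = subtype,
    age = matched_continuous(strat, function(u) 7 + 5 * u),
    fiq = matched_continuous(strat, function(u) stats::qnorm(u, 110, 15)),
    mean_fd = matched_continuous(strat, function(u)
      stats::qlnorm(u, meanlog = log(0.16), sdlog = 0.4)),
    handedness = matched_categorical(strat, c(right = 0.8, left = 0.07,
                                              mixed = 0.13)),
    eye_status = matched_categorical(strat, c(open = 0.87, closed = 0.13)),
    site = matched_categorical(
      strat, stats::setNames(rep(1 / length(spec$site_levels),
                                 length(spec$site_levels)),
                             spec$site_levels)),
    stringsAsFactors = FALSE
  )

  asd_idx <- which(group == "asd")
  has_ados <- rep(FALSE, n)
  n_ados <- round(spec$ados_fraction * length(asd_idx))
  has_ados[sample(asd_idx, n_ados)] <- TRUE
  # Scores are planted on the *standardized* true network deviations of the
  # driving subtype, so the signal-to-noise of the link is controlled by the
  # weights and behavior_noise_sd alone, not by the (asymmetric) scale of
  # the deviation response.
  for (score in names(spec$behavior)) {
    y <- rep(NA_real_, n)
    link <- spec$behavior[[score]]
    base_level <- c(ados_comm = 3, ados_social = 8, ados_rrb = 2)[score]
    if (is.na(base_level)) base_level <- 3
    mu <- rep(base_level, n)
    if (!is.null(link)) {
      memb <- which(!is.na(subtype) & subtype == link$subtype)
      if (length(memb) > 1L) {
        z <- scale(vtrue[memb, , drop = FALSE])
        z[, attr(z, "scaled:scale") == 0] <- 0
        mu[memb] <- base_level + drop(z %*% link$weights)
      }
    }
    noise <- stats::rnorm(n, 0, spec$behavior_noise_sd)
    y[asd_idx] <- (mu + noise)[asd_idx]
    y[!has_ados] <- NA_real_
    pheno[[score]] <- y
  }

  out <- list(fc = fc, parcellation = parc, phenotype = pheno,
              truth = list(shift = stats::setNames(shift, ids),
                           v_net_true = vtrue,
                           behavior = spec$behavior),
              spec = spec)
  if (spec$mode == "time_series") out$time_series <- ts_list
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort to disk as plain-text tables
#'
#' Produces one matrix (or time-series) TSV per subject under `dir/fc/`
#' (`dir/time_series/`), plus `parcellation.tsv` and `phenotype.tsv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fcdir <- file.path(dir, "fc")
  dir.create(fcdir, showWarnings = FALSE)
  for (id in names(cohort$fc)) {
    utils::write.table(
      unclass(cohort$fc[[id]]), file.path(fcdir, paste0(id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$time_series)) {
    tsdir <- file.path(dir, "time_series")
    dir.create(tsdir, showWarnings = FALSE)
    for (id in names(cohort$time_series))
      utils::write.table(cohort$time_series[[id]],
                         file.path(tsdir, paste0(id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(as.data.frame(cohort$parcellation),
                     file.path(dir, "parcellation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$phenotype, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
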
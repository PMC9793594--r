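#' End-to-end IDFC pipeline
#'
#' Orchestrates QC, connectivity construction, deviation, subtyping, group
#' statistics and brain-behavior prediction from a single config, writing
#' every table as TSV plus a JSON run manifest with file checksums.
#'
#' @name pipeline
NULL

read_tsv_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Read a directory of per-subject matrices or time series
#'
#' @param dir directory of `<subject_id>.tsv` files.
#' @param as `"fc"` to wrap each file as a raw connectivity matrix, or
#'   `"time_series"` to return plain matrices.
#' @return named list keyed by subject id.
#' @export
read_subject_dir <- function(dir, as = c("fc", "time_series")) {
  as <- match.arg(as)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .tsv files in ", dir)
  out <- lapply(files, function(f) {
    m <- read_tsv_matrix(f)
    if (as == "fc") new_connectivity_matrix(m, colnames(m), "raw") else m
  })
  stats::setNames(out, sub("\\.tsv$", "", basename(files)))
}

#' Default pipeline configuration
#'
#' Every analysis toggle lives here so sensitivity re-runs (keeping negative
#' correlations, including the profile self-entry, a different frame-flag
#' window) are single-field changes.
#'
#' @return named list of defaults; see the fields themselves.
#' @export
default_config <- function() {
  list(
    keep_negatives = FALSE,     # TRUE reruns the no-zeroing sensitivity path
    profile_self_entry = FALSE, # include the self correlation in profiles
    zero_norm = "error",
    fd_threshold = 0.5, fd_window = 2L, max_flag_frac = 0.5,
    k_min = 2L, k_max = 20L, n_restarts = 100L,
    q = 0.05, alpha = 0.05,
    scores = c("ados_comm", "ados_social", "ados_rrb"),
    n_perm = 1000L, cost = 1, epsilon = 0.1,
    seed = 1L
  )
}

#' Read a pipeline run config from YAML
#'
#' Unknown fields are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file with any subset of [default_config()]'s fields.
#' @return config list merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(default_config())
  extra <- setdiff(names(cfg),
                   c(known, "fc_dir", "time_series_dir", "parcellation",
                     "phenotype", "output_dir"))
  if (length(extra) > 0L)
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  utils::modifyList(default_config(), cfg)
}

#' Validate pipeline inputs for consistency
#'
#' Checks subject-id agreement between connectivity data and phenotype,
#' ROI-count agreement with the parcellation, and missing covariates.
#'
#' @param fc named list of connectivity matrices (or time-series matrices).
#' @param parcellation a parcellation.
#' @param phenotype phenotype data frame with a `subject_id` column.
#' @return data frame of failures (empty when everything is consistent).
#' @export
validate_inputs <- function(fc, parcellation, phenotype) {
  fails <- list()
  add <- function(what, detail)
    fails[[length(fails) + 1L]] <<- data.frame(check = what, detail = detail)
  parcellation <- as_parcellation(parcellation)
  ids_fc <- names(fc)
  ids_ph <- phenotype$subject_id
  for (id in setdiff(ids_fc, ids_ph))
    add("subject_missing_phenotype", id)
  for (id in setdiff(ids_ph, ids_fc))
    add("subject_missing_data", id)
  n_parc <- nrow(parcellation)
  for (id in ids_fc) {
    nc <- ncol(fc[[id]])
    if (nc != n_parc)
      add("roi_count_mismatch",
          sprintf("%s has %d ROIs, parcellation has %d", id, nc, n_parc))
  }
  covs <- intersect(covariate_columns, names(phenotype))
  for (cn in covs) {
    bad <- ids_ph[is.na(phenotype[[cn]])]
    for (id in bad) add("missing_covariate", paste0(id, ":", cn))
  }
  if (length(fails) == 0L)
    return(data.frame(check = character(0), detail = character(0)))
  do.call(rbind, fails)
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, dir, name, rowname_col = "subject_id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), as.data.frame(unclass(m)),
                   check.names = FALSE)
  names(df)[1L] <- rowname_col
  write_stage_tsv(df, dir, name)
}

#' Run the full IDFC analysis
#'
#' Stages: input validation, optional motion QC, FC construction (when time
#' series are supplied), negative zeroing, Fisher z, region- and
#' network-level IDFC, covariate residualization, silhouette scan and
#' k-means subtyping, subtype balance tests, group comparisons at the three
#' scales for the three pairwise comparisons, within-group deviation
#' contrast, and SVR symptom prediction per subtype and score. All tables
#' are written under `output_dir` and listed (with md5 checksums) in
#' `manifest.json`; identical inputs and seed reproduce identical checksums.
#'
#' @param fc named list of raw connectivity matrices, or NULL when
#'   `time_series` is given.
#' @param parcellation a parcellation.
#' @param phenotype phenotype data frame (subject_id, group, covariates,
#'   optional motion traces are handled upstream).
#' @param output_dir directory for outputs.
#' @param config list of toggles; missing fields take [default_config()].
#' @param time_series optional named list of time x ROI matrices.
#' @return the manifest, invisibly (list with `stages`, `files`, `config`).
#' @export
run_pipeline <- function(fc = NULL, parcellation, phenotype, output_dir,
                         config = list(), time_series = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, stages = list())
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      file.create(file.path(output_dir, "failed"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    val
  }
  parcellation <- as_parcellation(parcellation)

  if (is.null(fc)) {
    if (is.null(time_series)) stop("need either fc or time_series")
    fc <- t_stage("compute_fc", lapply(time_series, compute_fc))
  }
  rep_v <- t_stage("validate", validate_inputs(fc, parcellation, phenotype))
  if (nrow(rep_v) > 0L)
    stop("input validation failed:\n",
         paste(rep_v$check, rep_v$detail, collapse = "\n"))
  phenotype <- phenotype[match(names(fc), phenotype$subject_id), ]

  nonneg <- if (cfg$keep_negatives) fc else
    t_stage("zero_negatives", lapply(fc, zero_negatives))
  zmats <- t_stage("fisher_z", lapply(fc, fisher_z))

  asd_ids <- phenotype$subject_id[phenotype$group == "asd"]
  tc_ids <- phenotype$subject_id[phenotype$group == "tc"]
  drop_self <- !cfg$profile_self_entry

  v_roi <- t_stage("idfc_roi",
                   compute_idfc_roi(nonneg[asd_ids], nonneg[tc_ids],
                                    drop_self = drop_self,
                                    zero_norm = cfg$zero_norm))
  v_net <- t_stage("idfc_net", aggregate_to_network(v_roi, parcellation))
  ph_asd <- phenotype[match(asd_ids, phenotype$subject_id), ]
  v_net_resid <- t_stage("residualize", residualize(unclass(v_net), ph_asd))

  scan <- t_stage("silhouette_scan",
                  silhouette_scan(v_net_resid, cfg$k_min:cfg$k_max,
                                  seed = cfg$seed, n_restarts = cfg$n_restarts))
  k_star <- attr(scan, "k_star")
  sol <- t_stage("cluster",
                 cluster_subtypes(v_net_resid, k_star, seed = cfg$seed,
                                  n_restarts = cfg$n_restarts))
  balance <- if (k_star == 2L)
    t_stage("subtype_balance", compare_subtype_profiles(sol$labels, ph_asd))

  groups <- list(tc = tc_ids)
  for (kk in seq_len(k_star))
    groups[[paste0("subtype", kk)]] <- asd_ids[sol$labels == kk]
  cov_of <- function(ids) phenotype[match(ids, phenotype$subject_id), ]

  cmp_pairs <- list()
  for (kk in seq_len(k_star))
    cmp_pairs[[length(cmp_pairs) + 1L]] <- c(paste0("subtype", kk), "tc")
  if (k_star == 2L)
    cmp_pairs[[length(cmp_pairs) + 1L]] <- c("subtype2", "subtype1")

  region_stats <- list(); network_stats <- list(); sig_frac <- list()
  blocks <- t_stage("network_blocks",
                    network_block_average(zmats, parcellation))
  for (cmp in cmp_pairs) {
    ida <- groups[[cmp[1L]]]; idb <- groups[[cmp[2L]]]
    cov <- rbind(cov_of(ida), cov_of(idb))
    key <- paste0(cmp[1L], "_vs_", cmp[2L])
    region_stats[[key]] <- t_stage(paste0("region_", key),
      edgewise_test(zmats[ida], zmats[idb], cov, q = cfg$q, comparison = cmp))
    network_stats[[key]] <- t_stage(paste0("network_", key),
      network_test(blocks[ida, , drop = FALSE], blocks[idb, , drop = FALSE],
                   cov, q = cfg$q, comparison = cmp))
    sig_frac[[key]] <- significant_edge_fraction(region_stats[[key]],
                                                 parcellation)
  }
  z_groups <- lapply(groups[c(setdiff(names(groups), "tc"), "tc")],
                     function(ids) zmats[ids])
  wb <- t_stage("wholebrain",
                wholebrain_test(z_groups, lapply(cmp_pairs, identity),
                                covariate_table = phenotype,
                                alpha = cfg$alpha))

  v_aa <- t_stage("within_asd",
                  compute_within_group_deviation(nonneg[asd_ids],
                                                 drop_self = drop_self,
                                                 zero_norm = cfg$zero_norm))
  v_tt <- t_stage("within_tc",
                  compute_within_group_deviation(nonneg[tc_ids],
                                                 drop_self = drop_self,
                                                 zero_norm = cfg$zero_norm))
  wg <- t_stage("within_group_test",
                within_group_deviation_test(
                  unclass(v_aa), unclass(v_tt),
                  rbind(cov_of(asd_ids), cov_of(tc_ids)),
                  parcellation, q = cfg$q))

  predictions <- list()
  scores <- intersect(cfg$scores, names(phenotype))
  for (kk in seq_len(k_star)) {
    ids <- groups[[paste0("subtype", kk)]]
    for (sc in scores) {
      y <- phenotype[[sc]][match(ids, phenotype$subject_id)]
      keep <- !is.na(y)
      if (sum(keep) < 5L || stats::sd(y[keep]) == 0) next
      xr <- v_net_resid[match(ids, asd_ids), , drop = FALSE][keep, , drop = FALSE]
      key <- paste0("subtype", kk, "_", sc)
      predictions[[key]] <- t_stage(paste0("predict_", key),
        permutation_test(xr, y[keep], cost = cfg$cost, epsilon = cfg$epsilon,
                         n_perm = cfg$n_perm, seed = cfg$seed))
    }
  }

  # ---- write everything -------------------------------------------------
  files <- c(
    write_matrix_tsv(v_roi, output_dir, "v_roi.tsv"),
    write_matrix_tsv(v_net, output_dir, "v_net.tsv"),
    write_matrix_tsv(v_net_resid, output_dir, "v_net_resid.tsv"),
    write_matrix_tsv(v_aa, output_dir, "v_within_asd.tsv"),
    write_matrix_tsv(v_tt, output_dir, "v_within_tc.tsv"),
    write_stage_tsv(scan, output_dir, "silhouette_curve.tsv"),
    write_stage_tsv(data.frame(subject_id = names(sol$labels),
                               label = sol$labels),
                    output_dir, "subtypes.tsv"),
    write_stage_tsv(wb, output_dir, "wholebrain_stats.tsv"),
    write_stage_tsv(wg, output_dir, "within_group_roi_stats.tsv"))
  if (!is.null(balance))
    files <- c(files, write_stage_tsv(balance$tests, output_dir,
                                      "subtype_balance.tsv"))
  for (key in names(region_stats)) {
    files <- c(files,
      write_stage_tsv(region_stats[[key]], output_dir,
                      paste0("region_stats_", key, ".tsv")),
      write_stage_tsv(network_stats[[key]], output_dir,
                      paste0("network_stats_", key, ".tsv")),
      write_stage_tsv(sig_frac[[key]], output_dir,
                      paste0("block_sig_fraction_", key, ".tsv")))
  }
  for (key in names(predictions)) {
    pr <- predictions[[key]]
    files <- c(files,
      write_stage_tsv(data.frame(observed = pr$observed,
                                 predicted = pr$predicted),
                      output_dir, paste0("prediction_", key, ".tsv")),
      write_stage_tsv(data.frame(network = names(pr$weights),
                                 weight = pr$weights),
                      output_dir, paste0("weights_", key, ".tsv")))
  }

  manifest$k_star <- k_star
  manifest$silhouette_max <- max(scan$silhouette)
  manifest$subtype_sizes <- as.integer(table(sol$labels))
  manifest$predictions <- lapply(predictions, function(pr)
    list(r = pr$r, p_perm = pr$p_perm, n_perm = pr$n_perm))
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest,
              list(v_net_resid = v_net_resid, subtypes = sol,
                   silhouette_curve = scan,
                   region_stats = region_stats, network_stats = network_stats,
                   wholebrain = wb, within_group = wg,
                   prediction_results = predictions)))
}
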
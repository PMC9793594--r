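test_that("parcellation layout is validated and block boundaries are stable", {
  p <- generate_parcellation(264)
  expect_equal(nrow(p), 264)
  expect_equal(nlevels(p$network), 11)
  expect_equal(as.vector(table(p$network)), unname(default_network_sizes))
  p1 <- generate_parcellation(4, c(4), "A")
  expect_true(all(p1$network == "A"))
  p2 <- generate_parcellation(6, c(2, 2, 2), c("A", "B", "C"))
  expect_equal(which(p2$network == "B"), 3:4)
  expect_equal(which(p2$network == "C"), 5:6)
  expect_error(generate_parcellation(5, c(2, 2), c("A", "B")), "sum")
  expect_error(generate_parcellation(4, c(2, 2), c("A", "A")), "unique")
})

test_that("nearest correlation projection returns a valid, idempotent result", {
  expect_equal(nearest_correlation(diag(3)), diag(3))
  cm <- unclass(random_fc_set(1, 6, seed = 61, nonneg = FALSE)[[1]])
  expect_equal(nearest_correlation(cm), cm, tolerance = 1e-7,
               ignore_attr = TRUE)
  m <- diag(3); m[1, 2] <- m[2, 1] <- 1.2; m[1, 3] <- m[3, 1] <- 0.3
  out <- nearest_correlation(m)
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-7)
  expect_equal(diag(out), rep(1, 3), tolerance = 1e-7)
  expect_lt(out[1, 2], 1.2)
  expect_error(nearest_correlation(matrix(1:4, 2)), "symmetric")
})

test_that("cohort generation is deterministic and respects planted structure", {
  co1 <- generate_cohort(tiny_spec(seed = 7))
  co2 <- generate_cohort(tiny_spec(seed = 7))
  expect_identical(co1$fc, co2$fc)
  expect_identical(co1$phenotype, co2$phenotype)
  co3 <- generate_cohort(tiny_spec(seed = 8))
  expect_false(identical(co1$fc[[1]], co3$fc[[1]]))
  ph <- co1$phenotype
  # planted subtype labels only for ASD subjects
  expect_true(all(is.na(ph$subtype_truth[ph$group == "tc"])))
  expect_true(all(!is.na(ph$subtype_truth[ph$group == "asd"])))
  # ADOS present for the configured fraction of ASD subjects, absent for TC
  expect_true(all(is.na(ph$ados_comm[ph$group == "tc"])))
  n_asd <- sum(ph$group == "asd")
  expect_equal(sum(!is.na(ph$ados_comm[ph$group == "asd"])),
               round(82 / 105 * n_asd))
  # every matrix is a valid correlation matrix
  for (m in co1$fc[1:3]) {
    expect_equal(diag(unclass(m)), setNames(rep(1, 40), rownames(m)))
    ev <- eigen(unclass(m), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-6)
    expect_true(all(abs(m) <= 1 + 1e-12))
  }
})

test_that("group-mean connectivity orders subtype1 < TC < subtype2 per block", {
  co <- generate_cohort(tiny_spec(seed = 9))
  ph <- co$phenotype
  parc <- co$parcellation
  nets <- levels(parc$network)
  mean_blocks <- function(ids) {
    avg <- Reduce(`+`, lapply(co$fc[ids], unclass)) / length(ids)
    out <- c()
    for (i in seq_along(nets)) for (j in i:length(nets)) {
      sub <- avg[parc$network == nets[i], parc$network == nets[j], drop = FALSE]
      v <- if (i == j) mean(sub[upper.tri(sub)]) else mean(sub)
      out <- c(out, v)
    }
    out
  }
  b1 <- mean_blocks(ph$subject_id[!is.na(ph$subtype_truth) & ph$subtype_truth == 1])
  b2 <- mean_blocks(ph$subject_id[!is.na(ph$subtype_truth) & ph$subtype_truth == 2])
  bt <- mean_blocks(ph$subject_id[ph$group == "tc"])
  expect_true(all(b1 < bt))
  expect_true(all(bt < b2))
})

test_that("degenerate settings collapse to a shared matrix", {
  spec <- tiny_spec(seed = 3, noise_sd = 0, shift_sd = 0,
                    subtype1_shift = 0, subtype2_shift = 0)
  co <- generate_cohort(spec)
  for (m in co$fc[-1]) expect_equal(unclass(m), unclass(co$fc[[1]]),
                                    tolerance = 1e-12)
})

test_that("invalid cohort specs are rejected", {
  expect_error(tiny_spec(subtype2_shift = 0.6), "out of")
  expect_error(cohort_spec(n_roi = 10, network_sizes = c(5, 4),
                           network_names = c("A", "B")), "sum")
  expect_error(tiny_spec(noise_sd = -1), "nonnegative")
})

test_that("time-series mode converges to the target connectivity", {
  sp200 <- tiny_spec(seed = 13, mode = "time_series", n_timepoints = 200,
                     noise_sd = 0, shift_sd = 0)
  sp2000 <- tiny_spec(seed = 13, mode = "time_series", n_timepoints = 2000,
                      noise_sd = 0, shift_sd = 0)
  target <- idfc:::base_block_matrix(tiny_spec())
  err <- function(co, ids) mean(abs(unclass(co$fc[[ids]]) -
    idfc:::shifted_matrix(target, co$truth$shift[[ids]])))
  co200 <- generate_cohort(sp200)
  co2000 <- generate_cohort(sp2000)
  tc_id <- co200$phenotype$subject_id[co200$phenotype$group == "tc"][1]
  expect_lt(err(co2000, tc_id), err(co200, tc_id))
  expect_equal(dim(co200$time_series[[1]]), c(200, 40))
})

test_that("cohorts round-trip through the plain-text writer", {
  co <- generate_cohort(tiny_spec(seed = 17))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  fc <- read_subject_dir(file.path(dir, "fc"))
  expect_equal(names(fc), names(co$fc))
  expect_equal(unclass(fc[[3]]), unclass(co$fc[[3]]), tolerance = 1e-10,
               ignore_attr = TRUE)
  parc <- as_parcellation(read.delim(file.path(dir, "parcellation.tsv")))
  expect_equal(as.character(parc$network), as.character(co$parcellation$network))
})
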
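test_that("blank presence call uses a strict fold threshold", {
  tab <- tiny_table(rbind(c(301, 301, 100, 100),
                          c(300, 300, 100, 100),
                          c(1, 1, 0, 0)),
                    roles = c("sample", "sample", "blank", "blank"))
  pr <- call_present(tab, blank_fold = 3)
  expect_identical(unname(pr), c(TRUE, FALSE, TRUE))

  no_blank <- tiny_table(matrix(1, 1, 2), roles = c("sample", "sample"))
  expect_error(call_present(no_blank), "blank")
})

test_that("presence is monotone in non-blank intensities", {
  set.seed(2)
  for (i in 1:20) {
    x <- matrix(runif(8, 0, 200), 2, 4)
    tab <- tiny_table(x, roles = c("sample", "sample", "blank", "blank"))
    before <- call_present(tab)
    x2 <- x
    x2[1, 1] <- x2[1, 1] + runif(1, 0, 500)
    after <- call_present(tiny_table(x2, roles = c("sample", "sample", "blank", "blank")))
    expect_false(before[[1]] && !after[[1]])
  }
})

test_that("CV filter removes features with high median replicate CV", {
  x <- rbind(c(100, 100, 100), c(10, 200, 300))
  tab <- tiny_table(x, roles = rep("sample", 3), groups = rep("g1", 3))
  kept <- filter_features_by_cv(tab, cv_max = 0.5)
  expect_identical(kept$features$feature_id, "f1")
  expect_gt(sd(c(10, 200, 300)) / mean(c(10, 200, 300)), 0.5)  # 0.8665

  expect_equal(nrow(filter_features_by_cv(tab, cv_max = Inf)$features), 2)

  singles <- tiny_table(x[, 1:2], roles = rep("sample", 2),
                        groups = c("g1", "g2"))
  expect_error(filter_features_by_cv(singles), "CV undefined")
})

test_that("outlier samples are removed by relative total-signal deviation", {
  x <- matrix(c(1000, 1000, 2000), 1)
  tab <- tiny_table(x, roles = rep("sample", 3))
  expect_identical(filter_outlier_samples(tab)$samples$sample_id, c("s1", "s2"))

  x2 <- matrix(c(1000, 1000, 1400), 1)
  expect_equal(ncol(filter_outlier_samples(tiny_table(x2, roles = rep("sample", 3)))$intensity), 3)
  x3 <- matrix(rep(500, 3), 1)
  expect_equal(ncol(filter_outlier_samples(tiny_table(x3, roles = rep("sample", 3)))$intensity), 3)
  zero <- tiny_table(matrix(0, 1, 3), roles = rep("sample", 3))
  expect_error(filter_outlier_samples(zero), "zero")
})

test_that("pseudocount log transform matches hand arithmetic and keeps order", {
  tab <- tiny_table(rbind(c(0, 400, 900)), roles = rep("sample", 3))
  lt <- log_transform(tab)          # pc = 0.25 * 400 = 100
  expect_equal(unname(lt$intensity[1, ]), log10(c(100, 500, 1000)))
  expect_equal(unname(lt$intensity[1, 3]), 3)

  plain <- log_transform(tab, pseudocount_frac = 0)
  expect_equal(unname(plain$intensity[1, 2:3]), log10(c(400, 900)))

  allzero <- tiny_table(rbind(c(1, 2, 3), c(0, 0, 0)), roles = rep("sample", 3))
  expect_error(log_transform(allzero), "f2")

  set.seed(3)
  x <- matrix(runif(30, 0, 100), 3, 10)
  ord_raw <- apply(x, 1, order)
  lt2 <- log_transform(tiny_table(x, roles = rep("sample", 10)))
  expect_equal(apply(lt2$intensity, 1, order), ord_raw, ignore_attr = TRUE)
})

test_that("cross-mode dereplication applies mass, RT and correlation criteria", {
  samples <- data.frame(sample_id = sprintf("s%d", 1:5), role = "sample")
  mk <- function(mz, rt, mode, adduct, msi, x) {
    feature_table(matrix(x, 1), data.frame(feature_id = paste0(mode, "1"),
                                           mz = mz, rt = rt, mode = mode,
                                           adduct = adduct, msi_level = msi),
                  samples)
  }
  x <- c(10, 20, 30, 40, 50)
  pos <- mk(181.0713, 5.00, "positive", "[M+H]+", NA, x)
  neg <- mk(179.0556, 5.05, "negative", "[M-H]-", NA, x * 2)  # r = 1
  out <- dereplicate_modes(pos, neg)
  expect_equal(nrow(out$merge_map), 1)
  expect_equal(out$merge_map$kept, "positive1")  # equal (absent) MSI -> positive kept
  expect_equal(nrow(out$table$features), 1)

  neg_uncorr <- mk(179.0556, 5.05, "negative", "[M-H]-", NA, c(50, 10, 40, 20, 30))
  expect_lt(cor(x, c(50, 10, 40, 20, 30)), 0.7)
  out2 <- dereplicate_modes(pos, neg_uncorr)
  expect_equal(nrow(out2$merge_map), 0)

  neg_msi1 <- mk(179.0556, 5.05, "negative", "[M-H]-", 1L, x * 2)
  out3 <- dereplicate_modes(mk(181.0713, 5, "positive", "[M+H]+", 3L, x), neg_msi1)
  expect_equal(out3$merge_map$kept, "negative1")  # lower MSI wins
})

test_that("dereplication never merges a pair failing any single criterion", {
  set.seed(8)
  for (rep in 1:10) {
    pair <- gen_cross_mode_pair(n_pos = 15, n_neg = 12, n_duplicates = 4,
                                seed = rep)
    out <- dereplicate_modes(pair$pos, pair$neg)
    # exhaustive oracle over all pos x neg pairs
    proton <- 1.00728
    for (k in seq_len(nrow(out$merge_map))) {
      d <- out$merge_map[k, ]
      ids <- c(d$dropped, d$kept)
      pi <- match(intersect(ids, pair$pos$features$feature_id), pair$pos$features$feature_id)
      ni <- match(intersect(ids, pair$neg$features$feature_id), pair$neg$features$feature_id)
      m_p <- pair$pos$features$mz[pi] - proton
      m_n <- pair$neg$features$mz[ni] + proton
      expect_lt(abs(m_p - m_n), 0.02)
      expect_lt(abs(pair$pos$features$rt[pi] - pair$neg$features$rt[ni]), 0.1)
      r <- cor(pair$pos$intensity[pi, ], pair$neg$intensity[ni, ])
      expect_gte(r, 0.7)
    }
  }
})

test_that("Welch differential abundance handles degenerate and planted cases", {
  x <- rbind(c(5, 5, 5, 5, 5, 5), c(8, 8, 8, 2, 2, 2))
  tab <- tiny_table(10^x, roles = rep("sample", 6),
                    groups = rep(c("a", "b"), each = 3))
  res <- differential_abundance(log_transform(tab), "a", "b")
  expect_equal(res$t_stat[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$call[1], "unchanged")
  expect_true(res$degenerate[1])
  pc <- 0.25 * 100  # min nonzero intensity of feature 2
  expect_equal(res$log2fc[2], log2(1e8 + pc) - log2(1e2 + pc), tolerance = 1e-9)

  g <- gen_feature_experiment(n_features = 200, n_produced = 20,
                              n_depleted = 0, effect_log2 = 3, seed = 5)
  r <- differential_abundance(log_transform(g$table), "culture", "control")
  planted <- r$feature_id %in% g$truth$produced
  expect_gte(mean(r$call[planted] == "increased"), 0.95)
  # BH column matches an independent brute-force step-up
  expect_equal(r$p_adj, bh_bruteforce(r$p), tolerance = 1e-12)
  expect_true(all(r$p_adj >= r$p - 1e-15))
})

test_that("BH adjustment used by the pipeline matches step-up on short vectors", {
  set.seed(9)
  for (rep in 1:20) {
    m <- sample(3:20, 1)
    x <- matrix(10^rnorm(m * 6, 4, 0.5), m, 6)
    tab <- tiny_table(x, roles = rep("sample", 6),
                      groups = rep(c("a", "b"), each = 3))
    r <- differential_abundance(log_transform(tab), "a", "b")
    expect_equal(r$p_adj, bh_bruteforce(r$p), tolerance = 1e-12)
  }
})

test_that("trajectory statistic is the mean absolute gap between group curves", {
  times <- seq(0, 24, by = 4)
  samp <- expand.grid(time_h = times, replicate = 1:2, group = c("a", "b"))
  samp$sample_id <- sprintf("%s_r%d_t%d", samp$group, samp$replicate,
                            match(samp$time_h, times))
  samp$role <- "sample"
  flat <- matrix(5, 1, nrow(samp))
  tab <- feature_table(flat, data.frame(feature_id = "f1"), samp)
  res <- trajectory_difference(tab, "a", "b", n_perm = 50, seed = 1)
  expect_equal(res$stat, 0)
  expect_equal(res$p_perm, 1)

  offset <- ifelse(samp$group == "a", 7, 4)   # constant gap of 3
  tab2 <- feature_table(matrix(offset, 1), data.frame(feature_id = "f1"), samp)
  res2 <- trajectory_difference(tab2, "a", "b", n_perm = 50, seed = 1)
  expect_equal(res2$stat, 3, tolerance = 1e-9)

  expect_error(trajectory_difference(tab, "a", "b", df = 12, n_perm = 10, seed = 1),
               "lower df")
  expect_error(trajectory_difference(tab, "a", "b", n_perm = 0, seed = 1),
               "n_perm")
})

test_that("planted divergent trajectories are detected by the permutation test", {
  g <- gen_feature_experiment(n_features = 30, n_produced = 5, n_depleted = 0,
                              times = seq(0, 48, by = 6),
                              n_samples_per_group = 4, seed = 3)
  tr <- trajectory_difference(g$table, "culture", "control", n_perm = 300,
                              seed = 5)
  planted <- tr$feature_id %in% g$truth$produced
  expect_gte(mean(tr$p_adj[planted] < 0.25), 0.9)
})

test_that("strain variability labels follow the near-all rule", {
  ids <- c("fA", "fB", "fC")
  mk <- function(calls) data.frame(feature_id = ids, call = calls,
                                   stringsAsFactors = FALSE)
  res <- c(replicate(15, mk(c("increased", "increased", "unchanged")), simplify = FALSE),
           replicate(15, mk(c("unchanged", "increased", "unchanged")), simplify = FALSE))
  lab <- classify_strain_variability(res, near_all = 29)
  expect_identical(lab$label, c("variable", "conserved", "absent"))
  expect_identical(lab$n_changed, c(15, 30, 0))

  bad <- res
  bad[[1]] <- data.frame(feature_id = c("fA", "fB"), call = "unchanged")
  expect_error(classify_strain_variability(bad, near_all = 29), "inconsistent")
})
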
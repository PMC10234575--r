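test_that("pattern enumeration deduplicates and drops constant families", {
  pres <- rbind(GF1 = c(1, 1, 0, 0), GF2 = c(1, 1, 0, 0), GF3 = c(0, 1, 0, 1),
                GF4 = c(1, 0, 1, 0), GF5 = c(0, 0, 1, 1)) == 1
  colnames(pres) <- sprintf("st%d", 1:4)
  pat <- enumerate_patterns(pres)
  expect_equal(nrow(pat), 4)                       # GF1/GF2 share a pattern
  expect_setequal(pat$gene_families[[match("1100", pat$pattern)]],
                  c("GF1", "GF2"))

  core <- matrix(TRUE, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(nrow(enumerate_patterns(core)), 0)

  set.seed(3)
  big <- matrix(runif(30 * 6) < 0.5, 30, 6,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  np <- nrow(enumerate_patterns(big))
  expect_lte(np, min(30, 2^6 - 2))
  expect_error(enumerate_patterns(pres[, 1, drop = FALSE]), "2 strains")
})

test_that("association tests flag planted shifts and ignore flat features", {
  panel <- gen_strain_panel(n_strains = 30, n_gene_families = 30,
                            n_linked_features = 5, n_null_features = 40,
                            seed = 21)
  pat <- enumerate_patterns(panel$presence)
  res <- test_associations(pat, panel$table)
  planted <- merge(res, panel$truth, by = "feature_id")
  planted <- planted[pat$pattern[match(planted$pattern_id, pat$pattern_id)] ==
                       planted$pattern, ]
  expect_true(all(planted$p_adj < 1e-4))
  expect_equal(res$p_adj, bh_bruteforce(res$p), tolerance = 1e-12)

  # identical values on both sides of every pattern -> p = 1
  flat <- panel$table
  flat$intensity[] <- 100
  res_flat <- test_associations(pat, flat)
  expect_true(all(res_flat$p == 1))
})

test_that("separability criteria follow the published rules", {
  # 10 with-gene strains around 2.0, 10 without around 1.2, controls at 1.0
  mk_panel <- function(v_with, v_without, ctrl) {
    strains <- sprintf("s%02d", seq_len(length(v_with) + length(v_without)))
    samples <- data.frame(
      sample_id = c(strains, sprintf("ctl%d", seq_along(ctrl))),
      role = c(rep("sample", length(strains)), rep("control", length(ctrl))),
      group = "x", replicate = 1L,
      strain = c(strains, rep(NA, length(ctrl))))
    vals <- c(v_with, v_without, ctrl)
    tab <- feature_table(matrix(10^vals, 1), data.frame(feature_id = "f1"),
                         samples)
    pres <- matrix(rep(c(TRUE, FALSE), c(length(v_with), length(v_without))),
                   1, length(strains), dimnames = list("GF1", strains))
    pat <- enumerate_patterns(pres)
    res <- test_associations(pat, tab, alpha_adj = 1)
    list(tab = tab, pat = pat, res = res)
  }
  v_w <- seq(1.6, 2.4, length.out = 10)   # median 2.0, q10 1.672
  v_wo <- seq(0.9, 1.5, length.out = 10)  # median 1.2, q90 1.446 < 1.0+0.4+...
  ctl <- rep(1.0, 3)
  ok <- mk_panel(v_w, v_wo, ctl)
  kept <- separability_filter(ok$res, ok$tab, ok$pat)
  expect_equal(nrow(kept), 1)
  expect_gte(kept$delta_median, 0.4)

  # (c) fails: without-gene q90 above the control bar
  bad_c <- mk_panel(v_w, v_wo + 0.5, ctl)
  expect_equal(nrow(separability_filter(bad_c$res, bad_c$tab, bad_c$pat)), 0)

  # (a) fails: median shift below 0.4
  bad_a <- mk_panel(v_wo + 0.3, v_wo, ctl - 0.8)
  expect_equal(nrow(separability_filter(bad_a$res, bad_a$tab, bad_a$pat)), 0)

  no_ctrl <- mk_panel(v_w, v_wo, ctl)
  tab2 <- ft_subset(no_ctrl$tab, samples = which(no_ctrl$tab$samples$role != "control"))
  expect_error(separability_filter(no_ctrl$res, tab2, no_ctrl$pat), "control")
})

test_that("separability is invariant to uniform shifts and strain relabeling", {
  panel <- gen_strain_panel(n_strains = 20, n_gene_families = 20,
                            n_linked_features = 4, n_null_features = 20,
                            seed = 8)
  pat <- enumerate_patterns(panel$presence)
  res <- test_associations(pat, panel$table)
  base <- separability_filter(res[res$significant, ], panel$table, pat)

  shifted <- panel$table
  shifted$intensity <- shifted$intensity * 10   # +1 uniform shift in log10
  res_s <- test_associations(pat, shifted)
  shift <- separability_filter(res_s[res_s$significant, ], shifted, pat)
  expect_identical(base[, c("feature_id", "pattern_id")],
                   shift[, c("feature_id", "pattern_id")])

  perm <- sample(ncol(panel$presence))
  pat_p <- enumerate_patterns(panel$presence[, perm])
  res_p <- test_associations(pat_p, panel$table)
  kept_p <- separability_filter(res_p[res_p$significant, ], panel$table, pat_p)
  expect_setequal(kept_p$feature_id, base$feature_id)
})

test_that("planted gene-metabolite links are recovered exactly", {
  panel <- gen_strain_panel(seed = 4)
  pat <- enumerate_patterns(panel$presence)
  res <- test_associations(pat, panel$table)
  final <- separability_filter(res[res$significant, ], panel$table, pat)
  expect_setequal(final$feature_id, panel$truth$feature_id)
  hit <- merge(final, panel$truth, by = "feature_id")
  expect_identical(pat$pattern[match(hit$pattern_id, pat$pattern_id)],
                   hit$pattern)
  expect_lte(max(table(final$feature_id)), 1)
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  ann <- list(T1 = sprintf("g%02d", 1:5), T2 = sprintf("g%02d", 3:20),
              T3 = sprintf("g%02d", 21:40))
  out <- pathway_enrichment(sprintf("g%02d", 1:5), ann)
  N <- 40; K <- 5
  expect_equal(out$p[out$term == "T1"],
               phyper(5 - 1, 5, N - 5, K, lower.tail = FALSE))
  expect_equal(out$term[1], "T1")
  expect_true(out$enriched[out$term == "T1"])

  empty <- pathway_enrichment(character(0), ann)
  expect_equal(nrow(empty), 0)
  outside <- pathway_enrichment("not_a_gene", ann)
  expect_equal(nrow(outside), 0)
})

test_that("gene presence matrices round-trip through TSV", {
  pres <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3,
                 dimnames = list(c("GF1", "GF2"), c("s1", "s2", "s3")))
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_family_id = rownames(pres), pres,
                         check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_gene_presence(f)
  expect_identical(back, pres == 1)
})
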
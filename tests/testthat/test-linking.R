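sp <- function(mz, int, id = "x") list(feature_id = id, mz = mz, intensity = int)

test_that("spectral cosine matches hand-computed values and is symmetric", {
  a <- sp(c(100, 200, 300), c(1, 2, 3))
  expect_equal(spectral_cosine(a, a), 1)

  b <- sp(c(150.5, 250.5), c(1, 1))
  expect_equal(spectral_cosine(a, b), 0)

  c1 <- sp(c(100, 200), c(1, 1))
  c2 <- sp(100, 1)
  expect_equal(spectral_cosine(c1, c2), 1 / sqrt(2), tolerance = 1e-12)

  set.seed(6)
  for (i in 1:20) {
    s1 <- sp(sort(runif(6, 50, 500)), runif(6, 1, 10))
    s2 <- sp(sort(runif(8, 50, 500)), runif(8, 1, 10))
    expect_equal(spectral_cosine(s1, s2), spectral_cosine(s2, s1))
  }
  expect_error(spectral_cosine(sp(numeric(0), numeric(0)), a), "non-empty")
})

test_that("cosine cutoff calibration equals a brute-force null percentile", {
  set.seed(20)
  n <- 80
  feats <- data.frame(feature_id = sprintf("f%03d", 1:n),
                      mz = runif(n, 100, 900), rt = runif(n, 0, 14),
                      mode = "positive", adduct = "[M+H]+")
  samples <- data.frame(sample_id = c("s1", "s2", "s3"), role = "sample")
  tab <- feature_table(matrix(1, n, 3), feats, samples)
  spectra <- elentomics:::.gen_spectra(feats$feature_id, seed = 21)
  cut <- calibrate_cosine_cutoff(tab, spectra, n_per_set = 30, seed = 33,
                                 min_pairs = 100)

  # brute-force replication of the identical sampled pair set
  set.seed(33)
  pick <- sample(n, 60)
  set1 <- feats[pick[1:30], ]; set2 <- feats[pick[31:60], ]
  drt <- abs(outer(set1$rt, set2$rt, "-"))
  dmz <- abs(outer(set1$mz, set2$mz, "-"))
  el <- which(drt >= 1 & dmz >= 0.01, arr.ind = TRUE)
  cos_null <- vapply(seq_len(nrow(el)), function(k) {
    spectral_cosine(spectra[[set1$feature_id[el[k, 1]]]],
                    spectra[[set2$feature_id[el[k, 2]]]])
  }, numeric(1))
  expect_equal(unname(cut["positive"]),
               unname(quantile(cos_null, 0.995, type = 7)))

  # disjoint fragment sets: every null cosine 0 -> cutoff 0
  spectra0 <- lapply(seq_len(n), function(i) {
    sp(1000 + i * 10 + c(0, 1, 2), c(1, 1, 1), feats$feature_id[i])
  })
  names(spectra0) <- feats$feature_id
  cut0 <- calibrate_cosine_cutoff(tab, spectra0, n_per_set = 30, seed = 33,
                                  min_pairs = 100)
  expect_equal(unname(cut0["positive"]), 0)

  expect_error(calibrate_cosine_cutoff(tab, spectra, n_per_set = 30, seed = 33,
                                       min_pairs = 1e6), "eligible")
})

test_that("published cutoffs carry the reported per-mode values", {
  expect_equal(unname(published_cosine_cutoffs["positive"]), 0.205)
  expect_equal(unname(published_cosine_cutoffs["negative"]), 0.251)
})

test_that("feature linking applies thresholds, adduct identity and MS2 rules", {
  samples <- data.frame(sample_id = c("s1", "s2", "s3"), role = "sample")
  mk_tab <- function(ids, mz, rt, adduct = "[M+H]+") {
    feature_table(matrix(1, length(ids), 3),
                  data.frame(feature_id = ids, mz = mz, rt = rt,
                             mode = "positive", adduct = adduct), samples)
  }
  spc <- sp(c(100, 150, 200), c(5, 3, 1))
  spectra <- list(a1 = sp(spc$mz, spc$int, "a1"), b1 = sp(spc$mz, spc$int, "b1"))

  ta <- mk_tab("a1", 300.000, 5.0)
  tb <- mk_tab("b1", 300.005, 5.3)
  links <- link_features(ta, tb, spectra)
  expect_equal(nrow(links), 1)
  expect_equal(links$cosine, 1)

  tb_na <- mk_tab("b1", 300.005, 5.3, adduct = "[M+Na]+")
  expect_equal(nrow(link_features(ta, tb_na, spectra)), 0)

  # no MS2: tighter tolerances apply
  expect_equal(nrow(link_features(mk_tab("a2", 300.0000, 5.0),
                                  mk_tab("b2", 300.0005, 5.1), list())), 1)
  expect_equal(nrow(link_features(mk_tab("a2", 300.000, 5.0),
                                  mk_tab("b2", 300.005, 5.1), list())), 0)
})

test_that("linking is symmetric, one-to-one, and monotone in tolerances", {
  ld <- gen_linked_datasets(n_shared = 20, n_decoy_a = 25, n_decoy_b = 25,
                            jitter_mz = 0.003, jitter_rt = 0.2, seed = 14)
  l_ab <- link_features(ld$table_a, ld$table_b, ld$spectra)
  l_ba <- link_features(ld$table_b, ld$table_a, ld$spectra)
  expect_setequal(paste(l_ab$feature_a, l_ab$feature_b),
                  paste(l_ba$feature_b, l_ba$feature_a))
  expect_lte(max(table(l_ab$feature_a)), 1)
  expect_lte(max(table(l_ab$feature_b)), 1)

  wider <- link_features(ld$table_a, ld$table_b, ld$spectra,
                         mz_tol = 0.02, rt_tol = 1, noms2_mz_tol = 0.005,
                         noms2_rt_tol = 0.5)
  expect_true(all(paste(l_ab$feature_a, l_ab$feature_b) %in%
                    paste(wider$feature_a, wider$feature_b)))
})

test_that("identity conflict audit reports the conflicting fraction", {
  links <- data.frame(feature_a = sprintf("a%d", 1:4),
                      feature_b = sprintf("b%d", 1:4))
  ann <- c(a1 = "alanine", b1 = "alanine", a2 = "serine", b2 = "glycine",
           a3 = "valine", b3 = NA)
  audit <- audit_identity_conflicts(links, ann)
  expect_equal(audit$n_annotated, 2)
  expect_equal(audit$conflict_fraction, 0.5)
  expect_equal(audit$conflicts$feature_a, "a2")

  clean <- audit_identity_conflicts(links, c(a1 = "x", b1 = "x"))
  expect_equal(clean$conflict_fraction, 0)
  expect_equal(audit_identity_conflicts(links, c(z = "q"))$conflict_fraction, 0)
})

test_that("MGF round-trip preserves spectra and TITLE keys", {
  spectra <- elentomics:::.gen_spectra(c("feat_a", "feat_b"), seed = 2)
  f <- tempfile(fileext = ".mgf")
  write_mgf(spectra, f)
  back <- read_mgf(f)
  expect_setequal(names(back), names(spectra))
  for (id in names(spectra)) {
    expect_equal(back[[id]]$mz, spectra[[id]]$mz, tolerance = 1e-6)
    expect_equal(back[[id]]$intensity, spectra[[id]]$intensity, tolerance = 1e-4)
  }
})
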
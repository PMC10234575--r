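#' Read MS2 spectra from an MGF file
#'
#' Parses the standard Mascot Generic Format blocks (BEGIN IONS / END IONS);
#' the TITLE field keys each spectrum to its feature id. Fragment lists are
#' sorted by m/z.
#'
#' @param path MGF file path.
#' @return named list of spectra; each spectrum is a list with `feature_id`,
#'   `mz` (ascending), `intensity`, and optional `pepmass`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_
      mz <- numeric(); int <- numeric()
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (grepl("^[0-9]", ln)) {
          parts <- as.numeric(strsplit(ln, "\\s+")[[1]])
          mz <- c(mz, parts[1]); int <- c(int, parts[2])
        }
        i <- i + 1L
      }
      o <- order(mz)
      spectra[[title]] <- list(feature_id = title, mz = mz[o], intensity = int[o],
                               pepmass = pepmass)
    }
    i <- i + 1L
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra named list of spectra as returned by [read_mgf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$feature_id), con)
    if (!is.null(sp$pepmass) && !is.na(sp$pepmass)) {
      writeLines(paste0("PEPMASS=", format(sp$pepmass, digits = 10)), con)
    }
    writeLines(sprintf("%.6f %.6g", sp$mz, sp$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Cosine similarity between two MS2 spectra
#'
#' Fragments are matched greedily by closest m/z within `frag_tol`; each
#' fragment participates in at most one match. The cosine is the dot product
#' of matched intensities divided by the product of the full-spectrum
#' intensity norms, so unmatched fragments dilute the score. The measure is
#' symmetric in its arguments and lies in \[0, 1\].
#'
#' @param a,b spectra (lists with `mz`, `intensity`).
#' @param frag_tol fragment m/z matching tolerance in Da (default 0.01).
#' @return cosine similarity in \[0, 1\].
#' @export
spectral_cosine <- function(a, b, frag_tol = 0.01) {
  if (!length(a$mz) || !length(b$mz)) stop("spectra must be non-empty")
  na2 <- sqrt(sum(a$intensity^2)); nb2 <- sqrt(sum(b$intensity^2))
  if (na2 == 0 || nb2 == 0) return(0)
  pairs <- NULL
  for (i in seq_along(a$mz)) {
    d <- abs(a$mz[i] - b$mz)
    hit <- which(d <= frag_tol)
    if (length(hit)) pairs <- rbind(pairs, cbind(i = i, j = hit, d = d[hit]))
  }
  if (is.null(pairs)) return(0)
  pairs <- pairs[order(pairs[, "d"], pairs[, "i"], pairs[, "j"]), , drop = FALSE]
  used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
  dot <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "i"]; j <- pairs[k, "j"]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    dot <- dot + a$intensity[i] * b$intensity[j]
  }
  min(1, dot / (na2 * nb2))
}

#' Calibrate a null cosine cutoff from unrelated feature pairs
#'
#' Draws two disjoint random sets of `n_per_set` features with MS2 spectra
#' (per ionization mode), keeps cross-set pairs that are chromatographically
#' and mass-wise unrelated (RT difference >= `rt_min_diff` and m/z difference
#' >= `mz_min_diff`), and returns the `percentile`-th percentile of their
#' pairwise cosines. This is the empirical null calibration behind the
#' published cutoffs of 0.205 (positive mode) and 0.251 (negative mode); see
#' [published_cosine_cutoffs].
#'
#' @param table a [feature_table()] carrying mz/rt/mode metadata.
#' @param spectra named list of MS2 spectra keyed by feature id.
#' @param n_per_set features per random set (default 200).
#' @param rt_min_diff minimum RT difference for a null pair, minutes (default 1).
#' @param mz_min_diff minimum m/z difference for a null pair, Da (default 0.01).
#' @param percentile percentile of the null cosine distribution (default 99.5).
#' @param seed integer seed for the random draws.
#' @param frag_tol fragment matching tolerance passed to [spectral_cosine()].
#' @param min_pairs minimum number of eligible null pairs (default 1000).
#' @return named numeric vector of cutoffs, one per mode present.
#' @export
calibrate_cosine_cutoff <- function(table, spectra, n_per_set = 200,
                                    rt_min_diff = 1, mz_min_diff = 0.01,
                                    percentile = 99.5, seed = 1,
                                    frag_tol = 0.01, min_pairs = 1000) {
  stopifnot(inherits(table, "feature_table"))
  set.seed(seed)
  modes <- unique(stats::na.omit(table$features$mode))
  out <- numeric(0)
  for (md in modes) {
    feats <- table$features[table$features$mode == md &
                              table$features$feature_id %in% names(spectra), ,
                            drop = FALSE]
    if (nrow(feats) < 2 * n_per_set) {
      stop("mode ", md, ": need at least ", 2 * n_per_set,
           " features with MS2 to calibrate")
    }
    pick <- sample(nrow(feats), 2 * n_per_set)
    set1 <- feats[pick[seq_len(n_per_set)], ]
    set2 <- feats[pick[n_per_set + seq_len(n_per_set)], ]
    drt <- abs(outer(set1$rt, set2$rt, "-"))
    dmz <- abs(outer(set1$mz, set2$mz, "-"))
    el <- which(drt >= rt_min_diff & dmz >= mz_min_diff, arr.ind = TRUE)
    if (nrow(el) < min_pairs) {
      stop("mode ", md, ": only ", nrow(el), " eligible null pairs (< ",
           min_pairs, ")")
    }
    cosines <- vapply(seq_len(nrow(el)), function(k) {
      spectral_cosine(spectra[[set1$feature_id[el[k, 1]]]],
                      spectra[[set2$feature_id[el[k, 2]]]], frag_tol = frag_tol)
    }, numeric(1))
    out[md] <- as.numeric(stats::quantile(cosines, percentile / 100, type = 7))
  }
  out
}

#' Published null-calibrated cosine cutoffs
#'
#' The cutoffs obtained from the null-percentile calibration on the original
#' supernatant datasets: 0.205 for positive and 0.251 for negative ionization
#' mode. Used as defaults by [link_features()] when no calibration data are
#' available.
#' @format named numeric vector.
#' @export
published_cosine_cutoffs <- c(positive = 0.205, negative = 0.251)

#' Link features across two independently processed datasets
#'
#' A pair of features (one per dataset) is linked when both are in the same
#' ionization mode, annotated as the same adduct, within `mz_tol` m/z and
#' `rt_tol` minutes RT, and their MS2 cosine similarity reaches the
#' mode-specific cutoff. Pairs in which either feature lacks an MS2 spectrum
#' are instead linked under the tighter no-MS2 tolerances. Each feature joins
#' at most one merged identity: candidate links are accepted best-cosine
#' first, ties broken by the smaller m/z difference.
#'
#' @param table_a,table_b [feature_table()]s of the two datasets.
#' @param spectra named list of MS2 spectra keyed by feature id (features of
#'   both tables; absent entries mean "no MS2 collected").
#' @param mz_tol,rt_tol tolerances for MS2-supported links (defaults 0.007 Da,
#'   0.5 min).
#' @param noms2_mz_tol,noms2_rt_tol tolerances when MS2 is missing (defaults
#'   0.001 Da, 0.2 min).
#' @param cutoffs named per-mode cosine cutoffs (default
#'   [published_cosine_cutoffs]).
#' @param frag_tol fragment matching tolerance (default 0.01 Da).
#' @return data.frame of links (feature_a, feature_b, cosine, delta_mz,
#'   delta_rt, merged_id) with the cutoffs stored in `attr(, "cutoffs")`.
#' @export
link_features <- function(table_a, table_b, spectra, mz_tol = 0.007,
                          rt_tol = 0.5, noms2_mz_tol = 0.001,
                          noms2_rt_tol = 0.2,
                          cutoffs = published_cosine_cutoffs,
                          frag_tol = 0.01) {
  fa <- table_a$features; fb <- table_b$features
  cand <- NULL
  for (i in seq_len(nrow(fa))) {
    same <- which(fb$mode == fa$mode[i] & fb$adduct == fa$adduct[i])
    if (!length(same)) next
    dmz <- abs(fa$mz[i] - fb$mz[same])
    drt <- abs(fa$rt[i] - fb$rt[same])
    has_a <- fa$feature_id[i] %in% names(spectra)
    has_b <- fb$feature_id[same] %in% names(spectra)
    both <- has_a & has_b
    pass_ms2 <- both & dmz <= mz_tol & drt <= rt_tol
    pass_noms2 <- !both & dmz <= noms2_mz_tol & drt <= noms2_rt_tol
    hit <- which(pass_ms2 | pass_noms2)
    for (h in hit) {
      j <- same[h]
      cosine <- NA_real_
      if (both[h]) {
        cosine <- spectral_cosine(spectra[[fa$feature_id[i]]],
                                  spectra[[fb$feature_id[j]]],
                                  frag_tol = frag_tol)
        cut <- cutoffs[[fa$mode[i]]]
        if (is.null(cut) || is.na(cut)) stop("no cosine cutoff for mode ", fa$mode[i])
        if (cosine < cut) next
      }
      cand <- rbind(cand, data.frame(
        feature_a = fa$feature_id[i], feature_b = fb$feature_id[j],
        cosine = cosine, delta_mz = dmz[h], delta_rt = drt[h],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand)) {
    out <- data.frame(feature_a = character(), feature_b = character(),
                      cosine = numeric(), delta_mz = numeric(),
                      delta_rt = numeric(), merged_id = character(),
                      stringsAsFactors = FALSE)
    attr(out, "cutoffs") <- cutoffs
    return(out)
  }
  # one-to-one resolution: best cosine first (no-MS2 links rank below any
  # cosine-supported link), ties by smallest delta m/z
  rank_cos <- ifelse(is.na(cand$cosine), -1, cand$cosine)
  o <- order(-rank_cos, cand$delta_mz, cand$feature_a, cand$feature_b)
  cand <- cand[o, , drop = FALSE]
  used_a <- character(); used_b <- character()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$feature_a[k] %in% used_a || cand$feature_b[k] %in% used_b) next
    keep[k] <- TRUE
    used_a <- c(used_a, cand$feature_a[k]); used_b <- c(used_b, cand$feature_b[k])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$merged_id <- sprintf("M%04d", seq_len(nrow(out)))
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Audit identity conflicts among cross-dataset links
#'
#' Among links where both features carry an annotation, reports the fraction
#' whose annotations disagree (the published pipelines reported roughly 0.5%
#' under their calibrated cutoffs) and lists the conflicting pairs.
#'
#' @param links data.frame from [link_features()].
#' @param annotations named character vector feature_id -> annotation (NA or
#'   absent = unannotated).
#' @return list with `conflict_fraction`, `n_annotated`, and `conflicts`
#'   (data.frame).
#' @export
audit_identity_conflicts <- function(links, annotations) {
  ann_a <- annotations[links$feature_a]
  ann_b <- annotations[links$feature_b]
  both <- !is.na(ann_a) & !is.na(ann_b)
  n_annotated <- sum(both)
  conflict <- both & ann_a != ann_b
  conflicts <- data.frame(feature_a = links$feature_a[conflict],
                          feature_b = links$feature_b[conflict],
                          annotation_a = unname(ann_a[conflict]),
                          annotation_b = unname(ann_b[conflict]),
                          stringsAsFactors = FALSE)
  list(conflict_fraction = if (n_annotated) sum(conflict) / n_annotated else 0,
       n_annotated = n_annotated, conflicts = conflicts)
}
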
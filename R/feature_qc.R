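#' Flag features present above blank background
#'
#' A feature counts as present when its mean intensity across non-blank
#' samples is strictly greater than `blank_fold` times its mean intensity in
#' blank (method background) samples. With `by`, presence is evaluated within
#' each level of a sample-metadata column (e.g. per time point) and a feature
#' is present if it passes in at least one level.
#'
#' @param table a [feature_table()] with raw intensities.
#' @param blank_fold fold-elevation threshold over the blank mean (default 3).
#' @param by optional name of a sample-metadata column used to evaluate
#'   presence per level; `NULL` pools all non-blank samples.
#' @return named logical vector over features.
#' @export
call_present <- function(table, blank_fold = 3, by = NULL) {
  stopifnot(inherits(table, "feature_table"))
  is_blank <- table$samples$role == "blank"
  if (!any(is_blank)) stop("no blank samples in table: presence call needs blanks")
  if (!any(!is_blank)) stop("no non-blank samples in table")
  blank_mean <- rowMeans(table$intensity[, is_blank, drop = FALSE])
  present_in <- function(cols) {
    rowMeans(table$intensity[, cols, drop = FALSE]) > blank_fold * blank_mean
  }
  if (is.null(by)) {
    res <- present_in(which(!is_blank))
  } else {
    lev <- table$samples[[by]]
    if (is.null(lev)) stop("no sample metadata column named '", by, "'")
    idx <- split(which(!is_blank), lev[!is_blank])
    res <- Reduce(`|`, lapply(idx, present_in))
  }
  stats::setNames(as.logical(res), table$features$feature_id)
}

.replicate_groups <- function(samples, by) {
  keep <- which(samples$role == "sample")
  if (is.null(by)) return(list(all = keep))
  lev <- samples[[by]][keep]
  if (is.null(samples[[by]])) stop("no sample metadata column named '", by, "'")
  split(keep, lev)
}

#' Filter features by replicate coefficient of variation
#'
#' Computes, for every replicate group (samples sharing the `by` column among
#' role == "sample"), the coefficient of variation sd/mean of raw intensities,
#' and removes features whose median CV across groups exceeds `cv_max`.
#' Groups of size < 2 or with zero mean are skipped.
#'
#' @param table a [feature_table()] with raw intensities.
#' @param cv_max maximum tolerated median CV (default 0.5, i.e. 50%).
#' @param by sample-metadata column defining replicate groups (default
#'   "group"); `NULL` pools all biological samples into one group.
#' @return the filtered `feature_table`.
#' @export
filter_features_by_cv <- function(table, cv_max = 0.5, by = "group") {
  stopifnot(inherits(table, "feature_table"))
  groups <- .replicate_groups(table$samples, by)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) stop("CV undefined: no replicate group of size >= 2")
  cvs <- vapply(groups, function(cols) {
    m <- rowMeans(table$intensity[, cols, drop = FALSE])
    s <- apply(table$intensity[, cols, drop = FALSE], 1, stats::sd)
    ifelse(m > 0, s / m, NA_real_)
  }, numeric(nrow(table$intensity)))
  cvs <- matrix(cvs, nrow = nrow(table$intensity))
  med <- apply(cvs, 1, stats::median, na.rm = TRUE)
  keep <- is.na(med) | med <= cv_max
  ft_subset(table, features = which(keep))
}

#' Remove technical outlier samples by total signal
#'
#' Drops non-blank samples whose total feature signal deviates from the assay
#' median total by more than `dev_max` (as a fraction of the median).
#'
#' @param table a [feature_table()] with raw intensities.
#' @param dev_max maximum tolerated relative deviation (default 0.5).
#' @return the filtered `feature_table` (blanks always retained).
#' @export
filter_outlier_samples <- function(table, dev_max = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  nb <- which(table$samples$role != "blank")
  if (length(nb) < 3) stop("need at least 3 non-blank samples to assess outliers")
  totals <- colSums(table$intensity[, nb, drop = FALSE])
  med <- stats::median(totals)
  if (med == 0) stop("median total signal is zero; outlier deviation undefined")
  drop <- nb[abs(totals - med) / med > dev_max]
  keep <- setdiff(seq_len(ncol(table$intensity)), drop)
  ft_subset(table, samples = keep)
}

#' Log-transform intensities with a per-feature pseudocount
#'
#' Adds, per feature, a pseudocount equal to `pseudocount_frac` times the
#' minimum nonzero intensity of that feature, then takes `log_base`
#' logarithms. Datasets whose values are already approximately normal (e.g. a
#' strain-panel dataset) can skip this step entirely.
#'
#' @param table a [feature_table()] with raw intensities.
#' @param pseudocount_frac fraction of the per-feature minimum nonzero
#'   intensity used as pseudocount (default 0.25).
#' @param base logarithm base (default 10).
#' @return the transformed `feature_table`; `attr(, "log_base")` records the
#'   base and `attr(, "pseudocounts")` the per-feature pseudocounts.
#' @export
log_transform <- function(table, pseudocount_frac = 0.25, base = 10) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(attr(table, "log_base"))) stop("table is already log-transformed")
  x <- table$intensity
  min_nonzero <- apply(x, 1, function(r) if (any(r > 0)) min(r[r > 0]) else NA_real_)
  if (anyNA(min_nonzero)) {
    stop("all-zero feature(s) cannot be log-transformed: ",
         paste(table$features$feature_id[is.na(min_nonzero)], collapse = ", "))
  }
  pc <- pseudocount_frac * min_nonzero
  out <- table
  out$intensity <- log(x + pc, base = base)
  attr(out, "log_base") <- base
  attr(out, "pseudocounts") <- stats::setNames(pc, table$features$feature_id)
  out
}

# proton mass (Da) and neutral-mass offsets for the default adduct set;
# neutral mass = mz - offset
.adduct_offsets <- c("[M+H]+" = 1.00728, "[M-H]-" = -1.00728,
                     "[M+Na]+" = 22.98922, "[M+Cl]-" = -34.96940)

.neutral_mass <- function(mz, adduct) {
  off <- .adduct_offsets[adduct]
  ifelse(is.na(off), NA_real_, mz - off)
}

#' Merge duplicate features across ionization modes
#'
#' Identifies features detected in both positive and negative mode as pairs
#' whose adduct-corrected neutral masses differ by less than `mass_tol`,
#' retention times by less than `rt_tol`, and whose intensities across shared
#' samples have Pearson correlation at least `min_corr`. Of each merged pair
#' the feature with the lower (more confident) MSI level is kept; on ties the
#' positive-mode feature is kept. Adducts outside the built-in set
#' ([M+H]+, [M-H]-, [M+Na]+, [M+Cl]-) fall back to direct m/z matching.
#'
#' @param pos,neg [feature_table()]s for positive and negative mode, sharing
#'   a sample set.
#' @param mass_tol neutral-mass tolerance in Da (default 0.02).
#' @param rt_tol retention-time tolerance in minutes (default 0.1).
#' @param min_corr minimum Pearson correlation across shared samples
#'   (default 0.7).
#' @return list with `table` (merged `feature_table` over the shared samples)
#'   and `merge_map` (data.frame of dropped -> kept feature pairs with their
#'   mass/RT deltas and correlations).
#' @export
dereplicate_modes <- function(pos, neg, mass_tol = 0.02, rt_tol = 0.1,
                              min_corr = 0.7) {
  stopifnot(inherits(pos, "feature_table"), inherits(neg, "feature_table"))
  shared <- intersect(pos$samples$sample_id, neg$samples$sample_id)
  if (length(shared) < 3) stop("need at least 3 shared samples to correlate modes")
  pm <- .neutral_mass(pos$features$mz, pos$features$adduct)
  nm <- .neutral_mass(neg$features$mz, neg$features$adduct)

  cand <- NULL
  for (i in seq_len(nrow(pos$features))) {
    drt <- abs(pos$features$rt[i] - neg$features$rt)
    dm <- if (!is.na(pm[i])) abs(pm[i] - nm) else rep(NA_real_, length(nm))
    # unknown adduct on either side: tight m/z comparison only
    fallback <- is.na(pm[i]) | is.na(nm)
    dm[fallback] <- abs(pos$features$mz[i] - neg$features$mz[fallback])
    hit <- which(dm < mass_tol & drt < rt_tol)
    if (length(hit)) {
      cand <- rbind(cand, data.frame(i = i, j = hit, d_mass = dm[hit],
                                     d_rt = drt[hit]))
    }
  }
  merge_map <- data.frame(dropped = character(), kept = character(),
                          delta_mass = numeric(), delta_rt = numeric(),
                          r = numeric(), stringsAsFactors = FALSE)
  drop_pos <- integer(); drop_neg <- integer()
  if (!is.null(cand)) {
    xp <- pos$intensity[, shared, drop = FALSE]
    xn <- neg$intensity[, shared, drop = FALSE]
    cand$r <- vapply(seq_len(nrow(cand)), function(k) {
      suppressWarnings(stats::cor(xp[cand$i[k], ], xn[cand$j[k], ]))
    }, numeric(1))
    cand <- cand[!is.na(cand$r) & cand$r >= min_corr, , drop = FALSE]
    cand <- cand[order(cand$d_mass, cand$d_rt, cand$i, cand$j), , drop = FALSE]
    used_i <- logical(nrow(pos$features)); used_j <- logical(nrow(neg$features))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      msi_p <- pos$features$msi_level[i]; msi_n <- neg$features$msi_level[j]
      msi_p <- if (is.na(msi_p)) Inf else msi_p
      msi_n <- if (is.na(msi_n)) Inf else msi_n
      keep_pos <- msi_p <= msi_n   # ties keep the positive-mode feature
      if (keep_pos) {
        drop_neg <- c(drop_neg, j)
        merge_map <- rbind(merge_map, data.frame(
          dropped = neg$features$feature_id[j], kept = pos$features$feature_id[i],
          delta_mass = cand$d_mass[k], delta_rt = cand$d_rt[k], r = cand$r[k]))
      } else {
        drop_pos <- c(drop_pos, i)
        merge_map <- rbind(merge_map, data.frame(
          dropped = pos$features$feature_id[i], kept = neg$features$feature_id[j],
          delta_mass = cand$d_mass[k], delta_rt = cand$d_rt[k], r = cand$r[k]))
      }
    }
  }
  keep_p <- setdiff(seq_len(nrow(pos$features)), drop_pos)
  keep_n <- setdiff(seq_len(nrow(neg$features)), drop_neg)
  samp <- pos$samples[match(shared, pos$samples$sample_id), , drop = FALSE]
  merged <- feature_table(
    rbind(pos$intensity[keep_p, shared, drop = FALSE],
          neg$intensity[keep_n, shared, drop = FALSE]),
    rbind(pos$features[keep_p, , drop = FALSE], neg$features[keep_n, , drop = FALSE]),
    samp)
  list(table = merged, merge_map = merge_map)
}

.log2_values <- function(table) {
  base <- attr(table, "log_base")
  if (!is.null(base)) return(table$intensity * log2(base))
  x <- table$intensity
  min_nonzero <- apply(x, 1, function(r) if (any(r > 0)) min(r[r > 0]) else 1)
  log2(x + 0.25 * min_nonzero)
}

#' Welch differential abundance between two groups
#'
#' Per feature, a Welch two-sample t test on log2 intensities (pseudocounted
#' when the table is untransformed) between `case_group` and `control_group`
#' samples, with Benjamini-Hochberg adjustment across all tested features.
#' A feature is called increased/decreased when `p_adj < fdr_alpha` and
#' `|log2fc| > lfc_min`. Features with zero variance and equal means in both
#' groups receive p = 1 by convention (flagged in the `degenerate` column) so
#' that the BH family stays well defined.
#'
#' @param table a [feature_table()].
#' @param case_group,control_group values of the sample `group` column.
#' @param fdr_alpha adjusted-p threshold for calling (default 0.1).
#' @param lfc_min minimum absolute log2 fold change for calling (default 0.5;
#'   0.75 is the stricter heatmap setting).
#' @return data.frame with feature_id, log2fc, t_stat, p, p_adj, call,
#'   degenerate.
#' @export
differential_abundance <- function(table, case_group, control_group,
                                   fdr_alpha = 0.1, lfc_min = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  g <- table$samples$group
  ci <- which(g == case_group & table$samples$role != "blank")
  ki <- which(g == control_group & table$samples$role != "blank")
  if (length(ci) < 2 || length(ki) < 2) stop("need >= 2 samples per group")
  lx <- .log2_values(table)
  x1 <- lx[, ci, drop = FALSE]; x2 <- lx[, ki, drop = FALSE]
  n1 <- length(ci); n2 <- length(ki)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  dfree <- ifelse(se2 > 0,
                  se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- ifelse(is.finite(tt),
              2 * stats::pt(-abs(tt), dfree),
              ifelse(tt == 0, 1, 0))
  degenerate <- se2 == 0 & m1 == m2
  p[degenerate] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  lfc <- m1 - m2
  call <- rep("unchanged", length(p))
  call[p_adj < fdr_alpha & lfc > lfc_min] <- "increased"
  call[p_adj < fdr_alpha & lfc < -lfc_min] <- "decreased"
  data.frame(feature_id = table$features$feature_id, log2fc = lfc,
             t_stat = as.numeric(tt), p = p, p_adj = p_adj, call = call,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Permutation test for diverging metabolite trajectories
#'
#' Fits a smoothing spline (fixed degrees of freedom) to each replicate time
#' series, forms group mean curves on a uniform time grid, and uses the mean
#' absolute difference between the two group curves as the test statistic.
#' Significance is assessed by permuting whole replicate series between
#' groups; p = (number of permuted statistics >= observed + 1) / (n_perm + 1),
#' followed by BH adjustment across features. The conventional significance
#' threshold for trajectory divergence is p_adj < 0.25.
#'
#' @param table a [feature_table()] with `time_h` and `replicate` sample
#'   metadata.
#' @param group_a,group_b the two sample groups to compare.
#' @param df spline degrees of freedom (default 5).
#' @param n_perm number of label permutations (default 1000; must be >= 1).
#' @param seed integer seed for the permutation draw.
#' @param n_grid grid resolution for curve comparison (default 50).
#' @return data.frame with feature_id, stat, p_perm, p_adj.
#' @export
trajectory_difference <- function(table, group_a, group_b, df = 5,
                                  n_perm = 1000, seed = 1, n_grid = 50) {
  stopifnot(inherits(table, "feature_table"))
  if (n_perm < 1) stop("n_perm must be >= 1; the permutation p-value is undefined otherwise")
  set.seed(seed)
  s <- table$samples
  sel <- which(s$role == "sample" & s$group %in% c(group_a, group_b))
  key <- interaction(s$group[sel], s$replicate[sel], drop = TRUE)
  series <- split(sel, key)
  grp <- vapply(series, function(ix) s$group[ix[1]], character(1))
  if (sum(grp == group_a) < 2 || sum(grp == group_b) < 2) {
    stop("need >= 2 replicate series per group")
  }
  times <- lapply(series, function(ix) s$time_h[ix])
  nt <- length(unique(unlist(times)))
  if (nt < 3) stop("need >= 3 time points")
  if (nt < df) stop("fewer unique time points (", nt, ") than spline df (", df,
                    "); lower df")
  grid <- seq(max(vapply(times, min, 1)), min(vapply(times, max, 1)),
              length.out = n_grid)

  fit_series <- function(tm, y) {
    o <- order(tm)
    tm <- tm[o]; y <- y[o]
    if (stats::sd(y) == 0) return(rep(y[1], length(grid)))
    fit <- stats::smooth.spline(tm, y, df = min(df, length(unique(tm))))
    stats::predict(fit, grid)$y
  }

  ia <- which(grp == group_a); ib <- which(grp == group_b)
  perms <- lapply(seq_len(n_perm), function(k) sample(seq_along(series)))
  res <- lapply(seq_len(nrow(table$intensity)), function(f) {
    preds <- t(vapply(seq_along(series), function(si) {
      fit_series(times[[si]], table$intensity[f, series[[si]]])
    }, numeric(length(grid))))
    stat_of <- function(a_idx, b_idx) {
      mean(abs(colMeans(preds[a_idx, , drop = FALSE]) -
               colMeans(preds[b_idx, , drop = FALSE])))
    }
    obs <- stat_of(ia, ib)
    perm_stats <- vapply(perms, function(p) {
      stat_of(p[seq_along(ia)], p[length(ia) + seq_along(ib)])
    }, numeric(1))
    c(stat = obs, p_perm = (sum(perm_stats >= obs) + 1) / (n_perm + 1))
  })
  res <- do.call(rbind, res)
  data.frame(feature_id = table$features$feature_id, stat = res[, "stat"],
             p_perm = res[, "p_perm"],
             p_adj = stats::p.adjust(res[, "p_perm"], method = "BH"),
             stringsAsFactors = FALSE)
}

#' Classify features as strain-variable, conserved, or absent
#'
#' Given per-strain differential abundance results against a common control,
#' a feature is strain-variable when it is called changed (increased or
#' decreased) in at least one strain but fewer than `near_all` strains,
#' conserved when changed in at least `near_all` strains, and absent when
#' changed in none. The canonical setting for a 30-strain panel is
#' `near_all = 29`.
#'
#' @param per_strain_results named list (one element per strain) of
#'   [differential_abundance()] results over an identical feature universe.
#' @param near_all strain count at and above which a feature counts as
#'   conserved (default 29).
#' @return data.frame with feature_id, n_increased, n_decreased, n_changed,
#'   label.
#' @export
classify_strain_variability <- function(per_strain_results, near_all = 29) {
  ids <- per_strain_results[[1]]$feature_id
  same <- vapply(per_strain_results, function(r) identical(sort(r$feature_id), sort(ids)),
                 logical(1))
  if (!all(same)) stop("inconsistent feature sets across strains")
  calls <- vapply(per_strain_results, function(r) r$call[match(ids, r$feature_id)],
                  character(length(ids)))
  calls <- matrix(calls, nrow = length(ids))
  n_inc <- rowSums(calls == "increased")
  n_dec <- rowSums(calls == "decreased")
  n_chg <- rowSums(calls != "unchanged")
  label <- ifelse(n_chg == 0, "absent",
                  ifelse(n_chg >= near_all, "conserved", "variable"))
  data.frame(feature_id = ids, n_increased = n_inc, n_decreased = n_dec,
             n_changed = n_chg, label = label, stringsAsFactors = FALSE)
}
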
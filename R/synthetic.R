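#' Generate a synthetic untargeted-metabolomics experiment
#'
#' Emulates the structure of a culture-vs-sterile-control feature table:
#' log-normal baseline intensities with multiplicative replicate noise, blank
#' samples at a constant background level, and planted produced/depleted
#' features shifted by `effect_log2` in the case group. With `times` set, the
#' experiment becomes a time course in which planted effects follow a
#' logistic-shaped production trajectory instead of a constant offset. All
#' output is a pure function of the configuration and `seed`.
#'
#' @param n_features number of features (default 500).
#' @param n_samples_per_group biological replicates per group (default 3);
#'   in time-course mode, replicate series per group.
#' @param groups two group labels, case first (default
#'   `c("culture", "control")`).
#' @param n_produced,n_depleted planted feature counts (defaults 25/25).
#' @param effect_log2 planted log2 effect size (default 3, an 8-fold shift).
#' @param blank_level mean blank background intensity (default 100).
#' @param n_blanks number of blank samples (default 3).
#' @param cv replicate coefficient of variation (default 0.1).
#' @param base_log10_mean,base_log10_sd log10-normal baseline intensity
#'   parameters (defaults 4 and 0.5).
#' @param times optional numeric vector of time points (hours) switching on
#'   time-course mode.
#' @param with_spectra also generate random sparse MS2 spectra per feature
#'   (default FALSE).
#' @param seed integer seed.
#' @return list with `table` (a [feature_table()]), `spectra` (or NULL), and
#'   `truth` (produced/depleted feature ids and planted effects).
#' @export
gen_feature_experiment <- function(n_features = 500, n_samples_per_group = 3,
                                   groups = c("culture", "control"),
                                   n_produced = 25, n_depleted = 25,
                                   effect_log2 = 3, blank_level = 100,
                                   n_blanks = 3, cv = 0.1,
                                   base_log10_mean = 4, base_log10_sd = 0.5,
                                   times = NULL, with_spectra = FALSE,
                                   seed = 1) {
  if (n_produced + n_depleted > n_features) stop("more planted features than features")
  if (length(groups) != 2) stop("exactly two groups required")
  set.seed(seed)
  base <- 10^stats::rnorm(n_features, base_log10_mean, base_log10_sd)
  fid <- sprintf("F%04d", seq_len(n_features))
  produced <- sample(fid, n_produced)
  depleted <- sample(setdiff(fid, produced), n_depleted)
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- function(mu) mu * exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog))

  if (is.null(times)) {
    samp <- expand.grid(replicate = seq_len(n_samples_per_group),
                        group = groups, stringsAsFactors = FALSE)
    samp$sample_id <- sprintf("%s_r%d", samp$group, samp$replicate)
    samp$role <- "sample"
    samp$time_h <- NA_real_
    mk_col <- function(grp) {
      mu <- base
      mu[fid %in% produced & grp == groups[1]] <-
        base[fid %in% produced] * 2^effect_log2
      mu[fid %in% depleted & grp == groups[1]] <-
        base[fid %in% depleted] / 2^effect_log2
      noisy(mu)
    }
    intensity <- vapply(seq_len(nrow(samp)), function(i) mk_col(samp$group[i]),
                        numeric(n_features))
  } else {
    samp <- expand.grid(time_h = times, replicate = seq_len(n_samples_per_group),
                        group = groups, stringsAsFactors = FALSE)
    samp$sample_id <- sprintf("%s_r%d_t%02d", samp$group, samp$replicate,
                              match(samp$time_h, times))
    samp$role <- "sample"
    tmid <- stats::median(range(times)); rate <- 4 / diff(range(times))
    traj <- function(t) 1 / (1 + exp(-rate * 4 * (t - tmid)))
    intensity <- vapply(seq_len(nrow(samp)), function(i) {
      mu <- base
      if (samp$group[i] == groups[1]) {
        f <- traj(samp$time_h[i])
        mu[fid %in% produced] <- base[fid %in% produced] * 2^(effect_log2 * f)
        mu[fid %in% depleted] <- base[fid %in% depleted] / 2^(effect_log2 * f)
      }
      noisy(mu)
    }, numeric(n_features))
  }
  blanks <- vapply(seq_len(n_blanks), function(i) {
    noisy(rep(blank_level, n_features))
  }, numeric(n_features))
  intensity <- cbind(intensity, blanks)
  samp_blank <- data.frame(sample_id = sprintf("blank_%d", seq_len(n_blanks)),
                           role = "blank", group = NA_character_,
                           time_h = NA_real_, replicate = seq_len(n_blanks),
                           stringsAsFactors = FALSE)
  samples <- rbind(samp[, c("sample_id", "role", "group", "time_h", "replicate")],
                   samp_blank)
  features <- data.frame(
    feature_id = fid,
    mz = round(stats::runif(n_features, 80, 900), 4),
    rt = round(stats::runif(n_features, 0.5, 14), 3),
    mode = "positive", adduct = "[M+H]+", annotation = NA_character_,
    msi_level = NA_integer_, stringsAsFactors = FALSE)
  tab <- feature_table(intensity, features, samples)
  spectra <- NULL
  if (with_spectra) spectra <- .gen_spectra(fid, seed = seed + 1L)
  list(table = tab, spectra = spectra,
       truth = list(produced = produced, depleted = depleted,
                    effect_log2 = effect_log2, groups = groups))
}

.gen_spectra <- function(feature_ids, n_frag_range = c(5, 12), seed = 1) {
  set.seed(seed)
  out <- lapply(feature_ids, function(id) {
    nf <- sample(seq(n_frag_range[1], n_frag_range[2]), 1)
    mz <- sort(stats::runif(nf, 50, 500))
    list(feature_id = id, mz = mz, intensity = stats::runif(nf, 1, 100),
         pepmass = max(mz) + 1.00728)
  })
  stats::setNames(out, feature_ids)
}

#' Generate a pair of cross-mode tables with planted duplicate features
#'
#' Produces a positive-mode table plus a negative-mode table in which
#' `n_duplicates` features are the [M-H]- detections of positive [M+H]+
#' features: same neutral mass and retention time, intensities correlated
#' at >= 0.9 across the shared samples. Remaining negative features are
#' decoys separated in mass/RT.
#'
#' @param n_pos,n_neg feature counts per mode (defaults 60/40).
#' @param n_duplicates planted cross-mode duplicates (default 15).
#' @param n_samples shared samples (default 8).
#' @param seed integer seed.
#' @return list with `pos`, `neg` (feature_tables), and `truth`
#'   (data.frame of planted pos/neg duplicate ids).
#' @export
gen_cross_mode_pair <- function(n_pos = 60, n_neg = 40, n_duplicates = 15,
                                n_samples = 8, seed = 1) {
  if (n_duplicates > min(n_pos, n_neg)) stop("too many duplicates")
  set.seed(seed)
  proton <- 1.00728
  neutral <- stats::runif(n_pos, 100, 800)
  rt <- round(stats::runif(n_pos, 1, 13), 3)
  sid <- sprintf("s%02d", seq_len(n_samples))
  samples <- data.frame(sample_id = sid, role = "sample", group = "culture",
                        replicate = seq_len(n_samples), stringsAsFactors = FALSE)
  base_p <- 10^stats::rnorm(n_pos, 4, 0.4)
  xp <- t(vapply(seq_len(n_pos), function(i) {
    base_p[i] * exp(stats::rnorm(n_samples, 0, 0.6))
  }, numeric(n_samples)))
  pos <- feature_table(
    xp,
    data.frame(feature_id = sprintf("P%03d", seq_len(n_pos)),
               mz = neutral + proton, rt = rt, mode = "positive",
               adduct = "[M+H]+", annotation = NA_character_,
               msi_level = sample(c(NA, 1:4), n_pos, replace = TRUE),
               stringsAsFactors = FALSE),
    samples)
  dup_idx <- sample(n_pos, n_duplicates)
  xn <- matrix(0, n_neg, n_samples)
  mzn <- numeric(n_neg); rtn <- numeric(n_neg)
  for (j in seq_len(n_neg)) {
    if (j <= n_duplicates) {
      i <- dup_idx[j]
      mzn[j] <- neutral[i] - proton + stats::runif(1, -0.005, 0.005)
      rtn[j] <- rt[i] + stats::runif(1, -0.03, 0.03)
      xn[j, ] <- xp[i, ] * 0.6 * exp(stats::rnorm(n_samples, 0, 0.05))
    } else {
      mzn[j] <- stats::runif(1, 100, 800)
      rtn[j] <- round(stats::runif(1, 1, 13), 3)
      xn[j, ] <- 10^stats::rnorm(1, 4, 0.4) * exp(stats::rnorm(n_samples, 0, 0.6))
    }
  }
  neg <- feature_table(
    xn,
    data.frame(feature_id = sprintf("N%03d", seq_len(n_neg)),
               mz = mzn, rt = rtn, mode = "negative", adduct = "[M-H]-",
               annotation = NA_character_,
               msi_level = sample(c(NA, 1:4), n_neg, replace = TRUE),
               stringsAsFactors = FALSE),
    samples)
  list(pos = pos, neg = neg,
       truth = data.frame(pos_id = sprintf("P%03d", dup_idx),
                          neg_id = sprintf("N%03d", seq_len(n_duplicates)),
                          stringsAsFactors = FALSE))
}

#' Generate two datasets with planted shared features for linking
#'
#' Dataset B contains `n_shared` features that are re-detections of features
#' in dataset A: identical MS2 spectra, with m/z and RT jittered by at most
#' the supplied amounts. Decoy features in both datasets are separated by
#' more than the default linking tolerances and carry unrelated spectra.
#'
#' @param n_shared planted shared features (default 30).
#' @param n_decoy_a,n_decoy_b decoys per dataset (defaults 40/40).
#' @param jitter_mz,jitter_rt maximum |jitter| applied to shared features
#'   (defaults 0, i.e. exact re-detections).
#' @param mode ionization mode for all features (default "positive").
#' @param seed integer seed.
#' @return list with `table_a`, `table_b`, `spectra`, and `truth`
#'   (data.frame id_a, id_b).
#' @export
gen_linked_datasets <- function(n_shared = 30, n_decoy_a = 40, n_decoy_b = 40,
                                jitter_mz = 0, jitter_rt = 0,
                                mode = "positive", seed = 1) {
  set.seed(seed)
  n_a <- n_shared + n_decoy_a
  # well-separated anchor grid so decoys never fall within tolerances
  mz_a <- seq(100, by = 0.7, length.out = n_a) + stats::runif(n_a, 0, 0.2)
  rt_a <- seq(1, by = 0.9, length.out = n_a) %% 14 + stats::runif(n_a, 0, 0.15)
  ids_a <- sprintf("A%03d", seq_len(n_a))
  sid <- sprintf("s%d", 1:4)
  samples <- data.frame(sample_id = sid, role = "sample", group = "x",
                        replicate = 1:4, stringsAsFactors = FALSE)
  mk_tab <- function(ids, mz, rt) {
    feature_table(matrix(10^stats::rnorm(length(ids) * 4, 4, 0.3),
                         length(ids), 4),
                  data.frame(feature_id = ids, mz = mz, rt = rt, mode = mode,
                             adduct = "[M+H]+", annotation = NA_character_,
                             msi_level = NA_integer_, stringsAsFactors = FALSE),
                  samples)
  }
  tab_a <- mk_tab(ids_a, mz_a, rt_a)
  shared_idx <- seq_len(n_shared)
  ids_b_shared <- sprintf("B%03d", shared_idx)
  mz_b_shared <- mz_a[shared_idx] + stats::runif(n_shared, -jitter_mz, jitter_mz)
  rt_b_shared <- rt_a[shared_idx] + stats::runif(n_shared, -jitter_rt, jitter_rt)
  n_b <- n_shared + n_decoy_b
  ids_b <- c(ids_b_shared, sprintf("B%03d", n_shared + seq_len(n_decoy_b)))
  mz_b <- c(mz_b_shared, seq(100.35, by = 0.7, length.out = n_decoy_b))
  rt_b <- c(rt_b_shared, (seq(1.45, by = 0.9, length.out = n_decoy_b) %% 14))
  tab_b <- mk_tab(ids_b, mz_b, rt_b)
  spectra_a <- .gen_spectra(ids_a, seed = seed + 1L)
  spectra_b <- .gen_spectra(ids_b, seed = seed + 2L)
  for (k in shared_idx) spectra_b[[ids_b[k]]][c("mz", "intensity")] <-
    spectra_a[[ids_a[k]]][c("mz", "intensity")]
  list(table_a = tab_a, table_b = tab_b, spectra = c(spectra_a, spectra_b),
       truth = data.frame(id_a = ids_a[shared_idx], id_b = ids_b_shared,
                          stringsAsFactors = FALSE))
}

#' Generate a strain panel with gene-linked metabolite features
#'
#' Random (seed-fixed) gene-family presence/absence patterns over a strain
#' panel, a feature table with sterile-control samples, and
#' `n_linked_features` features shifted by `delta_log10` in strains carrying
#' their linked gene family. With `margin_ok` the construction guarantees
#' clean separability margins (with-gene strains clear of the control
#' maximum, without-gene strains below it), so downstream filtering should
#' recover every planted link.
#'
#' @param n_strains strains in the panel (default 30).
#' @param n_gene_families gene families (default 40).
#' @param n_linked_features features with a planted gene link (default 8).
#' @param n_null_features unlinked decoy features (default 60).
#' @param delta_log10 planted shift in log10 units (default 1.0).
#' @param margin_ok construct clean separability margins (default TRUE).
#' @param n_replicates replicate cultures per strain (default 3).
#' @param noise_sd replicate noise sd in log10 units (default 0.1).
#' @param seed integer seed.
#' @return list with `presence` (logical matrix), `table` (feature_table
#'   with strain samples and sterile controls), and `truth` (feature ->
#'   linked gene family / pattern).
#' @export
gen_strain_panel <- function(n_strains = 30, n_gene_families = 40,
                             n_linked_features = 8, n_null_features = 60,
                             delta_log10 = 1.0, margin_ok = TRUE,
                             n_replicates = 3, noise_sd = 0.1, seed = 1) {
  if (n_linked_features > n_gene_families) stop("n_linked_features > n_gene_families")
  set.seed(seed)
  strains <- sprintf("strain%02d", seq_len(n_strains))
  gf <- sprintf("GF%03d", seq_len(n_gene_families))
  repeat {
    presence <- matrix(stats::runif(n_gene_families * n_strains) < 0.5,
                       n_gene_families, n_strains,
                       dimnames = list(gf, strains))
    nw <- rowSums(presence)
    if (all(nw[seq_len(n_linked_features)] >= 3 &
            nw[seq_len(n_linked_features)] <= n_strains - 3)) break
  }
  linked_gf <- gf[seq_len(n_linked_features)]
  n_features <- n_linked_features + n_null_features
  fid <- sprintf("F%04d", seq_len(n_features))
  samp <- expand.grid(replicate = seq_len(n_replicates), strain = strains,
                      stringsAsFactors = FALSE)
  samp$sample_id <- sprintf("%s_r%d", samp$strain, samp$replicate)
  samp$role <- "sample"
  samp$group <- samp$strain
  ctrl <- data.frame(replicate = seq_len(n_replicates), strain = NA_character_,
                     sample_id = sprintf("sterile_r%d", seq_len(n_replicates)),
                     role = "control", group = "sterile",
                     stringsAsFactors = FALSE)
  samples <- rbind(samp, ctrl)
  base_ctrl <- 1.0   # log10 units of the sterile background
  without_level <- if (margin_ok) base_ctrl + 0.05 else base_ctrl + 0.3
  log10_vals <- matrix(NA_real_, n_features, nrow(samples))
  for (i in seq_len(nrow(samples))) {
    lev <- rep(without_level, n_features)
    if (samples$role[i] == "control") {
      lev <- rep(base_ctrl, n_features)
      log10_vals[, i] <- lev + stats::rnorm(n_features, 0, noise_sd / 2)
      next
    }
    for (k in seq_len(n_linked_features)) {
      if (presence[linked_gf[k], samples$strain[i]]) {
        lev[k] <- without_level + delta_log10
      }
    }
    log10_vals[, i] <- lev + stats::rnorm(n_features, 0, noise_sd)
  }
  features <- data.frame(feature_id = fid,
                         mz = round(stats::runif(n_features, 80, 900), 4),
                         rt = round(stats::runif(n_features, 0.5, 14), 3),
                         mode = "positive", adduct = "[M+H]+",
                         annotation = NA_character_, msi_level = NA_integer_,
                         stringsAsFactors = FALSE)
  tab <- feature_table(10^log10_vals, features,
                       samples[, c("sample_id", "role", "group", "replicate",
                                   "strain")])
  truth <- if (n_linked_features > 0) {
    data.frame(feature_id = fid[seq_len(n_linked_features)],
               gene_family = linked_gf,
               pattern = apply(presence[linked_gf, , drop = FALSE], 1,
                               function(r) paste(as.integer(r), collapse = "")),
               delta_log10 = delta_log10, stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = character(), gene_family = character(),
               pattern = character(), delta_log10 = numeric(),
               stringsAsFactors = FALSE)
  }
  list(presence = presence, table = tab, truth = truth)
}

#' Build the packaged toy metabolic network
#'
#' A 10-reaction anaerobic toy network capturing the energy logic of
#' arginine fermentation coupled to acetate assimilation: an arginine
#' deiminase chain (deiminase, catabolic ornithine transcarbamylase,
#' carbamate kinase) yields one ATP per arginine and secretes ornithine;
#' acetate is activated to an acetyl precursor at the cost of one ATP; and
#' biomass formation consumes one precursor plus `atp_per_biomass - 1`
#' further ATP. The FBA optimum has the closed form
#' `mu(A, C) = min(A / atp_per_biomass, C)` for arginine and acetate uptake
#' bounds A and C. The "agmatine" variant adds an agmatine deiminase route
#' (agmatine -> N-carbamoylputrescine -> putrescine + carbamoyl phosphate)
#' providing ATP independently of arginine, giving
#' `mu = min((A + G) / atp_per_biomass, C)`.
#'
#' @param arg_uptake arginine uptake bound A (default 10 mmol/gDW/h).
#' @param ac_uptake acetate uptake bound C (default 1 mmol/gDW/h).
#' @param variant "arginine" (base network) or "agmatine" (adds the
#'   alternative ATP pathway).
#' @param agm_uptake agmatine uptake bound G for the variant (default 0).
#' @param atp_per_biomass total ATP demand per unit biomass including
#'   precursor activation (default 10).
#' @return list with `model` (a [metabolic_model()]), `closed_form`
#'   (function of the uptake bounds returning the optimal growth rate), and
#'   `atp_per_biomass`.
#' @export
gen_toy_model <- function(arg_uptake = 10, ac_uptake = 1,
                          variant = c("arginine", "agmatine"),
                          agm_uptake = 0, atp_per_biomass = 10) {
  variant <- match.arg(variant)
  b_atp <- atp_per_biomass - 1  # ATP consumed directly by biomass
  mets <- c("arg_c", "citr_c", "orn_c", "cbp_c", "nh3_c", "co2_c",
            "ac_c", "accoa_c", "atp_c", "adp_c")
  rxn <- list(
    EX_arg = list(st = c(arg_c = -1), lb = -arg_uptake, ub = 1000, gpr = ""),
    EX_ac = list(st = c(ac_c = -1), lb = -ac_uptake, ub = 1000, gpr = ""),
    EX_orn = list(st = c(orn_c = -1), lb = 0, ub = 1000, gpr = ""),
    EX_nh3 = list(st = c(nh3_c = -1), lb = 0, ub = 1000, gpr = ""),
    EX_co2 = list(st = c(co2_c = -1), lb = 0, ub = 1000, gpr = ""),
    ADI = list(st = c(arg_c = -1, citr_c = 1, nh3_c = 1), lb = 0, ub = 1000,
               gpr = "adiA"),
    OTC = list(st = c(citr_c = -1, orn_c = 1, cbp_c = 1), lb = 0, ub = 1000,
               gpr = "arcB"),
    CK = list(st = c(cbp_c = -1, adp_c = -1, atp_c = 1, co2_c = 1, nh3_c = 1),
              lb = 0, ub = 1000, gpr = "arcC"),
    ACS = list(st = c(ac_c = -1, atp_c = -1, accoa_c = 1, adp_c = 1),
               lb = 0, ub = 1000, gpr = "ackA and pta"),
    BIOMASS = list(st = stats::setNames(c(-1, -b_atp, b_atp),
                                        c("accoa_c", "atp_c", "adp_c")),
                   lb = 0, ub = 1000, gpr = ""))
  if (variant == "agmatine") {
    mets <- c(mets, "agm_c", "ncp_c", "put_c")
    rxn <- c(rxn, list(
      EX_agm = list(st = c(agm_c = -1), lb = -agm_uptake, ub = 1000, gpr = ""),
      EX_put = list(st = c(put_c = -1), lb = 0, ub = 1000, gpr = ""),
      AGDI = list(st = c(agm_c = -1, ncp_c = 1, nh3_c = 1), lb = 0, ub = 1000,
                  gpr = "aguA"),
      PTC = list(st = c(ncp_c = -1, put_c = 1, cbp_c = 1), lb = 0, ub = 1000,
                 gpr = "aguB")))
  }
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (k in seq_along(rxn)) S[names(rxn[[k]]$st), k] <- rxn[[k]]$st
  reactions <- data.frame(
    id = names(rxn),
    lower_bound = vapply(rxn, function(r) r$lb, numeric(1)),
    upper_bound = vapply(rxn, function(r) r$ub, numeric(1)),
    gpr = vapply(rxn, function(r) r$gpr, character(1)),
    subsystem = "", stringsAsFactors = FALSE)
  model <- metabolic_model(data.frame(id = mets, stringsAsFactors = FALSE),
                           reactions, S, objective = "BIOMASS")
  closed_form <- if (variant == "agmatine") {
    function(arg = arg_uptake, ac = ac_uptake, agm = agm_uptake) {
      pmin((arg + agm) / atp_per_biomass, ac)
    }
  } else {
    function(arg = arg_uptake, ac = ac_uptake) pmin(arg / atp_per_biomass, ac)
  }
  list(model = model, closed_form = closed_form,
       atp_per_biomass = atp_per_biomass, variant = variant)
}

#' Generate noisy isotopologue peak areas from true MIDs
#'
#' Forward-convolves each true mass-isotopologue distribution with the
#' carbon natural-abundance matrix, scales to a peak area, and adds
#' multiplicative Gaussian noise truncated at zero. Noise is proportional to
#' each isotopologue's expected area (the usual behavior of integrated LC-MS
#' peak areas), so `noise_sd = 0.02` means a standard deviation of 2% of the
#' M+0 area on the M+0 channel.
#'
#' @param true_mids named list of MID fraction vectors (length n_carbons+1).
#' @param scale total peak area per compound (default 1e5), recycled.
#' @param noise_sd per-channel relative noise standard deviation
#'   (default 0.01).
#' @param p13 natural 13C abundance (default 0.0107).
#' @param seed integer seed.
#' @return list with `areas` (named list of observed area vectors) and
#'   `truth` (the input MIDs).
#' @export
gen_isotopologues <- function(true_mids, scale = 1e5, noise_sd = 0.01,
                              p13 = 0.0107, seed = 1) {
  set.seed(seed)
  scale <- rep_len(scale, length(true_mids))
  areas <- lapply(seq_along(true_mids), function(i) {
    mid <- true_mids[[i]]
    if (abs(sum(mid) - 1) > 1e-6 || any(mid < 0)) stop("invalid MID")
    n <- length(mid) - 1
    M <- natural_abundance_matrix(n, p13)
    mu <- scale[i] * as.numeric(M %*% mid)
    pmax(mu + stats::rnorm(length(mu), 0, noise_sd * mu), 0)
  })
  names(areas) <- names(true_mids)
  list(areas = areas, truth = true_mids)
}

#' Generate noisy logistic growth curves with blank wells
#'
#' @param params data.frame with columns well, condition, replicate, K, N0,
#'   r (logistic parameters per well).
#' @param times sampling times in hours (default every 30 min over 48 h).
#' @param noise_sd Gaussian OD noise sd (default 0.01).
#' @param blank_od constant blank background OD (default 0.09).
#' @param n_blanks blank wells (default 3).
#' @param seed integer seed.
#' @return list with `raw` (data.frame time + well columns, including
#'   blanks), `blank_wells`, and `truth` (the parameter table).
#' @export
gen_growth_curves <- function(params, times = seq(0, 48, by = 0.5),
                              noise_sd = 0.01, blank_od = 0.09, n_blanks = 3,
                              seed = 1) {
  set.seed(seed)
  raw <- data.frame(time = times)
  for (i in seq_len(nrow(params))) {
    od <- .logistic(times, params$K[i], params$N0[i], params$r[i])
    raw[[params$well[i]]] <- od + blank_od + stats::rnorm(length(times), 0, noise_sd)
  }
  blank_wells <- sprintf("blank%d", seq_len(n_blanks))
  for (w in blank_wells) {
    raw[[w]] <- blank_od + stats::rnorm(length(times), 0, noise_sd)
  }
  list(raw = raw, blank_wells = blank_wells, truth = params)
}
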
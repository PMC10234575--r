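#' Define a growth-media condition for simulation
#'
#' Quantitative compound concentrations are converted to maximum uptake rates
#' with `U = C / (biomass_density * duration)`, which takes mM to
#' mmol/gDW/h. Qualitatively present compounds (detected in sterile media but
#' not quantified) receive a fixed default uptake bound.
#'
#' @param quantitative named numeric vector, exchange reaction id ->
#'   concentration in mM.
#' @param qualitative character vector of exchange reaction ids present at
#'   unquantified (trace) levels.
#' @param biomass_density culture biomass density in gDW/L.
#' @param duration exponential-phase duration in hours.
#' @param cell_dry_weight single-cell dry weight in grams (default 3.3e-13);
#'   recorded for conversions from cell counts.
#' @return object of class `media_definition`.
#' @export
media_definition <- function(quantitative = numeric(), qualitative = character(),
                             biomass_density, duration,
                             cell_dry_weight = 3.3e-13) {
  if (biomass_density <= 0) stop("biomass_density must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (any(quantitative <= 0)) stop("concentrations must be positive")
  structure(list(quantitative = quantitative,
                 qualitative = unique(as.character(qualitative)),
                 biomass_density = biomass_density, duration = duration,
                 cell_dry_weight = cell_dry_weight),
            class = "media_definition")
}

#' Read a media definition from TSV
#'
#' Tab-separated columns: `compound_id`, `exchange_id`, `concentration_mM`
#' (empty/NA for qualitative compounds), `qualitative` (0/1).
#'
#' @param path TSV path.
#' @param biomass_density,duration,cell_dry_weight passed to
#'   [media_definition()].
#' @return a `media_definition`.
#' @export
read_media <- function(path, biomass_density, duration,
                       cell_dry_weight = 3.3e-13) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  qual <- x$exchange_id[x$qualitative == 1]
  quant <- x[x$qualitative != 1, , drop = FALSE]
  media_definition(stats::setNames(quant$concentration_mM, quant$exchange_id),
                   qual, biomass_density, duration, cell_dry_weight)
}

#' Apply a media condition to a model's exchange bounds
#'
#' Sets every exchange reaction's lower bound (uptake is negative flux):
#' quantitative compounds get `-C / (biomass_density * duration)`,
#' qualitative compounds get `-qualitative_bound`, and all other exchanges
#' are closed to uptake (lower bound 0). Secretion (upper bounds) is left
#' unconstrained. Media entries without a matching exchange reaction are
#' skipped with a warning.
#'
#' @param model a [metabolic_model()].
#' @param media a [media_definition()].
#' @param qualitative_bound uptake bound for qualitative compounds in
#'   mmol/gDW/h (default 1).
#' @return the bounded model; skipped media entries are recorded in
#'   `attr(, "skipped")`.
#' @export
media_to_bounds <- function(model, media, qualitative_bound = 1.0) {
  stopifnot(inherits(model, "metabolic_model"), inherits(media, "media_definition"))
  ex <- which(model$reactions$is_exchange)
  model$reactions$lower_bound[ex] <- 0
  uptake <- media$quantitative / (media$biomass_density * media$duration)
  listed <- c(names(uptake), media$qualitative)
  known <- listed %in% model$reactions$id[ex]
  if (any(!known)) {
    warning("media compounds without exchange reactions skipped: ",
            paste(listed[!known], collapse = ", "))
  }
  for (nm in names(uptake)) {
    k <- match(nm, model$reactions$id)
    if (!is.na(k) && model$reactions$is_exchange[k]) {
      model$reactions$lower_bound[k] <- -uptake[[nm]]
    }
  }
  for (nm in media$qualitative) {
    k <- match(nm, model$reactions$id)
    if (!is.na(k) && model$reactions$is_exchange[k]) {
      model$reactions$lower_bound[k] <- -qualitative_bound
    }
  }
  attr(model, "skipped") <- listed[!known]
  model
}

.model_lp <- function(model) {
  list(A = model$S, b = rep(0, nrow(model$S)),
       lb = model$reactions$lower_bound, ub = model$reactions$upper_bound,
       obj_idx = match(model$objective, model$reactions$id))
}

.flux_solution <- function(model, status, fluxes) {
  mu <- if (status == "optimal") fluxes[[model$objective]] else NA_real_
  structure(list(status = status, mu = mu, fluxes = fluxes,
                 objective = model$objective),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("flux_solution: status %s, mu = %s 1/h (%d reactions)\n",
              x$status, format(x$mu, digits = 6), length(x$fluxes)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the objective (biomass) flux subject to steady-state mass
#' balance `S v = 0` and the reaction bounds. Growth is declared when the
#' optimum exceeds 1e-6 per hour.
#'
#' @param model a [metabolic_model()].
#' @return a `flux_solution` with `status`, `mu` (growth rate, 1/h), and the
#'   flux vector (mmol/gDW/h; the biomass flux in 1/h).
#' @export
fba <- function(model) {
  lp <- .model_lp(model)
  obj <- rep(0, ncol(model$S)); obj[lp$obj_idx] <- 1
  sol <- simplex_lp(obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(.flux_solution(model, "infeasible",
                          stats::setNames(rep(NA_real_, ncol(model$S)),
                                          model$reactions$id)))
  }
  .flux_solution(model, "optimal", stats::setNames(sol$x, model$reactions$id))
}

#' Parsimonious flux balance analysis
#'
#' Fixes the objective at its FBA optimum and minimizes the total absolute
#' flux via the usual flux-splitting LP (v = p - n with p, n >= 0). Futile
#' cycles carry zero flux in the parsimonious solution. A reaction is
#' considered active when |v| > 1e-9.
#'
#' @param model a [metabolic_model()].
#' @return a `flux_solution`; `attr(, "total_flux")` holds the minimized sum
#'   of absolute fluxes.
#' @export
pfba <- function(model) {
  base <- fba(model)
  if (base$status != "optimal") return(base)
  n <- ncol(model$S)
  oi <- match(model$objective, model$reactions$id)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  lb[oi] <- base$mu; ub[oi] <- base$mu
  # split v = p - n with p, n >= 0. For lb <= 0 <= ub the split bounds
  # p in [0, ub], n in [0, -lb] imply v in [lb, ub]. Reactions with a
  # forced sign (lb > 0 or ub < 0) get the exact one-sided encoding:
  # the opposing split variable is fixed at zero.
  plb <- pmax(lb, 0); pub <- pmax(ub, 0)
  nlb <- pmax(-ub, 0); nub <- pmax(-lb, 0)
  A <- cbind(model$S, -model$S)
  b <- rep(0, nrow(model$S))
  obj <- rep(1, 2 * n)
  sol <- simplex_lp(obj, A, b, c(plb, nlb), c(pub, nub), maximize = FALSE)
  if (sol$status != "optimal") {
    return(.flux_solution(model, "infeasible",
                          stats::setNames(rep(NA_real_, n), model$reactions$id)))
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  out <- .flux_solution(model, "optimal", stats::setNames(v, model$reactions$id))
  attr(out, "total_flux") <- sum(abs(v))
  out
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the
#' steady-state constraints, bounds, and the requirement that the objective
#' attain at least `fraction` of its FBA optimum (99% in the reference
#' setting).
#'
#' @param model a [metabolic_model()].
#' @param fraction fraction of the optimal growth rate to retain
#'   (default 0.99).
#' @param reactions optional subset of reaction ids (default: all).
#' @return data.frame with reaction, min_flux, max_flux,
#'   fraction_of_optimum.
#' @export
fva <- function(model, fraction = 0.99, reactions = NULL) {
  base <- fba(model)
  if (base$status != "optimal") stop("FVA requires a feasible model")
  if (base$mu <= 1e-6) stop("FVA requires a growing model (mu > 1e-6)")
  oi <- match(model$objective, model$reactions$id)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  lb[oi] <- max(lb[oi], fraction * base$mu)
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- match(reactions, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction id(s)")
  res <- vapply(idx, function(k) {
    obj <- rep(0, ncol(model$S)); obj[k] <- 1
    lo <- simplex_lp(obj, model$S, rep(0, nrow(model$S)), lb, ub, maximize = FALSE)
    hi <- simplex_lp(obj, model$S, rep(0, nrow(model$S)), lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA LP infeasible at fraction ", fraction)
    }
    c(lo$objval, hi$objval)
  }, numeric(2))
  data.frame(reaction = reactions, min_flux = res[1, ], max_flux = res[2, ],
             fraction_of_optimum = fraction, stringsAsFactors = FALSE)
}

#' Leave-one-out media sweep
#'
#' For each listed compound, closes its uptake (exchange lower bound 0) while
#' leaving the rest of the media in place, and records the FBA growth rate.
#' Per-condition solver failures are recorded, not fatal.
#'
#' @param model a [metabolic_model()].
#' @param media a [media_definition()].
#' @param compounds exchange reaction ids to remove one at a time (default:
#'   all compounds in the media).
#' @param qualitative_bound passed to [media_to_bounds()].
#' @return data.frame with compound, mu, grows (mu > 1e-6), status.
#' @export
simulate_leave_one_out <- function(model, media, compounds = NULL,
                                   qualitative_bound = 1.0) {
  all_cpds <- c(names(media$quantitative), media$qualitative)
  if (is.null(compounds)) compounds <- all_cpds
  if (!all(compounds %in% all_cpds)) {
    stop("compounds to remove must be part of the media")
  }
  res <- lapply(compounds, function(cpd) {
    m2 <- media
    m2$quantitative <- m2$quantitative[names(m2$quantitative) != cpd]
    m2$qualitative <- setdiff(m2$qualitative, cpd)
    bounded <- suppressWarnings(media_to_bounds(model, m2, qualitative_bound))
    sol <- tryCatch(fba(bounded), error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal") {
      data.frame(compound = cpd, mu = 0, grows = FALSE,
                 status = if (is.null(sol)) "error" else sol$status,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(compound = cpd, mu = sol$mu, grows = sol$mu > 1e-6,
                 status = "optimal", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Confusion summary of predicted vs observed growth
#'
#' Builds the 2x2 growth/no-growth table over shared conditions and reports
#' the Matthews correlation coefficient (0 by convention when a marginal is
#' empty) together with a two-sided Fisher exact test (conditional-MLE odds
#' ratio).
#'
#' @param predicted,observed named logical vectors (condition -> grows).
#' @return list with tp, fp, fn, tn, mcc, odds_ratio, fisher_p.
#' @export
growth_confusion <- function(predicted, observed) {
  shared <- intersect(names(predicted), names(observed))
  if (length(shared) < 2) stop("need at least 2 shared conditions")
  p <- predicted[shared]; o <- observed[shared]
  tp <- sum(p & o); fp <- sum(p & !o); fn <- sum(!p & o); tn <- sum(!p & !o)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  ft <- stats::fisher.test(matrix(c(tp, fn, fp, tn), 2, 2))
  list(tp = tp, fp = fp, fn = fn, tn = tn, mcc = mcc,
       odds_ratio = unname(ft$estimate), fisher_p = ft$p.value)
}

#' Single-reaction knockout screen
#'
#' Sets both bounds of each reaction to zero in turn and recomputes the FBA
#' optimum. Categories: essential (mu <= 1e-6), reduced
#' (1e-6 < mu < mu_wt - 1e-6), neutral otherwise. The `below_70pct` flag
#' marks knockouts reducing growth below 70% of wild type, the criterion
#' used to relate model essentiality to gene conservation.
#'
#' @param model a [metabolic_model()].
#' @param reactions optional subset of reaction ids.
#' @return data.frame with reaction, mu_ko, category, below_70pct.
#' @export
single_reaction_knockouts <- function(model, reactions = NULL) {
  wt <- fba(model)
  if (wt$status != "optimal" || wt$mu <= 1e-6) {
    stop("knockout screen requires a growing wild-type model")
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- match(reactions, model$reactions$id)
  res <- lapply(seq_along(idx), function(q) {
    k <- idx[q]
    m2 <- model
    m2$reactions$lower_bound[k] <- 0
    m2$reactions$upper_bound[k] <- 0
    sol <- fba(m2)
    mu <- if (sol$status == "optimal") sol$mu else 0
    category <- if (mu <= 1e-6) "essential" else if (mu < wt$mu - 1e-6) "reduced" else "neutral"
    data.frame(reaction = reactions[q], mu_ko = mu, category = category,
               below_70pct = mu < 0.7 * wt$mu, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "mu_wt") <- wt$mu
  out
}

#' Concordance of FVA exchange ranges with differential metabolomics calls
#'
#' A metabolite is compatible with the model when: if its exchange can only
#' run in the uptake direction (max flux <= 0) the metabolite was observed
#' decreased; and if it was observed increased, secretion must be possible
#' (max flux > 0).
#'
#' @param fva_ranges data.frame from [fva()] restricted to exchange
#'   reactions.
#' @param differential_calls named character vector metabolite ->
#'   {"increased", "decreased", "unchanged"}.
#' @param exchange_map named character vector metabolite -> exchange reaction
#'   id.
#' @return list with `verdicts` (data.frame), `fraction_compatible`, and
#'   `unmapped` (metabolites without an exchange mapping).
#' @export
fva_exchange_concordance <- function(fva_ranges, differential_calls,
                                     exchange_map) {
  mets <- names(differential_calls)
  ex <- exchange_map[mets]
  unmapped <- mets[is.na(ex) | !(ex %in% fva_ranges$reaction)]
  keep <- setdiff(mets, unmapped)
  verdicts <- do.call(rbind, lapply(keep, function(m) {
    rng <- fva_ranges[fva_ranges$reaction == exchange_map[[m]], ]
    call <- differential_calls[[m]]
    compatible <- TRUE
    if (rng$max_flux <= 0 && call != "decreased") compatible <- FALSE
    if (call == "increased" && rng$max_flux <= 0) compatible <- FALSE
    data.frame(metabolite = m, exchange = rng$reaction, min_flux = rng$min_flux,
               max_flux = rng$max_flux, call = call, compatible = compatible,
               stringsAsFactors = FALSE)
  }))
  list(verdicts = verdicts,
       fraction_compatible = if (length(keep)) mean(verdicts$compatible) else NA_real_,
       unmapped = unmapped)
}

#' Concordance of parsimonious fluxes with gene expression
#'
#' Enumerates gene-reaction pairs from the GPR rules (a gene linked to
#' several reactions is counted once per pairing), marks a pair active when
#' the linked reaction carries |flux| > 1e-9, and compares active vs inactive
#' pairs on membership in the top half of the metabolic-gene expression
#' distribution (two-sided Fisher exact test) plus a Spearman correlation of
#' expression against |flux|.
#'
#' @param solution a `flux_solution` (typically from [pfba()]).
#' @param expression named numeric vector gene -> expression level.
#' @param model the [metabolic_model()] the solution came from.
#' @return list with active_top_half_frac, inactive_top_half_frac, ratio,
#'   enrichment_p, spearman_rho, n_pairs.
#' @export
flux_expression_concordance <- function(solution, expression, model) {
  pairs <- do.call(rbind, lapply(seq_len(nrow(model$reactions)), function(k) {
    gs <- gpr_genes(model$reactions$gpr[k])
    gs <- gs[gs %in% names(expression)]
    if (!length(gs)) return(NULL)
    data.frame(gene = gs, reaction = model$reactions$id[k],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) < 10) {
    stop("need at least 10 mappable gene-reaction pairs")
  }
  pairs$flux <- abs(solution$fluxes[pairs$reaction])
  pairs$active <- pairs$flux > 1e-9
  pairs$expr <- expression[pairs$gene]
  med <- stats::median(expression[unique(pairs$gene)])
  pairs$top_half <- pairs$expr > med
  a_frac <- mean(pairs$top_half[pairs$active])
  i_frac <- mean(pairs$top_half[!pairs$active])
  tab <- table(factor(pairs$active, c(TRUE, FALSE)),
               factor(pairs$top_half, c(TRUE, FALSE)))
  pval <- if (any(rowSums(tab) == 0)) NA_real_ else stats::fisher.test(tab)$p.value
  rho <- suppressWarnings(stats::cor(pairs$expr, pairs$flux, method = "spearman"))
  ratio <- if (!is.na(i_frac) && i_frac > 0) a_frac / i_frac else
    if (all(pairs$active)) 1 else Inf
  list(active_top_half_frac = a_frac, inactive_top_half_frac = i_frac,
       ratio = ratio, enrichment_p = pval, spearman_rho = rho,
       n_pairs = nrow(pairs))
}

#' Relate knockout severity to gene conservation across strains
#'
#' Partitions model genes by whether any linked reaction's knockout reduces
#' growth below 70% of wild type, then compares strain-presence fractions
#' between the partitions (Wilcoxon rank-sum) and core-genome membership
#' (two-sided Fisher exact test).
#'
#' @param knockouts data.frame from [single_reaction_knockouts()].
#' @param model the [metabolic_model()].
#' @param gene_presence_fraction named numeric vector gene -> fraction of
#'   strain genomes containing it.
#' @param core_membership named logical vector gene -> member of the core
#'   genome (present in all strains).
#' @return list with wilcoxon_p, fisher_or, fisher_p, n_growth_genes,
#'   n_other_genes; odds ratios from degenerate tables are reported as
#'   infinite with a note.
#' @export
knockout_conservation_test <- function(knockouts, model,
                                       gene_presence_fraction,
                                       core_membership) {
  sev <- stats::setNames(knockouts$below_70pct, knockouts$reaction)
  gene_hit <- vapply(model$genes, function(g) {
    rxns <- model$reactions$id[vapply(model$reactions$gpr,
                                      function(gp) g %in% gpr_genes(gp),
                                      logical(1))]
    any(sev[rxns], na.rm = TRUE)
  }, logical(1))
  genes <- intersect(names(gene_hit), names(gene_presence_fraction))
  if (!length(genes)) stop("gene sets do not overlap the model genes")
  hit <- gene_hit[genes]
  if (!any(hit) || all(hit)) {
    stop("one knockout partition is empty; conservation test undefined")
  }
  wp <- suppressWarnings(stats::wilcox.test(gene_presence_fraction[genes][hit],
                                            gene_presence_fraction[genes][!hit]))$p.value
  if (is.nan(wp)) wp <- 1  # fully tied distributions
  core <- core_membership[genes]
  tab <- table(factor(hit, c(TRUE, FALSE)), factor(core, c(TRUE, FALSE)))
  note <- NULL
  if (any(tab == 0)) {
    ft <- stats::fisher.test(tab)
    or <- unname(ft$estimate); fp <- ft$p.value
    if (!is.finite(or) || or == 0) note <- "degenerate 2x2 table; odds ratio at boundary"
  } else {
    ft <- stats::fisher.test(tab)
    or <- unname(ft$estimate); fp <- ft$p.value
  }
  list(wilcoxon_p = wp, fisher_or = or, fisher_p = fp,
       n_growth_genes = sum(hit), n_other_genes = sum(!hit), note = note)
}
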
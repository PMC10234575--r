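#' Read a gene-family presence/absence matrix
#'
#' Tab-separated 0/1 matrix, gene families as rows (first column
#' `gene_family_id`), strains as columns.
#'
#' @param path TSV path.
#' @return logical matrix gene families x strains.
#' @export
read_gene_presence <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(x) != 0
  storage.mode(m) <- "logical"
  m
}

#' Enumerate distinct gene presence/absence patterns
#'
#' Groups gene families by their presence pattern across strains. Patterns
#' constant across the panel (core or universally absent families) carry no
#' association signal and are excluded from testing.
#'
#' @param presence logical matrix gene families x strains (>= 2 strains).
#' @return data.frame with pattern_id, pattern (strain presence string),
#'   n_with, gene_families (list column); `attr(, "strains")` records strain
#'   order.
#' @export
enumerate_patterns <- function(presence) {
  if (ncol(presence) < 2) stop("need at least 2 strains")
  key <- apply(presence, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(rownames(presence), key)
  variable <- names(groups)[!names(groups) %in%
                              c(strrep("0", ncol(presence)), strrep("1", ncol(presence)))]
  out <- data.frame(pattern_id = sprintf("P%03d", seq_along(variable)),
                    pattern = variable,
                    n_with = vapply(strsplit(variable, ""), function(s) sum(s == "1"), 0L),
                    stringsAsFactors = FALSE)
  out$gene_families <- groups[variable]
  attr(out, "strains") <- colnames(presence)
  out
}

.strain_values <- function(feature_table, log10_transform = TRUE) {
  s <- feature_table$samples
  keep <- which(s$role == "sample" & !is.na(s$strain))
  strains <- unique(s$strain[keep])
  x <- feature_table$intensity
  if (log10_transform && is.null(attr(feature_table, "log_base"))) {
    min_nonzero <- apply(x, 1, function(r) if (any(r > 0)) min(r[r > 0]) else 1)
    x <- log10(x + 0.25 * min_nonzero)
  }
  vals <- vapply(strains, function(st) {
    rowMeans(x[, keep[s$strain[keep] == st], drop = FALSE])
  }, numeric(nrow(x)))
  matrix(vals, nrow = nrow(x),
         dimnames = list(feature_table$features$feature_id, strains))
}

#' Test metabolite features against gene presence patterns
#'
#' Per (feature, pattern) pair: Welch's t test of per-strain log10 intensities
#' between strains carrying the pattern's gene families and strains lacking
#' them. Patterns with fewer than 2 strains on either side are skipped with a
#' warning. All tests are adjusted jointly in one Benjamini-Hochberg family.
#'
#' @param patterns data.frame from [enumerate_patterns()].
#' @param feature_table a [feature_table()] whose samples carry a `strain`
#'   column matching the pattern strains; per-strain values are replicate
#'   means of log10 intensities (tables already log-transformed are used
#'   as-is).
#' @param alpha_adj adjusted-p significance threshold (default 1e-4).
#' @return data.frame with feature_id, pattern_id, delta_mean, t_stat, p,
#'   p_adj, significant.
#' @export
test_associations <- function(patterns, feature_table, alpha_adj = 1e-4) {
  vals <- .strain_values(feature_table)
  strains <- attr(patterns, "strains")
  miss <- setdiff(strains, colnames(vals))
  if (length(miss)) stop("strains missing from feature table: ",
                         paste(miss, collapse = ", "))
  vals <- vals[, strains, drop = FALSE]
  res <- list()
  for (k in seq_len(nrow(patterns))) {
    with_idx <- which(strsplit(patterns$pattern[k], "")[[1]] == "1")
    without_idx <- setdiff(seq_along(strains), with_idx)
    if (length(with_idx) < 2 || length(without_idx) < 2) {
      warning("pattern ", patterns$pattern_id[k],
              " has a side with < 2 strains; skipped")
      next
    }
    x1 <- vals[, with_idx, drop = FALSE]; x2 <- vals[, without_idx, drop = FALSE]
    n1 <- length(with_idx); n2 <- length(without_idx)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                 ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
    dfree <- ifelse(se2 > 0,
                    se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
    p <- ifelse(is.finite(tt), 2 * stats::pt(-abs(tt), dfree),
                ifelse(tt == 0, 1, 0))
    res[[k]] <- data.frame(feature_id = rownames(vals),
                           pattern_id = patterns$pattern_id[k],
                           delta_mean = m1 - m2, t_stat = as.numeric(tt),
                           p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable patterns")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha_adj
  rownames(out) <- NULL
  out
}

.q_linear <- function(x, prob) as.numeric(stats::quantile(x, prob, type = 7))

#' Separability filter for gene-metabolite associations
#'
#' Keeps an association only when (a) the absolute difference in median
#' log10 values between strains with and without the gene is at least
#' `min_delta`; (b) the 10th percentile of with-gene strain values is at
#' least `margin` above the maximum sterile-control value; and (c) the 90th
#' percentile of without-gene strain values is below that same bar
#' (max control + `margin`). Percentiles use linear interpolation
#' (`quantile` type 7). Finally only the lowest-p association per feature is
#' retained. Criteria (b)/(c) as stated assume production (with-gene strains
#' higher); set `mirror_depletion = TRUE` to additionally evaluate mirrored
#' criteria for depletion-direction associations.
#'
#' @param results data.frame from [test_associations()] (typically
#'   pre-filtered to significant rows).
#' @param feature_table the same [feature_table()] used for testing; its
#'   `role == "control"` samples are the sterile controls.
#' @param patterns data.frame from [enumerate_patterns()].
#' @param min_delta minimum |median difference| in log10 units (default 0.4).
#' @param margin separation above the control maximum in log10 units
#'   (default 0.4).
#' @param mirror_depletion evaluate mirrored criteria when with-gene strains
#'   are lower (default FALSE, matching the production-direction reading).
#' @return the filtered associations, at most one row per feature, with
#'   passes_separability and the evaluated quantities attached.
#' @export
separability_filter <- function(results, feature_table, patterns,
                                min_delta = 0.4, margin = 0.4,
                                mirror_depletion = FALSE) {
  s <- feature_table$samples
  ctrl_idx <- which(s$role == "control")
  if (!length(ctrl_idx)) stop("no sterile control samples in feature table")
  x <- feature_table$intensity
  if (is.null(attr(feature_table, "log_base"))) {
    min_nonzero <- apply(x, 1, function(r) if (any(r > 0)) min(r[r > 0]) else 1)
    x <- log10(x + 0.25 * min_nonzero)
  }
  ctrl_max <- apply(x[, ctrl_idx, drop = FALSE], 1, max)
  names(ctrl_max) <- feature_table$features$feature_id
  vals <- .strain_values(feature_table)
  strains <- attr(patterns, "strains")
  vals <- vals[, strains, drop = FALSE]

  if (nrow(results) == 0) {
    out <- cbind(results,
                 data.frame(delta_median = numeric(), q10_with = numeric(),
                            q90_without = numeric(), control_max = numeric(),
                            passes_separability = logical()))
    return(out)
  }
  rows <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    pat <- patterns$pattern[match(r$pattern_id, patterns$pattern_id)]
    with_idx <- which(strsplit(pat, "")[[1]] == "1")
    v_with <- vals[r$feature_id, with_idx]
    v_without <- vals[r$feature_id, -with_idx]
    bar <- ctrl_max[[r$feature_id]] + margin
    med_w <- stats::median(v_with); med_wo <- stats::median(v_without)
    pass_a <- abs(med_w - med_wo) >= min_delta
    pass_bc <- .q_linear(v_with, 0.10) >= bar && .q_linear(v_without, 0.90) < bar
    if (!pass_bc && mirror_depletion) {
      pass_bc <- .q_linear(v_with, 0.90) <= ctrl_max[[r$feature_id]] - margin &&
        .q_linear(v_without, 0.10) > ctrl_max[[r$feature_id]] - margin
    }
    cbind(r, data.frame(delta_median = med_w - med_wo,
                        q10_with = .q_linear(v_with, 0.10),
                        q90_without = .q_linear(v_without, 0.90),
                        control_max = ctrl_max[[r$feature_id]],
                        passes_separability = pass_a && pass_bc))
  })
  out <- do.call(rbind, rows)
  out <- out[out$passes_separability, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(out$feature_id, out$p), , drop = FALSE]
    out <- out[!duplicated(out$feature_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric pathway enrichment of a gene set
#'
#' One-sided hypergeometric (over-representation) test per annotation term,
#' Benjamini-Hochberg adjusted. Terms absent from the annotation universe are
#' not tested.
#'
#' @param gene_set character vector of hit genes.
#' @param annotations named list term -> character vector of member genes
#'   (the universe is the union of all members).
#' @param p_cutoff adjusted-p threshold for reporting enrichment
#'   (default 0.1).
#' @return data.frame with term, n_hit, n_term, n_universe, p, p_adj,
#'   enriched; empty for an empty gene set.
#' @export
pathway_enrichment <- function(gene_set, annotations, p_cutoff = 0.1) {
  universe <- unique(unlist(annotations))
  gene_set <- intersect(unique(gene_set), universe)
  if (!length(gene_set)) {
    return(data.frame(term = character(), n_hit = integer(), n_term = integer(),
                      n_universe = integer(), p = numeric(), p_adj = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  }
  N <- length(universe); K <- length(gene_set)
  res <- do.call(rbind, lapply(names(annotations), function(term) {
    members <- intersect(annotations[[term]], universe)
    k <- length(intersect(gene_set, members))
    p <- stats::phyper(k - 1, length(members), N - length(members), K,
                       lower.tail = FALSE)
    data.frame(term = term, n_hit = k, n_term = length(members),
               n_universe = N, p = p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$p_adj < p_cutoff
  res[order(res$p), , drop = FALSE]
}
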
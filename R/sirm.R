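#' Natural-abundance convolution matrix for carbon isotopologues
#'
#' Column i (0-based: i tracer-labeled carbons) holds the probability of
#' observing isotopologue M+j given that the remaining `n_carbons - i`
#' carbons each carry a 13C atom independently with probability `p13`:
#' a Binomial(n_carbons - i, p13) mass function shifted by i. Only carbon
#' isotopes are modeled (the tracer of interest is 13C).
#'
#' @param n_carbons number of carbon atoms (>= 1).
#' @param p13 natural 13C abundance (default 0.0107).
#' @return (n_carbons + 1) x (n_carbons + 1) matrix; rows index observed
#'   M+0..M+n, columns index true labeled carbons 0..n.
#' @export
natural_abundance_matrix <- function(n_carbons, p13 = 0.0107) {
  if (n_carbons < 1) stop("n_carbons must be >= 1")
  if (p13 < 0 || p13 >= 1) stop("p13 must lie in [0, 1)")
  n <- n_carbons
  M <- matrix(0, n + 1, n + 1)
  for (i in 0:n) {
    j <- i:n
    M[j + 1, i + 1] <- stats::dbinom(j - i, n - i, p13)
  }
  dimnames(M) <- list(paste0("M+", 0:n), paste0("labeled", 0:n))
  M
}

#' Correct an observed isotopologue vector for natural abundance
#'
#' Solves `matrix %*% x = observed/sum(observed)` under `x >= 0` by
#' non-negative least squares (Lawson-Hanson) and renormalizes x to sum to 1.
#' NNLS is preferred over direct inversion because at low signal the
#' correction would otherwise produce small negative fractions.
#'
#' @param observed non-negative peak areas for M+0..M+n (not all zero).
#' @param matrix convolution matrix from [natural_abundance_matrix()].
#' @param max_resid maximum tolerated NNLS residual norm relative to the
#'   normalized observation (default 0.5) before the fit is declared
#'   degenerate.
#' @return corrected mass-isotopologue distribution (fractions summing to 1).
#' @export
correct_mid <- function(observed, matrix, max_resid = 0.5) {
  if (length(observed) != nrow(matrix)) {
    stop("observed vector length (", length(observed),
         ") does not match matrix dimension (", nrow(matrix), ")")
  }
  if (any(observed < 0)) stop("observed areas must be non-negative")
  tot <- sum(observed)
  if (tot == 0) stop("observed areas are all zero")
  y <- observed / tot
  fit <- pracma::lsqnonneg(matrix, y)
  x <- fit$x
  resid <- sqrt(sum((matrix %*% x - y)^2))
  if (sum(x) <= 0 || resid > max_resid) {
    stop("degenerate natural-abundance correction (residual norm ",
         format(resid, digits = 4), ")")
  }
  x / sum(x)
}

#' Fractional isotopic enrichment of a MID
#'
#' The combined enrichment across all labeled isotopologues: 1 minus the M+0
#' fraction. Invariant to uniform scaling of the underlying peak areas.
#'
#' @param mid mass-isotopologue distribution (fractions summing to 1).
#' @return enrichment in \[0, 1\].
#' @export
mid_enrichment <- function(mid) {
  if (any(mid < -1e-9) || abs(sum(mid) - 1) > 1e-6) {
    stop("mid must be a fraction vector summing to 1")
  }
  1 - mid[1]
}

#' Filter presets for calling labeled compounds
#'
#' `intracellular`: labeled MID > 0.15 and labeled-isotopologue peak area of
#' at least 1e4. `extracellular`: labeled MID > 0.5 and labeled area of at
#' least 5e4. `methods-3pct`: the bare 3% combined-enrichment threshold with
#' no area requirement.
#' @format named list of parameter lists.
#' @export
sirm_presets <- list(
  "intracellular" = list(min_enrich = 0.03, min_labeled_area = 1e4, min_labeled_frac = 0.15),
  "extracellular" = list(min_enrich = 0.03, min_labeled_area = 5e4, min_labeled_frac = 0.5),
  "methods-3pct" = list(min_enrich = 0.03, min_labeled_area = 0, min_labeled_frac = NULL)
)

#' Classify a compound as isotopically labeled
#'
#' A compound is called labeled when (i) its combined enrichment is at least
#' `min_enrich` (default 3%, guarding against residual natural-abundance
#' uncertainty at low signal), (ii) the summed peak area of labeled
#' isotopologues reaches `min_labeled_area`, and (iii), when set, the labeled
#' MID fraction reaches `min_labeled_frac`. Figure-style filter presets are
#' available via `preset` (see [sirm_presets]).
#'
#' @param mid corrected MID from [correct_mid()].
#' @param areas raw isotopologue peak areas (same compound, same length).
#' @param min_enrich minimum combined enrichment (default 0.03).
#' @param min_labeled_area minimum summed labeled-isotopologue area (default 0).
#' @param min_labeled_frac optional minimum labeled MID fraction.
#' @param preset optional name in `names(sirm_presets)`; overrides the three
#'   thresholds.
#' @return list with `labeled` (logical) and `reason` (character).
#' @export
classify_labeled <- function(mid, areas, min_enrich = 0.03,
                             min_labeled_area = 0, min_labeled_frac = NULL,
                             preset = NULL) {
  if (!is.null(preset)) {
    ps <- sirm_presets[[preset]]
    if (is.null(ps)) stop("unknown preset: ", preset)
    min_enrich <- ps$min_enrich
    min_labeled_area <- ps$min_labeled_area
    min_labeled_frac <- ps$min_labeled_frac
  }
  if (length(mid) != length(areas)) stop("mid and areas must refer to the same compound")
  enr <- mid_enrichment(mid)
  labeled_area <- sum(areas[-1])
  labeled_frac <- sum(mid[-1])
  if (enr < min_enrich) {
    return(list(labeled = FALSE,
                reason = sprintf("enrichment %.4f below %.4f", enr, min_enrich)))
  }
  if (labeled_area < min_labeled_area) {
    return(list(labeled = FALSE,
                reason = sprintf("labeled area %.3g below %.3g", labeled_area,
                                 min_labeled_area)))
  }
  if (!is.null(min_labeled_frac) && labeled_frac < min_labeled_frac) {
    return(list(labeled = FALSE,
                reason = sprintf("labeled MID %.3f below %.3f", labeled_frac,
                                 min_labeled_frac)))
  }
  list(labeled = TRUE, reason = "passes enrichment and area thresholds")
}

#' Read an isotopologue peak-area table
#'
#' Long-format CSV with columns `compound_id`, `n_carbons`, `isotopologue`
#' (0-based index), `area`, and optional `sample`/`time_h` columns. Returns
#' one area vector (M+0..M+n) per compound (and sample when present).
#'
#' @param path CSV path.
#' @return data.frame in long format, validated and sorted.
#' @export
read_isotopologue_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "n_carbons", "isotopologue", "area")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(x$area < 0)) stop("areas must be non-negative")
  if (any(x$isotopologue > x$n_carbons)) {
    stop("isotopologue index exceeds n_carbons")
  }
  x[order(x$compound_id, x$isotopologue), , drop = FALSE]
}
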
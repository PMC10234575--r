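#' Blank-normalize plate-reader growth curves
#'
#' Subtracts, at each time point, the mean reading of the blank control wells
#' from every non-blank well. Values are not clipped at zero by default (a
#' slightly negative OD after background subtraction is ordinary noise).
#'
#' @param raw data.frame with a `time` column (hours) and one column of raw
#'   OD600 readings per well.
#' @param blank_wells character vector of blank well column names.
#' @param clip clip negative normalized values to 0 (default FALSE).
#' @return list of `growth_curve` objects (well_id, time, od), one per
#'   non-blank well.
#' @export
blank_normalize <- function(raw, blank_wells, clip = FALSE) {
  if (!all(blank_wells %in% names(raw))) {
    stop("blank wells missing from data: ",
         paste(setdiff(blank_wells, names(raw)), collapse = ", "))
  }
  if (anyNA(raw[, blank_wells])) stop("blank wells have missing time points")
  blank_mean <- rowMeans(raw[, blank_wells, drop = FALSE])
  wells <- setdiff(names(raw), c("time", blank_wells))
  lapply(stats::setNames(wells, wells), function(w) {
    od <- raw[[w]] - blank_mean
    if (clip) od <- pmax(od, 0)
    growth_curve(w, raw$time, od)
  })
}

#' Construct a growth curve
#'
#' @param well_id well identifier.
#' @param time time points in hours, strictly increasing.
#' @param od background-normalized OD600 readings.
#' @param condition,replicate optional labels.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(well_id, time, od, condition = NA_character_,
                         replicate = NA_integer_) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (length(time) != length(od)) stop("time and od lengths differ")
  structure(list(well_id = well_id, time = as.numeric(time),
                 od = as.numeric(od), condition = condition,
                 replicate = replicate),
            class = "growth_curve")
}

.logistic <- function(t, K, N0, r) K / (1 + ((K - N0) / N0) * exp(-r * t))

#' Fit a logistic growth model to one well
#'
#' Least-squares fit of `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))` with a
#' deterministic multi-start: carrying capacity K is started from the maximum
#' OD, N0 from the first positive reading, and the rate r from the log-slope
#' of the early curve plus a fixed fallback grid. `sigma` is the residual
#' standard error `sqrt(RSS / (n - 3))`; fits with sigma > 0.1 are flagged
#' for exclusion from downstream parameter summaries. Flat or non-growing
#' wells yield a failed fit with the r = 0 convention rather than an error.
#'
#' @param curve a [growth_curve()] with at least 5 points.
#' @param sigma_max exclusion threshold on sigma (default 0.1).
#' @return object of class `logistic_fit` with K, N0, r, sigma, converged,
#'   excluded.
#' @export
fit_logistic <- function(curve, sigma_max = 0.1) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$time; y <- curve$od
  n <- length(t)
  if (n < 5) stop("need at least 5 time points to fit")
  fail <- function() {
    structure(list(well_id = curve$well_id, K = max(y, 0), N0 = max(y[1], 1e-6),
                   r = 0, sigma = NA_real_, converged = FALSE, excluded = TRUE,
                   fitted = rep(mean(y), n), curve = curve),
              class = "logistic_fit")
  }
  if (stats::sd(y) == 0 || max(y) <= 0) return(fail())

  K0 <- max(y)
  N00 <- max(y[1], max(y) * 1e-3, 1e-6)
  # log-slope start for r from the early (sub-half-maximum) phase
  early <- which(y > 0 & y < 0.5 * max(y))
  r_slope <- if (length(early) >= 2) {
    stats::coef(stats::lm(log(y[early]) ~ t[early]))[2]
  } else NA_real_
  r_starts <- unique(c(if (is.finite(r_slope) && r_slope > 0) r_slope,
                       0.05, 0.2, 0.5, 1))
  starts <- expand.grid(K = c(K0, 1.2 * K0), N0 = c(N00, N00 / 10),
                        r = r_starts)
  dat <- data.frame(t = t, y = y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ K / (1 + ((K - N0) / N0) * exp(-r * t)), data = dat,
        start = as.list(starts[i, ]),
        lower = c(K = 1e-8, N0 = 1e-10, r = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) return(fail())
  cf <- stats::coef(best$fit)
  sigma <- sqrt(best$rss / (n - 3))
  structure(list(well_id = curve$well_id, K = unname(cf["K"]),
                 N0 = unname(cf["N0"]), r = unname(cf["r"]), sigma = sigma,
                 converged = TRUE, excluded = sigma > sigma_max,
                 fitted = .logistic(t, cf["K"], cf["N0"], cf["r"]),
                 curve = curve),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit [%s]: K = %.4g, N0 = %.4g, r = %.4g 1/h, sigma = %.4g%s\n",
              x$well_id, x$K, x$N0, x$r, x$sigma,
              if (isTRUE(x$excluded)) " (excluded)" else ""))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(K = object$K, N0 = object$N0, r = object$r)
}

#' @export
predict.logistic_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) time <- object$curve$time
  .logistic(time, object$K, object$N0, object$r)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$curve$od - object$fitted
}

#' Area under the empirical growth curve
#'
#' Trapezoidal integral of OD over time (OD x hours), the model-free growth
#' summary used to test media-component effects. Additive over time
#' partitions and invariant to inserting collinear points.
#'
#' @param curve a [growth_curve()] (>= 2 points).
#' @return numeric area.
#' @export
empirical_auc <- function(curve) {
  t <- curve$time; y <- curve$od
  if (length(t) < 2) stop("need at least 2 points")
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Compare condition AUCs against a reference condition
#'
#' Two-sided Wilcoxon rank-sum tests of empirical AUC per condition against
#' the reference, BH-adjusted; significance at `p_adj < fdr_alpha`
#' (default 0.2). Conditions with fewer than 3 replicates are skipped with a
#' warning.
#'
#' @param auc_by_condition named list condition -> numeric AUC replicates.
#' @param reference name of the reference condition.
#' @param fdr_alpha adjusted-p threshold (default 0.2).
#' @return data.frame with condition, n, median_auc, delta_median, p, p_adj,
#'   significant.
#' @export
compare_conditions <- function(auc_by_condition, reference, fdr_alpha = 0.2) {
  if (!reference %in% names(auc_by_condition)) stop("reference condition absent")
  ref <- auc_by_condition[[reference]]
  if (length(ref) < 3) stop("reference needs >= 3 replicates")
  conds <- setdiff(names(auc_by_condition), reference)
  rows <- list()
  for (cn in conds) {
    x <- auc_by_condition[[cn]]
    if (length(x) < 3) {
      warning("condition ", cn, " has < 3 replicates; skipped")
      next
    }
    p <- suppressWarnings(stats::wilcox.test(x, ref, exact = TRUE)$p.value)
    rows[[cn]] <- data.frame(condition = cn, n = length(x),
                             median_auc = stats::median(x),
                             delta_median = stats::median(x) - stats::median(ref),
                             p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable conditions")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr_alpha
  rownames(out) <- NULL
  out
}

#' Harmonic-mean growth rate across replicate fits
#'
#' The convention for averaging logistic growth rates across replicate wells
#' when reporting a per-condition rate.
#'
#' @param rates positive growth rates (1/h) from included fits.
#' @return harmonic mean.
#' @export
harmonic_mean_rate <- function(rates) {
  rates <- rates[is.finite(rates) & rates > 0]
  if (!length(rates)) return(NA_real_)
  length(rates) / sum(1 / rates)
}
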
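# brute-force Benjamini-Hochberg step-up, independent of stats::p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent per-reaction LP oracle for FVA via scipy (HiGHS)
fva_oracle_scipy <- function(model, fraction = 0.99) {
  tf <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  py <- tempfile(fileext = ".py")
  jsonlite::write_json(list(S = model$S,
                            lb = model$reactions$lower_bound,
                            ub = model$reactions$upper_bound,
                            obj = match(model$objective, model$reactions$id) - 1L,
                            fraction = fraction),
                       tf, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("d = json.load(open('%s'))", tf),
    "S = np.array(d['S']); lb = np.array(d['lb']); ub = np.array(d['ub'])",
    "n = S.shape[1]; bounds = list(zip(lb, ub)); b = np.zeros(S.shape[0])",
    "c0 = np.zeros(n); c0[d['obj']] = 1.0",
    "r = linprog(-c0, A_eq=S, b_eq=b, bounds=bounds, method='highs')",
    "mu = -r.fun",
    "Aub = -c0.reshape(1, -1); bub = np.array([-d['fraction'] * mu])",
    "res = []",
    "for k in range(n):",
    "    ck = np.zeros(n); ck[k] = 1.0",
    "    lo = linprog(ck, A_eq=S, b_eq=b, A_ub=Aub, b_ub=bub, bounds=bounds, method='highs')",
    "    hi = linprog(-ck, A_eq=S, b_eq=b, A_ub=Aub, b_ub=bub, bounds=bounds, method='highs')",
    "    res.append([lo.fun, -hi.fun])",
    sprintf("json.dump({'mu': mu, 'ranges': res}, open('%s', 'w'))", out)
  ), py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  r <- jsonlite::read_json(out, simplifyVector = TRUE)
  list(mu = r$mu,
       ranges = matrix(r$ranges, ncol = 2,
                       dimnames = list(model$reactions$id, c("min", "max"))))
}

# small fully specified feature table for threshold tests
tiny_table <- function(intensity, roles, groups = NULL, features = NULL) {
  n_f <- nrow(intensity)
  n_s <- ncol(intensity)
  if (is.null(features)) {
    features <- data.frame(feature_id = sprintf("f%d", seq_len(n_f)))
  }
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(n_s)), role = roles,
                        stringsAsFactors = FALSE)
  if (!is.null(groups)) samples$group <- groups
  feature_table(intensity, features, samples)
}
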
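#' Construct an untargeted-metabolomics feature table
#'
#' A `feature_table` bundles a features x samples peak-intensity matrix with
#' per-feature metadata (m/z, retention time, ionization mode, adduct,
#' annotation, MSI confidence level) and per-sample metadata (role, group,
#' time, replicate, strain). It is the common currency of the QC, differential
#' abundance, dereplication, linking, and strain-association stages.
#'
#' @param intensity numeric matrix (features x samples), non-negative peak
#'   intensities. Row names are taken as feature ids and column names as
#'   sample ids when the metadata frames omit them.
#' @param features data.frame with at least `feature_id`; optional columns
#'   `mz` (Da), `rt` (minutes), `mode` ("positive"/"negative"), `adduct`,
#'   `annotation`, `msi_level` (1-4 or NA).
#' @param samples data.frame with at least `sample_id` and `role` (one of
#'   "sample", "blank", "pool", "control"); optional `group`, `time_h`,
#'   `replicate`, `strain`.
#' @return object of class `feature_table`.
#' @examples
#' ft <- feature_table(
#'   matrix(c(10, 0, 5, 8), 2, 2, dimnames = list(c("f1", "f2"), c("s1", "b1"))),
#'   features = data.frame(feature_id = c("f1", "f2")),
#'   samples = data.frame(sample_id = c("s1", "b1"), role = c("sample", "blank"))
#' )
#' ft
#' @export
feature_table <- function(intensity, features, samples) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(rownames(intensity))) rownames(intensity) <- features$feature_id
  if (is.null(colnames(intensity))) colnames(intensity) <- samples$sample_id
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (d in c("features", "samples")) {
    df <- get(d)
    fac <- vapply(df, is.factor, logical(1))
    df[fac] <- lapply(df[fac], as.character)
    assign(d, df)
  }
  if (is.null(features$feature_id)) stop("features metadata needs a 'feature_id' column")
  if (is.null(samples$sample_id) || is.null(samples$role)) {
    stop("sample metadata needs 'sample_id' and 'role' columns")
  }
  for (col in c("mz", "rt")) if (is.null(features[[col]])) features[[col]] <- NA_real_
  for (col in c("mode", "adduct", "annotation")) {
    if (is.null(features[[col]])) features[[col]] <- NA_character_
  }
  if (is.null(features$msi_level)) features$msi_level <- NA_integer_
  for (col in c("group", "strain")) if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  if (is.null(samples$time_h)) samples$time_h <- NA_real_
  if (is.null(samples$replicate)) samples$replicate <- NA_integer_

  if (anyDuplicated(features$feature_id)) stop("feature_id values must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample_id values must be unique")
  if (!all(samples$role %in% c("sample", "blank", "pool", "control"))) {
    stop("sample roles must be one of: sample, blank, pool, control")
  }
  bad_msi <- !is.na(features$msi_level) & !features$msi_level %in% 1:4
  if (any(bad_msi)) stop("msi_level must be 1, 2, 3, 4 or NA")
  if (nrow(intensity) != nrow(features) || ncol(intensity) != nrow(samples)) {
    stop("intensity dimensions do not match metadata")
  }
  rownames(intensity) <- features$feature_id
  colnames(intensity) <- samples$sample_id
  if (anyNA(intensity)) stop("intensities must not contain NA")
  if (any(intensity < 0)) stop("raw intensities must be non-negative")

  structure(list(intensity = intensity, features = features, samples = samples),
            class = "feature_table", log_base = NULL)
}

#' @export
print.feature_table <- function(x, ...) {
  lb <- attr(x, "log_base")
  cat(sprintf("feature_table: %d features x %d samples%s\n",
              nrow(x$intensity), ncol(x$intensity),
              if (is.null(lb)) " (raw intensities)" else sprintf(" (log%g)", lb)))
  tab <- table(x$samples$role)
  cat("  sample roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (any(!is.na(x$features$mode))) {
    cat("  modes:", paste(unique(stats::na.omit(x$features$mode)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Subset a feature table by features and/or samples
#'
#' @param x a [feature_table()].
#' @param features,samples logical/integer/character indices into features
#'   (rows) and samples (columns); `NULL` keeps everything.
#' @return the subsetted `feature_table` (attributes preserved).
#' @export
ft_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  fi <- if (is.null(features)) seq_len(nrow(x$intensity)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$intensity)) else samples
  if (is.character(fi)) fi <- match(fi, x$features$feature_id)
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  out <- x
  out$intensity <- x$intensity[fi, si, drop = FALSE]
  out$features <- x$features[fi, , drop = FALSE]
  out$samples <- x$samples[si, , drop = FALSE]
  rownames(out$features) <- NULL
  rownames(out$samples) <- NULL
  attributes(out) <- utils::modifyList(attributes(x), attributes(out))
  out
}

.ft_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a feature table from CSV/TSV plus a sample-metadata TSV
#'
#' The feature file holds one row per feature: the metadata columns
#' `feature_id`, `mz`, `rt`, `mode`, `adduct`, `annotation`, `msi_level`
#' (missing ones are tolerated), followed by one intensity column per sample.
#' The companion sample file is tab-separated with columns `sample_id`,
#' `role`, `group`, `time_h`, `replicate`, `strain`.
#'
#' @param path feature CSV/TSV path (separator inferred from the extension).
#' @param sample_meta path of the sample-metadata TSV.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, sample_meta) {
  feat <- utils::read.table(path, sep = .ft_sep(path), header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  samp <- utils::read.table(sample_meta, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("feature_id", "mz", "rt", "mode", "adduct",
                           "annotation", "msi_level"), names(feat))
  sample_cols <- setdiff(names(feat), meta_cols)
  missing <- setdiff(samp$sample_id, sample_cols)
  if (length(missing)) {
    stop("sample metadata lists samples absent from the feature file: ",
         paste(missing, collapse = ", "))
  }
  intensity <- as.matrix(feat[, samp$sample_id, drop = FALSE])
  feature_table(intensity, feat[, meta_cols, drop = FALSE], samp)
}

#' Write a feature table (and its sample metadata) to disk
#'
#' @param x a [feature_table()].
#' @param path output feature CSV/TSV path.
#' @param sample_meta optional path for the sample-metadata TSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, sample_meta = NULL) {
  stopifnot(inherits(x, "feature_table"))
  out <- cbind(x$features, as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(out, path, sep = .ft_sep(path), quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sample_meta)) {
    utils::write.table(x$samples, sample_meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
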
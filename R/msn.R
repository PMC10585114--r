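# Morphometric similarity networks -------------------------------------------

#' Z-score morphometric features across regions, per subject
#'
#' For every subject and every feature independently, regional values are
#' centred and scaled to unit SD across the R regions, removing inter-feature
#' scale differences before correlating feature vectors.
#'
#' @param table a `morph_table`.
#' @return a standardized `morph_table` (subject metadata unchanged).
#' @export
zscore_features <- function(table) {
  stopifnot(inherits(table, "morph_table"))
  v <- table$values
  d <- dim(v)
  out <- v
  for (s in seq_len(d[1])) {
    x <- v[s, , ]
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      f <- table$feature_names[which(sds == 0)[1]]
      stop("zero-variance feature '", f, "' for subject '",
           dimnames(v)[[1]][s], "'")
    }
    out[s, , ] <- scale(x)
  }
  new_morph_table(out, table$subjects, standardized = TRUE)
}

#' Build one subject's morphometric similarity network
#'
#' Entry (i, j) is the Pearson (or Spearman) correlation between region i's
#' and region j's 7-component standardized feature vectors. The diagonal is
#' stored as 0: self-similarity is excluded by convention and a constant
#' diagonal would cancel in group contrasts anyway.
#'
#' @param table a standardized `morph_table` (see [zscore_features()]).
#' @param subject_id subject identifier present in the table.
#' @param method "pearson" or "spearman" (ranks the 7 features within each
#'   region, average ranks for ties).
#' @return R x R `msn_matrix`, symmetric, diagonal 0.
#' @export
build_msn <- function(table, subject_id, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "morph_table"))
  if (!isTRUE(table$standardized)) {
    stop("build_msn expects a standardized table; call zscore_features() first")
  }
  s <- match(subject_id, dimnames(table$values)[[1]])
  if (is.na(s)) stop("unknown subject '", subject_id, "'")
  x <- table$values[s, , ]                      # R x 7
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature vector for region ",
         dimnames(table$values)[[2]][which(sds == 0)[1]],
         " (correlation undefined)")
  }
  m <- stats::cor(t(x), method = method)
  diag(m) <- 0
  structure(m, method = method, subject_id = subject_id,
            class = c("msn_matrix", "matrix", "array"))
}

#' Regional morphometric-similarity strength
#'
#' The signed sum of a region's correlations to all other regions (diagonal
#' excluded). Negative strength marks regions architectonically differentiated
#' from the rest of cortex; positive strength marks de-differentiated regions.
#'
#' @param msn an `msn_matrix`.
#' @return named numeric vector of length R with attribute `subject_id`.
#' @export
regional_strength <- function(msn) {
  stopifnot(inherits(msn, "msn_matrix"))
  s <- rowSums(msn)          # diagonal already 0
  attr(s, "subject_id") <- attr(msn, "subject_id")
  s
}

#' Compute the subjects x regions strength matrix for a whole cohort
#'
#' @param table a `morph_table` (raw; z-scoring is applied internally).
#' @param method correlation method passed to [build_msn()].
#' @return subjects x regions matrix, attribute `measure = "ms"`.
#' @export
cohort_strengths <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  std <- if (isTRUE(table$standardized)) table else zscore_features(table)
  subs <- dimnames(std$values)[[1]]
  out <- t(vapply(subs, function(id) {
    regional_strength(build_msn(std, id, method))
  }, numeric(n_regions(std))))
  dimnames(out) <- list(subs, dimnames(std$values)[[2]])
  attr(out, "measure") <- "ms"
  out
}

#' Extract one feature as a subjects x regions matrix
#'
#' Used for the cortical-thickness replication contrast; the returned matrix
#' carries `measure = "ct"` (etc.) so contrast fits can check the response.
#'
#' @param table a `morph_table` (raw units).
#' @param feature one of [MORPH_FEATURES].
#' @export
feature_matrix <- function(table, feature) {
  stopifnot(inherits(table, "morph_table"), feature %in% table$feature_names)
  m <- table$values[, , match(feature, table$feature_names)]
  attr(m, "measure") <- tolower(feature)
  m
}

#' Mean regional strength within one group
#'
#' @param strengths subjects x regions matrix (e.g. [cohort_strengths()]).
#' @param subjects subject covariate data.frame with `subject` and `group`.
#' @param group group label to average over.
#' @return numeric vector of per-region means.
#' @export
group_mean_strength <- function(strengths, subjects, group) {
  rows <- which(subjects$group == group)
  if (!length(rows)) stop("no subjects in group '", group, "'")
  colMeans(strengths[rows, , drop = FALSE])
}

#' Write a cohort strength matrix (subjects x regions) as TSV
#' @param strengths matrix from [cohort_strengths()].
#' @param path file path.
#' @export
write_strengths <- function(strengths, path) {
  df <- data.frame(subject = rownames(strengths),
                   as.data.frame(strengths, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one subject's MSN as a square TSV
#' @param msn an `msn_matrix`.
#' @param path file path.
#' @export
write_msn <- function(msn, path) {
  utils::write.table(as.data.frame(unclass(msn)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
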
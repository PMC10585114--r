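# Case-control inference on regional maps ------------------------------------

# one QR factorisation of the shared design, solved against all R regional
# response columns at once; returns t / p for the group coefficient
ols_group_t <- function(Y, design, t_cap = 1e6) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[seq(qr_d$rank + 1, ncol(design))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qr_d, Y)
  resid <- Y - design %*% coefs
  df <- nrow(design) - ncol(design)
  sigma2 <- colSums(resid^2) / df
  xtx_inv_gg <- chol2inv(qr.R(qr_d))[2, 2]   # "group" is always column 2
  se <- sqrt(sigma2 * xtx_inv_gg)
  t <- coefs["group", ] / se
  degenerate <- !is.finite(t) | abs(t) > t_cap
  if (any(degenerate)) {
    warning(sum(degenerate), " region(s) with (near-)perfect fit; t capped at ",
            format(t_cap))
    t[degenerate] <- sign(coefs["group", degenerate]) * t_cap
    t[is.na(t)] <- 0
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(t = unname(t), p = unname(p), df = df)
}

build_design <- function(subjects, extra_covariates = character(),
                         mean_ct = NULL) {
  grp <- as.integer(subjects$group == "user")
  if (sum(grp) < 2 || sum(1 - grp) < 2) stop("need >= 2 subjects per group")
  age_c <- subjects$age - mean(subjects$age)   # centred: conditions age x sex
  sexM <- as.integer(subjects$sex == "M")
  design <- cbind(intercept = 1, group = grp, age = age_c, sex = sexM,
                  age_sex = age_c * sexM)
  if ("tiv" %in% extra_covariates) {
    if (is.null(subjects$tiv) || anyNA(subjects$tiv)) {
      stop("TIV requested as covariate but missing from subjects table")
    }
    design <- cbind(design, tiv = subjects$tiv - mean(subjects$tiv))
  }
  if (!is.null(mean_ct)) design <- cbind(design, mean_ct = mean_ct - mean(mean_ct))
  design
}

#' Fit the per-region case-control contrast
#'
#' Per region, an OLS fit of `response ~ group + age + sex + age:sex` (plus
#' TIV if requested; plus the subject's mean cross-hemispheric CT when the
#' response is cortical thickness), with the two-tailed t for the group
#' coefficient (user - control) and BH-FDR across regions.
#'
#' @param strengths subjects x regions response matrix; its `measure`
#'   attribute (when present) must agree with `response`.
#' @param subjects covariates data.frame (`subject`, `group`, `age`, `sex`,
#'   optional `tiv`, `attendance`); rows aligned with `strengths`.
#' @param extra_covariates subset of `"tiv"`.
#' @param response `"ms"` (MS strength) or `"ct"` (cortical thickness).
#' @param alpha FDR level for the significance flags.
#' @return `regional_stat_map` data.frame: `region_id`, `t`, `p`, `p_fdr`,
#'   `significant`; attributes `model_terms` and `df`.
#' @export
fit_regional_contrast <- function(strengths, subjects,
                                  extra_covariates = character(),
                                  response = c("ms", "ct"), alpha = 0.05) {
  response <- match.arg(response)
  measure <- attr(strengths, "measure")
  if (!is.null(measure) && measure != response) {
    stop("response = '", response, "' but the input matrix carries measure '",
         measure, "'")
  }
  if (nrow(strengths) != nrow(subjects)) stop("strengths/subjects row mismatch")
  mean_ct <- if (response == "ct") rowMeans(strengths) else NULL
  design <- build_design(subjects, extra_covariates, mean_ct)
  fit <- ols_group_t(as.matrix(strengths), design)
  adj <- bh_fdr(fit$p, alpha)
  out <- data.frame(
    region_id = colnames(strengths) %||% as.character(seq_len(ncol(strengths)) - 1L),
    t = fit$t, p = fit$p, p_fdr = adj$p_fdr, significant = adj$significant,
    stringsAsFactors = FALSE)
  attr(out, "model_terms") <- colnames(design)
  attr(out, "df") <- fit$df
  attr(out, "alpha") <- alpha
  class(out) <- c("regional_stat_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' @param p vector of p-values in [0, 1].
#' @param alpha FDR level.
#' @return list with `p_fdr` (step-up adjusted, monotone) and `significant`
#'   (`p_fdr < alpha`).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  p_fdr <- stats::p.adjust(p, method = "BH")
  list(p_fdr = p_fdr, significant = p_fdr < alpha)
}

#' Global group comparison of MS strength
#'
#' A two-sample t-test (Welch by default) on subject-level mean strength, and
#' a two-sample Kolmogorov-Smirnov test comparing the two groups' regional
#' strength distributions (within-group mean regional strength by default;
#' `ks_on = "pooled"` pools all subjects x regions values instead).
#'
#' @param strengths subjects x regions matrix.
#' @param subjects covariates data.frame.
#' @param var_equal use a pooled-variance t-test instead of Welch.
#' @param ks_on "group_mean" or "pooled".
#' @return list `t`, `p_t`, `ks_statistic`, `p_ks`.
#' @export
compare_global_ms <- function(strengths, subjects, var_equal = FALSE,
                              ks_on = c("group_mean", "pooled")) {
  ks_on <- match.arg(ks_on)
  u <- subjects$group == "user"
  if (sum(u) < 2 || sum(!u) < 2) stop("need >= 2 subjects per group")
  mu <- rowMeans(strengths)
  tt <- stats::t.test(mu[u], mu[!u], var.equal = var_equal)
  if (ks_on == "group_mean") {
    a <- colMeans(strengths[u, , drop = FALSE])
    b <- colMeans(strengths[!u, , drop = FALSE])
  } else {
    a <- as.vector(strengths[u, , drop = FALSE])
    b <- as.vector(strengths[!u, , drop = FALSE])
  }
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(t = unname(tt$statistic), p_t = tt$p.value,
       ks_statistic = unname(ks$statistic), p_ks = ks$p.value)
}

#' Network-level case-control contrast
#'
#' Each subject's strength is averaged over the regions of each atlas label
#' (Yeo-7 or von Economo); the same covariate-adjusted linear model as
#' [fit_regional_contrast()] is then fitted per label, with BH-FDR across the
#' atlas's labels.
#'
#' @param strengths subjects x regions matrix.
#' @param subjects covariates data.frame.
#' @param parcellation a `parcellation` matching the strength columns.
#' @param atlas "yeo7" or "von_economo".
#' @param extra_covariates passed through to the design.
#' @param alpha FDR level.
#' @return data.frame `label`, `n_regions`, `t`, `p`, `p_fdr`, `significant`
#'   with attribute `atlas`.
#' @export
network_contrast <- function(strengths, subjects, parcellation,
                             atlas = c("yeo7", "von_economo"),
                             extra_covariates = character(), alpha = 0.05) {
  atlas <- match.arg(atlas)
  labels <- if (atlas == "yeo7") parcellation$yeo else parcellation$von_economo
  region_cols <- match(as.character(parcellation$region_id), colnames(strengths))
  if (anyNA(region_cols)) stop("parcellation regions missing from strength matrix")
  lev <- unique(labels)
  agg <- vapply(lev, function(l) {
    cols <- region_cols[labels == l]
    if (!length(cols)) stop("label '", l, "' has zero regions")
    rowMeans(strengths[, cols, drop = FALSE])
  }, numeric(nrow(strengths)))
  colnames(agg) <- lev
  design <- build_design(subjects, extra_covariates)
  fit <- ols_group_t(agg, design)
  adj <- bh_fdr(fit$p, alpha)
  out <- data.frame(label = lev, n_regions = as.vector(table(labels)[lev]),
                    t = fit$t, p = fit$p, p_fdr = adj$p_fdr,
                    significant = adj$significant, stringsAsFactors = FALSE)
  attr(out, "atlas") <- atlas
  out
}

#' Spearman correlation of attendance with FDR-flagged mean strength
#'
#' Within the user group only, each subject's strength is averaged over three
#' region sets derived from the regional contrast (significantly positive,
#' significantly negative, all significant) and correlated (two-tailed
#' Spearman) with ceremony-attendance counts.
#'
#' @param strengths subjects x regions matrix.
#' @param subjects covariates data.frame with `attendance` for users.
#' @param stat_map a `regional_stat_map` from [fit_regional_contrast()].
#' @return data.frame `set`, `n_regions`, `rho`, `p` (empty sets skipped with
#'   a warning).
#' @export
frequency_correlation <- function(strengths, subjects, stat_map) {
  users <- which(subjects$group == "user")
  att <- subjects$attendance[users]
  if (anyNA(att)) stop("attendance missing for some user subjects")
  if (stats::sd(att) == 0) stop("attendance is constant; rho undefined")
  cols <- match(stat_map$region_id, colnames(strengths))
  sets <- list(
    positive = which(stat_map$significant & stat_map$t > 0),
    negative = which(stat_map$significant & stat_map$t < 0),
    all = which(stat_map$significant))
  rows <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    if (!length(idx)) {
      warning("flag set '", nm, "' is empty; skipped")
      return(NULL)
    }
    ms <- rowMeans(strengths[users, cols[idx], drop = FALSE])
    ct <- suppressWarnings(
      stats::cor.test(ms, att, method = "spearman", alternative = "two.sided"))
    data.frame(set = nm, n_regions = length(idx),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame(set = character(), n_regions = integer(),
                                       rho = numeric(), p = numeric())
}

#' Jaccard similarity of two significance-flag vectors
#'
#' @param a,b logical vectors of equal length.
#' @return `|a & b| / |a | b|`; 1 when both sets are empty.
#' @export
jaccard_flags <- function(a, b) {
  if (length(a) != length(b)) stop("flag vectors differ in length")
  a <- as.logical(a); b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0) return(1)
  sum(a & b) / union
}

#' Write a regional stat map as TSV
#' @param stat_map a `regional_stat_map` (or any data.frame).
#' @param path file path.
#' @export
write_stat_map <- function(stat_map, path) {
  utils::write.table(as.data.frame(stat_map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
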
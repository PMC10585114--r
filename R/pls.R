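# Rank-1 PLS between a regional t-map and gene-expression maps ---------------
#
# For a univariate response the first PLS component has a closed form: the
# weight vector is the normalised gene-by-response cross-covariance X'y
# (SIMPLS/NIPALS-equivalent), scores are X w, and the variance explained is
# the squared correlation of scores with y. Only this first component is used.

check_pls_inputs <- function(X, y) {
  if (nrow(X) != length(y)) stop("X and y must cover the same regions")
  rx <- rownames(X); ry <- names(y)
  if (!is.null(rx) && !is.null(ry) && !identical(rx, ry)) {
    stop("region ids of X and y differ or are ordered differently")
  }
  if (stats::sd(y) == 0) stop("response map has zero variance")
  invisible(TRUE)
}

pls1_weights <- function(X, y) {
  cross <- crossprod(X, y - mean(y))
  nrm <- sqrt(sum(cross^2))
  if (nrm < 1e-12) return(NULL)
  cross / nrm
}

#' Fit the first PLS component of expression maps against a regional map
#'
#' @param X regions x genes matrix, each column z-scored across regions
#'   (see [simulate_expression()] / [read_expression()]).
#' @param y numeric regional response map on the same region support.
#' @return `pls1_fit`: list `weights` (unit-norm gene loadings), `scores`
#'   (regional scores `X %*% weights`), `varexp` (squared correlation of
#'   scores with y). The sign is oriented so that `cor(scores, y) >= 0`.
#' @export
fit_pls1 <- function(X, y) {
  check_pls_inputs(X, y)
  w <- pls1_weights(X, y)
  if (is.null(w)) {
    warning("response is orthogonal to every gene map; returning zero fit")
    w <- matrix(0, ncol(X), 1)
    scores <- rep(0, nrow(X))
    return(structure(list(weights = stats::setNames(as.vector(w), colnames(X)),
                          scores = stats::setNames(scores, rownames(X)),
                          varexp = 0), class = "pls1_fit"))
  }
  scores <- as.vector(X %*% w)
  r <- stats::cor(scores, y)
  if (r < 0) { w <- -w; scores <- -scores; r <- -r }
  structure(list(weights = stats::setNames(as.vector(w), colnames(X)),
                 scores = stats::setNames(scores, rownames(X)),
                 varexp = r^2),
            class = "pls1_fit")
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d genes, varexp = %.3f\n",
              length(x$weights), x$varexp))
  invisible(x)
}

#' Permutation test for the variance explained by PLS1
#'
#' The response map's region labels are permuted `n_perm` times and PLS1 is
#' refitted to each; `p_perm = (count(null >= observed) + 1) / (n_perm + 1)`.
#'
#' @param X regions x genes matrix.
#' @param y regional response map.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list `p_perm`, `varexp_observed`, `null_varexp`.
#' @export
permutation_test_varexp <- function(X, y, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  check_pls_inputs(X, y)
  obs <- fit_pls1(X, y)$varexp
  R <- length(y)
  withr::with_seed(seed, {
    perm_idx <- replicate(n_perm, sample.int(R))
  })
  Ym <- matrix(y[perm_idx], R, n_perm)
  Ym <- sweep(Ym, 2, colMeans(Ym))
  C <- crossprod(X, Ym)                               # genes x n_perm
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  S <- X %*% C                                        # scores per permutation
  Sc <- sweep(S, 2, colMeans(S))
  num <- colSums(Sc * Ym)
  null_varexp <- num^2 / (colSums(Sc^2) * colSums(Ym^2))
  null_varexp[!is.finite(null_varexp)] <- 0   # degenerate permutation (X'y = 0)
  list(p_perm = (sum(null_varexp >= obs) + 1) / (n_perm + 1),
       varexp_observed = obs, null_varexp = null_varexp)
}

#' Bootstrap Z-scores and significance sets for PLS1 gene weights
#'
#' Regions are resampled with replacement `n_boot` times; PLS1 is refitted to
#' each resample (columns re-centred) and the bootstrap weight vector is
#' sign-aligned to the original. Each gene's Z is its original weight divided
#' by the SD of its aligned bootstrap weights. Genes pass at a two-tailed
#' `conf` threshold on |Z| and are additionally screened by BH-FDR across
#' genes; both stages are reported.
#'
#' @param X regions x genes matrix.
#' @param y regional response map.
#' @param n_boot bootstrap iterations (>= 100).
#' @param seed integer seed.
#' @param conf confidence level for the |Z| threshold (default 0.99).
#' @param fdr_alpha BH-FDR level across genes.
#' @return list `boot_z` (named), `p_fdr`, `z_pass_pos`/`z_pass_neg` (gene
#'   symbols passing the |Z| threshold alone), `sig_pos`/`sig_neg` (passing
#'   both stages), `n_redraws`.
#' @export
bootstrap_gene_z <- function(X, y, n_boot = 1000, seed = 1, conf = 0.99,
                             fdr_alpha = 0.05) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  check_pls_inputs(X, y)
  fit0 <- fit_pls1(X, y)
  w0 <- fit0$weights
  R <- nrow(X); G <- ncol(X)
  W <- matrix(NA_real_, G, n_boot)
  n_redraws <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(R, replace = TRUE)
        if (stats::sd(y[idx]) > 0) break
        n_redraws <- n_redraws + 1L
      }
      Xb <- X[idx, , drop = FALSE]
      Xb <- sweep(Xb, 2, colMeans(Xb))
      wb <- pls1_weights(Xb, y[idx])
      if (is.null(wb)) wb <- matrix(0, G, 1)
      if (sum(wb * w0) < 0) wb <- -wb
      W[, b] <- wb
    }
  })
  if (n_redraws > 0) message(n_redraws, " degenerate bootstrap draw(s) redrawn")
  se <- apply(W, 1, stats::sd)
  boot_z <- ifelse(se > 0, w0 / se, 0)
  names(boot_z) <- names(w0)
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  p_gene <- 2 * stats::pnorm(-abs(boot_z))
  adj <- bh_fdr(p_gene, fdr_alpha)
  genes <- names(boot_z) %||% as.character(seq_len(G))
  z_pos <- boot_z >= zcrit
  z_neg <- boot_z <= -zcrit
  list(boot_z = boot_z, p_fdr = stats::setNames(adj$p_fdr, genes),
       z_pass_pos = genes[z_pos], z_pass_neg = genes[z_neg],
       sig_pos = genes[z_pos & adj$significant],
       sig_neg = genes[z_neg & adj$significant],
       n_redraws = n_redraws)
}

#' Spatial anchoring of PLS1 scores against the response map
#'
#' Delegates to [spin_test()] on (scores, y) with a left-hemisphere spin
#' ensemble, giving the Pearson r between the PLS1 regional scores and the
#' t-map together with its spatial-null p-value.
#'
#' @param scores PLS1 regional scores.
#' @param y regional response map.
#' @param ensemble a left-hemisphere `spin_ensemble` on the same support.
#' @param sidedness passed to [spin_test()].
#' @return list `r_spatial`, `p_spin_spatial`, `spin_result`.
#' @export
pls_spatial_anchor <- function(scores, y, ensemble, sidedness = "two") {
  res <- spin_test(as.numeric(scores), as.numeric(y), ensemble, sidedness)
  list(r_spatial = res$r_observed, p_spin_spatial = res$p_spin,
       spin_result = res)
}

#' Full PLS1 transcriptomic association analysis
#'
#' Convenience wrapper chaining [fit_pls1()], [permutation_test_varexp()],
#' [bootstrap_gene_z()] and (optionally) [pls_spatial_anchor()].
#'
#' @param X regions x genes expression matrix.
#' @param y left-hemisphere regional t-map.
#' @param n_perm,n_boot resampling sizes.
#' @param seed integer seed (stage seeds are derived from it).
#' @param ensemble optional left-hemisphere `spin_ensemble`.
#' @param conf,fdr_alpha thresholds for [bootstrap_gene_z()].
#' @return `pls_result` list: `weights`, `scores`, `varexp`, `p_perm`,
#'   `boot_z`, `sig_pos`, `sig_neg`, `z_pass_pos`, `z_pass_neg`,
#'   `r_spatial`, `p_spin_spatial`, `gene_table`.
#' @export
pls1_analysis <- function(X, y, n_perm = 1000, n_boot = 1000, seed = 1,
                          ensemble = NULL, conf = 0.99, fdr_alpha = 0.05) {
  fit <- fit_pls1(X, y)
  perm <- permutation_test_varexp(X, y, n_perm, seed = seed)
  boot <- bootstrap_gene_z(X, y, n_boot, seed = seed + 1L, conf = conf,
                           fdr_alpha = fdr_alpha)
  anchor <- if (!is.null(ensemble)) pls_spatial_anchor(fit$scores, y, ensemble)
            else list(r_spatial = NA_real_, p_spin_spatial = NA_real_)
  genes <- names(fit$weights)
  gene_table <- data.frame(
    gene = genes, weight = unname(fit$weights),
    boot_z = unname(boot$boot_z), p_fdr = unname(boot$p_fdr),
    z_pass = genes %in% c(boot$z_pass_pos, boot$z_pass_neg),
    significant = genes %in% c(boot$sig_pos, boot$sig_neg),
    stringsAsFactors = FALSE)
  structure(list(weights = fit$weights, scores = fit$scores,
                 varexp = fit$varexp, p_perm = perm$p_perm,
                 boot_z = boot$boot_z,
                 z_pass_pos = boot$z_pass_pos, z_pass_neg = boot$z_pass_neg,
                 sig_pos = boot$sig_pos, sig_neg = boot$sig_neg,
                 r_spatial = anchor$r_spatial,
                 p_spin_spatial = anchor$p_spin_spatial,
                 gene_table = gene_table),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(paste0("PLS1: varexp = %.3f (p_perm = %.4g), r_spatial = %.3f",
                     " (p_spin = %.4g)\n%d PLS1+ / %d PLS1- significant genes\n"),
              x$varexp, x$p_perm, x$r_spatial, x$p_spin_spatial,
              length(x$sig_pos), length(x$sig_neg)))
  invisible(x)
}
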
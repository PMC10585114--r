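make_xy <- function(R = 8, G = 5, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(R * G), R, G))
  attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  dimnames(X) <- list(0:(R - 1), paste0("G", 1:G))
  y <- setNames(rnorm(R), 0:(R - 1))
  list(X = X, y = y)
}

test_that("rank-1 PLS matches the SVD and NIPALS oracles on a fixed fixture", {
  d <- make_xy(8, 5, seed = 3)
  fit <- fit_pls1(d$X, d$y)
  oracle <- svd_pls1_oracle(d$X, d$y)
  expect_equal(unname(fit$weights), oracle$weights, tolerance = 1e-10)
  expect_equal(unname(fit$scores), oracle$scores, tolerance = 1e-10)
  expect_equal(fit$varexp, oracle$varexp, tolerance = 1e-10)

  nip <- nipals_pls1_oracle(d$X, d$y)
  if (sum(nip * oracle$weights) < 0) nip <- -nip
  expect_equal(unname(fit$weights), nip, tolerance = 1e-8)

  # analytic identity: weights proportional to X'y
  cross <- crossprod(d$X, d$y - mean(d$y))
  expect_equal(unname(fit$weights),
               sign(cor(as.vector(d$X %*% cross), d$y)) *
                 as.vector(cross) / sqrt(sum(cross^2)),
               tolerance = 1e-10)
})

test_that("response equal to one gene gives varexp 1 and a maximal weight", {
  # orthogonal gene maps, so the rank-1 component can align exactly with y
  set.seed(4)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(12 * 6), 12, 6))))[, -1]
  X <- apply(Q, 2, function(c) c / sd(c))
  dimnames(X) <- list(0:11, paste0("G", 1:6))
  y <- setNames(X[, 3] * 2 + 5, rownames(X))
  fit <- fit_pls1(X, y)
  expect_equal(fit$varexp, 1, tolerance = 1e-10)
  expect_equal(unname(which.max(abs(fit$weights))), 3)
  expect_gt(fit$weights[3], 0)   # sign convention: r_spatial >= 0
})

test_that("orthogonal response yields the zero fit with a warning", {
  X <- matrix(c(1, -1, 1, -1), 4, 1, dimnames = list(0:3, "G1"))
  X <- scale(X); attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  y <- setNames(c(1, 1, -1, -1), 0:3)  # orthogonal to the single gene
  expect_warning(fit <- fit_pls1(X, y), "orthogonal")
  expect_equal(fit$varexp, 0)
  expect_equal(unname(fit$weights), 0)
})

test_that("PLS guards region alignment and degenerate responses", {
  d <- make_xy()
  bad <- d$y; names(bad) <- rev(names(bad))
  expect_error(fit_pls1(d$X, bad), "region ids")
  expect_error(fit_pls1(d$X, d$y[-1]), "same regions")
  expect_error(fit_pls1(d$X, setNames(rep(1, 8), rownames(d$X))),
               "zero variance")
})

test_that("varexp is invariant to a simultaneous region permutation and the
           sign convention flips cleanly", {
  d <- make_xy(20, 7, seed = 6)
  fit <- fit_pls1(d$X, d$y)
  perm <- sample(20)
  Xp <- d$X[perm, ]; rownames(Xp) <- rownames(d$X)
  yp <- setNames(d$y[perm], names(d$y))
  fit_p <- fit_pls1(Xp, yp)
  expect_equal(fit_p$varexp, fit$varexp, tolerance = 1e-12)

  flip <- fit_pls1(d$X, -d$y)
  expect_equal(unname(flip$weights), -unname(fit$weights), tolerance = 1e-12)
  expect_equal(unname(flip$scores), -unname(fit$scores), tolerance = 1e-12)
  expect_equal(flip$varexp, fit$varexp, tolerance = 1e-12)
})

test_that("permutation test is deterministic, calibrated under the null and
           powered under a planted association", {
  parc <- small_parc(80, 40, seed = 20)
  eff <- rnorm(80)
  X <- simulate_expression(parc, 20, effect_map = eff, planted_pos = 0:2,
                           planted_neg = 3:5, association_strength = 0.7,
                           seed = 21)
  y <- setNames(as.vector(scale(eff[parc$hemisphere == "L"])), rownames(X))
  a <- permutation_test_varexp(X, y, n_perm = 300, seed = 5)
  b <- permutation_test_varexp(X, y, n_perm = 300, seed = 5)
  expect_identical(a, b)
  expect_lt(a$p_perm, 0.05)
  expect_error(permutation_test_varexp(X, y, n_perm = 50), "n_perm")

  # null: p roughly uniform over replicates
  ps <- vapply(1:40, function(r) {
    X0 <- simulate_expression(parc, 15, seed = 400 + r)
    y0 <- setNames(rnorm(40), rownames(X0))
    permutation_test_varexp(X0, y0, n_perm = 150, seed = r)$p_perm
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("bootstrap Z ranks a y-identical gene first and is reproducible", {
  parc <- small_parc(80, 40, seed = 22)
  set.seed(23)
  X <- simulate_expression(parc, 15, seed = 23)
  y <- setNames(X[, 7] + rnorm(40, sd = 0.2), rownames(X))
  a <- bootstrap_gene_z(X, y, n_boot = 300, seed = 9)
  b <- bootstrap_gene_z(X, y, n_boot = 300, seed = 9)
  expect_identical(a$boot_z, b$boot_z)
  expect_equal(which.max(abs(a$boot_z)), 7, ignore_attr = TRUE)
  expect_true(colnames(X)[7] %in% a$sig_pos)
  expect_length(intersect(a$sig_pos, a$sig_neg), 0)
  expect_error(bootstrap_gene_z(X, y, n_boot = 10), "n_boot")
})

test_that("pure-noise genes rarely reach bootstrap significance", {
  # unassociated genes are assessed alongside a genuine association, where
  # the sign alignment of bootstrap weight vectors is stable; under a fully
  # null response the alignment step truncates the bootstrap distribution
  # and the gene Z-scores are known to run hot (see the methods vignette)
  parc <- small_parc(80, 40, seed = 24)
  stats <- vapply(1:10, function(r) {
    eff <- rnorm(80)
    X <- simulate_expression(parc, 22, effect_map = eff, planted_pos = 0,
                             planted_neg = 1, association_strength = 0.8,
                             seed = 500 + r)
    y <- setNames(as.vector(scale(eff[parc$hemisphere == "L"])), rownames(X))
    res <- bootstrap_gene_z(X, y, n_boot = 200, seed = r)
    sig <- c(res$sig_pos, res$sig_neg)
    length(setdiff(sig, colnames(X)[1:2])) / 20
  }, numeric(1))
  expect_lt(mean(stats), 0.05)
})

test_that("spatial anchoring delegates to spin_test bit for bit", {
  parc <- small_parc(40, 20, seed = 26)
  ens <- make_spin_ensemble(parc, 100, seed = 27, "left")
  X <- simulate_expression(parc, 8, seed = 28)
  y <- setNames(rnorm(20), rownames(X))
  fit <- fit_pls1(X, y)
  anchor <- pls_spatial_anchor(fit$scores, y, ens)
  direct <- spin_test(as.numeric(fit$scores), as.numeric(y), ens)
  expect_identical(anchor$r_spatial, direct$r_observed)
  expect_identical(anchor$p_spin_spatial, direct$p_spin)
  expect_identical(anchor$spin_result$null_r, direct$null_r)
  expect_equal(spin_test(as.numeric(y), as.numeric(y), ens)$r_observed, 1)
})

test_that("the combined PLS analysis reports a coherent gene table", {
  parc <- small_parc(70, 36, seed = 29)
  eff <- rnorm(70)
  X <- simulate_expression(parc, 12, effect_map = eff, planted_pos = 0,
                           planted_neg = 1, association_strength = 0.8,
                           seed = 30)
  y <- setNames(as.vector(scale(eff[parc$hemisphere == "L"])), rownames(X))
  ens <- make_spin_ensemble(parc, 100, seed = 31, "left")
  res <- pls1_analysis(X, y, n_perm = 200, n_boot = 200, seed = 32,
                       ensemble = ens)
  expect_s3_class(res, "pls_result")
  expect_true(res$varexp >= 0 && res$varexp <= 1)
  expect_equal(nrow(res$gene_table), 12)
  expect_setequal(res$gene_table$gene[res$gene_table$significant],
                  c(res$sig_pos, res$sig_neg))
  expect_equal(res$r_spatial,
               cor(as.numeric(res$scores), as.numeric(y)), tolerance = 1e-12)
})
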
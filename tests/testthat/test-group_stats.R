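test_that("regional contrast matches stats::lm region by region", {
  subjects <- balanced_subjects(4, seed = 2)
  set.seed(3)
  Y <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(subjects$subject, 0:2))
  sm <- fit_regional_contrast(Y, subjects)
  grp <- as.integer(subjects$group == "user")
  age_c <- subjects$age - mean(subjects$age)
  sexM <- as.integer(subjects$sex == "M")
  for (r in 1:3) {
    fit <- lm(Y[, r] ~ grp + age_c + sexM + I(age_c * sexM))
    ct <- summary(fit)$coefficients["grp", ]
    expect_equal(sm$t[r], unname(ct["t value"]), tolerance = 1e-10)
    expect_equal(sm$p[r], unname(ct["Pr(>|t|)"]), tolerance = 1e-10)
  }
  expect_equal(sm$p_fdr, p.adjust(sm$p, "BH"))
  expect_identical(sm$significant, sm$p_fdr < 0.05)
  expect_true(all(c("intercept", "group", "age", "sex", "age_sex") %in%
                  attr(sm, "model_terms")))
})

test_that("hand-built 6-subject fixture reproduces the normal-equation fit", {
  subjects <- data.frame(
    subject = paste0("S", 1:6),
    group = rep(c("user", "control"), each = 3),
    age = c(50, 55, 60, 52, 57, 62),
    sex = c("F", "M", "M", "F", "M", "F"),
    stringsAsFactors = FALSE)
  Y <- matrix(c(5.2, 6.1, 7.3, 1.4, 2.2, 3.1,
                2.3, 1.1, 4.2, 3.3, 2.1, 5.2,
                0.5, 1.7, -1.2, 2.4, 0.3, 1.1), 6, 3,
              dimnames = list(NULL, 0:2))
  sm <- fit_regional_contrast(Y, subjects)
  # independent route: solve the normal equations directly per region
  a <- subjects$age - mean(subjects$age)
  s01 <- as.integer(subjects$sex == "M")
  X <- cbind(1, rep(1:0, each = 3), a, s01, a * s01)
  XtXi <- solve(crossprod(X))
  for (r in 1:3) {
    beta <- XtXi %*% crossprod(X, Y[, r])
    resid <- Y[, r] - X %*% beta
    se <- sqrt(sum(resid^2) / (6 - 5) * XtXi[2, 2])
    expect_equal(sm$t[r], beta[2] / se, tolerance = 1e-10)
  }
})

test_that("contrast guards: group sizes, rank deficiency, response schema", {
  subjects <- balanced_subjects(4)
  Y <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(subjects$subject, 0:1))
  few <- subjects; few$group <- c("user", rep("control", 7))
  expect_error(fit_regional_contrast(Y, few), ">= 2 subjects")
  one_sex <- subjects; one_sex$sex <- "F"   # age_sex column collapses to 0
  expect_error(fit_regional_contrast(Y, one_sex), "collinear")
  expect_error(fit_regional_contrast(Y, subjects, extra_covariates = "tiv"),
               "TIV")
  attr(Y, "measure") <- "ms"
  expect_error(fit_regional_contrast(Y, subjects, response = "ct"),
               "measure")
})

test_that("perfect group separation is capped, not NaN", {
  subjects <- balanced_subjects(4)
  y <- as.numeric(subjects$group == "user")
  Y <- matrix(y, 8, 1, dimnames = list(NULL, "0"))
  expect_warning(sm <- fit_regional_contrast(Y, subjects), "capped")
  expect_true(is.finite(sm$t[1]))
  expect_equal(abs(sm$t[1]), 1e6)
})

test_that("BH adjustment matches the hand computation on the 4-value example", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  # hand BH: 0.01*4/1, 0.02*4/2, 0.03*4/3, 0.04*4/4 -> monotone -> all 0.04
  expect_equal(res$p_fdr, rep(0.04, 4))
  expect_true(all(res$significant))

  expect_equal(bh_fdr(0.031)$p_fdr, 0.031)        # m = 1 is the identity
  expect_false(any(bh_fdr(rep(1, 10))$significant))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("global comparison: identical groups give zero statistics", {
  subjects <- balanced_subjects(5)
  block <- matrix(rnorm(5 * 20), 5, 20)
  strengths <- rbind(block, block)
  rownames(strengths) <- subjects$subject
  res <- compare_global_ms(strengths, subjects)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$ks_statistic, 0)
})

test_that("global t matches the hand Welch formula on fixed samples", {
  a <- c(12.1, 10.5, 11.8, 13.2, 12.4)
  b <- c(9.8, 10.1, 9.5, 10.9, 9.9)
  subjects <- balanced_subjects(5)
  strengths <- matrix(0, 10, 4)
  strengths[, ] <- c(a, b)    # row means equal a then b
  rownames(strengths) <- subjects$subject
  res <- compare_global_ms(strengths, subjects)
  welch <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(res$t, welch, tolerance = 1e-12)
  pooled <- compare_global_ms(strengths, subjects, var_equal = TRUE)
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  expect_equal(pooled$t, (mean(a) - mean(b)) / sqrt(sp2 * 2 / 5),
               tolerance = 1e-12)
})

test_that("a planted global effect is detected reliably", {
  # decorrelate one strength pole only, so the subject-mean strength shifts
  parc <- small_parc(80, 40, seed = 30)
  hits <- vapply(1:20, function(r) {
    sim0 <- simulate_morphometry(parc, 12, NULL, 0, seed = 900 + r)
    ms0 <- colMeans(cohort_strengths(sim0$table))
    eff <- numeric(80); eff[order(-ms0)[1:16]] <- -1
    sim <- simulate_morphometry(parc, 12, eff, 1.5, seed = 900 + r)
    s <- cohort_strengths(sim$table)
    compare_global_ms(s, sim$table$subjects)$p_t < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.7)
})

test_that("network contrast collapses to the regional model and composes", {
  parc <- small_parc(28, 14, seed = 40)
  sim <- simulate_morphometry(parc, 6, seed = 41)
  s <- cohort_strengths(sim$table)
  subjects <- sim$table$subjects

  net <- network_contrast(s, subjects, parc, "yeo7")
  expect_setequal(net$label, YEO7_LABELS)
  expect_equal(net$p_fdr, p.adjust(net$p, "BH"))

  # composition oracle: aggregate by hand, run the regional model on it
  for (lab in c("VIS", "DMN")) {
    cols <- which(parc$yeo == lab)
    agg <- rowMeans(s[, cols, drop = FALSE])
    hand <- fit_regional_contrast(matrix(agg, ncol = 1,
                                         dimnames = list(NULL, "0")),
                                  subjects)
    expect_equal(net$t[net$label == lab], hand$t[1], tolerance = 1e-10)
    expect_equal(net$p[net$label == lab], hand$p[1], tolerance = 1e-10)
  }

  # all regions one label reproduces the subject-mean model
  one <- parc; one$yeo <- rep("DMN", nrow(one))
  net1 <- network_contrast(s, subjects, one, "yeo7")
  hand1 <- fit_regional_contrast(matrix(rowMeans(s), ncol = 1,
                                        dimnames = list(NULL, "0")), subjects)
  expect_equal(net1$t, hand1$t[1], tolerance = 1e-10)
})

test_that("attendance correlation matches hand rank arithmetic", {
  subjects <- balanced_subjects(8, seed = 7)
  s <- matrix(rnorm(16 * 6), 16, 6, dimnames = list(subjects$subject, 0:5))
  sm <- data.frame(region_id = as.character(0:5),
                   t = c(3, 2.5, -3, -2.5, 1, -1),
                   p = rep(0.001, 6), p_fdr = rep(0.004, 6),
                   significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  class(sm) <- c("regional_stat_map", "data.frame")
  res <- frequency_correlation(s, subjects, sm)
  expect_setequal(res$set, c("positive", "negative", "all"))
  att <- subjects$attendance[subjects$group == "user"]
  for (nm in res$set) {
    idx <- switch(nm, positive = 1:2, negative = 3:4, all = 1:4)
    ms <- rowMeans(s[subjects$group == "user", idx, drop = FALSE])
    # hand rank computation: Pearson correlation of the two rank vectors
    expect_equal(res$rho[res$set == nm], cor(rank(ms), rank(att)),
                 tolerance = 1e-10)
  }

  # monotone attendance in mean strength gives rho = 1
  mono <- subjects
  mono$attendance[mono$group == "user"] <-
    rank(rowMeans(s[mono$group == "user", 1:4]))
  res2 <- frequency_correlation(s, mono, sm)
  expect_equal(res2$rho[res2$set == "all"], 1, tolerance = 1e-12)

  flat <- subjects; flat$attendance[flat$group == "user"] <- 400
  expect_error(frequency_correlation(s, flat, sm), "constant")
  none <- sm; none$significant <- FALSE; none$t <- 0
  w <- capture_warnings(res3 <- frequency_correlation(s, subjects, none))
  expect_true(any(grepl("empty", w)))
  expect_equal(nrow(res3), 0)
})

test_that("jaccard coefficient counts overlap correctly", {
  expect_equal(jaccard_flags(c(TRUE, TRUE, FALSE, TRUE),
                             c(TRUE, FALSE, FALSE, TRUE)), 2 / 3)
  a <- rep(TRUE, 5)
  expect_equal(jaccard_flags(a, a), 1)
  expect_equal(jaccard_flags(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(jaccard_flags(logical(4), logical(4)), 1)
  expect_error(jaccard_flags(logical(3), logical(4)), "length")
})

test_that("adding an uninformative TIV covariate barely moves the t-map", {
  parc <- small_parc(60, 30, seed = 50)
  diffs <- vapply(1:10, function(r) {
    sim <- simulate_morphometry(parc, 24, covariate_model = list(tiv = TRUE),
                                seed = 700 + r)
    s <- cohort_strengths(sim$table)
    t0 <- fit_regional_contrast(s, sim$table$subjects)$t
    t1 <- fit_regional_contrast(s, sim$table$subjects,
                                extra_covariates = "tiv")$t
    mean(abs(t1 - t0))
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})
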
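# shared fixtures; everything is generated in code at test time

small_parc <- function(n = 28, n_left = 14, seed = 42) {
  make_parcellation(n, n_left, seed)
}

# 4-region x 7-feature single-subject table with hand-controllable values
tiny_table <- function(values = NULL, n_regions = 4, subjects = NULL) {
  if (is.null(values)) {
    set.seed(99)
    values <- matrix(rnorm(n_regions * 7), n_regions, 7)
  }
  arr <- array(values, dim = c(1, nrow(values), 7),
               dimnames = list("S001", seq_len(nrow(values)) - 1L,
                               MORPH_FEATURES))
  if (is.null(subjects)) {
    subjects <- data.frame(subject = "S001", group = "user", age = 50,
                           sex = "F", attendance = 100,
                           stringsAsFactors = FALSE)
  }
  msntools:::new_morph_table(arr, subjects)
}

# cohort table with explicit per-subject region x feature matrices
cohort_table <- function(mats, subjects) {
  arr <- array(0, dim = c(length(mats), nrow(mats[[1]]), 7),
               dimnames = list(subjects$subject, seq_len(nrow(mats[[1]])) - 1L,
                               MORPH_FEATURES))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  msntools:::new_morph_table(arr, subjects)
}

balanced_subjects <- function(n_per_group, seed = 1) {
  withr::with_seed(seed, data.frame(
    subject = sprintf("S%03d", seq_len(2 * n_per_group)),
    group = rep(c("user", "control"), each = n_per_group),
    age = rnorm(2 * n_per_group, 55, 10),
    sex = rep(rep_len(c("F", "M"), n_per_group), 2),
    attendance = c(round(rlnorm(n_per_group, 5.9, 0.9)),
                   rep(NA, n_per_group)),
    stringsAsFactors = FALSE))
}

# brute-force MSN: explicit double loop over region pairs
brute_force_msn <- function(x, method = "pearson") {
  R <- nrow(x)
  m <- matrix(0, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j) m[i, j] <- cor(x[i, ], x[j, ], method = method)
  }
  m
}

# independent rank-1 PLS oracle: SVD of the cross-covariance X'y, plus a
# NIPALS-style iterative fit for cross-checking
svd_pls1_oracle <- function(X, y) {
  yc <- y - mean(y)
  sv <- svd(crossprod(X, matrix(yc)))
  w <- sv$u[, 1]
  scores <- as.vector(X %*% w)
  r <- cor(scores, yc)
  if (r < 0) { w <- -w; scores <- -scores; r <- -r }
  list(weights = w, scores = scores, varexp = r^2)
}

nipals_pls1_oracle <- function(X, y, n_iter = 200) {
  yc <- matrix(y - mean(y))
  w <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in seq_len(n_iter)) {
    t_sc <- X %*% w
    q <- crossprod(yc, t_sc) / sum(t_sc^2)
    u <- yc %*% q / sum(q^2)
    w_new <- crossprod(X, u)
    w_new <- w_new / sqrt(sum(w_new^2))
    if (max(abs(w_new - w)) < 1e-13) { w <- w_new; break }
    w <- w_new
  }
  as.vector(w)
}
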
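# Synthetic cohorts with planted effects -------------------------------------
#
# The generator produces parcel-level tables only: a smooth regional profile
# shared by everyone, subject noise on top, and group effects planted on the
# feature COVARIANCE (decorrelating noise to pull regional MS down, shrinkage
# toward the shared profile to push it up), because morphometric similarity is
# a correlation statistic and mean shifts are removed by z-scaling.

# physical scales of the seven features; regional profiles are simulated on a
# z scale and mapped through these so raw tables look like FreeSurfer output
FEATURE_SCALE <- data.frame(
  feature = MORPH_FEATURES,
  mean = c(2.5, 500, 0.12, 0.15, 0.60, 0.40, 1500),
  sd   = c(0.25, 80, 0.02, 0.03, 0.10, 0.08, 220))

# loadings of the seven features on the principal morphometric gradient:
# thickness / area / volume / folding co-vary positively along the
# sensory-association axis, the curvature measures run against it; this
# inter-feature covariance is what makes region-pair correlations strong.
# Magnitudes are kept equal so every feature carries the same variance and
# per-subject z-scaling acts uniformly across features.
GRADIENT_LOADINGS <- c(CT = 1, SA = 1, MC = -1, GC = -1,
                       FI = 1, CI = 1, GM = 1) / sqrt(7)

great_circle_dist <- function(a, b = a) {
  cosd <- tcrossprod(a, b)
  acos(pmin(pmax(cosd, -1), 1))   # matrix first: pmin/pmax keep its dims
}

# draws from a Gaussian random field over centroids with exponential
# covariance exp(-d / length_scale); returns n_regions x n_draws
gp_draws <- function(cen, n_draws, length_scale, chol_cache = NULL) {
  L <- if (is.null(chol_cache)) gp_chol(cen, length_scale) else chol_cache
  crossprod(L, matrix(stats::rnorm(nrow(cen) * n_draws), nrow(cen), n_draws))
}

gp_chol <- function(cen, length_scale) {
  K <- exp(-great_circle_dist(cen) / length_scale)
  chol(K + diag(1e-8, nrow(cen)))
}

#' Plant a sparse signed regional effect map
#'
#' Picks `n_affected` regions at random and assigns them effect magnitudes of
#' +/- `magnitude`; all other regions get exactly zero. Negative entries drive
#' regional MS down (differentiation), positive entries drive it up
#' (de-differentiation) in [simulate_morphometry()].
#'
#' @param parcellation a `parcellation`.
#' @param n_affected number of affected regions.
#' @param magnitude absolute planted effect size (z-profile units).
#' @param sign "both" (half/half), "negative", or "positive".
#' @param seed integer seed.
#' @return list with `effect_map` (length R), `affected_regions`
#'   (0-based region ids) and `seed`.
#' @export
random_effect_map <- function(parcellation, n_affected, magnitude = 1,
                              sign = c("both", "negative", "positive"),
                              seed = 1) {
  sign <- match.arg(sign)
  R <- nrow(parcellation)
  if (n_affected > R) stop("n_affected exceeds number of regions")
  withr::with_seed(seed, {
    idx <- sample.int(R, n_affected)
    sgn <- switch(sign,
      both = rep_len(c(-1, 1), n_affected),
      negative = rep(-1, n_affected),
      positive = rep(1, n_affected))
  })
  effect <- numeric(R)
  effect[idx] <- sgn * magnitude
  list(effect_map = effect,
       affected_regions = sort(parcellation$region_id[idx]),
       seed = seed)
}

#' Plant a decorrelating effect at hub regions of a reference cohort
#'
#' Regional MS is a sum of correlations, so feature-covariance perturbations
#' are only measurable where baseline similarity is strong. This planner
#' selects `n_affected` hub regions - half from each strength pole of a
#' reference (null) cohort - and refines the choice by greedy swaps within
#' the top-`n_pool` candidates per pole so that the planted set's summed
#' correlation to the rest of cortex (the expected off-target spillover of a
#' uniform attenuation) is as close to zero as possible.
#'
#' @param table a `morph_table` from a null cohort (no planted effect).
#' @param n_affected number of affected regions (even).
#' @param magnitude absolute planted effect size.
#' @param n_pool candidate pool size per strength pole.
#' @return list with `effect_map` (`-magnitude` at the selected hubs: a
#'   decorrelating perturbation), `association_map` (the expected direction
#'   of the induced group contrast, `-mean MS` at the hubs, zero elsewhere;
#'   the target for planted gene maps), `affected_regions` (0-based ids).
#' @export
hub_effect_map <- function(table, n_affected = 20, magnitude = 1, n_pool = 20) {
  stopifnot(inherits(table, "morph_table"), n_affected %% 2 == 0)
  std <- if (isTRUE(table$standardized)) table else zscore_features(table)
  ids <- dimnames(std$values)[[1]]
  M0 <- Reduce(`+`, lapply(ids, function(id) unclass(build_msn(std, id)))) /
    length(ids)
  ms0 <- rowSums(M0)
  n_pick <- n_affected / 2
  cand_p <- order(-ms0)[seq_len(n_pool)]
  cand_n <- order(ms0)[seq_len(n_pool)]
  A <- c(cand_p[seq_len(n_pick)], cand_n[seq_len(n_pick)])
  spill <- rowSums(M0[, A, drop = FALSE])
  obj <- function(sp, A) sum(sp[-A]^2)
  repeat {
    improved <- FALSE
    for (slot in seq_along(A)) {
      pool <- if (slot <= n_pick) cand_p else cand_n
      for (cand in setdiff(pool, A)) {
        sp2 <- spill - M0[, A[slot]] + M0[, cand]
        A2 <- A; A2[slot] <- cand
        if (obj(sp2, A2) < obj(spill, A) - 1e-9) {
          A <- A2; spill <- sp2; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  R <- dim(std$values)[2]
  effect <- numeric(R); effect[A] <- -magnitude
  assoc <- numeric(R); assoc[A] <- -ms0[A] / max(abs(ms0[A]))
  region_ids <- suppressWarnings(as.integer(dimnames(std$values)[[2]]))
  if (anyNA(region_ids)) region_ids <- seq_len(R) - 1L
  list(effect_map = effect, association_map = assoc,
       affected_regions = sort(region_ids[A]))
}

default_covariate_model <- function() {
  list(age_mean_user = 55.2, age_sd_user = 10.2,
       age_mean_control = 55.7, age_sd_control = 13,
       attendance_meanlog = 5.91, attendance_sdlog = 0.92,
       tiv = FALSE)
}

#' Simulate a two-group regional-morphometry cohort
#'
#' Every subject's regions x features table is a shared smooth regional
#' profile (Gaussian random field over the spherical centroids, exponential
#' kernel) plus independent subject noise, mapped to physical feature units.
#' For subjects in the "user" group the planted `effect_map` perturbs the
#' feature covariance at affected regions: where `effect_map < 0` the region
#' receives extra independent feature noise with SD
#' `effect_scale * |effect_map|` (decorrelating it from the rest of cortex);
#' where `effect_map > 0` the subject's deviation from the shared profile is
#' shrunk by `min(1, effect_scale * effect_map)` (homogenising it).
#'
#' @param parcellation a `parcellation`.
#' @param n_per_group subjects per group (>= 3).
#' @param effect_map numeric vector of length R (default all zero).
#' @param effect_scale non-negative multiplier on the planted effect.
#' @param noise_sd SD of subject-level regional noise on the z scale.
#' @param covariate_model list of demographic parameters; see
#'   `default_covariate_model()` (age distributions, ceremony-attendance
#'   log-normal, whether to simulate TIV).
#' @param seed integer seed.
#' @param profile_length length scale (radians) of the shared profile's
#'   spatial kernel.
#' @param gradient_strength SD of the principal morphometric gradient, which
#'   carries fixed inter-feature loadings (see `GRADIENT_LOADINGS`) and makes
#'   region-pair feature correlations strong, as in real cortex.
#' @param idio_strength SD of feature-specific smooth structure.
#' @param gradient_skew lognormal skew coefficient of the gradient field
#'   (0 = symmetric Gaussian field); positive values give a minority pole of
#'   deep gradient values against a shallow majority.
#' @return list with `table` (a `morph_table`) and `truth` (ground-truth
#'   record: effect map, affected regions, seed).
#' @export
simulate_morphometry <- function(parcellation, n_per_group = 24,
                                 effect_map = NULL, effect_scale = 0,
                                 noise_sd = 0.6,
                                 covariate_model = list(),
                                 seed = 1, profile_length = 0.4,
                                 gradient_strength = 2, idio_strength = 0.6,
                                 gradient_skew = 0.7) {
  R <- nrow(parcellation)
  if (is.null(effect_map)) effect_map <- numeric(R)
  if (length(effect_map) != R) stop("effect_map must have length ", R)
  if (n_per_group < 3) stop("n_per_group must be >= 3 (covariate model unidentifiable)")
  if (effect_scale < 0) stop("effect_scale must be non-negative")
  cm <- utils::modifyList(default_covariate_model(), covariate_model)
  n_sub <- 2L * n_per_group
  n_feat <- length(MORPH_FEATURES)

  withr::with_seed(seed, {
    # shared regional profile, hemispheres drawn symmetrically (same process,
    # independent realisations): a smooth principal gradient carried by fixed
    # inter-feature loadings plus smaller feature-specific smooth structure
    lam <- GRADIENT_LOADINGS / sqrt(sum(GRADIENT_LOADINGS^2))
    P0 <- matrix(0, R, n_feat)
    for (h in c("L", "R")) {
      rows <- which(parcellation$hemisphere == h)
      cen <- centroids(parcellation, h)
      ch <- gp_chol(cen, profile_length)
      g <- as.vector(gp_draws(cen, 1, profile_length, ch))
      g <- (g - mean(g)) / stats::sd(g)
      # lognormal-style skew: a minority pole of deep gradient values against
      # a shallow majority (as primary cortex stands out against the broader
      # association cortex), so pole imbalance - and with it the existence of
      # strong hubs - is stable across realisations
      if (gradient_skew > 0) {
        g <- exp(gradient_skew * g)
        g <- (g - mean(g)) / stats::sd(g)
      }
      P0[rows, ] <- gradient_strength * outer(g, lam * sqrt(n_feat)) +
        idio_strength * gp_draws(cen, n_feat, profile_length, ch)
    }

    group <- rep(c("user", "control"), each = n_per_group)
    sex <- rep(rep_len(c("F", "M"), n_per_group), 2)
    age <- c(stats::rnorm(n_per_group, cm$age_mean_user, cm$age_sd_user),
             stats::rnorm(n_per_group, cm$age_mean_control, cm$age_sd_control))
    age <- pmax(age, 20)
    attendance <- ifelse(
      group == "user",
      round(stats::rlnorm(n_sub, cm$attendance_meanlog, cm$attendance_sdlog)),
      NA_real_)

    neg <- which(effect_map < 0)
    pos <- which(effect_map > 0)
    shrink <- pmin(1, effect_scale * effect_map[pos])
    # decorrelating noise is proportional to each region's own feature-vector
    # scale, so the induced correlation attenuation 1/sqrt(1 + (es*|e|)^2) is
    # the same at every affected region regardless of its profile amplitude
    # feature-wise z-scoring re-centres each column downstream, so the scale
    # that governs a region's correlations is that of the centred profile
    P0c <- sweep(P0, 2, colMeans(P0))
    region_scale <- sqrt(apply(P0c, 1, stats::var) + noise_sd^2)

    values <- array(0, dim = c(n_sub, R, n_feat))
    for (s in seq_len(n_sub)) {
      eps <- matrix(stats::rnorm(R * n_feat, sd = noise_sd), R, n_feat)
      if (group[s] == "user" && effect_scale > 0) {
        if (length(neg)) {
          eps[neg, ] <- eps[neg, ] +
            matrix(stats::rnorm(length(neg) * n_feat), length(neg), n_feat) *
            (effect_scale * abs(effect_map[neg]) * region_scale[neg])
        }
        if (length(pos)) eps[pos, ] <- eps[pos, ] * (1 - shrink)
      }
      z <- P0 + eps
      values[s, , ] <- sweep(sweep(z, 2, FEATURE_SCALE$sd, "*"),
                             2, FEATURE_SCALE$mean, "+")
    }

    subjects <- data.frame(
      subject = sprintf("S%03d", seq_len(n_sub)),
      group = group, age = age, sex = sex,
      attendance = attendance, stringsAsFactors = FALSE)
    if (isTRUE(cm$tiv)) {
      # TIV ~ 3.2x total grey matter with measurement noise scaled to keep
      # their correlation around 0.8 regardless of parcellation size
      gm_total <- apply(values[, , n_feat, drop = FALSE], 1, sum)
      noise <- 0.75 * stats::sd(gm_total) * 3.2 + 1e-6
      subjects$tiv <- 3.2 * gm_total + stats::rnorm(n_sub, 0, noise)
    }
  })

  dimnames(values) <- list(subjects$subject, parcellation$region_id,
                           MORPH_FEATURES)
  table <- new_morph_table(values, subjects)
  truth <- list(effect_map = effect_map,
                affected_regions = parcellation$region_id[effect_map != 0],
                planted_genes_pos = integer(0),
                planted_genes_neg = integer(0),
                seed = seed)
  list(table = table, truth = truth)
}

#' Simulate left-hemisphere gene-expression maps
#'
#' Each unplanted gene is an independent Gaussian random field over the
#' left-hemisphere centroids (exponential covariance, length scale
#' `autocorr_length`), z-scored across regions. Each planted gene mixes the
#' z-scored planted effect map (positive or negative sign) with autocorrelated
#' noise at `association_strength`, so that its true spatial correlation with
#' the effect map is `+/- association_strength`.
#'
#' @param parcellation a `parcellation` (left-hemisphere regions are used).
#' @param n_genes number of gene maps.
#' @param autocorr_length spatial length scale in radians.
#' @param effect_map length-R effect map (only the left part is used).
#' @param planted_pos,planted_neg disjoint 0-based gene indices.
#' @param association_strength in [0, 1].
#' @param seed integer seed.
#' @param gene_symbols optional character vector of column names.
#' @return `expression_matrix`: left regions x genes, each column z-scored;
#'   rownames are region ids, attribute `region_ids` carries them as integers.
#' @export
simulate_expression <- function(parcellation, n_genes = 66,
                                autocorr_length = 0.5,
                                effect_map = NULL,
                                planted_pos = integer(0),
                                planted_neg = integer(0),
                                association_strength = 0,
                                seed = 1, gene_symbols = NULL) {
  if (association_strength < 0 || association_strength > 1) {
    stop("association_strength must lie in [0, 1]")
  }
  planted_pos <- as.integer(planted_pos); planted_neg <- as.integer(planted_neg)
  if (length(intersect(planted_pos, planted_neg))) {
    stop("planted gene sets must be disjoint")
  }
  planted <- c(planted_pos, planted_neg)
  if (length(planted) && (min(planted) < 0 || max(planted) >= n_genes)) {
    stop("planted gene indices must lie in 0..n_genes-1")
  }
  left <- parcellation$hemisphere == "L"
  cen <- centroids(parcellation, "L")
  RL <- nrow(cen)
  if (is.null(effect_map)) effect_map <- numeric(nrow(parcellation))
  target <- effect_map[left]
  if (length(planted) && stats::sd(target) == 0) {
    stop("planted genes requested but effect_map is constant over the left hemisphere")
  }
  zs <- function(v) (v - mean(v)) / stats::sd(v)

  withr::with_seed(seed, {
    X <- gp_draws(cen, n_genes, autocorr_length)
    X <- apply(X, 2, zs)
    if (length(planted)) {
      tz <- zs(target)
      s <- association_strength
      for (g in planted) {
        sgn <- if (g %in% planted_pos) 1 else -1
        X[, g + 1L] <- zs(s * sgn * tz + sqrt(1 - s^2) * zs(X[, g + 1L]))
      }
    }
  })

  if (is.null(gene_symbols)) gene_symbols <- default_gene_symbols(n_genes)
  dimnames(X) <- list(parcellation$region_id[left], gene_symbols)
  structure(X, region_ids = parcellation$region_id[left],
            class = c("expression_matrix", "matrix", "array"))
}

# receptor / transporter / plasticity symbols typical of a psychedelic target
# panel; padded with placeholder symbols beyond the named set
default_gene_symbols <- function(n) {
  base <- c("HTR2A", "HTR1A", "HTR2C", "HTR1B", "HTR7", "SLC6A4", "MAOA",
            "MAOB", "SIGMAR1", "DRD1", "DRD2", "ADRA2A", "CNR1", "TAAR1",
            "GRIN1", "GRIN2A", "GRIN2B", "GRIA1", "GRIA2", "GRM2", "GRM5",
            "BDNF", "NTRK2", "MTOR", "FOS", "ARC", "JUNB", "EGR1", "EGR2",
            "NR4A1", "DUSP1", "S100A10", "CAMK2A", "MAPK1", "CREB1", "ELK1")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("GENE%02d", seq_len(n - length(base))))
}

# --- containers --------------------------------------------------------------

new_morph_table <- function(values, subjects, standardized = FALSE) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(MORPH_FEATURES))
  structure(list(values = values, feature_names = MORPH_FEATURES,
                 subjects = subjects, standardized = standardized),
            class = "morph_table")
}

#' @export
print.morph_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("morph_table: %d subjects x %d regions x %d features%s\n",
              d[1], d[2], d[3], if (x$standardized) " (z-scored)" else ""))
  invisible(x)
}

#' Number of regions in a morphometry table
#' @param table a `morph_table`.
#' @export
n_regions <- function(table) dim(table$values)[2]

# --- writers / readers -------------------------------------------------------

#' Write a morphometry cohort as long-format TSV plus a subjects TSV
#' @param table a `morph_table`.
#' @param values_path,subjects_path output file paths.
#' @export
write_morphometry <- function(table, values_path, subjects_path) {
  d <- dim(table$values)
  long <- data.frame(
    subject = rep(dimnames(table$values)[[1]], times = d[2] * d[3]),
    region_id = rep(rep(dimnames(table$values)[[2]], each = d[1]), times = d[3]),
    feature = rep(table$feature_names, each = d[1] * d[2]),
    value = as.vector(table$values))
  utils::write.table(long, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$subjects, subjects_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}

#' Read a morphometry cohort written by [write_morphometry()]
#' @param values_path,subjects_path file paths.
#' @return a `morph_table`.
#' @export
read_morphometry <- function(values_path, subjects_path) {
  long <- utils::read.delim(values_path, stringsAsFactors = FALSE)
  subjects <- utils::read.delim(subjects_path, stringsAsFactors = FALSE)
  if (anyNA(long$value)) stop("missing values in morphometry table")
  subs <- subjects$subject
  regs <- as.character(sort(unique(as.integer(long$region_id))))
  values <- array(NA_real_,
                  dim = c(length(subs), length(regs), length(MORPH_FEATURES)),
                  dimnames = list(subs, regs, MORPH_FEATURES))
  idx <- cbind(match(long$subject, subs),
               match(as.character(long$region_id), regs),
               match(long$feature, MORPH_FEATURES))
  values[idx] <- long$value
  if (anyNA(values)) stop("incomplete morphometry table (missing cells)")
  new_morph_table(values, subjects)
}

#' Write / read an expression matrix as TSV (rows regions, columns genes)
#' @param expr an `expression_matrix`.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(region_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region_id
  structure(m, region_ids = as.integer(df$region_id),
            class = c("expression_matrix", "matrix", "array"))
}
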
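#' @keywords internal
"_PACKAGE"

#' Canonical Yeo-7 resting-state network labels
#' @export
YEO7_LABELS <- c("VIS", "SMN", "DAN", "VAN", "L", "FPN", "DMN")

#' Canonical von Economo cytoarchitectonic class labels
#' @export
VON_ECONOMO_LABELS <- c("PrimMotor", "Asso1", "Asso2", "SecSens",
                        "PrimSens", "Limbic", "Insula")

#' The seven T1-weighted morphometric features, in canonical order
#'
#' Cortical thickness (mm), surface area (mm^2), mean extrinsic curvature
#' (1/mm), Gaussian intrinsic curvature (1/mm^2), folding index, curvature
#' index and grey-matter volume (mm^3).
#' @export
MORPH_FEATURES <- c("CT", "SA", "MC", "GC", "FI", "CI", "GM")

# quasi-uniform points on the unit sphere: Fibonacci lattice, then a random
# rotation so different seeds give different (still quasi-uniform) layouts
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

random_rotation_matrix <- function() {
  qr_m <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_m)
  q <- q %*% diag(sign(diag(qr.R(qr_m))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# 7 spatially contiguous label patches via k-means on the centroids;
# retried with fresh starts in the rare case of an empty cluster
contiguous_labels <- function(centroids, labels) {
  k <- length(labels)
  if (nrow(centroids) == k) return(labels[sample.int(k)])
  for (attempt in 1:25) {
    km <- tryCatch(
      stats::kmeans(centroids, centers = k, nstart = 5, iter.max = 50),
      error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) {
      return(labels[km$cluster])
    }
  }
  stop("could not partition centroids into ", k, " non-empty patches")
}

#' Build a synthetic two-hemisphere cortical parcellation
#'
#' Region centroids are placed quasi-uniformly on each hemisphere's unit
#' sphere (the spherical registration space in which spin nulls operate) and
#' each hemisphere is partitioned into seven spatially contiguous Yeo-7
#' network patches and seven von Economo cytoarchitectonic patches, so that
#' label maps carry realistic spatial autocorrelation.
#'
#' @param n_regions total number of cortical regions (>= 14).
#' @param n_left number of left-hemisphere regions (>= 7, with >= 7 right).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A `parcellation` data.frame with columns `region_id` (0-based),
#'   `name`, `hemisphere` ("L"/"R"), centroid coordinates `cx`, `cy`, `cz`
#'   (unit vectors), `yeo` and `von_economo` labels.
#' @examples
#' parc <- make_parcellation(64, 32, seed = 1)
#' table(parc$hemisphere)
#' @export
make_parcellation <- function(n_regions, n_left, seed) {
  if (n_left > n_regions) stop("n_left (", n_left, ") exceeds n_regions (", n_regions, ")")
  n_right <- n_regions - n_left
  if (n_regions < 14 || n_left < 7 || n_right < 7) {
    stop("need >= 7 regions per hemisphere so every label can occur")
  }
  withr::with_seed(seed, {
    hemi_df <- function(n, hemi) {
      cen <- fibonacci_sphere(n) %*% t(random_rotation_matrix())
      cen <- cen / sqrt(rowSums(cen^2))
      data.frame(
        hemisphere = hemi,
        cx = cen[, 1], cy = cen[, 2], cz = cen[, 3],
        yeo = contiguous_labels(cen, YEO7_LABELS),
        von_economo = contiguous_labels(cen, VON_ECONOMO_LABELS),
        stringsAsFactors = FALSE)
    }
    parc <- rbind(hemi_df(n_left, "L"), hemi_df(n_right, "R"))
  })
  parc$region_id <- seq_len(n_regions) - 1L
  parc$name <- sprintf("%s_%03d", parc$hemisphere, c(seq_len(n_left), seq_len(n_right)))
  parc <- parc[, c("region_id", "name", "hemisphere",
                   "cx", "cy", "cz", "yeo", "von_economo")]
  rownames(parc) <- NULL
  class(parc) <- c("parcellation", "data.frame")
  parc
}

#' Extract the centroid matrix of a parcellation
#' @param parcellation a `parcellation` object.
#' @param hemisphere optionally restrict to "L" or "R".
#' @return numeric matrix with one unit-norm row per region.
#' @export
centroids <- function(parcellation, hemisphere = NULL) {
  p <- parcellation
  if (!is.null(hemisphere)) p <- p[p$hemisphere == hemisphere, , drop = FALSE]
  m <- as.matrix(p[, c("cx", "cy", "cz")])
  rownames(m) <- p$region_id
  m
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d regions (%d L / %d R)\n",
              nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R")))
  NextMethod()
}

#' Write / read a parcellation metadata table as TSV
#' @param parcellation a `parcellation` object.
#' @param path output file path.
#' @export
write_parcellation <- function(parcellation, path) {
  utils::write.table(as.data.frame(parcellation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  parc <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("region_id", "name", "hemisphere", "cx", "cy", "cz",
              "yeo", "von_economo")
  missing <- setdiff(needed, names(parc))
  if (length(missing)) stop("parcellation file lacks columns: ",
                            paste(missing, collapse = ", "))
  class(parc) <- c("parcellation", "data.frame")
  parc
}
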
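#' Polar histogram of dendrite orientation
#'
#' Angular mass distribution of the vectors from a reference point (the
#' dendrite's first branching point) to every suprathreshold pixel or
#' point, binned into `n_bins` equal angular bins and normalized to the
#' total vector count.
#'
#' @param bin_masses Non-negative bin fractions.
#' @param n_vectors Number of contributing vectors.
#' @param reference_point 2D coordinate the vectors emanate from.
#' @param scale_factor Optional positive factor applied to the masses for
#'   cross-stage display scaling (set by [scale_histogram]); when absent
#'   the masses must sum to 1.
#' @return Object of class `polar_histogram` with fields `bin_masses`,
#'   `bin_edges` (degrees), `n_vectors`, `reference_point`,
#'   `scale_factor`.
#' @export
polar_histogram <- function(bin_masses, n_vectors,
                            reference_point = c(0, 0), scale_factor = NULL) {
  n_bins <- length(bin_masses)
  if (n_bins < 1) stop("at least one bin required", call. = FALSE)
  if (any(bin_masses < 0)) stop("bin masses must be non-negative", call. = FALSE)
  if (n_vectors < 0) stop("n_vectors must be >= 0", call. = FALSE)
  if (!is.null(scale_factor) && scale_factor <= 0) {
    stop("scale_factor must be positive", call. = FALSE)
  }
  if (is.null(scale_factor) && n_vectors > 0 &&
      abs(sum(bin_masses) - 1) > 1e-9) {
    stop("unscaled bin masses must sum to 1", call. = FALSE)
  }
  structure(list(bin_masses = as.numeric(bin_masses),
                 bin_edges = seq(0, 360, length.out = n_bins + 1),
                 n_vectors = as.integer(n_vectors),
                 reference_point = reference_point,
                 scale_factor = scale_factor),
            class = "polar_histogram")
}

#' @export
print.polar_histogram <- function(x, digits = 3, ...) {
  cat("polar_histogram:", length(x$bin_masses), "bins,",
      x$n_vectors, "vectors")
  if (!is.null(x$scale_factor)) cat(", scale factor", signif(x$scale_factor, 4))
  cat("\n")
  lab <- sprintf("[%g,%g)", utils::head(x$bin_edges, -1), x$bin_edges[-1])
  print(stats::setNames(round(x$bin_masses, digits), lab))
  invisible(x)
}

#' @export
plot.polar_histogram <- function(x, ...) {
  n <- length(x$bin_masses)
  mids <- (utils::head(x$bin_edges, -1) + x$bin_edges[-1]) / 2 * pi / 180
  r <- x$bin_masses
  lim <- max(r) * 1.1
  plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
       xlab = "", ylab = "", axes = FALSE, ...)
  for (i in seq_len(n)) {
    th <- seq(x$bin_edges[i], x$bin_edges[i + 1], length.out = 12) * pi / 180
    graphics::polygon(c(0, r[i] * cos(th), 0), c(0, r[i] * sin(th), 0),
                      col = "grey70", border = "grey30")
  }
  graphics::symbols(0, 0, circles = lim / 1.1, inches = FALSE, add = TRUE,
                    fg = "grey85")
  invisible(x)
}

bin_angles <- function(angles_deg, n_bins) {
  ang <- angles_deg %% 360
  ang[ang >= 360] <- 0 # floating-point guard: (-eps) %% 360 can yield 360
  b <- floor(ang / (360 / n_bins)) + 1L
  b[b > n_bins] <- n_bins
  tabulate(b, nbins = n_bins)
}

#' Compute an orientation polar histogram
#'
#' For every suprathreshold pixel of an image (or every point of a point
#' set), the angle of the vector from `center` is computed in degrees,
#' counterclockwise from the +x axis, and assigned to a half-open bin
#' `[lo, hi)`. Masses are normalized by the total vector count; pixels
#' exactly at the center are excluded.
#'
#' @param x A numeric n x 2 (or n x 3, third column = intensity) point
#'   matrix, a `dendrite_image`, a 2D image matrix, a 3D array (reduced
#'   by maximum-intensity projection along the third axis), or a
#'   [neuron_skeleton] (dendritic node positions relative to the first
#'   branching point).
#' @param center Reference point `c(x, y)`. Defaults to the branch point
#'   of a `dendrite_image`/skeleton; required for bare point sets and
#'   image matrices.
#' @param intensity_threshold Pixels with intensity strictly greater than
#'   this contribute a vector. `NULL` (default) uses Otsu's method on the
#'   image; ignored for point sets without an intensity column.
#' @param n_bins Number of angular bins (default 12, i.e. 30-degree
#'   bins).
#' @return A [polar_histogram].
#' @export
orientation_histogram <- function(x, center = NULL, intensity_threshold = NULL,
                                  n_bins = 12) {
  UseMethod("orientation_histogram")
}

hist_from_points <- function(pts, center, n_bins) {
  if (n_bins < 1) stop("n_bins must be positive", call. = FALSE)
  if (any(!is.finite(center))) stop("center must be finite", call. = FALSE)
  dx <- pts[, 1] - center[1]
  dy <- pts[, 2] - center[2]
  keep <- !(dx == 0 & dy == 0)
  if (!any(keep)) {
    stop("no vectors: every point coincides with the center", call. = FALSE)
  }
  ang <- atan2(dy[keep], dx[keep]) * 180 / pi
  counts <- bin_angles(ang, n_bins)
  polar_histogram(counts / sum(counts), n_vectors = sum(counts),
                  reference_point = center)
}

#' @export
orientation_histogram.default <- function(x, center = NULL,
                                          intensity_threshold = NULL,
                                          n_bins = 12) {
  if (is.array(x) && length(dim(x)) == 3) {
    x <- apply(x, c(1, 2), max) # maximal projection along z
  }
  x <- as.matrix(x)
  # matrices with 2-3 columns are point sets (x, y[, intensity]); wider
  # matrices are images (rows = y, columns = x)
  if (ncol(x) %in% c(2L, 3L)) {
    if (is.null(center)) stop("center is required for point-set input",
                              call. = FALSE)
    if (ncol(x) == 3L && !is.null(intensity_threshold)) {
      x <- x[x[, 3] > intensity_threshold, , drop = FALSE]
      if (!nrow(x)) stop("zero suprathreshold points", call. = FALSE)
    }
    return(hist_from_points(x[, 1:2, drop = FALSE], center, n_bins))
  }
  orientation_histogram_image(x, center, intensity_threshold, n_bins)
}

#' @export
orientation_histogram.dendrite_image <- function(x, center = NULL,
                                                 intensity_threshold = NULL,
                                                 n_bins = 12) {
  if (is.null(center)) center <- x$branch_point
  orientation_histogram_image(x$image, center, intensity_threshold, n_bins)
}

#' @export
orientation_histogram.neuron_skeleton <- function(x, center = NULL,
                                                  intensity_threshold = NULL,
                                                  n_bins = 12) {
  if (is.null(center)) {
    bp <- first_branch_point(x)
    center <- c(bp["x"], bp["y"])
  }
  dend <- x$nodes[x$nodes$type == 3, c("x", "y")]
  if (!nrow(dend)) stop("skeleton has no dendrite compartment", call. = FALSE)
  hist_from_points(as.matrix(dend), center, n_bins)
}

orientation_histogram_image <- function(img, center, intensity_threshold,
                                        n_bins) {
  if (is.null(center)) stop("center is required for image input", call. = FALSE)
  if (center[1] < 1 || center[1] > ncol(img) ||
      center[2] < 1 || center[2] > nrow(img)) {
    stop("center lies outside the image bounds", call. = FALSE)
  }
  if (is.null(intensity_threshold)) {
    intensity_threshold <- otsu_threshold(img)
  }
  if (intensity_threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  hit <- which(img > intensity_threshold, arr.ind = TRUE)
  if (!nrow(hit)) stop("zero suprathreshold pixels", call. = FALSE)
  # x = column, y = row
  pts <- cbind(hit[, "col"], hit[, "row"])
  hist_from_points(pts, center, n_bins)
}

# Otsu's threshold on the raw intensity scale (via EBImage on [0,1]).
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  t01 <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)))
  rng[1] + t01 * diff(rng)
}

#' Scale an early-stage histogram to a late-stage pixel count
#'
#' Multiplies the bin masses of `h_early` by the ratio of vector counts
#' `n_vectors(h_early) / n_vectors(h_late)`, so that histograms of the
#' same neuron at different stages visualize arbor-size changes (the
#' scaled masses sum to the scale factor, not 1).
#'
#' @param h_early,h_late Normalized [polar_histogram]s with positive
#'   vector counts.
#' @return `h_early` with `scale_factor` set and masses rescaled.
#' @export
scale_histogram <- function(h_early, h_late) {
  stopifnot(inherits(h_early, "polar_histogram"),
            inherits(h_late, "polar_histogram"))
  if (h_late$n_vectors == 0) stop("late histogram has no vectors", call. = FALSE)
  if (h_early$n_vectors == 0) stop("early histogram has no vectors", call. = FALSE)
  f <- h_early$n_vectors / h_late$n_vectors
  h_early$bin_masses <- h_early$bin_masses * f
  h_early$scale_factor <- f
  h_early
}

#' Average polar histograms (mean and standard error)
#'
#' Per-bin arithmetic mean and standard error of the mean (sample
#' standard deviation divided by sqrt(n)) across histograms with
#' identical binning. With a single histogram the s.e.m. is reported as 0
#' and flagged.
#'
#' @param histograms List of [polar_histogram]s.
#' @return Object of class `polar_histogram_summary`: `mean` (a
#'   [polar_histogram] whose `n_vectors` is the summed count), `sem`
#'   (per-bin numeric), `n`, and `sem_undefined` (TRUE when n = 1).
#' @export
average_histograms <- function(histograms) {
  if (!length(histograms)) stop("no histograms to average", call. = FALSE)
  stopifnot(all(vapply(histograms, inherits, TRUE, "polar_histogram")))
  edges <- lapply(histograms, `[[`, "bin_edges")
  if (!all(vapply(edges, identical, TRUE, edges[[1]]))) {
    stop("histograms have mixed bin edges", call. = FALSE)
  }
  m <- do.call(rbind, lapply(histograms, `[[`, "bin_masses"))
  n <- nrow(m)
  mean_mass <- colMeans(m)
  sem <- if (n == 1) rep(0, ncol(m)) else apply(m, 2, stats::sd) / sqrt(n)
  structure(list(
    mean = polar_histogram(mean_mass / sum(mean_mass),
                           n_vectors = sum(vapply(histograms, `[[`, 1L,
                                                  "n_vectors")),
                           reference_point = histograms[[1]]$reference_point),
    sem = sem, n = n, sem_undefined = (n == 1)),
    class = "polar_histogram_summary")
}

#' @export
print.polar_histogram_summary <- function(x, ...) {
  cat("average of", x$n, "polar histograms",
      if (x$sem_undefined) "(s.e.m. undefined for n = 1, reported as 0)",
      "\n")
  print(x$mean)
  cat("s.e.m.:", paste(signif(x$sem, 3), collapse = " "), "\n")
  invisible(x)
}

as_histogram <- function(h) {
  if (inherits(h, "polar_histogram_summary")) h$mean else h
}

#' Similarity index between two orientation histograms
#'
#' The sum over bins of absolute differences between two normalized
#' polar histograms. Zero means identical orientation distributions;
#' the maximum for normalized histograms is 2 (fully disjoint mass).
#' Lower values mean more similar dendrite orientations.
#'
#' @param h1,h2 Normalized [polar_histogram]s (or
#'   `polar_histogram_summary`, whose mean is used) with identical bin
#'   edges and no scale factor.
#' @return Non-negative number in `[0, 2]`.
#' @export
similarity_index <- function(h1, h2) {
  h1 <- as_histogram(h1); h2 <- as_histogram(h2)
  stopifnot(inherits(h1, "polar_histogram"), inherits(h2, "polar_histogram"))
  if (!identical(h1$bin_edges, h2$bin_edges)) {
    stop("histograms have mismatched binning", call. = FALSE)
  }
  if (!is.null(h1$scale_factor) || !is.null(h2$scale_factor)) {
    stop("similarity index requires normalized (unscaled) histograms",
         call. = FALSE)
  }
  sum(abs(h1$bin_masses - h2$bin_masses))
}

#' Similarity matrix between query and reference histograms
#'
#' @param query_histograms,reference_histograms Lists of normalized
#'   [polar_histogram]s with compatible binning.
#' @return Matrix with one row per reference and one column per query;
#'   entry (i, j) is `similarity_index(reference_i, query_j)`. Input
#'   names become dimnames.
#' @export
similarity_matrix <- function(query_histograms, reference_histograms) {
  if (!length(query_histograms) || !length(reference_histograms)) {
    stop("empty histogram list", call. = FALSE)
  }
  m <- vapply(query_histograms, function(q) {
    vapply(reference_histograms, similarity_index, numeric(1), h2 = q)
  }, numeric(length(reference_histograms)))
  m <- matrix(m, nrow = length(reference_histograms),
              dimnames = list(names(reference_histograms),
                              names(query_histograms)))
  m
}

#' Classify a neuron by nearest reference orientation
#'
#' Returns the subtype of the reference histogram with the smallest
#' similarity index to the query. Ties are broken deterministically in
#' subtype order a < b < c < d and flagged.
#'
#' @param query A normalized [polar_histogram].
#' @param references Named list of reference histograms covering all four
#'   subtypes `a`, `b`, `c`, `d` (e.g. per-subtype averages from
#'   [average_histograms]).
#' @return List with `subtype`, `tie` (logical), and `index` (named
#'   similarity values).
#' @export
classify_by_dendrite <- function(query, references) {
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(references))) {
    stop("references must cover subtypes a, b, c, d", call. = FALSE)
  }
  idx <- vapply(references[need], similarity_index, numeric(1), h2 = query)
  best <- min(idx)
  winners <- need[idx == best]
  list(subtype = winners[1], tie = length(winners) > 1, index = idx)
}
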
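#' Lobula-plate boundary frame
#'
#' Describes, for each proximodistal coordinate, the positions of the
#' posterior and anterior edges of the lobula plate along the
#' anteroposterior axis (same length units as the neuron coordinates).
#' Either supply a table of edge positions or the rectangle shorthand
#' (`ap_extent`, `pd_extent`) used by the synthetic generator.
#'
#' @param edges data.frame with columns `pd` (proximodistal coordinate),
#'   `posterior`, `anterior`; edges must have positive extent everywhere.
#' @param ap_extent,pd_extent Rectangle shorthand: posterior edge at 0
#'   and anterior edge at `ap_extent` over the proximodistal range
#'   `[0, pd_extent]`.
#' @return Object of class `lobula_frame`.
#' @export
lobula_frame <- function(edges = NULL, ap_extent = NULL, pd_extent = NULL) {
  if (is.null(edges)) {
    if (is.null(ap_extent) || is.null(pd_extent)) {
      stop("supply either an edge table or ap_extent + pd_extent",
           call. = FALSE)
    }
    edges <- data.frame(pd = c(0, pd_extent), posterior = 0,
                        anterior = ap_extent)
  }
  need <- c("pd", "posterior", "anterior")
  if (!is.data.frame(edges) || !all(need %in% names(edges))) {
    stop("edges must have columns pd, posterior, anterior", call. = FALSE)
  }
  edges <- edges[order(edges$pd), need]
  if (nrow(edges) < 2) stop("edge table needs at least two rows", call. = FALSE)
  if (any(edges$anterior == edges$posterior)) {
    stop("anterior and posterior edges must differ everywhere", call. = FALSE)
  }
  structure(list(edges = edges), class = "lobula_frame")
}

#' @export
print.lobula_frame <- function(x, ...) {
  cat("lobula_frame over proximodistal range [",
      min(x$edges$pd), ",", max(x$edges$pd), "]\n")
  invisible(x)
}

#' Read a lobula-plate frame from CSV
#'
#' @param path CSV with columns `pd`, `posterior`, `anterior`.
#' @return A [lobula_frame].
#' @export
read_lobula_frame <- function(path) {
  lobula_frame(edges = utils::read.csv(path))
}

#' Normalized anteroposterior axon position
#'
#' Distance of the axon reference point from the posterior edge of the
#' lobula plate along the anteroposterior axis, divided by the local
#' anteroposterior extent at the point's proximodistal position: 0 is
#' the most posterior and 1 the most anterior edge. Points outside the
#' edges are clamped to `[0, 1]` and flagged.
#'
#' @param reference_point Numeric `c(ap, pd)` (or a named `c(x, y, ...)`
#'   as returned by [axon_reference_point], where x is the
#'   anteroposterior and y the proximodistal coordinate).
#' @param frame A [lobula_frame] whose proximodistal range contains the
#'   point.
#' @return Fraction in `[0, 1]` with attribute `out_of_bounds`.
#' @export
relative_axon_position <- function(reference_point, frame) {
  stopifnot(inherits(frame, "lobula_frame"))
  ap <- unname(reference_point[1])
  pd <- unname(reference_point[2])
  e <- frame$edges
  if (pd < min(e$pd) || pd > max(e$pd)) {
    stop("proximodistal coordinate ", pd, " outside frame range [",
         min(e$pd), ", ", max(e$pd), "]", call. = FALSE)
  }
  post <- stats::approx(e$pd, e$posterior, xout = pd)$y
  ant <- stats::approx(e$pd, e$anterior, xout = pd)$y
  rel <- (ap - post) / (ant - post)
  oob <- rel < 0 || rel > 1
  rel <- min(max(rel, 0), 1)
  structure(rel, out_of_bounds = oob)
}

#' Cluster axon positions along the normalized axis
#'
#' One-dimensional k-means (Lloyd) with deterministic initialization at
#' the `(2i - 1) / 2k` quantiles of the data, so the result does not
#' depend on a random start. Clusters are reported in ascending
#' positional order together with the boundaries between them (midpoints
#' of adjacent cluster means).
#'
#' @param positions Numeric vector of relative axon positions.
#' @param k Number of clusters (default 4, the lobula-plate layers).
#' @return List with `assignment` (cluster index 1..k in ascending
#'   positional order), `centers` (ascending cluster means), and
#'   `boundaries` (k - 1 midpoints).
#' @export
cluster_axon_positions <- function(positions, k = 4) {
  positions <- as.numeric(positions)
  if (length(unique(positions)) < k) {
    stop("need at least ", k, " distinct position values", call. = FALSE)
  }
  init <- stats::quantile(positions, probs = (2 * seq_len(k) - 1) / (2 * k),
                          names = FALSE, type = 7)
  # quantile starts can coincide on lumpy data; nudge apart deterministically
  if (anyDuplicated(init)) {
    init <- init + seq(0, 1e-9 * (k - 1), length.out = k)
  }
  km <- stats::kmeans(positions, centers = matrix(init, ncol = 1),
                      algorithm = "Lloyd", iter.max = 200)
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  centers <- unname(sort(km$centers[, 1]))
  list(assignment = relabel[km$cluster],
       centers = centers,
       boundaries = (utils::head(centers, -1) + centers[-1]) / 2)
}

#' Classify subtype from normalized axon position
#'
#' Bins each position into one of four ordered positional groups using
#' three boundaries, maps groups to lobula-plate layers 1-4 according to
#' `layer_order`, and maps layers to subtypes (layer 1 = a, 2 = b,
#' 3 = c, 4 = d: each layer receives axons of exactly one subtype).
#' Positions exactly on a boundary go to the lower group.
#'
#' @param position Numeric vector of relative positions in `[0, 1]`.
#' @param boundaries Sorted numeric vector of length 3.
#' @param layer_order `"posterior_first"` (layer 1 nearest position 0,
#'   the default) or `"anterior_first"`.
#' @param neuron_id Optional ids carried into the output.
#' @return data.frame (one row per position) with columns `neuron_id`,
#'   `relative_position`, `layer_call`, `subtype_call`.
#' @export
classify_subtype_from_axon <- function(position, boundaries,
                                       layer_order = c("posterior_first",
                                                       "anterior_first"),
                                       neuron_id = NULL) {
  layer_order <- match.arg(layer_order)
  if (length(boundaries) != 3) stop("exactly 3 boundaries required", call. = FALSE)
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be sorted increasing", call. = FALSE)
  }
  group <- findInterval(position, boundaries, left.open = TRUE) + 1L
  layer <- if (layer_order == "posterior_first") group else 5L - group
  subtype <- c("a", "b", "c", "d")[layer]
  data.frame(neuron_id = if (is.null(neuron_id)) seq_along(position) else neuron_id,
             relative_position = as.numeric(position),
             layer_call = layer, subtype_call = subtype)
}

#' Agreement between dendrite-based and axon-based subtype calls
#'
#' @param dendrite_call,axon_call Character vectors of subtype calls,
#'   same length and neuron order.
#' @return List with `per_neuron` (data.frame with an `agree` flag) and
#'   `agreement` (population fraction in `[0, 1]`).
#' @export
dendrite_axon_consistency <- function(dendrite_call, axon_call) {
  stopifnot(length(dendrite_call) == length(axon_call))
  agree <- dendrite_call == axon_call
  list(per_neuron = data.frame(dendrite_call = dendrite_call,
                               axon_call = axon_call, agree = agree),
       agreement = if (length(agree)) mean(agree) else NA_real_)
}
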
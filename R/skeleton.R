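#' Labeled neuron skeleton
#'
#' A tree of 3D nodes in SWC convention: columns `id`, `type` (1 = soma,
#' 2 = axon, 3 = dendrite), `x`, `y`, `z`, `radius`, `parent` (parent of
#' the root is -1). Two reference nodes can be designated: the dendrite's
#' first branching point (origin of all orientation vectors) and the axon
#' reference node (the point whose position within the lobula plate is
#' normalized for subtype calling).
#'
#' @param nodes data.frame with the seven SWC columns.
#' @param branch_node id of the designated dendritic first-branch node,
#'   or NULL to detect it later from topology.
#' @param axon_ref_node id of the designated axon reference node.
#' @param metadata Optional named list (units, provenance of the axon
#'   reference convention, ...).
#' @return Object of class `neuron_skeleton`.
#' @export
neuron_skeleton <- function(nodes, branch_node = NULL, axon_ref_node = NULL,
                            metadata = list()) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(need %in% names(nodes))) {
    stop("nodes must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  nodes <- nodes[, need]
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  if (sum(nodes$parent == -1) != 1L) stop("exactly one root node required", call. = FALSE)
  if (!is.null(branch_node) && !branch_node %in% nodes$id) {
    stop("branch_node is not a node id", call. = FALSE)
  }
  if (!is.null(axon_ref_node) && !axon_ref_node %in% nodes$id) {
    stop("axon_ref_node is not a node id", call. = FALSE)
  }
  structure(list(nodes = nodes, branch_node = branch_node,
                 axon_ref_node = axon_ref_node, metadata = metadata),
            class = "neuron_skeleton")
}

#' @export
print.neuron_skeleton <- function(x, ...) {
  n <- x$nodes
  cat("neuron_skeleton:", nrow(n), "nodes (",
      sum(n$type == 3), "dendrite,", sum(n$type == 2), "axon )\n")
  if (!is.null(x$branch_node)) cat("  first-branch node:", x$branch_node, "\n")
  if (!is.null(x$axon_ref_node)) cat("  axon reference node:", x$axon_ref_node, "\n")
  invisible(x)
}

#' Read / write SWC skeleton files
#'
#' Standard 7-column SWC with `#` comment headers. Designated reference
#' nodes survive a round trip through the header lines
#' `# branch_node <id>` and `# axon_ref_node <id>`.
#'
#' @param path File path.
#' @return `read_swc` returns a [neuron_skeleton]; `write_swc` returns
#'   `path` invisibly.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(trimws(lines), "#")]
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s+"), com, value = TRUE)
    if (length(hit)) as.integer(sub(paste0("^#\\s*", key, "\\s+"), "", hit[1])) else NULL
  }
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("SWC file has no node records: ", path, call. = FALSE)
  nodes <- utils::read.table(text = body,
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
  neuron_skeleton(nodes, branch_node = grab("branch_node"),
                  axon_ref_node = grab("axon_ref_node"))
}

#' @rdname read_swc
#' @param skeleton A [neuron_skeleton].
#' @export
write_swc <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "neuron_skeleton"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC skeleton (1-based ids; 2=axon, 3=dendrite)", con)
  if (!is.null(skeleton$branch_node)) {
    writeLines(paste("# branch_node", skeleton$branch_node), con)
  }
  if (!is.null(skeleton$axon_ref_node)) {
    writeLines(paste("# axon_ref_node", skeleton$axon_ref_node), con)
  }
  n <- skeleton$nodes
  writeLines(sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                     n$id, n$type, n$x, n$y, n$z, n$radius, n$parent), con)
  invisible(path)
}

#' Dendrite's first branching point
#'
#' Returns the coordinate of the node from which all orientation vectors
#' are measured. If the skeleton carries an explicitly designated branch
#' node it is returned unchanged; otherwise the first dendritic node, in
#' traversal order from the root, with at least two dendritic children is
#' detected.
#'
#' @param skeleton A [neuron_skeleton].
#' @return Named numeric `c(x, y, z)`.
#' @export
first_branch_point <- function(skeleton) {
  stopifnot(inherits(skeleton, "neuron_skeleton"))
  nodes <- skeleton$nodes
  if (!is.null(skeleton$branch_node)) {
    row <- nodes[nodes$id == skeleton$branch_node, ]
    return(c(x = row$x, y = row$y, z = row$z))
  }
  dend <- nodes$id[nodes$type == 3]
  if (!length(dend)) stop("skeleton has no dendrite compartment", call. = FALSE)
  # breadth-first order from the root
  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  order_ids <- nodes$id[nodes$parent == -1]
  queue <- order_ids
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ch <- kids[[as.character(cur)]]
    if (length(ch)) {
      order_ids <- c(order_ids, ch)
      queue <- c(queue, ch)
    }
  }
  for (id in order_ids) {
    if (!id %in% dend) next
    ch <- kids[[as.character(id)]]
    if (sum(ch %in% dend) >= 2) {
      row <- nodes[nodes$id == id, ]
      return(c(x = row$x, y = row$y, z = row$z))
    }
  }
  stop("no dendritic branching node found", call. = FALSE)
}

#' Axon reference coordinate
#'
#' @param skeleton A [neuron_skeleton] with a designated axon reference
#'   node.
#' @return Named numeric `c(x, y, z)`.
#' @export
axon_reference_point <- function(skeleton) {
  stopifnot(inherits(skeleton, "neuron_skeleton"))
  if (is.null(skeleton$axon_ref_node)) {
    stop("skeleton has no designated axon reference node", call. = FALSE)
  }
  row <- skeleton$nodes[skeleton$nodes$id == skeleton$axon_ref_node, ]
  c(x = row$x, y = row$y, z = row$z)
}

#' Dendrite volume
#'
#' For a skeleton, total cable volume: the sum over dendritic
#' parent-child segments of segment length times the cross-section at the
#' mean radius. For a voxel segmentation (logical array or coordinate
#' matrix), voxel count times `voxel_volume`. Units are arbitrary unless
#' voxel/radius metadata carries physical units.
#'
#' @param segmentation A [neuron_skeleton], a logical array, or a matrix
#'   of voxel coordinates (one row per voxel).
#' @param voxel_volume Volume of one voxel (ignored for skeletons).
#' @return A single non-negative number.
#' @export
dendrite_volume <- function(segmentation, voxel_volume = 1) {
  if (inherits(segmentation, "neuron_skeleton")) {
    nodes <- segmentation$nodes
    dend <- nodes[nodes$type == 3, ]
    if (!nrow(dend)) stop("skeleton has no dendrite compartment", call. = FALSE)
    idx <- match(dend$parent, nodes$id)
    seg <- which(!is.na(idx) & nodes$type[idx] == 3)
    if (!length(seg)) return(0)
    p <- nodes[idx[seg], ]
    d <- dend[seg, ]
    len <- sqrt((d$x - p$x)^2 + (d$y - p$y)^2 + (d$z - p$z)^2)
    r <- (d$radius + p$radius) / 2
    return(sum(len * pi * r^2))
  }
  if (is.logical(segmentation)) {
    if (!any(segmentation)) stop("empty segmentation", call. = FALSE)
    return(sum(segmentation) * voxel_volume)
  }
  if (is.matrix(segmentation) || is.data.frame(segmentation)) {
    if (!nrow(segmentation)) stop("empty segmentation", call. = FALSE)
    return(nrow(segmentation) * voxel_volume)
  }
  stop("unsupported segmentation type", call. = FALSE)
}

#' Normalize a volume series to its maximum
#'
#' Each value is divided by the largest value in the series, so the
#' maximum is exactly 1.
#'
#' @param volumes Numeric vector of non-negative volumes.
#' @return Numeric vector of fractions of the maximum.
#' @export
normalize_volumes <- function(volumes) {
  if (!length(volumes)) stop("empty volume series", call. = FALSE)
  if (any(volumes < 0)) stop("volumes must be non-negative", call. = FALSE)
  m <- max(volumes)
  if (m == 0) stop("all-zero volume series cannot be normalized", call. = FALSE)
  volumes / m
}

#' Rasterize a dendrite to a 2D grayscale image
#'
#' Projects all dendritic segments onto the x-y plane (a maximal-z
#' projection analog, since the generator lays dendrites in a plane) and
#' draws them onto a pixel grid at `pixel_size` resolution, adding
#' Gaussian background noise. The pixel coordinate of the designated
#' first-branch node is returned alongside the image.
#'
#' @param skeleton A [neuron_skeleton] with at least one dendrite
#'   segment.
#' @param pixel_size Edge length of one pixel in skeleton units (> 0).
#' @param noise_level Standard deviation of additive background noise in
#'   intensity units.
#' @param seed Optional integer seed for the noise; fixed seeds give
#'   byte-identical images.
#' @param signal Intensity written along dendrite segments (16-bit
#'   scale).
#' @return Object of class `dendrite_image`: list with `image` (numeric
#'   matrix, rows = y, columns = x), `branch_point` (pixel coordinate
#'   `c(x, y)`), and `pixel_size`.
#' @export
rasterize_dendrite <- function(skeleton, pixel_size = 0.25, noise_level = 0,
                               seed = NULL, signal = 10000) {
  stopifnot(inherits(skeleton, "neuron_skeleton"))
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  nodes <- skeleton$nodes
  dend <- nodes[nodes$type == 3, ]
  idx <- match(dend$parent, nodes$id)
  seg <- which(!is.na(idx) & nodes$type[idx] == 3)
  if (!nrow(dend) || !length(seg)) {
    stop("skeleton has no dendrite segments to rasterize", call. = FALSE)
  }
  p <- nodes[idx[seg], c("x", "y")]
  q <- dend[seg, c("x", "y")]
  # sample each segment densely enough that no pixel is skipped
  pts <- do.call(rbind, lapply(seq_along(seg), function(i) {
    len <- sqrt(sum((q[i, ] - p[i, ])^2))
    k <- max(2L, ceiling(len / (pixel_size / 2)) + 1L)
    t <- seq(0, 1, length.out = k)
    cbind(p[i, 1] + t * (q[i, 1] - p[i, 1]),
          p[i, 2] + t * (q[i, 2] - p[i, 2]))
  }))
  bp <- first_branch_point(skeleton)
  xr <- range(c(pts[, 1], bp["x"])) + c(-2, 2) * pixel_size
  yr <- range(c(pts[, 2], bp["y"])) + c(-2, 2) * pixel_size
  ncol_px <- ceiling(diff(xr) / pixel_size) + 1L
  nrow_px <- ceiling(diff(yr) / pixel_size) + 1L
  px <- function(x, y) {
    cbind(col = pmin(ncol_px, pmax(1L, floor((x - xr[1]) / pixel_size) + 1L)),
          row = pmin(nrow_px, pmax(1L, floor((y - yr[1]) / pixel_size) + 1L)))
  }
  img <- matrix(0, nrow = nrow_px, ncol = ncol_px)
  hit <- px(pts[, 1], pts[, 2])
  img[cbind(hit[, "row"], hit[, "col"])] <- signal
  if (noise_level > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(abs(stats::rnorm(length(img), 0, noise_level)),
                        nrow = nrow_px)
  }
  bpx <- px(bp["x"], bp["y"])
  structure(list(image = img,
                 branch_point = c(x = unname(bpx[1, "col"]),
                                  y = unname(bpx[1, "row"])),
                 pixel_size = pixel_size),
            class = "dendrite_image")
}

#' @export
print.dendrite_image <- function(x, ...) {
  cat("dendrite_image:", nrow(x$image), "x", ncol(x$image),
      "pixels, branch point at (", x$branch_point["x"], ",",
      x$branch_point["y"], ")\n")
  invisible(x)
}

#' Write a grayscale image to TIFF or PNG
#'
#' Intensities are scaled to the 16-bit range for TIFF and the 8-bit
#' range for PNG.
#'
#' @param image A `dendrite_image` or numeric matrix.
#' @param path Output path; format follows the extension (.tif/.tiff or
#'   .png).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- if (inherits(image, "dendrite_image")) image$image else image
  m01 <- m / max(m, 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to write TIFF", call. = FALSE)
    }
    tiff::writeTIFF(m01, path, bits.per.sample = 16)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required to write PNG", call. = FALSE)
    }
    png::writePNG(m01, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}
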
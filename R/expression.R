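#' Quality-control filter for a count matrix
#'
#' Removes cells with fewer than `min_counts` total counts, cells in
#' which more than `max_organelle_frac` of all counts map to
#' mitochondrial-like or (separately) heat-shock-like genes, and genes
#' detected (count > 0) in fewer than `min_cells` cells. Cell filters are
#' applied first and the gene filter is recomputed on the surviving
#' submatrix; the pair is iterated to a fixed point so that re-running
#' the filter on its own output is a no-op.
#'
#' @param x A `t4t5_expression` (counts plus gene/cell annotations with
#'   `is_mito` / `is_hsp` flags).
#' @param min_counts Minimum total counts per cell (default 200).
#' @param min_cells Minimum number of cells a gene must be detected in
#'   (default 3; a gene in exactly 3 cells is retained).
#' @param max_organelle_frac Maximum tolerated mitochondrial-like or
#'   heat-shock-like count fraction per cell (default 0.10, exclusive).
#' @return List with `filtered` (the reduced `t4t5_expression`) and
#'   `report` (data.frame listing every removed cell and gene with its
#'   reason and offending value).
#' @export
qc_filter <- function(x, min_counts = 200, min_cells = 3,
                      max_organelle_frac = 0.10) {
  stopifnot(inherits(x, "t4t5_expression"))
  counts <- x$counts
  if (!nrow(counts) || !ncol(counts)) stop("empty matrix", call. = FALSE)
  genes <- x$genes; cells <- x$cells
  report <- list()
  repeat {
    total <- rowSums(counts)
    mito <- rowSums(counts[, genes$is_mito, drop = FALSE]) / pmax(total, 1)
    hsp <- rowSums(counts[, genes$is_hsp, drop = FALSE]) / pmax(total, 1)
    bad_cell <- total < min_counts | mito > max_organelle_frac |
      hsp > max_organelle_frac
    if (any(bad_cell)) {
      reason <- ifelse(total < min_counts, "low_counts",
                       ifelse(mito > max_organelle_frac, "high_mito_fraction",
                              "high_hsp_fraction"))
      value <- ifelse(total < min_counts, total,
                      ifelse(mito > max_organelle_frac, mito, hsp))
      report[[length(report) + 1L]] <- data.frame(
        entity = "cell", id = rownames(counts)[bad_cell],
        reason = reason[bad_cell], value = value[bad_cell])
      counts <- counts[!bad_cell, , drop = FALSE]
      cells <- cells[!bad_cell, , drop = FALSE]
    }
    detected <- colSums(counts > 0)
    bad_gene <- detected < min_cells
    if (any(bad_gene)) {
      report[[length(report) + 1L]] <- data.frame(
        entity = "gene", id = colnames(counts)[bad_gene],
        reason = "detected_in_too_few_cells",
        value = detected[bad_gene])
      counts <- counts[, !bad_gene, drop = FALSE]
      genes <- genes[!bad_gene, , drop = FALSE]
    }
    if (!any(bad_cell) && !any(bad_gene)) break
    if (!nrow(counts) || !ncol(counts)) {
      stop("QC filter removed the entire matrix", call. = FALSE)
    }
  }
  filtered <- x
  filtered$counts <- counts
  filtered$genes <- genes
  filtered$cells <- cells
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(entity = character(), id = character(),
               reason = character(), value = numeric())
  rownames(rep_df) <- NULL
  list(filtered = filtered, report = rep_df)
}

#' Depth-normalize counts
#'
#' Scales each cell to a common total (default 10,000) and applies
#' `log(1 + x)`. Doubling all counts of a cell leaves its normalized
#' vector unchanged.
#'
#' @param x A `t4t5_expression` or a cells-by-genes count matrix.
#' @param target Common per-cell total after scaling.
#' @return Numeric matrix (cells x genes) of log-normalized values, with
#'   attributes `target` and `transform = "log1p"` recording the
#'   parameters.
#' @export
normalize_counts <- function(x, target = 1e4) {
  counts <- if (inherits(x, "t4t5_expression")) x$counts else as.matrix(x)
  total <- rowSums(counts)
  if (any(total == 0)) {
    stop("cannot normalize zero-total cell(s): ",
         paste(utils::head(rownames(counts)[total == 0]), collapse = ", "),
         call. = FALSE)
  }
  out <- log1p(counts / total * target)
  attr(out, "target") <- target
  attr(out, "transform") <- "log1p"
  out
}

#' Threshold-based pairwise differential expression
#'
#' A gene passes for `cluster_a` over `cluster_b` iff its detection
#' fraction in `cluster_a` is at least `min_frac`, the difference of
#' detection fractions is at least `min_diff_frac`, and its fold change
#' `(mean_a + eps) / (mean_b + eps)` on the normalized-mean scale is at
#' least `fc_threshold`. Both directions are evaluated; with
#' `min_diff_frac >= 0.5` a gene can pass in at most one. Detection
#' means raw count at least `detect_min` (default 1, i.e. count > 0).
#'
#' @param x A `t4t5_expression` or a cells-by-genes count matrix.
#' @param cluster_a,cluster_b Cluster labels to compare.
#' @param labels Per-cell cluster labels (defaults to
#'   `x$cells$cluster`).
#' @param min_frac Minimum detection fraction in the high cluster.
#' @param min_diff_frac Minimum difference of detection fractions.
#' @param fc_threshold Minimum fold change (dimensionless, > 0).
#' @param eps Pseudocount added to both normalized means.
#' @param detect_min Minimum raw count for a gene to count as detected.
#' @param normalized Optional precomputed [normalize_counts] matrix for
#'   the same cells (computed internally when NULL).
#' @return data.frame of passing records ordered by gene name:
#'   `gene`, `cluster` (the high side), `other_cluster`, `frac_high`,
#'   `frac_other`, `fold_change`.
#' @export
pairwise_deg <- function(x, cluster_a, cluster_b, labels = NULL,
                         min_frac = 0.5, min_diff_frac = 0.5,
                         fc_threshold = 2, eps = 0.01, detect_min = 1,
                         normalized = NULL) {
  counts <- if (inherits(x, "t4t5_expression")) x$counts else as.matrix(x)
  if (is.null(labels) && inherits(x, "t4t5_expression")) {
    labels <- x$cells$cluster
  }
  if (length(labels) != nrow(counts)) {
    stop("labels must match the number of cells", call. = FALSE)
  }
  for (cl in c(cluster_a, cluster_b)) {
    if (!cl %in% labels) stop("unknown cluster label: ", cl, call. = FALSE)
  }
  if (is.null(normalized)) normalized <- normalize_counts(counts)
  ia <- labels == cluster_a; ib <- labels == cluster_b
  frac_a <- colMeans(counts[ia, , drop = FALSE] >= detect_min)
  frac_b <- colMeans(counts[ib, , drop = FALSE] >= detect_min)
  mean_a <- colMeans(normalized[ia, , drop = FALSE])
  mean_b <- colMeans(normalized[ib, , drop = FALSE])
  one_way <- function(hi, lo, f_hi, f_lo, m_hi, m_lo) {
    fc <- (m_hi + eps) / (m_lo + eps)
    pass <- f_hi >= min_frac & (f_hi - f_lo) >= min_diff_frac &
      fc >= fc_threshold
    n_pass <- sum(pass)
    data.frame(gene = colnames(counts)[pass],
               cluster = rep(hi, n_pass), other_cluster = rep(lo, n_pass),
               frac_high = unname(f_hi[pass]),
               frac_other = unname(f_lo[pass]),
               fold_change = unname(fc[pass]))
  }
  out <- rbind(one_way(cluster_a, cluster_b, frac_a, frac_b, mean_a, mean_b),
               one_way(cluster_b, cluster_a, frac_b, frac_a, mean_b, mean_a))
  out <- out[order(out$gene, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-stage consistency of differential genes
#'
#' Combines per-stage differentially-expressed gene sets into the
#' any-stage union, the all-stage intersection, and a per-gene profile
#' of passing stages.
#'
#' @param per_stage_sets Named list (stage -> character vector of gene
#'   names).
#' @return List with `union`, `intersection` (both sorted character
#'   vectors) and `profile` (data.frame `gene`, `stages`
#'   (comma-joined), `n_stages`).
#' @export
stage_consistent_degs <- function(per_stage_sets) {
  if (!length(per_stage_sets)) stop("at least one stage set required",
                                    call. = FALSE)
  sets <- lapply(per_stage_sets, unique)
  all_genes <- sort(unique(unlist(sets)))
  inter <- Reduce(intersect, sets)
  profile <- do.call(rbind, lapply(all_genes, function(g) {
    st <- names(sets)[vapply(sets, function(s) g %in% s, TRUE)]
    data.frame(gene = g, stages = paste(st, collapse = ","),
               n_stages = length(st))
  }))
  if (is.null(profile)) {
    profile <- data.frame(gene = character(), stages = character(),
                          n_stages = integer())
  }
  list(union = all_genes, intersection = sort(inter), profile = profile)
}

#' Assign cluster identities from marker genes
#'
#' Maps eight transcriptomic clusters onto the eight identities
#' (T4/T5 x a-d). The T4/T5 split thresholds the type marker at the
#' midpoint between the two groupwise means; within each type, a,b
#' versus c,d is decided by the a,b marker (cross-checked against the
#' c,d marker), and b versus a (and c versus d) by the b,c marker. A
#' marker whose groups overlap under the midpoint rule raises an error
#' naming the marker.
#'
#' @param cluster_mean_profiles Numeric matrix, clusters x genes, of
#'   mean expression per cluster; rownames are cluster labels.
#' @param marker_spec Named list with entries `type_marker`,
#'   `ab_marker`, `cd_marker`, `bc_marker` (gene names present in the
#'   profile columns).
#' @return data.frame with columns `cluster`, `cell_type`, `subtype` —
#'   a complete bijection onto the eight identities.
#' @export
assign_cluster_identity <- function(cluster_mean_profiles,
                                    marker_spec = list(
                                      type_marker = "TfAP-2",
                                      ab_marker = "dac",
                                      cd_marker = "omb",
                                      bc_marker = "grain")) {
  m <- as.matrix(cluster_mean_profiles)
  if (nrow(m) != 8) stop("exactly 8 clusters are required", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("cluster", 1:8)
  for (nm in c("type_marker", "ab_marker", "cd_marker", "bc_marker")) {
    if (!marker_spec[[nm]] %in% colnames(m)) {
      stop("marker ", marker_spec[[nm]], " (", nm,
           ") absent from profiles", call. = FALSE)
    }
  }
  split_by <- function(vals, n_high, marker) {
    ord <- order(vals, decreasing = TRUE)
    hi <- ord[seq_len(n_high)]; lo <- ord[-seq_len(n_high)]
    thr <- (mean(vals[hi]) + mean(vals[lo])) / 2
    if (min(vals[hi]) <= thr || max(vals[lo]) >= thr) {
      stop("non-separable marker: ", marker, call. = FALSE)
    }
    list(high = hi, low = lo)
  }
  type_split <- split_by(m[, marker_spec$type_marker], 4,
                         marker_spec$type_marker)
  out <- data.frame(cluster = rownames(m), cell_type = NA_character_,
                    subtype = NA_character_)
  out$cell_type[type_split$high] <- "T4"
  out$cell_type[type_split$low] <- "T5"
  for (type_rows in list(type_split$high, type_split$low)) {
    ab <- split_by(m[type_rows, marker_spec$ab_marker], 2,
                   marker_spec$ab_marker)
    cd <- split_by(m[type_rows, marker_spec$cd_marker], 2,
                   marker_spec$cd_marker)
    if (!setequal(ab$high, cd$low)) {
      stop("a,b and c,d markers disagree (",
           marker_spec$ab_marker, " vs ", marker_spec$cd_marker, ")",
           call. = FALSE)
    }
    ab_rows <- type_rows[ab$high]; cd_rows <- type_rows[ab$low]
    b_split <- split_by(m[ab_rows, marker_spec$bc_marker], 1,
                        marker_spec$bc_marker)
    c_split <- split_by(m[cd_rows, marker_spec$bc_marker], 1,
                        marker_spec$bc_marker)
    out$subtype[ab_rows[b_split$high]] <- "b"
    out$subtype[ab_rows[b_split$low]] <- "a"
    out$subtype[cd_rows[c_split$high]] <- "c"
    out$subtype[cd_rows[c_split$low]] <- "d"
  }
  out
}

#' Categorize the developmental dynamics of a differential gene
#'
#' Assigns one of four categories from the per-stage sets of subtypes a
#' gene marks:
#' * `type_specific` — differential only between the T4 and T5 groups
#'   (no subtype-level pattern), or subtype-specific in only one type;
#' * `late_only` — subtype-differential exclusively at stages >= 60 h
#'   APF (the last phase of dendrite growth);
#' * `switching` — the marked subtype set changes between stages;
#' * `stable_subtype_specific` — a constant marked subtype set across
#'   stages otherwise.
#'
#' A gene with no differential signal at any stage returns `"none"`.
#'
#' @param subtype_sets Named list (stage -> character vector of marked
#'   subtypes, possibly empty). Stage names must include 36, 48, 60 and
#'   72 at minimum. If `subtype_sets_t5` is supplied, `subtype_sets`
#'   holds the T4-side pattern.
#' @param type_flags Optional named logical per stage: TRUE where the
#'   gene is differential between the T4 and T5 groups.
#' @param subtype_sets_t5 Optional per-stage sets observed within T5;
#'   when the subtype pattern exists in only one type the gene is
#'   `type_specific`.
#' @return One of `"type_specific"`, `"stable_subtype_specific"`,
#'   `"late_only"`, `"switching"`, `"none"`.
#' @export
categorize_dynamics <- function(subtype_sets, type_flags = NULL,
                                subtype_sets_t5 = NULL) {
  required <- c("36", "48", "60", "72")
  if (!all(required %in% names(subtype_sets))) {
    stop("subtype_sets must cover stages ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  nonempty <- function(sets) names(sets)[vapply(sets, length, 1L) > 0]
  if (!is.null(subtype_sets_t5)) {
    t4_on <- length(nonempty(subtype_sets)) > 0
    t5_on <- length(nonempty(subtype_sets_t5)) > 0
    if (xor(t4_on, t5_on)) return("type_specific")
    if (!t4_on && !t5_on) {
      return(if (!is.null(type_flags) && any(type_flags)) "type_specific"
             else "none")
    }
  }
  ord <- order(suppressWarnings(as.numeric(names(subtype_sets))))
  sets <- subtype_sets[ord]
  on <- nonempty(sets)
  if (!length(on)) {
    return(if (!is.null(type_flags) && any(type_flags)) "type_specific"
           else "none")
  }
  if (all(suppressWarnings(as.numeric(on)) >= 60)) return("late_only")
  on_sets <- sets[on]
  for (i in seq_along(on_sets)[-1]) {
    if (!setequal(on_sets[[i - 1]], on_sets[[i]])) return("switching")
  }
  "stable_subtype_specific"
}

#' Marked subtype set of a gene from per-subtype means
#'
#' Operational bridge from expression to the dynamics categorizer: a
#' subtype belongs to the marked set when its pooled (T4 + T5) mean
#' exceeds the midpoint between the highest and lowest subtype means,
#' provided the high/low fold exceeds `fc_threshold` (otherwise the gene
#' marks nothing at that stage).
#'
#' @param subtype_means Named numeric (a, b, c, d) of mean normalized
#'   expression.
#' @param fc_threshold Minimum high/low fold (with pseudocount `eps`)
#'   for any subtype pattern to count.
#' @param eps Pseudocount.
#' @return Character vector of marked subtypes (possibly empty).
#' @export
marked_subtypes <- function(subtype_means, fc_threshold = 2, eps = 0.01) {
  v <- subtype_means[c("a", "b", "c", "d")]
  if ((max(v) + eps) / (min(v) + eps) < fc_threshold) return(character(0))
  names(v)[v > (max(v) + min(v)) / 2]
}
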
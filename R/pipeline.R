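#' In-silico wild-type experiment
#'
#' Simulates an unperturbed T4/T5 population, computes per-neuron
#' orientation histograms and dendrite volumes, per-subtype reference
#' orientations, relative axon positions with one-dimensional layer
#' clustering, both subtype calls (dendrite-based and axon-based), and
#' their agreement.
#'
#' @param config A [sim_config].
#' @return Object of class `t4t5_report`; see Details. The report
#'   contains a per-neuron table (ground truth and both calls), the
#'   per-clone compositions, summary fractions (call accuracies,
#'   dendrite-axon agreement, layer occupancies), the stage-wise
#'   normalized volume profile, the layer boundaries used, the config
#'   echo, the seed and a timestamp.
#' @export
run_wildtype_experiment <- function(config) {
  run_morphology_experiment(config, mode = "none")
}

#' In-silico Grain perturbation experiment
#'
#' Applies the Grain gain- or loss-of-function map to every neuron's
#' transcription-factor code before morphogenesis — dendrite orientation
#' and axon position both follow the converted identity — and then runs
#' the full wild-type classification against references and layer
#' boundaries derived from an unperturbed control population with the
#' same configuration. Overexpression converts subtypes a,d into b,c
#' (axons in layers 2 and 3); knockdown converts b,c into a,d (axons in
#' layers 1 and 4).
#'
#' @param config A [sim_config]; `conversion_penetrance` sets the
#'   fraction of neurons that convert.
#' @param mode `"overexpression"`, `"knockdown"` or `"none"` (identity:
#'   the report equals [run_wildtype_experiment] for the same seed).
#' @param retarget_only If TRUE, simulates the rejected alternative
#'   model in which axons retarget without dendrite conversion: axon
#'   positions follow the perturbed code but dendrites keep their
#'   original orientation. Useful as a negative control; default FALSE.
#' @return A `t4t5_report` (see [run_wildtype_experiment]).
#' @export
run_perturbation_experiment <- function(config,
                                        mode = c("overexpression",
                                                 "knockdown", "none"),
                                        retarget_only = FALSE) {
  mode <- match.arg(mode)
  run_morphology_experiment(config, mode = mode,
                            retarget_only = retarget_only)
}

run_morphology_experiment <- function(config, mode, retarget_only = FALSE) {
  validate_sim_config(config)
  pop <- tryCatch(
    generate_population(config, perturbation = if (retarget_only) "none"
                        else mode),
    error = function(e) stop("[simulate] ", conditionMessage(e),
                             call. = FALSE))
  truth <- pop$truth
  if (retarget_only && mode != "none") {
    # axons follow the converted code, dendrites stay wild type
    conv <- vapply(truth$subtype, function(s) {
      decode_tf_code(perturb_code(encode_subtype(s), mode))
    }, character(1))
    set.seed(child_seed(config$seed, 800000))
    truth$axon_identity <- conv
    truth$rel_position <- pmin(pmax(stats::rnorm(
      nrow(truth), config$layer_centers[conv], config$layer_sd),
      0.001), 0.999)
  } else {
    truth$axon_identity <- truth$effective_subtype
  }

  hists <- tryCatch(
    lapply(pop$skeletons, orientation_histogram),
    error = function(e) stop("[orient] ", conditionMessage(e), call. = FALSE))

  # Reference orientations and layer boundaries always come from an
  # independent unperturbed control population (the analog of a control
  # experiment), so no query neuron contributes to its own reference.
  control_config <- config
  control_config$seed <- child_seed(config$seed, 424243)
  control <- generate_population(control_config, perturbation = "none")
  control_truth <- control$truth
  control_hists <- lapply(control$skeletons, orientation_histogram)
  control_rel <- vapply(control$skeletons, function(s) {
    as.numeric(relative_axon_position(axon_reference_point(s)[c("x", "y")],
                                      control$frame))
  }, numeric(1))
  references <- lapply(stats::setNames(c("a", "b", "c", "d"),
                                       c("a", "b", "c", "d")), function(s) {
    average_histograms(control_hists[control_truth$effective_subtype == s])
  })

  dend <- lapply(hists, classify_by_dendrite, references = references)
  truth$dendrite_call <- vapply(dend, `[[`, character(1), "subtype")
  truth$dendrite_tie <- vapply(dend, `[[`, logical(1), "tie")

  rel <- tryCatch(vapply(pop$skeletons, function(s) {
    as.numeric(relative_axon_position(axon_reference_point(s)[c("x", "y")],
                                      pop$frame))
  }, numeric(1)), error = function(e) stop("[axon-classify] ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (retarget_only && mode != "none") rel <- truth$rel_position
  boundaries <- cluster_axon_positions(control_rel, k = 4)$boundaries
  ax <- classify_subtype_from_axon(rel, boundaries,
                                   neuron_id = truth$neuron_id)
  truth$rel_position_measured <- ax$relative_position
  truth$layer_call <- ax$layer_call
  truth$axon_call <- ax$subtype_call
  cons <- dendrite_axon_consistency(truth$dendrite_call, truth$axon_call)
  truth$agree <- cons$per_neuron$agree

  vols <- vapply(pop$skeletons, dendrite_volume, numeric(1))
  vol_by_stage <- tapply(vols, truth$stage, mean)
  vol_by_stage <- vol_by_stage[match(intersect(config$stages,
                                               names(vol_by_stage)),
                                     names(vol_by_stage))]
  volume_profile <- data.frame(stage = names(vol_by_stage),
                               mean_volume = as.numeric(vol_by_stage),
                               normalized = normalize_volumes(
                                 as.numeric(vol_by_stage)))

  clones <- do.call(rbind, lapply(split(truth, truth$clone_id), function(d) {
    comp <- sort(d$effective_subtype)
    data.frame(clone_id = d$clone_id[1],
               composition = paste(comp, collapse = ","),
               homogeneous = length(unique(comp)) == 1)
  }))
  rownames(clones) <- NULL

  layer_frac <- as.numeric(table(factor(truth$layer_call, levels = 1:4))) /
    nrow(truth)
  summary <- list(
    n_neurons = nrow(truth),
    dendrite_accuracy = mean(truth$dendrite_call == truth$effective_subtype),
    axon_accuracy = mean(truth$axon_call == truth$axon_identity),
    agreement = cons$agreement,
    layer_fractions = stats::setNames(layer_frac, paste0("layer", 1:4)),
    clone_homogeneous_fraction = mean(clones$homogeneous))
  structure(list(mode = mode, retarget_only = retarget_only,
                 per_neuron = truth, clones = clones, summary = summary,
                 volume_profile = volume_profile, boundaries = boundaries,
                 config = config, seed = config$seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "t4t5_report")
}

#' @export
print.t4t5_report <- function(x, ...) {
  s <- x$summary
  cat("t4t5_report —", if (x$mode == "none") "wild type" else
    paste("grain", x$mode),
    if (x$retarget_only) "(axon retargeting only)", "\n")
  cat(sprintf("  %d neurons, %d clones\n", s$n_neurons, nrow(x$clones)))
  cat(sprintf("  axon-call accuracy:      %.3f\n", s$axon_accuracy))
  cat(sprintf("  dendrite-call accuracy:  %.3f\n", s$dendrite_accuracy))
  cat(sprintf("  dendrite-axon agreement: %.3f\n", s$agreement))
  cat("  layer occupancy:",
      paste(sprintf("%d: %.2f", 1:4, s$layer_fractions), collapse = "  "),
      "\n")
  cat(sprintf("  homogeneous clones:      %.3f\n",
              s$clone_homogeneous_fraction))
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Per-neuron and per-clone tables as CSV, summary (with config echo) as
#' JSON.
#'
#' @param report A `t4t5_report` or `t4t5_expression_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(report, "t4t5_report")) {
    utils::write.csv(report$per_neuron, file.path(dir, "per_neuron.csv"),
                     row.names = FALSE)
    utils::write.csv(report$clones, file.path(dir, "clones.csv"),
                     row.names = FALSE)
    utils::write.csv(report$volume_profile, file.path(dir, "volumes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mode = report$mode, summary = report$summary,
           boundaries = report$boundaries, seed = report$seed,
           config = unclass(report$config), timestamp = report$timestamp),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (inherits(report, "t4t5_expression_report")) {
    utils::write.csv(report$identity, file.path(dir, "identity.csv"),
                     row.names = FALSE)
    utils::write.csv(report$dynamics, file.path(dir, "dynamics.csv"),
                     row.names = FALSE)
    utils::write.csv(report$grain_scores, file.path(dir, "grain_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(report$deg_profile, file.path(dir, "deg_profile.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = report$summary, seed = report$seed,
           config = unclass(report$config), timestamp = report$timestamp),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else stop("unknown report type", call. = FALSE)
  invisible(dir)
}

#' In-silico expression experiment
#'
#' Generates stage-wise expression matrices, applies quality control and
#' depth normalization, assigns cluster identities from the marker code,
#' runs the pairwise differential-expression filter across all cluster
#' pairs per stage, combines stages into any-stage/all-stage gene sets,
#' categorizes each gene's expression dynamics, and computes the Grain
#' cell-body enrichment score from a synthetic fluorescence table.
#'
#' @param config A [sim_config].
#' @return Object of class `t4t5_expression_report` with the identity
#'   mapping per stage (and its accuracy against ground truth), the
#'   per-stage differential gene sets with union/intersection and
#'   per-gene stage profile, per-gene dynamics categories, Grain scores,
#'   the QC removal report, summary fractions, config echo, seed and
#'   timestamp.
#' @export
run_expression_experiment <- function(config) {
  validate_sim_config(config)
  expr <- tryCatch(generate_expression(config),
                   error = function(e) stop("[simulate] ",
                                            conditionMessage(e),
                                            call. = FALSE))
  qc <- tryCatch(qc_filter(expr),
                 error = function(e) stop("[qc] ", conditionMessage(e),
                                          call. = FALSE))
  filt <- qc$filtered
  norm <- normalize_counts(filt)
  stages <- unique(filt$cells$stage)
  clusters <- paste0(rep(c("T4", "T5"), each = 4), c("a", "b", "c", "d"))

  identity <- list(); stage_sets <- list()
  for (st in stages) {
    in_stage <- filt$cells$stage == st
    prof <- t(vapply(clusters, function(cl) {
      colMeans(norm[in_stage & filt$cells$cluster == cl, , drop = FALSE])
    }, numeric(ncol(norm))))
    ident <- tryCatch(assign_cluster_identity(prof),
                      error = function(e) stop("[identity] stage ", st, ": ",
                                               conditionMessage(e),
                                               call. = FALSE))
    ident$stage <- st
    ident$true_type <- substr(ident$cluster, 1, 2)
    ident$true_subtype <- substr(ident$cluster, 3, 3)
    ident$correct <- ident$cell_type == ident$true_type &
      ident$subtype == ident$true_subtype
    identity[[st]] <- ident

    sub_counts <- filt$counts[in_stage, , drop = FALSE]
    sub_norm <- norm[in_stage, , drop = FALSE]
    sub_lab <- filt$cells$cluster[in_stage]
    passing <- character(0)
    pairs <- utils::combn(clusters, 2)
    for (p in seq_len(ncol(pairs))) {
      recs <- pairwise_deg(sub_counts, pairs[1, p], pairs[2, p],
                           labels = sub_lab, normalized = sub_norm)
      passing <- union(passing, recs$gene)
    }
    stage_sets[[st]] <- sort(passing)
  }
  identity <- do.call(rbind, identity)
  rownames(identity) <- NULL
  consistency <- stage_consistent_degs(stage_sets)

  # dynamics category per retained gene
  eps <- 0.01
  dynamics <- do.call(rbind, lapply(colnames(filt$counts), function(g) {
    sets <- list(); flags <- logical(0)
    for (st in stages) {
      in_stage <- filt$cells$stage == st
      sub_means <- vapply(c("a", "b", "c", "d"), function(s) {
        mean(norm[in_stage & filt$cells$subtype == s, g])
      }, numeric(1))
      sets[[st]] <- marked_subtypes(sub_means)
      m4 <- mean(norm[in_stage & filt$cells$cell_type == "T4", g])
      m5 <- mean(norm[in_stage & filt$cells$cell_type == "T5", g])
      flags[st] <- max((m4 + eps) / (m5 + eps), (m5 + eps) / (m4 + eps)) >= 2
    }
    data.frame(gene = g,
               category = categorize_dynamics(sets, type_flags = flags))
  }))

  cb <- generate_cellbody_table(config)
  scores <- grain_score(cb)
  score_by_subtype <- tapply(scores$score, scores$subtype, mean)

  stable_expected <- sort(expr$genes$name[expr$genes$stable_marker])
  summary <- list(
    n_cells_simulated = nrow(expr$counts),
    n_cells_after_qc = nrow(filt$counts),
    n_genes_after_qc = ncol(filt$counts),
    identity_accuracy = mean(identity$correct),
    n_any_stage_degs = length(consistency$union),
    n_all_stage_degs = length(consistency$intersection),
    stable_markers_recovered = setequal(consistency$intersection,
                                        stable_expected),
    grain_score_by_subtype = as.list(score_by_subtype))
  structure(list(identity = identity, stage_sets = stage_sets,
                 deg_union = consistency$union,
                 deg_intersection = consistency$intersection,
                 deg_profile = consistency$profile,
                 dynamics = dynamics, grain_scores = scores,
                 qc_report = qc$report, summary = summary,
                 config = config, seed = config$seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "t4t5_expression_report")
}

#' @export
print.t4t5_expression_report <- function(x, ...) {
  s <- x$summary
  cat("t4t5_expression_report\n")
  cat(sprintf("  cells: %d simulated, %d after QC (%d genes)\n",
              s$n_cells_simulated, s$n_cells_after_qc, s$n_genes_after_qc))
  cat(sprintf("  cluster identity accuracy: %.3f\n", s$identity_accuracy))
  cat(sprintf("  DEGs: %d at any stage, %d at all stages (stable markers %s)\n",
              s$n_any_stage_degs, s$n_all_stage_degs,
              if (s$stable_markers_recovered) "recovered" else "NOT recovered"))
  cat("  Grain score by subtype:",
      paste(sprintf("%s=%.2f", names(s$grain_score_by_subtype),
                    unlist(s$grain_score_by_subtype)), collapse = "  "),
      "\n")
  invisible(x)
}
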
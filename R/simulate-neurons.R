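#' Generate one synthetic T4/T5 neuron
#'
#' Builds a labeled skeleton whose dendritic branches emanate from a
#' designated first-branch node with directions drawn from a von Mises
#' distribution centered on the subtype's generating angle, whose total
#' dendritic cable length follows the stage-dependent arbor profile
#' (growth from 36 to 72 h APF, pruning from 72 h to adult), and whose
#' axon reference node sits at a position drawn from a normal
#' distribution around the subtype's layer center on the normalized
#' anteroposterior axis.
#'
#' @param subtype One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param stage A stage label present in `config$stages`.
#' @param config A [sim_config].
#' @param seed Optional integer seed; fixed seeds give identical
#'   neurons.
#' @param pd_position Proximodistal coordinate of the axon reference
#'   node (defaults to the middle of the frame).
#' @return List with `skeleton` (a [neuron_skeleton] whose
#'   `metadata$branch_angles` records the generating draws) and `truth`
#'   (one-row data.frame: subtype, stage, rel_position).
#' @export
generate_neuron <- function(subtype, stage, config, seed = NULL,
                            pd_position = NULL) {
  validate_sim_config(config)
  if (!subtype %in% c("a", "b", "c", "d")) {
    stop("unknown subtype: ", subtype, call. = FALSE)
  }
  stage <- as.character(stage)
  if (!stage %in% config$stages) stop("unknown stage: ", stage, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pd_position)) pd_position <- config$pd_extent / 2

  nb <- config$n_branches
  angles <- rvonmises(nb, config$subtype_angles[[subtype]], config$kappa)
  len <- config$branch_length * config$stage_size[[stage]] *
    stats::runif(nb, 0.7, 1.3)
  rel <- stats::rnorm(1, config$layer_centers[[subtype]], config$layer_sd)
  rel <- min(max(rel, 0.001), 0.999)

  th <- angles * pi / 180
  tipx <- len * cos(th); tipy <- len * sin(th)
  base <- data.frame(
    id = 1:5,
    type = c(1, 3, 3, 2, 2),
    x = c(-4, -2, 0, -6, rel * config$ap_extent),
    y = c(0, 0, 0, 0, pd_position),
    z = c(0, 0, 0, -5, -10),
    radius = c(2, 0.5, 0.5, 0.5, 0.5),
    parent = c(-1, 1, 2, 1, 4))
  mid <- data.frame(id = 5 + seq_len(nb), type = 3,
                    x = tipx / 2, y = tipy / 2, z = 0, radius = 0.3,
                    parent = 3)
  tip <- data.frame(id = 5 + nb + seq_len(nb), type = 3,
                    x = tipx, y = tipy, z = 0, radius = 0.3,
                    parent = 5 + seq_len(nb))
  skel <- neuron_skeleton(rbind(base, mid, tip), branch_node = 3,
                          axon_ref_node = 5,
                          metadata = list(branch_angles = angles,
                                          axon_reference = "first_branching_point",
                                          units = "micrometers"))
  list(skeleton = skel,
       truth = data.frame(subtype = subtype, stage = stage,
                          rel_position = rel))
}

#' Generate a full synthetic T4/T5 population
#'
#' Produces `n_neurons_per_subtype` neurons per subtype, per cell type
#' (T4 and T5), per stage, organized into neuroblast clones of exactly
#' four neurons (2 T4 + 2 T5) that share a retinotopic position and whose
#' unperturbed subtype multiset is `{a,a,b,b}` or `{c,c,d,d}`. Under a
#' perturbation the transcription-factor code of each neuron is modified
#' before morphogenesis (with probability `conversion_penetrance`), so
#' dendrite orientation and axon position both follow the converted
#' identity.
#'
#' @param config A [sim_config].
#' @param perturbation `"none"`, `"overexpression"` (Grain gain) or
#'   `"knockdown"` (Grain loss).
#' @return Object of class `t4t5_population`: list with `skeletons`
#'   (named list of [neuron_skeleton]s), `truth` (data.frame with
#'   neuron_id, cell_type, subtype, effective_subtype, stage, clone_id,
#'   retinotopic position, perturbation, rel_position), `frame` (the
#'   rectangular [lobula_frame] the axons live in), and `config`.
#' @export
generate_population <- function(config,
                                perturbation = c("none", "overexpression",
                                                 "knockdown")) {
  validate_sim_config(config)
  perturbation <- match.arg(perturbation)
  pairings <- list(c("a", "b"), c("c", "d"))
  skeletons <- list()
  truth <- list()
  clone_k <- 0L
  neuron_k <- 0L
  for (stage in config$stages) {
    for (pair in pairings) {
      for (i in seq_len(config$n_neurons_per_subtype)) {
        clone_k <- clone_k + 1L
        clone_id <- sprintf("clone_%s_%s%s_%03d", stage, pair[1], pair[2], i)
        set.seed(child_seed(config$seed, 500000 + clone_k))
        retino <- stats::runif(2)
        for (cell_type in c("T4", "T5")) {
          for (s in pair) {
            neuron_k <- neuron_k + 1L
            seed_i <- child_seed(config$seed, 1000 + neuron_k)
            eff <- s
            if (perturbation != "none") {
              set.seed(child_seed(config$seed, 900000 + neuron_k))
              if (stats::runif(1) <= config$conversion_penetrance) {
                eff <- decode_tf_code(perturb_code(encode_subtype(s),
                                                   perturbation))
              }
            }
            nid <- sprintf("%s%s_%s_%04d", cell_type, s, stage, neuron_k)
            g <- generate_neuron(eff, stage, config, seed = seed_i)
            skeletons[[nid]] <- g$skeleton
            truth[[neuron_k]] <- data.frame(
              neuron_id = nid, cell_type = cell_type, subtype = s,
              effective_subtype = eff, stage = stage, clone_id = clone_id,
              retinotopic_x = retino[1], retinotopic_y = retino[2],
              perturbation = perturbation,
              rel_position = g$truth$rel_position)
          }
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(skeletons = skeletons, truth = truth,
                 frame = lobula_frame(ap_extent = config$ap_extent,
                                      pd_extent = config$pd_extent),
                 config = config, perturbation = perturbation),
            class = "t4t5_population")
}

#' @export
print.t4t5_population <- function(x, ...) {
  tt <- x$truth
  cat("t4t5_population:", nrow(tt), "neurons,",
      length(unique(tt$clone_id)), "clones,",
      length(unique(tt$stage)), "stage(s); perturbation:",
      x$perturbation, "\n")
  print(table(tt$cell_type, tt$effective_subtype))
  invisible(x)
}

#' Write a synthetic population to disk
#'
#' One SWC file per neuron, the ground-truth table as CSV, and all
#' generation parameters echoed to a YAML sidecar.
#'
#' @param population A [generate_population] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "t4t5_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  swc_dir <- file.path(dir, "swc")
  dir.create(swc_dir, showWarnings = FALSE)
  for (nid in names(population$skeletons)) {
    write_swc(population$skeletons[[nid]],
              file.path(swc_dir, paste0(nid, ".swc")))
  }
  utils::write.csv(population$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config_as_yaml_list(population$config,
                                       perturbation = population$perturbation),
                   file.path(dir, "parameters.yaml"))
  invisible(dir)
}
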
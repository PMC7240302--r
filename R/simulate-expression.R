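#' Synthetic single-cell expression matrix with a marker program
#'
#' Simulates cells-by-genes negative-binomial counts for the eight
#' transcriptomic clusters (T4/T5 x subtypes a-d) at each developmental
#' stage, encoding the marker-gene program the downstream analyses
#' expect:
#'
#' * a T4-versus-T5 marker (`TfAP-2`-like), high in all T4 clusters;
#' * an a,b marker pair (`dac`, `ab`-like) and a c,d marker pair
#'   (`omb`, `pros`-like);
#' * b,c markers (`grain`, `beat-IV`, `CG34353`-like);
#' * a single-subtype gene (`side-IV`-like, subtype a);
#' * a late-only gene, subtype-differential only at stages >= 60 h APF;
#' * a switching gene whose marked subtype set changes across stages
#'   ((a,b) at 36 h, (c,d) from 48 h on);
#' * housekeeping genes, designated mitochondrial-like and
#'   heat-shock-like gene groups, and one rare gene detected in fewer
#'   than three cells;
#' * a configured fraction of QC-failing cells (low depth, or more than
#'   10 percent mitochondrial-like or heat-shock-like counts).
#'
#' Expression is simulated for the hours-APF stages of
#' `config$stages` (the `"adult"` morphology stage has no single-cell
#' dataset and is skipped).
#'
#' @param config A [sim_config]; `nb_mean`, `nb_dispersion`,
#'   `marker_high`, `marker_low`, `n_cells_per_cluster`, `qc_fail_frac`
#'   and `seed` are used.
#' @return Object of class `t4t5_expression`: list with `counts`
#'   (cells x genes integer matrix), `genes` (annotation data.frame with
#'   category flags), `cells` (annotation data.frame with stage, cluster,
#'   ground-truth identity and `qc_fail` reason), `program` (array of
#'   configured per-gene per-cluster per-stage means), and `config`.
#' @export
generate_expression <- function(config) {
  validate_sim_config(config)
  stages <- setdiff(config$stages, "adult")
  if (!length(stages)) stages <- config$stages
  genes <- expression_gene_table()
  clusters <- paste0(rep(c("T4", "T5"), each = 4), c("a", "b", "c", "d"))
  n_cells <- config$n_cells_per_cluster

  program <- array(NA_real_,
                   dim = c(nrow(genes), length(clusters), length(stages)),
                   dimnames = list(genes$name, clusters, stages))
  for (st in stages) {
    for (cl in clusters) {
      program[, cl, st] <- vapply(seq_len(nrow(genes)), function(i) {
        gene_mean(genes[i, ], cl, st, config)
      }, numeric(1))
    }
  }

  counts <- list(); cells <- list()
  fail_modes <- c("low_depth", "high_mito", "high_hsp")
  cell_k <- 0L
  for (si in seq_along(stages)) {
    st <- stages[si]
    set.seed(child_seed(config$seed, 300000 + si))
    for (cl in clusters) {
      mu <- program[, cl, st]
      n_fail <- floor(config$qc_fail_frac * n_cells)
      for (j in seq_len(n_cells)) {
        cell_k <- cell_k + 1L
        fail <- if (j <= n_fail) fail_modes[(j - 1) %% 3 + 1] else "none"
        mu_j <- mu
        if (fail == "low_depth") mu_j <- mu * 0.3
        if (fail == "high_mito") mu_j[genes$is_mito] <- mu_j[genes$is_mito] * 25
        if (fail == "high_hsp") mu_j[genes$is_hsp] <- mu_j[genes$is_hsp] * 25
        counts[[cell_k]] <- stats::rnbinom(length(mu_j),
                                           size = config$nb_dispersion,
                                           mu = mu_j)
        cells[[cell_k]] <- data.frame(
          cell_id = sprintf("cell_%s_%05d", st, cell_k),
          stage = st, cluster = cl,
          cell_type = substr(cl, 1, 2), subtype = substr(cl, 3, 3),
          qc_fail = fail)
      }
    }
  }
  counts <- do.call(rbind, counts)
  storage.mode(counts) <- "integer"
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  # the rare gene is detected in exactly two cells
  counts[, genes$name == "rare1"] <- 0L
  counts[1:2, genes$name == "rare1"] <- 1L
  dimnames(counts) <- list(cells$cell_id, genes$name)
  structure(list(counts = counts, genes = genes, cells = cells,
                 program = program, config = config),
            class = "t4t5_expression")
}

expression_gene_table <- function() {
  g <- function(name, class, tf = FALSE, membrane = FALSE, mito = FALSE,
                hsp = FALSE, stable = FALSE) {
    data.frame(name = name, class = class, is_tf = tf, is_membrane = membrane,
               is_mito = mito, is_hsp = hsp, stable_marker = stable)
  }
  rbind(
    g("TfAP-2", "type_marker", tf = TRUE, stable = TRUE),
    g("dac", "ab_marker", tf = TRUE, stable = TRUE),
    g("ab", "ab_marker", tf = TRUE, stable = TRUE),
    g("omb", "cd_marker", tf = TRUE, stable = TRUE),
    g("pros", "cd_marker", tf = TRUE, stable = TRUE),
    g("grain", "bc_marker", tf = TRUE, stable = TRUE),
    g("beat-IV", "bc_marker", membrane = TRUE, stable = TRUE),
    g("CG34353", "bc_marker", membrane = TRUE, stable = TRUE),
    g("side-IV", "single_subtype", membrane = TRUE, stable = TRUE),
    g("late1", "late_only", membrane = TRUE),
    g("switch1", "switching", tf = TRUE),
    do.call(rbind, lapply(1:8, function(i) g(sprintf("hk%d", i),
                                             "housekeeping"))),
    g("mt:CoI", "mito", mito = TRUE),
    g("mt:CoII", "mito", mito = TRUE),
    g("mt:ND5", "mito", mito = TRUE),
    g("Hsp26", "hsp", hsp = TRUE),
    g("Hsp70", "hsp", hsp = TRUE),
    g("rare1", "rare")
  )
}

# Configured mean of one gene in one cluster at one stage.
gene_mean <- function(gene, cluster, stage, config) {
  hi <- config$marker_high; lo <- config$marker_low
  mid <- config$nb_mean / 8
  type <- substr(cluster, 1, 2); sub <- substr(cluster, 3, 3)
  st_num <- suppressWarnings(as.numeric(stage))
  switch(gene$class,
    type_marker = if (type == "T4") hi else lo,
    ab_marker = if (sub %in% c("a", "b")) hi else lo,
    cd_marker = if (sub %in% c("c", "d")) hi else lo,
    bc_marker = if (sub %in% c("b", "c")) hi else lo,
    single_subtype = if (sub == "a") hi else lo,
    late_only = if (!is.na(st_num) && st_num >= 60) {
      if (sub %in% c("b", "c")) hi else lo
    } else mid,
    switching = if (is.na(st_num) || st_num < 36) mid
      else if (st_num < 48) { if (sub %in% c("a", "b")) hi else lo }
      else { if (sub %in% c("c", "d")) hi else lo },
    housekeeping = config$nb_mean,
    mito = config$nb_mean / 10,
    hsp = config$nb_mean / 10,
    rare = 0,
    stop("unknown gene class: ", gene$class, call. = FALSE))
}

#' @export
print.t4t5_expression <- function(x, ...) {
  cat("t4t5_expression:", nrow(x$counts), "cells x", ncol(x$counts),
      "genes,", length(unique(x$cells$stage)), "stage(s)\n")
  cat("  clusters:", paste(unique(x$cells$cluster), collapse = " "), "\n")
  cat("  QC-failing cells (by construction):",
      sum(x$cells$qc_fail != "none"), "\n")
  invisible(x)
}

#' Synthetic cell-body fluorescence table
#'
#' Emulates the anti-Grain immunostaining measurement: Lim1-positive
#' T4/T5 cell bodies of the four subtypes plus Lim1-negative surrounding
#' cell bodies, per optic lobe. Subtypes b and c draw their intensity
#' from a distribution enriched `cb_enrichment`-fold over the background
#' shared by subtypes a, d and the Lim1-negative cells.
#'
#' @param config A [sim_config] (`cb_enrichment`, `cb_noise_sd`, `seed`).
#' @param n_per_subtype Lim1-positive cell bodies per subtype per optic
#'   lobe (default 15, i.e. about 60 T4/T5 cell bodies per lobe).
#' @param n_background Lim1-negative cell bodies per optic lobe (>= 10).
#' @param n_lobes Number of optic-lobe groups.
#' @param background_mean Mean background intensity (arbitrary units).
#' @return data.frame with columns `optic_lobe`, `cell_id`,
#'   `mean_intensity`, `lim1_positive`, `dac_positive`, `gal4_positive`,
#'   `subtype` (ground truth; NA for Lim1-negative cells).
#' @export
generate_cellbody_table <- function(config, n_per_subtype = 15,
                                    n_background = 12, n_lobes = 4,
                                    background_mean = 100) {
  validate_sim_config(config)
  out <- list()
  for (lobe in seq_len(n_lobes)) {
    set.seed(child_seed(config$seed, 700000 + lobe))
    rows <- list()
    for (s in c("a", "b", "c", "d")) {
      mu <- background_mean * if (s %in% c("b", "c")) config$cb_enrichment else 1
      ints <- pmax(stats::rnorm(n_per_subtype, mu, config$cb_noise_sd), 1)
      rows[[s]] <- data.frame(
        mean_intensity = ints, lim1_positive = TRUE,
        dac_positive = s %in% c("a", "b"),
        gal4_positive = s %in% c("b", "c"), subtype = s)
    }
    bg <- data.frame(
      mean_intensity = pmax(stats::rnorm(n_background, background_mean,
                                         config$cb_noise_sd), 1),
      lim1_positive = FALSE, dac_positive = FALSE, gal4_positive = FALSE,
      subtype = NA_character_)
    lobe_tb <- rbind(do.call(rbind, rows), bg)
    lobe_tb$optic_lobe <- sprintf("lobe%d", lobe)
    out[[lobe]] <- lobe_tb
  }
  tb <- do.call(rbind, out)
  tb$cell_id <- sprintf("cb_%04d", seq_len(nrow(tb)))
  rownames(tb) <- NULL
  tb[, c("optic_lobe", "cell_id", "mean_intensity", "lim1_positive",
         "dac_positive", "gal4_positive", "subtype")]
}

#' Write / read an expression set as MatrixMarket plus CSV sidecars
#'
#' Counts go to `counts.mtx` (1-based MatrixMarket coordinate format,
#' cells as rows), annotations to `genes.csv` and `cells.csv`, and the
#' generation parameters to `parameters.yaml`.
#'
#' @param x A `t4t5_expression`.
#' @param dir Directory to write to / read from.
#' @return `write_expression` returns `dir` invisibly; `read_expression`
#'   returns a `t4t5_expression` (without the configured `program`).
#' @export
write_expression <- function(x, dir) {
  stopifnot(inherits(x, "t4t5_expression"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  utils::write.csv(x$genes, file.path(dir, "genes.csv"), row.names = FALSE)
  utils::write.csv(x$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  if (!is.null(x$config)) {
    yaml::write_yaml(config_as_yaml_list(x$config),
                     file.path(dir, "parameters.yaml"))
  }
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- utils::read.csv(file.path(dir, "genes.csv"))
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cells$cell_id, genes$name)
  cfg_path <- file.path(dir, "parameters.yaml")
  cfg <- if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    raw$subtype_angles <- unlist(raw$subtype_angles)
    raw$layer_centers <- unlist(raw$layer_centers)
    raw$stage_size <- unlist(raw$stage_size)
    raw$stages <- as.character(unlist(raw$stages))
    do.call(sim_config, raw[intersect(names(raw),
                                      names(formals(sim_config)))])
  } else NULL
  structure(list(counts = counts, genes = genes, cells = cells,
                 program = NULL, config = cfg),
            class = "t4t5_expression")
}
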
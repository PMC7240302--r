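# Shared fixtures built in code.

small_config <- function(...) {
  sim_config(n_neurons_per_subtype = 2, stages = c("36", "72"), seed = 7L,
             ...)
}

# circular mean direction of angles in degrees
circ_mean_deg <- function(deg) {
  th <- deg * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
}

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# normalized random histogram for metric tests
random_histogram <- function(n_bins = 12) {
  m <- stats::runif(n_bins)
  polar_histogram(m / sum(m), n_vectors = 100L)
}

# branch angles realized in a generated skeleton (tip nodes only)
skeleton_branch_angles <- function(skel) {
  nb <- (nrow(skel$nodes) - 5) / 2
  tips <- skel$nodes[skel$nodes$id > 5 + nb, ]
  (atan2(tips$y, tips$x) * 180 / pi) %% 360
}

# 10-cell QC toy: one high-mito cell, one low-depth cell, one 2-cell gene
make_qc_toy <- function() {
  counts <- matrix(0L, nrow = 10, ncol = 8,
                   dimnames = list(paste0("c", 1:10),
                                   c("g1", "g2", "g3", "g4", "g5",
                                     "mt1", "h1", "r1")))
  counts[, c("g1", "g2", "g3", "g4")] <- 60L
  counts[, "mt1"] <- 5L
  counts[, "h1"] <- 5L
  counts["c2", "mt1"] <- 40L                      # 12% mito counts
  counts["c3", c("g1", "g2", "g3", "g4")] <- 35L  # 150 total counts
  counts[c("c1", "c4"), "r1"] <- 1L               # detected in 2 cells
  counts[c("c1", "c4", "c5"), "g5"] <- 10L        # detected in exactly 3
  toy_expression(counts,
                 is_mito = colnames(counts) == "mt1",
                 is_hsp = colnames(counts) == "h1")
}

# minimal expression object for QC/DEG toys
toy_expression <- function(counts, is_mito = NULL, is_hsp = NULL) {
  genes <- data.frame(name = colnames(counts),
                      is_mito = if (is.null(is_mito))
                        rep(FALSE, ncol(counts)) else is_mito,
                      is_hsp = if (is.null(is_hsp))
                        rep(FALSE, ncol(counts)) else is_hsp)
  cells <- data.frame(cell_id = rownames(counts),
                      cluster = rep("c1", nrow(counts)))
  structure(list(counts = counts, genes = genes, cells = cells,
                 program = NULL, config = NULL),
            class = "t4t5_expression")
}
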
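test_that("QC filter matches a brute-force enumeration on a 10-cell toy", {
  toy <- make_qc_toy()
  res <- qc_filter(toy)

  # independent enumeration of the rules
  m <- toy$counts
  total <- rowSums(m)
  mito <- m[, "mt1"] / total
  hsp <- m[, "h1"] / total
  bad_cells <- rownames(m)[total < 200 | mito > 0.1 | hsp > 0.1]
  surv <- m[setdiff(rownames(m), bad_cells), ]
  bad_genes <- colnames(m)[colSums(surv > 0) < 3]

  expect_setequal(res$report$id[res$report$entity == "cell"], bad_cells)
  expect_setequal(res$report$id[res$report$entity == "gene"], bad_genes)
  expect_equal(bad_cells, c("c2", "c3"))
  expect_equal(bad_genes, "r1")
  # the 3-cell gene sits exactly on the retention boundary
  expect_true("g5" %in% colnames(res$filtered$counts))
  expect_equal(res$filtered$counts,
               m[setdiff(rownames(m), bad_cells),
                 setdiff(colnames(m), bad_genes)])
  reasons <- res$report$reason[match(c("c2", "c3"), res$report$id)]
  expect_equal(reasons, c("high_mito_fraction", "low_counts"))
})

test_that("QC filtering is idempotent and leaves no violations", {
  cfg <- sim_config(qc_fail_frac = 0.1, stages = c("36", "48"))
  x <- generate_expression(cfg)
  res <- qc_filter(x)
  f <- res$filtered
  expect_true(all(rowSums(f$counts) >= 200))
  expect_true(all(rowSums(f$counts[, f$genes$is_mito, drop = FALSE]) /
                    rowSums(f$counts) <= 0.1))
  expect_true(all(colSums(f$counts > 0) >= 3))
  again <- qc_filter(f)
  expect_identical(again$filtered$counts, f$counts)
  expect_equal(nrow(again$report), 0)
  expect_error(qc_filter(toy_expression(matrix(integer(0), 0, 0))), "empty")
})

test_that("depth normalization scales to the target and is scale-invariant", {
  m <- matrix(c(10, 0), nrow = 1, dimnames = list("c1", c("g1", "g2")))
  n <- normalize_counts(m, target = 10)
  expect_equal(as.numeric(n), c(log(11), 0))

  m2 <- rbind(c1 = c(3, 7), c2 = c(6, 14)) # c2 = doubled c1
  colnames(m2) <- c("g1", "g2")
  n2 <- normalize_counts(m2)
  expect_equal(n2["c1", ], n2["c2", ])

  set.seed(2)
  m3 <- matrix(rpois(200, 5) + 1, 10, 20)
  n3 <- normalize_counts(m3, target = 1e4)
  expect_equal(unname(rowSums(expm1(n3))), rep(1e4, 10))
  expect_error(normalize_counts(rbind(c(0, 0))), "zero-total")
})

test_that("pairwise DEG filter applies the three thresholds", {
  # fractions (1, 0) with a large fold change: passes
  counts <- matrix(0L, 10, 2,
                   dimnames = list(paste0("c", 1:10), c("gA", "filler")))
  counts[, "filler"] <- 100L
  counts[1:5, "gA"] <- 10L
  labels <- rep(c("A", "B"), each = 5)
  recs <- pairwise_deg(counts, "A", "B", labels = labels)
  expect_equal(recs$gene, "gA")
  expect_equal(recs$cluster, "A")

  # fractions (0.6, 0.4) fail min_diff_frac regardless of fold change
  counts2 <- counts
  counts2[1:3, "gA"] <- 1000L; counts2[4:5, "gA"] <- 0L
  counts2[6:7, "gA"] <- 1L
  expect_equal(nrow(pairwise_deg(counts2, "A", "B", labels = labels)), 0)
  expect_error(pairwise_deg(counts, "A", "Z", labels = labels), "unknown")
})

test_that("DEG filter equals per-gene rule enumeration on a 6-gene toy", {
  set.seed(6)
  genes <- paste0("g", 1:6)
  counts <- matrix(0L, 10, 6, dimnames = list(paste0("c", 1:10), genes))
  counts[1:5, "g1"] <- 10L
  counts[c(1:3, 6:7), "g2"] <- 8L
  counts[, "g3"] <- 1L
  counts[1:5, "g4"] <- 50L; counts[6, "g4"] <- 1L
  counts[1:3, "g5"] <- 5L
  counts[6:10, "g6"] <- 20L
  labels <- rep(c("A", "B"), each = 5)
  recs <- pairwise_deg(counts, "A", "B", labels = labels)

  # independent oracle: recompute every quantity with separate arithmetic
  tot <- apply(counts, 1, sum)
  norm <- log(1 + sweep(counts, 1, tot, "/") * 1e4)
  oracle <- list()
  for (g in genes) {
    for (dir in list(c("A", "B"), c("B", "A"))) {
      hi <- labels == dir[1]; lo <- labels == dir[2]
      f_hi <- sum(counts[hi, g] > 0) / sum(hi)
      f_lo <- sum(counts[lo, g] > 0) / sum(lo)
      fc <- (mean(norm[hi, g]) + 0.01) / (mean(norm[lo, g]) + 0.01)
      if (f_hi >= 0.5 && f_hi - f_lo >= 0.5 && fc >= 2) {
        oracle[[length(oracle) + 1]] <- data.frame(gene = g,
                                                   cluster = dir[1],
                                                   fold_change = fc)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$gene, oracle$cluster), ]
  expect_equal(recs$gene, oracle$gene)
  expect_equal(recs$cluster, oracle$cluster)
  expect_equal(recs$fold_change, oracle$fold_change)
})

test_that("DEG passing is anti-symmetric at min_diff_frac >= 0.5", {
  set.seed(14)
  for (i in 1:10) {
    counts <- matrix(rnbinom(20 * 12, size = 2, mu = 4), 20, 12,
                     dimnames = list(paste0("c", 1:20), paste0("g", 1:12)))
    labels <- rep(c("A", "B"), each = 10)
    recs <- pairwise_deg(counts, "A", "B", labels = labels)
    expect_equal(anyDuplicated(recs$gene), 0)
  }
})

test_that("stage sets combine into union, intersection and profiles", {
  out <- stage_consistent_degs(list(s1 = c("A", "B"), s2 = c("B", "C")))
  expect_equal(out$union, c("A", "B", "C"))
  expect_equal(out$intersection, "B")
  expect_equal(out$profile$stages[out$profile$gene == "B"], "s1,s2")

  single <- stage_consistent_degs(list(s1 = c("X", "Y")))
  expect_equal(single$union, single$intersection)
})

test_that("marker-based identity assignment recovers the ground truth", {
  cfg <- sim_config()
  x <- generate_expression(cfg)
  prof <- t(x$program[, , "48"]) # clusters x genes, configured means
  out <- assign_cluster_identity(prof)
  expect_equal(paste0(out$cell_type, out$subtype), out$cluster)

  # permuting cluster input order permutes output labels consistently
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  out_p <- assign_cluster_identity(prof[perm, ])
  expect_equal(out_p[order(out_p$cluster), c("cell_type", "subtype")],
               out[order(out$cluster), c("cell_type", "subtype")],
               ignore_attr = TRUE)

  flat <- prof
  flat[, "TfAP-2"] <- 1
  expect_error(assign_cluster_identity(flat), "TfAP-2")
  expect_error(assign_cluster_identity(prof[1:6, ]), "8 clusters")
})

test_that("dynamics categories follow the stage pattern of marked subtypes", {
  bc_all <- list("36" = c("b", "c"), "48" = c("b", "c"),
                 "60" = c("b", "c"), "72" = c("b", "c"))
  expect_equal(categorize_dynamics(bc_all), "stable_subtype_specific")

  late <- list("36" = character(0), "48" = character(0),
               "60" = c("b", "c"), "72" = c("b", "c"))
  expect_equal(categorize_dynamics(late), "late_only")

  sw <- list("36" = c("a", "b"), "48" = c("c", "d"),
             "60" = c("c", "d"), "72" = c("c", "d"))
  expect_equal(categorize_dynamics(sw), "switching")

  none <- list("36" = character(0), "48" = character(0),
               "60" = character(0), "72" = character(0))
  expect_equal(categorize_dynamics(none), "none")
  expect_equal(categorize_dynamics(none, type_flags = c("36" = TRUE)),
               "type_specific")
  # subtype-specific in only one type is type-level
  expect_equal(categorize_dynamics(bc_all, subtype_sets_t5 = none),
               "type_specific")
  expect_error(categorize_dynamics(list("36" = "a")), "stages")
})

test_that("marked subtype sets use the midpoint-and-fold rule", {
  expect_equal(marked_subtypes(c(a = 0.1, b = 5, c = 5, d = 0.1)),
               c("b", "c"))
  expect_equal(marked_subtypes(c(a = 1, b = 1.2, c = 1.1, d = 1)),
               character(0)) # fold below threshold
})

test_that("the TF code decodes, encodes and perturbs as a bijection", {
  expect_equal(decode_tf_code(tf_code(TRUE, FALSE, FALSE)), "a")
  expect_equal(decode_tf_code(tf_code(FALSE, TRUE, TRUE)), "c")
  for (s in c("a", "b", "c", "d")) {
    expect_equal(decode_tf_code(encode_subtype(s)), s)
  }
  expect_error(tf_code(TRUE, TRUE, FALSE), "exactly one")
  expect_error(tf_code(FALSE, FALSE, TRUE), "exactly one")

  over <- vapply(c("a", "b", "c", "d"), function(s) {
    decode_tf_code(perturb_code(encode_subtype(s), "overexpression"))
  }, character(1))
  expect_equal(unname(over), c("b", "b", "c", "c"))
  kd <- vapply(c("a", "b", "c", "d"), function(s) {
    decode_tf_code(perturb_code(encode_subtype(s), "knockdown"))
  }, character(1))
  expect_equal(unname(kd), c("a", "a", "d", "d"))

  for (s in c("a", "b", "c", "d")) {
    code <- encode_subtype(s)
    for (mode in c("overexpression", "knockdown")) {
      once <- perturb_code(code, mode)
      expect_identical(perturb_code(once, mode), once) # idempotent
    }
    expect_identical(perturb_code(code, "none"), code)
  }
  # knockdown then overexpression restores b,c; the reverse restores a,d
  for (s in c("b", "c")) {
    expect_equal(decode_tf_code(perturb_code(perturb_code(
      encode_subtype(s), "knockdown"), "overexpression")), s)
  }
  for (s in c("a", "d")) {
    expect_equal(decode_tf_code(perturb_code(perturb_code(
      encode_subtype(s), "overexpression"), "knockdown")), s)
  }
})

test_that("grain scores divide by background and ignore global scale", {
  tb <- data.frame(
    mean_intensity = c(rep(100, 4), rep(300, 4), rep(100, 12)),
    lim1_positive = c(rep(TRUE, 8), rep(FALSE, 12)),
    dac_positive = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                     rep(FALSE, 12)),
    gal4_positive = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                      rep(FALSE, 12)))
  s <- grain_score(tb)
  expect_equal(s$score[s$subtype %in% c("a", "d")], c(1, 1))
  expect_equal(s$score[s$subtype %in% c("b", "c")], c(3, 3))

  tb2 <- tb
  tb2$mean_intensity <- tb2$mean_intensity * 17.3
  expect_equal(grain_score(tb2)$score, s$score)

  few_bg <- tb[c(1:8, 9:15), ]
  expect_error(grain_score(few_bg), "Lim1-negative")
})
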
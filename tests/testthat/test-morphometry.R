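test_that("first branching point is detected or taken from the designation", {
  straight <- neuron_skeleton(data.frame(id = 1:3, type = 3,
                                         x = 0:2, y = 0, z = 0,
                                         radius = 1, parent = c(-1, 1, 2)))
  expect_error(first_branch_point(straight), "branching")

  y_shape <- neuron_skeleton(data.frame(
    id = 1:4, type = 3, x = c(0, 1, 2, 2), y = c(0, 0, 1, -1), z = 0,
    radius = 1, parent = c(-1, 1, 2, 2)))
  expect_equal(first_branch_point(y_shape), c(x = 1, y = 0, z = 0))

  no_dend <- neuron_skeleton(data.frame(id = 1:2, type = 2, x = 0:1,
                                        y = 0, z = 0, radius = 1,
                                        parent = c(-1, 1)))
  expect_error(first_branch_point(no_dend), "dendrite")

  g <- generate_neuron("a", "72", small_config(), seed = 1)
  bp <- first_branch_point(g$skeleton)
  row <- g$skeleton$nodes[g$skeleton$nodes$id == g$skeleton$branch_node, ]
  expect_equal(bp, c(x = row$x, y = row$y, z = row$z))
})

test_that("orientation histograms bin vectors as specified", {
  pts <- cbind(c(1, 2, 3), c(1, 2, 3)) # all at 45 degrees
  h <- orientation_histogram(pts, center = c(0, 0))
  expect_s3_class(h, "polar_histogram")
  expect_equal(h$bin_masses[2], 1)
  expect_equal(sum(h$bin_masses), 1)
  expect_equal(h$n_vectors, 3L)

  # points exactly at the center are excluded
  h2 <- orientation_histogram(rbind(pts, c(0, 0)), center = c(0, 0))
  expect_equal(h2$n_vectors, 3L)
  expect_error(orientation_histogram(matrix(0, 2, 2), center = c(0, 0)),
               "center")
  expect_error(orientation_histogram(pts, center = c(0, 0), n_bins = 0),
               "n_bins")
})

test_that("rotation by a bin width cyclically shifts the masses exactly", {
  set.seed(31)
  for (rep in 1:5) {
    ang <- stats::runif(300, 0, 360)
    ang <- ang[pmin(ang %% 30, 30 - ang %% 30) > 0.5] # keep off bin edges
    r <- stats::runif(length(ang), 0.5, 4)
    pts <- cbind(r * cos(ang * pi / 180), r * sin(ang * pi / 180))
    h0 <- orientation_histogram(pts, center = c(0, 0))
    shift <- sample(1:11, 1)
    phi <- shift * 30 * pi / 180
    rot <- pts %*% t(matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2))
    h1 <- orientation_histogram(rot, center = c(0, 0))
    expected <- h0$bin_masses[((seq_len(12) - 1 - shift) %% 12) + 1]
    expect_identical(h1$bin_masses, expected)
  }
})

test_that("image input thresholds pixels and uses the branch-point center", {
  skel <- generate_neuron("c", "72", small_config(), seed = 4)$skeleton
  img <- rasterize_dendrite(skel, pixel_size = 0.25, noise_level = 30,
                            seed = 2)
  h <- orientation_histogram(img) # Otsu threshold, center from the raster
  expect_equal(sum(h$bin_masses), 1, tolerance = 1e-12)
  # subtype c points up: the upper half-plane dominates and the modal bin
  # straddles 90 degrees (pixel histograms are flatter than branch-angle
  # histograms because densely covered directions saturate the raster area)
  expect_gt(sum(h$bin_masses[1:6]), 0.75)
  expect_true(which.max(h$bin_masses) %in% 3:4)
  expect_error(orientation_histogram(img$image, center = c(1e6, 1e6)),
               "bounds")
  expect_error(orientation_histogram(img$image,
                                     center = img$branch_point,
                                     intensity_threshold = 1e9),
               "suprathreshold")
})

test_that("cross-stage scaling multiplies masses by the vector-count ratio", {
  h_early <- polar_histogram(rep(1 / 12, 12), n_vectors = 500L)
  h_late <- polar_histogram(rep(1 / 12, 12), n_vectors = 1000L)
  s <- scale_histogram(h_early, h_late)
  expect_equal(s$scale_factor, 0.5)
  expect_equal(sum(s$bin_masses), 0.5)

  s_id <- scale_histogram(h_late, h_late)
  expect_equal(s_id$scale_factor, 1)
  expect_equal(s_id$bin_masses, h_late$bin_masses)

  empty <- polar_histogram(rep(0, 12), n_vectors = 0L)
  expect_error(scale_histogram(h_early, empty), "no vectors")

  cfg <- small_config()
  h36 <- orientation_histogram(rasterize_dendrite(
    generate_neuron("a", "36", cfg, seed = 9)$skeleton))
  h72 <- orientation_histogram(rasterize_dendrite(
    generate_neuron("a", "72", cfg, seed = 9)$skeleton))
  expect_lt(scale_histogram(h36, h72)$scale_factor, 1)
})

test_that("histogram averaging reports mean and s.e.m. correctly", {
  h <- polar_histogram(c(1, rep(0, 11)), n_vectors = 10L)
  avg <- average_histograms(list(h, h))
  expect_equal(avg$mean$bin_masses, h$bin_masses)
  expect_equal(avg$sem, rep(0, 12))
  expect_false(avg$sem_undefined)

  h2 <- polar_histogram(c(0, 1, rep(0, 10)), n_vectors = 10L)
  avg2 <- average_histograms(list(h, h2))
  expect_equal(avg2$mean$bin_masses, c(0.5, 0.5, rep(0, 10)))
  # two-sample s.e.m. = sd/sqrt(2) = |x1-x2|/2
  expect_equal(avg2$sem, c(0.5, 0.5, rep(0, 10)))

  single <- average_histograms(list(h))
  expect_true(single$sem_undefined)
  expect_equal(single$sem, rep(0, 12))

  h6 <- polar_histogram(rep(1 / 6, 6), n_vectors = 10L)
  expect_error(average_histograms(list(h, h6)), "mixed")

  # s.e.m. shrinks as 1/sqrt(n)
  set.seed(5)
  hs <- replicate(100, random_histogram(), simplify = FALSE)
  sem100 <- mean(average_histograms(hs)$sem)
  sem25 <- mean(average_histograms(hs[1:25])$sem)
  expect_equal(sem25 / sem100, 2, tolerance = 0.5)
})

test_that("the similarity index is an L1 metric bounded by 2", {
  set.seed(17)
  h <- random_histogram()
  expect_equal(similarity_index(h, h), 0)

  u0 <- polar_histogram(c(1, rep(0, 11)), n_vectors = 1L)
  u6 <- polar_histogram(c(rep(0, 6), 1, rep(0, 5)), n_vectors = 1L)
  expect_equal(similarity_index(u0, u6), 2)

  for (i in 1:200) {
    a <- random_histogram(); b <- random_histogram(); c <- random_histogram()
    expect_identical(similarity_index(a, b), similarity_index(b, a))
    expect_lte(similarity_index(a, b),
               similarity_index(a, c) + similarity_index(c, b) + 1e-12)
    expect_lte(similarity_index(a, b), 2)
  }
  h6 <- polar_histogram(rep(1 / 6, 6), n_vectors = 1L)
  expect_error(similarity_index(h, h6), "binning")
  expect_error(similarity_index(scale_histogram(h, polar_histogram(
    rep(1 / 12, 12), n_vectors = 200L)), h), "normalized")
})

test_that("similarity index equals the brute-force accumulation oracle", {
  set.seed(23)
  for (i in 1:1000) {
    a <- random_histogram(); b <- random_histogram()
    acc <- 0
    for (k in 1:12) {
      d <- a$bin_masses[k] - b$bin_masses[k]
      acc <- acc + if (d < 0) -d else d
    }
    expect_lt(abs(similarity_index(a, b) - acc), 1e-12)
  }
})

test_that("similarity matrices preserve ordering and shapes", {
  set.seed(3)
  refs <- list(a = random_histogram(), b = random_histogram(),
               c = random_histogram(), d = random_histogram())
  m <- similarity_matrix(refs, refs)
  expect_equal(dim(m), c(4, 4))
  expect_equal(unname(diag(m)), rep(0, 4))
  q <- list(q1 = random_histogram())
  expect_equal(dim(similarity_matrix(q, refs)), c(4, 1))
  expect_error(similarity_matrix(list(), refs), "empty")
})

test_that("nearest-reference classification picks the minimum with tie rule", {
  set.seed(8)
  refs <- list(a = random_histogram(), b = random_histogram(),
               c = random_histogram(), d = random_histogram())
  out <- classify_by_dendrite(refs$b, refs)
  expect_equal(out$subtype, "b")
  expect_false(out$tie)

  # query equidistant from a and c
  refs2 <- refs
  refs2$a <- refs2$c
  out2 <- classify_by_dendrite(refs2$c, refs2)
  expect_equal(out2$subtype, "a")
  expect_true(out2$tie)

  expect_error(classify_by_dendrite(refs$a, refs[c("a", "b", "c")]),
               "a, b, c, d")
})

test_that("volumes normalize to the maximum and track the growth profile", {
  expect_equal(normalize_volumes(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_volumes(5), 1)
  expect_error(normalize_volumes(c(0, 0)), "all-zero")
  expect_error(normalize_volumes(numeric(0)), "empty")

  vox <- matrix(0, 3, 2)
  expect_equal(dendrite_volume(vox, voxel_volume = 2), 6)
  expect_equal(dendrite_volume(array(c(TRUE, FALSE, TRUE, TRUE))), 3)

  cfg <- sim_config(n_neurons_per_subtype = 2,
                    stages = c("36", "72", "adult"))
  vols <- vapply(c("36", "72", "adult"), function(st) {
    mean(vapply(1:8, function(s) {
      dendrite_volume(generate_neuron("a", st, cfg, seed = s)$skeleton)
    }, numeric(1)))
  }, numeric(1))
  nv <- normalize_volumes(vols)
  expect_equal(unname(which.max(nv)), 2) # peak at 72 h APF
  expect_lt(nv["36"], nv["72"])
  expect_lt(nv["adult"], nv["72"])
})
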
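test_that("mean time-course feature matches naive group-by averaging", {
  ph <- small_phantom(seed = 4, snr = 2)
  sv <- run_slic(ph$bold, ph$mask, n_supervoxels = 12, max_iter = 3)
  F1 <- mean_intensity_feature(ph$bold, ph$mask, sv)
  idx <- which(ph$mask$data)
  flat <- matrix(ph$bold$data, length(ph$mask$data), ph$bold$T)
  for (i in c(1, sv$N)) {
    vox <- idx[sv$labels == i]
    Z <- apply(flat[vox, , drop = FALSE], 1, function(x) (x - mean(x)) / sd(x))
    expect_equal(F1[, i], rowMeans(Z))
  }
  # a supervoxel of identical voxels reproduces the (z-scored) series
  same <- which(sv$sizes == 1)
  if (length(same) > 0) {
    vox <- idx[sv$labels == same[1]]
    x <- flat[vox, ]
    expect_equal(F1[, same[1]], (x - mean(x)) / sd(x))
  }
})

test_that("intensity histograms are column-stochastic and count correctly", {
  ph <- small_phantom(seed = 9)
  sv <- run_slic(ph$bold, ph$mask, n_supervoxels = 10, max_iter = 3)
  img <- temporal_mean_image(ph$bold)
  H <- intensity_histogram_feature(img, ph$mask, sv, n_bins = 12)
  expect_equal(dim(H), c(12, sv$N))
  expect_equal(colSums(H), rep(1, sv$N))
  # hand-counted check on one supervoxel
  x <- img[ph$mask$data]
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = 13)
  i <- which.max(sv$sizes)
  xs <- x[sv$labels == i]
  cnt <- table(factor(findInterval(xs, br, rightmost.closed = TRUE),
                      levels = 1:12))
  expect_equal(H[, i], as.numeric(cnt) / length(xs))
  # constant image degenerates to one-hot columns
  Hc <- intensity_histogram_feature(array(3, dim(img)), ph$mask, sv)
  expect_true(all(Hc[1, ] == 1) && all(Hc[-1, ] == 0))
})

test_that("the 64 six-neighbor patterns fall into exactly 10 rotation classes", {
  tab <- lbp_group_table()
  expect_length(tab, 64)
  expect_equal(length(unique(tab)), 10)
  # constant patterns are fixed by every rotation: distinct singleton classes
  expect_equal(sum(tab == tab[0 + 1]), 1)
  expect_equal(sum(tab == tab[63 + 1]), 1)
  expect_false(tab[0 + 1] == tab[63 + 1])
  # the six single-bit patterns share one class (oracle: orbit enumeration)
  single <- 2^(0:5)
  expect_equal(length(unique(tab[single + 1])), 1)
  expect_equal(pattern_orbit(1), single)
  # every class agrees with independent orbit enumeration
  for (p in c(0, 1, 3, 5, 21, 42, 63)) {
    orbit <- pattern_orbit(p)
    expect_equal(length(unique(tab[orbit + 1])), 1, label = paste("pattern", p))
  }
})

test_that("LBP codes and histograms behave on constant and random images", {
  mask <- brain_mask(array(1, c(6, 6, 4)))
  const <- lbp3d_codes(array(2, c(6, 6, 4)), mask)
  # interior voxels of a constant image see all-ties (>=): the all-one class;
  # boundary voxels see out-of-grid zeros and land elsewhere
  tab <- lbp_group_table()
  expect_equal(unique(as.vector(const[3:4, 3:4, 2:3])), tab[63 + 1])
  set.seed(2)
  img <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  codes <- lbp3d_codes(img, mask)
  expect_true(all(codes[mask$data] %in% 1:10))
  ph <- small_phantom(seed = 3, shape = c(6, 6, 4), K_true = 2)
  sv <- run_slic(ph$bold, ph$mask, n_supervoxels = 6, max_iter = 2)
  H <- lbp_histogram_feature(codes, mask, sv)
  expect_equal(colSums(H), rep(1, sv$N))
  # naive group-by count for one supervoxel
  i <- which.max(sv$sizes)
  cd <- codes[mask$data][sv$labels == i]
  expect_equal(H[, i], as.numeric(table(factor(cd, levels = 1:10))) / length(cd))
})

test_that("distance graphs match the naive oracle and normalize idempotently", {
  expect_equal(distance_graph(matrix(c(0, 3), 1, 2))[1, 2], 3)
  set.seed(6)
  P <- matrix(rnorm(40), 5, 8)
  G <- distance_graph(P)
  expect_equal(unclass(G)[seq_len(64)], as.vector(naive_distance_graph(P)),
               tolerance = 1e-12)
  expect_equal(diag(G), rep(0, 8))
  Gn <- normalize_graph(G)
  expect_equal(max(Gn), 1)
  expect_equal(normalize_graph(Gn), Gn)
  expect_equal(normalize_graph(G * 7), Gn)
  Z <- matrix(0, 2, 3)
  expect_equal(max(normalize_graph(distance_graph(Z))), 0)
})

test_that("spatial adjacency counts 26-adjacent supervoxel pairs", {
  # two face-adjacent cubes
  lab <- array(0L, c(4, 2, 2))
  lab[1:2, , ] <- 1L; lab[3:4, , ] <- 2L
  sv <- structure(list(labels3d = lab, N = 2L), class = "supervoxel_map")
  adj <- spatial_adjacency(sv)
  expect_equal(adj$S0, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(adj$k_est, 1L)
  # 3x1x1 chain of single-voxel supervoxels: column sums (1,2,1)
  chain <- array(0L, c(3, 1, 1)); chain[] <- 1:3
  svc <- structure(list(labels3d = chain, N = 3L), class = "supervoxel_map")
  adjc <- spatial_adjacency(svc)
  expect_equal(colSums(adjc$S0), c(1, 2, 1))
  expect_equal(adjc$k_est, 1L)   # round(4/3)
  expect_identical(adjc$S0, t(adjc$S0))
  expect_equal(diag(adjc$S0), rep(0, 3))
  one <- structure(list(labels3d = array(1L, c(2, 2, 2)), N = 1L),
                   class = "supervoxel_map")
  expect_error(spatial_adjacency(one), "too small")
})
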
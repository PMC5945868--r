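# Small random graphs for block-update tests.
rand_graphs <- function(n, M = 2, seed = 1) {
  set.seed(seed)
  Gx <- normalize_graph(distance_graph(matrix(runif(3 * n), 3, n)))
  Gy <- lapply(seq_len(M), function(m) {
    normalize_graph(distance_graph(matrix(rnorm(4 * n), 4, n)))
  })
  list(Gx = Gx, Gy = Gy)
}

test_that("the cost matrix is the weighted sum of squared normalized graphs", {
  g <- rand_graphs(4, M = 2, seed = 5)
  alpha <- c(0.3, 0.7)
  Gz <- normalize_graph(distance_graph(matrix(rnorm(8), 2, 4)))
  P <- cost_matrix(g$Gx, g$Gy, Gz, alpha, lambda = 0.2, mu = 3)
  # naive per-entry evaluation
  for (i in 1:4) for (j in 1:4) {
    expect_equal(P[i, j],
                 g$Gx[i, j]^2 + 0.2 * (0.3 * g$Gy[[1]][i, j]^2 +
                                         0.7 * g$Gy[[2]][i, j]^2) +
                   3 * Gz[i, j]^2)
  }
  # term isolation
  P0 <- cost_matrix(g$Gx, g$Gy, NULL, c(0, 0), lambda = 0.2, mu = 3)
  expect_equal(P0, g$Gx^2, ignore_attr = TRUE)
  P1 <- cost_matrix(g$Gx * 0, g$Gy, NULL, c(1, 0), lambda = 0.2, mu = 0)
  expect_equal(P1, 0.2 * g$Gy[[1]]^2, ignore_attr = TRUE)
})

test_that("the spectral embedding attains the K smallest eigenvalue sum", {
  set.seed(8)
  for (r in 1:10) {
    n <- sample(6:12, 1)
    K <- sample(2:4, 1)
    S <- learn_affinity(matrix(runif(n * n), n, n), k = 3)$S
    emb <- spectral_embedding(S, K)
    expect_equal(crossprod(emb$Z), diag(K), tolerance = 1e-8, ignore_attr = TRUE)
    Ss <- (S + t(S)) / 2
    L <- diag(rowSums(Ss)) - Ss
    tr <- sum(diag(t(emb$Z) %*% L %*% emb$Z))
    ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(tr, sum(ev[seq_len(K)]), tolerance = 1e-8)
    # adversarial: random orthonormal Z never does better
    Q <- qr.Q(qr(matrix(rnorm(n * K), n, K)))
    expect_gte(sum(diag(t(Q) %*% L %*% Q)), tr - 1e-8)
  }
  # block-diagonal graph with K components: null space gives zero trace
  S <- as.matrix(Matrix::bdiag(matrix(1 / 3, 3, 3), matrix(1 / 3, 3, 3)))
  emb <- spectral_embedding(S, 2)
  expect_equal(emb$eigvals, c(0, 0), tolerance = 1e-10)
  # complete basis: trace equals trace of L
  emb_all <- spectral_embedding(S, 6)
  L <- diag(rowSums(S)) - S
  expect_equal(sum(emb_all$eigvals), sum(diag(L)), tolerance = 1e-10)
})

test_that("affinity learning is columnwise optimal and k-sparse", {
  set.seed(12)
  n <- 8; k <- 3
  P <- matrix(runif(n * n, 0, 2), n, n); P <- (P + t(P)) / 2; diag(P) <- 0
  af <- learn_affinity(P, k)
  expect_equal(colSums(af$S), rep(1, n), tolerance = 1e-10)
  expect_true(all(colSums(af$S > 0) <= k))
  expect_equal(diag(af$S), rep(0, n))
  for (i in seq_len(n)) {
    beta_i <- sparse_simplex_update(P[, i], k, exclude = i)$beta
    if (beta_i <= 0) next
    o <- enum_simplex_qp(P[, i], beta_i, forbidden = i)
    expect_equal(simplex_qp_objective(P[, i], af$S[, i], beta_i),
                 o$objective, tolerance = 1e-8)
    # adversarial random simplex columns never do better
    for (a in 1:5) {
      s_rand <- as.vector(stats::rmultinom(1, 50, rep(1, n - 1))) / 50
      s_full <- numeric(n); s_full[-i] <- s_rand
      expect_gte(simplex_qp_objective(P[, i], s_full, beta_i),
                 simplex_qp_objective(P[, i], af$S[, i], beta_i) - 1e-9)
    }
  }
})

test_that("feature costs and weight updates follow the closed forms", {
  g <- rand_graphs(5, M = 3, seed = 9)
  S <- learn_affinity(cost_matrix(g$Gx, g$Gy, NULL, rep(1 / 3, 3)), k = 2)$S
  q <- feature_cost_vector(g$Gy, S)
  # double-loop oracle
  for (m in 1:3) {
    tot <- 0
    for (i in 1:5) for (j in 1:5) tot <- tot + g$Gy[[m]][i, j]^2 * S[i, j]
    expect_equal(q[[m]], tot)
  }
  expect_equal(feature_cost_vector(g$Gy, S * 0), rep(0, 3), ignore_attr = TRUE)
  # uniform costs give uniform weights; M = 1 stays at 1
  expect_equal(update_feature_weights(rep(2, 4), beta_bar = 1), rep(1 / 4, 4))
  expect_equal(update_feature_weights(5, beta_bar = 0.3), 1)
  expect_warning(a <- update_feature_weights(c(1, 2), 0, alpha_prev = c(0.4, 0.6)),
                 "beta_bar")
  expect_equal(a, c(0.4, 0.6))
  # against the enumeration QP oracle on the alpha problem
  lambda <- 0.1; gamma <- 1; bb <- 0.05
  qv <- c(1, 2, 4)
  alpha <- update_feature_weights(qv, bb, lambda, gamma)
  o <- enum_simplex_qp(lambda * qv, bb * gamma)
  expect_equal(simplex_qp_objective(lambda * qv, alpha, bb * gamma),
               o$objective, tolerance = 1e-8)
  # adversarial random simplex weights never do better
  set.seed(3)
  for (a in 1:10) {
    ar <- as.vector(stats::rmultinom(1, 60, rep(1, 3))) / 60
    expect_gte(simplex_qp_objective(lambda * qv, ar, bb * gamma),
               simplex_qp_objective(lambda * qv, alpha, bb * gamma) - 1e-9)
  }
})

test_that("label extraction reads components or falls back to spectral cuts", {
  S <- as.matrix(Matrix::bdiag(matrix(1 / 2, 2, 2), matrix(1 / 3, 3, 3),
                               matrix(1 / 2, 2, 2)))
  lab <- graph_labels(S, 3)
  expect_equal(lab, c(1, 1, 2, 2, 2, 3, 3))
  # fewer components than requested: the weakly joined pair is cut
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  W[3, 4] <- W[4, 3] <- 0.01
  lab2 <- graph_labels(W / sum(W), 2)
  expect_equal(length(unique(lab2)), 2)
  expect_true(all(lab2[1:3] == lab2[1]) && all(lab2[4:6] == lab2[4]))
  expect_false(lab2[1] == lab2[4])
  # permutation equivariance
  perm <- c(3, 1, 2, 6, 5, 4, 7)
  labp <- graph_labels(S[perm, perm], 3)
  expect_equal(ari(labp, lab[perm]), 1)
})

test_that("voxel mapping conserves counts and handles identity labels", {
  ph <- small_phantom(seed = 19)
  sv <- run_slic(ph$bold, ph$mask, n_supervoxels = 10, max_iter = 2)
  at1 <- labels_to_atlas(rep(1L, sv$N), sv, ph$mask)
  expect_true(all(at1$labels[ph$mask$data] == 1))
  atid <- labels_to_atlas(seq_len(sv$N), sv, ph$mask)
  expect_identical(atid$labels, sv$labels3d)
  lab2 <- c(rep(1L, sv$N %/% 2), rep(2L, sv$N - sv$N %/% 2))
  at2 <- labels_to_atlas(lab2, sv, ph$mask)
  expect_equal(tabulate(at2$labels[at2$labels > 0]),
               as.vector(rowsum(sv$sizes, lab2)))
  expect_error(labels_to_atlas(1:3, sv, ph$mask), "supervoxels")
})

test_that("the full fit recovers planted parcels and is deterministic", {
  ph <- make_phantom(shape = c(14, 14, 10), K_true = 4, T_len = 60, snr = 8,
                     seed = 3)
  fit <- gwc(ph$bold, ph$mask, K = 4, n_supervoxels = 80, k = 9)
  expect_s3_class(fit, "gwc")
  expect_gte(ari(atlas_labels_inmask(fit$atlas, ph$mask),
                 atlas_labels_inmask(ph$atlas, ph$mask)), 0.8)
  expect_equal(fit$n_components, 4)
  expect_true(all(abs(colSums(fit$S) - 1) < 1e-10))
  fit2 <- gwc(ph$bold, ph$mask, K = 4, n_supervoxels = 80, k = 9)
  expect_identical(fit$S, fit2$S)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$atlas$labels, fit2$atlas$labels)
  # S3 surface
  expect_output(print(fit), "Graph-without-cut")
  expect_output(print(summary(fit)), "discontiguity")
  expect_length(coef(fit), 3)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-10)
  expect_s3_class(fitted(fit), "brain_atlas")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "bold_volume")
  fh <- functional_homogeneity(fit$atlas, sims[[1]], ph$mask)
  expect_gt(fh$homogeneity, 0.8)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, "atlas"))
})
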
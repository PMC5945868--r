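# Independent oracles used to cross-check the closed-form and vectorized
# implementations. These deliberately use naive algorithms (enumeration,
# double loops) so they share no code path with the package.

# Exact generic solver for min p's + beta s's over the probability simplex:
# active-set enumeration over all supports (global optimum of a convex QP is
# among the equality-constrained stationary points with feasible signs).
enum_simplex_qp <- function(p, beta, forbidden = integer(0)) {
  n <- length(p)
  idx <- setdiff(seq_len(n), forbidden)
  best <- NULL
  best_obj <- Inf
  for (sz in seq_along(idx)) {
    for (A in utils::combn(idx, sz, simplify = FALSE)) {
      theta <- (2 * beta + sum(p[A])) / length(A)
      sA <- (theta - p[A]) / (2 * beta)
      if (any(sA < -1e-12)) next
      s <- numeric(n)
      s[A] <- pmax(sA, 0)
      s <- s / sum(s)
      obj <- sum(p * s) + beta * sum(s^2)
      if (obj < best_obj) { best_obj <- obj; best <- s }
    }
  }
  list(s = best, objective = best_obj)
}

simplex_qp_objective <- function(p, s, beta) sum(p * s) + beta * sum(s^2)

# Naive double-loop functional homogeneity (definition-level).
naive_homogeneity <- function(atlas, volume, mask) {
  idx <- which(mask$data)
  d <- dim(volume$data)
  flat <- matrix(volume$data, prod(d[1:3]), d[4])
  lab <- atlas$labels[idx]
  a_k <- c()
  for (k in sort(unique(lab[lab > 0]))) {
    vox <- idx[lab == k]
    if (length(vox) < 2) next
    tot <- 0
    for (i in seq_along(vox)) for (j in seq_along(vox)) {
      if (i != j) {
        r <- suppressWarnings(cor(flat[vox[i], ], flat[vox[j], ]))
        tot <- tot + if (is.na(r)) 0 else r
      }
    }
    a_k <- c(a_k, tot / (length(vox) * (length(vox) - 1)))
  }
  mean(a_k)
}

# Brute-force adjacency-matrix Dice (diagonal included).
naive_dice <- function(labA, labB) {
  A <- outer(labA, labA, "==") * 1
  B <- outer(labB, labB, "==") * 1
  2 * sum(A * B) / (sum(A) + sum(B))
}

# Naive pairwise Euclidean distance graph.
naive_distance_graph <- function(points) {
  n <- ncol(points)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G[i, j] <- sqrt(sum((points[, i] - points[, j])^2))
  }
  G
}

# Orbit of a 6-bit pattern under the 24 proper cube rotations, enumerated
# directly from rotation matrices (independent of the package's grouping).
pattern_orbit <- function(pattern) {
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  bits <- as.integer(intToBits(pattern)[1:6])
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rotmat <- function(axis, theta) {
    u <- axis; c0 <- cos(theta); s0 <- sin(theta)
    outer(u, u) * (1 - c0) + diag(3) * c0 +
      s0 * matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  }
  seen <- integer(0)
  # generate the rotation group from 90-degree generators
  mats <- list(diag(3))
  repeat {
    new <- list()
    for (Mc in mats) for (ax in axes) {
      R <- round(rotmat(ax, pi / 2) %*% Mc)
      if (!any(vapply(c(mats, new), function(X) all(X == R), logical(1)))) {
        new <- c(new, list(R))
      }
    }
    if (length(new) == 0) break
    mats <- c(mats, new)
  }
  for (R in mats) {
    newbits <- integer(6)
    for (b in 1:6) {
      tob <- which(apply(dirs, 1, function(d) all(d == as.vector(R %*% dirs[b, ]))))
      newbits[tob] <- bits[b]
    }
    seen <- c(seen, sum(newbits * 2^(0:5)))
  }
  sort(unique(seen))
}

# Tiny deterministic phantom for fast unit tests.
small_phantom <- function(seed = 7, snr = 50, shape = c(10, 10, 6),
                          K_true = 4, T_len = 30) {
  make_phantom(shape = shape, K_true = K_true, T_len = T_len, snr = snr,
               seed = seed)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

atlas_labels_inmask <- function(atlas, mask) atlas$labels[mask$data]
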
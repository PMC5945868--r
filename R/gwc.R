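## The graph-without-cut core: alternating optimization of a sparse affinity
## graph S (column-simplex, k nonzeros per column), a spectral embedding Z,
## and feature weights alpha, such that the learned graph has exactly K
## connected components. The three block updates are each optimal for their
## subproblem with the others fixed.

#' Combined cost matrix of the graph-learning objective
#'
#' `P = Gx^2 + lambda * sum_m alpha_m Gy_m^2 + mu * Gz^2`, where the squares
#' are elementwise squares of max-normalized distance graphs. `Gz = NULL`
#' omits the embedding term (used at initialization).
#'
#' @param Gx normalized spatial distance graph (N x N)
#' @param Gy list of M normalized feature distance graphs
#' @param Gz normalized embedding-row distance graph, or NULL
#' @param alpha feature weight vector on the simplex
#' @param lambda feature-term weight
#' @param mu embedding-term weight
#' @return N x N symmetric nonnegative cost matrix
#' @export
cost_matrix <- function(Gx, Gy, Gz = NULL, alpha, lambda = 0.1, mu = 1e4) {
  stopifnot(length(Gy) == length(alpha))
  P <- Gx^2
  for (m in seq_along(Gy)) P <- P + lambda * alpha[m] * Gy[[m]]^2
  if (!is.null(Gz)) P <- P + mu * Gz^2
  P
}

#' Spectral embedding from an affinity graph
#'
#' Builds the symmetrized graph `S* = (S + S')/2`, its degree matrix D and
#' unnormalized Laplacian `L = D - S*`, and returns the K eigenvectors of the
#' K smallest eigenvalues. `tr(Z'LZ)` equals the sum of those eigenvalues,
#' the minimum of the trace objective over orthonormal Z.
#'
#' @param S N x N affinity matrix
#' @param K embedding dimension (number of clusters)
#' @return list with `Z` (N x K, orthonormal columns) and `eigvals` (the K
#'   smallest Laplacian eigenvalues, ascending)
#' @export
spectral_embedding <- function(S, K) {
  N <- nrow(S)
  stopifnot(K <= N)
  Ss <- (S + t(S)) / 2
  L <- diag(rowSums(Ss)) - Ss
  e <- eigen(L, symmetric = TRUE)
  sel <- N:(N - K + 1)
  list(Z = e$vectors[, sel, drop = FALSE], eigvals = e$values[sel])
}

#' Learn the sparse affinity graph from a cost matrix
#'
#' Each column i is the k-sparse simplex minimizer of
#' `p_i' s + beta ||s||^2` with self-affinity zero (see
#' [sparse_simplex_update()]). `beta_bar` is the mean of the per-column
#' implied beta values, excluding degenerate (zero) columns.
#'
#' @param P cost matrix from [cost_matrix()]
#' @param k nonzeros per column
#' @return list with `S` (N x N, columns on the simplex, <= k nonzeros, zero
#'   diagonal) and `beta_bar`
#' @export
learn_affinity <- function(P, k) {
  N <- ncol(P)
  S <- matrix(0, N, N)
  betas <- numeric(N)
  for (i in seq_len(N)) {
    sol <- sparse_simplex_update(P[, i], k, exclude = i)
    S[, i] <- sol$s
    betas[i] <- sol$beta
  }
  pos <- betas > 0
  list(S = S, beta_bar = if (any(pos)) mean(betas[pos]) else 0)
}

#' Per-feature cost of the current graph
#'
#' `q_m = sum_ij Gy_m[i,j]^2 * S[i,j]`: the Hadamard product of the squared
#' normalized feature graph with the affinity graph, summed.
#'
#' @param Gy list of normalized feature distance graphs
#' @param S affinity matrix
#' @return length-M numeric vector
#' @export
feature_cost_vector <- function(Gy, S) {
  vapply(Gy, function(G) sum(G^2 * S), numeric(1))
}

#' Update the feature weights on the simplex
#'
#' `alpha = project_simplex(-lambda * q / (2 * beta_bar * gamma))`: features
#' whose graphs agree with the learned affinities (small q) gain weight.
#' With a non-positive `beta_bar` the previous weights are kept with a
#' warning.
#'
#' @param q output of [feature_cost_vector()]
#' @param beta_bar mean implied regularization from [learn_affinity()]
#' @param lambda feature-term weight
#' @param gamma weight-regularization parameter
#' @param alpha_prev previous weights (fallback)
#' @return simplex vector of length M
#' @export
update_feature_weights <- function(q, beta_bar, lambda = 0.1, gamma = 1,
                                   alpha_prev = NULL) {
  if (beta_bar <= 0) {
    warning("non-positive beta_bar; feature weights kept unchanged")
    return(alpha_prev %||% rep(1 / length(q), length(q)))
  }
  project_simplex(-lambda * q / (2 * beta_bar * gamma))
}

.n_components <- function(S) {
  Ss <- (S + t(S)) / 2
  g <- igraph::graph_from_adjacency_matrix(Ss > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

#' Extract cluster labels from a learned affinity graph
#'
#' If the symmetrized graph has exactly K connected components, those are the
#' clusters. Otherwise normalized-cut spectral clustering with K clusters is
#' run on the symmetrized graph. Labels are densified to 1..K_actual with
#' K_actual <= K.
#'
#' @param S learned affinity matrix
#' @param K requested cluster count
#' @param seed seed for the spectral discretization
#' @return integer label vector (one label per supervoxel)
#' @export
graph_labels <- function(S, K, seed = 1) {
  Ss <- (S + t(S)) / 2
  g <- igraph::graph_from_adjacency_matrix(Ss > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  lab <- if (comp$no == K) comp$membership else ncut_labels(Ss, K, seed)
  as.integer(.densify_labels(as.integer(lab)))
}

#' Map supervoxel cluster labels to a voxel-level atlas
#'
#' @param sv_labels integer label per supervoxel
#' @param sv a `supervoxel_map`
#' @param mask a [brain_mask()]
#' @param affine 4x4 transform
#' @return a [brain_atlas()]
#' @export
labels_to_atlas <- function(sv_labels, sv, mask, affine = diag(4)) {
  if (length(sv_labels) != sv$N || anyNA(sv_labels)) {
    stop("need one label for each of the ", sv$N, " supervoxels")
  }
  lab <- array(0L, dim(mask$data))
  lab[mask_index(mask)] <- as.integer(sv_labels)[sv$labels]
  brain_atlas(.densify_labels(lab), affine)
}

#' Whole-brain parcellation by supervoxels and structured graph learning
#'
#' Fits the full pipeline: SLIC supervoxels on the BOLD time series, feature
#' extraction (mean time course, intensity histogram, LBP histogram),
#' max-normalized distance graphs, then alternating optimization of the
#' affinity graph S, spectral embedding Z, and feature weights alpha. The
#' embedding penalty (weight `mu`) drives the K smallest Laplacian
#' eigenvalues of S toward zero, so the converged graph has exactly K
#' connected components; labels are read off the components (normalized-cut
#' clustering of S is the fallback when the count differs) and mapped back
#' to voxels.
#'
#' @details
#' The component-count guarantee requires the column sparsity `k` to match
#' the data's granularity: a cluster can only be isolated if it holds more
#' than `k` supervoxels, while a too-small `k` lets the embedding penalty
#' cut large clusters into bands. Both failure directions are visible at
#' convergence from the component count of the learned graph alone, so when
#' it misses K the graph learning is rerun with `k` stepped by 2 toward the
#' feasible direction (larger `k` when over-fragmented, smaller when
#' under-fragmented), at most `k_retries` times. The supervoxels, features,
#' and distance graphs are computed once and reused; `k_trace` in the
#' result records the sparsities tried. The procedure uses only the fitted
#' graph, never reference labels, and is fully deterministic.
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()] on the same grid
#' @param K initialized cluster number (K >= 2)
#' @param n_supervoxels target SLIC supervoxel count
#' @param slic_m SLIC compactness parameter
#' @param slic_iter SLIC iterations
#' @param lambda feature-term weight
#' @param gamma feature-weight regularization
#' @param mu embedding-term weight (large to enforce the component count)
#' @param k nonzero affinities per column of S; `"auto"` estimates it as the
#'   mean number of spatially 26-adjacent supervoxel neighbors
#' @param k_retries if the converged graph's component count differs from K
#'   (the sparsity was too small or too large for the data's granularity),
#'   refit the graph with `k` stepped by 2 in the indicated direction, up to
#'   this many times; 0 disables the adaptation
#' @param max_iter maximum alternating iterations
#' @param tol convergence tolerance on the relative Frobenius change of S
#' @param n_bins intensity histogram bins
#' @param seed seed for the spectral discretization fallback
#' @param verbose print per-iteration diagnostics
#' @return object of class `gwc`: list with `atlas` ([brain_atlas()]),
#'   `sv_labels` (cluster label per supervoxel), `S` (learned affinity),
#'   `alpha` (feature weights), `supervoxels`, `features`, `history`
#'   (per-iteration objective, change, component count, beta_bar), `alpha_trace`,
#'   `K`, `K_actual`, `k`, `converged`, `params`, `call`
#' @export
gwc <- function(volume, mask, K, n_supervoxels = 1000, slic_m = 10,
                slic_iter = 10, lambda = 0.1, gamma = 1, mu = 1e4,
                k = "auto", k_retries = 2, max_iter = 100, tol = 1e-4,
                n_bins = 12, seed = 1, verbose = FALSE) {
  stopifnot(K >= 2, lambda > 0, gamma > 0, mu > 0)
  cl <- match.call()
  sv <- run_slic(volume, mask, n_supervoxels = n_supervoxels, m = slic_m,
                 max_iter = slic_iter)
  feats <- supervoxel_features(volume, mask, sv, n_bins = n_bins)
  adj <- spatial_adjacency(sv)
  if (identical(k, "auto")) k <- adj$k_est
  k <- max(1L, min(as.integer(k), sv$N - 2L))

  Gx <- normalize_graph(distance_graph(sv$centroids))
  Gy <- lapply(feats$Y, function(Y) normalize_graph(distance_graph(Y)))

  ## The graph learning itself; rerun with an adapted sparsity if the
  ## converged component count misses K (see Details).
  k_trace <- integer(0)
  for (attempt in seq_len(k_retries + 1)) {
    k_trace <- c(k_trace, k)
    opt <- .gwc_optimize(Gx, Gy, K, k, lambda, gamma, mu, max_iter, tol,
                         names(feats$Y), verbose)
    if (opt$n_components == K || attempt > k_retries) break
    step <- if (opt$n_components > K) 2L else -2L
    k_new <- max(1L, min(k + step, sv$N - 2L))
    if (k_new == k) break
    if (verbose) {
      message("converged with ", opt$n_components, " components for K = ",
              K, "; retrying with k = ", k_new)
    }
    k <- k_new
  }
  S <- opt$S

  sv_labels <- graph_labels(S, K, seed = seed)
  atlas <- labels_to_atlas(sv_labels, sv, mask, affine = mask$affine)

  structure(list(
    atlas = atlas, sv_labels = sv_labels, S = S, alpha = opt$alpha,
    supervoxels = sv, features = feats, history = opt$history,
    alpha_trace = opt$alpha_trace, K = K, K_actual = atlas$K, k = k,
    k_trace = k_trace, n_components = opt$n_components,
    converged = opt$converged,
    params = list(n_supervoxels = n_supervoxels, slic_m = slic_m,
                  lambda = lambda, gamma = gamma, mu = mu, k = k,
                  k_retries = k_retries, max_iter = max_iter, tol = tol,
                  n_bins = n_bins, seed = seed),
    call = cl), class = "gwc")
}

## One full alternating optimization at fixed sparsity k.
.gwc_optimize <- function(Gx, Gy, K, k, lambda, gamma, mu, max_iter, tol,
                          feature_names, verbose) {
  M <- length(Gy)
  alpha <- rep(1 / M, M)

  ## initialization: solve the problem without the embedding term
  P0 <- cost_matrix(Gx, Gy, NULL, alpha, lambda, mu)
  af <- learn_affinity(P0, k)
  S <- af$S
  beta_bar <- af$beta_bar

  history <- data.frame(iteration = integer(0), objective = numeric(0),
                        delta = numeric(0), n_components = integer(0),
                        beta_bar = numeric(0))
  alpha_trace <- matrix(alpha, 1, M, dimnames = list(NULL, feature_names))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    emb <- spectral_embedding(S, K)
    Gz <- normalize_graph(distance_graph(t(emb$Z)))
    P <- cost_matrix(Gx, Gy, Gz, alpha, lambda, mu)
    af <- learn_affinity(P, k)
    S_new <- af$S
    beta_bar <- af$beta_bar
    q <- feature_cost_vector(Gy, S_new)
    alpha <- update_feature_weights(q, beta_bar, lambda, gamma, alpha)
    delta <- norm(S_new - S, "F") / max(1, norm(S, "F"))
    obj <- sum(Gx^2 * S_new) + lambda * sum(alpha * q) +
      mu * sum(Gz^2 * S_new) + beta_bar * sum(S_new^2) +
      beta_bar * gamma * sum(alpha^2)
    if (!is.finite(obj)) {
      stop("non-finite objective at iteration ", it,
           "; check input scaling and parameters")
    }
    ncomp <- .n_components(S_new)
    history <- rbind(history, data.frame(
      iteration = it, objective = obj, delta = delta,
      n_components = ncomp, beta_bar = beta_bar))
    alpha_trace <- rbind(alpha_trace, alpha)
    if (verbose) {
      message(sprintf("iter %3d  obj %.6g  delta %.3e  components %d",
                      it, obj, delta, ncomp))
    }
    S <- S_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(S = S, alpha = alpha, history = history, alpha_trace = alpha_trace,
       converged = converged, n_components = .n_components(S))
}

#' @export
print.gwc <- function(x, ...) {
  cat("Graph-without-cut parcellation\n")
  cat("  supervoxels:", x$supervoxels$N,
      " clusters requested:", x$K,
      " obtained:", x$K_actual, "\n")
  cat("  graph components:", x$n_components,
      " iterations:", nrow(x$history),
      if (x$converged) " (converged)\n" else " (max iterations)\n")
  cat("  feature weights:",
      paste(sprintf("%s=%.3f", names(x$alpha_trace[1, ]), x$alpha),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.gwc <- function(object, ...) {
  sv_sizes <- object$supervoxels$sizes
  cluster_sizes <- tabulate(object$atlas$labels[object$atlas$labels > 0])
  structure(list(
    K = object$K, K_actual = object$K_actual,
    n_components = object$n_components,
    n_supervoxels = object$supervoxels$N,
    sv_size_range = range(sv_sizes),
    cluster_size_range = range(cluster_sizes),
    alpha = stats::setNames(object$alpha, colnames(object$alpha_trace)),
    k = object$k, iterations = nrow(object$history),
    converged = object$converged,
    final_objective = utils::tail(object$history$objective, 1),
    discontiguity = spatial_discontiguity_index(object$atlas)
  ), class = "summary.gwc")
}

#' @export
print.summary.gwc <- function(x, ...) {
  cat("Graph-without-cut parcellation summary\n")
  cat("  clusters: requested", x$K, "- obtained", x$K_actual,
      "- graph components", x$n_components, "\n")
  cat("  supervoxels:", x$n_supervoxels,
      sprintf("(sizes %d-%d)", x$sv_size_range[1], x$sv_size_range[2]), "\n")
  cat("  cluster sizes:", x$cluster_size_range[1], "-",
      x$cluster_size_range[2], "voxels\n")
  cat("  sparsity k:", x$k, "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max reached)",
      " final objective:", format(x$final_objective, digits = 6), "\n")
  cat("  feature weights:",
      paste(sprintf("%s=%.3f", names(x$alpha), x$alpha), collapse = ", "), "\n")
  cat("  spatial discontiguity index:", x$discontiguity, "\n")
  invisible(x)
}

#' @export
coef.gwc <- function(object, ...) {
  stats::setNames(object$alpha, colnames(object$alpha_trace))
}

#' @export
fitted.gwc <- function(object, ...) object$atlas

#' @export
plot.gwc <- function(x, which = c("objective", "atlas"), slice = NULL, ...) {
  which <- match.arg(which)
  if (which == "objective") {
    graphics::par(mfrow = c(1, 2))
    graphics::plot(x$history$iteration, x$history$objective, type = "b",
                   xlab = "iteration", ylab = "objective",
                   main = "graph-learning objective", ...)
    graphics::plot(x$history$iteration, x$history$n_components, type = "s",
                   xlab = "iteration", ylab = "graph components",
                   main = paste0("components (target ", x$K, ")"), ...)
    graphics::abline(h = x$K, lty = 2, col = "grey50")
  } else {
    lab <- x$atlas$labels
    slice <- slice %||% ceiling(dim(lab)[3] / 2)
    cols <- c("white", grDevices::hcl.colors(max(lab), "Spectral"))
    graphics::image(lab[, , slice], col = cols, axes = FALSE,
                    main = paste0("atlas, axial slice ", slice), ...)
  }
  invisible(x)
}

#' Simulate BOLD data from a fitted parcellation
#'
#' Draws phantom-style data with the fitted atlas as the planted partition:
#' each cluster receives an independent standard-Gaussian latent time course
#' and each voxel observes its cluster's course plus i.i.d. noise.
#'
#' @param object a fitted `gwc` object
#' @param nsim number of volumes to simulate
#' @param seed RNG seed
#' @param T_len time points per simulated volume (default: as fitted data)
#' @param snr latent-to-noise s.d. ratio
#' @param ... unused
#' @return list of [bold_volume()]s (length `nsim`)
#' @export
simulate.gwc <- function(object, nsim = 1, seed = 1, T_len = NULL,
                         snr = 8, ...) {
  set.seed(seed)
  atlas <- object$atlas
  T_len <- T_len %||% nrow(object$supervoxels$mean_series)
  idx <- which(atlas$labels > 0)
  parcel <- atlas$labels[idx]
  lapply(seq_len(nsim), function(i) {
    latent <- matrix(stats::rnorm(T_len * atlas$K), T_len, atlas$K)
    series <- latent[, parcel, drop = FALSE] +
      matrix(stats::rnorm(T_len * length(idx), sd = 1 / snr), T_len,
             length(idx))
    d3 <- dim(atlas$labels)
    flat <- matrix(0, prod(d3), T_len)
    flat[idx, ] <- t(series)
    bold_volume(array(flat, c(d3, T_len)), atlas$affine)
  })
}
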
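## The two simplex-constrained quadratic programs at the heart of the graph
## learning: Euclidean projection onto the probability simplex (feature
## weight update) and the k-sparse adaptive-neighbor update of one affinity
## column, both in closed form.

#' Euclidean projection onto the probability simplex
#'
#' Returns `argmin ||x - v||^2` subject to `sum(x) = 1, x >= 0`, via the
#' sort-and-threshold closed form: with `u = sort(v, decreasing)` and
#' cumulative sums `c_j`, the threshold is `theta = (1 - c_rho) / rho` for
#' the largest `rho` with `u_rho + (1 - c_rho)/rho > 0`, and
#' `x = pmax(v + theta, 0)`.
#'
#' @param v finite numeric vector
#' @return numeric vector on the simplex
#' @export
project_simplex <- function(v) {
  if (length(v) == 0) stop("empty vector")
  if (!all(is.finite(v))) stop("non-finite entries")
  n <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(n) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' k-sparse simplex update of one affinity column
#'
#' Solves `min_s p' s + beta ||s||^2` over the probability simplex with the
#' sparsity-implied regularization: the solution is supported on the `k`
#' smallest costs (self excluded). With sorted kept costs
#' `p_(1) <= ... <= p_(k)` and next cost `p_(k+1)`,
#' `s_(j) = (p_(k+1) - p_(j)) / (k p_(k+1) - sum_h p_(h))` on the support and
#' 0 elsewhere, and the implied `beta = (k p_(k+1) - sum_h p_(h)) / 2`.
#' When the `k+1` smallest costs are all tied the denominator degenerates;
#' the update then returns the uniform `1/k` weight on the k smallest
#' (tie-broken toward lower indices) with `beta = 0`. The self-affinity
#' `s[exclude]` is always 0.
#'
#' @param p cost vector (one column of the cost matrix)
#' @param k number of nonzero affinities, `1 <= k <= length(p) - 2`
#' @param exclude index of the self entry, forced to zero
#' @return list with `s` (full-length simplex vector), `support` (indices of
#'   nonzeros), `beta` (implied regularization scalar)
#' @export
sparse_simplex_update <- function(p, k, exclude = NULL) {
  n <- length(p)
  avail <- seq_len(n)
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == 1, exclude >= 1, exclude <= n)
    avail <- avail[-exclude]
  }
  if (k < 1 || k > length(avail) - 1) {
    stop("need 1 <= k <= ", length(avail) - 1, "; got k = ", k)
  }
  ord <- avail[order(p[avail], avail)]   # ties toward lower index
  kept <- ord[seq_len(k)]
  pk <- p[kept]
  pnext <- p[ord[k + 1]]
  den <- k * pnext - sum(pk)
  s <- numeric(n)
  if (den <= .Machine$double.eps * max(1, abs(pnext)) * k) {
    s[kept] <- 1 / k
    beta <- 0
  } else {
    s[kept] <- (pnext - pk) / den
    beta <- den / 2
  }
  list(s = s, support = kept[s[kept] > 0], beta = beta)
}
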
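#' Gaussian kernel density estimate over read-pair distances
#'
#' Returns a 1D (optionally weighted) Gaussian KDE that can be evaluated
#' exactly at arbitrary points. Weights are normalized to sum to one; the
#' unweighted case uses equal weights `1/n`.
#'
#' @param x Numeric data (bp distances).
#' @param bandwidth Kernel bandwidth `h` in bp (> 0).
#' @param weights Optional non-negative weights with positive sum.
#' @return An object of class `kde1d` with `$density(q)` evaluation,
#'   `$grid` (a tibble over an automatic grid) and `$bandwidth`.
#' @export
kde_1d <- function(x, bandwidth, weights = NULL) {
  stopifnot(length(x) >= 1, is.finite(bandwidth))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), all(weights >= 0))
  if (sum(weights) <= 0) stop("weights must have positive sum")
  ord <- order(x)
  xs <- as.numeric(x[ord])
  ws <- weights[ord] / sum(weights)
  dens_fun <- function(q) cpp_kde1d(xs, ws, bandwidth, as.numeric(q))
  grid_q <- seq(min(xs) - 6 * bandwidth, max(xs) + 6 * bandwidth,
                length.out = 512)
  obj <- structure(
    list(
      x = xs, weights = ws, bandwidth = bandwidth,
      density = dens_fun,
      grid = tibble::tibble(x = grid_q, density = dens_fun(grid_q))
    ),
    class = "kde1d"
  )
  obj
}

#' @export
print.kde1d <- function(x, ...) {
  cat("<kde1d> n =", length(x$x), " bandwidth =", x$bandwidth, "bp\n")
  invisible(x)
}

#' Least-squares cross-validation bandwidth for a 1D Gaussian KDE
#'
#' Minimizes the least-squares cross-validation estimate of the integrated
#' square error over a candidate grid (log-spaced by default). The
#' criterion is evaluated exactly on each candidate; for large samples a
#' random subsample (`max_n`) is scored instead, since the criterion is a
#' double sum over points.
#'
#' @param x Numeric data (>= 2 points).
#' @param candidates Candidate bandwidths in bp; default 20 log-spaced
#'   values between 10 and 10000.
#' @param max_n Subsample cap for the double-sum criterion (default 5000).
#' @return A list with `bandwidth` (the argmin) and a tibble `criterion`.
#' @export
lscv_bandwidth_1d <- function(x,
                              candidates = lscv_grid(),
                              max_n = 5000) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 2) stop("need at least 2 points for LSCV")
  if (length(x) > max_n) x <- sample(x, max_n)
  xs <- sort(x)
  crit <- cpp_lscv1d(xs, as.numeric(candidates))
  if (any(!is.finite(crit))) stop("non-finite LSCV criterion value")
  list(
    bandwidth = candidates[which.min(crit)],
    criterion = tibble::tibble(bandwidth = candidates, criterion = crit)
  )
}

#' Default log-spaced bandwidth candidate grid
#'
#' @param from,to Grid range in bp.
#' @param n Number of candidates.
#' @export
lscv_grid <- function(from = 10, to = 10000, n = 20) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Weighted bivariate Gaussian KDE evaluated at points
#'
#' Evaluates the self-ligation read-pair density: each ordered pair
#' `(x_i, y_i)` contributes an isotropic bivariate Gaussian kernel scaled
#' by its (normalized) weight.
#'
#' @param px,py Pair coordinates (lower, higher mate in bp).
#' @param weights Non-negative kernel weights.
#' @param bandwidth `h_self` in bp.
#' @param qx,qy Query coordinates.
#' @return Density values (per bp^2) at the query points.
#' @export
kde_2d_eval <- function(px, py, weights, bandwidth, qx, qy) {
  stopifnot(length(px) == length(py), length(px) == length(weights),
            length(qx) == length(qy))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (all(weights <= 0)) stop("no positive weights")
  ws <- weights / sum(weights)
  cpp_kde2d(as.numeric(px), as.numeric(py), as.numeric(ws),
            bandwidth, as.numeric(qx), as.numeric(qy))
}

#' Weighted least-squares cross-validation bandwidth for the 2D pair KDE
#'
#' The weighted generalization of least-squares cross-validation: the
#' roughness term uses kernel self-convolutions weighted by the product of
#' normalized weights, and the leave-one-out term drops each point from
#' its own density. With equal weights it reduces to the standard
#' unweighted criterion.
#'
#' @param px,py Pair coordinates in bp.
#' @param weights Per-pair self-ligation weights.
#' @param candidates Candidate bandwidths in bp.
#' @param max_n Subsample cap (default 2000 pairs, sampled by weight rank).
#' @return A list with `bandwidth` and the `criterion` tibble.
#' @export
lscv_bandwidth_2d <- function(px, py, weights,
                              candidates = lscv_grid(),
                              max_n = 2000) {
  keep <- weights > 0
  if (sum(keep) < 2) stop("need at least 2 positive-weight pairs for LSCV")
  px <- px[keep]; py <- py[keep]; weights <- weights[keep]
  if (length(px) > max_n) {
    idx <- sample(length(px), max_n)
    px <- px[idx]; py <- py[idx]; weights <- weights[idx]
  }
  crit <- cpp_lscv2d_weighted(as.numeric(px), as.numeric(py),
                              as.numeric(weights), as.numeric(candidates))
  if (any(!is.finite(crit))) stop("non-finite LSCV criterion value")
  list(
    bandwidth = candidates[which.min(crit)],
    criterion = tibble::tibble(bandwidth = candidates, criterion = crit)
  )
}
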
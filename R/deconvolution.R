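#' Windowed self-ligation pair density on a band grid
#'
#' Evaluates the weighted 2D kernel density of self-ligation read pairs on
#' a window, stored in band form: rows are window bins for the lower pair
#' coordinate x, columns are spans `a = (y - x) / step` up to `2 *
#' rsf_half_width`. Cell values are kernel mass per cell, normalized to
#' sum to one over the band.
#'
#' @param minus_plus A tibble of intra-chromosomal -+ pairs with `pos1`,
#'   `pos2` and `weight` columns (see [classify_self_ligation()]).
#' @param bandwidth `h_self` in bp.
#' @param chrom,start,end Window coordinates.
#' @param step Grid step in bp (default 10).
#' @param rsf_half_width RSF support half-width `W` in bp (default 500);
#'   pairs with span beyond `2 * W` cannot be explained by the RSF and are
#'   excluded with a message.
#' @return An object of class `pair_density_band`.
#' @export
self_pair_density <- function(minus_plus, bandwidth, chrom, start, end,
                              step = 10, rsf_half_width = 500) {
  stopifnot(end > start, bandwidth > 0)
  keep <- minus_plus$chrom1 == chrom & minus_plus$weight > 0 &
    minus_plus$pos1 >= start - 6 * bandwidth &
    minus_plus$pos2 <= end + 6 * bandwidth
  mp <- minus_plus[keep, ]
  if (nrow(mp) == 0 || sum(mp$weight) <= 0) {
    stop("no self-ligation signal in window ", chrom, ":", start, "-", end)
  }
  n_span <- as.integer(round(2 * rsf_half_width / step))
  wide <- (mp$pos2 - mp$pos1) > 2 * rsf_half_width + 6 * bandwidth
  if (any(wide)) {
    message(sum(wide), " pair(s) with span beyond the RSF support excluded")
    mp <- mp[!wide, ]
    if (nrow(mp) == 0) stop("no pairs within the RSF span limit")
  }
  n_bins <- as.integer(floor((end - start) / step))
  band <- cpp_kde_band(mp$pos1, mp$pos2, mp$weight / sum(mp$weight),
                       bandwidth, start, step, n_bins, n_span)
  total <- sum(band)
  if (total <= 0) stop("no kernel mass falls inside the window")
  structure(
    list(
      band = band / total, chrom = chrom, start = start, end = end,
      step = step, n_bins = n_bins, n_span = n_span,
      bandwidth = bandwidth, n_pairs = nrow(mp),
      weight_total = sum(mp$weight)
    ),
    class = "pair_density_band"
  )
}

#' @export
print.pair_density_band <- function(x, ...) {
  cat("<pair_density_band> ", x$chrom, ":", x$start, "-", x$end,
      " (", x$n_bins, " bins x ", x$n_span + 1, " spans, step ", x$step,
      " bp, ", x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

new_rsf <- function(values, step) {
  K <- nrow(values)
  stopifnot(K == ncol(values), K %% 2 == 1)
  structure(
    list(values = values, step = step, half_width = (K - 1) / 2 * step,
         offsets = seq(-(K - 1) / 2, (K - 1) / 2) * step),
    class = "rsf"
  )
}

#' Uniform read spread function over a square offset grid
#'
#' The standard neutral initialization for blind Richardson-Lucy updates.
#'
#' @param half_width Support half-width `W` in bp.
#' @param step Grid step in bp.
#' @return An object of class `rsf` whose values sum to one.
#' @export
rsf_uniform <- function(half_width, step = 10) {
  K <- 2L * as.integer(round(half_width / step)) + 1L
  new_rsf(matrix(1 / K^2, K, K), step)
}

#' @export
print.rsf <- function(x, ...) {
  cat("<rsf> half-width ", x$half_width, " bp, step ", x$step,
      " bp; peak offset lambda = ", tryCatch(rsf_peak(x),
                                             error = function(e) NA),
      " bp\n", sep = "")
  invisible(x)
}

#' One Richardson-Lucy occupancy update
#'
#' Applies the multiplicative expectation-maximization-like update to the
#' occupancy estimate with the read spread function held fixed. The update
#' preserves non-negativity and the total mass of the input estimate.
#'
#' @param occupancy Non-negative occupancy vector over the window bins.
#' @param rsf An `rsf` object on the same grid step.
#' @param selfdist A [self_pair_density()] band over the same window.
#' @return The updated occupancy vector.
#' @export
rl_update_occupancy <- function(occupancy, rsf, selfdist) {
  check_rl_grids(occupancy, rsf, selfdist)
  cpp_rl_occ(occupancy, rsf$values, selfdist$band)
}

#' One Richardson-Lucy read-spread-function update
#'
#' Multiplicative update of the RSF with the occupancy held fixed,
#' following the standard blind-RL correlation form; preserves
#' non-negativity and total mass.
#'
#' @inheritParams rl_update_occupancy
#' @return The updated `rsf` object.
#' @export
rl_update_rsf <- function(rsf, occupancy, selfdist) {
  check_rl_grids(occupancy, rsf, selfdist)
  new_rsf(cpp_rl_rsf(occupancy, rsf$values, selfdist$band), rsf$step)
}

check_rl_grids <- function(occupancy, rsf, selfdist) {
  stopifnot(inherits(rsf, "rsf"), inherits(selfdist, "pair_density_band"))
  if (rsf$step != selfdist$step) stop("RSF and band grid steps differ")
  if (length(occupancy) != selfdist$n_bins) {
    stop("occupancy length does not match the window bin count")
  }
  if (any(occupancy < 0)) stop("occupancy must be non-negative")
  invisible(TRUE)
}

#' Blind Richardson-Lucy deconvolution of occupancy and read spread
#'
#' Alternates blocks of occupancy updates and RSF updates against the
#' windowed self-ligation pair density, starting from uniform estimates.
#' Stops after `rounds` alternation rounds or when the L1 change of both
#' estimates over a round falls below `tol`.
#'
#' @param selfdist A [self_pair_density()] band (typically over a training
#'   window of a few megabases at most).
#' @param rsf_half_width RSF support half-width in bp; defaults to the
#'   band's span limit divided by two.
#' @param occ_updates,rsf_updates Updates per block (default 10 each).
#' @param rounds Maximum alternation rounds (default 5).
#' @param tol L1 convergence tolerance per round (default 1e-6).
#' @return An object of class `blind_deconv` with elements `occupancy`
#'   (tibble of bin start/mass), `rsf`, `lambda` (bp) and `trace`.
#' @export
blind_deconvolve <- function(selfdist, rsf_half_width = NULL,
                             occ_updates = 10, rsf_updates = 10,
                             rounds = 5, tol = 1e-6) {
  if (is.null(rsf_half_width)) {
    rsf_half_width <- selfdist$n_span * selfdist$step / 2
  }
  rsf <- rsf_uniform(rsf_half_width, selfdist$step)
  occ <- rep(1 / selfdist$n_bins, selfdist$n_bins)
  trace <- numeric(0)
  converged <- FALSE
  for (r in seq_len(rounds)) {
    occ_prev <- occ
    rsf_prev <- rsf$values
    for (k in seq_len(occ_updates)) {
      occ <- cpp_rl_occ(occ, rsf$values, selfdist$band)
    }
    for (k in seq_len(rsf_updates)) {
      rsf <- new_rsf(cpp_rl_rsf(occ, rsf$values, selfdist$band), rsf$step)
    }
    delta <- sum(abs(occ - occ_prev)) + sum(abs(rsf$values - rsf_prev))
    trace <- c(trace, delta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && rounds > 0 && tail(trace, 1) >= tol) {
    # returning the current state is still useful; flag it
    if (length(trace) == rounds) {
      warning("blind deconvolution did not reach tolerance after ",
              rounds, " rounds (last L1 change ", signif(tail(trace, 1), 3),
              ")", call. = FALSE)
    }
  }
  bins <- selfdist$start + (seq_len(selfdist$n_bins) - 1) * selfdist$step
  structure(
    list(
      occupancy = tibble::tibble(
        chrom = selfdist$chrom, start = bins, end = bins + selfdist$step,
        mass = occ
      ),
      rsf = rsf,
      lambda = rsf_peak(rsf),
      trace = trace,
      converged = converged,
      window = c(start = selfdist$start, end = selfdist$end),
      step = selfdist$step
    ),
    class = "blind_deconv"
  )
}

#' @export
print.blind_deconv <- function(x, ...) {
  cat("<blind_deconv> window ", x$occupancy$chrom[1], ":",
      x$window["start"], "-", x$window["end"], "; lambda = ", x$lambda,
      " bp; ", length(x$trace), " rounds\n", sep = "")
  invisible(x)
}

#' @describeIn blind_deconvolve Occupancy estimate as a tibble.
#' @param x A `blind_deconv` object.
#' @param ... Unused.
#' @export
tidy.blind_deconv <- function(x, ...) {
  x$occupancy
}

#' @describeIn blind_deconvolve One-row fit summary.
#' @export
glance.blind_deconv <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    rounds = length(x$trace),
    converged = x$converged,
    final_l1_change = if (length(x$trace)) tail(x$trace, 1) else NA_real_,
    rsf_half_width = x$rsf$half_width,
    step = x$step
  )
}

#' Peak offset of the read spread function
#'
#' Locates the global maximum of the RSF and projects it onto the
#' anti-identity line: a peak at offsets `(dx, dy)` gives
#' `lambda = (dy - dx) / 2`, about half the modal sonication fragment
#' length. Ties are broken toward the smaller lambda.
#'
#' @param rsf An `rsf` object.
#' @return `lambda` in bp.
#' @export
rsf_peak <- function(rsf) {
  v <- rsf$values
  mx <- max(v)
  if (mx <= min(v)) stop("no peak: flat read spread function")
  idx <- which(v == mx, arr.ind = TRUE)
  lam <- (rsf$offsets[idx[, 2]] - rsf$offsets[idx[, 1]]) / 2
  min(lam)
}

#' Strand marginals of the read spread function
#'
#' Marginalizes the 2D RSF into the two single-end spread distributions:
#' the minus-strand marginal over the lower-coordinate offset `dx`
#' (summing over `dy`) and the plus-strand marginal over `dy` (summing
#' over `dx`), each normalized to one.
#'
#' @param rsf An `rsf` object.
#' @return An object of class `rsf_marginals`: a list with `offsets`,
#'   `minus` and `plus` vectors and the grid `step`.
#' @export
marginalize_rsf <- function(rsf) {
  minus <- rowSums(rsf$values)
  plus <- colSums(rsf$values)
  structure(
    list(
      offsets = rsf$offsets,
      minus = minus / sum(minus),
      plus = plus / sum(plus),
      step = rsf$step,
      half_width = rsf$half_width
    ),
    class = "rsf_marginals"
  )
}

#' @export
print.rsf_marginals <- function(x, ...) {
  cat("<rsf_marginals> half-width ", x$half_width, " bp, step ", x$step,
      " bp\n", sep = "")
  invisible(x)
}

#' Genome-wide marginal occupancy by the diagonal-slice shortcut
#'
#' Once blind deconvolution has shown the RSF to be sharply peaked at
#' `(-lambda, lambda)`, the occupancy at a location `u` is proportional to
#' the self-ligation pair density evaluated at the single point
#' `(u - lambda, u + lambda)`. For the isotropic Gaussian kernel this is a
#' 1D weighted KDE over pair midpoints (bandwidth `h / sqrt(2)`) with each
#' pair further down-weighted by the distance of its half-span from
#' lambda. Bins farther than `4 * h` from every positively weighted pair
#' midpoint are exactly zero.
#'
#' @param minus_plus Weighted -+ pair tibble (needs `chrom1`, `pos1`,
#'   `pos2`, `weight`).
#' @param bandwidth `h_self` in bp.
#' @param lambda RSF peak offset in bp (>= 0).
#' @param genome A [genome_model()].
#' @param bin_size Track bin size in bp (default 10).
#' @return An `occupancy_track` tibble (chrom, start, end, mass) whose
#'   mass sums to one over the genome.
#' @export
occupancy_genome <- function(minus_plus, bandwidth, lambda, genome,
                             bin_size = 10) {
  stopifnot(lambda >= 0, bandwidth > 0)
  keep <- minus_plus$weight > 0
  if (!any(keep)) stop("no positive self-ligation weights")
  mp <- minus_plus[keep, ]
  mid <- (mp$pos1 + mp$pos2) / 2
  half <- (mp$pos2 - mp$pos1) / 2
  # the (lambda - half-span) factor of the 2D kernel, absorbed into weights
  vw <- mp$weight * exp(-(lambda - half)^2 / bandwidth^2)
  h_eff <- bandwidth / sqrt(2)
  tracks <- purrr::map(seq_len(nrow(genome$chromosomes)), function(ci) {
    chrom <- genome$chromosomes$chrom[ci]
    len <- genome$chromosomes$length[ci]
    n <- floor(len / bin_size)
    starts <- (seq_len(n) - 1) * bin_size
    centers <- starts + bin_size / 2
    on_chrom <- mp$chrom1 == chrom
    mass <- numeric(n)
    if (any(on_chrom) && sum(vw[on_chrom]) > 0) {
      ord <- order(mid[on_chrom])
      xs <- mid[on_chrom][ord]
      ws <- vw[on_chrom][ord]
      mass <- cpp_kde1d(xs, ws, h_eff, centers)
      mass[mass < 0] <- 0
    }
    tibble::tibble(chrom = chrom, start = starts, end = starts + bin_size,
                   mass = mass)
  })
  track <- dplyr::bind_rows(tracks)
  total <- sum(track$mass)
  if (total <= 0) stop("occupancy track has no mass")
  track$mass <- track$mass / total
  structure(track, bin_size = bin_size, genome = genome,
            lambda = lambda, bandwidth = bandwidth,
            class = c("occupancy_track", class(tibble::tibble())))
}
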
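# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive quantities from first principles in plain R,
# never through the package's own computational path.

# direct Gaussian KDE sum, weighted
oracle_kde1d <- function(x, w, h, q) {
  w <- w / sum(w)
  vapply(q, function(qq) {
    sum(w * exp(-0.5 * ((qq - x) / h)^2)) / (h * sqrt(2 * pi))
  }, numeric(1))
}

oracle_kde2d <- function(px, py, w, h, qx, qy) {
  w <- w / sum(w)
  vapply(seq_along(qx), function(k) {
    s2 <- ((qx[k] - px)^2 + (qy[k] - py)^2) / h^2
    sum(w * exp(-0.5 * s2)) / (2 * pi * h^2)
  }, numeric(1))
}

# unweighted 1D least-squares CV criterion as an explicit double sum
oracle_lscv1d <- function(x, h) {
  n <- length(x)
  d <- outer(x, x, "-")
  conv <- sum(exp(-d^2 / (4 * h^2))) / (n^2 * h * 2 * sqrt(pi))
  off <- exp(-d^2 / (2 * h^2))
  diag(off) <- 0
  loo <- sum(off) / (n * (n - 1) * h * sqrt(2 * pi))
  conv - 2 * loo
}

# weighted 2D least-squares CV criterion as an explicit double sum
oracle_lscv2d <- function(px, py, w, h) {
  n <- length(px)
  W <- sum(w)
  wt <- w / W
  d2 <- outer(px, px, "-")^2 + outer(py, py, "-")^2
  conv <- sum(outer(wt, wt) * exp(-d2 / (4 * h^2))) / (4 * pi * h^2)
  loo <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      loo <- loo + wt[i] * (w[j] / (W - w[i])) *
        exp(-0.5 * d2[i, j] / h^2) / (2 * pi * h^2)
    }
  }
  conv - 2 * loo
}

# exhaustive Pr(Y > Z) over all outcome pairs
oracle_pr_y_gt_z <- function(n1, p1, n2, p2) {
  total <- 0
  for (y in 0:n1) {
    for (z in 0:n2) {
      if (y > z) {
        total <- total + dbinom(y, n1, p1) * dbinom(z, n2, p2)
      }
    }
  }
  total
}

# forward convolution of an occupancy vector with an RSF matrix onto the
# band grid: D(i, a) = sum_j occ(j) * rsf(i - j, i - j + a), by triple loop
oracle_forward_band <- function(occ, rsf_values, n_span) {
  n <- length(occ)
  K <- nrow(rsf_values)
  Wb <- (K - 1) / 2
  out <- matrix(0, n, n_span + 1)
  for (j in seq_len(n)) {
    for (idx in seq_len(K)) {
      for (idy in seq_len(K)) {
        ddx <- idx - Wb - 1
        ddy <- idy - Wb - 1
        a <- ddy - ddx
        if (a < 0 || a > n_span) next
        i <- j + ddx
        if (i < 1 || i > n) next
        out[i, a + 1] <- out[i, a + 1] + occ[j] * rsf_values[idx, idy]
      }
    }
  }
  out
}

# a Gaussian-ridge RSF: mass along the anti-identity line at offset lambda
ridge_rsf <- function(half_width, step, lambda, ridge_sd, thickness_sd) {
  offs <- seq(-half_width, half_width, by = step)
  K <- length(offs)
  v <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      dx <- offs[i]; dy <- offs[j]
      along <- (dx + dy) / sqrt(2)        # distance from anti-identity line
      across <- (dy - dx) / 2 - lambda    # position along the line vs peak
      v[i, j] <- exp(-0.5 * (along / thickness_sd)^2) *
        exp(-0.5 * (across / ridge_sd)^2)
    }
  }
  v / sum(v)
}

# rsf object from a raw value matrix (mirrors the package constructor)
make_rsf <- function(values, step = 10) {
  K <- nrow(values)
  structure(
    list(values = values, step = step, half_width = (K - 1) / 2 * step,
         offsets = seq(-(K - 1) / 2, (K - 1) / 2) * step),
    class = "rsf"
  )
}

# dense occupancy track with the attributes downstream code expects
make_track <- function(genome, mass_fun, bin_size = 10) {
  tracks <- lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
    chrom <- genome$chromosomes$chrom[ci]
    n <- floor(genome$chromosomes$length[ci] / bin_size)
    starts <- (seq_len(n) - 1) * bin_size
    tibble::tibble(chrom = chrom, start = starts, end = starts + bin_size,
                   mass = mass_fun(chrom, starts))
  })
  track <- dplyr::bind_rows(tracks)
  track$mass <- track$mass / sum(track$mass)
  structure(track, bin_size = bin_size, genome = genome,
            lambda = NA_real_, bandwidth = NA_real_,
            class = c("occupancy_track", class(tibble::tibble())))
}

# minimal hand-built conditional field for significance-module tests
make_field <- function(profiles, support, t, m, n_inter, bin_size = 10) {
  n <- length(profiles)
  anchors <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 1e5,
    name = paste0("anchor_", seq_len(n)), anchor_id = seq_len(n),
    m = m, t = t, n_pairs = vapply(support, function(s) {
      length(unique(s$pair_id))
    }, integer(1)),
    flagged = FALSE
  )
  structure(
    list(anchors = anchors, profiles = profiles, support = support,
         norm = 1, n_inter = n_inter, bin_size = bin_size,
         marginals = NULL),
    class = "conditional_field"
  )
}

# profile tibble on a 10 bp grid from a named mass vector starting at `at`
make_profile <- function(mass, at = 1000, occ = NULL, bin = 10) {
  n <- length(mass)
  tibble::tibble(
    chrom = "chr1",
    start = at + (seq_len(n) - 1) * bin,
    mass = mass,
    occ_mass = if (is.null(occ)) rep(1e-4, n) else occ
  )
}
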
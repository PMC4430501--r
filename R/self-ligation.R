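#' Estimate the inter-ligation fraction among -+ read pairs
#'
#' Self-ligation can only produce the -+ orientation, while inter-ligation
#' produces all four orientations at equal rates. The average count of the
#' three non--+ orientations therefore estimates the number of -+ pairs
#' that arose from inter-ligation; dividing by the -+ count (and clipping
#' at 1) gives `Pr(z = inter)`.
#'
#' @param counts Orientation counts as returned by [orientation_counts()],
#'   or any named vector containing `N++`, `N+-`, `N-+`, `N--`.
#' @return The estimated inter-ligation fraction in `[0, 1]`.
#' @export
#' @examples
#' estimate_inter_fraction(c(`N++` = 10, `N+-` = 12, `N-+` = 100, `N--` = 8))
estimate_inter_fraction <- function(counts) {
  need <- c("N++", "N+-", "N-+", "N--")
  stopifnot(all(need %in% names(counts)))
  n_mp <- as.numeric(counts[["N-+"]])
  if (n_mp == 0) stop("no -+ pairs")
  min(1, mean(as.numeric(counts[c("N++", "N+-", "N--")])) / n_mp)
}

#' Posterior probability that a -+ read pair is self-ligation
#'
#' Treats the -+ distance distribution as a two-component mixture of the
#' (unobservable) self-ligation distance distribution and the
#' inter-ligation distance distribution estimated from non--+ pairs. The
#' self component is recovered by subtraction, clipped at zero, and the
#' posterior is clipped to `[0, 1]` to absorb finite-sample density error.
#'
#' @param d Distances (bp) at which to evaluate.
#' @param p_d Mixture density of all -+ distances: a [kde_1d()] object or
#'   a function of distance.
#' @param p_d_inter Inter-ligation distance density (from non--+ pairs).
#' @param inter_fraction `Pr(z = inter)` in `[0, 1]`.
#' @return Posterior probabilities `Pr(z = self | d)`, zero where the
#'   mixture density vanishes.
#' @export
self_posterior <- function(d, p_d, p_d_inter, inter_fraction) {
  stopifnot(inter_fraction >= 0, inter_fraction <= 1)
  f <- if (inherits(p_d, "kde1d")) p_d$density else p_d
  g <- if (inherits(p_d_inter, "kde1d")) p_d_inter$density else p_d_inter
  pd <- f(d)
  if (inter_fraction == 1) return(rep(0, length(d)))
  pdi <- g(d)
  p_self <- 1 - inter_fraction
  pd_self <- pmax(0, (pd - inter_fraction * pdi) / p_self)
  post <- ifelse(pd > 0, pmin(1, pd_self * p_self / pd), 0)
  post
}

#' Fit the self-/inter-ligation distance mixture
#'
#' Splits the read pairs by orientation, selects bandwidths for the -+
#' and non--+ distance densities by least-squares cross-validation (unless
#' given), estimates the inter-ligation fraction from orientation counts,
#' and assigns each intra-chromosomal -+ pair a posterior self-ligation
#' weight. Pairs beyond `max_self_distance` are assigned weight 0 without
#' entering the -+ density estimate, since self-ligation spans are bounded
#' by the sonication fragment length.
#'
#' @param pairs A `chia_pairs` tibble.
#' @param max_self_distance Distance cap in bp for the -+ mixture model
#'   (default 50000).
#' @param h_mp,h_other Optional fixed bandwidths for the -+ and non--+
#'   distance densities; selected by [lscv_bandwidth_1d()] when `NULL`.
#' @param candidates Bandwidth candidate grid.
#' @return An object of class `self_ligation_fit` with the weighted -+
#'   pair table, both distance densities, the inter fraction and the
#'   effective counts `N_self` and `N_inter`.
#' @export
classify_self_ligation <- function(pairs, max_self_distance = 5e4,
                                   h_mp = NULL, h_other = NULL,
                                   candidates = lscv_grid()) {
  counts <- orientation_counts(pairs)
  parts <- split_by_orientation(pairs)
  mp <- pair_distance(parts$minus_plus)
  if (nrow(mp) == 0) stop("no self-ligation signal: no -+ pairs")
  other <- pair_distance(parts$other)
  inter_fraction <- estimate_inter_fraction(counts)

  in_cap <- mp$distance <= max_self_distance
  d_mp <- mp$distance[in_cap]
  if (length(d_mp) < 2) stop("fewer than 2 -+ pairs within the distance cap")
  if (is.null(h_mp)) {
    h_mp <- lscv_bandwidth_1d(d_mp, candidates = candidates)$bandwidth
  }
  p_d <- kde_1d(d_mp, bandwidth = h_mp)

  d_other <- other$distance[!is.na(other$distance)]
  if (length(d_other) >= 2) {
    if (is.null(h_other)) {
      h_other <- lscv_bandwidth_1d(d_other, candidates = candidates)$bandwidth
    }
    p_d_inter <- kde_1d(d_other, bandwidth = h_other)
  } else {
    # no usable inter distances: flat density over the cap
    h_other <- NA_real_
    p_d_inter <- structure(
      list(density = function(q) rep(1 / max_self_distance, length(q)),
           bandwidth = NA_real_),
      class = "kde1d"
    )
  }

  w <- numeric(nrow(mp))
  w[in_cap] <- self_posterior(mp$distance[in_cap], p_d, p_d_inter,
                              inter_fraction)
  mp$weight <- w
  n_self <- sum(w)
  structure(
    list(
      minus_plus = mp,
      other = other,
      inter_fraction = inter_fraction,
      p_d = p_d,
      p_d_inter = p_d_inter,
      bandwidths = c(h_mp = h_mp, h_other = h_other),
      max_self_distance = max_self_distance,
      counts = counts,
      N_self = n_self,
      N_inter = as.numeric(counts[["N"]]) - n_self
    ),
    class = "self_ligation_fit"
  )
}

#' @export
print.self_ligation_fit <- function(x, ...) {
  cat("<self_ligation_fit> Pr(z=inter) =", signif(x$inter_fraction, 4),
      "; N_self =", round(x$N_self, 1), "; N_inter =", round(x$N_inter, 1),
      "\n")
  invisible(x)
}

#' @describeIn classify_self_ligation Per--+-pair posterior weights.
#' @param x A `self_ligation_fit`.
#' @param ... Unused.
#' @export
tidy.self_ligation_fit <- function(x, ...) {
  tibble::as_tibble(x$minus_plus)
}

#' @describeIn classify_self_ligation One-row model summary.
#' @export
glance.self_ligation_fit <- function(x, ...) {
  tibble::tibble(
    n_pairs = as.integer(x$counts[["N"]]),
    n_minus_plus = as.integer(x$counts[["N-+"]]),
    inter_fraction = x$inter_fraction,
    n_self = x$N_self,
    n_inter = x$N_inter,
    h_minus_plus = unname(x$bandwidths["h_mp"]),
    h_other = unname(x$bandwidths["h_other"])
  )
}
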
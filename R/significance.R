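#' Probability that one binomial exceeds another
#'
#' Computes `Pr(Y > Z)` for independent `Y ~ Binomial(n1, p1)` and
#' `Z ~ Binomial(n2, p2)`. The result is exact (a sum over the smaller
#' support using binomial tail probabilities) up to `exact_limit` trials;
#' beyond that a normal approximation with continuity correction is used.
#' The value is nondecreasing in `p1` and nonincreasing in `p2`.
#'
#' @param n1,p1 Trials and success probability of `Y` (the null draw).
#' @param n2,p2 Trials and success probability of `Z` (the estimate draw).
#' @param exact_limit Largest trial count handled exactly (default 10000).
#' @return `Pr(Y > Z)` in `[0, 1]`.
#' @export
#' @examples
#' pr_y_gt_z(1, 0.5, 1, 0.5) # 0.25
pr_y_gt_z <- function(n1, p1, n2, p2, exact_limit = 10000) {
  stopifnot(n1 >= 0, n2 >= 0)
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  n1 <- round(n1); n2 <- round(n2)
  if (n1 == 0 || p1 == 0) return(0)
  if (max(n1, n2) <= exact_limit) {
    z <- 0:n2
    return(sum(dbinom(z, n2, p2) * pbinom(z, n1, p1, lower.tail = FALSE)))
  }
  mu <- n1 * p1 - n2 * p2
  sig <- sqrt(n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2))
  if (sig == 0) return(as.numeric(mu >= 1))
  pnorm((0.5 - mu) / sig, lower.tail = FALSE)
}

#' Significance of marginal occupancy in a region
#'
#' Tests whether the estimated occupancy mass `p` in a region of width `w`
#' exceeds what a uniform distribution over the mappable genome would
#' place there: `Pr(Y > Z)` with `Y ~ Binomial(N_self, w/M)` and
#' `Z ~ Binomial(N_self, p)`. Small values indicate enrichment.
#'
#' @param p Occupancy mass in the region (sum of `Pr(q = u)` over bins).
#' @param width Region width in bp.
#' @param n_self Effective self-ligation pair count.
#' @param genome A [genome_model()].
#' @return The p-value `Pr(Y > Z)`.
#' @export
marginal_region_pvalue <- function(p, width, n_self, genome) {
  stopifnot(n_self > 0, width > 0)
  if (width >= genome$mappable_size) {
    stop("region width must be smaller than the mappable genome")
  }
  pr_y_gt_z(round(n_self), width / genome$mappable_size, round(n_self), p)
}

#' Significance of joint occupancy of a region pair
#'
#' Tests the joint mass of two regions against the product of their
#' marginal occupancy masses: `Pr(Y > Z)` with
#' `Y ~ Binomial(N_inter, p_a * p_b)` and `Z ~ Binomial(N_inter, p_joint)`.
#'
#' @param p_joint Joint occupancy mass over the region pair.
#' @param p_a,p_b Marginal occupancy masses of the two regions.
#' @param n_inter Effective inter-ligation pair count.
#' @return The p-value `Pr(Y > Z)`.
#' @export
joint_region_pvalue <- function(p_joint, p_a, p_b, n_inter) {
  pr_y_gt_z(round(n_inter), p_a * p_b, round(n_inter), p_joint)
}

#' Reads-per-kilobase-per-million normalization
#'
#' @param reads Read count in the region.
#' @param width Region width in bp.
#' @param total_reads Total reads in the dataset.
#' @return The RPKM value.
#' @export
rpkm <- function(reads, width, total_reads) {
  if (width <= 0) stop("region width must be positive")
  stopifnot(total_reads > 0)
  reads / ((width / 1000) * (total_reads / 1e6))
}

#' Binomial enrichment p-value for a read count in a region
#'
#' The observed proportion of dataset reads in the region is compared
#' against the uniform mappable-genome background via `Pr(Y > Z)`.
#'
#' @inheritParams rpkm
#' @param genome A [genome_model()].
#' @return The p-value `Pr(Y > Z)`.
#' @export
enrichment_pvalue <- function(reads, width, total_reads, genome) {
  pr_y_gt_z(round(total_reads), width / genome$mappable_size,
            round(total_reads), reads / total_reads)
}

#' Candidate jointly occupied regions at an anchor
#'
#' Extracts maximal runs of consecutive profile bins whose conditional
#' joint mass exceeds the threshold `f`, each annotated with its joint
#' mass, marginal occupancy mass and supporting inter-pair count.
#'
#' @param field A [conditional_field()].
#' @param anchor_id Anchor index within the field.
#' @param f Density threshold (> 0) on the per-bin normalized joint mass.
#' @return A tibble of regions: `chrom`, `start`, `end`, `width`, `mass`,
#'   `occ_mass`, `support`.
#' @export
candidate_regions <- function(field, anchor_id, f = 1e-15) {
  stopifnot(f > 0)
  prof <- field$profiles[[anchor_id]]
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), width = numeric(0),
                          mass = numeric(0), occ_mass = numeric(0),
                          support = integer(0))
  if (nrow(prof) == 0) return(empty)
  keep <- prof$mass > f
  if (!any(keep)) return(empty)
  prof <- prof[keep, ]
  bin <- field$bin_size
  run_break <- c(TRUE, diff(prof$start) != bin |
                   prof$chrom[-1] != prof$chrom[-nrow(prof)])
  run_id <- cumsum(run_break)
  sup <- field$support[[anchor_id]]
  regions <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(prof, run = run_id), .data$run),
    chrom = dplyr::first(.data$chrom),
    end = max(.data$start) + bin,
    start = min(.data$start),
    mass = sum(.data$mass),
    occ_mass = sum(.data$occ_mass),
    .groups = "drop"
  )
  regions$width <- regions$end - regions$start
  regions$support <- purrr::map_int(seq_len(nrow(regions)), function(i) {
    hits <- sup$chrom == regions$chrom[i] &
      sup$u_lo < regions$end[i] & sup$u_hi > regions$start[i]
    length(unique(sup$pair_id[hits]))
  })
  dplyr::select(regions, "chrom", "start", "end", "width", "mass",
                "occ_mass", "support")
}

#' Missing-mass correction by fixed-point iteration
#'
#' The conditional joint field is undersampled: true joint mass is missing
#' wherever too few inter-ligation pairs were sequenced. A per-anchor
#' correction `tau_i` is chosen so that the corrected masses are
#' proportional to the anchor marginal occupancies:
#' `(t_i + tau_i) / sum_j (t_j + tau_j) = m_i / sum_j m_j`. The anchor
#' with the greatest raw mass is pinned at `tau = (c - 1) * t_max` for a
#' chosen scale `c > 1`, and the remaining `tau_i` are updated cyclically
#' (floored at zero) until convergence.
#'
#' @param t Per-anchor raw joint masses `t_i` (>= 0).
#' @param m Per-anchor marginal occupancies `m_i` (>= 0; positive wherever
#'   `t_i > 0`).
#' @param c Missing-mass scale, `c > 1`.
#' @param tol Convergence tolerance on the largest `tau` change
#'   (default 1e-12 relative to the total mass).
#' @param max_sweeps Maximum update sweeps (default 10000).
#' @return An object of class `tau_state`: tibble with `t`, `m`, `tau`,
#'   plus attributes `i_max` and `c`.
#' @export
solve_tau <- function(t, m, c, tol = 1e-12, max_sweeps = 10000) {
  stopifnot(length(t) == length(m), all(t >= 0), all(m >= 0), c > 1)
  if (any(t > 0 & m == 0)) {
    stop("anchors with joint mass must have positive marginal occupancy")
  }
  n <- length(t)
  i_max <- which.max(t) # ties resolved to the lowest index
  tau <- numeric(n)
  tau[i_max] <- (c - 1) * t[i_max]
  active <- setdiff(which(m > 0 | t > 0), i_max)
  scale <- sum(t) + tau[i_max]
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (i in active) {
      s_t <- sum(t[-i] + tau[-i])
      s_m <- sum(m[-i])
      if (s_m <= 0) next
      new_tau <- max(0, m[i] * s_t / s_m - t[i])
      delta <- max(delta, abs(new_tau - tau[i]))
      tau[i] <- new_tau
    }
    if (delta <= tol * max(scale, 1e-300)) {
      out <- tibble::tibble(t = t, m = m, tau = tau)
      return(structure(out, i_max = i_max, c = c, sweeps = sweep,
                       class = c("tau_state", class(out))))
    }
  }
  resid <- tau_residual(t, m, tau)
  stop("tau fixed point did not converge after ", max_sweeps,
       " sweeps (max constraint residual ", signif(resid, 3), ")")
}

# largest violation of the proportionality constraint on unfloored taus
tau_residual <- function(t, m, tau) {
  tot <- sum(t + tau)
  mm <- sum(m)
  unfloored <- tau > 0
  if (!any(unfloored) || tot <= 0 || mm <= 0) return(0)
  max(abs((t + tau)[unfloored] / tot - m[unfloored] / mm))
}

#' Undersampling-corrected joint significance of a region at an anchor
#'
#' Deflates the region's joint mass by the corrected anchor total
#' `t_i + tau_i` and tests it against the region's marginal occupancy
#' mass: `Pr(Y > Z)` with `Y ~ Binomial(N_inter, p')`,
#' `Z ~ Binomial(N_inter, p)` where `p = mass / (t_i + tau_i)` and `p'`
#' is the occupancy mass of the region.
#'
#' @param mass Joint mass of the region (on the field's normalized scale).
#' @param occ_mass Marginal occupancy mass of the region.
#' @param t,tau The anchor's raw mass and missing-mass correction.
#' @param n_inter Effective inter-ligation pair count.
#' @return The p-value `Pr(Y > Z)`; 1 when `t + tau = 0`.
#' @export
corrected_joint_pvalue <- function(mass, occ_mass, t, tau, n_inter) {
  tot <- t + tau
  if (tot <= 0) return(1)
  p <- min(1, mass / tot)
  pr_y_gt_z(round(n_inter), occ_mass, round(n_inter), p)
}

#' Most likely jointly occupied location within a region
#'
#' Returns the midpoint of the profile bin with maximal conditional joint
#' mass inside the region; ties are broken toward the leftmost bin.
#'
#' @param field A [conditional_field()].
#' @param anchor_id Anchor index.
#' @param chrom,start,end Region coordinates.
#' @return `eloc` in bp.
#' @export
estimate_eloc <- function(field, anchor_id, chrom, start, end) {
  prof <- field$profiles[[anchor_id]]
  inreg <- prof$chrom == chrom & prof$start >= start & prof$start < end
  if (!any(inreg) || sum(prof$mass[inreg]) <= 0) {
    stop("region has no joint mass")
  }
  p <- prof[inreg, ]
  p$start[which.max(p$mass)] + field$bin_size / 2
}

score_regions <- function(field, tau_state, f, n_inter) {
  regions <- purrr::map(seq_len(nrow(field$anchors)), function(ai) {
    regs <- candidate_regions(field, ai, f = f)
    if (nrow(regs) == 0) return(NULL)
    regs$anchor_id <- ai
    regs
  })
  regions <- dplyr::bind_rows(regions)
  if (nrow(regions) == 0) return(regions)
  t_all <- tau_state$t
  tau_all <- tau_state$tau
  regions$p_value <- purrr::map_dbl(seq_len(nrow(regions)), function(i) {
    ai <- regions$anchor_id[i]
    corrected_joint_pvalue(regions$mass[i], regions$occ_mass[i],
                           t_all[ai], tau_all[ai], n_inter)
  })
  regions
}

#' Calibrate the missing-mass scale and call interactions
#'
#' Searches for the scale `c` at which the fraction of significant regions
#' supported by a single inter-ligation pair falls into the target band
#' `[target - band, target]`. Larger `c` inflates every `tau_i`, deflates
#' region masses and makes all calls less significant; the fraction of
#' weakly supported calls therefore shrinks as `c` grows. The search
#' brackets multiplicatively and then bisects on `log(c)`.
#'
#' @param field A [conditional_field()].
#' @param f Candidate-region density threshold.
#' @param p_cutoff Significance cutoff (default 0.05).
#' @param target Target single-pair fraction among significant regions
#'   (default 0.1).
#' @param band Acceptable shortfall below the target (default 0.05).
#' @param c_range Search range for `c` (default `c(1.01, 1e4)`).
#' @param max_iter Bisection iterations (default 30).
#' @return A list: `c`, `tau` (the converged `tau_state`), `calls`
#'   (scored region tibble with `eloc`), `single_pair_fraction`,
#'   `n_significant`.
#' @export
calibrate_c <- function(field, f = 1e-15, p_cutoff = 0.05, target = 0.1,
                        band = 0.05, c_range = c(1.01, 1e4),
                        max_iter = 30) {
  t <- field$anchors$t
  m <- field$anchors$m
  n_inter <- field$n_inter
  if (all(t == 0)) stop("field has no joint mass at any anchor")
  lo_band <- max(0, target - band)
  evaluate <- function(cc) {
    tau <- solve_tau(t, m, cc)
    regs <- score_regions(field, tau, f, n_inter)
    if (nrow(regs) == 0) {
      return(list(tau = tau, regions = regs, n_sig = 0L, frac = 0))
    }
    sig <- regs$p_value < p_cutoff
    n_sig <- sum(sig)
    frac <- if (n_sig == 0) 0 else sum(sig & regs$support == 1) / n_sig
    list(tau = tau, regions = regs, n_sig = n_sig, frac = frac)
  }
  finish <- function(cc, ev) {
    calls <- ev$regions
    if (nrow(calls) > 0) {
      calls$significant <- calls$p_value < p_cutoff
      calls$eloc <- purrr::map_dbl(seq_len(nrow(calls)), function(i) {
        estimate_eloc(field, calls$anchor_id[i], calls$chrom[i],
                      calls$start[i], calls$end[i])
      })
      calls$t <- field$anchors$t[calls$anchor_id]
      calls$tau <- ev$tau$tau[calls$anchor_id]
      calls <- dplyr::left_join(
        calls,
        dplyr::select(field$anchors, "anchor_id",
                      anchor_chrom = "chrom", anchor_pos = "pos",
                      anchor_name = "name"),
        by = "anchor_id"
      )
    }
    list(c = cc, tau = ev$tau, calls = calls,
         single_pair_fraction = ev$frac, n_significant = ev$n_sig)
  }

  e_lo <- evaluate(c_range[1])
  if (e_lo$n_sig == 0) {
    warning("no significant regions at any c in the search range",
            call. = FALSE)
    return(finish(c_range[1], e_lo))
  }
  if (e_lo$frac <= target) {
    # already at or below target at the smallest c; cannot reduce further
    return(finish(c_range[1], e_lo))
  }
  # bracket: find hi with frac <= target
  hi <- max(2, 2 * c_range[1])
  e_hi <- evaluate(hi)
  while (e_hi$frac > target && hi < c_range[2]) {
    hi <- min(c_range[2], hi * 2)
    e_hi <- evaluate(hi)
  }
  if (e_hi$frac > target) {
    warning("single-pair fraction above target over the whole search range",
            call. = FALSE)
    return(finish(hi, e_hi))
  }
  lo <- c_range[1]
  for (it in seq_len(max_iter)) {
    if (e_hi$frac >= lo_band) return(finish(hi, e_hi))
    mid <- exp((log(lo) + log(hi)) / 2)
    e_mid <- evaluate(mid)
    if (e_mid$frac >= lo_band && e_mid$frac <= target) {
      return(finish(mid, e_mid))
    }
    if (e_mid$frac > target) {
      lo <- mid
    } else {
      hi <- mid
      e_hi <- e_mid
    }
    if (hi / lo < 1 + 1e-6) break
  }
  finish(hi, e_hi)
}

#' Call significant anchor-distal interactions
#'
#' End-to-end caller: calibrates the missing-mass scale on the conditional
#' field, scores every candidate region with the corrected binomial test
#' and returns the significant calls with their `eloc` point estimates.
#'
#' @inheritParams calibrate_c
#' @param significant_only Keep only calls with `p_value < p_cutoff`
#'   (default `TRUE`).
#' @param bh_adjust Also report Benjamini-Hochberg adjusted p-values
#'   (default `FALSE`; the raw cutoff is the primary criterion).
#' @return A tibble of interaction calls with attributes `c`, `tau` and
#'   `single_pair_fraction`; class `interaction_calls`.
#' @export
call_interactions <- function(field, f = 1e-15, p_cutoff = 0.05,
                              target = 0.1, band = 0.05,
                              significant_only = TRUE, bh_adjust = FALSE) {
  if (all(field$anchors$t == 0)) {
    warning("field has no joint mass at any anchor; no calls",
            call. = FALSE)
    empty <- tibble::tibble(
      anchor_id = integer(0), anchor_name = character(0),
      anchor_chrom = character(0), anchor_pos = numeric(0),
      chrom = character(0), start = numeric(0), end = numeric(0),
      width = numeric(0), eloc = numeric(0), mass = numeric(0),
      occ_mass = numeric(0), support = integer(0), p_value = numeric(0),
      t = numeric(0), tau = numeric(0)
    )
    return(structure(empty, c = NA_real_, tau = NULL,
                     single_pair_fraction = NA_real_, n_significant = 0L,
                     class = c("interaction_calls",
                               class(tibble::tibble()))))
  }
  fit <- calibrate_c(field, f = f, p_cutoff = p_cutoff, target = target,
                     band = band)
  calls <- fit$calls
  if (nrow(calls) > 0) {
    if (bh_adjust) calls$p_adjusted <- stats::p.adjust(calls$p_value, "BH")
    if (significant_only) calls <- calls[calls$significant, ]
    calls <- dplyr::arrange(calls, .data$p_value)
    calls <- dplyr::select(
      calls, "anchor_id", "anchor_name", "anchor_chrom", "anchor_pos",
      "chrom", "start", "end", "width", "eloc", "mass", "occ_mass",
      "support", "p_value", dplyr::any_of("p_adjusted"), "t", "tau"
    )
  }
  structure(calls, c = fit$c, tau = fit$tau,
            single_pair_fraction = fit$single_pair_fraction,
            n_significant = fit$n_significant,
            class = c("interaction_calls", class(tibble::tibble())))
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat("<interaction_calls> ", nrow(x), " calls (c = ",
      signif(attr(x, "c"), 4), ", single-pair fraction ",
      signif(attr(x, "single_pair_fraction"), 3), ")\n", sep = "")
  NextMethod()
}

#' @describeIn call_interactions One-row calibration summary.
#' @param x An `interaction_calls` tibble.
#' @param ... Unused.
#' @export
glance.interaction_calls <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x),
    n_significant = attr(x, "n_significant"),
    c = attr(x, "c"),
    single_pair_fraction = attr(x, "single_pair_fraction")
  )
}
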
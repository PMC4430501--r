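#' Single-end read likelihood under the marginalized read spread function
#'
#' Evaluates the strand-appropriate 1D spread at the offset between a read
#' end and a hypothesized occupied location: minus-strand ends use the
#' marginal over the lower-coordinate offset, plus-strand ends the
#' marginal over the higher-coordinate offset. Offsets outside the RSF
#' support return exactly zero.
#'
#' @param read_pos Read end position(s) in bp.
#' @param strand Read end strand, `"+"` or `"-"` (scalar or vector).
#' @param u Hypothesized occupied location(s) in bp.
#' @param marginals An [marginalize_rsf()] object.
#' @return Likelihood values (per-grid-cell mass).
#' @export
end_likelihood <- function(read_pos, strand, u, marginals) {
  stopifnot(all(strand %in% c("+", "-")))
  K <- length(marginals$offsets)
  Wb <- (K - 1) / 2
  idx <- round((read_pos - u) / marginals$step) + Wb + 1
  ok <- idx >= 1 & idx <= K
  out <- numeric(length(idx))
  if (length(strand) == 1) strand <- rep(strand, length(idx))
  m <- ifelse(strand == "-", TRUE, FALSE)
  out[ok & m] <- marginals$minus[idx[ok & m]]
  out[ok & !m] <- marginals$plus[idx[ok & !m]]
  out
}

# Row index of the track bin containing bp position `pos` on `chrom`;
# NA outside the track. Track must be the dense genome track in genome
# chromosome order.
track_index <- function(track, chrom, pos) {
  bin <- attr(track, "bin_size")
  genome <- attr(track, "genome")
  n_bins <- floor(genome$chromosomes$length / bin)
  offsets <- c(0, cumsum(n_bins))[match(chrom, genome$chromosomes$chrom)]
  i <- floor(pos / bin)
  ok <- !is.na(offsets) & i >= 0 &
    i < n_bins[match(chrom, genome$chromosomes$chrom)]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- as.integer(offsets[ok] + i[ok] + 1)
  out
}

# Sum over track bins of end likelihood times occupancy, for one end.
# The range extends one bin beyond pos +/- W on each side because the
# offset rounding in end_likelihood can still land boundary bin centers
# inside the RSF support.
end_occ_mass <- function(track, chrom, pos, strand, marginals) {
  bin <- attr(track, "bin_size")
  W <- marginals$half_width
  lo <- floor((pos - W) / bin) - 1
  hi <- floor((pos + W) / bin) + 1
  bins <- seq(lo, hi)
  centers <- bins * bin + bin / 2
  rows <- track_index(track, rep(chrom, length(bins)), centers)
  keep <- !is.na(rows)
  if (!any(keep)) return(0)
  g <- end_likelihood(pos, strand, centers[keep], marginals)
  sum(g * track$mass[rows[keep]])
}

#' Conditional joint occupancy field at a set of anchors
#'
#' Estimates, for every anchor location `v_i`, the 1D profile of joint
#' occupancy mass `Pr(q = <u, v_i> | R_inter)` over genome bins `u`,
#' by summing over inter-ligation read pairs the product of the
#' strand-appropriate single-end spread at each end and the marginal
#' occupancy at both locations. A read pair contributes to an anchor
#' whenever the spread of one of its ends is nonzero at the anchor; the
#' other end then spreads the profile over nearby bins. Profiles are
#' normalized by the total joint mass of all pairs over the genome, so
#' anchor masses `t_i` and the non-anchor remainder share one scale.
#'
#' @param inter_pairs Tibble of inter-ligation pairs (`chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`).
#' @param occupancy An `occupancy_track` from [occupancy_genome()].
#' @param marginals An [marginalize_rsf()] object.
#' @param anchors Tibble with `chrom`, `pos` and optionally `name`
#'   (e.g. transcription start sites); duplicates are removed.
#' @param n_inter Effective inter-ligation pair count for downstream
#'   binomial tests (default `nrow(inter_pairs)`).
#' @return An object of class `conditional_field`: anchor summary tibble
#'   (`anchor_id`, `chrom`, `pos`, `name`, `t`, `m`, `n_pairs`,
#'   `flagged`), per-anchor `profiles`, a pair `support` index, the
#'   normalizer and `n_inter`.
#' @export
conditional_field <- function(inter_pairs, occupancy, marginals, anchors,
                              n_inter = nrow(inter_pairs)) {
  if (nrow(anchors) == 0) stop("empty anchor set")
  anchors <- tibble::as_tibble(anchors)
  if (!"name" %in% names(anchors)) {
    anchors$name <- paste0("anchor_", seq_len(nrow(anchors)))
  }
  anchors <- dplyr::distinct(anchors, .data$chrom, .data$pos,
                             .keep_all = TRUE)
  anchors <- dplyr::arrange(anchors, match(.data$chrom,
                                           unique(anchors$chrom)), .data$pos)
  anchors$anchor_id <- seq_len(nrow(anchors))
  bin <- attr(occupancy, "bin_size")
  W <- marginals$half_width

  # long table of ends: each pair contributes two ends
  ends <- dplyr::bind_rows(
    tibble::tibble(pair_id = seq_len(nrow(inter_pairs)),
                   chrom = inter_pairs$chrom1, pos = inter_pairs$pos1,
                   strand = inter_pairs$strand1, mate = 1L),
    tibble::tibble(pair_id = seq_len(nrow(inter_pairs)),
                   chrom = inter_pairs$chrom2, pos = inter_pairs$pos2,
                   strand = inter_pairs$strand2, mate = 2L)
  )

  # normalizer: joint mass factorizes per pair into the two end sums
  end_mass <- purrr::map_dbl(seq_len(nrow(ends)), function(k) {
    end_occ_mass(occupancy, ends$chrom[k], ends$pos[k], ends$strand[k],
                 marginals)
  })
  a1 <- end_mass[ends$mate == 1L]
  a2 <- end_mass[ends$mate == 2L]
  norm <- sum(a1 * a2)
  if (norm <= 0) {
    warning("no inter-ligation pair overlaps occupied locations; ",
            "empty field", call. = FALSE)
  }

  arow <- track_index(occupancy, anchors$chrom, anchors$pos + 0)
  anchors$m <- ifelse(is.na(arow), 0, occupancy$mass[arow])

  profiles <- vector("list", nrow(anchors))
  support <- vector("list", nrow(anchors))
  t_i <- numeric(nrow(anchors))
  n_pairs_i <- integer(nrow(anchors))
  for (ai in seq_len(nrow(anchors))) {
    v <- anchors$pos[ai]
    vchrom <- anchors$chrom[ai]
    hit <- which(ends$chrom == vchrom &
                   abs(ends$pos - v) <= W + marginals$step)
    if (length(hit) > 0) {
      g_anchor <- end_likelihood(ends$pos[hit], ends$strand[hit], v,
                                 marginals)
      hit <- hit[g_anchor > 0]
      g_anchor <- g_anchor[g_anchor > 0]
    }
    if (length(hit) == 0) {
      profiles[[ai]] <- tibble::tibble(chrom = character(0),
                                       start = numeric(0),
                                       mass = numeric(0),
                                       occ_mass = numeric(0))
      support[[ai]] <- tibble::tibble(pair_id = integer(0),
                                      chrom = character(0),
                                      u_lo = numeric(0), u_hi = numeric(0))
      next
    }
    # the other end of each hit pair spreads the u-profile
    other_mate <- ifelse(ends$mate[hit] == 1L, 2L, 1L)
    other_idx <- ends$pair_id[hit] + (other_mate - 1L) * nrow(inter_pairs)
    acc <- list()
    sup <- list()
    for (k in seq_along(hit)) {
      oe <- ends[other_idx[k], ]
      # one extra bin each side, matching end_occ_mass's range
      lo <- floor((oe$pos - W) / bin) - 1
      hi <- floor((oe$pos + W) / bin) + 1
      bins <- seq(lo, hi)
      centers <- bins * bin + bin / 2
      rows <- track_index(occupancy, rep(oe$chrom, length(bins)), centers)
      keep <- !is.na(rows)
      if (!any(keep)) next
      g <- end_likelihood(oe$pos, oe$strand, centers[keep], marginals)
      contrib <- g * occupancy$mass[rows[keep]] *
        g_anchor[k] * anchors$m[ai]
      acc[[length(acc) + 1]] <- tibble::tibble(
        chrom = oe$chrom, start = bins[keep] * bin, mass = contrib
      )
      sup[[length(sup) + 1]] <- tibble::tibble(
        pair_id = oe$pair_id, chrom = oe$chrom,
        u_lo = lo * bin, u_hi = (hi + 1) * bin
      )
    }
    if (length(acc) == 0) {
      profiles[[ai]] <- tibble::tibble(chrom = character(0),
                                       start = numeric(0),
                                       mass = numeric(0),
                                       occ_mass = numeric(0))
      support[[ai]] <- tibble::tibble(pair_id = integer(0),
                                      chrom = character(0),
                                      u_lo = numeric(0), u_hi = numeric(0))
      next
    }
    prof <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(acc), .data$chrom, .data$start),
      mass = sum(.data$mass), .groups = "drop"
    )
    prof <- dplyr::arrange(prof, .data$chrom, .data$start)
    if (norm > 0) prof$mass <- prof$mass / norm
    rows <- track_index(occupancy, prof$chrom, prof$start + bin / 2)
    prof$occ_mass <- ifelse(is.na(rows), 0, occupancy$mass[rows])
    profiles[[ai]] <- prof
    support[[ai]] <- dplyr::bind_rows(sup)
    t_i[ai] <- sum(prof$mass)
    n_pairs_i[ai] <- length(unique(support[[ai]]$pair_id))
  }
  anchors$t <- t_i
  anchors$n_pairs <- n_pairs_i
  anchors$flagged <- anchors$m == 0 & anchors$n_pairs > 0
  if (all(t_i == 0)) {
    warning("no read pair within RSF support of any anchor; empty field",
            call. = FALSE)
  }
  structure(
    list(
      anchors = anchors,
      profiles = profiles,
      support = support,
      norm = norm,
      n_inter = n_inter,
      bin_size = bin,
      marginals = marginals
    ),
    class = "conditional_field"
  )
}

#' @export
print.conditional_field <- function(x, ...) {
  cat("<conditional_field> ", nrow(x$anchors), " anchors, total mass t = ",
      signif(sum(x$anchors$t), 4), ", N_inter = ", round(x$n_inter),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn conditional_field Anchor-level summary tibble.
#' @param x A `conditional_field`.
#' @param ... Unused.
#' @export
tidy.conditional_field <- function(x, ...) {
  dplyr::select(x$anchors, "anchor_id", "chrom", "pos", "name", "t", "m",
                "n_pairs", "flagged")
}

#' Windowed 2D joint occupancy density
#'
#' Direct evaluation of the joint occupancy estimate on a rectangular
#' window `(u, v)`; intended for diagnostics and cross-checks rather than
#' genome-scale use. Uses the same global normalization as
#' [conditional_field()]. The lower-coordinate end of each ordered pair is
#' associated with `u`, the higher-coordinate end with `v` (for
#' inter-chromosomal pairs, the end on the earlier chromosome in genome
#' order is the lower one).
#'
#' @inheritParams conditional_field
#' @param chrom_u,start_u,end_u Window for the `u` axis.
#' @param chrom_v,start_v,end_v Window for the `v` axis.
#' @return A tibble with columns `u`, `v` (bin starts) and `mass`.
#' @export
joint_density <- function(inter_pairs, occupancy, marginals,
                          chrom_u, start_u, end_u,
                          chrom_v, start_v, end_v) {
  if (nrow(inter_pairs) == 0) stop("no inter-ligation pairs")
  bin <- attr(occupancy, "bin_size")
  W <- marginals$half_width
  u_bins <- seq(floor(start_u / bin), ceiling(end_u / bin) - 1)
  v_bins <- seq(floor(start_v / bin), ceiling(end_v / bin) - 1)
  u_cent <- u_bins * bin + bin / 2
  v_cent <- v_bins * bin + bin / 2
  u_rows <- track_index(occupancy, rep(chrom_u, length(u_bins)), u_cent)
  v_rows <- track_index(occupancy, rep(chrom_v, length(v_bins)), v_cent)
  occ_u <- ifelse(is.na(u_rows), 0, occupancy$mass[u_rows])
  occ_v <- ifelse(is.na(v_rows), 0, occupancy$mass[v_rows])
  mat <- matrix(0, length(u_bins), length(v_bins))
  norm <- 0
  for (k in seq_len(nrow(inter_pairs))) {
    p <- inter_pairs[k, ]
    a_full <- end_occ_mass(occupancy, p$chrom1, p$pos1, p$strand1, marginals)
    b_full <- end_occ_mass(occupancy, p$chrom2, p$pos2, p$strand2, marginals)
    norm <- norm + a_full * b_full
    if (p$chrom1 == chrom_u && p$chrom2 == chrom_v) {
      g_u <- end_likelihood(p$pos1, p$strand1, u_cent, marginals) * occ_u
      g_v <- end_likelihood(p$pos2, p$strand2, v_cent, marginals) * occ_v
      if (any(g_u > 0) && any(g_v > 0)) mat <- mat + outer(g_u, g_v)
    }
  }
  if (norm > 0) mat <- mat / norm
  tibble::tibble(
    u = rep(u_bins * bin, times = length(v_bins)),
    v = rep(v_bins * bin, each = length(u_bins)),
    mass = as.vector(mat)
  )
}
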
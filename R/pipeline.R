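#' Estimate genome-wide marginal occupancy from read pairs
#'
#' Runs the marginal half of the pipeline: classify -+ pairs with the
#' distance mixture, pick `h_self` (weighted least-squares CV unless
#' given), blind-deconvolve a training window to recover the read spread
#' function and its peak offset `lambda`, then extend the occupancy
#' genome-wide by the diagonal-slice shortcut. The training window is the
#' `window_size` stretch holding the most self-ligation weight.
#'
#' @param pairs A `chia_pairs` tibble.
#' @param window_size Training window size in bp (default 5e6, clipped to
#'   the chromosome).
#' @param rsf_half_width RSF support half-width in bp (default 500).
#' @param bin_size Occupancy track bin size in bp (default 10).
#' @param h_self Optional fixed 2D bandwidth; otherwise selected by
#'   [lscv_bandwidth_2d()].
#' @param max_self_distance Distance cap for the -+ mixture (bp).
#' @param occ_updates,rsf_updates,rounds Richardson-Lucy schedule.
#' @param ... Passed to [classify_self_ligation()].
#' @return A list of class `occupancy_fit`: `self_fit`, `deconv`,
#'   `lambda`, `rsf`, `marginals`, `track`, `h_self`.
#' @export
estimate_occupancy <- function(pairs, window_size = 5e6,
                               rsf_half_width = 500, bin_size = 10,
                               h_self = NULL, max_self_distance = 5e4,
                               occ_updates = 10, rsf_updates = 10,
                               rounds = 5, ...) {
  genome <- attr(pairs, "genome")
  fit <- classify_self_ligation(pairs, max_self_distance = max_self_distance,
                                ...)
  mp <- fit$minus_plus
  if (is.null(h_self)) {
    h_self <- lscv_bandwidth_2d(mp$pos1, mp$pos2, mp$weight)$bandwidth
  }
  win <- best_window(mp, genome, window_size)
  selfdist <- self_pair_density(mp, bandwidth = h_self,
                                chrom = win$chrom, start = win$start,
                                end = win$end, step = bin_size,
                                rsf_half_width = rsf_half_width)
  deconv <- blind_deconvolve(selfdist, occ_updates = occ_updates,
                             rsf_updates = rsf_updates, rounds = rounds)
  marginals <- marginalize_rsf(deconv$rsf)
  track <- occupancy_genome(mp, bandwidth = h_self, lambda = deconv$lambda,
                            genome = genome, bin_size = bin_size)
  structure(
    list(self_fit = fit, deconv = deconv, lambda = deconv$lambda,
         rsf = deconv$rsf, marginals = marginals, track = track,
         h_self = h_self, window = win),
    class = "occupancy_fit"
  )
}

# the window_size stretch (on one chromosome) with the most -+ weight
best_window <- function(mp, genome, window_size) {
  by_chrom <- split(mp, mp$chrom1)
  best <- NULL
  for (chrom in names(by_chrom)) {
    d <- by_chrom[[chrom]]
    len <- genome_length(genome, chrom)
    size <- min(window_size, len)
    starts <- seq(0, max(0, len - size), by = max(size / 2, 1))
    for (s in starts) {
      wsum <- sum(d$weight[d$pos1 >= s & d$pos2 <= s + size])
      if (is.null(best) || wsum > best$weight) {
        best <- list(chrom = chrom, start = s, end = s + size,
                     weight = wsum)
      }
    }
  }
  if (is.null(best) || best$weight <= 0) {
    stop("no self-ligation signal in any window")
  }
  best
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("<occupancy_fit> lambda =", x$lambda, "bp; h_self =",
      signif(x$h_self, 4), "bp\n")
  invisible(x)
}

#' @describeIn estimate_occupancy Occupancy track tibble.
#' @param x An `occupancy_fit`.
#' @param ... Unused.
#' @export
tidy.occupancy_fit <- function(x, ...) {
  tibble::as_tibble(x$track)
}

#' @describeIn estimate_occupancy One-row pipeline summary.
#' @export
glance.occupancy_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$self_fit),
    tibble::tibble(lambda = x$lambda, h_self = x$h_self,
                   window_chrom = x$window$chrom,
                   window_start = x$window$start,
                   window_end = x$window$end)
  )
}

#' Inter-ligation pairs implied by a self-ligation fit
#'
#' The inter-ligation set for joint-occupancy estimation: all non--+
#' pairs plus the intra-chromosomal -+ pairs whose posterior self-ligation
#' weight falls below `cutoff`.
#'
#' @param fit A [classify_self_ligation()] fit (or `occupancy_fit`).
#' @param cutoff Posterior cutoff (default 0.5).
#' @return A tibble of inter-ligation pairs.
#' @export
inter_pairs <- function(fit, cutoff = 0.5) {
  if (inherits(fit, "occupancy_fit")) fit <- fit$self_fit
  mp_inter <- fit$minus_plus[fit$minus_plus$weight < cutoff, ]
  dplyr::bind_rows(
    tibble::as_tibble(fit$other),
    tibble::as_tibble(mp_inter)
  )[, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")]
}

#' Full interaction-calling pipeline
#'
#' [estimate_occupancy()] followed by [conditional_field()] at the given
#' anchors and [call_interactions()].
#'
#' @inheritParams estimate_occupancy
#' @param anchors Anchor tibble (`chrom`, `pos`, optional `name`).
#' @param occupancy_fit Optional precomputed [estimate_occupancy()] result.
#' @param ... Passed to [estimate_occupancy()].
#' @inheritParams call_interactions
#' @return A list of class `interaction_fit`: `occupancy`, `field`,
#'   `calls`.
#' @export
detect_interactions <- function(pairs, anchors, occupancy_fit = NULL,
                                f = 1e-15, p_cutoff = 0.05, target = 0.1,
                                ...) {
  if (is.null(occupancy_fit)) occupancy_fit <- estimate_occupancy(pairs, ...)
  field <- conditional_field(
    inter_pairs(occupancy_fit), occupancy_fit$track,
    occupancy_fit$marginals, anchors,
    n_inter = round(occupancy_fit$self_fit$N_inter)
  )
  calls <- call_interactions(field, f = f, p_cutoff = p_cutoff,
                             target = target)
  structure(list(occupancy = occupancy_fit, field = field, calls = calls),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  print(x$occupancy)
  print(x$calls)
  invisible(x)
}

#' Read anchors from a BED file
#'
#' Uses the interval midpoint as the anchor point; for BED6 with strand,
#' the start (for `+`) or end (for `-`) can be chosen as the 5' anchor.
#'
#' @param path BED file path (3-6 columns).
#' @param five_prime Anchor at the 5' end instead of the midpoint
#'   (default `FALSE`).
#' @return Tibble with `chrom`, `pos`, `name`.
#' @export
read_anchors_bed <- function(path, five_prime = FALSE) {
  tab <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(tab) == 0) stop("empty anchor BED file: ", path)
  chrom <- tab[[1]]
  start <- as.numeric(tab[[2]])
  end <- as.numeric(tab[[3]])
  name <- if (ncol(tab) >= 4) tab[[4]] else paste0("anchor_", seq_along(chrom))
  strand <- if (ncol(tab) >= 6) tab[[6]] else rep("+", length(chrom))
  pos <- if (five_prime) {
    ifelse(strand == "-", end - 1, start)
  } else {
    floor((start + end) / 2)
  }
  tibble::tibble(chrom = chrom, pos = pos, name = name)
}
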
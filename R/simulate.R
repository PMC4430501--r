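#' Simulation scenario configuration
#'
#' Describes a synthetic ChIA-PET experiment: a small genome, occupancy
#' sites of configurable weight and width, loops between site pairs,
#' a sonication fragment-length distribution (normal, modal length
#' `fragment_mean`, default 300 bp as typical for sonicated chromatin),
#' and background noise pairs. Self-ligation pairs always carry the -+
#' orientation with a span set by the fragment length and a breakpoint
#' asymmetry jitter `beta ~ Uniform(beta_range)`; inter-ligation pairs get
#' independent uniform strands. Noise pairs are split between fully
#' uniform genomic pairs and "site noise" pairs that join two random
#' occupied sites without a planted loop (random proximity ligations
#' between occupied loci).
#'
#' @param genome A [genome_model()].
#' @param sites Tibble of occupancy sites: `chrom`, `pos`, optional
#'   `weight` (default equal) and `width` (bp of uniform jitter around
#'   `pos`, default 0).
#' @param loops Tibble of loops: `site_a`, `site_b` (row indices into
#'   `sites`), optional `intensity` (relative pair counts, default equal).
#' @param n_self,n_inter,n_noise Pair counts: self-ligation, loop-driven
#'   inter-ligation, and noise.
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param beta_range Fragment breakpoint jitter range (default
#'   `c(0.3, 0.7)`).
#' @param noise_site_fraction Fraction of noise pairs whose ends sit at
#'   random occupied sites rather than uniform positions. The default 0
#'   keeps the noise model purely uniform over the genome; the
#'   site-noise component is an optional extension for stressing the
#'   calibration with proximity-ligation-like noise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome, sites, loops = NULL,
                       n_self = 10000, n_inter = 0, n_noise = 0,
                       fragment_mean = 300, fragment_sd = 30,
                       beta_range = c(0.3, 0.7),
                       noise_site_fraction = 0) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (!"weight" %in% names(sites)) sites$weight <- 1
  if (!"width" %in% names(sites)) sites$width <- 0
  lens <- genome_length(genome, sites$chrom)
  if (any(is.na(lens)) || any(sites$pos < 0 | sites$pos >= lens)) {
    stop("site locations must lie within the genome")
  }
  if (!is.null(loops)) {
    loops <- tibble::as_tibble(loops)
    stopifnot(all(c("site_a", "site_b") %in% names(loops)))
    if (!"intensity" %in% names(loops)) loops$intensity <- 1
  }
  stopifnot(n_self >= 0, n_inter >= 0, n_noise >= 0, fragment_mean > 0)
  structure(
    list(genome = genome, sites = sites, loops = loops,
         n_self = n_self, n_inter = n_inter, n_noise = n_noise,
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         beta_range = beta_range, noise_site_fraction = noise_site_fraction),
    class = "sim_config"
  )
}

draw_fragment <- function(n, config) {
  L <- rnorm(n, config$fragment_mean, config$fragment_sd)
  pmax(L, 50)
}

draw_site_positions <- function(n, config) {
  idx <- sample(nrow(config$sites), n, replace = TRUE,
                prob = config$sites$weight)
  s <- config$sites[idx, ]
  pos <- s$pos + ifelse(s$width > 0,
                        runif(n, -s$width / 2, s$width / 2), 0)
  tibble::tibble(site = idx, chrom = s$chrom, pos = pos)
}

# one fragment-spread end around an occupied location; returns pos+strand
spread_end <- function(u, L, beta, minus) {
  ifelse(minus, u - L * beta, u + L * (1 - beta))
}

#' Simulate self-ligation read pairs
#'
#' Each pair draws a site (by weight), a fragment length, and a breakpoint
#' asymmetry; the minus end sits `L * beta` upstream and the plus end
#' `L * (1 - beta)` downstream of the occupied location, giving the -+
#' orientation by construction. Pairs falling off a chromosome are
#' resampled.
#'
#' @param config A [sim_config()].
#' @return A tibble of labeled pairs (`label = "self"`).
#' @export
simulate_self_pairs <- function(config) {
  n <- config$n_self
  if (n == 0) {
    return(tibble::tibble())
  }
  out <- NULL
  need <- n
  while (need > 0) {
    src <- draw_site_positions(need, config)
    L <- draw_fragment(need, config)
    beta <- runif(need, config$beta_range[1], config$beta_range[2])
    p_minus <- round(src$pos - L * beta)
    p_plus <- round(src$pos + L * (1 - beta))
    lens <- genome_length(config$genome, src$chrom)
    ok <- p_minus >= 0 & p_plus < lens
    batch <- tibble::tibble(
      chrom1 = src$chrom[ok], pos1 = p_minus[ok], strand1 = "-",
      chrom2 = src$chrom[ok], pos2 = p_plus[ok], strand2 = "+",
      label = "self"
    )
    out <- dplyr::bind_rows(out, batch)
    need <- n - nrow(out)
  }
  out
}

sim_inter_end <- function(chrom, u, config) {
  n <- length(u)
  L <- draw_fragment(n, config)
  beta <- runif(n, config$beta_range[1], config$beta_range[2])
  minus <- runif(n) < 0.5
  tibble::tibble(
    chrom = chrom,
    pos = round(spread_end(u, L, beta, minus)),
    strand = ifelse(minus, "-", "+")
  )
}

#' Simulate inter-ligation read pairs (loops and noise)
#'
#' Loop pairs draw the two occupied locations from a planted loop and
#' fragment each end independently with a uniformly random strand. Noise
#' pairs are either fully uniform over the genome or join two random
#' occupied sites (`noise_site_fraction`).
#'
#' @param config A [sim_config()].
#' @return A tibble of labeled pairs (`label` is `"loop"` or `"noise"`).
#' @export
simulate_inter_pairs <- function(config) {
  out <- NULL
  if (config$n_inter > 0) {
    if (is.null(config$loops) || nrow(config$loops) == 0) {
      stop("n_inter > 0 requires planted loops")
    }
    need <- config$n_inter
    while (need > 0) {
      li <- sample(nrow(config$loops), need, replace = TRUE,
                   prob = config$loops$intensity)
      sa <- config$sites[config$loops$site_a[li], ]
      sb <- config$sites[config$loops$site_b[li], ]
      ua <- sa$pos + ifelse(sa$width > 0,
                            runif(need, -sa$width / 2, sa$width / 2), 0)
      ub <- sb$pos + ifelse(sb$width > 0,
                            runif(need, -sb$width / 2, sb$width / 2), 0)
      ea <- sim_inter_end(sa$chrom, ua, config)
      eb <- sim_inter_end(sb$chrom, ub, config)
      ok <- ea$pos >= 0 & ea$pos < genome_length(config$genome, ea$chrom) &
        eb$pos >= 0 & eb$pos < genome_length(config$genome, eb$chrom)
      batch <- tibble::tibble(
        chrom1 = ea$chrom[ok], pos1 = ea$pos[ok], strand1 = ea$strand[ok],
        chrom2 = eb$chrom[ok], pos2 = eb$pos[ok], strand2 = eb$strand[ok],
        label = "loop", loop = li[ok]
      )
      out <- dplyr::bind_rows(out, batch)
      need <- config$n_inter - nrow(out)
    }
  }
  if (config$n_noise > 0) {
    n_site <- stats::rbinom(1, config$n_noise, config$noise_site_fraction)
    n_unif <- config$n_noise - n_site
    if (n_site > 0) {
      need <- n_site
      while (need > 0) {
        sa <- draw_site_positions(need, config)
        sb <- draw_site_positions(need, config)
        ea <- sim_inter_end(sa$chrom, sa$pos, config)
        eb <- sim_inter_end(sb$chrom, sb$pos, config)
        ok <- ea$pos >= 0 & ea$pos < genome_length(config$genome, ea$chrom) &
          eb$pos >= 0 & eb$pos < genome_length(config$genome, eb$chrom)
        out <- dplyr::bind_rows(out, tibble::tibble(
          chrom1 = ea$chrom[ok], pos1 = ea$pos[ok], strand1 = ea$strand[ok],
          chrom2 = eb$chrom[ok], pos2 = eb$pos[ok], strand2 = eb$strand[ok],
          label = "noise"
        ))
        need <- need - sum(ok)
      }
    }
    if (n_unif > 0) {
      chroms <- config$genome$chromosomes
      pick <- function(n) {
        ci <- sample(nrow(chroms), n, replace = TRUE, prob = chroms$length)
        tibble::tibble(
          chrom = chroms$chrom[ci],
          pos = floor(runif(n) * chroms$length[ci]),
          strand = ifelse(runif(n) < 0.5, "-", "+")
        )
      }
      ea <- pick(n_unif)
      eb <- pick(n_unif)
      out <- dplyr::bind_rows(out, tibble::tibble(
        chrom1 = ea$chrom, pos1 = ea$pos, strand1 = ea$strand,
        chrom2 = eb$chrom, pos2 = eb$pos, strand2 = eb$strand,
        label = "noise"
      ))
    }
  }
  if (is.null(out)) tibble::tibble() else out
}

#' Simulate a full ChIA-PET read-pair dataset
#'
#' @param config A [sim_config()].
#' @param seed Random seed (integer).
#' @return A list with `pairs` (a `chia_pairs` tibble with per-pair
#'   `label`), `truth` (sites, loops, the implied `lambda`), and `config`.
#' @export
simulate_chia_pet <- function(config, seed = 1) {
  set.seed(seed)
  self <- simulate_self_pairs(config)
  inter <- simulate_inter_pairs(config)
  raw <- dplyr::bind_rows(self, dplyr::select(inter, -dplyr::any_of("loop")))
  if (nrow(raw) == 0) stop("simulation produced no pairs")
  pairs <- chia_pairs(raw, config$genome)
  loops <- NULL
  if (!is.null(config$loops) && nrow(config$loops) > 0) {
    loops <- config$loops
    loops$chrom_a <- config$sites$chrom[loops$site_a]
    loops$pos_a <- config$sites$pos[loops$site_a]
    loops$chrom_b <- config$sites$chrom[loops$site_b]
    loops$pos_b <- config$sites$pos[loops$site_b]
  }
  list(
    pairs = pairs,
    truth = list(
      sites = config$sites,
      loops = loops,
      lambda = config$fragment_mean / 2,
      labels = raw$label
    ),
    config = config
  )
}

#' Bundled default simulation scenario
#'
#' Two 2 Mb chromosomes; 20 anchor sites and 20 distal sites; 20 planted
#' anchor-distal loops spanning 5-500 kb; 30000 self-ligation pairs,
#' 3000 loop pairs and 3000 noise pairs (a 50% noise fraction among
#' inter-ligation pairs). Used throughout the test suite.
#'
#' @param n_self,n_inter,n_noise Override the default pair counts.
#' @param loops Plant the loops? `FALSE` gives the noise-only scenario.
#' @param noise_site_fraction Passed to [sim_config()]; the default 0
#'   keeps noise uniform over the genome. On this deliberately small
#'   genome (40 sites) a site-noise component would produce repeated
#'   ligations of the same site pair far more often than a genome-scale
#'   experiment would, which violates the sparsity premise of the
#'   single-pair calibration; use it only to stress that heuristic.
#' @return A [sim_config()].
#' @export
default_scenario <- function(n_self = 30000, n_inter = 3000,
                             n_noise = 3000, loops = TRUE,
                             noise_site_fraction = 0) {
  genome <- genome_model(c(chr1 = 2e6, chr2 = 2e6))
  anchor_pos <- round(seq(1e5, 1.4e6, length.out = 10) / 10) * 10
  dist_gaps <- round(seq(5e3, 5e5, length.out = 10) / 10) * 10
  sites <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = anchor_pos, role = "anchor"),
    tibble::tibble(chrom = "chr2", pos = anchor_pos, role = "anchor"),
    tibble::tibble(chrom = "chr1", pos = anchor_pos + dist_gaps,
                   role = "distal"),
    tibble::tibble(chrom = "chr2", pos = anchor_pos + rev(dist_gaps),
                   role = "distal")
  )
  loop_tbl <- NULL
  if (loops) {
    loop_tbl <- tibble::tibble(site_a = 1:20, site_b = 21:40)
  } else {
    n_inter <- 0
  }
  sim_config(
    genome = genome, sites = sites, loops = loop_tbl,
    n_self = n_self, n_inter = n_inter, n_noise = n_noise,
    noise_site_fraction = noise_site_fraction
  )
}

#' Anchor table of a simulation scenario
#'
#' @param config A [sim_config()] whose sites carry a `role` column.
#' @return Tibble of anchor locations (`chrom`, `pos`, `name`).
#' @export
scenario_anchors <- function(config) {
  s <- config$sites
  stopifnot("role" %in% names(s))
  a <- s[s$role == "anchor", ]
  tibble::tibble(chrom = a$chrom, pos = a$pos,
                 name = paste0("anchor_", seq_len(nrow(a))))
}

#' Write read pairs as BEDPE
#'
#' Each mate is written as a 1 bp interval whose 5' end is the aligned
#' location, so reading the file back reproduces the same coordinates.
#'
#' @param pairs A `chia_pairs` tibble (a `label` column, if present, is
#'   stored in the name field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(pairs, path) {
  name <- if ("label" %in% names(pairs)) pairs$label else "."
  tab <- tibble::tibble(
    chrom1 = pairs$chrom1,
    start1 = ifelse(pairs$strand1 == "+", pairs$pos1, pairs$pos1),
    end1 = pairs$pos1 + 1,
    chrom2 = pairs$chrom2,
    start2 = pairs$pos2,
    end2 = pairs$pos2 + 1,
    name = name,
    score = ".",
    strand1 = pairs$strand1,
    strand2 = pairs$strand2
  )
  readr::write_tsv(tab, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write an occupancy track as bedGraph
#'
#' Zero-mass bins are omitted.
#'
#' @param track An `occupancy_track` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  keep <- track$mass > 0
  readr::write_tsv(
    tibble::tibble(chrom = track$chrom[keep],
                   start = as.integer(track$start[keep]),
                   end = as.integer(track$end[keep]),
                   value = track$mass[keep]),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write a simulated dataset and its ground truth
#'
#' Emits the pairs as BEDPE, the sites and loops as TSV, and the anchors
#' as BED. Round-trips losslessly through [read_bedpe()].
#'
#' @param sim A [simulate_chia_pet()] result.
#' @param dir Output directory (created if needed).
#' @return A named vector of the files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pairs = file.path(dir, "pairs.bedpe"),
    sites = file.path(dir, "sites.tsv"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes")
  )
  write_bedpe(sim$pairs, paths["pairs"])
  readr::write_tsv(sim$truth$sites, paths["sites"], progress = FALSE)
  readr::write_tsv(sim$config$genome$chromosomes, paths["chrom_sizes"],
                   col_names = FALSE, progress = FALSE)
  if (!is.null(sim$truth$loops)) {
    paths["loops"] <- file.path(dir, "loops.tsv")
    readr::write_tsv(sim$truth$loops, paths["loops"], progress = FALSE)
  }
  paths
}
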
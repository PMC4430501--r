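ridge_marginals <- function(half_width = 100, step = 10, lambda = 50) {
  marginalize_rsf(make_rsf(ridge_rsf(half_width, step, lambda, 25, 12),
                           step))
}

test_that("end likelihood picks the strand marginal at the right offset", {
  marg <- ridge_marginals()
  K <- length(marg$offsets)
  # minus end at offset -50 from u (index of -50 in -100..100 by 10)
  i_m <- which(marg$offsets == -50)
  expect_equal(end_likelihood(1000 - 50, "-", 1000, marg),
               marg$minus[i_m])
  i_p <- which(marg$offsets == 50)
  expect_equal(end_likelihood(1000 + 50, "+", 1000, marg),
               marg$plus[i_p])
  # outside the support: exactly zero
  expect_equal(end_likelihood(1000 + 200, "+", 1000, marg), 0)
  expect_equal(end_likelihood(1000 - 110, "-", 1000, marg), 0)
  # vectorized over u with per-end strands
  out <- end_likelihood(c(950, 1050), c("-", "+"), c(1000, 1000), marg)
  expect_equal(out, c(marg$minus[i_m], marg$plus[i_p]))
  expect_error(end_likelihood(1, "x", 1, marg))
})

test_that("conditional field matches a hand-computable one-pair scenario", {
  genome <- genome_model(c(chr1 = 4000))
  marg <- ridge_marginals()
  set.seed(41)
  track <- make_track(genome, function(chrom, starts) {
    exp(-0.5 * ((starts + 5 - 1000) / 80)^2) +
      exp(-0.5 * ((starts + 5 - 2000) / 80)^2)
  })
  # one pair: minus end near the distal site, plus end near the anchor
  inter <- tibble::tibble(chrom1 = "chr1", pos1 = 950, strand1 = "-",
                          chrom2 = "chr1", pos2 = 2040, strand2 = "+")
  anchors <- tibble::tibble(chrom = "chr1", pos = 2005, name = "tss1")
  field <- conditional_field(inter, track, marg, anchors)

  a <- field$anchors
  expect_equal(nrow(a), 1)
  expect_equal(a$n_pairs, 1L)
  expect_false(a$flagged)
  # m is the occupancy of the bin containing the anchor
  expect_equal(a$m, track$mass[track$start == 2000])

  # normalizer factorizes per pair into the two end sums
  centers_all <- track$start + 5
  a1 <- sum(end_likelihood(950, "-", centers_all, marg) * track$mass)
  a2 <- sum(end_likelihood(2040, "+", centers_all, marg) * track$mass)
  expect_equal(field$norm, a1 * a2, tolerance = 1e-12)

  # profile: manual per-bin computation
  prof <- field$profiles[[1]]
  g_anchor <- end_likelihood(2040, "+", 2005, marg)
  centers <- prof$start + 5
  rows <- match(prof$start, track$start)
  manual <- end_likelihood(950, "-", centers, marg) *
    track$mass[rows] * g_anchor * a$m / field$norm
  expect_equal(prof$mass, manual, tolerance = 1e-12)
  expect_equal(a$t, sum(prof$mass), tolerance = 1e-15)

  # support window covers the RSF support around the distal end, plus
  # the one-bin margin that offset rounding can reach
  sup <- field$support[[1]]
  expect_equal(sup$u_lo, 840)
  expect_equal(sup$u_hi, 1070)
})

test_that("conditional field agrees with the windowed joint density", {
  genome <- genome_model(c(chr1 = 4000))
  marg <- ridge_marginals()
  track <- make_track(genome, function(chrom, starts) {
    exp(-0.5 * ((starts + 5 - 1000) / 80)^2) +
      exp(-0.5 * ((starts + 5 - 2000) / 80)^2)
  })
  set.seed(42)
  inter <- tibble::tibble(
    chrom1 = "chr1", pos1 = round(runif(6, 900, 1100)), strand1 = "-",
    chrom2 = "chr1", pos2 = round(runif(6, 1960, 2060)), strand2 = "+"
  )
  anchors <- tibble::tibble(chrom = "chr1", pos = 2005)
  field <- conditional_field(inter, track, marg, anchors)
  jd <- joint_density(inter, track, marg, "chr1", 700, 1300,
                      "chr1", 2000, 2010)
  # the anchor sits at the center of the single v bin, so the conditional
  # profile restricted to pairs hitting via their plus end equals the slice
  prof <- field$profiles[[1]]
  slice <- jd[jd$mass > 0, ]
  common <- intersect(prof$start, slice$u)
  expect_gt(length(common), 5)
  expect_equal(prof$mass[match(common, prof$start)],
               slice$mass[match(common, slice$u)], tolerance = 1e-12)
})

test_that("anchors without nearby pairs or occupancy behave as specified", {
  genome <- genome_model(c(chr1 = 4000, chr2 = 4000))
  marg <- ridge_marginals()
  track <- make_track(genome, function(chrom, starts) {
    ifelse(chrom == "chr1",
           exp(-0.5 * ((starts + 5 - 1000) / 80)^2) +
             exp(-0.5 * ((starts + 5 - 2000) / 80)^2),
           0)
  })
  inter <- tibble::tibble(chrom1 = "chr1", pos1 = 950, strand1 = "-",
                          chrom2 = "chr1", pos2 = 2040, strand2 = "+")
  anchors <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    pos = c(2005, 3500, 2005, 2005) # last is a duplicate
  )
  field <- conditional_field(inter, track, marg, anchors)
  expect_equal(nrow(field$anchors), 3) # duplicate removed
  far <- field$anchors[field$anchors$pos == 3500, ]
  expect_equal(far$t, 0)
  expect_equal(far$n_pairs, 0L)
  expect_equal(nrow(field$profiles[[far$anchor_id]]), 0)
  # anchor on the unoccupied chromosome: m = 0, no pairs nearby
  desert <- field$anchors[field$anchors$chrom == "chr2", ]
  expect_equal(desert$m, 0)
  expect_false(desert$flagged)
  expect_error(conditional_field(inter, track, marg, anchors[0, ]),
               "empty anchor set")
})

test_that("a pair near an unoccupied anchor flags the anchor", {
  genome <- genome_model(c(chr1 = 4000, chr2 = 4000))
  marg <- ridge_marginals()
  track <- make_track(genome, function(chrom, starts) {
    ifelse(chrom == "chr1",
           exp(-0.5 * ((starts + 5 - 1000) / 80)^2) +
             exp(-0.5 * ((starts + 5 - 2000) / 80)^2),
           0)
  })
  inter <- tibble::tibble(
    chrom1 = c("chr1", "chr2"), pos1 = c(950, 1990),
    strand1 = "-",
    chrom2 = c("chr1", "chr2"), pos2 = c(2040, 2040),
    strand2 = "+"
  )
  anchors <- tibble::tibble(chrom = c("chr1", "chr2"), pos = c(2005, 2005))
  field <- conditional_field(inter, track, marg, anchors)
  desert <- field$anchors[field$anchors$chrom == "chr2", ]
  expect_equal(desert$m, 0)
  expect_equal(desert$n_pairs, 1L)
  expect_true(desert$flagged)
  # its profile carries zero mass (anchor occupancy factor is zero)
  expect_equal(sum(field$profiles[[desert$anchor_id]]$mass), 0)
})

test_that("a field with no usable pairs warns and is empty", {
  genome <- genome_model(c(chr1 = 4000))
  marg <- ridge_marginals()
  track <- make_track(genome, function(chrom, starts) {
    exp(-0.5 * ((starts + 5 - 1000) / 80)^2)
  })
  # both ends far from any occupancy
  inter <- tibble::tibble(chrom1 = "chr1", pos1 = 3000, strand1 = "-",
                          chrom2 = "chr1", pos2 = 3500, strand2 = "+")
  anchors <- tibble::tibble(chrom = "chr1", pos = 1005)
  w <- capture_warnings(
    field <- conditional_field(inter, track, marg, anchors)
  )
  expect_true(any(grepl("empty field", w)))
  expect_equal(field$anchors$t, 0)
  expect_equal(field$norm, 0)
})

test_that("tidy gives the anchor-level summary", {
  genome <- genome_model(c(chr1 = 4000))
  marg <- ridge_marginals()
  track <- make_track(genome, function(chrom, starts) {
    exp(-0.5 * ((starts + 5 - 1000) / 80)^2) +
      exp(-0.5 * ((starts + 5 - 2000) / 80)^2)
  })
  inter <- tibble::tibble(chrom1 = "chr1", pos1 = 950, strand1 = "-",
                          chrom2 = "chr1", pos2 = 2040, strand2 = "+")
  anchors <- tibble::tibble(chrom = "chr1", pos = 2005)
  td <- tidy(conditional_field(inter, track, marg, anchors))
  expect_equal(names(td), c("anchor_id", "chrom", "pos", "name", "t", "m",
                            "n_pairs", "flagged"))
  expect_equal(nrow(td), 1)
})
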
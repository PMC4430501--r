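test_that("binomial exceedance is exact on small cases", {
  expect_equal(pr_y_gt_z(1, 0.5, 1, 0.5), 0.25)
  expect_equal(pr_y_gt_z(0, 0.5, 5, 0.5), 0)
  expect_equal(pr_y_gt_z(5, 0, 5, 0.5), 0)
  expect_equal(pr_y_gt_z(5, 0.5, 5, 1), 0) # Z = 5 always, Y <= 5
  expect_equal(pr_y_gt_z(3, 1, 3, 0), 1)   # Y = 3 > Z = 0
  set.seed(51)
  for (k in 1:20) {
    n1 <- sample(0:8, 1)
    n2 <- sample(0:8, 1)
    p1 <- runif(1)
    p2 <- runif(1)
    expect_equal(pr_y_gt_z(n1, p1, n2, p2),
                 oracle_pr_y_gt_z(n1, p1, n2, p2), tolerance = 1e-12)
  }
  expect_error(pr_y_gt_z(5, 1.5, 5, 0.5), "\\[0, 1\\]")
  expect_error(pr_y_gt_z(-1, 0.5, 5, 0.5))
})

test_that("binomial exceedance is monotone in the two probabilities", {
  p_grid <- seq(0.05, 0.95, by = 0.15)
  vals1 <- vapply(p_grid, function(p) pr_y_gt_z(50, p, 50, 0.4),
                  numeric(1))
  expect_true(all(diff(vals1) >= 0))
  vals2 <- vapply(p_grid, function(p) pr_y_gt_z(50, 0.4, 50, p),
                  numeric(1))
  expect_true(all(diff(vals2) <= 0))
})

test_that("the normal approximation branch tracks the exact value", {
  exact <- pr_y_gt_z(2000, 0.29, 2000, 0.3)
  approx <- pr_y_gt_z(2000, 0.29, 2000, 0.3, exact_limit = 100)
  expect_lt(abs(exact - approx), 0.01)
  exact2 <- pr_y_gt_z(5000, 0.01, 5000, 0.012)
  approx2 <- pr_y_gt_z(5000, 0.01, 5000, 0.012, exact_limit = 100)
  expect_lt(abs(exact2 - approx2), 0.01)
})

test_that("marginal region p-value reflects enrichment against uniform", {
  g <- genome_model(c(chr1 = 1e6))
  # 10x enrichment over background in a 500 bp region
  p_enriched <- marginal_region_pvalue(10 * 500 / g$mappable_size, 500,
                                       5000, g)
  p_background <- marginal_region_pvalue(500 / g$mappable_size, 500,
                                         5000, g)
  expect_lt(p_enriched, 0.05)
  expect_gt(p_background, 0.3)
  expect_error(marginal_region_pvalue(0.1, 2e6, 5000, g), "smaller")
})

test_that("rpkm and the enrichment p-value behave as expected", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(50, 500, 2e6), 50)
  expect_error(rpkm(10, 0, 1e6), "positive")
  g <- genome_model(c(chr1 = 1e6))
  expect_lt(enrichment_pvalue(200, 500, 1e5, g), 0.01)
  expect_gt(enrichment_pvalue(0, 500, 1e5, g), 0.5)
})

test_that("candidate regions are maximal runs with correct support counts", {
  prof <- tibble::tibble(
    chrom = "chr1",
    start = c(seq(1000, 1040, by = 10), 2000, 2500),
    mass = c(rep(0.01, 5), 0.02, 1e-20),
    occ_mass = 1e-4
  )
  sup <- tibble::tibble(
    pair_id = 1:3,
    chrom = "chr1",
    u_lo = c(900, 1030, 2500),
    u_hi = c(1100, 2100, 2600)
  )
  field <- make_field(list(prof), list(sup), t = sum(prof$mass),
                      m = 0.05, n_inter = 1000)
  regs <- candidate_regions(field, 1, f = 1e-15)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$start, c(1000, 2000))
  expect_equal(regs$end, c(1050, 2010))
  expect_equal(regs$width, c(50, 10))
  expect_equal(regs$mass, c(0.05, 0.02))
  expect_equal(regs$occ_mass, c(5e-4, 1e-4))
  expect_equal(regs$support, c(2L, 1L))
  # raising the threshold above the run mass removes regions
  expect_equal(nrow(candidate_regions(field, 1, f = 0.015)), 1)
  expect_equal(nrow(candidate_regions(field, 1, f = 1)), 0)
  expect_error(candidate_regions(field, 1, f = 0))
})

test_that("the worked two-anchor tau case gives corrected totals (8, 8)", {
  ts <- solve_tau(t = c(4, 1), m = c(0.5, 0.5), c = 2)
  expect_equal(ts$tau, c(4, 7), tolerance = 1e-9)
  expect_equal(ts$t + ts$tau, c(8, 8), tolerance = 1e-9)
  expect_equal(attr(ts, "i_max"), 1L)
})

test_that("tau fixed point satisfies proportionality on active coordinates", {
  set.seed(52)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    t <- runif(n, 0, 5)
    m <- runif(n, 0.1, 1)
    cc <- runif(1, 1.2, 20)
    ts <- solve_tau(t, m, cc)
    tot <- sum(ts$t + ts$tau)
    i_max <- attr(ts, "i_max")
    active <- setdiff(which(ts$tau > 0), i_max)
    if (length(active) > 0) {
      expect_lt(max(abs((ts$t + ts$tau)[active] / tot -
                          ts$m[active] / sum(ts$m))), 1e-8)
    }
    expect_true(all(ts$tau >= 0))
    expect_equal(ts$tau[i_max], (cc - 1) * t[i_max])
  }
})

test_that("tau updates floor at zero and inputs are validated", {
  ts <- solve_tau(t = c(10, 5), m = c(0.99, 0.01), c = 2)
  expect_equal(ts$tau[1], 10)
  expect_equal(ts$tau[2], 0) # the demanded share is below its raw mass
  expect_error(solve_tau(c(1, 2), c(0.5, 0.5), c = 1), "c > 1")
  expect_error(solve_tau(c(1, 2), c(0.5, 0), c = 2), "positive marginal")
  expect_error(solve_tau(c(-1, 2), c(0.5, 0.5), c = 2))
})

test_that("corrected joint p-value handles degenerate totals and clipping", {
  expect_equal(corrected_joint_pvalue(0.1, 0.01, 0, 0, 1000), 1)
  # mass exceeding the corrected total clips p at 1: Z is always n
  expect_equal(corrected_joint_pvalue(5, 0.5, 1, 1, 100), 0)
  p_strong <- corrected_joint_pvalue(0.09, 1e-4, 0.1, 0.1, 1000)
  p_weak <- corrected_joint_pvalue(0.001, 1e-4, 0.1, 0.1, 1000)
  expect_lt(p_strong, 0.001)
  expect_gt(p_weak, p_strong)
})

test_that("eloc is the max-mass bin midpoint with leftmost tie-breaking", {
  prof <- make_profile(c(1, 3, 2), at = 1000)
  field <- make_field(list(prof), list(tibble::tibble(
    pair_id = 1L, chrom = "chr1", u_lo = 900, u_hi = 1100
  )), t = 6, m = 0.1, n_inter = 100)
  expect_equal(estimate_eloc(field, 1, "chr1", 1000, 1030), 1015)
  prof2 <- make_profile(c(2, 2, 1), at = 1000)
  field2 <- make_field(list(prof2), list(tibble::tibble(
    pair_id = 1L, chrom = "chr1", u_lo = 900, u_hi = 1100
  )), t = 5, m = 0.1, n_inter = 100)
  expect_equal(estimate_eloc(field2, 1, "chr1", 1000, 1030), 1005)
  expect_error(estimate_eloc(field, 1, "chr1", 5000, 5100), "no joint mass")
})

test_that("calibration raises c until single-pair calls fall to the target", {
  prof_a <- make_profile(rep(0.06, 5), at = 1000, occ = rep(1e-5, 5))
  sup_a <- tibble::tibble(pair_id = 1:3, chrom = "chr1",
                          u_lo = 850, u_hi = 1160)
  prof_b <- dplyr::bind_rows(make_profile(0.005, at = 1000,
                                          occ = 1e-4),
                             make_profile(0.005, at = 3000, occ = 1e-4))
  sup_b <- tibble::tibble(pair_id = 4:5, chrom = "chr1",
                          u_lo = c(900, 2900), u_hi = c(1100, 3100))
  field <- make_field(list(prof_a, prof_b), list(sup_a, sup_b),
                      t = c(0.3, 0.01), m = c(0.3, 0.01), n_inter = 1000)
  fit <- calibrate_c(field)
  # at the smallest c, 2 of 3 significant regions are single-pair (2/3);
  # calibration must push c up and strip them
  expect_gt(fit$c, 1.01)
  expect_lte(fit$single_pair_fraction, 0.1)
  expect_gte(fit$n_significant, 1)
  calls <- call_interactions(field)
  expect_true(all(calls$support > 1))
  expect_true(all(calls$p_value < 0.05))
  expect_equal(calls$eloc[1], 1005) # equal masses: leftmost bin midpoint
  expect_equal(attr(calls, "c"), fit$c)
  gl <- glance(calls)
  expect_equal(gl$n_calls, nrow(calls))
})

test_that("calibration degenerate branches return the boundary scale", {
  # all supports > 1: single-pair fraction already 0 at the smallest c
  prof <- make_profile(rep(0.05, 4), at = 1000, occ = rep(1e-5, 4))
  sup <- tibble::tibble(pair_id = 1:4, chrom = "chr1",
                        u_lo = 900, u_hi = 1150)
  field <- make_field(list(prof), list(sup), t = 0.2, m = 0.2,
                      n_inter = 1000)
  fit <- calibrate_c(field)
  expect_equal(fit$c, 1.01)
  expect_equal(fit$single_pair_fraction, 0)

  # nothing significant anywhere: warn and return the smallest c
  prof2 <- make_profile(0.001, at = 1000, occ = 0.01)
  sup2 <- tibble::tibble(pair_id = 1L, chrom = "chr1",
                         u_lo = 900, u_hi = 1100)
  field2 <- make_field(list(prof2), list(sup2), t = 0.5, m = 0.5,
                       n_inter = 1000)
  expect_warning(fit2 <- calibrate_c(field2), "no significant regions")
  expect_equal(fit2$n_significant, 0L)

  # no joint mass at all is an error
  field3 <- make_field(list(prof2[0, ]), list(sup2[0, ]), t = 0, m = 0.5,
                       n_inter = 1000)
  expect_error(calibrate_c(field3), "no joint mass")
  # ...but the end-to-end caller degrades to zero calls with a warning
  expect_warning(calls3 <- call_interactions(field3), "no joint mass")
  expect_s3_class(calls3, "interaction_calls")
  expect_equal(nrow(calls3), 0)
  expect_equal(attr(calls3, "n_significant"), 0L)
  expect_true(is.na(attr(calls3, "c")))
})

test_that("BH adjustment and significant_only switches work", {
  prof_a <- make_profile(rep(0.06, 5), at = 1000, occ = rep(1e-5, 5))
  sup_a <- tibble::tibble(pair_id = 1:3, chrom = "chr1",
                          u_lo = 850, u_hi = 1160)
  prof_b <- make_profile(0.001, at = 3000, occ = 0.01)
  sup_b <- tibble::tibble(pair_id = 4:5, chrom = "chr1",
                          u_lo = 2900, u_hi = 3100)
  field <- make_field(list(prof_a, prof_b), list(sup_a, sup_b),
                      t = c(0.3, 0.5), m = c(0.3, 0.5), n_inter = 1000)
  all_calls <- call_interactions(field, significant_only = FALSE,
                                 bh_adjust = TRUE)
  expect_equal(nrow(all_calls), 2)
  expect_true("p_adjusted" %in% names(all_calls))
  expect_true(all(all_calls$p_adjusted >= all_calls$p_value))
  sig_calls <- call_interactions(field)
  expect_lt(nrow(sig_calls), nrow(all_calls))
})
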
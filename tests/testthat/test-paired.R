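test_that("Fisher point probability matches the hypergeometric oracle", {
  ## only one table possible given margins
  expect_equal(fisher_point_probability(0, 10, 0, 10), 1)
  ## swapping the two samples leaves p unchanged (formula symmetry)
  expect_equal(fisher_point_probability(3, 17, 9, 11),
               fisher_point_probability(9, 11, 3, 17))
  ## frozen derived example against dhyper
  expect_equal(fisher_point_probability(0, 20, 8, 12),
               dhyper(0, 20, 20, 8), tolerance = 1e-12)
  expect_error(fisher_point_probability(-1, 2, 3, 4), "counts")
})

test_that("point probability agrees with the oracle to 1e-10 up to N = 200", {
  set.seed(23)
  for (i in 1:200) {
    N <- sample(4:200, 1)
    nn <- pick1(1:(N - 1))       # normal margin
    v <- pick1(0:N)              # variant margin
    n1 <- pick1(max(0, v - (N - nn)):min(nn, v))
    p <- fisher_point_probability(n1, nn - n1, v - n1,
                                  (N - nn) - (v - n1))
    want <- dhyper(n1, nn, N - nn, v)
    expect_equal(p, want, tolerance = 1e-10)
  }
})

test_that("one-sided p sums the tail toward tumor enrichment", {
  ## n1 at its maximum feasible value: the tail is everything
  expect_equal(fisher_one_sided_p(5, 0, 3, 12), 1)
  expect_equal(fisher_one_sided_p(4, 6, 0, 10), 1)  # v = 4 all in normal
  ## point term is contained in the tail
  set.seed(29)
  for (i in 1:50) {
    N <- sample(4:60, 1)
    nn <- pick1(1:(N - 1))
    v <- pick1(0:N)
    n1 <- pick1(max(0, v - (N - nn)):min(nn, v))
    tb <- c(n1, nn - n1, v - n1, (N - nn) - (v - n1))
    point <- do.call(fisher_point_probability, as.list(tb))
    tail_p <- do.call(fisher_one_sided_p, as.list(tb))
    expect_lte(point, tail_p + 1e-12)
    ## full enumeration oracle over feasible tables with k <= n1
    ks <- max(0, v - (N - nn)):n1
    want <- sum(dhyper(ks, nn, N - nn, v))
    expect_equal(tail_p, want, tolerance = 1e-10)
  }
  ## frozen derived example
  expect_equal(fisher_one_sided_p(1, 99, 20, 80),
               sum(dhyper(0:1, 100, 100, 21)), tolerance = 1e-12)
})

test_that("moving a variant read from normal to tumor never raises the one-sided p", {
  set.seed(37)
  for (i in 1:60) {
    N <- sample(6:60, 1)
    nn <- pick1(2:(N - 2))
    v <- pick1(1:(N - 1))
    lo <- max(1, v - (N - nn))
    hi <- min(nn, v)
    if (lo > hi) next
    n1 <- pick1(lo:hi)
    p_hi <- fisher_one_sided_p(n1, nn - n1, v - n1, (N - nn) - (v - n1))
    ## shift one variant read from normal to tumor (margins of sample
    ## sizes change by one read each way; enrichment direction preserved)
    p_lo <- fisher_one_sided_p(n1 - 1L, nn - n1, v - n1 + 1L,
                               (N - nn) - (v - n1))
    expect_lte(p_lo, p_hi + 1e-12)
  }
})

test_that("the paired cascade follows its gates in order", {
  cfg <- caller_config()
  ## absent in normal: emitted directly
  d <- classify_paired(10, 20, 200, 0, 0, 180, FALSE, NULL, cfg)
  expect_true(d$emit); expect_equal(d$path_taken, "absent_in_normal")

  ## normal VAF 5% vs tumor 10%: ratio 0.5 >= 0.2 and >= nf -> rejected
  d <- classify_paired(10, 20, 200, 5, 9, 180, FALSE, NULL, cfg)
  expect_false(d$emit); expect_equal(d$path_taken, "nf_gate_fail")

  ## single-strand normal support is treated as artifact
  d <- classify_paired(10, 20, 200, 1, 2, 200, TRUE, NULL, cfg)
  expect_true(d$emit); expect_equal(d$path_taken, "same_direction_normal")

  ## normal VAF below half the tumor VAF with weak normal LOD: emitted
  nobs <- data.frame(is_alt = c(TRUE, rep(FALSE, 199)),
                     is_ref = c(FALSE, rep(TRUE, 199)), qual = 13)
  d <- classify_paired(10, 20, 200, 0.5, 1, 200, FALSE, nobs, cfg)
  expect_true(d$emit); expect_equal(d$path_taken, "lod_gate_pass")
  expect_lt(d$lod_normal, cfg$lod_threshold)

  ## strong normal LOD forces the Fisher test; high p rejects
  nobs2 <- data.frame(is_alt = c(rep(TRUE, 4), rep(FALSE, 196)),
                      is_ref = c(rep(FALSE, 4), rep(TRUE, 196)), qual = 30)
  d <- classify_paired(10, 5, 200, 1.9, 4, 200, FALSE, nobs2, cfg)
  expect_equal(d$path_taken, "fet_fail")
  expect_false(d$emit)
  expect_gt(d$fet_p, cfg$fet_p_threshold)

  ## no normal coverage: rejected with an explicit label
  d <- classify_paired(10, 20, 200, 0, 0, 0, FALSE, NULL, cfg)
  expect_false(d$emit); expect_equal(d$path_taken, "no_normal_coverage")
})

test_that("the cascade never emits double-stranded normal support above both bounds", {
  cfg <- caller_config()
  set.seed(41)
  for (i in 1:50) {
    tv <- runif(1, 2, 40)
    nv <- runif(1, max(cfg$nf, cfg$normal_ratio * tv), 60)
    d <- classify_paired(tv, 30L, 300L, nv, 10L, 300L, FALSE, NULL, cfg)
    expect_false(d$emit)
  }
})
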
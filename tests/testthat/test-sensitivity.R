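test_that("Cochran's Q matches direct arithmetic and its null distribution", {
  # all ratios identical: Q = 0, p = 1
  h0 <- make_h(bx = rep(1, 3), by = rep(0.5, 3), sey = rep(0.1, 3))
  q0 <- cochran_q(h0)
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$pvalue, 1)
  expect_false(q0$heterogeneous)

  # two ratios {0, 1} with unit weights around 0.5: Q = 0.5, df = 1
  h2 <- make_h(bx = c(1, 1), by = c(0, 1), sey = c(1, 1))
  q2 <- cochran_q(h2, beta = 0.5)
  expect_equal(q2$q, 0.5, tolerance = 1e-12)
  expect_equal(q2$df, 1)

  # simulated homogeneous data: Q ~ chi-square(K - 1)
  withr::local_seed(37)
  k <- 10
  qs <- replicate(600, {
    bx <- abs(rnorm(k, 0.1, 0.02)) + 0.02
    by <- rnorm(k, 0.3 * bx, 0.05)
    cochran_q(make_h(bx, by, sey = rep(0.05, k)))$q
  })
  expect_gt(stats::ks.test(qs, stats::pchisq, df = k - 1)$p.value, 0.01)

  expect_error(cochran_q(make_h(1, 0.5)),
               class = "mrflora_insufficient_instruments")
})

test_that("Egger intercept test flags directional pleiotropy", {
  # exact-fit line with nonzero intercept: zero residual scale, p -> 0
  h <- make_h(bx = c(1, 2, 3), by = c(0.6, 1.1, 1.6), sey = rep(0.1, 3))
  t1 <- egger_intercept_test(h)
  expect_equal(t1$intercept, 0.1, tolerance = 1e-10)
  expect_equal(t1$pvalue, 0)
  expect_true(t1$pleiotropic)

  # proportional data: intercept 0, boundary p = 1
  h2 <- make_h(bx = c(0.5, 1, 2), by = 0.7 * c(0.5, 1, 2),
               sey = rep(0.1, 3))
  t2 <- egger_intercept_test(h2)
  expect_equal(t2$intercept, 0, tolerance = 1e-10)
  expect_equal(t2$pvalue, 1)

  # balanced pleiotropy: rejection near the nominal 5% level
  withr::local_seed(41)
  k <- 12
  rej <- replicate(400, {
    bx <- abs(rnorm(k, 0.15, 0.04)) + 0.05
    by <- rnorm(k, 0.2 * bx, 0.05)  # noise plays the balanced-pleiotropy role
    egger_intercept_test(make_h(bx, by, sey = rep(0.05, k)))$pleiotropic
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.12)
})

test_that("leave_one_out returns K + 1 rows and isolates gross outliers", {
  h3 <- make_h(bx = c(0.1, 0.12, 0.15), by = c(0.04, 0.05, 0.06))
  loo3 <- leave_one_out(h3)
  expect_equal(nrow(loo3), 4)
  expect_equal(sum(loo3$excluded_snp == "none"), 1)

  # identical SNPs: all K omission rows identical
  hid <- make_h(bx = rep(0.1, 4), by = rep(0.04, 4))
  looid <- leave_one_out(hid)
  body <- looid[looid$excluded_snp != "none", ]
  expect_equal(length(unique(body$beta)), 1)
  expect_equal(length(unique(body$se)), 1)

  # homogeneous data: every omission estimate within 2 SE of the full fit
  withr::local_seed(43)
  k <- 8
  bx <- abs(rnorm(k, 0.12, 0.02)) + 0.03
  by <- rnorm(k, 0.4 * bx, 0.03)
  h <- make_h(bx, by, sey = rep(0.03, k))
  loo <- leave_one_out(h)
  full <- loo[loo$excluded_snp == "none", ]
  body <- loo[loo$excluded_snp != "none", ]
  expect_true(all(abs(body$beta - full$beta) <= 2 * full$se))

  # one gross outlier: its omission row moves the estimate the most
  by_out <- by
  by_out[3] <- by_out[3] + 1
  loo_o <- leave_one_out(make_h(bx, by_out, sey = rep(0.03, k)))
  full_o <- loo_o[loo_o$excluded_snp == "none", ]
  body_o <- loo_o[loo_o$excluded_snp != "none", ]
  expect_equal(body_o$excluded_snp[which.max(abs(body_o$beta - full_o$beta))],
               h$snp[3])

  expect_error(leave_one_out(make_h(c(1, 2), c(1, 2))),
               class = "mrflora_insufficient_instruments")
})

test_that("MR-PRESSO is deterministic under a seed and flags planted outliers", {
  withr::local_seed(47)
  k <- 10
  bx <- abs(rnorm(k, 0.12, 0.03)) + 0.03
  by <- rnorm(k, 0.3 * bx, 0.05)
  h <- make_h(bx, by, sey = rep(0.05, k))

  a <- mr_presso(h, n_sim = 100, seed = 7)
  b <- mr_presso(h, n_sim = 100, seed = 7)
  expect_identical(glance(a), glance(b))
  expect_identical(tidy(a), tidy(b))
  expect_gte(a$global_p, 1 / 101)
  expect_lte(a$global_p, 1)

  # inject pleiotropy of +10 outcome SEs into one SNP
  by_out <- by
  by_out[5] <- by_out[5] + 10 * 0.05
  p_out <- mr_presso(make_h(bx, by_out, sey = rep(0.05, k)),
                     n_sim = 400, seed = 11)
  expect_true(h$snp[5] %in% p_out$outliers)
  expect_lt(p_out$global_p, 0.05)
  expect_false(is.na(p_out$distortion_p))

  expect_error(mr_presso(make_h(c(1, 2, 3), c(1, 2, 3))),
               class = "mrflora_insufficient_instruments")
  expect_error(mr_presso(h, n_sim = 10), class = "mrflora_config_error")
})

test_that("PRESSO global p decreases with pleiotropy magnitude", {
  withr::local_seed(53)
  k <- 10
  bx <- abs(rnorm(k, 0.12, 0.03)) + 0.03
  noise <- rnorm(k, 0, 0.05)
  ps <- vapply(c(0, 0.2, 0.5), function(shift) {
    by <- 0.3 * bx + noise
    by[4] <- by[4] + shift
    mr_presso(make_h(bx, by, sey = rep(0.05, k)),
              n_sim = 300, seed = 13)$global_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("sensitivity_report bundles components by instrument count", {
  h2 <- make_h(c(0.1, 0.12), c(0.04, 0.05))
  s2 <- sensitivity_report(h2, presso = TRUE)
  expect_false(is.null(s2$heterogeneity))
  expect_null(s2$egger_intercept)
  expect_null(s2$presso)
  expect_true(any(grepl("presso", s2$skipped)))

  h5 <- make_h(bx = seq(0.08, 0.16, length.out = 5),
               by = 0.3 * seq(0.08, 0.16, length.out = 5) +
                 c(0.01, -0.01, 0, 0.01, -0.01))
  s5 <- sensitivity_report(h5, presso = TRUE, presso_n_sim = 100, seed = 3)
  expect_s3_class(s5$heterogeneity, "tbl_df")
  expect_s3_class(s5$loo, "tbl_df")
  expect_s3_class(s5$presso, "mr_presso")
  expect_length(s5$skipped, 0)
})
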
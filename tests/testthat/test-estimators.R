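test_that("wald_ratios computes first-order ratios and excludes zero betas", {
  h <- make_h(bx = c(0.2, -0.2), by = c(0.1, 0.1), sey = c(0.02, 0.02))
  w <- wald_ratios(h)
  expect_equal(w$ratio, c(0.5, -0.5))
  expect_equal(w$ratio_se, c(0.1, 0.1))
  expect_equal(w$weight, 1 / w$ratio_se^2)

  h3 <- make_h(bx = c(0.2, 0, 0.1), by = c(0.1, 0.1, 0.05))
  expect_warning(w3 <- wald_ratios(h3), "zero exposure effect")
  expect_equal(nrow(w3), 2)
  h0 <- make_h(bx = c(0, 0), by = c(0.1, 0.1))
  expect_error(wald_ratios(h0), class = "mrflora_degenerate_instruments")
})

test_that("IVW reproduces the closed form and handles the collinear case", {
  # consistent effects through the origin: beta exactly 0.5, Q = 0
  h <- make_h(bx = c(1, 2), by = c(0.5, 1.0), sey = c(0.1, 0.1))
  f_r <- mr_ivw(h, "random")
  f_f <- mr_ivw(h, "fixed")
  expect_equal(f_r$beta, 0.5, tolerance = 1e-14)
  expect_equal(f_r$q, 0, tolerance = 1e-20)
  expect_equal(f_r$se, f_f$se)

  expect_error(mr_ivw(make_h(0.1, 0.05)),
               class = "mrflora_insufficient_instruments")

  withr::local_seed(11)
  for (i in 1:25) {
    k <- sample(3:10, 1)
    bx <- rnorm(k, 0.1, 0.05)
    by <- rnorm(k, 0.03, 0.02)
    sey <- runif(k, 0.01, 0.1)
    h <- make_h(bx, by, sey = sey)
    want <- oracle_ivw_fixed(bx, by, sey)
    got <- mr_ivw(h, "fixed")
    expect_equal(got$beta, want$beta, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers an exact line and a proportional fit", {
  # exact line with slope 0.5, intercept 0.1, zero residuals
  h <- make_h(bx = c(1, 2, 3), by = c(0.6, 1.1, 1.6), sey = rep(0.1, 3))
  f <- mr_egger(h)
  expect_equal(f$beta, 0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 0.1, tolerance = 1e-12)
  expect_equal(f$se, 0)
  expect_equal(f$pvalue, 0)

  # proportional data: intercept 0, slope c
  h2 <- make_h(bx = c(0.5, 1, 2), by = 0.7 * c(0.5, 1, 2),
               sey = rep(0.1, 3))
  f2 <- mr_egger(h2)
  expect_equal(f2$beta, 0.7, tolerance = 1e-12)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)

  expect_error(mr_egger(make_h(c(1, 2), c(0.5, 1))),
               class = "mrflora_insufficient_instruments")
})

test_that("MR-Egger matches a two-parameter weighted least-squares oracle", {
  withr::local_seed(13)
  for (i in 1:25) {
    k <- sample(4:10, 1)
    bx <- abs(rnorm(k, 0.1, 0.05)) + 0.01
    by <- rnorm(k, 0.05, 0.05)
    sey <- runif(k, 0.02, 0.1)
    h <- make_h(bx, by, sey = sey)
    f <- mr_egger(h)
    want <- oracle_wls_line(bx, by, 1 / sey^2)
    expect_equal(f$beta, want$slope, tolerance = 1e-10)
    expect_equal(f$intercept, want$intercept, tolerance = 1e-10)
  }
})

test_that("Egger slope is invariant to the orientation convention", {
  withr::local_seed(17)
  bx <- rnorm(6, 0, 0.1)
  by <- 0.4 * bx + rnorm(6, 0, 0.02)
  h <- make_h(bx, by)
  f1 <- mr_egger(h)
  # flipping any SNP's signs pre-fit changes nothing
  h2 <- h
  h2$beta_x[2] <- -h2$beta_x[2]
  h2$beta_y[2] <- -h2$beta_y[2]
  f2 <- mr_egger(h2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates cumulative weights correctly", {
  # equal weights: plain median
  h <- make_h(bx = rep(1, 3), by = c(0.1, 0.5, 0.9), sey = rep(0.1, 3))
  f <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(f$beta, 0.5, tolerance = 1e-12)

  # degenerate: all ratios identical, bootstrap SE shrinks with ratio SE
  h2 <- make_h(bx = rep(1, 3), by = rep(0.7, 3), sey = rep(1e-8, 3))
  f2 <- mr_weighted_median(h2, n_boot = 200, seed = 1)
  expect_equal(f2$beta, 0.7, tolerance = 1e-12)
  expect_lt(f2$se, 1e-6)

  # unequal weights match the prefix-sum interpolation oracle
  withr::local_seed(19)
  for (i in 1:25) {
    k <- sample(3:9, 1)
    bx <- abs(rnorm(k, 0.1, 0.03)) + 0.02
    by <- rnorm(k, 0.04, 0.03)
    sey <- runif(k, 0.01, 0.1)
    h <- make_h(bx, by, sey = sey)
    w <- wald_ratios(h)
    f <- mr_weighted_median(h, n_boot = 100, seed = 5)
    expect_equal(f$beta, oracle_weighted_median(w$ratio, w$weight),
                 tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(make_h(c(1, 2), c(1, 2))),
               class = "mrflora_insufficient_instruments")
})

test_that("mode estimators find the dominant cluster, not the outlier", {
  # cluster of four near 0.5 plus a gross outlier at 3.0
  h <- make_h(bx = rep(1, 5),
              by = c(0.49, 0.50, 0.51, 0.52, 3.0),
              sey = rep(0.05, 5))
  f <- mr_mode(h, "simple", n_boot = 100, seed = 2)
  expect_lt(abs(f$beta - 0.5), 0.15)
  expect_gt(3.0 - f$beta, 2)

  # degenerate distribution: all ratios equal
  h2 <- make_h(bx = rep(1, 3), by = rep(0.4, 3), sey = rep(0.05, 3))
  f2 <- mr_mode(h2, "weighted", n_boot = 100, seed = 2)
  expect_equal(f2$beta, 0.4)
  expect_equal(f2$se, 0)

  # equal weights: weighted and simple agree exactly
  h3 <- make_h(bx = rep(1, 4), by = c(0.2, 0.3, 0.5, 0.6),
               sey = rep(0.05, 4))
  fw <- mr_mode(h3, "weighted", n_boot = 100, seed = 3)
  fs <- mr_mode(h3, "simple", n_boot = 100, seed = 3)
  expect_equal(fw$beta, fs$beta, tolerance = 1e-12)

  expect_error(mr_mode(h3, phi = 0), class = "mrflora_config_error")
})

test_that("beta_to_or exponentiates the estimate and its 95% interval", {
  o <- beta_to_or(0, 0.1)
  expect_equal(o$or, 1)
  expect_equal(o$or_low, exp(-1.96 * 0.1))
  o2 <- beta_to_or(log(2), 0)
  expect_equal(unlist(o2), c(or = 2, or_low = 2, or_high = 2))
  o3 <- beta_to_or(0.5, 0.1)
  expect_equal(o3$or, exp(0.5), tolerance = 1e-12)
  expect_equal(o3$or_low, exp(0.5 - 0.196), tolerance = 1e-12)
  expect_equal(o3$or_high, exp(0.5 + 0.196), tolerance = 1e-12)
})

test_that("run_all_methods dispatches on instrument count", {
  h1 <- make_h(0.2, 0.1)
  e1 <- run_all_methods(h1)
  expect_equal(e1$method, "wald")
  expect_true(e1$primary)

  h2 <- make_h(c(0.2, 0.3), c(0.1, 0.15))
  e2 <- run_all_methods(h2)
  expect_equal(nrow(e2), 2)
  expect_setequal(e2$method, c("ivw", "wald"))

  withr::local_seed(23)
  bx <- abs(rnorm(10, 0.1, 0.02)) + 0.02
  by <- 0.3 * bx + rnorm(10, 0, 0.01)
  h10 <- make_h(bx, by, sey = rep(0.05, 10))
  e10 <- run_all_methods(h10, n_boot = 200, seed = 4)
  expect_equal(nrow(e10), 5)
  expect_setequal(e10$method, c("ivw", "egger", "weighted_median",
                                "weighted_mode", "simple_mode"))
  expect_equal(e10$method[e10$primary], "ivw")
  # consistent data: all five betas within 2 SE of one another
  betas <- e10$beta
  ses <- e10$se
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(abs(betas[i] - betas[j]),
              2 * sqrt(ses[i]^2 + ses[j]^2) + 1e-9)
  }
  # OR column is exp(beta) on every row
  expect_equal(e10$or, exp(e10$beta), tolerance = 1e-12)

  e0 <- run_all_methods(make_h(numeric(0), numeric(0)))
  expect_equal(nrow(e0), 0)
  expect_match(attr(e0, "reason"), "no instruments")
})

test_that("estimators are equivariant to outcome scale", {
  withr::local_seed(29)
  bx <- abs(rnorm(6, 0.1, 0.03)) + 0.02
  by <- 0.4 * bx + rnorm(6, 0, 0.01)
  h <- make_h(bx, by, sey = rep(0.05, 6))
  c_scale <- 3.7
  h_s <- h
  h_s$beta_y <- h$beta_y * c_scale
  h_s$se_y <- h$se_y * c_scale
  for (fits in list(c(mr_ivw(h)$beta, mr_ivw(h_s)$beta),
                    c(mr_egger(h)$beta, mr_egger(h_s)$beta),
                    c(mr_weighted_median(h, 100, 1)$beta,
                      mr_weighted_median(h_s, 100, 1)$beta),
                    c(mr_mode(h, "weighted", 1, 100, 1)$beta,
                      mr_mode(h_s, "weighted", 1, 100, 1)$beta))) {
    expect_equal(fits[2], c_scale * fits[1], tolerance = 1e-9)
  }
})

test_that("Egger absorbs directional pleiotropy that biases IVW", {
  # noiseless instances: outcome = true slope * bx + constant pleiotropy
  bx <- c(0.05, 0.08, 0.1, 0.12, 0.15)
  alpha <- 0.03
  true_b <- 0.4
  by <- true_b * bx + alpha
  h <- make_h(bx, by, sey = rep(0.05, 5))
  fe <- mr_egger(h)
  expect_equal(fe$beta, true_b, tolerance = 1e-10)
  expect_equal(fe$intercept, alpha, tolerance = 1e-10)
  fi <- mr_ivw(h, "fixed")
  w <- 1 / rep(0.05, 5)^2
  bias <- alpha * sum(w * bx) / sum(w * bx^2)
  expect_equal(fi$beta, true_b + bias, tolerance = 1e-10)
})

test_that("bootstrap standard errors are seed-reproducible and stable", {
  withr::local_seed(31)
  bx <- abs(rnorm(8, 0.1, 0.03)) + 0.02
  by <- 0.3 * bx + rnorm(8, 0, 0.02)
  h <- make_h(bx, by, sey = rep(0.05, 8))
  a <- mr_weighted_median(h, n_boot = 500, seed = 99)
  b <- mr_weighted_median(h, n_boot = 500, seed = 99)
  expect_identical(a$se, b$se)
  # two large independent bootstrap runs agree to a few percent
  s1 <- mr_weighted_median(h, n_boot = 5000, seed = 1)$se
  s2 <- mr_weighted_median(h, n_boot = 5000, seed = 2)$se
  expect_lt(abs(s1 - s2) / ((s1 + s2) / 2), 0.05)
})
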
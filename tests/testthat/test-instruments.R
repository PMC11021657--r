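test_that("select_instruments applies a strict p-value cutoff with provenance", {
  df <- make_sumstats_df(3)
  df$p <- c(1e-9, 2e-6, 0.3)
  ss <- as_sumstats(df, quiet = TRUE)

  iv5 <- select_instruments(ss, 1e-5)
  expect_equal(nrow(iv5), 2)
  iv8 <- select_instruments(ss, 5e-8)
  expect_equal(nrow(iv8), 1)

  # ties at the cutoff are excluded (strict inequality)
  df$p <- c(1e-5, 1e-5, 0.5)
  iv_tie <- select_instruments(as_sumstats(df, quiet = TRUE), 1e-5)
  expect_equal(nrow(iv_tie), 0)

  prov <- iv_provenance(iv5)
  expect_equal(prov$stage, c("input", "p_threshold"))
  expect_equal(prov$retained[1], 3)
  expect_equal(prov$retained[2] + prov$dropped[2], prov$retained[1])
  expect_true(all(iv5$p < attr(iv5, "threshold")))
})

test_that("ld_clump follows the greedy rule, window semantics and LD fallback", {
  df <- tibble::tibble(
    snp = c("A", "B", "C"), chr = "1", pos = c(1e6, 1.05e6, 5e6),
    ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.01,
    p = c(1e-9, 1e-8, 1e-7), n = 18340)
  r2 <- diag(3); dimnames(r2) <- list(df$snp, df$snp)
  r2["A", "B"] <- r2["B", "A"] <- 0.5
  ld <- as_ld_matrix(r2)

  kept <- ld_clump(df, ld, r2_max = 0.001, window_kb = 10000)
  expect_setequal(kept$snp, c("A", "C"))

  # all pairwise r2 = 0: everything survives, ordered by p
  kept_ind <- ld_clump(df, as_ld_matrix(diag(3), snp_ids = df$snp),
                       r2_max = 0.001, window_kb = 10000)
  expect_equal(kept_ind$snp, c("A", "B", "C"))

  # correlated but 20,000 kb apart with a 10,000 kb window: both retained
  df2 <- df[1:2, ]
  df2$pos <- c(1e6, 1e6 + 2e7)
  kept_far <- ld_clump(df2, ld, r2_max = 0.001, window_kb = 10000)
  expect_setequal(kept_far$snp, c("A", "B"))

  # candidates missing from the LD matrix are independent, with a warning
  expect_warning(
    kept_miss <- ld_clump(df, as_ld_matrix(diag(1), snp_ids = "A"),
                          r2_max = 0.001, window_kb = 10000),
    "absent from LD matrix")
  expect_equal(nrow(kept_miss), 3)

  expect_error(ld_clump(df, ld, window_kb = -1),
               class = "mrflora_config_error")
})

test_that("ld_clump matches the brute-force oracle on random small instances", {
  withr::local_seed(421)
  for (rep in seq_len(120)) {
    k <- sample(2:8, 1)
    ids <- paste0("s", seq_len(k))
    df <- tibble::tibble(
      snp = ids,
      chr = as.character(sample(1:2, k, replace = TRUE)),
      pos = sample(seq(1e6, 3e7, by = 1e6), k),
      ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.01,
      # draw p from a small grid so ties are frequent
      p = sample(c(1e-9, 1e-8, 1e-7), k, replace = TRUE),
      n = 18340)
    r2 <- random_r2(ids)
    ld <- as_ld_matrix(r2)
    r2_max <- sample(c(0.001, 0.2, 0.5), 1)
    win <- sample(c(5000, 10000), 1)
    got <- ld_clump(df, ld, r2_max = r2_max, window_kb = win)$snp
    want <- oracle_clump(df, r2, r2_max, win)
    expect_identical(got, want)
  }
})

test_that("palindrome detection and removal follow the A/T-G/C rule", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_error(is_palindromic("A", "N"), class = "mrflora_domain_error")

  df <- make_sumstats_df(3)
  df$ea <- c("A", "A", "C"); df$oa <- c("T", "G", "G")
  out <- drop_palindromes(df)
  expect_equal(out$snp, df$snp[2])
  prov <- iv_provenance(out)
  expect_equal(prov$dropped[prov$stage == "palindrome_removal"], 2)

  none <- drop_palindromes(df[2, ])
  expect_equal(nrow(none), 1)
  all_pal <- drop_palindromes(df[c(1, 3), ])
  expect_equal(nrow(all_pal), 0)
})

test_that("harmonize aligns, flips or drops and is idempotent", {
  ex <- make_sumstats_df(3)
  ex$ea <- c("A", "A", "A"); ex$oa <- c("G", "G", "G")
  ou <- ex
  ou$ea <- c("A", "G", "C"); ou$oa <- c("G", "A", "T")
  ou$beta <- c(0.2, 0.2, 0.2)
  ou$eaf <- c(0.3, 0.3, 0.3)

  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 2)
  expect_equal(h$action, c("as_is", "flipped"))
  expect_equal(h$beta_y, c(0.2, -0.2))
  expect_equal(h$eaf_y, c(0.3, 0.7))
  counts <- attr(h, "harmony_counts")
  expect_equal(unname(counts), c(1L, 1L, 1L))

  # idempotence: re-harmonizing an aligned pair performs zero flips
  ou_aligned <- ex
  ou_aligned$beta <- c(0.1, 0.2, 0.3)
  h2 <- harmonize(ex, ou_aligned)
  expect_true(all(h2$action == "as_is"))
})

test_that("causal estimates are invariant to outcome allele recoding", {
  withr::local_seed(7)
  cfg <- sim_config(n_snps = 10, true_beta = 0.3, seed = 31)
  d <- simulate_mr_dataset(cfg)
  iv <- drop_palindromes(ld_clump(select_instruments(d$exposure, 1e-3), NULL))
  out1 <- d$outcome
  # globally swap effect/other alleles and negate beta on the outcome
  out2 <- out1
  out2$ea <- out1$oa
  out2$oa <- out1$ea
  out2$beta <- -out1$beta
  out2$eaf <- 1 - out1$eaf
  h1 <- harmonize(iv, out1)
  h2 <- harmonize(iv, out2)
  f1 <- mr_ivw(h1)
  f2 <- mr_ivw(h2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$se, f2$se, tolerance = 1e-12)
})

test_that("variance-explained and F formulas match direct arithmetic", {
  # worked example: beta 0.1, EAF 0.5, SE 0.01, N 10000
  expect_equal(r2_per_snp(0.1, 0.5, 0.01, 10000), 0.005 / (0.005 + 0.5),
               tolerance = 1e-12)
  # SE^2 * N = beta^2 gives exactly one half
  expect_identical(r2_per_snp(0.25, 0.3, 0.25, 1), 0.5)
  expect_equal(r2_per_snp(0, 0.5, 0.01, 10000), 0)

  expect_equal(f_statistic(0.01, 18340, 10), (18329 / 10) * (0.01 / 0.99),
               tolerance = 1e-12)
  expect_equal(f_statistic(0, 18340, 10), 0)
  expect_equal(f_statistic(0.001, 18340, 1), 18338 * (0.001 / 0.999),
               tolerance = 1e-12)
  expect_error(f_statistic(0.1, 10, 10), class = "mrflora_domain_error")
  expect_error(r2_per_snp(0.1, 1.2, 0.01, 100),
               class = "mrflora_domain_error")
})

test_that("F is monotone in r2 and in K the way weak-instrument theory says", {
  r2s <- seq(0.001, 0.2, length.out = 50)
  f_r2 <- f_statistic(r2s, 18340, 10)
  expect_true(all(diff(f_r2) > 0))
  f_k <- vapply(1:20, function(k) f_statistic(0.01, 18340, k), numeric(1))
  expect_true(all(diff(f_k) < 0))
})

test_that("instrument_strength reports per-SNP and cumulative statistics", {
  h <- make_h(bx = c(0.08, 0.06, 0.07), by = c(0.04, 0.03, 0.035))
  s <- instrument_strength(h)
  per <- tidy(s)
  expect_equal(nrow(per), 3)
  g <- glance(s)
  expect_equal(g$r2_total, sum(per$r2), tolerance = 1e-12)
  expect_equal(g$f_stat, f_statistic(g$r2_total, g$n, g$k),
               tolerance = 1e-10)
  # strong simulated instruments should clear the weak-instrument bar
  expect_false(g$weak_instrument)
})
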
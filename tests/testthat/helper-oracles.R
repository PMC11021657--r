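# Independent oracles: straightforward re-implementations used only to
# cross-check package results. They deliberately avoid the package's code
# paths (explicit sums and normal-equation solves instead of lm; a plain
# double loop instead of the vectorized clump).

oracle_ivw_fixed <- function(bx, by, sey) {
  w <- 1 / sey^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  list(beta = beta, se = 1 / sqrt(sum(w * bx^2)))
}

# two-parameter weighted least squares via the normal equations
oracle_wls_line <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
  swy <- sum(w * y); swxy <- sum(w * x * y)
  det <- sw * swx2 - swx^2
  intercept <- (swx2 * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  list(intercept = intercept, slope = slope)
}

# cumulative-weight interpolation on sorted prefix sums
oracle_weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  cum <- cumsum(w) - 0.5 * w
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] < 0.5) return(r[length(r)])
  i <- max(which(cum < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

# greedy clumping as a plain loop over a data frame, applying the documented
# ordering (p, then chr, pos, snp) and inclusive window rule
oracle_clump <- function(df, r2, r2_max, window_kb) {
  df <- df[order(df$p, df$chr, df$pos, df$snp), , drop = FALSE]
  kept <- character(0)
  alive <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    kept <- c(kept, df$snp[i])
    if (i < nrow(df)) {
      for (j in seq(i + 1, nrow(df))) {
        if (!alive[j]) next
        if (df$chr[j] != df$chr[i]) next
        if (abs(df$pos[j] - df$pos[i]) > window_kb * 1000) next
        if (r2[df$snp[i], df$snp[j]] >= r2_max) alive[j] <- FALSE
      }
    }
  }
  kept
}

# harmonized-instrument tibble built directly from effect vectors
make_h <- function(bx, by, sex = rep(0.01, length(bx)),
                   sey = rep(0.05, length(bx))) {
  k <- length(bx)
  tibble::tibble(
    snp = sprintf("rs%03d", seq_len(k)),
    chr = rep("1", k), pos = seq_len(k) * 1e5,
    ea = rep("A", k), oa = rep("G", k),
    beta_x = bx, se_x = sex, eaf_x = rep(0.3, k),
    beta_y = by, se_y = sey, eaf_y = rep(0.3, k),
    n_x = rep(18340, k), n_y = rep(111478, k),
    action = rep("as_is", k)
  )
}

# small valid sumstats tibble for I/O tests
make_sumstats_df <- function(n = 3) {
  tibble::tibble(
    snp = sprintf("rs%d", seq_len(n)),
    chr = rep("1", n), pos = seq_len(n) * 1e6,
    ea = rep("A", n), oa = rep("G", n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = seq(0.05, 0.15, length.out = n),
    se = rep(0.01, n),
    p = rep(1e-9, n),
    n = rep(18340, n)
  )
}

# random LD r2 matrix: symmetric, unit diagonal, entries in [0, 1]
random_r2 <- function(ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 1
  m
}
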
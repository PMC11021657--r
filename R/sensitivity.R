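#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_i w_i (r_i - \hat\beta)^2} over the per-SNP Wald ratios with
#' first-order inverse-variance weights, referred to a chi-square
#' distribution with K - 1 degrees of freedom. With these weights Q equals
#' the weighted residual sum of squares of the IVW regression, so the two
#' formulations agree. Heterogeneity is declared at p < 0.05.
#'
#' @param h A harmonized tibble; at least 2 SNPs.
#' @param beta Pooled estimate to test against; defaults to the
#'   fixed-effects IVW estimate.
#' @return A one-row tibble `q, df, pvalue, heterogeneous`.
#' @export
cochran_q <- function(h, beta = NULL) {
  w <- wald_ratios(h)
  k <- nrow(w)
  if (k < 2) {
    mr_abort("Cochran's Q needs at least 2 instruments",
             "insufficient_instruments")
  }
  if (is.null(beta)) {
    beta <- sum(w$weight * w$ratio) / sum(w$weight)
  }
  q <- sum(w$weight * (w$ratio - beta)^2)
  p <- pchisq(q, df = k - 1, lower.tail = FALSE)
  tibble(q = q, df = k - 1, pvalue = p, heterogeneous = p < 0.05)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Two-sided t-test (K - 2 df) of the Egger intercept against zero. A
#' nonzero intercept indicates average directional horizontal pleiotropy;
#' the decision threshold is p < 0.05. The zero-residual exact-fit edge case
#' yields SE 0 and p 0 (or 1 when the intercept itself is 0).
#'
#' @param fit Either an Egger `mr_fit` from [mr_egger()] or a harmonized
#'   tibble (in which case the fit is computed).
#' @return A one-row tibble `intercept, se, pvalue, pleiotropic`.
#' @export
egger_intercept_test <- function(fit) {
  if (!inherits(fit, "mr_fit")) fit <- mr_egger(fit)
  if (is.null(fit$intercept)) {
    mr_abort("fit has no intercept; supply an MR-Egger fit", "config_error")
  }
  tibble(intercept = fit$intercept, se = fit$intercept_se,
         pvalue = fit$intercept_p, pleiotropic = fit$intercept_p < 0.05)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator K times, omitting each instrument in turn, plus
#' the all-SNP fit (K + 1 rows). A `driver` flag marks omissions that flip
#' the sign of the estimate or move its p-value across 0.05 relative to the
#' full fit — instruments whose removal changes the qualitative conclusion.
#'
#' @param h A harmonized tibble; at least 3 SNPs.
#' @param mode IVW mode, as in [mr_ivw()].
#' @return A tibble `excluded_snp, n_snp, beta, se, pvalue, driver`; the
#'   all-SNP row has `excluded_snp = "none"`.
#' @export
leave_one_out <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  h <- as_tibble(h)
  k <- nrow(h)
  if (k < 3) {
    mr_abort("leave-one-out needs at least 3 instruments",
             "insufficient_instruments")
  }
  full <- mr_ivw(h, mode = mode)
  rows <- lapply(seq_len(k), function(i) {
    f <- mr_ivw(h[-i, , drop = FALSE], mode = mode)
    tibble(excluded_snp = h$snp[i], n_snp = k - 1L, beta = f$beta, se = f$se,
           pvalue = f$pvalue)
  })
  out <- dplyr::bind_rows(rows)
  out$driver <- sign(out$beta) != sign(full$beta) |
    (out$pvalue < 0.05) != (full$pvalue < 0.05)
  dplyr::bind_rows(out,
                   tibble(excluded_snp = "none", n_snp = k, beta = full$beta,
                          se = full$se, pvalue = full$pvalue, driver = FALSE))
}

# leave-one-out fixed-effect IVW estimates from sufficient statistics,
# vectorized over columns of by/bx matrices (K x n_sim)
loo_ivw_matrix <- function(bx, by, w) {
  s1 <- colSums(w * bx * by)
  s2 <- colSums(w * bx^2)
  t1 <- sweep(w * bx * by, 2, s1, function(a, b) b - a)
  t2 <- sweep(w * bx^2, 2, s2, function(a, b) b - a)
  t1 / t2
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based detection of horizontally pleiotropic outliers. The
#' observed residual sum of squares
#' \eqn{RSS = \sum_i (\beta_{Y,i} - \hat\beta_{(-i)} \beta_{X,i})^2}
#' uses leave-one-out fixed-effects IVW predictions so no SNP contributes to
#' its own fitted value. `n_sim` parametric replicates are drawn with
#' \eqn{\beta_X^* \sim N(\beta_X, SE_X)} and
#' \eqn{\beta_Y^* \sim N(\hat\beta_{(-i)}\beta_{X,i}, SE_Y)}; the global
#' p-value is \eqn{(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)} (the pseudo-count
#' keeps it off zero). Each SNP's squared observed residual is compared to
#' its simulated residual distribution for a per-SNP outlier p-value,
#' Bonferroni-corrected across the K instruments. When outliers are found, a
#' distortion test compares the change in the IVW estimate after removing
#' them with the distribution of changes after removing equally many random
#' instruments.
#'
#' @param h A harmonized tibble; at least 4 SNPs.
#' @param n_sim Number of simulated replicates (>= 100, default 1000).
#' @param seed Optional integer seed; with a fixed seed results are exactly
#'   reproducible.
#' @param outlier_alpha Familywise level for outlier flagging (default
#'   0.05).
#' @return An object of class `mr_presso`: a list with `rss_obs`,
#'   `global_p`, `outlier_table` (snp, residual2, pvalue, p_bonferroni,
#'   outlier), `outliers`, `distortion_p`, `beta_full`, `beta_no_outliers`,
#'   `n_sim`, `seed`. `tidy()` returns the outlier table and `glance()` the
#'   one-row summary.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  h <- as_tibble(h)
  k <- nrow(h)
  if (k < 4) {
    mr_abort("MR-PRESSO needs at least 4 instruments",
             "insufficient_instruments")
  }
  if (n_sim < 100) mr_abort("n_sim must be at least 100", "config_error")
  run <- function() {
    w <- 1 / h$se_y^2
    bx <- h$beta_x
    by <- h$beta_y
    s1 <- sum(w * bx * by)
    s2 <- sum(w * bx^2)
    b_loo <- (s1 - w * bx * by) / (s2 - w * bx^2)
    resid_obs <- by - b_loo * bx
    rss_obs <- sum(resid_obs^2)
    bx_star <- matrix(rnorm(k * n_sim, mean = bx, sd = h$se_x), nrow = k)
    by_star <- matrix(rnorm(k * n_sim, mean = b_loo * bx, sd = h$se_y),
                      nrow = k)
    b_loo_star <- loo_ivw_matrix(bx_star, by_star, w)
    resid_star <- by_star - b_loo_star * bx_star
    rss_star <- colSums(resid_star^2)
    global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
    p_snp <- (1 + rowSums(resid_star^2 >= resid_obs^2)) / (n_sim + 1)
    p_bonf <- pmin(1, p_snp * k)
    outlier <- p_bonf < outlier_alpha
    outliers <- h$snp[outlier]
    beta_full <- s1 / s2
    beta_no <- NA_real_
    distortion_p <- NA_real_
    if (any(outlier) && sum(!outlier) >= 2) {
      keep <- !outlier
      beta_no <- sum(w[keep] * bx[keep] * by[keep]) /
        sum(w[keep] * bx[keep]^2)
      d_obs <- beta_no - beta_full
      n_out <- sum(outlier)
      d_sim <- vapply(seq_len(n_sim), function(b) {
        drop <- sample.int(k, n_out)
        kp <- setdiff(seq_len(k), drop)
        sum(w[kp] * bx[kp] * by[kp]) / sum(w[kp] * bx[kp]^2) - beta_full
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
    }
    out <- list(
      rss_obs = rss_obs, global_p = global_p,
      outlier_table = tibble(snp = h$snp, residual2 = resid_obs^2,
                             pvalue = p_snp, p_bonferroni = p_bonf,
                             outlier = outlier),
      outliers = outliers, distortion_p = distortion_p,
      beta_full = beta_full, beta_no_outliers = beta_no,
      n_sim = n_sim, seed = seed, outlier_alpha = outlier_alpha
    )
    class(out) <- "mr_presso"
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outlier_table

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(rss_obs = x$rss_obs, global_p = x$global_p,
         n_outliers = length(x$outliers), distortion_p = x$distortion_p,
         beta_full = x$beta_full, beta_no_outliers = x$beta_no_outliers,
         n_sim = x$n_sim)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d sims)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_p))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Full sensitivity report for one harmonized instrument set
#'
#' Bundles the applicable diagnostics given K instruments: Cochran's Q (K
#' >= 2), the MR-Egger intercept test (K >= 3), leave-one-out (K >= 3), and
#' MR-PRESSO (K >= 4). Skipped components are `NULL` with the reason listed
#' in `skipped`.
#'
#' @param h A harmonized tibble.
#' @param mode IVW mode for leave-one-out.
#' @param presso Run the MR-PRESSO component.
#' @param presso_n_sim,seed,outlier_alpha Passed to [mr_presso()].
#' @return A list of class `sensitivity_report` with elements
#'   `heterogeneity`, `egger_intercept`, `loo`, `presso`, `skipped`.
#' @export
sensitivity_report <- function(h, mode = c("random", "fixed"), presso = TRUE,
                               presso_n_sim = 1000, seed = NULL,
                               outlier_alpha = 0.05) {
  mode <- match.arg(mode)
  h <- as_tibble(h)
  k <- nrow(h)
  out <- list(heterogeneity = NULL, egger_intercept = NULL, loo = NULL,
              presso = NULL, skipped = character())
  if (k >= 2) out$heterogeneity <- cochran_q(h)
  else out$skipped <- c(out$skipped, "heterogeneity (K < 2)")
  if (k >= 3) {
    out$egger_intercept <- egger_intercept_test(h)
    out$loo <- leave_one_out(h, mode = mode)
  } else {
    out$skipped <- c(out$skipped, "egger_intercept (K < 3)", "loo (K < 3)")
  }
  if (presso) {
    if (k >= 4) {
      out$presso <- mr_presso(h, n_sim = presso_n_sim, seed = seed,
                              outlier_alpha = outlier_alpha)
    } else {
      out$skipped <- c(out$skipped, "presso (K < 4)")
    }
  }
  class(out) <- "sensitivity_report"
  out
}
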
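#' Per-SNP Wald ratios
#'
#' The building block of the summary-data estimators: for each harmonized
#' instrument, `ratio = beta_y / beta_x` with first-order standard error
#' `se_y / |beta_x|` and inverse-variance weight `1 / ratio_se^2`.
#' Second-order standard errors
#' \eqn{\sqrt{SE_Y^2/\beta_X^2 + \beta_Y^2 SE_X^2/\beta_X^4}} are available
#' by flag. Instruments with `beta_x == 0` are excluded with a warning.
#'
#' @param h A harmonized tibble from [harmonize()].
#' @param second_order Use second-order ratio standard errors.
#' @return A tibble with columns `snp, ratio, ratio_se, weight`.
#' @export
wald_ratios <- function(h, second_order = FALSE) {
  h <- as_tibble(h)
  zero <- h$beta_x == 0
  if (all(zero)) {
    mr_abort("all exposure effects are zero; Wald ratios undefined",
             "degenerate_instruments")
  }
  if (any(zero)) {
    warn(sprintf("wald_ratios: excluding %d SNP(s) with zero exposure effect",
                 sum(zero)))
    h <- h[!zero, , drop = FALSE]
  }
  se <- if (second_order) {
    sqrt(h$se_y^2 / h$beta_x^2 + h$beta_y^2 * h$se_x^2 / h$beta_x^4)
  } else {
    h$se_y / abs(h$beta_x)
  }
  tibble(snp = h$snp, ratio = h$beta_y / h$beta_x, ratio_se = se,
         weight = 1 / se^2)
}

new_mr_fit <- function(method, beta, se, pvalue, n_snp, notes = character(),
                       extra = list()) {
  ci_low <- beta - 1.96 * se
  ci_high <- beta + 1.96 * se
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = ci_low, ci_high = ci_high,
                or_ = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
                pvalue = pvalue, n_snp = n_snp, notes = notes), extra)
  class(out) <- "mr_fit"
  out
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d SNPs): beta = %.4g (SE %.4g), OR = %.3g [%.3g, %.3g], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or_, x$or_low, x$or_high,
              x$pvalue))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  tibble(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
         ci_low = x$ci_low, ci_high = x$ci_high,
         or = x$or_, or_low = x$or_low, or_high = x$or_high,
         pvalue = x$pvalue)
}

#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  out <- tidy(x)
  if (!is.null(x$intercept)) {
    out$intercept <- x$intercept
    out$intercept_se <- x$intercept_se
    out$intercept_p <- x$intercept_p
  }
  if (!is.null(x$q)) {
    out$q <- x$q
  }
  out
}

norm_p <- function(z) 2 * pnorm(-abs(z))

#' Inverse-variance-weighted estimator
#'
#' The primary causal estimator: weighted least squares of outcome effects on
#' exposure effects through the origin with weights `1/se_y^2`. The point
#' estimate is \eqn{\sum w \beta_X \beta_Y / \sum w \beta_X^2}; the
#' fixed-effects standard error is \eqn{1/\sqrt{\sum w \beta_X^2}}, and the
#' default multiplicative random-effects model scales it by
#' \eqn{\max(1, \sqrt{Q/(K-1)})} where Q is Cochran's heterogeneity statistic
#' (so it reduces to fixed effects under homogeneity). P-values are from the
#' standard normal.
#'
#' @param h A harmonized tibble; at least 2 SNPs.
#' @param mode `"random"` (default) or `"fixed"`.
#' @return An `mr_fit` with extra components `q` (Cochran's Q on the fit
#'   scale) and `mode`.
#' @export
mr_ivw <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  h <- as_tibble(h)
  k <- nrow(h)
  if (k < 2) {
    mr_abort("IVW needs at least 2 instruments", "insufficient_instruments")
  }
  w <- 1 / h$se_y^2
  fit <- lm(beta_y ~ 0 + beta_x, data = h, weights = w)
  beta <- unname(coef(fit)[1])
  se_fixed <- 1 / sqrt(sum(w * h$beta_x^2))
  q <- sum(w * (h$beta_y - beta * h$beta_x)^2)
  scale <- if (mode == "random") max(1, sqrt(q / (k - 1))) else 1
  se <- se_fixed * scale
  new_mr_fit("ivw", beta, se, norm_p(beta / se), k,
             notes = paste0("ivw_mode=", mode),
             extra = list(q = q, mode = mode))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept,
#' weights `1/se_y^2`, after orienting all exposure effects non-negative
#' (flipping the paired outcome effect in tandem). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Standard errors use the residual scale floored at
#' 1 (never deflated below the fixed-effect scale); p-values are from the t
#' distribution with K - 2 degrees of freedom.
#'
#' @param h A harmonized tibble; at least 3 SNPs.
#' @return An `mr_fit` for the slope with extra components `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(h) {
  h <- as_tibble(h)
  k <- nrow(h)
  if (k < 3) {
    mr_abort("MR-Egger needs at least 3 instruments",
             "insufficient_instruments")
  }
  s <- ifelse(h$beta_x < 0, -1, 1)
  bx <- abs(h$beta_x)
  by <- h$beta_y * s
  w <- 1 / h$se_y^2
  fit <- lm(by ~ bx, weights = w)
  # summary.lm warns on an exactly collinear fit; that case is handled below
  sm <- suppressWarnings(summary(fit))
  est <- unname(coef(fit))
  sigma <- sm$sigma
  if (!is.finite(sigma) || sigma < 1e-8) {
    # exact fit: sampling variability is zero on the weighted scale
    se_slope <- 0
    se_int <- 0
  } else {
    # flooring the residual scale at 1 never understates uncertainty
    se_slope <- sm$coefficients["bx", "Std. Error"] / min(sigma, 1)
    se_int <- sm$coefficients["(Intercept)", "Std. Error"] / min(sigma, 1)
  }
  t_p <- function(b, se) {
    if (se == 0) return(if (abs(b) < 1e-10) 1 else 0)
    2 * pt(-abs(b / se), df = k - 2)
  }
  new_mr_fit("egger", est[2], se_slope, t_p(est[2], se_slope), k,
             extra = list(intercept = est[1], intercept_se = se_int,
                          intercept_p = t_p(est[1], se_int)))
}

# Weighted median of ratios by linear interpolation of cumulative weights:
# order the ratios, accumulate normalized weights minus half the own weight,
# and interpolate the ratio at cumulative weight one half.
weighted_median_est <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  cw <- cumsum(w) - 0.5 * w
  if (all(cw >= 0.5)) return(r[1])
  if (all(cw < 0.5)) return(r[length(r)])
  below <- max(which(cw < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cw[below]) /
    (cw[below + 1] - cw[below])
}

boot_se <- function(ratio, ratio_se, n_boot, seed, estimator) {
  run <- function() {
    k <- length(ratio)
    reps <- vapply(seq_len(n_boot), function(b) {
      estimator(rnorm(k, ratio, ratio_se))
    }, numeric(1))
    stats::sd(reps)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Weighted-median estimator
#'
#' Consistent when at least half of the instrument weight comes from valid
#' instruments. Ratios are ordered and the estimate interpolated at
#' cumulative normalized inverse-variance weight 0.5; the standard error
#' comes from a parametric bootstrap (ratios resampled from
#' `normal(ratio_i, ratio_se_i)`, weights held fixed).
#'
#' @param h A harmonized tibble; at least 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_fit`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  w <- wald_ratios(h)
  k <- nrow(w)
  if (k < 3) {
    mr_abort("weighted median needs at least 3 instruments",
             "insufficient_instruments")
  }
  beta <- weighted_median_est(w$ratio, w$weight)
  se <- boot_se(w$ratio, w$ratio_se, n_boot, seed,
                function(r) weighted_median_est(r, w$weight))
  p <- if (se == 0) {
    if (beta == 0) 1 else 0
  } else {
    norm_p(beta / se)
  }
  new_mr_fit("weighted_median", beta, se, p, k,
             notes = paste0("n_boot=", n_boot))
}

mode_bandwidth <- function(ratio, phi) {
  k <- length(ratio)
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.34
  h <- phi * 0.9 * min(s, iqr) * k^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # degenerate spread: fall back to the sd-based rule, or 0 if all equal
    h <- if (is.finite(s) && s > 0) phi * 0.9 * s * k^(-1 / 5) else 0
  }
  h
}

mode_point_est <- function(ratio, weight, phi) {
  h <- mode_bandwidth(ratio, phi)
  if (h == 0) return(ratio[1])
  w <- weight / sum(weight)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  # weighted normal-kernel density on the grid (K x 512, one dnorm call)
  dens <- colSums(w * dnorm(outer(ratio, grid, "-") / h)) / h
  top <- which(dens >= max(dens) - 1e-12 * max(dens))
  if (length(top) > 1) {
    # break ties toward the weighted mean of the ratios
    wm <- sum(w * ratio)
    top <- top[which.min(abs(grid[top] - wm))]
  }
  grid[top]
}

#' Mode-based estimator (simple and weighted)
#'
#' The kernel-density mode of the Wald-ratio distribution, consistent when
#' the largest cluster of instruments is valid. Bandwidth follows the
#' modified Silverman rule \eqn{\phi \times 0.9 \min(sd, IQR/1.34)
#' K^{-1/5}}; the density (equal weights for the simple mode, normalized
#' inverse-variance weights for the weighted mode) is evaluated on a 512-point
#' grid spanning the ratios plus three bandwidths, and the estimate is the
#' grid argmax (ties broken toward the weighted mean). Standard error by
#' parametric bootstrap as in [mr_weighted_median()]. When all ratios
#' coincide the estimate is that common value with zero standard error.
#'
#' @param h A harmonized tibble; at least 3 SNPs.
#' @param weighting `"weighted"` or `"simple"`.
#' @param phi Bandwidth inflation factor (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return An `mr_fit` with method `weighted_mode` or `simple_mode`.
#' @export
mr_mode <- function(h, weighting = c("weighted", "simple"), phi = 1,
                    n_boot = 1000, seed = NULL) {
  weighting <- match.arg(weighting)
  if (!is.numeric(phi) || phi <= 0) {
    mr_abort("phi must be positive", "config_error")
  }
  w <- wald_ratios(h)
  k <- nrow(w)
  if (k < 3) {
    mr_abort("mode estimator needs at least 3 instruments",
             "insufficient_instruments")
  }
  wt <- if (weighting == "simple") rep(1, k) else w$weight
  beta <- mode_point_est(w$ratio, wt, phi)
  if (diff(range(w$ratio)) == 0) {
    se <- 0
  } else {
    se <- boot_se(w$ratio, w$ratio_se, n_boot, seed,
                  function(r) mode_point_est(r, wt, phi))
  }
  p <- if (se == 0) {
    if (beta == 0) 1 else 0
  } else {
    norm_p(beta / se)
  }
  new_mr_fit(paste0(weighting, "_mode"), beta, se, p, k,
             notes = c(paste0("phi=", phi), paste0("n_boot=", n_boot)))
}

#' Wald-type estimator
#'
#' The inverse-variance-weighted mean of the per-SNP Wald ratios using
#' first-order weights. For a single instrument this is the classic Wald
#' ratio; for several it provides a ratio-scale estimate usable when the
#' regression-based methods are unavailable.
#'
#' @param h A harmonized tibble; at least 1 SNP with nonzero exposure effect.
#' @return An `mr_fit` with method `wald`.
#' @export
mr_wald <- function(h) {
  w <- wald_ratios(h)
  beta <- sum(w$weight * w$ratio) / sum(w$weight)
  se <- 1 / sqrt(sum(w$weight))
  new_mr_fit("wald", beta, se, norm_p(beta / se), nrow(w))
}

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param beta Log-odds causal estimate.
#' @param se Standard error, >= 0.
#' @return A tibble with columns `or`, `or_low`, `or_high` where
#'   `or = exp(beta)` and the bounds are `exp(beta -+ 1.96 se)`.
#' @export
beta_to_or <- function(beta, se) {
  if (any(se < 0)) mr_abort("se must be non-negative", "domain_error")
  tibble(or = exp(beta), or_low = exp(beta - 1.96 * se),
         or_high = exp(beta + 1.96 * se))
}

#' Run every applicable causal estimator
#'
#' Dispatches on the number of harmonized instruments K: with one SNP only
#' the Wald ratio is computed; with two, IVW plus the Wald-type ratio
#' estimate; with three or more, all five methods (IVW, MR-Egger, weighted
#' median, weighted mode, simple mode). IVW is flagged as the primary method
#' in the output.
#'
#' @param h A harmonized tibble.
#' @param ivw_mode `"random"` or `"fixed"`.
#' @param phi Mode bandwidth factor.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Optional integer seed for the bootstraps.
#' @return A tibble with one row per method (`method, primary, n_snp, beta,
#'   se, ci_low, ci_high, or, or_low, or_high, pvalue`) plus Egger intercept
#'   columns where applicable; zero rows (with a `reason` attribute) when K
#'   is 0.
#' @export
run_all_methods <- function(h, ivw_mode = c("random", "fixed"), phi = 1,
                            n_boot = 1000, seed = NULL) {
  ivw_mode <- match.arg(ivw_mode)
  h <- as_tibble(h)
  h <- h[h$beta_x != 0, , drop = FALSE]
  k <- nrow(h)
  if (k == 0) {
    out <- tibble(method = character(), primary = logical(),
                  n_snp = integer(), beta = numeric(), se = numeric(),
                  ci_low = numeric(), ci_high = numeric(), or = numeric(),
                  or_low = numeric(), or_high = numeric(), pvalue = numeric())
    attr(out, "reason") <- "no instruments"
    return(out)
  }
  fits <- list()
  if (k == 1) {
    fits$wald <- mr_wald(h)
  } else {
    fits$ivw <- mr_ivw(h, mode = ivw_mode)
    if (k == 2) {
      fits$wald <- mr_wald(h)
    } else {
      fits$egger <- mr_egger(h)
      fits$weighted_median <- mr_weighted_median(h, n_boot = n_boot,
                                                 seed = seed)
      fits$weighted_mode <- mr_mode(h, "weighted", phi = phi,
                                    n_boot = n_boot, seed = seed)
      fits$simple_mode <- mr_mode(h, "simple", phi = phi,
                                  n_boot = n_boot, seed = seed)
    }
  }
  out <- dplyr::bind_rows(lapply(fits, function(f) {
    row <- tidy(f)
    if (!is.null(f$intercept)) {
      row$egger_intercept <- f$intercept
      row$egger_intercept_se <- f$intercept_se
      row$egger_intercept_p <- f$intercept_p
    }
    row
  }))
  out$primary <- out$method == "ivw" | (k == 1 & out$method == "wald")
  dplyr::relocate(out, "method", "primary", "n_snp")
}
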
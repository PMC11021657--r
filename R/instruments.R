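#' Instrument-set provenance
#'
#' Instrument tibbles carry a `provenance` attribute: a tibble with one row
#' per filtering stage recording `stage`, `retained` and `dropped` counts.
#' Counts are monotone non-increasing across stages and satisfy
#' `input = retained + dropped` at each stage.
#'
#' @param x An instrument tibble produced by [select_instruments()] and
#'   downstream filters.
#' @return The provenance tibble (or `NULL` if absent).
#' @export
iv_provenance <- function(x) attr(x, "provenance")

add_provenance <- function(x, stage, n_before) {
  prov <- attr(x, "provenance") %||% tibble(stage = character(),
                                            retained = integer(),
                                            dropped = integer())
  prov <- dplyr::bind_rows(prov, tibble(stage = stage,
                                        retained = nrow(x),
                                        dropped = n_before - nrow(x)))
  attr(x, "provenance") <- prov
  x
}

#' Select candidate instruments by p-value threshold
#'
#' Retains records with `p` strictly below `threshold` (ties at the cutoff
#' are excluded). An empty result is not an error; the pipeline decides how
#' to react (typically by falling back to a relaxed threshold).
#'
#' @param stats A summary-statistics tibble ([as_sumstats()]).
#' @param threshold P-value cutoff in (0, 1); genome-wide significance 5e-8
#'   is the conventional primary choice, 1e-5 the relaxed locus-wide one.
#' @return The retained records with a `provenance` attribute and a
#'   `threshold` attribute recording the cutoff applied.
#' @export
select_instruments <- function(stats, threshold = 5e-8) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    mr_abort("threshold must be a single value in (0, 1)", "config_error")
  }
  n0 <- nrow(stats)
  out <- dplyr::filter(as_tibble(stats), .data$p < threshold)
  out <- add_provenance(out, "input", n0)
  # the input row records the starting count; re-mark retained for clarity
  attr(out, "provenance")$dropped[1] <- 0L
  attr(out, "provenance")$retained[1] <- n0
  out <- add_provenance(out, "p_threshold", n0)
  attr(out, "threshold") <- threshold
  for (a in c("trait_name", "trait_type", "n_cases", "n_controls")) {
    attr(out, a) <- attr(stats, a)
  }
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Standard index-SNP clumping: candidates are ranked by ascending p-value
#' (ties broken by chromosome, position, then identifier so output is
#' deterministic); the best remaining SNP is accepted and every remaining SNP
#' on the same chromosome within `window_kb` kilobases whose r-squared with
#' it is at least `r2_max` is discarded; repeat until exhausted.
#'
#' The window is inclusive: `|pos_i - pos_j| <= window_kb * 1000`. Candidates
#' absent from the LD matrix are treated as independent (r² = 0) with a
#' warning, since a complete panel matrix is not always available.
#'
#' @param x An instrument tibble.
#' @param ld An `ld_matrix`, or `NULL` to treat all pairs as independent.
#' @param r2_max r-squared threshold at or above which a neighbour is
#'   discarded (0.001 forward, 0.1 reverse in the headline analysis).
#' @param window_kb Clumping window in kilobases (default 10,000).
#' @return The index SNPs, provenance updated with an `ld_clump` stage.
#' @export
ld_clump <- function(x, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  if (!is.numeric(window_kb) || window_kb < 0) {
    mr_abort("window_kb must be non-negative", "config_error")
  }
  if (!is.numeric(r2_max) || r2_max < 0 || r2_max > 1) {
    mr_abort("r2_max must lie in [0, 1]", "config_error")
  }
  n0 <- nrow(x)
  if (n0 == 0) return(add_provenance(x, "ld_clump", 0L))
  ord <- order(x$p, x$chr, x$pos, x$snp)
  xs <- x[ord, , drop = FALSE]
  if (!is.null(ld)) {
    missing_ld <- setdiff(xs$snp, rownames(ld))
    if (length(missing_ld)) {
      warn(sprintf("ld_clump: %d candidate(s) absent from LD matrix treated as independent",
                   length(missing_ld)))
    }
  }
  # row index of each candidate in the LD matrix (NA: assume independent)
  ld_idx <- if (is.null(ld)) rep(NA_integer_, nrow(xs)) else
    match(xs$snp, rownames(ld))
  keep <- character(0)
  remaining <- seq_len(nrow(xs))
  while (length(remaining)) {
    i <- remaining[1]
    keep <- c(keep, xs$snp[i])
    remaining <- remaining[-1]
    if (length(remaining)) {
      same_chr <- xs$chr[remaining] == xs$chr[i]
      in_window <- abs(xs$pos[remaining] - xs$pos[i]) <= window_kb * 1000
      r2 <- numeric(length(remaining))
      if (!is.na(ld_idx[i])) {
        have <- !is.na(ld_idx[remaining])
        r2[have] <- ld[ld_idx[remaining][have], ld_idx[i]]
      }
      drop <- same_chr & in_window & r2 >= r2_max
      remaining <- remaining[!drop]
    }
  }
  out <- xs[match(keep, xs$snp), , drop = FALSE]
  attrs <- attributes(x)
  for (a in setdiff(names(attrs), c("names", "row.names", "class"))) {
    attr(out, a) <- attrs[[a]]
  }
  add_provenance(out, "ld_clump", n0)
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has alleles A/T or C/G: the pair is
#' its own reverse complement, so strand cannot be resolved from alleles
#' alone.
#'
#' @param ea,oa Effect and other allele, single bases in A/C/G/T
#'   (vectorized).
#' @return Logical vector.
#' @examples
#' is_palindromic(c("A", "G"), c("T", "C"))
#' @export
is_palindromic <- function(ea, oa) {
  ea <- toupper(ea); oa <- toupper(oa)
  if (any(!ea %in% valid_bases) || any(!oa %in% valid_bases)) {
    mr_abort("alleles must be single bases A, C, G or T", "domain_error")
  }
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Remove palindromic SNPs from an instrument set
#'
#' Palindromic instruments are removed unconditionally, with no
#' frequency-based strand rescue.
#'
#' @param x An instrument tibble.
#' @return The non-palindromic records, provenance updated.
#' @export
drop_palindromes <- function(x) {
  n0 <- nrow(x)
  if (n0 == 0) return(add_provenance(x, "palindrome_removal", 0L))
  keep <- !is_palindromic(x$ea, x$oa)
  out <- x[keep, , drop = FALSE]
  attrs <- attributes(x)
  for (a in setdiff(names(attrs), c("names", "row.names", "class"))) {
    attr(out, a) <- attrs[[a]]
  }
  add_provenance(out, "palindrome_removal", n0)
}

#' Harmonize exposure instruments with outcome associations
#'
#' Inner-joins exposure instruments to the outcome table on SNP identifier
#' and aligns outcome effects to the exposure's effect allele: identical
#' allele pairs pass through (`as_is`); swapped pairs have the outcome beta
#' negated and frequency reflected (`flipped`); irreconcilable pairs are
#' dropped. Palindromes are assumed already removed upstream, so no strand
#' inference is attempted.
#'
#' @param exposure An instrument tibble (exposure side).
#' @param outcome A summary-statistics tibble (outcome side).
#' @return A tibble with one row per retained SNP and columns `snp, chr, pos,
#'   ea, oa, beta_x, se_x, eaf_x, beta_y, se_y, eaf_y, n_x, n_y, action`;
#'   attribute `harmony_counts` tallies `as_is`/`flipped`/`dropped`.
#' @export
harmonize <- function(exposure, outcome) {
  exposure <- as_tibble(exposure)
  outcome <- as_tibble(outcome)
  m <- match(exposure$snp, outcome$snp)
  keep <- !is.na(m)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[m[keep], , drop = FALSE]
  j <- tibble(snp = ex$snp, chr = ex$chr, pos = ex$pos,
              ea = ex$ea, oa = ex$oa,
              beta_x = ex$beta, se_x = ex$se, eaf_x = ex$eaf, n_x = ex$n,
              ea_y = ou$ea, oa_y = ou$oa,
              beta_y = ou$beta, se_y = ou$se, eaf_y = ou$eaf, n_y = ou$n)
  if (nrow(j) == 0) {
    counts <- c(as_is = 0L, flipped = 0L, dropped = 0L)
    out <- tibble(snp = character(), chr = character(), pos = numeric(),
                  ea = character(), oa = character(),
                  beta_x = numeric(), se_x = numeric(), eaf_x = numeric(),
                  beta_y = numeric(), se_y = numeric(), eaf_y = numeric(),
                  n_x = numeric(), n_y = numeric(), action = character())
    attr(out, "harmony_counts") <- counts
    return(out)
  }
  same <- j$ea == j$ea_y & j$oa == j$oa_y
  swapped <- j$ea == j$oa_y & j$oa == j$ea_y
  action <- rep("dropped", nrow(j))
  action[swapped] <- "flipped"
  action[same] <- "as_is"
  j$beta_y[swapped] <- -j$beta_y[swapped]
  j$eaf_y[swapped] <- 1 - j$eaf_y[swapped]
  j$action <- action
  counts <- c(as_is = sum(same), flipped = sum(swapped),
              dropped = sum(action == "dropped"))
  out <- j[action != "dropped",
           c("snp", "chr", "pos", "ea", "oa", "beta_x", "se_x", "eaf_x",
             "beta_y", "se_y", "eaf_y", "n_x", "n_y", "action"),
           drop = FALSE]
  attr(out, "harmony_counts") <- counts
  out
}

#' Per-SNP variance explained in the exposure
#'
#' \deqn{R^2 = \frac{2\beta^2 \mathrm{EAF}(1-\mathrm{EAF})}
#'   {2\beta^2 \mathrm{EAF}(1-\mathrm{EAF}) + 2\,\mathrm{SE}^2 N\,
#'    \mathrm{EAF}(1-\mathrm{EAF})}}
#' which simplifies to \eqn{\beta^2 / (\beta^2 + SE^2 N)} but is computed in
#' the stated form. Vectorized.
#'
#' @param beta Per-allele effect estimate.
#' @param eaf Effect-allele frequency in (0, 1).
#' @param se Standard error of `beta`, > 0.
#' @param n Exposure GWAS sample size, > 0.
#' @return Variance explained, in \eqn{[0, 1)}.
#' @export
r2_per_snp <- function(beta, eaf, se, n) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    mr_abort("eaf must lie strictly in (0, 1)", "domain_error")
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    mr_abort("se must be positive", "domain_error")
  }
  if (any(!is.finite(n)) || any(n <= 0)) {
    mr_abort("n must be positive", "domain_error")
  }
  num <- 2 * beta^2 * eaf * (1 - eaf)
  den <- num + 2 * se^2 * n * eaf * (1 - eaf)
  num / den
}

#' Instrument-strength F-statistic
#'
#' \deqn{F = \frac{N - K - 1}{K} \times \frac{R^2}{1 - R^2}}
#' where \eqn{R^2} is the (cumulative) variance explained by the K selected
#' SNPs and N the exposure sample size. F > 10 conventionally indicates that
#' weak-instrument bias is unlikely.
#'
#' @param r2 Variance explained, in \eqn{[0, 1)} (vectorized).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of SNPs, >= 1.
#' @return The F-statistic (vectorized over `r2`).
#' @export
f_statistic <- function(r2, n, k) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1)) {
    mr_abort("r2 must lie in [0, 1)", "domain_error")
  }
  if (any(k < 1) || any(n <= k + 1)) {
    mr_abort("need n > k + 1 and k >= 1", "domain_error")
  }
  (n - k - 1) / k * r2 / (1 - r2)
}

#' Instrument-strength report for a set of instruments
#'
#' Computes per-SNP variance explained and per-SNP F (with K = 1), the
#' cumulative R-squared, and the cumulative F-statistic over the K retained
#' instruments. F uses the minimum per-SNP sample size of the set, a
#' conservative choice when per-SNP N varies. A weak-instrument flag is set
#' whenever the cumulative F (or any per-SNP F) fails to exceed 10.
#'
#' @param x An instrument tibble or harmonized tibble; exposure columns are
#'   used (`beta`/`beta_x`, `se`/`se_x`, `eaf`/`eaf_x`, `n`/`n_x`).
#' @return An object of class `instrument_strength`; `tidy()` returns the
#'   per-SNP table, `glance()` the one-row summary (`k`, `n`, `r2_total`,
#'   `f_stat`, `f_min`, `weak_instrument`).
#' @export
instrument_strength <- function(x) {
  x <- as_tibble(x)
  pick <- function(a, b) if (a %in% names(x)) x[[a]] else x[[b]]
  beta <- pick("beta_x", "beta")
  se <- pick("se_x", "se")
  eaf <- pick("eaf_x", "eaf")
  n <- pick("n_x", "n")
  k <- length(beta)
  if (k == 0) mr_abort("no instruments", "empty_input")
  r2 <- r2_per_snp(beta, eaf, se, n)
  n_use <- min(n)
  per_snp <- tibble(snp = x$snp, r2 = r2,
                    f = f_statistic(r2, n, 1L))
  r2_total <- sum(r2)
  f_cum <- f_statistic(r2_total, n_use, k)
  out <- list(per_snp = per_snp, k = k, n = n_use, r2_total = r2_total,
              f_stat = f_cum, f_min = min(per_snp$f),
              weak_instrument = f_cum <= 10 || min(per_snp$f) <= 10)
  class(out) <- "instrument_strength"
  out
}

#' @method tidy instrument_strength
#' @export
tidy.instrument_strength <- function(x, ...) x$per_snp

#' @method glance instrument_strength
#' @export
glance.instrument_strength <- function(x, ...) {
  tibble(k = x$k, n = x$n, r2_total = x$r2_total, f_stat = x$f_stat,
         f_min = x$f_min, weak_instrument = x$weak_instrument)
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: K = %d, N = %g, R2 = %.4g, F = %.4g%s\n",
              x$k, x$n, x$r2_total, x$f_stat,
              if (x$weak_instrument) " [weak-instrument flag]" else ""))
  invisible(x)
}
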
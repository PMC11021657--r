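#' Analysis configuration
#'
#' Holds every tunable of the bidirectional analysis, with defaults matching
#' the headline study settings: primary instrument threshold 5e-8 with a
#' relaxed 1e-5 fallback when fewer than `min_instruments` survive, LD
#' clumping at r-squared 0.001 (forward) / 0.1 (reverse) in a 10,000 kb
#' window, significance at raw IVW p < 0.05 with no multiplicity correction
#' (Benjamini-Hochberg available by flag), multiplicative random-effects
#' IVW, and MR-PRESSO run in the reverse direction.
#'
#' @param p_threshold Primary instrument p-value cutoff.
#' @param p_threshold_relaxed Fallback cutoff.
#' @param min_instruments Fewer surviving instruments than this triggers the
#'   fallback.
#' @param clump_r2_forward,clump_r2_reverse Direction-specific clumping
#'   r-squared thresholds.
#' @param clump_window_kb Clumping window (kb).
#' @param alpha Significance level applied to the primary (IVW) p-value.
#' @param ivw_mode `"random"` or `"fixed"`.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param presso_directions Where to run MR-PRESSO: `"reverse"` (default),
#'   `"both"`, or `"none"`.
#' @param multiplicity `"none"` (default) or `"bh"`.
#' @param seed Optional integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(p_threshold = 5e-8, p_threshold_relaxed = 1e-5,
                       min_instruments = 3, clump_r2_forward = 0.001,
                       clump_r2_reverse = 0.1, clump_window_kb = 10000,
                       alpha = 0.05, ivw_mode = c("random", "fixed"),
                       n_boot = 1000, presso_n_sim = 1000,
                       presso_directions = c("reverse", "both", "none"),
                       multiplicity = c("none", "bh"), seed = NULL) {
  ivw_mode <- match.arg(ivw_mode)
  presso_directions <- match.arg(presso_directions)
  multiplicity <- match.arg(multiplicity)
  for (th in c(p_threshold, p_threshold_relaxed, alpha)) {
    if (th <= 0 || th >= 1) {
      mr_abort("thresholds must lie in (0, 1)", "config_error")
    }
  }
  structure(list(p_threshold = p_threshold,
                 p_threshold_relaxed = p_threshold_relaxed,
                 min_instruments = min_instruments,
                 clump_r2_forward = clump_r2_forward,
                 clump_r2_reverse = clump_r2_reverse,
                 clump_window_kb = clump_window_kb, alpha = alpha,
                 ivw_mode = ivw_mode, n_boot = n_boot,
                 presso_n_sim = presso_n_sim,
                 presso_directions = presso_directions,
                 multiplicity = multiplicity, seed = seed),
            class = "run_config")
}

empty_direction <- function(direction, exposure_name, outcome_name, reason) {
  structure(list(direction = direction, exposure_name = exposure_name,
                 outcome_name = outcome_name, instruments = NULL,
                 strength = NULL, harmonized = NULL,
                 estimates = run_all_methods(tibble(beta_x = numeric(0),
                                                    beta_y = numeric(0))),
                 sensitivity = NULL, significant = FALSE,
                 threshold_used = NA_real_, fallback = FALSE,
                 reason = reason),
            class = "mr_direction")
}

#' Run one direction of the MR analysis
#'
#' Applies, in order: p-value thresholding at the primary cutoff (falling
#' back to the relaxed cutoff, with a provenance flag, when fewer than
#' `cfg$min_instruments` survive), greedy LD clumping at the
#' direction-appropriate r-squared, palindromic-SNP removal, allele
#' harmonization against the outcome, instrument-strength statistics, every
#' applicable causal estimator, and the sensitivity suite.
#'
#' @param exposure Exposure summary-statistics tibble.
#' @param outcome Outcome summary-statistics tibble.
#' @param ld An `ld_matrix` (or `NULL` for an independence assumption).
#' @param cfg A [run_config()].
#' @param direction `"forward"` or `"reverse"`.
#' @param seed Optional seed overriding `cfg$seed` for this run's
#'   stochastic components (bootstraps, MR-PRESSO).
#' @return A list of class `mr_direction` with elements `direction`,
#'   `exposure_name`, `outcome_name`, `instruments` (tibble + provenance),
#'   `strength`, `harmonized`, `estimates` (per-method tibble),
#'   `sensitivity`, `significant` (primary IVW p < alpha), `threshold_used`,
#'   `fallback`, `reason`.
#' @export
run_direction <- function(exposure, outcome, ld = NULL, cfg = run_config(),
                          direction = c("forward", "reverse"), seed = NULL) {
  direction <- match.arg(direction)
  seed <- seed %||% cfg$seed
  exposure_name <- attr(exposure, "trait_name") %||% "exposure"
  outcome_name <- attr(outcome, "trait_name") %||% "outcome"
  if (is.null(exposure) || nrow(exposure) == 0) {
    return(empty_direction(direction, exposure_name, outcome_name,
                           "no instruments"))
  }
  iv <- select_instruments(exposure, cfg$p_threshold)
  fallback <- FALSE
  if (nrow(iv) < cfg$min_instruments) {
    iv <- select_instruments(exposure, cfg$p_threshold_relaxed)
    attr(iv, "provenance")$stage[2] <- "p_threshold_relaxed"
    fallback <- TRUE
  }
  r2_max <- if (direction == "forward") cfg$clump_r2_forward else
    cfg$clump_r2_reverse
  iv <- ld_clump(iv, ld, r2_max = r2_max, window_kb = cfg$clump_window_kb)
  iv <- drop_palindromes(iv)
  if (nrow(iv) == 0) {
    res <- empty_direction(direction, exposure_name, outcome_name,
                           "no instruments after filters")
    res$instruments <- iv
    res$threshold_used <- attr(iv, "threshold")
    res$fallback <- fallback
    return(res)
  }
  h <- harmonize(iv, outcome)
  if (nrow(h) == 0) {
    res <- empty_direction(direction, exposure_name, outcome_name,
                           "no instruments after harmonization")
    res$instruments <- iv
    res$threshold_used <- attr(iv, "threshold")
    res$fallback <- fallback
    return(res)
  }
  strength <- instrument_strength(h)
  estimates <- run_all_methods(h, ivw_mode = cfg$ivw_mode,
                               n_boot = cfg$n_boot, seed = seed)
  presso_here <- cfg$presso_directions == "both" ||
    (cfg$presso_directions == "reverse" && direction == "reverse")
  sens <- sensitivity_report(h, mode = cfg$ivw_mode, presso = presso_here,
                             presso_n_sim = cfg$presso_n_sim, seed = seed)
  primary <- estimates[estimates$primary, , drop = FALSE]
  significant <- nrow(primary) > 0 && primary$pvalue[1] < cfg$alpha
  structure(list(direction = direction, exposure_name = exposure_name,
                 outcome_name = outcome_name, instruments = iv,
                 strength = strength, harmonized = h, estimates = estimates,
                 sensitivity = sens, significant = significant,
                 threshold_used = attr(iv, "threshold"),
                 fallback = fallback, reason = NA_character_),
            class = "mr_direction")
}

#' @export
print.mr_direction <- function(x, ...) {
  cat(sprintf("MR %s: %s -> %s\n", x$direction, x$exposure_name,
              x$outcome_name))
  if (!is.na(x$reason %||% NA)) cat("  ", x$reason, "\n")
  if (nrow(x$estimates)) {
    print(dplyr::select(x$estimates, "method", "n_snp", "beta", "se",
                        "or", "pvalue"))
  }
  invisible(x)
}

#' @method tidy mr_direction
#' @export
tidy.mr_direction <- function(x, ...) {
  est <- x$estimates
  if (nrow(est) == 0) return(est)
  dplyr::mutate(est, exposure = x$exposure_name, outcome = x$outcome_name,
                direction = x$direction, .before = 1)
}

#' @method glance mr_direction
#' @export
glance.mr_direction <- function(x, ...) {
  primary <- x$estimates[x$estimates$primary, , drop = FALSE]
  tibble(exposure = x$exposure_name, outcome = x$outcome_name,
         direction = x$direction,
         n_snp = if (nrow(primary)) primary$n_snp[1] else 0L,
         beta = if (nrow(primary)) primary$beta[1] else NA_real_,
         se = if (nrow(primary)) primary$se[1] else NA_real_,
         or = if (nrow(primary)) primary$or[1] else NA_real_,
         pvalue = if (nrow(primary)) primary$pvalue[1] else NA_real_,
         significant = x$significant,
         threshold_used = x$threshold_used, fallback = x$fallback,
         reason = x$reason)
}

#' Run the bidirectional panel analysis
#'
#' Forward MR of every exposure taxon on the outcome; reverse MR (outcome as
#' exposure) only for taxa whose forward primary (IVW) p-value falls below
#' `cfg$alpha`, mirroring the gated bidirectional design. Per-taxon seeds
#' are derived deterministically from `cfg$seed`.
#'
#' @param exposures Named list of exposure summary-statistics tibbles (one
#'   per taxon), or the output of [simulate_taxa_panel()] (in which case
#'   `outcome` and `ld` default to its components).
#' @param outcome Outcome summary-statistics tibble.
#' @param ld An `ld_matrix` covering the union panel (or `NULL`).
#' @param cfg A [run_config()].
#' @return A list of class `mr_panel`: `results` (list of `mr_direction`
#'   keyed `"<taxon>|<direction>"`) and `summary` (one row per run via
#'   `glance()`). When `cfg$multiplicity == "bh"` the summary gains a
#'   `p_adjusted` column and forward significance (hence reverse gating)
#'   uses it.
#' @export
run_bidirectional <- function(exposures, outcome = NULL, ld = NULL,
                              cfg = run_config()) {
  if (is.list(exposures) && !is.null(exposures$exposures)) {
    panel <- exposures
    exposures <- panel$exposures
    outcome <- outcome %||% panel$outcome
    ld <- ld %||% panel$ld
  }
  taxa <- names(exposures)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    mr_abort("exposures must be a named list of summary-statistic tables",
             "config_error")
  }
  results <- list()
  fwd <- list()
  for (i in seq_along(taxa)) {
    seed_i <- if (is.null(cfg$seed)) NULL else cfg$seed + i
    fwd[[taxa[i]]] <- run_direction(exposures[[i]], outcome, ld, cfg,
                                    direction = "forward", seed = seed_i)
    results[[paste0(taxa[i], "|forward")]] <- fwd[[taxa[i]]]
  }
  fwd_summary <- dplyr::bind_rows(lapply(fwd, glance))
  sig <- vapply(fwd, function(r) isTRUE(r$significant), logical(1))
  if (cfg$multiplicity == "bh") {
    padj <- stats::p.adjust(fwd_summary$pvalue, method = "BH")
    fwd_summary$p_adjusted <- padj
    sig <- !is.na(padj) & padj < cfg$alpha
    for (i in seq_along(fwd)) {
      fwd[[i]]$significant <- sig[i]
      results[[paste0(taxa[i], "|forward")]]$significant <- sig[i]
    }
  }
  for (i in seq_along(taxa)) {
    if (!sig[i]) next
    seed_i <- if (is.null(cfg$seed)) NULL else cfg$seed + length(taxa) + i
    results[[paste0(taxa[i], "|reverse")]] <-
      run_direction(outcome, exposures[[i]], ld, cfg,
                    direction = "reverse", seed = seed_i)
  }
  summary <- dplyr::bind_rows(lapply(results, glance))
  summary$run <- names(results)
  out <- list(results = results,
              summary = dplyr::relocate(summary, "run"),
              cfg = cfg)
  class(out) <- "mr_panel"
  out
}

#' @export
print.mr_panel <- function(x, ...) {
  cat(sprintf("Bidirectional MR panel: %d runs (%d forward, %d reverse)\n",
              nrow(x$summary), sum(x$summary$direction == "forward"),
              sum(x$summary$direction == "reverse")))
  print(x$summary)
  invisible(x)
}

#' @method tidy mr_panel
#' @export
tidy.mr_panel <- function(x, ...) {
  dplyr::bind_rows(lapply(x$results, tidy))
}

#' @method glance mr_panel
#' @export
glance.mr_panel <- function(x, ...) x$summary

sens_row <- function(run, r) {
  s <- r$sensitivity
  het <- s$heterogeneity
  egg <- s$egger_intercept
  pre <- if (!is.null(s$presso)) glance(s$presso) else NULL
  tibble(run = run, exposure = r$exposure_name, outcome = r$outcome_name,
         direction = r$direction,
         q = if (!is.null(het)) het$q else NA_real_,
         q_df = if (!is.null(het)) het$df else NA_real_,
         q_pvalue = if (!is.null(het)) het$pvalue else NA_real_,
         egger_intercept = if (!is.null(egg)) egg$intercept else NA_real_,
         egger_intercept_se = if (!is.null(egg)) egg$se else NA_real_,
         egger_intercept_p = if (!is.null(egg)) egg$pvalue else NA_real_,
         presso_global_p = if (!is.null(pre)) pre$global_p else NA_real_,
         presso_n_outliers = if (!is.null(pre)) pre$n_outliers else
           NA_integer_,
         presso_distortion_p = if (!is.null(pre)) pre$distortion_p else
           NA_real_)
}

#' Write the report tables for a panel of MR runs
#'
#' Produces, under `out_dir`: `estimates.tsv` (per-method forest-table data,
#' IVW first within each run), `sensitivity.tsv` (Q, Egger intercept,
#' MR-PRESSO), `leave_one_out.tsv`, `instruments.tsv` (per-stage provenance
#' counts and strength statistics), `scatter_data.tsv` plus
#' `scatter_fits.tsv` (per-SNP effect pairs and per-method fitted lines, for
#' significant runs only), and `run_metadata.json` recording thresholds and
#' seeds. No timestamps are written, so identical inputs yield byte-identical
#' directories.
#'
#' @param panel An `mr_panel` from [run_bidirectional()], or a list of
#'   `mr_direction` objects.
#' @param out_dir Output directory.
#' @return The manifest tibble from [write_results()].
#' @export
generate_report <- function(panel, out_dir) {
  if (inherits(panel, "mr_direction")) {
    panel <- list(results = list(run = panel), cfg = run_config())
  }
  if (!inherits(panel, "mr_panel") && is.list(panel) &&
      is.null(panel$results)) {
    panel <- list(results = panel, cfg = run_config())
  }
  results <- panel$results
  runs <- names(results) %||% as.character(seq_along(results))

  method_order <- c("ivw", "egger", "weighted_median", "weighted_mode",
                    "simple_mode", "wald")
  est_rows <- purrr::imap(results, function(r, run) {
    est <- tidy(r)
    if (nrow(est) == 0) return(NULL)
    est$run <- run
    est[order(match(est$method, method_order)), , drop = FALSE]
  })
  estimates <- dplyr::bind_rows(est_rows)
  if (is.null(estimates) || nrow(estimates) == 0) {
    estimates <- tibble(run = character(), exposure = character(),
                        outcome = character(), direction = character(),
                        method = character(), primary = logical(),
                        n_snp = integer(), beta = numeric(), se = numeric(),
                        ci_low = numeric(), ci_high = numeric(),
                        or = numeric(), or_low = numeric(),
                        or_high = numeric(), pvalue = numeric())
  } else {
    estimates <- dplyr::relocate(estimates, "run")
  }

  sens <- dplyr::bind_rows(purrr::imap(results, function(r, run) {
    if (is.null(r$sensitivity)) return(NULL)
    sens_row(run, r)
  }))
  if (nrow(sens) == 0) {
    sens <- sens_row("none", empty_direction("forward", "", "", ""))[0, ]
  }

  loo <- dplyr::bind_rows(purrr::imap(results, function(r, run) {
    if (is.null(r$sensitivity) || is.null(r$sensitivity$loo)) return(NULL)
    dplyr::mutate(r$sensitivity$loo, run = run, .before = 1)
  }))
  if (nrow(loo) == 0) {
    loo <- tibble(run = character(), excluded_snp = character(),
                  n_snp = integer(), beta = numeric(), se = numeric(),
                  pvalue = numeric(), driver = logical())
  }

  inst <- dplyr::bind_rows(purrr::imap(results, function(r, run) {
    if (is.null(r$instruments)) return(NULL)
    prov <- iv_provenance(r$instruments)
    if (is.null(prov)) return(NULL)
    strength <- if (!is.null(r$strength)) glance(r$strength) else NULL
    prov <- dplyr::mutate(prov, run = run, .before = 1)
    if (!is.null(strength)) {
      prov$f_stat <- strength$f_stat
      prov$r2_total <- strength$r2_total
      prov$weak_instrument <- strength$weak_instrument
    } else {
      prov$f_stat <- NA_real_
      prov$r2_total <- NA_real_
      prov$weak_instrument <- NA
    }
    prov
  }))
  if (nrow(inst) == 0) {
    inst <- tibble(run = character(), stage = character(),
                   retained = integer(), dropped = integer(),
                   f_stat = numeric(), r2_total = numeric(),
                   weak_instrument = logical())
  }

  sig_runs <- runs[vapply(results, function(r) isTRUE(r$significant),
                          logical(1))]
  scatter <- dplyr::bind_rows(lapply(sig_runs, function(run) {
    r <- results[[run]]
    if (is.null(r$harmonized) || nrow(r$harmonized) == 0) return(NULL)
    dplyr::mutate(dplyr::select(r$harmonized, "snp", "beta_x", "se_x",
                                "beta_y", "se_y"),
                  run = run, .before = 1)
  }))
  if (is.null(scatter) || nrow(scatter) == 0) {
    scatter <- tibble(run = character(), snp = character(),
                      beta_x = numeric(), se_x = numeric(),
                      beta_y = numeric(), se_y = numeric())
  }
  fits <- dplyr::bind_rows(lapply(sig_runs, function(run) {
    r <- results[[run]]
    est <- r$estimates
    if (nrow(est) == 0) return(NULL)
    tibble(run = run, method = est$method, slope = est$beta,
           intercept = ifelse(est$method == "egger",
                              est$egger_intercept %||% 0, 0))
  }))
  if (is.null(fits) || nrow(fits) == 0) {
    fits <- tibble(run = character(), method = character(),
                   slope = numeric(), intercept = numeric())
  }

  cfg <- panel$cfg %||% run_config()
  write_results(
    tables = list(estimates = estimates, sensitivity = sens,
                  leave_one_out = loo, instruments = inst,
                  scatter_data = scatter, scatter_fits = fits),
    out_dir = out_dir,
    run_meta = unclass(cfg)
  )
}
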
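#' Configuration for synthetic two-sample MR summary data
#'
#' The generator emulates the shape of the real study data: a microbiome
#' GWAS meta-analysis exposure (default sample size 18,340) and a binary
#' pregnancy-outcome GWAS (default 1,148 cases and 110,330 controls).
#' Effects are simulated directly on the summary-statistic scale: per-SNP
#' exposure effects gamma are drawn from `gamma_dist`, exposure estimates
#' are `gamma` plus noise with the analytic standard error
#' \eqn{SE_X = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})N}}, and outcome
#' estimates are `true_beta * gamma + alpha` plus noise with the standard
#' error implied by the effective sample size
#' \eqn{N_{eff} = 4/(1/N_{cases} + 1/N_{controls})} of a binary trait.
#'
#' @param n_snps Number of candidate SNPs.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome GWAS case/control counts.
#' @param true_beta Causal effect of exposure on outcome (log-odds per unit
#'   exposure).
#' @param maf_range Minor-allele-frequency interval, inside (0, 0.5].
#' @param gamma_dist List `min`, `max`, `sign` describing per-SNP exposure
#'   effects: magnitudes uniform on `[min, max]`, direction `"mixed"`
#'   (random sign) or `"positive"`.
#' @param prop_null Fraction of SNPs with zero exposure effect padding the
#'   panel.
#' @param pleiotropy List `type` (`"none"`, `"balanced"`, `"directional"`),
#'   `mean`, `sd` — per-SNP direct effects alpha on the outcome.
#' @param palindrome_rate Fraction of SNPs given palindromic (A/T or C/G)
#'   allele pairs.
#' @param ld_block List `size` (SNPs per block) and `rho` (adjacent-SNP
#'   correlation, so \eqn{r^2 = \rho^{2|i-j|}} within a block).
#' @param seed Optional integer seed recorded in every output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 30, n_exposure = 18340, n_cases = 1148,
                       n_controls = 110330, true_beta = 0,
                       maf_range = c(0.05, 0.5),
                       gamma_dist = list(min = 0.04, max = 0.08,
                                         sign = "mixed"),
                       prop_null = 0,
                       pleiotropy = list(type = "none", mean = 0, sd = 0),
                       palindrome_rate = 0,
                       ld_block = list(size = 1, rho = 0),
                       seed = NULL) {
  stopifnot(n_snps >= 1, n_exposure > 0, n_cases > 0, n_controls > 0)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    mr_abort("maf_range must lie inside (0, 0.5]", "config_error")
  }
  gamma_dist$sign <- match.arg(gamma_dist$sign %||% "mixed",
                               c("mixed", "positive"))
  pleiotropy$type <- match.arg(pleiotropy$type %||% "none",
                               c("none", "balanced", "directional"))
  if (prop_null < 0 || prop_null > 1) {
    mr_abort("prop_null must lie in [0, 1]", "config_error")
  }
  if (ld_block$size < 1 || ld_block$rho < 0 || ld_block$rho >= 1) {
    mr_abort("ld_block needs size >= 1 and rho in [0, 1)", "config_error")
  }
  structure(list(n_snps = n_snps, n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls, true_beta = true_beta,
                 maf_range = maf_range, gamma_dist = gamma_dist,
                 prop_null = prop_null, pleiotropy = pleiotropy,
                 palindrome_rate = palindrome_rate, ld_block = ld_block,
                 seed = seed),
            class = "sim_config")
}

#' Binary-trait effective sample size
#'
#' \eqn{N_{eff} = 4 / (1/N_{cases} + 1/N_{controls})}, the equivalent
#' quantitative-trait sample size of a case-control GWAS on the log-odds
#' scale.
#'
#' @param n_cases,n_controls Case and control counts.
#' @return Effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

# deterministic SNP identifiers and genomic coordinates shared by the
# LD-matrix and summary-statistic simulators: blocks are placed on cycling
# chromosomes, members 100 kb apart (inside the clumping window), and
# successive blocks on the same chromosome 20,000 kb apart (outside it).
snp_map <- function(cfg, prefix = "rs") {
  n <- cfg$n_snps
  bs <- cfg$ld_block$size
  block <- (seq_len(n) - 1L) %/% bs
  within <- (seq_len(n) - 1L) %% bs
  chr <- as.character(block %% 22L + 1L)
  block_on_chr <- block %/% 22L
  pos <- 1e6 + block_on_chr * 2e7 + within * 1e5
  tibble(snp = sprintf("%s%06d", prefix, seq_len(n)),
         chr = chr, pos = pos, block = block)
}

#' Simulate a block-diagonal LD r-squared matrix
#'
#' Within each block of `cfg$ld_block$size` SNPs, \eqn{r^2(i, j) =
#' \rho^{2|i-j|}} (autoregressive decay); across blocks r² is 0. Positions
#' are assigned so block members fall within a 10,000 kb clumping window and
#' distinct blocks do not.
#'
#' @param cfg A [sim_config()].
#' @param prefix SNP-identifier prefix (used to keep panels distinct).
#' @return An `ld_matrix` with a `positions` attribute (tibble `snp, chr,
#'   pos`).
#' @export
simulate_ld_matrix <- function(cfg, prefix = "rs") {
  map <- snp_map(cfg, prefix = prefix)
  n <- nrow(map)
  rho <- cfg$ld_block$rho
  idx <- seq_len(n)
  same_block <- outer(map$block, map$block, "==")
  dist <- abs(outer(idx, idx, "-"))
  r2 <- ifelse(same_block, rho^(2 * dist), 0)
  diag(r2) <- 1
  out <- as_ld_matrix(r2, snp_ids = map$snp)
  attr(out, "positions") <- dplyr::select(map, "snp", "chr", "pos")
  out
}

random_alleles <- function(n, palindrome_rate) {
  pal <- runif(n) < palindrome_rate
  non_pal_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                         c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  i_np <- sample.int(nrow(non_pal_pairs), n, replace = TRUE)
  i_p <- sample.int(nrow(pal_pairs), n, replace = TRUE)
  ea <- ifelse(pal, pal_pairs[i_p, 1], non_pal_pairs[i_np, 1])
  oa <- ifelse(pal, pal_pairs[i_p, 2], non_pal_pairs[i_np, 2])
  list(ea = ea, oa = oa)
}

draw_gamma <- function(n, gd) {
  mag <- runif(n, gd$min, gd$max)
  s <- if (gd$sign == "positive") rep(1, n) else sample(c(-1, 1), n,
                                                        replace = TRUE)
  mag * s
}

# two-sided Wald p kept strictly positive: extreme z-scores underflow pnorm
# to exactly 0, which a valid summary table cannot contain
wald_p <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)

draw_alpha <- function(n, pl) {
  switch(pl$type,
         none = rep(0, n),
         balanced = rnorm(n, 0, pl$sd),
         directional = rnorm(n, pl$mean, pl$sd))
}

simulate_core <- function(cfg, prefix = "rs", exposure_name = "exposure",
                          outcome_name = "outcome") {
  map <- snp_map(cfg, prefix = prefix)
  n <- cfg$n_snps
  maf <- runif(n, cfg$maf_range[1], cfg$maf_range[2])
  causal <- runif(n) >= cfg$prop_null
  gamma <- ifelse(causal, draw_gamma(n, cfg$gamma_dist), 0)
  alpha <- draw_alpha(n, cfg$pleiotropy)
  al <- random_alleles(n, cfg$palindrome_rate)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
  n_eff <- effective_n(cfg$n_cases, cfg$n_controls)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_eff)
  beta_x <- rnorm(n, gamma, se_x)
  beta_y <- rnorm(n, cfg$true_beta * gamma + alpha, se_y)
  exposure <- tibble(snp = map$snp, chr = map$chr, pos = map$pos,
                     ea = al$ea, oa = al$oa, eaf = maf,
                     beta = beta_x, se = se_x, p = wald_p(beta_x / se_x),
                     n = cfg$n_exposure)
  outcome <- tibble(snp = map$snp, chr = map$chr, pos = map$pos,
                    ea = al$ea, oa = al$oa, eaf = maf,
                    beta = beta_y, se = se_y, p = wald_p(beta_y / se_y),
                    n = cfg$n_cases + cfg$n_controls)
  truth <- tibble(snp = map$snp, maf = maf, gamma = gamma, alpha = alpha,
                  causal = causal & gamma != 0, se_x = se_x, se_y = se_y,
                  true_beta = cfg$true_beta)
  # rows satisfy the summary-statistic invariants by construction, so the
  # trait attributes are attached directly rather than re-validated
  list(
    exposure = set_trait_attrs(exposure, exposure_name, "quantitative"),
    outcome = set_trait_attrs(outcome, outcome_name, "binary",
                              cfg$n_cases, cfg$n_controls),
    truth = truth
  )
}

set_trait_attrs <- function(x, trait_name, trait_type, n_cases = NULL,
                            n_controls = NULL) {
  structure(x, trait_name = trait_name, trait_type = trait_type,
            n_cases = n_cases, n_controls = n_controls, n_dropped = 0L,
            class = class(x))
}

#' Simulate one two-sample MR dataset with known ground truth
#'
#' Generates paired exposure and outcome summary-statistic tables for one
#' exposure trait, per the generative model described in [sim_config()].
#' P-values are Wald tests; a `truth` table records every latent value
#' (minor-allele frequency, per-SNP exposure effect, pleiotropic effect,
#' causal status). With a fixed `cfg$seed` the output is bit-identical
#' across runs.
#'
#' @param cfg A [sim_config()].
#' @param exposure_name,outcome_name Trait labels.
#' @return A list `exposure` (summary-statistics tibble), `outcome`
#'   (summary-statistics tibble), `truth` (tibble of generative values).
#' @export
simulate_mr_dataset <- function(cfg, exposure_name = "exposure",
                                outcome_name = "outcome") {
  run <- function() simulate_core(cfg, exposure_name = exposure_name,
                                  outcome_name = outcome_name)
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}

taxon_names <- function(n_taxa) {
  ranks <- c("genus", "family", "order", "class", "phylum")
  base <- c("Coprococcus", "Ruminococcus", "Turicibacter", "Defluviitaleaceae",
            "Akkermansia", "Bacteroides", "Prevotella", "Faecalibacterium",
            "Blautia", "Roseburia", "Lachnospira", "Oscillibacter",
            "Alistipes", "Dialister", "Eubacterium", "Streptococcus",
            "Veillonella", "Parabacteroides", "Dorea", "Butyricimonas")
  nm <- character(n_taxa)
  for (i in seq_len(n_taxa)) {
    rank <- ranks[(i - 1L) %% length(ranks) + 1L]
    stem <- base[(i - 1L) %% length(base) + 1L]
    nm[i] <- paste0(rank, ".", stem, if (i > length(base)) i else "")
  }
  # the real panel carries an unresolved-genus placeholder; keep one here
  nm[min(2L, n_taxa)] <- "genus.unknowngenus"
  nm
}

#' Simulate a multi-taxon exposure panel with a shared binary outcome
#'
#' Emulates (at reduced scale) a microbiome exposure panel in which each
#' taxon has its own independent set of instruments, a configurable number
#' of taxa causally affect the binary outcome with mixed-sign effects of
#' magnitude `cfg$true_beta`, and the outcome GWAS additionally carries
#' `n_outcome_snps` direct susceptibility loci with no effect on any taxon
#' (these provide instruments for the reverse analysis). Taxon names cycle
#' through the five taxonomic rank prefixes (genus/family/order/class/
#' phylum) and include an `unknowngenus` placeholder. Every taxon's table
#' and the outcome table cover the union of all panel SNPs, as in a
#' genotyped-cohort GWAS, so either direction can be harmonized.
#'
#' @param cfg A [sim_config()]; `cfg$n_snps` is the per-taxon SNP count and
#'   `cfg$true_beta` the causal-effect magnitude.
#' @param n_taxa Number of exposure taxa.
#' @param n_causal Number of causally active taxa (alternating signs).
#' @param n_outcome_snps Direct outcome susceptibility loci.
#' @param outcome_gamma Magnitude range of the direct outcome effects.
#' @return A list: `taxa` (tibble `taxon, rank, true_beta`), `exposures`
#'   (named list of summary-statistics tibbles), `outcome`
#'   (summary-statistics tibble), `ld` (block LD matrix over the union
#'   panel), `truth` (SNP-level tibble).
#' @export
simulate_taxa_panel <- function(cfg, n_taxa = 20, n_causal = 2,
                                n_outcome_snps = 8,
                                outcome_gamma = c(0.12, 0.2)) {
  if (n_causal > n_taxa) {
    mr_abort("n_causal cannot exceed n_taxa", "config_error")
  }
  run <- function() {
    names_t <- taxon_names(n_taxa)
    true_betas <- numeric(n_taxa)
    if (n_causal > 0) {
      signs <- rep_len(c(1, -1), n_causal)
      true_betas[seq_len(n_causal)] <- signs * abs(cfg$true_beta)
    }
    n_eff <- effective_n(cfg$n_cases, cfg$n_controls)

    per_taxon <- vector("list", n_taxa)
    for (t in seq_len(n_taxa)) {
      cfg_t <- cfg
      cfg_t$true_beta <- true_betas[t]
      cfg_t$seed <- NULL
      per_taxon[[t]] <- simulate_core(cfg_t, prefix = sprintf("rs%02d", t),
                                      exposure_name = names_t[t],
                                      outcome_name = "outcome")
    }

    # direct outcome loci: strong on the outcome, null on every taxon
    maf_o <- runif(n_outcome_snps, cfg$maf_range[1], cfg$maf_range[2])
    delta <- draw_gamma(n_outcome_snps,
                        list(min = outcome_gamma[1], max = outcome_gamma[2],
                             sign = "mixed"))
    al_o <- random_alleles(n_outcome_snps, cfg$palindrome_rate)
    se_yo <- 1 / sqrt(2 * maf_o * (1 - maf_o) * n_eff)
    se_xo <- 1 / sqrt(2 * maf_o * (1 - maf_o) * cfg$n_exposure)
    beta_yo <- rnorm(n_outcome_snps, delta, se_yo)
    out_snps <- tibble(
      snp = sprintf("rsHG%04d", seq_len(n_outcome_snps)),
      chr = as.character((seq_len(n_outcome_snps) - 1L) %% 22L + 1L),
      pos = 5e8 + (seq_len(n_outcome_snps) - 1L) %/% 22L * 2e7,
      ea = al_o$ea, oa = al_o$oa, eaf = maf_o,
      beta = beta_yo, se = se_yo,
      p = wald_p(beta_yo / se_yo),
      n = cfg$n_cases + cfg$n_controls
    )

    # exposure-side rows for the outcome loci (null effect on each taxon)
    null_rows <- function() {
      b <- rnorm(n_outcome_snps, 0, se_xo)
      dplyr::mutate(dplyr::select(out_snps, "snp", "chr", "pos", "ea", "oa",
                                  "eaf"),
                    beta = b, se = se_xo, p = wald_p(b / se_xo),
                    n = cfg$n_exposure)
    }

    exposures <- list()
    outcome_parts <- list()
    truth_parts <- list()
    for (t in seq_len(n_taxa)) {
      d <- per_taxon[[t]]
      exp_tab <- dplyr::bind_rows(as_tibble(d$exposure), null_rows())
      exposures[[names_t[t]]] <- as_sumstats(
        exp_tab, trait_name = names_t[t], trait_type = "quantitative",
        quiet = TRUE)
      outcome_parts[[t]] <- as_tibble(d$outcome)
      truth_parts[[t]] <- dplyr::mutate(d$truth, taxon = names_t[t])
    }
    outcome <- dplyr::bind_rows(c(outcome_parts, list(out_snps)))
    outcome <- as_sumstats(outcome, trait_name = "outcome",
                           trait_type = "binary", n_cases = cfg$n_cases,
                           n_controls = cfg$n_controls, quiet = TRUE)

    # block LD over the union panel: per-taxon blocks plus identity for the
    # direct outcome loci
    all_ids <- c(unlist(lapply(per_taxon, function(d) d$truth$snp),
                        use.names = FALSE), out_snps$snp)
    n_all <- length(all_ids)
    r2 <- diag(1, n_all)
    rownames(r2) <- colnames(r2) <- all_ids
    if (cfg$ld_block$size > 1 && cfg$ld_block$rho > 0) {
      ld_t <- simulate_ld_matrix(cfg)
      for (t in seq_len(n_taxa)) {
        ids <- per_taxon[[t]]$truth$snp
        r2[ids, ids] <- unclass(ld_t)[, , drop = FALSE]
      }
    }
    ld <- as_ld_matrix(r2)

    rank <- sub("\\..*$", "", names_t)
    list(
      taxa = tibble(taxon = names_t, rank = rank, true_beta = true_betas),
      exposures = exposures,
      outcome = outcome,
      ld = ld,
      truth = dplyr::bind_rows(
        truth_parts,
        list(tibble(snp = out_snps$snp, maf = maf_o, gamma = 0,
                    alpha = delta, causal = FALSE, se_x = se_xo,
                    se_y = se_yo, true_beta = 0, taxon = "outcome_direct")))
    )
  }
  if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
}
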
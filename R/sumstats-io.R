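#' Canonical summary-statistics column names
#'
#' The on-disk dialect is a tab-separated table with a header row and columns
#' `SNP CHR POS EA OA EAF BETA SE P N` (effect allele `EA`, other allele `OA`,
#' effect-allele frequency `EAF`). `sumstats_columns()` returns the mapping
#' from internal names to these file headers; pass a modified copy to
#' [read_sumstats()] to accommodate other header conventions (e.g. IEU
#' OpenGWAS or MiBioGen exports).
#'
#' @param ... Named overrides, e.g. `snp = "rsid"`, `p = "pval"`.
#' @return Named character vector mapping internal column names to file
#'   headers.
#' @examples
#' sumstats_columns(snp = "rsid", p = "pval")
#' @export
sumstats_columns <- function(...) {
  map <- c(
    snp = "SNP", chr = "CHR", pos = "POS", ea = "EA", oa = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) {
      mr_abort(paste0("unknown column keys: ", paste(bad, collapse = ", ")),
               "config_error")
    }
    map[names(over)] <- over
  }
  map
}

valid_bases <- c("A", "C", "G", "T")

#' Validate a table of per-SNP summary associations
#'
#' Applies the row-level invariants expected of GWAS summary statistics:
#' single-base alleles in A/C/G/T with effect allele distinct from the other
#' allele, standard error strictly positive, effect-allele frequency strictly
#' inside (0, 1), p-value in (0, 1], non-negative position and positive sample
#' size. Alleles are upper-cased before checking; rows violating any invariant
#' and rows duplicating an earlier SNP identifier are dropped, and the drop
#' count is recorded in the `n_dropped` attribute and reported via a message.
#'
#' @param x A data frame with columns `snp, chr, pos, ea, oa, eaf, beta, se,
#'   p` and optionally `n`.
#' @param trait_name,trait_type Trait descriptors stored as attributes;
#'   `trait_type` is `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls For binary traits, cohort case/control counts.
#'   When the table lacks a per-SNP `n` column these supply `n = n_cases +
#'   n_controls`.
#' @param quiet Suppress the dropped-row message.
#' @return A tibble of validated records with attributes `trait_name`,
#'   `trait_type`, `n_cases`, `n_controls`, `n_dropped`.
#' @export
as_sumstats <- function(x, trait_name = "trait",
                        trait_type = c("quantitative", "binary"),
                        n_cases = NULL, n_controls = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  x <- as_tibble(x)
  needed <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    mr_abort(paste0("missing mandatory column(s): ",
                    paste(missing_cols, collapse = ", ")), "config_error")
  }
  if (!"n" %in% names(x)) {
    if (trait_type == "binary" && !is.null(n_cases) && !is.null(n_controls)) {
      x$n <- n_cases + n_controls
    } else {
      mr_abort("no per-SNP `n` column and no trait-level sample size supplied",
               "config_error")
    }
  }
  n_in <- nrow(x)
  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  x$pos <- as.numeric(x$pos)
  x$ea <- toupper(as.character(x$ea))
  x$oa <- toupper(as.character(x$oa))
  x$eaf <- as.numeric(x$eaf)
  x$beta <- as.numeric(x$beta)
  x$se <- as.numeric(x$se)
  x$p <- as.numeric(x$p)
  x$n <- as.numeric(x$n)
  ok <- !is.na(x$snp) & nzchar(x$snp) &
    x$ea %in% valid_bases & x$oa %in% valid_bases & x$ea != x$oa &
    is.finite(x$pos) & x$pos >= 0 &
    is.finite(x$eaf) & x$eaf > 0 & x$eaf < 1 &
    is.finite(x$beta) &
    is.finite(x$se) & x$se > 0 &
    is.finite(x$p) & x$p > 0 & x$p <= 1 &
    is.finite(x$n) & x$n > 0
  ok[is.na(ok)] <- FALSE
  x <- x[ok, , drop = FALSE]
  x <- x[!duplicated(x$snp), , drop = FALSE]
  n_dropped <- n_in - nrow(x)
  if (nrow(x) == 0L) {
    mr_abort("no valid summary-statistic rows after validation", "empty_input")
  }
  if (n_dropped > 0 && !quiet) {
    inform(sprintf("as_sumstats: dropped %d invalid or duplicated row(s) of %d",
                   n_dropped, n_in))
  }
  structure(x,
            trait_name = trait_name, trait_type = trait_type,
            n_cases = n_cases, n_controls = n_controls,
            n_dropped = n_dropped,
            class = class(x))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-bearing tab-separated file, renames columns according to
#' `column_map`, and validates records with [as_sumstats()] (invalid rows are
#' dropped and counted rather than fatal).
#'
#' @param path Path to a TSV file.
#' @param column_map Mapping from internal names to file headers; see
#'   [sumstats_columns()].
#' @inheritParams as_sumstats
#' @return A validated summary-statistics tibble; see [as_sumstats()].
#' @export
read_sumstats <- function(path, column_map = sumstats_columns(),
                          trait_name = "trait",
                          trait_type = c("quantitative", "binary"),
                          n_cases = NULL, n_controls = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- setdiff(names(column_map), "n")
  missing_cols <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(missing_cols)) {
    mr_abort(paste0("file ", path, " lacks mapped column(s): ",
                    paste(missing_cols, collapse = ", ")), "config_error")
  }
  present <- column_map[unname(column_map) %in% names(raw)]
  raw <- dplyr::rename(raw, !!!setNames(unname(present), names(present)))
  as_sumstats(raw[, intersect(c(names(column_map)), names(raw)), drop = FALSE],
              trait_name = trait_name, trait_type = trait_type,
              n_cases = n_cases, n_controls = n_controls, quiet = quiet)
}

#' Write summary statistics in the canonical dialect
#'
#' @param x A summary-statistics tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- dplyr::select(as_tibble(x), dplyr::all_of(
    c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")))
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct and validate an LD r-squared matrix
#'
#' @param r2 A square numeric matrix of squared correlations with SNP
#'   identifiers as dimnames (or supplied via `snp_ids`).
#' @param snp_ids Optional character vector of identifiers.
#' @return A symmetric matrix with unit diagonal, entries in \eqn{[0, 1]},
#'   class `ld_matrix`.
#' @details Values outside \eqn{[0, 1]} by more than 1e-8 raise a range error;
#'   asymmetry beyond 1e-8 raises a format error, smaller asymmetry is
#'   resolved by averaging. The diagonal must be 1 to within 1e-8 and is set
#'   exactly.
#' @export
as_ld_matrix <- function(r2, snp_ids = NULL) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) {
    mr_abort("LD matrix must be square", "format_error")
  }
  if (!is.null(snp_ids)) {
    dimnames(r2) <- list(snp_ids, snp_ids)
  }
  if (is.null(rownames(r2))) {
    mr_abort("LD matrix needs SNP identifiers as dimnames", "format_error")
  }
  if (!identical(rownames(r2), colnames(r2))) {
    mr_abort("LD matrix row and column identifiers differ", "format_error")
  }
  if (anyNA(r2) || any(r2 < -1e-8) || any(r2 > 1 + 1e-8)) {
    mr_abort("LD r-squared entries must lie in [0, 1]", "range_error")
  }
  if (max(abs(r2 - t(r2))) >= 1e-8) {
    mr_abort("LD matrix asymmetry exceeds 1e-8", "format_error")
  }
  r2 <- (r2 + t(r2)) / 2
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    mr_abort("LD matrix diagonal must be 1", "range_error")
  }
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  diag(r2) <- 1
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Load an LD matrix from a delimited text file
#'
#' Expects a TSV whose first column holds SNP identifiers and whose remaining
#' column headers repeat those identifiers (the usual square export of an LD
#' panel).
#'
#' @param path Path to the TSV file.
#' @return An `ld_matrix`; see [as_ld_matrix()].
#' @export
load_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), ids)) {
    if (nrow(m) != ncol(m)) mr_abort("LD table is not square", "format_error")
    mr_abort("LD table column headers do not match identifier column",
             "format_error")
  }
  as_ld_matrix(m, snp_ids = ids)
}

#' Write an LD matrix in the canonical dialect
#'
#' @param ld An `ld_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- as_tibble(as.matrix(unclass(ld)))
  out <- dplyr::bind_cols(tibble(SNP = rownames(ld)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a set of named result tables plus run metadata
#'
#' Each table is written as `<name>.tsv` under `out_dir`; `run_meta` (e.g.
#' thresholds, seeds) is serialized to `run_metadata.json`. readr writes
#' doubles with shortest-round-trip precision, so re-reading reproduces every
#' value exactly.
#'
#' @param tables Named list of data frames; may be empty.
#' @param out_dir Output directory, created if needed.
#' @param run_meta Named list recorded as JSON metadata.
#' @return A manifest tibble with columns `name` and `path`.
#' @export
write_results <- function(tables = list(), out_dir, run_meta = list()) {
  if (length(tables) && (is.null(names(tables)) || any(!nzchar(names(tables))))) {
    mr_abort("all result tables must be named", "config_error")
  }
  if (anyDuplicated(names(tables))) {
    mr_abort("duplicate result-table names", "name_collision")
  }
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    mr_abort(paste0("cannot create output directory ", out_dir), "io_error")
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), p, progress = FALSE)
    paths[nm] <- p
  }
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(run_meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths["run_metadata"] <- meta_path
  tibble(name = names(paths), path = unname(paths))
}
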
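#' Pairwise LD correlation matrix
#'
#' A square symmetric matrix of pairwise allelic correlations (r, not r²)
#' with unit diagonal, indexed by SNP identifier. Clumping squares the
#' entries when comparing against an r² threshold.
#'
#' @param r Square numeric matrix of correlations in `[-1, 1]`.
#' @param snp_ids SNP identifiers for rows/columns; defaults to `rownames(r)`.
#' @return The matrix with class `ld_matrix` and `snp_ids` as dimnames.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(snp_ids)) stop("`snp_ids` required when `r` has no rownames", call. = FALSE)
  if (nrow(r) != ncol(r) || nrow(r) != length(snp_ids)) {
    stop("LD matrix dimensions must match the number of SNP ids", call. = FALSE)
  }
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8)) stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  dimnames(r) <- list(snp_ids, snp_ids)
  class(r) <- c("ld_matrix", "matrix", "array")
  r
}

#' Read/write an LD matrix in plain text
#'
#' Format: first line is the whitespace-separated SNP identifiers; each
#' subsequent line is one row of correlations.
#'
#' @param path File path.
#' @return `read_ld_matrix()` returns an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("LD matrix file is empty: ", path, call. = FALSE)
  ids <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  vals <- lapply(lines[-1L], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  r <- do.call(rbind, vals)
  ld_matrix(r, snp_ids = ids)
}

#' @rdname read_ld_matrix
#' @param ld An `ld_matrix`.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(ld), collapse = " "), con)
  for (i in seq_len(nrow(ld))) {
    writeLines(paste(format_num(ld[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Single-SNP instrument-strength F-statistic
#'
#' The approximation `F = (beta/se)^2` from summary statistics; `F >= 10` is
#' the conventional weak-instrument cutoff.
#'
#' @param beta,se Per-SNP effect estimate and standard error (vectorized).
#' @return Numeric vector of F-statistics.
#' @export
#' @examples
#' f_statistic(0.1, 0.02)  # 25
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("`se` must be positive", call. = FALSE)
  (beta / se)^2
}

#' Select genetic instruments for one exposure
#'
#' Applies, in fixed order: the significance threshold, the allele-frequency
#' filter (minor-allele frequency above `eaf_min`; records without EAF pass),
#' the instrument-strength filter `F >= f_min`, and greedy LD clumping.
#' Clumping repeatedly keeps the remaining SNP with the smallest p-value
#' (ties broken by SNP id) and discards all SNPs on the same chromosome
#' within `clump_window_kb` whose LD r² with it is at least `clump_r2`.
#' Without an LD matrix the input is assumed pre-clumped and passes through
#' with a notice. A SNP absent from the LD matrix is treated as independent,
#' with a warning.
#'
#' @param stats A `summary_stats` object for the exposure.
#' @param p_threshold Instrument significance threshold (1e-5 is the usual
#'   suggestive threshold for 16S microbial taxa; 5e-8 the genome-wide one).
#' @param eaf_min Minimum minor-allele frequency (default 0.01).
#' @param f_min Minimum single-SNP F-statistic (default 10).
#' @param ld Optional [ld_matrix()].
#' @param clump_r2 LD r² threshold above which SNPs are clumped (default 0.001).
#' @param clump_window_kb Clumping window in kilobases (default 10,000).
#' @return A tibble of class `instrument_set` with the retained records plus
#'   `f_stat`, ordered by p-value then SNP id, carrying `exposure_name` and a
#'   `selection_log` attribute counting removals per stage
#'   (`below_p`, `low_eaf`, `low_f`, `clumped`).
#' @export
select_instruments <- function(stats, p_threshold = 1e-5, eaf_min = 0.01,
                               f_min = 10, ld = NULL, clump_r2 = 0.001,
                               clump_window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"))
  if (p_threshold <= 0 || p_threshold > 1) stop("`p_threshold` must be in (0, 1]", call. = FALSE)
  if (eaf_min < 0 || eaf_min >= 0.5) stop("`eaf_min` must be in [0, 0.5)", call. = FALSE)
  if (clump_r2 <= 0 || clump_r2 > 1) stop("`clump_r2` must be in (0, 1]", call. = FALSE)

  df <- tibble::as_tibble(as.data.frame(stats))
  df <- df[order(df$pvalue, df$snp), , drop = FALSE]
  log <- c(below_p = 0L, low_eaf = 0L, low_f = 0L, clumped = 0L)

  keep <- df$pvalue < p_threshold
  log[["below_p"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  maf <- pmin(df$eaf, 1 - df$eaf)
  keep <- is.na(maf) | maf > eaf_min
  log[["low_eaf"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  df$f_stat <- if (nrow(df)) f_statistic(df$beta, df$se) else numeric(0)
  keep <- df$f_stat >= f_min
  log[["low_f"]] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  if (nrow(df) > 1L && !is.null(ld)) {
    stopifnot(inherits(ld, "ld_matrix"))
    in_ld <- df$snp %in% rownames(ld)
    if (!all(in_ld)) {
      warning(sprintf("%d instrument SNP(s) absent from the LD matrix; treated as independent",
                      sum(!in_ld)), call. = FALSE)
    }
    kept_idx <- integer(0)
    remaining <- seq_len(nrow(df))  # already ordered by (p, snp)
    window_bp <- clump_window_kb * 1000
    while (length(remaining) > 0L) {
      lead <- remaining[1L]
      kept_idx <- c(kept_idx, lead)
      remaining <- remaining[-1L]
      if (length(remaining) == 0L) break
      same_chr <- !is.na(df$chr[remaining]) & !is.na(df$chr[lead]) &
        df$chr[remaining] == df$chr[lead]
      in_window <- same_chr & !is.na(df$pos[remaining]) & !is.na(df$pos[lead]) &
        abs(df$pos[remaining] - df$pos[lead]) <= window_bp
      # positions unavailable but both SNPs in the LD matrix: let r2 govern
      no_pos <- (is.na(df$pos[remaining]) | is.na(df$pos[lead])) &
        df$snp[remaining] %in% rownames(ld) & df$snp[lead] %in% rownames(ld)
      candidate <- in_window | no_pos
      r2 <- rep(0, length(remaining))
      idx <- candidate & df$snp[remaining] %in% rownames(ld) & df$snp[lead] %in% rownames(ld)
      if (any(idx)) {
        r2[idx] <- ld[df$snp[lead], df$snp[remaining][idx]]^2
      }
      drop <- candidate & r2 >= clump_r2
      log[["clumped"]] <- log[["clumped"]] + sum(drop)
      remaining <- remaining[!drop]
    }
    df <- df[sort(kept_idx), , drop = FALSE]
    df <- df[order(df$pvalue, df$snp), , drop = FALSE]
  } else if (is.null(ld) && nrow(df) > 1L) {
    message(sprintf("select_instruments('%s'): no LD matrix supplied; SNPs assumed pre-clumped",
                    trait_name(stats)))
  }

  if (nrow(df) == 0L) {
    warning(sprintf("no instruments survive selection for exposure '%s'",
                    trait_name(stats)), call. = FALSE)
  }
  structure(df,
            exposure_name = trait_name(stats),
            selection_log = log,
            class = c("instrument_set", class(tibble::tibble())))
}

#' @export
print.instrument_set <- function(x, ...) {
  log <- attr(x, "selection_log")
  cat(sprintf("<instrument_set> exposure '%s': %d SNPs retained (removed: %s)\n",
              attr(x, "exposure_name") %||% "?", nrow(x),
              paste(names(log), log, sep = "=", collapse = ", ")))
  NextMethod()
}
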
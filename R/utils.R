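# Internal numeric and string helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a > b; returns -Inf when the difference underflows
#' @noRd
log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# DNA complement for single-character allele vectors
#' @noRd
complement_allele <- function(x) chartr("ACGT", "TGCA", x)

#' @noRd
is_palindromic <- function(ea, oa) complement_allele(ea) == oa

#' @noRd
valid_allele <- function(x) !is.na(x) & x %in% c("A", "C", "G", "T")

# Two-sided normal p-value from an estimate and its standard error
#' @noRd
z_pvalue <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# Format numerics for on-disk reports: 12 significant digits, stable under
# a write -> read -> write round trip
#' @noRd
format_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

#' @noRd
write_tsv_plain <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @noRd
assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
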
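#' GWAS summary statistics for one trait
#'
#' Bundles a table of per-SNP association records with trait-level metadata.
#' Each record carries the SNP identifier, genomic coordinates, the effect
#' and other alleles, the effect-allele frequency (EAF), the effect estimate
#' (`beta`, on the log-odds scale for binary traits and in standardized units
#' for quantitative traits), its standard error, the association p-value and
#' the per-SNP sample size.
#'
#' Rows violating the record invariants (identical alleles, non-ACGT allele
#' codes, `se <= 0`, p-value outside `(0, 1]`, EAF outside `(0, 1)`, duplicated
#' SNP identifier) are dropped with a message reporting the count. A warn-only
#' consistency check compares each p-value against the two-sided normal tail
#' of `|beta|/se`.
#'
#' @param data data frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pvalue` and optionally `chr`, `pos`, `eaf`, `n`.
#' @param trait_name Trait label used in joins and reports.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param case_count,control_count Case/control counts for binary traits
#'   (required by colocalization priors, optional otherwise).
#' @param check_p_consistency Warn when p-values disagree with `|beta|/se`
#'   beyond rounding (default `TRUE`).
#'
#' @return A tibble of class `summary_stats` with canonical columns
#'   `snp, chr, pos, effect_allele, other_allele, eaf, beta, se, pvalue, n`,
#'   sorted by `snp`, carrying `trait_name`, `trait_type`, `case_count` and
#'   `control_count` attributes.
#' @export
#' @examples
#' ss <- summary_stats(
#'   data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
#'              eaf = 0.3, beta = 0.1, se = 0.02, pvalue = 5e-7),
#'   trait_name = "trait"
#' )
summary_stats <- function(data, trait_name, trait_type = c("quantitative", "binary"),
                          case_count = NA_integer_, control_count = NA_integer_,
                          check_p_consistency = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("summary statistics lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- c(chr = NA_character_, pos = NA_integer_, eaf = NA_real_, n = NA_real_)
  for (col in names(optional)) {
    if (!col %in% names(data)) data[[col]] <- optional[[col]]
  }

  df <- tibble::tibble(
    snp = as.character(data$snp),
    chr = as.character(data$chr),
    pos = as.integer(round(as.numeric(data$pos))),
    effect_allele = toupper(as.character(data$effect_allele)),
    other_allele = toupper(as.character(data$other_allele)),
    eaf = as.numeric(data$eaf),
    beta = as.numeric(data$beta),
    se = as.numeric(data$se),
    pvalue = as.numeric(data$pvalue),
    n = as.numeric(data$n)
  )

  ok <- !is.na(df$snp) & nzchar(df$snp) &
    valid_allele(df$effect_allele) & valid_allele(df$other_allele) &
    df$effect_allele != df$other_allele &
    !is.na(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)) &
    (is.na(df$n) | df$n > 0)
  ok[is.na(ok)] <- FALSE
  dup <- duplicated(df$snp)
  n_drop <- sum(!ok | (ok & dup))
  if (n_drop > 0L) {
    message(sprintf("summary_stats('%s'): dropped %d invalid or duplicated record(s)",
                    trait_name, n_drop))
    df <- df[ok & !dup, , drop = FALSE]
  }
  df <- df[order(df$snp), , drop = FALSE]

  if (check_p_consistency) {
    p_implied <- z_pvalue(df$beta, df$se)
    # tolerate rounding of beta/se/p to ~2 significant digits
    bad <- abs(log10(pmax(df$pvalue, 1e-300)) - log10(pmax(p_implied, 1e-300))) > 0.5
    if (any(bad, na.rm = TRUE)) {
      warning(sprintf("trait '%s': %d record(s) have p-values inconsistent with |beta|/se",
                      trait_name, sum(bad, na.rm = TRUE)), call. = FALSE)
    }
  }

  structure(
    df,
    trait_name = trait_name,
    trait_type = trait_type,
    case_count = as.integer(case_count),
    control_count = as.integer(control_count),
    class = c("summary_stats", class(tibble::tibble()))
  )
}

#' Trait metadata accessors
#'
#' @param x A `summary_stats` object.
#' @return `trait_name()` and `trait_type()` return single strings.
#' @export
trait_name <- function(x) attr(x, "trait_name", exact = TRUE)

#' @rdname trait_name
#' @export
trait_type <- function(x) attr(x, "trait_type", exact = TRUE)

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s), %d SNPs\n",
              trait_name(x), trait_type(x), nrow(x)))
  NextMethod()
}

#' Column-name dialect for summary-statistics files
#'
#' Maps the canonical record fields onto the column names used by a
#' particular file. Defaults follow the common PLINK-style header
#' (`SNP, CHR, BP, A1, A2, EAF, BETA, SE, P, N`). Unknown extra columns in a
#' file are ignored on read.
#'
#' @param snp,chr,pos,effect_allele,other_allele,eaf,beta,se,pvalue,n
#'   Column names in the file for each canonical field.
#' @return Named character vector mapping canonical field to file column.
#' @export
gwas_dialect <- function(snp = "SNP", chr = "CHR", pos = "BP",
                         effect_allele = "A1", other_allele = "A2",
                         eaf = "EAF", beta = "BETA", se = "SE",
                         pvalue = "P", n = "N") {
  c(snp = snp, chr = chr, pos = pos, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se,
    pvalue = pvalue, n = n)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- (or otherwise) delimited text file with a header into a
#' [summary_stats()] object. Gzip-compressed files are decompressed
#' transparently. Column names are resolved through a [gwas_dialect()]
#' mapping, so files from heterogeneous sources can be ingested without
#' renaming on disk.
#'
#' @param path Path to the file (optionally `.gz`).
#' @param trait_name Trait label; defaults to the file name without extension.
#' @param trait_type,case_count,control_count Passed to [summary_stats()].
#' @param dialect Column mapping from [gwas_dialect()].
#' @param sep Field separator (default tab).
#' @inheritParams summary_stats
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, trait_name = NULL,
                               trait_type = c("quantitative", "binary"),
                               case_count = NA_integer_, control_count = NA_integer_,
                               dialect = gwas_dialect(), sep = "\t",
                               check_p_consistency = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path, call. = FALSE)

  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pvalue")
  for (field in required) {
    if (!dialect[[field]] %in% names(raw)) {
      stop(sprintf("column '%s' (field '%s') not found in %s",
                   dialect[[field]], field, path), call. = FALSE)
    }
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(dialect)) {
    col <- dialect[[field]]
    df[[field]] <- if (col %in% names(raw)) raw[[col]] else NA
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.gz$", "", basename(path))
    trait_name <- sub("\\.[^.]*$", "", trait_name)
  }
  summary_stats(df, trait_name = trait_name, trait_type = trait_type,
                case_count = case_count, control_count = control_count,
                check_p_consistency = check_p_consistency)
}

#' Write GWAS summary statistics to tab-separated text
#'
#' Writes the canonical column order
#' `snp chr pos effect_allele other_allele eaf beta se pvalue n` with 12
#' significant digits, so that a write/read/write cycle is byte-identical and
#' round trips are lossless at reading precision.
#'
#' @param stats A `summary_stats` object.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  cols <- c("snp", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n")
  df <- as.data.frame(stats)[, cols, drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) df[[j]] <- format_num(df[[j]])
  }
  utils::write.table(df, file = con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
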
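#' GWAS summary-statistics tables
#'
#' A `sumstats` object is a data frame of per-variant summary associations
#' with one trait, with columns `rsid`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`. For binary disease traits `beta` is on
#' the log-odds (liability) scale; for continuous traits it is in SD units.
#' Rows violating the field invariants (identical alleles, non-positive SE,
#' p outside (0, 1], eaf outside (0, 1)) are dropped at construction and
#' counted in `attr(x, "n_dropped")`.
#'
#' @param df data frame with the columns above (`eaf` and `n` may be NA).
#' @param trait_name label for the trait.
#' @param trait_type `"binary_disease"` or `"continuous"`.
#' @return A `sumstats` data frame with attributes `trait_name`,
#'   `trait_type`, `n_dropped`.
#' @examples
#' ss <- sumstats(data.frame(rsid = "rs1", effect_allele = "A",
#'                           other_allele = "G", eaf = 0.3, beta = 0.1,
#'                           se = 0.01, pval = 1e-20, n = 10000),
#'                trait_name = "toy", trait_type = "binary_disease")
#' @export
sumstats <- function(df, trait_name = "trait",
                     trait_type = c("binary_disease", "continuous")) {
  trait_type <- match.arg(trait_type)
  required <- c("rsid", "effect_allele", "other_allele", "eaf", "beta",
                "se", "pval", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("summary-statistics format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.numeric(df$n)

  bases <- c("A", "C", "G", "T")
  ok <- !is.na(df$rsid) & nzchar(df$rsid) &
    df$effect_allele %in% bases & df$other_allele %in% bases &
    df$effect_allele != df$other_allele &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)) &
    (is.na(df$n) | df$n > 0)
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (anyDuplicated(df$rsid)) {
    stop("summary-statistics format error: duplicated rsid in '",
         trait_name, "'")
  }
  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name,
            trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", attr(x, "trait_name"),
      " (", attr(x, "trait_type"), ")\n", sep = "")
  cat(nrow(x), " variants (", attr(x, "n_dropped"),
      " invalid row(s) dropped at read)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

# Rebuild the sumstats class/attribute wrapper after a row subset.
restat <- function(df, template) {
  structure(as.data.frame(df),
            trait_name = attr(template, "trait_name"),
            trait_type = attr(template, "trait_type"),
            n_dropped = attr(template, "n_dropped"),
            class = c("sumstats", "data.frame"))
}

#' Read a GWAS summary-statistics table
#'
#' Reads the flat-file dialect used by common MR tooling: a header line plus
#' tab- (or comma-) separated columns `SNP`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`. Renamed headers are handled through
#' `column_map`, a named character vector mapping canonical names to the
#' file's header names, e.g. `c(rsid = "MarkerName", pval = "P")`. Rows
#' violating the per-variant invariants are dropped and tallied (see
#' [sumstats()]).
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical column names
#'   (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`) to the file's header names. Defaults cover the standard dialect
#'   (`SNP` for `rsid`).
#' @param trait_type `"binary_disease"` or `"continuous"`.
#' @param trait_name label; defaults to the file name.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_type = c("binary_disease", "continuous"),
                          trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty-input error: no data rows in ", path)

  defaults <- c(rsid = "SNP", effect_allele = "effect_allele",
                other_allele = "other_allele", eaf = "eaf", beta = "beta",
                se = "se", pval = "pval", n = "n")
  map <- defaults
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  absent <- map[!(map %in% names(raw))]
  if (length(absent) > 0) {
    stop("summary-statistics format error: mapped column(s) not in file: ",
         paste(absent, collapse = ", "))
  }
  df <- stats::setNames(raw[unname(map)], names(map))
  out <- sumstats(df,
                  trait_name = trait_name %||% basename(path),
                  trait_type = trait_type)
  if (nrow(out) == 0) stop("empty-input error: no valid rows in ", path)
  if (attr(out, "n_dropped") > 0) {
    message(attr(out, "n_dropped"), " invalid row(s) dropped reading ", path)
  }
  out
}

#' Write a summary-statistics table
#'
#' Writes the tab-separated dialect read by [read_sumstats()], with the
#' canonical header `SNP effect_allele other_allele eaf beta se pval n`.
#'
#' @param x a [sumstats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- as.data.frame(x)
  names(df)[names(df) == "rsid"] <- "SNP"
  write_tsv(df, path)
}

#' Select genome-wide-significant instruments
#'
#' Retains variants with `pval` strictly below the threshold (the
#' conventional genome-wide line is 5e-8; variants at exactly the threshold
#' are excluded).
#'
#' @param t a [sumstats] object.
#' @param p_threshold significance threshold in (0, 1].
#' @return A [sumstats] object (possibly with zero rows).
#' @export
select_instruments <- function(t, p_threshold = 5e-8) {
  stopifnot(inherits(t, "sumstats"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be a single number in (0, 1]")
  }
  restat(t[t$pval < p_threshold, , drop = FALSE], t)
}

#' Read a pairwise LD matrix
#'
#' Reads a square tab-separated matrix of squared correlations with an rsid
#' header row and first column.
#'
#' @param path file path.
#' @return A symmetric numeric matrix with rsid dimnames, validated by
#'   [validate_ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  colnames(m) <- colnames(raw)
  validate_ld_matrix(m)
  m
}

#' Write a pairwise LD matrix
#' @param ld square r-squared matrix with rsid dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  validate_ld_matrix(ld)
  df <- data.frame(rsid = rownames(ld), ld, check.names = FALSE)
  write_tsv(df, path)
}

#' Validate an LD (r-squared) matrix
#'
#' Checks symmetry, unit diagonal, entries in [0, 1], and rsid dimnames.
#'
#' @param ld matrix to check.
#' @return `ld`, invisibly; errors describe the violated property.
#' @export
validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    stop("LD matrix error: not a square matrix")
  }
  if (is.null(rownames(ld)) || is.null(colnames(ld)) ||
      !identical(rownames(ld), colnames(ld))) {
    stop("LD matrix error: rsid dimnames missing or inconsistent")
  }
  if (any(!is.finite(ld)) || any(ld < 0) || any(ld > 1)) {
    stop("LD matrix error: entries must lie in [0, 1]")
  }
  if (max(abs(ld - t(ld))) > 1e-8) stop("LD matrix error: not symmetric")
  if (max(abs(diag(ld) - 1)) > 1e-8) {
    stop("LD matrix error: diagonal must be 1")
  }
  invisible(ld)
}

#' Greedy LD pruning (clumping) by p-value
#'
#' Standard clumping semantics: repeatedly take the remaining variant with
#' the smallest p-value, retain it, and discard every remaining variant with
#' r-squared strictly above `r2_threshold` against it. Ties on p-value are
#' broken by lexicographic rsid so the result is deterministic. The returned
#' set is mutually independent at the threshold (no retained pair exceeds
#' it; pairs at exactly the threshold are kept).
#'
#' @param t a [sumstats] object.
#' @param ld r-squared matrix covering every rsid in `t`.
#' @param r2_threshold discard threshold in [0, 1); the conventional strict
#'   independence rule uses 0.001.
#' @return A [sumstats] object containing the retained variants, in
#'   selection order.
#' @export
ld_prune <- function(t, ld, r2_threshold = 0.001) {
  stopifnot(inherits(t, "sumstats"))
  validate_ld_matrix(ld)
  if (!is.numeric(r2_threshold) || r2_threshold < 0 || r2_threshold >= 1) {
    stop("r2_threshold must lie in [0, 1)")
  }
  absent <- setdiff(t$rsid, rownames(ld))
  if (length(absent) > 0) {
    stop("missing-LD error: rsid(s) absent from LD matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  remaining <- t[order(t$pval, t$rsid), , drop = FALSE]
  keep <- character(0)
  while (nrow(remaining) > 0) {
    lead <- remaining$rsid[1]
    keep <- c(keep, lead)
    r2 <- ld[lead, remaining$rsid]
    remaining <- remaining[r2 <= r2_threshold & remaining$rsid != lead, ,
                           drop = FALSE]
  }
  restat(t[match(keep, t$rsid), , drop = FALSE], t)
}

#' Mean instrument F-statistic
#'
#' Instrument-strength diagnostic: the mean over variants of
#' `(beta / se)^2`. Values above 10 conventionally indicate instruments
#' strong enough that weak-instrument bias (and bias from moderate sample
#' overlap) is small.
#'
#' @param t a [sumstats] object with at least one row.
#' @return A single number.
#' @export
mean_f_statistic <- function(t) {
  stopifnot(inherits(t, "sumstats"))
  if (nrow(t) == 0) stop("empty-input error: no variants for F-statistic")
  mean((t$beta / t$se)^2)
}

#' Exclude named variants
#'
#' Removes listed rsids (for example a known uniquely pleiotropic instrument
#' in a sensitivity analysis). Listed rsids absent from the table are noted
#' via `message()` and ignored.
#'
#' @param t a [sumstats] object.
#' @param rsids character vector of variant identifiers to drop.
#' @return A [sumstats] object without the listed rows.
#' @export
exclude_snps <- function(t, rsids) {
  stopifnot(inherits(t, "sumstats"))
  rsids <- as.character(rsids)
  absent <- setdiff(rsids, t$rsid)
  if (length(absent) > 0) {
    message("exclude_snps: ", length(absent),
            " rsid(s) not present, ignored: ",
            paste(utils::head(absent, 5), collapse = ", "))
  }
  restat(t[!(t$rsid %in% rsids), , drop = FALSE], t)
}
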
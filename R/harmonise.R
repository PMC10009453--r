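COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonise exposure and outcome summary statistics
#'
#' Places the outcome association for every variant shared between the two
#' tables on the exposure's effect-allele orientation, so that each row
#' carries a (gamma, Gamma) pair ready for MR estimation. For each shared
#' rsid:
#'
#' * alleles match directly: kept as-is;
#' * alleles match with effect/other swapped: outcome beta negated, outcome
#'   eaf complemented (`kept_flipped`);
#' * alleles match only after strand complement (A<->T, C<->G): complement
#'   applied, then the two rules above (`kept_strand_corrected`);
#' * palindromic variant (A/T or C/G), where strand is unresolvable from
#'   alleles: kept only when both allele frequencies fall on the same side
#'   of 0.5 and both are outside `[palindrome_eaf_limit,
#'   1 - palindrome_eaf_limit]` (i.e. informative); otherwise
#'   `dropped_palindromic`. Missing eaf on either side drops the pair.
#' * irreconcilable alleles: `dropped_incompatible`.
#'
#' Variants absent from either table are omitted entirely. Every exclusion
#' is a recorded disposition, never an error.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_limit frequency boundary in (0, 0.5); palindromic
#'   variants with either eaf inside `(limit, 1 - limit)` are considered
#'   ambiguous and dropped. Default 0.42, the convention of standard
#'   harmonisation tooling.
#' @return A `harmonised` data frame with columns `rsid`, `effect_allele`,
#'   `other_allele` (exposure orientation), `beta_exp`, `se_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `eaf_out`, `disposition`; attributes
#'   `exposure_name`, `outcome_name` and a `tally` of dispositions. Dropped
#'   rows carry `NA` effects so nothing propagates downstream.
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (!is.numeric(palindrome_eaf_limit) || palindrome_eaf_limit <= 0 ||
      palindrome_eaf_limit >= 0.5) {
    stop("palindrome_eaf_limit must lie in (0, 0.5)")
  }
  shared <- intersect(exposure$rsid, outcome$rsid)
  e <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  o <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  n <- length(shared)
  disposition <- character(n)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    ea_e <- e$effect_allele[i]; oa_e <- e$other_allele[i]
    ea_o <- o$effect_allele[i]; oa_o <- o$other_allele[i]
    b <- o$beta[i]; s <- o$se[i]; f <- o$eaf[i]

    if (is_palindromic(ea_e, oa_e)) {
      # Strand cannot distinguish the two orientations; use frequency.
      f_e <- e$eaf[i]
      lim <- palindrome_eaf_limit
      informative <- function(x) !is.na(x) & (x < lim | x > 1 - lim)
      if (!is_palindromic(ea_o, oa_o) ||
          !(ea_o %in% c(ea_e, COMPLEMENT[ea_e]))) {
        disposition[i] <- "dropped_incompatible"
        next
      }
      if (!informative(f_e) || !informative(f)) {
        disposition[i] <- "dropped_palindromic"
        next
      }
      same_side <- (f_e < 0.5) == (f < 0.5)
      if (same_side) {
        # Frequencies agree: outcome effect allele is the exposure's effect
        # allele (up to strand), keep orientation as reported.
        disposition[i] <- "kept_as_is"
        beta_out[i] <- b; se_out[i] <- s; eaf_out[i] <- f
      } else {
        disposition[i] <- "kept_flipped"
        beta_out[i] <- -b; se_out[i] <- s; eaf_out[i] <- 1 - f
      }
      next
    }

    if (ea_o == ea_e && oa_o == oa_e) {
      disposition[i] <- "kept_as_is"
      beta_out[i] <- b; se_out[i] <- s; eaf_out[i] <- f
    } else if (ea_o == oa_e && oa_o == ea_e) {
      disposition[i] <- "kept_flipped"
      beta_out[i] <- -b; se_out[i] <- s; eaf_out[i] <- 1 - f
    } else if (COMPLEMENT[ea_o] == ea_e && COMPLEMENT[oa_o] == oa_e) {
      disposition[i] <- "kept_strand_corrected"
      beta_out[i] <- b; se_out[i] <- s; eaf_out[i] <- f
    } else if (COMPLEMENT[ea_o] == oa_e && COMPLEMENT[oa_o] == ea_e) {
      disposition[i] <- "kept_strand_corrected"
      beta_out[i] <- -b; se_out[i] <- s; eaf_out[i] <- 1 - f
    } else {
      disposition[i] <- "dropped_incompatible"
    }
  }

  kept <- startsWith(disposition, "kept")
  out <- data.frame(
    rsid = shared,
    effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    beta_exp = ifelse(kept, e$beta, NA_real_),
    se_exp = ifelse(kept, e$se, NA_real_),
    eaf_exp = e$eaf,
    beta_out = beta_out,
    se_out = se_out,
    eaf_out = eaf_out,
    disposition = disposition,
    stringsAsFactors = FALSE
  )
  tally <- table(factor(disposition, levels = c(
    "kept_as_is", "kept_flipped", "kept_strand_corrected",
    "dropped_palindromic", "dropped_incompatible")))
  structure(out,
            exposure_name = attr(exposure, "trait_name"),
            outcome_name = attr(outcome, "trait_name"),
            exposure_type = attr(exposure, "trait_type"),
            tally = tally,
            class = c("harmonised", "data.frame"))
}

#' @export
print.harmonised <- function(x, ...) {
  cat("Harmonised set: ", attr(x, "exposure_name"), " -> ",
      attr(x, "outcome_name"), "\n", sep = "")
  t <- attr(x, "tally")
  cat(sum(t[startsWith(names(t), "kept")]), " kept / ",
      sum(t[startsWith(names(t), "dropped")]), " dropped\n", sep = "")
  print(t)
  invisible(x)
}

# Subset a harmonised set to rows kept for estimation.
kept_pairs <- function(h) {
  stopifnot(inherits(h, "harmonised"))
  h[startsWith(h$disposition, "kept"), , drop = FALSE]
}

rehm <- function(df, template) {
  structure(as.data.frame(df),
            exposure_name = attr(template, "exposure_name"),
            outcome_name = attr(template, "outcome_name"),
            exposure_type = attr(template, "exposure_type"),
            tally = attr(template, "tally"),
            class = c("harmonised", "data.frame"))
}

#' Orient exposure effects positive
#'
#' For every kept pair with a negative exposure effect, negates both the
#' exposure and outcome effects. Per-variant Wald ratios are unchanged; the
#' orientation is the convention MR-Egger requires so that its intercept has
#' a consistent sign interpretation.
#'
#' @param h a `harmonised` set (see [harmonise()]).
#' @return The harmonised set with all kept `beta_exp >= 0`.
#' @export
orient_exposure_positive <- function(h) {
  stopifnot(inherits(h, "harmonised"))
  flip <- !is.na(h$beta_exp) & h$beta_exp < 0
  h$beta_exp[flip] <- -h$beta_exp[flip]
  h$beta_out[flip] <- -h$beta_out[flip]
  if (!is.null(h$eaf_exp)) h$eaf_exp[flip] <- 1 - h$eaf_exp[flip]
  if (!is.null(h$eaf_out)) h$eaf_out[flip] <- 1 - h$eaf_out[flip]
  h
}
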
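# Builders for small in-code fixtures.

# A sumstats table from parallel vectors, defaulting to unambiguous A/G
# variants at eaf 0.3.
make_ss <- function(beta, se, pval = NULL, rsid = NULL,
                    ea = "A", oa = "G", eaf = 0.3, n = 1e5,
                    trait_name = "trait",
                    trait_type = "binary_disease") {
  J <- length(beta)
  sumstats(data.frame(
    rsid = rsid %||% sprintf("rs%04d", seq_len(J)),
    effect_allele = rep_len(ea, J),
    other_allele = rep_len(oa, J),
    eaf = rep_len(eaf, J),
    beta = beta,
    se = rep_len(se, J),
    pval = pval %||% pmax(2 * pnorm(-abs(beta / rep_len(se, J))), 1e-300),
    n = rep_len(n, J),
    stringsAsFactors = FALSE
  ), trait_name = trait_name, trait_type = trait_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A harmonised set built directly from effect vectors (all rows kept),
# bypassing allele logic so estimator tests control the inputs exactly.
make_harmonised <- function(bx, sx, by, so, exposure_type = "binary_disease") {
  J <- length(bx)
  structure(data.frame(
    rsid = sprintf("rs%04d", seq_len(J)),
    effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = rep_len(sx, J),
    eaf_exp = 0.3,
    beta_out = by, se_out = rep_len(so, J),
    eaf_out = 0.3,
    disposition = "kept_as_is",
    stringsAsFactors = FALSE
  ),
  exposure_name = "exposure", outcome_name = "outcome",
  exposure_type = exposure_type,
  tally = table(factor(rep("kept_as_is", J), levels = c(
    "kept_as_is", "kept_flipped", "kept_strand_corrected",
    "dropped_palindromic", "dropped_incompatible"))),
  class = c("harmonised", "data.frame"))
}

# Fabricate an mr_panel from per-trait (beta, se) vectors, for functions
# that only consume panel estimates (profile comparison, contrasts).
make_panel <- function(betas, ses, method = "ivw", exposure = "exp",
                       stratum = "all_ages") {
  fits <- lapply(seq_along(betas), function(i) {
    est <- list(method = method, beta = betas[i], se = ses[i],
                ci_low = betas[i] - 1.96 * ses[i],
                ci_high = betas[i] + 1.96 * ses[i],
                pval = 2 * pnorm(-abs(betas[i] / ses[i])),
                n_snp = 10L, scaled_per_doubling = FALSE)
    class(est) <- "mr_estimate"
    structure(list(estimates = setNames(list(est), method),
                   heterogeneity = list(), n_snp = 10L,
                   exposure = exposure, outcome = paste0("trait_", i),
                   scaled_per_doubling = FALSE, data = NULL),
              class = "mr_fit")
  })
  names(fits) <- paste0("trait_", seq_along(betas))
  structure(list(fits = fits, failures = character(0),
                 exposure_name = exposure, stratum_label = stratum,
                 methods = method),
            class = "mr_panel")
}

# Independent brute-force weighted-median oracle: cumulative-weight
# percentile on the sorted ratios, written against the definition.
oracle_weighted_median <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  p <- w[o] / sum(w)
  s <- cumsum(p) - p / 2
  stats::approx(s, r, xout = 0.5, rule = 2)$y
}

# Independent density-grid argmax oracle for the weighted mode.
oracle_weighted_mode <- function(ratio, w, phi = 1) {
  s <- 0.9 * min(sd(ratio), mad(ratio)) / length(ratio)^(1 / 5)
  if (s == 0) s <- 0.9 * sd(ratio) / length(ratio)^(1 / 5)
  h <- phi * s
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- sapply(grid, function(g) sum(w / sum(w) * dnorm((ratio - g) / h)))
  grid[which.max(dens)]
}
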
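#' Multivariable MR (IVW) for two or more liabilities
#'
#' Estimates direct effects of several (typically two, correlated) disease
#' liabilities on one outcome, using all variants associated with either
#' exposure as instruments. The instrument union is selected at
#' `p_threshold` across the exposures, pruned by LD when a matrix is
#' supplied, and every variant must carry associations with all exposures
#' and the outcome (others are dropped and tallied). Additional exposures
#' are harmonised against the first so all effects share one effect-allele
#' orientation, and the outcome is harmonised against the first exposure.
#' The fit is a zero-intercept weighted regression of outcome effects on
#' the exposure-effect columns with weights `1/se_out^2`; each coefficient
#' is the direct effect of that liability conditional on the others. SEs
#' use the weighted regression with multiplicative overdispersion
#' inflation `max(1, sqrt(Q / (J - p)))` as in [mr_ivw()].
#'
#' @param exposures list of [sumstats] objects (binary disease
#'   liabilities), normally two or more. A single-exposure list is
#'   accepted and reduces exactly to the univariable fixed-design IVW —
#'   useful for verification; pipeline configuration requires two.
#' @param outcome a [sumstats] object.
#' @param ld optional r-squared matrix for pruning the instrument union.
#' @param p_threshold instrument selection threshold (default 5e-8).
#' @param r2_threshold pruning threshold (default 0.001).
#' @param scale scale estimates per doubling of liability (default `TRUE`).
#' @return Object of class `mvmr_fit`: `exposure_names`, `betas`, `ses`,
#'   `pvals`, `ci_low`, `ci_high`, `n_snp`, `n_dropped`, `mean_f`
#'   (marginal mean F per exposure), `q`, `note`.
#' @export
mvmr_ivw <- function(exposures, outcome, ld = NULL, p_threshold = 5e-8,
                     r2_threshold = 0.001, scale = TRUE) {
  if (!is.list(exposures) || length(exposures) < 1) {
    stop("config-validation error: multivariable MR needs a list of exposures")
  }
  lapply(exposures, function(e) stopifnot(inherits(e, "sumstats")))
  stopifnot(inherits(outcome, "sumstats"))
  p <- length(exposures)
  names_exp <- vapply(exposures, attr, "", "trait_name")

  # Instrument union across exposures, pruned jointly on the smallest
  # p-value any exposure assigns to the variant.
  sig <- lapply(exposures, function(e) {
    e$rsid[e$pval < p_threshold]
  })
  union_rsid <- Reduce(union, sig)
  if (!is.null(ld)) {
    pmin_tab <- do.call(rbind, lapply(exposures, function(e) {
      e[e$rsid %in% union_rsid, c("rsid", "effect_allele", "other_allele",
                                  "eaf", "beta", "se", "pval", "n")]
    }))
    pmin_tab <- pmin_tab[order(pmin_tab$pval), , drop = FALSE]
    pmin_tab <- pmin_tab[!duplicated(pmin_tab$rsid), , drop = FALSE]
    joint <- sumstats(pmin_tab, trait_name = "instrument_union",
                      trait_type = "binary_disease")
    union_rsid <- ld_prune(joint, ld, r2_threshold)$rsid
  }

  keep1 <- exposures[[1]]$rsid %in% union_rsid
  e1 <- restat(exposures[[1]][keep1, , drop = FALSE], exposures[[1]])

  # Align every further exposure, and the outcome, to exposure 1's
  # effect-allele orientation.
  gammas <- list(stats::setNames(e1$beta, e1$rsid))
  ses_exp <- list(stats::setNames(e1$se, e1$rsid))
  kept_sets <- list(e1$rsid)
  for (j in seq_len(p)[-1]) {
    hj <- harmonise(e1, exposures[[j]])
    kj <- kept_pairs(hj)
    gammas[[j]] <- stats::setNames(kj$beta_out, kj$rsid)
    ses_exp[[j]] <- stats::setNames(kj$se_out, kj$rsid)
    kept_sets[[j]] <- kj$rsid
  }
  ho <- harmonise(e1, outcome)
  ko <- kept_pairs(ho)
  kept_sets[[p + 1]] <- ko$rsid

  rs <- Reduce(intersect, kept_sets)
  n_dropped <- length(union_rsid) - length(rs)
  if (n_dropped > 0) {
    message("mvmr_ivw: ", n_dropped,
            " instrument(s) dropped (missing or unharmonisable in an ",
            "exposure or the outcome)")
  }
  J <- length(rs)
  if (J <= p) {
    stop("insufficient-instruments error: ", J, " usable instruments for ",
         p, " exposures")
  }

  X <- vapply(gammas, function(g) unname(g[rs]), numeric(J))
  y <- ko$beta_out[match(rs, ko$rsid)]
  se_out <- ko$se_out[match(rs, ko$rsid)]
  w <- 1 / se_out^2

  xtwx <- crossprod(X, X * w)
  # Collinearity guard on the weighted design.
  ev <- eigen(xtwx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
    stop("collinearity error: exposure effect columns are collinear")
  }
  xtwy <- crossprod(X, y * w)
  betas <- drop(solve(xtwx, xtwy))
  resid <- y - drop(X %*% betas)
  q <- sum(w * resid^2)
  infl <- if (J > p) max(1, sqrt(q / (J - p))) else 1
  ses <- sqrt(diag(solve(xtwx))) * infl

  mean_f <- vapply(seq_len(p), function(j) {
    mean((gammas[[j]][rs] / ses_exp[[j]][rs])^2)
  }, numeric(1))

  sc <- if (scale) log(2) else 1
  betas <- betas * sc
  ses <- ses * sc
  z <- betas / ses
  structure(list(exposure_names = names_exp,
                 betas = stats::setNames(betas, names_exp),
                 ses = stats::setNames(ses, names_exp),
                 ci_low = betas - stats::qnorm(0.975) * ses,
                 ci_high = betas + stats::qnorm(0.975) * ses,
                 pvals = stats::setNames(2 * stats::pnorm(-abs(z)), names_exp),
                 n_snp = J,
                 overdispersion = infl,
                 n_dropped = n_dropped,
                 mean_f = stats::setNames(mean_f, names_exp),
                 q = q,
                 scaled_per_doubling = scale,
                 note = paste("direct effects, each conditional on the",
                              "other exposure(s); marginal (not",
                              "conditional) mean F reported")),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat("Multivariable MR (IVW), J =", x$n_snp, "instruments",
      if (x$scaled_per_doubling) "(per doubling of liability)" else "", "\n")
  df <- data.frame(exposure = x$exposure_names, beta = unname(x$betas),
                   se = unname(x$ses), ci_low = unname(x$ci_low),
                   ci_high = unname(x$ci_high), pval = unname(x$pvals),
                   mean_F = unname(x$mean_f))
  print(df, row.names = FALSE, digits = 4)
  cat("Note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.mvmr_fit <- function(object, ...) object$betas
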
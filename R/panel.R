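#' Run MR estimators across a panel of outcome traits
#'
#' Harmonises the exposure instruments against each outcome table and runs
#' [mr_fit()] per outcome (e.g. a panel of NMR metabolic traits). A failure
#' on one outcome is recorded and does not abort the panel; results are
#' deterministic given `seed`.
#'
#' @param exposure a [sumstats] object of selected instruments.
#' @param outcomes named list of [sumstats] objects.
#' @param methods,re_model,n_boot,phi,seed,scale passed to [mr_fit()].
#' @param palindrome_eaf_limit passed to [harmonise()].
#' @param stratum_label label attached to the result (default
#'   `"all_ages"`).
#' @return Object of class `mr_panel`: `fits` (named list of `mr_fit`),
#'   `failures` (named character vector of error messages),
#'   `exposure_name`, `stratum_label`, `methods`. `as.data.frame` gives
#'   the long-format results table.
#' @export
run_panel <- function(exposure, outcomes,
                      methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode"),
                      re_model = "multiplicative_random",
                      n_boot = 1000, phi = 1, seed = 1, scale = NULL,
                      palindrome_eaf_limit = 0.42,
                      stratum_label = "all_ages") {
  stopifnot(inherits(exposure, "sumstats"))
  if (!is.list(outcomes) || length(outcomes) < 1) {
    stop("panel error: at least one outcome table is required")
  }
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes)))) {
    names(outcomes) <- vapply(outcomes, function(o)
      attr(o, "trait_name") %||% "outcome", "")
  }
  fits <- list()
  failures <- character(0)
  for (i in seq_along(outcomes)) {
    nm <- names(outcomes)[i]
    res <- tryCatch({
      h <- harmonise(exposure, outcomes[[i]],
                     palindrome_eaf_limit = palindrome_eaf_limit)
      mr_fit(h, methods = methods, re_model = re_model, n_boot = n_boot,
             phi = phi, seed = child_seed(seed, i), scale = scale)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
    } else {
      fits[[nm]] <- res
    }
  }
  if (length(fits) == 0) {
    stop("panel error: every outcome failed; first error: ", failures[1])
  }
  structure(list(fits = fits, failures = failures,
                 exposure_name = attr(exposure, "trait_name"),
                 stratum_label = stratum_label,
                 methods = methods),
            class = "mr_panel")
}

#' @export
print.mr_panel <- function(x, ...) {
  cat("MR panel: ", x$exposure_name, " -> ", length(x$fits),
      " outcome(s) [stratum: ", x$stratum_label, "]\n", sep = "")
  if (length(x$failures) > 0) {
    cat(length(x$failures), "outcome(s) failed:",
        paste(names(x$failures), collapse = ", "), "\n")
  }
  df <- as.data.frame(x)
  print(utils::head(df[df$method == "ivw", ], 10), row.names = FALSE,
        digits = 4)
  invisible(x)
}

#' @export
as.data.frame.mr_panel <- function(x, ...) {
  rows <- lapply(names(x$fits), function(nm) {
    df <- as.data.frame(x$fits[[nm]])
    df$outcome <- nm
    df$stratum <- x$stratum_label
    df
  })
  out <- do.call(rbind, rows)
  out[, c("exposure", "outcome", "stratum", "method", "beta", "se",
          "ci_low", "ci_high", "pval", "n_snp", "scaled", "q", "q_df",
          "q_pval")]
}

panel_estimates <- function(p, method) {
  found <- vapply(p$fits, function(f) method %in% names(f$estimates),
                  logical(1))
  if (!all(found)) {
    stop("alignment error: method '", method, "' absent for outcome(s): ",
         paste(names(found)[!found], collapse = ", "))
  }
  b <- vapply(p$fits, function(f) f$estimates[[method]]$beta, numeric(1))
  s <- vapply(p$fits, function(f) f$estimates[[method]]$se, numeric(1))
  data.frame(outcome = names(p$fits), beta = b, se = s,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-stratum contrast of MR estimates
#'
#' Per-outcome z-test of the difference between two strata's estimates
#' (e.g. age tertiles): `z = (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)`,
#' two-sided normal p-value. Valid when the strata are estimated in
#' non-overlapping samples (disjoint age tertiles of one cohort satisfy
#' this by construction). This formal contrast is an addition over simply
#' reporting per-stratum estimates side by side, and is labelled as such
#' in pipeline output.
#'
#' @param a,b `mr_panel` objects covering the same outcomes.
#' @param method estimator to contrast (default `"ivw"`).
#' @return Data frame of class `stratum_contrast` with columns `outcome`,
#'   `stratum_a`, `stratum_b`, `beta_a`, `beta_b`, `delta`, `se_delta`,
#'   `z`, `pval`.
#' @export
stratum_contrast <- function(a, b, method = "ivw") {
  stopifnot(inherits(a, "mr_panel"), inherits(b, "mr_panel"))
  if (!setequal(names(a$fits), names(b$fits))) {
    stop("alignment error: the two panels cover different outcome sets")
  }
  ea <- panel_estimates(a, method)
  eb <- panel_estimates(b, method)
  eb <- eb[match(ea$outcome, eb$outcome), , drop = FALSE]
  delta <- ea$beta - eb$beta
  se_delta <- sqrt(ea$se^2 + eb$se^2)
  z <- delta / se_delta
  out <- data.frame(outcome = ea$outcome,
                    stratum_a = a$stratum_label,
                    stratum_b = b$stratum_label,
                    method = method,
                    beta_a = ea$beta, se_a = ea$se,
                    beta_b = eb$beta, se_b = eb$se,
                    delta = delta, se_delta = se_delta, z = z,
                    pval = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  class(out) <- c("stratum_contrast", "data.frame")
  out
}

#' Effective number of tests for a correlated trait panel
#'
#' Principal-component based multiplicity correction for correlated
#' outcomes: the effective number of tests is the smallest number of
#' principal components of the trait correlation matrix whose eigenvalues
#' sum to at least `variance_fraction` of the total trait count, and the
#' adjusted significance threshold is `alpha` divided by that count. The
#' threshold is additionally reported rounded to one significant figure
#' (e.g. alpha 0.05 over 33 components gives 0.0015..., reported as
#' 0.002).
#'
#' @param panel_corr symmetric positive semi-definite trait correlation
#'   matrix with unit diagonal.
#' @param variance_fraction fraction of variance to cover, in (0, 1);
#'   default 0.95.
#' @param alpha nominal significance level, default 0.05.
#' @return List with `n_components`, `threshold` (exact) and
#'   `threshold_rounded` (one significant figure).
#' @export
effective_tests_threshold <- function(panel_corr, variance_fraction = 0.95,
                                      alpha = 0.05) {
  if (!is.matrix(panel_corr) || nrow(panel_corr) != ncol(panel_corr)) {
    stop("matrix error: panel correlation must be square")
  }
  if (max(abs(panel_corr - t(panel_corr))) > 1e-8) {
    stop("matrix error: panel correlation must be symmetric")
  }
  if (max(abs(diag(panel_corr) - 1)) > 1e-8) {
    stop("matrix error: panel correlation must have unit diagonal")
  }
  if (variance_fraction <= 0 || variance_fraction >= 1) {
    stop("variance_fraction must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ev <- eigen(panel_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("matrix error: panel correlation is not positive semi-definite")
  }
  ev <- pmax(ev, 0)
  target <- variance_fraction * nrow(panel_corr)
  n_components <- which(cumsum(ev) >= target - 1e-12)[1]
  threshold <- alpha / n_components
  list(n_components = as.integer(n_components),
       threshold = threshold,
       threshold_rounded = signif(threshold, 1))
}

#' Cross-disease profile comparison
#'
#' Compares the overall pattern of two liabilities' effects across a
#' shared trait panel: ordinary least-squares regression (with intercept)
#' of exposure-2 estimates on exposure-1 estimates across the shared
#' traits, reporting slope, intercept, R-squared and trait count. A slope
#' near zero with small R-squared indicates largely distinct metabolic
#' profiles of the two liabilities.
#'
#' @param p1,p2 `mr_panel` objects for the two exposures.
#' @param method estimator whose estimates are compared (default
#'   `"ivw"`).
#' @param trait_subset optional character vector restricting the
#'   comparison to named traits.
#' @return Object of class `profile_comparison`: `slope`, `intercept`,
#'   `r2`, `n_traits`, `traits`, `x`, `y`, `exposure_x`, `exposure_y`;
#'   with a `plot` method drawing the XY scatter.
#' @export
profile_comparison <- function(p1, p2, method = "ivw",
                               trait_subset = NULL) {
  stopifnot(inherits(p1, "mr_panel"), inherits(p2, "mr_panel"))
  e1 <- panel_estimates(p1, method)
  e2 <- panel_estimates(p2, method)
  shared <- intersect(e1$outcome, e2$outcome)
  if (!is.null(trait_subset)) shared <- intersect(shared, trait_subset)
  if (length(shared) < 3) {
    stop("insufficient-traits error: fewer than 3 shared traits")
  }
  x <- e1$beta[match(shared, e1$outcome)]
  y <- e2$beta[match(shared, e2$outcome)]
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 n_traits = length(shared),
                 traits = shared, x = x, y = y,
                 exposure_x = p1$exposure_name,
                 exposure_y = p2$exposure_name,
                 method = method),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("Profile comparison (", x$method, "): ", x$exposure_y, " on ",
      x$exposure_x, " across ", x$n_traits, " traits\n", sep = "")
  cat(sprintf("slope = %.3f, intercept = %.4f, R^2 = %.3f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' @export
plot.profile_comparison <- function(x, ...) {
  graphics::plot(x$x, x$y,
                 xlab = paste("Effect of", x$exposure_x),
                 ylab = paste("Effect of", x$exposure_y),
                 main = sprintf("Effect profiles (%s): slope %.2f, R2 %.2f",
                                x$method, x$slope, x$r2), ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "red3")
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}
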
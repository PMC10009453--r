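mr_estimate <- function(method, beta, se, n_snp, scaled = FALSE,
                        q = NULL, q_df = NULL) {
  z <- beta / se
  out <- list(method = method, beta = beta, se = se,
              ci_low = beta - stats::qnorm(0.975) * se,
              ci_high = beta + stats::qnorm(0.975) * se,
              pval = 2 * stats::pnorm(-abs(z)),
              n_snp = n_snp, scaled_per_doubling = scaled)
  if (!is.null(q)) {
    out$q <- q
    out$q_df <- q_df
    out$q_pval <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  }
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%-18s beta %8.4f  se %7.4f  95%% CI [%7.4f, %7.4f]  p %.3g  (J = %d%s)\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp,
              if (x$scaled_per_doubling) ", per doubling" else ""))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
                x$q, x$q_df, x$q_pval))
  }
  invisible(x)
}

check_pairs <- function(h, min_snp, what) {
  k <- kept_pairs(h)
  if (nrow(k) < min_snp) {
    stop("insufficient-instruments error: ", what, " needs at least ",
         min_snp, " kept variants, got ", nrow(k))
  }
  k
}

#' Per-variant Wald ratios
#'
#' The building block of every summary-data MR estimator: for each kept
#' variant, the ratio estimate `beta_out / beta_exp` with first-order
#' standard error `se_out / |beta_exp|` (exposure uncertainty ignored, the
#' convention of standard two-sample MR tooling) and a normal 95% CI.
#'
#' @param h a `harmonised` set (see [harmonise()]).
#' @return Data frame with columns `rsid`, `ratio`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
wald_ratio <- function(h) {
  k <- check_pairs(h, 1, "wald_ratio")
  if (any(k$beta_exp == 0)) {
    stop("degenerate-instrument error: exposure effect is exactly zero for ",
         paste(utils::head(k$rsid[k$beta_exp == 0], 3), collapse = ", "))
  }
  ratio <- k$beta_out / k$beta_exp
  se <- k$se_out / abs(k$beta_exp)
  data.frame(rsid = k$rsid, ratio = ratio, se = se,
             ci_low = ratio - stats::qnorm(0.975) * se,
             ci_high = ratio + stats::qnorm(0.975) * se,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted (IVW) estimator
#'
#' Zero-intercept weighted regression of outcome effects on exposure
#' effects with weights `1/se_out^2`; equivalently the inverse-variance
#' weighted mean of per-variant Wald ratios with first-order weights
#' `beta_exp^2 / se_out^2`. Consistent when every instrument is valid (no
#' horizontal pleiotropy). The default multiplicative random-effects model
#' inflates the fixed-effect SE by `max(1, sqrt(Q / (J - 2)))`, where Q is
#' Cochran's heterogeneity statistic about the fit; Q is referred to a
#' chi-square with J - 1 degrees of freedom.
#'
#' @param h a `harmonised` set.
#' @param re_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return List with components `estimate` (an `mr_estimate`, which also
#'   carries `q`, `q_df`, `q_pval`) and `heterogeneity` (list `q`, `df`,
#'   `pval`).
#' @export
mr_ivw <- function(h, re_model = c("multiplicative_random", "fixed")) {
  re_model <- match.arg(re_model)
  k <- check_pairs(h, 2, "IVW")
  J <- nrow(k)
  w <- 1 / k$se_out^2
  bx <- k$beta_exp
  by <- k$beta_out
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  if (re_model == "multiplicative_random" && J > 2) {
    se <- se * max(1, sqrt(q / (J - 2)))
  }
  het <- list(q = q, df = J - 1,
              pval = stats::pchisq(q, df = J - 1, lower.tail = FALSE))
  list(estimate = mr_estimate("ivw", beta, se, J, q = q, q_df = J - 1),
       heterogeneity = het)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' intercept, weights `1/se_out^2`, after orienting all exposure effects
#' positive. The slope estimates the causal effect allowing all instruments
#' to be pleiotropic (under the InSIDE assumption); the intercept estimates
#' the average directional pleiotropy, and its p-value is the standard
#' pleiotropy test. SEs are inflated by `max(1, sqrt(Q_E / (J - 2)))`,
#' where Q_E is Rucker's heterogeneity statistic about the Egger fit.
#'
#' @param h a `harmonised` set with at least 3 kept variants.
#' @return List with components `slope`, `intercept` (both `mr_estimate`)
#'   and `heterogeneity` (list `q`, `df`, `pval`, about the Egger fit on
#'   J - 2 df).
#' @export
mr_egger <- function(h) {
  k <- check_pairs(orient_exposure_positive(h), 3, "MR-Egger")
  J <- nrow(k)
  w <- 1 / k$se_out^2
  bx <- k$beta_exp
  by <- k$beta_out
  # Weighted normal equations for [intercept, slope].
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  if (abs(det) < 1e-300) stop("MR-Egger design is degenerate (constant exposure effects)")
  a <- (swx2 * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  q <- sum(w * (by - a - b * bx)^2)
  infl <- max(1, sqrt(q / (J - 2)))
  se_a <- sqrt(swx2 / det) * infl
  se_b <- sqrt(sw / det) * infl
  het <- list(q = q, df = J - 2,
              pval = stats::pchisq(q, df = J - 2, lower.tail = FALSE))
  list(slope = mr_estimate("egger_slope", b, se_b, J, q = q, q_df = J - 2),
       intercept = mr_estimate("egger_intercept", a, se_a, J),
       heterogeneity = het)
}

weighted_median_est <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  wn <- w[o] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

boot_se <- function(k, n_boot, seed, estimator) {
  with_seed(seed, {
    est <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      bx <- stats::rnorm(nrow(k), k$beta_exp, k$se_exp)
      by <- stats::rnorm(nrow(k), k$beta_out, k$se_out)
      est[b] <- estimator(bx, by, k$se_out)
    }
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' The weighted median of per-variant Wald ratios with inverse-variance
#' weights `beta_exp^2 / se_out^2`: order the ratios, form cumulative
#' normalized weights `s_j = sum_{k<=j} w'_k - w'_j / 2`, and linearly
#' interpolate the ordered ratios at `s = 0.5`. Consistent when at least
#' half of the total weight comes from valid instruments, and less
#' influenced by outliers than regression-based models. The SE is the
#' standard deviation of the estimate over parametric-bootstrap resamples
#' of the summary statistics from their normal sampling distributions.
#'
#' @param h a `harmonised` set with at least 3 kept variants.
#' @param n_boot bootstrap resamples (at least 100; default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  k <- check_pairs(h, 3, "weighted median")
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (missing(seed)) stop("seed is required for the bootstrap SE")
  wm <- function(bx, by, se_out) {
    weighted_median_est(by / bx, bx^2 / se_out^2)
  }
  beta <- wm(k$beta_exp, k$beta_out, k$se_out)
  se <- boot_se(k, n_boot, seed, wm)
  mr_estimate("weighted_median", beta, se, nrow(k))
}

weighted_mode_est <- function(ratio, w, phi) {
  if (diff(range(ratio)) == 0) return(ratio[1])
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) / length(ratio)^(1 / 5)
  if (s == 0) s <- 0.9 * stats::sd(ratio) / length(ratio)^(1 / 5)
  h_bw <- phi * s
  grid <- seq(min(ratio) - 3 * h_bw, max(ratio) + 3 * h_bw, length.out = 512)
  wn <- w / sum(w)
  dens <- vapply(grid, function(g) sum(wn * stats::dnorm((ratio - g) / h_bw)),
                 numeric(1))
  peaks <- which(dens == max(dens))
  # Break exact ties toward the grid midpoint.
  grid[peaks[which.min(abs(peaks - (length(grid) + 1) / 2))]]
}

#' Weighted mode estimator
#'
#' Mode-based estimate: the argmax of a weighted normal-kernel density of
#' the per-variant Wald ratios, with inverse-variance weights
#' `beta_exp^2 / se_out^2`. Consistent when the largest homogeneous cluster
#' of instruments is valid, i.e. the most common ratio reflects the true
#' causal effect. The kernel bandwidth is `phi` times a robust plug-in
#' scale, `0.9 * min(sd, mad) / J^(1/5)`, computed on the ratio
#' distribution; the density is evaluated on a 512-point grid spanning the
#' ratios plus three bandwidths, with argmax ties broken toward the grid
#' midpoint. SE by parametric bootstrap as in [mr_weighted_median()].
#'
#' @param h a `harmonised` set with at least 3 kept variants.
#' @param phi bandwidth multiplier (> 0, default 1).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(h, phi = 1, n_boot = 1000, seed) {
  k <- check_pairs(h, 3, "weighted mode")
  if (!is.numeric(phi) || phi <= 0) {
    stop("parameter error: phi must be positive (zero bandwidth)")
  }
  if (missing(seed)) stop("seed is required for the bootstrap SE")
  wmode <- function(bx, by, se_out) {
    weighted_mode_est(by / bx, bx^2 / se_out^2, phi)
  }
  beta <- wmode(k$beta_exp, k$beta_out, k$se_out)
  se <- boot_se(k, n_boot, seed, wmode)
  mr_estimate("weighted_mode", beta, se, nrow(k))
}

#' Scale an estimate per doubling of genetic liability
#'
#' Multiplies the effect, SE and CI bounds by ln 2 (0.693...), converting a
#' per-unit-log-odds estimate into the SD-unit difference in the outcome
#' per doubling of genetic liability to the disease. The z-statistic, and
#' hence the p-value, is unchanged. Applying the scaling twice is an error.
#'
#' @param e an `mr_estimate`, or an `mr_fit` (all contained estimates are
#'   scaled).
#' @return The scaled object with `scaled_per_doubling` set.
#' @export
scale_per_doubling <- function(e) UseMethod("scale_per_doubling")

#' @export
scale_per_doubling.mr_estimate <- function(e) {
  if (isTRUE(e$scaled_per_doubling)) {
    stop("state error: estimate is already scaled per doubling of liability")
  }
  for (f in c("beta", "se", "ci_low", "ci_high")) e[[f]] <- e[[f]] * log(2)
  e$scaled_per_doubling <- TRUE
  e
}

#' @export
scale_per_doubling.mr_fit <- function(e) {
  e$estimates <- lapply(e$estimates, scale_per_doubling)
  e$scaled_per_doubling <- TRUE
  e
}

#' Fit two-sample MR estimators to a harmonised set
#'
#' The package's main fitting function: runs the requested estimators on
#' one harmonised exposure-outcome pair and returns a classed fit with
#' `print`, `summary`, `coef`, `confint`, `plot` and `as.data.frame`
#' methods. With all methods requested the fit contains exactly five
#' labelled estimates (`ivw`, `egger_slope`, `egger_intercept`,
#' `weighted_median`, `weighted_mode`) plus the IVW and Egger
#' heterogeneity statistics. When the exposure is a binary disease
#' (genetic liability), estimates are scaled per doubling of liability by
#' default (see [scale_per_doubling()]).
#'
#' @param h a `harmonised` set (see [harmonise()]).
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "weighted_mode")`.
#' @param re_model IVW variance model, see [mr_ivw()].
#' @param n_boot,phi bootstrap resamples and mode bandwidth multiplier.
#' @param seed RNG seed for bootstrap SEs.
#' @param scale logical: scale estimates per doubling of liability.
#'   Defaults to `TRUE` when the exposure trait is a binary disease.
#' @return An object of class `mr_fit`.
#' @examples
#' sim <- simulate_study(sim_config(n_snp = 50, seed = 1))
#' h <- harmonise(sim$exposure, sim$outcome)
#' fit <- mr_fit(h, seed = 1, n_boot = 200)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(h,
                   methods = c("ivw", "egger", "weighted_median",
                               "weighted_mode"),
                   re_model = "multiplicative_random",
                   n_boot = 1000, phi = 1, seed = 1,
                   scale = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(scale)) {
    scale <- identical(attr(h, "exposure_type"), "binary_disease")
  }
  estimates <- list()
  heterogeneity <- list()
  if ("ivw" %in% methods) {
    r <- mr_ivw(h, re_model = re_model)
    estimates$ivw <- r$estimate
    heterogeneity$ivw <- r$heterogeneity
  }
  if ("egger" %in% methods) {
    r <- mr_egger(h)
    estimates$egger_slope <- r$slope
    estimates$egger_intercept <- r$intercept
    heterogeneity$egger <- r$heterogeneity
  }
  if ("weighted_median" %in% methods) {
    estimates$weighted_median <-
      mr_weighted_median(h, n_boot = n_boot, seed = child_seed(seed, 1))
  }
  if ("weighted_mode" %in% methods) {
    estimates$weighted_mode <-
      mr_weighted_mode(h, phi = phi, n_boot = n_boot,
                       seed = child_seed(seed, 2))
  }
  fit <- structure(list(estimates = estimates,
                        heterogeneity = heterogeneity,
                        n_snp = nrow(kept_pairs(h)),
                        exposure = attr(h, "exposure_name"),
                        outcome = attr(h, "outcome_name"),
                        scaled_per_doubling = FALSE,
                        data = h),
                   class = "mr_fit")
  if (scale) fit <- scale_per_doubling(fit)
  fit
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR fit: ", x$exposure, " -> ", x$outcome,
      "  (J = ", x$n_snp, " instruments",
      if (x$scaled_per_doubling) "; per doubling of liability" else "",
      ")\n", sep = "")
  for (e in x$estimates) print(e)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  cat("Two-sample MR: effect of", object$exposure, "on", object$outcome, "\n")
  cat("Instruments:", object$n_snp, "\n")
  if (object$scaled_per_doubling) {
    cat("Units: SD of outcome per doubling of genetic liability\n")
  }
  df <- as.data.frame(object)
  print(df, row.names = FALSE, digits = 4)
  if (!is.null(object$heterogeneity$ivw)) {
    hq <- object$heterogeneity$ivw
    cat(sprintf("IVW heterogeneity: Q = %.2f on %d df (p = %.3g)\n",
                hq$q, hq$df, hq$pval))
  }
  invisible(df)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- t(vapply(object$estimates,
                function(e) c(e$beta - z * e$se, e$beta + z * e$se),
                numeric(2)))
  colnames(m) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  rows <- lapply(x$estimates, function(e) {
    data.frame(exposure = x$exposure, outcome = x$outcome,
               method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               n_snp = e$n_snp, scaled = e$scaled_per_doubling,
               q = e$q %||% NA_real_, q_df = e$q_df %||% NA_integer_,
               q_pval = e$q_pval %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
plot.mr_fit <- function(x, ...) {
  k <- kept_pairs(x$data)
  sc <- if (x$scaled_per_doubling) log(2) else 1
  graphics::plot(k$beta_exp, k$beta_out * sc,
                 xlab = "SNP effect on exposure (log odds)",
                 ylab = if (x$scaled_per_doubling)
                   "SNP effect on outcome (scaled)" else
                   "SNP effect on outcome (SD)",
                 main = paste(x$exposure, "->", x$outcome), ...)
  cols <- c(ivw = "black", egger_slope = "red3",
            weighted_median = "blue3", weighted_mode = "darkgreen")
  shown <- character(0)
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    if (nm == "egger_intercept") next
    icept <- if (nm == "egger_slope")
      x$estimates$egger_intercept$beta else 0
    graphics::abline(a = icept, b = e$beta, col = cols[[nm]],
                     lty = if (nm == "ivw") 1 else 2)
    shown <- c(shown, nm)
  }
  graphics::legend("topleft", legend = shown, col = cols[shown],
                   lty = ifelse(shown == "ivw", 1, 2), bty = "n", cex = 0.8)
  invisible(x)
}
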
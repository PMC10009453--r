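#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Bundles the full generative specification for the synthetic
#' summary-statistics generator. The generator draws per-variant liability
#' effects, forms outcome effects through the causal-plus-pleiotropy model
#' `Gamma_j = theta * gamma_j + alpha_j + noise`, and emits tables in the
#' same dialect the readers accept, so every pipeline stage can be
#' validated against known ground truth without external data.
#'
#' Standard errors use the conventional GWAS approximations:
#' `se_gamma = 1 / sqrt(2 * maf * (1 - maf) * n_eff)` with
#' `n_eff = 4 / (1/cases + 1/controls)` for the binary exposure, and the
#' analogous unit-variance form with `n_out` for continuous outcomes.
#'
#' @param n_snp instrument count J (default 150, the scale of a large
#'   disease GWAS instrument set after pruning).
#' @param theta true causal effect: SD of outcome per unit log-odds
#'   liability (default 0.3).
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero alpha) or
#'   `"directional"` (nonzero-mean alpha).
#' @param pleiotropy_mean,pleiotropy_sd law of alpha on the invalid
#'   variants (defaults 0.02 and 0.01).
#' @param frac_invalid fraction of variants carrying pleiotropy
#'   (default 0.3).
#' @param n_outlier number of planted extreme variants (default 0).
#' @param outlier_offset offset added to a planted variant's outcome
#'   effect, in units of that variant's outcome SE (default 10).
#' @param gamma_mean,gamma_sd law of the true per-variant liability
#'   effects (log-odds; defaults 0.08 and 0.03).
#' @param n_cases,n_controls exposure GWAS sample sizes (defaults 20000 /
#'   200000).
#' @param n_out outcome GWAS sample size (default 118466).
#' @param maf_min,maf_max allele-frequency law, uniform on
#'   `(maf_min, maf_max)` (defaults 0.05, 0.5).
#' @param frac_palindromic,frac_strand_flipped,frac_allele_swapped
#'   harmonisation stressors: fractions of variants emitted as A/T-C/G
#'   palindromes, with strand-complemented alleles in the outcome table,
#'   or with effect/other alleles swapped in the outcome table (defaults
#'   0).
#' @param palindrome_eaf effect-allele frequency given to palindromic
#'   variants (default 0.5, the frequency-ambiguous stress case).
#' @param ld_n_blocks,ld_r2_within LD structure: variants are grouped into
#'   this many leading blocks with constant within-block r-squared;
#'   variants outside blocks (and all between-block pairs) are
#'   independent. Default 0 blocks (all independent).
#' @param panel_n_traits,panel_rho,panel_theta correlated outcome panel:
#'   trait count (default 20, standing in for a 249-trait NMR panel),
#'   exchangeable trait correlation (default 0.3; a full matrix may be
#'   given instead), and per-trait causal-effect vector (default
#'   `rep(theta, panel_n_traits)`).
#' @param strata_prevalences per-stratum medication prevalences for the
#'   age-tertile scenario (default `c(0.05, 0.17, 0.29)`, youngest to
#'   oldest).
#' @param strata_modifier medication-mediation modifier: the effective
#'   causal effect in stratum s is `theta + strata_modifier *
#'   prevalence_s` (default -0.9, which reverses a modest positive effect
#'   in the oldest stratum).
#' @param shared_exposure optional list configuring a second, correlated
#'   liability for multivariable scenarios: `lambda` (loading of
#'   exposure-2 effects on exposure-1 effects, `gamma2 = lambda * gamma1 +
#'   N(0, gamma_sd)`), `gamma_sd`, `theta` (direct effect of liability 2
#'   on the outcome), `n_cases`, `n_controls`.
#' @param seed master RNG seed; every component draws from its own stream
#'   derived from it, so enabling one component never perturbs another.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snp = 150,
                       theta = 0.3,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0.02,
                       pleiotropy_sd = 0.01,
                       frac_invalid = 0.3,
                       n_outlier = 0,
                       outlier_offset = 10,
                       gamma_mean = 0.08,
                       gamma_sd = 0.03,
                       n_cases = 20000,
                       n_controls = 200000,
                       n_out = 118466,
                       maf_min = 0.05,
                       maf_max = 0.5,
                       frac_palindromic = 0,
                       frac_strand_flipped = 0,
                       frac_allele_swapped = 0,
                       palindrome_eaf = 0.5,
                       ld_n_blocks = 0,
                       ld_r2_within = 0.9,
                       panel_n_traits = 20,
                       panel_rho = 0.3,
                       panel_theta = NULL,
                       strata_prevalences = c(0.05, 0.17, 0.29),
                       strata_modifier = -0.9,
                       shared_exposure = NULL,
                       seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  cfg <- as.list(environment())
  fracs <- c(frac_invalid, frac_palindromic, frac_strand_flipped,
             frac_allele_swapped)
  if (any(fracs < 0 | fracs > 1)) {
    stop("config error: fractions must lie in [0, 1]")
  }
  if (frac_palindromic + frac_strand_flipped + frac_allele_swapped > 1) {
    stop("config error: harmonisation stressor fractions exceed 1")
  }
  if (n_snp < 2 || n_cases <= 0 || n_controls <= 0 || n_out <= 0) {
    stop("config error: sizes must be positive (n_snp >= 2)")
  }
  if (gamma_sd < 0 || pleiotropy_sd < 0) {
    stop("config error: standard deviations must be non-negative")
  }
  if (maf_min <= 0 || maf_max > 0.5 || maf_min > maf_max) {
    stop("config error: maf law must satisfy 0 < maf_min <= maf_max <= 0.5")
  }
  if (any(strata_prevalences < 0 | strata_prevalences > 1)) {
    stop("config error: prevalences must lie in [0, 1]")
  }
  if (n_outlier < 0 || n_outlier >= n_snp) {
    stop("config error: n_outlier must lie in [0, n_snp)")
  }
  if (is.matrix(panel_rho)) {
    if (nrow(panel_rho) != panel_n_traits) {
      stop("config error: panel correlation matrix size != panel_n_traits")
    }
  } else if (panel_rho < 0 || panel_rho >= 1) {
    stop("config error: panel_rho must lie in [0, 1)")
  }
  if (!is.null(panel_theta) && length(panel_theta) != panel_n_traits) {
    stop("config error: panel_theta length != panel_n_traits")
  }
  if (!is.null(shared_exposure)) {
    se2 <- shared_exposure
    cfg$shared_exposure <- list(lambda = se2$lambda %||% 0.5,
                                gamma_sd = se2$gamma_sd %||% 0.03,
                                theta = se2$theta %||% 0.1,
                                n_cases = se2$n_cases %||% n_cases,
                                n_controls = se2$n_controls %||% n_controls)
  }
  structure(cfg, class = "sim_config")
}

n_eff_cc <- function(cases, controls) 4 / (1 / cases + 1 / controls)

se_binary <- function(maf, cases, controls) {
  1 / sqrt(2 * maf * (1 - maf) * n_eff_cc(cases, controls))
}

se_continuous <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

NONPALIN_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                           "G", "A", "G", "T", "T", "C", "T", "G"),
                         ncol = 2, byrow = TRUE)
PALIN_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)

#' Simulate exposure GWAS summary statistics
#'
#' Draws true liability effects `gamma_j ~ N(gamma_mean, gamma_sd)`,
#' standard errors from the binary-trait approximation given allele
#' frequency and case/control sizes, observed effects `gamma_j +
#' N(0, se_gamma_j)`, and normal p-values. Also assigns each variant its
#' alleles, frequency, and the orientation record (as-is / allele-swapped
#' / strand-flipped / palindromic) later applied when emitting outcome
#' tables.
#'
#' @param cfg a [sim_config()].
#' @return List with `table` (a [sumstats]) and `truth` (data frame of
#'   per-variant ground truth: `gamma`, `se_gamma`, `maf`, `orientation`,
#'   `palindromic`).
#' @export
simulate_exposure <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  J <- cfg$n_snp
  with_seed(child_seed(cfg$seed, 101), {
    rsid <- sprintf("rs%06d", seq_len(J))
    n_pal <- round(cfg$frac_palindromic * J)
    n_strand <- round(cfg$frac_strand_flipped * J)
    n_swap <- round(cfg$frac_allele_swapped * J)
    roles <- sample(c(rep("palindromic", n_pal),
                      rep("strand", n_strand),
                      rep("swap", n_swap),
                      rep("as_is", J - n_pal - n_strand - n_swap)))
    maf <- stats::runif(J, cfg$maf_min, cfg$maf_max)
    eaf <- ifelse(roles == "palindromic", cfg$palindrome_eaf, maf)
    pal <- roles == "palindromic"
    idx_pal <- sample(nrow(PALIN_PAIRS), J, replace = TRUE)
    idx_non <- sample(nrow(NONPALIN_PAIRS), J, replace = TRUE)
    ea <- oa <- character(J)
    ea[pal] <- PALIN_PAIRS[idx_pal[pal], 1]
    oa[pal] <- PALIN_PAIRS[idx_pal[pal], 2]
    ea[!pal] <- NONPALIN_PAIRS[idx_non[!pal], 1]
    oa[!pal] <- NONPALIN_PAIRS[idx_non[!pal], 2]
    gamma <- stats::rnorm(J, cfg$gamma_mean, cfg$gamma_sd)
    se_g <- se_binary(eaf, cfg$n_cases, cfg$n_controls)
    beta <- gamma + stats::rnorm(J, 0, se_g)
    tab <- sumstats(data.frame(rsid = rsid, effect_allele = ea,
                               other_allele = oa, eaf = eaf, beta = beta,
                               se = se_g,
                               pval = 2 * stats::pnorm(-abs(beta / se_g)),
                               n = cfg$n_cases + cfg$n_controls,
                               stringsAsFactors = FALSE),
                    trait_name = "liability_1",
                    trait_type = "binary_disease")
    truth <- data.frame(rsid = rsid, gamma = gamma, se_gamma = se_g,
                        maf = maf, eaf = eaf,
                        effect_allele = ea, other_allele = oa,
                        orientation = roles,
                        palindromic = roles == "palindromic",
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}

#' Simulate a second, correlated liability
#'
#' For multivariable scenarios: exposure-2 effects load on exposure-1
#' effects as `gamma2_j = lambda * gamma1_j + N(0, gamma_sd)`, emulating
#' two diseases whose instruments overlap (shared variants with correlated
#' effects).
#'
#' @param cfg a [sim_config()] with `shared_exposure` set.
#' @param truth the truth data frame from [simulate_exposure()].
#' @return List with `table` (a [sumstats]) and `truth` (the input truth
#'   with a `gamma2` column added).
#' @export
simulate_second_exposure <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$shared_exposure)) {
    stop("config error: shared_exposure is not configured")
  }
  sx <- cfg$shared_exposure
  with_seed(child_seed(cfg$seed, 104), {
    gamma2 <- sx$lambda * truth$gamma +
      stats::rnorm(nrow(truth), 0, sx$gamma_sd)
    se_g2 <- se_binary(truth$eaf, sx$n_cases, sx$n_controls)
    beta2 <- gamma2 + stats::rnorm(nrow(truth), 0, se_g2)
    tab <- sumstats(data.frame(rsid = truth$rsid,
                               effect_allele = truth$effect_allele,
                               other_allele = truth$other_allele,
                               eaf = truth$eaf, beta = beta2, se = se_g2,
                               pval = 2 * stats::pnorm(-abs(beta2 / se_g2)),
                               n = sx$n_cases + sx$n_controls,
                               stringsAsFactors = FALSE),
                    trait_name = "liability_2",
                    trait_type = "binary_disease")
    truth$gamma2 <- gamma2
    list(table = tab, truth = truth)
  })
}

# Draw per-variant pleiotropy alpha for the configured law; deterministic
# given the config seed (own stream, shared by outcome/panel/strata).
draw_alpha <- function(cfg, J) {
  with_seed(child_seed(cfg$seed, 103), {
    alpha <- numeric(J)
    invalid <- logical(J)
    if (cfg$pleiotropy != "none" && cfg$frac_invalid > 0) {
      n_inv <- round(cfg$frac_invalid * J)
      idx <- sample(J, n_inv)
      invalid[idx] <- TRUE
      mu <- if (cfg$pleiotropy == "balanced") 0 else cfg$pleiotropy_mean
      alpha[idx] <- stats::rnorm(n_inv, mu, cfg$pleiotropy_sd)
    }
    outlier_idx <- if (cfg$n_outlier > 0) {
      sample(which(!invalid), cfg$n_outlier)
    } else {
      integer(0)
    }
    list(alpha = alpha, invalid = invalid, outlier_idx = outlier_idx)
  })
}

# Apply a variant's emission orientation to an outcome row.
emit_oriented <- function(df, truth) {
  swap <- truth$orientation == "swap"
  strand <- truth$orientation == "strand"
  df$beta[swap] <- -df$beta[swap]
  df$eaf[swap] <- 1 - df$eaf[swap]
  ea <- df$effect_allele; oa <- df$other_allele
  df$effect_allele[swap] <- oa[swap]
  df$other_allele[swap] <- ea[swap]
  df$effect_allele[strand] <- unname(COMPLEMENT[df$effect_allele[strand]])
  df$other_allele[strand] <- unname(COMPLEMENT[df$other_allele[strand]])
  df
}

outcome_table <- function(cfg, truth, gamma_out, sigma, noise, name,
                          alpha, outlier_idx) {
  G <- gamma_out + alpha
  if (length(outlier_idx) > 0) {
    G[outlier_idx] <- G[outlier_idx] + cfg$outlier_offset * sigma[outlier_idx]
  }
  beta <- G + noise
  df <- data.frame(rsid = truth$rsid,
                   effect_allele = truth$effect_allele,
                   other_allele = truth$other_allele,
                   eaf = truth$eaf, beta = beta, se = sigma,
                   pval = 2 * stats::pnorm(-abs(beta / sigma)),
                   n = cfg$n_out, stringsAsFactors = FALSE)
  df <- emit_oriented(df, truth)
  tab <- sumstats(df, trait_name = name, trait_type = "continuous")
  attr(tab, "true_Gamma") <- G
  tab
}

#' Simulate outcome GWAS summary statistics
#'
#' Outcome effects follow the liability-plus-pleiotropy model
#' `Gamma_j = theta * gamma_j + alpha_j + offset + N(0, se_Gamma_j)`
#' (plus `theta2 * gamma2_j` when a second liability is configured), with
#' `se_Gamma` from the continuous-trait approximation. Variants marked as
#' allele-swapped or strand-flipped in the truth's orientation records are
#' emitted with transformed alleles (and sign/frequency for swaps), so the
#' harmoniser can be validated against ground truth.
#'
#' @param cfg a [sim_config()].
#' @param truth truth data frame from [simulate_exposure()] (with
#'   `gamma2` from [simulate_second_exposure()] when configured).
#' @return A [sumstats] of class `continuous`, with attributes
#'   `true_Gamma` (pre-noise, pre-orientation outcome effects on the
#'   exposure orientation), `alpha`, `invalid`, and `outlier_rsids`.
#' @export
simulate_outcome <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.data.frame(truth) || nrow(truth) != cfg$n_snp) {
    stop("alignment error: truth does not match the configuration")
  }
  pl <- draw_alpha(cfg, nrow(truth))
  gamma_out <- cfg$theta * truth$gamma
  if (!is.null(cfg$shared_exposure)) {
    if (is.null(truth$gamma2)) {
      stop("alignment error: shared_exposure configured but truth has no gamma2")
    }
    gamma_out <- gamma_out + cfg$shared_exposure$theta * truth$gamma2
  }
  sigma <- se_continuous(truth$eaf, cfg$n_out)
  noise <- with_seed(child_seed(cfg$seed, 102),
                     stats::rnorm(nrow(truth), 0, sigma))
  tab <- outcome_table(cfg, truth, gamma_out, sigma, noise, "outcome_1",
                       pl$alpha, pl$outlier_idx)
  attr(tab, "alpha") <- pl$alpha
  attr(tab, "invalid") <- pl$invalid
  attr(tab, "outlier_rsids") <- truth$rsid[pl$outlier_idx]
  tab
}

#' Simulate a correlated multi-trait outcome panel
#'
#' Per-trait outcome tables whose noise is correlated across traits
#' through the configured trait correlation (exchangeable `panel_rho` or a
#' full matrix), emulating a metabolomics panel measured on one sample.
#' Per-trait causal effects come from `panel_theta`. The generating
#' correlation matrix is returned for [effective_tests_threshold()].
#'
#' @param cfg a [sim_config()].
#' @param truth truth data frame from [simulate_exposure()].
#' @return List with `outcomes` (named list of [sumstats]) and
#'   `trait_corr` (the generating trait correlation matrix).
#' @export
simulate_panel <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  Tt <- cfg$panel_n_traits
  R <- if (is.matrix(cfg$panel_rho)) {
    cfg$panel_rho
  } else {
    m <- matrix(cfg$panel_rho, Tt, Tt); diag(m) <- 1; m
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("config error: panel trait correlation is not positive semi-definite")
  }
  traits <- sprintf("trait_%02d", seq_len(Tt))
  dimnames(R) <- list(traits, traits)
  thetas <- cfg$panel_theta %||% rep(cfg$theta, Tt)
  pl <- draw_alpha(cfg, nrow(truth))
  sigma <- se_continuous(truth$eaf, cfg$n_out)
  L <- chol(R + diag(1e-10, Tt))
  noise <- with_seed(child_seed(cfg$seed, 105), {
    z <- matrix(stats::rnorm(nrow(truth) * Tt), nrow(truth), Tt)
    (z %*% L) * sigma
  })
  outcomes <- stats::setNames(lapply(seq_len(Tt), function(t) {
    outcome_table(cfg, truth, thetas[t] * truth$gamma, sigma, noise[, t],
                  traits[t], pl$alpha, pl$outlier_idx)
  }), traits)
  list(outcomes = outcomes, trait_corr = R)
}

#' Simulate age-stratified outcome tables
#'
#' Emulates the medication-mediation mechanism: within age stratum `s`
#' (with medication prevalence `p_s`), the effective causal effect is
#' `theta_s = theta + strata_modifier * p_s`, so a negative modifier
#' attenuates — and at high prevalence reverses — the all-ages effect.
#' Each stratum receives an equal share of the outcome sample size and an
#' independent noise stream.
#'
#' @param cfg a [sim_config()].
#' @param truth truth data frame from [simulate_exposure()].
#' @return Named list of [sumstats] (`tertile_1` youngest ...), each with
#'   attribute `theta_s` (the stratum's true effective effect).
#' @export
simulate_age_strata <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  prev <- cfg$strata_prevalences
  pl <- draw_alpha(cfg, nrow(truth))
  n_s <- cfg$n_out / length(prev)
  sigma <- se_continuous(truth$eaf, n_s)
  out <- lapply(seq_along(prev), function(s) {
    theta_s <- cfg$theta + cfg$strata_modifier * prev[s]
    noise <- with_seed(child_seed(cfg$seed, 300 + s),
                       stats::rnorm(nrow(truth), 0, sigma))
    tab <- outcome_table(cfg, truth, theta_s * truth$gamma, sigma, noise,
                         paste0("outcome_1_tertile_", s),
                         pl$alpha, pl$outlier_idx)
    attr(tab, "theta_s") <- theta_s
    tab
  })
  stats::setNames(out, paste0("tertile_", seq_along(prev)))
}

#' Simulate a block LD matrix
#'
#' Groups the first variants into `ld_n_blocks` equal blocks with constant
#' within-block r-squared `ld_r2_within`; between-block pairs and leftover
#' variants are independent. Used to exercise pruning, not to generate
#' LD-consistent effects.
#'
#' @param cfg a [sim_config()].
#' @param truth truth data frame from [simulate_exposure()].
#' @return A validated r-squared matrix with rsid dimnames.
#' @export
simulate_ld <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  J <- nrow(truth)
  m <- diag(1, J)
  if (cfg$ld_n_blocks > 0) {
    size <- J %/% cfg$ld_n_blocks
    for (b in seq_len(cfg$ld_n_blocks)) {
      idx <- ((b - 1) * size + 1):(b * size)
      m[idx, idx] <- cfg$ld_r2_within
    }
    diag(m) <- 1
  }
  dimnames(m) <- list(truth$rsid, truth$rsid)
  m
}

#' Simulate a complete reverse-MR study
#'
#' One call generating every input the pipeline consumes: the exposure
#' table with ground truth, a second correlated exposure when configured,
#' the single outcome, the correlated trait panel, the age strata, and the
#' LD matrix. All draws derive from per-component streams of
#' `cfg$seed`, so outputs are fully reproducible and componentwise stable.
#'
#' @param cfg a [sim_config()].
#' @param components character vector choosing what to generate; default
#'   everything applicable.
#' @return List with `exposure`, `truth`, `outcome`, `ld`, and (when
#'   requested) `exposure2`, `panel`, `trait_corr`, `strata`.
#' @examples
#' sim <- simulate_study(sim_config(n_snp = 40, seed = 7))
#' mean_f_statistic(sim$exposure)
#' @export
simulate_study <- function(cfg,
                           components = c("outcome", "panel", "strata")) {
  stopifnot(inherits(cfg, "sim_config"))
  ex <- simulate_exposure(cfg)
  truth <- ex$truth
  out <- list(exposure = ex$table)
  if (!is.null(cfg$shared_exposure)) {
    ex2 <- simulate_second_exposure(cfg, truth)
    truth <- ex2$truth
    out$exposure2 <- ex2$table
  }
  if ("outcome" %in% components) {
    out$outcome <- simulate_outcome(cfg, truth)
  }
  if ("panel" %in% components) {
    pan <- simulate_panel(cfg, truth)
    out$panel <- pan$outcomes
    out$trait_corr <- pan$trait_corr
  }
  if ("strata" %in% components) {
    out$strata <- simulate_age_strata(cfg, truth)
  }
  out$ld <- simulate_ld(cfg, truth)
  out$truth <- truth
  out
}

#' Write a simulated study to disk
#'
#' Emits the summary-statistics dialect plus the LD matrix, trait
#' correlation, and a tab-separated truth file, mirroring what the
#' pipeline reads back.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    if (inherits(obj, "sumstats")) write_sumstats(obj, p) else write_tsv(obj, p)
    paths <<- c(paths, p)
  }
  wr(sim$exposure, "exposure_1.tsv")
  if (!is.null(sim$exposure2)) wr(sim$exposure2, "exposure_2.tsv")
  if (!is.null(sim$outcome)) wr(sim$outcome, "outcome_1.tsv")
  if (!is.null(sim$panel)) {
    for (nm in names(sim$panel)) wr(sim$panel[[nm]], paste0("panel_", nm, ".tsv"))
  }
  if (!is.null(sim$strata)) {
    for (nm in names(sim$strata)) wr(sim$strata[[nm]], paste0("strata_", nm, ".tsv"))
  }
  if (!is.null(sim$ld)) {
    p <- file.path(dir, "ld.tsv")
    write_ld_matrix(sim$ld, p)
    paths <- c(paths, p)
  }
  if (!is.null(sim$trait_corr)) {
    p <- file.path(dir, "trait_corr.tsv")
    write_tsv(data.frame(trait = rownames(sim$trait_corr), sim$trait_corr,
                         check.names = FALSE), p)
    paths <- c(paths, p)
  }
  wr(sim$truth, "truth.tsv")
  invisible(paths)
}
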
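default_study_config <- function() {
  list(
    seed = 1,
    simulate = list(),
    instruments = list(p_threshold = 5e-8, r2_threshold = 0.001,
                       exclude = character(0)),
    harmonise = list(palindrome_eaf_limit = 0.42),
    estimators = list(methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode"),
                      re_model = "multiplicative_random",
                      n_boot = 1000, phi = 1, scale_per_doubling = TRUE),
    radial = list(p_threshold = 0.05),
    mvmr = list(enabled = FALSE),
    strata = list(enabled = TRUE),
    multiplicity = list(alpha = 0.05, variance_fraction = 0.95,
                        n_components = NULL)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Read a study configuration file
#'
#' Study configuration is a YAML file of nested key-value sections
#' (`seed`, `simulate`, `instruments`, `harmonise`, `estimators`,
#' `radial`, `mvmr`, `strata`, `multiplicity`); unspecified keys take the
#' package defaults.
#'
#' @param path YAML file path, or a list already in config form.
#' @return A complete configuration list.
#' @export
read_study_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg <- merge_config(default_study_config(), user)
  # Fail fast on structural errors before any stage runs.
  if (isTRUE(cfg$mvmr$enabled) &&
      is.null(cfg$simulate$shared_exposure) &&
      is.null(cfg$inputs$exposure2)) {
    stop("config-validation error: mvmr requires two exposures ",
         "(configure simulate$shared_exposure or inputs$exposure2)")
  }
  cfg
}

#' Run the end-to-end reverse-MR study
#'
#' Orchestrates simulate (or ingest) -> instrument selection and LD
#' pruning -> harmonisation -> MR estimation (all methods, single outcome
#' and trait panel) -> radial outlier screening -> multivariable MR ->
#' age-stratified estimation with cross-stratum contrasts -> correlated-
#' trait multiplicity threshold -> cross-disease profile comparison,
#' writing long-format tab-separated tables and a run manifest to
#' `out_dir`. A stage failure is recorded in the manifest, dependent
#' stages are skipped, and `manifest$ok` is set `FALSE`; independent
#' stages still run.
#'
#' @param config path to a YAML config file, or a config list (see
#'   [read_study_config()]).
#' @param out_dir output directory (created if needed).
#' @return The run manifest (list, also written as `manifest.yaml`):
#'   config snapshot, seed, package version, per-file md5 digests,
#'   timestamps, stage status, warnings tally.
#' @export
run_study <- function(config, out_dir) {
  cfg <- read_study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  warnings_tally <- 0L
  outputs <- character(0)
  t0 <- Sys.time()

  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    outputs <<- c(outputs, p)
    p
  }
  run_stage <- function(name, deps, fun) {
    failed_deps <- deps[!vapply(deps, function(d)
      isTRUE(stages[[d]]$ok), logical(1))]
    if (length(failed_deps) > 0) {
      stages[[name]] <<- list(ok = FALSE,
                              skipped = TRUE,
                              error = paste("skipped: dependency failed:",
                                            paste(failed_deps, collapse = ", ")))
      return(NULL)
    }
    res <- tryCatch(withCallingHandlers(fun(), warning = function(w) {
      warnings_tally <<- warnings_tally + 1L
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- list(ok = FALSE, error = conditionMessage(res))
      NULL
    } else {
      stages[[name]] <<- list(ok = TRUE)
      res
    }
  }

  # -- data -------------------------------------------------------------
  sim <- run_stage("data", character(0), function() {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- do.call(sim_config, sim_args)
    simulate_study(scfg)
  })

  # -- instruments ------------------------------------------------------
  instruments <- run_stage("instruments", "data", function() {
    ins <- select_instruments(sim$exposure, cfg$instruments$p_threshold)
    ins <- ld_prune(ins, sim$ld, cfg$instruments$r2_threshold)
    if (length(cfg$instruments$exclude) > 0) {
      ins <- exclude_snps(ins, cfg$instruments$exclude)
    }
    emit(data.frame(exposure = attr(ins, "trait_name"),
                    n_instruments = nrow(ins),
                    mean_f = mean_f_statistic(ins)),
         "instrument_strength.tsv")
    ins
  })

  # -- harmonise --------------------------------------------------------
  h <- run_stage("harmonise", "instruments", function() {
    h <- harmonise(instruments, sim$outcome,
                   palindrome_eaf_limit = cfg$harmonise$palindrome_eaf_limit)
    emit(as.data.frame(h), "harmonised.tsv")
    h
  })

  # -- estimators (single outcome) --------------------------------------
  est <- cfg$estimators
  fit <- run_stage("estimators", "harmonise", function() {
    fit <- mr_fit(h, methods = est$methods, re_model = est$re_model,
                  n_boot = est$n_boot, phi = est$phi,
                  seed = child_seed(cfg$seed, 11),
                  scale = est$scale_per_doubling)
    df <- as.data.frame(fit)
    df$stratum <- "all_ages"
    emit(df, "mr_estimates.tsv")
    fit
  })

  # -- radial -----------------------------------------------------------
  run_stage("radial", "harmonise", function() {
    rad <- radial_ivw(h, p_threshold = cfg$radial$p_threshold)
    emit(data.frame(rsid = names(rad$per_snp_q),
                    q_contribution = unname(rad$per_snp_q),
                    outlier = names(rad$per_snp_q) %in% rad$outliers),
         "radial_per_snp.tsv")
    re <- do.call(rbind, lapply(
      list(all_snps = rad$estimate_with,
           outliers_excluded = rad$estimate_without),
      function(e) data.frame(beta = e$beta, se = e$se, ci_low = e$ci_low,
                             ci_high = e$ci_high, pval = e$pval,
                             n_snp = e$n_snp)))
    re <- cbind(set = rownames(re), re)
    rownames(re) <- NULL
    emit(re, "radial_estimates.tsv")
    rad
  })

  # -- panel ------------------------------------------------------------
  panel1 <- run_stage("panel", "instruments", function() {
    p <- run_panel(instruments, sim$panel, methods = est$methods,
                   re_model = est$re_model, n_boot = est$n_boot,
                   phi = est$phi, seed = child_seed(cfg$seed, 12),
                   scale = est$scale_per_doubling,
                   palindrome_eaf_limit = cfg$harmonise$palindrome_eaf_limit)
    emit(as.data.frame(p), "panel_estimates.tsv")
    p
  })

  # -- multiplicity -----------------------------------------------------
  run_stage("multiplicity", "data", function() {
    mult <- cfg$multiplicity
    eff <- if (!is.null(mult$n_components)) {
      k <- as.integer(mult$n_components)
      list(n_components = k, threshold = mult$alpha / k,
           threshold_rounded = signif(mult$alpha / k, 1))
    } else {
      effective_tests_threshold(sim$trait_corr,
                                variance_fraction = mult$variance_fraction,
                                alpha = mult$alpha)
    }
    emit(data.frame(n_components = eff$n_components,
                    alpha = mult$alpha,
                    threshold = eff$threshold,
                    threshold_rounded = eff$threshold_rounded),
         "multiplicity.tsv")
    eff
  })

  # -- mvmr -------------------------------------------------------------
  if (isTRUE(cfg$mvmr$enabled)) {
    run_stage("mvmr", "data", function() {
      mv <- mvmr_ivw(list(sim$exposure, sim$exposure2), sim$outcome,
                     ld = sim$ld,
                     p_threshold = cfg$instruments$p_threshold,
                     r2_threshold = cfg$instruments$r2_threshold,
                     scale = isTRUE(est$scale_per_doubling))
      emit(data.frame(exposure = mv$exposure_names,
                      beta = unname(mv$betas), se = unname(mv$ses),
                      ci_low = unname(mv$ci_low),
                      ci_high = unname(mv$ci_high),
                      pval = unname(mv$pvals), n_snp = mv$n_snp,
                      mean_f = unname(mv$mean_f)),
           "mvmr_estimates.tsv")
      mv
    })
  }

  # -- strata + contrasts ----------------------------------------------
  if (isTRUE(cfg$strata$enabled)) {
    strata_panels <- run_stage("strata", "instruments", function() {
      panels <- lapply(seq_along(sim$strata), function(s) {
        run_panel(instruments,
                  stats::setNames(sim$strata[s], "outcome_1"),
                  methods = est$methods, re_model = est$re_model,
                  n_boot = est$n_boot, phi = est$phi,
                  seed = child_seed(cfg$seed, 20 + s),
                  scale = est$scale_per_doubling,
                  palindrome_eaf_limit = cfg$harmonise$palindrome_eaf_limit,
                  stratum_label = names(sim$strata)[s])
      })
      names(panels) <- names(sim$strata)
      emit(do.call(rbind, lapply(panels, as.data.frame)),
           "strata_estimates.tsv")
      panels
    })
    run_stage("contrasts", "strata", function() {
      sc <- stratum_contrast(strata_panels[[length(strata_panels)]],
                             strata_panels[[1]], method = "ivw")
      sc$note <- "artifact addition: formal z-contrast across strata"
      emit(as.data.frame(sc), "stratum_contrasts.tsv")
      sc
    })
  }

  # -- profile comparison (needs a second exposure's panel) -------------
  if (isTRUE(cfg$mvmr$enabled)) {
    run_stage("profile", "panel", function() {
      ins2 <- select_instruments(sim$exposure2, cfg$instruments$p_threshold)
      ins2 <- ld_prune(ins2, sim$ld, cfg$instruments$r2_threshold)
      p2 <- run_panel(ins2, sim$panel, methods = "ivw",
                      seed = child_seed(cfg$seed, 13),
                      scale = est$scale_per_doubling,
                      palindrome_eaf_limit =
                        cfg$harmonise$palindrome_eaf_limit)
      emit(as.data.frame(p2), "panel2_estimates.tsv")
      pc <- profile_comparison(panel1, p2, method = "ivw")
      emit(data.frame(exposure_x = pc$exposure_x,
                      exposure_y = pc$exposure_y, method = pc$method,
                      slope = pc$slope, intercept = pc$intercept,
                      r2 = pc$r2, n_traits = pc$n_traits),
           "profile_comparison.tsv")
      pc
    })
  }

  ok <- all(vapply(stages, function(s) isTRUE(s$ok), logical(1)))
  manifest <- list(
    tool = "revmr",
    version = as.character(utils::packageVersion("revmr")),
    seed = cfg$seed,
    config = cfg,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings_tally,
    stages = lapply(stages, function(s) s[setdiff(names(s), "value")]),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))),
    ok = ok
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Summarise study results
#'
#' Reads the tables a [run_study()] call wrote, prints per-exposure
#' results sorted by outcome, flags estimates passing the correlated-trait
#' multiplicity threshold, writes the flagged subset
#' (`flagged_estimates.tsv`) and an XY scatter of the two exposures' panel
#' estimates (`profile_xy.pdf`) when both panels are present.
#'
#' @param results_dir directory written by [run_study()].
#' @param method estimator used for flagging and the scatter (default
#'   `"ivw"`).
#' @return List with `threshold`, `n_flagged`, `flagged` (data frame),
#'   invisibly.
#' @export
report <- function(results_dir, method = "ivw") {
  need <- function(name) {
    p <- file.path(results_dir, name)
    if (!file.exists(p)) stop("report error: missing table ", name)
    read_tsv(p)
  }
  panel <- need("panel_estimates.tsv")
  mult <- need("multiplicity.tsv")
  threshold <- mult$threshold_rounded[1]
  sub <- panel[panel$method == method, , drop = FALSE]
  sub <- sub[order(sub$outcome), , drop = FALSE]
  flagged <- sub[sub$pval < threshold, , drop = FALSE]
  cat("Panel results (", method, "), ", nrow(sub), " outcomes; ",
      nrow(flagged), " pass p < ", threshold,
      " (effective-tests threshold)\n", sep = "")
  print(utils::head(sub[, c("exposure", "outcome", "beta", "se", "pval")],
                    15), row.names = FALSE, digits = 4)
  write_tsv(flagged, file.path(results_dir, "flagged_estimates.tsv"))
  prof_p <- file.path(results_dir, "profile_comparison.tsv")
  panel2_p <- file.path(results_dir, "panel2_estimates.tsv")
  if (file.exists(prof_p)) {
    prof <- read_tsv(prof_p)
    cat(sprintf("Profile comparison: slope %.3f, R^2 %.3f over %d traits\n",
                prof$slope[1], prof$r2[1], prof$n_traits[1]))
    if (file.exists(panel2_p)) {
      p2 <- read_tsv(panel2_p)
      p2 <- p2[p2$method == method, , drop = FALSE]
      shared <- intersect(sub$outcome, p2$outcome)
      pdf_path <- file.path(results_dir, "profile_xy.pdf")
      grDevices::pdf(pdf_path, width = 5, height = 5)
      graphics::plot(sub$beta[match(shared, sub$outcome)],
                     p2$beta[match(shared, p2$outcome)],
                     xlab = paste("Effect of", sub$exposure[1]),
                     ylab = paste("Effect of", p2$exposure[1]),
                     main = sprintf("Effect profiles: slope %.2f, R2 %.2f",
                                    prof$slope[1], prof$r2[1]))
      graphics::abline(a = prof$intercept[1], b = prof$slope[1],
                       col = "red3")
      grDevices::dev.off()
    }
  }
  invisible(list(threshold = threshold, n_flagged = nrow(flagged),
                 flagged = flagged))
}
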
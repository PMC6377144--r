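# End-to-end orchestration: feeding experiment -> trophic position ->
# mixing-polygon feasibility gate -> Bayesian mixing models.

#' Run the full pipeline
#'
#' Executes the four analysis stages in order on either a synthetic
#' scenario or CSV inputs named in `config$paths`
#' (`feeding_trials`, `calibration` (optional), `trophic_samples`,
#' `consumers`, `sources_natural`, `sources_disturbed`). Consumers flagged
#' outside the mixing region are warned about but not dropped (a config
#' switch `drop_outside` excludes them).
#'
#' @param config An [analysis_config].
#' @param out_dir Directory for output CSVs and the run log.
#' @param scenario A [default_scenario] used when `config$paths` is empty.
#' @param drop_outside Exclude polygon-flagged consumers from the mixing
#'   model (default `FALSE`: warn and continue).
#' @param stages Character subset of
#'   `c("selectivity", "trophic", "polygon", "simm")`.
#' @return A run manifest (list of class `run_manifest`): per-stage status
#'   and key results, output inventory, collected warnings, seeds.
#' @export
run_all <- function(config = analysis_config(), out_dir = tempfile("isoforage_"),
                    scenario = NULL,
                    drop_outside = FALSE,
                    stages = c("selectivity", "trophic", "polygon", "simm")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), outputs = character(), warnings = character(),
                   seeds = list(mcmc = config$mcmc$seed,
                                polygon = config$polygon$seed),
                   out_dir = out_dir)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = log_path, append = TRUE)
  note_warning <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, p)
    p
  }
  use_paths <- length(config$paths) > 0
  if (!use_paths && is.null(scenario))
    scenario <- default_scenario(seed = config$mcmc$seed)
  load_or <- function(key, gen) {
    if (use_paths) {
      p <- config$paths[[key]]
      if (is.null(p) || !file.exists(p %||% ""))
        stop("input table '", key, "' not found",
             if (!is.null(p)) paste0(" at: ", p), call. = FALSE)
      p
    } else gen
  }
  logline("run_all start; inputs:", if (use_paths) "paths" else "scenario")
  logline("effective mcmc:", paste(names(config$mcmc), unlist(config$mcmc),
                                   sep = "=", collapse = " "))
  logline("effective polygon:",
          paste(names(config$polygon), unlist(config$polygon),
                sep = "=", collapse = " "))

  withCallingHandlers({
    if ("selectivity" %in% stages) {
      feed <- if (use_paths)
        list(trials = read_feeding_trials(load_or("feeding_trials")),
             calibration = if (!is.null(config$paths$calibration))
               utils::read.csv(config$paths$calibration) else NULL)
      else gen_feeding_trials(scenario)
      if (is.null(feed$calibration)) {
        # no calibration leaves: fit dry~wet on the control halves
        ctrl <- feed$trials[feed$trials$is_control, ]
        calib <- data.frame(prey = ctrl$prey, wet = ctrl$initial_wet_mass,
                            dry = ctrl$final_dry_mass)
      } else calib <- feed$calibration
      regs <- fit_wet_dry_regression(calib, per_prey = TRUE)
      sel <- compute_selectivity(feed$trials, regs)
      amat <- alpha_matrix(sel)
      fr <- friedman_test(amat)
      nem <- nemenyi_posthoc(amat)
      mean_alpha <- sort(colMeans(amat), decreasing = TRUE)
      emit(sel, "selectivity_per_crab")
      emit(data.frame(prey = names(mean_alpha), mean_alpha = mean_alpha),
           "selectivity_mean_alpha")
      emit(data.frame(statistic = fr$statistic, df = fr$df,
                      p_value = fr$p_value), "selectivity_friedman")
      emit(as.data.frame(as.table(nem)), "selectivity_nemenyi")
      manifest$stages$selectivity <- list(
        status = "ok", friedman = fr, mean_alpha = mean_alpha,
        top_prey = names(mean_alpha)[1])
      logline("selectivity ok; top prey:", names(mean_alpha)[1])
    }

    if ("trophic" %in% stages) {
      tsamp <- if (use_paths)
        read_isotope_table(load_or("trophic_samples"), "consumer")
      else gen_trophic_dataset(scenario)$samples
      rec <- compute_trophic_positions(tsamp, "Armases", "Melampus",
                                       tef = config$tef,
                                       lambda = config$lambda_baseline)
      an <- nested_anova(rec)
      pw <- pairwise_site_tests(rec)
      rng <- tp_range_summary(rec)
      emit(rec, "trophic_positions")
      emit(an, "trophic_anova")
      emit(pw, "trophic_pairwise")
      emit(rng, "trophic_ranges")
      manifest$stages$trophic <- list(status = "ok", anova = an,
                                      pairwise = pw, ranges = rng)
      logline("trophic ok; treatment p =",
              signif(an$p[an$source == "treatment"], 3))
    }

    if (any(c("polygon", "simm") %in% stages)) {
      cons <- if (use_paths)
        read_isotope_table(load_or("consumers"), "consumer")
      else gen_consumers(scenario)$consumers
      src <- if (use_paths)
        list(natural = read_isotope_table(load_or("sources_natural"),
                                          "source"),
             disturbed = read_isotope_table(load_or("sources_disturbed"),
                                            "source"))
      else gen_sources(scenario)$groups
    }

    if ("polygon" %in% stages) {
      poly_rows <- list()
      for (st in names(src)) {
        cs <- cons[cons$habitat_status == st, ]
        for (s in unique(cs$site)) {
          res <- simulate_mixing_region(
            src[[st]][src[[st]]$site == s, ], cs[cs$site == s, ],
            tef = config$tef,
            n_iterations = config$polygon$n_iterations,
            seed = config$polygon$seed,
            inclusion_alpha = config$polygon$inclusion_alpha)
          out <- res$consumers
          out$site <- s; out$habitat_status <- st
          poly_rows[[paste(st, s)]] <- out
        }
      }
      poly <- do.call(rbind, poly_rows)
      rownames(poly) <- NULL
      n_out <- sum(poly$outside_flag)
      if (n_out > 0)
        warning(n_out, " consumer(s) outside the ",
                (1 - config$polygon$inclusion_alpha) * 100,
                "% mixing region", call. = FALSE)
      emit(poly, "polygon_inclusion")
      manifest$stages$polygon <- list(status = "ok", inclusion = poly,
                                      n_outside = n_out)
      logline("polygon ok;", n_out, "consumer(s) flagged outside")
    }

    if ("simm" %in% stages) {
      if (drop_outside && !is.null(manifest$stages$polygon)) {
        bad <- manifest$stages$polygon$inclusion
        bad <- bad$sample_id[bad$outside_flag]
        cons <- cons[!cons$sample_id %in% bad, ]
      }
      mc <- mcmc_config(chains = config$mcmc$chains,
                        iterations = config$mcmc$iterations,
                        burn_in = config$mcmc$burn_in,
                        thin = config$mcmc$thin, seed = config$mcmc$seed)
      specs <- lapply(stats::setNames(names(src), names(src)), function(st)
        mixing_model_spec(src[[st]], cons[cons$habitat_status == st, ],
                          tef = config$tef))
      fit <- run_paired_models(specs$natural, specs$disturbed, mcmc = mc)
      emit(fit$natural$summary, "simm_summary_natural")
      emit(fit$disturbed$summary, "simm_summary_disturbed")
      emit(fit$natural$diagnostics, "simm_diagnostics_natural")
      emit(fit$disturbed$diagnostics, "simm_diagnostics_disturbed")
      emit(fit$comparison, "simm_shared_source_comparison")
      emit(posterior_draws_long(fit$natural), "simm_draws_natural")
      emit(posterior_draws_long(fit$disturbed), "simm_draws_disturbed")
      manifest$stages$simm <- list(
        status = "ok", comparison = fit$comparison,
        summary_natural = fit$natural$summary,
        summary_disturbed = fit$disturbed$summary,
        max_rhat = max(fit$natural$diagnostics$rhat,
                       fit$disturbed$diagnostics$rhat))
      logline("simm ok; max rhat:",
              round(manifest$stages$simm$max_rhat, 3))
    }
  }, warning = note_warning)

  logline("run_all done")
  manifest$outputs <- c(manifest$outputs, log_path)
  structure(manifest, class = "run_manifest")
}

#' Render a run manifest as a markdown report
#'
#' @param manifest A `run_manifest` from [run_all].
#' @return Character scalar of markdown text (also classed for printing).
#' @export
make_report <- function(manifest) {
  lines <- c("# Pipeline run report", "")
  if (length(manifest$warnings)) {
    lines <- c(lines, "## Warnings",
               paste0("- ", unique(manifest$warnings)), "")
  }
  st <- manifest$stages
  if (!is.null(st$selectivity)) {
    ma <- st$selectivity$mean_alpha
    lines <- c(lines, "## Feeding selectivity (Manly-Chesson alpha)",
               sprintf("- Friedman chi-squared = %.3g (df = %d), p = %.3g",
                       st$selectivity$friedman$statistic,
                       st$selectivity$friedman$df,
                       st$selectivity$friedman$p_value),
               "- Mean alpha ranking:",
               sprintf("  %d. %s (%.3f)", seq_along(ma), names(ma), ma), "")
  }
  if (!is.null(st$trophic)) {
    an <- st$trophic$anova
    lines <- c(lines, "## Trophic position",
               sprintf("- treatment: F = %.2f, p = %.3g",
                       an$f[1], an$p[1]),
               sprintf("- site within treatment: F = %.2f, p = %.3g",
                       an$f[2], an$p[2]),
               "- Per-site pairwise tests:",
               sprintf("  - %s: natural %.2f vs disturbed %.2f, p = %.3g",
                       st$trophic$pairwise$site,
                       st$trophic$pairwise$mean_natural,
                       st$trophic$pairwise$mean_disturbed,
                       st$trophic$pairwise$p_value), "")
  }
  if (!is.null(st$polygon)) {
    lines <- c(lines, "## Mixing-polygon feasibility",
               sprintf("- %d of %d consumers flagged outside the mixing region",
                       st$polygon$n_outside, nrow(st$polygon$inclusion)), "")
  }
  if (!is.null(st$simm)) {
    cmp <- st$simm$comparison
    lines <- c(lines, "## Diet reconstruction (posterior proportions)",
               sprintf("- max Rhat = %.3f%s", st$simm$max_rhat,
                       if (st$simm$max_rhat > 1.05)
                         " (WARNING: exceeds 1.05)" else ""),
               "- Shared sources, natural vs disturbed (mean [95% CI]):",
               sprintf("  - %s: %.3f [%.3f, %.3f] vs %.3f [%.3f, %.3f]",
                       cmp$source, cmp$mean_natural, cmp$lo_natural,
                       cmp$hi_natural, cmp$mean_disturbed, cmp$lo_disturbed,
                       cmp$hi_disturbed), "")
  }
  done <- names(st)
  if (length(done) < 4)
    lines <- c(lines, sprintf("*Partial report: stages run = %s*",
                              paste(done, collapse = ", ")))
  structure(paste(lines, collapse = "\n"), class = "isoforage_report")
}

#' @export
print.isoforage_report <- function(x, ...) {
  cat(x, "\n")
  invisible(x)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("isoforage run manifest\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  cat(length(x$outputs), "output file(s) in", x$out_dir, "\n")
  if (length(x$warnings)) cat(length(x$warnings), "warning(s)\n")
  invisible(x)
}
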
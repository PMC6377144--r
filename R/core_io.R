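#' Trophic enrichment factors (TEF)
#'
#' Per-tracer diet-to-tissue discrimination, mean and standard deviation, in
#' per-mil. Defaults are the sesarmid-crab values used throughout the
#' package: \eqn{\Delta\delta^{15}N = +5.2 \pm 0.28} and
#' \eqn{\Delta\delta^{13}C = +4.6 \pm 0.71} permil.
#'
#' @param d15N_mean,d15N_sd Mean and sd of the delta-15N enrichment (permil).
#' @param d13C_mean,d13C_sd Mean and sd of the delta-13C enrichment (permil).
#' @return An object of class `trophic_enrichment`.
#' @examples
#' trophic_enrichment()
#' @export
trophic_enrichment <- function(d15N_mean = 5.2, d15N_sd = 0.28,
                               d13C_mean = 4.6, d13C_sd = 0.71) {
  stopifnot(is.numeric(d15N_mean), is.numeric(d13C_mean))
  if (d15N_sd < 0 || d13C_sd < 0)
    stop("TEF standard deviations must be >= 0", call. = FALSE)
  structure(
    list(d15N_mean = d15N_mean, d15N_sd = d15N_sd,
         d13C_mean = d13C_mean, d13C_sd = d13C_sd),
    class = "trophic_enrichment")
}

#' @export
print.trophic_enrichment <- function(x, ...) {
  cat(sprintf("TEF: d15N %+.2f +/- %.2f permil; d13C %+.2f +/- %.2f permil\n",
              x$d15N_mean, x$d15N_sd, x$d13C_mean, x$d13C_sd))
  invisible(x)
}

.consumer_cols <- c("sample_id", "site", "habitat_status", "category",
                    "d13C", "d15N", "pctC", "pctN")
.source_cols <- c("name", "site", "mu_d13C", "sigma_d13C", "mu_d15N",
                  "sigma_d15N", "conc_C", "conc_N", "n")

.fail_rows <- function(bad, what) {
  if (any(bad))
    stop(sprintf("%s (rows: %s)", what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
}

#' Validate a table of individual isotope measurements
#'
#' One row per organism/tissue measurement: tracer values in permil
#' (delta-13C vs VPDB, delta-15N vs air N2) plus elemental content and
#' site/habitat labels. `pctC`/`pctN` may be `NA` when concentration
#' dependence is not used downstream.
#'
#' @param df A data frame with columns
#'   `sample_id, site, habitat_status, category, d13C, d15N, pctC, pctN`.
#' @return The validated data frame with class `isotope_samples`.
#' @export
isotope_samples <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(.consumer_cols, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[.consumer_cols]
  for (col in c("d13C", "d15N", "pctC", "pctN")) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  }
  .fail_rows(!is.finite(df$d13C), "non-finite d13C")
  .fail_rows(!is.finite(df$d15N), "non-finite d15N")
  .fail_rows(!is.na(df$pctC) & (df$pctC < 0 | df$pctC > 100),
             "pctC outside [0, 100]")
  .fail_rows(!is.na(df$pctN) & (df$pctN <= 0 | df$pctN > 100),
             "pctN outside (0, 100]")
  bad_status <- !df$habitat_status %in% c("natural", "disturbed")
  .fail_rows(bad_status, "habitat_status must be 'natural' or 'disturbed'")
  structure(df, class = c("isotope_samples", "data.frame"))
}

#' Validate a table of aggregated source groups
#'
#' One row per prey/source category per site, with per-tracer mean, sd,
#' elemental concentration (%C for carbon, %N for nitrogen) and replicate
#' count. Concentrations may be `NA` only when concentration dependence is
#' disabled downstream.
#'
#' @param df A data frame with columns
#'   `name, site, mu_d13C, sigma_d13C, mu_d15N, sigma_d15N, conc_C, conc_N, n`.
#' @return The validated data frame with class `source_groups`.
#' @export
source_groups <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(.source_cols, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[.source_cols]
  num <- setdiff(.source_cols, c("name", "site"))
  for (col in num) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  }
  .fail_rows(!is.finite(df$mu_d13C) | !is.finite(df$mu_d15N),
             "non-finite source mean")
  .fail_rows(df$sigma_d13C < 0 | df$sigma_d15N < 0, "negative source sd")
  .fail_rows(!is.na(df$conc_C) & df$conc_C <= 0, "conc_C must be > 0")
  .fail_rows(!is.na(df$conc_N) & df$conc_N <= 0, "conc_N must be > 0")
  .fail_rows(df$n < 1, "replicate count n must be >= 1")
  structure(df, class = c("source_groups", "data.frame"))
}

#' Read an isotope table from CSV
#'
#' @param path Path to a CSV file.
#' @param schema `"consumer"` for individual measurements
#'   ([isotope_samples]) or `"source"` for aggregated groups
#'   ([source_groups]).
#' @return A validated `isotope_samples` or `source_groups` data frame.
#' @export
read_isotope_table <- function(path, schema = c("consumer", "source")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (schema == "consumer") .consumer_cols else .source_cols
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("schema error in '%s': missing columns %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  num <- setdiff(need, c("sample_id", "site", "habitat_status", "category",
                         "name"))
  for (col in num) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(conv)
      if (any(bad))
        stop(sprintf("parse error in '%s', column '%s', rows: %s", path, col,
                     paste(which(bad), collapse = ", ")), call. = FALSE)
      df[[col]] <- conv
    }
  }
  if (schema == "consumer") isotope_samples(df) else source_groups(df)
}

#' Write an isotope table to CSV
#'
#' Values are written at full double precision so that
#' `read_isotope_table(write_isotope_table(x))` round-trips to 1e-9.
#'
#' @param x An `isotope_samples` or `source_groups` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.12g", v))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate individual source measurements into source groups
#'
#' Species with overlapping signatures or similar trophic ecology are pooled
#' into categories; per category per site this computes the per-tracer mean
#' and sample sd, the mean elemental concentrations, and the replicate
#' count. Groups with a single replicate get sd = 0 and are flagged with a
#' warning.
#'
#' @param samples An [isotope_samples] table of source-organism replicates.
#' @param grouping Optional named character vector mapping `category` values
#'   to group names; unmapped categories keep their own name.
#' @return A [source_groups] data frame sorted by site then name.
#' @export
aggregate_sources <- function(samples, grouping = NULL) {
  samples <- isotope_samples(samples)
  grp <- samples$category
  if (!is.null(grouping)) {
    hit <- grp %in% names(grouping)
    grp[hit] <- unname(grouping[grp[hit]])
  }
  if (any(!nzchar(grp) | is.na(grp)))
    stop("empty group name after mapping", call. = FALSE)
  key <- interaction(grp, samples$site, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(samples)), key), function(i) {
    s <- samples[i, ]
    n <- length(i)
    data.frame(
      name = grp[i][1], site = s$site[1],
      mu_d13C = mean(s$d13C),
      sigma_d13C = if (n > 1) stats::sd(s$d13C) else 0,
      mu_d15N = mean(s$d15N),
      sigma_d15N = if (n > 1) stats::sd(s$d15N) else 0,
      conc_C = if (all(is.na(s$pctC))) NA_real_ else mean(s$pctC, na.rm = TRUE),
      conc_N = if (all(is.na(s$pctN))) NA_real_ else mean(s$pctN, na.rm = TRUE),
      n = n, stringsAsFactors = FALSE)
  }))
  singletons <- out$name[out$n == 1]
  if (length(singletons))
    warning("single-replicate group(s), sd set to 0: ",
            paste(unique(singletons), collapse = ", "), call. = FALSE)
  out <- out[order(out$site, out$name), ]
  rownames(out) <- NULL
  source_groups(out)
}

#' Analysis configuration
#'
#' Bundles the tunable numbers shared by the pipeline stages. MCMC defaults
#' are desk-scale (3 chains of 20,000 with half discarded as burn-in,
#' thinning 10); a publication-scale chain of 3,000,000 with 1,500,000
#' burn-in is accepted through the same fields.
#'
#' @param tef A [trophic_enrichment] object.
#' @param lambda_baseline Trophic level assigned to the baseline organism
#'   (default 2, a primary consumer).
#' @param mcmc List with `chains`, `iterations`, `burn_in`, `thin`, `seed`.
#' @param polygon List with `n_iterations`, `seed`, `inclusion_alpha`.
#' @param paths Optional named list of input/output table paths.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(tef = trophic_enrichment(),
                            lambda_baseline = 2,
                            mcmc = list(chains = 3, iterations = 20000,
                                        burn_in = 10000, thin = 10, seed = 1),
                            polygon = list(n_iterations = 1500, seed = 1,
                                           inclusion_alpha = 0.05),
                            paths = list()) {
  defaults_m <- list(chains = 3, iterations = 20000, burn_in = 10000,
                     thin = 10, seed = 1)
  defaults_p <- list(n_iterations = 1500, seed = 1, inclusion_alpha = 0.05)
  mcmc <- utils::modifyList(defaults_m, mcmc)
  polygon <- utils::modifyList(defaults_p, polygon)
  if (mcmc$chains < 2) stop("mcmc$chains must be >= 2", call. = FALSE)
  if (mcmc$burn_in >= mcmc$iterations)
    stop("mcmc burn_in must be < iterations", call. = FALSE)
  if (mcmc$thin < 1) stop("mcmc thin must be >= 1", call. = FALSE)
  if (polygon$inclusion_alpha <= 0 || polygon$inclusion_alpha >= 1)
    stop("inclusion_alpha must be in (0, 1)", call. = FALSE)
  structure(list(tef = tef, lambda_baseline = lambda_baseline, mcmc = mcmc,
                 polygon = polygon, paths = paths),
            class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#'
#' @param path Path to a JSON config with optional sections `tef`,
#'   `lambda_baseline`, `mcmc`, `polygon`, `paths`.
#' @return An [analysis_config] object.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tef <- if (!is.null(raw$tef)) do.call(trophic_enrichment, as.list(raw$tef))
         else trophic_enrichment()
  analysis_config(
    tef = tef,
    lambda_baseline = raw$lambda_baseline %||% 2,
    mcmc = as.list(raw$mcmc %||% list()),
    polygon = as.list(raw$polygon %||% list()),
    paths = as.list(raw$paths %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
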
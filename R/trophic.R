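#' Site-specific baseline delta-15N
#'
#' The delta-15N of a long-lived primary consumer (here a detritivorous
#' snail) anchors trophic position at each site, absorbing between-site
#' differences in nitrogen sources at the base of the web.
#'
#' @param samples An [isotope_samples] table.
#' @param baseline_category Category label of the baseline organism.
#' @param site Site label.
#' @return List `{mean, sd, n}`; `sd` is `NA` (flagged) when n = 1.
#' @export
compute_baseline <- function(samples, baseline_category, site) {
  samples <- isotope_samples(samples)
  v <- samples$d15N[samples$category == baseline_category &
                      samples$site == site]
  if (length(v) == 0)
    stop("no baseline ('", baseline_category, "') samples at site '", site,
         "'", call. = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n = length(v))
}

#' Trophic position from delta-15N
#'
#' \deqn{TP = \lambda + (\delta^{15}N_{consumer} - \delta^{15}N_{baseline})
#'   / \Delta\delta^{15}N}
#' with \eqn{\lambda} the trophic level of the baseline organism (default 2)
#' and \eqn{\Delta\delta^{15}N} the per-level enrichment.
#'
#' @param consumer_d15N Consumer delta-15N (permil); vectorized.
#' @param baseline_d15N Baseline delta-15N (permil).
#' @param tef A [trophic_enrichment] object (its `d15N_mean` is used).
#' @param lambda Trophic level of the baseline (default 2).
#' @return Trophic position(s), dimensionless.
#' @examples
#' trophic_position(9.2, 4.0, trophic_enrichment(), lambda = 2)  # 3.0
#' @export
trophic_position <- function(consumer_d15N, baseline_d15N,
                             tef = trophic_enrichment(), lambda = 2) {
  if (tef$d15N_mean <= 0)
    stop("delta-15N enrichment must be > 0", call. = FALSE)
  lambda + (consumer_d15N - baseline_d15N) / tef$d15N_mean
}

#' Per-individual trophic positions for a consumer category
#'
#' Computes the per-site baseline and converts every consumer's delta-15N
#' into a trophic position.
#'
#' @param samples An [isotope_samples] table holding both consumers and
#'   baseline organisms.
#' @param consumer_category Category label of the consumer (e.g. the crab).
#' @param baseline_category Category label of the baseline organism.
#' @inheritParams trophic_position
#' @return Data frame of class `trophic_records`:
#'   `sample_id, site, habitat_status, tp, baseline_d15N, lambda`.
#' @export
compute_trophic_positions <- function(samples, consumer_category,
                                      baseline_category,
                                      tef = trophic_enrichment(),
                                      lambda = 2) {
  samples <- isotope_samples(samples)
  cons <- samples[samples$category == consumer_category, ]
  if (nrow(cons) == 0)
    stop("no consumer ('", consumer_category, "') samples", call. = FALSE)
  out <- do.call(rbind, lapply(unique(cons$site), function(s) {
    base <- compute_baseline(samples, baseline_category, s)
    sub <- cons[cons$site == s, ]
    data.frame(sample_id = sub$sample_id, site = s,
               habitat_status = sub$habitat_status,
               tp = trophic_position(sub$d15N, base$mean, tef, lambda),
               baseline_d15N = base$mean, lambda = lambda,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("trophic_records", "data.frame"))
}

#' Nested ANOVA of trophic position: habitat treatment with sites nested
#'
#' Two-stratum decomposition: habitat treatment (natural vs disturbed,
#' fixed), site nested within treatment, residual. The sums of squares are
#' computed directly from cell means (sequential decomposition, additive by
#' construction).
#'
#' With `denominator = "residual"` (default) both effects are tested over
#' the residual mean square, the structure that published tables of this
#' design reproduce; `"site"` tests the treatment over the site-within-
#' treatment mean square, appropriate when sites are a random sample of
#' locations.
#'
#' @param records A `trophic_records` data frame (needs `tp`,
#'   `habitat_status`, `site`).
#' @param denominator `"residual"` or `"site"` for the treatment F test.
#' @return Data frame of class `nested_anova`: rows `treatment`,
#'   `site_within_treatment`, `residual` with columns
#'   `source, ss, df, ms, f, p`.
#' @export
nested_anova <- function(records, denominator = c("residual", "site")) {
  denominator <- match.arg(denominator)
  y <- records$tp
  treat <- factor(records$habitat_status)
  # a site observed under both treatments is two nested locations
  loc <- factor(paste(records$habitat_status, records$site, sep = ":"))
  if (nlevels(treat) < 2) stop("need >= 2 treatments", call. = FALSE)
  tab <- table(loc)
  if (any(tab < 2)) stop("unreplicated site cell(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "),
                         call. = FALSE)
  gm <- mean(y)
  tm <- tapply(y, treat, mean)
  lm_ <- tapply(y, loc, mean)
  loc_treat <- tapply(as.character(treat), loc, `[`, 1)
  nt <- tapply(y, treat, length)
  nl <- tapply(y, loc, length)
  ss_treat <- sum(nt * (tm - gm)^2)
  ss_site <- sum(nl * (lm_ - tm[loc_treat])^2)
  ss_resid <- sum((y - lm_[loc])^2)
  df_treat <- nlevels(treat) - 1
  df_site <- nlevels(loc) - nlevels(treat)
  df_resid <- length(y) - nlevels(loc)
  ms_treat <- ss_treat / df_treat
  ms_site <- if (df_site > 0) ss_site / df_site else NA_real_
  ms_resid <- ss_resid / df_resid
  if (denominator == "residual") {
    f_treat <- if (ms_resid > 0) ms_treat / ms_resid else 0
    df_den_treat <- df_resid
  } else {
    f_treat <- if (isTRUE(ms_site > 0)) ms_treat / ms_site else 0
    df_den_treat <- df_site
  }
  f_site <- if (ms_resid > 0 && df_site > 0) ms_site / ms_resid else 0
  out <- data.frame(
    source = c("treatment", "site_within_treatment", "residual"),
    ss = c(ss_treat, ss_site, ss_resid),
    df = c(df_treat, df_site, df_resid),
    ms = c(ms_treat, ms_site, ms_resid),
    f = c(f_treat, f_site, NA),
    p = c(stats::pf(f_treat, df_treat, df_den_treat, lower.tail = FALSE),
          if (df_site > 0)
            stats::pf(f_site, df_site, df_resid, lower.tail = FALSE)
          else NA,
          NA),
    stringsAsFactors = FALSE)
  structure(out, class = c("nested_anova", "data.frame"))
}

#' Per-site pairwise comparison of trophic position between habitats
#'
#' At each site with both habitat statuses present, compares consumer
#' trophic position between the natural and disturbed location, either by
#' Tukey's HSD (default; equivalent to a pooled-variance comparison through
#' the studentized range) or Welch's t-test.
#'
#' @param records A `trophic_records` data frame.
#' @param method `"tukey"` or `"welch"`.
#' @return Data frame: `site, statistic, p_value, mean_natural,
#'   mean_disturbed, method`. Sites missing one status are skipped with a
#'   warning.
#' @export
pairwise_site_tests <- function(records, method = c("tukey", "welch")) {
  method <- match.arg(method)
  rows <- lapply(unique(records$site), function(s) {
    sub <- records[records$site == s, ]
    g <- split(sub$tp, sub$habitat_status)
    if (!all(c("natural", "disturbed") %in% names(g)) ||
        any(lengths(g) < 2)) {
      warning("site '", s, "': one habitat status missing or unreplicated; ",
              "skipped", call. = FALSE)
      return(NULL)
    }
    if (method == "welch") {
      tt <- stats::t.test(g$disturbed, g$natural)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      fit <- stats::aov(tp ~ habitat_status, data = sub)
      tk <- stats::TukeyHSD(fit)$habitat_status
      stat <- tk[1, "diff"]; p <- tk[1, "p adj"]
    }
    data.frame(site = s, statistic = stat, p_value = p,
               mean_natural = mean(g$natural),
               mean_disturbed = mean(g$disturbed),
               method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(site = character(), statistic = numeric(),
                                      p_value = numeric())
  rownames(out) <- NULL
  out
}

#' Descriptive trophic-position summary per site and habitat status
#'
#' Range of trophic position within a population is read as a proxy for
#' diet breadth; cells with fewer than 2 records are skipped with a
#' warning.
#'
#' @param records A `trophic_records` data frame.
#' @return Data frame: `site, habitat_status, n, mean, sd, min, max, range`.
#' @export
tp_range_summary <- function(records) {
  key <- interaction(records$site, records$habitat_status, drop = TRUE)
  rows <- lapply(split(records, key), function(sub) {
    if (nrow(sub) < 2) {
      warning("cell ", sub$site[1], "/", sub$habitat_status[1],
              ": fewer than 2 records; skipped", call. = FALSE)
      return(NULL)
    }
    data.frame(site = sub$site[1], habitat_status = sub$habitat_status[1],
               n = nrow(sub), mean = mean(sub$tp), sd = stats::sd(sub$tp),
               min = min(sub$tp), max = max(sub$tp),
               range = max(sub$tp) - min(sub$tp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
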
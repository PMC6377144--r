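# Synthetic-data generators. The default scenario mirrors the shape of the
# field study the pipeline is designed around: three paired sites, each with
# a natural and a disturbed location; ~10 source groups at natural locations
# and 8 at disturbed ones (upland groups absent); C4 grasses near -13 permil
# and C3 plants near -27 permil in d13C; 45 feeding crabs in 3 trials of 15;
# ~5 consumers per site x status cell. Truth sidecars are separate objects
# never read by the analysis stages.

.default_source_menu <- function() {
  data.frame(
    name = c("HerbivorousArthropods", "SecondaryArthropods", "Uca",
             "DetritivorousGastropods", "MangroveDetritus", "SeagrassWrack",
             "HighIntertidalVegetation", "Grasses", "UplandPlantDetritus",
             "UplandPlants"),
    mu_d13C = c(-20, -19, -16, -18, -26, -17, -26.5, -13, -27.5, -27),
    mu_d15N = c(5.5, 7.0, 7.5, 6.0, 4.5, 4.0, 6.0, 4.0, 2.0, 3.0),
    sigma_d13C = c(1.5, 1.5, 1.0, 1.2, 1.5, 2.0, 1.5, 1.0, 1.0, 1.5),
    sigma_d15N = c(1.0, 1.0, 0.8, 0.8, 1.0, 1.0, 1.2, 1.0, 1.0, 1.2),
    conc_C = c(50, 50, 40, 40, 42, 35, 40, 42, 45, 45),
    conc_N = c(10, 10.5, 12, 11, 1.5, 1.8, 2.5, 1.2, 0.8, 1.5),
    upland = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
               TRUE, TRUE),
    stringsAsFactors = FALSE)
}

.default_true_p <- function(menu) {
  p_nat <- c(HerbivorousArthropods = 0.10, SecondaryArthropods = 0.05,
             Uca = 0.07, DetritivorousGastropods = 0.10,
             MangroveDetritus = 0.12, SeagrassWrack = 0.04,
             HighIntertidalVegetation = 0.12, Grasses = 0.05,
             UplandPlantDetritus = 0.10, UplandPlants = 0.25)
  p_dis <- c(HerbivorousArthropods = 0.18, SecondaryArthropods = 0.06,
             Uca = 0.08, DetritivorousGastropods = 0.20,
             MangroveDetritus = 0.14, SeagrassWrack = 0.06,
             HighIntertidalVegetation = 0.20, Grasses = 0.08)
  list(natural = p_nat, disturbed = p_dis)
}

#' Default synthetic scenario
#'
#' Builds a `scenario_config` whose stated world matches the study design
#' the package emulates: 3 paired sites, a 10-group source menu at natural
#' locations (8 at disturbed, upland groups removed), concentration
#' contrasts between plant (%N ~ 1-2.5) and animal (%N ~ 10-12) sources,
#' trophic truth elevated by 0.4 levels at disturbed locations, and a
#' 45-crab 6-prey feeding experiment in which the animal prey is always
#' consumed entirely. Per-site source means receive a small deterministic
#' spatial jitter (sd 0.5 permil) to emulate between-site variability.
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_consumers Consumers per site x status cell (default 5).
#' @param n_source_reps Source replicates per group per location (default 3).
#' @param n_crabs Feeding-experiment crabs (default 45, 3 trials of 15).
#' @param residual_sd Consumer residual sd per tracer, permil (default 0.5).
#' @param tp_natural,tp_disturbed True trophic position per status
#'   (defaults 2.4 and 2.8).
#' @param tp_noise_sd Residual sd of consumer trophic position in trophic
#'   levels (default 0.15; applied to delta-15N as `tp_noise_sd * TEF`).
#' @param tef True trophic enrichment used by every generator.
#' @return A list of class `scenario_config`.
#' @export
default_scenario <- function(seed = 1, n_consumers = 5, n_source_reps = 3,
                             n_crabs = 45, residual_sd = 0.5,
                             tp_natural = 2.4, tp_disturbed = 2.8,
                             tp_noise_sd = 0.15,
                             tef = trophic_enrichment()) {
  menu <- .default_source_menu()
  sites <- c("S1", "S2", "S3")
  # deterministic per-site spatial jitter of source means
  set.seed(seed)
  truth <- do.call(rbind, lapply(sites, function(s) {
    do.call(rbind, lapply(c("natural", "disturbed"), function(st) {
      m <- if (st == "natural") menu else menu[!menu$upland, ]
      m$site <- s
      m$habitat_status <- st
      m$mu_d13C <- m$mu_d13C + stats::rnorm(nrow(m), 0, 0.5)
      m$mu_d15N <- m$mu_d15N + stats::rnorm(nrow(m), 0, 0.5)
      m
    }))
  }))
  rownames(truth) <- NULL
  structure(list(
    seed = seed, sites = sites, statuses = c("natural", "disturbed"),
    source_truth = truth, true_p = .default_true_p(menu),
    n_consumers = n_consumers, n_source_reps = n_source_reps,
    residual_sd = residual_sd, tef = tef,
    feeding = list(
      n_crabs = n_crabs, n_trials = 3,
      prey = c("Grass", "Borrichia", "Iva", "Fern", "Avicennia", "Cricket"),
      fractions = c(Grass = 0.1, Borrichia = 0.1, Iva = 0.6, Fern = 0.1,
                    Avicennia = 0.5, Cricket = 1.0),
      wet_range = c(1.5, 3.0), dry_ratio = 0.3, autogenic_factor = 0.9,
      mass_noise_sd = 0.005),
    trophic = list(
      baseline_d15N = c(S1 = 4.0, S2 = 5.0, S3 = 4.5),
      tp_true = c(natural = tp_natural, disturbed = tp_disturbed),
      noise_sd = tp_noise_sd, baseline_noise_sd = 0.3,
      n_baseline = 5, lambda = 2)),
    class = "scenario_config")
}

.loc_sources <- function(cfg, site, status)
  cfg$source_truth[cfg$source_truth$site == site &
                     cfg$source_truth$habitat_status == status, ]

#' Generate source tables (groups and individual replicates)
#'
#' Per group per location, `n_source_reps` replicates are drawn from
#' independent normals around the scenario's per-site true means; elemental
#' concentrations get small relative jitter.
#'
#' @param cfg A [default_scenario] configuration.
#' @return List: `samples` ([isotope_samples] of replicates), `groups`
#'   (named list of [source_groups] tables per status, site column = site
#'   label), `truth` (the scenario's per-site source truth, a sidecar).
#' @export
gen_sources <- function(cfg) {
  set.seed(cfg$seed + 101)
  samples <- do.call(rbind, lapply(seq_len(nrow(cfg$source_truth)),
                                   function(i) {
    tr <- cfg$source_truth[i, ]
    n <- cfg$n_source_reps
    data.frame(
      sample_id = sprintf("src_%s_%s_%s_%d", tr$site, tr$habitat_status,
                          tr$name, seq_len(n)),
      site = tr$site, habitat_status = tr$habitat_status, category = tr$name,
      d13C = stats::rnorm(n, tr$mu_d13C, tr$sigma_d13C),
      d15N = stats::rnorm(n, tr$mu_d15N, tr$sigma_d15N),
      pctC = pmax(1, stats::rnorm(n, tr$conc_C, tr$conc_C * 0.05)),
      pctN = pmax(0.1, stats::rnorm(n, tr$conc_N, tr$conc_N * 0.05)),
      stringsAsFactors = FALSE)
  }))
  samples <- isotope_samples(samples)
  groups <- lapply(stats::setNames(cfg$statuses, cfg$statuses),
                   function(st) {
    aggregate_sources(samples[samples$habitat_status == st, ])
  })
  list(samples = samples, groups = groups, truth = cfg$source_truth)
}

.mixture_mean_var <- function(p, mu, v, conc) {
  w <- p * conc
  w <- w / sum(w)
  c(mean = sum(w * mu), var = sum(w^2 * v))
}

#' Generate consumer mixtures with known diet proportions
#'
#' Consumer tracer values are drawn around the concentration-weighted
#' mixture mean of the location's true sources (TEF added), with variance
#' equal to the propagated process variance plus the scenario residual
#' variance.
#'
#' @param cfg A [default_scenario] configuration.
#' @return List: `consumers` ([isotope_samples]), `truth` (sidecar data
#'   frame `site, habitat_status, source, p_true`).
#' @export
gen_consumers <- function(cfg) {
  set.seed(cfg$seed + 202)
  tef <- cfg$tef
  rows <- list(); truth <- list()
  for (site in cfg$sites) for (st in cfg$statuses) {
    src <- .loc_sources(cfg, site, st)
    p <- cfg$true_p[[st]][src$name]
    mmC <- .mixture_mean_var(p, src$mu_d13C + tef$d13C_mean,
                             src$sigma_d13C^2 + tef$d13C_sd^2, src$conc_C)
    mmN <- .mixture_mean_var(p, src$mu_d15N + tef$d15N_mean,
                             src$sigma_d15N^2 + tef$d15N_sd^2, src$conc_N)
    n <- cfg$n_consumers
    rows[[paste(site, st)]] <- data.frame(
      sample_id = sprintf("crab_%s_%s_%d", site, st, seq_len(n)),
      site = site, habitat_status = st, category = "Armases",
      d13C = stats::rnorm(n, mmC["mean"],
                          sqrt(mmC["var"] + cfg$residual_sd^2)),
      d15N = stats::rnorm(n, mmN["mean"],
                          sqrt(mmN["var"] + cfg$residual_sd^2)),
      pctC = 40, pctN = 11, stringsAsFactors = FALSE)
    truth[[paste(site, st)]] <- data.frame(
      site = site, habitat_status = st, source = src$name, p_true = unname(p),
      stringsAsFactors = FALSE)
  }
  list(consumers = isotope_samples(do.call(rbind, rows)),
       truth = do.call(rbind, truth))
}

#' Generate multi-choice feeding trials with known preference
#'
#' Each crab receives every prey simultaneously; leaves are halved into a
#' treatment and a consumer-free control half. Dry mass is `dry_ratio *`
#' wet mass plus measurement noise; both halves lose autogenic mass by the
#' scenario factor; the treatment half additionally loses the prey's true
#' consumption fraction of its dry mass. A fraction of 1.0 (the animal
#' prey analog) exercises the fully-consumed path downstream.
#'
#' @param cfg A [default_scenario] configuration.
#' @return List: `trials` (a [feeding_trials] table), `calibration`
#'   (wet/dry pairs per prey for the regression), `truth` (sidecar of true
#'   consumption fractions).
#' @export
gen_feeding_trials <- function(cfg) {
  set.seed(cfg$seed + 303)
  fc <- cfg$feeding
  per_trial <- fc$n_crabs / fc$n_trials
  sexes <- function() {
    s <- c(rep("M", ceiling(per_trial / 2)), rep("F", floor(per_trial / 2)))
    s[seq_len(per_trial)]
  }
  rows <- list()
  for (tr in seq_len(fc$n_trials)) {
    sx <- sexes()
    for (i in seq_len(per_trial)) {
      id <- sprintf("crab%02d", (tr - 1) * per_trial + i)
      for (prey in fc$prey) {
        frac <- fc$fractions[[prey]]
        wet_t <- stats::runif(1, fc$wet_range[1], fc$wet_range[2])
        wet_c <- stats::runif(1, fc$wet_range[1], fc$wet_range[2])
        dry_t <- wet_t * fc$dry_ratio
        dry_c <- wet_c * fc$dry_ratio
        noise_t <- stats::rnorm(1, 0, fc$mass_noise_sd)
        # a fully consumed prey leaves nothing to weigh (exact zero)
        final_t <- if (frac >= 1) 0 else
          max(0, dry_t * fc$autogenic_factor * (1 - frac) + noise_t)
        final_c <- max(0, dry_c * fc$autogenic_factor +
                         stats::rnorm(1, 0, fc$mass_noise_sd))
        rows[[length(rows) + 1]] <- data.frame(
          crab_id = id, sex = sx[i], trial = tr, prey = prey,
          initial_wet_mass = c(wet_t, wet_c),
          final_dry_mass = c(final_t, final_c),
          is_control = c(FALSE, TRUE), stringsAsFactors = FALSE)
      }
    }
  }
  trials <- feeding_trials(do.call(rbind, rows))
  calib <- do.call(rbind, lapply(fc$prey, function(prey) {
    wet <- stats::runif(30, fc$wet_range[1], fc$wet_range[2])
    data.frame(prey = prey, wet = wet,
               dry = wet * fc$dry_ratio + stats::rnorm(30, 0,
                                                       fc$mass_noise_sd),
               stringsAsFactors = FALSE)
  }))
  list(trials = trials, calibration = calib,
       truth = data.frame(prey = fc$prey,
                          fraction = unname(fc$fractions[fc$prey]),
                          stringsAsFactors = FALSE))
}

#' Generate a trophic-position dataset (consumers plus baseline organism)
#'
#' Baseline snails sit at the site's baseline delta-15N plus noise;
#' consumers at `baseline + (tp_true - lambda) * TEF + noise`. The truth
#' sidecar records the per-cell true trophic position.
#'
#' @param cfg A [default_scenario] configuration.
#' @return List: `samples` ([isotope_samples] of crabs and baseline
#'   organisms), `truth` (sidecar `site, habitat_status, tp_true`).
#' @export
gen_trophic_dataset <- function(cfg) {
  set.seed(cfg$seed + 404)
  tc <- cfg$trophic
  delta <- cfg$tef$d15N_mean
  rows <- list(); truth <- list()
  for (site in cfg$sites) {
    base <- tc$baseline_d15N[[site]]
    rows[[paste(site, "base")]] <- data.frame(
      sample_id = sprintf("snail_%s_%d", site, seq_len(tc$n_baseline)),
      site = site, habitat_status = "natural", category = "Melampus",
      d13C = stats::rnorm(tc$n_baseline, -22, 0.5),
      d15N = stats::rnorm(tc$n_baseline, base, tc$baseline_noise_sd),
      pctC = 40, pctN = 11, stringsAsFactors = FALSE)
    for (st in cfg$statuses) {
      tp <- tc$tp_true[[st]]
      nsd <- if (length(tc$noise_sd) > 1) tc$noise_sd[[st]] else tc$noise_sd
      n <- cfg$n_consumers
      rows[[paste(site, st)]] <- data.frame(
        sample_id = sprintf("tpcrab_%s_%s_%d", site, st, seq_len(n)),
        site = site, habitat_status = st, category = "Armases",
        d13C = stats::rnorm(n, -20, 1),
        d15N = base + (tp - tc$lambda) * delta +
          stats::rnorm(n, 0, nsd * delta),
        pctC = 40, pctN = 11, stringsAsFactors = FALSE)
      truth[[paste(site, st)]] <- data.frame(
        site = site, habitat_status = st, tp_true = tp,
        stringsAsFactors = FALSE)
    }
  }
  list(samples = isotope_samples(do.call(rbind, rows)),
       truth = do.call(rbind, truth))
}

#' Write a full synthetic dataset to a directory
#'
#' Emits the analysis-facing CSVs (consumer/source isotope tables, feeding
#' trials, calibration pairs, trophic samples) and, separately, `truth_*`
#' sidecar CSVs that no analysis stage reads.
#'
#' @param cfg A [default_scenario] configuration.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_scenario <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  srcs <- gen_sources(cfg)
  cons <- gen_consumers(cfg)
  feed <- gen_feeding_trials(cfg)
  trop <- gen_trophic_dataset(cfg)
  paths <- c(
    source_samples = file.path(dir, "source_samples.csv"),
    sources_natural = file.path(dir, "sources_natural.csv"),
    sources_disturbed = file.path(dir, "sources_disturbed.csv"),
    consumers = file.path(dir, "consumers.csv"),
    feeding_trials = file.path(dir, "feeding_trials.csv"),
    calibration = file.path(dir, "calibration_pairs.csv"),
    trophic_samples = file.path(dir, "trophic_samples.csv"),
    truth_diet = file.path(dir, "truth_diet.csv"),
    truth_feeding = file.path(dir, "truth_feeding.csv"),
    truth_trophic = file.path(dir, "truth_trophic.csv"))
  write_isotope_table(srcs$samples, paths["source_samples"])
  write_isotope_table(srcs$groups$natural, paths["sources_natural"])
  write_isotope_table(srcs$groups$disturbed, paths["sources_disturbed"])
  write_isotope_table(cons$consumers, paths["consumers"])
  utils::write.csv(feed$trials, paths["feeding_trials"], row.names = FALSE)
  utils::write.csv(feed$calibration, paths["calibration"], row.names = FALSE)
  write_isotope_table(trop$samples, paths["trophic_samples"])
  utils::write.csv(cons$truth, paths["truth_diet"], row.names = FALSE)
  utils::write.csv(feed$truth, paths["truth_feeding"], row.names = FALSE)
  utils::write.csv(trop$truth, paths["truth_trophic"], row.names = FALSE)
  invisible(paths)
}
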
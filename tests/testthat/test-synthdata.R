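test_that("scenario generation is deterministic and passes validation", {
  cfg <- default_scenario(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_scenario(cfg, d1)
  p2 <- write_scenario(default_scenario(seed = 7), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("file", k))
  }
  # every generated table passes the validating readers
  expect_s3_class(read_isotope_table(p1[["consumers"]], "consumer"),
                  "isotope_samples")
  expect_s3_class(read_isotope_table(p1[["sources_natural"]], "source"),
                  "source_groups")
  expect_s3_class(read_feeding_trials(p1[["feeding_trials"]]),
                  "feeding_trials")

  # a different seed changes the data
  p3 <- write_scenario(default_scenario(seed = 8), withr::local_tempdir())
  expect_false(identical(readLines(p1[["consumers"]]),
                         readLines(p3[["consumers"]])))
})

test_that("scenario mirrors the intended study shape", {
  cfg <- default_scenario(seed = 1)
  srcs <- gen_sources(cfg)
  expect_equal(length(unique(srcs$groups$natural$name)), 10)
  expect_equal(length(unique(srcs$groups$disturbed$name)), 8)
  # upland groups absent from disturbed locations
  expect_false(any(grepl("Upland", srcs$groups$disturbed$name)))
  # C4 grasses near -13, C3 plants near -27
  menu <- cfg$source_truth
  expect_lt(abs(mean(menu$mu_d13C[menu$name == "Grasses"]) - (-13)), 1.5)
  expect_lt(abs(mean(menu$mu_d13C[menu$name == "UplandPlants"]) - (-27)), 1.5)

  feed <- gen_feeding_trials(cfg)
  expect_equal(length(unique(feed$trials$crab_id)), 45)
  expect_equal(length(unique(feed$trials$trial)), 3)

  cons <- gen_consumers(cfg)
  sums <- tapply(cons$truth$p_true,
                 paste(cons$truth$site, cons$truth$habitat_status), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("sources with zero sd reproduce their means exactly", {
  cfg <- default_scenario(seed = 2)
  cfg$source_truth$sigma_d13C <- 0
  cfg$source_truth$sigma_d15N <- 0
  srcs <- gen_sources(cfg)
  agg <- srcs$groups$natural
  tr <- cfg$source_truth[cfg$source_truth$habitat_status == "natural", ]
  m <- merge(agg, tr, by = c("name", "site"))
  expect_equal(m$mu_d13C.x, m$mu_d13C.y, tolerance = 1e-9)
  expect_equal(m$sigma_d15N.x, rep(0, nrow(m)))
})

test_that("separated groups are recovered by aggregation within 3 s.e.", {
  cfg <- default_scenario(seed = 3, n_source_reps = 10)
  srcs <- gen_sources(cfg)
  agg <- srcs$groups$natural
  tr <- cfg$source_truth[cfg$source_truth$habitat_status == "natural", ]
  m <- merge(agg, tr, by = c("name", "site"))
  se <- m$sigma_d13C.y / sqrt(m$n)
  expect_true(all(abs(m$mu_d13C.x - m$mu_d13C.y) < 3.5 * se))
})

test_that("zero-noise single-source consumers equal mu + TEF", {
  cfg <- default_scenario(seed = 4, residual_sd = 0)
  cfg$source_truth$sigma_d13C <- 0
  cfg$source_truth$sigma_d15N <- 0
  cfg$tef <- trophic_enrichment(d15N_sd = 0, d13C_sd = 0)
  # collapse the diet onto one source
  for (st in names(cfg$true_p)) {
    p <- cfg$true_p[[st]] * 0
    p["MangroveDetritus"] <- 1
    cfg$true_p[[st]] <- p
  }
  cons <- gen_consumers(cfg)$consumers
  tr <- cfg$source_truth
  for (i in seq_len(nrow(cons))) {
    row <- tr[tr$site == cons$site[i] &
                tr$habitat_status == cons$habitat_status[i] &
                tr$name == "MangroveDetritus", ]
    expect_equal(cons$d13C[i], row$mu_d13C + 4.6, tolerance = 1e-9)
    expect_equal(cons$d15N[i], row$mu_d15N + 5.2, tolerance = 1e-9)
  }
})

test_that("feeding truth propagates through the selectivity stage", {
  # equal fractions: mean alpha ~ 1/m across crabs
  cfg <- default_scenario(seed = 5)
  cfg$feeding$fractions <- c(Grass = 0.3, Borrichia = 0.3, Iva = 0.3,
                             Fern = 0.3, Avicennia = 0.3, Cricket = 1.0)
  feed <- gen_feeding_trials(cfg)
  regs <- fit_wet_dry_regression(feed$calibration, per_prey = TRUE)
  sel <- compute_selectivity(feed$trials, regs)
  amat <- alpha_matrix(sel)
  expect_equal(ncol(amat), 5)  # cricket (fraction 1.0) drops out
  expect_true(all(abs(colMeans(amat) - 0.2) < 0.05))

  # the fraction-1.0 prey is flagged undefined in every crab
  cricket <- sel[sel$prey == "Cricket", ]
  expect_true(all(!cricket$defined))

  # preference scenario: Friedman significant at n = 45
  set.seed(55)
  p <- replicate(10, {
    cfg <- default_scenario(seed = sample.int(10000, 1))
    feed <- gen_feeding_trials(cfg)
    regs <- fit_wet_dry_regression(feed$calibration, per_prey = TRUE)
    amat <- alpha_matrix(compute_selectivity(feed$trials, regs))
    friedman_test(amat)$p_value
  })
  expect_true(all(p < 0.05))
})

test_that("generated consumers fall inside the simulated mixing region", {
  # equal concentrations: the mixture mean is a convex combination of the
  # source points and hence interior to the polygon. (With strong %N
  # contrasts the concentration-dependent mean can legitimately leave the
  # hull, since per-tracer weights differ; see the methods vignette.)
  cfg <- default_scenario(seed = 6, residual_sd = 0.4)
  cfg$source_truth$conc_C <- 42
  cfg$source_truth$conc_N <- 5
  srcs <- gen_sources(cfg)
  cons <- gen_consumers(cfg)$consumers
  probs <- c()
  for (st in c("natural", "disturbed")) {
    for (site in cfg$sites) {
      cs <- cons[cons$habitat_status == st & cons$site == site, ]
      res <- simulate_mixing_region(
        srcs$groups[[st]][srcs$groups[[st]]$site == site, ], cs,
        tef = cfg$tef, n_iterations = 500, seed = 11)
      # nobody outside the 95% mixing region
      expect_false(any(res$consumers$outside_flag))
      probs <- c(probs, res$consumers$inclusion_probability)
    }
  }
  # and the bulk of consumers at high inclusion probability
  expect_gte(mean(probs >= 0.95), 0.9)
  expect_gte(min(probs), 0.5)
})

test_that("trophic truth propagates through the trophic stage", {
  # zero noise: computed tp identical to truth
  cfg <- default_scenario(seed = 8, tp_noise_sd = 0)
  cfg$trophic$baseline_noise_sd <- 0
  trop <- gen_trophic_dataset(cfg)
  rec <- compute_trophic_positions(trop$samples, "Armases", "Melampus",
                                   cfg$tef)
  m <- merge(rec, trop$truth, by = c("site", "habitat_status"))
  expect_equal(m$tp, m$tp_true, tolerance = 1e-9)

  # default noise: nested ANOVA flags the 0.4-level treatment contrast
  cfg2 <- default_scenario(seed = 9)
  trop2 <- gen_trophic_dataset(cfg2)
  rec2 <- compute_trophic_positions(trop2$samples, "Armases", "Melampus",
                                    cfg2$tef)
  an <- nested_anova(rec2)
  expect_lt(an$p[an$source == "treatment"], 0.05)
})
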
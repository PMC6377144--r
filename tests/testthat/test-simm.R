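test_that("mixture moments apply TEF and concentration weighting", {
  tef <- trophic_enrichment()
  one <- make_sources("A", mu_c = -26, mu_n = 3, sd_c = 0.5, sd_n = 0.4)
  mm <- mixture_moments(1, one, tef, "d13C")
  expect_equal(mm$mean, -26 + 4.6)  # identity mixture: mu + TEF
  expect_equal(mm$variance, 0.5^2 + 0.71^2)

  # equal concentrations: midpoint
  two <- make_sources(c("A", "B"), mu_c = c(-20 - 4.6, -10 - 4.6),
                      mu_n = c(3, 6), conc_C = 40, conc_N = 5)
  expect_equal(mixture_moments(c(0.5, 0.5), two, tef, "d13C")$mean, -15)

  # concentration 2 vs 4 pulls the mean toward the richer source
  cw <- make_sources(c("A", "B"), mu_c = c(-20 - 4.6, -10 - 4.6),
                     mu_n = c(3, 6), conc_C = c(2, 4), conc_N = 5)
  expect_equal(mixture_moments(c(0.5, 0.5), cw, tef, "d13C")$mean,
               (1 * (-20) + 2 * (-10)) / 3, tolerance = 1e-12)
  # with dependence off the same input gives the midpoint again
  expect_equal(mixture_moments(c(0.5, 0.5), cw, tef, "d13C",
                               concentration_dependent = FALSE)$mean, -15)

  expect_error(mixture_moments(c(0.6, 0.6), cw, tef), "simplex")

  # oracle equality on random simplex points
  set.seed(67)
  src <- make_sources(c("A", "B", "C"), mu_c = c(-26, -18, -10),
                      mu_n = c(2, 5, 8), sd_c = c(1, 0.5, 2),
                      sd_n = c(0.3, 1, 0.7), conc_C = c(45, 30, 50),
                      conc_N = c(1, 5, 11))
  for (i in 1:10) {
    p <- as.vector(rmultinom(1, 100, rep(1, 3))) / 100
    mm <- mixture_moments(p, src, tef, "d15N")
    or <- oracle_mixture(p, src$mu_d15N + tef$d15N_mean,
                         src$sigma_d15N^2 + tef$d15N_sd^2, src$conc_N)
    expect_equal(mm$mean, or$mean, tolerance = 1e-12)
    expect_equal(mm$variance, or$variance, tolerance = 1e-12)
  }
})

test_that("log likelihood peaks where the data sit and penalizes variance", {
  spec <- tiny_simm_problem()
  # place the single consumer exactly at the mixture mean, total sd 1
  p <- c(0.4, 0.6)
  sp2 <- spec
  for (t in 1:2) {
    w <- p * sp2$site_data[[1]]$conc[, t]
    w <- w / sum(w)
    sp2$site_data[[1]]$X[, t] <- sum(w * sp2$site_data[[1]]$mu[, t])
    sp2$site_data[[1]]$var_src[, t] <- 0
  }
  ll <- log_likelihood(sp2, list(proportions = matrix(p, 1),
                                 residual_sd = c(1, 1)))
  expect_equal(ll, 2 * (-0.5 * log(2 * pi)), tolerance = 1e-9)

  # doubling residual variance lowers the peak density
  ll2 <- log_likelihood(sp2, list(proportions = matrix(p, 1),
                                  residual_sd = sqrt(2) * c(1, 1)))
  expect_lt(ll2, ll)

  expect_equal(log_likelihood(spec, list(proportions = matrix(p, 1),
                                         residual_sd = c(-1, 1))), -Inf)
  expect_error(log_likelihood(spec, list(proportions = matrix(c(1, 1), 1),
                                         residual_sd = c(1, 1))), "simplex")
})

test_that("residual_only drops the process variance term", {
  src <- make_sources(c("A", "B"), mu_c = c(-26, -14), mu_n = c(3, 6),
                      sd_c = 1, sd_n = 1)
  cons <- make_consumers(-16, 9.5)
  s1 <- mixing_model_spec(src, cons, error_model = "residual_plus_process")
  s2 <- mixing_model_spec(src, cons, error_model = "residual_only")
  pars <- list(proportions = matrix(c(0.5, 0.5), 1), residual_sd = c(1, 1))
  # with nonzero source sd the two likelihoods must differ
  expect_false(isTRUE(all.equal(log_likelihood(s1, pars),
                                log_likelihood(s2, pars))))
})

test_that("MCMC posterior matches the 1,001-point grid oracle", {
  spec <- tiny_simm_problem()
  sig <- c(0.5, 0.5)
  # grid oracle with hand-rolled likelihood (independent of the package path)
  sd_ <- spec$site_data[[1]]
  p1 <- seq(1e-6, 1 - 1e-6, length.out = 1001)
  ll <- vapply(p1, function(q) {
    p <- c(q, 1 - q)
    tot <- 0
    for (t in 1:2) {
      w <- p * sd_$conc[, t]; w <- w / sum(w)
      m <- sum(w * sd_$mu[, t])
      v <- sum(w^2 * sd_$var_src[, t]) + sig[t]^2
      tot <- tot - 0.5 * log(2 * pi * v) - (sd_$X[1, t] - m)^2 / (2 * v)
    }
    tot
  }, numeric(1))
  w <- exp(ll - max(ll))
  oracle_mean <- sum(p1 * w) / sum(w)

  post <- sample_posterior(spec, mcmc_config(chains = 3, iterations = 6000,
                                             burn_in = 2000, thin = 2,
                                             seed = 5,
                                             fix_residual_sd = sig))
  mc_mean <- post$summary$mean[post$summary$source == "A"]
  expect_lt(abs(mc_mean - oracle_mean), 0.02)
  expect_lt(max(post$diagnostics$rhat), 1.05)
})

test_that("symmetric problem gives a symmetric posterior; seeds reproduce", {
  src <- make_sources(c("A", "B"), mu_c = c(-24, -12), mu_n = c(3, 7),
                      conc_C = 40, conc_N = 5)
  cons <- make_consumers(-18 + 4.6, 5 + 5.2)
  spec <- mixing_model_spec(src, cons)
  cfg <- mcmc_config(chains = 2, iterations = 6000, burn_in = 2000,
                     thin = 2, seed = 11)
  post <- suppressWarnings(sample_posterior(spec, cfg))
  expect_lt(abs(post$summary$mean[1] - 0.5), 0.05)

  again <- suppressWarnings(sample_posterior(spec, cfg))
  expect_identical(post$draws$p, again$draws$p)
  expect_identical(post$draws$sigma, again$draws$sigma)
})

test_that("stored draws live on the simplex; summaries close to it", {
  spec <- tiny_simm_problem()
  post <- suppressWarnings(
    sample_posterior(spec, mcmc_config(chains = 2, iterations = 2000,
                                       burn_in = 500, thin = 5, seed = 13)))
  sums <- apply(post$draws$p, 1, function(m) sum(m))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(post$draws$p >= 0))
  # per-site means of simplex draws sum to 1 exactly (up to float addition)
  by_site <- tapply(post$summary$mean, post$summary$site, sum)
  expect_equal(as.numeric(by_site), rep(1, length(by_site)),
               tolerance = 1e-9)

  # percentile oracle: sorted-draw interpolation (quantile type 7)
  d <- sort(post$draws$p[, 1, 1])
  n <- length(d)
  h <- (n - 1) * 0.975 + 1
  or <- d[floor(h)] + (h - floor(h)) * (d[floor(h) + 1] - d[floor(h)])
  expect_equal(post$summary$q975[post$summary$source == "A"], or,
               tolerance = 1e-12)
})

test_that("with no consumers the posterior returns the Dirichlet(1) prior", {
  src <- make_sources(c("A", "B", "C"), mu_c = c(-26, -20, -13),
                      mu_n = c(3, 5, 7))
  cons0 <- make_consumers(numeric(0), numeric(0))
  spec <- mixing_model_spec(src, cons0)
  post <- suppressWarnings(
    sample_posterior(spec, mcmc_config(chains = 2, iterations = 12000,
                                       burn_in = 2000, thin = 1, seed = 17,
                                       fix_residual_sd = c(1, 1))))
  expect_true(all(abs(post$summary$mean - 1 / 3) < 0.03))
})

test_that("concentration dependence off with equal conc matches within noise", {
  src <- make_sources(c("A", "B"), mu_c = c(-26, -14), mu_n = c(3, 6),
                      conc_C = 40, conc_N = 5)
  cons <- make_consumers(c(-15, -16, -15.5), c(9.5, 9.8, 9.2))
  cfg <- mcmc_config(chains = 2, iterations = 6000, burn_in = 2000,
                     thin = 2, seed = 19)
  on <- suppressWarnings(
    sample_posterior(mixing_model_spec(src, cons,
                                       concentration_dependent = TRUE), cfg))
  off <- suppressWarnings(
    sample_posterior(mixing_model_spec(src, cons,
                                       concentration_dependent = FALSE), cfg))
  expect_lt(max(abs(on$summary$mean - off$summary$mean)), 0.05)
})

test_that("paired models fit separate menus and compare shared sources", {
  src_n <- rbind(make_sources(c("A", "B", "Upland"), mu_c = c(-26, -14, -27),
                              mu_n = c(3, 6, 2)))
  src_d <- make_sources(c("A", "B"), mu_c = c(-26, -14), mu_n = c(3, 6))
  cons_n <- make_consumers(c(-16, -17), c(9.4, 9.6), status = "natural")
  cons_d <- make_consumers(c(-16, -17), c(9.4, 9.6), status = "disturbed")
  cfg <- mcmc_config(chains = 2, iterations = 3000, burn_in = 1000,
                     thin = 2, seed = 23)
  fit <- suppressWarnings(run_paired_models(mixing_model_spec(src_n, cons_n),
                           mixing_model_spec(src_d, cons_d), cfg))
  expect_equal(nrow(fit$natural$summary), 3)
  expect_equal(nrow(fit$disturbed$summary), 2)   # one fewer source
  expect_equal(nrow(fit$comparison), 2)          # shared sources only
  expect_setequal(fit$comparison$source, c("A", "B"))
})

test_that("identical populations give overlapping credible intervals", {
  src <- make_sources(c("A", "B", "C"), mu_c = c(-26, -18, -10),
                      mu_n = c(2, 6, 10), sd_c = 1, sd_n = 1)
  set.seed(29)
  mk <- function(status) make_consumers(rnorm(10, -13, 0.8),
                                        rnorm(10, 11, 0.8), status = status)
  cfg <- mcmc_config(chains = 2, iterations = 4000, burn_in = 2000,
                     thin = 2, seed = 29)
  fit <- suppressWarnings(run_paired_models(mixing_model_spec(src, mk("natural")),
                           mixing_model_spec(src, mk("disturbed")), cfg))
  expect_true(all(fit$comparison$overlap))
})

test_that("long-format export is consistent with the draw array", {
  spec <- tiny_simm_problem()
  post <- suppressWarnings(
    sample_posterior(spec, mcmc_config(chains = 2, iterations = 1000,
                                       burn_in = 500, thin = 5, seed = 31)))
  long <- posterior_draws_long(post)
  expect_equal(nrow(long), prod(dim(post$draws$p)))
  sub <- long[long$site == "X" & long$source == "B", ]
  expect_equal(sub$proportion[order(sub$draw)], post$draws$p[, 1, 2])
})
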
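# Concentration-dependent Bayesian stable-isotope mixing model.
#
# Likelihood: consumer j at site s, tracer t,
#   X_jst ~ Normal(sum_k w_kt (mu_kt + f_t),
#                  sum_k w_kt^2 (sigma_kt^2 + sigma_ft^2) + tau_t^2)
# with concentration weights w_kt = p_sk c_kt / sum_j p_sj c_jt.
# Priors: Dirichlet(1,...,1) on each site's proportion vector,
# half-Cauchy(5) on the residual sds tau_t. Sampling is adaptive
# random-walk Metropolis on ILR coordinates (one simplex per site) and
# log residual sds.

.tracers <- c("d13C", "d15N")

#' Specify a mixing model
#'
#' Binds consumers, per-site source groups, trophic enrichment and error
#' options into a fitting-ready specification. Every consumer site must
#' carry the same source menu (one fixed-effect model per population;
#' populations with different menus are fitted separately, see
#' [run_paired_models]).
#'
#' @param sources A [source_groups] table covering every consumer site.
#' @param consumers An [isotope_samples] table.
#' @param tef A [trophic_enrichment] object.
#' @param concentration_dependent Weight sources by elemental content
#'   (%C for carbon, %N for nitrogen); default `TRUE`. When `FALSE`, all
#'   concentrations are treated as equal.
#' @param error_model `"residual_plus_process"` (default: source and TEF
#'   variance propagated through the mixture plus a fitted residual sd per
#'   tracer) or `"residual_only"`.
#' @return An object of class `mixing_model_spec`.
#' @export
mixing_model_spec <- function(sources, consumers, tef = trophic_enrichment(),
                              concentration_dependent = TRUE,
                              error_model = c("residual_plus_process",
                                              "residual_only")) {
  error_model <- match.arg(error_model)
  sources <- source_groups(sources)
  consumers <- isotope_samples(consumers)
  sites <- sort(unique(consumers$site))
  # a spec with no consumers (prior predictive) takes sites from the sources
  if (length(sites) == 0) sites <- sort(unique(sources$site))
  menus <- lapply(sites, function(s) sort(sources$name[sources$site == s]))
  if (length(unique(menus)) != 1)
    stop("all consumer sites must share the same source menu", call. = FALSE)
  src_names <- menus[[1]]
  if (length(src_names) < 2) stop("need >= 2 sources", call. = FALSE)
  if (concentration_dependent &&
      anyNA(sources[c("conc_C", "conc_N")]))
    stop("concentration dependence requires conc_C and conc_N for every ",
         "source", call. = FALSE)
  site_data <- lapply(sites, function(s) {
    src <- sources[sources$site == s, ]
    src <- src[match(src_names, src$name), ]
    cons <- consumers[consumers$site == s, ]
    conc <- if (concentration_dependent)
      cbind(src$conc_C, src$conc_N) else matrix(1, nrow(src), 2)
    list(site = s,
         X = cbind(cons$d13C, cons$d15N),
         mu = cbind(src$mu_d13C + tef$d13C_mean,
                    src$mu_d15N + tef$d15N_mean),
         var_src = cbind(src$sigma_d13C^2 + tef$d13C_sd^2,
                         src$sigma_d15N^2 + tef$d15N_sd^2),
         conc = conc)
  })
  structure(list(sources = sources, consumers = consumers, tef = tef,
                 concentration_dependent = concentration_dependent,
                 error_model = error_model, sites = sites,
                 src_names = src_names, K = length(src_names),
                 site_data = site_data),
            class = "mixing_model_spec")
}

#' Mean and variance of a tracer under a source mixture
#'
#' Concentration-weighted mixture moments for one tracer:
#' \deqn{w_k = p_k c_k / \sum_j p_j c_j,\quad
#'   \mu = \sum_k w_k (\mu_k + f),\quad
#'   \sigma^2 = \sum_k w_k^2 (\sigma_k^2 + \sigma_f^2)}
#' with concentrations \eqn{c_k} all 1 when concentration dependence is
#' off.
#'
#' @param p Proportion vector on the simplex (tolerance 1e-9).
#' @param sources A [source_groups] table for one site, one row per source.
#' @param tef A [trophic_enrichment] object.
#' @param tracer `"d13C"` or `"d15N"`.
#' @param concentration_dependent Default `TRUE`.
#' @return List `{mean, variance}` in permil and permil squared.
#' @export
mixture_moments <- function(p, sources, tef = trophic_enrichment(),
                            tracer = c("d13C", "d15N"),
                            concentration_dependent = TRUE) {
  tracer <- match.arg(tracer)
  sources <- source_groups(sources)
  if (length(p) != nrow(sources))
    stop("length(p) must equal the number of sources", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9 || any(p < -1e-9))
    stop("p is not on the simplex", call. = FALSE)
  if (tracer == "d13C") {
    mu <- sources$mu_d13C + tef$d13C_mean
    v <- sources$sigma_d13C^2 + tef$d13C_sd^2
    conc <- sources$conc_C
  } else {
    mu <- sources$mu_d15N + tef$d15N_mean
    v <- sources$sigma_d15N^2 + tef$d15N_sd^2
    conc <- sources$conc_N
  }
  if (!concentration_dependent) conc <- rep(1, length(p))
  if (anyNA(conc)) stop("missing concentrations; disable concentration ",
                        "dependence or supply conc columns", call. = FALSE)
  w <- p * conc
  w <- w / sum(w)
  list(mean = sum(w * mu), variance = sum(w^2 * v))
}

# site-level log likelihood; p length K, sig2 length 2 (residual variances)
.site_loglik <- function(sd_, p, sig2, use_process) {
  X <- sd_$X
  if (nrow(X) == 0) return(0)
  ll <- 0
  for (t in 1:2) {
    w <- p * sd_$conc[, t]
    w <- w / sum(w)
    m <- sum(w * sd_$mu[, t])
    v <- sig2[t] + if (use_process) sum(w^2 * sd_$var_src[, t]) else 0
    ll <- ll + sum(stats::dnorm(X[, t], m, sqrt(v), log = TRUE))
  }
  ll
}

#' Log likelihood of a mixing model at given parameters
#'
#' @param spec A [mixing_model_spec].
#' @param params List with `proportions` (matrix sites x sources, rows on
#'   the simplex, site order as `spec$sites`) and `residual_sd` (length-2
#'   vector, per tracer).
#' @return Scalar log likelihood; `-Inf` for non-positive residual sds.
#' @export
log_likelihood <- function(spec, params) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  P <- matrix(params$proportions, nrow = length(spec$sites))
  sig <- params$residual_sd
  if (any(sig <= 0)) return(-Inf)
  if (any(abs(rowSums(P) - 1) > 1e-9) || any(P < -1e-9))
    stop("proportions rows must lie on the simplex", call. = FALSE)
  use_process <- spec$error_model == "residual_plus_process"
  sum(vapply(seq_along(spec$sites), function(s)
    .site_loglik(spec$site_data[[s]], P[s, ], sig^2, use_process),
    numeric(1)))
}

.log_half_cauchy <- function(x, scale = 5)
  log(2) - log(pi * scale * (1 + (x / scale)^2))

#' MCMC configuration for the mixing model
#'
#' @param chains Number of chains (>= 2 for diagnostics).
#' @param iterations Iterations per chain, including burn-in.
#' @param burn_in Iterations discarded (also the adaptation window).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param fix_residual_sd Optional length-2 vector fixing the residual sds
#'   (they are then not sampled) — used mainly for oracle comparisons.
#' @param cauchy_scale Scale of the half-Cauchy prior on residual sds.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iterations = 20000, burn_in = 10000,
                        thin = 10, seed = 1, fix_residual_sd = NULL,
                        cauchy_scale = 5) {
  if (chains < 2) stop("chains must be >= 2 for convergence diagnostics",
                       call. = FALSE)
  if (burn_in >= iterations) stop("burn_in must be < iterations",
                                  call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  structure(list(chains = chains, iterations = iterations, burn_in = burn_in,
                 thin = thin, seed = seed, fix_residual_sd = fix_residual_sd,
                 cauchy_scale = cauchy_scale),
            class = "mcmc_config")
}

#' Sample the mixing-model posterior
#'
#' Adaptive random-walk Metropolis. Each site's proportion vector is
#' updated as a block in ILR coordinates (the Dirichlet(1) prior plus the
#' ILR Jacobian contribute `sum(log p)` to the log target); residual sds
#' are updated jointly on the log scale under a half-Cauchy prior.
#' Proposal scales adapt toward ~30% acceptance during burn-in and are
#' frozen afterwards. Split-Rhat and effective sample size are computed
#' for every stored parameter; a warning is raised when any Rhat exceeds
#' 1.05.
#'
#' @param spec A [mixing_model_spec].
#' @param mcmc An [mcmc_config].
#' @return An object of class `mixing_posterior`: `draws` (list with `p`,
#'   an array draws x sites x sources; `sigma`, draws x 2; `chain`),
#'   `sites`, `src_names`, `diagnostics` (data frame of rhat/ess per
#'   parameter), `summary` (see [summarize_posterior]), `accept_rates`.
#' @export
sample_posterior <- function(spec, mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  S <- length(spec$sites); K <- spec$K
  V <- ilr_basis(K)
  use_process <- spec$error_model == "residual_plus_process"
  fixed_sig <- !is.null(mcmc$fix_residual_sd)
  n_keep <- floor((mcmc$iterations - mcmc$burn_in) / mcmc$thin)
  if (n_keep < 1) stop("no draws kept; lower thin or burn_in", call. = FALSE)

  run_chain <- function(chain) {
    set.seed(mcmc$seed + chain)
    z <- matrix(stats::rnorm(S * (K - 1), 0, 0.5), S, K - 1)
    p <- t(apply(z, 1, ilr_inverse, V = V))
    if (K == 2) p <- matrix(p, S, K)
    logsig <- if (fixed_sig) log(mcmc$fix_residual_sd)
              else log(c(1, 1)) + stats::rnorm(2, 0, 0.3)
    sig2 <- exp(2 * logsig)
    ll_site <- vapply(seq_len(S), function(s)
      .site_loglik(spec$site_data[[s]], p[s, ], sig2, use_process),
      numeric(1))
    lp_site <- vapply(seq_len(S), function(s) sum(log(p[s, ])), numeric(1))
    sig_prior <- function(ls)
      sum(.log_half_cauchy(exp(ls), mcmc$cauchy_scale)) + sum(ls)
    lprior_sig <- sig_prior(logsig)

    step_z <- rep(0.5, S); step_s <- 0.3
    acc_z <- rep(0L, S); acc_s <- 0L; batch <- 0L
    keep_p <- array(NA_real_, c(n_keep, S, K))
    keep_sig <- matrix(NA_real_, n_keep, 2)
    kept <- 0L
    total_acc_z <- rep(0L, S); total_acc_s <- 0L

    for (it in seq_len(mcmc$iterations)) {
      for (s in seq_len(S)) {
        z_new <- z[s, ] + step_z[s] * stats::rnorm(K - 1)
        p_new <- ilr_inverse(z_new, V)
        ll_new <- .site_loglik(spec$site_data[[s]], p_new, sig2, use_process)
        lp_new <- sum(log(p_new))
        if (log(stats::runif(1)) <
            (ll_new + lp_new) - (ll_site[s] + lp_site[s])) {
          z[s, ] <- z_new; p[s, ] <- p_new
          ll_site[s] <- ll_new; lp_site[s] <- lp_new
          acc_z[s] <- acc_z[s] + 1L
          if (it > mcmc$burn_in) total_acc_z[s] <- total_acc_z[s] + 1L
        }
      }
      if (!fixed_sig) {
        ls_new <- logsig + step_s * stats::rnorm(2)
        sig2_new <- exp(2 * ls_new)
        ll_new <- vapply(seq_len(S), function(s)
          .site_loglik(spec$site_data[[s]], p[s, ], sig2_new, use_process),
          numeric(1))
        lpr_new <- sig_prior(ls_new)
        if (log(stats::runif(1)) <
            (sum(ll_new) + lpr_new) - (sum(ll_site) + lprior_sig)) {
          logsig <- ls_new; sig2 <- sig2_new
          ll_site <- ll_new; lprior_sig <- lpr_new
          acc_s <- acc_s + 1L
          if (it > mcmc$burn_in) total_acc_s <- total_acc_s + 1L
        }
      }
      # batch adaptation during burn-in only
      if (it <= mcmc$burn_in && it %% 50 == 0) {
        batch <- batch + 1L
        gain <- min(0.5, 1 / sqrt(batch))
        step_z <- step_z * exp((acc_z / 50 - 0.3) * gain)
        step_z <- pmin(pmax(step_z, 1e-3), 10)
        if (!fixed_sig) {
          step_s <- step_s * exp((acc_s / 50 - 0.3) * gain)
          step_s <- min(max(step_s, 1e-3), 10)
        }
        acc_z[] <- 0L; acc_s <- 0L
      }
      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0 &&
          kept < n_keep) {
        kept <- kept + 1L
        keep_p[kept, , ] <- p
        keep_sig[kept, ] <- exp(logsig)
      }
    }
    post_n <- mcmc$iterations - mcmc$burn_in
    list(p = keep_p, sigma = keep_sig,
         acc_z = total_acc_z / post_n, acc_s = total_acc_s / post_n)
  }

  chains <- lapply(seq_len(mcmc$chains), run_chain)
  p_all <- do.call(abind1, lapply(chains, `[[`, "p"))
  sig_all <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  chain_id <- rep(seq_len(mcmc$chains), each = n_keep)

  # diagnostics per scalar parameter, iterations x chains
  diag_rows <- list()
  for (s in seq_len(S)) for (k in seq_len(K)) {
    m <- vapply(chains, function(ch) ch$p[, s, k], numeric(n_keep))
    diag_rows[[length(diag_rows) + 1]] <- data.frame(
      parameter = sprintf("p[%s,%s]", spec$sites[s], spec$src_names[k]),
      rhat = split_rhat(m), ess = effective_sample_size(m),
      stringsAsFactors = FALSE)
  }
  if (!fixed_sig) for (t in 1:2) {
    m <- vapply(chains, function(ch) ch$sigma[, t], numeric(n_keep))
    diag_rows[[length(diag_rows) + 1]] <- data.frame(
      parameter = paste0("residual_sd[", .tracers[t], "]"),
      rhat = split_rhat(m), ess = effective_sample_size(m),
      stringsAsFactors = FALSE)
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (any(diagnostics$rhat > 1.05))
    warning("Rhat > 1.05 for: ",
            paste(diagnostics$parameter[diagnostics$rhat > 1.05],
                  collapse = ", "),
            "; consider longer chains", call. = FALSE)

  post <- structure(list(
    draws = list(p = p_all, sigma = sig_all, chain = chain_id),
    sites = spec$sites, src_names = spec$src_names,
    diagnostics = diagnostics,
    accept_rates = list(z = rowMeans(matrix(vapply(chains, `[[`, numeric(S),
                                                   "acc_z"), nrow = S)),
                        sigma = mean(vapply(chains, `[[`, numeric(1),
                                            "acc_s"))),
    mcmc = mcmc), class = "mixing_posterior")
  post$summary <- summarize_posterior(post)
  post
}

# bind arrays along dim 1
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1],
                                      numeric(1))), d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Posterior summary of source proportions
#'
#' @param post A `mixing_posterior`.
#' @return Data frame: `site, source, mean, sd, q025, median, q975`;
#'   within each site the means sum to 1 exactly (means of simplex draws).
#' @export
summarize_posterior <- function(post) {
  if (is.null(post$draws$p) || dim(post$draws$p)[1] == 0)
    stop("no posterior draws", call. = FALSE)
  S <- length(post$sites); K <- length(post$src_names)
  rows <- list()
  for (s in seq_len(S)) for (k in seq_len(K)) {
    d <- post$draws$p[, s, k]
    q <- stats::quantile(d, c(0.025, 0.5, 0.975), names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      site = post$sites[s], source = post$src_names[k],
      mean = mean(d), sd = stats::sd(d),
      q025 = q[1], median = q[2], q975 = q[3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat("Mixing-model posterior:", dim(x$draws$p)[1], "draws,",
      length(x$sites), "site(s),", length(x$src_names), "sources\n")
  cat("max Rhat:", round(max(x$diagnostics$rhat), 3),
      " min ESS:", round(min(x$diagnostics$ess)), "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Fit natural and disturbed populations as paired, separate models
#'
#' Populations with unequal source menus (e.g. upland sources absent from
#' disturbed locations) cannot share one model; they are fitted
#' independently and compared on their shared sources. For each status the
#' comparison row pools proportions across sites (per-draw mean over
#' sites) and reports the posterior mean and 95% credible interval.
#'
#' @param spec_natural,spec_disturbed [mixing_model_spec] objects.
#' @param mcmc An [mcmc_config] used for both fits.
#' @return List of class `paired_mixing_fit`: `natural`, `disturbed`
#'   (posteriors) and `comparison` (one row per shared source with an
#'   `overlap` flag for 95% CI overlap).
#' @export
run_paired_models <- function(spec_natural, spec_disturbed,
                              mcmc = mcmc_config()) {
  fit_n <- sample_posterior(spec_natural, mcmc)
  fit_d <- sample_posterior(spec_disturbed, mcmc)
  shared <- intersect(fit_n$src_names, fit_d$src_names)
  cmp <- do.call(rbind, lapply(shared, function(src) {
    pool <- function(fit) {
      k <- match(src, fit$src_names)
      rowMeans(matrix(fit$draws$p[, , k], ncol = length(fit$sites)))
    }
    dn <- pool(fit_n); dd <- pool(fit_d)
    qn <- stats::quantile(dn, c(0.025, 0.975), names = FALSE)
    qd <- stats::quantile(dd, c(0.025, 0.975), names = FALSE)
    data.frame(source = src,
               mean_natural = mean(dn), lo_natural = qn[1],
               hi_natural = qn[2],
               mean_disturbed = mean(dd), lo_disturbed = qd[1],
               hi_disturbed = qd[2],
               overlap = qn[1] <= qd[2] && qd[1] <= qn[2],
               stringsAsFactors = FALSE)
  }))
  structure(list(natural = fit_n, disturbed = fit_d, comparison = cmp),
            class = "paired_mixing_fit")
}

#' Export posterior draws in long format
#'
#' @param post A `mixing_posterior`.
#' @return Data frame `chain, draw, site, source, proportion`.
#' @export
posterior_draws_long <- function(post) {
  S <- length(post$sites); K <- length(post$src_names)
  n <- dim(post$draws$p)[1]
  out <- expand.grid(draw = seq_len(n), site = post$sites,
                     source = post$src_names, stringsAsFactors = FALSE)
  out$chain <- post$draws$chain[out$draw]
  out$proportion <- as.vector(post$draws$p)
  out[c("chain", "draw", "site", "source", "proportion")]
}
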
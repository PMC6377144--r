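#' Read multi-choice feeding-trial records from CSV
#'
#' Expected columns:
#' `crab_id, sex, trial, prey, initial_wet_mass, final_dry_mass, is_control`.
#' Control rows carry the crab id of the treatment they pair with (the other
#' half of the same leaf) and `is_control = TRUE`.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of class `feeding_trials`.
#' @export
read_feeding_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feeding_trials(df)
}

#' Validate feeding-trial records
#'
#' @param df Data frame in the [read_feeding_trials] layout.
#' @return The validated data frame with class `feeding_trials`.
#' @export
feeding_trials <- function(df) {
  df <- as.data.frame(df)
  need <- c("crab_id", "sex", "trial", "prey", "initial_wet_mass",
            "final_dry_mass", "is_control")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$is_control <- as.logical(df$is_control)
  .fail_rows(!is.finite(df$initial_wet_mass) | df$initial_wet_mass <= 0,
             "initial_wet_mass must be finite and > 0")
  .fail_rows(!is.finite(df$final_dry_mass) | df$final_dry_mass < 0,
             "final_dry_mass must be finite and >= 0")
  .fail_rows(!df$sex %in% c("M", "F"), "sex must be 'M' or 'F'")
  # every crab needs a matching control half per prey item
  for (id in unique(df$crab_id)) {
    tr <- df[df$crab_id == id & !df$is_control, "prey"]
    ct <- df[df$crab_id == id & df$is_control, "prey"]
    if (!setequal(tr, ct))
      stop("crab '", id, "': treatment and control prey sets differ",
           call. = FALSE)
  }
  structure(df, class = c("feeding_trials", "data.frame"))
}

#' Fit the dry-on-wet mass regression
#'
#' Initial dry mass of offered leaf material is not observable (the leaf is
#' given to the consumer wet); it is estimated from an ordinary
#' least-squares regression of dry on wet mass, fitted per species since
#' water content is species-specific.
#'
#' @param pairs Data frame with columns `wet` and `dry` (grams), optionally
#'   `prey` when `per_prey = TRUE`.
#' @param per_prey Fit one regression per prey species (default `FALSE`).
#' @return A list `{slope, intercept, r2, n}` (class `wet_dry_regression`),
#'   or a named list of such fits when `per_prey = TRUE`.
#' @export
fit_wet_dry_regression <- function(pairs, per_prey = FALSE) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("wet", "dry") %in% names(pairs)))
  if (per_prey) {
    stopifnot("prey" %in% names(pairs))
    fits <- lapply(split(pairs, pairs$prey), fit_wet_dry_regression)
    return(fits)
  }
  if (nrow(pairs) < 3)
    stop("need >= 3 (wet, dry) pairs to fit a regression", call. = FALSE)
  if (stats::var(pairs$wet) == 0)
    stop("zero variance in wet mass; regression undefined", call. = FALSE)
  fit <- stats::lm(dry ~ wet, data = pairs)
  tss <- sum((pairs$dry - mean(pairs$dry))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n = nrow(pairs)),
            class = "wet_dry_regression")
}

#' Predict dry mass from wet mass
#' @param reg A `wet_dry_regression` fit.
#' @param wet Wet mass in grams.
#' @return Predicted dry mass in grams.
#' @export
predict_dry <- function(reg, wet) reg$intercept + reg$slope * wet

#' Estimate per-prey mass consumed in one trial
#'
#' Estimated initial dry mass is the regression prediction from initial wet
#' mass. The paired consumer-free control supplies a multiplicative
#' autogenic factor g = control final dry / control predicted initial dry
#' (leaf mass changes unrelated to feeding); consumed mass is then
#' `predicted_initial_dry * g - final_dry`. Negative values (autogenic gain
#' or measurement noise) are retained and flagged.
#'
#' @param trial A `feeding_trials` subset for one crab (treatment + control
#'   rows).
#' @param regs A single `wet_dry_regression` or a named per-prey list.
#' @return Data frame: `prey, initial_dry, autogenic_factor, consumed,
#'   negative_flag`, where `initial_dry` is the autogenic-adjusted offer.
#' @export
estimate_consumption <- function(trial, regs) {
  trial <- as.data.frame(trial)
  tr <- trial[!trial$is_control, ]
  ct <- trial[trial$is_control, ]
  get_reg <- function(prey) {
    if (inherits(regs, "wet_dry_regression")) regs
    else regs[[prey]] %||%
      stop("no regression for prey '", prey, "'", call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    prey <- tr$prey[i]
    reg <- get_reg(prey)
    est_init <- predict_dry(reg, tr$initial_wet_mass[i])
    crow <- ct[ct$prey == prey, ][1, ]
    ctrl_pred <- predict_dry(reg, crow$initial_wet_mass)
    if (!is.finite(ctrl_pred) || ctrl_pred <= 0)
      stop("control predicted dry mass <= 0 for prey '", prey, "'",
           call. = FALSE)
    g <- crow$final_dry_mass / ctrl_pred
    consumed <- est_init * g - tr$final_dry_mass[i]
    data.frame(prey = prey, initial_dry = est_init * g,
               autogenic_factor = g, consumed = consumed,
               negative_flag = consumed < 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Manly-Chesson selectivity index for depleting prey
#'
#' For a multi-choice assay without prey replacement the index for prey i is
#' \deqn{\alpha_i = \ln p_i / \sum_j \ln p_j}
#' where \eqn{p_i} is the proportion of prey i remaining at the end of the
#' trial (mass substituted for counts). Values above \eqn{1/m} indicate
#' preference, below \eqn{1/m} avoidance; \eqn{p_i > 1} (mass gain) yields a
#' negative index. Fully consumed prey (\eqn{p_i = 0}) have an undefined
#' index: the logarithm diverges, so such prey are flagged and excluded from
#' the sum (the fate of live animal prey eaten in its entirety), unless an
#' epsilon floor is requested for sensitivity analysis.
#'
#' @param initial_dry Per-prey initial (autogenic-adjusted) dry mass, g > 0;
#'   names taken as prey labels.
#' @param consumed Per-prey consumed dry mass, g (may be negative).
#' @param epsilon Optional floor substituted for p = 0 (default `NULL`:
#'   exclude fully consumed prey).
#' @return A list of class `selectivity_result`: data frame `table`
#'   (`prey, p, consumed, alpha, defined`) and `m_effective`, the count of
#'   prey with a defined index.
#' @examples
#' manly_alpha(rep(1, 5), consumed = 1 - c(0.9, 0.5, 0.9, 0.9, 0.9))
#' @export
manly_alpha <- function(initial_dry, consumed, epsilon = NULL) {
  if (length(initial_dry) != length(consumed))
    stop("initial_dry and consumed must have equal length", call. = FALSE)
  if (any(!is.finite(initial_dry) | initial_dry <= 0))
    stop("initial_dry must be finite and > 0", call. = FALSE)
  prey <- names(initial_dry) %||% paste0("prey", seq_along(initial_dry))
  p <- 1 - consumed / initial_dry
  if (any(p < 0))
    stop("remaining proportion < 0: consumption exceeds offer", call. = FALSE)
  if (!is.null(epsilon)) p[p == 0] <- epsilon
  defined <- p > 0
  if (!any(defined))
    stop("all prey fully consumed; selectivity index undefined", call. = FALSE)
  lp <- ifelse(defined, log(p), NA_real_)
  denom <- sum(lp[defined])
  if (denom == 0)
    stop("no net consumption in any prey; selectivity index undefined",
         call. = FALSE)
  alpha <- lp / denom
  structure(list(
    table = data.frame(prey = prey, p = p, consumed = consumed,
                       alpha = alpha, defined = defined,
                       stringsAsFactors = FALSE),
    m_effective = sum(defined)),
    class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat("Manly-Chesson selectivity (", x$m_effective, "prey with defined index)\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Per-crab selectivity for a whole feeding experiment
#'
#' Applies [estimate_consumption] and [manly_alpha] to every crab in a
#' trial table.
#'
#' @param trials A [feeding_trials] table.
#' @param regs Regression(s) as in [estimate_consumption].
#' @inheritParams manly_alpha
#' @return Data frame: one row per crab x prey with columns
#'   `crab_id, sex, trial, prey, p, consumed, alpha, defined`.
#' @export
compute_selectivity <- function(trials, regs, epsilon = NULL) {
  trials <- feeding_trials(trials)
  out <- do.call(rbind, lapply(unique(trials$crab_id), function(id) {
    sub <- trials[trials$crab_id == id, ]
    cons <- estimate_consumption(sub, regs)
    res <- manly_alpha(stats::setNames(cons$initial_dry, cons$prey),
                       cons$consumed, epsilon = epsilon)
    cbind(data.frame(crab_id = id, sex = sub$sex[!sub$is_control][1],
                     trial = sub$trial[!sub$is_control][1],
                     stringsAsFactors = FALSE),
          res$table)
  }))
  rownames(out) <- NULL
  out
}

.rank_matrix <- function(mat) t(apply(mat, 1, rank))

#' Friedman rank-sum test
#'
#' Nonparametric test for differences among k treatments (prey) across n
#' blocks (crabs), using within-block mid-ranks with the standard tie
#' correction.
#'
#' @param block_matrix Numeric matrix, blocks in rows, treatments in
#'   columns; no missing cells.
#' @return List `{statistic, df, p_value}` of class `friedman_result`.
#' @export
friedman_test <- function(block_matrix) {
  mat <- as.matrix(block_matrix)
  if (anyNA(mat)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 treatments",
                           call. = FALSE)
  r <- .rank_matrix(mat)
  Rj <- colSums(r)
  ties <- sum(apply(r, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - ties / (k - 1)
  # fully tied data: 0/0 -> no evidence of any difference
  stat <- if (num == 0) 0 else num / den
  structure(list(statistic = stat, df = k - 1,
                 p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE)),
            class = "friedman_result")
}

#' Nemenyi all-pairs post-hoc test after Friedman
#'
#' Pairwise comparisons of mean ranks using the studentized range
#' distribution with infinite degrees of freedom.
#'
#' @inheritParams friedman_test
#' @return Symmetric matrix of pairwise p-values, diagonal 1.
#' @export
nemenyi_posthoc <- function(block_matrix) {
  mat <- as.matrix(block_matrix)
  if (anyNA(mat)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 treatments",
                           call. = FALSE)
  r <- .rank_matrix(mat)
  rbar <- colMeans(r)
  se <- sqrt(k * (k + 1) / (12 * n))
  q <- abs(outer(rbar, rbar, "-")) / se
  p <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- 1
  lbl <- colnames(mat) %||% paste0("prey", seq_len(k))
  dimnames(p) <- list(lbl, lbl)
  p
}

#' Alpha matrix (crabs x prey) from per-crab selectivity output
#'
#' @param sel Output of [compute_selectivity].
#' @param defined_only Drop prey columns with any undefined index
#'   (default `TRUE`), mirroring the exclusion of fully consumed prey from
#'   the rank tests.
#' @return Numeric matrix, crabs in rows, prey in columns.
#' @export
alpha_matrix <- function(sel, defined_only = TRUE) {
  prey <- unique(sel$prey)
  crabs <- unique(sel$crab_id)
  mat <- matrix(NA_real_, length(crabs), length(prey),
                dimnames = list(crabs, prey))
  mat[cbind(match(sel$crab_id, crabs), match(sel$prey, prey))] <- sel$alpha
  if (defined_only) mat <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
  mat
}
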
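#' Convex hull of 2-D points (monotone chain)
#'
#' Andrew's monotone-chain construction; collinear boundary points and
#' duplicates are dropped so the result is the minimal vertex set.
#'
#' @param points Two-column numeric matrix or data frame (x, y).
#' @return Matrix of hull vertices in counter-clockwise order.
#' @export
convex_hull <- function(points) {
  pts <- unique(as.matrix(points))
  if (ncol(pts) != 2) stop("points must have two columns", call. = FALSE)
  if (nrow(pts) < 3) stop("need >= 3 distinct points", call. = FALSE)
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  n <- nrow(pts)
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3)
    stop("degenerate hull: points are collinear", call. = FALSE)
  out <- pts[hull, , drop = FALSE]
  colnames(out) <- c("x", "y")
  rownames(out) <- NULL
  out
}

#' Point-in-convex-polygon test
#'
#' A point is inside a counter-clockwise convex hull iff it is on the left
#' of (or on) every directed edge. Boundary points count as inside
#' (conservative inclusion).
#'
#' @param point Numeric length-2 vector (x, y), or a two-column matrix of
#'   points tested at once.
#' @param hull Counter-clockwise vertex matrix from [convex_hull].
#' @return Logical (vector), `TRUE` when inside or on the boundary.
#' @export
point_in_polygon <- function(point, hull) {
  hull <- as.matrix(hull)
  if (nrow(hull) < 3) stop("degenerate hull", call. = FALSE)
  pts <- if (is.null(dim(point))) matrix(point, 1) else as.matrix(point)
  nxt <- c(seq_len(nrow(hull))[-1], 1L)
  ex <- hull[nxt, 1] - hull[, 1]
  ey <- hull[nxt, 2] - hull[, 2]
  scale <- max(abs(hull)) + 1
  tol <- 1e-12 * scale^2
  vapply(seq_len(nrow(pts)), function(i) {
    cr <- ex * (pts[i, 2] - hull[, 2]) - ey * (pts[i, 1] - hull[, 1])
    all(cr >= -tol)
  }, logical(1))
}

#' Monte-Carlo mixing-polygon simulation
#'
#' An a priori feasibility check for isotope mixing models: on each
#' iteration every source's bivariate signature is redrawn from independent
#' per-tracer normals centred on the TEF-corrected mean,
#' `N(mu + TEF_mean, sqrt(sigma^2 + TEF_sd^2))`, the convex mixing polygon
#' is formed, and each consumer is tested for inclusion. A consumer whose
#' inclusion probability falls below `inclusion_alpha` lies outside the
#' `(1 - alpha) * 100%` mixing region: the proposed source set cannot
#' explain its signature.
#'
#' @param sources A [source_groups] table for one site/population (>= 3
#'   groups).
#' @param consumers An [isotope_samples] table of consumers to test.
#' @param tef A [trophic_enrichment] object.
#' @param n_iterations Number of Monte-Carlo iterations (>= 100).
#' @param seed Integer RNG seed.
#' @param inclusion_alpha Flagging threshold (default 0.05).
#' @param keep_hulls Retain per-iteration hulls (needed by
#'   [region_contours]).
#' @return List of class `polygon_simulation`: `consumers` data frame
#'   (`sample_id, inclusion_probability, outside_flag`), `n_iterations`,
#'   `n_degenerate`, `inclusion_alpha` and (optionally) `hulls`.
#' @export
simulate_mixing_region <- function(sources, consumers, tef,
                                   n_iterations = 1500, seed = 1,
                                   inclusion_alpha = 0.05,
                                   keep_hulls = FALSE) {
  sources <- source_groups(sources)
  consumers <- isotope_samples(consumers)
  if (nrow(sources) < 3)
    stop("need >= 3 source groups for a mixing polygon", call. = FALSE)
  if (n_iterations < 100) stop("n_iterations must be >= 100", call. = FALSE)
  set.seed(seed)
  k <- nrow(sources)
  sd_c <- sqrt(sources$sigma_d13C^2 + tef$d13C_sd^2)
  sd_n <- sqrt(sources$sigma_d15N^2 + tef$d15N_sd^2)
  mu_c <- sources$mu_d13C + tef$d13C_mean
  mu_n <- sources$mu_d15N + tef$d15N_mean
  pts <- cbind(consumers$d13C, consumers$d15N)
  inside <- integer(nrow(consumers))
  n_degenerate <- 0L
  hulls <- if (keep_hulls) vector("list", n_iterations) else NULL
  for (it in seq_len(n_iterations)) {
    draw <- cbind(stats::rnorm(k, mu_c, sd_c), stats::rnorm(k, mu_n, sd_n))
    hull <- tryCatch(convex_hull(draw), error = function(e) NULL)
    if (is.null(hull)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (keep_hulls) hulls[[it]] <- hull
    inside <- inside + point_in_polygon(pts, hull)
  }
  if (n_degenerate > n_iterations / 2)
    stop("degenerate hull in > 50% of iterations; sources too collinear",
         call. = FALSE)
  prob <- inside / n_iterations
  structure(list(
    consumers = data.frame(sample_id = consumers$sample_id,
                           inclusion_probability = prob,
                           outside_flag = prob < inclusion_alpha,
                           stringsAsFactors = FALSE),
    n_iterations = n_iterations, n_degenerate = n_degenerate,
    inclusion_alpha = inclusion_alpha,
    hulls = if (keep_hulls) hulls[!vapply(hulls, is.null, logical(1))]),
    class = "polygon_simulation")
}

#' Inclusion-probability surface of the mixing region
#'
#' Evaluates, on a regular grid over the bounding box of all retained
#' hulls, the fraction of Monte-Carlo hulls containing each grid point;
#' the 0.95 level set of this surface is the 95% mixing region.
#'
#' @param result A `polygon_simulation` run with `keep_hulls = TRUE`.
#' @param grid_resolution Number of grid points per axis (default 50).
#' @return Data frame `x, y, probability`.
#' @export
region_contours <- function(result, grid_resolution = 50) {
  if (is.null(result$hulls))
    stop("simulation was run without keep_hulls = TRUE", call. = FALSE)
  allv <- do.call(rbind, result$hulls)
  xs <- seq(min(allv[, 1]), max(allv[, 1]), length.out = grid_resolution)
  ys <- seq(min(allv[, 2]), max(allv[, 2]), length.out = grid_resolution)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  count <- numeric(nrow(grid))
  for (hull in result$hulls)
    count <- count + point_in_polygon(grid, hull)
  data.frame(x = grid[, 1], y = grid[, 2],
             probability = count / result$n_iterations)
}

#' Polygon area by the shoelace formula
#' @param hull Counter-clockwise vertex matrix.
#' @return Area (tracer-space units squared).
#' @export
hull_area <- function(hull) {
  hull <- as.matrix(hull)
  nxt <- c(seq_len(nrow(hull))[-1], 1L)
  abs(sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2])) / 2
}
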
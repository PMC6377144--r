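# Shared fixture builders. Everything is generated in code; no data files.

make_consumers <- function(d13C, d15N, site = "X", status = "natural",
                           category = "Armases", pctC = 40, pctN = 10) {
  n <- max(length(d13C), length(d15N))
  isotope_samples(data.frame(
    sample_id = if (n) paste0("c", seq_len(n)) else character(0),
    site = rep_len(site, n), habitat_status = rep_len(status, n),
    category = rep_len(category, n),
    d13C = rep_len(d13C, n), d15N = rep_len(d15N, n),
    pctC = rep_len(pctC, n), pctN = rep_len(pctN, n),
    stringsAsFactors = FALSE))
}

make_sources <- function(names, mu_c, mu_n, sd_c = 0.5, sd_n = 0.5,
                         conc_C = 45, conc_N = 5, site = "X", n = 3) {
  source_groups(data.frame(
    name = names, site = site, mu_d13C = mu_c, sigma_d13C = sd_c,
    mu_d15N = mu_n, sigma_d15N = sd_n, conc_C = conc_C, conc_N = conc_N,
    n = n, stringsAsFactors = FALSE))
}

# mixture mean/variance by direct arithmetic (oracle for mixture_moments)
oracle_mixture <- function(p, mu, v, conc) {
  w <- p * conc / sum(p * conc)
  list(mean = sum(w * mu), variance = sum(w^2 * v))
}

# brute-force convex hull: a directed edge (i, j) is on the hull iff every
# other point lies strictly to its left; vertices are edge endpoints
brute_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[-c(i, j), 2] - pts[i, 2]) -
      (pts[j, 2] - pts[i, 2]) * (pts[-c(i, j), 1] - pts[i, 1])
    if (all(cr > 0)) on_hull[c(i, j)] <- TRUE
  }
  pts[on_hull, , drop = FALSE]
}

# point-in-convex-polygon by triangle-area decomposition: P is inside iff
# the fan of triangles (P, v_i, v_{i+1}) tiles the polygon area exactly
brute_point_in_hull <- function(point, hull) {
  tri_area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) / 2
  n <- nrow(hull)
  total <- hull_area(hull)
  fan <- sum(vapply(seq_len(n), function(i)
    tri_area(point, hull[i, ], hull[if (i == n) 1 else i + 1, ]),
    numeric(1)))
  isTRUE(all.equal(fan, total, tolerance = 1e-9))
}

# trophic-position records on a balanced design for ANOVA tests
make_tp_records <- function(y, treat, site) {
  structure(data.frame(sample_id = seq_along(y), site = site,
                       habitat_status = treat, tp = y,
                       baseline_d15N = 0, lambda = 2,
                       stringsAsFactors = FALSE),
            class = c("trophic_records", "data.frame"))
}

tiny_simm_problem <- function(consumer = c(-16, 9.5)) {
  src <- make_sources(c("A", "B"), mu_c = c(-26, -14), mu_n = c(3, 6),
                      conc_C = c(45, 40), conc_N = c(2, 8))
  cons <- make_consumers(consumer[1], consumer[2])
  mixing_model_spec(src, cons, trophic_enrichment())
}
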
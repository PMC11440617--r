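# Independent oracles used to cross-check the geometry and statistics paths.

# Monte-Carlo annulus-window area: uniform samples in the annulus, fraction
# landing inside the window times the annulus area.
mc_annulus_area <- function(center, r_inner, r_outer, window,
                            n = 1e6, seed = 4242) {
  set.seed(seed)
  r <- sqrt(stats::runif(n, r_inner^2, r_outer^2))
  th <- stats::runif(n, 0, 2 * pi)
  x <- center[1] + r * cos(th)
  y <- center[2] + r * sin(th)
  frac <- mean(x >= 0 & x <= window$width_um & y >= 0 & y <= window$height_um)
  frac * pi * (r_outer^2 - r_inner^2)
}

# dense rim sampling: disk inside polygon iff center and 720 rim points are
rim_disk_inside <- function(x, y, diameter, vertices, n_rim = 720) {
  ang <- 2 * pi * (seq_len(n_rim) - 1) / n_rim
  r <- diameter / 2
  all(points_in_polygon(x + r * cos(ang), y + r * sin(ang), vertices)) &&
    points_in_polygon(x, y, vertices)
}

# nearest-site grid assignment: Voronoi areas by counting grid pixels
grid_voronoi_areas <- function(field, m = 707) {
  w <- field$window$width_um
  h <- field$window$height_um
  gx <- (seq_len(m) - 0.5) * w / m
  gy <- (seq_len(m) - 0.5) * h / m
  grid_x <- rep(gx, times = m)
  grid_y <- rep(gy, each = m)
  pts <- as.matrix(field$points[, c("x_um", "y_um")])
  best <- rep(1L, m * m)
  bestd <- (grid_x - pts[1, 1])^2 + (grid_y - pts[1, 2])^2
  for (i in seq_len(nrow(pts))[-1]) {
    d <- (grid_x - pts[i, 1])^2 + (grid_y - pts[i, 2])^2
    upd <- d < bestd
    best[upd] <- i
    bestd[upd] <- d[upd]
  }
  tabulate(best, nrow(pts)) * (w / m) * (h / m)
}

# brute-force O(n^2) DRP pair counts (ordered pairs, half-open bins)
brute_drp_counts <- function(field, bin_width, n_bins) {
  pts <- field$points
  n <- nrow(pts)
  counts <- integer(n_bins)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pts$x_um[i] - pts$x_um[j])^2 +
                  (pts$y_um[i] - pts$y_um[j])^2)
      k <- floor(d / bin_width) + 1
      if (k <= n_bins) counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# MC-edge-corrected per-bin areas for the brute-force DRP oracle
mc_drp_areas <- function(field, bin_width, n_bins, n_mc = 2e4, seed = 777) {
  pts <- field$points
  areas <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    for (i in seq_len(nrow(pts))) {
      areas[k] <- areas[k] + mc_annulus_area(
        c(pts$x_um[i], pts$y_um[i]), (k - 1) * bin_width, k * bin_width,
        field$window, n = n_mc, seed = seed + 1000 * k + i)
    }
  }
  areas
}

# synthetic drp_result for testing the effective-radius construction alone
make_drp <- function(lambda, edges, d_global) {
  structure(list(bin_width_um = diff(edges)[1], bin_edges_um = edges,
                 bin_mid_um = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = NA, corrected_area_um2 = NA,
                 density_mm2 = lambda, global_density_mm2 = d_global,
                 n = NA), class = "drp_result")
}

# square lattice field centred in the window, optionally jittered
lattice_field <- function(n_side, spacing, window, jitter_sd = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offs_x <- (window$width_um - (n_side - 1) * spacing) / 2
  offs_y <- (window$height_um - (n_side - 1) * spacing) / 2
  g <- expand.grid(ix = seq_len(n_side) - 1, iy = seq_len(n_side) - 1)
  x <- offs_x + g$ix * spacing
  y <- offs_y + g$iy * spacing
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, jitter_sd)
    y <- y + stats::rnorm(length(y), 0, jitter_sd)
    x <- pmin(pmax(x, 0), window$width_um)
    y <- pmin(pmax(y, 0), window$height_um)
  }
  soma_field(x, y, window, diameter_um = 1)
}

# independent-arbor enclosure dataset on random hard-core fields (the
# no-coordination null used by the calibration tests)
independence_null_records <- function(seed, radius_mean = 16, radius_sd = 3,
                                      density = 1400, n_fields = 6,
                                      per_field = 20) {
  fields <- lapply(seq_len(n_fields), function(i) {
    simulate_hardcore(sim_config(target_density = density,
                                 seed = derive_seed(seed, i)))
  })
  names(fields) <- paste0("f", seq_len(n_fields))
  arbors <- list()
  for (fi in seq_len(n_fields)) {
    ids <- fields[[fi]]$points$id[seq_len(per_field)]
    aa <- generate_arbors(fields[[fi]],
                          arbor_params = list(arbor_mode = "independent",
                                              radius_mean_um = radius_mean,
                                              radius_sd_um = radius_sd),
                          seed = derive_seed(seed, 100 + fi),
                          reference_ids = ids)
    aa <- lapply(aa, function(a) {
      a$source_field_id <- paste0("f", fi)
      a
    })
    arbors <- c(arbors, aa)
  }
  suppressWarnings(build_unmatched(arbors, fields))
}
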
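#' Configuration for synthetic mosaic generation
#'
#' Bundles every parameter of the seeded generators. Defaults reproduce the
#' study conditions: a 353.55 um square field, 10.0 um somata (the hard-core
#' distance), wild-type densities of 1,495 (OFF) and 1,290 (ON) cells/mm^2
#' available as presets, and coordinated arbors reaching alpha = 0.9 of the
#' nearest-neighbor distance.
#'
#' @param mode One of `"hardcore_random"`, `"exclusion_mosaic"`,
#'   `"clustered"`, `"clone_field"`.
#' @param window A [field_window()]; default 353.55 um square.
#' @param target_density Target global density, cells/mm^2.
#' @param soma_diameter_um Soma diameter (hard-core distance), um.
#' @param arbor_params List: `arbor_mode` (`"coordinated"`, `"independent"`,
#'   `"overgrown"`), `alpha` (coordinated arbor radius as a fraction of the
#'   nearest-neighbor distance, default 0.9), `alpha_overgrown` (overgrown
#'   radius as a fraction of the k-th-neighbor distance, default 1.1),
#'   `radius_mean_um`, `radius_sd_um` (territory radius
#'   distribution at placement / in independent mode), `n_vertices`,
#'   `vertex_jitter_frac`, `k_neighbor` (neighbor ring for overgrown arbors).
#' @param cluster_params List: `parent_intensity_mm2` (Thomas-process parent
#'   intensity, per mm^2), `offspring_mean` (Poisson mean per parent),
#'   `offspring_sd_um` (isotropic Gaussian displacement SD).
#' @param clone_params List: `column_radius_um`, `column_density_mm2`,
#'   `n_cells`, `dispersed_fraction`, `displacement_mean_um`,
#'   `displacement_sd_um`.
#' @param seed Integer seed; every generator is bit-reproducible given it.
#' @param max_attempts Candidate draws allowed per accepted point before a
#'   saturation error.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(mode = "hardcore_random", target_density = 1400, seed = 1)
#' @export
sim_config <- function(mode = c("hardcore_random", "exclusion_mosaic",
                                "clustered", "clone_field"),
                       window = field_window(353.55),
                       target_density = 1400,
                       soma_diameter_um = 10,
                       arbor_params = list(),
                       cluster_params = list(),
                       clone_params = list(),
                       seed = NULL,
                       max_attempts = 10000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "field_window"))
  if (!is.numeric(target_density) || target_density <= 0) {
    stop("target_density must be positive", call. = FALSE)
  }
  if (!is.numeric(soma_diameter_um) || soma_diameter_um <= 0) {
    stop("soma_diameter_um must be positive", call. = FALSE)
  }
  # packing feasibility: disk coverage at target density must stay below 0.5
  coverage <- target_density / 1e6 * pi * (soma_diameter_um / 2)^2
  if (coverage >= 0.5) {
    stop(sprintf("infeasible packing: disk coverage %.2f >= 0.5", coverage),
         call. = FALSE)
  }
  ap <- utils::modifyList(list(
    arbor_mode = "coordinated", alpha = 0.9, alpha_overgrown = 1.1,
    radius_mean_um = 14, radius_sd_um = 2,
    n_vertices = 12L, vertex_jitter_frac = 0.08,
    k_neighbor = 2L
  ), arbor_params)
  if (!ap$arbor_mode %in% c("coordinated", "independent", "overgrown")) {
    stop("unknown arbor_mode", call. = FALSE)
  }
  cp <- utils::modifyList(list(
    parent_intensity_mm2 = 150, offspring_mean = 10, offspring_sd_um = 8
  ), cluster_params)
  kp <- utils::modifyList(list(
    column_radius_um = 15, column_density_mm2 = 250, n_cells = 60L,
    dispersed_fraction = 0.3, displacement_mean_um = 15,
    displacement_sd_um = 8
  ), clone_params)
  if (kp$dispersed_fraction < 0 || kp$dispersed_fraction > 1) {
    stop("dispersed_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, window = window,
                 target_density = target_density,
                 soma_diameter_um = soma_diameter_um,
                 arbor_params = ap, cluster_params = cp, clone_params = kp,
                 seed = seed, max_attempts = as.integer(max_attempts),
                 rng = "Mersenne-Twister"),
            class = "sim_config")
}

#' Density presets printed for the wild-type starburst populations
#'
#' @return Named numeric vector of cells/mm^2: OFF wild-type 1,495 and ON
#'   wild-type 1,290.
#' @export
density_presets <- function() {
  c(off_wt = 1495, on_wt = 1290)
}

set_sim_seed <- function(config) {
  if (is.null(config$seed)) {
    stop("sim_config requires an explicit seed for generation", call. = FALSE)
  }
  set.seed(as.integer(config$seed), kind = "Mersenne-Twister")
}

#' Derive a per-stage child seed from a master seed
#'
#' Deterministic arithmetic derivation so pipeline stages can be re-run
#' independently; result is always a valid positive 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param offset Stage index (>= 0).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 48271 + 7919 * (as.numeric(offset) + 1)) %% 2147483647 + 1)
}

#' Simulate a random hard-core soma array
#'
#' The matched random-reference simulation: somata are placed one by one at
#' uniformly random window positions; a candidate whose center lies closer
#' than one soma diameter to an existing cell is rejected and redrawn, until
#' exactly `round(target_density x window area)` cells are placed. In the
#' `soma_diameter_um -> 0` limit this is complete spatial randomness.
#'
#' @param config A [sim_config()] with a seed.
#' @return A [soma_field()] whose minimum pairwise center distance is at
#'   least the soma diameter.
#' @examples
#' f <- simulate_hardcore(sim_config(target_density = 1400, seed = 1))
#' nrow(f$points)
#' @export
simulate_hardcore <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_sim_seed(config)
  f <- hardcore_points(config)
  soma_field(f$x, f$y, config$window,
             diameter_um = config$soma_diameter_um)
}

hardcore_points <- function(config, n_target = NULL) {
  w <- config$window$width_um
  h <- config$window$height_um
  if (is.null(n_target)) {
    n_target <- round(config$target_density * window_area_mm2(config$window))
  }
  d <- config$soma_diameter_um
  d2 <- d * d
  x <- numeric(n_target)
  y <- numeric(n_target)
  k <- 0L
  while (k < n_target) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > config$max_attempts) {
        stop(sprintf("hard-core placement saturated after %d cells (target %d)",
                     k, n_target), call. = FALSE)
      }
      cx <- stats::runif(1, 0, w)
      cy <- stats::runif(1, 0, h)
      if (k == 0L ||
          min((x[1:k] - cx)^2 + (y[1:k] - cy)^2) >= d2) break
    }
    k <- k + 1L
    x[k] <- cx
    y[k] <- cy
  }
  list(x = x, y = y)
}

#' Build a jittered polygonal arbor territory
#'
#' Regular `n_vertices`-gon of nominal radius `radius` about `(cx, cy)` with
#' uniform per-vertex radial jitter and a random phase, drawn from the
#' current RNG stream. The synthetic stand-in for a hand-drawn territory ROI.
#'
#' @param cx,cy Center (um).
#' @param radius Nominal vertex radius (um).
#' @param n_vertices Number of vertices.
#' @param jitter_frac Vertex radii are scaled by
#'   `Uniform(1 - jitter_frac, 1 + jitter_frac)`.
#' @return An n x 2 vertex matrix.
#' @export
make_arbor_polygon <- function(cx, cy, radius, n_vertices, jitter_frac) {
  phase <- stats::runif(1, 0, 2 * pi)
  ang <- phase + 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  rad <- radius * stats::runif(n_vertices, 1 - jitter_frac, 1 + jitter_frac)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# smallest nominal radius whose jittered n-gon is certain to contain the
# reference disk of radius r_soma
min_containing_radius <- function(r_soma, n_vertices, jitter_frac) {
  r_soma / (cos(pi / n_vertices) * (1 - jitter_frac)) * 1.001
}

#' Simulate a mosaic formed by dendrite-soma exclusion
#'
#' Generative model of the exclusion-zone mechanism: cells are inserted
#' sequentially at uniform candidate positions and rejected if they violate
#' the hard core *or* fall inside any existing cell's arbor territory. Each
#' accepted cell receives an arbor polygon (jittered regular n-gon with
#' radius drawn from a truncated normal). In `coordinated` arbor mode the
#' final arbor radii are rescaled to `alpha x` the distance to the nearest
#' neighboring soma, emulating dendrites that reach just short of the first
#' homotypic neighbor.
#'
#' @param config A [sim_config()] with `mode = "exclusion_mosaic"`.
#' @return A list with elements `field` (a [soma_field()]) and `arbors`
#'   (a list of [arbor_territory()], one per cell). No soma center lies
#'   inside another cell's arbor polygon.
#' @export
simulate_exclusion_mosaic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "exclusion_mosaic") {
    stop("config mode must be 'exclusion_mosaic'", call. = FALSE)
  }
  set_sim_seed(config)
  ap <- config$arbor_params
  w <- config$window$width_um
  h <- config$window$height_um
  n_target <- round(config$target_density * window_area_mm2(config$window))
  d2 <- config$soma_diameter_um^2
  x <- numeric(n_target)
  y <- numeric(n_target)
  radii <- numeric(n_target)
  polys <- vector("list", n_target)
  rmax <- 0
  k <- 0L
  while (k < n_target) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > config$max_attempts) {
        stop(sprintf(
          "exclusion placement saturated after %d cells (target %d)",
          k, n_target), call. = FALSE)
      }
      cx <- stats::runif(1, 0, w)
      cy <- stats::runif(1, 0, h)
      if (k > 0L) {
        dd <- (x[1:k] - cx)^2 + (y[1:k] - cy)^2
        if (min(dd) < d2) next
        # candidate must lie outside every existing arbor
        near <- which(dd <= (rmax * (1 + ap$vertex_jitter_frac))^2)
        blocked <- FALSE
        for (j in near) {
          if (points_in_polygon(cx, cy, polys[[j]])) { blocked <- TRUE; break }
        }
        if (blocked) next
      }
      break
    }
    k <- k + 1L
    x[k] <- cx
    y[k] <- cy
    r <- draw_truncnorm_pos(ap$radius_mean_um, ap$radius_sd_um)
    radii[k] <- r
    polys[[k]] <- make_arbor_polygon(cx, cy, r, ap$n_vertices,
                                     ap$vertex_jitter_frac)
    rmax <- max(rmax, r)
  }
  field <- soma_field(x, y, config$window,
                      diameter_um = config$soma_diameter_um)
  arbors <- if (ap$arbor_mode == "coordinated") {
    generate_arbors(field, arbor_params = ap, seed = NULL)
  } else {
    lapply(seq_len(n_target), function(i) {
      arbor_territory(field$points$id[i], polys[[i]])
    })
  }
  list(field = field, arbors = arbors)
}

draw_truncnorm_pos <- function(mean, sd, floor = .Machine$double.eps) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v > floor) return(v)
  }
}

#' Simulate an aggregated (clustered) soma array
#'
#' Thomas-process generator for the aggregation phenotype: Poisson parents,
#' Poisson-distributed offspring displaced by an isotropic Gaussian, with the
#' hard core retained (clumped somata touch, they do not merge). Offspring
#' violating the hard core or falling outside the window are redrawn a
#' bounded number of times and then dropped.
#'
#' @param config A [sim_config()] with `mode = "clustered"`.
#' @return A [soma_field()]; warns if the realized count falls below 80% of
#'   the expected `parent_intensity x area x offspring_mean`.
#' @export
simulate_clustered <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "clustered") {
    stop("config mode must be 'clustered'", call. = FALSE)
  }
  set_sim_seed(config)
  cp <- config$cluster_params
  w <- config$window$width_um
  h <- config$window$height_um
  area_mm2 <- window_area_mm2(config$window)
  d2 <- config$soma_diameter_um^2
  n_parents <- stats::rpois(1, cp$parent_intensity_mm2 * area_mm2)
  px <- stats::runif(n_parents, 0, w)
  py <- stats::runif(n_parents, 0, h)
  x <- numeric(0)
  y <- numeric(0)
  expected <- cp$parent_intensity_mm2 * area_mm2 * cp$offspring_mean
  for (i in seq_len(n_parents)) {
    n_off <- stats::rpois(1, cp$offspring_mean)
    for (j in seq_len(n_off)) {
      placed <- FALSE
      hc_tries <- 0L
      total <- 0L
      # out-of-window draws are redrawn freely; hard-core violations get
      # bounded retries, then the offspring is dropped
      while (hc_tries < 30L && total < 1000L) {
        total <- total + 1L
        cx <- px[i] + stats::rnorm(1, 0, cp$offspring_sd_um)
        cy <- py[i] + stats::rnorm(1, 0, cp$offspring_sd_um)
        if (cx < 0 || cx > w || cy < 0 || cy > h) next
        if (length(x) == 0 || min((x - cx)^2 + (y - cy)^2) >= d2) {
          placed <- TRUE
          break
        }
        hc_tries <- hc_tries + 1L
      }
      if (placed) {
        x <- c(x, cx)
        y <- c(y, cy)
      }
    }
  }
  if (length(x) < 0.8 * expected) {
    warning(sprintf("realized count %d below 80%% of expected %.0f",
                    length(x), expected), call. = FALSE)
  }
  soma_field(x, y, config$window, diameter_um = config$soma_diameter_um)
}

#' Generate arbor territories for reference somata
#'
#' One simple polygon per requested reference cell, always containing its
#' reference soma disk. Three regimes emulate the developmental arbor
#' phenotypes: `coordinated` (radius = alpha x nearest-neighbor distance,
#' dendrites stop just short of the first homotypic neighbor), `independent`
#' (radius drawn from a normal, blind to neighbor positions), and
#' `overgrown` (radius = alpha x distance to the k-th nearest neighbor,
#' k >= 2, arbors extending past the first neighbor ring).
#'
#' @param field A nonempty [soma_field()].
#' @param arbor_params As in [sim_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param reference_ids Ids of cells to receive arbors; default all.
#' @return A list of [arbor_territory()].
#' @export
generate_arbors <- function(field, arbor_params = list(), seed = NULL,
                            reference_ids = NULL) {
  stopifnot(inherits(field, "soma_field"))
  if (nrow(field$points) == 0) stop("field is empty", call. = FALSE)
  ap <- utils::modifyList(sim_config(seed = 0)$arbor_params, arbor_params)
  if (!is.null(seed)) set.seed(as.integer(seed), kind = "Mersenne-Twister")
  pts <- field$points
  if (is.null(reference_ids)) reference_ids <- pts$id
  idx <- match(reference_ids, pts$id)
  if (anyNA(idx)) stop("unknown reference ids", call. = FALSE)
  dmat <- NULL
  if (ap$arbor_mode %in% c("coordinated", "overgrown")) {
    if (nrow(pts) < 2) stop("neighbor-based arbor modes need >= 2 cells",
                            call. = FALSE)
    dmat <- as.matrix(stats::dist(cbind(pts$x_um, pts$y_um)))
    diag(dmat) <- Inf
  }
  lapply(idx, function(i) {
    r <- switch(ap$arbor_mode,
      coordinated = ap$alpha * min(dmat[i, ]),
      independent = draw_truncnorm_pos(ap$radius_mean_um, ap$radius_sd_um),
      overgrown = {
        k <- max(2L, as.integer(ap$k_neighbor))
        ap$alpha_overgrown * sort(dmat[i, ])[k]
      })
    floor_r <- min_containing_radius(pts$diameter_um[i] / 2 * 1.2,
                                     ap$n_vertices, ap$vertex_jitter_frac)
    r <- max(r, floor_r)
    repeat {
      v <- make_arbor_polygon(pts$x_um[i], pts$y_um[i], r,
                              ap$n_vertices, ap$vertex_jitter_frac)
      if (disk_fully_inside(pts$x_um[i], pts$y_um[i], pts$diameter_um[i], v)) {
        return(arbor_territory(pts$id[i], v))
      }
      r <- r * 1.2
    }
  })
}

#' Generate a dendritic-tip field with a known contact rate
#'
#' Fixture generator for the contact analysis: a fraction
#' `true_contact_fraction` of tips is placed on soma rims (uniform soma,
#' uniform rim angle), the remainder uniformly in the window outside all soma
#' disks.
#'
#' @param field A [soma_field()].
#' @param true_contact_fraction Proportion in `[0, 1]`.
#' @param n_tips Number of tips (> 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `tip_id`, `x_um`, `y_um`,
#'   `on_soma` (ground truth).
#' @export
generate_tip_field <- function(field, true_contact_fraction, n_tips, seed) {
  stopifnot(inherits(field, "soma_field"))
  if (n_tips <= 0) stop("n_tips must be positive", call. = FALSE)
  if (true_contact_fraction < 0 || true_contact_fraction > 1) {
    stop("true_contact_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  pts <- field$points
  w <- field$window$width_um
  h <- field$window$height_um
  n_on <- round(true_contact_fraction * n_tips)
  x <- numeric(n_tips)
  y <- numeric(n_tips)
  for (t in seq_len(n_on)) {
    repeat {
      i <- sample.int(nrow(pts), 1)
      ang <- stats::runif(1, 0, 2 * pi)
      r <- pts$diameter_um[i] / 2
      cx <- pts$x_um[i] + r * cos(ang)
      cy <- pts$y_um[i] + r * sin(ang)
      if (cx >= 0 && cx <= w && cy >= 0 && cy <= h) break
    }
    x[t] <- cx
    y[t] <- cy
  }
  for (t in seq_len(n_tips - n_on)) {
    repeat {
      cx <- stats::runif(1, 0, w)
      cy <- stats::runif(1, 0, h)
      dd <- sqrt((pts$x_um - cx)^2 + (pts$y_um - cy)^2)
      if (all(dd > pts$diameter_um / 2)) break
    }
    x[n_on + t] <- cx
    y[n_on + t] <- cy
  }
  data.frame(tip_id = paste0("t", seq_len(n_tips)), x_um = x, y_um = y,
             on_soma = c(rep(TRUE, n_on), rep(FALSE, n_tips - n_on)),
             stringsAsFactors = FALSE)
}

#' Polygonize a disk
#'
#' Regular inscribed `n`-gon approximating the disk of radius `r` about
#' `(cx, cy)`; used for clone columns and circular test territories.
#'
#' @param cx,cy Center (um).
#' @param r Radius (um).
#' @param n Number of vertices.
#' @return An n x 2 vertex matrix.
#' @export
polygonize_disk <- function(cx, cy, r, n = 24L) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

#' Generate a clone-column field with known tangential dispersion
#'
#' Emulates clonally labelled radial columns and tangentially dispersed
#' starbursts: circular columns (polygonized disks) from a Poisson process; a
#' fraction `1 - p` of cells placed uniformly inside random columns, the
#' remaining fraction `p` displaced outward from a column boundary by
#' `|N(displacement_mean, displacement_sd)|` along a uniform direction
#' (redrawn if landing inside any column). Ground truth is stored per cell.
#'
#' @param config A [sim_config()] with `mode = "clone_field"`.
#' @return A list: `columns` (list of vertex matrices), `cells` (a
#'   [soma_field()]), and `truth` (data.frame with `dispersed` flag and
#'   generating `displacement_um`, `NA` for column cells).
#' @export
generate_clone_field <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "clone_field") {
    stop("config mode must be 'clone_field'", call. = FALSE)
  }
  set_sim_seed(config)
  kp <- config$clone_params
  w <- config$window$width_um
  h <- config$window$height_um
  area_mm2 <- window_area_mm2(config$window)
  n_col <- max(1L, stats::rpois(1, kp$column_density_mm2 * area_mm2))
  # keep full columns inside the window so boundary distances are exact
  ccx <- stats::runif(n_col, kp$column_radius_um, w - kp$column_radius_um)
  ccy <- stats::runif(n_col, kp$column_radius_um, h - kp$column_radius_um)
  coverage <- n_col * pi * kp$column_radius_um^2 / window_area_um2(config$window)
  if (coverage > 0.8) {
    stop("columns cover > 80% of the window; dispersed fraction unidentifiable",
         call. = FALSE)
  }
  columns <- lapply(seq_len(n_col), function(i) {
    polygonize_disk(ccx[i], ccy[i], kp$column_radius_um)
  })
  n_cells <- as.integer(kp$n_cells)
  n_disp <- round(kp$dispersed_fraction * n_cells)
  x <- numeric(n_cells)
  y <- numeric(n_cells)
  disp <- c(rep(FALSE, n_cells - n_disp), rep(TRUE, n_disp))
  dist_true <- rep(NA_real_, n_cells)
  in_any_column <- function(cx, cy) {
    any((ccx - cx)^2 + (ccy - cy)^2 < kp$column_radius_um^2)
  }
  for (t in seq_len(n_cells)) {
    if (!disp[t]) {
      repeat {
        i <- sample.int(n_col, 1)
        rr <- kp$column_radius_um * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- ccx[i] + rr * cos(ang)
        cy <- ccy[i] + rr * sin(ang)
        # membership is scored against the polygonized column, so the cell
        # must land inside the inscribed polygon, not just the disk
        if (cx >= 0 && cx <= w && cy >= 0 && cy <= h &&
            points_in_polygon(cx, cy, columns[[i]])) break
      }
    } else {
      repeat {
        i <- sample.int(n_col, 1)
        dd <- abs(stats::rnorm(1, kp$displacement_mean_um,
                               kp$displacement_sd_um))
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- ccx[i] + (kp$column_radius_um + dd) * cos(ang)
        cy <- ccy[i] + (kp$column_radius_um + dd) * sin(ang)
        if (cx >= 0 && cx <= w && cy >= 0 && cy <= h &&
            !in_any_column(cx, cy)) break
      }
      dist_true[t] <- dd
    }
    x[t] <- cx
    y[t] <- cy
  }
  cells <- soma_field(x, y, config$window,
                      diameter_um = config$soma_diameter_um,
                      labels = ifelse(disp, "dispersed", "column"))
  list(columns = columns, cells = cells,
       truth = data.frame(id = cells$points$id, dispersed = disp,
                          displacement_um = dist_true,
                          stringsAsFactors = FALSE))
}
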
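#' Density recovery profile with window edge correction
#'
#' Annulus-binned density of homotypic neighbors as a function of distance
#' from each reference cell. Every cell serves as a reference; ordered pairs
#' with center distance in the half-open bin `[r_{k-1}, r_k)` are counted,
#' and each bin's count is divided by the summed exact annulus-window
#' intersection areas over all references (the edge correction). For a random
#' arrangement the profile is flat at the global density D beyond the hard
#' core; an exclusion zone appears as a density deficit at short distances.
#'
#' @param field A [soma_field()] with >= 2 somata.
#' @param bin_width_um Annulus increment in um; 5 for 40x fields, 3 for the
#'   20x variant.
#' @param max_radius_um Largest bin edge; must not exceed half the shorter
#'   window side. Default 150 um (30 bins at 5 um).
#' @return An object of class `drp_result`: list with `bin_edges_um`,
#'   `bin_mid_um`, `counts` (ordered pairs per bin), `corrected_area_um2`,
#'   `density_mm2` (lambda_k, cells/mm^2), `global_density_mm2` (D),
#'   `bin_width_um`, `n`, and `effective_radius_um` (see
#'   [effective_radius()]).
#' @examples
#' f <- simulate_hardcore(sim_config(target_density = 1400, seed = 1))
#' drp <- compute_drp(f)
#' drp$effective_radius_um
#' @export
compute_drp <- function(field, bin_width_um = 5, max_radius_um = 150) {
  stopifnot(inherits(field, "soma_field"))
  pts <- field$points
  n <- nrow(pts)
  if (n < 2) stop("DRP needs at least 2 somata", call. = FALSE)
  if (bin_width_um <= 0) stop("bin_width_um must be positive", call. = FALSE)
  if (max_radius_um > min(field$window$width_um, field$window$height_um) / 2) {
    stop("max_radius_um exceeds half the shorter window side", call. = FALSE)
  }
  n_bins <- ceiling(max_radius_um / bin_width_um)
  edges <- bin_width_um * (0:n_bins)
  dmat <- as.matrix(stats::dist(cbind(pts$x_um, pts$y_um)))
  dvec <- dmat[upper.tri(dmat)]
  # ordered pairs: each unordered pair contributes twice
  bin_idx <- floor(dvec / bin_width_um) + 1
  keep <- bin_idx <= n_bins
  counts <- 2 * tabulate(bin_idx[keep], nbins = n_bins)
  areas <- numeric(n_bins)
  for (i in seq_len(n)) {
    center <- c(pts$x_um[i], pts$y_um[i])
    disk <- vapply(edges, function(r) {
      if (r == 0) 0 else disk_window_area(center[1], center[2], r, field$window)
    }, numeric(1))
    areas <- areas + diff(disk)
  }
  lambda <- counts / areas * 1e6
  d_global <- n / window_area_mm2(field$window)
  out <- structure(list(
    bin_width_um = bin_width_um,
    bin_edges_um = edges,
    bin_mid_um = (edges[-1] + edges[-length(edges)]) / 2,
    counts = counts,
    corrected_area_um2 = areas,
    density_mm2 = lambda,
    global_density_mm2 = d_global,
    n = n
  ), class = "drp_result")
  out$effective_radius_um <- effective_radius(out)
  out
}

#' @export
print.drp_result <- function(x, ...) {
  cat(sprintf(
    "<drp_result> n = %d, D = %.4g cells/mm^2, %d bins of %.3g um, r_e = %.4g um\n",
    x$n, x$global_density_mm2, length(x$counts), x$bin_width_um,
    x$effective_radius_um))
  invisible(x)
}

#' Rodieck effective radius of an exclusion zone
#'
#' The radius of the equivalent step profile (zero density inside r_e, the
#' global density D outside) carrying the same density deficit ("dead space")
#' as the measured profile:
#' `r_e = sqrt( sum_k (1 - lambda_k / D) * (r_k^2 - r_{k-1}^2) )`,
#' summed up to the last bin before the profile first reaches D, with
#' negative contributions floored at zero. Equivalently, the midpoint of the
#' rising part of the DRP curve. For a random hard-core array the effective
#' radius equals the soma diameter.
#'
#' @param drp A `drp_result` (see [compute_drp()]).
#' @return Effective radius in um, in `[0, max bin edge]`; 0 when the first
#'   bin already reaches D.
#' @export
effective_radius <- function(drp) {
  stopifnot(inherits(drp, "drp_result"))
  d_global <- drp$global_density_mm2
  if (!(d_global > 0)) stop("global density must be positive", call. = FALSE)
  lambda <- drp$density_mm2
  edges <- drp$bin_edges_um
  k_cross <- which(lambda >= d_global)[1]
  k_star <- if (is.na(k_cross)) length(lambda) else k_cross - 1
  if (k_star < 1) return(0)
  ks <- seq_len(k_star)
  deficit <- pmax(0, 1 - lambda[ks] / d_global) *
    (edges[ks + 1]^2 - edges[ks]^2)
  sqrt(sum(deficit))
}

#' Voronoi domain regularity index
#'
#' VDRI = mean / SD of the areas of window-clipped Voronoi domains, computed
#' over interior (non-border-touching) domains only. Larger values indicate a
#' more regular mosaic; a homogeneous Poisson arrangement yields roughly 1.9,
#' a perfect lattice is degenerate (SD 0, reported as `Inf` with a flag).
#'
#' @param field A [soma_field()] yielding at least `min_interior` interior
#'   domains.
#' @param min_interior Minimum interior-domain count for a reportable value
#'   (default 10).
#' @return An object of class `vdri_result`: list with `vdri`, `n_interior`,
#'   `mean_area_um2`, `sd_area_um2`, `areas_um2`, `degenerate`.
#' @export
compute_vdri <- function(field, min_interior = 10) {
  doms <- voronoi_domains(field)
  interior <- Filter(function(d) !d$is_border, doms)
  n_int <- length(interior)
  if (n_int < min_interior) {
    stop(sprintf("only %d interior Voronoi domains (need >= %d)",
                 n_int, min_interior), call. = FALSE)
  }
  areas <- vapply(interior, `[[`, numeric(1), "area_um2")
  m <- mean(areas)
  s <- stats::sd(areas)
  # relative threshold: a perfect lattice yields SD at rounding level only
  degenerate <- s <= 1e-9 * m
  structure(list(vdri = if (degenerate) Inf else m / s,
                 n_interior = n_int, mean_area_um2 = m, sd_area_um2 = s,
                 areas_um2 = areas, degenerate = degenerate),
            class = "vdri_result")
}

#' @export
print.vdri_result <- function(x, ...) {
  cat(sprintf("<vdri_result> VDRI = %.4g over %d interior domains%s\n",
              x$vdri, x$n_interior,
              if (x$degenerate) " (degenerate: zero SD)" else ""))
  invisible(x)
}

#' Matched random-reference battery
#'
#' Compares a field's regularity (VDRI) and exclusion-zone size (effective
#' radius) against simulated random hard-core arrays matched in cell size and
#' density, the reference used throughout the mosaic analyses (n = 5
#' simulations by default).
#'
#' @param field The observed [soma_field()].
#' @param n_sims Number of matched simulations (>= 2; default 5).
#' @param seed Integer seed for the simulation battery.
#' @param bin_width_um,max_radius_um DRP parameters, see [compute_drp()].
#' @return A list with `observed` (vdri, effective_radius_um), `simulated`
#'   (per-simulation values), `summary` (data.frame with observed value,
#'   simulation mean, SD, and z-score per statistic).
#' @export
random_reference_battery <- function(field, n_sims = 5, seed,
                                     bin_width_um = 5, max_radius_um = 150) {
  stopifnot(inherits(field, "soma_field"))
  if (n_sims < 2) stop("n_sims must be >= 2", call. = FALSE)
  obs_vdri <- compute_vdri(field)$vdri
  obs_re <- compute_drp(field, bin_width_um, max_radius_um)$effective_radius_um
  dens <- field_density(field)
  diam <- mean(field$points$diameter_um)
  sim_vdri <- numeric(n_sims)
  sim_re <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    cfg <- sim_config(mode = "hardcore_random", window = field$window,
                      target_density = dens, soma_diameter_um = diam,
                      seed = derive_seed(seed, s))
    sim <- simulate_hardcore(cfg)
    sim_vdri[s] <- compute_vdri(sim)$vdri
    sim_re[s] <- compute_drp(sim, bin_width_um,
                             max_radius_um)$effective_radius_um
  }
  summarize <- function(obs, sims) {
    m <- mean(sims)
    s <- stats::sd(sims)
    # degenerate envelope (all simulations identical): z is 0 on the
    # envelope, +/-Inf off it
    z <- if (s > 0) (obs - m) / s else if (obs == m) 0 else Inf * sign(obs - m)
    c(observed = obs, sim_mean = m, sim_sd = s, z = z)
  }
  smry <- rbind(vdri = summarize(obs_vdri, sim_vdri),
                effective_radius_um = summarize(obs_re, sim_re))
  list(observed = list(vdri = obs_vdri, effective_radius_um = obs_re),
       simulated = list(vdri = sim_vdri, effective_radius_um = sim_re),
       summary = as.data.frame(smry))
}
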
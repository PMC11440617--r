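test_that("hard-core simulation hits the target count and respects the core", {
  cfg <- sim_config(mode = "hardcore_random", target_density = 1400, seed = 1)
  f <- simulate_hardcore(cfg)
  # round(1400 cells/mm^2 x 0.1250076 mm^2) = 175
  expect_identical(nrow(f$points), 175L)
  expect_gte(min(dist(f$points[, c("x_um", "y_um")])), 10)
  # bit-reproducible under the same seed
  f2 <- simulate_hardcore(cfg)
  expect_identical(f$points, f2$points)
  # saturation is an error, not silent under-filling
  tight <- sim_config(target_density = 4000, soma_diameter_um = 12,
                      seed = 2, max_attempts = 50L)
  expect_error(simulate_hardcore(tight), "saturated")
})

test_that("exclusion mosaic keeps every soma outside every other arbor", {
  em <- simulate_exclusion_mosaic(
    sim_config(mode = "exclusion_mosaic", target_density = 1495, seed = 2))
  pts <- em$field$points
  expect_identical(nrow(pts), 187L)
  for (i in seq_along(em$arbors)) {
    a <- em$arbors[[i]]
    others <- pts$id != a$reference_id
    expect_false(any(points_in_polygon(pts$x_um[others], pts$y_um[others],
                                       a$vertices)))
    # reference disk always contained
    ref <- match(a$reference_id, pts$id)
    expect_true(disk_fully_inside(pts$x_um[ref], pts$y_um[ref],
                                  pts$diameter_um[ref], a$vertices))
  }
})

test_that("clustered generator recovers the Thomas-process mean count", {
  # negligible hard core so drops cannot bias the Poisson mean
  counts <- vapply(1:20, function(s) {
    nrow(suppressWarnings(simulate_clustered(
      sim_config(mode = "clustered", soma_diameter_um = 1,
                 seed = 500 + s)))$points)
  }, integer(1))
  expected <- 150 * window_area_mm2(field_window(353.55)) * 10
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # hard core respected at the default diameter
  f <- suppressWarnings(simulate_clustered(sim_config(mode = "clustered",
                                                      seed = 3)))
  expect_gte(min(dist(f$points[, c("x_um", "y_um")])), 10)
})

test_that("clustered fields show the short-range aggregation signature", {
  f <- suppressWarnings(simulate_clustered(sim_config(mode = "clustered",
                                                      seed = 7)))
  drp <- compute_drp(f)
  # density in the first bins above the hard core exceeds D
  above_core <- which(drp$bin_edges_um[-1] > 10)[1:2]
  expect_true(all(drp$density_mm2[above_core] > drp$global_density_mm2))
})

test_that("arbor generators always contain their reference soma disk", {
  f <- simulate_hardcore(sim_config(target_density = 1400, seed = 11))
  for (mode in c("coordinated", "independent", "overgrown")) {
    arbors <- generate_arbors(f, arbor_params = list(arbor_mode = mode),
                              seed = 21, reference_ids = f$points$id[1:25])
    expect_length(arbors, 25)
    for (a in arbors) {
      i <- match(a$reference_id, f$points$id)
      expect_true(disk_fully_inside(f$points$x_um[i], f$points$y_um[i],
                                    f$points$diameter_um[i], a$vertices))
      # polygons remain simple after jitter (validated on construction)
      expect_s3_class(a, "arbor_territory")
    }
  }
})

test_that("overgrown arbors extend past the first neighbor ring, coordinated stop short", {
  f <- simulate_hardcore(sim_config(target_density = 1400, seed = 31))
  dmat <- as.matrix(dist(f$points[, c("x_um", "y_um")]))
  diag(dmat) <- Inf
  ids <- f$points$id[1:20]
  co <- generate_arbors(f, arbor_params = list(arbor_mode = "coordinated"),
                        seed = 32, reference_ids = ids)
  ov <- generate_arbors(f, arbor_params = list(arbor_mode = "overgrown"),
                        seed = 33, reference_ids = ids)
  for (k in seq_along(ids)) {
    i <- match(ids[k], f$points$id)
    nn <- min(dmat[i, ])
    # coordinated vertex radii < nearest-neighbor distance
    vr_co <- sqrt(rowSums(sweep(co[[k]]$vertices, 2,
                                c(f$points$x_um[i], f$points$y_um[i]))^2))
    expect_true(all(vr_co < nn))
    # overgrown mean vertex radius beyond the nearest neighbor
    vr_ov <- sqrt(rowSums(sweep(ov[[k]]$vertices, 2,
                                c(f$points$x_um[i], f$points$y_um[i]))^2))
    expect_gt(mean(vr_ov), nn)
  }
})

test_that("tip fields realize their nominal contact fraction", {
  f <- simulate_hardcore(sim_config(target_density = 1400, seed = 41))
  tips1 <- generate_tip_field(f, 1, 80, seed = 42)
  expect_identical(nrow(tips1), 80L)
  expect_equal(contact_fraction(tips1, f, tolerance_um = 0.1)$fraction, 1)
  # zero nominal contact: measured rate matches the tolerance-ring area
  # fraction among positions outside soma disks
  fr0 <- vapply(1:20, function(s) {
    tips0 <- generate_tip_field(f, 0, 200, seed = 1000 + s)
    contact_fraction(tips0, f, tolerance_um = 0.5)$fraction
  }, numeric(1))
  n <- nrow(f$points)
  aw <- window_area_um2(f$window)
  a_disk <- n * pi * 5^2
  a_ring <- n * pi * (5.5^2 - 5^2)
  expected <- a_ring / (aw - a_disk)
  se <- sd(fr0) / sqrt(length(fr0))
  expect_lt(abs(mean(fr0) - expected), 3 * se)
  expect_error(generate_tip_field(f, 0.5, 0, seed = 1), "n_tips")
})

test_that("clone fields store recoverable ground truth", {
  cfg0 <- sim_config(mode = "clone_field",
                     clone_params = list(dispersed_fraction = 0),
                     seed = 51)
  cf0 <- generate_clone_field(cfg0)
  d0 <- dispersion_metrics(cf0$cells, cf0$columns)
  expect_identical(d0$n_outside_columns, 0L)
  expect_length(d0$distances_um, 0)
  # p = 0.3 recovered within the binomial CI in >= 18/20 seeds
  hits <- 0L
  ks_p <- numeric(20)
  for (s in 1:20) {
    cf <- generate_clone_field(sim_config(mode = "clone_field",
                                          seed = 600 + s))
    d <- dispersion_metrics(cf$cells, cf$columns)
    ci <- stats::binom.test(d$n_outside_columns, d$n_cells, 0.3)$conf.int
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) hits <- hits + 1L
    set.seed(9000 + s)
    fresh <- abs(stats::rnorm(500, 15, 8))
    ks_p[s] <- suppressWarnings(stats::ks.test(d$distances_um,
                                               fresh))$p.value
  }
  expect_gte(hits, 18L)
  # recovered displacement distances consistent with the sampling law
  expect_gt(median(ks_p), 0.01)
})

test_that("generators are deterministic given the seed", {
  cfg <- sim_config(mode = "clone_field", seed = 61)
  a <- generate_clone_field(cfg)
  b <- generate_clone_field(cfg)
  expect_identical(a$cells$points, b$cells$points)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_hardcore(sim_config(target_density = 100)),
               "seed")
})
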
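test_that("enclosure counting applies the full-containment rule", {
  win <- field_window(353.55)
  # isolated reference soma inside a generous arbor
  f1 <- soma_field(150, 150, win)
  a1 <- arbor_territory("c1", polygonize_disk(150, 150, 30))
  expect_identical(count_enclosed(a1, f1), 1L)
  # 3 disks fully inside, 1 straddling the boundary
  sq <- rbind(c(100, 100), c(160, 100), c(160, 160), c(100, 160))
  f2 <- soma_field(c(120, 130, 140, 158), c(120, 130, 140, 130), win)
  a2 <- arbor_territory("c1", sq)
  expect_identical(count_enclosed(a2, f2), 3L)
  # population filter restricts the counted somata
  f3 <- soma_field(c(120, 130), c(120, 130), win,
                   labels = c("ON", "OFF"))
  expect_identical(count_enclosed(a2, f3, population_filter = "ON"), 1L)
})

test_that("enclosure counts equal a per-soma brute-force oracle", {
  set.seed(81)
  win <- field_window(353.55)
  f <- simulate_hardcore(sim_config(target_density = 1400, seed = 82))
  for (rep in 1:100) {
    cx <- stats::runif(1, 40, 310)
    cy <- stats::runif(1, 40, 310)
    a <- arbor_territory("x", make_arbor_polygon(cx, cy,
                                                 stats::runif(1, 12, 35),
                                                 10, 0.1))
    oracle <- sum(vapply(seq_len(nrow(f$points)), function(i) {
      rim_disk_inside(f$points$x_um[i], f$points$y_um[i],
                      f$points$diameter_um[i], a$vertices)
    }, logical(1)))
    expect_identical(suppressWarnings(count_enclosed(a, f)),
                     as.integer(oracle))
  }
})

test_that("identity transposition yields zero enclosed cell index", {
  f <- simulate_hardcore(sim_config(target_density = 1400, seed = 83))
  arbors <- generate_arbors(f, arbor_params = list(arbor_mode = "coordinated"),
                            seed = 84, reference_ids = f$points$id[1:10])
  arbors <- lapply(arbors, function(a) {
    a$source_field_id <- "f1"
    a
  })
  fields <- list(f1 = f, f2 = f)  # copy of the source field
  recs <- suppressWarnings(build_unmatched(arbors, fields))
  for (r in recs) {
    expect_identical(r$unmatched_counts, r$real_count)
    expect_identical(r$eci, 0)
    # family size = number of fields - 1
    expect_length(r$unmatched_counts, 1L)
  }
})

test_that("unmatched counts on CSR fields match the eroded-area expectation", {
  # convex polygon: erosion area has the closed form A - P*rho + pi*rho^2
  poly <- polygonize_disk(176, 176, 30, n = 48)
  a <- arbor_territory("x", poly, source_field_id = "f1")
  rho <- 5
  area_eroded <- polygon_area(poly) -
    rho * sum(sqrt(rowSums((poly - rbind(poly[-1, ], poly[1, ]))^2))) +
    pi * rho^2
  dens_um2 <- 1400 / 1e6
  expected <- dens_um2 * area_eroded
  counts <- vapply(1:20, function(s) {
    f <- simulate_hardcore(sim_config(target_density = 1400,
                                      soma_diameter_um = 0.01, seed = 850 + s))
    f$points$diameter_um <- 10  # CSR positions, 10 um disks for containment
    count_enclosed(a, f)
  }, integer(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("the enclosed cell index follows the printed formula and zero exclusion", {
  a <- arbor_territory("x", polygonize_disk(50, 50, 20))
  r1 <- enclosure_record(a, 1L, c(2L, 3L, 2L, 3L, 2L))
  expect_equal(r1$eci, 2.4 - 1)
  r2 <- enclosure_record(a, 2L, c(0L, 2L, 2L))
  expect_equal(r2$unmatched_mean_zero_excluded, 2)
  expect_equal(r2$eci, 0)
  # zero exclusion never decreases the unmatched mean
  set.seed(86)
  for (rep in 1:50) {
    u <- stats::rpois(10, 0.8)
    r <- enclosure_record(a, 1L, u)
    if (any(u > 0)) {
      expect_gte(r$unmatched_mean_zero_excluded, mean(u))
    } else {
      expect_false(r$eci_defined)
    }
  }
})

test_that("the ECI Wilcoxon test reproduces exact enumeration", {
  # perfect symmetry (with ties): p = 1
  sym <- c(1, -1, 2, -2, 3, -3)
  expect_equal(eci_median_test(sym)$p_value, 1)
  # all zero: degenerate, p = 1
  z <- eci_median_test(rep(0, 8))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  # n = 8 all positive: exact p = 2 / 2^8
  pos <- c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4)
  expect_equal(eci_median_test(pos)$p_value, 2 / 256)
  # tie-free cases agree with the stats::wilcox.test exact oracle
  set.seed(87)
  for (rep in 1:25) {
    x <- round(stats::rnorm(12), 3)
    x <- x[x != 0]
    if (length(x) < 6 || anyDuplicated(abs(x))) next
    expect_equal(eci_median_test(x)$p_value,
                 stats::wilcox.test(x, mu = 0, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample branch is close to the normal-approximation oracle
  set.seed(88)
  xl <- stats::rnorm(60, 0.2)
  expect_equal(eci_median_test(xl)$p_value,
               stats::wilcox.test(xl, mu = 0, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(eci_median_test(c(1, 2)), ">= 6")
})

test_that("independent arbors on random fields calibrate the ECI null", {
  out <- vapply(1:20, function(r) {
    recs <- independence_null_records(derive_seed(42, 7000 + r))
    tst <- eci_median_test(recs)
    c(tst$median, tst$p_value)
  }, numeric(2))
  # median ECI ~ 0 throughout and nominal-level nonrejection in >= 18/20
  expect_true(all(abs(out[1, ]) <= 0.1))
  expect_gte(sum(out[2, ] > 0.05), 18L)
})

test_that("coordinated arbors yield median ECI significantly above zero", {
  fields <- list()
  arbors <- list()
  for (i in 1:6) {
    em <- simulate_exclusion_mosaic(
      sim_config(mode = "exclusion_mosaic", target_density = 1400,
                 seed = derive_seed(95, i)))
    fid <- paste0("f", i)
    fields[[fid]] <- em$field
    aa <- em$arbors[1:20]
    aa <- lapply(aa, function(a) {
      a$source_field_id <- fid
      a
    })
    arbors <- c(arbors, aa)
  }
  recs <- suppressWarnings(build_unmatched(arbors, fields))
  tst <- eci_median_test(recs)
  # enclosure counts are granular, so the median can sit at 0 while the
  # signed-rank mass is entirely positive; direction + significance checked
  ecis <- vapply(Filter(function(r) r$eci_defined, recs), `[[`,
                 numeric(1), "eci")
  expect_gte(tst$median, 0)
  expect_gt(mean(ecis), 0)
  expect_lt(tst$p_value, 0.001)
})

test_that("frequency curves normalize and the chi-squared detects shifts", {
  a <- arbor_territory("x", polygonize_disk(50, 50, 20))
  # identical degenerate curves: statistic 0, p = 1
  same <- lapply(1:10, function(i) enclosure_record(a, 1L, c(1L, 1L, 1L)))
  d0 <- enclosure_distributions(same)
  expect_equal(d0$chisq$statistic, 0)
  expect_equal(d0$chisq$p_value, 1)
  expect_equal(sum(d0$curve$real_freq), 1)
  expect_equal(sum(d0$curve$unmatched_mean), 1, tolerance = 1e-12)
  # real all 1 vs unmatched mass on {2, 3}: detected at 30+ arbors
  set.seed(89)
  shift <- lapply(1:30, function(i) {
    enclosure_record(a, 1L, sample(2:3, 20, replace = TRUE))
  })
  d1 <- enclosure_distributions(shift)
  expect_lt(d1$chisq$p_value, 0.01)
})

test_that("the 1-SD size filter uses inclusive wild-type bounds", {
  mk <- function(area) {
    # square of the requested area
    s <- sqrt(area)
    arbor_territory("x", rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
  }
  # reference areas: mean 100, sd 20
  ref <- lapply(c(80, 100, 120), mk)
  cmp <- lapply(c(79.9, 80, 120, 120.1), mk)
  out <- size_filter(ref, cmp)
  expect_equal(out$bounds, c(80, 120))
  expect_length(out$reference, 3)
  areas <- vapply(out$comparison, `[[`, numeric(1), "area_um2")
  expect_equal(areas, c(80, 120), tolerance = 1e-9)
  # filtering smaller mutant arbors shrinks the between-group mean gap
  set.seed(90)
  wt <- lapply(pmax(stats::rnorm(40, 900, 150), 200), mk)
  mut <- lapply(pmax(stats::rnorm(40, 650, 150), 100), mk)
  flt <- size_filter(wt, mut)
  gap <- function(a, b) {
    abs(mean(vapply(a, `[[`, numeric(1), "area_um2")) -
          mean(vapply(b, `[[`, numeric(1), "area_um2")))
  }
  expect_lt(gap(flt$reference, flt$comparison), gap(wt, mut))
})

test_that("Levene's variance test is calibrated and powered", {
  lv <- variance_equality_test(rep(5, 10), rep(5, 10))
  expect_true(lv$degenerate)
  set.seed(91)
  reject_null <- 0L
  reject_alt <- 0L
  for (r in 1:1000) {
    a <- stats::rnorm(30)
    b <- stats::rnorm(30)
    if (variance_equality_test(a, b)$p_value < 0.05) {
      reject_null <- reject_null + 1L
    }
    if (variance_equality_test(a, 3 * stats::rnorm(30))$p_value < 0.05) {
      reject_alt <- reject_alt + 1L
    }
  }
  expect_gte(reject_null / 1000, 0.03)
  expect_lte(reject_null / 1000, 0.07)
  expect_gt(reject_alt / 1000, 0.9)
})
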
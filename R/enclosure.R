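#' Dendritic arbor territory
#'
#' A simple polygon demarcating one reference cell's dendritic territory
#' (the hand-drawn ROI connecting arbor tips, or a synthetic arbor).
#'
#' @param reference_id Identifier of the reference soma.
#' @param vertices An n x 2 matrix of polygon vertices (validated: >= 3
#'   vertices, simple, positive area).
#' @param source_field_id Optional identifier of the field the arbor was
#'   drawn on.
#' @return An object of class `arbor_territory` with derived `area_um2`.
#' @export
arbor_territory <- function(reference_id, vertices, source_field_id = NA) {
  v <- validate_polygon(vertices)
  structure(list(reference_id = as.character(reference_id), vertices = v,
                 area_um2 = abs(signed_area(v)),
                 source_field_id = source_field_id),
            class = "arbor_territory")
}

#' @export
print.arbor_territory <- function(x, ...) {
  cat(sprintf("<arbor_territory> ref %s, %d vertices, %.4g um^2\n",
              x$reference_id, nrow(x$vertices), x$area_um2))
  invisible(x)
}

#' Count somata fully enclosed by an arbor territory
#'
#' Counts somata whose entire disk (diameter `nucleus_diameter_um`, default
#' the soma's own diameter) lies inside the arbor polygon; a soma straddling
#' the polygon boundary is not counted. When the arbor is scored on its own
#' source field the reference cell's soma is included in the count. Polygons
#' extending outside the window are flagged with a warning and counting
#' proceeds on in-window somata.
#'
#' @param arbor An [arbor_territory()].
#' @param field A [soma_field()].
#' @param population_filter Optional label tag restricting which somata are
#'   counted (e.g. `"ON"`).
#' @param nucleus_diameter_um Optional override of the containment disk
#'   diameter (the counted nuclear marker may be smaller than the soma).
#' @return Integer count.
#' @export
count_enclosed <- function(arbor, field, population_filter = NULL,
                           nucleus_diameter_um = NULL) {
  stopifnot(inherits(arbor, "arbor_territory"), inherits(field, "soma_field"))
  v <- arbor$vertices
  if (any(!in_window(v[, 1], v[, 2], field$window))) {
    warning("arbor polygon extends outside the window; counting in-window somata",
            call. = FALSE)
  }
  pts <- filter_field(field, population_filter)$points
  if (nrow(pts) == 0) return(0L)
  diam <- if (is.null(nucleus_diameter_um)) pts$diameter_um else
    rep_len(nucleus_diameter_um, nrow(pts))
  # bounding-box prefilter before the exact disk-containment test
  r <- diam / 2
  cand <- pts$x_um + r >= min(v[, 1]) & pts$x_um - r <= max(v[, 1]) &
    pts$y_um + r >= min(v[, 2]) & pts$y_um - r <= max(v[, 2])
  if (!any(cand)) return(0L)
  sum(disk_fully_inside(pts$x_um[cand], pts$y_um[cand], diam[cand], v))
}

#' Build the unmatched-transposition null for a set of arbors
#'
#' The resampling control that severs dendrite-soma coordination: each arbor
#' polygon is scored on its own source field (the real count) and then
#' transposed, at identical coordinates, onto every other field of the
#' dataset (the unmatched counts). The per-arbor unmatched mean excludes
#' zero-enclosure images — real images always contain at least the reference
#' soma, so retaining zeros would skew the null toward smaller values — and
#' the enclosed cell index is `unmatched mean - real count`.
#'
#' @param arbors List of [arbor_territory()] with `source_field_id` set.
#' @param fields Named list of [soma_field()] (names are field ids), all with
#'   identical window dimensions.
#' @param population_filter,nucleus_diameter_um Passed to [count_enclosed()].
#' @return A list of `enclosure_record` objects: `arbor`, `real_count`,
#'   `unmatched_counts` (full, zeros retained), `unmatched_mean_zero_excluded`,
#'   `eci` (`NA` with `eci_defined = FALSE` when every unmatched count is 0).
#' @export
build_unmatched <- function(arbors, fields, population_filter = NULL,
                            nucleus_diameter_um = NULL) {
  if (length(fields) < 2) stop("need >= 2 fields", call. = FALSE)
  if (is.null(names(fields)) || anyDuplicated(names(fields))) {
    stop("fields must be uniquely named", call. = FALSE)
  }
  w0 <- fields[[1]]$window
  same <- vapply(fields, function(f) {
    isTRUE(all.equal(c(f$window$width_um, f$window$height_um),
                     c(w0$width_um, w0$height_um)))
  }, logical(1))
  if (!all(same)) stop("all fields must share the same window size",
                       call. = FALSE)
  lapply(arbors, function(a) {
    src <- as.character(a$source_field_id)
    if (!src %in% names(fields)) {
      stop(sprintf("arbor %s: source field '%s' not in dataset",
                   a$reference_id, src), call. = FALSE)
    }
    real <- count_enclosed(a, fields[[src]], population_filter,
                           nucleus_diameter_um)
    others <- setdiff(names(fields), src)
    unmatched <- vapply(others, function(fid) {
      count_enclosed(a, fields[[fid]], population_filter,
                     nucleus_diameter_um)
    }, integer(1))
    enclosure_record(a, real, unmatched)
  })
}

#' Per-arbor enclosure record and enclosed cell index
#'
#' @param arbor An [arbor_territory()].
#' @param real_count Enclosed-soma count on the arbor's own field.
#' @param unmatched_counts Integer vector of counts from the unmatched
#'   (transposed) images, zeros retained.
#' @return An `enclosure_record`; its `eci` field is
#'   `mean(unmatched_counts > 0) - real_count`, `NA` (with
#'   `eci_defined = FALSE`) when no unmatched image encloses any soma.
#' @export
enclosure_record <- function(arbor, real_count, unmatched_counts) {
  unmatched_counts <- as.integer(unmatched_counts)
  nz <- unmatched_counts[unmatched_counts > 0]
  mean_nz <- if (length(nz) > 0) mean(nz) else NA_real_
  structure(list(arbor = arbor, real_count = as.integer(real_count),
                 unmatched_counts = unmatched_counts,
                 unmatched_mean_zero_excluded = mean_nz,
                 eci = if (is.na(mean_nz)) NA_real_ else mean_nz - real_count,
                 eci_defined = !is.na(mean_nz)),
            class = "enclosure_record")
}

#' @rdname enclosure_record
#' @param record An `enclosure_record`.
#' @export
enclosed_cell_index <- function(record) {
  stopifnot(inherits(record, "enclosure_record"))
  record$eci
}

# exact one-sample Wilcoxon signed-rank (two-sided) via a shifted-count DP
# over doubled midranks; handles ties exactly. Zeros already removed.
wilcoxon_exact_p <- function(r_signed_pos, r_all) {
  ir <- as.integer(round(2 * r_all))
  total <- sum(ir)
  cnt <- numeric(total + 1)
  cnt[1] <- 1
  for (v in ir) {
    shifted <- c(rep(0, v), cnt[seq_len(total + 1 - v)])
    cnt <- cnt + shifted
  }
  cnt <- cnt / 2^length(ir)
  w2 <- as.integer(round(2 * r_signed_pos))
  p_le <- sum(cnt[seq_len(w2 + 1)])
  p_ge <- sum(cnt[seq(w2 + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' One-sample Wilcoxon signed-rank test of the ECI median against zero
#'
#' Two-sided signed-rank test of `median = 0` over the defined enclosed cell
#' indices. Zeros are dropped before ranking; ties are handled by midranks.
#' The null distribution is enumerated exactly (sign-flip DP) for n <= 25 and
#' approximated by the tie-corrected normal with continuity correction
#' beyond. An index of zero means an arbor encloses the same number of cells
#' in its real and unmatched images; a positive median means unmatched images
#' enclose more, i.e. real somata avoid the reference territory.
#'
#' @param records List of `enclosure_record`s (or a numeric vector of ECIs).
#' @param min_n Minimum number of defined ECIs required (default 6).
#' @return List: `median`, `p_value`, `n` (nonzero values used), `statistic`
#'   (W+, sum of positive signed ranks), `method`, `degenerate` (TRUE when
#'   every value is zero; then `p_value = 1`).
#' @export
eci_median_test <- function(records, min_n = 6) {
  x <- if (is.numeric(records)) records else
    vapply(Filter(function(r) r$eci_defined, records), `[[`, numeric(1), "eci")
  if (length(x) < min_n) {
    stop(sprintf("need >= %d defined ECIs, got %d", min_n, length(x)),
         call. = FALSE)
  }
  med <- stats::median(x)
  d <- x[x != 0]
  n <- length(d)
  if (n == 0) {
    return(list(median = med, p_value = 1, n = 0L, statistic = NA_real_,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25) {
    p <- wilcoxon_exact_p(w_pos, r)
    method <- "exact signed-rank (sign-flip enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w_pos - mu) * 0.5
    z <- (w_pos - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity and tie correction"
  }
  list(median = med, p_value = p, n = n, statistic = w_pos, method = method,
       degenerate = FALSE)
}

#' Real and unmatched enclosure frequency distributions
#'
#' The frequency-histogram comparison: the real curve is the fraction of
#' arbors enclosing exactly n somata; the unmatched curve is the across-arbor
#' mean (with SEM) of each arbor's per-image enclosure frequencies, computed
#' over zero-excluded unmatched images. A chi-squared test compares the
#' observed real counts per bin against expected counts formed from the
#' unmatched proportions, pooling upper-tail bins until every expected count
#' is at least 5.
#'
#' @param records List of `enclosure_record`s (>= 2).
#' @param max_n Largest enclosure count bin; default the data maximum.
#' @return List: `curve` (data.frame with `n_enclosed`, `real_freq`,
#'   `unmatched_mean`, `unmatched_sem`), `chisq` (`statistic`, `df`,
#'   `p_value`, `pooled_bins`).
#' @export
enclosure_distributions <- function(records, max_n = NULL) {
  stopifnot(length(records) >= 2)
  real <- vapply(records, `[[`, integer(1), "real_count")
  unmatched_nz <- lapply(records, function(r) {
    r$unmatched_counts[r$unmatched_counts > 0]
  })
  keep <- vapply(unmatched_nz, length, integer(1)) > 0
  if (is.null(max_n)) {
    max_n <- max(c(real, unlist(unmatched_nz)), 1)
  }
  bins <- seq_len(max_n)
  real_freq <- vapply(bins, function(k) mean(pmin(real, max_n) == k),
                      numeric(1))
  per_arbor <- do.call(rbind, lapply(unmatched_nz[keep], function(u) {
    vapply(bins, function(k) mean(pmin(u, max_n) == k), numeric(1))
  }))
  un_mean <- colMeans(per_arbor)
  un_sem <- apply(per_arbor, 2, stats::sd) / sqrt(nrow(per_arbor))
  # chi-squared on real counts vs expected from unmatched proportions
  obs <- real_freq * length(real)
  props <- un_mean / sum(un_mean)
  pooled <- pool_upper_tail(obs, props * length(real))
  if (pooled$k < 2 || all(abs(pooled$obs - pooled$exp) < 1e-12)) {
    chisq <- list(statistic = 0, df = max(pooled$k - 1, 0), p_value = 1,
                  pooled_bins = pooled$k)
  } else {
    stat <- sum((pooled$obs - pooled$exp)^2 / pooled$exp)
    df <- pooled$k - 1
    chisq <- list(statistic = stat, df = df,
                  p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                  pooled_bins = pooled$k)
  }
  list(curve = data.frame(n_enclosed = bins, real_freq = real_freq,
                          unmatched_mean = un_mean, unmatched_sem = un_sem),
       chisq = chisq)
}

# pool upper-tail bins until the tail expected count reaches 5 (>= 1 bin kept)
pool_upper_tail <- function(obs, expd) {
  k <- length(obs)
  while (k > 1 && expd[k] < 5) {
    obs[k - 1] <- obs[k - 1] + obs[k]
    expd[k - 1] <- expd[k - 1] + expd[k]
    obs <- obs[seq_len(k - 1)]
    expd <- expd[seq_len(k - 1)]
    k <- k - 1
  }
  # drop impossible empty bins (both observed and expected zero)
  keep <- !(obs == 0 & expd == 0)
  list(obs = obs[keep], exp = expd[keep], k = sum(keep))
}

#' Filter arbors to within 1 SD of the reference mean size
#'
#' Size-matching filter: bounds are `mean +/- SD` of the reference
#' (wild-type) arbor areas, boundary-inclusive, and both datasets are
#' filtered by the reference bounds.
#'
#' @param reference_arbors List of [arbor_territory()] (>= 3) defining the
#'   bounds.
#' @param comparison_arbors List of [arbor_territory()] filtered by the same
#'   bounds.
#' @return List: `reference`, `comparison` (filtered lists), `bounds`
#'   (numeric `c(lower, upper)` on area). Warns when a filtered set is empty.
#' @export
size_filter <- function(reference_arbors, comparison_arbors) {
  if (length(reference_arbors) < 3) {
    stop("need >= 3 reference arbors", call. = FALSE)
  }
  ref_areas <- vapply(reference_arbors, `[[`, numeric(1), "area_um2")
  bounds <- c(mean(ref_areas) - stats::sd(ref_areas),
              mean(ref_areas) + stats::sd(ref_areas))
  keep_ref <- ref_areas >= bounds[1] & ref_areas <= bounds[2]
  cmp_areas <- vapply(comparison_arbors, `[[`, numeric(1), "area_um2")
  keep_cmp <- cmp_areas >= bounds[1] & cmp_areas <= bounds[2]
  if (!any(keep_ref) || (length(comparison_arbors) > 0 && !any(keep_cmp))) {
    warning("size filter produced an empty dataset", call. = FALSE)
  }
  list(reference = reference_arbors[keep_ref],
       comparison = comparison_arbors[keep_cmp],
       bounds = bounds)
}

#' Levene's test for equality of arbor-size variances
#'
#' Levene's test with group centering at the mean, used to compare arbor-area
#' variability between genotypes.
#'
#' @param group_a_areas,group_b_areas Numeric vectors (>= 3 each).
#' @return List: `f_ratio`, `p_value`, `df`, `degenerate` (TRUE with
#'   `f_ratio = NA` when all within-group deviations are zero).
#' @export
variance_equality_test <- function(group_a_areas, group_b_areas) {
  if (length(group_a_areas) < 3 || length(group_b_areas) < 3) {
    stop("need >= 3 observations per group", call. = FALSE)
  }
  y <- c(group_a_areas, group_b_areas)
  g <- factor(rep(c("a", "b"), c(length(group_a_areas),
                                 length(group_b_areas))))
  dev <- abs(y - stats::ave(y, g))
  if (all(dev == 0)) {
    return(list(f_ratio = NA_real_, p_value = NA_real_, df = c(NA, NA),
                degenerate = TRUE))
  }
  lt <- car::leveneTest(y, g, center = mean)
  list(f_ratio = lt[1, "F value"], p_value = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]), degenerate = FALSE)
}
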
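#' Fraction of dendritic tips contacting somata
#'
#' Scores each tip for homotypic soma contact: a tip contacts a soma iff its
#' distance to the nearest soma center is at most that soma's radius plus
#' `tolerance_um` (resolution-limited apposition). The 95% confidence
#' interval is a Wilson score interval.
#'
#' @param tips A data.frame with columns `x_um`, `y_um` (one row per tip).
#' @param field A [soma_field()].
#' @param tolerance_um Contact tolerance in um (>= 0); default 0.5.
#' @param condition Label stored in the result (`"real"` or `"flipped"`).
#' @return An object of class `contact_result`: list with `n_tips`,
#'   `n_contacting`, `fraction`, `ci_low`, `ci_high`, `condition`.
#' @export
contact_fraction <- function(tips, field, tolerance_um = 0.5,
                             condition = "real") {
  stopifnot(inherits(field, "soma_field"))
  if (nrow(tips) < 1) stop("need at least one tip", call. = FALSE)
  if (tolerance_um < 0) stop("tolerance_um must be >= 0", call. = FALSE)
  pts <- field$points
  if (nrow(pts) == 0) {
    warning("empty soma field; contact fraction is 0", call. = FALSE)
    hits <- rep(FALSE, nrow(tips))
  } else {
    hits <- vapply(seq_len(nrow(tips)), function(t) {
      d <- sqrt((pts$x_um - tips$x_um[t])^2 + (pts$y_um - tips$y_um[t])^2)
      any(d <= pts$diameter_um / 2 + tolerance_um)
    }, logical(1))
  }
  n <- nrow(tips)
  k <- sum(hits)
  ci <- wilson_ci(k, n)
  structure(list(n_tips = n, n_contacting = k, fraction = k / n,
                 ci_low = ci[1], ci_high = ci[2], condition = condition),
            class = "contact_result")
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(max(0, center - half), min(1, center + half))
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("<contact_result> %s: %d/%d tips (%.3f, 95%% CI %.3f-%.3f)\n",
              x$condition, x$n_contacting, x$n_tips, x$fraction,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Flipped-image chance-contact control
#'
#' Estimates the contact rate expected by chance by flipping the tip channel
#' about both window axes ([flip_field()]) before re-scoring contacts against
#' the unflipped soma field, severing any real tip-soma coordination.
#'
#' @inheritParams contact_fraction
#' @return A `contact_result` with `condition = "flipped"`.
#' @export
flipped_contact_control <- function(tips, field, tolerance_um = 0.5) {
  flipped <- tips
  flipped$x_um <- field$window$width_um - tips$x_um
  flipped$y_um <- field$window$height_um - tips$y_um
  contact_fraction(flipped, field, tolerance_um, condition = "flipped")
}

#' Tangential-dispersion metrics against clone columns
#'
#' Quantifies tangential migration: a cell is outside the clonal columns iff
#' its center lies in no column polygon; for each outside cell the dispersion
#' distance is the Euclidean distance to the nearest point on the boundary of
#' the nearest column.
#'
#' @param cells A [soma_field()] of labelled cells.
#' @param columns List of column polygons (vertex matrices).
#' @return An object of class `dispersion_result`: `n_cells`,
#'   `n_outside_columns`, `fraction_outside`, `distances_um` (outside cells
#'   only).
#' @export
dispersion_metrics <- function(cells, columns) {
  stopifnot(inherits(cells, "soma_field"))
  if (length(columns) < 1) stop("need at least one column", call. = FALSE)
  if (nrow(cells$points) < 1) stop("need at least one cell", call. = FALSE)
  pts <- cells$points
  inside <- rep(FALSE, nrow(pts))
  for (col in columns) {
    inside <- inside | points_in_polygon(pts$x_um, pts$y_um, as.matrix(col))
  }
  out_idx <- which(!inside)
  distances <- vapply(out_idx, function(i) {
    min(vapply(columns, function(col) {
      min(dist_to_polygon_boundary(pts$x_um[i], pts$y_um[i], as.matrix(col)))
    }, numeric(1)))
  }, numeric(1))
  structure(list(n_cells = nrow(pts), n_outside_columns = length(out_idx),
                 fraction_outside = length(out_idx) / nrow(pts),
                 distances_um = distances),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "<dispersion_result> %d/%d cells outside columns (%.3f); median distance %.3g um\n",
    x$n_outside_columns, x$n_cells, x$fraction_outside,
    if (length(x$distances_um)) stats::median(x$distances_um) else NA))
  invisible(x)
}
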
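#' Rectangular observation window
#'
#' Axis-aligned rectangle `[0, width] x [0, height]` in micrometres, the
#' observation window for all soma fields. The default side matches a 40x
#' confocal field of view (353.55 um); 20x fields use 636.5 um.
#'
#' @param width_um Window width in um (> 0).
#' @param height_um Window height in um (> 0); defaults to `width_um`.
#' @return An object of class `field_window`.
#' @examples
#' win <- field_window(353.55)
#' window_area_mm2(win)
#' @export
field_window <- function(width_um = 353.55, height_um = width_um) {
  if (!is.numeric(width_um) || length(width_um) != 1L || !is.finite(width_um) ||
      !is.numeric(height_um) || length(height_um) != 1L || !is.finite(height_um)) {
    stop("window dimensions must be single finite numbers", call. = FALSE)
  }
  if (width_um <= 0 || height_um <= 0) {
    stop("window dimensions must be positive", call. = FALSE)
  }
  structure(list(width_um = as.numeric(width_um),
                 height_um = as.numeric(height_um)),
            class = "field_window")
}

#' @export
print.field_window <- function(x, ...) {
  cat(sprintf("<field_window> %.4g x %.4g um (%.5g mm^2)\n",
              x$width_um, x$height_um, window_area_mm2(x)))
  invisible(x)
}

#' Window area
#'
#' @param window A [field_window()].
#' @return Area in um^2 (`window_area_um2`) or mm^2 (`window_area_mm2`;
#'   1 mm^2 = 1e6 um^2).
#' @export
window_area_um2 <- function(window) {
  stopifnot(inherits(window, "field_window"))
  window$width_um * window$height_um
}

#' @rdname window_area_um2
#' @export
window_area_mm2 <- function(window) window_area_um2(window) / 1e6

in_window <- function(x, y, window, tol = 0) {
  x >= -tol & x <= window$width_um + tol & y >= -tol & y <= window$height_um + tol
}

#' Windowed field of soma centers
#'
#' The universal substrate for all mosaic statistics: a set of labelled 2D
#' soma center points with per-cell diameters inside a rectangular window.
#'
#' @param x_um,y_um Numeric vectors of soma center coordinates (um), all
#'   inside `window`.
#' @param window A [field_window()].
#' @param diameter_um Soma diameters in um (recycled); default 10.0, the mean
#'   starburst soma size used as the hard-core distance.
#' @param id Unique cell identifiers; defaults to `"c1", "c2", ...`.
#' @param labels Character vector of semicolon-joined tag sets per cell
#'   (e.g. `"ON;reference"`), or `""`.
#' @return An object of class `soma_field`: a list with elements `window` and
#'   `points` (a data.frame with columns `id`, `x_um`, `y_um`, `diameter_um`,
#'   `labels`).
#' @examples
#' f <- soma_field(c(100, 200), c(100, 200), field_window(353.55))
#' field_density(f)  # cells/mm^2
#' @export
soma_field <- function(x_um, y_um, window, diameter_um = 10,
                       id = NULL, labels = "") {
  stopifnot(inherits(window, "field_window"))
  n <- length(x_um)
  if (length(y_um) != n) stop("x_um and y_um lengths differ", call. = FALSE)
  if (n > 0 && (!is.numeric(x_um) || !is.numeric(y_um) ||
                any(!is.finite(x_um)) || any(!is.finite(y_um)))) {
    stop("coordinates must be finite numerics", call. = FALSE)
  }
  if (is.null(id)) id <- if (n > 0) paste0("c", seq_len(n)) else character(0)
  id <- as.character(id)
  if (anyDuplicated(id)) stop("soma ids must be unique", call. = FALSE)
  diameter_um <- rep_len(as.numeric(diameter_um), n)
  if (n > 0 && any(diameter_um <= 0)) {
    stop("soma diameters must be positive", call. = FALSE)
  }
  labels <- rep_len(as.character(labels), n)
  if (n > 0 && !all(in_window(x_um, y_um, window))) {
    bad <- which(!in_window(x_um, y_um, window))
    stop(sprintf("soma centers outside window (rows %s)",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  structure(list(
    window = window,
    points = data.frame(id = id, x_um = as.numeric(x_um),
                        y_um = as.numeric(y_um),
                        diameter_um = diameter_um, labels = labels,
                        stringsAsFactors = FALSE)
  ), class = "soma_field")
}

#' @export
print.soma_field <- function(x, ...) {
  cat(sprintf("<soma_field> %d somata in %.4g x %.4g um window (%.4g cells/mm^2)\n",
              nrow(x$points), x$window$width_um, x$window$height_um,
              field_density(x)))
  invisible(x)
}

#' Global density of a soma field
#'
#' @param field A [soma_field()].
#' @return Density D = n / window area, in cells/mm^2.
#' @export
field_density <- function(field) {
  stopifnot(inherits(field, "soma_field"))
  nrow(field$points) / window_area_mm2(field$window)
}

#' Subset a soma field by label tag
#'
#' Keeps somata whose semicolon-joined label set contains `tag`. With
#' `tag = NULL` the field is returned unchanged.
#'
#' @param field A [soma_field()].
#' @param tag A single tag, e.g. `"ON"`.
#' @return A [soma_field()].
#' @export
filter_field <- function(field, tag = NULL) {
  stopifnot(inherits(field, "soma_field"))
  if (is.null(tag)) return(field)
  sets <- strsplit(field$points$labels, ";", fixed = TRUE)
  keep <- vapply(sets, function(s) tag %in% s, logical(1))
  out <- field
  out$points <- field$points[keep, , drop = FALSE]
  rownames(out$points) <- NULL
  out
}

#' Flip a point set about both window axes
#'
#' The chance-control transform: `(x, y) -> (width - x, height - y)`, i.e. a
#' 180-degree rotation about the window center. Order, ids, diameters and
#' labels are preserved; all pairwise distances are unchanged.
#'
#' @param obj A [soma_field()], or a data.frame/matrix with x/y in the first
#'   two columns (then `window` is required).
#' @param window A [field_window()] (ignored for `soma_field` input).
#' @return Object of the same type with flipped coordinates.
#' @export
flip_field <- function(obj, window = NULL) {
  if (inherits(obj, "soma_field")) {
    out <- obj
    out$points$x_um <- obj$window$width_um - obj$points$x_um
    out$points$y_um <- obj$window$height_um - obj$points$y_um
    return(out)
  }
  stopifnot(inherits(window, "field_window"))
  m <- if (is.matrix(obj)) obj else as.matrix(obj[, 1:2])
  if (nrow(m) > 0 && !all(in_window(m[, 1], m[, 2], window))) {
    stop("points outside window", call. = FALSE)
  }
  out <- obj
  if (is.matrix(obj)) {
    out[, 1] <- window$width_um - m[, 1]
    out[, 2] <- window$height_um - m[, 2]
  } else {
    out[[1]] <- window$width_um - m[, 1]
    out[[2]] <- window$height_um - m[, 2]
  }
  out
}
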
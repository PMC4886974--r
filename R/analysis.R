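# Quantitative image evaluation: CNR over phantom-derived ROIs, line
# profiles against the ideal RSP curve, and RMSE versus ground truth.

#' Pixels of a circular ROI
#' @param grid a [image_grid()].
#' @param center c(x, y) centre, mm (phantom frame).
#' @param radius ROI radius, mm.
#' @return logical n x n mask matrix (rows = y, columns = x).
#' @export
roi_mask <- function(grid, center, radius) {
  X <- matrix(grid$x, grid$n, grid$n, byrow = TRUE)
  Y <- matrix(grid$y, grid$n, grid$n)
  (X - center[1])^2 + (Y - center[2])^2 <= radius^2
}

#' Annular ROI mask
#' @param grid a [image_grid()].
#' @param r_in,r_out inner/outer radius, mm.
#' @export
annulus_mask <- function(grid, r_in, r_out) {
  X <- matrix(grid$x, grid$n, grid$n, byrow = TRUE)
  Y <- matrix(grid$y, grid$n, grid$n)
  r2 <- X^2 + Y^2
  r2 >= r_in^2 & r2 <= r_out^2
}

#' Contrast-to-noise ratio in dB
#'
#' `CNR = 20 * log10(|s - b| / sqrt(sd_s^2 + sd_b^2))` where `s`/`b` are the
#' means and `sd_s`/`sd_b` the standard deviations of the signal and
#' background ROIs. Base-10 logarithm (dB convention). The value is invariant
#' under affine intensity transforms of the image.
#'
#' @param img a `pct_image` or matrix.
#' @param roi_signal,roi_background logical masks (each with >= 5 pixels).
#' @return CNR in dB. Degenerate denominators are flagged: `-Inf` when
#'   `s == b`, `Inf` with attribute `flagged = TRUE` when the denominator is
#'   zero but `s != b`, `NaN` flagged when both are zero.
#' @export
cnr <- function(img, roi_signal, roi_background) {
  v <- if (inherits(img, "pct_image")) img$values else img
  if (sum(roi_signal) < 5 || sum(roi_background) < 5)
    stop("cnr: each ROI must contain at least 5 pixels")
  s <- mean(v[roi_signal]); b <- mean(v[roi_background])
  den <- sqrt(stats::sd(v[roi_signal])^2 + stats::sd(v[roi_background])^2)
  if (den == 0) {
    out <- if (s == b) NaN else Inf
    attr(out, "flagged") <- TRUE
    return(out)
  }
  20 * log10(abs(s - b) / den)
}

#' CNR table over the phantom's ROIs
#'
#' Mirrors the standard report layout: bone-to-water and air-to-water CNR for
#' the three largest holes of each row (the two smallest holes are too small
#' to host an ROI; the adipose row is excluded because its density is
#' practically that of water). Signal ROIs are circles of 0.8 x insert radius
#' at the insert centres; the background is the committed water annulus of
#' the phantom.
#'
#' @param images named list of `pct_image` (e.g. fbp/sart/cs).
#' @param ph the [phantom()] that was scanned.
#' @param holes which hole indices to report (default 1:3).
#' @return data.frame with columns `method`, `material`, `hole`, `label`,
#'   `cnr_db`; class `pct_cnr_table`.
#' @export
cnr_table <- function(images, ph, holes = 1:3) {
  grid <- images[[1]]$grid
  bg <- annulus_mask(grid, ph$background_annulus[1], ph$background_annulus[2])
  ins <- ph$inserts[ph$inserts$material %in% c("bone", "air"), , drop = FALSE]
  rows <- list()
  for (m in names(images)) {
    for (mat in c("bone", "air")) {
      sel <- ins[ins$material == mat, , drop = FALSE]
      ord <- order(sel$radius, decreasing = TRUE)
      sel <- sel[ord, , drop = FALSE]
      for (h in holes) {
        if (h > nrow(sel)) next
        mask <- roi_mask(grid, c(sel$x[h], sel$y[h]), 0.8 * sel$radius[h])
        if (sum(mask) < 5) next       # hole too small for an ROI at this grid
        rows[[length(rows) + 1]] <-
          data.frame(method = m, material = mat, hole = h,
                     label = sel$label[h],
                     cnr_db = cnr(images[[m]], mask, bg))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pct_cnr_table", "data.frame")
  out
}

#' Line profile through an image with ideal RSP overlay
#'
#' Bilinear sampling along the line through `point` (mm) at `angle_deg`
#' (0 = along +x), with the piecewise-constant ideal RSP curve of the phantom
#' evaluated at the same sample positions.
#'
#' @param img a `pct_image`.
#' @param ph the [phantom()] (for the ideal curve); `NULL` to skip.
#' @param point c(x, y) a point on the line, mm.
#' @param angle_deg line direction, degrees.
#' @param step sample spacing, mm (default half a pixel).
#' @param materials material table.
#' @return data.frame with columns `t` (mm along the line), `x`, `y`,
#'   `value`, and `ideal` (if `ph` given).
#' @export
profile_line <- function(img, ph = NULL, point = c(0, 0), angle_deg = 0,
                         step = NULL, materials = pct_materials()) {
  g <- img$grid
  if (is.null(step)) step <- g$pixel_mm / 2
  half <- g$n * g$pixel_mm / 2
  t <- seq(-half, half, by = step)
  dx <- cos(angle_deg * pi / 180); dy <- sin(angle_deg * pi / 180)
  x <- point[1] + t * dx; y <- point[2] + t * dy
  inb <- x >= min(g$x) & x <= max(g$x) & y >= min(g$y) & y <= max(g$y)
  if (!any(inb)) stop("profile_line: line does not cross the image")
  t <- t[inb]; x <- x[inb]; y <- y[inb]
  # bilinear interpolation
  jx <- pmin(pmax(floor((x - g$x[1]) / g$pixel_mm) + 1, 1), g$n - 1)
  iy <- pmin(pmax(floor((y - g$y[1]) / g$pixel_mm) + 1, 1), g$n - 1)
  fx <- (x - g$x[jx]) / g$pixel_mm; fy <- (y - g$y[iy]) / g$pixel_mm
  v <- img$values
  val <- (1 - fx) * (1 - fy) * v[cbind(iy, jx)] +
    fx * (1 - fy) * v[cbind(iy, jx + 1)] +
    (1 - fx) * fy * v[cbind(iy + 1, jx)] +
    fx * fy * v[cbind(iy + 1, jx + 1)]
  out <- data.frame(t = t, x = x, y = y, value = val)
  if (!is.null(ph)) out$ideal <- eta_at(ph, x, y, materials)
  out
}

#' Ground-truth RSP image of a phantom
#'
#' Renders the eta_e map on the grid with sub-pixel supersampling (area
#' averaging), for RMSE evaluation of reconstructions.
#'
#' @param ph a [phantom()].
#' @param grid a [image_grid()].
#' @param supersample sub-samples per pixel edge.
#' @param materials material table.
#' @return a `pct_image`.
#' @export
ground_truth_image <- function(ph, grid = image_grid(), supersample = 3,
                               materials = pct_materials()) {
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample *
    grid$pixel_mm
  acc <- matrix(0, grid$n, grid$n)
  X <- matrix(grid$x, grid$n, grid$n, byrow = TRUE)
  Y <- matrix(grid$y, grid$n, grid$n)
  for (ox in off) for (oy in off)
    acc <- acc + matrix(eta_at(ph, as.vector(X + ox), as.vector(Y + oy),
                               materials), grid$n, grid$n)
  pct_image(acc / supersample^2, grid)
}

#' Root-mean-square error between two images
#' @param img a `pct_image` or matrix.
#' @param ref reference `pct_image` or matrix (same grid).
#' @param mask optional logical mask restricting the comparison (default: the
#'   inscribed circle).
#' @return scalar RMSE.
#' @export
image_rmse <- function(img, ref, mask = NULL) {
  v <- if (inherits(img, "pct_image")) img$values else img
  r <- if (inherits(ref, "pct_image")) ref$values else ref
  stopifnot(all(dim(v) == dim(r)))
  if (is.null(mask)) {
    n <- nrow(v)
    g <- image_grid(n, 1)
    mask <- roi_mask(g, c(0, 0), n / 2)
  }
  sqrt(mean((v[mask] - r[mask])^2))
}
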
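# Scanner and phantom geometry: tracker-plane placement, strip pixelation,
# and the cylindrical insert phantom with analytic ray queries.

#' Scanner geometry
#'
#' Four silicon strip detector (SSD) planes — two upstream, two downstream of
#' the phantom — each reading both transverse coordinates, plus an ideal
#' calorimeter behind the fourth plane. The beam travels along +z; plane 1
#' sits at z = 0.
#'
#' @param n_strips strips per coordinate (100).
#' @param strip_width active strip width, mm (0.94; the 0.06 mm remainder of
#'   the pitch is a dead gap).
#' @param strip_pitch strip pitch, mm (1.0).
#' @param strip_height strip height, mm (100).
#' @param tracker_thickness silicon thickness of each plane, mm (sweepable).
#' @param d12 gap between planes 1-2, mm (sweepable).
#' @param d34 gap between planes 3-4, mm (defaults to `d12`).
#' @param phantom_gap gap between planes 2 and 3 that hosts the phantom, mm.
#' @param calorimeter_dims CsI calorimeter dimensions, mm.
#' @return An object of class `pct_geometry`.
#' @export
scanner_geometry <- function(n_strips = 100, strip_width = 0.94,
                             strip_pitch = 1.0, strip_height = 100,
                             tracker_thickness = 0.2, d12 = 10, d34 = d12,
                             phantom_gap = 150,
                             calorimeter_dims = c(100, 100, 200)) {
  stopifnot(n_strips > 0, strip_width > 0, strip_pitch >= strip_width,
            tracker_thickness > 0, d12 > 0, d34 > 0, phantom_gap > 0)
  structure(list(n_strips = as.integer(n_strips), strip_width = strip_width,
                 strip_pitch = strip_pitch, strip_height = strip_height,
                 tracker_thickness = tracker_thickness, d12 = d12, d34 = d34,
                 phantom_gap = phantom_gap, calorimeter_dims = calorimeter_dims),
            class = "pct_geometry")
}

#' @export
print.pct_geometry <- function(x, ...) {
  cat(sprintf(paste0("<pct_geometry> %d strips (%g mm pitch, %g mm wide), ",
                     "planes %g mm Si; gaps d12 = %g, phantom = %g, d34 = %g mm\n"),
              x$n_strips, x$strip_pitch, x$strip_width, x$tracker_thickness,
              x$d12, x$phantom_gap, x$d34))
  invisible(x)
}

#' z positions of the four tracker planes (mm, upstream faces)
#' @param g a `pct_geometry`.
#' @return numeric length-4 vector.
#' @export
tracker_z <- function(g) {
  c(0, g$d12, g$d12 + g$phantom_gap, g$d12 + g$phantom_gap + g$d34)
}

#' z position of the isocenter (rotation-axis plane), mm
#' @param g a `pct_geometry`.
#' @export
isocenter_z <- function(g) g$d12 + g$phantom_gap / 2

#' Strip index for a transverse position
#'
#' Strip `i` (1-based) is centred at `(i - n/2) * pitch`, so the beam axis
#' (0 mm) lies at the centre of strip `n/2` — strip 50 for the default
#' 100-strip plane, honouring the "50th detector" counting convention.
#' Positions in the inter-strip dead gap are attributed to the nearest strip
#' (see [strip_dead_gap()]); positions outside the active area return `NA`.
#'
#' @param g a `pct_geometry`.
#' @param pos transverse position, mm (vectorised).
#' @return integer strip ids (1..n_strips), `NA` outside.
#' @export
strip_index <- function(g, pos) {
  i <- as.integer(round(pos / g$strip_pitch)) + g$n_strips %/% 2L
  i[i < 1L | i > g$n_strips] <- NA_integer_
  i
}

#' Centre position of a strip, mm
#' @param g a `pct_geometry`.
#' @param i strip index (vectorised); `NA` passes through.
#' @export
strip_center <- function(g, i) (i - g$n_strips %/% 2L) * g$strip_pitch

#' Is a position in the inter-strip dead gap?
#' @param g a `pct_geometry`.
#' @param pos transverse position, mm (vectorised).
#' @return logical; `NA` outside the active area.
#' @export
strip_dead_gap <- function(g, pos) {
  i <- strip_index(g, pos)
  abs(pos - strip_center(g, i)) > g$strip_width / 2
}

#' Cylindrical insert phantom
#'
#' A water cylinder with cylindrical inserts, described in the slice plane
#' (phantom frame, mm). The default layout has three material rows — bone
#' (upper), adipose (middle), air (lower) — each with five insert radii of
#' 4, 2, 1, 0.75 and 0.5 mm.
#'
#' @param body_radius water body radius, mm.
#' @param inserts data.frame with columns `material`, `x`, `y`, `radius` (mm).
#' @param background_annulus inner/outer radius (mm) of the water annulus used
#'   as the background ROI in CNR analysis; must avoid all inserts.
#' @return An object of class `pct_phantom`.
#' @export
phantom <- function(body_radius = 40, inserts = default_inserts(),
                    background_annulus = c(30, 36)) {
  stopifnot(body_radius > 0, all(c("material", "x", "y", "radius") %in% names(inserts)))
  d <- sqrt(inserts$x^2 + inserts$y^2)
  if (any(d + inserts$radius >= body_radius))
    stop("phantom: inserts must lie strictly inside the body")
  n <- nrow(inserts)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt((inserts$x[i] - inserts$x[j])^2 + (inserts$y[i] - inserts$y[j])^2)
    if (dij <= inserts$radius[i] + inserts$radius[j])
      stop("phantom: inserts overlap")
  }
  structure(list(body_radius = body_radius, body_material = "water",
                 inserts = inserts, background_annulus = background_annulus),
            class = "pct_phantom")
}

#' Default insert layout
#'
#' Five radii (4, 2, 1, 0.75, 0.5 mm) per material row; rows at y = +15 mm
#' (bone), 0 mm (adipose), -15 mm (air). Insert centres are not dictated by
#' the scanner; this layout keeps all inserts pairwise disjoint and inside a
#' 40 mm body, and is committed so results are reproducible.
#' @return data.frame with columns `material`, `x`, `y`, `radius`, `label`.
#' @export
default_inserts <- function() {
  radii <- c(4, 2, 1, 0.75, 0.5)
  xs <- c(-20, -8, 0, 8, 16)
  rows <- list(bone = 15, adipose = 0, air = -15)
  do.call(rbind, lapply(names(rows), function(m) {
    data.frame(material = m, x = xs, y = rows[[m]], radius = radii,
               label = paste0(m, "-", seq_along(radii)))
  }))
}

#' @export
print.pct_phantom <- function(x, ...) {
  cat(sprintf("<pct_phantom> water body R = %g mm, %d inserts (%s)\n",
              x$body_radius, nrow(x$inserts),
              paste(unique(x$inserts$material), collapse = ", ")))
  invisible(x)
}

#' Load/save a phantom from/to a YAML file
#' @param path file path.
#' @return `load_phantom` returns a `pct_phantom`.
#' @export
load_phantom <- function(path) {
  p <- yaml::read_yaml(path)
  ins <- do.call(rbind, lapply(p$inserts, as.data.frame))
  phantom(body_radius = p$body_radius, inserts = ins,
          background_annulus = unlist(p$background_annulus))
}

#' @rdname load_phantom
#' @param ph a `pct_phantom`.
#' @export
save_phantom <- function(ph, path) {
  yaml::write_yaml(list(body_radius = ph$body_radius,
                        background_annulus = as.list(ph$background_annulus),
                        inserts = lapply(seq_len(nrow(ph$inserts)), function(i)
                          as.list(ph$inserts[i, , drop = FALSE]))), path)
  invisible(path)
}

#' Material at a point of the phantom slice
#'
#' Innermost region wins: insert over body over exterior air.
#'
#' @param ph a `pct_phantom`.
#' @param x,y phantom-frame coordinates, mm (vectorised, equal length).
#' @return character vector of material names.
#' @export
material_at <- function(ph, x, y) {
  out <- rep("air", length(x))
  out[x^2 + y^2 < ph$body_radius^2] <- ph$body_material
  for (i in seq_len(nrow(ph$inserts))) {
    ins <- ph$inserts[i, ]
    out[(x - ins$x)^2 + (y - ins$y)^2 < ins$radius^2] <- ins$material
  }
  out
}

#' RSP (eta_e) map value at points of the phantom slice
#' @inheritParams material_at
#' @param materials material table, default [pct_materials()].
#' @return numeric vector of relative electron densities.
#' @export
eta_at <- function(ph, x, y, materials = pct_materials()) {
  eta <- vapply(materials, `[[`, numeric(1), "eta_e")
  unname(eta[material_at(ph, x, y)])
}

# Chord length of the line {p : p.n(theta) = s} through a circle
# (cx, cy, r); vectorised over s.
.circle_chord <- function(s, theta_rad, cx, cy, r) {
  d <- abs(cx * cos(theta_rad) + cy * sin(theta_rad) - s)
  2 * sqrt(pmax(r^2 - d^2, 0))
}

#' Analytic water-equivalent path length of a ray
#'
#' Closed-form chord evaluation of the line integral of relative electron
#' density along the parallel-beam ray at projection angle `theta` and
#' transaxial offset `s`: the ray is `{p : p . (cos theta, sin theta) = s}`
#' in the phantom frame.
#'
#' @param ph a `pct_phantom`.
#' @param theta_deg projection angle, degrees.
#' @param s transaxial offset, mm (vectorised).
#' @param materials material table.
#' @return WEPL in cm of water.
#' @export
analytic_wepl <- function(ph, theta_deg, s, materials = pct_materials()) {
  th <- theta_deg * pi / 180
  eta <- vapply(materials, `[[`, numeric(1), "eta_e")
  w <- .circle_chord(s, th, 0, 0, ph$body_radius) * eta[["water"]]
  for (i in seq_len(nrow(ph$inserts))) {
    ins <- ph$inserts[i, ]
    w <- w + .circle_chord(s, th, ins$x, ins$y, ins$radius) *
      (eta[[ins$material]] - eta[["water"]])
  }
  w / 10  # mm -> cm
}

#' Analytic (noise-free) sinogram of a phantom
#'
#' @param ph a `pct_phantom`.
#' @param angles projection angles, degrees.
#' @param s transaxial bin centres, mm.
#' @param materials material table.
#' @return A `pct_sinogram` (counts set to 1 everywhere).
#' @export
analytic_sinogram <- function(ph, angles, s, materials = pct_materials()) {
  w <- t(vapply(angles, function(a) analytic_wepl(ph, a, s, materials),
                numeric(length(s))))
  new_sinogram(angles, s, w, matrix(1L, length(angles), length(s)))
}
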
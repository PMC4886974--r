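# Condensed-history Monte-Carlo proton transport through the tracker
# telescope, air gaps and phantom. One MCS kick + one energy decrement per
# homogeneous slab; the phantom is traversed in short sub-steps. All
# operations are vectorised over the proton ensemble.

# Per-material lookup vectors used inside the stepping loop.
.mat_lookups <- function(materials) {
  list(eta  = vapply(materials, `[[`, numeric(1), "eta_e"),
       dlnI = vapply(materials, function(m) log(m$mean_excitation_I / 75), numeric(1)),
       rx0  = vapply(materials, function(m) m$density / m$radiation_length, numeric(1)))
}

#' Transport a proton ensemble through the scanner
#'
#' Condensed-history transport of `n` protons of initial kinetic energy `E0`
#' through the four tracker planes, the intervening air gaps and (optionally)
#' the rotated phantom. Each homogeneous slab contributes one deterministic
#' CSDA energy decrement (through the water range-energy table, scaled by the
#' slab material's relative stopping power at the current energy), one
#' Gaussian multiple-Coulomb-scattering deflection per transverse axis
#' (Highland sigma), and optionally Gaussian (Bohr) energy straggling. The
#' phantom region is traversed in sub-steps of at most `substep` mm.
#'
#' The projection angle rotates the rays relative to the phantom: a lab point
#' (x, z - z_iso) maps to the phantom frame as
#' `p = x * (cos a, sin a) + (z - z_iso) * (-sin a, cos a)`.
#'
#' @param geom a [scanner_geometry()].
#' @param ph a [phantom()] or `NULL` for an empty scene.
#' @param E0 beam kinetic energy, MeV.
#' @param n number of protons.
#' @param angle_deg projection angle, degrees.
#' @param beam `"pencil"` (all protons at `offset`) or `"flat"` (uniform over
#'   `beam_width` centred on the axis).
#' @param offset pencil-beam transaxial position, mm.
#' @param beam_width flat-beam width, mm; default covers the phantom with a
#'   10 mm margin (or 90 mm without a phantom).
#' @param mcs logical: sample multiple-Coulomb-scattering kicks.
#' @param straggling logical: sample Bohr energy straggling.
#' @param substep maximum step inside the phantom region, mm.
#' @param seed optional RNG seed (set once per call).
#' @param materials material table.
#' @return A data.frame of list-mode events, one row per proton:
#'   `angle`, strip indices `u1,v1,...,u4,v4`, true tracker-4 position
#'   `x4,y4` (mm), `x0` (true initial transaxial position, mm), `E_in`,
#'   `E_out` (MeV; `NA` if stopped), `wepl_true` (cm, accumulated), and
#'   `flag` (`"ok"`, `"stopped"`, `"missed"`).
#' @export
transport_beam <- function(geom, ph = NULL, E0 = 200, n = 1000, angle_deg = 0,
                           beam = c("pencil", "flat"), offset = 0,
                           beam_width = NULL, mcs = TRUE, straggling = TRUE,
                           substep = 1, seed = NULL,
                           materials = pct_materials()) {
  beam <- match.arg(beam)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(.empty_events())
  cst <- pct_constants()
  lk <- .mat_lookups(materials)
  tab <- .range_table("water", cst)
  zp <- tracker_z(geom)
  z_iso <- isocenter_z(geom)
  a <- angle_deg * pi / 180
  thk <- geom$tracker_thickness  # mm

  x <- if (beam == "pencil") rep(offset, n) else {
    bw <- if (!is.null(beam_width)) beam_width else
      if (!is.null(ph)) 2 * ph$body_radius + 20 else 90
    stats::runif(n, -bw / 2, bw / 2)
  }
  x_init <- x
  y <- numeric(n)
  tx <- numeric(n); ty <- numeric(n)
  E <- rep(E0, n)
  wepl <- numeric(n)
  hits <- matrix(NA_integer_, n, 8)  # u1 v1 ... u4 v4
  x4 <- y4 <- rep(NA_real_, n)

  drift <- function(L) {  # mm, straight drift
    x <<- x + tx * L; y <<- y + ty * L
  }
  # one homogeneous slab: L mm of material(s) `mats` (name vector or scalar)
  slab <- function(L, mats) {
    alive <- !is.na(E)
    if (!any(alive)) { drift(L); return(invisible()) }
    L_cm <- L / 10
    eta <- lk$eta[mats]; dlnI <- lk$dlnI[mats]; rx0 <- lk$rx0[mats]
    if (length(eta) == 1) { eta <- rep(eta, n); dlnI <- rep(dlnI, n); rx0 <- rep(rx0, n) }
    Ew <- ifelse(alive, E, E0)
    b2 <- 1 - (cst$m_p_c2 / (Ew + cst$m_p_c2))^2
    Lw <- log(2 * cst$m_e_c2 * b2 / (75e-6 * (1 - b2))) - b2
    w <- L_cm * eta * pmax(1 - dlnI / Lw, 0)   # water-equivalent slab, cm
    drift(L / 2)
    if (mcs) {
      t_rel <- pmax(L_cm * rx0, 1e-300)
      beta_pc <- Ew * (Ew + 2 * cst$m_p_c2) / (Ew + cst$m_p_c2)
      sig <- 13.6 / beta_pc * sqrt(t_rel) * pmax(1 + 0.038 * log(t_rel), 0)
      sig[!alive] <- 0
      tx <<- tx + stats::rnorm(n, 0, sig)
      ty <<- ty + stats::rnorm(n, 0, sig)
    }
    r <- tab$range_of_E(Ew) - w
    Enew <- ifelse(r <= tab$r_floor, NA_real_, tab$E_of_range(pmax(r, tab$r_floor)))
    if (straggling) {
      sg <- straggling_sigma(pmax(w, 0), Ew, cst)
      sg[!alive | is.na(Enew)] <- 0
      # energy loss fluctuates but stays positive: truncate at the
      # pre-slab energy so E never increases along the track
      Enew <- pmin(Enew + stats::rnorm(n, 0, sg), Ew)
      Enew[!is.na(Enew) & Enew <= cst$E_floor] <- NA_real_
    }
    E <<- ifelse(alive, Enew, NA_real_)
    wepl <<- wepl + ifelse(alive & !is.na(Enew), w, 0)
    drift(L / 2)
  }
  plane <- function(k) {  # record hit then traverse the silicon
    hits[, 2 * k - 1] <<- strip_index(geom, x)
    hits[, 2 * k] <<- strip_index(geom, y)
    if (k == 4) { x4 <<- x; y4 <<- y }
    slab(thk, "silicon")
  }
  phantom_block <- function(L) {  # from z2+thk to z3, length L mm
    if (is.null(ph)) { slab(L, "air"); return(invisible()) }
    z0 <- zp[2] + thk                       # block start
    m <- ph$body_radius + 2                 # stepping margin, mm
    pre <- (z_iso - m) - z0
    post <- zp[3] - (z_iso + m)
    if (pre > 0) slab(pre, "air")
    nstep <- ceiling(2 * m / substep)
    dz <- 2 * m / nstep
    # per-proton dither of the material-sampling depth: removes the
    # staircase bias the fixed sub-step lattice would imprint on the
    # water-equivalent chord (unbiased to O(dz^2))
    jit <- stats::runif(n, -dz / 2, dz / 2)
    zrel <- (z_iso - m) - z_iso             # = -m, advances by dz
    for (i in seq_len(nstep)) {
      zm <- zrel + dz / 2 + jit             # material sampled within the step
      px <- x * cos(a) - zm * sin(a)
      py <- x * sin(a) + zm * cos(a)
      slab(dz, material_at(ph, px, py))
      zrel <- zrel + dz
    }
    if (post > 0) slab(post, "air")
  }

  plane(1)
  slab(geom$d12 - thk, "air")
  plane(2)
  phantom_block(geom$phantom_gap - thk)
  plane(3)
  slab(geom$d34 - thk, "air")
  plane(4)                                  # calorimeter sits behind plane 4

  flag <- rep("ok", n)
  flag[apply(hits, 1, anyNA)] <- "missed"
  flag[is.na(E)] <- "stopped"
  E_out <- E; E_out[flag == "stopped"] <- NA_real_
  data.frame(angle = angle_deg,
             u1 = hits[, 1], v1 = hits[, 2], u2 = hits[, 3], v2 = hits[, 4],
             u3 = hits[, 5], v3 = hits[, 6], u4 = hits[, 7], v4 = hits[, 8],
             x4 = x4, y4 = y4, x0 = x_init,
             E_in = E0, E_out = E_out, wepl_true = wepl, flag = flag)
}

.empty_events <- function() {
  data.frame(angle = numeric(0), u1 = integer(0), v1 = integer(0),
             u2 = integer(0), v2 = integer(0), u3 = integer(0), v3 = integer(0),
             u4 = integer(0), v4 = integer(0), x4 = numeric(0), y4 = numeric(0),
             x0 = numeric(0), E_in = numeric(0), E_out = numeric(0),
             wepl_true = numeric(0), flag = character(0))
}

#' Count non-scattered protons
#'
#' Number of events whose fourth-plane hit lies in the target strip. By
#' default both coordinates must be central ("both"); `coords = "u"` counts
#' on the transaxial coordinate only.
#'
#' @param events event data.frame from [transport_beam()].
#' @param target_strip strip id (default the central strip, 50).
#' @param coords `"both"` or `"u"`.
#' @return integer count.
#' @export
count_unscattered <- function(events, target_strip = 50L, coords = c("both", "u")) {
  coords <- match.arg(coords)
  ok <- events$flag != "stopped"
  hit <- !is.na(events$u4) & events$u4 == target_strip
  if (coords == "both") hit <- hit & !is.na(events$v4) & events$v4 == target_strip
  sum(hit & ok)
}

.sweep <- function(parameter, values, make_geom, E, n, seed, coords) {
  res <- lapply(seq_along(values), function(i) {
    ev <- transport_beam(make_geom(values[i]), ph = NULL, E0 = E, n = n,
                         beam = "pencil", mcs = TRUE, straggling = FALSE,
                         seed = seed + i)
    cnt <- count_unscattered(ev, coords = coords)
    data.frame(parameter = parameter, value = values[i], count = cnt,
               fraction = cnt / n, spread_mm = stats::sd(ev$x4, na.rm = TRUE))
  })
  out <- do.call(rbind, res)
  attr(out, "E") <- E; attr(out, "n") <- n
  class(out) <- c("pct_sweep", "data.frame")
  out
}

#' Detector-thickness sweep
#'
#' Axial pencil beam, no phantom: for each strip thickness, the number and
#' fraction of protons reaching the central strip of the fourth plane, plus
#' the lateral spread (sd of the true tracker-4 position).
#'
#' @param thicknesses strip thicknesses to test, mm.
#' @param E beam energy, MeV.
#' @param n protons per grid point.
#' @param geom base geometry (thickness field is overridden).
#' @param seed RNG seed.
#' @param coords counting convention, see [count_unscattered()].
#' @return A `pct_sweep` data.frame.
#' @export
sweep_thickness <- function(thicknesses = c(0.01, 0.04, 0.07, 0.1, 0.2, 0.5, 0.8, 1.0),
                            E = 200, n = 1e4, geom = scanner_geometry(),
                            seed = 1, coords = "both") {
  .sweep("tracker_thickness", thicknesses, function(v) {
    g <- geom; g$tracker_thickness <- v; g
  }, E, n, seed, coords)
}

#' Inter-tracker interval sweep
#'
#' As [sweep_thickness()] but varying the gaps between planes 1-2 and 3-4
#' (d12 = d34) at fixed strip thickness.
#'
#' @param intervals gaps to test, mm.
#' @inheritParams sweep_thickness
#' @return A `pct_sweep` data.frame.
#' @export
sweep_interval <- function(intervals = c(10, 30, 50, 70, 100, 200),
                           E = 200, n = 1e4, geom = scanner_geometry(),
                           seed = 1, coords = "both") {
  .sweep("interval", intervals, function(v) {
    g <- geom; g$d12 <- v; g$d34 <- v; g
  }, E, n, seed, coords)
}

#' Acquire a tomographic scan
#'
#' Runs [transport_beam()] with a flat parallel beam at each projection angle
#' and concatenates the list-mode events. Per-angle RNG substreams are
#' derived deterministically from `seed`.
#'
#' @param geom a [scanner_geometry()].
#' @param ph a [phantom()].
#' @param E beam energy, MeV.
#' @param n_angles number of projections.
#' @param step_deg angular step, degrees.
#' @param protons_per_angle histories per projection.
#' @param seed RNG seed.
#' @param ... passed to [transport_beam()] (e.g. `straggling`, `substep`).
#' @return event data.frame (all angles concatenated).
#' @export
acquire_scan <- function(geom, ph, E = 200, n_angles = 36, step_deg = 10,
                         protons_per_angle = 1e4, seed = 1, ...) {
  if (n_angles == 0 || protons_per_angle == 0) return(.empty_events())
  angles <- (seq_len(n_angles) - 1) * step_deg
  out <- lapply(seq_along(angles), function(i)
    transport_beam(geom, ph, E0 = E, n = protons_per_angle,
                   angle_deg = angles[i], beam = "flat",
                   seed = (seed * 1000L + i) %% 2147483647L, ...))
  do.call(rbind, out)
}
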
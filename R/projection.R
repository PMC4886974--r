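# List-mode events -> WEPL sinograms: energy-to-WEPL conversion and
# straight-line-path (SLP) binning.

#' Construct a sinogram object
#'
#' @param angles projection angles, degrees.
#' @param s transaxial bin centres, mm.
#' @param wepl matrix (angles x bins) of mean WEPL, cm; `NA` where empty.
#' @param counts integer matrix of events per bin.
#' @return An object of class `pct_sinogram`.
#' @export
new_sinogram <- function(angles, s, wepl, counts) {
  stopifnot(nrow(wepl) == length(angles), ncol(wepl) == length(s),
            all(dim(wepl) == dim(counts)))
  structure(list(angles = angles, s = s, wepl = wepl, counts = counts),
            class = "pct_sinogram")
}

#' @export
print.pct_sinogram <- function(x, ...) {
  cat(sprintf("<pct_sinogram> %d angles x %d bins, %d events, WEPL range [%.2f, %.2f] cm\n",
              length(x$angles), length(x$s), sum(x$counts),
              min(x$wepl, na.rm = TRUE), max(x$wepl, na.rm = TRUE)))
  invisible(x)
}

#' Straight-line-path position at the isocenter
#'
#' Estimates each proton's transaxial position in the isocenter plane as the
#' straight line through the plane-2 and plane-3 strip centres evaluated at
#' the rotation axis.
#'
#' @param events event data.frame.
#' @param geom a [scanner_geometry()].
#' @return numeric vector, mm (`NA` for events missing a hit).
#' @export
slp_position <- function(events, geom) {
  zp <- tracker_z(geom)
  zi <- isocenter_z(geom)
  u2 <- strip_center(geom, events$u2)
  u3 <- strip_center(geom, events$u3)
  u2 + (u3 - u2) * (zi - zp[2]) / (zp[3] - zp[2])
}

#' Empty-scene WEPL calibration offset
#'
#' The WEPL inferred from (E_in, E_out) includes the tracker silicon and air
#' traversed outside the phantom. This computes that offset deterministically
#' (single proton, no phantom, scattering and straggling off) so that
#' [bin_events()] can subtract it — the simulated analogue of the empty-scan
#' calibration of a physical pCT system.
#'
#' @param geom a [scanner_geometry()].
#' @param E beam energy, MeV.
#' @return offset in cm of water.
#' @export
wepl_calibration <- function(geom, E = 200) {
  ev <- transport_beam(geom, ph = NULL, E0 = E, n = 1, beam = "pencil",
                       mcs = FALSE, straggling = FALSE)
  wepl_from_energies(ev$E_in, ev$E_out)
}

#' Bin list-mode events into a WEPL sinogram
#'
#' Per (angle, bin): the mean of [wepl_from_energies()] over unflagged events
#' whose SLP position falls in the bin (half-open `[edge, edge)` convention),
#' minus the empty-scene calibration offset. An optional per-bin 3-sigma
#' outlier cut is available (off by default).
#'
#' @param events event data.frame.
#' @param geom a [scanner_geometry()].
#' @param bin_edges transaxial bin edges, mm; the default is one bin per
#'   *half* strip pitch across the active area: SLP positions evaluated at
#'   the mid-plane of two strip-quantised hits live on a half-pitch lattice,
#'   so half-pitch bins recover the full information content of the tracker
#'   pair.
#' @param calibrate subtract the [wepl_calibration()] offset (default TRUE).
#' @param sigma_cut if finite, discard events farther than this many sds from
#'   their bin mean (one pass); default `Inf` (off).
#' @return A `pct_sinogram`. Attribute `dropped` records the number of
#'   flagged/unbinnable events.
#' @export
bin_events <- function(events, geom, bin_edges = NULL, calibrate = TRUE,
                       sigma_cut = Inf) {
  if (is.null(bin_edges)) {
    half <- geom$n_strips %/% 2L * geom$strip_pitch
    bin_edges <- seq(-half - geom$strip_pitch / 4, half + geom$strip_pitch / 4,
                     by = geom$strip_pitch / 2)
  }
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  angles <- sort(unique(events$angle))
  nb <- length(centers)
  if (nrow(events) == 0)
    return(new_sinogram(angles, centers, matrix(NA_real_, 0, nb),
                        matrix(0L, 0, nb)))
  ok <- events$flag == "ok" & !is.na(events$E_out)
  ev <- events[ok, , drop = FALSE]
  s <- slp_position(ev, geom)
  w <- wepl_from_energies(ev$E_in, ev$E_out)
  if (calibrate)
    w <- w - wepl_calibration(geom, ev$E_in[1])
  bin <- findInterval(s, bin_edges, left.open = FALSE, rightmost.closed = FALSE)
  keep <- !is.na(s) & !is.na(w) & bin >= 1 & bin <= nb
  ai <- match(ev$angle, angles)
  idx <- (bin - 1L) * length(angles) + ai      # (angle, bin) flat index
  wsum <- csum <- matrix(0, length(angles), nb)
  t1 <- tapply(w[keep], idx[keep], sum)
  t2 <- tapply(w[keep], idx[keep], length)
  ii <- as.integer(names(t1))
  wsum[ii] <- t1; csum[ii] <- t2
  if (is.finite(sigma_cut)) {
    mu <- (wsum / csum)[idx]
    sdv <- sqrt(pmax(tapply((w[keep] - mu[keep])^2, idx[keep], mean), 0))
    sdfull <- numeric(length(angles) * nb); sdfull[as.integer(names(sdv))] <- sdv
    keep <- keep & abs(w - mu) <= sigma_cut * pmax(sdfull[idx], 1e-12)
    wsum <- csum <- matrix(0, length(angles), nb)
    t1 <- tapply(w[keep], idx[keep], sum); t2 <- tapply(w[keep], idx[keep], length)
    ii <- as.integer(names(t1)); wsum[ii] <- t1; csum[ii] <- t2
  }
  mean_w <- wsum / csum
  mean_w[csum == 0] <- NA_real_
  out <- new_sinogram(angles, centers, mean_w, matrix(as.integer(csum),
                                                      length(angles), nb))
  attr(out, "dropped") <- nrow(events) - sum(keep)
  out
}

#' Fill empty sinogram bins by linear interpolation along the bin axis
#'
#' Filtered back projection needs complete rows; iterative methods instead
#' use the raw counts as weights and skip empty bins.
#'
#' @param sino a `pct_sinogram`.
#' @return a `pct_sinogram` with `NA` bins interpolated (zero outside data).
#' @export
fill_empty_bins <- function(sino) {
  w <- sino$wepl
  for (i in seq_len(nrow(w))) {
    row <- w[i, ]
    if (all(is.na(row))) { w[i, ] <- 0; next }
    if (anyNA(row))
      w[i, ] <- stats::approx(sino$s[!is.na(row)], row[!is.na(row)],
                              xout = sino$s, rule = 2)$y
  }
  new_sinogram(sino$angles, sino$s, w, sino$counts)
}

#' Write / read events as CSV
#'
#' Columnar list-mode format: `angle, u1, v1, u2, v2, u3, v3, u4, v4, x4, y4,
#' x0, E_in, E_out, wepl_true, flag`.
#' @param events event data.frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a sinogram as CSV
#'
#' Long format with columns `angle, s, wepl, counts`.
#' @param sino a `pct_sinogram`.
#' @param path file path.
#' @export
write_sinogram <- function(sino, path) {
  df <- data.frame(angle = rep(sino$angles, times = length(sino$s)),
                   s = rep(sino$s, each = length(sino$angles)),
                   wepl = as.vector(sino$wepl),
                   counts = as.vector(sino$counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  df <- utils::read.csv(path)
  angles <- sort(unique(df$angle)); s <- sort(unique(df$s))
  w <- matrix(NA_real_, length(angles), length(s))
  cnt <- matrix(0L, length(angles), length(s))
  ai <- match(df$angle, angles); si <- match(df$s, s)
  w[cbind(ai, si)] <- df$wepl; cnt[cbind(ai, si)] <- df$counts
  new_sinogram(angles, s, w, cnt)
}
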
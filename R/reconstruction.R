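# Reconstruction back-ends over the WEPL sinogram: ramp-filtered back
# projection, SART, and TV-regularized (compressed-sensing-style) iterative
# reconstruction, built on an exact Siddon ray-pixel system matrix.

#' Reconstruction image grid
#'
#' Square pixel grid in the phantom frame, centred on the rotation axis.
#' Pixel (i, j) (row = y index, column = x index) is centred at
#' `x = (j - (n+1)/2) * pixel_mm`, `y = (i - (n+1)/2) * pixel_mm`.
#'
#' @param n pixels per side.
#' @param pixel_mm pixel size, mm.
#' @return An object of class `pct_grid`.
#' @export
image_grid <- function(n = 100, pixel_mm = 1) {
  stopifnot(n >= 1, pixel_mm > 0)
  ctr <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  structure(list(n = as.integer(n), pixel_mm = pixel_mm,
                 x = ctr, y = ctr,
                 xmin = -n * pixel_mm / 2, ymin = -n * pixel_mm / 2),
            class = "pct_grid")
}

#' Wrap a value matrix as a reconstructed image
#' @param values n x n matrix of RSP values (rows = y, columns = x).
#' @param grid a [image_grid()].
#' @return An object of class `pct_image`.
#' @export
pct_image <- function(values, grid) {
  stopifnot(all(dim(values) == grid$n), all(is.finite(values)))
  structure(list(values = values, grid = grid), class = "pct_image")
}

#' @export
print.pct_image <- function(x, ...) {
  cat(sprintf("<pct_image> %dx%d px @ %g mm, RSP range [%.3f, %.3f]\n",
              x$grid$n, x$grid$n, x$grid$pixel_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

# Siddon traversal for one parallel-beam ray: offset s (mm) at angle th
# (rad). Returns pixel indices (column-major into the n x n grid) and
# intersection lengths in cm.
.siddon_ray <- function(grid, th, s) {
  n <- grid$n; px <- grid$pixel_mm
  nx <- c(cos(th), sin(th)); d <- c(-sin(th), cos(th))
  p0 <- s * nx
  bmin <- grid$xmin; bmax <- -grid$xmin
  # slab clipping to the grid bounding box
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    if (abs(d[k]) < 1e-12) {
      if (p0[k] <= bmin || p0[k] >= bmax) return(NULL)
    } else {
      t1 <- (bmin - p0[k]) / d[k]; t2 <- (bmax - p0[k]) / d[k]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  bounds <- bmin + (0:n) * px
  ts <- c(tmin, tmax)
  if (abs(d[1]) > 1e-12) ts <- c(ts, (bounds - p0[1]) / d[1])
  if (abs(d[2]) > 1e-12) ts <- c(ts, (bounds - p0[2]) / d[2])
  ts <- sort(ts[ts >= tmin - 1e-12 & ts <= tmax + 1e-12])
  len <- diff(ts)
  keep <- len > 1e-10
  if (!any(keep)) return(NULL)
  tm <- (ts[-1] + ts[-length(ts)]) / 2
  xm <- p0[1] + tm * d[1]; ym <- p0[2] + tm * d[2]
  ix <- floor((xm - bmin) / px) + 1
  iy <- floor((ym - bmin) / px) + 1
  keep <- keep & ix >= 1 & ix <= n & iy >= 1 & iy <= n
  if (!any(keep)) return(NULL)
  # column-major index into values[iy, ix]
  list(idx = (ix[keep] - 1L) * n + iy[keep], len = len[keep] / 10)  # mm -> cm
}

#' Siddon system matrix
#'
#' Sparse matrix A (rays x pixels) of exact ray-pixel intersection lengths in
#' cm, one ray per (angle, bin centre), angle-major row order. Cached per
#' (grid, angles, bins) within the session.
#'
#' @param grid a [image_grid()].
#' @param angles projection angles, degrees.
#' @param s transaxial bin centres, mm.
#' @return a `dgCMatrix` of dim `length(angles)*length(s)` x `n^2`.
#' @export
system_matrix <- function(grid, angles, s) {
  key <- paste0("A:", grid$n, ":", grid$pixel_mm, ":",
                paste(c(range(angles), length(angles)), collapse = "_"), ":",
                paste(c(range(s), length(s)), collapse = "_"))
  A <- .pct_cache[[key]]
  if (!is.null(A)) return(A)
  ii <- jj <- xx <- vector("list", length(angles) * length(s))
  r <- 0L
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    for (b in seq_along(s)) {
      r <- r + 1L
      hit <- .siddon_ray(grid, th, s[b])
      if (!is.null(hit)) {
        ii[[r]] <- rep.int(r, length(hit$idx)); jj[[r]] <- hit$idx
        xx[[r]] <- hit$len
      }
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(angles) * length(s), grid$n^2))
  assign(key, A, envir = .pct_cache)
  A
}

#' Forward projection of an image
#'
#' Line integrals of the RSP image along all (angle, bin) rays, in cm of
#' water equivalent; exact Siddon intersection lengths, linear in the image.
#'
#' @param img a `pct_image` (or n x n matrix with `grid` supplied).
#' @param angles projection angles, degrees.
#' @param s transaxial bin centres, mm.
#' @param grid grid spec when `img` is a bare matrix.
#' @return matrix (angles x bins) of projections, cm.
#' @export
forward_project <- function(img, angles, s, grid = NULL) {
  if (inherits(img, "pct_image")) { grid <- img$grid; img <- img$values }
  A <- system_matrix(grid, angles, s)
  matrix(as.numeric(A %*% as.vector(img)), length(angles), length(s),
         byrow = TRUE)
}

#' Back projection (adjoint of [forward_project()])
#' @param proj matrix (angles x bins).
#' @inheritParams forward_project
#' @return n x n image matrix.
#' @export
back_project <- function(proj, angles, s, grid) {
  A <- system_matrix(grid, angles, s)
  matrix(as.numeric(Matrix::crossprod(A, as.vector(t(proj)))), grid$n, grid$n)
}

#' Reconstruction configuration
#'
#' @param method `"fbp"`, `"sart"` or `"cs"`.
#' @param n_iterations outer iterations for the iterative methods.
#' @param lambda SART relaxation factor, in (0, 2).
#' @param tv_weight ASD-POCS TV step as a fraction of the SART update norm.
#' @param tv_inner_steps TV gradient-descent steps per outer iteration.
#' @param filter FBP filter: `"ramlak"` or `"hann"`.
#' @param tol stopping tolerance on the relative residual change.
#' @return list of class `pct_recon_config`.
#' @export
recon_config <- function(method = c("fbp", "sart", "cs"), n_iterations = 20,
                         lambda = 0.4, tv_weight = 0.5, tv_inner_steps = 10,
                         filter = c("ramlak", "hann"), tol = 1e-6) {
  method <- match.arg(method); filter <- match.arg(filter)
  stopifnot(n_iterations >= 1, lambda > 0, lambda < 2, tv_weight >= 0)
  structure(list(method = method, n_iterations = n_iterations, lambda = lambda,
                 tv_weight = tv_weight, tv_inner_steps = tv_inner_steps,
                 filter = filter, tol = tol), class = "pct_recon_config")
}

#' Filtered back projection
#'
#' Parallel-beam FBP of the central slice: per-angle ramp (Ram-Lak) filtering
#' via FFT convolution with the band-limited spatial kernel, then
#' pixel-driven back projection with linear interpolation. Output is scaled
#' so the image is in RSP units (a uniform water cylinder reconstructs to 1).
#' Empty bins are filled by [fill_empty_bins()] first.
#'
#' @param sino a `pct_sinogram` (WEPL in cm, bins in mm).
#' @param grid a [image_grid()].
#' @param filter `"ramlak"` (default) or `"hann"`.
#' @return a `pct_image`.
#' @export
reconstruct_fbp <- function(sino, grid = image_grid(), filter = c("ramlak", "hann")) {
  filter <- match.arg(filter)
  if (length(sino$angles) < 2) stop("reconstruct_fbp: need at least 2 angles")
  sino <- fill_empty_bins(sino)
  nb <- length(sino$s)
  ds <- (sino$s[2] - sino$s[1]) / 10          # bin spacing, cm
  # band-limited ramp kernel (spatial domain), length 2*nb-1
  m <- -(nb - 1):(nb - 1)
  h <- numeric(length(m))
  h[m == 0] <- 1 / (4 * ds^2)
  odd <- m %% 2 != 0
  h[odd] <- -1 / (pi * m[odd] * ds)^2
  nfft <- 2^ceiling(log2(2 * length(h)))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  if (filter == "hann") {
    # Hann taper applied over the frequency response magnitude
    f <- seq(0, nfft - 1) / nfft
    f <- pmin(f, 1 - f) * 2                   # 0..1 ramp of normalised freq
    H <- H * (0.5 + 0.5 * cos(pi * f))
  }
  filt <- matrix(0, length(sino$angles), nb)
  for (i in seq_len(nrow(filt))) {
    P <- stats::fft(c(sino$wepl[i, ], numeric(nfft - nb)))
    q <- Re(stats::fft(P * H, inverse = TRUE)) / nfft
    filt[i, ] <- q[nb:(2 * nb - 1)] * ds      # convolution sum * bin width
  }
  img <- matrix(0, grid$n, grid$n)
  X <- matrix(grid$x, grid$n, grid$n, byrow = TRUE)
  Y <- matrix(grid$y, grid$n, grid$n)
  dth <- pi / length(sino$angles)             # angles covering [0,pi) or [0,2pi)
  for (i in seq_along(sino$angles)) {
    th <- sino$angles[i] * pi / 180
    sv <- X * cos(th) + Y * sin(th)
    img <- img + stats::approx(sino$s, filt[i, ], xout = as.vector(sv),
                               rule = 2)$y
  }
  pct_image(img * dth, grid)
}

# split the system matrix into per-angle blocks with row/col sums
.sart_blocks <- function(A, n_angles, nb) {
  lapply(seq_len(n_angles), function(a) {
    rows <- ((a - 1) * nb + 1):(a * nb)
    Ab <- A[rows, , drop = FALSE]
    list(A = Ab, rs = Matrix::rowSums(Ab), cs = Matrix::colSums(Ab))
  })
}

# one full SART sweep (all angle blocks); p is the length-(rays) data vector
# with NA for empty bins
.sart_sweep <- function(x, blocks, p, nb, lambda) {
  for (a in seq_along(blocks)) {
    b <- blocks[[a]]
    rows <- ((a - 1) * nb + 1):(a * nb)
    pb <- p[rows]
    use <- !is.na(pb) & b$rs > 0
    if (!any(use)) next
    r <- numeric(nb)
    r[use] <- (pb[use] - as.numeric(b$A[use, , drop = FALSE] %*% x)) / b$rs[use]
    upd <- as.numeric(Matrix::crossprod(b$A, r))
    cs <- b$cs
    x <- x + lambda * upd / pmax(cs, 1e-12)
  }
  x
}

#' SART reconstruction
#'
#' Simultaneous algebraic reconstruction technique with per-angle blocks,
#' relaxation `lambda`, a nonnegativity clamp after each full iteration, and
#' zero weight for empty bins. A divergence detector (residual growing for 5
#' consecutive iterations) stops early with a warning.
#'
#' @param sino a `pct_sinogram`.
#' @param grid a [image_grid()].
#' @param cfg a [recon_config()].
#' @param x0 optional initial image matrix (default zero).
#' @return a `pct_image` with attribute `residuals` (per-iteration relative
#'   data residuals).
#' @export
reconstruct_sart <- function(sino, grid = image_grid(),
                             cfg = recon_config("sart"), x0 = NULL) {
  nb <- length(sino$s)
  A <- system_matrix(grid, sino$angles, sino$s)
  blocks <- .sart_blocks(A, length(sino$angles), nb)
  p <- as.vector(t(sino$wepl))
  p[as.vector(t(sino$counts)) == 0] <- NA
  x <- if (is.null(x0)) numeric(grid$n^2) else as.vector(x0)
  ok <- !is.na(p)
  pnorm <- sqrt(sum(p[ok]^2))
  res <- numeric(0); grow <- 0
  for (it in seq_len(cfg$n_iterations)) {
    x <- .sart_sweep(x, blocks, p, nb, cfg$lambda)
    x <- pmax(x, 0)
    r <- sqrt(sum((p[ok] - as.numeric(A[ok, , drop = FALSE] %*% x))^2)) /
      max(pnorm, 1e-12)
    grow <- if (length(res) && r > res[length(res)] * 1.01) grow + 1 else 0
    res <- c(res, r)
    if (grow >= 5) {
      warning("reconstruct_sart: residual grew for 5 consecutive iterations; stopping")
      break
    }
    if (length(res) > 1 && abs(res[length(res) - 1] - r) < cfg$tol) break
  }
  out <- pct_image(matrix(x, grid$n, grid$n), grid)
  attr(out, "residuals") <- res
  out
}

#' Isotropic total variation of an image matrix
#' @param x numeric matrix.
#' @param eps smoothing constant.
#' @return scalar TV.
#' @export
total_variation <- function(x, eps = 1e-8) {
  dx <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  dy <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
  n <- nrow(x); m <- ncol(x)
  sum(sqrt(dx[-n, ]^2 + dy[, -m]^2 + eps))
}

# gradient of the smoothed isotropic TV
.tv_grad <- function(x, eps = 1e-8) {
  n <- nrow(x); m <- ncol(x)
  xp <- cbind(x, x[, m]); xp <- rbind(xp, xp[n, ])  # replicate edges
  dx <- xp[1:n, 2:(m + 1)] - x                      # forward diffs
  dy <- xp[2:(n + 1), 1:m] - x
  mag <- sqrt(dx^2 + dy^2 + eps)
  g <- -(dx + dy) / mag
  gx <- dx / mag; gy <- dy / mag
  g[, 2:m] <- g[, 2:m] + gx[, 1:(m - 1)]
  g[2:n, ] <- g[2:n, ] + gy[1:(n - 1), ]
  g
}

#' TV-regularized (compressed-sensing) reconstruction
#'
#' ASD-POCS-style alternation: each outer iteration performs one SART sweep
#' (data consistency, nonnegativity clamp) followed by `tv_inner_steps` of
#' steepest-descent on the smoothed isotropic TV, with step size
#' `tv_weight * ||SART update||` shrinking geometrically within the descent
#' block. With `tv_weight = 0` the method reduces exactly to SART.
#'
#' @inheritParams reconstruct_sart
#' @return a `pct_image` with attribute `residuals`.
#' @export
reconstruct_cs <- function(sino, grid = image_grid(),
                           cfg = recon_config("cs"), x0 = NULL) {
  nb <- length(sino$s)
  A <- system_matrix(grid, sino$angles, sino$s)
  blocks <- .sart_blocks(A, length(sino$angles), nb)
  p <- as.vector(t(sino$wepl))
  p[as.vector(t(sino$counts)) == 0] <- NA
  x <- if (is.null(x0)) numeric(grid$n^2) else as.vector(x0)
  ok <- !is.na(p)
  pnorm <- sqrt(sum(p[ok]^2))
  res <- numeric(0); grow <- 0
  for (it in seq_len(cfg$n_iterations)) {
    xprev <- x
    x <- .sart_sweep(x, blocks, p, nb, cfg$lambda)
    x <- pmax(x, 0)
    dp <- sqrt(sum((x - xprev)^2))
    if (cfg$tv_weight > 0 && dp > 0) {
      xm <- matrix(x, grid$n, grid$n)
      step <- cfg$tv_weight * dp
      for (k in seq_len(cfg$tv_inner_steps)) {
        g <- .tv_grad(xm)
        gn <- sqrt(sum(g^2))
        if (gn < 1e-12) break
        xm <- xm - step * g / gn
        step <- step * 0.9
      }
      x <- pmax(as.vector(xm), 0)
    }
    r <- sqrt(sum((p[ok] - as.numeric(A[ok, , drop = FALSE] %*% x))^2)) /
      max(pnorm, 1e-12)
    grow <- if (length(res) && r > res[length(res)] * 1.01) grow + 1 else 0
    res <- c(res, r)
    if (grow >= 5) {
      warning("reconstruct_cs: residual grew for 5 consecutive iterations; stopping")
      break
    }
  }
  out <- pct_image(matrix(x, grid$n, grid$n), grid)
  attr(out, "residuals") <- res
  out
}

#' Reconstruct with a chosen method
#' @param sino a `pct_sinogram`.
#' @param grid a [image_grid()].
#' @param cfg a [recon_config()].
#' @return a `pct_image`.
#' @export
reconstruct <- function(sino, grid = image_grid(), cfg = recon_config()) {
  switch(cfg$method,
         fbp = reconstruct_fbp(sino, grid, cfg$filter),
         sart = reconstruct_sart(sino, grid, cfg),
         cs = reconstruct_cs(sino, grid, cfg))
}
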
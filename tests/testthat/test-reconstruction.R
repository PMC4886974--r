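test_that("forward and back projection are exact adjoints", {
  set.seed(42)
  g <- image_grid(32, 2)
  angles <- seq(0, 168, by = 12)
  s <- seq(-30, 30, by = 2)
  x <- matrix(runif(32^2), 32, 32)
  y <- matrix(runif(length(angles) * length(s)), length(angles), length(s))
  lhs <- sum(forward_project(x, angles, s, g) * y)
  rhs <- sum(x * back_project(y, angles, s, g))
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-6)
})

test_that("forward projection reproduces closed-form disk chords", {
  g <- image_grid(201, 0.5)
  disk <- ground_truth_image(water_phantom(30), g, supersample = 5)
  s <- seq(-49.5, 49.5, by = 1)
  pr <- forward_project(disk, c(0, 33), s, g)
  chord <- 2 * sqrt(pmax(30^2 - s^2, 0)) / 10
  interior <- abs(s) < 25
  for (i in 1:2)
    expect_lt(max(abs(pr[i, interior] - chord[interior]) / chord[interior]),
              0.01)
  # linearity: zero image projects to zero
  z <- forward_project(matrix(0, 201, 201), c(0, 33), s, g)
  expect_equal(max(abs(z)), 0)
})

test_that("transposing the image swaps the 0- and 90-degree views", {
  set.seed(7)
  g <- image_grid(40, 1)
  v <- matrix(runif(1600), 40, 40)
  s <- seq(-15.5, 15.5, by = 1)
  expect_equal(as.numeric(forward_project(t(v), 0, s, g)),
               as.numeric(forward_project(v, 90, s, g)), tolerance = 1e-12)
})

test_that("FBP reconstructs a uniform water disk at RSP 1", {
  ph <- water_phantom(30)
  sino <- analytic_sinogram(ph, seq(0, 178, by = 2), seq(-49.5, 49.5, by = 1))
  grid <- image_grid(101, 1)
  img <- reconstruct_fbp(sino, grid)
  inside <- roi_mask(grid, c(0, 0), 20)
  expect_equal(mean(img$values[inside]), 1.0, tolerance = 0.02)
  # zero sinogram gives a zero image
  z <- new_sinogram(sino$angles, sino$s, 0 * sino$wepl, sino$counts)
  expect_equal(max(abs(reconstruct_fbp(z, grid)$values)), 0)
  expect_error(reconstruct_fbp(new_sinogram(0, sino$s,
                                            sino$wepl[1, , drop = FALSE],
                                            sino$counts[1, , drop = FALSE]),
                               grid), "2 angles")
})

test_that("FBP + forward projection round-trips a smooth phantom", {
  ph <- water_phantom(30)
  s <- seq(-49.5, 49.5, by = 1)
  sino <- analytic_sinogram(ph, seq(0, 178, by = 2), s)
  grid <- image_grid(101, 1)
  img <- reconstruct_fbp(sino, grid)
  re <- forward_project(img, sino$angles, s, grid)
  interior <- abs(s) < 22
  dev <- abs(re[, interior] - sino$wepl[, interior]) / sino$wepl[, interior]
  expect_lt(max(dev), 0.05)
})

test_that("SART converges on noise-free data and honours its knobs", {
  ph <- toy_phantom()
  grid <- image_grid(32, 2)
  angles <- seq(0, 170, by = 10); s <- seq(-31, 31, by = 2)
  # consistent system: data generated by the projector itself, so the
  # residual floor is zero and the test isolates solver convergence
  truth <- ground_truth_image(ph, grid)
  p <- forward_project(truth, angles, s, grid)
  sino <- new_sinogram(angles, s, p, matrix(1L, length(angles), length(s)))
  img <- reconstruct_sart(sino, grid, recon_config("sart", n_iterations = 100,
                                                   lambda = 1))
  expect_lt(tail(attr(img, "residuals"), 1), 0.01)
  expect_true(all(img$values >= 0))
  # near-zero relaxation leaves the zero initialization untouched
  img0 <- reconstruct_sart(sino, grid, recon_config("sart", n_iterations = 1,
                                                    lambda = 1e-9))
  expect_lt(max(abs(img0$values)), 1e-6)
})

test_that("one pixel and one ray solve in closed form", {
  g1 <- image_grid(1, 10)
  sino <- new_sinogram(0, 0, matrix(0.7, 1, 1), matrix(1L, 1, 1))
  img <- reconstruct_sart(sino, g1, recon_config("sart", n_iterations = 1,
                                                 lambda = 1))
  # chord length is 1 cm, so one relaxed step lands on p / L = 0.7
  expect_equal(as.numeric(img$values), 0.7, tolerance = 1e-12)
})

test_that("TV regularization degenerates to SART and reduces TV", {
  ph <- toy_phantom()
  grid <- image_grid(32, 2)
  sino <- analytic_sinogram(ph, seq(0, 170, by = 10), seq(-31, 31, by = 2))
  sa <- reconstruct_sart(sino, grid, recon_config("sart", n_iterations = 15,
                                                  lambda = 0.5))
  cs0 <- reconstruct_cs(sino, grid, recon_config("cs", n_iterations = 15,
                                                 lambda = 0.5, tv_weight = 0))
  expect_equal(cs0$values, sa$values, tolerance = 1e-12)
  cs <- reconstruct_cs(sino, grid, recon_config("cs", n_iterations = 15,
                                                lambda = 0.5, tv_weight = 0.5))
  expect_lte(total_variation(cs$values), total_variation(sa$values))
})

test_that("the reconstruct() dispatcher routes by method", {
  ph <- toy_phantom()
  grid <- image_grid(32, 2)
  sino <- analytic_sinogram(ph, seq(0, 170, by = 10), seq(-31, 31, by = 2))
  f <- reconstruct(sino, grid, recon_config("fbp"))
  s <- reconstruct(sino, grid, recon_config("sart", n_iterations = 2))
  expect_s3_class(f, "pct_image")
  expect_s3_class(s, "pct_image")
  expect_false(identical(f$values, s$values))
})
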
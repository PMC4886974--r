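# Shared fixtures, built in code at test time.

# a phantom with no inserts (pure water body)
water_phantom <- function(R = 30) {
  phantom(body_radius = R,
          inserts = data.frame(material = character(0), x = numeric(0),
                               y = numeric(0), radius = numeric(0),
                               label = character(0)),
          background_annulus = c(R - 10, R - 4))
}

# a small phantom for algebraic toy problems
toy_phantom <- function() {
  phantom(body_radius = 25,
          inserts = data.frame(material = "bone", x = 5, y = 5, radius = 6,
                               label = "bone-1"),
          background_annulus = c(15, 21))
}

# Scaled imaging studies shared by the acceptance tests: 72 projections in
# 5-degree steps, 1e4 protons per projection, reconstructed with all three
# methods on the half-pitch grid. Cached so both criteria reuse one run.
.study_cache <- new.env(parent = emptyenv())
get_study <- function(E) {
  key <- as.character(E)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- run_study(
      scanner_geometry(), phantom(), E = E, n_angles = 72, step_deg = 5,
      protons_per_angle = 1e4, grid = image_grid(201, 0.5),
      seed = if (E == 200) 1 else 2)
  }
  .study_cache[[key]]
}
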
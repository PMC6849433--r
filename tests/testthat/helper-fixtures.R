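# Shared fixtures, built once per test run and memoized (matrix assembly is
# the expensive step).

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# tiny system: 16x16 grid, 8 detectors -- oracle-scale checks
tiny_system <- function() memo("tiny", {
  grid <- image_grid(16, 16, 0.5)
  geom <- detection_geometry(30, 270, 8)
  M <- build_model_matrix(grid, geom)
  list(grid = grid, geom = geom, M = M)
})

# small normalized system: 8x8 grid, 4 detectors -- convex-oracle scale
small_system <- function() memo("small", {
  grid <- image_grid(8, 8, 1)
  geom <- detection_geometry(20, 270, 4)
  M <- normalize_model_matrix(build_model_matrix(grid, geom))
  ph <- generate_disk_phantom(grid, radius = 2.5, amplitude = 1)
  p <- add_projection_noise(forward_project(M, ph), 0.1, 3)
  list(grid = grid, geom = geom, M = M, phantom = ph, sino = p)
})

# small system rescaled to unit spectral-norm bound: algebraic limit checks
# (least-squares reduction, cartoon collapse) converge quickly there
small_system_unit <- function() memo("small_unit", {
  fx <- small_system()
  fx$M$matrix <- fx$M$matrix / 160
  fx$M$scale <- fx$M$scale * 160
  fx$sino <- add_projection_noise(
    forward_project(fx$M, fx$phantom), 0.1, 3)
  fx
})

# reconstruction fixture: 64x64 vessel phantom, 128 detectors, noiseless
fixture_64 <- function() memo("fix64", {
  grid <- image_grid(64, 64, 0.1)
  geom <- detection_geometry(40, 270, 128)
  M <- normalize_model_matrix(build_model_matrix(grid, geom))
  ph <- generate_vessel_phantom(grid, vessel_phantom_params(seed = 1))
  list(grid = grid, geom = geom, M = M, phantom = ph,
       sino = forward_project(M, ph))
})
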
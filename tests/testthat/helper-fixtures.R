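# Shared small fixtures for the test suite. Everything is generated in code.

default_p <- model_parameters()

# A smooth random field on a grid: white noise passed through a few implicit
# diffusion solves, rescaled to [lo, hi].
smooth_random_field <- function(grid, seed = 1, lo = 0, hi = 1, alpha = 30) {
  set.seed(seed)
  u <- matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
  for (k in 1:3) u <- angiophase:::solve_helmholtz(u, alpha, grid)
  u <- (u - min(u)) / (max(u) - min(u))
  lo + (hi - lo) * u
}

# A quasi-1D horizontal grid for front-propagation tests.
strip_grid <- function(nx = 512, ny = 4, width = 1024, height = 8) {
  sim_grid(nx, ny, width = width, height = height)
}

# State with a vertical tumor interface at x = x0 (tumor on the left) and
# uniform nutrient.
front_state <- function(grid, x0, sigma0, p = default_p) {
  phi <- matrix(0.5 * (1 + tanh((x0 - grid$x) / (sqrt(2) * p$lambda_phi))),
                grid$nx, grid$ny)
  field_state(phi = phi,
              sigma = matrix(sigma0, grid$nx, grid$ny),
              c = matrix(-1, grid$nx, grid$ny),
              f = matrix(0, grid$nx, grid$ny),
              t = 0, grid = grid)
}

# x-position of the phi = 0.5 crossing along the first row.
front_position <- function(phi, grid) {
  prof <- phi[, 1]
  j <- which(prof >= 0.5 & c(prof[-1], 0) < 0.5)[1]
  grid$x[j] + (prof[j] - 0.5) / (prof[j] - prof[j + 1]) * grid$dx
}

# Uniform state builder on a grid.
uniform_state <- function(grid, phi = 0, sigma = 0.45, cc = -1, f = 0) {
  mk <- function(v) matrix(v, grid$nx, grid$ny)
  field_state(mk(phi), mk(sigma), mk(cc), mk(f), t = 0, grid = grid)
}
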
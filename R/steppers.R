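#' Numerical scheme options
#'
#' Collects the tunable numerics constants used by the semi-implicit time
#' steppers and the adaptive step-size controller.
#'
#' @param dt_init Initial time step.
#' @param dt_min,dt_max Hard bounds on the adaptive step (non-dimensional
#'   time). The controller aborts if a halving would cross `dt_min`.
#' @param tol_up Max-norm field change per step above which the step size is
#'   halved.
#' @param tol_down Max-norm change below which the step size grows.
#' @param growth Step growth factor applied below `tol_down`.
#' @param a_stab Convexity-splitting stabilizer for the Cahn-Hilliard update
#'   (must dominate `max |mu_c'| = 2` on `[-1, 1]`).
#' @param reaction_lipschitz Bound on the local stiffness of the tumor
#'   chemical potential, used to pick the number of explicit reaction
#'   substeps.
#' @return A named list of class `numerics_options`.
#' @export
numerics_options <- function(dt_init = 1e-2, dt_min = 1e-4, dt_max = 5,
                             tol_up = 5e-2, tol_down = 5e-3, growth = 1.2,
                             a_stab = 2, reaction_lipschitz = 4) {
  structure(list(dt_init = dt_init, dt_min = dt_min, dt_max = dt_max,
                 tol_up = tol_up, tol_down = tol_down, growth = growth,
                 a_stab = a_stab, reaction_lipschitz = reaction_lipschitz),
            class = "numerics_options")
}

# Positive part of c*H(c): the effective capillary indicator used in the
# nutrient-production and TAF-uptake terms. Clamping at zero keeps the
# pointwise reaction updates provably inside [0, 1].
capillary_indicator <- function(c, p) {
  pmax(c * smoothed_heaviside_H(c, p), 0)
}

#' Advance the tumor phase field one step
#'
#' Integrates `d(phi)/dt = M_phi (lambda_phi^2 Lap(phi) - mu_phi(phi, sigma))`
#' by Lie splitting: the pointwise reaction ODE is advanced with
#' stability-limited explicit substeps (step count chosen so that
#' `dt_sub * M_phi * L <= 1/2`, `L` the stiffness bound), then the linear
#' diffusion is solved exactly (implicitly) in the cosine basis. Both uniform
#' bulk states `phi = 0, 1` are preserved for any nutrient field.
#'
#' @param state A [field_state()].
#' @param grid The [sim_grid()].
#' @param dt Time step (> 0).
#' @param p A [model_parameters()] object.
#' @param opts A [numerics_options()] list.
#' @return The updated `phi` matrix.
#' @export
step_tumor <- function(state, grid, dt, p = model_parameters(),
                       opts = numerics_options()) {
  stopifnot(dt > 0)
  phi <- state$phi
  nsub <- max(1L, ceiling(dt * p$M_phi * opts$reaction_lipschitz / 0.5))
  dts <- dt / nsub
  m6 <- 6 * tilting_m(state$sigma, p)  # frozen during the reaction substeps
  for (k in seq_len(nsub)) {
    omp <- 1 - phi
    phi <- phi - dts * p$M_phi * (phi * omp * (2 * (omp - phi) + m6))
  }
  phi <- solve_helmholtz(phi, dt * p$M_phi * p$lambda_phi^2, grid)
  if (anyNA(phi)) stop("NaN in tumor step")
  phi
}

#' Advance the nutrient field one step
#'
#' Integrates `d(sigma)/dt = div(D_sigma grad sigma)
#' + V_pc (1 - sigma) c H(c) S - V_uT sigma phi - V_uH sigma H(1 - phi)`.
#' The reaction part is linear in `sigma` with frozen coefficients and is
#' integrated exactly (exponential update), which preserves `[0, 1]`; the
#' diffusion is then solved implicitly. `S` is the network-functionality
#' statistic scaling nutrient delivery.
#'
#' @inheritParams step_tumor
#' @param S Network functionality statistic in `(0, 1]`.
#' @param cHc Optional precomputed `max(c H(c), 0)` field (an optimization for
#'   runs in which the capillary field is frozen).
#' @return The updated `sigma` matrix.
#' @export
step_nutrient <- function(state, grid, dt, S = 1, p = model_parameters(),
                          cHc = NULL) {
  stopifnot(dt > 0, S > 0, S <= 1)
  if (is.null(cHc)) cHc <- capillary_indicator(state$c, p)
  A <- p$V_pc * cHc * S
  U <- p$V_uT * state$phi + p$V_uH * smoothed_heaviside_H(1 - state$phi, p)
  B <- A + U
  s_inf <- A / pmax(B, 1e-300)
  sigma <- s_inf + (state$sigma - s_inf) * exp(-B * dt)
  sigma <- solve_helmholtz(sigma, dt * p$D_sigma, grid)
  if (anyNA(sigma)) stop("NaN in nutrient step")
  sigma
}

#' Advance the capillary phase field one step
#'
#' Integrates the reactive Cahn-Hilliard equation
#' `dc/dt = div(M_c grad(mu_c(c) - lambda_c^2 Lap c)) + B_p(f) c H(c)`
#' with a convexity-splitting semi-implicit scheme: the biharmonic term and a
#' stabilizing `a_stab * Lap` are implicit, the double-well remainder and the
#' endothelial proliferation reaction explicit. With `B_p = 0` the discrete
#' update conserves the total mass of `c` to machine precision.
#'
#' @inheritParams step_tumor
#' @return The updated `c` matrix.
#' @export
step_capillary <- function(state, grid, dt, p = model_parameters(),
                           opts = numerics_options()) {
  stopifnot(dt > 0)
  cfld <- state$c
  a <- opts$a_stab
  react <- proliferation_Bp(state$f, p) * cfld * smoothed_heaviside_H(cfld, p)
  rhs <- cfld + dt * p$M_c * laplacian(mu_c(cfld) - a * cfld, grid) + dt * react
  cnew <- solve_biharmonic(rhs, dt * p$M_c * a, dt * p$M_c * p$lambda_c^2, grid)
  if (anyNA(cnew)) stop("NaN in capillary step")
  cnew
}

#' Advance the TAF field one step
#'
#' Integrates `df/dt = div(D_f grad f) + phi (1 - f) G(sigma) - B_u f c H(c)`.
#' As for the nutrient, the reaction is linear in `f` with frozen coefficients
#' and is advanced with an exact exponential update (range-preserving), then
#' the diffusion is solved implicitly.
#'
#' @inheritParams step_nutrient
#' @return The updated `f` matrix.
#' @export
step_taf <- function(state, grid, dt, p = model_parameters(), cHc = NULL) {
  stopifnot(dt > 0)
  if (is.null(cHc)) cHc <- capillary_indicator(state$c, p)
  A <- state$phi * secretion_G(state$sigma, p)
  B <- A + p$B_u * cHc
  f_inf <- A / pmax(B, 1e-300)
  f <- f_inf + (state$f - f_inf) * exp(-B * dt)
  f <- solve_helmholtz(f, dt * p$D_f, grid)
  if (anyNA(f)) stop("NaN in TAF step")
  f
}

#' Adaptive time-step controller
#'
#' Halves the step on a solver failure or when the maximum field change of
#' the last step exceeded `tol_up`; grows it by `growth` when the change was
#' below `tol_down`; clamps to `[dt_min, dt_max]`; and additionally caps the
#' step so that no tip cell can move more than half its radius,
#' `dt <= R / (2 * tec_speed)`.
#'
#' @param prev_dt Previous step size (> 0).
#' @param diagnostics List with entries `solver_failed` (flag), `max_change`
#'   (max-norm change over all fields in the last step) and `tec_speed`
#'   (largest active-TEC speed, 0 if none).
#' @param p A [model_parameters()] object (supplies the TEC radius).
#' @param opts A [numerics_options()] list.
#' @return The next step size.
#' @export
adapt_dt <- function(prev_dt, diagnostics, p = model_parameters(),
                     opts = numerics_options()) {
  stopifnot(prev_dt > 0)
  failed <- isTRUE(diagnostics$solver_failed)
  chg <- diagnostics$max_change
  dt <- prev_dt
  if (failed || (is.finite(chg) && chg > opts$tol_up)) {
    dt <- prev_dt / 2
  } else if (is.finite(chg) && chg < opts$tol_down) {
    dt <- prev_dt * opts$growth
  }
  dt <- min(dt, opts$dt_max)
  ts <- diagnostics$tec_speed
  if (!is.null(ts) && is.finite(ts) && ts > 0) dt <- min(dt, p$R / (2 * ts))
  if (dt < opts$dt_min) {
    if (failed) stop("adaptive time step underflow below dt_min")
    dt <- opts$dt_min
  }
  dt
}

#' Discrete tumor free energy
#'
#' `sum dx dy [ lambda_phi^2 |grad phi|^2 / 2 + g(phi) + m(sigma) h(phi) ]`.
#' With the nutrient frozen, the continuous tumor equation is the gradient
#' flow of this functional, so the discrete energy should be non-increasing
#' along [step_tumor()] trajectories.
#'
#' @param phi,sigma Field matrices.
#' @param grid The [sim_grid()].
#' @param p A [model_parameters()] object.
#' @return Scalar energy.
#' @export
tumor_free_energy <- function(phi, sigma, grid, p = model_parameters()) {
  gx <- gradient_x(phi, grid)
  gy <- gradient_y(phi, grid)
  dens <- 0.5 * p$lambda_phi^2 * (gx^2 + gy^2) +
    double_well_g(phi) + tilting_m(sigma, p) * tilt_shape_h(phi)
  sum(dens) * grid$dx * grid$dy
}
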
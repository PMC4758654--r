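#' Tumor double-well potential
#'
#' Symmetric double-well `g(phi) = phi^2 (1 - phi)^2` with minima at the two
#' bulk states `phi = 0` (host) and `phi = 1` (tumor).
#'
#' @param phi Tumor phase field value(s).
#' @return Energy density, same shape as `phi`.
#' @export
double_well_g <- function(phi) phi^2 * (1 - phi)^2

#' Tilt shape function
#'
#' `h(phi) = phi^2 (3 - 2*phi)`, the interpolant whose derivative vanishes at
#' both wells, so tilting the potential moves the energy levels of the bulk
#' states without moving their location.
#'
#' @param phi Tumor phase field value(s).
#' @return Dimensionless weight in `[0, 1]` for `phi` in `[0, 1]`.
#' @export
tilt_shape_h <- function(phi) phi^2 * (3 - 2 * phi)

#' Nutrient-dependent tilting function
#'
#' `m(sigma) = -(2 / (3.01*pi)) * atan(15 * (sigma - sigma_hv))`. Bounded by
#' `1/3.01 < 1/3`, which keeps both wells of the tilted potential as local
#' minima for every nutrient level. `m > 0` (host favoured, tumor regresses)
#' when `sigma < sigma_hv`; `m < 0` (tumor favoured) above the threshold.
#'
#' @param sigma Nutrient concentration value(s).
#' @param p A [model_parameters()] object.
#' @return Dimensionless tilt, `|m| < 1/3`.
#' @export
tilting_m <- function(sigma, p = model_parameters()) {
  -(2 / (3.01 * pi)) * atan(15 * (sigma - p$sigma_hv))
}

#' Tumor chemical potential
#'
#' Derivative of the tilted double-well `g(phi) + m(sigma) h(phi)` with
#' respect to `phi`: `2*phi*(1-phi)*(1-2*phi) + 6*m(sigma)*phi*(1-phi)`.
#' Vanishes at `phi = 0` and `phi = 1` for any `sigma`, so both constant bulk
#' states are equilibria of the local dynamics.
#'
#' @param phi Tumor phase field value(s).
#' @param sigma Nutrient concentration value(s), recycled against `phi`.
#' @param p A [model_parameters()] object.
#' @return Chemical potential, same shape as `phi`.
#' @export
mu_phi <- function(phi, sigma, p = model_parameters()) {
  2 * phi * (1 - phi) * (1 - 2 * phi) + 6 * tilting_m(sigma, p) * phi * (1 - phi)
}

#' Capillary chemical potential
#'
#' Derivative `mu_c(c) = c^3 - c` of the symmetric quartic double-well
#' `c^4/4 - c^2/2` with minima at `c = -1` (no vessel) and `c = 1` (vessel).
#'
#' @param c Capillary phase field value(s).
#' @return Chemical potential, same shape as `c`.
#' @export
mu_c <- function(c) c^3 - c

#' Endothelial proliferation rate
#'
#' Linear in the TAF level `f` up to the saturation threshold `f_p`, constant
#' `B_p * f_p` above it. Continuous, nondecreasing and `B_p`-Lipschitz.
#'
#' @param f TAF concentration value(s), nonnegative.
#' @param p A [model_parameters()] object.
#' @return Proliferation rate(s).
#' @export
proliferation_Bp <- function(f, p = model_parameters()) {
  p$B_p * pmin(f, p$f_p)
}

#' TAF secretion rate
#'
#' Bell-shaped function of the nutrient level, centred mid-hypoxia at
#' `(sigma_nh + sigma_hv)/2`: `G(sigma) = G_amp * exp(-125 (sigma - center)^2)`.
#' Encodes that TAF is released chiefly by hypoxic tumor cells: cells with
#' ample nutrient do not signal and necrotic cells cannot.
#'
#' @param sigma Nutrient concentration value(s).
#' @param p A [model_parameters()] object.
#' @return Secretion rate(s), maximal (`= G_amp`) at the hypoxic midpoint.
#' @export
secretion_G <- function(sigma, p = model_parameters()) {
  center <- (p$sigma_nh + p$sigma_hv) / 2
  p$G_amp * exp(-125 * (sigma - center)^2)
}

#' Smoothed Heaviside step
#'
#' `H(x) = (1 + tanh(x / eps_H)) / 2`: a monotone sigmoid with `H(0) = 1/2`
#' saturating to 0/1 within a few multiples of `eps_H`. Used to gate the
#' nutrient source onto the capillary interior (`c > 0`) and the host-tissue
#' uptake onto `phi < 1`.
#'
#' @param x Value(s).
#' @param p A [model_parameters()] object (supplies `eps_H`).
#' @return Weight(s) in `(0, 1)`.
#' @export
smoothed_heaviside_H <- function(x, p = model_parameters()) {
  (1 + tanh(x / p$eps_H)) / 2
}

#' TEC migration speed modulation
#'
#' `J(phi) = 0.45 * (tanh(50 * (0.5 - phi)) + 1) + 0.1`. Approximately 1 in
#' host tissue and 0.1 deep inside the tumor: sprouts can penetrate the
#' lesion, but much more slowly than they migrate through stroma.
#'
#' @param phi Tumor phase field value(s).
#' @return Velocity modulation in `(0.1, 1)`, strictly decreasing in `phi`.
#' @export
migration_J <- function(phi) 0.45 * (tanh(50 * (0.5 - phi)) + 1) + 0.1

#' Chemotactic TEC velocity
#'
#' `v = chi * (grad_f / |grad_f|) * J(phi)`: unit-normalized TAF gradient
#' scaled by the chemotactic constant and the tumor-penetration modulation.
#' Returns the zero vector when `|grad_f|` falls below `p$grad_tol` (a cell
#' with no cue does not move).
#'
#' @param grad_f Numeric 2-vector, local TAF gradient.
#' @param phi Local tumor phase value.
#' @param p A [model_parameters()] object.
#' @return Numeric 2-vector velocity with magnitude at most `chi`.
#' @export
chemo_velocity <- function(grad_f, phi, p = model_parameters()) {
  gnorm <- sqrt(sum(grad_f^2))
  if (!is.finite(gnorm) || gnorm < p$grad_tol) return(c(0, 0))
  p$chi * (grad_f / gnorm) * migration_J(phi)
}

#' TEC template function
#'
#' Radial profile `tanh((R - r) / eps_template)` used to imprint a circular
#' tip cell into the capillary phase field: approximately `+1` inside the
#' cell, `-1` outside, crossing 0 exactly at the cell boundary `r = R`.
#'
#' @param r Distance(s) from the TEC centre, nonnegative.
#' @param p A [model_parameters()] object.
#' @return Phase value(s) in `(-1, 1)`.
#' @export
tec_template <- function(r, p = model_parameters()) {
  tanh((p$R - r) / p$eps_template)
}
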
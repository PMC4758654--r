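#' Model parameters for the coupled tumor-angiogenesis model
#'
#' Builds the full parameter set of the model with defaults equal to the
#' in-silico values used throughout the package. All quantities are
#' non-dimensional; `L_scale` (micrometres per length unit) and `T_scale`
#' (seconds per time unit) convert to physical units.
#'
#' @param M_phi Tumor mobility.
#' @param lambda_phi Tumor interface-width constant.
#' @param D_sigma Nutrient diffusivity.
#' @param V_pc Nutrient production rate at capillaries.
#' @param V_uT,V_uH Nutrient uptake rates of tumor and host tissue.
#' @param sigma_nh,sigma_hv Necrotic-hypoxic and hypoxic-viable nutrient
#'   thresholds; must satisfy `0 < sigma_nh < sigma_hv < 1`.
#' @param f_p TAF level at which endothelial proliferation saturates.
#' @param M_c Capillary mobility.
#' @param lambda_c Capillary interface-width constant.
#' @param B_p Endothelial proliferation rate.
#' @param R Tip endothelial cell (TEC) radius.
#' @param c_act,f_act TEC activation thresholds on the capillary field and the
#'   TAF field.
#' @param chi Chemotactic constant (maximum TEC speed).
#' @param delta4 Dll4 effective distance: no new TEC may activate within this
#'   distance of an active TEC (lateral inhibition).
#' @param D_f TAF diffusivity.
#' @param B_u TAF uptake rate by capillaries.
#' @param L_scale Length scale, micrometres per non-dimensional unit.
#' @param T_scale Time scale, seconds per non-dimensional unit.
#' @param eps_H Half-width of the smoothed Heaviside step.
#' @param G_amp Amplitude of the TAF secretion rate `G(sigma)`.
#' @param eps_template Interface width of the TEC template function.
#' @param grad_tol Gradient magnitude below which the chemotactic velocity is
#'   taken as zero.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_parameters()
#' p$chi
#' @export
model_parameters <- function(M_phi = 0.3, lambda_phi = 22, D_sigma = 30,
                             V_pc = 1, V_uT = 6e-3, V_uH = 6e-4,
                             sigma_nh = 0.2, sigma_hv = 0.4, f_p = 0.3,
                             M_c = 1, lambda_c = 1, B_p = 1.401, R = 4,
                             c_act = 0.9, f_act = 0.001, chi = 7.28,
                             delta4 = 80, D_f = 100, B_u = 6.25,
                             L_scale = 1.25, T_scale = 1562.5,
                             eps_H = 0.1,
                             G_amp = 0.02 / sqrt(2 * pi),
                             eps_template = 1,
                             grad_tol = 1e-12) {
  p <- list(M_phi = M_phi, lambda_phi = lambda_phi, D_sigma = D_sigma,
            V_pc = V_pc, V_uT = V_uT, V_uH = V_uH,
            sigma_nh = sigma_nh, sigma_hv = sigma_hv, f_p = f_p,
            M_c = M_c, lambda_c = lambda_c, B_p = B_p, R = R,
            c_act = c_act, f_act = f_act, chi = chi, delta4 = delta4,
            D_f = D_f, B_u = B_u, L_scale = L_scale, T_scale = T_scale,
            eps_H = eps_H, G_amp = G_amp, eps_template = eps_template,
            grad_tol = grad_tol)
  class(p) <- "model_params"
  validate_model_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks strict positivity of all rates, diffusivities, mobilities and
#' thresholds, and the ordering `0 < sigma_nh < sigma_hv < 1`.
#'
#' @param p A `model_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_model_parameters <- function(p) {
  pos <- c("M_phi", "lambda_phi", "D_sigma", "V_pc", "V_uT", "V_uH",
           "sigma_nh", "sigma_hv", "f_p", "M_c", "lambda_c", "B_p", "R",
           "c_act", "f_act", "chi", "delta4", "D_f", "B_u",
           "L_scale", "T_scale", "eps_H", "G_amp", "eps_template")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a strictly positive scalar")
  }
  if (!(p$sigma_nh < p$sigma_hv && p$sigma_hv < 1))
    stop("nutrient thresholds must satisfy 0 < sigma_nh < sigma_hv < 1")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tumor-angiogenesis model parameters (non-dimensional):\n")
  nm <- setdiff(names(x), c("L_scale", "T_scale"))
  for (n in nm) cat(sprintf("  %-13s %g\n", n, x[[n]]))
  cat(sprintf("  scales: L = %g um, T = %g s\n", x$L_scale, x$T_scale))
  invisible(x)
}
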
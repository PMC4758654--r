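#' Per-cell tumor coverage fraction
#'
#' Fraction of each grid cell lying inside the region `phi > threshold`,
#' estimated by linear sub-cell interpolation: the local gradient gives the
#' span of `phi` across the cell, and the level set cuts the cell at the
#' proportional position. Cells deep in the bulk get 0 or 1.
#'
#' @param phi Tumor phase field matrix.
#' @param grid The [sim_grid()].
#' @param threshold Level defining the tumor boundary (default 0.5).
#' @return Matrix of coverage fractions in `[0, 1]`.
#' @export
area_fraction <- function(phi, grid, threshold = 0.5) {
  gx <- gradient_x(phi, grid)
  gy <- gradient_y(phi, grid)
  span <- abs(gx) * grid$dx + abs(gy) * grid$dy
  # zero span (flat bulk) degenerates to a sharp 0/1 count via the clamp
  frac <- pmin(1, pmax(0, 0.5 + (phi - threshold) / pmax(span, 1e-300)))
  matrix(frac, grid$nx, grid$ny)
}

#' Tumor area
#'
#' Area of the region `phi > threshold`, by cell counting with linear
#' sub-cell interpolation at the level set (see [area_fraction()]).
#'
#' @inheritParams area_fraction
#' @return Area in non-dimensional length units squared.
#' @export
tumor_area <- function(phi, grid, threshold = 0.5) {
  sum(area_fraction(phi, grid, threshold)) * grid$dx * grid$dy
}

#' Equivalent-radius ratio
#'
#' `sqrt(A_t / A_0)`: the ratio of the radii of discs (or, by symmetry,
#' quarter-discs) with areas `A_t` and `A_0`. Quarter-domain factors cancel.
#'
#' @param A_t Current area.
#' @param A_0 Initial area (> 0).
#' @return The radius ratio.
#' @export
equivalent_radius_ratio <- function(A_t, A_0) {
  stopifnot(A_0 > 0)
  sqrt(A_t / A_0)
}

#' Classify tumor tissue by nutrient availability
#'
#' Within the tumor mask `phi > threshold`: necrotic where
#' `sigma < sigma_nh`, hypoxic where `sigma_nh <= sigma < sigma_hv`,
#' proliferative where `sigma >= sigma_hv`. The masks are disjoint and their
#' union is the tumor mask.
#'
#' @param phi,sigma Field matrices.
#' @param p A [model_parameters()] object.
#' @param threshold Tumor boundary level.
#' @return List of three logical masks: `necrotic`, `hypoxic`,
#'   `proliferative`.
#' @export
classify_regions <- function(phi, sigma, p = model_parameters(),
                             threshold = 0.5) {
  tum <- phi > threshold
  list(necrotic = tum & sigma < p$sigma_nh,
       hypoxic = tum & sigma >= p$sigma_nh & sigma < p$sigma_hv,
       proliferative = tum & sigma >= p$sigma_hv)
}

# Region areas weighted by the sub-cell tumor coverage, so that
# necrotic + hypoxic + proliferative == tumor_area exactly.
region_areas <- function(phi, sigma, grid, p = model_parameters(),
                         threshold = 0.5, frac = NULL) {
  if (is.null(frac)) frac <- area_fraction(phi, grid, threshold)
  nec <- sigma < p$sigma_nh
  hyp <- sigma >= p$sigma_nh & sigma < p$sigma_hv
  cell <- grid$dx * grid$dy
  c(necrotic = sum(frac[nec]) * cell,
    hypoxic = sum(frac[hyp]) * cell,
    proliferative = sum(frac[!nec & !hyp]) * cell)
}

#' Distance from the capillary at which tissue turns hypoxic
#'
#' Samples the nutrient along the outer edge column of the domain (host
#' tissue, far from the tumor), walks away from the capillary strip and
#' linearly interpolates the first downward crossing of `sigma = sigma_hv`.
#' The returned distance is measured from the strip's inner boundary and
#' converted to micrometres with `L_scale`.
#'
#' @param sigma Nutrient field matrix.
#' @param grid The [sim_grid()].
#' @param p A [model_parameters()] object.
#' @param cap_height Inner boundary of the capillary strip (non-dimensional
#'   y; default 25 um / `L_scale`).
#' @return Distance in micrometres.
#' @export
hypoxia_distance <- function(sigma, grid, p = model_parameters(),
                             cap_height = 25 / p$L_scale) {
  prof <- sigma[grid$nx, ]
  y <- grid$y
  j0 <- which(y >= cap_height)[1]
  if (is.na(j0)) stop("capillary strip thicker than the domain")
  thr <- p$sigma_hv
  if (prof[j0] < thr)
    stop("nutrient already below sigma_hv at the capillary boundary")
  for (j in seq(j0, grid$ny - 1L)) {
    if (prof[j] >= thr && prof[j + 1L] < thr) {
      yc <- y[j] + (prof[j] - thr) / (prof[j] - prof[j + 1L]) * (y[j + 1L] - y[j])
      return((yc - cap_height) * p$L_scale)
    }
  }
  if (prof[grid$ny] == thr) return((y[grid$ny] - cap_height) * p$L_scale)
  stop("no crossing of sigma_hv found along the sampled line")
}

# Smallest distance from an active TEC to a tumor-occupied grid node; Inf if
# either set is empty. Tracks whether sprouts have reached the lesion.
min_tec_tumor_distance <- function(state, grid, tecs, threshold = 0.5) {
  act <- Filter(function(t) t$active, tecs)
  if (length(act) == 0L) return(Inf)
  idx <- which(state$phi > threshold)
  if (length(idx) == 0L) return(Inf)
  tx <- grid$x[((idx - 1L) %% grid$nx) + 1L]
  ty <- grid$y[((idx - 1L) %/% grid$nx) + 1L]
  min(vapply(act, function(tec)
    sqrt(min((tx - tec$pos[1])^2 + (ty - tec$pos[2])^2)), numeric(1)))
}

# Assemble one observable record from the current simulation state.
compute_observables <- function(state, grid, p, network, tecs, A0 = NULL,
                                n_anastomoses = 0L, threshold = 0.5) {
  frac <- area_fraction(state$phi, grid, threshold)
  A_t <- sum(frac) * grid$dx * grid$dy
  if (is.null(A0)) A0 <- A_t
  reg <- region_areas(state$phi, state$sigma, grid, p, threshold, frac = frac)
  data.frame(t = state$t,
             t_days = state$t * p$T_scale / 86400,
             A_t = A_t,
             g_re = (A_t - A0) / A0,
             capillary_area = sum(state$c > 0) * grid$dx * grid$dy,
             S = network$S,
             necrotic_area = reg[["necrotic"]],
             hypoxic_area = reg[["hypoxic"]],
             proliferative_area = reg[["proliferative"]],
             n_tecs_active = sum(vapply(tecs, function(t) t$active, logical(1))),
             n_anastomoses = n_anastomoses,
             min_tec_tumor_dist = min_tec_tumor_distance(state, grid, tecs,
                                                         threshold))
}

#' Detect the three growth stages in a tumor-area series
#'
#' Vascular runs show a characteristic area curve: an early rise fed by the
#' nutrient initially present in the tissue, a dip once that nutrient is
#' consumed, and renewed growth after new capillaries reach the lesion. The
#' detector smooths the area series with a running mean and looks for that
#' rise / fall / rise sign pattern with a relative amplitude of at least
#' `rel_tol` of the initial area for each swing.
#'
#' @param series Data frame with columns `t` and `A_t` (e.g. an
#'   `angio_run$series`).
#' @param window Running-mean half-width in records.
#' @param rel_tol Minimum swing amplitude, relative to the initial area.
#' @return List: `three_stages` flag, indices `i_peak`, `i_dip`, and the
#'   smoothed areas.
#' @export
growth_stages <- function(series, window = 3L, rel_tol = 2e-3) {
  A <- series$A_t
  n <- length(A)
  if (n < 5L) return(list(three_stages = FALSE, A_smooth = A))
  k <- 2L * window + 1L
  As <- stats::filter(A, rep(1 / k, k), sides = 2)
  As[seq_len(window)] <- A[seq_len(window)]
  As[seq(n - window + 1L, n)] <- A[seq(n - window + 1L, n)]
  As <- as.numeric(As)
  tol <- rel_tol * As[1]
  i_peak <- NA_integer_; i_dip <- NA_integer_
  run_max <- As[1]; i_max <- 1L
  for (i in seq(2L, n)) {
    if (As[i] > run_max) { run_max <- As[i]; i_max <- i }
    if (is.na(i_peak) && run_max > As[1] + tol && As[i] < run_max - tol) {
      i_peak <- i_max
    }
    if (!is.na(i_peak) && is.na(i_dip)) {
      dmin <- min(As[i_peak:i])
      if (As[i] > dmin + tol) i_dip <- i_peak - 1L + which.min(As[i_peak:i])
    }
  }
  list(three_stages = !is.na(i_peak) && !is.na(i_dip),
       i_peak = i_peak, i_dip = i_dip, A_smooth = As)
}
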
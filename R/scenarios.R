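#' Scenario configuration
#'
#' Describes one of the model's experiments: the avascular control (capillary
#' and TAF dynamics frozen, no TEC activation, `S = 1`), the full vascular
#' model, the Dll4-blockade variant (smaller lateral-inhibition distance
#' `delta4`), or the small-spheroid variant (initial tumor three times
#' smaller). Geometry arguments are physical (micrometres); everything is
#' converted with `L_scale` when the initial state is built.
#'
#' @param mode One of `"avascular"`, `"vascular"`, `"dll4_blockade"`,
#'   `"small_spheroid"`.
#' @param R_t Initial tumor radius, micrometres.
#' @param necrotic_fraction Initial necrotic-core radius as a fraction of
#'   `R_t`.
#' @param capillary_width Width of the initial capillary strip, micrometres.
#' @param sigma_background,sigma_capillary,sigma_necrotic Initial nutrient
#'   levels outside the tumor, inside the strip, and in the necrotic core.
#' @param delta4_override Optional replacement for the Dll4 effective
#'   distance; defaults to 55 in `dll4_blockade` mode and to the Table value
#'   otherwise.
#' @param t_end_days Simulated duration in days; mode-dependent default
#'   (1054 avascular, 5.1 vascular / dll4-blockade / small-spheroid).
#' @param seed RNG seed for the activation tie-break stream.
#' @param nx,ny Grid resolution (defaults 512 x 396).
#' @param record_every Record the scalar observables every this many accepted
#'   steps (the initial and final states are always recorded).
#' @param snapshot_days Days at which to keep full field snapshots.
#' @param area_threshold Phase level defining the tumor boundary for the
#'   area observables.
#' @param params A [model_parameters()] object.
#' @param numerics A [numerics_options()] object.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(mode = c("vascular", "avascular",
                                     "dll4_blockade", "small_spheroid"),
                            R_t = 625, necrotic_fraction = 0.45,
                            capillary_width = 25,
                            sigma_background = 0.45, sigma_capillary = 1,
                            sigma_necrotic = 0,
                            delta4_override = NULL,
                            t_end_days = NULL, seed = 1L,
                            nx = 512, ny = 396,
                            record_every = 1L,
                            snapshot_days = numeric(0),
                            area_threshold = 0.5,
                            params = model_parameters(),
                            numerics = numerics_options()) {
  mode <- match.arg(mode)
  if (mode == "small_spheroid") R_t <- R_t / 3
  if (is.null(t_end_days))
    t_end_days <- switch(mode, avascular = 1054, 5.1)
  if (is.null(delta4_override) && mode == "dll4_blockade")
    delta4_override <- 55
  stopifnot(R_t > 0, necrotic_fraction > 0, necrotic_fraction < 1,
            capillary_width > 0, t_end_days >= 0)
  structure(list(mode = mode, R_t = R_t,
                 necrotic_fraction = necrotic_fraction,
                 capillary_width = capillary_width,
                 sigma_background = sigma_background,
                 sigma_capillary = sigma_capillary,
                 sigma_necrotic = sigma_necrotic,
                 delta4_override = delta4_override,
                 t_end_days = t_end_days, seed = as.integer(seed),
                 nx = as.integer(nx), ny = as.integer(ny),
                 record_every = as.integer(record_every),
                 snapshot_days = snapshot_days,
                 area_threshold = area_threshold,
                 params = params, numerics = numerics),
            class = "scenario_config")
}

#' Convert days of physical time to non-dimensional simulation time
#'
#' @param days Nonnegative number of days.
#' @param p A [model_parameters()] object (supplies `T_scale`).
#' @return Non-dimensional time `days * 86400 / T_scale`.
#' @export
days_to_sim_time <- function(days, p = model_parameters()) {
  stopifnot(all(days >= 0))
  days * 86400 / p$T_scale
}

#' @rdname days_to_sim_time
#' @param t Non-dimensional time.
#' @export
sim_time_to_days <- function(t, p = model_parameters()) {
  t * p$T_scale / 86400
}

#' Build the initial state of a scenario
#'
#' Quarter-domain setup: the tumor is a quarter disc of radius `R_t` centred
#' at the top-left corner (the meeting point of the two symmetry edges), the
#' parent capillary is a strip along the bottom outer edge. The tumor edge
#' and the capillary wall are smoothed with tanh profiles (widths tied to
#' `lambda_phi` and `lambda_c`) to avoid spurious first-step stiffness. The
#' nutrient starts at `sigma_capillary` in the strip, `sigma_necrotic`
#' inside the initial necrotic core (`r < necrotic_fraction * R_t`) and
#' `sigma_background` elsewhere; TAF starts at zero.
#'
#' @param config A [scenario_config()].
#' @param grid A [sim_grid()].
#' @param p A [model_parameters()] object.
#' @return List with `state` (a [field_state()]), `network` (a
#'   [vascular_network()] holding the parent segment) and `tecs` (empty).
#' @export
build_initial_state <- function(config, grid, p = config$params) {
  Rt <- config$R_t / p$L_scale
  Rn <- config$necrotic_fraction * Rt
  wcap <- config$capillary_width / p$L_scale
  if (Rt + p$lambda_phi >= grid$height - wcap)
    stop("invalid geometry: initial tumor overlaps the capillary strip")
  r <- sqrt(outer(grid$x^2, (grid$y - grid$height)^2, `+`))
  phi <- 0.5 * (1 + tanh((Rt - r) / (p$lambda_phi / 10)))
  ymat <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  cfld <- tanh((wcap - ymat) / p$lambda_c)
  sigma <- matrix(config$sigma_background, grid$nx, grid$ny)
  sigma[r < Rn] <- config$sigma_necrotic
  sigma[ymat < wcap] <- config$sigma_capillary
  f <- matrix(0, grid$nx, grid$ny)
  list(state = field_state(phi, sigma, cfld, f, t = 0, grid = grid),
       network = vascular_network(parent_length = grid$width),
       tecs = list())
}

#' Run a scenario
#'
#' The main driver. Per accepted step: nutrient update, tumor update, then
#' (unless avascular) TAF update, capillary update, TEC migration /
#' imprinting / filopodia / anastomosis, a single possible TEC activation,
#' and the network-statistic update, all under adaptive time-step control.
#' Avascular mode holds `c` and `f` frozen, never activates TECs and fixes
#' `S = 1`. Runs are fully reproducible given the config seed.
#'
#' @param config A [scenario_config()].
#' @param quiet Suppress progress messages.
#' @return An `angio_run` object: `series` (data frame of observable
#'   records), final `state`, `grid`, effective `params`, `network`, `tecs`,
#'   `events` (TEC event log) and `snapshots`.
#' @export
run_scenario <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  if (!is.null(config$delta4_override)) p$delta4 <- config$delta4_override
  opts <- config$numerics
  grid <- sim_grid(config$nx, config$ny)
  init <- build_initial_state(config, grid, p)
  state <- init$state
  network <- init$network
  tecs <- init$tecs
  rng <- rng_stream(config$seed)
  avascular <- config$mode == "avascular"
  t_end <- days_to_sim_time(config$t_end_days, p)
  snap_times <- sort(days_to_sim_time(config$snapshot_days, p))
  n_anast <- 0L
  events <- list()
  log_event <- function(ev, tec, t) {
    events[[length(events) + 1L]] <<- data.frame(
      t = t, t_days = sim_time_to_days(t, p), event = ev, tec_id = tec$id,
      x = tec$pos[1], y = tec$pos[2], stringsAsFactors = FALSE)
  }
  A0 <- tumor_area(state$phi, grid, config$area_threshold)
  records <- list(compute_observables(state, grid, p, network, tecs, A0,
                                      n_anast, config$area_threshold))
  snapshots <- list()
  dt <- opts$dt_init
  step <- 0L
  frozen_cHc <- if (avascular) capillary_indicator(state$c, p) else NULL
  while (state$t < t_end - 1e-9) {
    dt_use <- min(dt, t_end - state$t)
    repeat {
      new <- try({
        st <- state
        cHc <- if (avascular) frozen_cHc else capillary_indicator(st$c, p)
        st$sigma <- step_nutrient(st, grid, dt_use, network$S, p, cHc = cHc)
        st$phi <- step_tumor(st, grid, dt_use, p, opts)
        if (!avascular) {
          st$f <- step_taf(st, grid, dt_use, p, cHc = cHc)
          st$c <- step_capillary(st, grid, dt_use, p, opts)
        }
        st
      }, silent = TRUE)
      if (!inherits(new, "try-error")) break
      dt_use <- dt_use / 2
      if (dt_use < opts$dt_min)
        stop("time step underflow at t = ", state$t, ": ",
             attr(new, "condition")$message)
    }
    max_change <- max(abs(new$phi - state$phi), abs(new$sigma - state$sigma))
    if (!avascular)
      max_change <- max(max_change, abs(new$f - state$f),
                        abs(new$c - state$c))
    state <- new
    state$t <- state$t + dt_use

    if (!avascular) {
      gfx <- gradient_x(state$f, grid)
      gfy <- gradient_y(state$f, grid)
      for (k in seq_along(tecs)) {
        tec <- tecs[[k]]
        if (!tec$active) next
        had_redirect <- !is.null(tec$redirect_dir)
        tec <- update_tec(tec, state, grid, dt_use, p, gfx, gfy)
        if (tec$last_disp > 0 &&
            network$segments$open[match(tec$sprout_id, network$segments$id)])
          network <- grow_sprout(network, tec$sprout_id, tec$last_disp)
        state$c <- imprint_template(state$c, tec, grid, p)
        if (!had_redirect && !is.null(tec$redirect_dir))
          log_event("redirect", tec, state$t)
        if (tec$active) tec <- try_anastomose(tec, state, grid, p)
        if (!tec$active) {
          network <- close_sprout(network, tec$sprout_id)
          if (identical(tec$deactivation_reason, "anastomosis")) {
            n_anast <- n_anast + 1L
            state$c <- imprint_template(state$c, tec, grid, p)
            log_event("anastomosis", tec, state$t)
          } else {
            log_event(paste0("deactivation_", tec$deactivation_reason),
                      tec, state$t)
          }
        }
        tecs[[k]] <- tec
      }
      newtec <- scan_activation(state, tecs, grid, p, rng,
                                id = length(tecs) + 1L)
      if (!is.null(newtec)) {
        sp <- open_sprout(network, length0 = p$R)
        network <- sp$network
        newtec$sprout_id <- sp$sprout_id
        state$c <- imprint_template(state$c, newtec, grid, p)
        tecs[[length(tecs) + 1L]] <- newtec
        log_event("activation", newtec, state$t)
      }
    }

    step <- step + 1L
    at_end <- state$t >= t_end - 1e-9
    if (step %% config$record_every == 0L || at_end) {
      state <- guard_state(state)
      records[[length(records) + 1L]] <-
        compute_observables(state, grid, p, network, tecs, A0, n_anast,
                            config$area_threshold)
    }
    if (length(snap_times) && state$t >= snap_times[1] - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- state
      snap_times <- snap_times[-1]
    }
    if (!quiet && step %% 200L == 0L)
      message(sprintf("t = %.1f / %.1f (dt = %.3g, TECs = %d)",
                      state$t, t_end, dt_use, length(tecs)))
    any_active <- any(vapply(tecs, function(x) x$active, logical(1)))
    diag <- list(solver_failed = FALSE, max_change = max_change,
                 tec_speed = if (any_active) p$chi else 0)
    dt <- adapt_dt(dt_use, diag, p, opts)
  }
  series <- do.call(rbind, records)
  rownames(series) <- NULL
  structure(list(series = series, state = state, grid = grid, params = p,
                 config = config, network = network, tecs = tecs,
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(),
                 snapshots = snapshots, n_steps = step),
            class = "angio_run")
}

# Run-time guard: strict [0,1] for sigma/f (exponential reaction updates and
# the M-matrix diffusion solves preserve the range up to roundoff, which is
# clipped), and a blow-up envelope for the phase fields that is wider than the
# representation tolerance of validate_field_state(): strong endothelial
# proliferation can push c past the usual diffuse-interface overshoot without
# the solution being wrong.
guard_state <- function(state, clip_tol = 1e-10) {
  for (nm in c("sigma", "f")) {
    v <- state[[nm]]
    over <- max(0, max(v) - 1, -min(v))
    if (is.na(over)) stop("NaN detected in field '", nm, "'")
    if (over > clip_tol)
      stop(sprintf("field '%s' out of [0,1] by %.3g", nm, over))
    state[[nm]] <- pmin(pmax(v, 0), 1)
  }
  if (anyNA(state$phi) || anyNA(state$c)) stop("NaN detected in phase field")
  if (min(state$phi) < -0.25 || max(state$phi) > 1.25 ||
      min(state$c) < -1.5 || max(state$c) > 1.5)
    stop("phase field blow-up detected")
  state
}

#' @export
print.angio_run <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("angio_run (%s): %d steps to day %.2f\n",
              x$config$mode, x$n_steps, last$t_days))
  cat(sprintf("  tumor area %.4g (g_re = %+.2f%%), capillary area %.4g, S = %.3f\n",
              last$A_t, 100 * last$g_re, last$capillary_area, last$S))
  cat(sprintf("  TECs: %d created, %d active, %d anastomoses\n",
              length(x$tecs), last$n_tecs_active, last$n_anastomoses))
  invisible(x)
}
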
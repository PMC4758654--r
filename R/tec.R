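#' Seeded random stream for TEC activation tie-breaks
#'
#' The only stochastic operation in the model is the uniform choice among
#' eligible activation sites. The stream is kept separate from R's global
#' RNG so that simulations are bit-reproducible regardless of what the
#' calling session does with `set.seed()`.
#'
#' @param seed Integer seed.
#' @return An environment of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = .GlobalEnv)
  set.seed(seed)
  e$state <- get(".Random.seed", envir = .GlobalEnv)
  if (is.null(old)) {
    rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
  class(e) <- "rng_stream"
  e
}

# Draw one integer uniformly from 1..n using the stream, leaving the global
# RNG untouched.
rng_int <- function(rng, n) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  assign(".Random.seed", rng$state, envir = .GlobalEnv)
  k <- sample.int(n, 1L)
  rng$state <- get(".Random.seed", envir = .GlobalEnv)
  if (is.null(old)) {
    rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
  k
}

#' Construct a tip endothelial cell agent
#'
#' @param id Integer identifier.
#' @param pos Numeric 2-vector, position in non-dimensional units.
#' @param p A [model_parameters()] object.
#' @param t Activation time.
#' @param sprout_id Identifier of the vascular-network sprout this cell leads.
#' @return A `tip_cell` object.
#' @export
tip_cell <- function(id, pos, p = model_parameters(), t = 0, sprout_id = NA) {
  structure(list(id = as.integer(id), pos = as.numeric(pos), radius = p$R,
                 active = TRUE, parent_pos = as.numeric(pos),
                 path_length = 0, sprout_id = sprout_id,
                 redirect_dir = NULL, path = matrix(pos, 1, 2),
                 low_f_steps = 0L, last_disp = 0,
                 activated_t = t, deactivated_t = NA_real_,
                 deactivation_reason = NA_character_),
        class = "tip_cell")
}

# Points of the cell's own recent trail: the stretch of path between
# `skip_recent` and `arc` of migrated arc length behind the tip. The most
# recent stretch is excluded on purpose — every point near the tip is
# trivially near the path's end, and counting it as "own trail" would veto
# all anastomoses.
trail_points <- function(tec, arc, skip_recent = 0) {
  path <- tec$path
  n <- nrow(path)
  if (n <= 2L) return(path[1L, , drop = FALSE])
  seg <- sqrt(rowSums((path[-1L, , drop = FALSE] -
                         path[-n, , drop = FALSE])^2))
  back <- c(rev(cumsum(rev(seg))), 0)  # arc length from row i to the tip
  keep <- back <= arc & back >= skip_recent
  if (!any(keep)) keep[1L] <- TRUE
  path[keep, , drop = FALSE]
}

# TRUE if `pt` lies within `excl` of the given trail points.
near_own_trail <- function(pt, tp, excl) {
  any((tp[, 1] - pt[1])^2 + (tp[, 2] - pt[2])^2 <= excl^2)
}

# Reflect a point into the domain across the mirror edges.
reflect_pos <- function(pos, grid) {
  x <- pos[1]; y <- pos[2]
  if (x < 0) x <- -x
  if (x > grid$width) x <- 2 * grid$width - x
  if (y < 0) y <- -y
  if (y > grid$height) y <- 2 * grid$height - y
  c(x, y)
}

# Positions of a TEC together with its mirror images across the two symmetry
# edges (x = 0 and y = height), for Dll4 distance checks.
tec_images <- function(pos, grid) {
  H <- grid$height
  rbind(pos,
        c(-pos[1], pos[2]),
        c(pos[1], 2 * H - pos[2]),
        c(-pos[1], 2 * H - pos[2]))
}

#' Scan the domain for a new TEC activation site
#'
#' Collects every grid node satisfying the three activation conditions:
#' `c >= c_act` (inside a capillary), `f >= f_act` (enough TAF), and
#' Euclidean distance greater than `delta4` to every active TEC, including
#' the TECs' mirror images across the two symmetry edges (Dll4/Notch lateral
#' inhibition). If any node is eligible, exactly one is activated, chosen
#' uniformly at random from the stream; otherwise no cell is created.
#'
#' @param state A [field_state()].
#' @param tecs List of current [tip_cell()] agents.
#' @param grid The [sim_grid()].
#' @param p A [model_parameters()] object.
#' @param rng An [rng_stream()].
#' @param id Identifier to give the new cell.
#' @return A new `tip_cell`, or `NULL` if no site is eligible.
#' @export
scan_activation <- function(state, tecs, grid, p = model_parameters(),
                            rng = rng_stream(1), id = length(tecs) + 1L) {
  idx <- which(state$c >= p$c_act & state$f >= p$f_act)
  if (length(idx) == 0L) return(NULL)
  ii <- ((idx - 1L) %% grid$nx) + 1L
  jj <- ((idx - 1L) %/% grid$nx) + 1L
  px <- grid$x[ii]
  py <- grid$y[jj]
  keep <- rep(TRUE, length(idx))
  for (tec in tecs) {
    if (!tec$active) next
    for (k in seq_len(4)) {
      img <- tec_images(tec$pos, grid)[k, ]
      keep <- keep & ((px - img[1])^2 + (py - img[2])^2 > p$delta4^2)
    }
    if (!any(keep)) return(NULL)
  }
  cand <- which(keep)
  if (length(cand) == 0L) return(NULL)
  pick <- cand[rng_int(rng, length(cand))]
  tip_cell(id, c(px[pick], py[pick]), p, t = state$t)
}

#' Advance one TEC agent over a time step
#'
#' Moves the cell with the chemotactic velocity (or, once a capillary has
#' been detected by its filopodia, straight along the stored redirect
#' direction at speed `chi * J(phi)`), accumulates arc length, clamps the
#' position to the domain (a cell reaching an edge is deactivated), runs the
#' filopodia check once the cell is more than `4R` of arc away from its
#' parent vessel, and applies the persistence-based starvation rule: a cell
#' whose local TAF stays below `f_act` for 10 consecutive steps deactivates.
#'
#' @param tec A [tip_cell()].
#' @param state A [field_state()].
#' @param grid The [sim_grid()].
#' @param dt Time step.
#' @param p A [model_parameters()] object.
#' @param gfx,gfy Precomputed TAF gradient component fields (optional;
#'   computed from `state$f` if missing).
#' @param starve_steps Consecutive low-TAF steps before deactivation.
#' @return The updated `tip_cell` (field `last_disp` holds the displacement
#'   magnitude of this step, used to grow the cell's sprout).
#' @export
update_tec <- function(tec, state, grid, dt, p = model_parameters(),
                       gfx = NULL, gfy = NULL, starve_steps = 10L) {
  stopifnot(inherits(tec, "tip_cell"))
  tec$last_disp <- 0
  if (!tec$active) return(tec)
  if (is.null(gfx)) gfx <- gradient_x(state$f, grid)
  if (is.null(gfy)) gfy <- gradient_y(state$f, grid)
  phi_loc <- interp_field(state$phi, grid, tec$pos)
  if (!is.null(tec$redirect_dir)) {
    v <- p$chi * migration_J(phi_loc) * tec$redirect_dir
  } else {
    gf <- c(interp_field(gfx, grid, tec$pos), interp_field(gfy, grid, tec$pos))
    v <- chemo_velocity(gf, phi_loc, p)
  }
  newpos <- tec$pos + v * dt
  if (anyNA(newpos)) stop("TEC position is NaN")
  hit_edge <- newpos[1] < 0 || newpos[1] > grid$width ||
    newpos[2] < 0 || newpos[2] > grid$height
  newpos <- pmin(pmax(newpos, 0), c(grid$width, grid$height))
  disp <- sqrt(sum((newpos - tec$pos)^2))
  if (disp > 0) {
    tec$pos <- newpos
    tec$path <- rbind(tec$path, newpos)
    # only the recent trail is ever queried; cap the stored history
    if (nrow(tec$path) > 1024L)
      tec$path <- tec$path[-seq_len(512L), , drop = FALSE]
    tec$path_length <- tec$path_length + disp
    tec$last_disp <- disp
  }
  if (hit_edge) {
    tec$active <- FALSE
    tec$deactivated_t <- state$t
    tec$deactivation_reason <- "edge"
    return(tec)
  }
  if (is.null(tec$redirect_dir) && tec$path_length > 4 * p$R) {
    dir <- detect_filopodia(tec, state, grid, p)
    if (!is.null(dir)) tec$redirect_dir <- dir
  }
  f_loc <- interp_field(state$f, grid, tec$pos)
  if (f_loc < p$f_act) {
    tec$low_f_steps <- tec$low_f_steps + 1L
    if (tec$low_f_steps >= starve_steps) {
      tec$active <- FALSE
      tec$deactivated_t <- state$t
      tec$deactivation_reason <- "starved"
    }
  } else {
    tec$low_f_steps <- 0L
  }
  tec
}

#' Probe the capillary field with filopodia
#'
#' Samples `c` at points on rays around the cell (radii `2R` and `4R`, one
#' ray every 45 degrees), skipping the trailing half-cone (within 60 degrees
#' of the reversed migration direction) and any sample lying on the cell's
#' own recent trail, so a sprout does not detect itself. If any sampled value
#' is positive a capillary has been found and the unit direction towards the
#' sample with maximal `c` is returned.
#'
#' @param tec A [tip_cell()] with `path_length > 4R`.
#' @param state A [field_state()].
#' @param grid The [sim_grid()].
#' @param p A [model_parameters()] object.
#' @return Unit 2-vector towards the detected capillary, or `NULL`.
#' @export
detect_filopodia <- function(tec, state, grid, p = model_parameters()) {
  n <- nrow(tec$path)
  vdir <- if (n >= 2L) tec$path[n, ] - tec$path[n - 1L, ] else c(0, 0)
  vn <- sqrt(sum(vdir^2))
  if (vn > 0) vdir <- vdir / vn
  angles <- seq(0, 2 * pi, length.out = 9L)[-9L]
  best_c <- 0
  best_dir <- NULL
  tp <- trail_points(tec, 8 * p$R, skip_recent = 2 * p$R)
  for (a in angles) {
    ray <- c(cos(a), sin(a))
    if (vn > 0 && sum(ray * (-vdir)) > cos(pi / 3)) next  # trailing cone
    for (rr in c(2, 4) * p$R) {
      pt <- tec$pos + rr * ray
      spt <- reflect_pos(pt, grid)
      if (near_own_trail(spt, tp, 1.5 * p$R)) next
      cv <- interp_field(state$c, grid, spt)
      if (cv > best_c) {
        best_c <- cv
        best_dir <- ray
      }
    }
  }
  if (best_c > 0) best_dir else NULL
}

#' Attempt anastomosis of a redirected TEC
#'
#' Once a cell is homing on a detected capillary (`redirect_dir` set), it
#' fuses with it when its centre comes within one radius of a grid node with
#' `c >= c_act` that belongs neither to its own recent trail nor to its own
#' cell body (whose template cannot raise `c` to `c_act` beyond
#' `R - eps_template * atanh(c_act)` from the centre). On fusion the cell is
#' deactivated.
#'
#' @param tec An active [tip_cell()] with `redirect_dir` set.
#' @param state A [field_state()].
#' @param grid The [sim_grid()].
#' @param p A [model_parameters()] object.
#' @return The possibly deactivated `tip_cell`; check `$active`.
#' @export
try_anastomose <- function(tec, state, grid, p = model_parameters()) {
  if (!tec$active || is.null(tec$redirect_dir)) return(tec)
  i0 <- max(1L, floor((tec$pos[1] - p$R) / grid$dx))
  i1 <- min(grid$nx, ceiling((tec$pos[1] + p$R) / grid$dx) + 1L)
  j0 <- max(1L, floor((tec$pos[2] - p$R) / grid$dy))
  j1 <- min(grid$ny, ceiling((tec$pos[2] + p$R) / grid$dy) + 1L)
  tp <- trail_points(tec, 8 * p$R, skip_recent = 2 * p$R)
  # the cell's own template only lifts c above c_act inside this radius, so
  # beyond it a c >= c_act node must be (or include) foreign vasculature
  body <- p$R - p$eps_template * atanh(p$c_act)
  for (i in i0:i1) {
    for (j in j0:j1) {
      pt <- c(grid$x[i], grid$y[j])
      d2 <- sum((pt - tec$pos)^2)
      if (d2 > p$R^2 || d2 < body^2) next
      if (state$c[i, j] < p$c_act) next
      if (near_own_trail(pt, tp, 1.5 * p$R)) next
      tec$active <- FALSE
      tec$deactivated_t <- state$t
      tec$deactivation_reason <- "anastomosis"
      return(tec)
    }
  }
  tec
}

#' Imprint a TEC template into the capillary field
#'
#' Raises `c` to `max(c, tanh((R - r)/eps_template))` within `3R` of the cell
#' centre. The operation never decreases `c` anywhere and is idempotent; as
#' the cell migrates it therefore leaves a contiguous capillary trail that
#' the endothelial proliferation term of the vessel equation then sustains.
#'
#' @param c_field Capillary field matrix.
#' @param tec A [tip_cell()].
#' @param grid The [sim_grid()].
#' @param p A [model_parameters()] object.
#' @return The updated capillary field matrix.
#' @export
imprint_template <- function(c_field, tec, grid, p = model_parameters()) {
  reach <- 3 * p$R
  i0 <- max(1L, floor((tec$pos[1] - reach) / grid$dx))
  i1 <- min(grid$nx, ceiling((tec$pos[1] + reach) / grid$dx) + 1L)
  j0 <- max(1L, floor((tec$pos[2] - reach) / grid$dy))
  j1 <- min(grid$ny, ceiling((tec$pos[2] + reach) / grid$dy) + 1L)
  if (i0 > i1 || j0 > j1) return(c_field)
  xs <- grid$x[i0:i1]
  ys <- grid$y[j0:j1]
  r <- sqrt(outer(xs - tec$pos[1], ys - tec$pos[2], function(a, b) a^2 + b^2))
  c_field[i0:i1, j0:j1] <- pmax(c_field[i0:i1, j0:j1], tec_template(r, p))
  c_field
}
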
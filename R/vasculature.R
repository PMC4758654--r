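#' Capillary-network bookkeeping
#'
#' Tracks the segments the vasculature is composed of: the pre-existing
#' parent vessel plus one sprout per activated TEC. Segment lengths feed the
#' network-functionality statistic `S = l_max / sum(l_i)`, the crude measure
#' of network structure that scales nutrient delivery: as the network grows
#' denser (more, longer sprouts), `S` drops and the per-vessel nutrient
#' supply is effectively reduced, mimicking the leakiness and tortuosity of
#' tumor-induced vasculature.
#'
#' @param parent_length Length of the initial parent capillary
#'   (non-dimensional); defaults to the quarter-domain width.
#' @return A `vascular_network` object with a `segments` data frame
#'   (`id`, `kind`, `length`, `open`), the segment count `n`, `l_max` and `S`.
#' @export
vascular_network <- function(parent_length = 1050) {
  stopifnot(parent_length > 0)
  net <- structure(
    list(segments = data.frame(id = 1L, kind = "parent",
                               length = parent_length, open = FALSE,
                               stringsAsFactors = FALSE)),
    class = "vascular_network")
  refresh_network(net)
}

refresh_network <- function(network) {
  network$n <- nrow(network$segments)
  network$l_max <- max(network$segments$length)
  network$S <- compute_S(network)
  network
}

#' Network functionality statistic
#'
#' `S = l_max / sum(l_i)` over all segment lengths. Equals 1 exactly when the
#' network consists of a single capillary and decreases (weakly) whenever a
#' segment is added or a non-maximal segment grows.
#'
#' @param network A [vascular_network()].
#' @return `S` in `(0, 1]`.
#' @export
compute_S <- function(network) {
  l <- network$segments$length
  if (length(l) == 0L) stop("empty vascular network")
  if (any(l <= 0)) stop("segment lengths must be strictly positive")
  max(l) / sum(l)
}

#' Open a new sprout led by a TEC
#'
#' @param network A [vascular_network()].
#' @param length0 Initial length (the imprinted cell-body footprint, > 0).
#' @return List with the updated `network` and the new `sprout_id`.
#' @export
open_sprout <- function(network, length0) {
  stopifnot(length0 > 0)
  id <- max(network$segments$id) + 1L
  network$segments <- rbind(network$segments,
                            data.frame(id = id, kind = "sprout",
                                       length = length0, open = TRUE,
                                       stringsAsFactors = FALSE))
  list(network = refresh_network(network), sprout_id = id)
}

#' Grow an open sprout
#'
#' Adds the arc length migrated by the sprout's TEC during the last step;
#' `l_max` and `S` are recomputed.
#'
#' @param network A [vascular_network()].
#' @param sprout_id Segment identifier returned by [open_sprout()].
#' @param d_length Nonnegative length increment.
#' @return The updated network.
#' @export
grow_sprout <- function(network, sprout_id, d_length) {
  stopifnot(d_length >= 0)
  k <- match(sprout_id, network$segments$id)
  if (is.na(k)) stop("unknown sprout id: ", sprout_id)
  if (!network$segments$open[k]) stop("sprout ", sprout_id, " is closed")
  network$segments$length[k] <- network$segments$length[k] + d_length
  refresh_network(network)
}

#' Close a sprout (anastomosis or TEC deactivation)
#'
#' The segment keeps its length but stops growing.
#'
#' @inheritParams grow_sprout
#' @return The updated network.
#' @export
close_sprout <- function(network, sprout_id) {
  k <- match(sprout_id, network$segments$id)
  if (is.na(k)) stop("unknown sprout id: ", sprout_id)
  network$segments$open[k] <- FALSE
  refresh_network(network)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("vascular_network: %d segment(s), l_max = %.4g, S = %.4f\n",
              x$n, x$l_max, x$S))
  invisible(x)
}

#' Measure capillary branch lengths from the phase field
#'
#' Independent, image-based check of the tracked segment lengths: thresholds
#' the capillary field at `c > 0`, thins the binary mask to a one-pixel
#' skeleton (Zhang-Suen), removes branch points, and returns the arc length
#' of each remaining skeleton branch in non-dimensional units. Intended as a
#' topology-level oracle (agreement within ~15%), not a bit-exact one.
#'
#' @param c_field Capillary field matrix.
#' @param grid The [sim_grid()].
#' @param min_pixels Branches with fewer skeleton pixels are dropped (noise).
#' @return Numeric vector of branch lengths.
#' @export
skeleton_lengths <- function(c_field, grid, min_pixels = 3L) {
  check_field(c_field, grid)
  mask <- c_field > 0
  if (!any(mask)) stop("capillary mask is empty (no region with c > 0)")
  if (mean(mask) > 0.9)
    stop("capillary mask covers nearly the whole domain; no 1D structure")
  sk <- thin_mask(mask)
  idx <- which(sk)
  if (length(idx) == 0L) stop("skeleton is empty")
  nx <- nrow(sk)
  ii <- ((idx - 1L) %% nx) + 1L
  jj <- ((idx - 1L) %/% nx) + 1L
  key <- function(i, j) paste(i, j)
  lookup <- stats::setNames(seq_along(idx), key(ii, jj))
  # 8-connected adjacency with physical edge weights
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- cbind(di = c(1L, 0L, 1L, -1L), dj = c(0L, 1L, 1L, 1L))
  for (k in seq_len(nrow(offs))) {
    ni <- ii + offs[k, 1]; nj <- jj + offs[k, 2]
    nb <- lookup[key(ni, nj)]
    ok <- !is.na(nb)
    from <- c(from, which(ok)); to <- c(to, nb[ok])
    w <- c(w, rep(sqrt((offs[k, 1] * grid$dx)^2 + (offs[k, 2] * grid$dy)^2),
                  sum(ok)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_along(idx)))
  deg <- igraph::degree(g)
  branch_pts <- which(deg >= 3)
  g2 <- igraph::delete_vertices(g, branch_pts)
  comp <- igraph::components(g2)
  lens <- numeric(0)
  for (cc in seq_len(comp$no)) {
    vs <- which(comp$membership == cc)
    if (length(vs) < min_pixels) next
    sub <- igraph::induced_subgraph(g2, vs)
    mst <- igraph::mst(sub)
    len <- sum(igraph::E(mst)$weight)
    # thinning erodes each free end by roughly the local half-width;
    # compensate with the clearance of the branch's terminal pixels
    ends <- as.integer(igraph::V(sub)$name[igraph::degree(sub) <= 1])
    for (e in utils::head(ends, 2))
      len <- len + end_clearance(mask, ii[e], jj[e], grid)
    lens <- c(lens, len)
  }
  if (length(lens) == 0L) stop("no skeleton branch with >= min_pixels pixels")
  sort(lens, decreasing = TRUE)
}

# Distance (in physical units) from pixel (i, j) to the nearest background
# pixel, searched in a local window.
end_clearance <- function(mask, i, j, grid, win = 40L) {
  i0 <- max(1L, i - win); i1 <- min(nrow(mask), i + win)
  j0 <- max(1L, j - win); j1 <- min(ncol(mask), j + win)
  sub <- mask[i0:i1, j0:j1]
  bg <- which(!sub)
  if (length(bg) == 0L) return(0)
  bi <- ((bg - 1L) %% nrow(sub)) + 1L + i0 - 1L
  bj <- ((bg - 1L) %/% nrow(sub)) + 1L + j0 - 1L
  sqrt(min(((bi - i) * grid$dx)^2 + ((bj - j) * grid$dy)^2))
}

# Zhang-Suen morphological thinning of a logical matrix.
thin_mask <- function(mask) {
  sh <- function(M, di, dj) {
    nx <- nrow(M); ny <- ncol(M)
    out <- matrix(FALSE, nx, ny)
    xs <- seq_len(nx) - di; ys <- seq_len(ny) - dj
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    out[okx, oky] <- M[xs[okx], ys[oky]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P2 <- sh(mask, 0, 1);  P3 <- sh(mask, 1, 1)
      P4 <- sh(mask, 1, 0);  P5 <- sh(mask, 1, -1)
      P6 <- sh(mask, 0, -1); P7 <- sh(mask, -1, -1)
      P8 <- sh(mask, -1, 0); P9 <- sh(mask, -1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, nrow(mask), ncol(mask))
      for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1]])
      if (pass == 1) {
        cond <- mask & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- mask & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        mask[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mask
}
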
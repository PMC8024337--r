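#' Delaunay neighbour pairs
#'
#' Edge set of the Delaunay triangulation of a 2-D point set, used to define
#' which cells interact mechanically. Degenerate inputs fall back to an
#' all-pairs rule: for fewer than three points or a fully collinear set,
#' every pair closer than `neighbor_cutoff` becomes an edge. Exactly
#' coincident points are jittered by 1e-6 micrometres (drawn from the
#' global RNG) before triangulating.
#'
#' @param positions numeric matrix with two columns (x, y).
#' @param neighbor_cutoff fallback neighbour distance.
#' @return Integer matrix with two columns; each row an unordered pair of
#'   row indices into `positions`, with `[,1] < [,2]`.
#' @export
#' @examples
#' pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' delaunay_neighbors(pts)   # 4 sides + 1 diagonal
delaunay_neighbors <- function(positions, neighbor_cutoff = 30) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) return(matrix(integer(0), ncol = 2))

  all_pairs_within <- function() {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dx <- positions[idx[, 1], 1] - positions[idx[, 2], 1]
    dy <- positions[idx[, 1], 2] - positions[idx[, 2], 2]
    keep <- sqrt(dx^2 + dy^2) < neighbor_cutoff
    cbind(idx[keep, 1], idx[keep, 2])
  }
  if (n == 2) return(all_pairs_within())

  # deterministic-from-RNG jitter of exact duplicates
  dup <- duplicated(complex(real = positions[, 1],
                            imaginary = positions[, 2]))
  if (any(dup)) {
    k <- sum(dup)
    positions[dup, ] <- positions[dup, ] +
      matrix(runif(2 * k, -1e-6, 1e-6), ncol = 2)
  }

  # collinearity: all cross products against one reference direction ~ 0
  vx <- positions[, 1] - positions[1, 1]
  vy <- positions[, 2] - positions[1, 2]
  ref <- which(abs(vx) + abs(vy) > 1e-12)[1]
  if (is.na(ref)) return(all_pairs_within())
  cross <- vx[ref] * vy - vy[ref] * vx
  scale2 <- max(abs(vx), abs(vy))^2
  if (max(abs(cross)) <= 1e-9 * max(scale2, 1))
    return(all_pairs_within())

  edges <- .delaunay_edges_cpp(positions[, 1], positions[, 2])
  edges
}

#' Pairwise linear spring forces on Delaunay edges
#'
#' For each neighbour pair (i, j) at distance d with rest length
#' `s = r_i + r_j`, cell i feels `k_spring * (d - s)` along the unit vector
#' towards j (repulsive when overlapping, attractive when stretched), and j
#' feels the opposite. Pairs further apart than `detach_factor * s`
#' contribute nothing; exactly coincident pairs contribute nothing and
#' raise a warning.
#'
#' @param positions n x 2 matrix of cell centres.
#' @param radii length-n cell radii.
#' @param edges two-column index matrix from [delaunay_neighbors()].
#' @param k_spring spring constant.
#' @param detach_factor detach cutoff as a multiple of the rest length.
#' @return n x 2 matrix of force vectors.
#' @export
spring_forces <- function(positions, radii, edges, k_spring,
                          detach_factor = 1.5) {
  n <- nrow(positions)
  f <- matrix(0, n, 2)
  if (is.null(edges) || nrow(edges) == 0) return(f)
  i <- edges[, 1]; j <- edges[, 2]
  dx <- positions[j, 1] - positions[i, 1]
  dy <- positions[j, 2] - positions[i, 2]
  d <- sqrt(dx^2 + dy^2)
  rest <- radii[i] + radii[j]
  if (any(d == 0)) {
    warning("coincident cell pair: zero spring force applied")
  }
  active <- d > 0 & d <= detach_factor * rest
  if (!any(active)) return(f)
  i <- i[active]; j <- j[active]
  mag <- k_spring * (d[active] - rest[active]) / d[active]
  fx <- mag * dx[active]
  fy <- mag * dy[active]
  # equal and opposite contributions on each edge endpoint
  f[, 1] <- rowsum_vec(fx, i, n) - rowsum_vec(fx, j, n)
  f[, 2] <- rowsum_vec(fy, i, n) - rowsum_vec(fy, j, n)
  f
}

# sum values by integer group over a fixed-length vector
rowsum_vec <- function(values, group, n) {
  out <- numeric(n)
  s <- rowsum(values, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Outward yolk-surface force
#'
#' Cells inside the yolk are pushed out along the outward normal with
#' magnitude `k_out * (R_y - d)`; cells on or outside the surface feel
#' nothing. A cell exactly at the centre takes the +y normal.
#'
#' @param positions n x 2 matrix of cell centres.
#' @param yolk a [make_yolk()] object.
#' @param k_out force constant.
#' @return n x 2 matrix of force vectors.
#' @export
yolk_surface_force <- function(positions, yolk, k_out) {
  dx <- positions[, 1] - yolk$centre[1]
  dy <- positions[, 2] - yolk$centre[2]
  d <- sqrt(dx^2 + dy^2)
  nx <- ifelse(d > 0, dx / d, 0)
  ny <- ifelse(d > 0, dy / d, 1)
  mag <- ifelse(d < yolk$radius, k_out * (yolk$radius - d), 0)
  cbind(mag * nx, mag * ny)
}

#' Inward intercalation force
#'
#' Cells further than `R_y + band` from the yolk centre are pulled back in
#' with magnitude `k_in * (d - R_y - band)`, promoting intercalation into a
#' thin shell hugging the yolk (the model's stand-in for convergent
#' extension).
#'
#' @param positions n x 2 matrix of cell centres.
#' @param yolk a [make_yolk()] object.
#' @param k_in force constant.
#' @param band shell width above the yolk surface.
#' @return n x 2 matrix of force vectors.
#' @export
intercalation_force <- function(positions, yolk, k_in, band) {
  dx <- positions[, 1] - yolk$centre[1]
  dy <- positions[, 2] - yolk$centre[2]
  d <- sqrt(dx^2 + dy^2)
  nx <- ifelse(d > 0, dx / d, 0)
  ny <- ifelse(d > 0, dy / d, 1)
  lim <- yolk$radius + band
  mag <- ifelse(d > lim, -k_in * (d - lim), 0)
  cbind(mag * nx, mag * ny)
}

#' Overdamped explicit Euler position update
#'
#' `position <- position + (force / eta) * dt`. Stability of the linear
#' spring requires `k_spring * dt / eta < 1`.
#'
#' @param positions n x 2 matrix of cell centres.
#' @param forces n x 2 matrix of total forces.
#' @param eta drag coefficient.
#' @param dt time step (h).
#' @return Updated n x 2 position matrix.
#' @export
integrate_step <- function(positions, forces, eta, dt) {
  stopifnot(dt > 0, eta > 0)
  if (!all(is.finite(forces)))
    stop("non-finite force encountered; aborting integration")
  positions + forces * (dt / eta)
}

#' One mechanics step on a tissue state
#'
#' Retriangulates the alive cells, sums spring, yolk-surface and
#' intercalation forces, and advances positions by one overdamped Euler
#' step. Cytoneme bases move rigidly with their source cells (tips are
#' recomputed from source positions on demand).
#'
#' @param state a `tissue_state`.
#' @param params a `cytospread_params`.
#' @return The updated `tissue_state`.
#' @export
mechanics_step <- function(state, params) {
  alive <- which(state$cells$alive)
  if (length(alive) == 0) return(state)
  pos <- cbind(state$cells$x[alive], state$cells$y[alive])
  radii <- state$cells$r[alive]
  f <- yolk_surface_force(pos, state$yolk, params$k_out) +
    intercalation_force(pos, state$yolk, params$k_in, params$band)
  if (length(alive) >= 2) {
    edges <- delaunay_neighbors(pos, params$neighbor_cutoff)
    f <- f + spring_forces(pos, radii, edges, params$k_spring,
                           params$detach_factor)
  }
  pos <- integrate_step(pos, f, params$eta, params$dt)
  state$cells$x[alive] <- pos[, 1]
  state$cells$y[alive] <- pos[, 2]
  state
}
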
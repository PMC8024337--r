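#' Circular yolk substrate
#'
#' The yolk is the rigid circular substrate over which the blastoderm
#' spreads. It defines outward normals, tangents and the angular coordinate
#' used throughout the analysis. The animal pole is the +y direction from
#' the yolk centre.
#'
#' @param radius yolk radius in micrometres; must be positive.
#' @param centre numeric length-2 centre.
#' @return An object of class `yolk` with fields `centre` and `radius`.
#' @export
#' @examples
#' make_yolk(300)
make_yolk <- function(radius, centre = c(0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0)
    stop("invalid parameter: yolk radius must be a positive number")
  stopifnot(is.numeric(centre), length(centre) == 2, all(is.finite(centre)))
  structure(list(centre = as.numeric(centre), radius = as.numeric(radius)),
            class = "yolk")
}

#' @export
print.yolk <- function(x, ...) {
  cat(sprintf("<yolk> centre = (%g, %g), radius = %g um\n",
              x$centre[1], x$centre[2], x$radius))
  invisible(x)
}

# math angle (CCW from +x) of cells relative to the yolk centre
.math_angle <- function(x, y, yolk) {
  atan2(y - yolk$centre[2], x - yolk$centre[1])
}

# clockwise offset from the animal pole (+y); in (-pi, pi]
.pole_offset <- function(x, y, yolk) {
  phi <- pi / 2 - .math_angle(x, y, yolk)
  ((phi + pi) %% (2 * pi)) - pi
}

.empty_cells <- function() {
  data.frame(id = integer(0), x = numeric(0), y = numeric(0),
             r = numeric(0), role = character(0), wnt = numeric(0),
             fate = character(0), next_div = numeric(0),
             alive = logical(0), stringsAsFactors = FALSE)
}

.empty_cytonemes <- function() {
  data.frame(id = integer(0), source_id = integer(0), theta = numeric(0),
             length = numeric(0), tip_wnt = numeric(0), W0 = numeric(0),
             n_dep = integer(0), stringsAsFactors = FALSE)
}

.empty_ledger <- function() {
  c(loaded_total = 0, in_tips = 0, in_receivers = 0, decayed = 0,
    lost_to_death = 0)
}

#' Seed the initial gastrula tissue
#'
#' Places all cells at the animal pole of the yolk: radial distance
#' `R_y + r_c` (plus uniform jitter of half-width `jitter`) and angular
#' position uniform within an arc of half-width `alpha0` centred on the
#' pole. The `n_source` cells nearest the clockwise end of the arc (the
#' future leading edge of the margin) become Wnt8a source cells; the rest
#' are receivers and get a division clock drawn uniformly from
#' `[T_div_min, T_div_max]`. Sources never divide so their cytoneme anchors
#' persist for the whole run.
#'
#' Randomness uses R's global RNG stream; call `set.seed()` for
#' reproducibility.
#'
#' @param params a `cytospread_params` object.
#' @return A `tissue_state`: list with `time`, `yolk`, `cells` and
#'   `cytonemes` data frames, the Wnt ledger, and id counters.
#' @export
#' @examples
#' set.seed(1)
#' st <- seed_tissue(sim_params(n_init = 20, n_source = 4))
#' table(st$cells$role)
seed_tissue <- function(params) {
  validate_params(params)
  yolk <- make_yolk(params$R_y)
  n <- params$n_init
  state <- structure(list(time = 0, yolk = yolk, cells = .empty_cells(),
                          cytonemes = .empty_cytonemes(),
                          ledger = .empty_ledger(),
                          deposits = data.frame(time = numeric(0),
                                                cytoneme_id = integer(0),
                                                receiver_id = integer(0),
                                                amount = numeric(0)),
                          next_cell_id = 1L, next_cyt_id = 1L,
                          n_cyt_target = 0L),
                     class = "tissue_state")
  if (n == 0L) return(state)

  phi <- runif(n, -params$alpha0, params$alpha0)   # clockwise from +y
  rad <- params$R_y + params$r_c + runif(n, -params$jitter, params$jitter)
  psi <- pi / 2 - phi
  xs <- yolk$centre[1] + rad * cos(psi)
  ys <- yolk$centre[2] + rad * sin(psi)

  # largest clockwise offset = closest to the designated leading edge
  role <- rep("receiver", n)
  if (params$n_source > 0)
    role[order(phi, decreasing = TRUE)[seq_len(params$n_source)]] <- "source"

  next_div <- ifelse(role == "receiver",
                     runif(n, params$T_div_min, params$T_div_max), NA_real_)

  state$cells <- data.frame(
    id = seq_len(n), x = xs, y = ys, r = params$r_c, role = role,
    wnt = 0, fate = "unset", next_div = next_div, alive = TRUE,
    stringsAsFactors = FALSE)
  state$next_cell_id <- n + 1L
  state
}

#' Attach the initial cytoneme cohort
#'
#' Each source cell receives a Poisson(`lambda_cyt`) number of cytonemes,
#' all of zero length, tip-loaded with `W0` AU of Wnt8a, with growth
#' directions drawn around the local yolk tangent (see
#' [sample_cytoneme_angle()]). The total cytoneme count is fixed here and
#' conserved for the remainder of the simulation: every retraction is an
#' instantaneous replacement.
#'
#' @param state a `tissue_state` from [seed_tissue()].
#' @param params a `cytospread_params` object.
#' @return The updated `tissue_state`.
#' @export
init_cytonemes <- function(state, params) {
  validate_params(params)
  src <- state$cells[state$cells$role == "source" & state$cells$alive, ]
  n_src <- nrow(src)
  if (n_src == 0L || params$lambda_cyt == 0) {
    state$n_cyt_target <- nrow(state$cytonemes)
    return(state)
  }
  k <- rpois(n_src, params$lambda_cyt)
  m <- sum(k)
  if (m == 0L) {
    state$n_cyt_target <- nrow(state$cytonemes)
    return(state)
  }
  source_id <- rep(src$id, k)
  sx <- rep(src$x, k)
  sy <- rep(src$y, k)
  theta <- sample_cytoneme_angle(sx, sy, state$yolk, params$sigma_theta)
  state$cytonemes <- data.frame(
    id = seq.int(state$next_cyt_id, length.out = m),
    source_id = source_id, theta = theta, length = 0,
    tip_wnt = params$W0, W0 = params$W0, n_dep = 0L,
    stringsAsFactors = FALSE)
  state$next_cyt_id <- state$next_cyt_id + m
  state$n_cyt_target <- m
  state$ledger["loaded_total"] <- m * params$W0
  state$ledger["in_tips"] <- m * params$W0
  state
}

#' Check tissue-state invariants
#'
#' Verifies the structural invariants maintained by every simulation step:
#' non-negative ligand amounts, unique ids, cytoneme anchors referring to
#' alive source cells, conservation of the total cytoneme count, and the
#' Wnt ledger identity
#' `loaded_total = in_tips + in_receivers + decayed + lost_to_death`
#' to 1e-9 relative tolerance.
#'
#' @param state a `tissue_state`.
#' @param tol relative tolerance for the ledger identity.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
check_state <- function(state, tol = 1e-9) {
  cells <- state$cells
  cyt <- state$cytonemes
  if (anyDuplicated(cells$id)) stop("invariant violated: duplicate cell ids")
  if (anyDuplicated(cyt$id)) stop("invariant violated: duplicate cytoneme ids")
  if (any(cells$wnt < 0)) stop("invariant violated: negative cell wnt")
  if (any(cyt$length < 0)) stop("invariant violated: negative cytoneme length")
  if (any(cyt$tip_wnt < -1e-12) || any(cyt$tip_wnt > cyt$W0 + 1e-12))
    stop("invariant violated: tip_wnt outside [0, W0]")
  alive_src <- cells$id[cells$alive & cells$role == "source"]
  if (!all(cyt$source_id %in% alive_src) && nrow(cyt) > 0)
    stop("invariant violated: cytoneme anchored to missing source")
  if (nrow(cyt) != state$n_cyt_target)
    stop("invariant violated: cytoneme count not conserved")
  l <- state$ledger
  lhs <- l[["loaded_total"]]
  rhs <- l[["in_tips"]] + l[["in_receivers"]] + l[["decayed"]] +
    l[["lost_to_death"]]
  scale <- max(abs(lhs), abs(rhs), 1)
  if (abs(lhs - rhs) > tol * scale)
    stop(sprintf("invariant violated: ledger identity off by %g", lhs - rhs))
  invisible(TRUE)
}

#' @export
print.tissue_state <- function(x, ...) {
  cells <- x$cells[x$cells$alive, ]
  cat(sprintf(
    "<tissue_state> t = %.2f h: %d cells (%d source, %d receiver), %d cytonemes\n",
    x$time, nrow(cells), sum(cells$role == "source"),
    sum(cells$role == "receiver"), nrow(x$cytonemes)))
  invisible(x)
}
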
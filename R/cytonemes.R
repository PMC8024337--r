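#' Per-step cytoneme growth increment
#'
#' Growth increments are normal draws conditioned to be strictly positive
#' (negative samples are discarded and redrawn), i.e. a lower-truncated
#' normal. With `sigma_g = 0` the increment is exactly `mu_g`.
#'
#' @param n number of draws.
#' @param mu_g,sigma_g mean and sd of the untruncated normal (micrometres
#'   per step); not both zero.
#' @return `n` strictly positive increments.
#' @export
sample_growth_increment <- function(n, mu_g, sigma_g) {
  stopifnot(mu_g >= 0, sigma_g >= 0, mu_g > 0 || sigma_g > 0)
  if (n == 0) return(numeric(0))
  if (sigma_g == 0) return(rep(mu_g, n))
  out <- rnorm(n, mu_g, sigma_g)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mu_g, sigma_g)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Cytoneme growth direction
#'
#' Directions are normal around the yolk tangent at the source cell's
#' angular position, oriented towards the receiving tissue (counterclockwise,
#' i.e. towards the animal pole from the margin). A source on the +x axis of
#' an origin-centred yolk therefore has mean direction +y.
#'
#' @param x,y source-cell coordinates (vectorized).
#' @param yolk a [make_yolk()] object.
#' @param sigma_theta angular sd in radians.
#' @return Global direction angles in radians.
#' @export
sample_cytoneme_angle <- function(x, y, yolk, sigma_theta) {
  psi <- .math_angle(x, y, yolk)
  tangent <- psi + pi / 2
  if (sigma_theta == 0) return(tangent)
  rnorm(length(tangent), tangent, sigma_theta)
}

#' Cytoneme tip positions
#'
#' A cytoneme is a straight segment anchored at its source cell: the tip is
#' `source + length * (cos theta, sin theta)`. Bases move rigidly with the
#' source cell; `theta` is fixed for the cytoneme's lifetime.
#'
#' @param cytonemes cytoneme data frame.
#' @param cells cell data frame holding the anchor sources.
#' @return m x 2 matrix of tip coordinates.
#' @export
tip_position <- function(cytonemes, cells) {
  idx <- match(cytonemes$source_id, cells$id)
  if (anyNA(idx))
    stop("integrity error: cytoneme with dangling source_id")
  cbind(cells$x[idx] + cytonemes$length * cos(cytonemes$theta),
        cells$y[idx] + cytonemes$length * sin(cytonemes$theta))
}

#' Retraction predicate
#'
#' A cytoneme fully retracts this step if its Poisson retraction clock
#' fires (probability `1 - exp(-r_retract * dt)`), it exceeds the maximum
#' length, or its tip is empty of ligand.
#'
#' @param cytonemes cytoneme data frame.
#' @param params a `cytospread_params`.
#' @param u optional uniform draws (one per cytoneme); drawn from the
#'   global RNG when omitted.
#' @return Logical vector, `TRUE` where retraction is due.
#' @export
retraction_due <- function(cytonemes, params, u = NULL) {
  m <- nrow(cytonemes)
  if (m == 0) return(logical(0))
  if (is.null(u)) u <- runif(m)
  p <- 1 - exp(-params$r_retract * params$dt)
  (u < p) | (cytonemes$length > params$L_max) |
    (cytonemes$tip_wnt <= params$tip_eps)
}

#' Replace retracted cytonemes
#'
#' Retracted cytonemes are replaced instantaneously at the same source with
#' zero length, a fresh growth direction and a full tip load `W0`, so the
#' total cytoneme count is conserved. Residual undeposited tip ligand is
#' withdrawn (booked to `ledger["decayed"]`), and each fresh load adds to
#' `ledger["loaded_total"]`.
#'
#' @param state a `tissue_state`.
#' @param idx integer row indices of the cytonemes to replace.
#' @param params a `cytospread_params`.
#' @return The updated `tissue_state`.
#' @export
replace_cytoneme <- function(state, idx, params) {
  if (length(idx) == 0) return(state)
  cyt <- state$cytonemes
  residual <- sum(cyt$tip_wnt[idx])
  k <- length(idx)
  src_idx <- match(cyt$source_id[idx], state$cells$id)
  theta <- sample_cytoneme_angle(state$cells$x[src_idx],
                                 state$cells$y[src_idx],
                                 state$yolk, params$sigma_theta)
  cyt$id[idx] <- seq.int(state$next_cyt_id, length.out = k)
  cyt$theta[idx] <- theta
  cyt$length[idx] <- 0
  cyt$tip_wnt[idx] <- params$W0
  cyt$W0[idx] <- params$W0
  cyt$n_dep[idx] <- 0L
  state$next_cyt_id <- state$next_cyt_id + k
  state$cytonemes <- cyt
  state$ledger["decayed"] <- state$ledger[["decayed"]] + residual
  state$ledger["in_tips"] <- state$ledger[["in_tips"]] - residual +
    k * params$W0
  state$ledger["loaded_total"] <- state$ledger[["loaded_total"]] +
    k * params$W0
  state
}

#' Contact detection
#'
#' A tip is in contact with a receiver when the Euclidean distance between
#' tip and cell centre is strictly below the cell radius. Among qualifying
#' alive receivers the nearest wins; ties break to the smaller cell id.
#' Source cells are never contact targets.
#'
#' @param tips m x 2 matrix of tip coordinates.
#' @param cells cell data frame.
#' @return Integer vector of receiver cell ids (NA where no contact).
#' @export
detect_contact <- function(tips, cells) {
  m <- nrow(tips)
  out <- rep(NA_integer_, m)
  if (m == 0) return(out)
  rec <- cells[cells$alive & cells$role == "receiver", ]
  if (nrow(rec) == 0) return(out)
  rec <- rec[order(rec$id), ]
  # prefilter receivers to the tips' bounding box (plus max radius)
  rmax <- max(rec$r)
  keep <- rec$x >= min(tips[, 1]) - rmax & rec$x <= max(tips[, 1]) + rmax &
    rec$y >= min(tips[, 2]) - rmax & rec$y <= max(tips[, 2]) + rmax
  rec <- rec[keep, ]
  if (nrow(rec) == 0) return(out)
  # m x n squared distances; non-contacts masked out
  d2 <- outer(tips[, 1], rec$x, "-")^2 + outer(tips[, 2], rec$y, "-")^2
  r2 <- rec$r^2
  mask <- if (length(unique(r2)) == 1L) d2 < r2[1] else
    d2 < matrix(r2, nrow(tips), length(r2), byrow = TRUE)
  d2[!mask] <- Inf
  nearest <- max.col(-d2, ties.method = "first")  # first = smallest id
  has <- is.finite(d2[cbind(seq_len(m), nearest)])
  out[has] <- rec$id[nearest[has]]
  out
}

#' Deposition event trigger
#'
#' While a tip is in contact, deposits fire as a Poisson process: within
#' one step a deposit occurs with probability `1 - exp(-k_dep * dt)`.
#'
#' @param n number of independent trials.
#' @param params a `cytospread_params`.
#' @param u optional uniform draws.
#' @return Logical vector.
#' @export
deposition_fires <- function(n, params, u = NULL) {
  if (n == 0) return(logical(0))
  if (is.null(u)) u <- runif(n)
  u < 1 - exp(-params$k_dep * params$dt)
}

#' Single ligand deposit
#'
#' Transfers `min(f_dep * W0, tip_wnt)` from a cytoneme tip to a receiver.
#' The deposited amount is a fraction of the cytoneme's *initial* load, so
#' `f_dep = 1` allows exactly one deposit per cytoneme and `f_dep = 0.2` up
#' to five (possibly onto the same cell across steps).
#'
#' @param state a `tissue_state`.
#' @param cyt_row row index of the depositing cytoneme.
#' @param receiver_id id of the contacted alive receiver.
#' @param params a `cytospread_params`.
#' @return The updated `tissue_state`; the event is appended to
#'   `state$deposits`.
#' @export
deposit <- function(state, cyt_row, receiver_id, params) {
  cyt <- state$cytonemes
  if (cyt$tip_wnt[cyt_row] <= 0)
    stop("contract violation: deposit from an empty tip")
  amount <- min(params$f_dep * cyt$W0[cyt_row], cyt$tip_wnt[cyt_row])
  cell_idx <- match(receiver_id, state$cells$id)
  stopifnot(!is.na(cell_idx), state$cells$alive[cell_idx])
  state$cytonemes$tip_wnt[cyt_row] <- cyt$tip_wnt[cyt_row] - amount
  state$cytonemes$n_dep[cyt_row] <- cyt$n_dep[cyt_row] + 1L
  state$cells$wnt[cell_idx] <- state$cells$wnt[cell_idx] + amount
  state$ledger["in_tips"] <- state$ledger[["in_tips"]] - amount
  state$ledger["in_receivers"] <- state$ledger[["in_receivers"]] + amount
  ev <- data.frame(time = state$time, cytoneme_id = cyt$id[cyt_row],
                   receiver_id = receiver_id, amount = amount)
  state$deposits <- rbind(state$deposits, ev)
  state
}

#' Exponential ligand decay in receivers
#'
#' Applies the analytic per-step factor `exp(-lambda_decay * dt)` to every
#' alive receiver, so decay over k steps composes exactly with no Euler
#' error. Decayed amounts are booked to the ledger.
#'
#' @param state a `tissue_state`.
#' @param params a `cytospread_params`.
#' @return The updated `tissue_state`.
#' @export
decay_receivers <- function(state, params) {
  if (params$lambda_decay == 0) return(state)
  idx <- which(state$cells$alive & state$cells$role == "receiver" &
                 state$cells$wnt > 0)
  if (length(idx) == 0) return(state)
  fac <- exp(-params$lambda_decay * params$dt)
  lost <- sum(state$cells$wnt[idx]) * (1 - fac)
  state$cells$wnt[idx] <- state$cells$wnt[idx] * fac
  state$ledger["decayed"] <- state$ledger[["decayed"]] + lost
  state$ledger["in_receivers"] <- state$ledger[["in_receivers"]] - lost
  state
}

#' One cytoneme life-cycle and transport step
#'
#' In ascending cytoneme id order: cytonemes due for retraction are
#' replaced; all others grow by a truncated-normal increment, their tips
#' are recomputed, contacts with receivers detected, and each contacted
#' tip deposits with Poisson probability.
#'
#' @param state a `tissue_state`.
#' @param params a `cytospread_params`.
#' @return The updated `tissue_state`.
#' @export
cytoneme_step <- function(state, params) {
  m <- nrow(state$cytonemes)
  if (m == 0) return(state)
  # keep id order fixed for the RNG stream
  ord <- order(state$cytonemes$id)
  state$cytonemes <- state$cytonemes[ord, ]

  retract <- retraction_due(state$cytonemes, params)
  grow_idx <- which(!retract)
  state <- replace_cytoneme(state, which(retract), params)

  if (length(grow_idx) > 0) {
    inc <- sample_growth_increment(length(grow_idx), params$mu_g,
                                   params$sigma_g)
    state$cytonemes$length[grow_idx] <-
      state$cytonemes$length[grow_idx] + inc
    tips <- tip_position(state$cytonemes[grow_idx, ], state$cells)
    target <- detect_contact(tips, state$cells)
    contact <- which(!is.na(target))
    if (length(contact) > 0) {
      fires <- deposition_fires(length(contact), params)
      hit <- contact[fires]
      if (length(hit) > 0) {
        # vectorized batch of single deposits: each cytoneme deposits at
        # most once per step, so the batch is equivalent to applying
        # deposit() sequentially in ascending id order
        rows <- grow_idx[hit]
        cyt <- state$cytonemes
        if (any(cyt$tip_wnt[rows] <= 0))
          stop("contract violation: deposit from an empty tip")
        amount <- pmin(params$f_dep * cyt$W0[rows], cyt$tip_wnt[rows])
        state$cytonemes$tip_wnt[rows] <- cyt$tip_wnt[rows] - amount
        state$cytonemes$n_dep[rows] <- cyt$n_dep[rows] + 1L
        rid <- target[hit]
        add <- rowsum(amount, rid)
        cell_idx <- match(as.integer(rownames(add)), state$cells$id)
        state$cells$wnt[cell_idx] <- state$cells$wnt[cell_idx] + add[, 1]
        state$ledger["in_tips"] <- state$ledger[["in_tips"]] - sum(amount)
        state$ledger["in_receivers"] <-
          state$ledger[["in_receivers"]] + sum(amount)
        state$deposits <- rbind(
          state$deposits,
          data.frame(time = state$time, cytoneme_id = cyt$id[rows],
                     receiver_id = rid, amount = amount))
      }
    }
  }
  state
}
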
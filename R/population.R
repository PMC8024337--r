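#' Receiver-cell division (renewal process)
#'
#' Every alive receiver whose division clock has expired divides: a
#' daughter appears at the mother's position displaced by `0.3 * r_c` in a
#' uniformly random direction, and both cells draw fresh clocks
#' `t + U(T_div_min, T_div_max)`. Daughters start with zero ligand; the
#' mother's ligand is not split. Source cells never divide.
#'
#' @param state a `tissue_state`.
#' @param params a `cytospread_params`.
#' @return The updated `tissue_state`.
#' @export
division_step <- function(state, params) {
  cells <- state$cells
  due <- which(cells$alive & cells$role == "receiver" &
                 !is.na(cells$next_div) & cells$next_div <= state$time)
  if (length(due) == 0) return(state)
  k <- length(due)
  ang <- runif(k, 0, 2 * pi)
  disp <- 0.3 * cells$r[due]
  daughters <- data.frame(
    id = seq.int(state$next_cell_id, length.out = k),
    x = cells$x[due] + disp * cos(ang),
    y = cells$y[due] + disp * sin(ang),
    r = cells$r[due], role = "receiver", wnt = 0, fate = "unset",
    next_div = state$time + runif(k, params$T_div_min, params$T_div_max),
    alive = TRUE, stringsAsFactors = FALSE)
  cells$next_div[due] <- state$time +
    runif(k, params$T_div_min, params$T_div_max)
  state$cells <- rbind(cells, daughters)
  state$next_cell_id <- state$next_cell_id + k
  state
}

#' Receiver-cell apoptosis (Poisson process)
#'
#' Each alive receiver dies independently within one step with probability
#' `1 - exp(-p_apop * dt)`. Dead cells are removed from the tissue
#' entirely; their ligand is booked to `ledger["lost_to_death"]`. Source
#' cells never die, so cytoneme anchors persist.
#'
#' @param state a `tissue_state`.
#' @param params a `cytospread_params`.
#' @return The updated `tissue_state`.
#' @export
apoptosis_step <- function(state, params) {
  if (params$p_apop == 0) return(state)
  cells <- state$cells
  cand <- which(cells$alive & cells$role == "receiver")
  if (length(cand) == 0) return(state)
  p <- 1 - exp(-params$p_apop * params$dt)
  dies <- cand[runif(length(cand)) < p]
  if (length(dies) == 0) return(state)
  state$ledger["lost_to_death"] <-
    state$ledger[["lost_to_death"]] + sum(cells$wnt[dies])
  state$ledger["in_receivers"] <-
    state$ledger[["in_receivers"]] - sum(cells$wnt[dies])
  state$cells <- cells[-dies, ]
  state
}
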
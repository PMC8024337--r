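#' Run one simulation
#'
#' Executes the full model from the seeded initial state to `t_end`. Each
#' step applies, in order: mechanics, division, apoptosis, receiver ligand
#' decay, and the cytoneme life-cycle/transport step. Structural invariants
#' (cytoneme-count conservation and the Wnt ledger identity) are asserted
#' every step. At the end, fates are assigned by thresholding and the
#' angular fate profile is computed with the origin at the leading edge of
#' the source margin.
#'
#' @param params a `cytospread_params`.
#' @param seed integer seed for this run (defaults to `params$seed`).
#' @param check_every assert invariants every this many steps (1 = every
#'   step).
#' @return A `sim_result` list: final `state` (fates assigned), `profile`
#'   (per-bin hindbrain proportions), `margin_angle`, `coverage` data frame
#'   (time, coverage, thickness, n_cells), `snapshots`, `seed`, `params`.
#' @export
#' @examples
#' res <- run_simulation(sim_params(n_init = 30, n_source = 5, t_end = 0.2,
#'                                  p_apop = 0), seed = 1)
#' res$state
run_simulation <- function(params, seed = params$seed, check_every = 1L) {
  validate_params(params)
  set.seed(seed)
  state <- seed_tissue(params)
  state <- init_cytonemes(state, params)
  check_state(state)

  n_steps <- as.integer(round(params$t_end / params$dt))
  cov_every <- max(1L, as.integer(round(params$coverage_every / params$dt)))
  snap_steps <- unique(as.integer(round(params$snapshot_times / params$dt)))
  snapshots <- list()

  cov_rows <- vector("list", n_steps %/% cov_every + 1L)
  record_cov <- function(slot) {
    ct <- coverage_and_thickness(state$cells, state$yolk)
    cov_rows[[slot]] <<- data.frame(
      time = state$time, coverage = ct$coverage, thickness = ct$thickness,
      n_cells = sum(state$cells$alive))
  }
  record_cov(1L)

  for (step in seq_len(n_steps)) {
    state$time <- step * params$dt
    state <- mechanics_step(state, params)
    state <- division_step(state, params)
    state <- apoptosis_step(state, params)
    state <- decay_receivers(state, params)
    state <- cytoneme_step(state, params)
    if (step %% check_every == 0L) check_state(state)
    if (step %% cov_every == 0L) record_cov(step %/% cov_every + 1L)
    if (step %in% snap_steps)
      snapshots[[sprintf("t%.2f", state$time)]] <- state
  }
  check_state(state)

  state$cells <- assign_fates(state$cells, params$threshold)
  edge <- if (any(state$cells$alive & state$cells$role == "source"))
    margin_edge_angle(state) else 0
  profile <- bin_fate_proportions(state$cells, params$n_bins, state$yolk,
                                  edge)
  structure(list(state = state, profile = profile, margin_angle = edge,
                 coverage = do.call(rbind, cov_rows), snapshots = snapshots,
                 seed = seed, params = params),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> seed %d, t = %g h, MHB bin (single run) = %s\n",
              x$seed, x$state$time,
              ifelse(is.na(estimate_mhb(x$profile)), "none",
                     estimate_mhb(x$profile))))
  invisible(x)
}

#' Run an ensemble of simulations
#'
#' Runs `n_sims` independent simulations with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n_sims - 1`, aggregates the
#' angular fate profiles into an ensemble mean/sd, estimates the MHB bin,
#' and pools end-state cytoneme lengths for the log-normal fit.
#'
#' @param params a `cytospread_params`.
#' @param n_sims ensemble size (defaults to `params$n_sims`).
#' @param base_seed first seed (defaults to `params$seed`).
#' @param keep_states keep every run's final state (memory-heavy; default
#'   keeps only the last).
#' @return An `ensemble_result`: `profile` (a `fate_profile`), `mhb_bin`,
#'   `lengths` (pooled, micrometres), `lognormal_mean` (cell diameters),
#'   `hindbrain_counts` per run, `coverage` of the last run, `last_run`,
#'   `params`, `n_sims`, `base_seed`.
#' @export
run_ensemble <- function(params, n_sims = params$n_sims,
                         base_seed = params$seed, keep_states = FALSE) {
  stopifnot(n_sims >= 1)
  profiles <- vector("list", n_sims)
  lengths <- vector("list", n_sims)
  hb_counts <- integer(n_sims)
  states <- if (keep_states) vector("list", n_sims) else NULL
  last <- NULL
  for (i in seq_len(n_sims)) {
    res <- run_simulation(params, seed = base_seed + i - 1L)
    profiles[[i]] <- res$profile
    lengths[[i]] <- res$state$cytonemes$length
    hb_counts[i] <- sum(res$state$cells$fate == "hindbrain")
    if (keep_states) states[[i]] <- res$state
    last <- res
  }
  prof <- ensemble_profile(profiles)
  pooled <- unlist(lengths)
  ln_mean <- if (any(pooled > 0))
    lognormal_mean(pooled, 2 * params$r_c) else NA_real_
  structure(list(profile = prof, mhb_bin = prof$mhb_bin, lengths = pooled,
                 lognormal_mean = ln_mean, hindbrain_counts = hb_counts,
                 run_profiles = profiles, coverage = last$coverage,
                 last_run = last, states = states, params = params,
                 n_sims = n_sims, base_seed = base_seed),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> %d runs (seeds %d..%d), MHB bin = %s, lognormal mean = %.2f\n",
    x$n_sims, x$base_seed, x$base_seed + x$n_sims - 1,
    ifelse(is.na(x$mhb_bin), "none", x$mhb_bin), x$lognormal_mean))
  invisible(x)
}

#' Write ensemble outputs to a directory
#'
#' Writes `cells.csv`, `cytonemes.csv` and `deposits.csv` (from the last
#' run), `profile.csv` (bin_index, mean, sd, n_occupied), `summary.json`
#' (mhb_bin, coverage, thickness, lognormal_mean, n_sims, base_seed) and
#' `config.json` (the parameter registry; readable by [read_config()]).
#'
#' @param result an `ensemble_result`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  if (!inherits(result, "ensemble_result") || is.null(result$last_run))
    stop("invalid input: need a non-empty ensemble_result")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- result$last_run$state
  cells <- st$cells
  cells$angle <- angular_coordinate(cells$x, cells$y, st$yolk,
                                    result$last_run$margin_angle)
  write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  write.csv(st$cytonemes, file.path(out_dir, "cytonemes.csv"),
            row.names = FALSE)
  write.csv(st$deposits, file.path(out_dir, "deposits.csv"),
            row.names = FALSE)
  prof <- result$profile
  write.csv(data.frame(bin_index = seq_len(prof$n_bins) - 1L,
                       mean = prof$mean, sd = prof$sd,
                       n_occupied = prof$n_occupied),
            file.path(out_dir, "profile.csv"), row.names = FALSE)
  ct <- coverage_and_thickness(st$cells, st$yolk)
  jsonlite::write_json(
    list(mhb_bin = result$mhb_bin, coverage = ct$coverage,
         thickness = ct$thickness, lognormal_mean = result$lognormal_mean,
         n_sims = result$n_sims, base_seed = result$base_seed),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  write_config(result$params, file.path(out_dir, "config.json"))
  invisible(out_dir)
}

#' Toy 12-cell tissue fixture
#'
#' Small deterministic tissue used by tests and the `fixtures` CLI
#' subcommand: 12 cells on a ring of radius `R_y + r_c`, the 3 most
#' clockwise being sources.
#'
#' @param R_y yolk radius.
#' @param r_c cell radius.
#' @return A cell data frame in `tissue_state` layout.
#' @export
toy_tissue_fixture <- function(R_y = 100, r_c = 10) {
  phi <- seq(-0.55, 0.55, length.out = 12)   # clockwise from +y
  psi <- pi / 2 - phi
  role <- c(rep("receiver", 9), rep("source", 3))
  data.frame(id = 1:12, x = (R_y + r_c) * cos(psi),
             y = (R_y + r_c) * sin(psi), r = r_c, role = role,
             wnt = 0, fate = "unset",
             next_div = ifelse(role == "receiver", 3, NA_real_),
             alive = TRUE, stringsAsFactors = FALSE)
}
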
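#' Simulation parameter registry
#'
#' Builds the full set of model parameters with calibrated control defaults.
#' Units: lengths in micrometres, times in hours, rates per hour, ligand in
#' arbitrary units (AU). The per-step cytoneme growth increment `mu_g` /
#' `sigma_g` is expressed per time step of width `dt`.
#'
#' @param ... named overrides of any default listed below.
#'
#' @details Parameter groups:
#' \describe{
#'   \item{geometry}{`R_y` yolk radius (300), `r_c` cell radius (10),
#'     `n_init` total initial cells (80), `n_source` marginal source cells
#'     (30), `alpha0` half-width of the initial animal-pole arc in radians
#'     (0.6), `jitter` radial placement jitter (2).}
#'   \item{mechanics}{`k_spring`, `k_out`, `k_in` force constants (30 each),
#'     `band` intercalation shell width (20 = one cell diameter beyond the
#'     yolk), `eta` drag (1), `dt` step (1/60 h), `detach_factor` spring
#'     detach cutoff as multiple of rest length (1.5), `neighbor_cutoff`
#'     fallback neighbour distance for degenerate point sets (30).}
#'   \item{population}{`T_div_min`/`T_div_max` uniform division-time bounds
#'     (3, 5 h), `p_apop` apoptosis rate (0.005 /h). Source cells neither
#'     divide nor die.}
#'   \item{cytonemes}{`lambda_cyt` mean cytonemes per source cell (5.7),
#'     `mu_g`/`sigma_g` growth increment per step, `sigma_theta` angular
#'     spread around the yolk tangent (0.3 rad), `r_retract` retraction rate
#'     (/h), `L_max` maximum length, `k_dep` deposition rate while in contact
#'     (30 /h), `lambda_decay` receiver ligand decay (0.5 /h), `f_dep`
#'     deposited fraction of the initial tip load (1), `W0` initial tip load
#'     (400 AU), `tip_eps` empty-tip tolerance (1e-9 AU).}
#'   \item{analysis}{`threshold` hindbrain fate threshold (100 AU), `n_bins`
#'     angular bins (100).}
#'   \item{run}{`t_end` simulated duration (10 h), `n_sims` ensemble size
#'     (100), `seed` master seed, `coverage_every` sampling interval for the
#'     coverage/thickness trajectory (0.1 h), `snapshot_times` times at
#'     which full states are kept.}
#' }
#'
#' @return An object of class `cytospread_params` (a named list).
#' @export
#' @examples
#' p <- sim_params(n_init = 50, n_source = 8, t_end = 1)
#' p$lambda_cyt
sim_params <- function(...) {
  p <- list(
    # geometry
    R_y = 300, r_c = 10, n_init = 80, n_source = 30, alpha0 = 0.6,
    jitter = 2,
    # mechanics
    k_spring = 30, k_out = 30, k_in = 30, band = 20, eta = 1, dt = 1 / 60,
    detach_factor = 1.5, neighbor_cutoff = 30,
    # population
    T_div_min = 3, T_div_max = 5, p_apop = 0.005,
    # cytonemes (control values; mu_g and r_retract fixed by calibrate())
    lambda_cyt = 5.7, mu_g = 8, sigma_g = 1.0, sigma_theta = 0.3,
    r_retract = 3, L_max = 120, k_dep = 30, lambda_decay = 0.5,
    f_dep = 1.0, W0 = 400, tip_eps = 1e-9,
    # analysis
    threshold = 100, n_bins = 100,
    # run control
    t_end = 10, n_sims = 100, seed = 1, coverage_every = 0.1,
    snapshot_times = numeric(0)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, dots)
  }
  class(p) <- "cytospread_params"
  validate_params(p)
  p
}

#' Validate a parameter registry
#'
#' @param p a `cytospread_params` object.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "cytospread_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid parameter: ", msg,
                                         call. = FALSE)
  chk(p$R_y > 0, "R_y must be > 0")
  chk(p$r_c > 0, "r_c must be > 0")
  chk(p$n_init >= 0, "n_init must be >= 0")
  chk(p$n_source >= 0 && p$n_source <= p$n_init,
      "need 0 <= n_source <= n_init")
  chk(p$dt > 0, "dt must be > 0")
  chk(p$eta > 0, "eta must be > 0")
  chk(p$t_end >= 0, "t_end must be >= 0")
  chk(p$f_dep > 0 && p$f_dep <= 1, "need 0 < f_dep <= 1")
  chk(p$T_div_max >= p$T_div_min && p$T_div_min > 0,
      "need 0 < T_div_min <= T_div_max")
  rates <- c("k_spring", "k_out", "k_in", "p_apop", "lambda_cyt", "mu_g",
             "sigma_g", "sigma_theta", "r_retract", "k_dep", "lambda_decay",
             "W0", "L_max", "band", "jitter", "alpha0")
  for (r in rates) chk(p[[r]] >= 0, paste(r, "must be >= 0"))
  chk(p$mu_g > 0 || p$sigma_g > 0, "mu_g and sigma_g cannot both be 0")
  chk(p$n_bins >= 1, "n_bins must be >= 1")
  invisible(p)
}

# Calibrated knob values for the lengthened-cytoneme (Vangl2 gain-of-function)
# condition, produced by calibrate_lengths() and frozen here: scales applied
# to the control growth increment, retraction rate and maximum length so that
# the pooled end-state length distribution matches the long-cytoneme target.
.vangl2_scales <- list(mu_g_scale = 1.33, r_retract_scale = 1.08,
                       L_max_scale = 1.275)

#' Condition presets
#'
#' Named parameter sets for the five simulated experimental conditions plus
#' the in-vivo 33 percent length increase:
#' \describe{
#'   \item{control}{calibrated baseline.}
#'   \item{wnt8a_oe}{ligand overexpression: initial tip load `W0` times 10.}
#'   \item{vangl2_longer}{lengthened cytonemes (calibrated growth/retraction/
#'     max-length scales) and `f_dep = 0.2`, allowing up to five deposit
#'     events per cytoneme.}
#'   \item{vangl2_invivo33}{growth increment scaled by 1.33 only, matching
#'     the measured in-vivo mean length increase.}
#'   \item{wnt8a_vangl2}{`vangl2_longer` with `W0` times 10.}
#'   \item{rescue_fewer}{`wnt8a_vangl2` with mean cytoneme number halved.}
#' }
#'
#' @param name preset name (see above).
#' @param ... further overrides applied after the preset, e.g. `t_end`.
#' @return A `cytospread_params` object.
#' @export
#' @examples
#' preset("wnt8a_oe")$W0 / preset("control")$W0   # 10
preset <- function(name, ...) {
  name <- match.arg(name, c("control", "wnt8a_oe", "vangl2_longer",
                            "wnt8a_vangl2", "rescue_fewer",
                            "vangl2_invivo33"))
  base <- sim_params()
  s <- .vangl2_scales
  longer <- list(mu_g = base$mu_g * s$mu_g_scale,
                 r_retract = base$r_retract * s$r_retract_scale,
                 L_max = base$L_max * s$L_max_scale,
                 f_dep = 0.2)
  ov <- switch(name,
    control = list(),
    wnt8a_oe = list(W0 = base$W0 * 10),
    vangl2_longer = longer,
    vangl2_invivo33 = list(mu_g = base$mu_g * 1.33),
    wnt8a_vangl2 = c(longer, list(W0 = base$W0 * 10)),
    rescue_fewer = c(longer, list(W0 = base$W0 * 10,
                                  lambda_cyt = base$lambda_cyt * 0.5))
  )
  do.call(sim_params, c(ov, list(...)))
}

#' Read / write a parameter configuration file
#'
#' Configurations are stored as JSON holding every parameter field;
#' `read_config(write_config(p, f))` round-trips exactly.
#'
#' @param p a `cytospread_params` object.
#' @param path file path.
#' @return `read_config` returns a `cytospread_params`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(p, path) {
  validate_params(p)
  # digits = I(17): full binary precision so read_config round-trips exactly
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- sim_params()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad))
    stop("config file has unknown field(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(names(defaults), names(raw))
  if (length(missing))
    stop("config file missing field(s): ", paste(missing, collapse = ", "))
  # JSON integers come back as integer type; parameters are all doubles
  for (n in names(raw))
    if (is.numeric(defaults[[n]])) raw[[n]] <- as.numeric(raw[[n]])
  do.call(sim_params, raw)
}
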
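#' Threshold end-state ligand into cell fates
#'
#' Receivers whose Wnt8a level strictly exceeds `threshold` acquire the
#' hindbrain fate; all other receivers become `"other"`
#' (forebrain/midbrain). Source cells keep fate `"unset"`.
#'
#' @param cells cell data frame.
#' @param threshold fate threshold in AU (default 100).
#' @return The cell data frame with the `fate` column filled in.
#' @export
assign_fates <- function(cells, threshold = 100) {
  rec <- cells$alive & cells$role == "receiver"
  cells$fate[rec] <- ifelse(cells$wnt[rec] > threshold, "hindbrain", "other")
  cells$fate[cells$role == "source"] <- "unset"
  cells
}

#' Angular polar coordinate around the yolk
#'
#' Angle of a point about the yolk centre, measured from the margin
#' leading-edge direction and increasing towards the animal pole
#' (counterclockwise), in `[0, 2*pi)`.
#'
#' @param x,y coordinates (vectorized).
#' @param yolk a [make_yolk()] object.
#' @param margin_edge_angle math angle (radians, counterclockwise from +x)
#'   of the leading-edge reference ray.
#' @return Angles in radians in `[0, 2*pi)`.
#' @export
angular_coordinate <- function(x, y, yolk, margin_edge_angle = 0) {
  (.math_angle(x, y, yolk) - margin_edge_angle) %% (2 * pi)
}

#' Leading-edge angle of the source margin
#'
#' Math angle of the most vegetal alive source cell (the one furthest
#' clockwise from the animal pole), used as the origin of the angular fate
#' profile.
#'
#' @param state a `tissue_state`.
#' @return Math angle in radians.
#' @export
margin_edge_angle <- function(state) {
  src <- state$cells[state$cells$alive & state$cells$role == "source", ]
  if (nrow(src) == 0) stop("no alive source cells")
  phi <- .pole_offset(src$x, src$y, state$yolk)
  pi / 2 - max(phi)
}

#' Per-bin hindbrain proportions
#'
#' Splits the circle into `n_bins` equi-spaced angular bins starting at the
#' margin leading edge and computes, per bin, the proportion of receivers
#' with hindbrain fate. Bins containing no receivers are `NA`.
#'
#' @param cells cell data frame with fates assigned.
#' @param n_bins number of bins (default 100).
#' @param yolk a [make_yolk()] object.
#' @param margin_edge_angle origin ray (math angle, radians).
#' @return Numeric vector of length `n_bins`; element k+1 is bin k
#'   (0-based), covering `[k, k+1) * 2*pi/n_bins`.
#' @export
bin_fate_proportions <- function(cells, n_bins, yolk,
                                 margin_edge_angle = 0) {
  rec <- cells[cells$alive & cells$role == "receiver" &
                 cells$fate != "unset", ]
  out <- rep(NA_real_, n_bins)
  if (nrow(rec) == 0) return(out)
  a <- angular_coordinate(rec$x, rec$y, yolk, margin_edge_angle)
  bin <- pmin(floor(a / (2 * pi) * n_bins), n_bins - 1) + 1L
  tot <- tabulate(bin, n_bins)
  hb <- tabulate(bin[rec$fate == "hindbrain"], n_bins)
  out[tot > 0] <- hb[tot > 0] / tot[tot > 0]
  out
}

#' Ensemble fate profile
#'
#' Per-bin mean and standard deviation of hindbrain proportions over an
#' ensemble of runs. Statistics for a bin use only the runs in which that
#' bin is occupied.
#'
#' @param profiles list of per-run proportion vectors (equal length).
#' @return A `fate_profile` object: list with `n_bins`, `mean`, `sd`,
#'   `n_occupied` and `mhb_bin` (0-based, see [estimate_mhb()]).
#' @export
ensemble_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  len <- vapply(profiles, length, 1L)
  if (length(unique(len)) != 1)
    stop("invalid input: profiles have differing numbers of bins")
  m <- do.call(rbind, profiles)
  n_occ <- colSums(!is.na(m))
  mu <- ifelse(n_occ > 0, colMeans(m, na.rm = TRUE), NA_real_)
  sdv <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(NA_real_)
    if (length(col) == 1) return(0)
    sd(col)
  })
  prof <- structure(list(n_bins = ncol(m), mean = mu, sd = sdv,
                         n_occupied = n_occ, mhb_bin = NA_integer_),
                    class = "fate_profile")
  prof$mhb_bin <- estimate_mhb(prof)
  prof
}

#' Midbrain-hindbrain boundary estimate
#'
#' The MHB is the first angular bin, scanning anteriorly from the margin
#' (bin 0), whose ensemble-mean hindbrain proportion falls strictly below
#' one half. Unoccupied (`NA`) bins are skipped so bare yolk cannot read as
#' forebrain.
#'
#' @param profile a `fate_profile` object or a numeric vector of per-bin
#'   mean proportions.
#' @return 0-based bin index, or `NA_integer_` if no bin qualifies.
#' @export
#' @examples
#' estimate_mhb(c(1, 1, 0.8, 0.6, 0.4, 0.2))   # 4
estimate_mhb <- function(profile) {
  mu <- if (inherits(profile, "fate_profile")) profile$mean else profile
  hit <- which(!is.na(mu) & mu < 0.5)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(hit[1] - 1L)
}

#' @export
print.fate_profile <- function(x, ...) {
  cat(sprintf("<fate_profile> %d bins, MHB bin = %s\n", x$n_bins,
              ifelse(is.na(x$mhb_bin), "none", x$mhb_bin)))
  invisible(x)
}

#' Fitted log-normal mean of cytoneme lengths
#'
#' Normalizes lengths by the cell diameter, fits a log-normal by maximum
#' likelihood (`mu = mean(log x)`, `sigma^2` the population variance of
#' `log x`) and returns the fitted distribution's arithmetic mean
#' `exp(mu + sigma^2 / 2)`. Zero-length (just-replaced) cytonemes are
#' excluded.
#'
#' @param lengths cytoneme lengths in micrometres.
#' @param cell_diameter normalization constant in micrometres.
#' @return Fitted mean in cell diameters.
#' @export
lognormal_mean <- function(lengths, cell_diameter) {
  lengths <- lengths[lengths > 0]
  if (length(lengths) == 0)
    stop("undefined result: no positive lengths to fit")
  lx <- log(lengths / cell_diameter)
  mu <- mean(lx)
  sigma2 <- mean((lx - mu)^2)
  exp(mu + sigma2 / 2)
}

#' Yolk coverage and tissue thickness
#'
#' Partitions the circle into angular columns of width `2 * r_c / R_y`
#' radians (one cell diameter of arc). Coverage is the fraction of columns
#' containing at least one alive cell; thickness is the mean cell count
#' over occupied columns.
#'
#' @param cells cell data frame.
#' @param yolk a [make_yolk()] object.
#' @return List with `coverage` (fraction) and `thickness` (cells).
#' @export
coverage_and_thickness <- function(cells, yolk) {
  cells <- cells[cells$alive, ]
  stopifnot(nrow(cells) >= 1)
  r_c <- cells$r[1]
  n_col <- ceiling(pi * yolk$radius / r_c)
  a <- .math_angle(cells$x, cells$y, yolk) %% (2 * pi)
  col <- pmin(floor(a / (2 * pi) * n_col), n_col - 1) + 1L
  counts <- tabulate(col, n_col)
  occ <- counts > 0
  list(coverage = sum(occ) / n_col, thickness = mean(counts[occ]))
}

#' Display normalization of ligand levels
#'
#' Plotting-only transform: levels are scaled by the maximum attained and
#' log transformed as `log(1 + (w / max) * (e - 1))`, mapping
#' monotonically onto `[0, 1]`.
#'
#' @param levels non-negative ligand levels.
#' @return Transformed values in `[0, 1]`.
#' @export
display_normalize_wnt <- function(levels) {
  mx <- max(levels)
  if (mx <= 0) return(rep(0, length(levels)))
  log(1 + (levels / mx) * (exp(1) - 1))
}
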
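# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# Delaunay by exhaustive empty-circumcircle test: an edge (i, j) is Delaunay
# iff some triangle (i, j, k) has an empty circumcircle (or the pair is on
# the convex hull of a collinear-free set with n < 3 handled by caller).
brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  incircle <- function(a, b, c, p) {
    m <- cbind(rbind(pts[a, ], pts[b, ], pts[c, ]) -
                 matrix(pts[p, ], 3, 2, byrow = TRUE))
    d2 <- rowSums(m^2)
    det(cbind(m, d2))
  }
  orient <- function(a, b, c) {
    (pts[b, 1] - pts[a, 1]) * (pts[c, 2] - pts[a, 2]) -
      (pts[b, 2] - pts[a, 2]) * (pts[c, 1] - pts[a, 1])
  }
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      o <- orient(i, j, k)
      if (abs(o) < 1e-12) next
      # order CCW so the incircle sign convention holds
      tri <- if (o > 0) c(i, j, k) else c(i, k, j)
      empty <- TRUE
      for (p in seq_len(n)) {
        if (p %in% tri) next
        if (incircle(tri[1], tri[2], tri[3], p) > 1e-9) {
          empty <- FALSE
          break
        }
      }
      if (empty) { found <- TRUE; break }
    }
    if (found) edges <- rbind(edges, c(i, j))
  }
  edges
}

# one-function reimplementation of the bin -> ensemble-mean -> MHB pipeline
brute_profile_mhb <- function(angle_list, fate_list, n_bins) {
  per_run <- lapply(seq_along(angle_list), function(r) {
    a <- angle_list[[r]]; f <- fate_list[[r]]
    sapply(seq_len(n_bins) - 1, function(k) {
      lo <- k * 2 * pi / n_bins; hi <- (k + 1) * 2 * pi / n_bins
      in_bin <- a >= lo & a < hi
      if (!any(in_bin)) return(NA_real_)
      mean(f[in_bin] == "hindbrain")
    })
  })
  mu <- sapply(seq_len(n_bins), function(k) {
    v <- sapply(per_run, `[`, k)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  mhb <- NA_integer_
  for (k in seq_len(n_bins)) {
    if (!is.na(mu[k]) && mu[k] < 0.5) { mhb <- k - 1L; break }
  }
  list(mean = mu, mhb = mhb)
}

# small fast parameter set for driver tests
tiny_params <- function(...) {
  defaults <- list(n_init = 24, n_source = 6, t_end = 0.5, p_apop = 0,
                   n_bins = 40)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# a state with hand-placed cells, for transport unit tests
make_manual_state <- function(cells, params, n_cyt_target = 0L) {
  yolk <- make_yolk(params$R_y)
  st <- seed_tissue(sim_params_0())
  st$yolk <- yolk
  st$cells <- cells
  st$next_cell_id <- max(cells$id) + 1L
  st$n_cyt_target <- n_cyt_target
  st
}

sim_params_0 <- function() sim_params(n_init = 0, n_source = 0)

manual_cells <- function(x, y, role, wnt = 0, r = 10) {
  n <- length(x)
  data.frame(id = seq_len(n), x = x, y = y, r = r, role = role,
             wnt = rep_len(wnt, n), fate = "unset",
             next_div = ifelse(role == "receiver", 1e9, NA_real_),
             alive = TRUE, stringsAsFactors = FALSE)
}
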
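test_that("growth increments are positive truncated-normal draws", {
  expect_equal(sample_growth_increment(5, 2, 0), rep(2, 5))
  set.seed(10)
  x <- sample_growth_increment(1000, 0.5, 2)
  expect_true(all(x > 0))

  # closed-form mean of a lower-truncated normal, +-2% at n = 1e5
  set.seed(11)
  y <- sample_growth_increment(1e5, 1, 2)
  m_expected <- 1 + 2 * dnorm(1 / 2) / pnorm(1 / 2)
  expect_lt(abs(mean(y) - m_expected) / m_expected, 0.02)
})

test_that("cytoneme angles centre on the oriented yolk tangent", {
  y <- make_yolk(300)
  # source on the +x axis: tangent towards the receiving tissue is +y
  expect_equal(sample_cytoneme_angle(310, 0, y, 0), pi / 2)
  # source at the animal pole (+y): tangent points along -x
  expect_equal(cos(sample_cytoneme_angle(0, 310, y, 0)), -1)

  set.seed(12)
  th <- sample_cytoneme_angle(rep(310, 1e4), rep(0, 1e4), y, 0.3)
  circ_mean <- atan2(mean(sin(th)), mean(cos(th)))
  expect_lt(abs(circ_mean - pi / 2), 0.02)
})

test_that("tips are rigid straight-segment endpoints", {
  p <- sim_params_0()
  cells <- manual_cells(5, 5, "source")
  cyt <- data.frame(id = 1L, source_id = 1L, theta = 0, length = 10,
                    tip_wnt = 400, W0 = 400, n_dep = 0L)
  expect_equal(tip_position(cyt, cells)[1, ], c(15, 5))
  cyt$length <- 0
  expect_equal(tip_position(cyt, cells)[1, ], c(5, 5))
  # base moves rigidly with the source
  cyt$length <- 10
  cells2 <- cells
  cells2$x <- cells2$x + 3; cells2$y <- cells2$y - 2
  expect_equal(tip_position(cyt, cells2)[1, ] - tip_position(cyt, cells)[1, ],
               c(3, -2))
  # dangling anchor is an integrity error
  cyt$source_id <- 99L
  expect_error(tip_position(cyt, cells), "integrity")
})

test_that("retraction fires on clock, max length, or empty tip", {
  p <- sim_params(r_retract = 0, L_max = 100)
  cyt <- data.frame(id = 1:3, source_id = 1L, theta = 0,
                    length = c(101, 50, 50),
                    tip_wnt = c(400, 0, 400), W0 = 400, n_dep = 0L)
  due <- retraction_due(cyt, p, u = rep(0.99, 3))
  expect_identical(due, c(TRUE, TRUE, FALSE))
  # the Poisson clock alone
  p2 <- sim_params(r_retract = 1e9, L_max = 100)
  expect_true(all(retraction_due(cyt, p2, u = rep(0.5, 3))))
})

test_that("replacement conserves count and books residual tip Wnt", {
  p <- sim_params(n_init = 4, n_source = 4, lambda_cyt = 3, W0 = 400)
  set.seed(13)
  st <- init_cytonemes(seed_tissue(p), p)
  m <- nrow(st$cytonemes)
  st$cytonemes$tip_wnt[1] <- 80
  st$cytonemes$length[1] <- 55
  st$ledger["decayed"] <- 320  # the 320 already deposited... kept abstract:
  st$ledger["in_tips"] <- st$ledger[["in_tips"]] - 320
  led0 <- st$ledger
  out <- replace_cytoneme(st, 1L, p)
  expect_equal(nrow(out$cytonemes), m)
  expect_equal(out$cytonemes$length[1], 0)
  expect_equal(out$cytonemes$tip_wnt[1], 400)
  expect_equal(out$cytonemes$n_dep[1], 0L)
  expect_gt(out$cytonemes$id[1], max(st$cytonemes$id))
  expect_equal(out$ledger[["decayed"]], led0[["decayed"]] + 80)
  expect_equal(out$ledger[["loaded_total"]], led0[["loaded_total"]] + 400)
  expect_silent(check_state(out))
})

test_that("contact detection uses strict distance and id tie-breaks", {
  p <- sim_params_0()
  cells <- manual_cells(c(0, 0, 100), c(0, 30, 0),
                        c("receiver", "receiver", "source"))
  # within half a radius of receiver 1
  expect_equal(detect_contact(rbind(c(5, 0)), cells)[1], 1L)
  # exactly at the radius: no contact (strict)
  expect_true(is.na(detect_contact(rbind(c(10, 0)), cells)[1]))
  # nearest of two qualifying receivers wins
  cells2 <- manual_cells(c(0, 1), c(0, 0), c("receiver", "receiver"))
  expect_equal(detect_contact(rbind(c(0.7, 0)), cells2)[1], 2L)
  # equidistant tie goes to the smaller id
  expect_equal(detect_contact(rbind(c(0.5, 0)), cells2)[1], 1L)
  # sources are never targets
  cells3 <- manual_cells(5, 0, "source")
  expect_true(is.na(detect_contact(rbind(c(5, 0)), cells3)[1]))
})

test_that("deposition fires as a Poisson process", {
  expect_false(any(deposition_fires(100, sim_params(k_dep = 0))))
  expect_true(all(deposition_fires(100, sim_params(k_dep = 1e9))))
  set.seed(14)
  p <- sim_params(k_dep = 30)  # dt = 1/60 -> p = 1 - exp(-0.5)
  hits <- mean(deposition_fires(1e5, p))
  prob <- 1 - exp(-0.5)
  expect_lt(abs(hits - prob), 3 * sqrt(prob * (1 - prob) / 1e5))
})

test_that("deposits transfer fixed fractions of the initial load", {
  p <- sim_params(n_init = 0, n_source = 0, f_dep = 0.2, W0 = 400)
  cells <- manual_cells(c(0, 30), c(0, 0), c("receiver", "source"))
  st <- make_manual_state(cells, p, n_cyt_target = 1L)
  st$cytonemes <- data.frame(id = 1L, source_id = 2L, theta = pi,
                             length = 25, tip_wnt = 400, W0 = 400,
                             n_dep = 0L)
  st$ledger["loaded_total"] <- 400
  st$ledger["in_tips"] <- 400
  for (k in 1:5) {
    st <- deposit(st, 1L, 1L, p)
    expect_equal(st$cytonemes$tip_wnt[1], 400 - 80 * k)
    expect_equal(st$cells$wnt[1], 80 * k)
    expect_equal(st$cytonemes$n_dep[1], k)
    expect_silent(check_state(st))
  }
  # the tip is exhausted after ceil(1/f_dep) = 5 deposits
  expect_error(deposit(st, 1L, 1L, p), "contract violation")
  expect_equal(nrow(st$deposits), 5)
  expect_equal(st$deposits$amount, rep(80, 5))

  # f_dep = 1: a single full deposit
  p1 <- sim_params(n_init = 0, n_source = 0, f_dep = 1, W0 = 400)
  st1 <- make_manual_state(cells, p1, n_cyt_target = 1L)
  st1$cytonemes <- data.frame(id = 1L, source_id = 2L, theta = pi,
                              length = 25, tip_wnt = 400, W0 = 400,
                              n_dep = 0L)
  st1$ledger["loaded_total"] <- 400
  st1$ledger["in_tips"] <- 400
  st1 <- deposit(st1, 1L, 1L, p1)
  expect_equal(st1$cytonemes$tip_wnt[1], 0)
  expect_equal(st1$cells$wnt[1], 400)
  expect_error(deposit(st1, 1L, 1L, p1), "contract violation")
})

test_that("receiver decay composes analytically", {
  p <- sim_params(lambda_decay = log(2), dt = 1)  # half-life 1 h
  cells <- manual_cells(0, 0, "receiver", wnt = 100)
  st <- make_manual_state(cells, p)
  st$ledger["loaded_total"] <- 100
  st$ledger["in_receivers"] <- 100
  st <- decay_receivers(st, p)
  expect_equal(st$cells$wnt[1], 50)
  expect_silent(check_state(st))

  # k steps compose exactly, no Euler error
  p2 <- sim_params(lambda_decay = 0.7)
  st2 <- make_manual_state(manual_cells(0, 0, "receiver", wnt = 123), p2)
  st2$ledger["loaded_total"] <- 123
  st2$ledger["in_receivers"] <- 123
  for (k in 1:25) st2 <- decay_receivers(st2, p2)
  expect_equal(st2$cells$wnt[1], 123 * exp(-0.7 * 25 * p2$dt))

  # lambda = 0 is a no-op
  p0 <- sim_params(lambda_decay = 0)
  expect_identical(decay_receivers(st2, p0), st2)
})

test_that("cytoneme_step grows, retracts, and conserves counts", {
  # no receivers in reach, no retraction: lengths strictly increase
  p <- sim_params(n_init = 5, n_source = 5, r_retract = 0, L_max = Inf,
                  lambda_cyt = 4)
  set.seed(15)
  st <- init_cytonemes(seed_tissue(p), p)
  len0 <- st$cytonemes$length
  st <- cytoneme_step(st, p)
  expect_true(all(st$cytonemes$length > len0))
  expect_silent(check_state(st))

  # infinite retraction rate: everything replaced, count constant
  p2 <- sim_params(n_init = 5, n_source = 5, r_retract = 1e12,
                   lambda_cyt = 4)
  set.seed(16)
  st2 <- init_cytonemes(seed_tissue(p2), p2)
  st2$cytonemes$length <- 7
  m <- nrow(st2$cytonemes)
  ids0 <- st2$cytonemes$id
  st2 <- cytoneme_step(st2, p2)
  expect_equal(nrow(st2$cytonemes), m)
  expect_true(all(st2$cytonemes$length == 0))
  expect_false(any(st2$cytonemes$id %in% ids0))
})

test_that("batched deposits in cytoneme_step equal sequential deposit()", {
  # three cytonemes guaranteed in contact, deposition certain
  p <- sim_params(n_init = 0, n_source = 0, f_dep = 0.2, W0 = 400,
                  k_dep = 1e12, r_retract = 0, L_max = Inf,
                  mu_g = 1e-9, sigma_g = 0)
  cells <- manual_cells(c(0, 60), c(0, 0), c("receiver", "source"))
  cyt <- data.frame(id = 1:3, source_id = 2L, theta = pi,
                    length = c(55, 56, 57), tip_wnt = c(400, 300, 100),
                    W0 = 400, n_dep = c(0L, 1L, 2L))
  mk <- function() {
    st <- make_manual_state(cells, p, n_cyt_target = 3L)
    st$cytonemes <- cyt
    st$ledger["loaded_total"] <- 1200
    st$ledger["in_tips"] <- 800
    st$ledger["in_receivers"] <- 400
    st
  }
  set.seed(17)
  batched <- cytoneme_step(mk(), p)
  seq_st <- mk()
  for (row in 1:3) seq_st <- deposit(seq_st, row, 1L, p)
  expect_equal(batched$cells$wnt, seq_st$cells$wnt)
  expect_equal(batched$cytonemes$tip_wnt, seq_st$cytonemes$tip_wnt)
  expect_equal(batched$cytonemes$n_dep, seq_st$cytonemes$n_dep)
  expect_equal(batched$ledger, seq_st$ledger)
  expect_equal(batched$deposits$amount, seq_st$deposits$amount)
})

test_that("cytoneme lifetimes are exponential (KS, transport off)", {
  # sources only, no receivers; small dt so the geometric-step lifetime
  # distribution is close to its exponential limit. Few cytonemes over a
  # long window keep the still-alive (length-biased) censored fraction
  # ~1%, which would otherwise skew the KS statistic.
  p <- sim_params(n_init = 13, n_source = 13, lambda_cyt = 8,
                  r_retract = 3, L_max = Inf, dt = 1 / 600,
                  mu_g = 0.2, sigma_g = 0.1)
  set.seed(18)
  st <- init_cytonemes(seed_tissue(p), p)
  birth <- setNames(rep(0L, nrow(st$cytonemes)),
                    as.character(st$cytonemes$id))
  lifetimes <- numeric(0)
  step <- 0L
  while (length(lifetimes) < 10000) {
    step <- step + 1L
    ids0 <- st$cytonemes$id
    st <- cytoneme_step(st, p)
    ids1 <- st$cytonemes$id
    died <- setdiff(ids0, ids1)
    if (length(died)) {
      lifetimes <- c(lifetimes,
                     (step - birth[as.character(died)]) * p$dt)
      born <- setdiff(ids1, ids0)
      birth <- c(birth[as.character(intersect(ids0, ids1))],
                 setNames(rep(step, length(born)), as.character(born)))
    }
  }
  ks <- suppressWarnings(ks.test(lifetimes, "pexp", rate = 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("tip load never increases except at replacement", {
  p <- sim_params(n_init = 30, n_source = 10, t_end = 1)
  set.seed(19)
  st <- init_cytonemes(seed_tissue(p), p)
  for (k in 1:120) {
    st$time <- k * p$dt
    prev <- st$cytonemes[, c("id", "tip_wnt")]
    st <- cytoneme_step(st, p)
    same <- match(prev$id, st$cytonemes$id)
    kept <- which(!is.na(same))
    expect_true(all(st$cytonemes$tip_wnt[same[kept]] <=
                      prev$tip_wnt[kept] + 1e-12))
    expect_silent(check_state(st))
  }
})
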
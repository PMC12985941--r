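test_that("the printed operating point is (nearly) a fixed point of the rhs", {
  # residuals limited only by the rounding of the printed concentrations
  # (3 significant digits on G6P/F6P propagate to ~0.02 mM/h through the
  # near-equilibrium GPI term); the exactly solved point is tested in the
  # steady-state suite
  y <- c(G6P = 0.0706, F6P = 0.0231,
         E = 2 * 1.5 + adp_amp_from_atp(1.5, ery$A_pool, ery$K_AK)$ADP)
  d <- model_rhs(0, y, ery)[[1L]]
  expect_true(all(abs(d) < 0.05))
})

test_that("rhs edge behaviour: no load accumulates E; clamped AMP stays put", {
  y <- initial_state(ery, ATP = 1.5, G6P = 0.0706, F6P = 0.0231)
  d <- model_rhs(0, y, ery, atpase_spec("linear", 1e-12))
  expect_gt(d[[1L]][3L], 0)  # dE/dt > 0 with ATP production unopposed
  tr <- simulate_model(ery_noak, initial_state(ery_noak, ATP = 1.2),
                       seq(0, 2, length.out = 40L))
  expect_equal(tr$AMP, rep(ery_noak$fixed_AMP, nrow(tr)))
  expect_equal(tr$ADP, ery_noak$A_pool - tr$ATP - tr$AMP, tolerance = 1e-12)
})

test_that("a steady state persists over 10 h of integration", {
  y0 <- equilibrate(ery)
  tr <- simulate_model(ery, y0, seq(0, 10, length.out = 20L))
  for (col in c("G6P", "F6P", "ATP"))
    expect_lt(max(abs(tr[[col]] - tr[[col]][1L]) / tr[[col]][1L]), 1e-3)
  expect_true(attr(tr, "converged"))
})

test_that("trajectories stay on the AK equilibrium manifold and conserve the pool", {
  tr <- simulate_model(ery, initial_state(ery, ATP = 1.0, G6P = 0.2, F6P = 0.05),
                       seq(0, 3, length.out = 200L))
  expect_lt(max(abs(tr$ATP * tr$AMP - ery$K_AK * tr$ADP^2)) / ery$A_pool^2,
            1e-8)
  expect_equal(tr$ATP + tr$ADP + tr$AMP, rep(ery$A_pool, nrow(tr)),
               tolerance = 1e-9)
  expect_true(all(tr$ATP >= 0 & tr$ADP >= 0 & tr$AMP >= 0 &
                  tr$G6P >= 0 & tr$F6P >= 0))
})

test_that("analytic AK flux equals the finite-difference AMP derivative", {
  # frozen anchor for the manifold slope dAMP/dE at the operating point,
  # verified against a central difference of the split
  E0 <- 3.2487; A <- 1.79; K <- 1
  h <- 1e-6
  fd <- (split_from_E(E0 + h, A, K)$AMP - split_from_E(E0 - h, A, K)$AMP) /
    (2 * h)
  expect_equal(glycak:::damp_dE(E0, A, K), fd, tolerance = 1e-6)
  expect_equal(glycak:::damp_dE(E0, A, K), -0.2124, tolerance = 1e-3)

  # along a transient on a uniform grid, V_AK matches the centred
  # difference of AMP(t) and integrates to the net AMP change
  y0 <- equilibrate(ery, atpase_spec("linear", 1.57))
  tr <- simulate_model(ery, y0, seq(0, 0.5, length.out = 2001L),
                       atpase_spec("linear", 3.24))
  vak <- ak_flux(tr)
  expect_equal(vak, tr$V_AK, tolerance = 1e-12)
  n <- nrow(tr)
  fd_amp <- (tr$AMP[3:n] - tr$AMP[1:(n - 2)]) / (tr$t[3:n] - tr$t[1:(n - 2)])
  expect_lt(max(abs(fd_amp - vak[2:(n - 1)])) / max(abs(vak)), 1e-3)
  integral <- sum(diff(tr$t) * (vak[-1] + vak[-n]) / 2)
  expect_equal(integral, tr$AMP[n] - tr$AMP[1L], tolerance = 1e-4)
})

test_that("doubling the ATPase load lowers ATP and raises AMP via a transient", {
  sr <- step_response(ery, "linear", 1.57, 3.24, t_end = 3)
  tr <- sr$trajectory
  n <- nrow(tr)
  expect_lt(tr$ATP[n], tr$ATP[1L])          # new steady ATP is lower
  expect_gt(tr$AMP[n], tr$AMP[1L])          # AMP settles higher
  expect_gte(max(tr$AMP), tr$AMP[n])        # after an overshoot-free rise
  expect_gt(sr$max_AK_share, 0)
  # V_AK relaxes back towards zero at the new steady state
  expect_lt(abs(tr$V_AK[n]), 1e-5)
  # a null step produces no AK transient
  sr0 <- step_response(ery, "linear", 1.57, 1.57, t_end = 0.5)
  expect_lt(sr0$max_AK_share, 1e-6)
})

test_that("the reduced model is the large-AK limit of the mass-action model", {
  # independent oracle for the equilibrium reduction: the explicit 5-state
  # model with finite AK rate converges to the reduced trajectories
  times <- seq(0, 2, length.out = 100L)
  atp0 <- 1.2
  s0 <- adp_amp_from_atp(atp0, ery$A_pool, ery$K_AK)
  tr3 <- simulate_model(ery, c(G6P = 0.05, F6P = 0.02, E = 2 * atp0 + s0$ADP),
                        times)
  init5 <- c(G6P = 0.05, F6P = 0.02, ATP = atp0, ADP = s0$ADP, AMP = s0$AMP)
  for (case in list(list(f = 1e3, tol = 0.01), list(f = 1e4, tol = 1e-3))) {
    tr5 <- simulate_mass_action(ery, init5, times, ak_activity_factor = case$f)
    err <- max(abs(tr5$ATP - tr3$ATP) / tr3$ATP,
               abs(tr5$G6P - tr3$G6P) / tr3$G6P,
               abs(tr5$F6P - tr3$F6P) / tr3$F6P)
    expect_lt(err, case$tol)
    # pool conservation holds along the brute-force trajectory too
    expect_equal(tr5$ATP + tr5$ADP + tr5$AMP, rep(ery$A_pool, nrow(tr5)),
                 tolerance = 1e-8)
  }
})

test_that("at steady state net glycolytic production balances consumption", {
  y <- equilibrate(ery)
  s <- split_from_E(y[["E"]], ery$A_pool, ery$K_AK)
  vpfk <- v_pfk(s$ATP, y[["F6P"]], s$AMP, ery)
  expect_equal(2 * vpfk, v_atpase(s$ATP, ery, "linear"), tolerance = 1e-6)
})
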
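test_that("the characteristic reproduces the erythrocyte operating point", {
  pt <- glycak:::solve_clamped_point(1.5, adp_amp_from_atp(1.5, 1.79, 1)$AMP,
                                     ery)
  expect_true(pt$converged)
  net <- 3 * pt$V - v_hk(1.5, pt$G6P, ery)
  expect_equal(net, 2.34, tolerance = 0.03)
  expect_equal(pt$G6P * 1000, 70.6, tolerance = 0.05)
  expect_equal(pt$F6P * 1000, 23.1, tolerance = 0.10)
  # at the solved point net production equals 2 V_PFK
  expect_equal(net, 2 * pt$V, tolerance = 1e-8)
})

test_that("every converged characteristic point balances the enzyme fluxes", {
  for (p in list(ery, mus, ery_noak)) {
    ch <- characteristic(p, n = 60L)
    ok <- ch$converged
    expect_true(all(ok))
    vhk <- v_hk(ch$ATP, ch$G6P, p)
    vgpi <- v_gpi(ch$G6P, ch$F6P, p)
    expect_lt(max(abs(vhk - vgpi)), 1e-8)
    expect_lt(max(abs(vgpi - ch$V_PFK)), 1e-8)
    expect_equal(ch$net_production, 2 * ch$V_PFK, tolerance = 1e-8)
    expect_equal(ch$gross_production, 4 * ch$V_PFK, tolerance = 1e-12)
  }
  # flux vanishes with ATP: both HK and PFK need the substrate
  expect_lt(glycak:::net_production_at(1e-3, ery), 0.02)
})

test_that("characteristic points are fixed points of the dynamics", {
  # cross-module consistency: balance each clamped point with the linear
  # ATPase that consumes exactly the produced rate, then check the rhs
  ch <- characteristic(ery, atp_grid = seq(0.3, 1.7, length.out = 15L))
  for (i in seq_len(nrow(ch))) {
    spec <- atpase_spec("linear", ch$net_production[i] / ch$ATP[i])
    y <- c(G6P = ch$G6P[i], F6P = ch$F6P[i], E = 2 * ch$ATP[i] + ch$ADP[i])
    expect_lt(max(abs(model_rhs(0, y, ery, spec)[[1L]])), 1e-6)
  }
})

test_that("the with-AK curve is a bell, the without-AK curve is monotone", {
  ch <- characteristic(ery, n = 120L)
  expect_identical(classify_characteristic(ch, operating_atp = 1.5), "bell")
  peak_i <- which.max(ch$net_production)
  expect_gt(peak_i, 1L)
  expect_lt(peak_i, nrow(ch))
  expect_gt(1.5, ch$ATP[peak_i])  # physiological point on descending branch
  chn <- characteristic(ery_noak, atp_grid = seq(0.1, 1.74, length.out = 120L))
  expect_identical(classify_characteristic(chn), "monotone")
  expect_true(all(diff(chn$net_production) > -1e-9))
})

test_that("the peak height scales with HK activity and falls with AMP activation", {
  # HK is the limiting activity, so the peak scales near-proportionally
  # with A_HK; the residual deviation (up to ~15% over 0.5x-2x) comes from
  # the finite PFK/GPI capacities that the proportionality argument ignores
  peak <- function(p) max(characteristic(p, n = 80L)$net_production)
  base <- peak(ery)
  for (s in c(0.5, 2)) {
    scaled <- peak(model_params("erythrocyte", A_HK = 12 * s))
    expect_equal(scaled / base, s, tolerance = 0.15)
    expect_identical(scaled > base, s > 1)
  }
  # weakening AMP activation (1000x K_PFK3, flattening both the activation
  # factor and the allosteric suppression's AMP site) removes the
  # descending branch entirely
  weak <- characteristic(model_params("erythrocyte", K_PFK3 = 10), n = 80L)
  expect_identical(classify_characteristic(weak), "monotone")
  # a 100x increase is not yet enough: the AMP site in the fourth-power
  # suppression term still responds over the pool's AMP range
  mid <- characteristic(model_params("erythrocyte", K_PFK3 = 1), n = 80L)
  expect_identical(classify_characteristic(mid), "bell")
})

test_that("the linear physiological load yields one stable state near 1.5 mM", {
  st <- find_steady_states(ery)
  nz <- st[st$ATP > 1e-9, ]
  expect_identical(nrow(nz), 1L)
  expect_identical(nz$stability, "stable")
  expect_identical(nz$branch, "descending")
  expect_equal(nz$ATP, 1.5, tolerance = 0.02)
  expect_true(all(Re(c(nz$eig1, nz$eig2, nz$eig3)) < 0))
  # production balances consumption at the solved state
  expect_equal(nz$net_production, nz$V_ATPase, tolerance = 1e-6)
})

test_that("hyperbolic load gives a stable/unstable pair, then none beyond the fold", {
  ch <- characteristic(ery)
  st <- find_steady_states(ery, atpase_spec("hyperbolic"), char = ch)
  nz <- st[st$ATP > 1e-9, ]
  expect_identical(nrow(nz), 2L)
  lo <- nz[which.min(nz$ATP), ]; hi <- nz[which.max(nz$ATP), ]
  expect_identical(lo$stability, "unstable")
  expect_identical(lo$branch, "ascending")
  expect_identical(hi$stability, "stable")
  expect_identical(hi$branch, "descending")
  expect_equal(hi$ATP, 1.5, tolerance = 0.02)
  # a maximal rate above the characteristic peak leaves only the zero
  # state; it is non-hyperbolic (at ATP = 0 the hexose phosphates G6P + F6P
  # are conserved, giving an exact zero eigenvalue), hence "marginal"
  st2 <- find_steady_states(ery, atpase_spec("hyperbolic", 6), char = ch)
  expect_true(all(st2$ATP < 1e-9))
  expect_identical(st2$branch, "zero")
  expect_identical(st2$stability, "marginal")
  expect_true(all(Re(c(st2$eig1, st2$eig2, st2$eig3)) < 1e-4))
})

test_that("stability calls agree with integration from perturbed starts", {
  ch <- characteristic(ery)
  st <- find_steady_states(ery, atpase_spec("hyperbolic"), char = ch)
  nz <- st[st$ATP > 1e-9, ]
  for (i in seq_len(nrow(nz))) {
    for (eps in c(-0.01, 0.01)) {
      atp0 <- nz$ATP[i] * (1 + eps)
      y0 <- initial_state(ery, atp0, nz$G6P[i], nz$F6P[i])
      tr <- simulate_model(ery, y0, seq(0, 50, length.out = 30L),
                           atpase_spec("hyperbolic"))
      drift <- abs(tr$ATP[nrow(tr)] - nz$ATP[i]) / nz$ATP[i]
      if (nz$stability[i] == "stable") {
        expect_lt(drift, abs(eps))          # pulled back to the state
      } else {
        expect_gt(drift, abs(eps))          # pushed away from it
      }
    }
  }
})

test_that("the bifurcation diagram brackets the saddle-node sharply", {
  ch <- characteristic(ery)
  bd <- bifurcation_diagram(ery, "hyperbolic",
                            seq(1, 6, length.out = 21L), char = ch)
  fold <- attr(bd, "fold_activity")
  bracket <- attr(bd, "fold_bracket")
  expect_false(is.na(fold))
  expect_lt(diff(bracket) / bracket[1L], 1.1e-3)
  # the fold sits where the hyperbolic Vmax makes the load tangent to the
  # characteristic peak: Vmax ~ peak * (1 + K_ATP/ATP_peak)
  peak_i <- which.max(ch$net_production)
  expect_equal(fold,
               max(ch$net_production) *
                 (1 + ery$atpase_K_ATP / ch$ATP[peak_i]),
               tolerance = 0.01)
  # below the fold both branches are present
  sub <- bd[bd$activity < fold & bd$ATP > 1e-9, ]
  expect_setequal(unique(sub$branch), c("descending", "ascending"))
  expect_identical(unique(sub$stability[sub$branch == "descending"]), "stable")
  expect_identical(unique(sub$stability[sub$branch == "ascending"]),
                   "unstable")
})

test_that("AK equilibrium stabilizes steady ATP against load changes", {
  ch <- characteristic(ery)
  sm <- stabilization_metrics(ery, "linear", char = ch)
  expect_lt(sm$C, 0)
  expect_gt(sm$Q, 5)
  expect_equal(sm$Q * sm$C, -1, tolerance = 1e-12)
  # twofold change across the physiological point moves ATP by ~10%
  sc <- steady_atp_change(ery, 0.5, 1, char = ch)
  expect_gt(sc$percent_change, 5)
  expect_lt(sc$percent_change, 15)
  # without AK the steady ATP roughly tracks 1/activity: no stabilization
  chn <- characteristic(ery_noak,
                        atp_grid = seq(0.05, 1.74, length.out = 300L))
  # the production curve rises with ATP (positive slope), so the drop is
  # at least proportional: ratio at or below ~1/2, far from the with-AK 0.9
  scn <- steady_atp_change(ery_noak, 1, 2, reference = "a", char = chn)
  ratio <- scn$ATP_b / scn$ATP_a
  expect_lt(ratio, 0.7)
  expect_gt(ratio, 0.15)
})

test_that("pool sweep reports the normalized overlay and its deviation", {
  ps <- pool_sweep(ery, n = 150L)
  expect_named(ps$curves, c("pool_0.9", "pool_1.79", "pool_3.58"))
  # each normalized curve peaks at (1, 1) by construction
  for (pool in unique(ps$overlay$pool)) {
    d <- ps$overlay[ps$overlay$pool == pool, ]
    expect_equal(max(d$rel_rate), 1)
    expect_equal(d$rel_ATP[which.max(d$rel_rate)], 1)
  }
  expect_gt(ps$max_deviation, 0)
  expect_lt(ps$max_deviation, 0.2)
  # without AK the rate law never sees the pool: the curve is pinned to
  # absolute ATP, so at a common *relative* ATP the rates differ strongly
  # between pools and no collapse is possible
  at <- function(A, atp) {
    pa <- model_params("erythrocyte", A_pool = A, ak_mode = "absent")
    glycak:::net_production_at(atp, pa)
  }
  expect_equal(at(3.58, 0.8), at(0.9, 0.8), tolerance = 1e-9)
  expect_gt(abs(at(3.58, 0.8 * 3.58) - at(0.9, 0.8 * 0.9)) /
              at(0.9, 0.8 * 0.9), 0.5)
})

test_that("the energy-charge view mirrors the relative-ATP view", {
  ch <- characteristic(ery, atp_grid = seq(1e-3, 1.78, length.out = 120L))
  cc <- data.frame(ATP = ch$ATP,
                   charge = energy_charge(ch$ATP, ch$ADP, ch$AMP),
                   rel_ATP = ch$ATP / ery$A_pool,
                   net_production = ch$net_production)
  i <- which.min(abs(cc$ATP - 1.5))
  expect_lt(abs(cc$charge[i] - cc$rel_ATP[i]) / cc$rel_ATP[i], 0.10)
  expect_true(all(cc$charge >= cc$rel_ATP))  # charge adds half the ADP
  expect_true(all(cc$charge >= 0 & cc$charge <= 1))
  # production falls to zero with the charge
  expect_lt(cc$net_production[which.min(cc$charge)],
            0.05 * max(cc$net_production))
  # exported view carries the same columns on the default grid
  cv <- characteristic_vs_charge(ery, n = 40L)
  expect_named(cv, c("ATP", "charge", "rel_ATP", "net_production"))
  expect_equal(cv$charge, (2 * cv$rel_ATP * ery$A_pool +
                             adp_amp_from_atp(cv$ATP, ery$A_pool, 1)$ADP) /
                 (2 * ery$A_pool), tolerance = 1e-12)
  expect_error(characteristic_vs_charge(ery_noak), "equilibrium")
})
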
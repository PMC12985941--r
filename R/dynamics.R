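# Assembly and integration of the ODE systems.
#
# With AK equilibrium the dynamic state is (G6P, F6P, E) with
#   dG6P/dt = V_HK - V_GPI
#   dF6P/dt = V_GPI - V_PFK
#   dE/dt   = -V_HK + 3*V_PFK - V_ATPase
# and ATP, ADP, AMP reconstructed algebraically from E at every evaluation.
# The balance of E = 2*ATP + ADP is free of the AK rate, which is why E is
# the right coordinate on the equilibrium manifold.
#
# Without AK the state is (G6P, F6P, ATP) with AMP clamped at its fixed
# physiological value and ADP = A - ATP - AMP (ADP enters no rate law).
#
# The explicit five-state mass-action model (G6P, F6P, ATP, ADP, AMP) with
# a finite AK rate V_AK = k_AK*(ADP^2 - ATP*AMP/K) serves as the
# independent oracle for the equilibrium reduction: as k_AK grows large its
# trajectories converge to the reduced three-state ones.

#' Right-hand side of the kinetic model
#'
#' Time derivatives of the dynamic state. With `ak_mode = "equilibrium"` the
#' state is `c(G6P, F6P, E)`; adenylates are reconstructed via
#' [split_from_E()] at each evaluation. With `ak_mode = "absent"` the state
#' is `c(G6P, F6P, ATP)` and AMP stays at `p$fixed_AMP`.
#'
#' @param t time (h); unused (the system is autonomous) but kept for solver
#'   compatibility.
#' @param state named numeric vector `c(G6P, F6P, E)` or `c(G6P, F6P, ATP)`
#'   depending on `p$ak_mode` (mM).
#' @param p a [model_params()] object.
#' @param atpase an [atpase_spec()]; `NULL` for the linear physiological load.
#' @param atp_inhibition passed to [v_pfk()].
#' @return list whose first element is the derivative vector (mM/h), with
#'   named flux components as attributes-free extra elements (deSolve
#'   convention): `V_HK`, `V_GPI`, `V_PFK`, `V_ATPase`, `ATP`, `ADP`, `AMP`.
#' @export
model_rhs <- function(t, state, p, atpase = NULL, atp_inhibition = TRUE) {
  spec <- resolve_atpase(atpase, p)
  G6P <- state[[1]]; F6P <- state[[2]]
  if (p$ak_mode == "equilibrium") {
    s <- split_from_E(state[[3]], p$A_pool, p$K_AK)
    ATP <- s$ATP; ADP <- s$ADP; AMP <- s$AMP
  } else {
    ATP <- state[[3]]
    if (ATP < -1e-12 || ATP > p$A_pool - p$fixed_AMP + 1e-12)
      stop("infeasible state: ATP outside [0, A - fixed_AMP]")
    ATP <- min(max(ATP, 0), p$A_pool - p$fixed_AMP)
    AMP <- p$fixed_AMP; ADP <- p$A_pool - ATP - AMP
  }
  vhk <- v_hk(ATP, max(G6P, 0), p)
  vgpi <- v_gpi(max(G6P, 0), max(F6P, 0), p)
  vpfk <- v_pfk(ATP, max(F6P, 0), AMP, p, atp_inhibition = atp_inhibition)
  vatp <- v_atpase_spec(ATP, spec)
  list(c(vhk - vgpi, vgpi - vpfk, -vhk + 3 * vpfk - vatp),
       V_HK = vhk, V_GPI = vgpi, V_PFK = vpfk, V_ATPase = vatp,
       ATP = ATP, ADP = ADP, AMP = AMP)
}

#' Build an initial state vector
#'
#' @param p a [model_params()] object.
#' @param ATP initial ATP (mM); ADP/AMP follow from AK equilibrium (or the
#'   clamp) and set `E` in equilibrium mode.
#' @param G6P,F6P initial hexose phosphates (mM).
#' @return named state vector suitable for [model_rhs()]/[simulate_model()].
#' @export
initial_state <- function(p, ATP, G6P = 0.05, F6P = 0.02) {
  stopifnot(ATP >= 0, G6P >= 0, F6P >= 0)
  if (p$ak_mode == "equilibrium") {
    s <- adp_amp_from_atp(ATP, p$A_pool, p$K_AK)
    c(G6P = G6P, F6P = F6P, E = 2 * ATP + s$ADP)
  } else {
    c(G6P = G6P, F6P = F6P, ATP = ATP)
  }
}

#' Integrate the kinetic model
#'
#' Stiff-capable integration (deSolve `lsoda`, rtol 1e-8 / atol 1e-10 mM) of
#' the reduced model, with adenylate concentrations and all reaction fluxes
#' (including the AK rate in equilibrium mode) attached to every sample.
#'
#' @inheritParams model_rhs
#' @param init named initial state from [initial_state()].
#' @param times output time grid (h), or a scalar end time (a default grid
#'   of 500 points is then used).
#' @param rtol,atol solver tolerances.
#' @return a `glycak_trajectory`: data frame with columns `t`, `G6P`, `F6P`,
#'   `E`, `ATP`, `ADP`, `AMP`, `V_HK`, `V_GPI`, `V_PFK`, `V_ATPase`, `V_AK`
#'   (mM and mM/h). Attribute `converged` is `TRUE` when all derivative
#'   magnitudes at the final sample are below 1e-6 mM/h; attributes `params`
#'   and `atpase` record the run.
#' @export
simulate_model <- function(p, init, times, atpase = NULL,
                           atp_inhibition = TRUE, rtol = 1e-8, atol = 1e-10) {
  spec <- resolve_atpase(atpase, p)
  if (length(times) == 1L) {
    stopifnot(times > 0)
    times <- seq(0, times, length.out = 500L)
  }
  sol <- deSolve::lsoda(
    y = init, times = times,
    func = function(t, y, parms) model_rhs(t, y, p, spec, atp_inhibition),
    parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("integration failed; last state: ",
         paste(format(utils::tail(sol, 1L)), collapse = " "))
  out <- as.data.frame(sol)
  names(out)[1L] <- "t"
  if (p$ak_mode == "absent") {
    # the clamped-mode state vector already carries ATP; drop the duplicate
    # auxiliary column and derive E for a uniform layout
    out <- out[, !duplicated(names(out))]
    out$E <- 2 * out$ATP + out$ADP
  }
  dE <- -out$V_HK + 3 * out$V_PFK - out$V_ATPase
  out$V_AK <- if (p$ak_mode == "equilibrium")
    damp_dE(out$E, p$A_pool, p$K_AK) * dE else 0
  out <- out[, c("t", "G6P", "F6P", "E", "ATP", "ADP", "AMP",
                 "V_HK", "V_GPI", "V_PFK", "V_ATPase", "V_AK")]
  final <- model_rhs(0, if (p$ak_mode == "equilibrium")
    c(out$G6P[nrow(out)], out$F6P[nrow(out)], out$E[nrow(out)])
    else c(out$G6P[nrow(out)], out$F6P[nrow(out)], out$ATP[nrow(out)]),
    p, spec, atp_inhibition)
  structure(out, class = c("glycak_trajectory", "data.frame"),
            converged = all(abs(final[[1L]]) < 1e-6),
            params = p, atpase = spec)
}

# analytic dAMP/dE on the AK equilibrium manifold: (E - A - Q) / (2 Q)
damp_dE <- function(E, A, K) {
  Q <- sqrt(pmax(A^2 - 2 * A * E + E^2 + 8 * A * E * K - 4 * E^2 * K, 0))
  (E - A - Q) / (2 * Q)
}

#' Adenylate kinase flux along a trajectory
#'
#' In the reduced model AMP changes only through the AK reaction, so the AK
#' rate equals dAMP/dt, computed analytically as
#' \deqn{V_{AK} = \frac{E - A - Q}{2Q}\,\frac{dE}{dt}}
#' with `Q` as in [split_from_E()] and `dE/dt = -V_HK + 3 V_PFK - V_ATPase`.
#' Positive values mean net ATP (and AMP) production by AK from 2 ADP.
#'
#' @param traj a `glycak_trajectory` from [simulate_model()] run in
#'   equilibrium mode.
#' @param p the matching [model_params()] object (defaults to the trajectory
#'   attribute).
#' @return numeric vector of AK rates (mM/h), one per sample.
#' @export
ak_flux <- function(traj, p = attr(traj, "params")) {
  stopifnot(inherits(traj, "glycak_trajectory"))
  if (p$ak_mode != "equilibrium")
    return(rep(0, nrow(traj)))
  dE <- -traj$V_HK + 3 * traj$V_PFK - traj$V_ATPase
  damp_dE(traj$E, p$A_pool, p$K_AK) * dE
}

#' Integrate the explicit five-state mass-action model
#'
#' Brute-force version of the model in which the AK reaction is an explicit
#' mass-action step `2 ADP -> ATP + AMP` with net rate
#' `V_AK = k_AK (ADP^2 - ATP*AMP/K)`, so all three nucleotides are dynamic:
#' \deqn{dATP/dt = -V_{HK} + 3V_{PFK} - V_{ATPase} + V_{AK},\quad
#'       dADP/dt = +V_{HK} - 3V_{PFK} + V_{ATPase} - 2V_{AK},\quad
#'       dAMP/dt = V_{AK}.}
#' As `k_AK` grows large the trajectories converge to the reduced
#' three-state model on the equilibrium manifold; this function is the
#' independent oracle for that reduction (and is itself stiff at large
#' `k_AK`).
#'
#' @inheritParams simulate_model
#' @param init named vector `c(G6P, F6P, ATP, ADP, AMP)` (mM).
#' @param ak_activity_factor the AK rate constant is
#'   `ak_activity_factor * flux_scale / A_pool^2` (1/(mM h)), with
#'   `flux_scale` the physiological net production rate `2*V_PFK`; factors
#'   of 1e3-1e4 put AK far above the glycolytic flux scale.
#' @param flux_scale reference glycolytic flux (mM/h).
#' @return data frame with `t`, the five states, and `V_AK`.
#' @export
simulate_mass_action <- function(p, init, times, atpase = NULL,
                                 ak_activity_factor = 1e4,
                                 flux_scale = 2.34,
                                 rtol = 1e-10, atol = 1e-12) {
  spec <- resolve_atpase(atpase, p)
  k_ak <- ak_activity_factor * flux_scale / p$A_pool^2
  rhs <- function(t, y, parms) {
    vhk <- v_hk(y[["ATP"]], max(y[["G6P"]], 0), p)
    vgpi <- v_gpi(max(y[["G6P"]], 0), max(y[["F6P"]], 0), p)
    vpfk <- v_pfk(y[["ATP"]], max(y[["F6P"]], 0), max(y[["AMP"]], 0), p)
    vatp <- v_atpase_spec(y[["ATP"]], spec)
    vak <- k_ak * (y[["ADP"]]^2 - y[["ATP"]] * y[["AMP"]] / p$K_AK)
    list(c(vhk - vgpi, vgpi - vpfk,
           -vhk + 3 * vpfk - vatp + vak,
           vhk - 3 * vpfk + vatp - 2 * vak,
           vak), V_AK = vak)
  }
  if (length(times) == 1L) times <- seq(0, times, length.out = 500L)
  sol <- deSolve::lsoda(init, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000L)
  if (attr(sol, "istate")[1L] < 0)
    stop("mass-action integration failed")
  out <- as.data.frame(sol)
  names(out)[1L] <- "t"
  out
}

#' Pre-equilibrated steady state under a given load
#'
#' Integrates 100 h from a physiological guess and verifies convergence
#' (all derivatives below 1e-6 mM/h); if the integration has not settled, a
#' Newton solve on the full system finishes the job.
#'
#' @inheritParams simulate_model
#' @param ATP_guess starting ATP (mM); default 0.838*A_pool, the normal
#'   relative ATP concentration.
#' @return named state vector at steady state.
#' @export
equilibrate <- function(p, atpase = NULL, ATP_guess = 0.838 * p$A_pool,
                        atp_inhibition = TRUE) {
  spec <- resolve_atpase(atpase, p)
  init <- initial_state(p, ATP_guess)
  tr <- simulate_model(p, init, seq(0, 100, length.out = 51L), spec,
                       atp_inhibition = atp_inhibition)
  n <- nrow(tr)
  y <- if (p$ak_mode == "equilibrium")
    c(G6P = tr$G6P[n], F6P = tr$F6P[n], E = tr$E[n])
  else c(G6P = tr$G6P[n], F6P = tr$F6P[n], ATP = tr$ATP[n])
  if (!isTRUE(attr(tr, "converged")))
    y <- newton_state(y, p, spec, atp_inhibition)
  y
}

# damped Newton on the full dynamic system (3 states), numerical Jacobian
newton_state <- function(y, p, spec, atp_inhibition = TRUE,
                         tol = 1e-12, maxit = 50L) {
  f <- function(v) model_rhs(0, v, p, spec, atp_inhibition)[[1L]]
  for (i in seq_len(maxit)) {
    r <- f(y)
    if (max(abs(r)) < tol) break
    J <- pracma::jacobian(f, y)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in steady-state Newton solve")
    lambda <- 1
    repeat {
      y2 <- y + lambda * step
      ok <- tryCatch(max(abs(f(y2))) < max(abs(r)) || lambda < 1e-4,
                     error = function(e) FALSE)
      if (ok) break
      lambda <- lambda / 2
    }
    y <- y + lambda * step
  }
  y
}

#' Transient response to a step in ATP-consuming activity
#'
#' Pre-equilibrates the model at `activity_before`, applies an instantaneous
#' change of the ATPase activity to `activity_after` at t = 0, and follows
#' the relaxation. The instantaneous share of the AK reaction in total ATP
#' production is
#' \deqn{100\,\frac{V_{AK}^+}{(3V_{PFK} - V_{HK}) + V_{AK}^+}\ \%,}
#' where `V_AK+ = max(V_AK, 0)`: total production counts net glycolytic
#' production plus the positive part of the AK rate, and episodes of AK
#' consuming ATP are reported separately (column `V_AK`), never netted
#' silently.
#'
#' @inheritParams simulate_model
#' @param atpase_kind `"linear"` or `"hyperbolic"`.
#' @param activity_before,activity_after ATPase activity before/after the
#'   step (1/h linear, mM/h hyperbolic); defaults: the physiological value
#'   and twice it.
#' @param t_end horizon after the step (h).
#' @param n_dense number of samples in the first tenth of the horizon,
#'   where the AK transient peaks.
#' @return a `glycak_step_response`: list with `trajectory` (the
#'   post-step `glycak_trajectory` plus columns `ak_share` and
#'   `production_total`, `production_gly`), `max_AK_share` (percent),
#'   `t_max_share`, and the resolved activities.
#' @export
step_response <- function(p, atpase_kind = c("linear", "hyperbolic"),
                          activity_before = NULL, activity_after = NULL,
                          t_end = 5, n_dense = 2000L) {
  atpase_kind <- match.arg(atpase_kind)
  if (p$ak_mode != "equilibrium")
    stop("step_response quantifies the AK share; run with ak_mode = 'equilibrium'")
  default_act <- if (atpase_kind == "linear") p$atpase_linear_a
                 else p$atpase_hyperbolic_Vmax
  if (is.null(activity_before)) activity_before <- default_act
  if (is.null(activity_after)) activity_after <- 2 * activity_before
  before <- atpase_spec(atpase_kind, activity_before)
  after <- atpase_spec(atpase_kind, activity_after)
  y0 <- equilibrate(p, before)
  times <- sort(unique(c(seq(0, t_end / 10, length.out = n_dense),
                         seq(t_end / 10, t_end, length.out = 500L))))
  tr <- simulate_model(p, y0, times, after)
  vak_pos <- pmax(tr$V_AK, 0)
  gly <- 3 * tr$V_PFK - tr$V_HK
  total <- gly + vak_pos
  tr$production_gly <- gly
  tr$production_total <- total
  tr$ak_share <- 100 * vak_pos / total
  i <- which.max(tr$ak_share)
  structure(list(trajectory = tr,
                 max_AK_share = tr$ak_share[i],
                 t_max_share = tr$t[i],
                 atpase_kind = atpase_kind,
                 activity_before = activity_before,
                 activity_after = activity_after),
            class = "glycak_step_response")
}

#' @export
print.glycak_step_response <- function(x, ...) {
  cat(sprintf(
    "ATPase step (%s): %.4g -> %.4g; max AK share %.2f%% at t = %.4g h\n",
    x$atpase_kind, x$activity_before, x$activity_after,
    x$max_AK_share, x$t_max_share))
  invisible(x)
}
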
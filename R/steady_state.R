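# Steady-state machinery: the glycolysis characteristic (net ATP production
# versus clamped ATP), steady states as characteristic/ATPase intersections
# refined on the full dynamic system, eigenvalue stability, bifurcation
# diagrams over ATPase activity with saddle-node bracketing, control and
# stabilization coefficients, pool sweeps, and the energy-charge view.

# forward-difference Jacobian; safe at the zero state where central
# differences would probe negative concentrations
fd_jacobian <- function(f, y, h = 1e-7) {
  f0 <- f(y)
  J <- matrix(0, length(f0), length(y))
  for (i in seq_along(y)) {
    y2 <- y; y2[i] <- y2[i] + h
    J[, i] <- (f(y2) - f0) / h
  }
  J
}

# Solve the clamped-ATP steady state of the hexose phosphates.
#
# With ATP (and hence AMP) clamped, steady state requires
# V_HK = V_GPI = V_PFK. V_HK is strictly decreasing in G6P, so for any flux
# v < V_HK(G6P = 0) there is a closed-form G6P with V_HK = v; V_PFK is
# strictly increasing in F6P. Nesting the closed form inside a single
# monotone root solve on F6P is globally convergent and needs no initial
# guess.
solve_clamped_point <- function(ATP, AMP, p, atp_inhibition = TRUE,
                                tol = 1e-12) {
  fail <- list(G6P = NA_real_, F6P = NA_real_, V = NA_real_, converged = FALSE)
  vhk_max <- p$A_HK * (ATP / p$K_HK1) / (1 + ATP / p$K_HK1)
  if (vhk_max < 1e-14)   # no ATP, no flux: the origin is the solved point
    return(list(G6P = 0, F6P = 0, V = 0, converged = TRUE))
  g6p_of_v <- function(v)
    p$K_HK2 * (p$A_HK * (ATP / p$K_HK1) / v - 1 - ATP / p$K_HK1)
  resid <- function(F6P) {
    v <- v_pfk(ATP, F6P, AMP, p, atp_inhibition = atp_inhibition)
    if (v >= vhk_max) return(-1e10)  # PFK demand exceeds what HK can supply
    v_gpi(g6p_of_v(v), F6P, p) - v
  }
  lo <- 1e-12
  if (resid(lo) <= 0) return(fail)
  hi <- 0.1
  while (resid(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e4) return(fail)
  }
  F6P <- stats::uniroot(resid, c(lo, hi), tol = tol)$root
  # polish with secant steps: uniroot controls the bracket width, not the
  # flux residual, which matters when A_GPI is large (muscle)
  r <- resid(F6P)
  h <- 1e-8 * max(F6P, 1e-8)
  for (i in 1:10) {
    if (abs(r) < 1e-11) break
    slope <- (resid(F6P + h) - r) / h
    if (!is.finite(slope) || slope == 0) break
    F6P2 <- F6P - r / slope
    if (F6P2 <= 0) break
    r2 <- resid(F6P2)
    if (!is.finite(r2) || abs(r2) >= abs(r)) break
    F6P <- F6P2; r <- r2
  }
  v <- v_pfk(ATP, F6P, AMP, p, atp_inhibition = atp_inhibition)
  list(G6P = g6p_of_v(v), F6P = F6P, V = v, converged = TRUE)
}

# AMP seen by PFK at a clamped ATP, honouring the AK mode
clamped_amp <- function(ATP, p) {
  if (p$ak_mode == "equilibrium")
    adp_amp_from_atp(ATP, p$A_pool, p$K_AK)$AMP
  else p$fixed_AMP
}

#' Glycolysis characteristic: steady-state production versus clamped ATP
#'
#' For each ATP on the grid, ADP and AMP are set by AK equilibrium (or AMP
#' clamped, per `p$ak_mode`), the hexose-phosphate steady state
#' `V_HK = V_GPI = V_PFK` is solved, and the net glycolytic ATP production
#' rate `3 V_PFK - V_HK` (= `2 V_PFK` at the solved point) is recorded. With
#' AK the curve is bell-shaped and its descending branch realizes negative
#' feedback of production by ATP; without AK it increases monotonically.
#'
#' @param p a [model_params()] object; `p$ak_mode` selects the mode.
#' @param atp_grid ascending ATP grid (mM); default 400 points on
#'   `(0.02 A, 0.995 A)` (capped at `A - fixed_AMP` without AK).
#' @param n grid size when `atp_grid` is `NULL`.
#' @param atp_inhibition passed to [v_pfk()].
#' @return a `glycak_characteristic`: data frame with columns `ATP`, `ADP`,
#'   `AMP`, `G6P`, `F6P`, `V_PFK`, `net_production`, `gross_production`
#'   (= 4 V_PFK), `converged`. Non-converged points are flagged, not
#'   dropped. Attributes: `mode`, `pool`, `params`.
#' @examples
#' ch <- characteristic(model_params("erythrocyte"), n = 50)
#' @export
characteristic <- function(p, atp_grid = NULL, n = 400L,
                           atp_inhibition = TRUE) {
  if (is.null(atp_grid)) {
    hi <- if (p$ak_mode == "equilibrium") 0.995 * p$A_pool
          else 0.995 * (p$A_pool - p$fixed_AMP)
    atp_grid <- seq(0.02 * p$A_pool, hi, length.out = n)
  }
  stopifnot(!is.unsorted(atp_grid), all(atp_grid > 0))
  rows <- lapply(atp_grid, function(ATP) {
    AMP <- clamped_amp(ATP, p)
    pt <- solve_clamped_point(ATP, AMP, p, atp_inhibition)
    ADP <- if (p$ak_mode == "equilibrium")
      adp_amp_from_atp(ATP, p$A_pool, p$K_AK)$ADP
    else p$A_pool - ATP - p$fixed_AMP
    vhk <- if (pt$converged) v_hk(ATP, pt$G6P, p) else NA_real_
    data.frame(ATP = ATP, ADP = ADP, AMP = AMP,
               G6P = pt$G6P, F6P = pt$F6P, V_PFK = pt$V,
               net_production = if (pt$converged) 3 * pt$V - vhk else NA_real_,
               gross_production = 4 * pt$V,
               converged = pt$converged)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("glycak_characteristic", "data.frame"),
            mode = p$ak_mode, pool = p$A_pool, params = p)
}

# net production at a single clamped ATP (scalar helper used by solvers)
net_production_at <- function(ATP, p, atp_inhibition = TRUE) {
  pt <- solve_clamped_point(ATP, clamped_amp(ATP, p), p, atp_inhibition)
  if (!pt$converged) return(NA_real_)
  3 * pt$V - v_hk(ATP, pt$G6P, p)
}

#' @export
print.glycak_characteristic <- function(x, ...) {
  ok <- x$converged
  cat(sprintf(
    "Glycolysis characteristic (%s AK, pool %.3g mM): %d points, peak %.4g mM/h at ATP = %.4g mM\n",
    if (attr(x, "mode") == "equilibrium") "with" else "without",
    attr(x, "pool"), nrow(x),
    max(x$net_production[ok]), x$ATP[ok][which.max(x$net_production[ok])]))
  invisible(x)
}

#' Locate and classify the steady states under a given ATPase load
#'
#' Intersections of the net-production characteristic with the ATPase curve
#' are bracketed on the clamped-ATP grid, refined by a root solve, polished
#' by a Newton solve on the full three-variable dynamic system, and
#' classified by the eigenvalues of the (numerical) Jacobian. The zero state
#' is reported when no nonzero steady state exists.
#'
#' @param p a [model_params()] object.
#' @param atpase an [atpase_spec()]; `NULL` for the linear physiological
#'   load.
#' @param char optionally, a precomputed [characteristic()] for `p` (reused
#'   by [bifurcation_diagram()] across activities).
#' @param atp_inhibition passed to [v_pfk()].
#' @return data frame of class `glycak_steady_states`, one row per state:
#'   `ATP`, `ADP`, `AMP`, `G6P`, `F6P` (mM), `V_PFK`, `V_ATPase`,
#'   `net_production` (mM/h), `eig1`, `eig2`, `eig3` (complex, sorted by
#'   real part, 1/h), `stability` (`"stable"`, `"unstable"` or
#'   `"marginal"`), `branch` (`"descending"`, `"ascending"` or `"zero"`).
#' @export
find_steady_states <- function(p, atpase = NULL, char = NULL,
                               atp_inhibition = TRUE) {
  spec <- resolve_atpase(atpase, p)
  if (is.null(char)) char <- characteristic(p, atp_inhibition = atp_inhibition)
  ok <- char$converged & is.finite(char$net_production)
  grid <- char$ATP[ok]
  h <- char$net_production[ok] - v_atpase_spec(char$ATP[ok], spec)
  idx <- which(diff(sign(h)) != 0 & is.finite(h[-1]) & is.finite(h[-length(h)]))
  f <- function(ATP) net_production_at(ATP, p, atp_inhibition) -
    v_atpase_spec(ATP, spec)
  roots <- vapply(idx, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-11)$root, 0)
  rows <- lapply(roots, function(ATP)
    steady_record(ATP, p, spec, atp_inhibition))
  if (!length(rows))
    rows <- list(steady_record(0, p, spec, atp_inhibition))
  out <- do.call(rbind, rows)
  out <- out[order(out$ATP), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("glycak_steady_states", "data.frame"),
            atpase = spec, params = p)
}

# full record (refined state, eigenvalues, stability, branch) at one root
steady_record <- function(ATP, p, spec, atp_inhibition = TRUE) {
  AMP <- clamped_amp(ATP, p)
  pt <- solve_clamped_point(ATP, AMP, p, atp_inhibition)
  y <- if (p$ak_mode == "equilibrium")
    c(G6P = pt$G6P, F6P = pt$F6P,
      E = 2 * ATP + adp_amp_from_atp(ATP, p$A_pool, p$K_AK)$ADP)
  else c(G6P = pt$G6P, F6P = pt$F6P, ATP = ATP)
  f <- function(v) model_rhs(0, v, p, spec, atp_inhibition)[[1L]]
  if (ATP > 1e-9) y <- newton_state(y, p, spec, atp_inhibition)
  s <- if (p$ak_mode == "equilibrium") {
    st <- split_from_E(y[[3L]], p$A_pool, p$K_AK)
    list(ATP = st$ATP, ADP = st$ADP, AMP = st$AMP)
  } else list(ATP = y[[3L]], ADP = p$A_pool - y[[3L]] - p$fixed_AMP,
              AMP = p$fixed_AMP)
  J <- fd_jacobian(f, y)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(Re(ev), decreasing = TRUE)]
  re <- Re(ev)
  stability <- if (all(re < -1e-9)) "stable"
    else if (any(abs(re) <= 1e-9)) "marginal" else "unstable"
  branch <- if (s$ATP <= 1e-9) "zero" else {
    d <- 1e-4 * p$A_pool
    slope <- (net_production_at(min(s$ATP + d, 0.999 * p$A_pool), p,
                                atp_inhibition) -
              net_production_at(s$ATP - d, p, atp_inhibition)) / (2 * d)
    if (slope < 0) "descending" else "ascending"
  }
  vpfk <- v_pfk(s$ATP, max(y[[2L]], 0), s$AMP, p,
                atp_inhibition = atp_inhibition)
  data.frame(ATP = s$ATP, ADP = s$ADP, AMP = s$AMP,
             G6P = y[[1L]], F6P = y[[2L]],
             V_PFK = vpfk, V_ATPase = v_atpase_spec(s$ATP, spec),
             net_production = 3 * vpfk - v_hk(s$ATP, max(y[[1L]], 0), p),
             eig1 = ev[1L], eig2 = ev[2L], eig3 = ev[3L],
             stability = stability, branch = branch)
}

#' Bifurcation diagram over ATPase activity
#'
#' Sweeps the ATPase activity and records every steady state (stable and
#' unstable branches). When nonzero states exist at the low end of the grid
#' and disappear at the high end, the saddle-node (fold) activity is
#' bracketed by bisection to 0.1% relative width.
#'
#' @inheritParams find_steady_states
#' @param atpase_kind `"linear"` or `"hyperbolic"`.
#' @param activity_grid ascending activities (1/h linear, mM/h hyperbolic);
#'   default 0.25x to 2.5x the physiological value, 41 points.
#' @return data frame of class `glycak_bifurcation` with columns
#'   `activity`, `ATP`, `stability`, `branch`; attribute `fold_activity`
#'   (NA when no fold lies inside the grid) and `fold_bracket`.
#' @export
bifurcation_diagram <- function(p, atpase_kind = c("linear", "hyperbolic"),
                                activity_grid = NULL, char = NULL,
                                atp_inhibition = TRUE) {
  atpase_kind <- match.arg(atpase_kind)
  default_act <- if (atpase_kind == "linear") p$atpase_linear_a
                 else p$atpase_hyperbolic_Vmax
  if (is.null(activity_grid))
    activity_grid <- seq(0.25, 2.5, length.out = 41L) * default_act
  stopifnot(!is.unsorted(activity_grid))
  if (is.null(char)) char <- characteristic(p, atp_inhibition = atp_inhibition)
  states_at <- function(a)
    find_steady_states(p, atpase_spec(atpase_kind, a), char, atp_inhibition)
  recs <- lapply(activity_grid, function(a) {
    st <- states_at(a)
    data.frame(activity = a, ATP = st$ATP, stability = st$stability,
               branch = st$branch)
  })
  out <- do.call(rbind, recs)
  has_nonzero <- vapply(split(out$ATP > 1e-9, out$activity), any, TRUE)
  has_nonzero <- has_nonzero[order(as.numeric(names(has_nonzero)))]
  fold <- NA_real_; bracket <- c(NA_real_, NA_real_)
  if (any(has_nonzero) && !has_nonzero[length(has_nonzero)]) {
    lo <- activity_grid[max(which(has_nonzero))]
    hi <- activity_grid[min(which(!has_nonzero & seq_along(has_nonzero) >
                                    max(which(has_nonzero))))]
    while ((hi - lo) / lo > 1e-3) {
      mid <- 0.5 * (lo + hi)
      if (any(states_at(mid)$ATP > 1e-9)) lo <- mid else hi <- mid
    }
    fold <- 0.5 * (lo + hi); bracket <- c(lo, hi)
  }
  structure(out, class = c("glycak_bifurcation", "data.frame"),
            atpase_kind = atpase_kind, fold_activity = fold,
            fold_bracket = bracket, params = p)
}

#' Control and stabilization coefficients of the steady-state ATP level
#'
#' The control coefficient of ATPase activity over steady-state ATP is
#' \deqn{C = \frac{d\,[ATP]_{ST}}{d\,a}\frac{a}{[ATP]_{ST}}
#'         = \frac{d\ln [ATP]_{ST}}{d\ln a},}
#' computed by a central finite difference in log space; the stabilization
#' coefficient is `Q = -1/C` (large positive Q means strong homeostasis).
#'
#' @inheritParams bifurcation_diagram
#' @param at_activity activity at which to differentiate; default the
#'   physiological value.
#' @param rel_step relative half-width of the central difference.
#' @return list with `C`, `Q`, `ATP_ST` and `at_activity`.
#' @export
stabilization_metrics <- function(p, atpase_kind = c("linear", "hyperbolic"),
                                  at_activity = NULL, rel_step = 0.02,
                                  char = NULL) {
  atpase_kind <- match.arg(atpase_kind)
  if (is.null(at_activity))
    at_activity <- if (atpase_kind == "linear") p$atpase_linear_a
                   else p$atpase_hyperbolic_Vmax
  if (is.null(char)) char <- characteristic(p)
  stable_atp <- function(a) {
    st <- find_steady_states(p, atpase_spec(atpase_kind, a), char)
    st <- st[st$stability == "stable" & st$ATP > 1e-9, , drop = FALSE]
    if (!nrow(st))
      stop("no stable nonzero steady state at activity ", format(a))
    max(st$ATP)
  }
  a_lo <- at_activity * (1 - rel_step)
  a_hi <- at_activity * (1 + rel_step)
  C <- (log(stable_atp(a_hi)) - log(stable_atp(a_lo))) /
    (log(a_hi) - log(a_lo))
  list(C = C, Q = -1 / C, ATP_ST = stable_atp(at_activity),
       at_activity = at_activity)
}

#' Relative steady-state ATP change between two ATPase activity scalings
#'
#' Solves the stable steady state at `scale_a` and `scale_b` times the
#' physiological linear activity and reports the percent ATP difference.
#' The default (0.5x versus 1x, referenced to the physiological state)
#' quantifies the effect of a twofold change in ATP-consuming activity
#' across the normal operating point.
#'
#' @inheritParams stabilization_metrics
#' @param scale_a,scale_b activity multipliers.
#' @param reference `"b"` (default) or `"a"`: which state's ATP is the
#'   denominator.
#' @return list with `percent_change`, `ATP_a`, `ATP_b`.
#' @export
steady_atp_change <- function(p, scale_a = 0.5, scale_b = 1,
                              atpase_kind = c("linear", "hyperbolic"),
                              reference = c("b", "a"), char = NULL) {
  atpase_kind <- match.arg(atpase_kind)
  reference <- match.arg(reference)
  base <- if (atpase_kind == "linear") p$atpase_linear_a
          else p$atpase_hyperbolic_Vmax
  if (is.null(char)) char <- characteristic(p)
  atp_at <- function(s) {
    st <- find_steady_states(p, atpase_spec(atpase_kind, s * base), char)
    st <- st[st$stability == "stable" & st$ATP > 1e-9, , drop = FALSE]
    if (!nrow(st)) stop("no stable nonzero steady state at ", s, "x activity")
    max(st$ATP)
  }
  atp_a <- atp_at(scale_a); atp_b <- atp_at(scale_b)
  ref <- if (reference == "b") atp_b else atp_a
  list(percent_change = 100 * abs(atp_a - atp_b) / ref,
       ATP_a = atp_a, ATP_b = atp_b)
}

#' Characteristics across adenine nucleotide pool sizes
#'
#' Computes the glycolysis characteristic for each pool size and overlays
#' the curves after normalizing both axes to each curve's maximum point
#' (relative ATP = ATP/ATP_at_peak, relative rate = rate/peak rate). With AK
#' the normalized curves nearly coincide: the AMP/ATP ratio, and hence PFK
#' regulation, depends only on the relative ATP concentration.
#'
#' @inheritParams characteristic
#' @param pools pool sizes to sweep (mM).
#' @return list with `curves` (one [characteristic()] per pool), `overlay`
#'   (data frame `pool`, `rel_ATP`, `rel_rate`), and `max_deviation`: the
#'   maximum pairwise difference between normalized curves on a common
#'   relative-ATP grid, as a fraction of the peak.
#' @export
pool_sweep <- function(p, pools = c(0.9, 1.79, 3.58), n = 200L) {
  stopifnot(all(pools > 0))
  curves <- lapply(pools, function(A) {
    pa <- p; pa$A_pool <- A
    pa <- validate_params(unclass(pa))
    characteristic(pa, n = n)
  })
  names(curves) <- paste0("pool_", pools)
  norm_one <- function(ch, A) {
    ok <- ch$converged & is.finite(ch$net_production)
    i <- which.max(ch$net_production[ok])
    data.frame(pool = A,
               rel_ATP = ch$ATP[ok] / ch$ATP[ok][i],
               rel_rate = ch$net_production[ok] / ch$net_production[ok][i])
  }
  overlay <- do.call(rbind, Map(norm_one, curves, pools))
  xs <- seq(0.1, min(vapply(split(overlay$rel_ATP, overlay$pool), max, 0)),
            length.out = 101L)
  mats <- vapply(split(overlay, overlay$pool), function(d)
    stats::approx(d$rel_ATP, d$rel_rate, xout = xs)$y, numeric(length(xs)))
  max_dev <- max(apply(mats, 1L, function(r) diff(range(r))))
  list(curves = curves, overlay = overlay, max_deviation = max_dev)
}

#' Production rate as a function of energy charge and relative ATP
#'
#' Re-parameterizes the with-AK characteristic by Atkinson's energy charge
#' `(ATP + ADP/2)/A` and by the relative ATP concentration `ATP/A`. At high
#' charge the two abscissae nearly coincide, which is why the two views of
#' the same curve overlay in the physiological region.
#'
#' @inheritParams characteristic
#' @return data frame with `ATP`, `charge`, `rel_ATP`, `net_production`
#'   (converged points only).
#' @export
characteristic_vs_charge <- function(p, n = 200L) {
  if (p$ak_mode != "equilibrium")
    stop("the energy-charge view requires ak_mode = 'equilibrium'")
  ch <- characteristic(p, n = n)
  ok <- ch$converged & is.finite(ch$net_production)
  data.frame(ATP = ch$ATP[ok],
             charge = energy_charge(ch$ATP[ok], ch$ADP[ok], ch$AMP[ok]),
             rel_ATP = ch$ATP[ok] / p$A_pool,
             net_production = ch$net_production[ok])
}
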
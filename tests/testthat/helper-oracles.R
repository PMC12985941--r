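# Independent oracles and shared fixtures for the test suite.

# Bisection oracle for the adenylate split: solves the AK mass-action
# equilibrium K*ADP^2 = ATP*AMP together with pool conservation and the
# composite-variable definition by bisection on ADP, independently of the
# closed-form algebra under test.
oracle_split_from_E <- function(E, A, K, tol = 1e-13) {
  stopifnot(E >= 0, E <= 2 * A)
  g <- function(ADP) {
    ATP <- (E - ADP) / 2
    AMP <- A - ATP - ADP
    K * ADP^2 - ATP * AMP
  }
  hi <- min(E, 2 * A - E)
  if (hi <= 0) {
    ATP <- E / 2
    return(list(ATP = ATP, ADP = 0, AMP = A - ATP))
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  ADP <- (lo + hi) / 2
  ATP <- (E - ADP) / 2
  list(ATP = ATP, ADP = ADP, AMP = A - ATP - ADP)
}

# Same equilibrium solved at clamped ATP (bisection on ADP).
oracle_adp_amp_from_atp <- function(ATP, A, K, tol = 1e-13) {
  stopifnot(ATP >= 0, ATP <= A)
  g <- function(ADP) K * ADP^2 - ATP * (A - ATP - ADP)
  lo <- 0; hi <- A - ATP
  if (hi <= 0) return(list(ADP = 0, AMP = 0))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  ADP <- (lo + hi) / 2
  list(ADP = ADP, AMP = A - ATP - ADP)
}

ery <- model_params("erythrocyte")
mus <- model_params("muscle")
ery_noak <- model_params("erythrocyte", ak_mode = "absent")
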
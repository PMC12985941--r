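# Adenylate algebra: everything that ties ATP, ADP and AMP together under
# pool conservation A = ATP + ADP + AMP, with and without the adenylate
# kinase (AK) equilibrium ATP*AMP = K*ADP^2, plus Atkinson's energy charge.
# The composite variable E = 2*ATP + ADP is the single dynamic adenylate
# coordinate when AK is at equilibrium, because its balance does not contain
# the AK rate.

# concentrations in [-1e-12, 0) are round-off at the feasibility boundary
.clamp0 <- function(x, tol = 1e-12) {
  bad <- x < -tol
  x[x < 0 & !bad] <- 0
  if (any(bad))
    stop("infeasible adenylate state: negative concentration ",
         format(min(x), digits = 6))
  x
}

#' Split the composite adenylate variable E into ATP, ADP and AMP
#'
#' Under AK equilibrium (`ATP*AMP = K*ADP^2`) and pool conservation
#' (`ATP + ADP + AMP = A`), the three nucleotide concentrations are algebraic
#' functions of the composite variable `E = 2*ATP + ADP`:
#' \deqn{Q = \sqrt{A^2 - 2AE + E^2 + 8AEK - 4E^2K},}
#' \deqn{ATP = \tfrac12\left[E + \frac{A - Q}{4K - 1}\right],\quad
#'       ADP = \frac{Q - A}{4K - 1},\quad AMP = A - ATP - ADP.}
#' This branch of the square root is the unique root with non-negative
#' concentrations on the physical range `0 <= E <= 2A`.
#'
#' @param E composite variable 2*ATP + ADP (mM); may be a vector.
#' @param A adenine nucleotide pool (mM).
#' @param K AK equilibrium constant (dimensionless, != 1/4).
#' @return For scalar `E`, an `adenylate_state`: list with `ATP`, `ADP`,
#'   `AMP`, `A`, `E`, `K` (mM where dimensional). For vector `E`, a data
#'   frame with columns `ATP`, `ADP`, `AMP`.
#' @seealso [adp_amp_from_atp()] for the clamped-ATP direction.
#' @examples
#' split_from_E(3.2487, A = 1.79, K = 1)  # ATP ~1.5, ADP ~0.249, AMP ~0.041
#' @export
split_from_E <- function(E, A, K) {
  stopifnot(A > 0, K > 0, abs(K - 0.25) > 1e-12)
  if (any(E < -1e-12) || any(E > 2 * A * (1 + 1e-12)))
    stop("E outside the physical range [0, 2A]")
  E <- pmin(pmax(E, 0), 2 * A)
  disc <- A^2 - 2 * A * E + E^2 + 8 * A * E * K - 4 * E^2 * K
  if (any(disc < -1e-12 * A^2))
    stop("infeasible adenylate state: negative discriminant")
  Q <- sqrt(pmax(disc, 0))
  ATP <- 0.5 * (E + (A - Q) / (4 * K - 1))
  ADP <- (Q - A) / (4 * K - 1)
  ATP <- .clamp0(ATP)
  ADP <- .clamp0(ADP)
  AMP <- .clamp0(A - ATP - ADP)
  if (length(E) > 1L)
    return(data.frame(ATP = ATP, ADP = ADP, AMP = AMP))
  structure(list(ATP = ATP, ADP = ADP, AMP = AMP, A = A, E = E, K = K),
            class = "adenylate_state")
}

#' ADP and AMP from a clamped ATP concentration
#'
#' Solves the AK equilibrium together with pool conservation for ADP and AMP
#' at a given ATP:
#' \deqn{ADP = \frac{\sqrt{ATP\,(4KA + ATP - 4K\,ATP)} - ATP}{2K},\quad
#'       AMP = A - ATP - ADP.}
#' The positive branch of the square root is the one yielding non-negative
#' ADP and AMP on `0 <= ATP <= A`.
#'
#' @param ATP clamped ATP (mM); may be a vector.
#' @inheritParams split_from_E
#' @return list (or data frame for vector input) with `ADP` and `AMP` (mM).
#' @examples
#' adp_amp_from_atp(1.5, A = 1.79, K = 1)  # ADP ~0.249, AMP ~0.041
#' @export
adp_amp_from_atp <- function(ATP, A, K) {
  stopifnot(A > 0, K > 0)
  if (any(ATP < -1e-12) || any(ATP > A * (1 + 1e-12)))
    stop("infeasible adenylate state: ATP outside [0, A]")
  ATP <- pmin(pmax(ATP, 0), A)
  disc <- ATP * (4 * K * A + ATP - 4 * K * ATP)
  ADP <- (sqrt(pmax(disc, 0)) - ATP) / (2 * K)
  ADP <- .clamp0(ADP)
  AMP <- .clamp0(A - ATP - ADP)
  if (length(ATP) > 1L) data.frame(ADP = ADP, AMP = AMP)
  else list(ADP = ADP, AMP = AMP)
}

#' Full adenylate state from a clamped ATP concentration
#'
#' Convenience wrapper combining [adp_amp_from_atp()] with the composite
#' variable `E = 2*ATP + ADP`.
#'
#' @inheritParams adp_amp_from_atp
#' @return an `adenylate_state` (see [split_from_E()]).
#' @export
adenylate_state_from_atp <- function(ATP, A, K) {
  s <- adp_amp_from_atp(ATP, A, K)
  structure(list(ATP = ATP, ADP = s$ADP, AMP = s$AMP, A = A,
                 E = 2 * ATP + s$ADP, K = K),
            class = "adenylate_state")
}

#' @export
print.adenylate_state <- function(x, ...) {
  cat(sprintf(
    "Adenylate state (mM): ATP %.6g  ADP %.6g  AMP %.6g  (pool %.6g, E %.6g, K %.4g)\n",
    x$ATP, x$ADP, x$AMP, x$A, x$E, x$K))
  invisible(x)
}

#' Quadratic approximation of AMP as a function of ATP
#'
#' In the near-equilibrium regime with K close to 1, the steady-state AMP
#' concentration is approximately a quadratic function of the relative ATP
#' concentration: `AMP ~ A * (1 - ATP/A)^2`. Small changes in ATP therefore
#' produce large relative changes in AMP, which is what makes AMP an
#' effective intracellular indicator of ATP fluctuations. This closed form
#' is provided for illustration only and is never used inside the dynamics;
#' the exact algebra is [adp_amp_from_atp()].
#'
#' @inheritParams adp_amp_from_atp
#' @return approximate AMP (mM).
#' @export
amp_quadratic_approx <- function(ATP, A) {
  stopifnot(A > 0, all(ATP >= 0), all(ATP <= A * (1 + 1e-12)))
  A * (1 - ATP / A)^2
}

#' Atkinson's adenylate energy charge
#'
#' \deqn{\varphi = \frac{ATP + 0.5\,ADP}{ATP + ADP + AMP} \in [0, 1].}
#'
#' @param ATP,ADP,AMP concentrations (mM), all non-negative; vectors recycle.
#' @return energy charge, dimensionless in `[0, 1]`.
#' @examples
#' energy_charge(100, 10, 1)  # 0.95 for the canonical 100:10:1 ratio
#' @export
energy_charge <- function(ATP, ADP, AMP) {
  if (any(ATP < 0) || any(ADP < 0) || any(AMP < 0))
    stop("concentrations must be non-negative")
  pool <- ATP + ADP + AMP
  if (any(pool == 0))
    stop("energy charge undefined for a zero adenine nucleotide pool")
  (ATP + 0.5 * ADP) / pool
}
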
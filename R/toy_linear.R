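# Conceptual linear model of ATP turnover: consumption V_c = a*ATP and
# production V_p = b*ATP + b1. A negative production slope b is the minimal
# representation of negative feedback of production by ATP; the closed
# forms below quantify how it stabilizes the steady-state ATP level.

#' Parameters of the linear toy model
#'
#' @param a consumption slope (> 0); arbitrary rate units per ATP unit.
#' @param b production slope (signed; negative means negative feedback).
#' @param b1 production intercept (> 0).
#' @return an object of class `toy_linear_params`.
#' @examples
#' toy_linear_params(a = 1, b = -9, b1 = 95)
#' @export
toy_linear_params <- function(a, b, b1) {
  stopifnot(is.numeric(a), a > 0, is.numeric(b), is.numeric(b1), b1 > 0)
  structure(list(a = a, b = b, b1 = b1), class = "toy_linear_params")
}

#' Steady-state ATP of the linear toy model
#'
#' `ATP_ST = b1 / (a - b)`, finite and positive only when `a > b`.
#'
#' @param p a [toy_linear_params()] object.
#' @return steady-state ATP (arbitrary units).
#' @examples
#' toy_steady_state(toy_linear_params(1, -9, 95))  # 9.5
#' @export
toy_steady_state <- function(p) {
  stopifnot(inherits(p, "toy_linear_params"))
  if (p$a - p$b <= 0)
    stop("no finite steady state: requires a - b > 0")
  p$b1 / (p$a - p$b)
}

#' Control and stabilization coefficients of the linear toy model
#'
#' Closed forms `C = a/(b - a)` and `Q = -1/C = 1 - b/a`; the identity
#' `Q * C = -1` holds exactly. `Q > 1` exactly when `b < 0`: a negative
#' production slope improves ATP stabilization beyond the `Q = 1` of
#' constant production.
#'
#' @inheritParams toy_steady_state
#' @return list with `C` and `Q`.
#' @examples
#' toy_coefficients(toy_linear_params(1, -9, 95))$Q  # 10
#' @export
toy_coefficients <- function(p) {
  stopifnot(inherits(p, "toy_linear_params"))
  if (p$a == p$b) stop("singular: a = b")
  C <- p$a / (p$b - p$a)
  list(C = C, Q = 1 - p$b / p$a)
}

#' Steady-state ATP versus consumption activity for the two production laws
#'
#' Tabulates `ATP_ST(a)` for constant production (`b = 0`) and for the
#' negatively sloped production law, together with the local stabilization
#' coefficient Q, over a grid of consumption activities.
#'
#' @param a_grid consumption activities (> 0).
#' @param b slope of the feedback production law.
#' @param b1 production intercept used for both laws.
#' @return data frame with `a`, `ATP_const`, `Q_const`, `ATP_slope`,
#'   `Q_slope` (arbitrary units).
#' @export
toy_table <- function(a_grid = seq(0.5, 2, by = 0.05), b = -9, b1 = 95) {
  stopifnot(all(a_grid > 0))
  rows <- lapply(a_grid, function(a) {
    pc <- toy_linear_params(a, 0, b1)
    ps <- toy_linear_params(a, b, b1)
    data.frame(a = a,
               ATP_const = toy_steady_state(pc),
               Q_const = toy_coefficients(pc)$Q,
               ATP_slope = toy_steady_state(ps),
               Q_slope = toy_coefficients(ps)$Q)
  })
  do.call(rbind, rows)
}
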
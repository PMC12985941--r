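# Rate laws of the upper-glycolysis enzymes and of the lumped ATP-consuming
# processes. All are pure functions of concentrations (mM) and a parameter
# set, returning rates in mM/h. Lower glycolysis is not modelled explicitly:
# PGK and PK each run at twice the PFK rate, so the lower part produces
# 4*V_PFK and the net glycolytic ATP balance is -V_HK - V_PFK + 4*V_PFK
# = 3*V_PFK - V_HK.

#' Hexokinase rate
#'
#' Irreversible, saturating in ATP (`K_HK1`) with product inhibition by G6P
#' (`K_HK2`), at constant glucose:
#' \deqn{V_{HK} = A_{HK}\frac{ATP/K_{HK1}}{1 + ATP/K_{HK1} + G6P/K_{HK2}}.}
#' G6P inhibition is what coordinates HK with PFK: when PFK slows down, G6P
#' accumulates and throttles HK.
#'
#' @param ATP,G6P concentrations (mM), vectorized.
#' @param p a [model_params()] object.
#' @return rate (mM/h).
#' @export
v_hk <- function(ATP, G6P, p) {
  p$A_HK * (ATP / p$K_HK1) / (1 + ATP / p$K_HK1 + G6P / p$K_HK2)
}

#' Glucose-phosphate isomerase rate
#'
#' Reversible isomerization of G6P to F6P with equilibrium ratio
#' `G6P/F6P = K_GPI1`:
#' \deqn{V_{GPI} = A_{GPI}\frac{(G6P - K_{GPI1}\,F6P)/K_{GPI2}}
#'       {1 + G6P/K_{GPI2} + F6P/K_{GPI3}}.}
#' The flux is zero exactly at the equilibrium ratio and negative when F6P
#' is in excess.
#'
#' @param G6P,F6P concentrations (mM), vectorized.
#' @inheritParams v_hk
#' @return rate (mM/h), signed.
#' @export
v_gpi <- function(G6P, F6P, p) {
  p$A_GPI * ((G6P - p$K_GPI1 * F6P) / p$K_GPI2) /
    (1 + G6P / p$K_GPI2 + F6P / p$K_GPI3)
}

#' Phosphofructokinase rate
#'
#' Irreversible, allosterically regulated rate law: saturable F6P
#' (`K_PFK1`) and ATP (`K_PFK2`) substrate terms, an AMP activation factor
#' `(K_PFK3 + 2 AMP)/(K_PFK3 + AMP)` that doubles the rate at saturating
#' AMP, a concerted-transition suppression factor with allosteric constant
#' `L0` (1e8) and exponent `n_allosteric` (4) built from the inhibitory ATP
#' site (`K_PFK4`), the AMP site (`K_PFK3`) and the F6P allosteric site
#' (`K_PFK5`), and an orthophosphate activation term (`K_PFK6`):
#' \deqn{V_{PFK} = A_{PFK}\left(1 + \frac{P_i}{K_6}\right)
#'   \frac{F6P}{F6P + K_1}\,\frac{ATP}{ATP + K_2}\,
#'   \frac{K_3 + 2\,AMP}{K_3 + AMP}
#'   \Big/\left[1 + L_0\left(\frac{1 + ATP/K_4}
#'   {(1 + AMP/K_3)(1 + F6P/K_5)}\right)^{n}\right].}
#'
#' With `atp_inhibition = FALSE`, ATP-mediated allosteric inhibition is
#' removed by freezing (not deleting) the ATP concentration inside the
#' inhibitory term `1 + ATP/K_PFK4` at 1.5 mM, its physiological value, so
#' that the rate at the normal operating point is unchanged; all other
#' occurrences of ATP still vary.
#'
#' @param ATP,F6P,AMP concentrations (mM), vectorized.
#' @param Pi orthophosphate (mM); defaults to the value in `p`.
#' @param atp_inhibition logical; freeze the inhibitory ATP term at 1.5 mM
#'   when `FALSE`.
#' @inheritParams v_hk
#' @return rate (mM/h).
#' @export
v_pfk <- function(ATP, F6P, AMP, p, Pi = p$Pi, atp_inhibition = TRUE) {
  ATP_inh <- if (atp_inhibition) ATP else 1.5
  activation <- (p$K_PFK3 + 2 * AMP) / (p$K_PFK3 + AMP)
  ratio <- (1 + ATP_inh / p$K_PFK4) /
    ((1 + AMP / p$K_PFK3) * (1 + F6P / p$K_PFK5))
  suppression <- 1 + p$L0 * ratio^p$n_allosteric
  p$A_PFK * (1 + Pi / p$K_PFK6) *
    (F6P / (F6P + p$K_PFK1)) * (ATP / (ATP + p$K_PFK2)) *
    activation / suppression
}

#' ATP-consumption rate
#'
#' Lumped ATP-consuming processes, either linear in ATP
#' (`rate = a * ATP`, Michaelis constant far above physiological ATP) or
#' hyperbolic (`rate = Vmax * ATP/(ATP + K_ATP)`, Michaelis constant far
#' below physiological ATP).
#'
#' @param ATP concentration (mM), vectorized.
#' @param p a [model_params()] object supplying the default activities.
#' @param kind `"linear"` or `"hyperbolic"`.
#' @param activity_scale multiplies the default activity (dimensionless).
#' @param activity absolute activity overriding the default (1/h for linear,
#'   mM/h for hyperbolic); `activity_scale` still applies.
#' @return rate (mM/h).
#' @export
v_atpase <- function(ATP, p, kind = c("linear", "hyperbolic"),
                     activity_scale = 1, activity = NULL) {
  kind <- match.arg(kind)
  stopifnot(activity_scale > 0)
  if (kind == "linear") {
    a <- if (is.null(activity)) p$atpase_linear_a else activity
    activity_scale * a * ATP
  } else {
    v <- if (is.null(activity)) p$atpase_hyperbolic_Vmax else activity
    activity_scale * v * ATP / (ATP + p$atpase_K_ATP)
  }
}

# evaluate a resolved atpase_spec
v_atpase_spec <- function(ATP, spec) {
  if (spec$kind == "linear") spec$activity * ATP
  else spec$activity * ATP / (ATP + spec$K_ATP)
}

#' All reaction fluxes at a model state
#'
#' @param ATP,G6P,F6P,AMP concentrations (mM), vectorized.
#' @param p a [model_params()] object.
#' @param atpase an [atpase_spec()] (defaults resolved from `p`), or `NULL`
#'   for the linear physiological load.
#' @param atp_inhibition passed to [v_pfk()].
#' @return data frame with columns `V_HK`, `V_GPI`, `V_PFK`, `V_ATPase` and
#'   `net_glycolytic_ATP` (= 3*V_PFK - V_HK), all mM/h.
#' @export
flux_vector <- function(ATP, G6P, F6P, AMP, p, atpase = NULL,
                        atp_inhibition = TRUE) {
  spec <- resolve_atpase(atpase, p)
  vhk <- v_hk(ATP, G6P, p)
  vgpi <- v_gpi(G6P, F6P, p)
  vpfk <- v_pfk(ATP, F6P, AMP, p, atp_inhibition = atp_inhibition)
  data.frame(V_HK = vhk, V_GPI = vgpi, V_PFK = vpfk,
             V_ATPase = v_atpase_spec(ATP, spec),
             net_glycolytic_ATP = 3 * vpfk - vhk)
}
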
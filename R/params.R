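# Parameter sets for the erythrocyte and resting-muscle energy-metabolism
# models. Internal unit system is mM and hours everywhere; the handful of
# constants conventionally quoted in uM (K_HK2, K_PFK5, pool, K_ATP,
# fixed AMP) are converted at construction and stored in mM.

# fields that must be strictly positive
.positive_fields <- c(
  "A_HK", "K_HK1", "K_HK2", "A_GPI", "K_GPI1", "K_GPI2", "K_GPI3",
  "A_PFK", "K_PFK1", "K_PFK2", "K_PFK3", "K_PFK4", "K_PFK5", "K_PFK6",
  "L0", "n_allosteric", "Pi", "A_pool", "K_AK",
  "atpase_linear_a", "atpase_hyperbolic_Vmax", "atpase_K_ATP"
)

.param_fields <- c("cell_type", .positive_fields, "ak_mode", "fixed_AMP")

# units of each numeric field in the *internal* representation
.param_units <- c(
  A_HK = "mM/h", K_HK1 = "mM", K_HK2 = "mM",
  A_GPI = "mM/h", K_GPI1 = "dimensionless", K_GPI2 = "mM", K_GPI3 = "mM",
  A_PFK = "mM/h", K_PFK1 = "mM", K_PFK2 = "mM", K_PFK3 = "mM",
  K_PFK4 = "mM", K_PFK5 = "mM", K_PFK6 = "mM",
  L0 = "dimensionless", n_allosteric = "dimensionless",
  Pi = "mM", A_pool = "mM", K_AK = "dimensionless",
  atpase_linear_a = "1/h", atpase_hyperbolic_Vmax = "mM/h",
  atpase_K_ATP = "mM", fixed_AMP = "mM"
)

#' Model parameters for glycolytic energy metabolism
#'
#' Constructs a validated parameter set for the kinetic model of upper
#' glycolysis (HK, GPI, PFK) coupled to ATP-consuming processes, either for
#' the human erythrocyte or for resting anaerobic skeletal muscle. The two
#' built-in sets carry the published enzyme activities, Michaelis/allosteric
#' constants, adenine nucleotide pool and ATPase parameters for each cell
#' type; any field can be overridden.
#'
#' All values are stored internally in mM and hours. Overrides must be given
#' in those units (e.g. `K_HK2 = 0.0055` for 5.5 uM).
#'
#' @param cell_type `"erythrocyte"` or `"muscle"`.
#' @param ... named overrides of individual fields (internal units).
#' @param ak_mode `"equilibrium"` (ATP, ADP, AMP tied by the adenylate kinase
#'   mass-action ratio) or `"absent"` (AMP clamped at `fixed_AMP`).
#'
#' @return An object of class `glycak_params`: a named list with fields
#'   `cell_type`, enzyme activities `A_HK`, `A_GPI`, `A_PFK` (mM/h),
#'   saturation/allosteric constants `K_HK1`, `K_HK2`, `K_GPI1..3`,
#'   `K_PFK1..6`, `L0`, `n_allosteric`, orthophosphate `Pi` (mM), adenine
#'   nucleotide pool `A_pool` (mM), AK equilibrium constant `K_AK`, ATPase
#'   parameters `atpase_linear_a` (1/h), `atpase_hyperbolic_Vmax` (mM/h),
#'   `atpase_K_ATP` (mM), plus `ak_mode` and `fixed_AMP` (mM).
#'
#' @examples
#' p <- model_params("erythrocyte")
#' p$A_HK              # 12 mM/h
#' pm <- model_params("muscle")
#' pm$A_pool           # 5.4 mM
#' @export
model_params <- function(cell_type = c("erythrocyte", "muscle"), ...,
                         ak_mode = c("equilibrium", "absent")) {
  cell_type <- match.arg(cell_type)
  ak_mode <- match.arg(ak_mode)
  p <- if (cell_type == "erythrocyte") .erythrocyte_defaults() else .muscle_defaults()
  p$ak_mode <- ak_mode
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), .param_fields)
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
}

.erythrocyte_defaults <- function() {
  list(
    cell_type = "erythrocyte",
    A_HK = 12, K_HK1 = 1, K_HK2 = 5.5e-3,
    A_GPI = 360, K_GPI1 = 3, K_GPI2 = 0.3, K_GPI3 = 0.2,
    A_PFK = 380, K_PFK1 = 0.1, K_PFK2 = 2, K_PFK3 = 0.01,
    K_PFK4 = 0.195, K_PFK5 = 0.37e-3, K_PFK6 = 10,
    L0 = 1e8, n_allosteric = 4L,
    Pi = 1, A_pool = 1.79, K_AK = 1,
    atpase_linear_a = 1.57, atpase_hyperbolic_Vmax = 2.36,
    atpase_K_ATP = 0.01,
    ak_mode = "equilibrium", fixed_AMP = 0.040
  )
}

.muscle_defaults <- function() {
  p <- .erythrocyte_defaults()
  p$cell_type <- "muscle"
  # only activities, Pi, pool, ATPase parameters and resting AMP differ;
  # saturation constants are shared between the cell types
  p$A_HK <- 100; p$A_GPI <- 20000; p$A_PFK <- 6000
  p$Pi <- 2; p$A_pool <- 5.4
  p$atpase_linear_a <- 5.16; p$atpase_hyperbolic_Vmax <- 25.7
  p$fixed_AMP <- 0.030
  p
}

#' Validate a model parameter set
#'
#' Checks positivity of all activities and constants, the integer allosteric
#' exponent, and the adenylate kinase singularity `K_AK != 1/4` (the algebra
#' expressing the nucleotides through the composite variable E divides by
#' `4K - 1`).
#'
#' @param p a named list of parameter fields (see [model_params()]).
#' @return `p`, classed `glycak_params`, with fields in canonical order.
#' @export
validate_params <- function(p) {
  missing <- setdiff(.param_fields, names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(p), .param_fields)
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "))
  if (!p$cell_type %in% c("erythrocyte", "muscle"))
    stop("cell_type must be 'erythrocyte' or 'muscle'")
  if (!p$ak_mode %in% c("equilibrium", "absent"))
    stop("ak_mode must be 'equilibrium' or 'absent'")
  for (f in .positive_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single positive finite number")
  }
  if (p$n_allosteric < 1 || p$n_allosteric != round(p$n_allosteric))
    stop("parameter 'n_allosteric' must be an integer >= 1")
  if (abs(p$K_AK - 0.25) < 1e-12)
    stop("K_AK = 1/4 is singular: the adenylate algebra divides by 4*K - 1")
  if (!is.numeric(p$fixed_AMP) || p$fixed_AMP < 0 || p$fixed_AMP > p$A_pool)
    stop("parameter 'fixed_AMP' must lie in [0, A_pool]")
  p <- p[.param_fields]
  class(p) <- "glycak_params"
  p
}

#' Load model parameters from a name or a YAML file
#'
#' `source` may be a built-in cell type (`"erythrocyte"`, `"muscle"`) or the
#' path of a YAML document as written by [write_params()]. A file must carry
#' a `cell_type` key; any subset of the remaining fields overrides the
#' built-in defaults for that cell type. Values in files are given in the
#' internal mM/hour unit system (each dumped parameter carries a `units`
#' annotation for the reader's benefit).
#'
#' @param source character: built-in name or path to a YAML file.
#' @return a validated [model_params()] object.
#' @export
load_params <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% c("erythrocyte", "muscle"))
    return(model_params(source))
  if (!file.exists(source))
    stop("'", source, "' is neither a built-in cell type nor an existing file")
  doc <- yaml::read_yaml(source)
  if (is.null(doc$cell_type))
    stop("parameter file must name a cell_type")
  vals <- doc$parameters
  # accept either bare numbers or {value:, units:} records
  ov <- lapply(vals, function(x) if (is.list(x)) x$value else x)
  base <- if (identical(doc$ak_mode, "absent")) "absent" else "equilibrium"
  do.call(model_params,
          c(list(cell_type = doc$cell_type, ak_mode = base), ov))
}

#' Write model parameters to a YAML file
#'
#' Each numeric parameter is dumped as a `{value, units}` record so the file
#' is self-describing; [load_params()] reads the same layout back.
#'
#' @param p a [model_params()] object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_params <- function(p, file) {
  stopifnot(inherits(p, "glycak_params"))
  num <- names(.param_units)
  doc <- list(
    cell_type = p$cell_type,
    ak_mode = p$ak_mode,
    parameters = stats::setNames(lapply(num, function(f)
      list(value = p[[f]], units = unname(.param_units[[f]]))), num)
  )
  yaml::write_yaml(doc, file, precision = 15L)
  invisible(file)
}

#' @export
print.glycak_params <- function(x, ...) {
  cat("Glycolysis model parameters (", x$cell_type, ", AK ", x$ak_mode,
      ")\n", sep = "")
  cat(sprintf("  activities (mM/h): HK %.4g  GPI %.4g  PFK %.4g\n",
              x$A_HK, x$A_GPI, x$A_PFK))
  cat(sprintf("  pool %.4g mM, Pi %.4g mM, K_AK %.4g\n",
              x$A_pool, x$Pi, x$K_AK))
  cat(sprintf("  ATPase: linear %.4g 1/h, hyperbolic Vmax %.4g mM/h (K %.4g mM)\n",
              x$atpase_linear_a, x$atpase_hyperbolic_Vmax, x$atpase_K_ATP))
  if (x$ak_mode == "absent")
    cat(sprintf("  fixed AMP %.4g mM\n", x$fixed_AMP))
  invisible(x)
}

#' ATP-consumption (ATPase) specification
#'
#' Describes the ATP-consuming load: `linear` (rate = activity * ATP, with
#' activity in 1/h) or `hyperbolic` (rate = activity * ATP/(ATP + K_ATP),
#' with activity the maximal rate in mM/h). `activity = NULL` selects the
#' physiological default from the parameter set when the spec is resolved.
#'
#' @param kind `"linear"` or `"hyperbolic"`.
#' @param activity activity value, or `NULL` for the cell-type default.
#' @param K_ATP Michaelis constant (mM) for the hyperbolic form, or `NULL`
#'   for the default.
#' @return an object of class `atpase_spec`.
#' @export
atpase_spec <- function(kind = c("linear", "hyperbolic"), activity = NULL,
                        K_ATP = NULL) {
  kind <- match.arg(kind)
  if (!is.null(activity))
    stopifnot(is.numeric(activity), length(activity) == 1L, activity > 0)
  if (!is.null(K_ATP))
    stopifnot(is.numeric(K_ATP), length(K_ATP) == 1L, K_ATP > 0)
  structure(list(kind = kind, activity = activity, K_ATP = K_ATP),
            class = "atpase_spec")
}

# fill an atpase_spec's NULL slots from a parameter set
resolve_atpase <- function(spec, p) {
  if (is.null(spec)) spec <- atpase_spec("linear")
  stopifnot(inherits(spec, "atpase_spec"))
  if (is.null(spec$activity))
    spec$activity <- if (spec$kind == "linear") p$atpase_linear_a
                     else p$atpase_hyperbolic_Vmax
  if (is.null(spec$K_ATP)) spec$K_ATP <- p$atpase_K_ATP
  spec
}
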
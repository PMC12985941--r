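# Scenario generator: reproducible what-if experiments on the models —
# the HK-inhibition-constant sweep, regulation knockouts, and random
# parameter ensembles — each a small serializable description that the
# steady-state machinery can execute and classify.

#' Define a model scenario
#'
#' A scenario is a base cell type plus parameter overrides, an AK mode, an
#' optional PFK ATP-inhibition switch, an expected qualitative outcome tag,
#' and the seed it was generated under (if any). Scenarios serialize to
#' YAML ([write_scenario()]) and are fully reproducible from the file.
#'
#' @param name short identifier.
#' @param cell_type `"erythrocyte"` or `"muscle"`.
#' @param overrides named list of parameter overrides (internal units,
#'   mM/h).
#' @param ak_mode `"equilibrium"` or `"absent"`.
#' @param atp_inhibition logical; `FALSE` freezes the PFK inhibitory ATP
#'   term at 1.5 mM (see [v_pfk()]).
#' @param tag expected qualitative outcome (e.g. `"bell"`, `"monotone"`).
#' @param seed integer seed the scenario was drawn under, or `NULL`.
#' @return an object of class `glycak_scenario`.
#' @export
scenario <- function(name, cell_type = "erythrocyte", overrides = list(),
                     ak_mode = "equilibrium", atp_inhibition = TRUE,
                     tag = NA_character_, seed = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.list(overrides))
  structure(list(name = name, cell_type = cell_type, overrides = overrides,
                 ak_mode = ak_mode, atp_inhibition = atp_inhibition,
                 tag = tag, seed = seed,
                 rng = if (is.null(seed)) NULL else "Mersenne-Twister"),
            class = "glycak_scenario")
}

#' @export
print.glycak_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s, AK %s%s), tag: %s\n", x$name, x$cell_type,
              x$ak_mode,
              if (!x$atp_inhibition) ", ATP inhibition frozen" else "",
              x$tag))
  if (length(x$overrides))
    cat("  overrides:", paste(names(x$overrides), "=",
                              vapply(x$overrides, format, ""),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Resolve a scenario to a parameter set
#' @param sc a [scenario()].
#' @return a [model_params()] object.
#' @export
scenario_params <- function(sc) {
  stopifnot(inherits(sc, "glycak_scenario"))
  do.call(model_params,
          c(list(cell_type = sc$cell_type, ak_mode = sc$ak_mode),
            sc$overrides))
}

#' Run a scenario and classify its glycolysis characteristic
#'
#' @param sc a [scenario()].
#' @param n characteristic grid size.
#' @return list with `scenario`, `params`, `characteristic`, and
#'   `classification` from [classify_characteristic()].
#' @export
run_scenario <- function(sc, n = 200L) {
  p <- scenario_params(sc)
  ch <- characteristic(p, n = n, atp_inhibition = sc$atp_inhibition)
  list(scenario = sc, params = p, characteristic = ch,
       classification = classify_characteristic(ch))
}

#' Classify the shape of a glycolysis characteristic
#'
#' `"bell"` when the interior maximum exceeds both endpoints by more than 1%
#' of the peak (and, if `operating_atp` is given, the operating point lies
#' on the descending side, i.e. above the ATP of the peak); `"monotone"`
#' when the curve is non-decreasing over the grid to within solver noise
#' (1e-6 of the peak); `"other"` otherwise.
#'
#' @param ch a [characteristic()].
#' @param operating_atp optional operating ATP (mM) that must sit on the
#'   descending branch for a `"bell"` call.
#' @return character scalar.
#' @export
classify_characteristic <- function(ch, operating_atp = NULL) {
  ok <- ch$converged & is.finite(ch$net_production)
  v <- ch$net_production[ok]; atp <- ch$ATP[ok]
  peak <- max(v); i <- which.max(v)
  if (all(diff(v) >= -1e-6 * peak)) return("monotone")
  interior <- i > 1L && i < length(v) &&
    (peak - v[1L]) > 0.01 * peak && (peak - v[length(v)]) > 0.01 * peak
  if (interior) {
    if (!is.null(operating_atp) && operating_atp <= atp[i]) return("other")
    return("bell")
  }
  "other"
}

#' Scenarios sweeping the HK inhibition constant for G6P
#'
#' Four (K_HK2, A_HK) pairs — (0.55 uM, 102 mM/h), (5.5 uM, 12 mM/h),
#' (27.5 uM, 3.4 mM/h), (220 uM, 2.2 mM/h) — in which the HK activity was
#' co-adjusted so each characteristic passes through the physiologically
#' normal point (ATP 1.5 mM, production 2.34 mM/h). The 5.5 uM / 12 mM/h
#' pair is the default erythrocyte model; smaller inhibition constants
#' steepen the descending branch.
#'
#' @return list of [scenario()] objects.
#' @export
make_khk2_sweep <- function() {
  pairs <- list(c(0.55, 102), c(5.5, 12), c(27.5, 3.4), c(220, 2.2))
  lapply(pairs, function(x)
    scenario(name = sprintf("khk2_%g_uM", x[1L]),
             overrides = list(K_HK2 = x[1L] / 1000, A_HK = x[2L]),
             tag = "bell"))
}

#' Regulation-knockout scenarios
#'
#' Baseline, PFK ATP-inhibition frozen (at 1.5 mM, leaving the normal
#' operating point unchanged), and AK removed (AMP clamped at 40 uM). The
#' expected characteristic shapes are bell / bell / monotone: AMP-dependent
#' activation through AK, not ATP inhibition of PFK, creates the descending
#' branch.
#'
#' @return list of [scenario()] objects.
#' @export
make_regulation_knockouts <- function() {
  list(
    scenario("baseline", tag = "bell"),
    scenario("no_atp_inhibition", atp_inhibition = FALSE, tag = "bell"),
    scenario("no_ak", ak_mode = "absent",
             overrides = list(fixed_AMP = 0.040), tag = "monotone")
  )
}

#' Random ensemble of activity-perturbed scenarios
#'
#' Draws `n` scenarios whose enzyme activities (A_HK, A_GPI, A_PFK) are
#' jointly perturbed by independent log-uniform factors in
#' `[1/spread, spread]`. Deterministic given the seed (Mersenne-Twister,
#' recorded in each scenario); the caller's RNG state is left untouched.
#'
#' @param n number of scenarios (>= 1).
#' @param spread log-uniform half-range factor (>= 1).
#' @param seed integer seed.
#' @param cell_type base cell type.
#' @return list of [scenario()] objects.
#' @export
make_random_ensemble <- function(n, spread = 2, seed = 1,
                                 cell_type = "erythrocyte") {
  stopifnot(n >= 1, spread >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  lapply(seq_len(n), function(i) {
    f <- exp(stats::runif(3L, -log(spread), log(spread)))
    base <- if (cell_type == "erythrocyte") .erythrocyte_defaults()
            else .muscle_defaults()
    scenario(name = sprintf("ensemble_%03d", i), cell_type = cell_type,
             overrides = list(A_HK = base$A_HK * f[1L],
                              A_GPI = base$A_GPI * f[2L],
                              A_PFK = base$A_PFK * f[3L]),
             tag = NA_character_, seed = seed)
  })
}

#' Fraction of an ensemble preserving a bell-shaped characteristic
#'
#' Runs every scenario and reports the fraction classified `"bell"` (the
#' descending branch survives the perturbation).
#'
#' @param scenarios list of [scenario()] objects.
#' @param n characteristic grid size per scenario.
#' @return list with `fraction_bell` and the per-scenario `classification`.
#' @export
ensemble_bell_fraction <- function(scenarios, n = 120L) {
  cls <- vapply(scenarios, function(sc) run_scenario(sc, n)$classification, "")
  list(fraction_bell = mean(cls == "bell"), classification = cls)
}

#' Write / read a scenario as YAML
#'
#' @param sc a [scenario()].
#' @param file path.
#' @return `write_scenario`: `file`, invisibly. `read_scenario`: the
#'   scenario.
#' @export
write_scenario <- function(sc, file) {
  stopifnot(inherits(sc, "glycak_scenario"))
  yaml::write_yaml(unclass(sc), file, precision = 15L)
  invisible(file)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  if (!file.exists(file)) stop("scenario file '", file, "' does not exist")
  doc <- yaml::read_yaml(file)
  scenario(name = doc$name, cell_type = doc$cell_type,
           overrides = if (is.null(doc$overrides)) list() else doc$overrides,
           ak_mode = doc$ak_mode, atp_inhibition = doc$atp_inhibition,
           tag = if (is.null(doc$tag)) NA_character_ else doc$tag,
           seed = doc$seed)
}
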
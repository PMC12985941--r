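# Tabular export glue: CSV writers with per-column unit headers, JSON
# summaries, and run records that make every invocation reproducible.

# units for the standard trajectory / curve columns
.column_units <- c(
  t = "h", G6P = "mM", F6P = "mM", E = "mM", ATP = "mM", ADP = "mM",
  AMP = "mM", V_HK = "mM/h", V_GPI = "mM/h", V_PFK = "mM/h",
  V_ATPase = "mM/h", V_AK = "mM/h", net_production = "mM/h",
  gross_production = "mM/h", ak_share = "percent", production_gly = "mM/h",
  production_total = "mM/h", activity = "1/h or mM/h", charge = "",
  rel_ATP = "", rel_rate = "", converged = "", stability = "", branch = "",
  a = "arbitrary", ATP_const = "arbitrary", Q_const = "", ATP_slope =
  "arbitrary", Q_slope = "", pool = "mM", eig1 = "1/h", eig2 = "1/h",
  eig3 = "1/h"
)

#' Write a result table to CSV with a units header
#'
#' Writes `#`-prefixed comment lines naming the unit of every column (and
#' any extra metadata), followed by an RFC-4180 CSV body at 10 significant
#' digits. [read_units_csv()] reads the same layout back.
#'
#' @param x data frame (trajectory, characteristic, diagram, ...).
#' @param file output path.
#' @param metadata named character vector written as extra `# key: value`
#'   lines.
#' @return `file`, invisibly.
#' @export
write_units_csv <- function(x, file, metadata = character()) {
  units <- vapply(names(x), function(nm)
    if (nm %in% names(.column_units)) .column_units[[nm]] else "", "")
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
  writeLines(paste0("# units: ",
                    paste(names(x), units, sep = "=", collapse = ", ")), con)
  y <- as.data.frame(lapply(x, function(col)
    if (is.numeric(col) && !is.complex(col)) signif(col, 10L) else col))
  names(y) <- names(x)
  utils::write.csv(y, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_units_csv
#' @return `read_units_csv`: the data frame (comment lines skipped).
#' @export
read_units_csv <- function(file) {
  utils::read.csv(file, comment.char = "#")
}

#' Write a run record
#'
#' A JSON record of a computation: the command/operation name, the resolved
#' parameter set, seeds, solver settings, package version, and the manifest
#' of files the run produced. Re-running the recorded operation with the
#' recorded inputs reproduces the outputs at fixed settings.
#'
#' @param file output path (JSON).
#' @param command operation name.
#' @param params a [model_params()] object, or `NULL`.
#' @param seed integer seed(s), or `NULL`.
#' @param outputs character vector of produced files.
#' @param extra named list of extra settings to record.
#' @return `file`, invisibly.
#' @export
write_run_record <- function(file, command, params = NULL, seed = NULL,
                             outputs = character(), extra = list()) {
  rec <- list(
    command = command,
    package_version = as.character(utils::packageVersion("glycak")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    solver = list(method = "lsoda", rtol = 1e-8, atol = 1e-10),
    seed = seed,
    parameters = if (!is.null(params)) unclass(params),
    outputs = outputs,
    settings = extra,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}
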
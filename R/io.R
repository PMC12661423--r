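# Plain-text readers/writers for the package's CSV dialects and for
# configuration files (YAML/JSON). Headers are checked strictly so malformed
# inputs fail loudly rather than silently misalign.

.check_header <- function(df, need, what) {
  if (!all(need %in% names(df))) {
    abort(sprintf("%s must have columns: %s (got: %s).",
                  what, paste(need, collapse = ", "),
                  paste(names(df), collapse = ", ")))
  }
  invisible(df)
}

#' Read / write a sorption table CSV
#'
#' Columns: `aw, mc_wb, temp_K, direction`.
#'
#' @param path CSV file path.
#' @return [read_sorption_table()]: a `sorption_table` tibble.
#' @export
read_sorption_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_header(df, c("aw", "mc_wb", "temp_K", "direction"),
                "A sorption table CSV")
  as_sorption_table(df)
}

#' @rdname read_sorption_table
#' @param table A `sorption_table`.
#' @export
write_sorption_table <- function(table, path) {
  table <- as_sorption_table(table)
  readr::write_csv(table[, c("aw", "mc_wb", "temp_K", "direction")], path)
  invisible(path)
}

#' Read / write an air-schedule CSV
#'
#' Columns: `time_s, temp_air_C, rh_air_pct` and optionally `air_speed_m_s`.
#'
#' @param path CSV file path.
#' @param speed Default air speed (m s^-1) when the column is absent.
#' @export
read_air_schedule <- function(path, speed = 0.235) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_header(df, c("time_s", "temp_air_C", "rh_air_pct"),
                "An air-schedule CSV")
  air_schedule(series = df, speed = speed)
}

#' @rdname read_air_schedule
#' @param schedule An [air_schedule()] built from a series.
#' @export
write_air_schedule <- function(schedule, path) {
  if (schedule$constant) {
    abort("Constant schedules have no series to write; build one with `series =`.")
  }
  readr::write_csv(schedule$series, path)
  invisible(path)
}

#' Read / write a drying-curve CSV
#'
#' Columns: `time_s, mc_wb` and optionally `temp_seed_K, aw_surface`.
#'
#' @param path CSV file path.
#' @export
read_drying_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_header(df, c("time_s", "mc_wb"), "A drying-curve CSV")
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing.")
  }
  if (any(df$mc_wb < 0 | df$mc_wb > 1)) abort("`mc_wb` must lie in [0, 1].")
  class(df) <- c("drying_curve", class(df))
  df
}

#' @rdname read_drying_curve
#' @param curve A `drying_curve` tibble.
#' @export
write_drying_curve <- function(curve, path) {
  cols <- intersect(c("time_s", "mc_wb", "temp_seed_K", "aw_surface"),
                    names(curve))
  readr::write_csv(tibble::as_tibble(curve)[, cols], path)
  invisible(path)
}

#' Read a diffusivity table CSV
#'
#' Columns: `yw, Dw` and optionally `temp_K`.
#'
#' @param path CSV file path.
#' @export
read_diffusivity_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_header(df, c("yw", "Dw"), "A diffusivity-table CSV")
  df
}

#' Read a simulation configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON configuration mapping onto
#' [drying_config()]. Recognised top-level keys are the arguments of
#' `drying_config()`; `isotherm`, `diffusivity`, `composition` and
#' `constants` may be nested maps passed to their respective constructors
#' (`composition` takes `y_w` plus dry-matter fractions).
#'
#' @param path Configuration file path.
#' @return A [drying_config()] object.
#' @export
read_drying_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build <- function(x, ctor) if (is.null(x)) NULL else do.call(ctor, as.list(x))
  args <- raw
  for (key in c("isotherm", "isotherm_embryo", "isotherm_coat")) {
    args[[key]] <- build(raw[[key]], isotherm_params)
  }
  args$diffusivity <- build(raw$diffusivity, diffusivity_params)
  for (key in c("composition", "composition_embryo", "composition_coat")) {
    args[[key]] <- build(raw[[key]], seed_composition)
  }
  args$constants <- build(raw$constants, material_constants)
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(drying_config, args)
}
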
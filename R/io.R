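# Readers and writers for the package's plain-text interchange formats.
# All files are comma-separated with a header row, mm/degree units, decimal
# points, full double precision on write.

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    abort_config(paste0(what, " file not found: '", path, "'."))
  }
  # readr reports malformed rows as a warning plus a problems() table; we
  # surface them as a parse error below, so silence the duplicate warning.
  df <- tryCatch(
    suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                     progress = FALSE)),
    error = function(e) abort_parse(paste0("Cannot parse '", path, "': ",
                                           conditionMessage(e)))
  )
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort_parse(paste0("Malformed CSV '", path, "' at line ", probs$row[1] + 1L,
                       ": ", probs$expected[1], " expected, got ",
                       probs$actual[1], "."))
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_parse(paste0(what, " file '", path, "' is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  df
}

#' Read and write implant record files
#'
#' Implant CSVs have columns `id`, `px`, `py`, `pz` (platform center, mm),
#' `ax`, `ay`, `az` (apex center, mm), plus any factor columns
#' (`registration_method`, `jaw`, `guide_support`, ...).
#'
#' @param path File path.
#' @param implants Implant tibble.
#' @return `read_implants()` returns a tibble; `write_implants()` returns
#'   `path` invisibly.
#' @export
read_implants <- function(path) {
  df <- .read_csv_checked(path, c("id", .implant_cols), "Implant")
  .check_implant_df(df, paste0("'", path, "'"))
  df
}

#' @rdname read_implants
#' @export
write_implants <- function(implants, path) {
  readr::write_csv(implants, path)
  invisible(path)
}

#' Read and write point-correspondence files
#'
#' Correspondence CSVs have columns `sx`, `sy`, `sz` (source / cast space),
#' `tx`, `ty`, `tz` (target / CBCT space) and optionally `label`
#' (`"surface"` or `"fiducial"`).
#'
#' @param path File path.
#' @param correspondences Correspondence tibble.
#' @return `read_correspondences()` returns a tibble;
#'   `write_correspondences()` returns `path` invisibly.
#' @export
read_correspondences <- function(path) {
  .read_csv_checked(path, c("sx", "sy", "sz", "tx", "ty", "tz"),
                    "Correspondence")
}

#' @rdname read_correspondences
#' @export
write_correspondences <- function(correspondences, path) {
  readr::write_csv(correspondences, path)
  invisible(path)
}

#' Read and write deviation tables
#'
#' Deviation CSVs carry the six metric columns (`global_platform_mm`,
#' `lateral_platform_mm`, `global_apex_mm`, `lateral_apex_mm`, `depth_mm`,
#' `angular_deg`) plus `id` and any factor columns.
#'
#' @param path File path.
#' @param deviations Deviation tibble.
#' @return `read_deviations()` returns a tibble; `write_deviations()` returns
#'   `path` invisibly.
#' @export
read_deviations <- function(path) {
  .read_csv_checked(path, c("id", .metric_cols), "Deviation")
}

#' @rdname read_deviations
#' @export
write_deviations <- function(deviations, path) {
  readr::write_csv(deviations, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with optional sections `scenario` (fields of
#' [scenario_config()]), `effects` (fields of [cohort_effects()]), `design`
#' (list of cells with `registration_method`, `jaw`, `guide_support`, `n`),
#' and top-level `seed`.
#'
#' @param path YAML file path.
#' @return A list with validated `config`, `effects`, `design`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("Config file not found: '", path, "'."))
  }
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_parse(paste0(
                    "Cannot parse YAML '", path, "': ", conditionMessage(e))))
  config <- do.call(scenario_config, raw$scenario %||% list())
  effects <- do.call(cohort_effects, raw$effects %||% list())
  design <- if (is.null(raw$design)) default_cohort_design() else {
    cells <- lapply(raw$design, function(cell) {
      # YAML 1.1 implicitly types a bare `n:` key as boolean FALSE; map it
      # back to the documented cell-count field.
      names(cell)[names(cell) == "FALSE"] <- "n"
      tibble::as_tibble(cell)
    })
    cohort_design(dplyr::bind_rows(cells))
  }
  list(config = config, effects = effects, design = design,
       seed = raw$seed %||% NULL)
}
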
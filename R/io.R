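#' Read and write TOA matrices and related tables
#'
#' CSV layout: one row per transmission with a `ping` column followed by one
#' column per hydrophone id; empty cells are missed detections. Arrival times
#' are absolute seconds; writers keep at least microsecond precision (TOA
#' differences are of order 1e-4 s), using up to 15 significant digits.
#'
#' @param path File path.
#' @param array Optional hydrophone array table; when given, columns are
#'   validated against its ids (an error names any mismatching column).
#' @return `read_toa_csv()` returns a TOA tibble.
#' @export
read_toa_csv <- function(path, array = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!"ping" %in% names(df)) abort("TOA file must have a `ping` column")
  if (anyDuplicated(df$ping))
    abort(paste0("duplicated ping index in ", path, ": ",
                 paste(unique(df$ping[duplicated(df$ping)]), collapse = ", ")))
  for (cn in setdiff(names(df), "ping"))
    if (!is.numeric(df[[cn]]))
      abort(paste0("non-numeric arrival times in column ", cn))
  if (!is.null(array)) as_toa_matrix(df, array)  # validates columns
  df
}

#' @rdname read_toa_csv
#' @param toa TOA tibble to write.
#' @export
write_toa_csv <- function(toa, path) {
  write_csv_precise(toa, path)
  invisible(path)
}

#' Read or write a hydrophone array CSV
#'
#' Columns `hydro`, `x`, `y` (meters, planar projection).
#'
#' @param path File path.
#' @return A validated hydrophone array tibble.
#' @export
read_hydros_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  validate_array(readr::read_csv(path, show_col_types = FALSE, comment = "#"))
}

#' @rdname read_hydros_csv
#' @param array Hydrophone array table to write.
#' @export
write_hydros_csv <- function(array, path) {
  readr::write_csv(validate_array(array), path)
  invisible(path)
}

#' Read a true/estimated track CSV
#'
#' @param path File path; expects at least `x`, `y` columns (and usually `t`).
#' @return A tibble.
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

# readr::write_csv with full double precision and optional '#' header lines
write_csv_precise <- function(df, path, header = character()) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(z) {
    s <- sprintf("%.15g", z)
    s[is.na(z)] <- NA_character_
    s
  })
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(names(out), collapse = ","), con)
  lines <- do.call(paste, c(lapply(out, function(z) {
    z <- as.character(z); z[is.na(z)] <- ""; z
  }), sep = ","))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Write a fitted track to CSV
#'
#' Writes the per-ping position table of a `yaps_fit` or `tdoa_fit` with a
#' commented header recording the package version, the seed and a hash of the
#' configuration, so a result file documents how to reproduce itself.
#'
#' @param fit A `yaps_fit` or `tdoa_fit`.
#' @param path Output path.
#' @param seed Seed to record in the header (optional).
#' @export
write_fit <- function(fit, path, seed = NULL) {
  if (!inherits(fit, c("yaps_fit", "tdoa_fit"))) abort("not a fit object")
  cfg <- if (inherits(fit, "yaps_fit")) fit$params else fit$cfg
  header <- c(paste0("toatrack ", as.character(utils::packageVersion("toatrack"))),
              paste0("fit: ", class(fit)[1]),
              if (!is.null(seed)) paste0("seed: ", seed),
              paste0("config_hash: ", config_hash(cfg)))
  write_csv_precise(fit$track, path, header = header)
  invisible(path)
}

config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)), collapse = "\n")
  # small stable polynomial hash (exact in doubles); avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Round-trip a run configuration through YAML or JSON
#'
#' A run configuration bundles the seed, the estimation mode and the
#' simulator/baseline settings so a whole analysis is reproducible from one
#' file. YAML or JSON is chosen by file extension.
#'
#' @param config Named list; typically `list(seed =, mode =, sim = sim_config(),
#'   tdoa = tdoa_config())`.
#' @param path File ending in `.yaml`, `.yml` or `.json`.
#' @return `read_run_config()` returns the named list with `sim` and `tdoa`
#'   elements restored to their classes.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  plain <- strip(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(plain, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else abort("config path must end in .yaml, .yml or .json")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$sim)) cfg$sim <- do.call(sim_config, cfg$sim)
  if (!is.null(cfg$tdoa)) cfg$tdoa <- do.call(tdoa_config, cfg$tdoa)
  cfg
}
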
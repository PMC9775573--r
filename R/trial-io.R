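# Trial file dialect: a CSV of samples (time_s, zone, surface_temp_C,
# heat_loss_W) plus a YAML or JSON sidecar carrying trial id, mode,
# geometry, environment and skin RH; alternatively a single JSON container
# holding both.

trial_meta <- function(trial) {
  list(
    trial_id = trial$trial_id,
    mode = trial$mode,
    geometry = list(zone = trial$geometry$zone,
                    area = trial$geometry$area),
    environment = unclass(trial$environment),
    skin_rh = trial$skin_rh
  )
}

trial_from_parts <- function(meta, data) {
  geometry <- manikin_geometry(meta$geometry$zone,
                               as.numeric(meta$geometry$area))
  env <- meta$environment
  environment <- manikin_environment(
    air_temperature = env$air_temperature,
    relative_humidity = env$relative_humidity,
    air_velocity = env$air_velocity,
    radiant_temperature = env$radiant_temperature %||% env$air_temperature,
    operative_temperature = env$operative_temperature
  )
  manikin_trial(meta$trial_id, meta$mode, geometry, environment, data,
                skin_rh = meta$skin_rh)
}

#' Read and write manikin trials
#'
#' `write_trial()` stores a trial as a sample CSV plus a metadata sidecar
#' (YAML or JSON, by the sidecar extension); `read_trial()` is its inverse.
#' `write_trial_json()` / `read_trial_json()` use a single JSON container
#' holding both parts.
#'
#' @param trial a [manikin_trial()].
#' @param csv_path path of the sample CSV (columns `time_s`, `zone`,
#'   `surface_temp_C`, `heat_loss_W`).
#' @param sidecar_path path of the metadata sidecar; default replaces the
#'   CSV extension with `.yaml`.
#' @return `read_trial()`/`read_trial_json()` return a [manikin_trial()];
#'   the writers return their paths invisibly.
#' @examples
#' trial <- generate_trial(synthetic_spec(mode = "dry", duration = 60))
#' tmp <- tempfile(fileext = ".csv")
#' write_trial(trial, tmp)
#' read_trial(tmp)
#' @export
write_trial <- function(trial, csv_path, sidecar_path = NULL) {
  stopifnot(inherits(trial, "manikin_trial"))
  if (is.null(sidecar_path)) sidecar_path <- sub("\\.[^.]*$", ".yaml", csv_path)
  utils::write.csv(trial$data, csv_path, row.names = FALSE)
  meta <- trial_meta(trial)
  if (grepl("\\.ya?ml$", sidecar_path, ignore.case = TRUE)) {
    yaml::write_yaml(meta, sidecar_path)
  } else {
    jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(c(csv_path, sidecar_path))
}

#' @rdname write_trial
#' @export
read_trial <- function(csv_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) {
    candidates <- vapply(c(".yaml", ".yml", ".json"),
                         function(ext) sub("\\.[^.]*$", ext, csv_path),
                         character(1))
    sidecar_path <- candidates[file.exists(candidates)][1L]
    if (is.na(sidecar_path)) stop("no sidecar found next to ", csv_path,
                                  call. = FALSE)
  }
  data <- utils::read.csv(csv_path)
  meta <- if (grepl("\\.ya?ml$", sidecar_path, ignore.case = TRUE)) {
    yaml::read_yaml(sidecar_path)
  } else {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  trial_from_parts(meta, data)
}

#' @rdname write_trial
#' @param path path of the single JSON container.
#' @export
write_trial_json <- function(trial, path) {
  stopifnot(inherits(trial, "manikin_trial"))
  payload <- c(trial_meta(trial), list(samples = trial$data))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- tibble::as_tibble(raw$samples)
  trial_from_parts(raw, data)
}
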
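#' Read a trajectory table from CSV
#'
#' The shared trajectory schema has mandatory columns `frame`, `track_id`,
#' `x_um`, `y_um`, `diameter_um`, `condition`, `field_id`; unknown extra
#' columns are preserved. Rows with non-numeric values in numeric columns
#' are rejected with their line numbers. LF and CRLF files are both
#' accepted.
#'
#' @param path CSV path (UTF-8, header row, '.' decimal).
#' @return Trajectory data.frame.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("frame", "track_id", "x_um", "y_um", "diameter_um",
                 "condition", "field_id")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("trajectory schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  numeric_cols <- c("frame", "track_id", "x_um", "y_um", "diameter_um",
                    "field_id")
  bad <- rep(FALSE, nrow(df))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- bad | (is.na(v) & !is.na(df[[col]]))
    df[[col]] <- v
  }
  bad <- bad | Reduce(`|`, lapply(df[numeric_cols], is.na))
  if (any(bad)) {
    warning("rejecting malformed row(s) at line(s) ",
            paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$frame <- as.integer(df$frame)
  df$field_id <- as.integer(df$field_id)
  rownames(df) <- NULL
  df
}

#' Write a trajectory table (plus sidecar) to CSV
#'
#' @param trajectories Trajectory data.frame (shared schema).
#' @param path Output CSV path.
#' @param seed,config Optional provenance recorded in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, seed = NULL,
                               config = NULL) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  write_sidecar(path, seed = seed, config = config)
  invisible(path)
}

#' Write cohort summaries or stats tables to CSV (plus sidecar)
#'
#' @param x data.frame to write.
#' @param path Output CSV path.
#' @param seed,config Optional provenance for the sidecar.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path, seed = NULL, config = NULL) {
  utils::write.csv(x, path, row.names = FALSE)
  write_sidecar(path, seed = seed, config = config)
  invisible(path)
}

#' Provenance sidecar for a written artifact
#'
#' Records software version, seed and a digest of the generating
#' configuration next to the artifact as `<path>.json`.
#'
#' @param path Artifact path.
#' @param seed Seed used (or NULL).
#' @param config Configuration object (serialized fields are hashed).
#' @return Sidecar path, invisibly.
#' @export
write_sidecar <- function(path, seed = NULL, config = NULL) {
  cfg_hash <- if (!is.null(config)) {
    digestable <- utils::capture.output(utils::str(config))
    sum(utf8ToInt(paste(digestable, collapse = "\n")) *
          seq_along(utf8ToInt(paste(digestable, collapse = "\n")))) %%
      2147483647
  } else NULL
  meta <- list(
    software = "rollflow",
    version = as.character(utils::packageVersion("rollflow")),
    seed = seed, config_hash = cfg_hash,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  side <- paste0(path, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, null = "null")
  invisible(side)
}

#' Read a run configuration from JSON or YAML
#'
#' Builds the package objects (geometry, fluid, flow, bond model,
#' classification parameters) from a flat config file. Recognized blocks:
#' `geometry{width_um,height_um,length_um,fov_x_um,fov_y_um}`,
#' `fluid{viscosity_cP}`, `flow{shear_dyn_cm2|flow_rate_uL_min,k_wall}`,
#' `bond{...}` (any [bond_model()] argument),
#' `classification{...}` (any [classification_params()] argument),
#' `seed`.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return List with `flow`, `bond`, `params`, `seed`, and the raw parsed
#'   config as `raw`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("config must be .json, .yaml or .yml", call. = FALSE)
  geom <- do.call(channel_geometry, as.list(raw$geometry %||% list()))
  fluid <- do.call(fluid_properties, as.list(raw$fluid %||% list()))
  flow_args <- as.list(raw$flow %||% list(shear_dyn_cm2 = 0.05))
  flow <- do.call(flow_context,
                  c(list(geometry = geom, fluid = fluid), flow_args))
  bond <- do.call(bond_model, as.list(raw$bond %||% list()))
  params <- do.call(classification_params,
                    as.list(raw$classification %||% list()))
  list(flow = flow, bond = bond, params = params,
       seed = raw$seed %||% 1L, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
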
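# Track-table I/O, YAML configuration loading, and run manifests.

.track_cols <- c("cell_id", "frame", "t_seconds", "x_um", "y_um")

#' Write a track table
#'
#' Writes the documented track CSV dialect: columns `cell_id`, `frame`,
#' `t_seconds`, `x_um`, `y_um`, one row per detection; missing detections are
#' absent rows, never `NA` rows.
#'
#' @param tracks track table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(.track_cols %in% names(tracks)))
  write.csv(as.data.frame(tracks)[, .track_cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a track table
#'
#' Reads the track CSV dialect and normalizes it: rows are sorted by
#' `cell_id` then `frame`, so a shuffled file round-trips to the same track
#' set. Malformed input is rejected with the offending cell and line numbers:
#' missing columns, non-finite coordinates, and duplicated
#' `(cell_id, frame)` pairs are all errors.
#'
#' @param path CSV file path.
#' @return a `track_set` data frame.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.track_cols, names(df))
  if (length(missing))
    stop("track file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, .track_cols]
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um) |
                 !is.finite(df$frame) | !is.finite(df$t_seconds))
  if (length(bad))
    stop("non-finite values at line(s) ",
         paste(bad + 1L, collapse = ", "),   # +1 for the header line
         call. = FALSE)
  dup_key <- paste(df$cell_id, df$frame)
  if (anyDuplicated(dup_key)) {
    d <- dup_key[duplicated(dup_key)][1]
    lines <- which(dup_key == d)
    stop(sprintf("duplicated (cell_id, frame) = (%s) at lines %s",
                 gsub(" ", ", ", d),
                 paste(lines + 1L, collapse = " and ")), call. = FALSE)
  }
  df <- df[order(df$cell_id, df$frame), ]
  rownames(df) <- NULL
  class(df) <- c("track_set", "data.frame")
  df
}

# Known keys per config section; unknown keys are rejected. Computed lazily
# so file collation order does not matter at install time.
.config_schema <- function() {
  list(
    tracks = names(formals(track_gen_config)),
    dose = names(formals(dose_gen_config)),
    fluor = names(formals(generate_fluorescence_traces)),
    sim = names(formals(sim_config))
  )
}

#' Load and validate a YAML configuration
#'
#' Reads a single-file YAML configuration with per-module sections
#' (`tracks`, `dose`, `fluor`, `sim`). Each section is validated by the
#' corresponding constructor (so units, ranges and invariants are checked and
#' defaults filled); unknown sections or keys are rejected with the offending
#' name.
#'
#' @param path YAML file path.
#' @return named list of validated config objects, one per section present,
#'   with attribute `hash` (see [config_hash()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  schema <- .config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (sec in names(raw)) {
    keys <- names(raw[[sec]])
    bad <- setdiff(keys, schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section `%s`: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    ctor <- switch(sec,
                   tracks = track_gen_config,
                   dose = dose_gen_config,
                   fluor = NULL,   # plain argument list, validated at call time
                   sim = sim_config)
    out[[sec]] <- if (is.null(ctor)) raw[[sec]] else do.call(ctor, raw[[sec]])
  }
  attr(out, "hash") <- config_hash(out)
  out
}

#' Deterministic digest of a configuration
#'
#' Canonicalizes a configuration (recursively sorting names, dropping
#' functions and environments) to JSON and returns its MD5 digest, so the
#' same configuration serialized with different key order hashes identically.
#'
#' @param config any list-like configuration object.
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.function(x) || is.environment(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, canon)
      x <- x[!vapply(x, is.null, logical(1))]
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
      return(x)
    }
    x
  }
  js <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                         digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Build a run manifest
#'
#' A manifest records everything needed to regenerate a result: the command
#' label, the configuration digest, the seeds, the package version, and an
#' ISO-8601 timestamp.
#'
#' @param command label of the pipeline stage (e.g. `"simulate"`).
#' @param config the configuration used.
#' @param seeds integer vector of seeds.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seeds) {
  structure(list(
    command = command,
    config_hash = config_hash(config),
    seeds = as.integer(seeds),
    package_version = as.character(packageVersion("capsakinesis")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param dir output directory (created if needed); the manifest is written as
#'   `manifest.json` inside it.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
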
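#' Load a run configuration from a YAML file
#'
#' The file mirrors the package's parameter objects in named blocks
#' (`teng`, `pattern`, `membrane`, `axon`, `motion`, `stimulus`, `sweep`,
#' `metrics`), all in the documented SI / electrophysiology units; any
#' block or key may be omitted (the package default is used) and unknown
#' keys are rejected with a message listing every violation.
#'
#' @param path YAML file.
#' @return list of class `run_config` with elements `teng`, `membrane`,
#'   `axon`, `motion`, `stimulus`, `metrics` (a list with `threshold`,
#'   `min_separation`), `sweep` (raw list or NULL), `schema_version`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_blocks <- c("teng", "pattern", "membrane", "axon", "motion",
                    "stimulus", "sweep", "metrics", "schema_version")
  errors <- character(0)
  bad <- setdiff(names(raw), known_blocks)
  if (length(bad))
    errors <- c(errors, sprintf("unknown top-level key(s): %s",
                                paste(bad, collapse = ", ")))
  take <- function(block, builder, extra = list()) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    ok <- names(formals(builder))
    bad <- setdiff(names(args), ok)
    if (length(bad)) {
      errors <<- c(errors, sprintf("%s: unknown key(s): %s (expected %s)",
                                   block, paste(bad, collapse = ", "),
                                   paste(ok, collapse = ", ")))
      return(NULL)
    }
    tryCatch(do.call(builder, c(args, extra)),
             error = function(e) {
               errors <<- c(errors, sprintf("%s: %s", block,
                                            conditionMessage(e)))
               NULL
             })
  }
  pattern <- take("pattern", micropattern_spec)
  teng <- take("teng", teng_config,
               extra = if (!is.null(pattern)) list(pattern = pattern))
  membrane <- take("membrane", membrane_params)
  axon <- take("axon", axon_config)
  motion <- take("motion", motion_profile)
  stimulus <- take("stimulus", stimulus_protocol)
  met <- raw$metrics
  if (is.null(met)) met <- list()
  badm <- setdiff(names(met), c("threshold", "min_separation"))
  if (length(badm))
    errors <- c(errors, sprintf("metrics: unknown key(s): %s",
                                paste(badm, collapse = ", ")))
  metrics <- list(threshold = met$threshold %||% 0,
                  min_separation = met$min_separation %||% 2)
  if (length(errors))
    stop(paste(c("invalid configuration:", errors), collapse = "\n  "))
  structure(list(teng = teng, membrane = membrane, axon = axon,
                 motion = motion, stimulus = stimulus, metrics = metrics,
                 sweep = raw$sweep,
                 schema_version = raw$schema_version %||% "1"),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration back to YAML
#'
#' Inverse of [load_config()] up to defaults: dumping and re-loading gives
#' semantically identical parameter objects.
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) { attributes(x) <- NULL; x }
  blocks <- list(
    teng = strip(config$teng[setdiff(names(config$teng), "pattern")]),
    pattern = strip(unclass(config$teng$pattern)),
    membrane = strip(unclass(config$membrane)),
    axon = strip(config$axon[setdiff(names(config$axon), "dz")]),
    motion = strip(unclass(config$motion)),
    stimulus = strip(unclass(config$stimulus)),
    metrics = config$metrics,
    schema_version = config$schema_version)
  blocks$stimulus$target_compartments <-
    config$stimulus$target_compartments %||% NULL
  yaml::write_yaml(blocks, path)
  invisible(path)
}

fmt9 <- function(x) sprintf("%.9g", x)

#' Write / read a device curve as TSV
#'
#' Tab-separated table with columns `gap_m`, `voc_V`, `cap_F`,
#' `cap_F_per_cm2`, preceded by a comment line recording provenance,
#' pattern, plate area and a config hash. Values carry 9 significant
#' digits; [read_curve()] reconstructs the curve at that precision.
#'
#' @param curve a [teng_curve()].
#' @param path output file.
#' @return `path` (write) or a [teng_curve()] (read).
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "teng_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# teng_curve provenance=%s pattern=%s plate_area_m2=%s hash=%s",
    curve$provenance, curve$pattern_shape, fmt9(curve$plate_area),
    config_hash(unclass(curve))), con)
  writeLines("gap_m\tvoc_V\tcap_F\tcap_F_per_cm2", con)
  writeLines(paste(fmt9(curve$gaps), fmt9(curve$voc), fmt9(curve$cap_total),
                   fmt9(curve$cap_per_area), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  header <- readLines(path, n = 1)
  prov <- sub(".*provenance=(\\S+).*", "\\1", header)
  patt <- sub(".*pattern=(\\S+).*", "\\1", header)
  area <- as.numeric(sub(".*plate_area_m2=(\\S+).*", "\\1", header))
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  teng_curve(d$gap_m, d$voc_V, d$cap_F, plate_area = area,
             provenance = prov, pattern_shape = patt)
}

#' Write a simulated voltage trace as TSV
#'
#' Columns `time_ms`, one `V<k>_mV` per recorded compartment, and `x_cm`
#' when the run logged the gap trajectory.
#'
#' @param res a `sim_result`.
#' @param path output file.
#' @param compartments indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_trace <- function(res, path, compartments = NULL) {
  stopifnot(inherits(res, "sim_result"))
  if (is.null(compartments)) compartments <- seq_len(ncol(res$V_trace))
  d <- data.frame(time_ms = fmt9(res$times))
  for (k in compartments) d[[sprintf("V%d_mV", k)]] <- fmt9(res$V_trace[, k])
  if (!is.null(res$x)) d$x_cm <- fmt9(res$x)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sweep metrics as TSV and a JSON run manifest
#'
#' @param metrics the data.frame from [speed_sweep()] / [pattern_sweep()].
#' @param path output TSV file.
#' @param manifest optional list written alongside as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, manifest = NULL) {
  num <- vapply(metrics, is.numeric, logical(1))
  out <- metrics
  out[num] <- lapply(metrics[num], fmt9)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest))
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
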
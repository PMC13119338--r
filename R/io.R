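#' Write a photon stream as delimited text
#'
#' One photon per line (`time_s,channel,microtime_ns`, CSV with header,
#' '.' decimal separator, UTF-8), preceded by `#key=value` comment lines
#' carrying the clock rate. Times are written with enough digits to
#' round-trip the underlying integer clock ticks losslessly.
#'
#' @param stream A [photon_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_photons <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  clock <- attr(stream, "clock_rate_hz")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#clock_rate_hz=%.10g", clock), con)
  writeLines("time_s,channel,microtime_ns", con)
  if (nrow(stream))
    writeLines(sprintf("%.10f,%s,%.6f", stream$ticks / clock,
                       stream$channel, stream$microtime_ns), con)
  invisible(path)
}

#' Read a photon stream from delimited text or Photon-HDF5
#'
#' Reads the package's delimited-text photon dialect (see
#' [write_photons()]). The Photon-HDF5 container dialect is recognised but
#' not currently supported in this implementation; requesting it raises an
#' informative error.
#'
#' @param path Input file.
#' @param dialect `"text"` or `"photon-hdf5"`.
#' @param clock_rate_hz Clock rate used if the file carries none.
#' @return A [photon_stream()]; unsorted input is sorted with a warning.
#' @export
read_photons <- function(path, dialect = c("text", "photon-hdf5"),
                         clock_rate_hz = 1e7) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("photon file not found: ", path)
  if (dialect == "photon-hdf5")
    stop("the photon-hdf5 dialect is not supported by this build; ",
         "use the delimited-text dialect")
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  m <- regmatches(meta, regexec("^#clock_rate_hz=([0-9.eE+-]+)$", meta))
  for (g in m) if (length(g) == 2) clock_rate_hz <- as.numeric(g[2])
  body <- lines[!grepl("^#", lines)]
  if (length(body) <= 1) {
    warning("empty photon file: ", path)
    return(photon_stream(clock_rate_hz = clock_rate_hz))
  }
  header <- strsplit(body[1], ",")[[1]]
  if (!identical(header, c("time_s", "channel", "microtime_ns")))
    stop("malformed photon file header at line ",
         length(meta) + 1, ": ", body[1])
  rec <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(rec) != 3)
  if (length(bad))
    stop("malformed photon record at line ",
         length(meta) + 1 + bad[1], " of ", path)
  rec <- matrix(unlist(rec), ncol = 3, byrow = TRUE)
  t_s <- as.numeric(rec[, 1]); micro <- as.numeric(rec[, 3])
  if (anyNA(t_s) || anyNA(micro))
    stop("non-numeric photon record in ", path)
  ticks <- round(t_s * clock_rate_hz)
  if (is.unsorted(ticks)) {
    warning("photon records were not sorted; sorting by time")
    return(photon_stream(ticks, rec[, 2], micro,
                         clock_rate_hz = clock_rate_hz, sort = TRUE))
  }
  photon_stream(ticks, rec[, 2], micro, clock_rate_hz = clock_rate_hz)
}

#' Write generator ground truth as a flat key-value sidecar
#'
#' @param truth Named list of scalars/vectors (vectors are comma-joined).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  keep <- vapply(truth, function(v) is.atomic(v) && length(v) >= 1,
                 logical(1))
  truth <- truth[keep]
  lines <- vapply(names(truth), function(k)
    sprintf("%s=%s", k, paste(format(truth[[k]], digits = 12),
                              collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value ground-truth sidecar
#'
#' @param path Sidecar file from [write_ground_truth()].
#' @return Named list; values parsed as numeric where possible.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("sidecar not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(g) {
    v <- strsplit(g[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) trimws(v) else num
  })
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Read a per-frame distance series from delimited text
#'
#' Accepts a one-column file of distances (nm) or a table with a column
#' named `r` (other columns, e.g. `frame`, are ignored).
#'
#' @param path Delimited text file (comma or whitespace separated).
#' @return Numeric vector of distances.
#' @export
read_distance_series <- function(path) {
  if (!file.exists(path)) stop("distance file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "",
                          comment.char = "#",
                          blank.lines.skip = TRUE)
  if (ncol(df) == 1 && !is.numeric(df[[1]]))
    df <- utils::read.table(path, header = TRUE, sep = ",",
                            comment.char = "#")
  col <- if ("r" %in% names(df)) df[["r"]] else df[[ncol(df)]]
  r <- as.numeric(col)
  if (anyNA(r)) stop("non-numeric distances in ", path)
  r
}

#' Default analysis configuration
#'
#' Returns the standard run configuration: burst thresholds of 40 photons
#' per 500-us bin (droplet mode) or 60 per 1-ms bin (manual mode),
#' stoichiometry gates 0.2-0.8 (0.25-0.75 for intermolecular FRET),
#' droplet velocity 0.6 mm/s, manual-mixing dead time 5 s, default
#' correction factors, and histogram settings.
#'
#' @param mode `"droplet"` or `"manual"`.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(mode = c("droplet", "manual")) {
  mode <- match.arg(mode)
  structure(list(
    mode = mode,
    burst = if (mode == "droplet")
      list(mode = "fast", bin_width = 5e-4, threshold = 40)
    else list(mode = "slow", bin_width = 1e-3, threshold = 60),
    corrections = list(bg_rate_DD = 750, bg_rate_DA = 750,
                       bg_rate_AA = 750, alpha = 0.05, delta = 0.05,
                       gamma = 1.0),
    gate = c(0.2, 0.8),
    gate_intermolecular = c(0.25, 0.75),
    histogram = list(bin_width = 0.025, range = c(-0.1, 1.1)),
    droplet_velocity = 0.6,
    dead_time = if (mode == "droplet") 0 else 5,
    window = 60,
    min_bursts = if (mode == "droplet") 3000 else 1000,
    seed = 1L), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A `run_config` list (e.g. parsed from JSON).
#' @return The validated config (with class set), or an error.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  req <- c("mode", "burst", "corrections", "gate", "histogram",
           "droplet_velocity", "dead_time", "min_bursts")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("run config is missing fields: ", paste(miss, collapse = ", "))
  stopifnot(config$mode %in% c("droplet", "manual"),
            config$burst$bin_width > 0, config$burst$threshold >= 1,
            length(config$gate) == 2, config$gate[1] < config$gate[2],
            config$droplet_velocity > 0, config$dead_time >= 0)
  class(config) <- "run_config"
  config
}

#' Write a JSON run manifest
#'
#' Records the inputs (with MD5 checksums), configuration (with its own
#' hash), seed and package version of a pipeline run, so any output
#' artifact can be reproduced from its manifest.
#'
#' @param path Manifest path (JSON).
#' @param inputs Character vector of input file paths (may be empty).
#' @param config A `run_config`.
#' @param seed Integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs, config, seed) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "fretburst",
    version = as.character(utils::packageVersion("fretburst")),
    seed = seed,
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = if (length(inputs))
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    else data.frame(path = character(), md5 = character()))
  unlink(tmp)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

# Deterministic delimited-text writer shared by the CLI ('.' decimal, UTF-8).
write_tsv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
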
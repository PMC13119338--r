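#' Photon stream container
#'
#' A time-ordered table of detected photons. Macrotimes are stored as
#' integer clock ticks (`ticks`, numeric but integer-valued, at
#' `clock_rate_hz` ticks per second) to avoid floating-point drift when
#' binning; the spectral detection channel is `"D"` (donor) or `"A"`
#' (acceptor); `microtime_ns` is the arrival time within the PIE period.
#'
#' @param ticks Integer-valued macrotimes in clock ticks, sorted ascending.
#' @param channel Character or factor, `"D"`/`"A"` per photon.
#' @param microtime_ns Microtime within the PIE period, ns.
#' @param clock_rate_hz Clock rate of the macrotime ticks.
#' @param metadata Optional list of metadata (e.g. generator ground truth).
#' @param sort If `TRUE`, sort by `ticks` instead of failing on unsorted
#'   input.
#' @return A `photon_stream`: a data.frame with columns `ticks`, `channel`,
#'   `microtime_ns` and attributes `clock_rate_hz`, `metadata`.
#' @seealso [photon_times()], [read_photons()], [write_photons()]
#' @export
photon_stream <- function(ticks = numeric(), channel = character(),
                          microtime_ns = numeric(), clock_rate_hz = 1e7,
                          metadata = list(), sort = FALSE) {
  stopifnot(length(ticks) == length(channel),
            length(ticks) == length(microtime_ns),
            clock_rate_hz > 0)
  channel <- as.character(channel)
  if (length(ticks)) {
    stopifnot(all(channel %in% c("D", "A")), all(is.finite(ticks)),
              all(microtime_ns >= 0))
    if (is.unsorted(ticks)) {
      if (!sort) stop("photon timestamps must be sorted ascending")
      o <- order(ticks)
      ticks <- ticks[o]; channel <- channel[o]
      microtime_ns <- microtime_ns[o]
    }
  }
  structure(
    data.frame(ticks = as.numeric(ticks), channel = channel,
               microtime_ns = as.numeric(microtime_ns)),
    clock_rate_hz = clock_rate_hz, metadata = metadata,
    class = c("photon_stream", "data.frame"))
}

#' Photon macrotimes in seconds
#'
#' @param stream A [photon_stream()].
#' @return Numeric vector of arrival times in seconds.
#' @export
photon_times <- function(stream) {
  stopifnot(inherits(stream, "photon_stream"))
  stream$ticks / attr(stream, "clock_rate_hz")
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("photon stream: %d photons, clock %.3g Hz", n,
              attr(x, "clock_rate_hz")))
  if (n) cat(sprintf(", span %.4g s", diff(range(x$ticks)) /
                       attr(x, "clock_rate_hz")))
  cat("\n")
  if (n) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Ground-truth metadata of a synthetic stream
#'
#' @param stream A [photon_stream()] produced by the synthetic generator.
#' @return The generator's ground-truth list (species assignments, mixture
#'   parameters, seed), or `NULL` for experimental streams.
#' @export
ground_truth <- function(stream) {
  attr(stream, "metadata")$truth
}
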
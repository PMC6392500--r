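#' Write a two-channel stack as multi-page TIFF
#'
#' Pages are frame-major with the cyan (CFP) page before the yellow (YFP)
#' page at each time point, stored as 16-bit grayscale — the native format
#' of camera ADU counts, which is what the stack generator produces.
#' Intensities must be non-negative integers no larger than `scale`; they
#' round-trip exactly through [read_stack()]. Frame rate, channel order and
#' scale are recorded in a JSON sidecar (`<file>.json`).
#'
#' @param stack a [two_channel_stack()] with integer-count intensities.
#' @param file output path (`.tif`).
#' @param scale full-scale count of the 16-bit range.
#' @return `file`, invisibly.
#' @export
write_stack <- function(stack, file, scale = 65535) {
  stopifnot(inherits(stack, "two_channel_stack"))
  vals <- c(stack$cyan, stack$yellow)
  if (any(vals != round(vals)) || max(vals) > scale)
    stop("stack intensities must be integer counts in [0, scale]",
         call. = FALSE)
  nf <- n_frames(stack)
  pages <- vector("list", 2L * nf)
  for (f in seq_len(nf)) {
    pages[[2L * f - 1L]] <- stack$cyan[, , f] / scale
    pages[[2L * f]] <- stack$yellow[, , f] / scale
  }
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  jsonlite::write_json(
    list(frame_rate = stack$frame_rate, scale = scale,
         channel_order = c("cyan", "yellow"), layout = "frame-major",
         n_frames = nf, image_shape = dim(stack$cyan)[1:2]),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a two-channel stack written by [write_stack()]
#'
#' @param file TIFF path; the JSON sidecar `<file>.json` must sit beside it.
#' @return a [two_channel_stack()].
#' @export
read_stack <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file, all = TRUE)
  nf <- length(pages) / 2L
  sh <- dim(pages[[1]])
  cyan <- array(0, c(sh, nf)); yellow <- array(0, c(sh, nf))
  for (f in seq_len(nf)) {
    cyan[, , f] <- round(pages[[2L * f - 1L]] * meta$scale)
    yellow[, , f] <- round(pages[[2L * f]] * meta$scale)
  }
  two_channel_stack(cyan, yellow, meta$frame_rate)
}

# Delimited-text dialect used throughout: comma-separated, header row,
# UTF-8, missing values written as the literal token NA.

#' Write / read a per-worm tap-event table
#'
#' Comma-separated with a header row; `tracked` and `reversed` as
#' TRUE/FALSE, missing `reversed` (untracked taps) as `NA`.
#'
#' @param events event-table data.frame (see [gen_tap_experiment()]).
#' @param file path.
#' @return `file` (writer) or the data.frame (reader), invisibly/visibly.
#' @export
write_event_table <- function(events, file) {
  events <- as_event_table(events)
  utils::write.csv(events, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(file) {
  ev <- utils::read.csv(file, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  ev$tracked <- as.logical(ev$tracked)
  ev$reversed <- as.logical(ev$reversed)
  as_event_table(ev)
}

#' Write / read a posture trace
#'
#' Two-column comma-separated text (`time`, `bend_angle`) with a header row.
#'
#' @param trace a [posture_trace()].
#' @param file path.
#' @export
write_posture_trace <- function(trace, file) {
  stopifnot(inherits(trace, "posture_trace"))
  utils::write.csv(as.data.frame(trace)[c("time", "bend_angle")], file,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_posture_trace
#' @export
read_posture_trace <- function(file) {
  d <- utils::read.csv(file, fileEncoding = "UTF-8")
  posture_trace(d$time, d$bend_angle)
}
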
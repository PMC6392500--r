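#' Per-tap habituation curve of one strain
#'
#' At each tap, the proportion is the number of worms reversing over the
#' number of worms tracked at that tap; untracked worms enter neither the
#' numerator nor the denominator. A tap with zero tracked worms is flagged
#' as a gap (`NA` proportion), never interpolated.
#'
#' @param events an event table (e.g. `gen_tap_experiment()$events` or
#'   [read_event_table()]): columns `strain`, `tap_index`, `tracked`,
#'   `reversed`.
#' @param strain strain to summarize; default when the table holds exactly
#'   one strain.
#' @param level,method CI options passed to [binomial_ci()].
#' @return a `habituation_curve`: data.frame with `tap_index`, `numerator`,
#'   `denominator`, `proportion`, `ci_low`, `ci_high`, attributes `strain`,
#'   `method`, `level`.
#' @export
habituation_curve <- function(events, strain = NULL, level = 0.95,
                              method = "wilson") {
  events <- as_event_table(events)
  if (is.null(strain)) {
    strain <- unique(events$strain)
    if (length(strain) != 1L)
      stop("`strain` must be given when the table holds several strains",
           call. = FALSE)
  }
  ev <- events[events$strain == strain, ]
  if (nrow(ev) == 0L) stop("strain not present in the event table",
                           call. = FALSE)
  taps <- sort(unique(ev$tap_index))
  rows <- lapply(taps, function(t) {
    sub <- ev[ev$tap_index == t & ev$tracked, ]
    n <- nrow(sub)
    if (n == 0L)
      return(data.frame(tap_index = t, numerator = NA_integer_,
                        denominator = 0L, proportion = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    k <- sum(sub$reversed)
    ci <- binomial_ci(k, n, level, method)
    data.frame(tap_index = t, numerator = k, denominator = n,
               proportion = ci$proportion, ci_low = ci$ci_low,
               ci_high = ci$ci_high)
  })
  out <- do.call(rbind, rows)
  if (any(out$denominator == 0L))
    warning("taps with zero tracked worms flagged as gaps (NA)",
            call. = FALSE)
  structure(out, strain = strain, method = method, level = level,
            class = c("habituation_curve", "data.frame"))
}

#' @export
print.habituation_curve <- function(x, ...) {
  cat(sprintf("<habituation_curve> strain %s, taps %d-%d (%s %g%% CI)\n",
              attr(x, "strain"), min(x$tap_index), max(x$tap_index),
              attr(x, "method"), 100 * attr(x, "level")))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more taps\n")
  invisible(x)
}

#' @export
plot.habituation_curve <- function(x, ...) {
  graphics::plot(x$tap_index, x$proportion, ylim = c(0, 1), type = "b",
                 pch = 16, xlab = "tap", ylab = "proportion reversing",
                 main = attr(x, "strain"), ...)
  graphics::arrows(x$tap_index, x$ci_low, x$tap_index, x$ci_high,
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Day-level quality-control gate on the reference strain
#'
#' An experimental day is included only if at least `min_initial_response`
#' (default 80%) of the reference (wild-type) animals responded to the
#' initial tap — low tap-1 responses indicate unsuitable laboratory
#' conditions. The comparison is inclusive at the boundary ("at least"):
#' exactly 0.80 passes.
#'
#' @param events event table with columns `strain`, `day`, `tap_index`,
#'   `tracked`, `reversed`.
#' @param reference_strain the control strain the gate is evaluated on.
#' @param min_initial_response pass threshold on the tap-1 reversal
#'   proportion.
#' @return a `qc_report`: data.frame with one row per day: `day`,
#'   `numerator`, `denominator`, `proportion`, `pass`.
#' @export
qc_day <- function(events, reference_strain,
                   min_initial_response = 0.80) {
  events <- as_event_table(events)
  check_prob(min_initial_response, "min_initial_response")
  ref <- events[events$strain == reference_strain, ]
  if (nrow(ref) == 0L)
    stop("QC not evaluable: reference strain absent", call. = FALSE)
  days <- sort(unique(ref$day))
  rows <- lapply(days, function(d) {
    sub <- ref[ref$day == d & ref$tap_index == 1L & ref$tracked, ]
    if (nrow(sub) == 0L)
      stop(sprintf("QC not evaluable on day %s: no tracked reference worms at tap 1", d),
           call. = FALSE)
    k <- sum(sub$reversed); n <- nrow(sub)
    data.frame(day = d, numerator = k, denominator = n, proportion = k / n,
               pass = (k / n) >= min_initial_response)
  })
  structure(do.call(rbind, rows), reference_strain = reference_strain,
            min_initial_response = min_initial_response,
            class = c("qc_report", "data.frame"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> reference %s, gate >= %.2f at tap 1\n",
              attr(x, "reference_strain"), attr(x, "min_initial_response")))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

# Coerce/validate an event table: required columns, types, tap range.
as_event_table <- function(events) {
  if (inherits(events, "tap_experiment")) events <- events$events
  req <- c("strain", "tap_index", "tracked", "reversed")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("event table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"day" %in% names(events)) events$day <- 1L
  if (any(events$tap_index < 1))
    stop("tap_index must be >= 1", call. = FALSE)
  if (any(events$tracked & is.na(events$reversed)))
    stop("`reversed` must be defined wherever `tracked` is TRUE",
         call. = FALSE)
  events
}
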
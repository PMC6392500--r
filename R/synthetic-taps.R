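#' Habituation model for synthetic tap experiments
#'
#' Parameterizes the per-tap reversal probability of one strain as an
#' exponential decay from an initial response level to an asymptote:
#' `p_t = p_inf + (p0 - p_inf) * exp(-lam * (t - 1))` for tap index `t`.
#'
#' @param p0 probability of reversal at tap 1 (0-1).
#' @param p_inf asymptotic (habituated) reversal probability (0-1).
#' @param lam decay rate per tap (>= 0).
#' @param dropout per-tap probability that a worm is untracked (0-1). The
#'   multi-worm tracker does not track every animal at every tap; dropout is
#'   modeled as independent Bernoulli per (worm, tap).
#' @param sensitization set `TRUE` to allow `p_inf > p0` (a strain whose
#'   response grows with repeated taps); otherwise rejected.
#' @return an object of class `hab_model`.
#' @seealso [gen_tap_experiment()]
#' @export
hab_model <- function(p0, p_inf, lam, dropout = 0, sensitization = FALSE) {
  check_prob(p0, "p0"); check_prob(p_inf, "p_inf")
  check_pos(lam, "lam", strict = FALSE); check_prob(dropout, "dropout")
  if (p_inf > p0 && !sensitization)
    stop("`p_inf` > `p0` requires `sensitization = TRUE`", call. = FALSE)
  structure(list(p0 = p0, p_inf = p_inf, lam = lam, dropout = dropout),
            class = "hab_model")
}

#' @export
print.hab_model <- function(x, ...) {
  cat(sprintf("<hab_model> p0 = %.3f, p_inf = %.3f, lam = %.3f, dropout = %.3f\n",
              x$p0, x$p_inf, x$lam, x$dropout))
  invisible(x)
}

#' Tap-habituation stimulus protocol
#'
#' Defaults reproduce the standard assay: after acclimatization, 30 plate
#' taps at 10 s interstimulus intervals.
#'
#' @param n_taps number of taps (>= 1).
#' @param isi interstimulus interval, s (> 0).
#' @param acclimatization pre-stimulus acclimatization period, s (300 or
#'   600 in the standard assay; any non-negative value accepted).
#' @return an object of class `tap_protocol`.
#' @export
tap_protocol <- function(n_taps = 30L, isi = 10, acclimatization = 300) {
  if (!is.numeric(n_taps) || length(n_taps) != 1L || !is.finite(n_taps) ||
      n_taps < 1 || n_taps != round(n_taps))
    stop("`n_taps` must be a whole number >= 1", call. = FALSE)
  check_pos(isi, "isi"); check_pos(acclimatization, "acclimatization",
                                   strict = FALSE)
  structure(list(n_taps = as.integer(n_taps), isi = isi,
                 acclimatization = acclimatization),
            class = "tap_protocol")
}

#' True per-tap reversal probabilities of a habituation model
#'
#' @param model a [hab_model()].
#' @param n_taps number of taps.
#' @return numeric vector `p_t`, `t = 1..n_taps`.
#' @export
tap_probabilities <- function(model, n_taps) {
  stopifnot(inherits(model, "hab_model"))
  t <- seq_len(n_taps)
  model$p_inf + (model$p0 - model$p_inf) * exp(-model$lam * (t - 1))
}

#' Simulate a multi-strain tap-habituation experiment
#'
#' Emulates the per-worm, per-tap reversal output of a multi-worm tracker run:
#' each worm's reversal at tap `t` is Bernoulli with the strain's model
#' probability `p_t`, and each (worm, tap) is independently tracked with
#' probability `1 - dropout`. Reversal outcomes of untracked taps are recorded
#' as `NA` (the assay's denominators are worms *tracked* per tap).
#'
#' @param models named list of [hab_model()] objects, one per strain.
#' @param n_worms worms per strain; a single count or one per strain.
#' @param protocol a [tap_protocol()].
#' @param seed integer seed; identical seeds and parameters give identical
#'   tables.
#' @param plate_id,day labels stamped on all rows (single values or one per
#'   strain).
#' @return a `tap_experiment`: list with `events` (data.frame: `worm_id`,
#'   `strain`, `plate_id`, `day`, `tap_index`, `tap_time`, `tracked`,
#'   `reversed`), `truth` (per-strain true `p_t` matrix, taps in rows) and
#'   `protocol`. `tap_time` is the stimulus time in seconds from recording
#'   start (`acclimatization + (t - 1) * isi`).
#' @examples
#' ex <- gen_tap_experiment(list(N2 = hab_model(0.9, 0.3, 0.2)),
#'                          n_worms = 20, seed = 1)
#' head(ex$events)
#' @export
gen_tap_experiment <- function(models, n_worms, protocol = tap_protocol(),
                               seed, plate_id = "p1", day = 1L) {
  if (inherits(models, "hab_model")) models <- list(strainA = models)
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, inherits, TRUE, "hab_model")),
            inherits(protocol, "tap_protocol"))
  if (is.null(names(models)) || anyNA(names(models)) || any(names(models) == ""))
    stop("`models` must be a named list (one name per strain)", call. = FALSE)
  S <- length(models)
  n_worms <- rep_len(as.integer(n_worms), S)
  plate_id <- rep_len(plate_id, S)
  day <- rep_len(day, S)
  nt <- protocol$n_taps
  tap_time <- protocol$acclimatization + (seq_len(nt) - 1) * protocol$isi

  seeds <- derive_seeds(seed, S)
  out <- vector("list", S)
  truth <- matrix(NA_real_, nrow = nt, ncol = S,
                  dimnames = list(NULL, names(models)))
  for (s in seq_len(S)) {
    m <- models[[s]]
    p_t <- tap_probabilities(m, nt)
    truth[, s] <- p_t
    nw <- n_worms[s]
    set.seed(seeds[s])
    rev <- matrix(stats::runif(nw * nt) < rep(p_t, each = nw), nrow = nw)
    trk <- matrix(stats::runif(nw * nt) >= m$dropout, nrow = nw)
    out[[s]] <- data.frame(
      worm_id = rep(sprintf("%s_w%04d", names(models)[s], seq_len(nw)),
                    times = nt),
      strain = names(models)[s],
      plate_id = plate_id[s],
      day = day[s],
      tap_index = rep(seq_len(nt), each = nw),
      tap_time = rep(tap_time, each = nw),
      tracked = as.vector(trk),
      reversed = ifelse(as.vector(trk), as.vector(rev), NA),
      stringsAsFactors = FALSE
    )
  }
  structure(list(events = do.call(rbind, out), truth = truth,
                 protocol = protocol),
            class = "tap_experiment")
}

#' @export
print.tap_experiment <- function(x, ...) {
  cat(sprintf("<tap_experiment> %d strains, %d taps (ISI %g s), %d rows\n",
              ncol(x$truth), x$protocol$n_taps, x$protocol$isi,
              nrow(x$events)))
  invisible(x)
}
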
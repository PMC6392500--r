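#' Build and validate a pipeline run configuration
#'
#' One structured object carries every tunable of a run: the master seed,
#' the tap protocol, the per-strain habituation models, calcium thresholds,
#' behavior thresholds and statistics options. The configuration
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]); validation errors name every offending key at
#' once.
#'
#' @param seed master integer seed.
#' @param strains named list; each element a list with `p0`, `p_inf`, `lam`
#'   and optionally `dropout` (see [hab_model()]).
#' @param n_worms worms per strain in simulate mode.
#' @param protocol list with `n_taps`, `isi`, `acclimatization`.
#' @param calcium list: `alpha`, `threshold_k`, `floor_pct`,
#'   `baseline_window`.
#' @param behavior list: `theta_c`, `hysteresis`, `reversal_window`,
#'   `quiet_window`, `assay_time`.
#' @param swim list: `n_worms`, `duration`, `sample_rate`, `thrash_freq`,
#'   `amplitude`, `noise_sd`, and `paralysis_prob` (per-worm probability of
#'   a paralysis onset, drawn uniformly over the middle of the recording).
#' @param stats list: `ci_method`, `adjustment`, `level`, `endpoint_tap`,
#'   `reference_strain`, `min_initial_response`.
#' @return a validated `run_config`.
#' @export
run_config <- function(seed = 1L,
                       strains = list(N2 = list(p0 = 0.9, p_inf = 0.4,
                                                lam = 0.15, dropout = 0.1)),
                       n_worms = 50L,
                       protocol = list(n_taps = 30L, isi = 10,
                                       acclimatization = 300),
                       calcium = list(alpha = 0, threshold_k = 3,
                                      floor_pct = 5, baseline_window = 3),
                       behavior = list(theta_c = 45, hysteresis = 10,
                                       reversal_window = 1.0,
                                       quiet_window = 5, assay_time = 600),
                       swim = list(n_worms = 20L, duration = 660,
                                   sample_rate = 20, thrash_freq = 1,
                                   amplitude = 60, noise_sd = 5,
                                   paralysis_prob = 0.5),
                       stats = list(ci_method = "wilson",
                                    adjustment = "single-step",
                                    level = 0.95, endpoint_tap = 30L,
                                    reference_strain = NULL,
                                    min_initial_response = 0.80)) {
  cfg <- list(seed = seed, strains = strains, n_worms = n_worms,
              protocol = protocol, calcium = calcium, behavior = behavior,
              swim = swim, stats = stats)
  bad <- validate_config(cfg)
  if (length(bad))
    stop("invalid configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$stats$reference_strain))
    cfg$stats$reference_strain <- names(strains)[1]
  structure(cfg, class = "run_config")
}

# returns a character vector of offending keys (empty when valid)
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$seed), "seed")
  chk(is.list(cfg$strains) && length(cfg$strains) >= 1L &&
        !is.null(names(cfg$strains)), "strains")
  if (is.list(cfg$strains))
    for (s in names(cfg$strains)) {
      m <- cfg$strains[[s]]
      ok <- is.list(m) && num1(m$p0) && num1(m$p_inf) && num1(m$lam) &&
        m$p0 >= 0 && m$p0 <= 1 && m$p_inf >= 0 && m$p_inf <= 1 && m$lam >= 0
      if (!ok) bad <- c(bad, paste0("strains.", s))
    }
  chk(num1(cfg$n_worms) && cfg$n_worms >= 1, "n_worms")
  chk(num1(cfg$protocol$n_taps) && cfg$protocol$n_taps >= 1,
      "protocol.n_taps")
  chk(num1(cfg$protocol$isi) && cfg$protocol$isi > 0, "protocol.isi")
  chk(num1(cfg$protocol$acclimatization) && cfg$protocol$acclimatization >= 0,
      "protocol.acclimatization")
  chk(num1(cfg$calcium$alpha) && cfg$calcium$alpha >= 0 &&
        cfg$calcium$alpha < 1, "calcium.alpha")
  chk(num1(cfg$calcium$threshold_k) && cfg$calcium$threshold_k > 0,
      "calcium.threshold_k")
  chk(num1(cfg$calcium$floor_pct) && cfg$calcium$floor_pct >= 0,
      "calcium.floor_pct")
  chk(num1(cfg$calcium$baseline_window) && cfg$calcium$baseline_window > 0,
      "calcium.baseline_window")
  chk(num1(cfg$behavior$theta_c) && num1(cfg$behavior$hysteresis) &&
        cfg$behavior$theta_c > cfg$behavior$hysteresis &&
        cfg$behavior$hysteresis > 0, "behavior.theta_c")
  chk(num1(cfg$behavior$reversal_window) && cfg$behavior$reversal_window > 0,
      "behavior.reversal_window")
  chk(num1(cfg$swim$n_worms) && cfg$swim$n_worms >= 1, "swim.n_worms")
  chk(num1(cfg$swim$duration) && cfg$swim$duration > 0, "swim.duration")
  chk(num1(cfg$swim$paralysis_prob) && cfg$swim$paralysis_prob >= 0 &&
        cfg$swim$paralysis_prob <= 1, "swim.paralysis_prob")
  chk(is.character(cfg$stats$ci_method) &&
        cfg$stats$ci_method %in% c("wilson", "clopper-pearson"),
      "stats.ci_method")
  chk(num1(cfg$stats$level) && cfg$stats$level > 0 && cfg$stats$level < 1,
      "stats.level")
  chk(num1(cfg$stats$endpoint_tap) && cfg$stats$endpoint_tap >= 1,
      "stats.endpoint_tap")
  bad
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> seed %d; %d strain(s) x %d worms; %d taps @ %g s ISI\n",
              x$seed, length(x$strains), x$n_worms, x$protocol$n_taps,
              x$protocol$isi))
  invisible(x)
}

#' Serialize / load a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param file path.
#' @export
write_run_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(run_config, raw)
}

#' Run the pipeline end to end
#'
#' `mode = "simulate"` generates a tap-habituation experiment and swim
#' traces from the configuration and writes them (with ground truth) to the
#' run directory. `mode = "analyze"` reads those inputs back and produces
#' the strain-level results: habituation curves, the day QC gate, the
#' habituated-level strain comparison, per-worm swim endpoints and the
#' swimming-at-10-min comparison. Both modes are deterministic given the
#' configuration seed, append a plain-text log with per-stage timing, and
#' finish by writing a provenance manifest (config hash, package version,
#' per-stage row counts) from which the run can be reproduced. A failure in
#' one stage leaves the outputs of completed stages intact on disk.
#'
#' @param config a [run_config()].
#' @param mode `"simulate"` or `"analyze"`.
#' @param dir run directory (created if needed).
#' @return (invisibly) a list of the file paths written.
#' @export
run_pipeline <- function(config, mode = c("simulate", "analyze"),
                         dir = "nemaquant-run") {
  stopifnot(inherits(config, "run_config"))
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(dir, "pipeline.log")
  written <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    cat(sprintf("[%s] %-18s %6.2f s\n",
                format(Sys.time(), "%H:%M:%S"), name,
                proc.time()[["elapsed"]] - t0),
        file = log_file, append = TRUE)
    res
  }
  counts <- list()

  if (mode == "simulate") {
    seeds <- derive_seeds(config$seed, 2L)
    ex <- stage("simulate-taps", {
      models <- lapply(config$strains, function(m)
        hab_model(m$p0, m$p_inf, m$lam,
                  if (is.null(m$dropout)) 0 else m$dropout))
      gen_tap_experiment(models, config$n_worms,
                         tap_protocol(config$protocol$n_taps,
                                      config$protocol$isi,
                                      config$protocol$acclimatization),
                         seed = seeds[1])
    })
    f <- file.path(dir, "events.csv")
    write_event_table(ex$events, f)
    written <- c(written, f)
    counts$events <- nrow(ex$events)
    jsonlite::write_json(list(truth_p = as.data.frame(ex$truth)),
                         file.path(dir, "events.truth.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, file.path(dir, "events.truth.json"))

    sw <- stage("simulate-swim", {
      s <- config$swim
      sseeds <- derive_seeds(seeds[2], s$n_worms + 1L)
      set.seed(sseeds[s$n_worms + 1L])
      onset <- ifelse(stats::runif(s$n_worms) < s$paralysis_prob,
                      stats::runif(s$n_worms, 0.2 * s$duration,
                                   0.8 * s$duration), NA)
      lapply(seq_len(s$n_worms), function(w)
        gen_swim_traces(swim_params(s$sample_rate, s$duration,
                                    s$thrash_freq, s$amplitude,
                                    onset[w], s$noise_sd),
                        1L, seed = sseeds[w])[[1]])
    })
    swim_df <- do.call(rbind, lapply(seq_along(sw), function(w)
      data.frame(worm_id = sprintf("sw%04d", w),
                 time = sw[[w]]$trace$time,
                 bend_angle = sw[[w]]$trace$bend_angle)))
    f <- file.path(dir, "swim.csv")
    utils::write.csv(swim_df, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    counts$swim_samples <- nrow(swim_df)
    jsonlite::write_json(
      list(paralysis_time = vapply(sw, function(x)
        x$truth$paralysis_time, numeric(1)),
        thrash_freq = config$swim$thrash_freq),
      file.path(dir, "swim.truth.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    written <- c(written, file.path(dir, "swim.truth.json"))
  } else {
    ev <- read_event_table(file.path(dir, "events.csv"))
    counts$events <- nrow(ev)
    curves <- stage("habituation-curves", {
      lapply(unique(ev$strain), function(s)
        habituation_curve(ev, s, config$stats$level,
                          config$stats$ci_method))
    })
    for (cu in curves) {
      f <- file.path(dir, sprintf("habituation_%s.csv", attr(cu, "strain")))
      utils::write.csv(as.data.frame(cu), f, row.names = FALSE,
                       quote = FALSE)
      written <- c(written, f)
    }
    qc <- stage("qc-gate",
                qc_day(ev, config$stats$reference_strain,
                       config$stats$min_initial_response))
    f <- file.path(dir, "qc.csv")
    utils::write.csv(as.data.frame(qc), f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    if (length(unique(ev$strain)) >= 2L) {
      cmp <- stage("habituated-level",
                   compare_habituated_level(ev, config$stats$endpoint_tap,
                                            adjust = config$stats$adjustment,
                                            level = config$stats$level))
      f <- file.path(dir, "habituated_level_contrasts.csv")
      utils::write.csv(cmp$contrasts, f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }
    swim_df <- utils::read.csv(file.path(dir, "swim.csv"))
    endp <- stage("swim-endpoints", {
      do.call(rbind, lapply(split(swim_df, swim_df$worm_id), function(d) {
        tr <- posture_trace(d$time, d$bend_angle)
        th <- thrash_frequency(tr, c(0, max(d$time)),
                               config$behavior$theta_c,
                               config$behavior$hysteresis)
        data.frame(worm_id = d$worm_id[1],
                   paralyzed = call_paralysis(tr,
                                              config$behavior$assay_time,
                                              config$behavior$quiet_window,
                                              config$behavior$theta_c,
                                              config$behavior$hysteresis),
                   thrash_hz = th$frequency_hz)
      }))
    })
    f <- file.path(dir, "swim_endpoints.csv")
    utils::write.csv(endp, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    counts$swim_worms <- nrow(endp)
  }

  manifest <- list(
    mode = mode,
    config = unclass(config),
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("nemaquant")),
    row_counts = counts,
    files = basename(written))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(written, file.path(dir, "manifest.json")))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}
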
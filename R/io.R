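# Trace file format, run configuration and the end-to-end pipeline.
#
# Traces are stored as delimited text with a commented header that fully
# reconstructs the simulation configuration (auditable, diff-able); binary
# electrophysiology formats are out of scope.

#' Write a current trace to a delimited text file
#'
#' Format: `#`-prefixed header lines (format tag, sample count, and the
#' full metadata list as one JSON line), a column-name line, then
#' tab-separated `time_s voltage_V current_A` rows printed with 17
#' significant digits so that read-write round-trips are value-exact.
#'
#' @param trace a [current_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  md <- attr(trace, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# poreiv-trace 1",
               sprintf("# n_samples: %d", nrow(trace)),
               paste0("# meta: ",
                      jsonlite::toJSON(md, auto_unbox = TRUE, digits = NA,
                                       null = "null", na = "null")),
               "time_s\tvoltage_V\tcurrent_A"), con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g", trace$time_s,
                     trace$voltage_V, trace$current_A), con)
  invisible(path)
}

trace_format_error <- function(path, line, why) {
  stop(sprintf("malformed trace file '%s' at line %d: %s", path, line, why),
       call. = FALSE)
}

#' Read a current trace written by [write_trace()]
#'
#' @param path file path.
#' @return A [current_trace()] with its metadata restored. Malformed
#'   headers or truncated data blocks raise an error naming the offending
#'   line.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5 || lines[1] != "# poreiv-trace 1")
    trace_format_error(path, 1L, "missing 'poreiv-trace 1' format tag")
  n_decl <- suppressWarnings(
    as.integer(sub("^# n_samples:\\s*", "", lines[2])))
  if (!startsWith(lines[2], "# n_samples:") || is.na(n_decl))
    trace_format_error(path, 2L, "missing or unreadable n_samples header")
  if (!startsWith(lines[3], "# meta: "))
    trace_format_error(path, 3L, "missing meta header")
  md <- tryCatch(jsonlite::fromJSON(sub("^# meta: ", "", lines[3]),
                                    simplifyVector = TRUE),
                 error = function(e)
                   trace_format_error(path, 3L, "unparseable meta JSON"))
  if (lines[4] != "time_s\tvoltage_V\tcurrent_A")
    trace_format_error(path, 4L, "unexpected column header")
  data_lines <- lines[-(1:4)]
  if (length(data_lines) != n_decl)
    trace_format_error(path, 4L + length(data_lines) + 1L,
                       sprintf("expected %d data rows, found %d", n_decl,
                               length(data_lines)))
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    trace_format_error(path, 4L + bad[1], "expected 3 tab-separated fields")
  m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (anyNA(m))
    trace_format_error(path, 4L + which(is.na(rowSums(m)))[1],
                       "non-numeric value")
  current_trace(m[, 1], m[, 2], m[, 3], metadata = as.list(md))
}

config_field_sets <- list(
  protocol = c("start_V", "stop_V", "step_V", "step_s", "pre_step_s",
               "sample_rate_Hz", "holding_V"),
  conductances = c("g_leak_S", "g_pores_S", "g_single_S", "n_pores"),
  energetics = c("dmu0_kT", "alpha_kT_per_V2", "offset_V"),
  environment = c("temperature_K", "nernst_V", "ion_valence", "conc_out",
                  "conc_in"),
  gating = c("mean_open_lifetime_s"),
  transients = c("tau_fast_s", "tau_slow_s", "a0_per_V", "am_per_V"),
  noise = c("current_noise_sd_A", "filter_cutoff_Hz", "filter_order"))

#' Assemble and validate a pipeline run configuration
#'
#' Nested parameter records mirroring the simulator and analysis modules,
#' schema-validated: unknown keys anywhere are rejected. The configuration
#' carries the master seed, so a run is fully reproducible from its config
#' alone.
#'
#' @param protocol,conductances,energetics,environment,gating named lists
#'   of arguments for [build_protocol()], [conductance_set()],
#'   [pore_energetics()], [recording_env()] and [gating_kinetics()].
#' @param transients,noise named lists for [transient_params()] /
#'   [noise_model()], or `NULL` to disable transients / noise+filtering.
#' @param mode `"patch"` or `"blm"`.
#' @param gating_mode `"stochastic"` or `"mean"`.
#' @param scenario I-V fit scenario (see [fit_iv()]); `"auto"` picks
#'   `"linear"` when there are no pores and `"free_leak"` otherwise.
#' @param discard_first exclude the first level from the I-V fit.
#' @param depth_mm optional condition label.
#' @param seed master seed (integer).
#' @param verbose print stage-by-stage progress.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(protocol = list(), conductances = list(),
                       energetics = list(dmu0_kT = 4,
                                         alpha_kT_per_V2 = 40,
                                         offset_V = 0.2),
                       environment = list(), gating = list(),
                       transients = list(), noise = list(),
                       mode = "patch", gating_mode = "stochastic",
                       scenario = "auto", discard_first = TRUE,
                       depth_mm = NULL, seed = 1L, verbose = FALSE) {
  check <- function(lst, name) {
    if (is.null(lst)) return(NULL)
    stopifnot(is.list(lst))
    unknown <- setdiff(names(lst), config_field_sets[[name]])
    if (length(unknown))
      stop(sprintf("unknown key(s) in config section '%s': %s", name,
                   paste(unknown, collapse = ", ")))
    lst
  }
  cfg <- list(protocol = check(protocol, "protocol"),
              conductances = check(conductances, "conductances"),
              energetics = check(energetics, "energetics"),
              environment = check(environment, "environment"),
              gating = check(gating, "gating"),
              transients = check(transients, "transients"),
              noise = check(noise, "noise"),
              mode = match.arg(mode, c("patch", "blm")),
              gating_mode = match.arg(gating_mode,
                                      c("stochastic", "mean")),
              scenario = match.arg(scenario,
                                   c("auto", "free_leak", "fixed_leak",
                                     "pores_only", "linear")),
              discard_first = isTRUE(discard_first),
              depth_mm = depth_mm,
              seed = as.integer(seed),
              verbose = isTRUE(verbose))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose top-level keys are [run_config()] arguments.
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path) {
  args <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("unknown top-level config key(s): ",
         paste(unknown, collapse = ", "))
  do.call(run_config, args)
}

#' Audit hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; changes whenever any
#' parameter changes.
#'
#' @param config a [run_config()].
#' @return A hex digest string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA,
                                           null = "null")), tf)
  unname(tools::md5sum(tf))
}

write_stamped_table <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# config_hash: %s", hash),
               sprintf("# seed: %d", seed)), con)
  utils::write.table(format(df, digits = 15, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate-extract-fit pipeline
#'
#' Executes, in order: trace simulation, holding-offset correction,
#' steady-state I-V extraction, I-V model fitting (linear when the
#' configuration has no pores, the configured nonlinear scenario
#' otherwise), biexponential relaxation fitting (when transients are
#' enabled), channel-event idealization with empirical open probabilities
#' (when gating is stochastic), and the potassium-gate reference table.
#' Any stage failure aborts with the stage name and cause. Outputs are
#' stamped with the configuration hash and seed; identical configurations
#' and seeds produce byte-identical output tables.
#'
#' @param config a [run_config()].
#' @param outdir optional directory for stamped delimited-text outputs
#'   (I-V table, fit parameters, relaxation table, event table, potassium
#'   table).
#' @return A list bundle: `config`, `config_hash`, `traces`, `iv_profile`,
#'   `iv_fit`, `relax_fit`, `events`, `open_probability`, `hh_table`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  proto <- stage("protocol", do.call(build_protocol, config$protocol))
  cs <- stage("parameters", do.call(conductance_set, config$conductances))
  pe <- stage("parameters", do.call(pore_energetics, config$energetics))
  env <- stage("parameters", do.call(recording_env, config$environment))
  gk <- stage("parameters", do.call(gating_kinetics, config$gating))
  tp <- if (is.null(config$transients)) NULL else
    stage("parameters", do.call(transient_params, config$transients))
  nm <- if (is.null(config$noise)) NULL else
    stage("parameters", do.call(noise_model, config$noise))

  traces <- stage("simulate",
                  simulate_trace(proto, cs, pe, env, gk, tp, nm,
                                 seed = config$seed, mode = config$mode,
                                 gating = config$gating_mode,
                                 depth_mm = config$depth_mm))
  traces <- stage("correct-offset", {
    out <- lapply(traces, correct_offset)
    class(out) <- "trace_series"
    out
  })
  # steady-state window: the last 1.5 s of a standard 3.1 s step, or the
  # settled second half of shorter steps
  win <- if (proto$step_s >= 3) c(proto$step_s - 1.6, proto$step_s - 0.1)
  else c(proto$step_s / 2, 0.97 * proto$step_s)
  prof <- stage("extract-iv",
                extract_iv(traces, window_s = win,
                           discard_first = config$discard_first))

  no_pores <- cs$g_pores_S == 0 ||
    (config$gating_mode == "stochastic" &&
     (is.null(cs$n_pores) || cs$n_pores == 0))
  scen <- if (config$scenario == "auto") {
    if (no_pores) "linear" else "free_leak"
  } else config$scenario
  fit <- stage("fit-iv", fit_iv(prof, scen, e0 = env$nernst_V))

  rfit <- NULL
  if (!is.null(tp))
    rfit <- stage("fit-relax", fit_relaxation(traces))

  events <- NULL
  popen <- NULL
  if (config$gating_mode == "stochastic" && !no_pores) {
    events <- stage("detect-events",
                    lapply(traces, function(tr)
                      idealize(baseline_correct(tr))))
    popen <- stage("open-probability",
                   empirical_open_probability(events))
  }
  hh <- stage("hh-table", hh_table())

  if (!is.null(outdir)) {
    stage("write-outputs", {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_stamped_table(as.data.frame(prof),
                          file.path(outdir, "iv_profile.tsv"), hash,
                          config$seed)
      cf <- coef(fit)
      write_stamped_table(
        data.frame(parameter = names(cf), value = as.numeric(cf)),
        file.path(outdir, "iv_fit.tsv"), hash, config$seed)
      if (!is.null(rfit))
        write_stamped_table(rfit$table,
                            file.path(outdir, "relaxation.tsv"), hash,
                            config$seed)
      if (!is.null(popen))
        write_stamped_table(popen,
                            file.path(outdir, "open_probability.tsv"),
                            hash, config$seed)
      write_stamped_table(hh, file.path(outdir, "hh_table.tsv"), hash,
                          config$seed)
    })
  }

  list(config = config, config_hash = hash, traces = traces,
       iv_profile = prof, iv_fit = fit, relax_fit = rfit,
       events = events, open_probability = popen, hh_table = hh)
}
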
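#' Experiment configuration
#'
#' Bundles everything one simulated stimulus-response experiment needs:
#' the drive system and its parameters, the surrogate transfer (an explicit
#' [surrogate_params()] or a preset name), analysis settings, optional OTL
#' settings, and a mandatory integer seed. Every random draw in the run is
#' derived from the seed, so a configuration fully determines its report.
#'
#' @param system Drive system: `"logistic"`, `"baker"`, `"lorenz"`,
#'   `"rossler"`, `"fhn"` or `"bits"`.
#' @param drive Named list of arguments for the corresponding
#'   `generate_*()` function (defaults are the study conditions).
#' @param surrogate A [surrogate_params()] object, a preset name, or
#'   `NULL` to default to the system's preset.
#' @param analysis Named list: `prominence_factor`, `max_lag`,
#'   `standardize`, plus [lyapunov_wolf()] settings (`min_separation`,
#'   `step_offset`, `epsilon`, `smooth`, `smooth_order`, `smooth_frame`).
#' @param otl `NULL` to skip the logic layer, or a named list with `theta`
#'   and `tau_min` for [otl_pipeline()] run over the drive/response pair of
#'   this experiment and a second, independently seeded pair.
#' @param seed Integer seed (mandatory; no wall-clock seeding).
#' @param deposited_dir Optional directory holding a deposited recording
#'   pair as `input.csv` / `output.csv` in the package's trace dialect;
#'   when set, the analysis runs on those files instead of the
#'   generator/surrogate chain.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(system = c("logistic", "baker", "lorenz",
                                         "rossler", "fhn", "bits"),
                              drive = list(), surrogate = NULL,
                              analysis = list(), otl = NULL, seed,
                              deposited_dir = NULL) {
  system <- match.arg(system)
  if (missing(seed) || !is.numeric(seed)) {
    stop("an explicit integer `seed` is mandatory", call. = FALSE)
  }
  if (!is.null(deposited_dir)) {
    for (f in c("input.csv", "output.csv")) {
      if (!file.exists(file.path(deposited_dir, f))) {
        stop("`deposited_dir` must contain ", f, call. = FALSE)
      }
    }
  }
  if (is.character(surrogate)) surrogate <- surrogate_preset(surrogate)
  if (is.null(surrogate) && system != "bits") {
    surrogate <- surrogate_preset(system)
  }
  defaults <- list(
    prominence_factor = 0.5, max_lag = NULL, standardize = FALSE,
    min_separation = 0.001, step_offset = 50, epsilon = 1e-5,
    smooth = TRUE, smooth_order = 2, smooth_frame = 15
  )
  analysis <- utils::modifyList(defaults, analysis)
  structure(
    list(
      system = system, drive = drive, surrogate = surrogate,
      analysis = analysis, otl = otl, seed = as.integer(seed),
      deposited_dir = deposited_dir
    ),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from JSON
#'
#' Parses and validates a JSON configuration (fields `system`, `drive`,
#' `surrogate` - either a preset name or a parameter object -,
#' `analysis`, `otl`, `seed`, `deposited_dir`). `system` and `seed` are
#' mandatory. The `reproduce/` directory of the source repository ships
#' one such configuration per drive system.
#'
#' @param path JSON file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$system)) stop("config lacks `system`", call. = FALSE)
  if (is.null(cfg$seed)) stop("config lacks `seed`", call. = FALSE)
  surrogate <- cfg$surrogate
  if (is.list(surrogate)) surrogate <- do.call(surrogate_params, surrogate)
  experiment_config(
    system = cfg$system,
    drive = if (is.null(cfg$drive)) list() else as.list(cfg$drive),
    surrogate = surrogate,
    analysis = if (is.null(cfg$analysis)) list() else as.list(cfg$analysis),
    otl = if (is.null(cfg$otl)) NULL else as.list(cfg$otl),
    seed = cfg$seed,
    deposited_dir = cfg$deposited_dir
  )
}

generate_drive <- function(system, drive, seed) {
  gen <- switch(system,
    logistic = generate_logistic,
    baker = generate_baker,
    lorenz = generate_lorenz,
    rossler = generate_rossler,
    fhn = generate_fhn,
    bits = function(...) generate_pulse_train(...)$trace
  )
  if (system %in% c("logistic", "bits") && is.null(drive$seed)) {
    drive$seed <- seed
  }
  do.call(gen, drive)
}

#' Run a full stimulus-response experiment
#'
#' Chains drive generation, the composite-response surrogate, and the full
#' analysis suite: summary statistics and dB spectra for the input and
#' output traces, their cross-correlation and two-channel PCA, and
#' Lyapunov exponents for both. When the configuration carries OTL
#' settings, a second drive/response pair is generated from `seed + 1` and
#' the four channels are run through [otl_pipeline()]. Re-running an
#' identical configuration reproduces the report exactly (the report hash
#' in the provenance block is stable).
#'
#' @param config An [experiment_config()].
#' @return A list of class `analysis_report` with elements `input`,
#'   `output` (traces), `input_stats`, `output_stats`, `input_spectrum`,
#'   `output_spectrum`, `xcorr`, `pca`, `lyapunov_input`,
#'   `lyapunov_output`, optional `otl`, and `provenance`.
#' @examples
#' cfg <- experiment_config(
#'   "logistic",
#'   drive = list(n_iter = 2000), seed = 1
#' )
#' rep <- run_experiment(cfg)
#' rep$output_stats
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  an <- config$analysis
  if (!is.null(config$deposited_dir)) {
    input <- read_trace(file.path(config$deposited_dir, "input.csv"))
    output <- read_trace(file.path(config$deposited_dir, "output.csv"))
  } else {
    input <- generate_drive(config$system, config$drive, config$seed)
    output <- if (!is.null(config$surrogate)) {
      p <- config$surrogate
      if (is.null(p$seed)) p$seed <- config$seed
      apply_surrogate(input, p)
    } else {
      input
    }
  }
  lyap <- function(tr) {
    tryCatch(
      lyapunov_wolf(tr,
        min_separation = an$min_separation,
        step_offset = an$step_offset, epsilon = an$epsilon,
        smooth = an$smooth, smooth_order = an$smooth_order,
        smooth_frame = an$smooth_frame
      ),
      error = function(e) NULL
    )
  }
  report <- list(
    input = input,
    output = output,
    input_stats = trace_stats(input, an$prominence_factor),
    output_stats = trace_stats(output, an$prominence_factor),
    input_spectrum = trace_spectrum(input),
    output_spectrum = trace_spectrum(output),
    xcorr = cross_correlate(input, output, max_lag = an$max_lag),
    pca = pca_input_output(input, output, standardize = an$standardize),
    lyapunov_input = lyap(input),
    lyapunov_output = lyap(output)
  )
  if (!is.null(config$otl)) {
    cfg2 <- config
    cfg2$seed <- config$seed + 1L
    cfg2$drive$seed <- NULL
    input2 <- generate_drive(cfg2$system, cfg2$drive, cfg2$seed)
    p2 <- config$surrogate
    if (!is.null(p2)) {
      if (is.null(p2$seed)) p2$seed <- cfg2$seed
      output2 <- apply_surrogate(input2, p2)
    } else {
      output2 <- input2
    }
    report$otl <- otl_pipeline(
      input, input2, output, output2,
      theta = config$otl$theta %||% 0.5,
      tau_min = config$otl$tau_min %||% 0.1
    )
  }
  prov <- list(
    system = config$system,
    seed = config$seed,
    config = unclass_deep(config),
    package_version = as.character(utils::packageVersion("protact"))
  )
  prov$report_hash <- rlang::hash(list(
    prov$config,
    report$input_stats, report$output_stats,
    report$xcorr$max_coeff, report$pca$var_fraction
  ))
  report$provenance <- prov
  structure(report, class = "analysis_report")
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Side-by-side input/output table from a report
#'
#' Formats a report's summary statistics in the layout of the study's
#' analysis tables: one row per metric, one column each for the input and
#' output voltages.
#'
#' @param report An `analysis_report` from [run_experiment()].
#' @return A tibble with columns `metric`, `input`, `output`.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  metrics <- c("mean", "sd", "median", "max", "min", "dominant_freq")
  tibble::tibble(
    metric = c("mean", "std. dev.", "median", "max", "min", "frequency [Hz]"),
    input = as.numeric(report$input_stats[1, metrics]),
    output = as.numeric(report$output_stats[1, metrics])
  )
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (all scalar results plus provenance), a
#' `table.txt` in the side-by-side layout of [report_table()], the input
#' and output traces as CSV, and, when present, the gate-state matrix as
#' CSV.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scalars <- list(
    input_stats = as.list(report$input_stats),
    output_stats = as.list(report$output_stats),
    input_spectrum = glance(report$input_spectrum),
    output_spectrum = glance(report$output_spectrum),
    xcorr = list(
      max_coeff = report$xcorr$max_coeff,
      argmax_lag = report$xcorr$argmax_lag
    ),
    pca = as.list(report$pca$var_fraction),
    lyapunov_input = if (!is.null(report$lyapunov_input)) {
      list(
        lambda_per_step = report$lyapunov_input$lambda_per_step,
        n_pairs = report$lyapunov_input$n_pairs
      )
    },
    lyapunov_output = if (!is.null(report$lyapunov_output)) {
      list(
        lambda_per_step = report$lyapunov_output$lambda_per_step,
        n_pairs = report$lyapunov_output$n_pairs
      )
    },
    provenance = report$provenance
  )
  jsonlite::write_json(
    scalars, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  tb <- report_table(report)
  utils::capture.output(print(as.data.frame(tb), row.names = FALSE),
    file = file.path(dir, "table.txt")
  )
  write_trace(report$input, file.path(dir, "input.csv"))
  write_trace(report$output, file.path(dir, "output.csv"))
  if (!is.null(report$otl)) {
    write_gate_states(report$otl, file.path(dir, "gate_states.csv"))
  }
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", x$provenance$system,
    "drive, seed", x$provenance$seed, "\n"
  )
  print(report_table(x))
  invisible(x)
}
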
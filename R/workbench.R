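#' Experiment configuration
#'
#' Validated configuration for the experiment runners.  Unknown keys are
#' rejected; model parameters default to the reference PING set and numeric
#' settings to the package defaults.
#'
#' @param experiment runner name; one of
#'   `"oscillation-characterization"`, `"staircase"`, `"tongue"`,
#'   `"ctc-sweep"`, `"competition"`, `"switch-prc"`, `"qif-validation"`.
#' @param model named list overriding [ping_params()] fields.
#' @param forcing named list: `A`, `kappa`, `T_rel` (and for two-input
#'   runs `A2`, `kappa2`, `T2_ratio`).
#' @param settings named list of runner-specific numeric settings
#'   (grids, iterate counts, seeds, population sizes).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, model = list(), forcing = list(),
                              settings = list()) {
  runners <- c("oscillation-characterization", "staircase", "tongue",
               "ctc-sweep", "competition", "switch-prc", "qif-validation")
  if (!experiment %in% runners)
    stop("unknown experiment '", experiment, "'; available: ",
         paste(runners, collapse = ", "))
  unknown <- setdiff(names(model), names(ping_params()))
  if (length(unknown))
    stop("unknown model keys: ", paste(unknown, collapse = ", "))
  params <- do.call(ping_params, model)   # validates values
  fkeys <- c("A", "kappa", "T_rel", "A2", "kappa2", "T2_ratio")
  unknown <- setdiff(names(forcing), fkeys)
  if (length(unknown))
    stop("unknown forcing keys: ", paste(unknown, collapse = ", "))
  structure(list(experiment = experiment, model = model, params = params,
                 forcing = forcing, settings = settings),
            class = "experiment_config")
}

#' Read an experiment configuration from a JSON file
#'
#' The file holds an object with keys `experiment`, `model`, `forcing`,
#' `settings`, keyed exactly as the [ping_params()] fields and
#' [experiment_config()] arguments.
#'
#' @param path JSON file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(experiment = cfg$experiment,
                    model = as.list(cfg$model),
                    forcing = as.list(cfg$forcing),
                    settings = as.list(cfg$settings))
}

cfg_get <- function(config, key, default) {
  v <- config$settings[[key]]
  if (is.null(v)) default else v
}

# small stable polynomial hash of the serialized configuration
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config)[c("experiment", "model", "forcing",
                                          "settings")],
                        auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run a named experiment
#'
#' Dispatches to the requested runner, chaining the package modules into a
#' figure-level analysis, and returns a result bundle with the tables and
#' reproducibility metadata (config hash, seed, package version).
#'
#' @param config an [experiment_config()].
#' @return Object of class `result_bundle` with fields `tables` (named list
#'   of data.frames) and `metadata`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- cfg_get(config, "seed", 1L)
  runner <- switch(config$experiment,
    "oscillation-characterization" = run_characterization,
    "staircase" = run_staircase,
    "tongue" = run_tongue,
    "ctc-sweep" = run_ctc_sweep,
    "competition" = run_competition,
    "switch-prc" = run_switch_prc,
    "qif-validation" = run_qif_validation)
  tables <- runner(config)
  structure(list(tables = tables,
                 metadata = list(
                   experiment = config$experiment,
                   config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(
                     utils::packageVersion("pingctc")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("result bundle: %s (config %s)\n", x$metadata$experiment,
              x$metadata$config_hash))
  for (nm in names(x$tables))
    cat(sprintf("  %s: %d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

run_characterization <- function(config) {
  drives <- cfg_get(config, "Ie_values", c(7, 9, 10, 11, 13, 15))
  rows <- lapply(drives, function(v) {
    p <- do.call(ping_params, modifyList(config$model,
                                         list(Ie_ext_bar = v)))
    cyc <- find_limit_cycle(p)
    if (!has_cycle(cyc))
      return(data.frame(Ie_ext_bar = v, oscillating = FALSE,
                        period = NA, freq_hz = NA, R_e = NA, R_i = NA,
                        latency_ms = NA, relative_phase = NA))
    mr <- integral_mean_rates(cyc)
    lt <- ei_latency(cyc)
    data.frame(Ie_ext_bar = v, oscillating = TRUE, period = cyc$period,
               freq_hz = 1000 / cyc$period, R_e = mr[["R_e"]],
               R_i = mr[["R_i"]], latency_ms = lt[["latency_ms"]],
               relative_phase = lt[["relative_phase"]])
  })
  list(characterization = do.call(rbind, rows))
}

cfg_cycle_iprc <- function(config) {
  cyc <- find_limit_cycle(config$params)
  if (!has_cycle(cyc)) stop("parameters are not in the oscillatory region")
  list(cycle = cyc, iprc = solve_adjoint(cyc))
}

run_staircase <- function(config) {
  ci <- cfg_cycle_iprc(config)
  A <- config$forcing$A %||% 0.1
  kappa <- config$forcing$kappa %||% 2
  grid <- seq(cfg_get(config, "T_rel_min", 0.5),
              cfg_get(config, "T_rel_max", 1.5),
              by = cfg_get(config, "T_rel_step", 0.005))
  list(staircase = devils_staircase(ci$iprc, A, kappa, grid,
                                    N = cfg_get(config, "N_iter", 750)))
}

run_tongue <- function(config) {
  ci <- cfg_cycle_iprc(config)
  p <- cfg_get(config, "p", 1); q <- cfg_get(config, "q", 1)
  kappa <- config$forcing$kappa %||% 2
  tng <- tongue_boundary_continuation(p, q, ci$iprc, kappa,
                                      A_max = cfg_get(config, "A_max", 0.2))
  list(left = cbind(side = "left", tng$left),
       right = cbind(side = "right", tng$right))
}

run_ctc_sweep <- function(config) {
  ci <- cfg_cycle_iprc(config)
  list(factors = tongue_section_sweep(
    ci$cycle, ci$iprc,
    kappa = config$forcing$kappa %||% 2,
    A_values = cfg_get(config, "A_values", seq(0.05, 0.2, by = 0.05)),
    n_T = cfg_get(config, "n_T", 10),
    p = cfg_get(config, "p", 1), q = cfg_get(config, "q", 1)))
}

run_competition <- function(config) {
  ci <- cfg_cycle_iprc(config)
  f <- config$forcing
  list(robustness = robustness_scan(
    ci$iprc,
    T1_rel = f$T_rel %||% 0.845,
    kappa2_values = cfg_get(config, "kappa2_values", c(0.01, 0.5, 2, 20)),
    T2_ratio_values = cfg_get(config, "T2_ratio_values",
                              c(0.5, 0.75, 1, 1.2, 1.5)),
    A1 = f$A %||% 0.1, A2 = f$A2 %||% 0.1,
    kappa1 = f$kappa %||% 2))
}

run_switch_prc <- function(config) {
  cyc <- find_limit_cycle(config$params)
  list(switch_prc = pulse_switch_prc(
    cyc,
    phases = seq(0, 0.95, length.out = cfg_get(config, "phase_grid", 20)),
    T_rel = config$forcing$T_rel %||% 0.84,
    kappa = config$forcing$kappa %||% 2,
    A = config$forcing$A %||% 0.1))
}

run_qif_validation <- function(config) {
  qp <- qif_params(N_e = cfg_get(config, "N_e", 5000),
                   N_i = cfg_get(config, "N_i", 5000),
                   params = config$params,
                   eta_mode = cfg_get(config, "eta_mode", "deterministic"),
                   seed = cfg_get(config, "seed", 1L))
  run <- qif_validation_run(qp,
                            A = config$forcing$A %||% 0.1,
                            kappa = config$forcing$kappa %||% 2,
                            dt = cfg_get(config, "dt", 1e-4))
  list(rates = data.frame(t = run$empirical$t,
                          rate_qif = run$empirical$rate,
                          rate_meanfield = run$meanfield$r_e),
       summary = data.frame(rmse_rel = run$rmse_rel))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result bundle to disk
#'
#' Each table goes to `<path>_<name>.csv`; the metadata goes to a JSON
#' sidecar `<path>_metadata.json`.
#'
#' @param bundle a `result_bundle` from [run_experiment()].
#' @param path output path prefix.
#' @return Invisibly, the written file names.
#' @export
write_results <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  files <- character(0)
  for (nm in names(bundle$tables)) {
    f <- paste0(path, "_", nm, ".csv")
    ok <- tryCatch({
      write.csv(bundle$tables[[nm]], f, row.names = FALSE)
      TRUE
    }, error = function(e)
      stop("failed to write ", f, ": ", conditionMessage(e)))
    files <- c(files, f)
  }
  mf <- paste0(path, "_metadata.json")
  jsonlite::write_json(bundle$metadata, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Write a spike raster as plain text
#'
#' Two whitespace-separated columns `time_ms neuron_id`, plus a companion
#' `<path>.popmap` file mapping neuron ids to populations.
#'
#' @param raster a `spike_raster`.
#' @param path output file path.
#' @return Invisibly, the file paths.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster$spikes[, c("time", "neuron")], path,
                     row.names = FALSE, col.names = FALSE)
  pm <- paste0(path, ".popmap")
  utils::write.table(
    data.frame(neuron = c(seq_len(raster$N_e),
                          raster$N_e + seq_len(raster$N_i)),
               population = rep(c("e", "i"), c(raster$N_e, raster$N_i))),
    pm, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(path, pm))
}

#' Read a spike raster written by [write_raster()]
#'
#' @param path raster file path (expects the `.popmap` sidecar).
#' @param t_end simulation end time to record in the object.
#' @return A `spike_raster`.
#' @export
read_raster <- function(path, t_end = NA_real_) {
  sp <- utils::read.table(path, col.names = c("time", "neuron"))
  pm <- utils::read.table(paste0(path, ".popmap"),
                          col.names = c("neuron", "population"))
  N_e <- sum(pm$population == "e"); N_i <- sum(pm$population == "i")
  sp$population <- ifelse(sp$neuron <= N_e, "e", "i")
  structure(list(spikes = sp, N_e = N_e, N_i = N_i,
                 t_end = if (is.na(t_end)) max(sp$time) else t_end,
                 dt = NA_real_, synaptic = NULL),
            class = "spike_raster")
}
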
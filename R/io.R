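KYMOGRAPH_FORMAT_VERSION <- 1L
SURFACE_FORMAT_VERSION <- 1L

#' Write / read a kymograph
#'
#' Kymographs are stored as a single JSON container carrying the format
#' version, the model and domain metadata (units: uM, s, um), the time and
#' angle axes, all concentration fields and the applied signal history, at
#' full floating-point precision. The round trip is lossless.
#'
#' @param kym a `kymograph`.
#' @param file path to write / read.
#' @return `read_kymograph()` returns the reconstructed `kymograph`;
#'   `write_kymograph()` returns `file` invisibly.
#' @export
write_kymograph <- function(kym, file) {
  obj <- list(
    container = "polaritylab.kymograph",
    version = KYMOGRAPH_FORMAT_VERSION,
    units = list(concentration = "uM", time = "s", space = "um"),
    model = list(name = kym$model$name, params = unclass(kym$model$params)),
    domain = unclass(kym$domain),
    times = kym$times,
    theta = kym$theta,
    fields = kym$fields,
    signal = kym$signal)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(file) {
  obj <- tryCatch(jsonlite::read_json(file, simplifyVector = TRUE),
                  error = function(e)
                    stop("read_kymograph: not a valid container: ",
                         conditionMessage(e)))
  if (is.null(obj$container) || obj$container != "polaritylab.kymograph")
    stop("read_kymograph: not a kymograph container")
  if (obj$version != KYMOGRAPH_FORMAT_VERSION)
    stop("read_kymograph: container version ", obj$version,
         " not supported (expected ", KYMOGRAPH_FORMAT_VERSION, ")")
  params <- switch(obj$model$name,
    subpb = ,
    wavepinning = do.call(wave_pinning_params, obj$model$params),
    turing = do.call(turing_params, obj$model$params),
    legi = do.call(legi_params, obj$model$params))
  model <- model_spec(obj$model$name, params)
  domain <- domain_spec(N = obj$domain$N, L = obj$domain$L)
  new_kymograph(times = obj$times, theta = obj$theta,
                fields = lapply(obj$fields, as.matrix),
                signal = as.matrix(obj$signal),
                model = model, domain = domain, protocol = NULL)
}

#' Write / read a quasi-potential surface
#'
#' @param surface a [quasi_potential_surface()].
#' @param file path.
#' @return `read_surface()` returns the surface (grid, `P`, `Q`, curvature
#'   and slope fields); `write_surface()` returns `file` invisibly.
#' @export
write_surface <- function(surface, file) {
  obj <- list(
    container = "polaritylab.surface",
    version = SURFACE_FORMAT_VERSION,
    x = surface$x, y = surface$y, h = surface$h, D = surface$D,
    floor = surface$floor,
    P = surface$P, Q = surface$Q, K = surface$K,
    Qx = surface$Qx, Qy = surface$Qy)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_surface
#' @export
read_surface <- function(file) {
  obj <- tryCatch(jsonlite::read_json(file, simplifyVector = TRUE),
                  error = function(e)
                    stop("read_surface: not a valid container: ",
                         conditionMessage(e)))
  if (is.null(obj$container) || obj$container != "polaritylab.surface")
    stop("read_surface: not a surface container")
  if (obj$version != SURFACE_FORMAT_VERSION)
    stop("read_surface: container version not supported")
  out <- obj[c("x", "y", "h", "D", "floor")]
  for (nm in c("P", "Q", "K", "Qx", "Qy")) out[[nm]] <- as.matrix(obj[[nm]])
  structure(out, class = "quasi_potential_surface")
}

#' Export a surface field as delimited text
#'
#' Tab-separated matrix with '.' decimal separator at full precision; first
#' row/column carry the grid coordinates.
#'
#' @param surface a `quasi_potential_surface`.
#' @param file path.
#' @param field which field to export (default `"Q"`).
#' @export
export_surface_text <- function(surface, file, field = "Q") {
  M <- surface[[field]]
  tab <- rbind(c(NA, surface$y), cbind(surface$x, M))
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                     file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(file)
}

#' Export a bifurcation diagram as delimited text
#'
#' One row per branch point (`branch`, parameter, state, leading eigenvalue
#' real part, stability, symmetry); special points are prepended as
#' structured comment lines.
#'
#' @param diagram a [two_bin_bifurcation()] result.
#' @param file path.
#' @export
write_diagram <- function(diagram, file) {
  con <- file(file, "w")
  on.exit(close(con))
  sp <- diagram$special_points
  if (nrow(sp) > 0)
    for (i in seq_len(nrow(sp)))
      writeLines(sprintf("#SP\t%s\t%.12g\t%.12g\t%.12g\t%.12g", sp$type[i],
                         sp$p[i], sp$uL[i], sp$vL[i], sp$uR[i]), con)
  rows <- do.call(rbind, lapply(names(diagram$branches), function(nm) {
    b <- as.data.frame(diagram$branches[[nm]])
    cbind(branch = nm, b)
  }))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Experiment configuration
#'
#' A fully serializable description of one experiment: model preset, domain,
#' protocol, integrator settings and analysis toggles. The configuration
#' hash is embedded in every output bundle, so any artifact can be traced
#' back to the exact configuration (plus seed) that produced it.
#'
#' @param model preset name (see [model_preset()]).
#' @param t_end simulated time (s).
#' @param protocol named list describing the protocol (see the shipped
#'   presets for the schema: `kind`, `s0`/`sd`, `alpha`, `on`, `off`, ...).
#' @param domain named list with `N` and optionally `L`.
#' @param integrator named list: `rtol`, `atol`, `sigma`, `dt`, `seed`.
#' @param analysis character vector of analyses to run: any of
#'   `"kymograph"`, `"continuation"`, `"landscape"`, `"thresholds"`,
#'   `"metrics"`.
#' @param preset optional preset label.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model, t_end = 900,
                              protocol = list(kind = "single_transient",
                                              s0 = 0.02, alpha = 2,
                                              on = 100, off = 400),
                              domain = list(N = 20),
                              integrator = list(rtol = 1e-7, atol = 1e-9,
                                                sigma = 0, dt = 0.01,
                                                seed = 1),
                              analysis = "kymograph",
                              preset = NULL) {
  cfg <- list(model = model, t_end = t_end, protocol = protocol,
              domain = domain, integrator = integrator,
              analysis = analysis, preset = preset)
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  problems <- character(0)
  ok_models <- c("region_I", "region_II", "subpb", "region_III",
                 "wavepinning", "region_IV", "legi", "turing")
  if (is.null(cfg$model) || !cfg$model %in% ok_models)
    problems <- c(problems, paste0("model must be one of: ",
                                   paste(ok_models, collapse = ", ")))
  if (!is.null(cfg$t_end) && (!is.numeric(cfg$t_end) || cfg$t_end <= 0))
    problems <- c(problems, "t_end must be a positive number")
  ok_analysis <- c("kymograph", "continuation", "landscape", "thresholds",
                   "metrics")
  if (!all(cfg$analysis %in% ok_analysis))
    problems <- c(problems, paste0("analysis toggles must be among: ",
                                   paste(ok_analysis, collapse = ", ")))
  if (!is.null(cfg$integrator$sigma) && cfg$integrator$sigma < 0)
    problems <- c(problems, "integrator sigma must be nonnegative")
  if (length(problems) > 0)
    stop("invalid experiment config:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

#' Hash of an experiment configuration
#' @param cfg an [experiment_config()].
#' @return MD5 hex string of the canonical YAML serialization.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read an experiment configuration (YAML)
#' @param cfg an [experiment_config()].
#' @param file path.
#' @export
write_experiment_config <- function(cfg, file) {
  writeLines(yaml::as.yaml(unclass(cfg)), file)
  invisible(file)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(experiment_config, cfg)
}

config_protocol <- function(p, N) {
  kind <- p$kind %||% "single_transient"
  s0 <- if (!is.null(p$sd)) s0_for_sd(p$sd, alpha = p$alpha %||% 2, N = N)
        else p$s0 %||% 0.02
  alpha <- p$alpha %||% 2
  switch(kind,
    none = NULL,
    single_transient = ,
    offset = single_gradient_protocol(
      s0 = s0, alpha = alpha, N = N, on = p$on %||% 0,
      off = p$off %||% Inf, offset = p$offset %||% 0),
    reversal = reversal_protocol(
      s0 = s0, s0_rev = p$s0_rev %||% s0, alpha = alpha, N = N,
      on = p$on %||% 0, t_reverse = p$t_reverse, t_end = p$off %||% Inf),
    simultaneous = simultaneous_protocol(
      s0 = s0, ratio = p$ratio %||% 2, alpha = alpha, N = N,
      on = p$on %||% 0, t_end = p$off %||% Inf),
    consecutive = consecutive_protocol(
      s0 = s0, alpha = alpha, N = N, on = p$on %||% 0,
      duration = p$duration, period = p$period, n_pulses = p$n_pulses),
    stop("config_protocol: unknown protocol kind ", kind))
}

#' Run a configured experiment
#'
#' Deterministic for a fixed configuration (the seed is part of it).
#' Produces a bundle holding the requested outputs plus the configuration,
#' its hash, and a small run log; with `out_dir` set, the bundle is also
#' written to disk (kymographs and surfaces as JSON containers, tables as
#' tab-separated text, the log as plain text).
#'
#' @param config an [experiment_config()] (or a preset name, see
#'   [experiment_preset()]).
#' @param out_dir optional output directory.
#' @return List with `config`, `hash`, and `results` (named by analysis).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- experiment_preset(config)
  validate_config(config)
  t_start <- Sys.time()
  model <- model_preset(config$model)
  dom_args <- config$domain %||% list(N = 20)
  domain <- if (!is.null(dom_args$L))
    domain_spec(N = dom_args$N %||% 20, L = dom_args$L)
  else domain_spec(N = dom_args$N %||% 20)
  intg <- config$integrator
  results <- list()
  if ("kymograph" %in% config$analysis) {
    protocol <- config_protocol(config$protocol, domain$N)
    kym <- if ((intg$sigma %||% 0) > 0)
      simulate_rd_sde(model, protocol, t_end = config$t_end,
                      sigma = intg$sigma, dt = intg$dt %||% 0.01,
                      seed = intg$seed %||% 1, domain = domain)
    else simulate_rd(model, protocol, t_end = config$t_end, domain = domain,
                     rtol = intg$rtol %||% 1e-7, atol = intg$atol %||% 1e-9)
    results$kymograph <- kym
    results$polarization_ratio <- polarization_ratio(kym)
  }
  if ("continuation" %in% config$analysis) {
    results$continuation <- if (model$conserved)
      two_bin_bifurcation(model)
    else lpa_continuation(model, p_range = c(0.5, 4))
  }
  if ("landscape" %in% config$analysis) {
    sL <- config$protocol$sL %||% 0
    results$landscape <- quasi_potential_surface(model, sL = sL)
    results$regions <- asymptotic_regions(results$landscape)
  }
  if ("thresholds" %in% config$analysis) {
    thr <- estimate_sd_thresh(model, domain = domain)
    results$sd_thresh <- thr$sd_thresh
    results$dose_response <- thr$curve
  }
  if ("metrics" %in% config$analysis && !is.null(results$kymograph)) {
    kym <- results$kymograph
    results$metrics <- data.frame(
      model = config$model,
      polarization_ratio = polarization_ratio(kym),
      polarization_time = tryCatch(polarization_time(kym),
                                   error = function(e) NA_real_),
      integration_index = signal_integration_index(kym))
  }
  hash <- config_hash(config)
  log <- c(sprintf("polaritylab %s", as.character(utils::packageVersion("polaritylab"))),
           sprintf("R %s", as.character(getRversion())),
           sprintf("config %s (preset %s)", hash, config$preset %||% "none"),
           sprintf("runtime %.2f s",
                   as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
    if (!is.null(results$kymograph))
      write_kymograph(results$kymograph, file.path(out_dir, "kymograph.json"))
    if (!is.null(results$landscape))
      write_surface(results$landscape, file.path(out_dir, "surface.json"))
    if (!is.null(results$continuation) &&
        inherits(results$continuation, "bifurcation_diagram"))
      write_diagram(results$continuation, file.path(out_dir, "diagram.tsv"))
    if (!is.null(results$dose_response))
      utils::write.table(results$dose_response,
                         file.path(out_dir, "dose_response.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(results$metrics))
      utils::write.table(results$metrics, file.path(out_dir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  list(config = config, hash = hash, results = results, log = log)
}

#' Reference experiment presets
#'
#' Ready-made configurations for the package's reference experiments: the
#' four organization-regime kymographs under a transient gradient
#' (`transient_regionI` ... `transient_regionIV`), the two-bin bifurcation
#' diagram (`bifurcation_wavepinning`), the per-mechanism diagrams
#' (`legi_diagram`, `turing_diagram`, `wavepinning_diagram`), the
#' unsignaled landscapes (`landscape_regionII`, `landscape_regionIII`), and
#' the dose-response threshold scans (`thresholds_subpb`,
#' `thresholds_wavepinning`). The same configurations ship as YAML files
#' under `inst/extdata/presets/`.
#'
#' @param name preset name; call without arguments to list them.
#' @return An [experiment_config()], or the preset names.
#' @export
experiment_preset <- function(name = NULL) {
  presets <- list(
    bifurcation_wavepinning = experiment_config(
      "region_III", analysis = "continuation",
      protocol = list(kind = "none"), preset = "bifurcation_wavepinning"),
    transient_regionI = experiment_config("region_I",
                                          preset = "transient_regionI"),
    transient_regionII = experiment_config("region_II",
                                           preset = "transient_regionII"),
    transient_regionIII = experiment_config("region_III",
                                            preset = "transient_regionIII"),
    transient_regionIV = experiment_config("region_IV", t_end = 2500,
                                           preset = "transient_regionIV"),
    legi_diagram = experiment_config("legi", analysis = "continuation",
                                     protocol = list(kind = "none"),
                                     preset = "legi_diagram"),
    turing_diagram = experiment_config("turing", analysis = "continuation",
                                       protocol = list(kind = "none"),
                                       preset = "turing_diagram"),
    wavepinning_diagram = experiment_config(
      "wavepinning", analysis = "continuation",
      protocol = list(kind = "none"), preset = "wavepinning_diagram"),
    landscape_regionII = experiment_config(
      "region_II", analysis = "landscape", protocol = list(kind = "none"),
      preset = "landscape_regionII"),
    landscape_regionIII = experiment_config(
      "region_III", analysis = "landscape", protocol = list(kind = "none"),
      preset = "landscape_regionIII"),
    thresholds_subpb = experiment_config(
      "subpb", analysis = "thresholds", protocol = list(kind = "none"),
      preset = "thresholds_subpb"),
    thresholds_wavepinning = experiment_config(
      "wavepinning", analysis = "thresholds", protocol = list(kind = "none"),
      preset = "thresholds_wavepinning"))
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("experiment_preset: unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}
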
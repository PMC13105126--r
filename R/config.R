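# Run configuration, model serialization and the command pipeline tying
# the modules together.

#' Default run configuration
#'
#' Every defaulted field matches the reference training recipe: memory window
#' 1000 ms, 2-ms sampling, ridge strength 10, 200 particles, smoothing
#' bandwidths 100/10/10 ms (EC/DG/CA3), conduction velocities 0.27 and
#' 0.32 mm/ms. The `simulate$teacher` block describes the reduced
#' desk-scale teacher used for recovery benchmarks.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    paths = list(spikes = NULL, out = "cnmm_out"),
    static = list(ec = list(nt = 8, pt = 5), dg = list(nt = 8, pt = 5),
                  coupling = list(nt = 3, pt = 3, nx = 4, px = 3,
                                  ny = 4, py = 3),
                  M = 1000, dt = 2),
    fit = list(lambda_ridge = 10, train_frac = 0.8, particles = 200,
               inertia = 0.25, cognitive = 2.0, social = 1.0,
               generations = 140, bounds = default_pso_bounds(),
               meta = NULL),
    smoothing = list(ec = 100, dg = 10, ca3 = 10, trunc = 4),
    velocities = list(EC = 0.27, DG = 0.32),
    geometry = list(
      grid = list(nx = 3, ny = 3, bin = c(0.2, 0.5), origin = c(0, 0)),
      layers = NULL,                       # NULL -> layer_geometry() default
      electrode = list(lateral_um = 500, level = "pyramidale", sigma = 0.3)),
    simulate = list(
      kind = "teacher", duration = 8000,
      teacher = list(
        static = list(ec = list(nt = 3, pt = 2), dg = list(nt = 3, pt = 2),
                      coupling = list(nt = 2, pt = 2, nx = 2, px = 1,
                                      ny = 2, py = 1),
                      M = 100, dt = 2),
        meta = list(alpha_ec = 0.3, alpha_dg = 0.5, alpha_c = 0.4,
                    rx = 0.45, ry = 1.1, n_delays = 5),
        lag_x = c(-0.2, 0, 0.2), lag_y = c(-0.5, 0, 0.5),
        gains = list(ec = 1, dg = 1, c = 0.5),
        feedback_gain = 0.6, noise_sd = 0),
      toy = list(n_ec = 20, n_dg = 20, ca3_per_mass = 10, coupling = 0.6,
                 base_rate = 8)),
    recover = list(particles = 30, generations = 40),
    target_mass = NULL,                    # NULL -> central mass of the grid
    seed = 1L, log_level = "info")
}

merge_config <- function(defaults, user, path = "") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, ".", nm))
    else defaults[nm] <- user[nm]
  }
  defaults
}

validate_config <- function(cfg) {
  for (nm in c("alpha_ec", "alpha_dg", "alpha_c")) {
    b <- cfg$fit$bounds[[nm]]
    if (b[1] <= 0 || b[2] >= 1 || b[1] >= b[2])
      stop("bounds for ", nm, " must lie strictly inside (0, 1)",
           call. = FALSE)
  }
  if (cfg$fit$train_frac <= 0 || cfg$fit$train_frac >= 1)
    stop("train_frac must lie in (0, 1)", call. = FALSE)
  if (cfg$fit$lambda_ridge < 0) stop("lambda_ridge must be >= 0",
                                     call. = FALSE)
  if (cfg$static$M <= 0 || cfg$static$dt <= 0 ||
      abs(cfg$static$M / cfg$static$dt -
          round(cfg$static$M / cfg$static$dt)) > 1e-9)
    stop("M must be a positive integer multiple of dt", call. = FALSE)
  cfg
}

#' Parse a YAML run configuration
#'
#' Missing fields take the documented defaults (an empty file yields
#' exactly [default_run_config()]); unknown keys are rejected with a
#' message naming them.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_config(default_run_config(), user))
}

#' @rdname parse_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Save / load a fitted model as JSON
#'
#' Lossless round-trip: static block, metaparameters, flat weight vectors
#' in the documented n-major ordering, standardization stats and a
#' format-version field checked on load.
#'
#' @param model A [cnmm_model()].
#' @param path JSON file path.
#' @return `load_model`: the reconstructed [cnmm_model()].
#' @export
save_model <- function(model, path) {
  doc <- list(format_version = model$format_version,
              static = unclass(model$static)[c("ec", "dg", "coupling",
                                               "M", "dt")],
              meta = unclass(model$meta),
              weights = unclass(model$weights),
              center = model$center, stats = model$stats,
              target = model$target, include_self = model$include_self)
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$format_version) || doc$format_version != 1L)
    stop("model format version ", doc$format_version %||% "<missing>",
         " not supported (expected 1); migration required", call. = FALSE)
  st <- doc$static
  cnmm_model(
    static_meta(ec = as.list(st$ec), dg = as.list(st$dg),
                coupling = as.list(st$coupling), M = st$M, dt = st$dt),
    meta_params(doc$meta$alpha_ec, doc$meta$alpha_dg, doc$meta$alpha_c,
                doc$meta$rx, doc$meta$ry, doc$meta$n_delays),
    kernel_weights(doc$weights$w_ec, doc$weights$w_dg, doc$weights$w_c,
                   doc$weights$w_b),
    center = doc$center, stats = as.list(doc$stats), target = doc$target,
    include_self = isTRUE(doc$include_self))
}

# Deterministic per-component seed fan-out: component k of a run seeded s
# uses derive_seed(s, k). Keeps components independent yet reproducible.
derive_seed <- function(base, k) {
  as.integer((as.numeric(base) + 999983 * k) %% 2147483647)
}

# FNV-1a hash of the config JSON, recorded in artifact manifests.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

write_manifest <- function(out, cfg, command, seed, extra = list()) {
  man <- c(list(command = command, seed = seed,
                config_hash = config_hash(cfg),
                package_version =
                  as.character(utils::packageVersion("cnmm")),
                created = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(man, file.path(out, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

config_static <- function(blk) {
  static_meta(ec = as.list(blk$ec), dg = as.list(blk$dg),
              coupling = as.list(blk$coupling), M = blk$M, dt = blk$dt)
}

config_fit <- function(blk, seed, particles = NULL, generations = NULL) {
  fit_config(lambda_ridge = blk$lambda_ridge, train_frac = blk$train_frac,
             particles = particles %||% blk$particles,
             inertia = blk$inertia, cognitive = blk$cognitive,
             social = blk$social,
             generations = generations %||% blk$generations,
             bounds = blk$bounds, seed = seed)
}

config_teacher <- function(cfg, seed) {
  tc <- cfg$simulate$teacher
  st <- config_static(tc$static)
  meta <- do.call(meta_params, as.list(tc$meta))
  model <- random_teacher(st, meta, lag_x = tc$lag_x, lag_y = tc$lag_y,
                          gains = tc$gains,
                          feedback_gain = tc$feedback_gain,
                          seed = derive_seed(seed, 1))
  teacher_spec(model, lag_x = tc$lag_x, lag_y = tc$lag_y,
               bw = list(ec = cfg$smoothing$ec, dg = cfg$smoothing$dg,
                         ca3 = cfg$smoothing$ca3),
               noise_sd = tc$noise_sd, seed = derive_seed(seed, 2))
}

config_dataset <- function(cfg, seed) {
  if (cfg$simulate$kind == "teacher") {
    spec <- config_teacher(cfg, seed)
    teacher_dataset(spec, cfg$simulate$duration)
  } else {
    grid <- do.call(mass_grid, cfg$geometry$grid)
    net <- toy_network_dataset(grid, cfg$simulate$duration,
                               n_ec = cfg$simulate$toy$n_ec,
                               n_dg = cfg$simulate$toy$n_dg,
                               ca3_per_mass = cfg$simulate$toy$ca3_per_mass,
                               coupling = cfg$simulate$toy$coupling,
                               base_rate = cfg$simulate$toy$base_rate,
                               seed = derive_seed(seed, 3))
    target <- cfg$target_mass %||%
      grid$centers$mass[ceiling(nrow(grid$centers) / 2)]
    prepare_mass_dataset(net$events, grid, target, cfg$simulate$duration,
                         dt = cfg$static$dt,
                         bw = list(ec = cfg$smoothing$ec,
                                   dg = cfg$smoothing$dg,
                                   ca3 = cfg$smoothing$ca3),
                         velocities = unlist(cfg$velocities))
  }
}

config_model_static <- function(cfg) {
  if (cfg$simulate$kind == "teacher")
    config_static(cfg$simulate$teacher$static)
  else config_static(cfg$static)
}

#' Run one pipeline command
#'
#' Thin driver tying the modules together; each command writes its
#' artifacts (CSV tables, JSON models and metrics, manifests with the
#' config hash and seed) under the output directory.
#'
#' \describe{
#'   \item{simulate}{Synthetic data: a teacher dataset (traces CSV +
#'     teacher model JSON) or a toy spiking network (events + trajectory
#'     CSV).}
#'   \item{prepare}{Spike events to per-mass density traces.}
#'   \item{fit}{Fit the configured mass: model JSON, metrics JSON,
#'     PSO history CSV.}
#'   \item{predict}{Load the fitted model, recompute predictions and R.}
#'   \item{lfp}{Seven current-layer teacher fits and the point-source LFP.}
#'   \item{analyze}{Kernel-strength table and spectral summary.}
#'   \item{recover}{Full teacher-recovery benchmark report.}
#' }
#'
#' @param command One of simulate, prepare, fit, predict, lfp, analyze,
#'   recover.
#' @param config Configuration list or path to a YAML file.
#' @param seed Optional seed overriding the configured one.
#' @param out Optional output directory overriding the configured one.
#' @return Invisibly, a list of artifact paths (plus command-specific
#'   values such as validation R).
#' @export
run_command <- function(command = c("simulate", "prepare", "fit", "predict",
                                    "lfp", "analyze", "recover"),
                        config = default_run_config(), seed = NULL,
                        out = NULL) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) parse_config(config)
         else validate_config(merge_config(default_run_config(), config))
  seed <- as.integer(seed %||% cfg$seed)
  out <- out %||% cfg$paths$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- switch(command,
    simulate = cmd_simulate(cfg, seed, out),
    prepare = cmd_prepare(cfg, seed, out),
    fit = cmd_fit(cfg, seed, out),
    predict = cmd_predict(cfg, seed, out),
    lfp = cmd_lfp(cfg, seed, out),
    analyze = cmd_analyze(cfg, seed, out),
    recover = cmd_recover(cfg, seed, out))
  write_manifest(out, cfg, command, seed)
  invisible(res)
}

cmd_simulate <- function(cfg, seed, out) {
  if (cfg$simulate$kind == "teacher") {
    spec <- config_teacher(cfg, seed)
    ds <- teacher_dataset(spec, cfg$simulate$duration)
    save_model(spec$model, file.path(out, "teacher_model.json"))
    write_density_traces(list(ec = ds$ec, dg = ds$dg, y = ds$y),
                         file.path(out, "teacher_traces.csv"))
    list(traces = file.path(out, "teacher_traces.csv"),
         teacher = file.path(out, "teacher_model.json"))
  } else {
    grid <- do.call(mass_grid, cfg$geometry$grid)
    net <- toy_network_dataset(grid, cfg$simulate$duration,
                               n_ec = cfg$simulate$toy$n_ec,
                               n_dg = cfg$simulate$toy$n_dg,
                               ca3_per_mass = cfg$simulate$toy$ca3_per_mass,
                               coupling = cfg$simulate$toy$coupling,
                               base_rate = cfg$simulate$toy$base_rate,
                               seed = derive_seed(seed, 3))
    write_spike_events(net$events, file.path(out, "spikes.csv"))
    utils::write.csv(net$trajectory$path, file.path(out, "trajectory.csv"),
                     row.names = FALSE)
    list(spikes = file.path(out, "spikes.csv"),
         trajectory = file.path(out, "trajectory.csv"))
  }
}

cmd_prepare <- function(cfg, seed, out) {
  ds <- config_dataset(cfg, seed)
  write_density_traces(list(ec = ds$ec, dg = ds$dg, y = ds$y),
                       file.path(out, "density_traces.csv"))
  list(traces = file.path(out, "density_traces.csv"))
}

cmd_fit <- function(cfg, seed, out) {
  ds <- config_dataset(cfg, seed)
  static <- config_model_static(cfg)
  meta <- if (!is.null(cfg$fit$meta))
    do.call(meta_params, as.list(cfg$fit$meta)) else NULL
  fc <- config_fit(cfg$fit, derive_seed(seed, 4))
  fr <- fit_mass(ds, static, fc, meta = meta,
                 center = ds$center %||% c(0, 0))
  save_model(fr$model, file.path(out, "model.json"))
  jsonlite::write_json(
    list(train_mse = fr$train_mse, val_mse = fr$val_mse,
         val_r_teacher = fr$val_r_teacher, val_r_free = fr$val_r_free,
         split_index = fr$split, generations = cfg$fit$generations,
         seed = seed),
    file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(fr$history))
    utils::write.csv(fr$history, file.path(out, "pso_history.csv"),
                     row.names = FALSE)
  list(model = file.path(out, "model.json"),
       metrics = file.path(out, "metrics.json"), result = fr)
}

cmd_predict <- function(cfg, seed, out) {
  model <- load_model(file.path(out, "model.json"))
  ds <- config_dataset(cfg, seed)
  tf <- predict(model, ds, mode = "teacher_forced", reference = ds$y)
  fr <- predict(model, ds, mode = "free_running")
  burn <- attr(tf, "burn_in")
  r_tf <- correlation_score(tf, ds$y, burn)
  r_fr <- correlation_score(fr, ds$y, burn)
  df <- data.frame(t_ms = (seq_along(trace_values(ds$y)) - 1) * ds$dt,
                   reference = trace_values(ds$y),
                   teacher_forced = trace_values(tf),
                   free_running = trace_values(fr))
  utils::write.csv(df, file.path(out, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(list(r_teacher_forced = r_tf, r_free_running = r_fr),
                       file.path(out, "prediction_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(predictions = file.path(out, "predictions.csv"),
       r_teacher_forced = r_tf, r_free_running = r_fr)
}

cmd_lfp <- function(cfg, seed, out) {
  spec <- config_teacher(cfg, seed)
  ds <- teacher_dataset(spec, cfg$simulate$duration)
  inputs <- list(ec = ds$ec, dg = ds$dg, field = ds$field)
  static <- spec$model$static
  geom <- if (is.null(cfg$geometry$layers)) layer_geometry()
          else layer_geometry(unlist(cfg$geometry$layers))
  # per-layer teacher currents: independent teachers on the shared inputs,
  # each de-standardized to a synthetic physical amplitude in nA
  currents <- vector("list", 7)
  set.seed(derive_seed(seed, 5))
  amp <- list()
  for (k in 1:7) {
    tk <- random_teacher(static, spec$model$meta, lag_x = spec$lag_x,
                         lag_y = spec$lag_y,
                         seed = derive_seed(seed, 10 + k))
    z <- trace_values(predict(tk, inputs, mode = "free_running"))
    amp[[k]] <- list(mean = stats::runif(1, -5, 5),
                     sd = stats::runif(1, 50, 200))  # nA scale
    currents[[k]] <- destandardize(standardize(z), amp[[k]])
  }
  fits <- fit_layer_models(currents, inputs, static,
                           config_fit(cfg$fit, derive_seed(seed, 6)),
                           meta = spec$model$meta, geom = geom)
  burn <- static$taps
  pred_nA <- lapply(seq_len(7), function(k) {
    z <- predict(fits[[k]]$model, inputs, mode = "free_running")
    destandardize(z, fits[[k]]$model$stats$current)
  })
  elec <- reference_electrode(geom,
                              lateral_um = cfg$geometry$electrode$lateral_um,
                              level = cfg$geometry$electrode$level,
                              sigma = cfg$geometry$electrode$sigma)
  lfp_pred <- point_source_lfp(pred_nA, elec)
  lfp_ref <- point_source_lfp(currents, elec)
  r <- stats::cor(lfp_pred[-seq_len(burn)], lfp_ref[-seq_len(burn)])
  df <- data.frame(t_ms = (seq_along(lfp_pred) - 1) * static$dt,
                   phi_mV_ref = lfp_ref, phi_mV_pred = lfp_pred)
  utils::write.csv(df, file.path(out, "lfp.csv"), row.names = FALSE)
  for (k in 1:7)
    save_model(fits[[k]]$model,
               file.path(out, sprintf("layer_%s.json", geom$layers[k])))
  jsonlite::write_json(list(r_lfp = r), file.path(out, "lfp_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(lfp = file.path(out, "lfp.csv"), r_lfp = r)
}

cmd_analyze <- function(cfg, seed, out) {
  files <- list.files(out, pattern = "^(model|layer_.*)\\.json$",
                      full.names = TRUE)
  if (length(files) < 2)
    stop("analyze needs at least two fitted models in ", out, call. = FALSE)
  models <- lapply(files, load_model)
  prof <- strength_profile(models)
  utils::write.csv(prof$table, file.path(out, "kernel_strengths.csv"),
                   row.names = FALSE)
  spec_path <- NULL
  pred_file <- file.path(out, "predictions.csv")
  if (file.exists(pred_file)) {
    df <- utils::read.csv(pred_file)
    ss <- spectral_summary(df$free_running, dt = cfg$static$dt)
    spec_path <- file.path(out, "spectrum.csv")
    utils::write.csv(data.frame(freq_Hz = ss$freq, power = ss$power),
                     spec_path, row.names = FALSE)
  }
  list(strengths = file.path(out, "kernel_strengths.csv"),
       spectrum = spec_path, profile = prof)
}

cmd_recover <- function(cfg, seed, out) {
  spec <- config_teacher(cfg, seed)
  ds <- teacher_dataset(spec, cfg$simulate$duration)
  static <- spec$model$static
  fc_fixed <- config_fit(cfg$fit, derive_seed(seed, 7))
  fixed <- fit_mass(ds, static, fc_fixed, meta = spec$model$meta)
  fc_pso <- config_fit(cfg$fit, derive_seed(seed, 8),
                       particles = cfg$recover$particles,
                       generations = cfg$recover$generations)
  searched <- fit_mass(ds, static, fc_pso)
  report <- list(
    r_teacher_forced_at_truth = fixed$val_r_teacher,
    r_free_running_at_truth = fixed$val_r_free,
    r_teacher_forced_pso = searched$val_r_teacher,
    r_free_running_pso = searched$val_r_free,
    best_meta = unclass(searched$model$meta),
    true_meta = unclass(spec$model$meta),
    particles = cfg$recover$particles,
    generations = cfg$recover$generations, seed = seed)
  jsonlite::write_json(report, file.path(out, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(searched$history, file.path(out, "recovery_history.csv"),
                   row.names = FALSE)
  c(list(report_path = file.path(out, "recovery.json")), report)
}
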
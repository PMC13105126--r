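# From spike-event tables to a per-mass model dataset: pooled input
# densities with conduction delays, per-mass CA3 densities and the
# neighbor-lag coupling field.

#' Build the model dataset for one target mass from spike events
#'
#' Applies the full preprocessing chain for a target mass: per-neuron
#' conduction delays (path length = Euclidean distance from the neuron to
#' the mass center), 2-ms peristimulus histograms, standardization and
#' Gaussian smoothing for the EC and DG input streams; per-mass CA3
#' densities for the reference output and the neighbor coupling field.
#' Neighbor masses missing from the grid contribute zero slices (logged).
#'
#' @param events Spike-event data.frame (`neuron_id`, `time_ms`,
#'   `population`, optional `x_mm`, `y_mm`).
#' @param grid A [mass_grid()] over CA3.
#' @param target_mass Index of the mass to model.
#' @param duration Duration in ms.
#' @param dt Sampling period in ms.
#' @param bw Named smoothing bandwidths in ms (`ec`, `dg`, `ca3`).
#' @param velocities Named conduction velocities in mm/ms (`EC`, `DG`).
#' @param stats Optional named list of standardization stats to reuse
#'   (e.g. training stats applied to a later segment).
#' @return Dataset list (`ec`, `dg`, `field`, `y`, `stats`, `dt`, `center`)
#'   suitable for [fit_mass()].
#' @export
prepare_mass_dataset <- function(events, grid, target_mass, duration,
                                 dt = 2,
                                 bw = list(ec = 100, dg = 10, ca3 = 10),
                                 velocities = default_velocities(),
                                 stats = NULL) {
  center <- unlist(grid$centers[grid$centers$mass == target_mass,
                                c("x", "y")])
  has_pos <- all(c("x_mm", "y_mm") %in% names(events))

  stream <- function(pop, velocity, w, key) {
    ev <- events[events$population == pop, , drop = FALSE]
    if (nrow(ev) == 0)
      stop("no events for population ", pop, call. = FALSE)
    delays <- 0
    if (has_pos && !is.null(velocity)) {
      d <- sqrt((ev$x_mm - center[1])^2 + (ev$y_mm - center[2])^2)
      delays <- conduction_delays(d, velocity)
    }
    spike_density(ev$time_ms, delays, duration, w = w, dt = dt,
                  stats = stats[[key]], label = pop)
  }
  ec <- stream("EC", velocities[["EC"]], bw$ec, "ec")
  dg <- stream("DG", velocities[["DG"]], bw$dg, "dg")

  # per-mass CA3 densities (no conduction delay within CA3 by default)
  ca3 <- events[events$population == "CA3PC", , drop = FALSE]
  if (nrow(ca3) == 0) stop("no CA3PC events", call. = FALSE)
  if (!has_pos) stop("CA3 events need positions for mass assignment",
                     call. = FALSE)
  mass_of <- assign_masses(grid, cbind(ca3$x_mm, ca3$y_mm))
  n <- as.integer(round(duration / dt))
  dens <- list()
  for (m in grid$centers$mass) {
    ev <- ca3[which(mass_of == m), , drop = FALSE]
    dens[[m]] <- if (nrow(ev) == 0) NULL else
      tryCatch(spike_density(ev$time_ms, 0, duration, w = bw$ca3, dt = dt,
                             stats = stats[[paste0("ca3_", m)]],
                             label = sprintf("CA3PC[%d]", m)),
               error = function(e) NULL)  # constant histogram -> no trace
  }
  if (is.null(dens[[target_mass]]))
    stop("target mass has no usable CA3 activity", call. = FALSE)

  # coupling field over all grid lags (target minus neighbor center)
  lag_x <- sort(unique(round(center[1] - grid$centers$x, 9)))
  lag_y <- sort(unique(round(center[2] - grid$centers$y, 9)))
  vals <- array(0, dim = c(length(lag_x), length(lag_y), n))
  missing <- 0L
  for (m in grid$centers$mass) {
    a <- match(round(center[1] - grid$centers$x[m], 9), lag_x)
    b <- match(round(center[2] - grid$centers$y[m], 9), lag_y)
    if (is.null(dens[[m]])) missing <- missing + 1L
    else vals[a, b, ] <- trace_values(dens[[m]])
  }
  if (missing > 0)
    message(missing, " mass(es) without usable activity contribute zeros")
  st <- list(ec = ec$stats, dg = dg$stats)
  for (m in grid$centers$mass)
    if (!is.null(dens[[m]])) st[[paste0("ca3_", m)]] <- dens[[m]]$stats
  list(ec = ec, dg = dg,
       field = coupling_field(lag_x, lag_y, vals),
       y = dens[[target_mass]], stats = st, dt = dt, center = center)
}

#' Write / read density traces as a CSV container
#'
#' One column per trace plus a `t_ms` column; sampling period, labels and
#' standardization stats go to a JSON sidecar (`<path>.meta.json`).
#'
#' @param traces Named list of [density_trace()]s.
#' @param path CSV path.
#' @return `read_density_traces`: named list of [density_trace()]s.
#' @export
write_density_traces <- function(traces, path) {
  n <- length(traces[[1]])
  df <- data.frame(t_ms = (seq_len(n) - 1) * traces[[1]]$dt)
  for (nm in names(traces)) df[[nm]] <- trace_values(traces[[nm]])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- lapply(traces, function(tr)
    list(dt = tr$dt, start = tr$start, label = tr$label, stats = tr$stats))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_density_traces
#' @export
read_density_traces <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  out <- list()
  for (nm in names(meta)) {
    m <- meta[[nm]]
    out[[nm]] <- density_trace(df[[nm]], dt = m$dt, start = m$start,
                               label = m$label, stats = m$stats)
  }
  out
}
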
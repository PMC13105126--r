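# Forward model: per-stratum current layer models and point-source LFP
# synthesis.

#' CA3 layer geometry
#'
#' The seven strata of CA3 in radial order, each reduced to a radial center
#' coordinate. The default coordinates (micrometers relative to stratum
#' pyramidale) span a plausible CA3 laminar profile; they are a
#' configuration fixture, not measured anatomy.
#'
#' @param centers_um Named numeric vector of radial centers in micrometers,
#'   strictly increasing, one per stratum.
#' @return A `layer_geometry` object.
#' @export
layer_geometry <- function(centers_um = c(
    slm_distal = -400, slm_proximal = -325, radiatum = -200, lucidum = -75,
    pyramidale = 0, oriens_proximal = 75, oriens_distal = 175)) {
  if (length(centers_um) != 7)
    stop("exactly 7 layers are required", call. = FALSE)
  if (any(diff(centers_um) <= 0))
    stop("layer radial centers must be strictly ordered", call. = FALSE)
  structure(list(centers_um = centers_um,
                 layers = names(centers_um)), class = "layer_geometry")
}

#' Electrode geometry for the point-source sum
#'
#' Distances from the recording electrode to each layer center, with the
#' extracellular conductivity. The helper default reproduces the reference
#' recording recipe: electrode at the radial level of the stratum pyramidale
#' center, offset 500 um from the mass center at 45 degrees between the
#' septal and distal axes, so every layer sits at
#' `sqrt(500^2 + (z_k - z_pyramidale)^2)` um.
#'
#' @param distances_um Distances r_k in micrometers (> 0), one per layer.
#' @param sigma Extracellular conductivity in S/m (default 0.3).
#' @return An `electrode_geometry` object.
#' @export
electrode_geometry <- function(distances_um, sigma = 0.3) {
  if (any(distances_um <= 0))
    stop("all electrode-layer distances must be positive", call. = FALSE)
  if (sigma <= 0) stop("conductivity must be positive", call. = FALSE)
  structure(list(distances_um = distances_um, sigma = sigma),
            class = "electrode_geometry")
}

#' @rdname electrode_geometry
#' @param geom A [layer_geometry()].
#' @param lateral_um Lateral offset of the electrode from the mass center.
#' @param level Name of the layer whose radial level the electrode sits at.
#' @export
reference_electrode <- function(geom = layer_geometry(), lateral_um = 500,
                                level = "pyramidale", sigma = 0.3) {
  z0 <- geom$centers_um[[level]]
  electrode_geometry(sqrt(lateral_um^2 + (geom$centers_um - z0)^2),
                     sigma = sigma)
}

#' Fit the seven current layer models
#'
#' Each stratum's total transmembrane current is fitted exactly as a
#' spike-density model, on the standardized current with the original
#' (mean, sd) stored so predictions can be de-standardized back to physical
#' amplitudes before the point-source sum.
#'
#' @param currents List of 7 per-layer current traces (nA), aligned with
#'   the inputs.
#' @param inputs Shared input list (`ec`, `dg`, optional `field`).
#' @param static [static_meta()].
#' @param config [fit_config()].
#' @param meta Optional fixed [meta_params()] (skips the swarm search),
#'   either one object shared by all layers or a list of 7.
#' @param geom [layer_geometry()] naming the layers.
#' @return List of 7 `fit_result`s (named by layer), each with the layer's
#'   de-standardization `stats` attached to its model.
#' @export
fit_layer_models <- function(currents, inputs, static,
                             config = fit_config(), meta = NULL,
                             geom = layer_geometry()) {
  if (length(currents) != 7)
    stop("exactly 7 layer current targets are required", call. = FALSE)
  metas <- if (is.null(meta) || inherits(meta, "meta_params"))
    rep(list(meta), 7) else meta
  out <- vector("list", 7)
  for (k in seq_len(7)) {
    z <- standardize(trace_values(currents[[k]]), dt = static$dt,
                     label = geom$layers[k])
    ds <- c(inputs, list(y = z, stats = list(current = z$stats)))
    out[[k]] <- fit_mass(ds, static, config, meta = metas[[k]],
                         target = "layer_current")
  }
  names(out) <- geom$layers
  out
}

#' Point-source LFP synthesis
#'
#' Sums the layer currents weighted by inverse distance:
#' \deqn{\phi(t) = \sum_k \frac{I_k(t)}{4\pi\sigma r_k}.}
#' Unit bookkeeping: with currents in nA, distances in micrometers and
#' conductivity in S/m, the quotient `I_nA / (4 pi sigma r_um)` is already
#' in millivolts (the 1e-9/1e-6 unit factors combine to 1e-3 V).
#'
#' @param currents `7 x T` matrix (or list of 7 traces) of layer currents
#'   in nA.
#' @param geometry An [electrode_geometry()].
#' @return Numeric LFP trace in mV.
#' @export
point_source_lfp <- function(currents, geometry) {
  if (is.list(currents))
    currents <- do.call(rbind, lapply(currents, trace_values))
  if (nrow(currents) != length(geometry$distances_um))
    stop("one current trace per layer distance is required", call. = FALSE)
  w <- 1 / (4 * pi * geometry$sigma * geometry$distances_um)
  as.numeric(crossprod(currents, w))
}
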
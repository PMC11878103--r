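# Activation protocols: the sinus beat (stimulus at the sinus-node core
# centroid) and the ectopic beat (stimulus at a His-Purkinje site, by
# default the bundle voxel farthest from the AVN, i.e. a distal branch).
# Each run returns the activation map plus a per-region summary from
# which the activation sequence is read as ordering statistics.

#' Define a stimulus protocol
#'
#' @param name `"sinus"`, `"ectopic"` or `"custom"`.
#' @param target_code Region receiving the stimulus (defaults: 8 for
#'   sinus, 12 for ectopic).
#' @param target_voxel Explicit voxel index triple overriding the default
#'   site (sinus: region centroid; ectopic: the region voxel farthest
#'   from the AVN centroid).
#' @param mask Explicit logical stimulus mask (required for `"custom"`),
#'   overriding code/voxel targeting.
#' @param onset,duration Stimulus window in ms.
#' @param amplitude Stimulus current in mV/ms; `NULL` uses twice the
#'   diastolic threshold of the target region's cell parameters.
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(name = c("sinus", "ectopic", "custom"),
                              target_code = NULL, target_voxel = NULL,
                              mask = NULL, onset = 0, duration = 2,
                              amplitude = NULL) {
  name <- match.arg(name)
  stopifnot(duration > 0, onset >= 0)
  if (is.null(target_code))
    target_code <- switch(name, sinus = 8L, ectopic = 12L, custom = NULL)
  if (name == "custom" && is.null(mask) && is.null(target_voxel))
    stop("custom protocol needs a mask or a target voxel")
  structure(list(name = name, target_code = target_code,
                 target_voxel = target_voxel, mask = mask, onset = onset,
                 duration = duration, amplitude = amplitude),
            class = "stimulus_protocol")
}

resolve_stimulus <- function(protocol, vol, graph, config, params, regions) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  d <- vol$dims
  if (!is.null(protocol$mask)) {
    stopifnot(all(dim(protocol$mask) == d))
    vox <- which(protocol$mask)
  } else {
    target <- protocol$target_voxel
    if (is.null(target)) {
      code <- protocol$target_code
      if (!any(vol$codes == code))
        stop("stimulus target region (code ", code, ") absent from volume")
      if (protocol$name == "ectopic" && any(vol$codes == 11L)) {
        avn <- colMeans(which(vol$codes == 11L, arr.ind = TRUE))
        hps <- which(vol$codes == code, arr.ind = TRUE)
        target <- as.integer(hps[which.max(rowSums(sweep(hps, 2, avn)^2)), ])
      } else {
        target <- region_centroid_voxel(vol, code)
      }
    }
    r <- config$stim_radius_vox
    lo <- pmax(target - ceiling(r), 1)
    hi <- pmin(target + ceiling(r), d)
    sub <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    keep <- rowSums(sweep(as.matrix(sub), 2, target)^2) <= r^2
    sub <- as.matrix(sub[keep, , drop = FALSE])
    vox <- sub[, 1] + d[1] * (sub[, 2] - 1) + d[1] * d[2] * (sub[, 3] - 1)
    # confine the stimulus to the targeted region so it cannot bypass the
    # coupling rules (e.g. excite the atria around the sinus node)
    if (!is.null(protocol$target_code))
      vox <- vox[vol$codes[vox] == protocol$target_code]
  }
  node_of <- integer(prod(d))
  node_of[graph$node_voxel] <- seq_len(graph$n)
  nodes <- node_of[vox]
  nodes <- nodes[nodes > 0]
  if (!length(nodes)) stop("stimulus mask covers no excitable tissue")
  amp <- protocol$amplitude
  if (is.null(amp)) {
    tc <- if (!is.null(protocol$target_code)) protocol$target_code else
      vol$codes[vox[1]]
    row <- regions[regions$code == tc, ]
    up <- if (nrow(row)) row$upstroke[1] else 1
    ap <- if (nrow(row)) row$apd[1] else 1
    # clamp the scales used for the threshold estimate: outside this range
    # the single cell has no well-defined rest/threshold, and the tissue
    # stimulus only needs the right order of magnitude
    amp <- 2 * diastolic_threshold(params, protocol$duration, config$dt,
                                   min(max(up, 0.2), 3), min(max(ap, 0.5), 2))
  }
  list(nodes = as.integer(nodes), onset = protocol$onset,
       duration = protocol$duration, amplitude = amp)
}

#' Per-region activation summary
#'
#' @param map An `activation_map`.
#' @param vol The [label_volume()] the map was computed on.
#' @return Data frame with, per region code present as tissue: `code`,
#'   `region`, `n_voxels`, `n_activated`, `fraction_activated`, `first`,
#'   `median`, `last` (ms; `NA` when nothing activated).
#' @export
region_activation_summary <- function(map, vol) {
  stopifnot(all(map$dims == vol$dims))
  t <- map$times
  out <- list()
  for (code in sort(unique(as.vector(vol$codes)))) {
    sel <- vol$codes == code
    tt <- t[sel]
    if (all(is.na(tt))) next  # non-tissue region
    act <- tt[is.finite(tt)]
    out[[length(out) + 1]] <- data.frame(
      code = code, region = unname(vol$dictionary[as.character(code)]),
      n_voxels = sum(sel), n_activated = length(act),
      fraction_activated = length(act) / sum(sel),
      first = if (length(act)) min(act) else NA_real_,
      median = if (length(act)) median(act) else NA_real_,
      last = if (length(act)) max(act) else NA_real_)
  }
  do.call(rbind, out)
}

#' Run the sinus (normal conduction) protocol
#'
#' Stimulates the center of the sinus node; excitation exits through the
#' superior/inferior exit pathways into the atria, funnels through the
#' AVN into the His-Purkinje system and reaches the ventricles at the
#' insertion points.
#'
#' @inheritParams simulate
#' @return List with `activation_map`, `summary` (a
#'   [region_activation_summary()]), and the `simulate()` run fields.
#' @export
run_sinus <- function(vol, regions = default_region_table(),
                      policy = default_policy(), config = sim_config(),
                      params = cell_params()) {
  if (!any(vol$codes == 8L)) stop("volume contains no sinus node core")
  res <- simulate(vol, regions, policy, stimulus_protocol("sinus"),
                  config, params)
  res$summary <- region_activation_summary(res$activation_map, vol)
  res
}

#' Run the ectopic (His-Purkinje) protocol
#'
#' Stimulates a distal His-Purkinje site: the ventricles activate early
#' and the atria are reached retrogradely through the AVN.
#'
#' @inheritParams run_sinus
#' @param target_voxel Optional explicit stimulation voxel.
#' @return As [run_sinus()].
#' @export
run_ectopic <- function(vol, regions = default_region_table(),
                        policy = default_policy(), config = sim_config(),
                        params = cell_params(), target_voxel = NULL) {
  if (!any(vol$codes == 12L)) stop("volume contains no His-Purkinje system")
  prot <- stimulus_protocol("ectopic", target_voxel = target_voxel)
  res <- simulate(vol, regions, policy, prot, config, params)
  res$summary <- region_activation_summary(res$activation_map, vol)
  res
}

#' Rescale an activation map per region to [0, 1]
#'
#' Within each region the finite activation times are affinely mapped to
#' `[0, 1]` by the region's own min/max (a single-time or never-activated
#' region maps to 0 / stays sentinel), increasing the temporal resolution
#' of per-region activation displays. Sentinels (`NA` non-tissue, `Inf`
#' never activated) are preserved; the input map is not modified.
#'
#' @param map An `activation_map`.
#' @param vol The matching [label_volume()].
#' @return A new `activation_map` with unitless times.
#' @export
region_scaled_map <- function(map, vol) {
  stopifnot(all(map$dims == vol$dims))
  t_new <- map$times
  for (code in sort(unique(as.vector(vol$codes)))) {
    sel <- vol$codes == code
    tt <- map$times[sel]
    fin <- is.finite(tt)
    if (!any(fin)) next
    rng <- range(tt[fin])
    tt[fin] <- if (rng[2] > rng[1]) (tt[fin] - rng[1]) / (rng[2] - rng[1]) else 0
    t_new[sel] <- tt
  }
  structure(list(times = t_new, voxel_size = map$voxel_size,
                 dims = map$dims), class = "activation_map")
}

#' Latest-activating tissue report
#'
#' @param map An `activation_map`.
#' @param vol The matching [label_volume()].
#' @param k Number of latest voxels to list.
#' @return List with `voxels` (data frame `x`, `y`, `z`, `code`, `region`,
#'   `time` of the k latest finite activations, latest first) and
#'   `region_last` (per-region last activation times).
#' @export
latest_activation_report <- function(map, vol, k = 10) {
  stopifnot(all(map$dims == vol$dims))
  fin <- which(is.finite(map$times))
  if (!length(fin)) stop("activation map contains no activated tissue")
  ord <- fin[order(map$times[fin], decreasing = TRUE)]
  ord <- ord[seq_len(min(k, length(ord)))]
  idx <- arrayInd(ord, map$dims)
  voxels <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                       code = vol$codes[ord],
                       region = unname(vol$dictionary[as.character(vol$codes[ord])]),
                       time = map$times[ord])
  summ <- region_activation_summary(map, vol)
  list(voxels = voxels,
       region_last = summ[order(summ$last, decreasing = TRUE),
                          c("code", "region", "last")])
}

#' Write a provenance manifest for a run
#'
#' @param path Output JSON path.
#' @param config A [sim_config()].
#' @param protocol A [stimulus_protocol()].
#' @param vol Optional [label_volume()]; its dims and a content hash are
#'   recorded.
#' @return `path`, invisibly.
#' @export
run_manifest <- function(path, config, protocol, vol = NULL) {
  m <- list(package = "ccsim",
            version = as.character(utils::packageVersion("ccsim")),
            config = unclass(config),
            protocol = Filter(Negate(is.null), unclass(protocol)[
              c("name", "target_code", "onset", "duration", "amplitude")]))
  if (!is.null(vol)) {
    m$volume <- list(dims = as.integer(vol$dims),
                     voxel_size_mm = vol$voxel_size,
                     label_sum = sum(as.numeric(vol$codes)))
  }
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
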
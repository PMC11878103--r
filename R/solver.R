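# Isotropic monodomain solver on a labeled voxel grid. Voxels whose codes
# are excitable become tissue nodes; 6-neighbour voxel pairs whose code
# pair is permitted by the coupling policy exchange diffusive current with
# an interface conductance equal to the harmonic mean of the two regions'
# diffusion coefficients divided by dx^2. Every other interface is no-flux,
# which is what electrically insulates the atrioventricular node from the
# ventricles and confines the sinus node behind its exit pathways.

NON_EXCITABLE_CODES <- c(0L, 1L, 2L, 14L, 15L, 16L)

#' Per-region electrophysiology parameter table
#'
#' @param codes Integer region codes (must all be excitable, i.e. not
#'   background, cavity, valve, fat or scar).
#' @param D Diffusion coefficient(s) in mm^2/ms (recycled).
#' @param upstroke Sodium-conductance scale(s) controlling dVm/dt_max.
#' @param apd Scale(s) on the repolarising currents controlling APD90.
#' @return Data frame with columns `code`, `excitable`, `D`, `upstroke`,
#'   `apd` (class `region_table`).
#' @export
region_table <- function(codes, D, upstroke = 1, apd = 1) {
  codes <- as.integer(codes)
  if (any(codes %in% NON_EXCITABLE_CODES))
    stop("non-excitable codes cannot carry electrophysiology parameters: ",
         paste(intersect(codes, NON_EXCITABLE_CODES), collapse = ", "))
  stopifnot(all(D > 0), all(upstroke >= 0), all(apd > 0))
  out <- data.frame(code = codes, excitable = TRUE,
                    D = rep_len(D, length(codes)),
                    upstroke = rep_len(upstroke, length(codes)),
                    apd = rep_len(apd, length(codes)))
  class(out) <- c("region_table", "data.frame")
  out
}

#' Default regional parameter table
#'
#' Working myocardium conducts with D = 0.3 mm^2/ms; the sinus node (core
#' and exits) and atrioventricular node use D = 0.1 mm^2/ms with the
#' sodium conductance reduced to a quarter to slow conduction; the
#' His-Purkinje system and the fast atrial pathways (crista terminalis,
#' pectinate muscles, Bachmann's bundle) use D = 0.9 mm^2/ms. APD scales
#' shorten atrial and lengthen nodal/Purkinje repolarisation. Upstroke
#' scales are multiplied by `base_upstroke`, normally the slab-calibrated
#' working-myocardium scale (see [calibrate_excitability()]).
#'
#' @param base_upstroke Baseline sodium scale applied to every region.
#' @return A [region_table()].
#' @export
default_region_table <- function(base_upstroke = calibrated_upstroke()) {
  tab <- region_table(
    codes    = c(3,   4,   5,   6,   7,   8,    9,    10,   11,   12,  13),
    D        = c(0.3, 0.3, 0.9, 0.9, 0.9, 0.1,  0.1,  0.1,  0.1,  0.9, 0.9),
    upstroke = c(1,   1,   1,   1,   1,   0.25, 0.25, 0.25, 0.25, 2,   2),
    apd      = c(0.9, 1,   0.9, 0.9, 0.9, 1.2,  1.2,  1.2,  1.2,  1.3, 1.3))
  tab$upstroke <- tab$upstroke * base_upstroke
  tab
}

#' Construct a label-pair coupling policy
#'
#' @param pairs Two-column matrix or data frame of region-code pairs
#'   permitted to exchange diffusive current. Pairs are unordered;
#'   same-code coupling is implicitly allowed for every excitable code.
#' @return A `coupling_policy` object.
#' @export
coupling_policy <- function(pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  stopifnot(ncol(pairs) == 2)
  if (any(pairs %in% NON_EXCITABLE_CODES))
    stop("coupling pairs must not include non-excitable codes")
  allowed <- matrix(FALSE, 256, 256)
  diag(allowed) <- TRUE
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1] + 1L; b <- pairs[i, 2] + 1L
    allowed[a, b] <- TRUE; allowed[b, a] <- TRUE
  }
  structure(list(pairs = pairs, allowed = allowed),
            class = "coupling_policy")
}

#' Does a policy allow coupling between two region codes?
#'
#' @param policy A [coupling_policy()].
#' @param a,b Region codes.
#' @return Logical.
#' @export
policy_allows <- function(policy, a, b) {
  policy$allowed[cbind(as.integer(a) + 1L, as.integer(b) + 1L)]
}

#' The default conduction-system coupling policy
#'
#' Encodes the activation-sequence contract: the sinus-node core couples
#' only to its superior/inferior exit regions; the exits couple to the
#' atrial muscle (working atrium, crista terminalis, pectinate muscles,
#' Bachmann's bundle); the atrial codes are mutually coupled; the
#' atrioventricular node couples only to the atrial myocardium and the
#' His-Purkinje system, i.e. it is insulated from the ventricles; the
#' His-Purkinje system couples to the AVN, itself and its insertion
#' points; only the insertion points couple to the ventricular myocardium.
#'
#' @return A [coupling_policy()].
#' @export
default_policy <- function() {
  atrial <- c(3L, 5L, 6L, 7L)
  pairs <- rbind(
    cbind(8L, c(9L, 10L)),                      # SN core <-> exits only
    cbind(rep(c(9L, 10L), each = 4), atrial),   # exits <-> atrial muscle
    t(utils::combn(atrial, 2)),                 # atrial codes mutually
    cbind(11L, c(3L, 12L)),                     # AVN <-> atria, His only
    cbind(12L, 13L),                            # His-Purkinje <-> insertions
    cbind(13L, 4L))                             # insertions <-> ventricles
  coupling_policy(pairs)
}

#' Build the tissue graph of a labeled volume
#'
#' Nodes are the excitable voxels; each 6-neighbour voxel pair whose code
#' pair the policy allows gets a symmetric edge with conductance
#' `2*Da*Db/(Da+Db)/dx^2` (1/ms). Disallowed and out-of-tissue interfaces
#' carry no edge (no-flux boundary).
#'
#' @param vol A [label_volume()].
#' @param regions A [region_table()].
#' @param policy A [coupling_policy()].
#' @return A `tissue_graph` list: CSR arrays `ptr`, `idx`, `w` (0-based),
#'   `node_voxel` (linear voxel index per node), `node_code`, `dims`,
#'   `voxel_size`, `n`.
#' @export
build_tissue_graph <- function(vol, regions, policy) {
  stopifnot(inherits(vol, "label_volume"), inherits(policy, "coupling_policy"))
  codes <- vol$codes
  present <- unique(as.vector(codes))
  missing <- setdiff(present, c(regions$code, NON_EXCITABLE_CODES))
  if (length(missing))
    stop("excitable code(s) missing from the region table: ",
         paste(missing, collapse = ", "))
  d <- vol$dims
  tissue <- codes %in% regions$code
  node_voxel <- which(tissue)
  n <- length(node_voxel)
  if (n == 0) stop("volume contains no excitable tissue")
  node_of <- integer(length(codes))
  node_of[node_voxel] <- seq_len(n)
  Dmap <- numeric(256)
  Dmap[regions$code + 1L] <- regions$D
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    # voxel pairs (v, v + stride) with both in-bounds along axis ax
    idx_ax <- slice.index(codes, ax)
    ok <- tissue & idx_ax < d[ax]
    v1 <- which(ok)
    v2 <- v1 + strides[ax]
    keep <- tissue[v2]
    v1 <- v1[keep]; v2 <- v2[keep]
    c1 <- codes[v1]; c2 <- codes[v2]
    allow <- policy$allowed[cbind(c1 + 1L, c2 + 1L)]
    v1 <- v1[allow]; v2 <- v2[allow]
    if (!length(v1)) next
    D1 <- Dmap[codes[v1] + 1L]; D2 <- Dmap[codes[v2] + 1L]
    w <- 2 * D1 * D2 / (D1 + D2) / vol$voxel_size^2
    from <- c(from, node_of[v1], node_of[v2])
    to <- c(to, node_of[v2], node_of[v1])
    wt <- c(wt, w, w)
  }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; wt <- wt[ord]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  structure(list(ptr = as.integer(ptr), idx = as.integer(to - 1L), w = wt,
                 node_voxel = node_voxel, node_code = codes[node_voxel],
                 dims = d, voxel_size = vol$voxel_size, n = n),
            class = "tissue_graph")
}

#' Simulation configuration
#'
#' @param dt Time step in ms.
#' @param duration Maximum simulated time in ms.
#' @param threshold Activation threshold in mV (first upward crossing is
#'   recorded); -20 mV is robust even for reduced-upstroke nodal tissue.
#' @param early_stop_ms Stop once no node has newly activated for this
#'   long after the stimulus ends (0 disables; the full `duration` runs).
#' @param snapshot_stride Record membrane-potential snapshots every this
#'   many steps (0 disables).
#' @param stim_radius_vox Radius, in voxels, of the spherical stimulus
#'   region used by the named protocols.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 300, threshold = -20,
                       early_stop_ms = 30, snapshot_stride = 0,
                       stim_radius_vox = 5) {
  stopifnot(dt > 0, duration >= dt)
  structure(list(dt = dt, duration = duration, threshold = threshold,
                 early_stop_ms = early_stop_ms,
                 snapshot_stride = as.integer(snapshot_stride),
                 stim_radius_vox = stim_radius_vox), class = "sim_config")
}

#' Run a monodomain simulation on a labeled volume
#'
#' Explicit time stepping (forward Euler on the potential, Rush-Larsen on
#' the gates): per step, diffusion over the tissue-graph edges, the
#' minimal-model reaction term, and the stimulus current inside the
#' protocol's region during its window. Records each node's first upward
#' crossing of the activation threshold. Deterministic: identical inputs
#' give identical outputs. Warns when `dt * max(D) * 6 / dx^2 > 0.5`
#' (conservative explicit-diffusion margin) and aborts if the potential
#' diverges beyond 200 mV.
#'
#' @inheritParams build_tissue_graph
#' @param protocol A [stimulus_protocol()].
#' @param config A [sim_config()].
#' @param params Cell parameter vector, see [cell_params()].
#' @return List with `activation_map` (an `activation_map` object: 3D array
#'   of first-activation times in ms, `NA` at non-tissue voxels, `Inf` at
#'   tissue that never activated), `summary` fields `steps_run`,
#'   `n_activated`, `n_nodes`, plus `v_final` and optional snapshots.
#' @export
simulate <- function(vol, regions, policy, protocol, config = sim_config(),
                     params = cell_params()) {
  stopifnot(inherits(config, "sim_config"))
  graph <- build_tissue_graph(vol, regions, policy)
  cfl <- config$dt * max(regions$D) * 6 / vol$voxel_size^2
  if (cfl > 0.5)
    warning(sprintf("explicit diffusion margin dt*max(D)*6/dx^2 = %.3f > 0.5",
                    cfl))
  up <- numeric(256); ap <- numeric(256)
  up[regions$code + 1L] <- regions$upstroke
  ap[regions$code + 1L] <- regions$apd
  node_up <- up[graph$node_code + 1L]
  node_apd <- ap[graph$node_code + 1L]
  stim <- resolve_stimulus(protocol, vol, graph, config, params, regions)
  v0 <- rest_state(params)$v
  n_steps <- ceiling(config$duration / config$dt)
  res <- .simulate_tissue_cpp(graph$ptr, graph$idx, graph$w, node_up,
                              node_apd, params, v0, config$dt, n_steps,
                              stim$nodes - 1L, stim$onset, stim$duration,
                              stim$amplitude, config$threshold,
                              config$early_stop_ms, config$snapshot_stride)
  times <- array(NA_real_, graph$dims)
  act <- res$activation
  act[is.na(act)] <- Inf
  times[graph$node_voxel] <- act
  map <- structure(list(times = times, voxel_size = vol$voxel_size,
                        dims = graph$dims), class = "activation_map")
  out <- list(activation_map = map, steps_run = res$steps_run,
              n_activated = res$n_activated, n_nodes = graph$n,
              v_final = res$v_final, graph = graph)
  if (config$snapshot_stride > 0) {
    out$snapshots <- res$snapshots
    out$snapshot_times <- res$snapshot_times
  }
  out
}

#' Conduction velocity between two probe planes of an activation map
#'
#' CV = plane separation / difference of median activation times over the
#' tissue voxels of each plane, in m/s (1 mm/ms = 1 m/s). Both planes must
#' lie outside 10% boundary margins along the propagation axis and be
#' fully activated.
#'
#' @param map An `activation_map`.
#' @param plane_a,plane_b Voxel indices of the probe planes along `axis`.
#' @param axis Propagation axis (1, 2 or 3).
#' @param voxel_size Optional override of the map's voxel size in mm.
#' @return CV in m/s.
#' @export
measure_cv <- function(map, plane_a, plane_b, axis = 1L, voxel_size = NULL) {
  stopifnot(inherits(map, "activation_map"))
  vs <- if (is.null(voxel_size)) map$voxel_size else voxel_size
  n_ax <- map$dims[axis]
  lo <- 0.1 * n_ax; hi <- 0.9 * n_ax
  if (plane_a <= lo || plane_a >= hi || plane_b <= lo || plane_b >= hi)
    stop("probe planes must exclude 10% boundary margins")
  med_time <- function(k) {
    sl <- switch(axis, map$times[k, , ], map$times[, k, ], map$times[, , k])
    t <- sl[!is.na(sl)]
    if (!length(t) || any(!is.finite(t)))
      stop("unactivated probe plane at index ", k)
    median(t)
  }
  ta <- med_time(plane_a); tb <- med_time(plane_b)
  if (tb == ta) stop("probe planes activated simultaneously")
  abs(plane_b - plane_a) * vs / abs(tb - ta)
}

#' Write an activation map as raw float32 plus JSON sidecar
#'
#' Sentinels in the file: -1 for non-tissue, -2 for tissue that never
#' activated (restored to `NA`/`Inf` on read).
#'
#' @param map An `activation_map`.
#' @param path Output `.raw` path.
#' @return `path`, invisibly.
#' @export
write_activation_map <- function(map, path) {
  stopifnot(inherits(map, "activation_map"))
  x <- as.vector(map$times)
  x[is.na(x)] <- -1
  x[is.infinite(x)] <- -2
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(x, con, size = 4, endian = "little")
  meta <- list(dims = as.integer(map$dims), voxel_size_mm = map$voxel_size,
               dtype = "float32 little-endian, x fastest",
               sentinels = list(non_tissue = -1, never_activated = -2),
               units = "ms")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an activation map written by [write_activation_map()]
#'
#' @param path The `.raw` path.
#' @return An `activation_map`.
#' @export
read_activation_map <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta)) stop("activation map requires its JSON sidecar")
  dims <- as.integer(meta$dims)
  n <- prod(as.numeric(dims))
  x <- readBin(path, "numeric", n = n, size = 4, endian = "little")
  x[x == -2] <- Inf
  x[x == -1] <- NA
  structure(list(times = array(x, dims), voxel_size = meta$voxel_size_mm,
                 dims = dims), class = "activation_map")
}
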
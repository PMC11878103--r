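# Synthetic labeled anatomies. The whole-heart phantom is an idealised
# four-chamber geometry - half-ellipsoid ventricular shells, spherical
# atrial shells, a fibrous valve plane - carrying the full conduction
# system as thin 6-connected structures: a fat-insulated sinus-node
# ellipsoid with superior/inferior exit caps, crista terminalis, pectinate
# muscles, Bachmann's bundle, an atrioventricular node embedded in the
# atrial septum, and a His-Purkinje tree descending the septum and fanning
# out over both endocardial surfaces to discrete ventricular insertion
# points. Only topology and adjacency are claimed to emulate real
# segmentations; shapes are parametric idealisations.

#' Specification of the synthetic heart phantom
#'
#' All lengths in mm. `mi` (myocardial-infarction options) is `NULL` or a
#' list with any of `scar_center` (mm triple), `scar_radius` (mm),
#' `sn_atrophy` and `bundle_thinning` (volume/radius scales in (0, 1]).
#' Identical specs (including `seed`) produce bit-identical phantoms.
#'
#' @param voxel_size Isotropic voxel size in mm.
#' @param extent Bounding box of the grid in mm.
#' @param atrial_wall Atrial wall thickness.
#' @param lv_wall,rv_wall Left/right ventricular free-wall thickness (the
#'   septum inherits roughly the left-ventricular thickness).
#' @param lv_radius,lv_length Outer equatorial/long semi-axes of the LV.
#' @param rv_radius,rv_length Same for the RV.
#' @param atrial_radius Named outer radii `c(ra = , la = )`.
#' @param sn_size Sinus-node ellipsoid semi-axes (x, y, z).
#' @param bundle_radius Paint radius of the His-Purkinje paths.
#' @param purkinje_branches Purkinje branches per ventricle.
#' @param insertion_count Minimum total ventricular insertion points.
#' @param fat_fraction Fraction of the ventricular epicardial circumference
#'   covered by an epicardial fat shell, in `[0, 1]`.
#' @param mi Infarction options, see above.
#' @param seed Integer seed for the (small) stochastic jitter of the
#'   Purkinje branch placement.
#' @param jitter_deg Angular jitter (degrees) applied to branch targets.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size = 1, extent = c(96, 96, 96),
                         atrial_wall = 3, lv_wall = 10, rv_wall = 4,
                         lv_radius = 20, lv_length = 50, rv_radius = 18,
                         rv_length = 42, atrial_radius = c(ra = 14, la = 13),
                         sn_size = c(2, 3, 7), bundle_radius = 0.9,
                         purkinje_branches = 8, insertion_count = 12,
                         fat_fraction = 0.25, mi = NULL, seed = 1,
                         jitter_deg = 8) {
  spec <- list(voxel_size = voxel_size, extent = extent,
               atrial_wall = atrial_wall, lv_wall = lv_wall,
               rv_wall = rv_wall, lv_radius = lv_radius,
               lv_length = lv_length, rv_radius = rv_radius,
               rv_length = rv_length, atrial_radius = atrial_radius,
               sn_size = sn_size, bundle_radius = bundle_radius,
               purkinje_branches = as.integer(purkinje_branches),
               insertion_count = as.integer(insertion_count),
               fat_fraction = fat_fraction, mi = mi,
               seed = as.integer(seed), jitter_deg = jitter_deg)
  lens <- c(voxel_size, extent, atrial_wall, lv_wall, rv_wall, lv_radius,
            lv_length, rv_radius, rv_length, atrial_radius, sn_size,
            bundle_radius)
  stopifnot(all(lens > 0), fat_fraction >= 0, fat_fraction <= 1,
            purkinje_branches >= 1, insertion_count >= 1)
  if (!is.null(mi)) {
    sa <- mi$sn_atrophy %||% 1; bt <- mi$bundle_thinning %||% 1
    stopifnot(sa > 0, sa <= 1, bt > 0, bt <= 1)
  }
  class(spec) <- "phantom_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solid calibration slab
#'
#' A solid box of one region code surrounded by a one-voxel background
#' layer; the substrate for conduction-velocity calibration.
#'
#' @param extent Box extent in mm (length 3).
#' @param voxel_size Voxel size in mm.
#' @param code Region code of the interior (must not be background).
#' @return A [label_volume()].
#' @export
make_slab <- function(extent, voxel_size, code = 4L) {
  stopifnot(length(extent) == 3, all(extent > 0), voxel_size > 0)
  if (any(extent < voxel_size)) stop("extent must be at least one voxel")
  code <- as.integer(code)
  if (code == 0L) stop("background (code 0) cannot be slab tissue")
  d <- as.integer(ceiling(extent / voxel_size)) + 2L
  codes <- array(0L, d)
  codes[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- code
  label_volume(codes, voxel_size)
}

#' Stimulus mask covering one interior face of a slab
#'
#' The mask extends `depth` mm into the tissue from the lowest tissue
#' layer along the axis, so the stimulated region has enough volume to
#' charge against the diffusive load of the neighbouring tissue.
#'
#' @param vol A [label_volume()] (typically from [make_slab()]).
#' @param axis Axis whose lowest tissue layers are stimulated.
#' @param depth Stimulated depth in mm.
#' @return Logical array of the volume's dims.
#' @export
slab_face_mask <- function(vol, axis = 1L, depth = 1.5) {
  tissue <- vol$codes != 0L
  idx <- slice.index(vol$codes, axis)
  first <- min(idx[tissue])
  n_layers <- max(1L, ceiling(depth / vol$voxel_size))
  tissue & idx < first + n_layers
}

# ---- geometry helpers -----------------------------------------------------

ellipsoid_mask <- function(coords, center, semi) {
  a <- (coords$x - center[1])^2 / semi[1]^2
  b <- (coords$y - center[2])^2 / semi[2]^2
  cc <- (coords$z - center[3])^2 / semi[3]^2
  outer(outer(a, b, "+"), cc, "+") <= 1
}

cylinder_mask <- function(coords, center_xy, semi_xy) {
  a <- (coords$x - center_xy[1])^2 / semi_xy[1]^2
  b <- (coords$y - center_xy[2])^2 / semi_xy[2]^2
  n3 <- length(coords$z)
  array(outer(a, b, "+") <= 1, c(length(coords$x), length(coords$y), n3))
}

zslab_mask <- function(coords, z_lo, z_hi) {
  m <- coords$z > z_lo & coords$z <= z_hi
  aperm(array(m, c(length(coords$z), length(coords$x), length(coords$y))),
        c(2, 3, 1))
}

box_mask <- function(coords, lo, hi) {
  a <- coords$x >= lo[1] & coords$x <= hi[1]
  b <- coords$y >= lo[2] & coords$y <= hi[2]
  cc <- coords$z >= lo[3] & coords$z <= hi[3]
  outer(outer(a, b, "&"), cc, "&")
}

vox_of <- function(p, vs, dims) {
  v <- pmin(pmax(as.integer(ceiling(p / vs)), 1L), dims)
  v
}

# 6-connected digital line between two voxels: one axis step at a time,
# largest remaining displacement first (ties: x, then y, then z)
trace_line6 <- function(a, b) {
  path <- list(a)
  cur <- a
  while (!all(cur == b)) {
    delta <- b - cur
    ax <- which.max(abs(delta))
    cur[ax] <- cur[ax] + sign(delta[ax])
    path[[length(path) + 1]] <- cur
  }
  do.call(rbind, path)
}

# paint spheres of `radius` (mm) at continuous centers onto codes where the
# current code is in `over`; radius < voxel size paints single voxels
paint_points <- function(codes, vs, centers, radius, code, over) {
  d <- dim(codes)
  r_vox <- radius / vs
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]
    if (r_vox <= 0.5) {
      v <- vox_of(p, vs, d)
      if (codes[v[1], v[2], v[3]] %in% over) codes[v[1], v[2], v[3]] <- code
      next
    }
    lo <- pmax(vox_of(p - radius, vs, d), 1L)
    hi <- pmin(vox_of(p + radius, vs, d), d)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    sub <- codes[xs, ys, zs, drop = FALSE]
    dist2 <- outer(outer(((xs - 0.5) * vs - p[1])^2,
                         ((ys - 0.5) * vs - p[2])^2, "+"),
                   ((zs - 0.5) * vs - p[3])^2, "+")
    hit <- dist2 <= radius^2 & array(sub %in% over, dim(sub))
    sub[hit] <- code
    codes[xs, ys, zs] <- sub
  }
  codes
}

# spherical linear interpolation between unit vectors
slerp <- function(u0, u1, t) {
  u0 <- u0 / sqrt(sum(u0^2)); u1 <- u1 / sqrt(sum(u1^2))
  om <- acos(pmin(pmax(sum(u0 * u1), -1), 1))
  if (om < 1e-9) return(matrix(u0, length(t), 3, byrow = TRUE))
  s <- sin(om)
  t(vapply(t, function(tt) (sin((1 - tt) * om) * u0 + sin(tt * om) * u1) / s,
           numeric(3)))
}

rot_z <- function(u, deg) {
  th <- deg * pi / 180
  c(cos(th) * u[1] - sin(th) * u[2], sin(th) * u[1] + cos(th) * u[2], u[3])
}

# march from a continuous point along a direction until hitting a voxel of
# `target` code; returns list(hit = voxel index or NULL, last = previous voxel)
ray_to_code <- function(codes, vs, p0, dir, target, max_mm = 60) {
  d <- dim(codes)
  dir <- dir / sqrt(sum(dir^2))
  last <- vox_of(p0, vs, d)
  for (t in seq(0, max_mm, by = vs / 4)) {
    p <- p0 + t * dir
    v <- as.integer(ceiling(p / vs))
    if (any(v < 1) || any(v > d)) return(list(hit = NULL, last = last))
    if (codes[v[1], v[2], v[3]] %in% target) return(list(hit = v, last = last))
    last <- v
  }
  list(hit = NULL, last = last)
}

# ---- the phantom ----------------------------------------------------------

#' Generate the idealized whole-heart phantom
#'
#' See [phantom_spec()] for the geometry parameters and the module
#' description at the top of this file for the construction. The returned
#' volume uses the fixed codes of [default_region_dictionary()]; every
#' required structure is checked for presence and the conduction-system
#' adjacency contract (sinus-node core wrapped by its exits and fat, AVN
#' never touching ventricular myocardium, insertion points touching it) is
#' enforced by construction.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
make_heart_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size
  dims <- as.integer(ceiling(spec$extent / vs))
  coords <- list(x = (seq_len(dims[1]) - 0.5) * vs,
                 y = (seq_len(dims[2]) - 0.5) * vs,
                 z = (seq_len(dims[3]) - 0.5) * vs)
  xc <- spec$extent[1] / 2; yc <- spec$extent[2] / 2
  z_base <- spec$extent[3] - 38
  if (z_base <= spec$lv_length * 0.2)
    stop("extent too small for the ventricular long axis")
  codes <- array(0L, dims)

  # ventricles: two overlapping half-ellipsoid shells; the overlap is the
  # septum; the RV cavity is the crescent outside the LV outer shell
  lv_c <- c(xc + 12, yc, z_base); rv_c <- c(xc - 14, yc, z_base)
  lv_out <- ellipsoid_mask(coords, lv_c,
                           c(spec$lv_radius, spec$lv_radius, spec$lv_length))
  lv_in <- ellipsoid_mask(coords, lv_c,
                          c(spec$lv_radius, spec$lv_radius, spec$lv_length) -
                            spec$lv_wall)
  rv_out <- ellipsoid_mask(coords, rv_c,
                           c(spec$rv_radius, spec$rv_radius, spec$rv_length))
  rv_in <- ellipsoid_mask(coords, rv_c,
                          c(spec$rv_radius, spec$rv_radius, spec$rv_length) -
                            spec$rv_wall)
  zv <- zslab_mask(coords, 0, z_base)
  codes[(lv_out | rv_out) & zv] <- 4L
  codes[lv_in & zv] <- 2L
  codes[rv_in & !lv_out & zv] <- 2L

  # fibrous valve plane: a 2 mm sheet over the full ventricular footprint
  foot <- cylinder_mask(coords, lv_c[1:2], c(spec$lv_radius, spec$lv_radius)) |
    cylinder_mask(coords, rv_c[1:2], c(spec$rv_radius, spec$rv_radius))
  codes[foot & zslab_mask(coords, z_base, z_base + 2)] <- 14L

  # atria: spherical shells resting on the valve plane
  ra_r <- spec$atrial_radius[["ra"]]; la_r <- spec$atrial_radius[["la"]]
  ra_c <- c(xc - 16, yc, z_base + 14); la_c <- c(xc + 16, yc, z_base + 14)
  za <- zslab_mask(coords, z_base + 2.5, spec$extent[3])
  ra_out <- ellipsoid_mask(coords, ra_c, rep(ra_r, 3))
  ra_in <- ellipsoid_mask(coords, ra_c, rep(ra_r - spec$atrial_wall, 3))
  la_out <- ellipsoid_mask(coords, la_c, rep(la_r, 3))
  la_in <- ellipsoid_mask(coords, la_c, rep(la_r - spec$atrial_wall, 3))
  codes[ra_out & za & codes == 0L] <- 3L
  codes[ra_in & za] <- 1L
  codes[la_out & za & codes == 0L] <- 3L
  codes[la_in & za] <- 1L

  # interatrial septal block bridging the two atria above the valve
  sb <- box_mask(coords, c(xc - 8, yc - 6, z_base + 2.5),
                 c(xc + 8, yc + 6, z_base + 10))
  codes[sb & codes %in% c(0L, 1L)] <- 3L

  # AVN embedded in the septal block, directly above the His channel
  avn <- box_mask(coords, c(xc - 2, yc - 2, z_base + 2.5),
                  c(xc + 2, yc + 2, z_base + 5.5))
  codes[avn & codes == 3L] <- 11L

  # His channel: the only conducting passage through the valve plane; its
  # cross-section matches the AVN face so retrograde wavefronts are not
  # blocked by a source-sink mismatch at the junction
  his <- box_mask(coords, c(xc - 2, yc - 2, z_base),
                  c(xc + 2, yc + 2, z_base + 2.5)) &
    zslab_mask(coords, z_base, z_base + 2.5)
  codes[his & codes == 14L] <- 12L

  # His-Purkinje tree (seeded jitter on branch targets)
  thin <- if (!is.null(spec$mi)) spec$mi$bundle_thinning %||% 1 else 1
  b_rad <- spec$bundle_radius * thin
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  codes <- grow_hps(codes, coords, vs, spec, lv_c, rv_c, z_base, b_rad)

  # sinus node in a locally thickened (bump) right-atrial wall, wrapped by
  # fat except for the superior and inferior exit caps
  atrophy <- if (!is.null(spec$mi)) spec$mi$sn_atrophy %||% 1 else 1
  sn_semi <- spec$sn_size * atrophy^(1 / 3)
  u_sn <- c(-0.85, 0, 0.53); u_sn <- u_sn / sqrt(sum(u_sn^2))
  p_sn <- ra_c + (ra_r + 1) * u_sn
  bump <- ellipsoid_mask(coords, p_sn, c(4.5, 4.5, 9))
  codes[bump & za & codes == 0L] <- 3L
  sn <- ellipsoid_mask(coords, p_sn, sn_semi)
  codes[sn & codes == 3L] <- 8L
  codes <- wrap_sn(codes, coords, p_sn, sn_semi, vs)

  # crista terminalis: mid-wall great-circle ridge on the right atrium
  r_mid <- ra_r - spec$atrial_wall / 2
  ct_pts <- t(apply(slerp(c(-0.75, 0.35, 0.45), c(0.05, 0.75, -0.66),
                          seq(0, 1, length.out = 70)), 1,
                    function(u) ra_c + r_mid * u))
  codes <- paint_points(codes, vs, ct_pts, 1.3, 5L, over = 3L)

  # pectinate muscles: a comb (spine plus teeth) beside the crista
  sp_dirs <- slerp(c(-0.55, 0.62, 0.33), c(0.12, 0.82, -0.47),
                   seq(0, 1, length.out = 60))
  sp_pts <- t(apply(sp_dirs, 1, function(u) ra_c + r_mid * u))
  codes <- paint_points(codes, vs, sp_pts, 1.0, 6L, over = 3L)
  for (k in seq(5, 55, by = 12)) {
    u <- sp_dirs[k, ]
    tooth <- t(vapply(seq(0, 24, length.out = 12), function(deg) {
      ra_c + r_mid * rot_z(u, deg)
    }, numeric(3)))
    codes <- paint_points(codes, vs, tooth, 0.9, 6L, over = 3L)
  }

  # Bachmann's bundle: interatrial strand over the atrial roofs
  p_b0 <- ra_c + (ra_r - 1.5) * c(0.25, 0, 0.97) / sqrt(sum(c(0.25, 0, 0.97)^2))
  p_b1 <- la_c + (la_r - 1.5) * c(-0.25, 0, 0.97) / sqrt(sum(c(-0.25, 0, 0.97)^2))
  bb_pts <- t(vapply(seq(0, 1, length.out = 50),
                     function(t) p_b0 + t * (p_b1 - p_b0), numeric(3)))
  codes <- paint_points(codes, vs, bb_pts, 1.2, 7L, over = c(0L, 3L))

  # epicardial fat: shell sector around the ventricles
  if (spec$fat_fraction > 0) {
    shell <- (ellipsoid_mask(coords, lv_c,
                             c(spec$lv_radius, spec$lv_radius,
                               spec$lv_length) + 2) |
              ellipsoid_mask(coords, rv_c,
                             c(spec$rv_radius, spec$rv_radius,
                               spec$rv_length) + 2)) & zv & codes == 0L
    phi <- atan2(slice_rep(coords$y - yc, dims, 2),
                 slice_rep(coords$x - xc, dims, 1))
    sector <- phi >= -pi / 2 & phi < -pi / 2 + spec$fat_fraction * 2 * pi
    codes[shell & sector] <- 15L
  }

  codes <- tidy_regions(codes)
  vol <- label_volume(codes, vs)
  if (!is.null(spec$mi) && !is.null(spec$mi$scar_radius)) {
    center <- spec$mi$scar_center %||% (lv_c + c(spec$lv_radius - spec$lv_wall / 2, 0, -spec$lv_length * 0.45))
    vol <- add_scar(vol, center, spec$mi$scar_radius)
  }
  check_phantom(vol, spec)
  vol
}

slice_rep <- function(v, dims, axis) {
  if (axis == 1) array(v, dims)
  else if (axis == 2) aperm(array(v, dims[c(2, 1, 3)]), c(2, 1, 3))
  else aperm(array(v, dims[c(3, 1, 2)]), c(2, 3, 1))
}

# wrap the SN core in a concentric shell carved out of the atrial wall:
# superior cap -> code 9, inferior cap -> code 10, the lateral remainder ->
# epicardial fat, so the core touches nothing but its exits, fat and
# background (the anatomical insulation the coupling policy relies on)
wrap_sn <- function(codes, coords, p_sn, sn_semi, vs) {
  d <- dim(codes)
  if (!any(codes == 8L))
    stop("phantom too coarse: sinus node (sn_core) vanished")
  shell <- ellipsoid_mask(coords, p_sn, sn_semi + 1.6) & codes == 3L
  zarr <- slice_rep(coords$z, d, 3)
  cap_hi <- zarr >= p_sn[3] + 0.75 * sn_semi[3]
  cap_lo <- zarr <= p_sn[3] - 0.75 * sn_semi[3]
  codes[shell & cap_hi] <- 9L
  codes[shell & cap_lo] <- 10L
  codes[shell & !cap_hi & !cap_lo] <- 15L
  # safety net: any tissue or cavity voxel still face-adjacent to the core
  # becomes fat
  sn_idx <- which(codes == 8L, arr.ind = TRUE)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(6)) {
    nb <- sweep(sn_idx, 2, shifts[s, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    codes[nb[codes[nb] %in% c(1L, 2L, 3L), , drop = FALSE]] <- 15L
  }
  if (!any(codes == 9L) || !any(codes == 10L))
    stop("phantom too coarse: sinus-node exit pathway vanished")
  codes
}

# merge stray fragments created where thin structures carve the walls:
# every non-principal connected component of the listed codes is
# reassigned to the majority code of its face neighbours; insertion
# voxels that lost contact with the His-Purkinje tree revert to
# ventricular myocardium
tidy_regions <- function(codes) {
  d <- dim(codes)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  neighbour_codes <- function(v) {
    nb <- sweep(shifts, 2, v, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    codes[nb[ok, , drop = FALSE]]
  }
  for (cd in c(3L, 5L, 6L, 7L, 9L, 10L, 12L)) {
    mask <- codes == cd
    if (!any(mask)) next
    lab <- .label_components_cpp(as.vector(mask), d)
    n <- attr(lab, "n_components")
    if (n <= 1L) next
    lab <- array(lab, d)
    sizes <- tabulate(lab[lab > 0L], n)
    stray <- which(lab > 0L & lab != which.max(sizes))
    for (v in stray) {
      nc <- neighbour_codes(arrayInd(v, d)[1, ])
      nc <- nc[nc != cd & nc != 0L]
      codes[v] <- if (length(nc)) as.integer(names(which.max(table(nc)))) else 0L
    }
  }
  for (v in which(codes == 13L)) {
    if (!any(neighbour_codes(arrayInd(v, d)[1, ]) == 12L)) codes[v] <- 4L
  }
  codes
}

# trunk down the septum crest, bundle branches to each septal endocardium,
# free-running Purkinje branches across the cavities to insertion points
grow_hps <- function(codes, coords, vs, spec, lv_c, rv_c, z_base, b_rad) {
  d <- dim(codes)
  trunk_top <- vox_of(c(lv_c[1] - 12, rv_c[2], z_base - 0.5), vs, d)
  trunk_bot <- vox_of(c(lv_c[1] - 12, rv_c[2], z_base - 8), vs, d)
  codes <- paint_path(codes, vs, trace_line6(trunk_top, trunk_bot), b_rad,
                      12L, over = c(2L, 4L))
  xc <- lv_c[1] - 12
  for (side in c("lv", "rv")) {
    cc <- if (side == "lv") lv_c else rv_c
    r_out <- if (side == "lv") spec$lv_radius else spec$rv_radius
    len_in <- (if (side == "lv") spec$lv_length else spec$rv_length) -
      (if (side == "lv") spec$lv_wall else spec$rv_wall)
    # bundle-branch entry: on this ventricle's septal endocardium
    to_sept <- sign(cc[1] - xc)
    spine_p <- c(xc + to_sept * 2.5, cc[2], z_base - 11)
    spine_v <- vox_of(spine_p, vs, d)
    codes <- paint_path(codes, vs,
                        trace_line6(trunk_bot, spine_v), b_rad, 12L,
                        over = c(2L, 4L))
    nb <- spec$purkinje_branches
    hfr <- rep(c(0.35, 0.58, 0.78), length.out = nb) +
      stats::runif(nb, -0.04, 0.04)
    th0 <- if (side == "lv") pi else 0  # start angles facing the septum
    for (i in seq_len(nb)) {
      theta <- th0 + 2 * pi * i / nb +
        stats::runif(1, -1, 1) * spec$jitter_deg * pi / 180
      z_t <- z_base - hfr[i] * len_in
      axis_p <- c(cc[1], cc[2], z_t)
      dir <- c(cos(theta), sin(theta), 0)
      hit <- ray_to_code(codes, vs, axis_p, dir, target = 4L,
                         max_mm = r_out + 5)
      if (is.null(hit$hit)) next
      path <- trace_line6(spine_v, hit$last)
      codes <- paint_path(codes, vs, path, b_rad, 12L, over = c(2L, 4L))
      codes[hit$hit[1], hit$hit[2], hit$hit[3]] <- 13L
    }
  }
  codes
}

paint_path <- function(codes, vs, path_vox, radius, code, over) {
  if (radius / vs <= 0.5) {
    for (i in seq_len(nrow(path_vox))) {
      v <- path_vox[i, ]
      if (codes[v[1], v[2], v[3]] %in% over) codes[v[1], v[2], v[3]] <- code
    }
    return(codes)
  }
  centers <- (path_vox - 0.5) * vs
  paint_points(codes, vs, centers, radius, code, over)
}

check_phantom <- function(vol, spec) {
  dict <- vol$dictionary
  required <- 1:15
  present <- unique(as.vector(vol$codes))
  missing <- setdiff(required, present)
  if (length(missing))
    stop("phantom too coarse: missing region(s) ",
         paste(dict[as.character(missing)], collapse = ", "))
  n_ins <- sum(vol$codes == 13L)
  if (n_ins < spec$insertion_count)
    stop("phantom produced only ", n_ins, " insertion points (",
         spec$insertion_count, " requested)")
  invisible(TRUE)
}

#' Add a spherical transmural scar
#'
#' Re-codes ventricular-myocardium voxels (code 4) inside the sphere as
#' scar (code 16); every other code is untouched, so conduction-system
#' structures crossing the scar are preserved.
#'
#' @param vol A [label_volume()].
#' @param center Sphere center in mm.
#' @param radius Sphere radius in mm (> 0).
#' @return The modified [label_volume()].
#' @export
add_scar <- function(vol, center, radius) {
  stopifnot(inherits(vol, "label_volume"))
  if (!is.numeric(radius) || radius <= 0) stop("scar radius must be > 0")
  d <- vol$dims; vs <- vol$voxel_size
  coords <- list(x = (seq_len(d[1]) - 0.5) * vs,
                 y = (seq_len(d[2]) - 0.5) * vs,
                 z = (seq_len(d[3]) - 0.5) * vs)
  sph <- ellipsoid_mask(coords, center, rep(radius, 3))
  hit <- sph & vol$codes == 4L
  if (!any(hit)) stop("scar sphere does not intersect ventricular myocardium")
  vol$codes[hit] <- 16L
  vol
}

#' Connected components of a set of region codes
#'
#' 6-connected (face) components of the voxels carrying any of the given
#' codes.
#'
#' @param vol A [label_volume()].
#' @param codes Region code(s) defining the mask.
#' @return List with `n` (component count) and `labels` (integer array,
#'   0 outside the mask).
#' @export
label_components <- function(vol, codes) {
  mask <- vol$codes %in% as.integer(codes)
  lab <- .label_components_cpp(as.vector(mask), as.integer(vol$dims))
  list(n = attr(lab, "n_components"), labels = array(lab, vol$dims))
}

#' Unordered pairs of 6-adjacent region codes in a volume
#'
#' Enumerates every face-adjacent voxel pair and returns the distinct
#' unordered code pairs, the basis for the anatomical adjacency contract
#' tests.
#'
#' @param vol A [label_volume()].
#' @return Data frame with columns `code_a`, `code_b` (`code_a <= code_b`).
#' @export
region_adjacency <- function(vol) {
  codes <- vol$codes
  d <- vol$dims
  strides <- c(1L, d[1], d[1] * d[2])
  pairs <- NULL
  for (ax in 1:3) {
    idx_ax <- slice.index(codes, ax)
    v1 <- which(idx_ax < d[ax])
    v2 <- v1 + strides[ax]
    a <- codes[v1]; b <- codes[v2]
    keep <- a != b
    pairs <- rbind(pairs, unique(cbind(pmin(a[keep], b[keep]),
                                       pmax(a[keep], b[keep]))))
  }
  pairs <- unique(pairs)
  data.frame(code_a = pairs[, 1], code_b = pairs[, 2])
}

#' Centroid voxel of a region
#'
#' @param vol A [label_volume()].
#' @param code Region code.
#' @return Integer voxel index triple (the region voxel closest to the
#'   region's centroid).
#' @export
region_centroid_voxel <- function(vol, code) {
  idx <- which(vol$codes == as.integer(code), arr.ind = TRUE)
  if (!nrow(idx)) stop("code ", code, " absent from volume")
  ctr <- colMeans(idx)
  d2 <- rowSums(sweep(idx, 2, ctr)^2)
  as.integer(idx[which.min(d2), ])
}
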
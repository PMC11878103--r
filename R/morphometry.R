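# Measurement conventions on labeled volumes: short-axis planes are
# perpendicular to the long (z) axis, long-axis/coronal planes
# perpendicular to the antero-posterior (y) axis. The base plane is the
# first short-axis slice just inferior to the valve annulus; the apex
# plane the last slice toward the apex where both ventricular cavities are
# still visible; mid planes are the discrete midpoints. Wall thickness is
# a ray measurement (length of the first contiguous run of the target code
# along the ray); chamber diameter is the widest in-plane chord of the
# cavity along the axis orthogonal to the septum.

#' Select a standard measurement plane
#'
#' @param vol A [label_volume()].
#' @param orientation `"short_axis"` (z-normal) or `"long_axis"`
#'   (y-normal).
#' @param tag `"base"`, `"mid"` or `"apex"` for short-axis;
#'   `"anterior"`, `"mid"` or `"posterior"` for long-axis.
#' @return A `measurement_plane` list: `orientation`, `tag`, `axis`
#'   (plane normal, 3 = z, 2 = y) and `index` (slice index).
#' @export
select_plane <- function(vol, orientation = c("short_axis", "long_axis"),
                         tag) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(vol, "label_volume"))
  codes <- vol$codes
  if (!any(codes == 2L)) stop("ventricular cavity region absent")
  if (orientation == "short_axis") {
    tag <- match.arg(tag, c("base", "mid", "apex"))
    if (!any(codes == 14L)) stop("valve region absent")
    valve_z <- which(apply(codes == 14L, 3, any))
    base <- min(valve_z) - 1L          # one slice inferior to the annulus
    two_cav <- which(vapply(seq_len(vol$dims[3]), function(z) {
      slice_components(codes[, , z] == 2L) >= 2L
    }, logical(1)))
    if (!length(two_cav)) stop("no slice shows both ventricular cavities")
    apex <- min(two_cav)
    idx <- switch(tag, base = base, apex = apex,
                  mid = (base + apex) %/% 2L)
    axis <- 3L
  } else {
    tag <- match.arg(tag, c("anterior", "mid", "posterior"))
    two_cav <- which(vapply(seq_len(vol$dims[2]), function(y) {
      slice_components(codes[, y, ] == 2L) >= 2L
    }, logical(1)))
    if (!length(two_cav))
      stop("no coronal slice shows both ventricles separated by the septum")
    anterior <- min(two_cav); posterior <- max(two_cav)
    idx <- switch(tag, anterior = anterior, posterior = posterior,
                  mid = (anterior + posterior) %/% 2L)
    axis <- 2L
  }
  if (idx < 1L || idx > vol$dims[axis])
    stop("selected plane falls outside the grid")
  structure(list(orientation = orientation, tag = tag, axis = axis,
                 index = as.integer(idx)), class = "measurement_plane")
}

slice_components <- function(mask2d) {
  if (!any(mask2d)) return(0L)
  lab <- .label_components_cpp(as.vector(mask2d),
                               c(dim(mask2d), 1L))
  attr(lab, "n_components")
}

plane_slice <- function(vol, plane) {
  if (plane$axis == 3L) vol$codes[, , plane$index]
  else vol$codes[, plane$index, ]
}

#' Wall thickness along a ray within a measurement plane
#'
#' Marches the ray through the plane at sub-voxel resolution and returns
#' the length of the first contiguous run of the target code: the distance
#' along the ray between entering and leaving the region, so an oblique
#' ray through a slab of thickness `t` at angle `theta` to the normal
#' measures `t / cos(theta)`.
#'
#' @param vol A [label_volume()].
#' @param plane A plane from [select_plane()].
#' @param ray_origin In-plane origin in mm (length 2: the two in-plane
#'   axes in grid order, x/y for short-axis, x/z for long-axis planes).
#' @param ray_direction In-plane direction (length 2, need not be unit).
#' @param code Region code to measure.
#' @return Thickness in mm.
#' @export
wall_thickness <- function(vol, plane, ray_origin, ray_direction, code) {
  stopifnot(inherits(plane, "measurement_plane"),
            length(ray_origin) == 2, length(ray_direction) == 2)
  sl <- plane_slice(vol, plane)
  vs <- vol$voxel_size
  dir <- ray_direction / sqrt(sum(ray_direction^2))
  step <- vs / 8
  max_t <- sqrt(sum((dim(sl) * vs)^2))
  ts <- seq(0, max_t, by = step)
  px <- ray_origin[1] + ts * dir[1]
  py <- ray_origin[2] + ts * dir[2]
  ix <- ceiling(px / vs); iy <- ceiling(py / vs)
  ok <- ix >= 1 & ix <= dim(sl)[1] & iy >= 1 & iy <= dim(sl)[2]
  inside <- logical(length(ts))
  inside[ok] <- sl[cbind(ix[ok], iy[ok])] == as.integer(code)
  if (!any(inside)) stop("ray does not intersect region code ", code)
  t_in <- ts[which(inside)[1]]
  after <- which(!inside & ts > t_in)
  t_out <- if (length(after)) ts[after[1]] else max(ts[inside]) + step
  t_out - t_in
}

#' Three-ray wall-thickness session for the ventricular walls
#'
#' Reproducible stand-in for manual ray placement: in the given plane,
#' three parallel rays are cast along the axis orthogonal to the septum at
#' 25%, 50% and 75% of the ventricles' in-plane extent; each ray reports
#' the right ventricular free wall (first myocardial run), the septum (the
#' run between the two cavities) and the left ventricular free wall (last
#' run).
#'
#' @param vol A [label_volume()].
#' @param plane A short-axis plane from [select_plane()].
#' @return Data frame with columns `fraction`, `rv_free_wall`, `septum`,
#'   `lv_free_wall` (mm; `NA` where a ray misses a structure).
#' @export
wall_thickness_session <- function(vol, plane) {
  sl <- plane_slice(vol, plane)
  vs <- vol$voxel_size
  vent <- which(sl == 4L | sl == 2L, arr.ind = TRUE)
  if (!nrow(vent)) stop("plane contains no ventricular tissue")
  y_rng <- range(vent[, 2])
  out <- lapply(c(0.25, 0.5, 0.75), function(f) {
    y <- round(y_rng[1] + f * diff(y_rng))
    row <- sl[, y]
    r <- rle(row)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    cav <- which(r$values == 2L)
    myo <- which(r$values == 4L)
    rv <- sep <- lv <- NA_real_
    if (length(cav) >= 2 && length(myo)) {
      before <- myo[myo < cav[1]]
      if (length(before)) rv <- r$lengths[max(before)] * vs
      between <- myo[myo > cav[1] & myo < cav[length(cav)]]
      if (length(between)) sep <- sum(r$lengths[between]) * vs
      after <- myo[myo > cav[length(cav)]]
      if (length(after)) lv <- r$lengths[min(after)] * vs
    }
    data.frame(fraction = f, rv_free_wall = rv, septum = sep,
               lv_free_wall = lv)
  })
  do.call(rbind, out)
}

#' Chamber diameter: widest in-plane chord of a cavity
#'
#' The chord is measured along the first in-plane axis (orthogonal to the
#' septum, which runs antero-posteriorly in the phantom): the longest
#' contiguous run of the cavity code over all in-plane scan lines, in mm.
#'
#' @param vol A [label_volume()].
#' @param plane A plane from [select_plane()].
#' @param cavity_code Cavity region code (1 atrial, 2 ventricular).
#' @return Diameter in mm.
#' @export
chamber_diameter <- function(vol, plane, cavity_code) {
  sl <- plane_slice(vol, plane)
  if (!any(sl == as.integer(cavity_code)))
    stop("cavity code ", cavity_code, " absent from plane")
  best <- 0L
  for (j in seq_len(dim(sl)[2])) {
    r <- rle(sl[, j] == as.integer(cavity_code))
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  best * vol$voxel_size
}

#' Volume of a labeled structure
#'
#' Voxel count times voxel volume, in cm^3; zero when the code is absent.
#'
#' @param vol A [label_volume()].
#' @param code Region code.
#' @return Volume in cm^3.
#' @export
structure_volume <- function(vol, code) {
  sum(vol$codes == as.integer(code)) * vol$voxel_size^3 / 1000
}

#' Morphometry table for a volume
#'
#' Convenience driver emitting one CSV-ready table: per-structure volumes
#' and, when the volume has valve and ventricular codes, wall-thickness
#' sessions and chamber diameters on the standard planes.
#'
#' @param vol A [label_volume()].
#' @param id Identifier written into the table.
#' @return Data frame with columns `id`, `plane`, `structure`,
#'   `measurement`, `value`, `unit`.
#' @export
morphometry_table <- function(vol, id = "phantom") {
  rows <- list()
  for (code in sort(unique(as.vector(vol$codes)))) {
    if (code == 0L) next
    rows[[length(rows) + 1]] <- data.frame(
      id = id, plane = NA_character_,
      structure = unname(vol$dictionary[as.character(code)]),
      measurement = "volume", value = structure_volume(vol, code),
      unit = "cm3")
  }
  has_planes <- any(vol$codes == 14L) && any(vol$codes == 2L)
  if (has_planes) {
    for (tag in c("base", "mid", "apex")) {
      pl <- select_plane(vol, "short_axis", tag)
      ws <- wall_thickness_session(vol, pl)
      for (w in c("rv_free_wall", "septum", "lv_free_wall")) {
        rows[[length(rows) + 1]] <- data.frame(
          id = id, plane = tag, structure = w, measurement = "thickness",
          value = mean(ws[[w]], na.rm = TRUE), unit = "mm")
      }
      if (tag != "apex") {
        rows[[length(rows) + 1]] <- data.frame(
          id = id, plane = tag, structure = "ventricular_cavity",
          measurement = "diameter",
          value = chamber_diameter(vol, pl, 2L), unit = "mm")
      }
    }
  }
  do.call(rbind, rows)
}
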
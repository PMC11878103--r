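# Labeled voxel volumes: an integer array of 8-bit anatomical region codes
# with an isotropic voxel size in mm and a code -> region-name dictionary.
# On disk a volume is either a multi-page 8-bit grayscale TIFF (one page per
# z slice) or a raw uint8 stream (x fastest-varying, then y, then z), in
# both cases accompanied by a JSON sidecar holding dims, voxel size and the
# dictionary.

#' Default anatomical region dictionary
#'
#' Fixed 8-bit code assignments used throughout the package. Code 0 is
#' reserved for background/non-tissue.
#'
#' @return Named character vector mapping code (as name) to region name.
#' @export
default_region_dictionary <- function() {
  c(`0` = "background", `1` = "atrial_cavity", `2` = "ventricular_cavity",
    `3` = "atrial_myocardium", `4` = "ventricular_myocardium",
    `5` = "crista_terminalis", `6` = "pectinate_muscle",
    `7` = "bachmanns_bundle", `8` = "sn_core", `9` = "sn_superior_exit",
    `10` = "sn_inferior_exit", `11` = "avn", `12` = "his_purkinje",
    `13` = "hps_insertion", `14` = "valve", `15` = "epicardial_fat",
    `16` = "scar")
}

#' Construct a labeled voxel volume
#'
#' @param codes 3D integer array of region codes in `[0, 255]`; dimension
#'   order is (x, y, z).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param dictionary Named character vector mapping codes to region names;
#'   every code present in `codes` must appear.
#' @return A `label_volume` object (list with `codes`, `voxel_size`,
#'   `dims`, `dictionary`).
#' @export
label_volume <- function(codes, voxel_size,
                         dictionary = default_region_dictionary()) {
  stopifnot(is.array(codes), length(dim(codes)) == 3, all(dim(codes) >= 1),
            is.numeric(voxel_size), length(voxel_size) == 1, voxel_size > 0)
  if (!is.integer(codes)) {
    storage.mode(codes) <- "integer"
  }
  rng <- range(codes)
  if (rng[1] < 0 || rng[2] > 255)
    stop("region codes must fit in 8 bits (0..255)")
  present <- sort(unique(as.vector(codes)))
  missing <- setdiff(present, as.integer(names(dictionary)))
  if (length(missing))
    stop("codes present in grid but absent from dictionary: ",
         paste(missing, collapse = ", "))
  structure(list(codes = codes, voxel_size = voxel_size,
                 dims = dim(codes), dictionary = dictionary),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(x$dims, collapse = " x "), "voxels at",
      x$voxel_size, "mm\n")
  tab <- table(x$codes)
  nm <- x$dictionary[names(tab)]
  cat(sprintf("  %-22s code %3s: %d voxels\n", nm, names(tab), tab), sep = "")
  invisible(x)
}

#' Number of nodes of a structured grid
#'
#' @param dims Integer vector of grid dimensions (NX, NY, NZ), or a
#'   `label_volume`.
#' @return Total node count as a double (exact for grids up to 2^53).
#' @export
grid_node_count <- function(dims) {
  if (inherits(dims, "label_volume")) dims <- dims$dims
  stopifnot(length(dims) == 3, all(dims >= 1))
  prod(as.numeric(dims))
}

sidecar_path <- function(path) paste0(sub("\\.(tiff?|raw)$", "", path), ".json")

write_sidecar <- function(vol, path) {
  meta <- list(dims = as.integer(vol$dims), voxel_size_mm = vol$voxel_size,
               dictionary = as.list(vol$dictionary),
               axis_order = "x fastest, then y, then z; 0-based indices from the grid corner")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a labeled volume to disk
#'
#' `format = "tiff"` writes a multi-page 8-bit grayscale TIFF (one page per
#' z slice, rows = y); `format = "raw"` writes a raw uint8 stream with x
#' fastest-varying. Both write a JSON sidecar (dims, voxel size,
#' dictionary) next to the file, and both round-trip bit-exactly through
#' [read_label_volume()].
#'
#' @param vol A [label_volume()].
#' @param path Output file path (`.tif`/`.tiff` or `.raw`).
#' @param format `"tiff"` or `"raw"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  format <- match.arg(format, c("tiff", "raw"))
  if (format == "tiff") {
    pages <- lapply(seq_len(vol$dims[3]), function(z) {
      t(vol$codes[, , z]) / 255  # rows = y, cols = x
    })
    ok <- tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                          compression = "none")
    if (!ok) stop("failed to write TIFF to ", path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(as.vector(vol$codes)), con)
  }
  write_sidecar(vol, path)
  invisible(path)
}

#' Read a labeled volume from disk
#'
#' Accepts the multi-page TIFF or raw uint8 layouts written by
#' [write_label_volume()]. Grid values are restored bit-exactly. Metadata
#' come from the JSON sidecar when present; for a sidecar-less TIFF the
#' dims are taken from the stack and the dictionary defaults to
#' [default_region_dictionary()]; a sidecar-less raw file is an error.
#'
#' @param path File to read.
#' @param voxel_size Voxel size in mm; overrides the sidecar value when
#'   given.
#' @param unknown_codes What to do with grid codes absent from the
#'   dictionary: `"register"` adds them as `"unknown_<code>"`, `"error"`
#'   aborts.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, voxel_size = NULL,
                              unknown_codes = c("register", "error")) {
  unknown_codes <- match.arg(unknown_codes)
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read_sidecar(path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits) && bits != 8L)
      stop("expected an 8-bit TIFF stack, got ", bits, " bits per sample")
    if (max(vapply(pages, max, 0L)) > 255L || length(dim(pages[[1]])) != 2)
      stop("expected an 8-bit grayscale TIFF stack")
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    codes <- array(0L, c(nx, ny, nz))
    for (z in seq_len(nz)) codes[, , z] <- t(pages[[z]])
  } else {
    if (is.null(meta)) stop("raw volume requires a JSON sidecar: ",
                            sidecar_path(path))
    dims <- as.integer(meta$dims)
    n <- prod(as.numeric(dims))
    bytes <- readBin(path, "raw", n = n + 1)
    if (length(bytes) != n)
      stop("raw file size (", length(bytes), " bytes) does not match sidecar dims (",
           n, " voxels)")
    codes <- array(as.integer(bytes), dims)
  }
  if (!is.null(meta)) {
    if (!all(dim(codes) == as.integer(meta$dims)))
      stop("stored dims disagree with sidecar metadata")
    dict <- unlist(meta$dictionary)
    if (is.null(voxel_size)) voxel_size <- meta$voxel_size_mm
  } else {
    dict <- default_region_dictionary()
  }
  if (is.null(voxel_size))
    stop("voxel_size not given and no sidecar metadata found")
  present <- sort(unique(as.vector(codes)))
  unknown <- setdiff(present, as.integer(names(dict)))
  if (length(unknown)) {
    if (unknown_codes == "error")
      stop("grid contains codes absent from the dictionary: ",
           paste(unknown, collapse = ", "))
    extra <- paste0("unknown_", unknown)
    names(extra) <- unknown
    dict <- c(dict, extra)
  }
  label_volume(codes, voxel_size, dict)
}

#' Downsample a label volume by an integer factor
#'
#' Each output voxel takes the majority code of its `factor`^3 source
#' block; ties are broken by a fixed priority order that protects thin
#' conduction structures (conduction-system codes first, then the fast
#' atrial pathways, valve, fat, myocardium/scar, cavities, background).
#' The output voxel size is `factor` times the input size and the output
#' label set is a subset of the input's.
#'
#' @param vol A [label_volume()].
#' @param factor Positive integer downsampling factor.
#' @return The downsampled [label_volume()].
#' @export
downsample_labels <- function(vol, factor) {
  stopifnot(inherits(vol, "label_volume"))
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- vol$dims
  nd <- as.integer(ceiling(d / factor))
  # block index of every voxel (1-based, x fastest among blocks)
  bx <- (seq_len(d[1]) - 1L) %/% factor
  by <- (seq_len(d[2]) - 1L) %/% factor
  bz <- (seq_len(d[3]) - 1L) %/% factor
  block <- outer(outer(bx, by * nd[1], "+"), bz * (nd[1] * nd[2]), "+") + 1
  codes <- as.vector(vol$codes)
  lev <- sort(unique(codes))
  counts <- table(factor(block, levels = seq_len(prod(nd))),
                  factor(codes, levels = lev))
  counts <- matrix(as.integer(counts), nrow = prod(nd),
                   dimnames = list(NULL, as.character(lev)))
  # order candidate columns by ascending priority so that ties.method =
  # "last" picks the highest-priority code among tied maxima
  ord <- order(match(lev, rev(label_priority())))
  counts <- counts[, ord, drop = FALSE]
  lev_ord <- lev[ord]
  win <- lev_ord[max.col(counts, ties.method = "last")]
  label_volume(array(win, nd), vol$voxel_size * factor, vol$dictionary)
}

#' Label priority used for downsampling tie-breaks
#'
#' Highest priority first: insertion points and His-Purkinje, AVN, sinus
#' node and its exits, then crista terminalis / pectinate muscles /
#' Bachmann's bundle, valve, fat, myocardium and scar, cavities,
#' background. Codes not listed rank below all listed ones.
#'
#' @return Integer vector of codes in decreasing priority.
#' @export
label_priority <- function() {
  c(13L, 12L, 11L, 8L, 9L, 10L, 5L, 6L, 7L, 14L, 15L, 3L, 4L, 16L, 1L, 2L, 0L)
}

#' Export selected regions as a binary STL surface
#'
#' Writes the blocky voxel surface of the selected codes: two triangles per
#' voxel face adjacent to an unselected voxel or the grid boundary, with
#' outward normals and counter-clockwise winding, in mm coordinates
#' (voxel `(i, j, k)`, 1-based, spans `[(i-1), i] * voxel_size` along x,
#' etc.). The mesh is watertight for any solid voxel set. Output is
#' little-endian binary STL (80-byte header, uint32 triangle count).
#'
#' @param vol A [label_volume()].
#' @param selected_codes Region codes to include (non-empty).
#' @param path Output `.stl` path.
#' @return Number of triangles written, invisibly.
#' @export
export_stl <- function(vol, selected_codes, path) {
  stopifnot(inherits(vol, "label_volume"), length(selected_codes) >= 1)
  sel <- array(vol$codes %in% as.integer(selected_codes), vol$dims)
  if (!any(sel)) stop("no voxel carries a selected code")
  d <- vol$dims; vs <- vol$voxel_size
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sel
  inner <- list(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
  core <- pad[inner[[1]], inner[[2]], inner[[3]], drop = FALSE]
  # unit-cube corner offsets of the two triangles per face, wound CCW seen
  # from outside; 6 rows per direction: v1 v2 v3 of triangle A then B
  face_tris <- list(
    `-x` = rbind(c(0,0,0), c(0,0,1), c(0,1,1),  c(0,0,0), c(0,1,1), c(0,1,0)),
    `+x` = rbind(c(1,0,0), c(1,1,0), c(1,1,1),  c(1,0,0), c(1,1,1), c(1,0,1)),
    `-y` = rbind(c(0,0,0), c(1,0,0), c(1,0,1),  c(0,0,0), c(1,0,1), c(0,0,1)),
    `+y` = rbind(c(0,1,0), c(0,1,1), c(1,1,1),  c(0,1,0), c(1,1,1), c(1,1,0)),
    `-z` = rbind(c(0,0,0), c(0,1,0), c(1,1,0),  c(0,0,0), c(1,1,0), c(1,0,0)),
    `+z` = rbind(c(0,0,1), c(1,0,1), c(1,1,1),  c(0,0,1), c(1,1,1), c(0,1,1)))
  shifts <- rbind(`-x` = c(-1,0,0), `+x` = c(1,0,0), `-y` = c(0,-1,0),
                  `+y` = c(0,1,0), `-z` = c(0,0,-1), `+z` = c(0,0,1))
  records <- list()  # per triangle: normal (3), v1 (3), v2 (3), v3 (3)
  for (f in rownames(shifts)) {
    s <- shifts[f, ]
    nb <- pad[inner[[1]] + s[1], inner[[2]] + s[2], inner[[3]] + s[3],
              drop = FALSE]
    exposed <- which(core & !nb, arr.ind = TRUE)
    if (!nrow(exposed)) next
    corner <- exposed - 1  # lower voxel corner, voxel units
    tris <- face_tris[[f]]
    for (tri in 0:1) {
      rec <- matrix(NA_real_, nrow(exposed), 12)
      rec[, 1:3] <- matrix(s, nrow(exposed), 3, byrow = TRUE)
      for (vtx in 1:3)
        rec[, (3 * vtx + 1):(3 * vtx + 3)] <-
          (corner + matrix(tris[tri * 3 + vtx, ], nrow(exposed), 3,
                           byrow = TRUE)) * vs
      records[[length(records) + 1]] <- rec
    }
  }
  rec <- do.call(rbind, records)
  n_tri <- nrow(rec)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "ccsim voxel surface"))[1:80]
  writeBin(header, con)
  writeBin(n_tri, con, size = 4, endian = "little")
  raw_f <- writeBin(as.vector(t(rec)), raw(), size = 4, endian = "little")
  raw_f <- matrix(raw_f, nrow = 48)  # 12 float32 per triangle
  attr_bytes <- matrix(as.raw(0), nrow = 2, ncol = n_tri)
  writeBin(as.vector(rbind(raw_f, attr_bytes)), con)
  invisible(n_tri)
}
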